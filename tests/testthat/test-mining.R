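# Genome-mining post-processing: tblout/BLAST parsing, filtering, best-model
# resolution, copy counting, species dedup, summaries.

toy_manifest <- tibble::tibble(
  model_id = c("AHL_synth_1", "AHL_synth_2", "LuxR_reg_1"),
  family = c("synthase", "synthase", "receptor")
)

tblout_line <- function(target, model, evalue, score) {
  sprintf("%-12s - %-12s - %9.3g %6.1f 0.0 %9.3g %6.1f 0.0 1.0 1 1 1 1 1 1 1 -",
          target, model, evalue, score, evalue, score)
}

test_that("tblout parsing handles rows, comments and bad input", {
  f <- withr::local_tempfile(fileext = ".tblout")
  writeLines(c(
    "# comment",
    tblout_line("p1", "AHL_synth_1", 1e-20, 80),
    tblout_line("p2", "LuxR_reg_1", 1e-8, 40),
    tblout_line("p3", "AHL_synth_2", 2e-3, 12)
  ), f)
  hits <- read_tblout(f, toy_manifest)
  expect_identical(nrow(hits), 3L)
  expect_identical(hits$family, c("synthase", "receptor", "synthase"))
  expect_equal(hits$evalue, c(1e-20, 1e-8, 2e-3))
  expect_identical(unique(hits$assembly_id),
                   sub("\\.tblout$", "", basename(f)))

  only_comments <- withr::local_tempfile(fileext = ".tblout")
  writeLines(c("# a", "# b"), only_comments)
  expect_identical(nrow(read_tblout(only_comments, toy_manifest)), 0L)

  unknown <- withr::local_tempfile(fileext = ".tblout")
  writeLines(tblout_line("p1", "Mystery_1", 1e-20, 80), unknown)
  expect_error(read_tblout(unknown, toy_manifest), "Mystery_1")

  short <- withr::local_tempfile(fileext = ".tblout")
  writeLines("p1 - AHL_synth_1 1e-20", short)
  expect_error(read_tblout(short, toy_manifest), "line")
})

test_that("significance filtering is strictly below the threshold", {
  hits <- tibble::tibble(
    target_id = c("a", "b", "c", "d"),
    evalue = c(9.7e-5, 1e-6, 1e-5, 9.99e-6)
  )
  kept <- filter_significant(hits)
  expect_identical(kept$target_id, c("b", "d"))  # 9.7e-5 and exactly 1e-5 out
  expect_error(filter_significant(hits, threshold = 0), "positive")
})

test_that("best-model resolution keeps the lowest E-value per target", {
  hits <- tibble::tibble(
    target_id = c("t1", "t1", "t2"),
    assembly_id = "A1",
    model_id = c("A", "B", "A"),
    evalue = c(1e-10, 1e-8, 1e-7),
    bit_score = c(50, 40, 30)
  )
  res <- assign_best_model(hits)
  expect_identical(nrow(res), 2L)
  expect_identical(res$model_id[res$target_id == "t1"], "A")
  # single-hit targets are untouched
  single <- hits[3, ]
  expect_equal(assign_best_model(single), single)
})

test_that("best-model resolution matches a brute-force oracle on random tables", {
  withr::with_seed(101, {
    hits <- tibble::tibble(
      target_id = sample(sprintf("t%02d", 1:60), 200, replace = TRUE),
      assembly_id = sample(c("A1", "A2"), 200, replace = TRUE),
      model_id = sample(LETTERS[1:4], 200, replace = TRUE),
      evalue = 10^runif(200, -30, -6),
      bit_score = round(runif(200, 10, 100), 1)
    )
  })
  res <- assign_best_model(hits)
  expect_identical(nrow(res),
                   nrow(unique(hits[, c("assembly_id", "target_id")])))
  oracle <- do.call(rbind, lapply(
    split(hits, paste(hits$assembly_id, hits$target_id)),
    function(g) {
      g <- g[order(g$evalue, -g$bit_score, g$model_id), ]
      g[1, ]
    }
  ))
  oracle <- oracle[order(oracle$assembly_id, oracle$target_id), ]
  rownames(oracle) <- NULL
  expect_equal(as.data.frame(res), as.data.frame(oracle))
  # idempotence
  expect_equal(assign_best_model(res), res)
})

test_that("copy counting covers the assembly universe including zero-hit genomes", {
  hits <- tibble::tibble(
    target_id = c(sprintf("i%d", 1:5), sprintf("r%d", 1:120)),
    assembly_id = "A1",
    species_name = "Streptomyces x",
    model_id = "m",
    family = c(rep("synthase", 5), rep("receptor", 120)),
    evalue = 1e-10, bit_score = 50
  )
  universe <- tibble::tibble(
    assembly_id = c("A1", "A2"),
    species_name = c("Streptomyces x", "Streptomyces y")
  )
  counts <- count_copies(hits, universe)
  expect_identical(nrow(counts), 2L)
  a1 <- counts[counts$assembly_id == "A1", ]
  expect_identical(c(a1$luxI_count, a1$luxR_count, a1$product),
                   c(5L, 120L, 600L))
  a2 <- counts[counts$assembly_id == "A2", ]
  expect_identical(c(a2$luxI_count, a2$luxR_count, a2$product), c(0L, 0L, 0L))
})

test_that("species dedup keeps the assembly maximising the copy product", {
  recs <- tibble::tibble(
    assembly_id = c("A1", "A2"),
    species_name = "Streptomyces x",
    luxI_count = c(5L, 4L), luxR_count = c(100L, 150L),
    product = c(500L, 600L)
  )
  kept <- dedup_species(recs)
  expect_identical(kept$assembly_id, "A2")  # 4 x 150 = 600 beats 500
  single <- recs[1, ]
  expect_equal(dedup_species(single), single)
})

test_that("species dedup matches a brute-force argmax oracle on random cohorts", {
  withr::with_seed(77, {
    for (rep in 1:25) {
      recs <- random_records(n_species = sample(3:12, 1))
      got <- dedup_species(recs)
      want <- dedup_oracle(recs)
      expect_equal(as.data.frame(got), as.data.frame(want))
      expect_identical(anyDuplicated(got$species_name), 0L)
      # every dropped record has product <= the kept record's
      for (sp in unique(recs$species_name)) {
        expect_true(all(recs$product[recs$species_name == sp] <=
                          got$product[got$species_name == sp]))
      }
    }
  })
})

test_that("strain suffixes collapse to the binomial name", {
  expect_identical(
    collapse_strain(c("Streptomyces lividans TK24",
                      "Streptomyces coelicolor A3(2)",
                      "Streptomyces griseus")),
    c("Streptomyces lividans", "Streptomyces coelicolor",
      "Streptomyces griseus")
  )
  recs <- tibble::tibble(
    assembly_id = c("A1", "A2"),
    species_name = c("Streptomyces lividans TK24", "Streptomyces lividans 1326"),
    luxI_count = c(5L, 6L), luxR_count = c(100L, 150L),
    product = c(500L, 900L)
  )
  kept <- dedup_species(recs, strain_regex = "^(\\S+\\s+\\S+).*$")
  expect_identical(nrow(kept), 1L)
  expect_identical(kept$assembly_id, "A2")
})

test_that("copy-number summaries compute the printed statistics", {
  recs <- tibble::tibble(
    assembly_id = sprintf("A%d", 1:5),
    species_name = sprintf("s%d", 1:5),
    luxI_count = c(4L, 5L, 5L, 6L, 7L),
    luxR_count = c(10L, 10L, 10L, 10L, 10L),
    product = c(40L, 50L, 50L, 60L, 70L)
  )
  s <- summarize_copy_numbers(recs)
  syn <- s[s$family == "synthase", ]
  expect_equal(syn$median, 5)
  expect_equal(syn$mean, 5.4)
  expect_identical(c(syn$min, syn$max), c(4L, 7L))
  rec <- s[s$family == "receptor", ]
  expect_true(rec$median == rec$mean && rec$mean == rec$min &&
                rec$min == rec$max)
  # even count: midpoint median
  s4 <- summarize_copy_numbers(recs[1:4, ])
  expect_equal(s4$median[s4$family == "synthase"], 5)
  expect_error(summarize_copy_numbers(recs[0, ]), "no records")
})

test_that("pipeline order invariance: dedup commutes with pre-counted tables", {
  withr::with_seed(55, {
    for (rep in 1:10) {
      recs <- random_records(n_species = 8)
      direct <- dedup_species(recs)
      # shuffling rows does not change the winner
      shuffled <- recs[sample(nrow(recs)), ]
      expect_equal(as.data.frame(dedup_species(shuffled)),
                   as.data.frame(direct))
    }
  })
})

test_that("BLAST filtering counts significant hits and unique species", {
  hits <- tibble::tibble(
    query_id = "LuxR",
    subject_id = sprintf("W%02d", 1:10),
    species_name = c("s1", "s1", "s2", "s3", "s4", "s4", "s5", "s6", "s7", "s8"),
    percent_identity = seq(30, 57, by = 3),
    query_coverage = seq(12, 48, by = 4),
    evalue = c(1e-30, 1e-12, 5e-3, 9e-3, 1e-4, 2e-3, 0.5, 0.011, 0.2, 1)
  )
  res <- filter_blast(hits)
  expect_identical(res$n_hits, 6L)
  expect_identical(res$n_unique_species, 4L)
  expect_equal(res$identity_range,
               range(hits$percent_identity[hits$evalue < 0.01]))
  expect_equal(res$coverage_range,
               range(hits$query_coverage[hits$evalue < 0.01]))

  none <- filter_blast(hits[hits$evalue >= 0.01, ])
  expect_identical(none$n_hits, 0L)
  expect_identical(none$n_unique_species, 0L)
  expect_null(none$identity_range)
})

test_that("filter, resolve and count are idempotent", {
  dir <- withr::local_tempdir()
  co <- make_cohort(cohort_spec(n_species = 15, seed = 8), dir)
  models <- read_model_manifest(co$model_manifest)
  asm <- read_assembly_manifest(co$assembly_manifest)
  hits <- read_tblout_dir(co$tblout_dir, models, asm)
  f1 <- filter_significant(hits)
  expect_equal(filter_significant(f1), f1)
  r1 <- assign_best_model(f1)
  expect_equal(assign_best_model(r1), r1)
  c1 <- count_copies(r1, asm)
  d1 <- dedup_species(c1)
  expect_equal(dedup_species(d1), d1)
})
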