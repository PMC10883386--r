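# Genome-mining post-processing: HMMER3 tblout and BLAST tabular hit tables,
# significance filtering, best-model resolution, per-assembly copy counting,
# species deduplication and distribution summaries.

#' Read a model manifest
#'
#' Two-column TSV mapping each profile-HMM model id to the protein family it
#' represents: `"synthase"` (LuxI homologs) or `"receptor"` (LuxR homologs).
#'
#' @param path TSV with columns `model_id`, `family`.
#' @return A tibble.
#' @export
read_model_manifest <- function(path) {
  man <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
  if (!all(c("model_id", "family") %in% names(man))) {
    stop("model manifest needs columns model_id, family", call. = FALSE)
  }
  bad <- setdiff(unique(man$family), c("synthase", "receptor"))
  if (length(bad)) {
    stop(sprintf("unknown family value(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  man
}

#' Read an assembly manifest
#'
#' TSV mapping each genome assembly id to its species name; this defines the
#' assembly universe, so genomes with zero surviving hits still appear in the
#' copy-number table.
#'
#' @param path TSV with columns `assembly_id`, `species_name`.
#' @return A tibble.
#' @export
read_assembly_manifest <- function(path) {
  man <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
  if (!all(c("assembly_id", "species_name") %in% names(man))) {
    stop("assembly manifest needs columns assembly_id, species_name", call. = FALSE)
  }
  man
}

#' Read an HMMER3 `--tblout` per-target table
#'
#' Parses the whitespace-delimited 18-column layout ('#' lines are comments;
#' the free-text description after column 18 is ignored). The model family is
#' assigned from the model manifest, and the assembly id is taken from the
#' file name (`<assembly_id>.tblout`), the convention under which per-genome
#' searches are archived.
#'
#' @param path A `.tblout` file.
#' @param model_manifest Tibble from [read_model_manifest()].
#' @param assembly_manifest Optional tibble from [read_assembly_manifest()]
#'   used to attach `species_name`.
#' @return Tibble of hits: `target_id`, `assembly_id`, `species_name`,
#'   `model_id`, `family`, `evalue` (full-sequence), `bit_score`.
#' @export
read_tblout <- function(path, model_manifest, assembly_manifest = NULL) {
  lines <- readLines(path, warn = FALSE)
  data <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  assembly_id <- sub("\\.tblout$", "", basename(path))
  if (length(data) == 0L) {
    hits <- tibble::tibble(
      target_id = character(0), assembly_id = character(0),
      model_id = character(0), family = character(0),
      evalue = numeric(0), bit_score = numeric(0)
    )
  } else {
    fields <- strsplit(trimws(data), "\\s+")
    short <- which(lengths(fields) < 18L)
    if (length(short)) {
      stop(sprintf("malformed tblout row at line %d of %s",
                   which(!grepl("^#", lines) & nzchar(trimws(lines)))[short[1]], path),
           call. = FALSE)
    }
    hits <- tibble::tibble(
      target_id = vapply(fields, `[[`, character(1), 1L),
      assembly_id = assembly_id,
      model_id = vapply(fields, `[[`, character(1), 3L),
      evalue = as.numeric(vapply(fields, `[[`, character(1), 5L)),
      bit_score = as.numeric(vapply(fields, `[[`, character(1), 6L))
    )
    unknown <- setdiff(unique(hits$model_id), model_manifest$model_id)
    if (length(unknown)) {
      stop(sprintf(
        "model id(s) %s not in manifest (known: %s)",
        paste(unknown, collapse = ", "),
        paste(model_manifest$model_id, collapse = ", ")
      ), call. = FALSE)
    }
    hits <- dplyr::left_join(hits, model_manifest, by = "model_id")
    hits <- dplyr::select(hits, "target_id", "assembly_id", "model_id",
                          "family", "evalue", "bit_score")
  }
  if (!is.null(assembly_manifest)) {
    hits <- dplyr::left_join(hits, assembly_manifest, by = "assembly_id")
  } else {
    hits$species_name <- NA_character_
  }
  dplyr::select(hits, "target_id", "assembly_id", "species_name",
                "model_id", "family", "evalue", "bit_score")
}

#' Read all tblout files in a directory
#'
#' @param dir Directory containing `<assembly_id>.tblout` files.
#' @inheritParams read_tblout
#' @return Row-bound hit tibble across assemblies.
#' @export
read_tblout_dir <- function(dir, model_manifest, assembly_manifest = NULL) {
  files <- sort(list.files(dir, pattern = "\\.tblout$", full.names = TRUE))
  if (length(files) == 0L) {
    stop(sprintf("no .tblout files found in %s", dir), call. = FALSE)
  }
  purrr::map_dfr(files, read_tblout, model_manifest = model_manifest,
                 assembly_manifest = assembly_manifest)
}

#' Filter hits for significance
#'
#' Keeps exactly the hits with E-value strictly below the threshold. The
#' strict inequality matters at the margin: a borderline hit at 9.7e-5
#' against a 1e-5 threshold is excluded, as is one at exactly 1e-5.
#'
#' @param hits Hit tibble with an `evalue` column.
#' @param threshold Significance threshold (default 1e-5).
#' @return The significant subset.
#' @export
filter_significant <- function(hits, threshold = 1e-5) {
  if (threshold <= 0) stop("`threshold` must be positive", call. = FALSE)
  hits[hits$evalue < threshold, , drop = FALSE]
}

#' Resolve targets recognised by multiple models
#'
#' When one protein is hit by several profile HMMs, only the hit with the
#' lowest E-value is kept; ties break by higher bit score, then by
#' lexicographically smallest model id, so the outcome is deterministic.
#'
#' @param hits Filtered hit tibble.
#' @return At most one row per (`assembly_id`, `target_id`).
#' @export
assign_best_model <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  hits |>
    dplyr::group_by(.data$assembly_id, .data$target_id) |>
    dplyr::arrange(.data$evalue, dplyr::desc(.data$bit_score), .data$model_id,
                   .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$assembly_id, .data$target_id)
}

#' Count homolog copies per assembly
#'
#' Per assembly, the synthase (LuxI) and receptor (LuxR) copy numbers are the
#' counts of distinct surviving target proteins per family, plus their
#' product (the quantity the species-deduplication rule maximises).
#' Assemblies present in the universe but absent from the hits report zeros.
#'
#' @param hits Filtered, model-resolved hit tibble.
#' @param assembly_manifest Tibble from [read_assembly_manifest()] defining
#'   the assembly universe; `NULL` restricts to assemblies with hits.
#' @return Tibble: `assembly_id`, `species_name`, `luxI_count`, `luxR_count`,
#'   `product`.
#' @export
count_copies <- function(hits, assembly_manifest = NULL) {
  counted <- hits |>
    dplyr::distinct(.data$assembly_id, .data$target_id, .data$family) |>
    dplyr::count(.data$assembly_id, .data$family) |>
    tidyr::pivot_wider(names_from = "family", values_from = "n", values_fill = 0L)
  for (col in c("synthase", "receptor")) {
    if (!col %in% names(counted)) counted[[col]] <- 0L
  }
  if (is.null(assembly_manifest)) {
    assembly_manifest <- dplyr::distinct(hits, .data$assembly_id, .data$species_name)
  }
  out <- assembly_manifest |>
    dplyr::left_join(counted, by = "assembly_id") |>
    dplyr::mutate(
      luxI_count = as.integer(dplyr::coalesce(.data$synthase, 0L)),
      luxR_count = as.integer(dplyr::coalesce(.data$receptor, 0L)),
      product = .data$luxI_count * .data$luxR_count
    ) |>
    dplyr::select("assembly_id", "species_name", "luxI_count", "luxR_count",
                  "product") |>
    dplyr::arrange(.data$assembly_id)
  out
}

#' Collapse strain-level names to a binomial species name
#'
#' @param species_name Character vector of names possibly carrying strain
#'   suffixes.
#' @param strain_regex Pattern removed from the end of each name; the default
#'   keeps the first two whitespace-separated words (genus + epithet).
#' @return Character vector of collapsed names.
#' @export
collapse_strain <- function(species_name,
                            strain_regex = "^(\\S+\\s+\\S+).*$") {
  sub(strain_regex, "\\1", species_name)
}

#' Deduplicate species across assemblies
#'
#' Where several assemblies share a species name, the assembly with the
#' highest LuxI-count times LuxR-count product is kept. Ties break by higher
#' receptor count, then by lexicographically smallest assembly id.
#'
#' @param records Copy-number tibble from [count_copies()].
#' @param strain_regex Optional regex passed to [collapse_strain()] applied
#'   to `species_name` before grouping; `NULL` groups on the raw names.
#' @return One record per species name.
#' @export
dedup_species <- function(records, strain_regex = NULL) {
  if (!is.null(strain_regex)) {
    records$species_name <- collapse_strain(records$species_name, strain_regex)
  }
  records |>
    dplyr::group_by(.data$species_name) |>
    dplyr::arrange(dplyr::desc(.data$product), dplyr::desc(.data$luxR_count),
                   .data$assembly_id, .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$species_name)
}

#' Summarise copy-number distributions per family
#'
#' Distribution statistics over deduplicated species: median (midpoint
#' average for even counts), mean, min, max, the number of species with at
#' least one copy and with exactly one copy.
#'
#' @param records Deduplicated copy-number tibble.
#' @return Tibble with one row per family (`synthase`, `receptor`) and
#'   columns `family`, `n_species`, `median`, `mean`, `min`, `max`,
#'   `n_with_at_least_one`, `n_with_exactly_one`.
#' @export
summarize_copy_numbers <- function(records) {
  if (nrow(records) == 0L) stop("no records to summarise", call. = FALSE)
  one <- function(family, counts) {
    tibble::tibble(
      family = family,
      n_species = length(counts),
      median = stats::median(counts),
      mean = mean(counts),
      min = min(counts),
      max = max(counts),
      n_with_at_least_one = sum(counts >= 1L),
      n_with_exactly_one = sum(counts == 1L)
    )
  }
  dplyr::bind_rows(
    one("synthase", records$luxI_count),
    one("receptor", records$luxR_count)
  )
}

#' Read a BLAST tabular (`-outfmt 6`) hit table
#'
#' Standard 12 columns (qseqid sseqid pident length mismatch gapopen qstart
#' qend sstart send evalue bitscore); a 13th column, when present, is read as
#' percent query coverage (`qcovs`). Species names come from a sidecar TSV
#' mapping subject ids to species.
#'
#' @param path Tab-separated BLAST output.
#' @param species_map Optional tibble/TSV path with columns `subject_id`,
#'   `species_name`.
#' @return Tibble: `query_id`, `subject_id`, `species_name`,
#'   `percent_identity`, `query_coverage`, `evalue`, `bit_score`.
#' @export
read_blast <- function(path, species_map = NULL) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 12L) stop("expected >= 12 tab-separated columns", call. = FALSE)
  hits <- tibble::tibble(
    query_id = as.character(tab[[1]]),
    subject_id = as.character(tab[[2]]),
    percent_identity = as.numeric(tab[[3]]),
    query_coverage = if (ncol(tab) >= 13L) as.numeric(tab[[13]]) else NA_real_,
    evalue = as.numeric(tab[[11]]),
    bit_score = as.numeric(tab[[12]])
  )
  if (is.character(species_map)) {
    species_map <- readr::read_tsv(species_map,
                                   col_types = readr::cols(.default = "c"))
  }
  if (!is.null(species_map)) {
    hits <- dplyr::left_join(hits, species_map, by = "subject_id")
  } else {
    hits$species_name <- NA_character_
  }
  dplyr::select(hits, "query_id", "subject_id", "species_name",
                "percent_identity", "query_coverage", "evalue", "bit_score")
}

#' Filter a BLAST table and summarise the significant hits
#'
#' Strict E-value filter, a unique-species count over `species_name`, and the
#' identity/coverage ranges of the surviving hits.
#'
#' @param hits Tibble from [read_blast()].
#' @param evalue_threshold Significance threshold (default 0.01, strict `<`).
#' @return List: `hits` (significant subset), `n_hits`, `n_unique_species`,
#'   `identity_range`, `coverage_range` (each `c(min, max)` or `NULL` when
#'   empty).
#' @export
filter_blast <- function(hits, evalue_threshold = 0.01) {
  if (evalue_threshold <= 0) stop("`evalue_threshold` must be positive", call. = FALSE)
  sig <- hits[hits$evalue < evalue_threshold, , drop = FALSE]
  rng <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0L) NULL else range(v)
  }
  list(
    hits = sig,
    n_hits = nrow(sig),
    n_unique_species = length(unique(stats::na.omit(sig$species_name))),
    identity_range = rng(sig$percent_identity),
    coverage_range = rng(sig$query_coverage)
  )
}
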