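# Screening chain: characteristic-ion screen, confirmation, EIC, peaks,
# control comparison, pipeline, clustering.

test_that("the m/z 102 screen keeps exactly the qualifying spectra", {
  run <- make_run(list(
    make_spectrum(256, 1, c(74, 102.0), c(5, 100), scan = 1L),
    make_spectrum(230, 2, c(104.1, 80), c(100, 50), scan = 2L),
    make_spectrum(300, 3, c(102.3, 60), c(100, 40), scan = 3L),
    make_spectrum(310, 4, c(102.0, 60), c(0.5, 100), scan = 4L)  # below gate
  ))
  idx <- precursor_ion_screen(run, tol = 0.5, min_rel_intensity = 0.01)
  expect_identical(idx, c(1L, 3L))
  expect_error(precursor_ion_screen(run, tol = 0), "positive")
  expect_error(precursor_ion_screen(run, min_rel_intensity = 1), "0, 1")
})

test_that("confirmation requires a second daughter from {56, 74, 84}", {
  with74 <- make_spectrum(256, 1, c(74, 102), c(5, 100))
  only102 <- make_spectrum(256, 1, 102, 100)
  res <- confirm_daughters(with74)
  expect_true(res$confirmed)
  expect_equal(res$observed, 74)
  res <- confirm_daughters(only102)
  expect_false(res$confirmed)
  expect_length(res$observed, 0)
})

test_that("screening is monotone in tolerance, anti-monotone in intensity gate", {
  set.seed(42)
  spectra <- lapply(1:30, function(i) {
    make_spectrum(150 + i * 7, i * 0.2,
                  mz = runif(6, 50, 140), intensity = runif(6, 1, 100),
                  scan = i)
  })
  run <- make_run(spectra)
  tols <- c(0.1, 0.5, 1, 5, 20)
  screened <- lapply(tols, function(tol) precursor_ion_screen(run, tol = tol))
  for (i in seq_len(length(tols) - 1)) {
    expect_true(all(screened[[i]] %in% screened[[i + 1]]))
  }
  gates <- c(0, 0.05, 0.2, 0.8)
  screened <- lapply(gates, function(g) {
    precursor_ion_screen(run, tol = 5, min_rel_intensity = g)
  })
  for (i in seq_len(length(gates) - 1)) {
    expect_true(all(screened[[i + 1]] %in% screened[[i]]))
  }
})

test_that("EICs keep the scan axis and partition the TIC", {
  one <- make_run(list(make_spectrum(256, 12.0, c(102, 74), c(80, 20))))
  eic <- extract_eic(one, 256)
  expect_identical(nrow(eic), 1L)
  expect_equal(eic$rt, 12.0)
  expect_equal(eic$intensity, 100)

  set.seed(7)
  run <- make_run(lapply(1:40, function(i) {
    make_spectrum(sample(c(228, 256, 298), 1), i * 0.1,
                  mz = runif(4, 50, 200), intensity = runif(4, 10, 1000),
                  scan = i)
  }))
  tic <- total_ion_chromatogram(run)
  eics <- lapply(c(228, 256, 298), function(m) extract_eic(run, m, tol = 0.5))
  for (e in eics) expect_identical(nrow(e), n_spectra(run))
  summed <- Reduce(`+`, lapply(eics, function(e) e$intensity))
  expect_equal(summed, tic$intensity)
  expect_true(all(vapply(eics, function(e) all(e$intensity >= 0), logical(1))))
})

test_that("peak detection recovers planted elution profiles", {
  grid <- seq(0, 40, by = 0.05)
  flat <- structure(tibble::tibble(rt = grid, intensity = 0),
                    class = c("eic", "tbl_df", "tbl", "data.frame"))
  expect_identical(nrow(detect_peaks(flat)), 0L)

  run1 <- make_run(c(gaussian_compound_spectra(256, 14.02, 0.1, 5e4, grid),
                     baseline_spectra(grid)))
  pk <- detect_peaks(extract_eic(run1, 256))
  expect_identical(nrow(pk), 1L)
  # apex within half a scan interval of the planted RT
  expect_lt(abs(pk$apex_rt - 14.02), 0.025 + 1e-9)
  expect_true(pk$left_rt < pk$apex_rt && pk$apex_rt <= pk$right_rt)
  expect_gt(pk$height, 0)

  run2 <- make_run(c(
    gaussian_compound_spectra(256, 10, 0.1, 5e4, grid),
    gaussian_compound_spectra(256, 20, 0.1, 3e4, grid),
    baseline_spectra(grid)
  ))
  pk2 <- detect_peaks(extract_eic(run2, 256))
  expect_identical(nrow(pk2), 2L)
  expect_equal(sort(pk2$apex_rt), c(10, 20), tolerance = 0.03)
})

test_that("control comparison removes medium-background peaks", {
  grid <- seq(0, 40, by = 0.05)
  sample_run <- make_run(c(gaussian_compound_spectra(256, 14, 0.1, 5e4, grid),
                           baseline_spectra(grid)))
  silent_control <- make_run(list(make_spectrum(120.5, 1, 60, 5)),
                             label = "control")
  pk <- detect_peaks(extract_eic(sample_run, 256))
  kept <- control_compare(pk, silent_control, 256)
  expect_identical(nrow(kept), 1L)
  expect_gt(kept$fold_change, 1000)

  mirrored <- make_run(gaussian_compound_spectra(256, 14, 0.1, 5e4, grid),
                       label = "control")
  kept <- control_compare(pk, mirrored, 256, fold_threshold = 3)
  expect_identical(nrow(kept), 0L)

  expect_error(control_compare(pk, NULL, 256), "control")
  not_control <- make_run(list(make_spectrum(120.5, 1, 60, 5)), label = "sample")
  expect_error(control_compare(pk, not_control, 256), "control")
})

test_that("the pipeline recovers planted AHLs and rejects a mirrored sample", {
  dir <- withr::local_tempdir()
  spec <- noiseless_spec(
    dplyr::bind_rows(planted_ahl(8, rt = 10), planted_ahl(10, rt = 14),
                     planted_ahl(12, oxo = TRUE, rt = 18)),
    seed = 21
  )
  res <- make_ms_run(spec, dir)
  sample <- read_ms_run(res$sample_mgf, label = "sample")
  control <- read_ms_run(res$control_mgf, label = "control")
  lib <- build_library()
  feats <- screen_pipeline(sample, control, lib)
  expect_identical(nrow(feats), 3L)
  expect_identical(feats$mz, c(228L, 256L, 298L))  # 14n + 116 (+14 for 3-oxo)
  expect_identical(feats$annotation, c("C8-HSL", "C10-HSL", "Oxo-C12-HSL"))
  counts <- attr(feats, "stage_counts")
  expect_true(counts$confirmed <= counts$screened)
  expect_true(counts$screened <= counts$scanned)

  # a sample identical to the control yields nothing
  mirrored <- read_ms_run(res$control_mgf, label = "sample")
  expect_identical(nrow(screen_pipeline(mirrored, control, lib)), 0L)
})

test_that("confirmed spectra are a subset of screened spectra for any setting", {
  dir <- withr::local_tempdir()
  res <- make_ms_run(ms_run_spec(
    planted = planted_ahl(10, rt = 12), noise_sdlog = 0.4,
    chem_noise_lambda = 5, seed = 9
  ), dir)
  run <- read_ms_run(res$sample_mgf, label = "sample")
  for (tol in c(0.2, 0.5, 1)) {
    for (gate in c(0, 0.05)) {
      screened <- precursor_ion_screen(run, tol = tol, min_rel_intensity = gate)
      confirmed <- screened[vapply(screened, function(i) {
        confirm_daughters(run$spectra[[i]], tol = tol,
                          min_rel_intensity = gate)$confirmed
      }, logical(1))]
      expect_true(all(confirmed %in% screened))
      expect_true(all(screened %in% seq_len(n_spectra(run))))
    }
  }
})

test_that("features from the printed mass list annotate as predicted", {
  lib <- build_library()
  masses <- c(130, 142, 176, 230, 256, 262)
  ann <- lapply(masses, annotate_mz, library = lib, tolerance = 0.5)
  names(ann) <- masses
  expect_identical(ann[["256"]]$name[1], "C10-HSL")
})

test_that("k-means clustering of features is sane and reproducible", {
  feats <- tibble::tibble(
    species = "s", mz = c(130, 135, 140, 320, 330, 340),
    rt = c(2, 2.5, 3, 25, 26, 27)
  )
  one <- cluster_features(feats, k = 1, seed = 4)
  expect_true(all(one$features$cluster == 1L))
  expect_equal(unname(one$centers[1, ]), c(0, 0), tolerance = 1e-12)

  two <- cluster_features(feats, k = 2, seed = 4)
  expect_identical(length(unique(two$features$cluster[1:3])), 1L)
  expect_identical(length(unique(two$features$cluster[4:6])), 1L)
  expect_false(two$features$cluster[1] == two$features$cluster[4])

  again <- cluster_features(feats, k = 2, seed = 4)
  expect_identical(two$features$cluster, again$features$cluster)

  expect_error(cluster_features(feats[1:3, ], k = 4), "at least")
})
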