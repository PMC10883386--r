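# Product-ion screening chain: characteristic-daughter screen at m/z 102,
# confirmation at 56/74/84, EIC extraction, peak detection, medium-control
# comparison, annotation and feature clustering.

#' Screen a run for the AHL-characteristic daughter ion
#'
#' Emulates a precursor-ion scan: a spectrum is retained when it contains at
#' least one fragment within `tol` of `characteristic_mz` (m/z 102, the
#' protonated homoserine-lactone ring) whose intensity reaches
#' `min_rel_intensity` of the spectrum's base peak.
#'
#' @param run An [ms_run()].
#' @param characteristic_mz Target daughter m/z; 102 for AHLs.
#' @param tol Fragment tolerance in m/z units (> 0).
#' @param min_rel_intensity Minimum fragment intensity as a fraction of the
#'   base peak, in `[0, 1)`.
#' @return Integer vector of spectrum indices into `run$spectra` that pass.
#' @export
precursor_ion_screen <- function(run, characteristic_mz = 102, tol = 0.5,
                                 min_rel_intensity = 0.01) {
  stopifnot(inherits(run, "ms_run"))
  if (tol <= 0) stop("`tol` must be positive", call. = FALSE)
  if (min_rel_intensity < 0 || min_rel_intensity >= 1) {
    stop("`min_rel_intensity` must be in [0, 1)", call. = FALSE)
  }
  hits <- vapply(run$spectra, function(sp) {
    .has_daughter(sp, characteristic_mz, tol, min_rel_intensity)
  }, logical(1))
  which(hits)
}

.has_daughter <- function(sp, target, tol, min_rel) {
  if (length(sp$mz) == 0L) return(FALSE)
  gate <- min_rel * max(sp$intensity)
  any(abs(sp$mz - target) <= tol & sp$intensity >= gate)
}

#' Confirm a candidate spectrum by secondary daughter ions
#'
#' A spectrum passing the m/z 102 screen counts as a confirmed AHL candidate
#' only if at least one further daughter at m/z 56, 74 or 84 is present under
#' the same tolerance and relative-intensity rule.
#'
#' @param spectrum One spectrum from an [ms_run()] (normally one that already
#'   passed [precursor_ion_screen()]).
#' @param confirm_set Daughter masses accepted as confirmation.
#' @inheritParams precursor_ion_screen
#' @return List with `confirmed` (logical) and `observed` (the numeric subset
#'   of `confirm_set` seen).
#' @export
confirm_daughters <- function(spectrum, confirm_set = c(56, 74, 84), tol = 0.5,
                              min_rel_intensity = 0.01) {
  seen <- confirm_set[vapply(confirm_set, function(m) {
    .has_daughter(spectrum, m, tol, min_rel_intensity)
  }, logical(1))]
  list(confirmed = length(seen) > 0L, observed = seen)
}

#' Extracted ion chromatogram for one precursor mass
#'
#' For every scan of the run the EIC carries one point: the summed fragment
#' intensity of the scan when its precursor lies within `tol` of `target_mz`,
#' zero otherwise. Zero points are kept so that the retention-time axis equals
#' the run's scan times and per-mass EICs over disjoint bins sum to the TIC.
#'
#' @param run An [ms_run()].
#' @param target_mz Precursor m/z to extract.
#' @param tol Precursor tolerance (> 0).
#' @return A tibble of class `eic` with columns `rt`, `intensity`, and
#'   attributes `target_mz` and `tol`.
#' @export
extract_eic <- function(run, target_mz, tol = 0.5) {
  stopifnot(inherits(run, "ms_run"))
  if (tol <= 0) stop("`tol` must be positive", call. = FALSE)
  pts <- purrr::map_dfr(run$spectra, function(sp) {
    hit <- abs(sp$precursor_mz - target_mz) <= tol
    tibble::tibble(rt = sp$rt, intensity = if (hit) sum(sp$intensity) else 0)
  })
  attr(pts, "target_mz") <- target_mz
  attr(pts, "tol") <- tol
  class(pts) <- c("eic", class(pts))
  pts
}

#' Total ion chromatogram of a run
#' @param run An [ms_run()].
#' @return A tibble with `rt` and `intensity` (summed fragment intensity per scan).
#' @export
total_ion_chromatogram <- function(run) {
  purrr::map_dfr(run$spectra, function(sp) {
    tibble::tibble(rt = sp$rt, intensity = sum(sp$intensity))
  })
}

#' Detect chromatographic peaks in an EIC
#'
#' A peak is a local maximum whose height reaches `min_height` and
#' `min_snr` times the noise floor, taken as the median absolute deviation of
#' the EIC intensities (a zero MAD, e.g. in noiseless traces, disables the
#' SNR gate). An apex must also be the maximum within `window` minutes on
#' either side: the EIC keeps a zero point for every scan of the run, so
#' scans devoted to other precursors interleave zeros into an elution
#' profile, and without the window rule a shoulder sample flanked by such
#' zeros would count as a separate peak. Peak bounds extend to the nearest
#' valley on each side.
#'
#' @param eic An [extract_eic()] result.
#' @param min_height Minimum apex intensity (arbitrary units).
#' @param min_snr Minimum apex signal-to-noise ratio over the MAD floor.
#' @param window Minimum apex spacing in minutes; of two maxima closer than
#'   this, only the higher survives.
#' @return Tibble with one row per peak: `apex_rt`, `height`, `area`
#'   (trapezoidal), `left_rt`, `right_rt`.
#' @export
detect_peaks <- function(eic, min_height = 1000, min_snr = 3, window = 0.2) {
  if (nrow(eic) == 0L) stop("empty EIC", call. = FALSE)
  y <- eic$intensity
  x <- eic$rt
  n <- length(y)
  empty <- tibble::tibble(
    apex_rt = numeric(0), height = numeric(0), area = numeric(0),
    left_rt = numeric(0), right_rt = numeric(0)
  )
  if (all(y <= 0)) return(empty)
  noise <- stats::mad(y)
  floor_h <- max(min_height, if (noise > 0) min_snr * noise else 0)
  yl <- c(-Inf, y[-n])
  yr <- c(y[-1], -Inf)
  apex <- which(y >= yl & y >= yr & y >= floor_h & y > 0)
  # collapse plateaus: keep the first index of each run of equal-height apices
  if (length(apex) > 1L) {
    keep <- c(TRUE, !(diff(apex) == 1L & y[apex[-length(apex)]] == y[apex[-1]]))
    apex <- apex[keep]
  }
  # window rule: an apex must dominate its rt neighbourhood
  apex <- apex[vapply(apex, function(i) {
    y[i] >= max(y[abs(x - x[i]) <= window])
  }, logical(1))]
  # of any pair closer than `window`, keep the higher (ties: the earlier)
  if (length(apex) > 1L) {
    keep <- rep(TRUE, length(apex))
    for (a in seq_along(apex)) {
      if (!keep[a]) next
      for (b in seq_along(apex)) {
        if (a == b || !keep[b]) next
        if (abs(x[apex[a]] - x[apex[b]]) <= window &&
            (y[apex[b]] > y[apex[a]] ||
             (y[apex[b]] == y[apex[a]] && b < a))) {
          keep[a] <- FALSE
          break
        }
      }
    }
    apex <- apex[keep]
  }
  if (length(apex) == 0L) return(empty)
  purrr::map_dfr(apex, function(i) {
    l <- i
    while (l > 1L && y[l - 1L] <= y[l]) l <- l - 1L
    r <- i
    while (r < n && y[r + 1L] <= y[r]) r <- r + 1L
    seg <- l:r
    area <- if (length(seg) > 1L) {
      sum(diff(x[seg]) * (utils::head(y[seg], -1) + utils::tail(y[seg], -1)) / 2)
    } else {
      0
    }
    tibble::tibble(apex_rt = x[i], height = y[i], area = area,
                   left_rt = x[l], right_rt = x[r])
  })
}

#' Compare sample peaks against the medium control
#'
#' Medium components and instrument background elute in both the culture
#' extract and the uninoculated control. A sample peak is retained only when
#' its apex height is at least `fold_threshold` times the maximum control EIC
#' intensity for the same target mass within `rt_window` of the apex (the
#' control maximum is floored at `epsilon` so a silent control yields a
#' finite fold-change).
#'
#' @param sample_peaks Peak table from [detect_peaks()].
#' @param control_run The control [ms_run()] (must carry label `"control"`).
#' @param target_mz Precursor mass the peaks belong to.
#' @param tol Precursor tolerance for the control EIC.
#' @param rt_window Half-width of the retention-time window (minutes).
#' @param fold_threshold Minimum sample/control height ratio.
#' @param epsilon Floor for the control maximum (intensity units).
#' @return `sample_peaks` rows that survive, with a `fold_change` column.
#' @export
control_compare <- function(sample_peaks, control_run, target_mz, tol = 0.5,
                            rt_window = 0.5, fold_threshold = 3, epsilon = 1) {
  if (missing(control_run) || is.null(control_run)) {
    stop("a medium control run is required for background comparison", call. = FALSE)
  }
  stopifnot(inherits(control_run, "ms_run"))
  if (!identical(control_run$label, "control")) {
    stop("`control_run` must be labelled 'control'", call. = FALSE)
  }
  ctrl <- extract_eic(control_run, target_mz, tol)
  fold <- vapply(seq_len(nrow(sample_peaks)), function(i) {
    apex <- sample_peaks$apex_rt[i]
    near <- abs(ctrl$rt - apex) <= rt_window
    ref <- max(c(ctrl$intensity[near], 0))
    sample_peaks$height[i] / max(ref, epsilon)
  }, numeric(1))
  out <- sample_peaks
  out$fold_change <- fold
  out[fold >= fold_threshold, , drop = FALSE]
}

#' Full AHL screening pipeline
#'
#' Runs the complete chain on one sample/control pair: characteristic-ion
#' screen at m/z 102, confirmation by m/z 56/74/84, per-mass EIC extraction
#' and peak detection, control comparison, and annotation against the
#' theoretical mass library. Masses are collapsed to nominal integers, as a
#' unit-resolution triple quadrupole reports them.
#'
#' @param sample,control Sample and control [ms_run()]s.
#' @param library An `ahl_library` from [build_library()]; `NULL` skips
#'   annotation.
#' @param config Parameter list from [ahl_config()].
#' @param species Sample label recorded in the feature table.
#' @return A tibble of candidate features: `species`, `mz` (nominal integer),
#'   `rt` (apex, minutes), `daughters` (";"-joined confirmation masses),
#'   `fold_change`, `annotation` (best library name or `NA`), `mass_error`.
#'   The `stage_counts` attribute carries per-stage totals (scanned, screened,
#'   confirmed, masses, peaks, retained).
#' @export
screen_pipeline <- function(sample, control, library = build_library(),
                            config = ahl_config(), species = "sample") {
  stopifnot(inherits(sample, "ms_run"))
  counts <- list(scanned = n_spectra(sample))
  screened <- precursor_ion_screen(
    sample, characteristic_mz = config$characteristic_mz,
    tol = config$fragment_tol, min_rel_intensity = config$min_rel_intensity
  )
  counts$screened <- length(screened)
  conf <- lapply(screened, function(i) {
    confirm_daughters(sample$spectra[[i]], confirm_set = config$confirm_set,
                      tol = config$fragment_tol,
                      min_rel_intensity = config$min_rel_intensity)
  })
  ok <- vapply(conf, `[[`, logical(1), "confirmed")
  confirmed_idx <- screened[ok]
  observed <- conf[ok]
  counts$confirmed <- length(confirmed_idx)

  feature_rows <- tibble::tibble(
    species = character(0), mz = integer(0), rt = numeric(0),
    daughters = character(0), fold_change = numeric(0),
    annotation = character(0), mass_error = numeric(0)
  )
  masses <- sort(unique(vapply(
    confirmed_idx, function(i) as.integer(round(sample$spectra[[i]]$precursor_mz)),
    integer(1)
  )))
  counts$masses <- length(masses)
  counts$peaks <- 0L
  for (m in masses) {
    eic <- extract_eic(sample, m, tol = config$precursor_tol)
    peaks <- detect_peaks(eic, min_height = config$min_peak_height,
                          min_snr = config$min_snr,
                          window = config$peak_window)
    counts$peaks <- counts$peaks + nrow(peaks)
    if (nrow(peaks) == 0L) next
    kept <- control_compare(
      peaks, control, target_mz = m, tol = config$precursor_tol,
      rt_window = config$rt_window, fold_threshold = config$fold_threshold,
      epsilon = config$epsilon
    )
    if (nrow(kept) == 0L) next
    contrib <- vapply(confirmed_idx, function(i) {
      abs(sample$spectra[[i]]$precursor_mz - m) <= config$precursor_tol
    }, logical(1))
    daughters <- sort(unique(unlist(lapply(observed[contrib], `[[`, "observed"))))
    ann_name <- NA_character_
    ann_err <- NA_real_
    if (!is.null(library)) {
      ann <- annotate_mz(m, library, tolerance = config$annotation_tol,
                         mode = "nominal")
      if (nrow(ann) > 0L) {
        ann_name <- ann$name[1]
        ann_err <- ann$mass_error[1]
      }
    }
    feature_rows <- dplyr::bind_rows(feature_rows, tibble::tibble(
      species = species, mz = as.integer(m), rt = kept$apex_rt,
      daughters = paste(daughters, collapse = ";"),
      fold_change = kept$fold_change,
      annotation = ann_name, mass_error = ann_err
    ))
  }
  counts$retained <- nrow(feature_rows)
  feature_rows <- dplyr::arrange(feature_rows, .data$mz, .data$rt)
  attr(feature_rows, "stage_counts") <- counts
  feature_rows
}

#' Cluster candidate features by mass and retention time
#'
#' k-means in z-standardised (m/z, retention time) space, mirroring the
#' dot-plot grouping of detected AHLs by size range and elution. Both axes
#' are standardised so neither dominates; the RNG seed and restart count make
#' the partition reproducible.
#'
#' @param features Feature table from [screen_pipeline()] (needs `mz`, `rt`).
#' @param k Number of clusters (default 4).
#' @param seed RNG seed for the k-means starts.
#' @param nstart Number of random restarts.
#' @return List of class `feature_clustering`: `features` (input plus a
#'   `cluster` column), `centers` (standardised space), `k`, `withinss`,
#'   `tot_withinss`.
#' @export
cluster_features <- function(features, k = 4L, seed = 1L, nstart = 10L) {
  if (nrow(features) < k) {
    stop(sprintf("need at least k=%d features, got %d", k, nrow(features)),
         call. = FALSE)
  }
  if (k < 1L) stop("`k` must be >= 1", call. = FALSE)
  zscore <- function(v) {
    s <- stats::sd(v)
    (v - mean(v)) / if (is.na(s) || s == 0) 1 else s
  }
  mat <- cbind(mz = zscore(features$mz), rt = zscore(features$rt))
  km <- withr::with_seed(seed, stats::kmeans(mat, centers = k, nstart = nstart))
  out <- features
  out$cluster <- km$cluster
  structure(
    list(features = out, centers = km$centers, k = k,
         withinss = km$withinss, tot_withinss = km$tot.withinss),
    class = "feature_clustering"
  )
}

#' @export
print.feature_clustering <- function(x, ...) {
  cat(sprintf("<feature_clustering> %d features in %d clusters (tot WSS %.3f)\n",
              nrow(x$features), x$k, x$tot_withinss))
  invisible(x)
}
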