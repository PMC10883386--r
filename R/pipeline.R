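# Pipeline configuration and the high-level entry points behind the
# command-line front end (inst/scripts/ahltools).

#' Pipeline configuration
#'
#' All tunable thresholds of the screening and mining tracks in one list,
#' with the package defaults. Values can be overridden by arguments or by a
#' YAML file ([read_config()]); every report echoes the effective
#' configuration for provenance.
#'
#' Screening defaults assume unit-resolution triple-quadrupole data:
#' fragment and precursor tolerances of 0.5 m/z, the m/z 102 ring daughter
#' with confirmation set 56/74/84, a 0.01 relative-intensity gate, peaks of
#' at least 1000 a.u. and 3x MAD signal-to-noise, and retention of sample
#' peaks at least 3-fold above the control maximum in a +/-0.5 min window.
#' Mining defaults: strict E-value threshold 1e-5 for HMM hits, 0.01 for
#' BLAST.
#'
#' @param ... Named overrides of any default.
#' @return Named list of class `ahl_config`.
#' @export
ahl_config <- function(...) {
  cfg <- list(
    characteristic_mz = 102,
    confirm_set = c(56, 74, 84),
    fragment_tol = 0.5,
    precursor_tol = 0.5,
    min_rel_intensity = 0.01,
    min_peak_height = 1000,
    min_snr = 3,
    peak_window = 0.2,
    rt_window = 0.5,
    fold_threshold = 3,
    epsilon = 1,
    annotation_tol = 0.5,
    cluster_k = 4L,
    cluster_nstart = 10L,
    hmm_evalue_threshold = 1e-5,
    blast_evalue_threshold = 0.01,
    seed = 1L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    stop(sprintf("unknown config field(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  cfg[names(over)] <- over
  numeric_fields <- c("fragment_tol", "precursor_tol", "min_peak_height",
                      "min_snr", "peak_window", "rt_window", "fold_threshold",
                      "epsilon",
                      "annotation_tol", "hmm_evalue_threshold",
                      "blast_evalue_threshold")
  bad <- numeric_fields[vapply(numeric_fields,
                               function(f) !is.numeric(cfg[[f]]) || cfg[[f]] <= 0,
                               logical(1))]
  if (length(bad)) {
    stop(sprintf("config field(s) must be positive: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  structure(cfg, class = "ahl_config")
}

#' Read / write a configuration as YAML
#'
#' The file round-trips losslessly: unspecified fields take the defaults.
#'
#' @param path YAML file.
#' @param config An [ahl_config()].
#' @return An `ahl_config` (reader); `path` invisibly (writer).
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$confirm_set)) vals$confirm_set <- as.numeric(vals$confirm_set)
  do.call(ahl_config, vals)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

.write_json_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Run the screening track end to end
#'
#' Reads a sample and a control run, applies [screen_pipeline()] and
#' [cluster_features()], and writes `features.csv`, `clusters.csv`,
#' `eics.csv` (the per-feature-mass EIC traces) and `report.json` with
#' per-stage counts and the effective configuration.
#'
#' @param sample_path,control_path MS run files (mzML or MGF).
#' @param out_dir Output directory.
#' @param config An [ahl_config()].
#' @param species Sample label written into the feature table.
#' @param library Annotation library (default [build_library()]).
#' @return Invisibly, a list with `features`, `clustering` (or `NULL` when
#'   there are fewer features than `cluster_k`), `report` and output paths.
#' @export
run_screen <- function(sample_path, control_path, out_dir,
                       config = ahl_config(), species = "sample",
                       library = build_library()) {
  if (is.null(control_path) || !file.exists(control_path)) {
    stop("a medium control run is required (control_path missing)", call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sample <- read_ms_run(sample_path, label = "sample")
  control <- read_ms_run(control_path, label = "control")
  features <- screen_pipeline(sample, control, library = library,
                              config = config, species = species)
  counts <- attr(features, "stage_counts")

  clustering <- NULL
  if (nrow(features) >= config$cluster_k) {
    clustering <- cluster_features(features, k = config$cluster_k,
                                   seed = config$seed,
                                   nstart = config$cluster_nstart)
  }

  features_path <- file.path(out_dir, "features.csv")
  feat_out <- features
  for (col in c("rt", "fold_change", "mass_error")) {
    feat_out[[col]] <- sprintf("%.6f", feat_out[[col]])
  }
  readr::write_csv(feat_out, features_path)

  clusters_path <- file.path(out_dir, "clusters.csv")
  if (!is.null(clustering)) {
    cl_out <- clustering$features[, c("species", "mz", "rt", "cluster")]
    cl_out$rt <- sprintf("%.6f", cl_out$rt)
    readr::write_csv(cl_out, clusters_path)
  } else {
    readr::write_csv(tibble::tibble(species = character(0), mz = integer(0),
                                    rt = character(0), cluster = integer(0)),
                     clusters_path)
  }

  eics_path <- file.path(out_dir, "eics.csv")
  eics <- purrr::map_dfr(unique(features$mz), function(m) {
    e <- extract_eic(sample, m, tol = config$precursor_tol)
    tibble::tibble(mz = m, rt = sprintf("%.6f", e$rt),
                   intensity = sprintf("%.6f", e$intensity))
  })
  if (nrow(eics) == 0L) {
    eics <- tibble::tibble(mz = integer(0), rt = character(0),
                           intensity = character(0))
  }
  readr::write_csv(eics, eics_path)

  report <- list(
    command = "screen",
    inputs = list(sample = sample_path, control = control_path),
    species = species,
    stage_counts = counts,
    n_features = nrow(features),
    n_clusters = if (is.null(clustering)) 0L else clustering$k,
    config = unclass(config)
  )
  report_path <- file.path(out_dir, "report.json")
  .write_json_report(report, report_path)

  invisible(list(features = features, clustering = clustering, report = report,
                 features_path = features_path, clusters_path = clusters_path,
                 eics_path = eics_path, report_path = report_path))
}

#' Run the genome-mining track end to end
#'
#' Reads every tblout file in a directory, applies the
#' filter / best-model / count / deduplicate / summarise chain, optionally
#' filters a BLAST table, and writes `copy_numbers.csv` (per assembly),
#' `species_copy_numbers.csv` (deduplicated) and `summary.json`.
#'
#' @param tblout_dir Directory of `<assembly_id>.tblout` files.
#' @param model_manifest_path,assembly_manifest_path Manifest TSVs.
#' @param out_dir Output directory.
#' @param blast_path Optional BLAST `-outfmt 6` file.
#' @param blast_species_map Optional sidecar TSV (`subject_id`,
#'   `species_name`) for the BLAST table.
#' @param config An [ahl_config()].
#' @return Invisibly, a list with `per_assembly`, `per_species`, `summary`,
#'   `blast` (or `NULL`) and output paths.
#' @export
run_mine <- function(tblout_dir, model_manifest_path, assembly_manifest_path,
                     out_dir, blast_path = NULL, blast_species_map = NULL,
                     config = ahl_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  models <- read_model_manifest(model_manifest_path)
  assemblies <- read_assembly_manifest(assembly_manifest_path)
  hits <- read_tblout_dir(tblout_dir, models, assemblies)
  unresolved <- setdiff(unique(hits$assembly_id), assemblies$assembly_id)
  if (length(unresolved)) {
    stop(sprintf("assembly id(s) not in manifest: %s",
                 paste(unresolved, collapse = ", ")), call. = FALSE)
  }
  kept <- hits |>
    filter_significant(threshold = config$hmm_evalue_threshold) |>
    assign_best_model()
  per_assembly <- count_copies(kept, assemblies)
  per_species <- dedup_species(per_assembly)
  summary_tbl <- summarize_copy_numbers(per_species)

  blast_res <- NULL
  if (!is.null(blast_path)) {
    blast_hits <- read_blast(blast_path, species_map = blast_species_map)
    blast_res <- filter_blast(blast_hits,
                              evalue_threshold = config$blast_evalue_threshold)
  }

  per_assembly_path <- file.path(out_dir, "copy_numbers.csv")
  per_species_path <- file.path(out_dir, "species_copy_numbers.csv")
  readr::write_csv(per_assembly, per_assembly_path)
  readr::write_csv(per_species, per_species_path)
  summary_path <- file.path(out_dir, "summary.json")
  summary_json <- list(
    command = "mine",
    n_assemblies = nrow(per_assembly),
    n_species = nrow(per_species),
    families = purrr::pmap(summary_tbl, function(...) list(...)),
    blast = if (is.null(blast_res)) NULL else list(
      n_hits = blast_res$n_hits,
      n_unique_species = blast_res$n_unique_species,
      identity_range = blast_res$identity_range,
      coverage_range = blast_res$coverage_range
    ),
    config = unclass(config)
  )
  .write_json_report(summary_json, summary_path)

  invisible(list(per_assembly = per_assembly, per_species = per_species,
                 summary = summary_tbl, blast = blast_res,
                 per_assembly_path = per_assembly_path,
                 per_species_path = per_species_path,
                 summary_path = summary_path))
}

#' Generate synthetic fixtures from a spec file
#'
#' The JSON/YAML spec has a top-level `kind` (`"ms_run"` or `"cohort"`) and a
#' `params` object whose fields are passed to [ms_run_spec()] (with `planted`
#' rows as a list of [planted_ahl()] argument sets) or [cohort_spec()]. A
#' `manifest.json` listing every produced file is written alongside.
#'
#' @param spec_path JSON or YAML spec file.
#' @param out_dir Output directory.
#' @param seed Optional seed overriding the spec's.
#' @return Invisibly, the generator's result list plus `manifest_path`.
#' @export
run_simulate <- function(spec_path, out_dir, seed = NULL) {
  if (!file.exists(spec_path)) {
    stop(sprintf("spec file not found: %s", spec_path), call. = FALSE)
  }
  raw <- if (grepl("\\.ya?ml$", spec_path, ignore.case = TRUE)) {
    yaml::read_yaml(spec_path)
  } else {
    jsonlite::read_json(spec_path, simplifyVector = TRUE)
  }
  if (is.null(raw$kind) || !raw$kind %in% c("ms_run", "cohort")) {
    stop("spec must declare kind: 'ms_run' or 'cohort'", call. = FALSE)
  }
  params <- raw$params %||% list()
  if (!is.null(seed)) params$seed <- as.integer(seed)
  res <- if (raw$kind == "ms_run") {
    if (!is.null(params$planted)) {
      planted <- params$planted
      if (is.data.frame(planted)) planted <- purrr::transpose(planted)
      params$planted <- purrr::map_dfr(planted, function(p) {
        do.call(planted_ahl, p)
      })
    }
    if (!is.null(params$background)) {
      params$background <- tibble::as_tibble(params$background)
    }
    make_ms_run(do.call(ms_run_spec, params), out_dir)
  } else {
    make_cohort(do.call(cohort_spec, params), out_dir)
  }
  files <- unlist(res[vapply(res, is.character, logical(1))], use.names = TRUE)
  manifest_path <- file.path(out_dir, "manifest.json")
  .write_json_report(list(kind = raw$kind, files = as.list(files)),
                     manifest_path)
  invisible(c(res, list(manifest_path = manifest_path)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
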