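# Synthetic-data generators: spiked MS/MS runs (sample + medium control) and
# genome-mining hit-table cohorts, each with a planted ground-truth table.

#' Specify one planted AHL for a synthetic run
#'
#' @param n,oxo,unsat Acyl-chain descriptor fields (see [acyl_descriptor()]).
#' @param rt Apex retention time in minutes.
#' @param intensity Apex base-peak intensity (arbitrary units).
#' @param width Gaussian elution sigma in minutes.
#' @return One-row tibble usable in `ms_run_spec(planted = ...)`.
#' @export
planted_ahl <- function(n, oxo = FALSE, unsat = 0L, rt, intensity = 5e4,
                        width = 0.1) {
  d <- acyl_descriptor(n, oxo, unsat)
  tibble::tibble(
    name = ahl_name(d), n = d$chain_length, oxo = d$oxo3,
    unsat = d$unsaturations, mz = nominal_mh(formula_of(d)),
    rt = rt, intensity = intensity, width = width
  )
}

#' Specification of a synthetic MS/MS acquisition
#'
#' Describes a sample/control pair from a 40-minute gradient on a
#' unit-resolution triple quadrupole: planted AHLs eluting as Gaussian peaks
#' whose product spectra carry the m/z 102 ring daughter plus a random
#' non-empty subset of the 56/74/84 confirmation set; decoy spectra of two
#' kinds (fragments lacking 102 entirely, and 102 present without any
#' confirmation daughter); medium-background ions that elute identically in
#' sample and control; lognormal intensity scatter and Poisson-count chemical
#' noise fragments.
#'
#' @param planted Tibble of planted AHLs (rows from [planted_ahl()]).
#' @param n_decoy_no102 Number of decoy spectra without the m/z 102 daughter.
#' @param n_decoy_noconfirm Number of decoys with 102 but no 56/74/84.
#' @param background Tibble of medium ions shared by sample and control:
#'   columns `mz`, `rt`, `intensity`, `width`.
#' @param noise_sdlog Lognormal sigma for fragment-intensity scatter
#'   (0 = noiseless).
#' @param chem_noise_lambda Poisson mean count of uniform-mass noise fragments
#'   per spectrum (0 = none).
#' @param scan_interval Scan spacing in minutes.
#' @param rt_span Gradient span in minutes.
#' @param seed RNG seed; a fixed seed makes the output byte-identical.
#' @return List of class `ms_run_spec`.
#' @export
ms_run_spec <- function(planted = NULL, n_decoy_no102 = 10L,
                        n_decoy_noconfirm = 5L, background = default_background(),
                        noise_sdlog = 0.3, chem_noise_lambda = 4,
                        scan_interval = 0.05, rt_span = c(0, 40), seed = 1L) {
  if (is.null(planted)) {
    planted <- tibble::tibble(
      name = character(0), n = integer(0), oxo = logical(0), unsat = integer(0),
      mz = integer(0), rt = numeric(0), intensity = numeric(0), width = numeric(0)
    )
  }
  if (nrow(planted) > 0 &&
      (any(planted$rt < rt_span[1]) || any(planted$rt > rt_span[2]))) {
    stop("planted retention times must lie within the gradient span", call. = FALSE)
  }
  if (!is.null(background) && nrow(background) > 0 &&
      (any(background$rt < rt_span[1]) || any(background$rt > rt_span[2]))) {
    stop("background retention times must lie within the gradient span",
         call. = FALSE)
  }
  if (scan_interval <= 0 || noise_sdlog < 0 || chem_noise_lambda < 0) {
    stop("invalid noise/scan parameters", call. = FALSE)
  }
  structure(
    list(planted = planted, n_decoy_no102 = as.integer(n_decoy_no102),
         n_decoy_noconfirm = as.integer(n_decoy_noconfirm),
         background = background, noise_sdlog = noise_sdlog,
         chem_noise_lambda = chem_noise_lambda, scan_interval = scan_interval,
         rt_span = rt_span, seed = as.integer(seed)),
    class = "ms_run_spec"
  )
}

#' Default medium-background ions
#'
#' Two ions standing for medium components that survive extraction; they
#' fragment AHL-like (102 plus 74) so they reach the control-comparison stage
#' and are removed there, not earlier.
#'
#' @return Tibble with `mz`, `rt`, `intensity`, `width`.
#' @export
default_background <- function() {
  tibble::tibble(
    mz = c(137, 279), rt = c(3.0, 21.0), intensity = c(2e4, 4e4),
    width = c(0.15, 0.15)
  )
}

.CONFIRM_SET <- c(56, 74, 84)
# exclusion half-width used when drawing noise/decoy masses so that chance
# fragments never land inside a diagnostic window
.EXCL <- 0.8

.draw_mass_avoiding <- function(n, lo, hi, avoid) {
  out <- numeric(0)
  while (length(out) < n) {
    cand <- stats::runif(n - length(out), lo, hi)
    ok <- !vapply(cand, function(m) any(abs(m - avoid) <= .EXCL), logical(1))
    out <- c(out, cand[ok])
  }
  out
}

.elution_scans <- function(grid, rt, width) grid[abs(grid - rt) <= 3 * width]

.lognorm <- function(n, sdlog) {
  if (sdlog == 0) rep(1, n) else stats::rlnorm(n, meanlog = 0, sdlog = sdlog)
}

# Build the spectrum list for one eluting compound.
.compound_spectra <- function(grid, mz, rt, width, apex_intensity, daughters,
                              rel, sdlog, chem_lambda, avoid) {
  times <- .elution_scans(grid, rt, width)
  lapply(times, function(t) {
    scale <- apex_intensity * exp(-(t - rt)^2 / (2 * width^2))
    fmz <- daughters
    fint <- scale * rel * .lognorm(length(rel), sdlog)
    n_noise <- if (chem_lambda > 0) stats::rpois(1, chem_lambda) else 0L
    if (n_noise > 0L) {
      nm <- .draw_mass_avoiding(n_noise, 50, max(mz - 1, 51),
                                c(102, .CONFIRM_SET, avoid))
      fmz <- c(fmz, nm)
      fint <- c(fint, scale * stats::runif(n_noise, 0.005, 0.05))
    }
    list(precursor_mz = as.numeric(mz), rt = t, mz = fmz, intensity = fint)
  })
}

#' Generate a synthetic sample/control MS/MS pair with ground truth
#'
#' Writes the sample and control runs as both mzML and MGF from one internal
#' truth, plus a `truth.csv` listing every planted, decoy and background
#' entity with its class. Identical spec and seed give byte-identical files.
#'
#' @param spec An [ms_run_spec()].
#' @param dir Output directory (created if needed).
#' @return List with file paths (`sample_mzml`, `sample_mgf`, `control_mzml`,
#'   `control_mgf`, `truth_csv`) and the `truth` tibble.
#' @export
make_ms_run <- function(spec, dir) {
  stopifnot(inherits(spec, "ms_run_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  grid <- seq(spec$rt_span[1], spec$rt_span[2], by = spec$scan_interval)
  planted_mz <- if (nrow(spec$planted)) spec$planted$mz else numeric(0)
  bg <- spec$background
  bg_mz <- if (!is.null(bg) && nrow(bg)) bg$mz else numeric(0)
  reserved <- c(planted_mz, bg_mz)

  built <- withr::with_seed(spec$seed, {
    sample_spectra <- list()
    control_spectra <- list()
    truth <- list()

    if (nrow(spec$planted)) {
      for (i in seq_len(nrow(spec$planted))) {
        p <- spec$planted[i, ]
        n_conf <- sample(1:3, 1)
        conf <- sort(sample(.CONFIRM_SET, n_conf))
        daughters <- c(102, conf)
        rel <- c(1, stats::runif(length(conf), 0.2, 0.6))
        sample_spectra <- c(sample_spectra, .compound_spectra(
          grid, p$mz, p$rt, p$width, p$intensity, daughters, rel,
          spec$noise_sdlog, spec$chem_noise_lambda, reserved
        ))
        truth[[length(truth) + 1L]] <- tibble::tibble(
          class = "planted", name = p$name, mz = p$mz, rt = p$rt,
          intensity = p$intensity, daughters = paste(conf, collapse = ";")
        )
      }
    }

    if (!is.null(bg) && nrow(bg)) {
      for (i in seq_len(nrow(bg))) {
        b <- bg[i, ]
        daughters <- c(102, 74)
        rel <- c(1, 0.35)
        for (role in c("sample", "control")) {
          sp <- .compound_spectra(grid, b$mz, b$rt, b$width, b$intensity,
                                  daughters, rel, spec$noise_sdlog,
                                  spec$chem_noise_lambda, reserved)
          if (role == "sample") sample_spectra <- c(sample_spectra, sp)
          else control_spectra <- c(control_spectra, sp)
        }
        truth[[length(truth) + 1L]] <- tibble::tibble(
          class = "background", name = sprintf("medium_%d", round(b$mz)),
          mz = b$mz, rt = b$rt, intensity = b$intensity, daughters = "74"
        )
      }
    }

    add_decoys <- function(kind, n_decoys) {
      for (j in seq_len(n_decoys)) {
        prec <- .draw_mass_avoiding(1, 125, 445, reserved)
        t <- sample(grid, 1)
        n_frag <- sample(3:7, 1)
        base <- stats::runif(1, 5e3, 5e4)
        if (kind == "no102") {
          fmz <- .draw_mass_avoiding(n_frag, 50, prec - 1, c(102, reserved))
          fint <- base * c(1, stats::runif(n_frag - 1, 0.05, 0.8))
        } else {
          fmz <- c(102, .draw_mass_avoiding(n_frag - 1, 50, prec - 1,
                                            c(102, .CONFIRM_SET, reserved)))
          fint <- base * c(1, stats::runif(n_frag - 1, 0.05, 0.8))
        }
        sample_spectra[[length(sample_spectra) + 1L]] <<- list(
          precursor_mz = prec, rt = t, mz = fmz, intensity = fint
        )
        truth[[length(truth) + 1L]] <<- tibble::tibble(
          class = paste0("decoy_", kind),
          name = sprintf("decoy_%s_%d", kind, j), mz = prec, rt = t,
          intensity = base,
          daughters = if (kind == "no102") "" else "102"
        )
      }
    }
    add_decoys("no102", spec$n_decoy_no102)
    add_decoys("noconfirm", spec$n_decoy_noconfirm)

    if (length(control_spectra) == 0L) {
      # solvent blank so the control file parses even with no medium ions
      control_spectra <- list(list(precursor_mz = 121, rt = grid[2],
                                   mz = 60.0, intensity = 10))
      truth[[length(truth) + 1L]] <- tibble::tibble(
        class = "blank", name = "solvent_blank", mz = 121, rt = grid[2],
        intensity = 10, daughters = ""
      )
    }
    list(sample = sample_spectra, control = control_spectra,
         truth = dplyr::bind_rows(truth))
  })

  order_spectra <- function(sp) {
    sp <- sp[order(vapply(sp, `[[`, numeric(1), "rt"),
                   vapply(sp, `[[`, numeric(1), "precursor_mz"))]
    lapply(seq_along(sp), function(i) {
      s <- sp[[i]]
      ord <- order(s$mz)
      s$mz <- s$mz[ord]
      s$intensity <- s$intensity[ord]
      s$scan <- i
      s
    })
  }
  sample_spectra <- order_spectra(built$sample)
  control_spectra <- order_spectra(built$control)

  paths <- list(
    sample_mzml = file.path(dir, "sample.mzML"),
    sample_mgf = file.path(dir, "sample.mgf"),
    control_mzml = file.path(dir, "control.mzML"),
    control_mgf = file.path(dir, "control.mgf"),
    truth_csv = file.path(dir, "truth.csv")
  )
  write_mzml(sample_spectra, paths$sample_mzml)
  write_mgf(sample_spectra, paths$sample_mgf)
  write_mzml(control_spectra, paths$control_mzml)
  write_mgf(control_spectra, paths$control_mgf)
  truth <- built$truth
  truth_out <- truth
  truth_out$rt <- sprintf("%.6f", truth_out$rt)
  truth_out$intensity <- sprintf("%.6f", truth_out$intensity)
  truth_out$mz <- sprintf("%.6f", truth_out$mz)
  readr::write_csv(truth_out, paths$truth_csv)
  c(paths, list(truth = truth))
}

#' Write spectra as MGF
#'
#' Plain-text Mascot generic format: one `BEGIN IONS` block per spectrum with
#' `PEPMASS`, `RTINSECONDS`, `SCANS` and fixed-precision peak lines, so the
#' output is byte-stable for a given spectrum list.
#'
#' @param spectra List of spectra (`precursor_mz`, `rt` minutes, `mz`,
#'   `intensity`, `scan`).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  blocks <- vapply(spectra, function(sp) {
    peaks <- paste(sprintf("%.6f %.6f", sp$mz, sp$intensity), collapse = "\n")
    sprintf("BEGIN IONS\nTITLE=scan=%d\nPEPMASS=%.6f\nRTINSECONDS=%.6f\nSCANS=%d\nCHARGE=1+\n%s\nEND IONS",
            sp$scan, sp$precursor_mz, sp$rt * 60, sp$scan, peaks)
  }, character(1))
  writeLines(blocks, path)
  invisible(path)
}

.b64_doubles <- function(x) {
  # base64_enc wraps long output; the encodedLength attribute needs one line
  gsub("\n", "", jsonlite::base64_enc(writeBin(as.numeric(x), raw(), size = 8,
                                               endian = "little")), fixed = TRUE)
}

.mzml_spectrum <- function(sp, index) {
  mzb <- .b64_doubles(sp$mz)
  inb <- .b64_doubles(sp$intensity)
  sprintf(
    paste0(
      '<spectrum index="%d" id="scan=%d" defaultArrayLength="%d">\n',
      '<cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="2"/>\n',
      '<cvParam cvRef="MS" accession="MS:1000580" name="MSn spectrum" value=""/>\n',
      '<cvParam cvRef="MS" accession="MS:1000127" name="centroid spectrum" value=""/>\n',
      '<scanList count="1"><cvParam cvRef="MS" accession="MS:1000795" name="no combination" value=""/>\n',
      '<scan><cvParam cvRef="MS" accession="MS:1000016" name="scan start time" value="%.6f" unitCvRef="UO" unitAccession="UO:0000031" unitName="minute"/></scan></scanList>\n',
      '<precursorList count="1"><precursor><selectedIonList count="1"><selectedIon>\n',
      '<cvParam cvRef="MS" accession="MS:1000744" name="selected ion m/z" value="%.6f" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>\n',
      '</selectedIon></selectedIonList><activation><cvParam cvRef="MS" accession="MS:1000133" name="collision-induced dissociation" value=""/></activation></precursor></precursorList>\n',
      '<binaryDataArrayList count="2">\n',
      '<binaryDataArray encodedLength="%d"><cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/><cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/><cvParam cvRef="MS" accession="MS:1000514" name="m/z array" value="" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/><binary>%s</binary></binaryDataArray>\n',
      '<binaryDataArray encodedLength="%d"><cvParam cvRef="MS" accession="MS:1000515" name="intensity array" value="" unitCvRef="MS" unitAccession="MS:1000131" unitName="number of detector counts"/><cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/><cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/><binary>%s</binary></binaryDataArray>\n',
      '</binaryDataArrayList></spectrum>'
    ),
    index, sp$scan, length(sp$mz), sp$rt, sp$precursor_mz,
    nchar(mzb), mzb, nchar(inb), inb
  )
}

#' Write spectra as mzML
#'
#' Minimal PSI mzML 1.1.0 with uncompressed 64-bit little-endian peak arrays,
#' readable by proteowizard-based parsers (e.g. `mzR`). Retention times are
#' written in minutes with an explicit unit term.
#'
#' @inheritParams write_mgf
#' @return `path`, invisibly.
#' @export
write_mzml <- function(spectra, path) {
  body <- vapply(seq_along(spectra), function(i) {
    .mzml_spectrum(spectra[[i]], i - 1L)
  }, character(1))
  doc <- sprintf(
    paste0(
      '<?xml version="1.0" encoding="utf-8"?>\n',
      '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">\n',
      '<cvList count="2"><cv id="MS" fullName="PSI-MS" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/><cv id="UO" fullName="UO" URI="http://ontologies.berkeleybop.org/uo.obo"/></cvList>\n',
      '<fileDescription><fileContent><cvParam cvRef="MS" accession="MS:1000580" name="MSn spectrum" value=""/></fileContent></fileDescription>\n',
      '<softwareList count="1"><software id="ahltools" version="0.1.0"><cvParam cvRef="MS" accession="MS:1000799" name="custom unreleased software tool" value="ahltools"/></software></softwareList>\n',
      '<instrumentConfigurationList count="1"><instrumentConfiguration id="IC1"><cvParam cvRef="MS" accession="MS:1000031" name="instrument model" value=""/></instrumentConfiguration></instrumentConfigurationList>\n',
      '<dataProcessingList count="1"><dataProcessing id="dp1"><processingMethod order="1" softwareRef="ahltools"><cvParam cvRef="MS" accession="MS:1000544" name="Conversion to mzML" value=""/></processingMethod></dataProcessing></dataProcessingList>\n',
      '<run id="run1" defaultInstrumentConfigurationRef="IC1">\n',
      '<spectrumList count="%d" defaultDataProcessingRef="dp1">\n%s\n</spectrumList></run></mzML>'
    ),
    length(spectra), paste(body, collapse = "\n")
  )
  writeLines(doc, path)
  invisible(path)
}

#' Specification of a synthetic genome-mining cohort
#'
#' Emulates the shape of a genus-wide homolog search: per-assembly synthase
#' copy counts drawn as 1 + Poisson(`synthase_lambda`) and receptor counts as
#' a rounded Normal floored at `receptor_min` (receptor counts far exceed
#' synthase counts, as LuxR-family regulators do in actinomycete genomes);
#' significant E-values log-uniform below 1e-5; decoy rows above threshold;
#' a fraction of targets hit by two models of the same family; a fraction of
#' species represented by a second assembly with independently drawn counts.
#'
#' @param n_species Number of distinct species.
#' @param dup_fraction Fraction of species carrying a duplicate assembly.
#' @param synthase_lambda Poisson mean of the synthase count above
#'   `synthase_min`.
#' @param synthase_min Floor of the synthase count; set it and the receptor
#'   parameters to zero for a decoy-only cohort.
#' @param receptor_mean,receptor_sd,receptor_min Receptor count distribution.
#' @param evalue_log10_range Log10 range of significant E-values.
#' @param decoy_lambda Poisson mean count of above-threshold decoy rows per
#'   assembly.
#' @param collision_rate Fraction of planted targets also hit by a second
#'   model (higher E-value, same family).
#' @param blast_n_hits,blast_sig_fraction Size and significant fraction of the
#'   companion BLAST table.
#' @param seed RNG seed.
#' @return List of class `cohort_spec`.
#' @export
cohort_spec <- function(n_species = 200L, dup_fraction = 0.1,
                        synthase_lambda = 4.3, synthase_min = 1L,
                        receptor_mean = 123,
                        receptor_sd = 25, receptor_min = 5L,
                        evalue_log10_range = c(-30, -6), decoy_lambda = 2,
                        collision_rate = 0.1, blast_n_hits = 20L,
                        blast_sig_fraction = 0.6, seed = 1L) {
  if (n_species < 1L || dup_fraction < 0 || dup_fraction > 1) {
    stop("invalid cohort size or duplicate fraction", call. = FALSE)
  }
  if (evalue_log10_range[2] >= -5) {
    stop("significant E-value range must stay below the 1e-5 threshold",
         call. = FALSE)
  }
  structure(
    list(n_species = as.integer(n_species), dup_fraction = dup_fraction,
         synthase_lambda = synthase_lambda,
         synthase_min = as.integer(synthase_min),
         receptor_mean = receptor_mean,
         receptor_sd = receptor_sd, receptor_min = as.integer(receptor_min),
         evalue_log10_range = evalue_log10_range, decoy_lambda = decoy_lambda,
         collision_rate = collision_rate, blast_n_hits = as.integer(blast_n_hits),
         blast_sig_fraction = blast_sig_fraction, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

.SYNTHASE_MODELS <- c("AHL_synth_1", "AHL_synth_2")
.RECEPTOR_MODELS <- c("LuxR_reg_1", "LuxR_reg_2", "LuxR_reg_3")

.tblout_row <- function(target, model, evalue, score) {
  sprintf("%-24s -          %-14s -            %9.3g %7.1f   0.0 %9.3g %7.1f   0.0   1.0   1   1   1   1   1   1   1 synthetic hit",
          target, model, evalue, score, evalue, score)
}

#' Generate a synthetic genome-mining cohort with ground truth
#'
#' Writes one tblout file per assembly, the model and assembly manifests, a
#' BLAST tabular file with a species sidecar, and truth CSVs recording the
#' planted per-assembly counts and the expected species-deduplication winner.
#'
#' @param spec A [cohort_spec()].
#' @param dir Output directory.
#' @return List: `tblout_dir`, `model_manifest`, `assembly_manifest`,
#'   `blast_path`, `blast_species_map`, `truth_assemblies_csv`,
#'   `truth_species_csv`, `truth_blast_csv`, plus the in-memory
#'   `truth_assemblies`, `truth_species`, `truth_blast` tibbles.
#' @export
make_cohort <- function(spec, dir) {
  stopifnot(inherits(spec, "cohort_spec"))
  tbl_dir <- file.path(dir, "tblout")
  dir.create(tbl_dir, showWarnings = FALSE, recursive = TRUE)

  out <- withr::with_seed(spec$seed, {
    species <- sprintf("Streptomyces sp%04d", seq_len(spec$n_species))
    n_dup <- floor(spec$n_species * spec$dup_fraction)
    dup_species_idx <- if (n_dup > 0) sort(sample(spec$n_species, n_dup)) else integer(0)
    assemblies <- tibble::tibble(
      assembly_id = c(sprintf("GCF_%06d.1", seq_len(spec$n_species)),
                      sprintf("GCF_%06d.2", dup_species_idx)),
      species_name = c(species, species[dup_species_idx])
    )
    assemblies <- dplyr::arrange(assemblies, .data$assembly_id)

    lo <- spec$evalue_log10_range[1]
    hi <- spec$evalue_log10_range[2]
    truth_rows <- list()
    file_lines <- list()
    for (i in seq_len(nrow(assemblies))) {
      aid <- assemblies$assembly_id[i]
      nI <- spec$synthase_min + stats::rpois(1, spec$synthase_lambda)
      nR <- max(spec$receptor_min,
                as.integer(round(stats::rnorm(1, spec$receptor_mean, spec$receptor_sd))))
      lines <- character(0)
      plant <- function(count, models, tag) {
        for (k in seq_len(count)) {
          target <- sprintf("%s_%s%03d", aid, tag, k)
          ev <- 10^stats::runif(1, lo, hi)
          score <- round(-4 * log10(ev) + stats::runif(1, 0, 5), 1)
          model <- sample(models, 1)
          lines <<- c(lines, .tblout_row(target, model, ev, score))
          if (length(models) > 1L && stats::runif(1) < spec$collision_rate) {
            other <- sample(setdiff(models, model), 1)
            ev2 <- min(10^(log10(ev) + stats::runif(1, 0.5, 3)), 10^hi)
            lines <<- c(lines, .tblout_row(target, other, ev2,
                                           round(score - stats::runif(1, 1, 10), 1)))
          }
        }
      }
      plant(nI, .SYNTHASE_MODELS, "I")
      plant(nR, .RECEPTOR_MODELS, "R")
      n_decoy <- stats::rpois(1, spec$decoy_lambda)
      for (k in seq_len(n_decoy)) {
        ev <- 10^stats::runif(1, -4.9, -0.1)
        lines <- c(lines, .tblout_row(
          sprintf("%s_dec%03d", aid, k),
          sample(c(.SYNTHASE_MODELS, .RECEPTOR_MODELS), 1), ev,
          round(-2 * log10(ev), 1)
        ))
      }
      file_lines[[aid]] <- lines
      truth_rows[[i]] <- tibble::tibble(
        assembly_id = aid, species_name = assemblies$species_name[i],
        luxI_count = nI, luxR_count = nR, product = nI * nR
      )
    }
    truth_assemblies <- dplyr::bind_rows(truth_rows) |>
      dplyr::arrange(.data$assembly_id)

    # expected dedup winner under the product rule (ties: luxR, then assembly id)
    truth_species <- truth_assemblies |>
      dplyr::group_by(.data$species_name) |>
      dplyr::arrange(dplyr::desc(.data$product), dplyr::desc(.data$luxR_count),
                     .data$assembly_id, .by_group = TRUE) |>
      dplyr::slice(1L) |>
      dplyr::ungroup() |>
      dplyr::arrange(.data$species_name)

    n_sig <- round(spec$blast_n_hits * spec$blast_sig_fraction)
    blast_species <- sample(species, spec$blast_n_hits, replace = TRUE)
    is_sig <- seq_len(spec$blast_n_hits) <= n_sig
    blast <- tibble::tibble(
      query_id = "LuxR_model",
      subject_id = sprintf("WP_%09d.1", seq_len(spec$blast_n_hits)),
      species_name = blast_species,
      percent_identity = round(stats::runif(spec$blast_n_hits, 25, 55), 2),
      query_coverage = round(stats::runif(spec$blast_n_hits, 10, 48), 0),
      evalue = ifelse(is_sig, 10^stats::runif(spec$blast_n_hits, -30, -2.1),
                      10^stats::runif(spec$blast_n_hits, -1.9, 1)),
      bit_score = round(stats::runif(spec$blast_n_hits, 30, 200), 1)
    )
    truth_blast <- tibble::tibble(
      n_hits = spec$blast_n_hits,
      n_significant = sum(blast$evalue < 0.01),
      n_unique_species = length(unique(blast$species_name[blast$evalue < 0.01]))
    )
    list(assemblies = assemblies, file_lines = file_lines,
         truth_assemblies = truth_assemblies, truth_species = truth_species,
         blast = blast, truth_blast = truth_blast)
  })

  header <- c(
    "#                                                               --- full sequence ---- --- best 1 domain ---- --- domain number estimation ----",
    "# target name        accession  query name     accession    E-value  score  bias   E-value  score  bias   exp reg clu  ov env dom rep inc description of target",
    "#------------------- ---------- -------------- ---------- --------- ------ ----- --------- ------ -----   --- --- --- --- --- --- --- --- ---------------------"
  )
  for (aid in out$assemblies$assembly_id) {
    writeLines(c(header, out$file_lines[[aid]]),
               file.path(tbl_dir, paste0(aid, ".tblout")))
  }

  model_manifest_path <- file.path(dir, "model_manifest.tsv")
  readr::write_tsv(tibble::tibble(
    model_id = c(.SYNTHASE_MODELS, .RECEPTOR_MODELS),
    family = c(rep("synthase", length(.SYNTHASE_MODELS)),
               rep("receptor", length(.RECEPTOR_MODELS)))
  ), model_manifest_path)
  assembly_manifest_path <- file.path(dir, "assembly_manifest.tsv")
  readr::write_tsv(out$assemblies, assembly_manifest_path)

  blast_path <- file.path(dir, "blast.tsv")
  b <- out$blast
  blast_lines <- sprintf(
    "%s\t%s\t%.2f\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%.3g\t%.1f\t%d",
    b$query_id, b$subject_id, b$percent_identity, 200L, 50L, 3L, 1L, 200L,
    1L, 200L, b$evalue, b$bit_score, as.integer(b$query_coverage)
  )
  writeLines(blast_lines, blast_path)
  blast_map_path <- file.path(dir, "blast_species.tsv")
  readr::write_tsv(
    tibble::tibble(subject_id = b$subject_id, species_name = b$species_name),
    blast_map_path
  )

  truth_assemblies_csv <- file.path(dir, "truth_assemblies.csv")
  truth_species_csv <- file.path(dir, "truth_species.csv")
  truth_blast_csv <- file.path(dir, "truth_blast.csv")
  readr::write_csv(out$truth_assemblies, truth_assemblies_csv)
  readr::write_csv(out$truth_species, truth_species_csv)
  readr::write_csv(out$truth_blast, truth_blast_csv)

  list(
    tblout_dir = tbl_dir, model_manifest = model_manifest_path,
    assembly_manifest = assembly_manifest_path, blast_path = blast_path,
    blast_species_map = blast_map_path,
    truth_assemblies_csv = truth_assemblies_csv,
    truth_species_csv = truth_species_csv, truth_blast_csv = truth_blast_csv,
    truth_assemblies = out$truth_assemblies,
    truth_species = out$truth_species, truth_blast = out$truth_blast
  )
}
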