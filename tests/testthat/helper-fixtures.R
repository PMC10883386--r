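# Shared fixture builders: in-memory spectra and noiseless run specs.

make_spectrum <- function(precursor_mz, rt, mz, intensity, scan = 1L) {
  list(scan = scan, precursor_mz = precursor_mz, rt = rt,
       mz = mz, intensity = intensity)
}

# A minimal run holding the given spectra (already a valid ms_run).
make_run <- function(spectra, label = "sample") {
  ms_run(spectra, label = label, source = "<memory>")
}

# Noiseless sample/control spec planting the given AHL descriptor rows.
noiseless_spec <- function(planted, seed = 1L, ...) {
  ms_run_spec(planted = planted, noise_sdlog = 0, chem_noise_lambda = 0,
              seed = seed, ...)
}

# Gaussian elution of a single compound as explicit spectra on a scan grid.
gaussian_compound_spectra <- function(mz, rt, width, apex, grid,
                                      fragments = c(102, 74),
                                      rel = c(1, 0.4)) {
  times <- grid[abs(grid - rt) <= 3 * width]
  lapply(seq_along(times), function(i) {
    scale <- apex * exp(-(times[i] - rt)^2 / (2 * width^2))
    make_spectrum(mz, times[i], fragments, scale * rel, scan = i)
  })
}

# Low-intensity scans of an unrelated precursor across the gradient, so an
# EIC has a baseline and the MAD noise floor reflects noise, not the peak.
baseline_spectra <- function(grid, precursor = 150, every = 0.5) {
  times <- grid[seq(1, length(grid), by = round(every / (grid[2] - grid[1])))]
  lapply(seq_along(times), function(i) {
    make_spectrum(precursor, times[i], c(60, 90), c(5, 3), scan = 1000L + i)
  })
}

# Random copy-number record table for dedup/summary oracle checks.
random_records <- function(n_species, max_assemblies = 3L) {
  rows <- lapply(seq_len(n_species), function(i) {
    k <- sample(max_assemblies, 1)
    tibble::tibble(
      assembly_id = sprintf("A%03d.%d", i, seq_len(k)),
      species_name = sprintf("Streptomyces sp%03d", i),
      luxI_count = sample(0:8, k, replace = TRUE),
      luxR_count = sample(0:200, k, replace = TRUE)
    )
  })
  out <- dplyr::bind_rows(rows)
  out$product <- out$luxI_count * out$luxR_count
  out[sample(nrow(out)), ]
}

# Brute-force dedup oracle: direct argmax scan, independent of dplyr grouping.
dedup_oracle <- function(records) {
  out <- lapply(split(records, records$species_name), function(g) {
    best <- g[1, ]
    for (i in seq_len(nrow(g))[-1]) {
      r <- g[i, ]
      better <- r$product > best$product ||
        (r$product == best$product && r$luxR_count > best$luxR_count) ||
        (r$product == best$product && r$luxR_count == best$luxR_count &&
           r$assembly_id < best$assembly_id)
      if (better) best <- r
    }
    best
  })
  res <- dplyr::bind_rows(out)
  res[order(res$species_name), ]
}
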