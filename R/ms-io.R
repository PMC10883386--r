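# MS/MS run container and readers for mzML (via mzR) and MGF.

#' Build an MS/MS run object
#'
#' A run is an ordered collection of product-ion (MS2) spectra with a role
#' label: `"sample"` for a culture extract, `"control"` for the uninoculated
#' medium extract acquired alongside it. Spectra are reordered by retention
#' time; precursors outside the acquisition mass range 120-450 m/z are kept
#' but flagged `in_range = FALSE`.
#'
#' @param spectra List of spectra, each a list with `scan` (id), `precursor_mz`,
#'   `rt` (minutes), and numeric vectors `mz` and `intensity` (fragments,
#'   sorted by m/z).
#' @param label `"sample"` or `"control"`.
#' @param source Path or description of origin.
#' @param mass_range Acquisition range used for the `in_range` flag.
#' @return An object of class `ms_run`.
#' @export
ms_run <- function(spectra, label = c("sample", "control"), source = NA_character_,
                   mass_range = c(120, 450)) {
  label <- match.arg(label)
  spectra <- lapply(spectra, function(sp) {
    stopifnot(is.numeric(sp$mz), is.numeric(sp$intensity),
              length(sp$mz) == length(sp$intensity))
    if (any(sp$mz <= 0) || any(sp$intensity < 0)) {
      stop("fragment m/z must be positive and intensities non-negative", call. = FALSE)
    }
    ord <- order(sp$mz)
    sp$mz <- sp$mz[ord]
    sp$intensity <- sp$intensity[ord]
    sp$in_range <- sp$precursor_mz >= mass_range[1] && sp$precursor_mz <= mass_range[2]
    sp
  })
  rts <- vapply(spectra, function(sp) sp$rt, numeric(1))
  structure(
    list(spectra = spectra[order(rts)], label = label, source = source,
         mass_range = mass_range),
    class = "ms_run"
  )
}

#' @export
print.ms_run <- function(x, ...) {
  cat(sprintf("<ms_run> %d MS2 spectra, label=%s, source=%s\n",
              length(x$spectra), x$label, x$source))
  invisible(x)
}

#' Number of spectra in a run
#' @param run An `ms_run`.
#' @return Integer scan count.
#' @export
n_spectra <- function(run) length(run$spectra)

#' Scan retention times of a run
#' @param run An `ms_run`.
#' @return Numeric vector of retention times (minutes), one per spectrum.
#' @export
scan_times <- function(run) vapply(run$spectra, function(sp) sp$rt, numeric(1))

#' Read an MS/MS run from mzML or MGF
#'
#' mzML is parsed with `mzR` (proteowizard backend); MGF with a plain-text
#' reader. Only MS2 scans with a selected precursor are kept; retention times
#' are normalised to minutes (mzML stores seconds, MGF `RTINSECONDS`).
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"mzML"` or `"MGF"`.
#' @param label Run role, `"sample"` or `"control"`.
#' @return An [ms_run()].
#' @export
read_ms_run <- function(path, format = c("auto", "mzML", "MGF"),
                        label = c("sample", "control")) {
  format <- match.arg(format)
  label <- match.arg(label)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, mzml = "mzML", mgf = "MGF",
                     stop(sprintf("cannot infer format from extension '.%s'", ext),
                          call. = FALSE))
  }
  spectra <- if (format == "mzML") .read_mzml(path) else .read_mgf(path)
  if (length(spectra) == 0L) {
    warning(sprintf("no MS2 spectra found in %s", path), call. = FALSE)
  }
  ms_run(spectra, label = label, source = path)
}

.read_mzml <- function(path) {
  handle <- mzR::openMSfile(path, backend = "pwiz")
  on.exit(mzR::close(handle), add = TRUE)
  hd <- mzR::header(handle)
  ms2 <- which(hd$msLevel == 2L & !is.na(hd$precursorMZ) & hd$precursorMZ > 0)
  lapply(ms2, function(i) {
    pk <- mzR::peaks(handle, i)
    list(
      scan = hd$seqNum[i],
      precursor_mz = hd$precursorMZ[i],
      rt = hd$retentionTime[i] / 60,
      mz = as.numeric(pk[, 1]),
      intensity = as.numeric(pk[, 2])
    )
  })
}

.read_mgf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stop(sprintf("empty MGF file: %s", path), call. = FALSE)
  begin <- grep("^BEGIN IONS\\s*$", lines)
  end <- grep("^END IONS\\s*$", lines)
  if (length(begin) != length(end) || any(end < begin)) {
    stop(sprintf("unbalanced BEGIN IONS/END IONS blocks in %s", path), call. = FALSE)
  }
  purrr::map2(begin, end, function(b, e) {
    block <- lines[(b + 1):(e - 1)]
    kv <- grep("^[A-Z]+=", block, value = TRUE)
    fields <- stats::setNames(
      sub("^[A-Z]+=", "", kv),
      sub("=.*$", "", kv)
    )
    if (is.na(fields["PEPMASS"])) {
      stop(sprintf("MGF block at line %d lacks PEPMASS", b), call. = FALSE)
    }
    peak_lines <- block[!grepl("^[A-Z]+=", block) & nzchar(trimws(block))]
    pk <- if (length(peak_lines)) {
      mat <- do.call(rbind, lapply(strsplit(trimws(peak_lines), "\\s+"), function(x) {
        v <- suppressWarnings(as.numeric(x[1:2]))
        if (anyNA(v)) stop(sprintf("malformed peak line in MGF block at line %d", b),
                           call. = FALSE)
        v
      }))
      mat
    } else {
      matrix(numeric(0), ncol = 2)
    }
    rt_sec <- suppressWarnings(as.numeric(fields["RTINSECONDS"]))
    list(
      scan = if (!is.na(fields["SCANS"])) as.integer(fields["SCANS"]) else NA_integer_,
      precursor_mz = as.numeric(strsplit(fields[["PEPMASS"]], "\\s+")[[1]][1]),
      rt = if (is.na(rt_sec)) NA_real_ else rt_sec / 60,
      mz = as.numeric(pk[, 1]),
      intensity = as.numeric(pk[, 2])
    )
  })
}

#' Convert a run to a long fragment table
#'
#' @param run An `ms_run`.
#' @return A tibble with one row per fragment peak: `scan`, `rt`,
#'   `precursor_mz`, `mz`, `intensity`.
#' @export
run_fragments <- function(run) {
  purrr::map_dfr(run$spectra, function(sp) {
    tibble::tibble(
      scan = sp$scan, rt = sp$rt, precursor_mz = sp$precursor_mz,
      mz = sp$mz, intensity = sp$intensity
    )
  })
}
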