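# Theoretical AHL mass library: descriptors, elemental formulas, [M+H]+ masses,
# enumeration and m/z annotation.

# Monoisotopic atomic masses (most abundant isotope) and the proton mass, in u.
.MONO_MASS <- c(C = 12, H = 1.0078250319, N = 14.0030740052, O = 15.9949146221)
.NOMINAL_MASS <- c(C = 12L, H = 1L, N = 14L, O = 16L)
.PROTON_MONO <- 1.00727646
.ELEMENTS <- c("C", "H", "N", "O")

#' Describe an acyl-homoserine lactone by its acyl chain
#'
#' An AHL is a homoserine-lactone ring amide-linked to a fatty acyl chain.
#' Within the straight-chain family the molecule is fully determined by the
#' number of acyl carbons `n`, whether the chain carries a 3-oxo substitution,
#' and the number of C=C double bonds.
#'
#' @param chain_length Integer number of carbons in the acyl chain (>= 2).
#' @param oxo3 Logical; `TRUE` for a 3-oxo substituted chain.
#' @param unsaturations Non-negative integer count of C=C double bonds; must
#'   not exceed `chain_length - 3` (a double bond needs two carbons beyond the
#'   carbonyl, and C2 chains admit none).
#' @return A list of class `acyl_descriptor` with the three validated fields.
#' @examples
#' acyl_descriptor(10)                      # C10-HSL
#' acyl_descriptor(14, oxo3 = TRUE, unsaturations = 1)  # Oxo-C14:1-HSL
#' @export
acyl_descriptor <- function(chain_length, oxo3 = FALSE, unsaturations = 0L) {
  chain_length <- as.integer(chain_length)
  unsaturations <- as.integer(unsaturations)
  if (length(chain_length) != 1L || is.na(chain_length) || chain_length < 2L) {
    stop("`chain_length` must be a single integer >= 2", call. = FALSE)
  }
  if (!is.logical(oxo3) || length(oxo3) != 1L || is.na(oxo3)) {
    stop("`oxo3` must be TRUE or FALSE", call. = FALSE)
  }
  if (length(unsaturations) != 1L || is.na(unsaturations) || unsaturations < 0L) {
    stop("`unsaturations` must be a single non-negative integer", call. = FALSE)
  }
  max_unsat <- max(chain_length - 3L, 0L)
  if (unsaturations > max_unsat) {
    stop(sprintf(
      "a C%d acyl chain admits at most %d double bond(s), got %d",
      chain_length, max_unsat, unsaturations
    ), call. = FALSE)
  }
  structure(
    list(chain_length = chain_length, oxo3 = oxo3, unsaturations = unsaturations),
    class = "acyl_descriptor"
  )
}

#' @export
print.acyl_descriptor <- function(x, ...) {
  cat("<acyl_descriptor>", ahl_name(x), "\n")
  invisible(x)
}

#' @export
format.acyl_descriptor <- function(x, ...) ahl_name(x)

#' Canonical AHL name for a descriptor
#'
#' Names follow the field convention: `"Cn-HSL"`, `"Oxo-Cn-HSL"` and
#' `"Oxo-Cn:u-HSL"` / `"Cn:u-HSL"` when double bonds are present.
#'
#' @param descriptor An [acyl_descriptor()].
#' @return A character scalar such as `"Oxo-C14:1-HSL"`.
#' @export
ahl_name <- function(descriptor) {
  stopifnot(inherits(descriptor, "acyl_descriptor"))
  core <- if (descriptor$unsaturations > 0L) {
    sprintf("C%d:%d", descriptor$chain_length, descriptor$unsaturations)
  } else {
    sprintf("C%d", descriptor$chain_length)
  }
  paste0(if (descriptor$oxo3) "Oxo-" else "", core, "-HSL")
}

#' Elemental formula of an AHL
#'
#' A saturated unsubstituted AHL with `n` acyl carbons is C(n+4) H(2n+5) N O3
#' (four ring carbons plus the chain; one ring nitrogen; two lactone oxygens
#' plus the amide oxygen). The 3-oxo substitution adds one O and removes two H;
#' each C=C double bond removes two H.
#'
#' @param descriptor An [acyl_descriptor()].
#' @return A named integer vector over elements C, H, N, O, of class
#'   `ahl_formula`.
#' @examples
#' formula_of(acyl_descriptor(4))   # C8H13NO3, butanoyl-HSL
#' @export
formula_of <- function(descriptor) {
  stopifnot(inherits(descriptor, "acyl_descriptor"))
  n <- descriptor$chain_length
  counts <- c(
    C = n + 4L,
    H = 2L * n + 5L - 2L * as.integer(descriptor$oxo3) - 2L * descriptor$unsaturations,
    N = 1L,
    O = 3L + as.integer(descriptor$oxo3)
  )
  structure(counts, class = "ahl_formula")
}

#' Construct an elemental formula directly
#'
#' @param C,H,N,O Non-negative integer atom counts.
#' @return A named integer vector of class `ahl_formula`.
#' @export
elemental_formula <- function(C = 0L, H = 0L, N = 0L, O = 0L) {
  counts <- c(C = as.integer(C), H = as.integer(H), N = as.integer(N), O = as.integer(O))
  if (anyNA(counts) || any(counts < 0L)) {
    stop("atom counts must be non-negative integers", call. = FALSE)
  }
  structure(counts, class = "ahl_formula")
}

#' @export
format.ahl_formula <- function(x, ...) {
  parts <- vapply(.ELEMENTS, function(el) {
    k <- unclass(x)[[el]]
    if (k == 0L) "" else if (k == 1L) el else paste0(el, k)
  }, character(1))
  paste0(parts, collapse = "")
}

#' @export
print.ahl_formula <- function(x, ...) {
  cat("<ahl_formula>", format(x), "\n")
  invisible(x)
}

#' Parse a Hill-style formula string over C, H, N, O
#'
#' @param x String such as `"C14H25NO3"`.
#' @return An `ahl_formula`.
#' @export
parse_formula <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  m <- gregexpr("([CHNO])([0-9]*)", x)[[1]]
  toks <- regmatches(x, gregexpr("([CHNO])([0-9]*)", x))[[1]]
  if (sum(attr(m, "match.length")) != nchar(x)) {
    stop(sprintf("cannot parse formula '%s' (elements beyond CHNO?)", x), call. = FALSE)
  }
  counts <- c(C = 0L, H = 0L, N = 0L, O = 0L)
  for (tok in toks) {
    el <- substr(tok, 1, 1)
    k <- substr(tok, 2, nchar(tok))
    counts[[el]] <- counts[[el]] + if (nzchar(k)) as.integer(k) else 1L
  }
  structure(counts, class = "ahl_formula")
}

.check_formula <- function(formula) {
  if (!inherits(formula, "ahl_formula")) formula <- do.call(elemental_formula, as.list(formula))
  if (unclass(formula)[["C"]] < 1L) stop("formula must contain at least one carbon", call. = FALSE)
  formula
}

#' Nominal protonated mass [M+H]+
#'
#' Sum of integer atomic masses (C=12, H=1, N=14, O=16) plus 1 for the proton,
#' the unit-resolution mass a triple-quadrupole instrument reports.
#'
#' @param formula An `ahl_formula` (or named vector with C, H, N, O counts).
#' @return Integer m/z.
#' @examples
#' nominal_mh(formula_of(acyl_descriptor(10)))  # 256
#' @export
nominal_mh <- function(formula) {
  formula <- .check_formula(formula)
  as.integer(sum(unclass(formula)[.ELEMENTS] * .NOMINAL_MASS[.ELEMENTS]) + 1L)
}

#' Monoisotopic protonated mass [M+H]+
#'
#' Sum of most-abundant-isotope exact masses plus the proton mass, for
#' high-resolution matching.
#'
#' @inheritParams nominal_mh
#' @return Numeric m/z in Th.
#' @export
monoisotopic_mh <- function(formula) {
  formula <- .check_formula(formula)
  sum(unclass(formula)[.ELEMENTS] * .MONO_MASS[.ELEMENTS]) + .PROTON_MONO
}

#' Enumerate the theoretical AHL library
#'
#' One entry per valid acyl descriptor over the Cartesian range of chain
#' length, 3-oxo state and unsaturation count. Defaults cover the common
#' straight-chain family from C4 to C18 with up to two double bonds, which
#' spans all nine commercial standards used to establish the m/z 102 daughter
#' ion as well as longer predicted species. 3-hydroxy variants (+O, same H)
#' are off by default and can be enabled.
#'
#' @param n_min,n_max Inclusive chain-length bounds, 2 <= n_min <= n_max <= 20.
#' @param allow_oxo Include 3-oxo variants.
#' @param max_unsat Maximum number of C=C double bonds per entry.
#' @param allow_hydroxy Also include 3-hydroxy variants (rare; default off).
#' @return A tibble of class `ahl_library`, sorted by `nominal_mh` then name,
#'   with columns `name`, `n`, `oxo`, `hydroxy`, `unsat`, `formula`,
#'   `nominal_mh`, `monoisotopic_mh`.
#' @examples
#' build_library(4, 12, allow_oxo = TRUE, max_unsat = 0)  # 18 entries
#' @export
build_library <- function(n_min = 4L, n_max = 18L, allow_oxo = TRUE,
                          max_unsat = 2L, allow_hydroxy = FALSE) {
  n_min <- as.integer(n_min); n_max <- as.integer(n_max)
  if (is.na(n_min) || is.na(n_max) || n_min < 2L || n_max > 20L || n_min > n_max) {
    stop("need 2 <= n_min <= n_max <= 20", call. = FALSE)
  }
  if (max_unsat < 0L) stop("`max_unsat` must be >= 0", call. = FALSE)
  mods <- c("none", if (allow_oxo) "oxo", if (allow_hydroxy) "hydroxy")
  grid <- expand.grid(
    n = seq(n_min, n_max), mod = mods, unsat = 0:max_unsat,
    stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE
  )
  grid <- grid[grid$unsat <= pmax(grid$n - 3L, 0L), , drop = FALSE]
  rows <- purrr::pmap(grid, function(n, mod, unsat) {
    d <- acyl_descriptor(n, oxo3 = identical(mod, "oxo"), unsaturations = unsat)
    f <- formula_of(d)
    nm <- ahl_name(d)
    if (identical(mod, "hydroxy")) {
      f <- elemental_formula(C = f[["C"]], H = f[["H"]], N = f[["N"]], O = f[["O"]] + 1L)
      nm <- sub("^", "OH-", nm)
    }
    tibble::tibble(
      name = nm, n = as.integer(n), oxo = identical(mod, "oxo"),
      hydroxy = identical(mod, "hydroxy"), unsat = as.integer(unsat),
      formula = format(f), nominal_mh = nominal_mh(f),
      monoisotopic_mh = monoisotopic_mh(f)
    )
  })
  lib <- dplyr::bind_rows(rows)
  lib <- dplyr::arrange(lib, .data$nominal_mh, .data$name)
  attr(lib, "params") <- list(
    n_min = n_min, n_max = n_max, allow_oxo = allow_oxo,
    max_unsat = as.integer(max_unsat), allow_hydroxy = allow_hydroxy
  )
  class(lib) <- c("ahl_library", class(lib))
  lib
}

#' Annotate an observed m/z against the library
#'
#' Returns every library entry within `tolerance` of `query_mz` in the chosen
#' mass mode, ranked by absolute mass error. An empty result is a valid
#' outcome: the observed mass may not belong to the straight-chain family at
#' all. Nominal mode at +/-0.5 suits unit-resolution triple-quadrupole data;
#' monoisotopic mode with a tight tolerance suits high-resolution instruments.
#'
#' @param query_mz Observed m/z.
#' @param library An `ahl_library` from [build_library()].
#' @param tolerance Match window in m/z units; must be positive.
#' @param mode `"nominal"` or `"monoisotopic"`.
#' @return A tibble with the matching library rows plus `query_mz`,
#'   `mass_error` (signed, query minus theory) and `tolerance`, ordered by
#'   `abs(mass_error)`. Nominal isomers (equal mass error) are all reported;
#'   among them even chain lengths rank first -- acyl chains are assembled
#'   from C2 units, so even-length chains dominate in nature -- then fewer
#'   double bonds, then name.
#' @examples
#' lib <- build_library()
#' annotate_mz(256, lib)$name[1]  # "C10-HSL"
#' @export
annotate_mz <- function(query_mz, library, tolerance = 0.5,
                        mode = c("nominal", "monoisotopic")) {
  mode <- match.arg(mode)
  if (!is.numeric(tolerance) || length(tolerance) != 1L || tolerance <= 0) {
    stop("`tolerance` must be a single positive number", call. = FALSE)
  }
  stopifnot(is.numeric(query_mz), length(query_mz) == 1L)
  ref <- if (mode == "nominal") library$nominal_mh else library$monoisotopic_mh
  err <- query_mz - ref
  keep <- abs(err) <= tolerance
  out <- tibble::as_tibble(library[keep, , drop = FALSE])
  out$query_mz <- query_mz
  out$mass_error <- err[keep]
  out$tolerance <- tolerance
  dplyr::arrange(out, abs(.data$mass_error), .data$n %% 2L, .data$unsat,
                 .data$name)
}

#' Write / read an AHL library as CSV
#'
#' Plain CSV with the library columns; generation parameters are not
#' persisted in this format.
#'
#' @param library An `ahl_library`.
#' @param path Output file.
#' @return `path`, invisibly (writer); the library tibble (reader).
#' @export
write_library_csv <- function(library, path) {
  readr::write_csv(tibble::as_tibble(library), path)
  invisible(path)
}

#' @rdname write_library_csv
#' @export
read_library_csv <- function(path) {
  lib <- readr::read_csv(
    path,
    col_types = readr::cols(
      name = "c", n = "i", oxo = "l", hydroxy = "l", unsat = "i",
      formula = "c", nominal_mh = "i", monoisotopic_mh = "d"
    )
  )
  class(lib) <- c("ahl_library", class(lib))
  lib
}

#' Write / read an AHL library as JSON
#'
#' JSON round-trips the generation parameters alongside the entries.
#'
#' @inheritParams write_library_csv
#' @export
write_library_json <- function(library, path) {
  jsonlite::write_json(
    list(params = attr(library, "params"), entries = tibble::as_tibble(library)),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_library_json
#' @export
read_library_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  lib <- tibble::as_tibble(obj$entries)
  lib$n <- as.integer(lib$n)
  lib$unsat <- as.integer(lib$unsat)
  lib$nominal_mh <- as.integer(lib$nominal_mh)
  attr(lib, "params") <- obj$params
  class(lib) <- c("ahl_library", class(lib))
  lib
}
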