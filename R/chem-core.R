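# Molecular-formula parsing and monoisotopic mass/adduct arithmetic.
# All downstream m/z matching rests on these constants, so they are pinned
# in source (principal-isotope masses, >= 6 decimal places) rather than
# taken from a runtime dependency.

# Principal-isotope (monoisotopic) atomic masses, Da. 12C is exactly 12 by
# definition; the rest are IUPAC/CODATA values.
.element_masses <- c(
  C  = 12,
  H  = 1.00782503207,
  O  = 15.99491461956,
  N  = 14.0030740048,
  P  = 30.97376163,
  S  = 31.97207100,
  F  = 18.99840322,
  Cl = 34.96885268,
  Br = 78.9183371,
  Si = 27.9769265325
)

# Proton mass (H atom minus electron), Da. [M+Cl]- gains a Cl atom plus an
# electron.
.proton_mass   <- 1.007276
.chloride_mass <- 34.969402

#' Supported elements
#'
#' Element symbols accepted by [parse_formula()], with their principal-isotope
#' (monoisotopic) masses in Da. The set covers the elements used for formula
#' generation in electrospray small-molecule screening (C, H, O, N, P, S, F,
#' Cl, Br) plus Si, which occurs in common textile-related siloxanes.
#'
#' @return Named numeric vector of monoisotopic masses (Da).
#' @export
#' @examples
#' element_masses()[["C"]]  # exactly 12
element_masses <- function() .element_masses

#' Parse a molecular formula
#'
#' Parses a Hill-notation formula string (element symbols each optionally
#' followed by a positive integer count; no isotopes, charges or parentheses)
#' into a `molformula` object: a named integer vector of element counts.
#'
#' @param text Formula string, e.g. `"C6H4N2O5"`.
#' @return A `molformula`: named integer vector, names are element symbols.
#' @export
#' @examples
#' parse_formula("C6H4N2O5")
#' parse_formula("CHF3O3S")
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(text))
    stop("formula must be a single non-empty string")
  tokens <- regmatches(text, gregexpr("[A-Z][a-z]?[0-9]*", text))[[1]]
  if (!identical(paste0(tokens, collapse = ""), text))
    stop("malformed formula '", text, "': unparseable text near '",
         sub(paste0("^\\Q", paste0(tokens, collapse = ""), "\\E"), "", text), "'")
  counts <- integer(0)
  for (tok in tokens) {
    elem <- sub("[0-9]*$", "", tok)
    ndig <- sub("^[A-Za-z]+", "", tok)
    if (!elem %in% names(.element_masses))
      stop("unknown element symbol '", elem, "' in formula '", text, "'")
    n <- if (nzchar(ndig)) as.integer(ndig) else 1L
    if (n < 1L)
      stop("zero count for element '", elem, "' in formula '", text, "'")
    counts[elem] <- (if (elem %in% names(counts)) counts[[elem]] else 0L) + n
  }
  structure(counts, class = "molformula")
}

#' Format a molecular formula in Hill order
#'
#' Hill order: C first, then H, then the remaining elements alphabetically
#' (alphabetical throughout if no carbon). A count of 1 is omitted.
#'
#' @param f A `molformula` (or named count vector).
#' @return Formula string.
#' @export
format_formula <- function(f) {
  counts <- unclass(f)
  elems <- names(counts)
  if ("C" %in% elems) {
    ord <- c(intersect(c("C", "H"), elems), sort(setdiff(elems, c("C", "H"))))
  } else {
    ord <- sort(elems)
  }
  paste0(vapply(ord, function(e) {
    n <- counts[[e]]
    if (n == 1L) e else paste0(e, n)
  }, character(1)), collapse = "")
}

#' @export
print.molformula <- function(x, ...) {
  cat("<molformula>", format_formula(x), "\n")
  invisible(x)
}

#' Monoisotopic neutral mass
#'
#' Sum over elements of count times the principal-isotope mass.
#'
#' @param f A `molformula`, or a formula string (parsed on the fly).
#' @return Neutral monoisotopic mass, Da.
#' @export
#' @examples
#' monoisotopic_mass("C6H4N2O5")  # 184.0120
monoisotopic_mass <- function(f) {
  if (is.character(f)) f <- parse_formula(f)
  counts <- unclass(f)
  sum(counts * .element_masses[names(counts)])
}

#' Adduct registry
#'
#' The adducts supported by the workflow: protonation in positive mode,
#' deprotonation and chloride attachment in negative mode. Charge states
#' beyond |z| = 1 and molecular ions \[M\]+ are out of scope.
#'
#' @return data.frame with columns `name`, `mass_shift` (Da, signed) and
#'   `polarity`.
#' @export
adducts <- function() {
  data.frame(
    name = c("[M+H]+", "[M-H]-", "[M+Cl]-"),
    mass_shift = c(.proton_mass, -.proton_mass, .chloride_mass),
    polarity = c("positive", "negative", "negative"),
    stringsAsFactors = FALSE
  )
}

.adduct_shift <- function(adduct) {
  reg <- adducts()
  i <- match(adduct, reg$name)
  if (is.na(i)) stop("unknown adduct '", adduct, "'; supported: ",
                     paste(reg$name, collapse = ", "))
  reg$mass_shift[i]
}

#' Adduct m/z from a neutral mass
#'
#' @param neutral_mass Neutral monoisotopic mass, Da (> 0).
#' @param adduct Adduct name: `"[M+H]+"`, `"[M-H]-"` or `"[M+Cl]-"`.
#' @return m/z of the singly charged ion, Da.
#' @export
#' @examples
#' adduct_mz(240.0746, "[M-H]-")  # 239.0673
adduct_mz <- function(neutral_mass, adduct) {
  stopifnot(all(neutral_mass > 0))
  neutral_mass + .adduct_shift(adduct)
}

#' Neutral mass from an adduct m/z
#'
#' Inverse of [adduct_mz()].
#'
#' @param mz Measured m/z, Da.
#' @param adduct Adduct name.
#' @return Neutral mass, Da.
#' @export
neutral_from_mz <- function(mz, adduct) {
  mz - .adduct_shift(adduct)
}

#' Mass error between observed and theoretical m/z
#'
#' @param observed Observed m/z, Da.
#' @param theoretical Theoretical m/z, Da (> 0).
#' @return data.frame with `observed_mz`, `theoretical_mz`, `error_mda`
#'   (signed, mDa) and `error_ppm` (signed, ppm).
#' @export
#' @examples
#' mass_error(239.0677, 239.0673)
mass_error <- function(observed, theoretical) {
  stopifnot(all(theoretical > 0))
  d <- observed - theoretical
  data.frame(
    observed_mz = observed,
    theoretical_mz = theoretical,
    error_mda = d * 1000,
    error_ppm = d / theoretical * 1e6
  )
}

# Round half away from zero (base round() is round-half-even); used for all
# reported masses and metrics so printed values match field convention.
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
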