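# Elemental-formula arithmetic and mass computation.
#
# Three mass modes are carried everywhere:
#   monoisotopic - exact mass of the most abundant isotope per element
#   average      - abundance-weighted standard atomic weight
#   nominal      - integer mass number of the most abundant isotope
# Mixing modes in arithmetic is a hard error (the classic MS bug).

# IUPAC 2021 values; nominal = mass number of the most abundant isotope.
# Element order is Hill order (C, H, then alphabetical), which formatting
# relies on.
.ATOMIC_MASS <- list(
  monoisotopic = c(
    C = 12.0,        H = 1.00782503207, I = 126.904473,
    N = 14.0030740048, O = 15.9949146196, P = 30.97376163,
    S = 31.97207100
  ),
  average = c(
    C = 12.011, H = 1.008,         I = 126.90447,
    N = 14.007, O = 15.999,        P = 30.973761998,
    S = 32.06
  ),
  nominal = c(C = 12, H = 1, I = 127, N = 14, O = 16, P = 31, S = 32)
)

.ELEMENTS <- names(.ATOMIC_MASS$monoisotopic)

.MASS_MODES <- c("monoisotopic", "average", "nominal")

# Proton mass used when converting neutral mass to m/z; integral in
# nominal mode so nominal ions stay integers.
.PROTON <- c(monoisotopic = 1.00727646688, average = 1.00727646688,
             nominal = 1)

#' Parse an elemental formula string
#'
#' Accepts the usual condensed notation, e.g. `"C6H13NO3"` or `"H2O"`;
#' an omitted count means 1. Supported elements: C, H, N, O, S, P, I.
#'
#' @param text Formula string.
#' @return An object of class `chem_formula`: a named integer vector of
#'   element counts in Hill order (C, H, then alphabetical).
#' @examples
#' parse_formula("C6H13NO3")
#' parse_formula("H2O") + parse_formula("CO")
#' @export
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  if (text == "") return(chem_formula(integer(0)))
  tokens <- gregexpr("[A-Z][a-z]?[0-9]*", text)[[1]]
  matched <- regmatches(text, list(tokens))[[1]]
  if (sum(attr(tokens, "match.length")) != nchar(text)) {
    stop("malformed formula: ", sQuote(text))
  }
  el <- sub("[0-9]*$", "", matched)
  n <- sub("^[A-Za-z]+", "", matched)
  n <- ifelse(n == "", 1L, as.integer(n))
  unknown <- setdiff(el, .ELEMENTS)
  if (length(unknown)) {
    stop("unknown element symbol: ", paste(unknown, collapse = ", "))
  }
  counts <- tapply(n, factor(el, levels = .ELEMENTS), sum)
  counts[is.na(counts)] <- 0L
  chem_formula(stats::setNames(as.integer(counts), .ELEMENTS))
}

#' Construct a chem_formula from a named count vector
#'
#' @param counts Named integer vector (names are element symbols);
#'   missing elements are taken as zero.
#' @return A `chem_formula`.
#' @export
chem_formula <- function(counts = integer(0)) {
  full <- stats::setNames(integer(length(.ELEMENTS)), .ELEMENTS)
  if (length(counts)) {
    unknown <- setdiff(names(counts), .ELEMENTS)
    if (length(unknown)) {
      stop("unknown element symbol: ", paste(unknown, collapse = ", "))
    }
    if (any(counts < 0)) stop("negative element count")
    full[names(counts)] <- as.integer(counts)
  }
  structure(full, class = "chem_formula")
}

#' Format a chem_formula as a condensed string
#'
#' Hill order; count 1 is implicit; the empty formula formats as `""`.
#' `parse_formula(format_formula(f))` is the identity.
#'
#' @param f A `chem_formula`.
#' @return A string.
#' @export
format_formula <- function(f) {
  stopifnot(inherits(f, "chem_formula"))
  counts <- unclass(f)
  nz <- counts[counts > 0]
  if (!length(nz)) return("")
  paste0(names(nz), ifelse(nz == 1L, "", nz), collapse = "")
}

#' @export
print.chem_formula <- function(x, ...) {
  cat("<chem_formula> ", format_formula(x), "\n", sep = "")
  invisible(x)
}

#' @export
Ops.chem_formula <- function(e1, e2) {
  if (!.Generic %in% c("+", "-", "==")) {
    stop("operation ", sQuote(.Generic), " not defined for formulas")
  }
  if (.Generic == "==") return(all(unclass(e1) == unclass(e2)))
  stopifnot(inherits(e1, "chem_formula"), inherits(e2, "chem_formula"))
  out <- unclass(e1) + if (.Generic == "+") unclass(e2) else -unclass(e2)
  if (any(out < 0)) {
    bad <- names(out)[out < 0]
    stop("subtraction drives element count negative: ",
         paste(bad, collapse = ", "))
  }
  structure(as.integer(out), names = names(out), class = "chem_formula")
}

.check_mode <- function(mode) {
  match.arg(mode, .MASS_MODES)
}

#' A mass value carrying its mode
#'
#' @param value Mass in daltons.
#' @param mode One of `"monoisotopic"`, `"average"`, `"nominal"`.
#' @return A `mass_value` (numeric with a `mode` attribute). Addition and
#'   subtraction of two `mass_value`s require matching modes.
#' @export
mass_value <- function(value, mode) {
  mode <- .check_mode(mode)
  if (mode == "nominal" && any(value != round(value))) {
    stop("nominal mass must be an integer")
  }
  structure(as.numeric(value), mode = mode, class = "mass_value")
}

#' @export
print.mass_value <- function(x, ...) {
  cat(format(as.numeric(x)), " Da (", attr(x, "mode"), ")\n", sep = "")
  invisible(x)
}

#' Mode of a mass value
#' @param x A `mass_value`.
#' @return The mode string.
#' @export
mass_mode <- function(x) attr(x, "mode")

#' @export
Ops.mass_value <- function(e1, e2) {
  if (missing(e2)) return(get(.Generic)(as.numeric(e1)))
  both <- inherits(e1, "mass_value") && inherits(e2, "mass_value")
  if (both && .Generic %in% c("+", "-")) {
    if (attr(e1, "mode") != attr(e2, "mode")) {
      stop("mixed-mode mass arithmetic: ", attr(e1, "mode"), " vs ",
           attr(e2, "mode"))
    }
    return(mass_value(get(.Generic)(as.numeric(e1), as.numeric(e2)),
                      attr(e1, "mode")))
  }
  get(.Generic)(as.numeric(e1), as.numeric(e2))
}

#' Mass of an elemental formula
#'
#' @param f A `chem_formula` or formula string.
#' @param mode Mass mode.
#' @return A [mass_value()]. The empty formula has mass 0 in every mode.
#' @examples
#' formula_mass("C5H8O2", "nominal")   # 100, the Boc neutral loss
#' formula_mass("H2O", "monoisotopic") # 18.0106
#' @export
formula_mass <- function(f, mode = "monoisotopic") {
  if (is.character(f)) f <- parse_formula(f)
  stopifnot(inherits(f, "chem_formula"))
  mode <- .check_mode(mode)
  tbl <- .ATOMIC_MASS[[mode]]
  mass_value(sum(tbl[names(f)] * as.numeric(f)), mode)
}

#' m/z of a protonated or deprotonated ion
#'
#' `(M + z*p)/z` for `[M + zH]z+`, `(M - z*p)/z` for `[M - zH]z-`, with a
#' proton mass consistent with the mode (exactly 1 in nominal mode).
#'
#' @param neutral A [mass_value()] (or numeric, with `mode` supplied).
#' @param ion `"M_plus_H"` or `"M_minus_H"`.
#' @param charge Positive integer charge state.
#' @param mode Required when `neutral` is a bare numeric.
#' @return m/z as a plain numeric.
#' @examples
#' ion_mz(formula_mass("C6H13NO3", "nominal"), "M_plus_H")  # 148
#' @export
ion_mz <- function(neutral, ion = c("M_plus_H", "M_minus_H"), charge = 1L,
                   mode = NULL) {
  ion <- match.arg(ion)
  if (!is.numeric(charge) || length(charge) != 1L || charge < 1 ||
      charge != round(charge)) {
    stop("invalid charge state: charge must be a positive integer")
  }
  if (inherits(neutral, "mass_value")) {
    mode <- attr(neutral, "mode")
  } else {
    if (is.null(mode)) stop("mode required for a bare numeric mass")
    mode <- .check_mode(mode)
  }
  p <- .PROTON[[mode]]
  sign <- if (ion == "M_plus_H") 1 else -1
  (as.numeric(neutral) + sign * charge * p) / charge
}

# --- modifications ---------------------------------------------------------

# Signed element deltas for the two modifications observed in intact-mass
# spectra: loss of the tert-butoxycarbonyl group (-C5H8O2, the -100 Da
# satellite) and reduction of an aryl azide to the amine (-N2 +H2).
.MODIFICATIONS <- list(
  boc_loss        = list(minus = c(C = 5L, H = 8L, O = 2L), plus = c()),
  azide_reduction = list(minus = c(N = 2L), plus = c(H = 2L))
)

#' Known modification deltas
#'
#' @param name `"boc_loss"` (−C5H8O2) or `"azide_reduction"` (−N2 +H2).
#' @return A list with `name`, `minus` and `plus` `chem_formula`s.
#' @export
modification_delta <- function(name = c("boc_loss", "azide_reduction")) {
  name <- match.arg(name)
  d <- .MODIFICATIONS[[name]]
  list(name = name, minus = chem_formula(d$minus), plus = chem_formula(d$plus))
}

#' Apply a modification delta to a formula
#'
#' Errors when the subtraction would drive an element count negative,
#' i.e. the modification is chemically impossible on the input.
#'
#' @param f A `chem_formula`.
#' @param mod Result of [modification_delta()] or a modification name.
#' @return The modified `chem_formula`.
#' @export
apply_modification <- function(f, mod) {
  if (is.character(mod)) mod <- modification_delta(mod)
  stopifnot(inherits(f, "chem_formula"))
  f - mod$minus + mod$plus
}

#' Mass shift of a modification
#'
#' @param mod Modification name or [modification_delta()] result.
#' @param mode Mass mode.
#' @return Signed mass shift in daltons (plain numeric).
#' @export
modification_shift <- function(mod, mode = "monoisotopic") {
  if (is.character(mod)) mod <- modification_delta(mod)
  as.numeric(formula_mass(mod$plus, mode)) -
    as.numeric(formula_mass(mod$minus, mode))
}
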