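# Monomer registry: canonical amino acids, non-canonical amino acids
# (compounds 1-5) and alpha hydroxy acids (compounds 6-16).

.registry_cache <- new.env(parent = emptyenv())

#' Load a monomer registry
#'
#' Reads a TSV with columns `id`, `name`, `formula`, `backbone_link`,
#' `side_chain_class` ('#' comments allowed). With no argument, returns
#' the registry shipped with the package: the 20 canonical amino acids
#' plus compounds 1--16 (five non-canonical amino acids and eleven alpha
#' hydroxy acids). Free-monomer formulas include the monomer's own H2O;
#' hydroxy acids carry `backbone_link = "ester"`.
#'
#' @param path Optional path to a registry TSV.
#' @return A data frame of class `monomer_registry`, row names = `id`.
#' @export
monomer_registry <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.registry_cache$default)) return(.registry_cache$default)
    path <- system.file("extdata", "monomers.tsv", package = "depsicode",
                        mustWork = TRUE)
    default <- TRUE
  } else default <- FALSE
  reg <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  needed <- c("id", "name", "formula", "backbone_link", "side_chain_class")
  missing_cols <- setdiff(needed, names(reg))
  if (length(missing_cols)) {
    stop("registry is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(reg$id)) stop("duplicate monomer id in registry")
  bad <- !reg$backbone_link %in% c("amide", "ester")
  if (any(bad)) stop("invalid backbone_link for: ",
                     paste(reg$id[bad], collapse = ", "))
  # validate formulas eagerly so a broken registry fails at load
  lapply(reg$formula, parse_formula)
  rownames(reg) <- reg$id
  class(reg) <- c("monomer_registry", "data.frame")
  if (default) .registry_cache$default <- reg
  reg
}

.monomer_idx <- function(ids, registry) {
  idx <- match(ids, registry$id)
  if (anyNA(idx)) {
    stop("monomer(s) missing from registry: ",
         paste(unique(ids[is.na(idx)]), collapse = ", "))
  }
  idx
}

.lookup_monomer <- function(ids, registry) {
  registry[.monomer_idx(ids, registry), , drop = FALSE]
}

#' Free-monomer formula from the registry
#'
#' @param id Monomer id (e.g. `"G"`, `"6"`, `"15"`).
#' @param registry A [monomer_registry()].
#' @return A `chem_formula`.
#' @export
monomer_formula <- function(id, registry = monomer_registry()) {
  parse_formula(.lookup_monomer(id, registry)$formula)
}

#' Residue formula (free monomer minus H2O)
#'
#' The condensation residue: one H2O is lost per backbone bond, amide and
#' ester alike, so the same subtraction applies to every monomer class.
#'
#' @inheritParams monomer_formula
#' @return A `chem_formula`.
#' @export
residue_formula <- function(id, registry = monomer_registry()) {
  monomer_formula(id, registry) - parse_formula("H2O")
}

#' Residue mass of a monomer
#'
#' @inheritParams monomer_formula
#' @param mode Mass mode.
#' @return A [mass_value()].
#' @examples
#' residue_mass("G")                    # 57.0215
#' residue_mass("14", mode = "average") # phenyllactic acid residue
#' @export
residue_mass <- function(id, mode = "monoisotopic",
                         registry = monomer_registry()) {
  formula_mass(residue_formula(id, registry), mode)
}

# Vector of residue masses (plain numeric) for an id sequence; the hot
# path used by species_mass and fragment theory. Parsed formula masses
# are memoized per (formula, mode).
.mass_memo <- new.env(parent = emptyenv())

.free_mass <- function(formula, mode) {
  key <- paste0(formula, "|", mode)
  hit <- .mass_memo[[key]]
  if (!is.null(hit)) return(hit)
  val <- as.numeric(formula_mass(formula, mode))
  .mass_memo[[key]] <- val
  val
}

.residue_masses <- function(ids, mode, registry) {
  formulas <- registry$formula[.monomer_idx(ids, registry)]
  vapply(formulas, .free_mass, numeric(1), mode = mode,
         USE.NAMES = FALSE) - .free_mass("H2O", mode)
}

#' Is a monomer ester-linked (an alpha hydroxy acid)?
#'
#' @inheritParams monomer_formula
#' @return Logical vector.
#' @export
is_ester_monomer <- function(id, registry = monomer_registry()) {
  registry$backbone_link[.monomer_idx(id, registry)] == "ester"
}
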