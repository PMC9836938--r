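# Macrocycle templates, cyclic species and mass accounting.
#
# A template is an ordered slot list with exactly one A and one B
# placeholder; instantiating it under a reassignment scheme substitutes
# the scheme's monomers. Ring bond i joins monomer i to monomer i+1
# (wrapping); a bond is an ester iff its ACCEPTOR monomer (i+1) is an
# alpha hydroxy acid, whose alpha-OH esterifies the preceding monomer's
# carbonyl. Hydrolysis therefore splits N-terminal | hydroxy-acid.

#' Define a macrocycle template
#'
#' @param name Template label (e.g. user-configured SanA- or YM-inspired
#'   sequences in their AB and BA variants).
#' @param slots Character vector over canonical one-letter residue codes
#'   plus the placeholders `"A"` and `"B"` (exactly one of each;
#'   ring length at least 3). Because `"A"` doubles as alanine's code,
#'   templates use placeholders, never direct monomer ids, for the two
#'   programmed positions.
#' @return A list of class `macrocycle_template`.
#' @examples
#' macrocycle_template("demo", c("L", "A", "V", "B", "C"))
#' @export
macrocycle_template <- function(name, slots) {
  stopifnot(is.character(slots))
  if (length(slots) < 3L) stop("template ring must have length >= 3")
  if (sum(slots == "A") != 1L || sum(slots == "B") != 1L) {
    stop("template must contain exactly one A and one B placeholder")
  }
  structure(list(name = name, slots = slots), class = "macrocycle_template")
}

#' Instantiate a template under a reassignment scheme
#'
#' Replaces the A and B placeholders by the scheme's monomers and derives
#' the ester bond positions from the monomers' backbone link types.
#'
#' @param template A [macrocycle_template()].
#' @param scheme A [reassignment_scheme()].
#' @param registry A [monomer_registry()].
#' @return A [cyclic_species()].
#' @export
instantiate <- function(template, scheme, registry = monomer_registry()) {
  stopifnot(inherits(template, "macrocycle_template"),
            inherits(scheme, "reassignment_scheme"))
  ids <- template$slots
  ids[ids == "A"] <- scheme$monomer_A
  ids[ids == "B"] <- scheme$monomer_B
  cyclic_species(ids, registry = registry,
                 name = paste0(template$name, "_", scheme$scheme_id))
}

#' An ordered ring of monomers
#'
#' @param monomers Character vector of registry monomer ids, read as a
#'   head-to-tail ring (no termini).
#' @param registry A [monomer_registry()].
#' @param name Optional label.
#' @return A list of class `cyclic_species` with elements `monomers`,
#'   `ester_positions` (1-based ring bond indices, bond i joining monomer
#'   i to i+1 with wrap-around) and `name`.
#' @export
cyclic_species <- function(monomers, registry = monomer_registry(),
                           name = NULL) {
  stopifnot(is.character(monomers), length(monomers) >= 1L)
  .lookup_monomer(monomers, registry)
  n <- length(monomers)
  acceptor <- monomers[c(seq_len(n)[-1L], 1L)]     # monomer at bond end i+1
  ester <- which(is_ester_monomer(acceptor, registry))
  structure(list(monomers = monomers, ester_positions = ester,
                 name = name),
            class = "cyclic_species")
}

#' @export
print.cyclic_species <- function(x, ...) {
  cat("<cyclic_species>", if (!is.null(x$name)) x$name else "",
      "\n  ring: ", paste(x$monomers, collapse = "-"),
      "\n  ester bonds: ",
      if (length(x$ester_positions)) paste(x$ester_positions, collapse = ", ")
      else "none", "\n", sep = "")
  invisible(x)
}

#' Neutral mass of a linear or cyclic monomer sequence
#'
#' Linear chains weigh the residue-mass sum plus one H2O (terminal H and
#' OH); a head-to-tail cycle has formed one more bond and weighs the
#' residue-mass sum alone. The same accounting covers amide and ester
#' bonds: condensation loses one H2O either way.
#'
#' @param x A [cyclic_species()] or a character vector of monomer ids.
#' @param cyclic Logical; ignored (taken as TRUE) when `x` is a
#'   `cyclic_species`.
#' @param mode Mass mode.
#' @param registry A [monomer_registry()].
#' @return A [mass_value()].
#' @examples
#' species_mass(rep("G", 5), cyclic = TRUE)  # 285.1073
#' @export
species_mass <- function(x, cyclic = FALSE, mode = "monoisotopic",
                         registry = monomer_registry()) {
  if (inherits(x, "cyclic_species")) {
    monomers <- x$monomers
    cyclic <- TRUE
  } else monomers <- x
  total <- sum(.residue_masses(monomers, mode, registry))
  if (!cyclic) total <- total + .free_mass("H2O", mode)
  mass_value(total, mode)
}

#' Elemental formula of a linear or cyclic monomer sequence
#'
#' @inheritParams species_mass
#' @return A `chem_formula`.
#' @export
species_formula <- function(x, cyclic = FALSE,
                            registry = monomer_registry()) {
  if (inherits(x, "cyclic_species")) {
    monomers <- x$monomers
    cyclic <- TRUE
  } else monomers <- x
  water <- parse_formula("H2O")
  f <- chem_formula()
  for (id in monomers) f <- f + residue_formula(id, registry)
  if (!cyclic) f <- f + water
  f
}

#' Ester-bond hydrolysis products of a cyclic species
#'
#' One ring-opened linear product per ester bond (mass = cyclic + H2O,
#' the opened chain starting at the hydroxy acid whose alpha-hydroxyl is
#' freed). For two or more esters, every pairwise double cleavage is also
#' enumerated; each pair of complementary fragments sums to cyclic +
#' 2 H2O. A cycle without esters returns an empty list.
#'
#' @param s A [cyclic_species()].
#' @param mode Mass mode.
#' @param registry A [monomer_registry()].
#' @return List of products, each a list with `type` (`"linear"` or
#'   `"fragment_pair"`), `bonds` (cleaved ring bond indices), `monomers`
#'   (one vector, or a list of two for fragment pairs) and `mass`
#'   (one [mass_value()], or a list of two).
#' @export
hydrolysis_products <- function(s, mode = "monoisotopic",
                                registry = monomer_registry()) {
  stopifnot(inherits(s, "cyclic_species"))
  n <- length(s$monomers)
  esters <- s$ester_positions
  out <- list()
  open_at <- function(b) {
    # bond b joins monomer b -> b+1; opening yields a chain starting at b+1
    idx <- ((b + seq_len(n) - 1L) %% n) + 1L
    s$monomers[idx]
  }
  for (b in esters) {
    seq_b <- open_at(b)
    out[[length(out) + 1L]] <- list(
      type = "linear", bonds = b, monomers = seq_b,
      mass = species_mass(seq_b, cyclic = FALSE, mode = mode,
                          registry = registry))
  }
  if (length(esters) >= 2L) {
    pairs <- utils::combn(esters, 2L)
    for (k in seq_len(ncol(pairs))) {
      b1 <- pairs[1L, k]; b2 <- pairs[2L, k]
      idx1 <- ((b1 + seq_len((b2 - b1) %% n) - 1L) %% n) + 1L
      idx2 <- ((b2 + seq_len((b1 - b2) %% n) - 1L) %% n) + 1L
      frag1 <- s$monomers[idx1]
      frag2 <- s$monomers[idx2]
      out[[length(out) + 1L]] <- list(
        type = "fragment_pair", bonds = c(b1, b2),
        monomers = list(frag1, frag2),
        mass = list(
          species_mass(frag1, cyclic = FALSE, mode = mode,
                       registry = registry),
          species_mass(frag2, cyclic = FALSE, mode = mode,
                       registry = registry)))
    }
  }
  out
}

#' Mass of a carrier protein with one substituted monomer
#'
#' Models e.g. a reporter protein expressed from a gene with a single
#' reassigned codon: the residue at `position` (1-based) is replaced by
#' the given monomer. With `hydrolysed_at_ester = TRUE` (only valid when
#' the substituted monomer is an alpha hydroxy acid) the two ester-bond
#' cleavage fragments are returned: the N-terminal chain ending before
#' the hydroxy acid as a free acid, and the C-terminal chain beginning
#' with the hydroxy acid bearing its free alpha-hydroxyl. Fragment masses
#' sum to the intact mass + H2O.
#'
#' @param sequence Character vector of monomer ids, or a single string of
#'   one-letter canonical codes.
#' @param position 1-based residue index to substitute.
#' @param monomer Registry id of the substituting monomer.
#' @param hydrolysed_at_ester Logical.
#' @param mode Mass mode.
#' @param registry A [monomer_registry()].
#' @return A [mass_value()] (intact), or a named list with `n_terminal`
#'   and `c_terminal` [mass_value()]s (hydrolysed).
#' @export
protein_variant_mass <- function(sequence, position, monomer,
                                 hydrolysed_at_ester = FALSE,
                                 mode = "monoisotopic",
                                 registry = monomer_registry()) {
  if (length(sequence) == 1L && nchar(sequence) > 1L) {
    sequence <- strsplit(sequence, "")[[1]]
  }
  n <- length(sequence)
  if (position < 1L || position > n) stop("substitution position out of range")
  sequence[position] <- monomer
  if (!hydrolysed_at_ester) {
    return(species_mass(sequence, cyclic = FALSE, mode = mode,
                        registry = registry))
  }
  if (!is_ester_monomer(monomer, registry)) {
    stop("hydrolysis requested at an amide position: ", monomer,
         " is not an alpha hydroxy acid")
  }
  if (position == 1L) stop("no ester bond N-terminal of position 1")
  list(
    n_terminal = species_mass(sequence[seq_len(position - 1L)],
                              cyclic = FALSE, mode = mode,
                              registry = registry),
    c_terminal = species_mass(sequence[position:n], cyclic = FALSE,
                              mode = mode, registry = registry))
}

#' Species report table
#'
#' One row per (template, scheme) combination with formula, neutral
#' masses and singly protonated ion.
#'
#' @param templates List of [macrocycle_template()]s.
#' @param schemes List of [reassignment_scheme()]s.
#' @param registry A [monomer_registry()].
#' @return Data frame with columns name, scheme, formula, monoisotopic,
#'   average, mz_MH, ester_count.
#' @export
species_report <- function(templates, schemes,
                           registry = monomer_registry()) {
  rows <- list()
  for (tpl in templates) for (sch in schemes) {
    sp <- instantiate(tpl, sch, registry)
    mono <- species_mass(sp, mode = "monoisotopic", registry = registry)
    rows[[length(rows) + 1L]] <- data.frame(
      name = tpl$name, scheme = sch$scheme_id,
      formula = format_formula(species_formula(sp, registry = registry)),
      monoisotopic = as.numeric(mono),
      average = as.numeric(species_mass(sp, mode = "average",
                                        registry = registry)),
      mz_MH = ion_mz(mono, "M_plus_H"),
      ester_count = length(sp$ester_positions),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
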