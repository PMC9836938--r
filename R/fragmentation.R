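# Ring-opening enumeration and a/b/y fragment-ion theory for cyclic
# peptides and depsipeptides.
#
# A ring of n monomers can open at any of its n backbone bonds (amide or
# ester alike), giving n rotationally related linear sequences; each is
# fragmented with the standard singly protonated series over residue
# masses:
#   b_i = sum(residues 1..i) + proton
#   a_i = b_i - CO
#   y_i = sum(residues n-i+1..n) + H2O + proton
# Ester-linked positions use the same arithmetic: the residue masses
# already encode the O-for-NH swap of a hydroxy acid.

#' Enumerate the ring-opened linearizations of a cyclic species
#'
#' A ring of n monomers yields exactly n linearizations, one per backbone
#' bond; opening bond b yields the chain that starts at monomer b+1. The
#' distinct-sequence count is below n only for rotationally symmetric
#' rings.
#'
#' @param s A [cyclic_species()].
#' @return List of linearizations; each has `opened_bond` (ring bond
#'   index), `monomers` (linear id vector) and `is_ester` (whether the
#'   opened bond is an ester).
#' @export
linearize <- function(s) {
  stopifnot(inherits(s, "cyclic_species"))
  n <- length(s$monomers)
  if (n < 1L) stop("empty ring")
  lapply(seq_len(n), function(b) {
    idx <- ((b + seq_len(n) - 1L) %% n) + 1L
    list(opened_bond = b, monomers = s$monomers[idx],
         is_ester = b %in% s$ester_positions)
  })
}

# Lean numeric core: a/b/y m/z vectors from a residue-mass vector.
.ion_series <- function(res, mode) {
  proton <- .PROTON[[mode]]
  water <- .free_mass("H2O", mode)
  co <- .free_mass("CO", mode)
  b <- cumsum(res) + proton
  list(a = b - co, b = b, y = cumsum(rev(res)) + water + proton)
}

#' Theoretical a/b/y fragment ions of one linear sequence
#'
#' Singly protonated ions by default (charge 1). `y_n` equals the
#' `[M+H]+` of the full linear sequence, and `b_i + y_(n-i)` equals that
#' precursor plus one proton (the standard complementarity identity).
#'
#' @param monomers Character vector of monomer ids (a linearization's
#'   `monomers`, or any linear sequence).
#' @param series Subset of `c("a", "b", "y")`.
#' @param mode Mass mode.
#' @param registry A [monomer_registry()].
#' @return Data frame with columns `series`, `index` (1..n), `mz`.
#' @export
theoretical_ions <- function(monomers, series = c("a", "b", "y"),
                             mode = "monoisotopic",
                             registry = monomer_registry()) {
  series <- match.arg(series, several.ok = TRUE)
  if (inherits(monomers, "cyclic_species")) {
    stop("pass a linearization's monomer vector, not the cyclic species; ",
         "see linearize()")
  }
  res <- .residue_masses(monomers, mode, registry)
  ions <- .ion_series(res, mode)
  n <- length(res)
  data.frame(series = rep(series, each = n),
             index = rep.int(seq_len(n), length(series)),
             mz = unlist(ions[series], use.names = FALSE),
             stringsAsFactors = FALSE)
}

#' Full theoretical fragment table of a cyclic species
#'
#' All a/b/y ions of every ring-opened linearization, plus the shared
#' `[M+H]+` precursor (identical across linearizations).
#'
#' @param s A [cyclic_species()].
#' @param series Subset of `c("a", "b", "y")`.
#' @param mode Mass mode.
#' @param registry A [monomer_registry()].
#' @return Data frame with columns `opened_bond`, `opened_is_ester`,
#'   `series`, `index`, `mz`, `label`.
#' @export
fragment_table <- function(s, series = c("a", "b", "y"),
                           mode = "monoisotopic",
                           registry = monomer_registry()) {
  lins <- linearize(s)
  tab <- do.call(rbind, lapply(lins, function(l) {
    ions <- theoretical_ions(l$monomers, series, mode, registry)
    cbind(data.frame(opened_bond = l$opened_bond,
                     opened_is_ester = l$is_ester), ions)
  }))
  tab$label <- paste0(tab$series, tab$index)
  tab
}

#' Precursor m/z of a cyclic species
#'
#' @param s A [cyclic_species()].
#' @param mode Mass mode.
#' @param registry A [monomer_registry()].
#' @return `[M+H]+` m/z at charge 1.
#' @export
precursor_mz <- function(s, mode = "monoisotopic",
                         registry = monomer_registry()) {
  ion_mz(species_mass(s, mode = mode, registry = registry), "M_plus_H")
}

#' Annotate an observed peak list against a cyclic species
#'
#' Each observed peak is matched to every theoretical a/b/y ion (over all
#' ring-opened linearizations) within `tolerance`; when several ions
#' match one peak all are reported and the peak is flagged ambiguous
#' rather than silently resolved. Peaks matching the precursor are
#' annotated `[M+H]+`. The report carries both absolute m/z and the
#' offset from the precursor.
#'
#' @param peaks Data frame with columns `mz` and `intensity`.
#' @param s A [cyclic_species()].
#' @param tolerance Match tolerance in Da (default 0.1, quadrupole-TOF
#'   scale).
#' @param series Subset of `c("a", "b", "y")`.
#' @param mode Mass mode.
#' @param registry A [monomer_registry()].
#' @return List of class `annotation` with elements `matches` (one row
#'   per peak-ion match), `unmatched` (peaks with no match), `coverage`
#'   (per-linearization count of distinct matched ions) and
#'   `precursor_mz`.
#' @export
annotate <- function(peaks, s, tolerance = 0.1, series = c("a", "b", "y"),
                     mode = "monoisotopic", registry = monomer_registry()) {
  stopifnot(is.data.frame(peaks), all(c("mz", "intensity") %in% names(peaks)))
  if (any(peaks$mz <= 0)) stop("peak m/z must be positive")
  if (tolerance <= 0) stop("tolerance must be positive")
  theo <- fragment_table(s, series, mode, registry)
  prec <- precursor_mz(s, mode, registry)
  matches <- list()
  matched_peak <- logical(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    dmz <- abs(theo$mz - peaks$mz[i])
    hit <- which(dmz <= tolerance)
    is_prec <- abs(prec - peaks$mz[i]) <= tolerance
    if (is_prec) {
      matched_peak[i] <- TRUE
      matches[[length(matches) + 1L]] <- data.frame(
        opened_bond = NA_integer_, opened_is_ester = NA,
        series = "precursor", index = NA_integer_, mz = prec,
        label = "[M+H]+", peak_mz = peaks$mz[i],
        intensity = peaks$intensity[i], error = prec - peaks$mz[i],
        nearest = TRUE, ambiguous = FALSE,
        delta_from_precursor = peaks$mz[i] - prec,
        stringsAsFactors = FALSE)
    }
    if (length(hit)) {
      m <- theo[hit, , drop = FALSE]
      m$peak_mz <- peaks$mz[i]
      m$intensity <- peaks$intensity[i]
      m$error <- m$mz - peaks$mz[i]
      m$nearest <- dmz[hit] == min(dmz[hit])
      m$ambiguous <- length(hit) > 1L
      m$delta_from_precursor <- peaks$mz[i] - prec
      matches[[length(matches) + 1L]] <- m
      matched_peak[i] <- TRUE
    }
  }
  matches <- if (length(matches)) do.call(rbind, matches) else
    theo[0, c("opened_bond", "opened_is_ester", "series", "index", "mz",
              "label")]
  n <- length(s$monomers)
  frag <- matches[!is.na(matches$opened_bond), , drop = FALSE]
  coverage <- data.frame(
    opened_bond = seq_len(n),
    n_matched = vapply(seq_len(n), function(b) {
      sub <- frag[frag$opened_bond == b, , drop = FALSE]
      nrow(unique(sub[, c("series", "index")]))
    }, integer(1)))
  structure(list(matches = matches,
                 unmatched = peaks[!matched_peak, , drop = FALSE],
                 coverage = coverage, precursor_mz = prec,
                 tolerance = tolerance),
            class = "annotation")
}

#' @export
print.annotation <- function(x, ...) {
  cat("<annotation> precursor [M+H]+ = ", format(x$precursor_mz),
      ", tolerance ", x$tolerance, " Da\n",
      "  matched ", length(unique(x$matches$peak_mz)), " peak(s), ",
      nrow(x$unmatched), " unmatched\n",
      "  per-linearization distinct ions matched: ",
      paste(x$coverage$n_matched, collapse = ", "), "\n", sep = "")
  invisible(x)
}
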