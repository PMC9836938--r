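# Seeded generators producing every input the pipeline consumes, with
# known ground truth. All generators are pure functions of their
# arguments plus `seed`, and restore the caller's RNG state.

.with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L) stop("seed must be a number")
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Ground-truth orthogonal pairs implied by a boolean activity pattern,
# derived combinatorially by construction (valid when every non-active
# cell is sampled below the inactivity threshold).
.pairs_from_pattern <- function(active, groups) {
  rows <- rownames(active); cols <- colnames(active)
  out <- list()
  for (i1 in seq_len(nrow(active))) for (i2 in seq_len(nrow(active))) {
    if (i2 <= i1 || groups[i1] == groups[i2]) next
    for (j1 in seq_along(cols)) for (j2 in seq_along(cols)) {
      if (j1 == j2) next
      if (active[i1, j1] && !active[i1, j2] &&
          active[i2, j2] && !active[i2, j1]) {
        left <- c(rows[i1], cols[j1]); right <- c(rows[i2], cols[j2])
        if (paste(left, collapse = "\r") > paste(right, collapse = "\r")) {
          tmp <- left; left <- right; right <- tmp
        }
        out[[length(out) + 1L]] <- data.frame(
          aars1 = left[1], monomer1 = left[2],
          aars2 = right[1], monomer2 = right[2], stringsAsFactors = FALSE)
      }
    }
  }
  pairs <- if (length(out)) unique(do.call(rbind, out)) else
    data.frame(aars1 = character(0), monomer1 = character(0),
               aars2 = character(0), monomer2 = character(0))
  pairs <- pairs[order(pairs$aars1, pairs$monomer1, pairs$aars2,
                       pairs$monomer2), , drop = FALSE]
  rownames(pairs) <- NULL
  pairs
}

#' Generate a synthetic activity matrix with known orthogonal structure
#'
#' Emulates the screening-matrix structure of the study (three
#' mutual-orthogonality groups of 3 + 2 + 2 synthetases by 16 monomers):
#' each synthetase is made active on a few random monomers (or on the
#' cells implied by an explicit `planted` pair list), active cells are
#' sampled above the activity threshold and every other cell below the
#' inactivity threshold, so at zero noise the ground-truth pair set is
#' exact by construction.
#'
#' @param seed Integer seed.
#' @param group_sizes Synthetases per group (default `c(3, 2, 2)`).
#' @param n_monomers Number of monomer columns (default 16).
#' @param active_per_aars Active monomers drawn per synthetase when no
#'   `planted` list is given (default 2).
#' @param planted Optional data frame with columns `aars1`, `monomer1`,
#'   `aars2`, `monomer2` naming pairs to plant; both synthetases of a
#'   pair must sit in different groups.
#' @param active_range Uniform sampling range for active cells,
#'   RFU/OD600 (default 15,000--40,000).
#' @param inactive_range Uniform range for inactive cells (default
#'   0--1,000).
#' @param noise_sd Gaussian noise added to every cell (truncated at 0);
#'   large values can cross the thresholds, degrading recovery.
#' @return List with `matrix` (an [activity_matrix()]), `truth` (the
#'   ground-truth pair set, same layout as [find_pairs()] output) and
#'   `active` (the boolean pattern).
#' @export
gen_activity_matrix <- function(seed, group_sizes = c(3, 2, 2),
                                n_monomers = 16, active_per_aars = 2,
                                planted = NULL,
                                active_range = c(15000, 40000),
                                inactive_range = c(0, 1000),
                                noise_sd = 0) {
  .with_seed(seed, {
    n_aars <- sum(group_sizes)
    groups <- rep(paste0("group", seq_along(group_sizes)), group_sizes)
    aars <- paste0("aaRS", seq_len(n_aars), "_g",
                   rep(seq_along(group_sizes), group_sizes))
    monomers <- paste0("m", seq_len(n_monomers))
    active <- matrix(FALSE, n_aars, n_monomers,
                     dimnames = list(aars, monomers))
    if (is.null(planted)) {
      for (i in seq_len(n_aars)) {
        active[i, sample.int(n_monomers, active_per_aars)] <- TRUE
      }
    } else {
      for (k in seq_len(nrow(planted))) {
        a1 <- planted$aars1[k]; a2 <- planted$aars2[k]
        if (!all(c(a1, a2) %in% aars)) stop("planted pair names unknown aaRS")
        g <- stats::setNames(groups, aars)
        if (g[[a1]] == g[[a2]]) {
          stop("planted pair within one group: ", a1, " / ", a2)
        }
        active[a1, planted$monomer1[k]] <- TRUE
        active[a2, planted$monomer2[k]] <- TRUE
      }
    }
    values <- matrix(stats::runif(n_aars * n_monomers, inactive_range[1],
                                  inactive_range[2]),
                     n_aars, n_monomers, dimnames = list(aars, monomers))
    values[active] <- stats::runif(sum(active), active_range[1],
                                   active_range[2])
    if (noise_sd > 0) {
      values <- pmax(values + stats::rnorm(length(values), 0, noise_sd), 0)
    }
    list(matrix = activity_matrix(values, groups),
         truth = .pairs_from_pattern(active, groups),
         active = active)
  })
}

#' Generate a random coding sequence with planted target codons
#'
#' Starts with ATG, ends with a TAA stop, and draws interior codons from
#' the sense codons other than TCG/TCA/TAG; the requested numbers of
#' TCG, TCA and TAG codons are then planted at random distinct interior
#' positions, so the violation counts are known exactly.
#'
#' @param seed Integer seed.
#' @param n_codons Total length in codons including start and stop
#'   (at least `n_tcg + n_tca + n_tag + 2`).
#' @param n_tcg,n_tca,n_tag Planted codon counts.
#' @return List with `id`, `cds` (DNA string), `counts` (named planted
#'   counts) and `positions` (0-based codon indices per codon, a list).
#' @export
gen_cds <- function(seed, n_codons = 100, n_tcg = 0, n_tca = 0, n_tag = 0) {
  n_planted <- n_tcg + n_tca + n_tag
  if (n_codons < n_planted + 2L) stop("n_codons too small for planted codons")
  .with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    all_codons <- apply(expand.grid(bases, bases, bases), 1, paste,
                        collapse = "")
    safe <- setdiff(all_codons, c("TCG", "TCA", "TAG", "TAA", "TGA"))
    codons <- c("ATG", sample(safe, n_codons - 2L, replace = TRUE), "TAA")
    interior <- 2:(n_codons - 1L)
    slots <- sample(interior, n_planted)
    planted <- rep(c("TCG", "TCA", "TAG"), c(n_tcg, n_tca, n_tag))
    codons[slots] <- planted
    positions <- split(slots - 1L, factor(planted,
                                          levels = c("TCG", "TCA", "TAG")))
    list(id = paste0("synthetic_cds_seed", seed),
         cds = paste(codons, collapse = ""),
         counts = c(TCG = n_tcg, TCA = n_tca, TAG = n_tag),
         positions = lapply(positions, sort))
  })
}

#' Generate a synthetic fragment spectrum of a cyclic species
#'
#' Plants a chosen number of theoretical a/b/y ions per ring-opened
#' linearization (each observed within the match tolerance after m/z
#' jitter), adds decoy peaks guaranteed to lie outside twice the
#' tolerance of every theoretical ion and of the precursor, and includes
#' the `[M+H]+` precursor peak.
#'
#' @param s A [cyclic_species()].
#' @param seed Integer seed.
#' @param ions_per_linearization Planted ions per linearization
#'   (default 3, mirroring a minimum-evidence criterion of at least
#'   three fragments per linear sequence).
#' @param n_decoys Number of decoy peaks (default 5).
#' @param mz_jitter_sd Gaussian m/z jitter of planted peaks, truncated
#'   to the tolerance (default 0.02 Da).
#' @param tolerance Match tolerance the spectrum is built for (default
#'   0.1 Da).
#' @param mode Mass mode.
#' @param registry A [monomer_registry()].
#' @return List with `peaks` (data frame `mz`, `intensity`), `truth`
#'   (planted ions with observed m/z) and `precursor_mz`.
#' @export
gen_spectrum <- function(s, seed, ions_per_linearization = 3, n_decoys = 5,
                         mz_jitter_sd = 0.02, tolerance = 0.1,
                         mode = "monoisotopic",
                         registry = monomer_registry()) {
  stopifnot(inherits(s, "cyclic_species"))
  theo <- fragment_table(s, mode = mode, registry = registry)
  prec <- precursor_mz(s, mode, registry)
  .with_seed(seed, {
    planted <- do.call(rbind, lapply(split(theo, theo$opened_bond),
      function(sub) {
        if (nrow(sub) < ions_per_linearization) {
          stop("linearization has fewer theoretical ions than requested")
        }
        sub[sample.int(nrow(sub), ions_per_linearization), , drop = FALSE]
      }))
    jitter <- stats::rnorm(nrow(planted), 0, mz_jitter_sd)
    jitter <- pmin(pmax(jitter, -0.95 * tolerance), 0.95 * tolerance)
    planted$mz_observed <- planted$mz + jitter
    all_theo <- c(theo$mz, prec)
    lo <- min(all_theo) - 30; hi <- max(all_theo) + 30
    decoys <- numeric(0)
    attempts <- 0L
    while (length(decoys) < n_decoys) {
      attempts <- attempts + 1L
      if (attempts > 1000L) {
        stop("decoy collision after 1000 attempts (m/z range overcrowded)")
      }
      cand <- stats::runif(1, lo, hi)
      if (min(abs(all_theo - cand)) > 2 * tolerance) {
        decoys <- c(decoys, cand)
      }
    }
    peaks <- data.frame(
      mz = c(planted$mz_observed, decoys, prec),
      intensity = c(stats::runif(nrow(planted), 50, 100),
                    stats::runif(length(decoys), 5, 20), 100))
    peaks <- peaks[order(peaks$mz), , drop = FALSE]
    rownames(peaks) <- NULL
    list(peaks = peaks, truth = planted, precursor_mz = prec)
  })
}
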