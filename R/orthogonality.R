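# Automated identification of mutually orthogonal synthetase/monomer
# pairs from normalized fluorescence activity matrices.
#
# (aaRS1, monomer1) forms an orthogonal pair with (aaRS2, monomer2) when
# aaRS1 is active with monomer1 and inactive with monomer2, aaRS2 is
# active with monomer2 and inactive with monomer1, and the two
# synthetases come from different mutual-orthogonality groups (pairs
# within one group cannot decode distinct codons simultaneously).

#' Construct an activity matrix
#'
#' @param values Numeric matrix of normalized fluorescence (RFU/OD600),
#'   rows = synthetase (aaRS) variants, columns = monomer ids; values
#'   must be non-negative and complete (a missing cell is an error, not
#'   a zero -- silent zeros would fabricate inactivity).
#' @param groups Group label per row (same length as `nrow(values)`):
#'   synthetases in the same group are never paired.
#' @param excluded Optional logical matrix of the same shape marking
#'   cells removed from analysis (see [apply_exclusions()]).
#' @return A list of class `activity_matrix`.
#' @export
activity_matrix <- function(values, groups, excluded = NULL) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (anyNA(values)) stop("missing cell value in activity matrix")
  if (any(values < 0)) stop("negative fluorescence value")
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("activity matrix needs aaRS row names and monomer column names")
  }
  if (length(groups) != nrow(values)) {
    stop("one group label required per aaRS row")
  }
  if (is.null(excluded)) {
    excluded <- matrix(FALSE, nrow(values), ncol(values),
                       dimnames = dimnames(values))
  }
  stopifnot(is.logical(excluded), all(dim(excluded) == dim(values)))
  structure(list(values = values,
                 groups = stats::setNames(as.character(groups),
                                          rownames(values)),
                 excluded = excluded),
            class = "activity_matrix")
}

#' @export
print.activity_matrix <- function(x, ...) {
  cat("<activity_matrix> ", nrow(x$values), " aaRS x ", ncol(x$values),
      " monomers, ", length(unique(x$groups)), " group(s), ",
      sum(x$excluded), " excluded cell(s)\n", sep = "")
  invisible(x)
}

#' Read an activity matrix from CSV
#'
#' Dialect: first column the aaRS label, second column its group label,
#' remaining columns one per monomer; '#' comments; missing values are
#' errors.
#'
#' @param path CSV path.
#' @return An [activity_matrix()].
#' @export
read_activity_matrix <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE,
                        stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("activity CSV needs aaRS, group and >=1 monomer ",
                          "column")
  if (!identical(tolower(names(df)[2]), "group")) {
    stop("second column must be named 'group', got: ", names(df)[2])
  }
  values <- as.matrix(df[, -(1:2), drop = FALSE])
  mode(values) <- "numeric"
  rownames(values) <- df[[1]]
  activity_matrix(values, df[[2]])
}

#' Write an activity matrix to CSV
#'
#' @param m An [activity_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_activity_matrix <- function(m, path) {
  df <- data.frame(aaRS = rownames(m$values), group = m$groups,
                   m$values, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Default exclusion rules
#'
#' The aromatic hydroxy acids (F-OH, pIF-OH, NapA-OH; registry ids 14,
#' 15, 16) are converted to their amino acid counterparts in cells, so
#' fluorescence read with the two tyrosyl synthetases reports amino acid,
#' not hydroxy acid, incorporation; those six cells are removed from the
#' analysis.
#'
#' @return Data frame with columns `aars` and `monomer`.
#' @export
default_exclusions <- function() {
  expand.grid(aars = c("AfTyrRS(pIF)", "AfTyrRS(pAzF)"),
              monomer = c("14", "15", "16"),
              stringsAsFactors = FALSE)
}

#' Mask cells of an activity matrix
#'
#' Marks the named (aaRS, monomer) cells as excluded; original values are
#' retained but never contribute to activity or inactivity judgements.
#'
#' @param m An [activity_matrix()].
#' @param rules Data frame with columns `aars` and `monomer`; default
#'   [default_exclusions()]. An empty rule set is the identity.
#' @return The masked [activity_matrix()].
#' @export
apply_exclusions <- function(m, rules = default_exclusions()) {
  stopifnot(inherits(m, "activity_matrix"))
  if (!nrow(rules)) return(m)
  bad_r <- setdiff(rules$aars, rownames(m$values))
  if (length(bad_r)) stop("unknown aaRS label: ", paste(bad_r, collapse = ", "))
  bad_c <- setdiff(rules$monomer, colnames(m$values))
  if (length(bad_c)) stop("unknown monomer label: ",
                          paste(bad_c, collapse = ", "))
  for (i in seq_len(nrow(rules))) {
    m$excluded[rules$aars[i], rules$monomer[i]] <- TRUE
  }
  m
}

#' Find mutually orthogonal synthetase/monomer pairs
#'
#' Returns every unordered pair {(aaRS1, monomer1), (aaRS2, monomer2)}
#' with the synthetases in different groups, no cell excluded, and
#' value(aaRS1, monomer1) > active_min, value(aaRS1, monomer2) <
#' inactive_max, value(aaRS2, monomer2) > active_min, value(aaRS2,
#' monomer1) < inactive_max. Deterministic and order-independent; pairs
#' are canonicalized by sorted (aaRS, monomer) labels.
#'
#' @param m An [activity_matrix()] (apply exclusions first if wanted).
#' @param active_min Activity threshold, RFU/OD600 (default 10,000).
#' @param inactive_max Inactivity threshold, RFU/OD600 (default 2,500;
#'   must be below `active_min`). The default is a package choice --
#'   tune it to your assay's noise floor.
#' @return Data frame of class `orthogonal_pairs` with columns `aars1`,
#'   `monomer1`, `aars2`, `monomer2`, one row per pair.
#' @export
find_pairs <- function(m, active_min = 10000, inactive_max = 2500) {
  stopifnot(inherits(m, "activity_matrix"))
  if (inactive_max >= active_min) {
    stop("inactive_max must be below active_min")
  }
  v <- m$values
  usable <- !m$excluded
  active <- v > active_min & usable
  inactive <- v < inactive_max & usable
  rows <- rownames(v); cols <- colnames(v)
  out <- list()
  for (i1 in seq_len(nrow(v))) for (i2 in seq_len(nrow(v))) {
    if (i2 <= i1 || m$groups[i1] == m$groups[i2]) next
    for (j1 in which(active[i1, ])) for (j2 in which(active[i2, ])) {
      if (j1 == j2) next
      if (inactive[i1, j2] && inactive[i2, j1]) {
        left <- c(rows[i1], cols[j1]); right <- c(rows[i2], cols[j2])
        if (paste(left, collapse = "\r") > paste(right, collapse = "\r")) {
          tmp <- left; left <- right; right <- tmp
        }
        out[[length(out) + 1L]] <- data.frame(
          aars1 = left[1], monomer1 = left[2],
          aars2 = right[1], monomer2 = right[2],
          stringsAsFactors = FALSE)
      }
    }
  }
  pairs <- if (length(out)) unique(do.call(rbind, out)) else
    data.frame(aars1 = character(0), monomer1 = character(0),
               aars2 = character(0), monomer2 = character(0))
  pairs <- pairs[order(pairs$aars1, pairs$monomer1, pairs$aars2,
                       pairs$monomer2), , drop = FALSE]
  rownames(pairs) <- NULL
  class(pairs) <- c("orthogonal_pairs", "data.frame")
  pairs
}

#' Unique substrate pairings of an orthogonal-pair set
#'
#' Projects each synthetase/monomer pair onto its unordered (monomer,
#' monomer) substrate combination and returns the distinct set -- the
#' number of distinct codon reassignment schemes the pair set supports.
#'
#' @param pairs Result of [find_pairs()].
#' @return Data frame with columns `monomer1`, `monomer2` (sorted within
#'   each row), one row per distinct pairing.
#' @export
unique_pairings <- function(pairs) {
  if (!nrow(pairs)) {
    return(data.frame(monomer1 = character(0), monomer2 = character(0)))
  }
  a <- pmin(pairs$monomer1, pairs$monomer2)
  b <- pmax(pairs$monomer1, pairs$monomer2)
  u <- unique(data.frame(monomer1 = a, monomer2 = b,
                         stringsAsFactors = FALSE))
  u <- u[order(u$monomer1, u$monomer2), , drop = FALSE]
  rownames(u) <- NULL
  u
}
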