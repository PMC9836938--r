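# Independent oracles used to cross-check the package's computations.
# Constants here were computed with an external mass library (pyteomics)
# and frozen; the oracles never call the code paths they check.

# Free-monomer monoisotopic masses for the oracle alphabet.
ORACLE_FREE_MASS <- c(
  "G"  = 75.032028,   # glycine        C2H5NO2
  "A"  = 89.047678,   # alanine        C3H7NO2
  "V"  = 117.078979,  # valine         C5H11NO2
  "L"  = 131.094629,  # leucine        C6H13NO2
  "C"  = 121.019749,  # cysteine       C3H7NO2S
  "14" = 166.062994,  # phenyllactic   C9H10O3
  "8"  = 229.095023,  # AlkynK-OH      C10H15NO5
  "5"  = 206.080376,  # pAzF           C9H10N4O2
  "6"  = 247.141973,  # BocK-OH        C11H21NO5
  "7"  = 231.110673,  # AllocK-OH      C10H17NO5
  "12" = 281.126323   # CbzK-OH        C14H19NO5
)
ORACLE_H2O <- 18.010565
ORACLE_CO <- 27.994915
ORACLE_PROTON <- 1.00727647

# a/b/y m/z of a linear sequence from free-monomer masses: the i-mer
# prefix peptide weighs sum(free) - (i-1) H2O; b is that minus H2O plus
# a proton, y is the suffix peptide plus a proton, a is b minus CO.
oracle_ions <- function(ids) {
  free <- unname(ORACLE_FREE_MASS[ids])
  stopifnot(!anyNA(free))
  i <- seq_along(ids)
  prefix <- cumsum(free) - (i - 1) * ORACLE_H2O
  suffix <- cumsum(rev(free)) - (i - 1) * ORACLE_H2O
  b <- prefix - ORACLE_H2O + ORACLE_PROTON
  list(a = b - ORACLE_CO, b = b, y = suffix + ORACLE_PROTON)
}

# Neutral mass of a linear (or cyclic) chain from free masses.
oracle_chain_mass <- function(ids, cyclic = FALSE) {
  free <- unname(ORACLE_FREE_MASS[ids])
  sum(free) - (length(ids) - if (cyclic) 0 else 1) * ORACLE_H2O
}

# Exhaustive orthogonal-pair search by matrix algebra over ordered
# quadruples: structurally independent of find_pairs' direct search.
oracle_find_pairs <- function(m, active_min, inactive_max) {
  v <- m$values
  usable <- !m$excluded
  act <- v > active_min & usable
  inact <- v < inactive_max & usable
  rows <- rownames(v); cols <- colnames(v)
  found <- character(0)
  for (i1 in seq_len(nrow(v))) for (i2 in seq_len(nrow(v))) {
    if (i1 == i2 || m$groups[i1] == m$groups[i2]) next
    ok <- outer(act[i1, ] & inact[i2, ], act[i2, ] & inact[i1, ], "&")
    diag(ok) <- FALSE
    idx <- which(ok, arr.ind = TRUE)
    if (nrow(idx)) {
      left <- paste(rows[i1], cols[idx[, 1]], sep = "\r")
      right <- paste(rows[i2], cols[idx[, 2]], sep = "\r")
      key <- ifelse(left < right, paste(left, right, sep = "\n"),
                    paste(right, left, sep = "\n"))
      found <- c(found, key)
    }
  }
  found <- sort(unique(found))
  if (!length(found)) {
    return(data.frame(aars1 = character(0), monomer1 = character(0),
                      aars2 = character(0), monomer2 = character(0)))
  }
  parts <- do.call(rbind, strsplit(found, "[\n\r]"))
  data.frame(aars1 = parts[, 1], monomer1 = parts[, 2],
             aars2 = parts[, 3], monomer2 = parts[, 4],
             stringsAsFactors = FALSE)
}

# Random activity matrix for equivalence trials: a mixture of clearly
# active, clearly inactive and mid-range values so thresholds bite.
random_activity_matrix <- function(n_aars, n_monomers, n_groups = 3) {
  groups <- sample(paste0("g", seq_len(n_groups)), n_aars, replace = TRUE)
  level <- sample(1:3, n_aars * n_monomers, replace = TRUE,
                  prob = c(0.5, 0.2, 0.3))
  values <- matrix(
    c(runif(sum(level == 1), 0, 3000),
      runif(sum(level == 2), 3000, 12000),
      runif(sum(level == 3), 12000, 40000))[order(order(level))],
    n_aars, n_monomers,
    dimnames = list(paste0("r", seq_len(n_aars)),
                    paste0("c", seq_len(n_monomers))))
  activity_matrix(values, groups)
}
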