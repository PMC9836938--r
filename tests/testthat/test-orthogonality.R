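# Orthogonal synthetase/monomer pair identification.

test_that("a clean 2x2 cross-group matrix yields exactly one pair", {
  v <- matrix(c(20000, 100, 100, 20000), 2, 2, byrow = TRUE,
              dimnames = list(c("rs1", "rs2"), c("mA", "mB")))
  m <- activity_matrix(v, groups = c("g1", "g2"))
  p <- find_pairs(m)
  expect_equal(nrow(p), 1L)
  expect_equal(sort(c(p$monomer1, p$monomer2)), c("mA", "mB"))
  # same values, one group: no pairs
  same <- activity_matrix(v, groups = c("g1", "g1"))
  expect_equal(nrow(find_pairs(same)), 0L)
  expect_error(find_pairs(m, active_min = 100, inactive_max = 200),
               "below active_min")
})

test_that("find_pairs agrees with an exhaustive oracle on random matrices", {
  set.seed(7)
  for (trial in 1:100) {
    m <- random_activity_matrix(sample(3:10, 1), sample(4:20, 1))
    got <- find_pairs(m)
    want <- oracle_find_pairs(m, 10000, 2500)
    expect_identical(as.data.frame(got), want)
  }
})

test_that("threshold monotonicity holds", {
  set.seed(21)
  pair_key <- function(p) paste(p$aars1, p$monomer1, p$aars2, p$monomer2)
  for (trial in 1:20) {
    m <- random_activity_matrix(6, 10)
    base <- find_pairs(m, 10000, 2500)
    # weakening the inactivity requirement never removes a pair
    wider <- find_pairs(m, 10000, 5000)
    expect_true(all(pair_key(base) %in% pair_key(wider)))
    # strengthening the activity requirement never adds one
    stricter <- find_pairs(m, 15000, 2500)
    expect_true(all(pair_key(stricter) %in% pair_key(base)))
  }
})

test_that("pair finding is invariant under row and column permutation", {
  set.seed(5)
  m <- random_activity_matrix(6, 8)
  ri <- sample(6); ci <- sample(8)
  perm <- activity_matrix(m$values[ri, ci], m$groups[ri])
  expect_identical(as.data.frame(find_pairs(perm)),
                   as.data.frame(find_pairs(m)))
})

test_that("exclusion masks silence cells without deleting data", {
  v <- matrix(runif(7 * 16, 0, 1000), 7, 16,
              dimnames = list(
                c("MmPylRS", "MmPylRS(PheOH_6)", "MmPylRS(ArOH)",
                  "1R26PylRS", "1R26PylRS(CbzK)",
                  "AfTyrRS(pIF)", "AfTyrRS(pAzF)"),
                as.character(1:16)))
  m <- activity_matrix(v, groups = c(1, 1, 1, 2, 2, 3, 3))
  masked <- apply_exclusions(m)
  expect_equal(sum(masked$excluded), 6L)
  expect_identical(masked$values, m$values)  # values retained, inert
  # empty rule set is the identity
  none <- apply_exclusions(m, data.frame(aars = character(0),
                                         monomer = character(0)))
  expect_identical(none, m)
  expect_error(apply_exclusions(m, data.frame(aars = "nope", monomer = "1")),
               "unknown aaRS")
  # an excluded active cell can no longer support a pair
  v2 <- matrix(c(20000, 100, 100, 20000), 2, 2, byrow = TRUE,
               dimnames = list(c("r1", "r2"), c("c1", "c2")))
  m2 <- activity_matrix(v2, groups = c("g1", "g2"))
  expect_equal(nrow(find_pairs(m2)), 1L)
  m2x <- apply_exclusions(m2, data.frame(aars = "r1", monomer = "c1"))
  expect_equal(nrow(find_pairs(m2x)), 0L)
})

test_that("unique pairings project pairs onto substrate combinations", {
  pairs <- data.frame(
    aars1 = c("a", "a2"), monomer1 = c("x", "x"),
    aars2 = c("b", "b2"), monomer2 = c("y", "y"),
    stringsAsFactors = FALSE)
  u <- unique_pairings(pairs)
  expect_equal(nrow(u), 1L)
  expect_equal(unname(unlist(u)), c("x", "y"))
  empty <- unique_pairings(find_pairs(
    activity_matrix(matrix(0, 1, 1, dimnames = list("r", "c")), "g1")))
  expect_equal(nrow(empty), 0L)
})

test_that("activity matrices reject incomplete or invalid input", {
  v <- matrix(c(1, NA, 3, 4), 2, 2,
              dimnames = list(c("r1", "r2"), c("c1", "c2")))
  expect_error(activity_matrix(v, c("g1", "g2")), "missing cell")
  v[is.na(v)] <- -1
  expect_error(activity_matrix(v, c("g1", "g2")), "negative")
  v[v < 0] <- 1
  expect_error(activity_matrix(v, "g1"), "one group label")
  expect_error(activity_matrix(unname(v), c("g1", "g2")), "row names")
})

test_that("activity CSV round-trips through writer and reader", {
  g <- gen_activity_matrix(3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_activity_matrix(g$matrix, path)
  back <- read_activity_matrix(path)
  expect_equal(back$values, g$matrix$values, tolerance = 1e-9)
  expect_identical(unname(back$groups), unname(g$matrix$groups))
  expect_identical(as.data.frame(find_pairs(back)),
                   as.data.frame(find_pairs(g$matrix)))
})
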