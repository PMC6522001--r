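transfac_fixture <- function() {
  path <- tempfile(fileext = ".dat")
  writeLines(c(
    "AC  M00001", "XX", "ID  V$TEST_01", "XX",
    "P0      A      C      G      T",
    "01      10      0      0      0  A",
    "02       0      5      5      0  S",
    "03       2      2      2      4  T",
    "XX", "//",
    "AC  M00002", "XX", "ID  V$TEST_02", "XX",
    "P0      A      C      G      T",
    "01       1      1      1      1  N",
    "02       9      1      0      0  A",
    "XX", "//"), path)
  path
}

test_that("TRANSFAC records parse with counts preserved", {
  lib <- parse_matrices(transfac_fixture(), "transfac")
  expect_length(lib$pwms, 2)
  p1 <- lib$pwms[["V$TEST_01"]]
  expect_identical(ncol(p1$matrix), 3L)
  expect_false(p1$is_probability)
  expect_equal(unname(p1$matrix[, 1]), c(10, 0, 0, 0))
  expect_equal(unname(p1$matrix[, 3]), c(2, 2, 2, 4))
  expect_identical(ncol(lib$pwms[["V$TEST_02"]]$matrix), 2L)
})

test_that("JASPAR records parse in both bracket and bare styles", {
  path <- tempfile(fileext = ".pfm")
  writeLines(c(">MA0001.1 TEST",
               "A  [ 0  3 79 40 66 48 ]",
               "C  [94 75  4  3  1  2 ]",
               "G  [ 1  0  3  4  1  0 ]",
               "T  [ 2 19 11 50 29 47 ]",
               ">MA0002.1 BARE",
               "4 17 0",
               "16 0 0",
               "0 0 20",
               "0 3 0"), path)
  lib <- parse_matrices(path, "jaspar")
  expect_length(lib$pwms, 2)
  expect_identical(ncol(lib$pwms[["MA0001.1"]]$matrix), 6L)
  expect_equal(unname(lib$pwms[["MA0001.1"]]$matrix["C", 1]), 94)
  expect_equal(unname(lib$pwms[["MA0002.1"]]$matrix["A", 2]), 17)
})

test_that("malformed matrix files raise parse errors with line numbers", {
  bad <- tempfile()
  writeLines(c("AC  M1", "P0      A      C      G      T",
               "01      1      2      3", "//"), bad)
  expect_error(parse_matrices(bad, "transfac"), "4 numeric")
  wrong_order <- tempfile()
  writeLines(c("AC  M1", "P0      A      G      C      T",
               "01      1      2      3      4", "//"), wrong_order)
  expect_error(parse_matrices(wrong_order, "transfac"), "base order")
  empty <- tempfile(); writeLines(character(), empty)
  expect_error(parse_matrices(empty, "transfac"), "empty")
  threerow <- tempfile()
  writeLines(c(">M1", "1 2", "3 4", "5 6"), threerow)
  expect_error(parse_matrices(threerow, "jaspar"), "4 base rows")
})

test_that("normalize_pwm applies the pseudocount formula per column", {
  p <- new_pwm(matrix(c(10, 0, 0, 0), 4, 1), "one_hot")
  expect_equal(unname(normalize_pwm(p, 0)$matrix[, 1]), c(1, 0, 0, 0))
  p <- new_pwm(matrix(c(1, 1, 1, 1), 4, 1), "flat")
  expect_equal(unname(normalize_pwm(p, 3)$matrix[, 1]), rep(0.25, 4))
  p <- new_pwm(matrix(c(3, 1, 0, 0), 4, 1), "mix")
  expect_equal(unname(normalize_pwm(p, 1)$matrix[, 1]),
               c(0.5, 0.25, 0.125, 0.125))
  zero <- new_pwm(matrix(0, 4, 1), "zero")
  expect_error(normalize_pwm(zero, 0), "all-zero")
  set.seed(5)
  for (i in 1:20) {
    q <- normalize_pwm(random_prob_pwm(sprintf("r%d", i)), pseudocount = 0.01)
    expect_true(all(abs(colSums(q$matrix) - 1) < 1e-9))
  }
})

test_that("information_content matches closed forms and stays in [0, 2L]", {
  flat <- new_pwm(matrix(0.25, 4, 1), "flat", is_probability = TRUE)
  expect_equal(information_content(flat), 0)
  hot <- new_pwm(matrix(c(1, 0, 0, 0), 4, 1), "hot", is_probability = TRUE)
  expect_equal(information_content(hot), 2)
  half <- new_pwm(matrix(c(0.5, 0.5, 0, 0), 4, 1), "half",
                  is_probability = TRUE)
  expect_equal(information_content(half), 1)
  set.seed(6)
  for (i in 1:50) {
    p <- random_prob_pwm(sprintf("r%d", i))
    ic <- information_content(p)
    expect_gte(ic, 0)
    expect_lte(ic, 2 * ncol(p$matrix) + 1e-9)
  }
  expect_error(information_content(hot, c(0, 1 / 3, 1 / 3, 1 / 3)),
               "zero probability")
})

test_that("pwm_correlation: identity, padding invariance, symmetry", {
  set.seed(7)
  a <- random_prob_pwm("a", L = 6)
  expect_equal(pwm_correlation(a, a), 1.0)
  padded <- new_pwm(cbind(a$matrix, matrix(0.25, 4, 2)), "pad",
                    is_probability = TRUE)
  expect_equal(pwm_correlation(a, padded), 1.0, tolerance = 1e-12)
  for (i in 1:100) {
    x <- random_prob_pwm("x"); y <- random_prob_pwm("y")
    expect_equal(pwm_correlation(x, y), pwm_correlation(y, x),
                 tolerance = 1e-12)
  }
})

test_that("pwm_correlation equals exhaustive offset/orientation maximization", {
  # independent oracle: enumerate every placement of b (both orientations)
  # against a and take the maximum correlation over >= min-overlap windows
  oracle_corr <- function(a, b, mo = 3) {
    rc <- function(m) { r <- m[4:1, rev(seq_len(ncol(m)))]; r }
    best <- -Inf
    for (mb in list(b$matrix, rc(b$matrix))) {
      la <- ncol(a$matrix); lb <- ncol(mb)
      k <- min(mo, la, lb)
      for (shift in -(lb - k):(la - k)) {
        cols_a <- intersect(seq_len(la), seq_len(lb) + shift)
        if (length(cols_a) < k) next
        va <- as.vector(a$matrix[, cols_a]); vb <- as.vector(mb[, cols_a - shift])
        if (sd(va) == 0 || sd(vb) == 0) next
        best <- max(best, cor(va, vb))
      }
    }
    if (is.finite(best)) best else 0
  }
  set.seed(8)
  for (i in 1:200) {
    x <- random_prob_pwm("x"); y <- random_prob_pwm("y")
    expect_equal(pwm_correlation(x, y), oracle_corr(x, y), tolerance = 1e-12)
  }
})

test_that("cluster_and_select merges duplicates and keeps the max-IC PWM", {
  set.seed(9)
  sharp <- new_pwm(matrix(rep(c(0.97, 0.01, 0.01, 0.01), 6), 4, 6), "ic_high",
                   is_probability = TRUE)
  soft <- new_pwm(sweep(sharp$matrix * 0.6 + 0.1, 2,
                        colSums(sharp$matrix * 0.6 + 0.1), "/"), "ic_low",
                  is_probability = TRUE)
  dup <- new_pwm(sharp$matrix, "zz_copy", is_probability = TRUE)
  lib <- motif_library(list(sharp, soft, dup))
  out <- cluster_and_select(lib, correlation_cutoff = 0.8)
  # the whole cluster collapses to its highest-IC member
  expect_identical(names(out$pwms), "ic_high")

  single <- motif_library(list(sharp))
  expect_identical(cluster_and_select(single)$pwms, single$pwms)

  # anti-correlated/unrelated flat-ish motifs stay separate
  lowcorr <- motif_library(lapply(1:4, function(i) {
    m <- matrix(0.05, 4, 6); m[i, ] <- 0.85
    new_pwm(m, sprintf("solo%d", i), is_probability = TRUE)
  }))
  kept <- cluster_and_select(lowcorr, correlation_cutoff = 0.99)
  expect_lte(length(kept$pwms), 4)
  expect_gte(length(kept$pwms), 1)
})

test_that("cluster_and_select never grows the library on random input", {
  set.seed(10)
  for (r in 1:10) {
    n <- sample(3:8, 1)
    lib <- motif_library(lapply(seq_len(n), function(i)
      random_prob_pwm(sprintf("m%02d", i), L = sample(5:9, 1))))
    out <- cluster_and_select(lib, correlation_cutoff = 0.8)
    expect_lte(length(out$pwms), n)
    expect_true(all(names(out$pwms) %in% names(lib$pwms)))
  }
})

test_that("filter_by_tf_expression keeps the >= tau boundary and any-qualifies", {
  expr <- structure(list(values = matrix(c(1.46, 0.1, 9.0, 0.2),
                                         nrow = 4,
                                         dimnames = list(c("tfA", "tfB1",
                                                           "tfB2", "tfC"),
                                                         "liver")),
                         aggregation = "mean"),
                    class = "TissueExpression")
  mk <- function(id, genes) new_pwm(matrix(0.25, 4, 4), id, genes,
                                    is_probability = TRUE)
  lib <- motif_library(list(mk("at_boundary", "tfA"),
                            mk("any_rule", c("tfB1", "tfB2")),
                            mk("below", "tfC"),
                            mk("unmapped", character())))
  expect_warning(out <- filter_by_tf_expression(lib, expr, "liver", 1.46),
                 "no mapped TF gene")
  expect_setequal(names(out$pwms), c("at_boundary", "any_rule"))
  expect_error(filter_by_tf_expression(lib, expr, "brain", 1.46), "brain")
})
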