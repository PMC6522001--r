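write_expr_table <- function(df) {
  path <- tempfile(fileext = ".tsv")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

tmap4 <- c(s1 = "liver", s2 = "liver", s3 = "lung", s4 = "lung")

test_that("load_expression reads a valid table and preserves row order", {
  path <- write_expr_table(data.frame(gene = c("G1", "G2", "G3"),
                                      s1 = c(1, 0, 5), s2 = c(2, 0, 4),
                                      s3 = c(0, 3, 1), s4 = c(0.5, 2, 0)))
  em <- load_expression(path, tmap4)
  expect_s3_class(em, "ExpressionMatrix")
  expect_identical(rownames(em$values), c("G1", "G2", "G3"))
  expect_identical(dim(em$values), c(3L, 4L))
  expect_setequal(unique(em$sample_tissues), c("liver", "lung"))
})

test_that("load_expression rejects malformed tables with informative errors", {
  dup <- write_expr_table(data.frame(gene = c("G1", "G1"), s1 = c(1, 2),
                                     s2 = c(1, 2), s3 = c(1, 2), s4 = c(1, 2)))
  expect_error(load_expression(dup, tmap4), "G1")
  neg <- write_expr_table(data.frame(gene = c("G1", "G2"), s1 = c(1, -1),
                                     s2 = c(1, 2), s3 = c(1, 2), s4 = c(1, 2)))
  expect_error(load_expression(neg, tmap4), "negative")
  txt <- write_expr_table(data.frame(gene = c("G1", "G2"), s1 = c("1", "oops"),
                                     s2 = c(1, 2), s3 = c(1, 2), s4 = c(1, 2)))
  expect_error(load_expression(txt, tmap4), "non-numeric")
  ok <- write_expr_table(data.frame(gene = "G1", s1 = 1, s2 = 1, s3 = 1,
                                    s9 = 1))
  expect_error(load_expression(ok, tmap4), "s9")
})

test_that("threshold estimation: fixed, bimodal valley, degenerate input", {
  th <- estimate_threshold(NULL, method = "fixed", tau = 1.46)
  expect_equal(th$tau, 1.46)

  set.seed(11)
  vals <- 10^c(rnorm(5000, log10(0.1), 0.3), rnorm(5000, log10(100), 0.3))
  m <- matrix(sample(vals), ncol = 4,
              dimnames = list(sprintf("G%04d", 1:2500),
                              sprintf("s%d", 1:4)))
  em <- expression_matrix(m, c(s1 = "a", s2 = "a", s3 = "b", s4 = "b"))
  th <- estimate_threshold(em)
  # the valley of the two planted modes must fall strictly between them
  expect_gt(th$tau, 0.1)
  expect_lt(th$tau, 100)
  # oracle: the density grid value at tau is an interior local minimum
  lx <- log10(as.vector(m) + 1e-3)
  d <- density(lx, bw = "nrd", n = 512)
  i <- which.min(abs(d$x - log10(th$tau + 1e-3)))
  expect_true(d$y[i] <= d$y[max(1, i - 2)] && d$y[i] <= d$y[min(512, i + 2)])

  const <- expression_matrix(matrix(5, 3, 2,
                                    dimnames = list(c("a", "b", "c"),
                                                    c("s1", "s2"))),
                             c(s1 = "x", s2 = "y"))
  expect_error(estimate_threshold(const), "fixed")
})

test_that("drop_unexpressed keeps exactly the genes above tau and is idempotent", {
  m <- matrix(c(0.5, 1.0,
                0.5, 2.0,
                3.0, 4.0), nrow = 3, byrow = TRUE,
              dimnames = list(c("low", "mid", "high"), c("s1", "s2")))
  em <- expression_matrix(m, c(s1 = "a", s2 = "b"))
  f <- drop_unexpressed(em, 1.46)
  expect_identical(rownames(f$values), c("mid", "high"))
  expect_identical(drop_unexpressed(f, 1.46)$values, f$values)
  expect_identical(rownames(drop_unexpressed(em, 0)$values), rownames(m))
  expect_error(drop_unexpressed(em, 100), "no gene")
})

test_that("aggregate_by_tissue takes arithmetic means per tissue", {
  m <- matrix(c(2, 4, 1, 3,
                0, 0, 0, 0), nrow = 2, byrow = TRUE,
              dimnames = list(c("g1", "g2"), names(tmap4)))
  agg <- aggregate_by_tissue(expression_matrix(m, tmap4))
  expect_equal(agg$values["g1", "liver"], 3)
  expect_equal(agg$values["g1", "lung"], 2)
  expect_equal(unname(agg$values["g2", ]), c(0, 0))
})

test_that("select_tsg applies the inclusive two-thirds rule", {
  m <- rbind(boundary = c(8, 2, 1, 1),    # 8 >= 2/3 * 12, inclusive
             below    = c(7, 2, 2, 1),    # 7 < 8
             solo     = c(5, 0, 0, 0),    # single-tissue expression
             zero     = c(0, 0, 0, 0))
  colnames(m) <- paste0("t", 1:4)
  tsg <- select_tsg(structure(list(values = m, aggregation = "mean"),
                              class = "TissueExpression"))
  expect_identical(tsg$genes$t1, c("boundary", "solo"))
  expect_identical(unlist(tsg$genes[2:4], use.names = FALSE), character(0))
  expect_error(select_tsg(structure(list(values = m), class = "TissueExpression"),
                          fraction = 1.2), "fraction")
})

test_that("select_tsg matches brute force and is exclusive on random matrices", {
  set.seed(301)
  for (r in 1:200) {
    ng <- sample(2:10, 1); nt <- sample(2:5, 1)
    m <- matrix(round(runif(ng * nt, 0, 10), 2), ng, nt,
                dimnames = list(sprintf("g%d", 1:ng), sprintf("t%d", 1:nt)))
    if (r %% 7 == 0) m[sample(ng, 1), ] <- 0  # exercise all-zero rows
    te <- structure(list(values = m, aggregation = "mean"),
                    class = "TissueExpression")
    got <- select_tsg(te)
    want <- brute_tsg(m)
    for (t in colnames(m)) expect_identical(got$genes[[t]], want[[t]])
    sel <- unlist(got$genes, use.names = FALSE)
    expect_identical(anyDuplicated(sel), 0L)  # 2/3 > 1/2 => exclusive
  }
})

test_that("combine_tsg intersects per policy", {
  mk <- function(...) structure(list(genes = list(...), fraction = 2 / 3),
                                class = "TSGSet")
  sets <- list(A = mk(liver = c("g1", "g2")),
               B = mk(liver = c("g2", "g3")),
               C = mk(liver = "g2", lung = "g9"))
  got <- combine_tsg(sets, list(liver = c("A", "B", "C")))
  expect_identical(got$genes$liver, "g2")
  expect_identical(combine_tsg(sets, list(lung = "C"))$genes$lung, "g9")
  expect_warning(combine_tsg(list(A = mk(liver = "g1"), B = mk(liver = "g2")),
                             list(liver = c("A", "B"))), "no common")
  expect_error(combine_tsg(sets, list(lung = c("A", "C"))), "lung.*A|A.*lung")
  expect_error(combine_tsg(sets, list(liver = "Z")), "Z")
})

test_that("TSG sets round-trip through TSV", {
  tsg <- structure(list(genes = list(liver = c("g1", "g2"), lung = "g3"),
                        fraction = 2 / 3), class = "TSGSet")
  path <- tempfile(fileext = ".tsv")
  write_tsg(tsg, path)
  back <- read_tsg(path)
  expect_identical(back$genes[order(names(back$genes))],
                   tsg$genes[order(names(tsg$genes))])
})
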