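test_that("DE filtering applies the inclusive significance/fold/abundance rules", {
  det <- flat_det(gene = c("a", "b", "c", "d", "e"),
                  fold_change = c(2, 10, 1.9, 0.5, 4),
                  significant = c(TRUE, TRUE, TRUE, TRUE, FALSE),
                  max_abundance = c(1, 0.5, 5, 3, 8))
  kept <- filter_de(det)
  # a: FC exactly 2, abundance exactly 1 -> retained (inclusive thresholds)
  # b: strong FC but abundance below 1 -> removed
  # c: FC below 2 -> removed; d: 2-fold down, kept; e: not significant
  expect_setequal(kept$gene, c("a", "d"))
})

test_that("planted passing genes are retained exactly", {
  gx <- gen_expression(n_genes = 600, seed = 2)
  det <- de_table(gx$expr, gx$conditions, "BMP", "mTeSR")
  kept <- filter_de(det)
  up_in <- mean(gx$truth$up$BMP %in% kept$gene)
  dn_in <- mean(gx$truth$down$BMP %in% kept$gene)
  expect_gt(up_in, 0.99)
  expect_gt(dn_in, 0.99)
})

test_that("union of top lists has the expected size in degenerate cases", {
  mk <- function(genes, fc) flat_det(gene = genes, fold_change = fc,
                                     significant = TRUE, max_abundance = 10)
  up <- sprintf("u%03d", 1:150); dn <- sprintf("d%03d", 1:150)
  det <- mk(c(up, dn), c(seq(50, 2, length.out = 150),
                         seq(1 / 50, 1 / 2, length.out = 150)))
  identical3 <- list(A = det, B = det, C = det)
  expect_identical(union_top_set(identical3, n_top = 100)$size, 200L)
  # pairwise-disjoint top lists
  det2 <- mk(c(paste0("x", up), paste0("x", dn)),
             c(seq(50, 2, length.out = 150), seq(1 / 50, 1 / 2, length.out = 150)))
  det3 <- mk(c(paste0("y", up), paste0("y", dn)),
             c(seq(50, 2, length.out = 150), seq(1 / 50, 1 / 2, length.out = 150)))
  expect_identical(suppressWarnings(
    union_top_set(list(det, det2, det3), 100))$size, 600L)
  # monotone in n_top and warns when a direction runs short
  expect_lte(union_top_set(identical3, 50)$size,
             union_top_set(identical3, 100)$size)
  expect_warning(union_top_set(identical3, 200), "taking all")
})

test_that("fold-change ranking breaks ties lexicographically", {
  det <- flat_det(gene = c("b", "a", "c"), fold_change = c(4, 4, 8),
                  significant = TRUE, max_abundance = 10)
  uts <- suppressWarnings(union_top_set(list(A = det, B = det, C = det),
                                        n_top = 2))
  expect_identical(uts$per_condition$A$up, c("c", "a"))
})

test_that("Venn regions count every subset and sum to the union", {
  sets <- list(A = c("a", "b", "c", "x"), B = c("b", "c", "y"),
               C = c("c", "x", "z"))
  v <- venn_overlap(sets)
  expect_identical(unname(v["A&B&C"]), 1L)   # c
  expect_identical(unname(v["A&C"]), 1L)     # x
  expect_identical(unname(v["A&B"]), 1L)     # b
  expect_identical(sum(v), attr(v, "union"))
  # disjoint and identical extremes
  expect_identical(unname(venn_overlap(list(A = "a", B = "b", C = "c"))["A&B&C"]), 0L)
  same <- venn_overlap(list(A = letters[1:5], B = letters[1:5], C = letters[1:5]))
  expect_identical(unname(same["A&B&C"]), 5L)
})

test_that("correlation matrix handles duplicates, negation and constants", {
  set.seed(1)
  x <- matrix(rexp(200, 0.2), 50, 4,
              dimnames = list(sprintf("g%02d", 1:50), paste0("s", 1:4)))
  x[, 2] <- x[, 1]
  cm <- correlation_matrix(x, rownames(x))
  expect_equal(cm["s1", "s2"], 1)
  expect_true(all(diag(cm) == 1))
  expect_identical(cm, t(cm))
  # z-scored sample versus its negation
  z <- t(scale(t(x[, c(1, 3)])))
  y <- cbind(z[, 1], -z[, 1])
  rownames(y) <- rownames(x); colnames(y) <- c("p", "q")
  expect_equal(correlation_matrix(y, rownames(y))["p", "q"], -1)
  # constant gene vector under z-scoring is dropped, constant sample gives NA
  xc <- x; xc[, 4] <- 3
  expect_true(is.na(correlation_matrix(xc, rownames(xc))["s4", "s1"]))
  expect_error(correlation_matrix(x, c("g01", "nope")), "absent")
})

test_that("correlation of samples sharing a planted signal fraction matches theory", {
  # common-factor model: two samples share a factor with loading rho;
  # expected Pearson r equals rho^2 / (rho^2 + (1 - rho^2)) = rho^2 for
  # unit-variance factors
  set.seed(9)
  n <- 4000; rho <- 0.8
  f <- rnorm(n)
  s1 <- rho * f + sqrt(1 - rho^2) * rnorm(n)
  s2 <- rho * f + sqrt(1 - rho^2) * rnorm(n)
  x <- cbind(s1, s2) - min(s1, s2) + 0.1  # shift non-negative
  rownames(x) <- sprintf("g%04d", 1:n); colnames(x) <- c("a", "b")
  r <- correlation_matrix(x, rownames(x))["a", "b"]
  expect_equal(r, rho^2, tolerance = 0.05)
})

test_that("lineage-specific selection applies all three rules", {
  lineages <- rep(c("EPI", "PE", "TE"), each = 3)
  days <- rep(c("E5", "E6", "E7"), times = 3)
  mk <- function(...) matrix(c(...), nrow = 1)
  expr <- rbind(
    te_marker  = c(1, 1, 1,  1, 1, 1,  100, 100, 100),   # clean TE marker
    te_drift   = c(1, 1, 1,  1, 1, 1,  10, 100, 1000),   # DE across days -> out
    te_low     = c(0.1, 0.1, 0.1, 0.1, 0.1, 0.1, 9, 9, 12), # low in 2 of 3 -> out
    epi_marker = c(80, 85, 90, 2, 2, 2, 3, 3, 3),
    housekeeping = c(50, 50, 50, 50, 50, 50, 50, 50, 50))
  colnames(expr) <- paste(lineages, days, sep = "_")
  sel <- lineage_specific_genes(expr, lineages, days)
  expect_true("te_marker" %in% sel$per_lineage$TE)
  expect_false("te_drift" %in% sel$genes)
  expect_false("te_low" %in% sel$genes)
  expect_true("epi_marker" %in% sel$per_lineage$EPI)
  expect_false("housekeeping" %in% sel$genes)
  # a missing time point is rejected
  expect_error(lineage_specific_genes(expr[, -9], lineages[-9], days[-9]),
               "missing")
})

test_that("expression matrices round-trip through CSV and gene sets through text", {
  gx <- gen_expression(n_genes = 300, seed = 3)
  p <- file.path(tempdir(), "expr.csv")
  utils::write.csv(data.frame(gene = rownames(gx$expr), gx$expr,
                              check.names = FALSE), p, row.names = FALSE)
  back <- read_expression(p)
  expect_equal(back, gx$expr, tolerance = 1e-12)
  gs <- file.path(tempdir(), "genes.txt")
  write_gene_set(gx$truth$up$BMP, gs)
  expect_identical(readLines(gs), gx$truth$up$BMP)
})
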