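test_that("tissue correlation matches the textbook formula", {
  set.seed(71)
  expr <- matrix(c(
    1.2, 0.4, -0.7, 2.2,
    0.3, 1.9, 0.8, -1.1,
    -0.5, 0.6, 1.4, 0.9,
    2.0, -0.2, 0.3, 1.5,
    0.1, 1.1, -0.9, 0.4
  ), nrow = 5, byrow = TRUE,
  dimnames = list(paste0("G", 1:5), paste0("S", 1:4)))

  # independent oracle: sum-formula Pearson correlation per pair
  pearson_oracle <- function(x, y) {
    n <- length(x)
    num <- sum(x * y) - n * mean(x) * mean(y)
    den <- sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
    num / den
  }
  r <- tissue_correlation(expr, standardize = FALSE)
  for (a in 1:3) {
    for (b in (a + 1):4) {
      expect_equal(r[a, b], pearson_oracle(expr[, a], expr[, b]),
                   tolerance = 1e-12)
    }
  }
  expect_true(isSymmetric(r))
  expect_equal(unname(diag(r)), rep(1, 4))

  # standardized path equals manual per-gene z-scoring
  z <- t(apply(expr, 1, function(g) (g - mean(g)) / sd(g)))
  rz <- tissue_correlation(expr, standardize = TRUE)
  expect_equal(rz[1, 2], pearson_oracle(z[, 1], z[, 2]), tolerance = 1e-12)
})

test_that("tissue correlation handles identical, negated, and bad profiles", {
  expr <- cbind(a = c(1, 2, 3), b = c(1, 2, 3), c = -c(1, 2, 3))
  rownames(expr) <- paste0("G", 1:3)
  r <- tissue_correlation(expr, standardize = FALSE)
  expect_equal(r["a", "b"], 1)
  expect_equal(r["a", "c"], -1)

  flat <- cbind(a = c(1, 2, 3), b = c(5, 5, 5))
  rownames(flat) <- paste0("G", 1:3)
  expect_error(tissue_correlation(flat, standardize = FALSE), "b")

  expect_error(tissue_correlation(matrix(1:4, nrow = 1)), ">= 2 genes")
  expect_warning(
    tissue_correlation(rbind(matrix(rnorm(8), 2), c(3, 3, 3, 3))),
    "constant gene"
  )
})

test_that("pairwise distances are Euclidean and metric", {
  samples <- data.frame(
    sample_id = c("a", "b", "c"),
    x_mm = c(0, 3, 0), y_mm = c(0, 4, 0), z_mm = c(0, 0, 0),
    tissue_class = "t1", network = "none"
  )
  d <- pairwise_distance(samples)
  expect_equal(d["a", "b"], 5)
  expect_equal(d["a", "c"], 0)
  expect_equal(unname(diag(d)), rep(0, 3))

  set.seed(12)
  cloud <- data.frame(
    sample_id = sprintf("s%02d", 1:10),
    x_mm = runif(10, 0, 100), y_mm = runif(10, 0, 100),
    z_mm = runif(10, 0, 100), tissue_class = "t1", network = "none"
  )
  dm <- pairwise_distance(cloud)
  for (a in 1:10) for (b in 1:10) for (cc in 1:10) {
    expect_lte(dm[a, b], dm[a, cc] + dm[cc, b] + 1e-12)
  }
})

test_that("edge table enumerates unordered pairs with correct flags", {
  set.seed(31)
  n <- 10
  samples <- data.frame(
    sample_id = sprintf("s%02d", 1:n),
    x_mm = runif(n, 0, 100), y_mm = runif(n, 0, 100),
    z_mm = runif(n, 0, 100),
    tissue_class = rep(c("t1", "t2"), each = 5),
    network = c(rep("netA", 3), rep("netB", 3), rep("none", 4))
  )
  expr <- matrix(rnorm(20 * n), nrow = 20,
                 dimnames = list(paste0("G", 1:20), samples$sample_id))
  edges <- build_edge_table(samples, expr)
  expect_equal(nrow(edges), n * (n - 1) / 2)
  expect_equal(sum(edges$wi), choose(3, 2) + choose(3, 2))
  expect_true(all(edges$included))
  expect_true(all(edges$r >= -1 & edges$r <= 1))
  expect_true(all(edges$d >= 0))

  # wi implies both endpoints labeled
  net <- samples$network
  expect_true(all(net[edges$i[edges$wi]] != "none"))

  one_net <- samples
  one_net$network <- "netA"
  expect_true(all(build_edge_table(one_net, expr)$wi))

  small <- build_edge_table(samples[1:4, ], expr[, 1:4])
  expect_equal(nrow(small), 6L)

  expect_error(build_edge_table(samples, expr[, 1:5]), "missing")
})

test_that("correlation matrix is positive semidefinite", {
  fx <- small_fixture(seed = 13, n_samples = 60, n_genes = 80)
  r <- tissue_correlation(fx$ds$expression)
  expect_gt(min(eigen(r, symmetric = TRUE, only.values = TRUE)$values),
            -1e-8)
})

test_that("same-tissue and distance filters behave and commute", {
  et <- make_edge_table(
    r = c(0.9, 0.5, 0.2, -0.1),
    d = c(5, 15, 16, 40),
    wi = c(TRUE, FALSE, TRUE, FALSE),
    same_tissue = c(TRUE, TRUE, FALSE, FALSE)
  )
  expect_equal(filter_min_distance(et, 0)$included, rep(TRUE, 4))
  expect_equal(filter_min_distance(et, 16)$included,
               c(FALSE, FALSE, TRUE, TRUE)) # strict <: keeps d == 16
  expect_equal(sum(filter_min_distance(et, 100)$included), 0L)
  expect_error(filter_min_distance(et, -1), "d_min")

  expect_equal(filter_same_tissue(et)$included,
               c(FALSE, FALSE, TRUE, TRUE))
  all_same <- make_edge_table(r = c(0.1, 0.2), d = c(1, 2),
                              wi = FALSE, same_tissue = TRUE)
  expect_equal(sum(filter_same_tissue(all_same)$included), 0L)
  all_diff <- make_edge_table(r = c(0.1, 0.2), d = c(1, 2),
                              wi = FALSE, same_tissue = FALSE)
  expect_equal(filter_same_tissue(all_diff)$included, c(TRUE, TRUE))

  # composition order does not matter
  ab <- filter_min_distance(filter_same_tissue(et), 15)
  ba <- filter_same_tissue(filter_min_distance(et, 15))
  expect_identical(ab$included, ba$included)

  # input table untouched
  expect_true(all(et$included))
})

test_that("distance residualization matches the normal-equations oracle", {
  # exact linear relation -> zero residuals
  lin <- make_edge_table(r = 0.8 - 0.01 * c(5, 10, 20, 40),
                         d = c(5, 10, 20, 40), wi = FALSE)
  res_lin <- residualize_distance(lin)
  expect_equal(res_lin$weight, rep(0, 4), tolerance = 1e-12)

  # 5-edge hand table vs closed-form (X'X)^-1 X'y
  et <- make_edge_table(r = c(0.62, 0.35, 0.41, 0.10, -0.05),
                        d = c(4, 12, 18, 33, 47), wi = FALSE)
  res <- residualize_distance(et)
  X <- cbind(1, et$d)
  beta <- solve(t(X) %*% X, t(X) %*% et$r)
  expect_equal(res$weight, as.numeric(et$r - X %*% beta),
               tolerance = 1e-12)
  expect_true(attr(res, "residualized"))

  # OLS orthogonality on a larger random set
  set.seed(9)
  big <- make_edge_table(r = rnorm(200), d = runif(200, 1, 90), wi = FALSE)
  rb <- residualize_distance(big)
  expect_lt(abs(cor(rb$weight, rb$d)), 1e-10)
  expect_lt(abs(sum(rb$weight)), 1e-10)

  # degenerate inputs
  const_d <- make_edge_table(r = c(0.1, 0.2, 0.3), d = c(5, 5, 5),
                             wi = FALSE)
  expect_error(residualize_distance(const_d), "constant")
  one_edge <- make_edge_table(r = 0.5, d = 3, wi = FALSE)
  expect_error(residualize_distance(one_edge), ">= 2")

  # residuals only cover included edges
  part <- make_edge_table(r = c(0.5, 0.4, 0.3, 0.2), d = c(2, 9, 20, 35),
                          wi = FALSE, included = c(TRUE, TRUE, TRUE, FALSE))
  rp <- residualize_distance(part)
  expect_true(is.na(rp$weight[4]))
  expect_false(anyNA(rp$weight[1:3]))
})
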