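test_that("SF reduces to known values on hand-built tables", {
  all_wi <- make_edge_table(r = c(0.3, 0.5, 0.2), d = 1:3, wi = TRUE)
  expect_equal(strength_fraction(all_wi), 1)

  no_wi <- make_edge_table(r = c(0.3, 0.5), d = 1:2, wi = FALSE)
  expect_equal(strength_fraction(no_wi), 0)

  # equal weights: SF collapses to the edge-count fraction 6/15
  eq <- make_edge_table(r = rep(0.4, 15), d = 1:15,
                        wi = c(rep(TRUE, 6), rep(FALSE, 9)))
  expect_equal(strength_fraction(eq), 0.4)

  # mixed signs, positive_only: brute-force sum over the positive subset
  et <- make_edge_table(
    r = c(0.62, -0.31, 0.44, 0.05, -0.12, 0.28),
    d = 1:6,
    wi = c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE)
  )
  expected_pos <- (0.62 + 0.05) / (0.62 + 0.44 + 0.05 + 0.28)
  expect_equal(strength_fraction(et, positive_only = TRUE), expected_pos,
               tolerance = 1e-15)
  expected_signed <- (0.62 - 0.31 + 0.05) / sum(et$r)
  expect_equal(strength_fraction(et, positive_only = FALSE),
               expected_signed, tolerance = 1e-15)
})

test_that("SF errors distinguish empty from all-negative denominators", {
  none_inc <- make_edge_table(r = c(0.2, 0.3), d = 1:2, wi = TRUE,
                              included = FALSE)
  expect_error(strength_fraction(none_inc), "no included edges")

  all_neg <- make_edge_table(r = c(-0.2, -0.3), d = 1:2, wi = TRUE)
  expect_error(strength_fraction(all_neg, positive_only = TRUE),
               "positive")
  # signed SF over the same table is fine
  expect_equal(strength_fraction(all_neg, positive_only = FALSE), 1)
})

test_that("positive-only SF is bounded and monotone in added Wi weight", {
  set.seed(44)
  for (rep in 1:25) {
    m <- sample(5:20, 1)
    et <- make_edge_table(r = runif(m, -1, 1), d = seq_len(m),
                          wi = sample(c(TRUE, FALSE), m, replace = TRUE))
    ok <- tryCatch(strength_fraction(et), error = function(e) NULL)
    if (is.null(ok)) next
    expect_gte(ok, 0)
    expect_lte(ok, 1)
    # append a positive Wi edge: SF strictly increases while SF < 1
    et2 <- make_edge_table(r = c(et$r, 0.5), d = c(et$d, m + 1),
                           wi = c(et$wi, TRUE))
    if (ok < 1) expect_gt(strength_fraction(et2), ok)
  }
})

test_that("permutation p-values use add-one correction with >= ties", {
  expect_equal(sf_pvalue(0.9, rep(0.1, 999)), 0.001)
  expect_equal(sf_pvalue(0.1, rep(0.9, 9)), 1)
  expect_equal(sf_pvalue(0.5, c(0.5, 0.5, 0.5, 0.5, rep(0.1, 5))), 0.5)
  expect_error(sf_pvalue(0.5, numeric(0)), "empty")
})

test_that("permutation null is deterministic and label-structure invariant", {
  fx <- small_fixture(seed = 21, n_samples = 50, n_genes = 60,
                      network_sizes = rep(8L, 3))
  a <- permutation_null(fx$edges, fx$ds$samples, n_perm = 50, seed = 99)
  b <- permutation_null(fx$edges, fx$ds$samples, n_perm = 50, seed = 99)
  expect_identical(a, b)

  # renaming networks leaves the null unchanged (only the partition matters)
  renamed <- fx$ds$samples
  renamed$network <- chartr("123", "789", renamed$network)
  expect_identical(
    permutation_null(fx$edges, renamed, n_perm = 50, seed = 99), a
  )

  # degenerate case: one network containing every sample
  one <- fx$ds$samples
  one$network <- "theone"
  ed <- fx$edges
  ed$wi <- TRUE
  null_one <- permutation_null(ed, one, n_perm = 20, seed = 1)
  expect_equal(null_one, rep(1, 20))
})

test_that("Monte-Carlo null matches the exhaustive placement oracle", {
  set.seed(61)
  samples <- data.frame(
    sample_id = paste0("s", 1:6),
    x_mm = runif(6, 0, 80), y_mm = runif(6, 0, 80), z_mm = runif(6, 0, 80),
    tissue_class = "t1",
    network = c("net", "net", "net", "none", "none", "none")
  )
  expr <- matrix(rnorm(40 * 6), nrow = 40,
                 dimnames = list(paste0("G", 1:40), samples$sample_id))
  edges <- build_edge_table(samples, expr)

  exact <- exact_sf_null(edges, samples$network)
  mc <- permutation_null(edges, samples, n_perm = 10000, seed = 5)
  mc_r <- round(mc, 12)
  for (k in seq_along(exact$atoms)) {
    p_hat <- mean(mc_r == exact$atoms[k])
    p <- exact$probs[k]
    se <- sqrt(p * (1 - p) / length(mc))
    expect_lt(abs(p_hat - p), 3 * se + 1e-12)
  }
  # and the MC support is a subset of the exact support
  expect_true(all(mc_r %in% exact$atoms))
})

test_that("sf_test records edge counts and the permutation configuration", {
  fx <- small_fixture(seed = 33, n_samples = 60, n_genes = 80,
                      network_sizes = rep(10L, 3))
  res <- sf_test(fx$edges, fx$ds$samples, n_perm = 99, seed = 7)
  expect_s3_class(res, "sf_result")
  expect_equal(res$n_perm, 99L)
  expect_gt(res$n_within_edges, 0)
  expect_lt(res$n_within_edges, res$n_total_edges)
  expect_true(res$p_value > 0 && res$p_value <= 1)
  expect_equal(res$p_value, sf_pvalue(res$sf, res$null_sf))
})

test_that("distance sweep recomputes a null per threshold and flags
           degenerate ones", {
  fx <- small_fixture(seed = 2, n_samples = 100, n_genes = 120,
                      lengthscale_mm = 15, network_sizes = rep(15L, 4))
  sw <- distance_sweep(fx$edges, fx$ds$samples,
                       thresholds = c(0, 500), n_perm = 49, seed = 3)
  expect_named(sw, c("tissue", "d0", "d500"))
  # threshold 0 equals the plain unfiltered SF
  expect_equal(sw$d0$sf, strength_fraction(fx$edges))
  # a threshold beyond the cloud diameter empties the table: flagged,
  # not thrown
  expect_true(sw$d500$degenerate)
  expect_false(sw$d0$degenerate)
  expect_error(distance_sweep(fx$edges, fx$ds$samples, c(10, 5)),
               "ascending")
})

test_that("SF declines and loses significance as short edges are removed", {
  fx <- small_fixture(seed = 2, n_samples = 150, n_genes = 200,
                      lengthscale_mm = 15, network_sizes = rep(20L, 4))
  thresholds <- seq(0, 45, by = 5)
  sw <- distance_sweep(fx$edges, fx$ds$samples, thresholds,
                       n_perm = 199, seed = 4, include_tissue = FALSE)
  sf_vals <- vapply(sw, function(x) x$sf, numeric(1))
  # monotone decline, allowing one non-monotone step from sampling noise
  expect_lte(sum(diff(sf_vals) > 0), 1)
  # beyond three length scales the network signal is gone
  p_tail <- vapply(sw[paste0("d", thresholds[thresholds >= 45])],
                   function(x) x$p_value, numeric(1))
  expect_true(all(p_tail > 0.05))
})
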