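# Shared fixture builders. Everything is generated in code at test time.

# Hand-assembled edge table for unit tests that need exact edge-level
# control; bypasses build_edge_table() on purpose.
make_edge_table <- function(r, d, wi, same_tissue = FALSE, included = TRUE,
                            i = NULL, j = NULL, n_samples = NULL) {
  m <- length(r)
  if (is.null(i) || is.null(j)) {
    # default: a star of edges out of sample 1 (indices only matter for
    # permutation tests, which these hand tables are not used for)
    i <- rep(1L, m)
    j <- seq_len(m) + 1L
  }
  structure(
    data.frame(
      i = i, j = j,
      sample_i = paste0("S", i), sample_j = paste0("S", j),
      r = r, d = d,
      wi = rep_len(wi, m),
      same_tissue = rep_len(same_tissue, m),
      included = rep_len(included, m),
      stringsAsFactors = FALSE
    ),
    class = c("edge_table", "data.frame"),
    n_samples = n_samples %||% (max(i, j)),
    residualized = FALSE
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# The standard synthetic fixture: 500 cortical-like samples, 500 genes,
# 20 mm spatial length scale, 4 contiguous networks of 25 samples each,
# 8 Voronoi tissue parcels.
standard_fixture <- function(seed = 1) {
  ds <- simulate_dataset(synthetic_config(seed = seed))
  edges <- build_edge_table(ds$samples, ds$expression)
  list(ds = ds, edges = edges, filtered = filter_same_tissue(edges))
}

# A small, fast autocorrelated fixture for property tests.
small_fixture <- function(seed = 1, n_samples = 120, n_genes = 150,
                          lengthscale_mm = 20, network_sizes = rep(12L, 4),
                          nugget_var = 1) {
  cfg <- synthetic_config(
    n_samples = n_samples, n_genes = n_genes,
    lengthscale_mm = lengthscale_mm, nugget_var = nugget_var,
    n_networks = length(network_sizes), network_sizes = network_sizes,
    n_tissue_parcels = 6, seed = seed
  )
  ds <- simulate_dataset(cfg)
  list(ds = ds, edges = build_edge_table(ds$samples, ds$expression))
}

# Exact null distribution of SF for a tiny sample set by enumerating every
# placement of the network labels; the independent oracle for the
# Monte-Carlo permutation null. Returns atoms (unique SF values) and their
# exact probabilities.
exact_sf_null <- function(edges, networks, positive_only = TRUE) {
  n <- length(networks)
  labeled <- which(networks != "none")
  k <- length(labeled)
  stopifnot(length(unique(networks[labeled])) == 1) # single network
  placements <- utils::combn(n, k)
  sf_vals <- apply(placements, 2, function(members) {
    lab <- rep("none", n)
    lab[members] <- "net"
    e <- edges
    e$wi <- lab[e$i] == lab[e$j] & lab[e$i] != "none"
    strength_fraction(e, positive_only = positive_only)
  })
  atoms <- sort(unique(round(sf_vals, 12)))
  probs <- vapply(atoms, function(a) mean(round(sf_vals, 12) == a),
                  numeric(1))
  list(atoms = atoms, probs = probs)
}
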