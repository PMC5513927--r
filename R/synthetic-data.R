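#' Configuration for the synthetic spatial expression generator
#'
#' Bundles and validates the parameters of the synthetic data model: a point
#' cloud of tissue samples drawn uniformly in a 3D box, per-gene expression
#' drawn from a zero-mean Gaussian process with exponential spatial
#' covariance, a handful of contiguous "functional networks" grown around
#' random centers, and a coarse Voronoi "tissue class" parcellation.
#'
#' The covariance between two samples at Euclidean distance `d` mm is
#' `signal_var * exp(-d / lengthscale_mm)`, plus `nugget_var` on the
#' diagonal. The exponential (rather than squared-exponential) kernel gives
#' the steep short-range decay that flattens out by a couple of length
#' scales, which is the regime in which same-tissue-class edge removal fails
#' to control proximity.
#'
#' @param n_samples Number of tissue samples (>= 2).
#' @param n_genes Number of genes (independent GP draws).
#' @param domain Axis-aligned box extents in mm; default `c(140, 170, 120)`,
#'   roughly the bounding box of a human cortex in MNI coordinates.
#' @param lengthscale_mm Spatial covariance length scale lambda in mm.
#' @param signal_var Marginal variance of the spatially structured component.
#' @param nugget_var Non-negative iid noise variance added on the diagonal.
#' @param n_networks Number of contiguous functional networks K (>= 0).
#' @param network_sizes Integer vector of length K; samples per network.
#' @param n_tissue_parcels Number of Voronoi tissue classes T (>= 1).
#' @param seed Integer seed; every generator is a pure function of
#'   (config, seed).
#' @return An object of class `synthetic_config` (a validated list).
#' @seealso [simulate_dataset()] for the one-call generator.
#' @export
synthetic_config <- function(n_samples = 500,
                             n_genes = 500,
                             domain = c(140, 170, 120),
                             lengthscale_mm = 20,
                             signal_var = 1,
                             nugget_var = 1,
                             n_networks = 4,
                             network_sizes = rep(25L, 4),
                             n_tissue_parcels = 32,
                             seed = 1L) {
  n_samples <- as.integer(n_samples)
  n_genes <- as.integer(n_genes)
  n_networks <- as.integer(n_networks)
  network_sizes <- as.integer(network_sizes)
  n_tissue_parcels <- as.integer(n_tissue_parcels)

  if (is.na(n_samples) || n_samples < 2) {
    stopf("`n_samples` must be an integer >= 2")
  }
  if (is.na(n_genes) || n_genes < 2) {
    stopf("`n_genes` must be an integer >= 2")
  }
  if (length(domain) != 3 || any(!is.finite(domain)) || any(domain <= 0)) {
    stopf("`domain` must be three positive box extents in mm")
  }
  if (!is.finite(lengthscale_mm) || lengthscale_mm <= 0) {
    stopf("`lengthscale_mm` must be > 0")
  }
  if (!is.finite(signal_var) || signal_var <= 0) {
    stopf("`signal_var` must be > 0")
  }
  if (!is.finite(nugget_var) || nugget_var < 0) {
    stopf("`nugget_var` must be >= 0")
  }
  if (n_networks < 0) stopf("`n_networks` must be >= 0")
  if (length(network_sizes) != n_networks) {
    stopf("`network_sizes` must have length `n_networks` (%d)", n_networks)
  }
  if (n_networks > 0 && any(network_sizes < 1)) {
    stopf("all `network_sizes` must be positive")
  }
  if (sum(network_sizes) > n_samples) {
    stopf("sum(network_sizes) = %d exceeds n_samples = %d",
          sum(network_sizes), n_samples)
  }
  if (is.na(n_tissue_parcels) || n_tissue_parcels < 1) {
    stopf("`n_tissue_parcels` must be >= 1")
  }
  if (n_tissue_parcels > n_samples) {
    stopf("`n_tissue_parcels` (%d) cannot exceed `n_samples` (%d)",
          n_tissue_parcels, n_samples)
  }

  structure(
    list(
      n_samples = n_samples, n_genes = n_genes, domain = as.numeric(domain),
      lengthscale_mm = as.numeric(lengthscale_mm),
      signal_var = as.numeric(signal_var),
      nugget_var = as.numeric(nugget_var),
      n_networks = n_networks, network_sizes = network_sizes,
      n_tissue_parcels = n_tissue_parcels, seed = as.integer(seed)
    ),
    class = "synthetic_config"
  )
}

#' Draw sample coordinates uniformly in the configured box
#'
#' @param config A [synthetic_config()].
#' @return An `n_samples` x 3 numeric matrix of coordinates in mm, columns
#'   `x_mm`, `y_mm`, `z_mm`. Any exactly duplicated points are perturbed by
#'   1e-6 mm so that all pairwise distances are strictly positive.
#' @export
gen_coordinates <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_samples
  with_seed(child_seed(config$seed, 1L), {
    coords <- cbind(
      x_mm = stats::runif(n, 0, config$domain[1]),
      y_mm = stats::runif(n, 0, config$domain[2]),
      z_mm = stats::runif(n, 0, config$domain[3])
    )
    # uniform draws essentially never coincide, but a duplicated point would
    # put a zero distance into the correlation-vs-distance regression
    dup <- duplicated(coords)
    while (any(dup)) {
      coords[dup, ] <- coords[dup, ] +
        matrix(stats::rnorm(3 * sum(dup), sd = 1e-6), ncol = 3)
      dup <- duplicated(coords)
    }
    rownames(coords) <- sprintf("S%03d", seq_len(n))
    coords
  })
}

# Exponential spatial covariance over a coordinate cloud.
spatial_covariance <- function(coords, lengthscale_mm, signal_var, nugget_var) {
  d <- as.matrix(stats::dist(coords))
  k <- signal_var * exp(-d / lengthscale_mm)
  diag(k) <- diag(k) + nugget_var
  k
}

#' Draw spatially autocorrelated expression over a point cloud
#'
#' Each gene is an independent draw from a zero-mean Gaussian process over
#' the samples with covariance
#' `k(d) = signal_var * exp(-d / lengthscale_mm) + nugget_var * 1[d == 0]`.
#' The covariance is factorized by Cholesky decomposition; if factorization
#' fails, diagonal jitter starting at 1e-8 is doubled until it succeeds
#' (giving up above 1e-2).
#'
#' @param coords Coordinate matrix from [gen_coordinates()].
#' @param config A [synthetic_config()].
#' @return A `n_genes` x `n_samples` numeric matrix, rows named `G...`,
#'   columns named by sample.
#' @export
gen_expression <- function(coords, config) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!all(is.finite(coords))) stopf("coordinates must be finite")
  n <- nrow(coords)
  k <- spatial_covariance(coords, config$lengthscale_mm,
                          config$signal_var, config$nugget_var)
  ch <- NULL
  jitter <- 0
  repeat {
    ch <- tryCatch(chol(k + diag(jitter, n)), error = function(e) NULL)
    if (!is.null(ch)) break
    jitter <- if (jitter == 0) 1e-8 else jitter * 2
    if (jitter > 1e-2) {
      stopf("spatial covariance not factorizable even with jitter up to 1e-2")
    }
  }
  with_seed(child_seed(config$seed, 2L), {
    z <- matrix(stats::rnorm(n * config$n_genes), nrow = n)
    expr <- t(crossprod(ch, z)) # genes x samples
    dimnames(expr) <- list(sprintf("G%04d", seq_len(config$n_genes)),
                           rownames(coords))
    expr
  })
}

# Round-robin contiguous cluster growth shared by gen_networks() and
# random_cluster_sets(): each cluster, in index order, claims its nearest
# unclaimed sample (by distance to the cluster's center; ties broken by
# lowest sample index) until it reaches its target size. Round-robin keeps
# one cluster from exhausting a whole region before the others start.
grow_clusters <- function(coords, center_idx, sizes) {
  n <- nrow(coords)
  k <- length(center_idx)
  labels <- integer(n) # 0 = unclaimed
  if (k == 0) return(labels)
  # per-cluster preference order over samples
  pref <- lapply(center_idx, function(ci) {
    d <- sqrt(colSums((t(coords) - coords[ci, ])^2))
    order(d, seq_len(n))
  })
  ptr <- rep(1L, k)
  claimed <- integer(k)
  repeat {
    progressed <- FALSE
    for (cl in seq_len(k)) {
      if (claimed[cl] >= sizes[cl]) next
      p <- ptr[cl]
      while (p <= n && labels[pref[[cl]][p]] != 0L) p <- p + 1L
      if (p > n) stopf("cluster %d cannot reach its target size", cl)
      labels[pref[[cl]][p]] <- cl
      ptr[cl] <- p + 1L
      claimed[cl] <- claimed[cl] + 1L
      progressed <- TRUE
    }
    if (all(claimed >= sizes)) break
    if (!progressed) stopf("cluster growth stalled; sizes infeasible")
  }
  labels
}

#' Assign contiguous network labels by seeded cluster growth
#'
#' `K` cluster centers are chosen uniformly without replacement from the
#' sample points; clusters then grow round-robin, each claiming its nearest
#' unclaimed sample until it reaches its target size. Samples claimed by no
#' cluster are labeled `"none"`. This produces spatially contiguous networks
#' whose within-network edges are systematically shorter than out-of-network
#' edges — the geometry that drives the proximity confound.
#'
#' @inheritParams gen_expression
#' @return Character vector of length `n_samples` with values
#'   `"network_1" ... "network_K"` or `"none"`.
#' @export
gen_networks <- function(coords, config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- nrow(coords)
  if (sum(config$network_sizes) > n) {
    stopf("network sizes exceed available samples")
  }
  if (config$n_networks == 0) return(rep("none", n))
  with_seed(child_seed(config$seed, 3L), {
    centers <- sample.int(n, config$n_networks)
    lab <- grow_clusters(coords, centers, config$network_sizes)
    ifelse(lab == 0L, "none", paste0("network_", lab))
  })
}

#' Assign tissue-class labels by Voronoi parcellation
#'
#' `T` seed points are chosen uniformly from the samples and every sample is
#' labeled by its nearest seed. A Voronoi parcellation deliberately exhibits
#' the boundary pathology of label-based proximity control: pairs straddling
#' a parcel boundary can be closer together than pairs deep inside one
#' parcel, so removing same-class edges removes the wrong edges.
#'
#' @inheritParams gen_expression
#' @return Character vector of length `n_samples`, values `"tissue_1" ...`.
#' @export
gen_tissue_parcellation <- function(coords, config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- nrow(coords)
  t_parc <- config$n_tissue_parcels
  if (t_parc > n) stopf("more tissue parcels than samples")
  with_seed(child_seed(config$seed, 4L), {
    seeds <- sample.int(n, t_parc)
    d_to_seed <- vapply(seeds, function(si) {
      sqrt(colSums((t(coords) - coords[si, ])^2))
    }, numeric(n))
    lab <- max.col(-d_to_seed, ties.method = "first")
    paste0("tissue_", lab)
  })
}

#' Generate a complete synthetic dataset
#'
#' Runs [gen_coordinates()], [gen_expression()], [gen_networks()] and
#' [gen_tissue_parcellation()] and assembles the results into the sample
#' annotation table / expression matrix pair used by the rest of the
#' package.
#'
#' @param config A [synthetic_config()].
#' @return A list with `samples` (a data.frame with columns `sample_id`,
#'   `x_mm`, `y_mm`, `z_mm`, `tissue_class`, `network`) and `expression`
#'   (a genes x samples matrix), plus the `config` used.
#' @examples
#' ds <- simulate_dataset(synthetic_config(n_samples = 60, n_genes = 50,
#'                                         network_sizes = rep(10L, 4),
#'                                         seed = 1))
#' table(ds$samples$network)
#' @export
simulate_dataset <- function(config = synthetic_config()) {
  coords <- gen_coordinates(config)
  expr <- gen_expression(coords, config)
  networks <- gen_networks(coords, config)
  tissue <- gen_tissue_parcellation(coords, config)
  samples <- data.frame(
    sample_id = rownames(coords),
    x_mm = coords[, "x_mm"],
    y_mm = coords[, "y_mm"],
    z_mm = coords[, "z_mm"],
    tissue_class = tissue,
    network = networks,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  list(samples = validate_samples(samples), expression = expr,
       config = config)
}
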