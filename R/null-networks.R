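#' Random contiguous cluster sets matched to network sizes
#'
#' For each of `n_sets` draws, cluster centers are chosen uniformly without
#' replacement from the sample points and grown into contiguous clusters of
#' exactly the reference sizes (round-robin nearest-unclaimed growth, ties
#' broken by lowest sample index) — the same growth rule the synthetic
#' network generator uses. Remaining samples are labeled `"none"`. Each set
#' therefore preserves the total number of labeled (Wi) nodes exactly.
#' Centers are drawn from sampled locations (not free space) so clusters
#' are never empty; sets may overlap the real networks by chance and no
#' exclusion is applied.
#'
#' @param samples A validated sample table (coordinates are used).
#' @param reference_sizes Integer vector of cluster sizes, typically the
#'   observed network label counts.
#' @param n_sets Number of independent cluster sets to draw.
#' @param seed Integer seed.
#' @return A list of `n_sets` character label vectors (values
#'   `"cluster_1" ...` / `"none"`), each of length `nrow(samples)`.
#' @export
random_cluster_sets <- function(samples, reference_sizes, n_sets = 100,
                                seed = NULL) {
  samples <- validate_samples(samples)
  reference_sizes <- as.integer(reference_sizes)
  n <- nrow(samples)
  if (any(reference_sizes < 1)) stopf("all reference sizes must be positive")
  if (sum(reference_sizes) > n) {
    stopf("sum(reference_sizes) = %d exceeds n_samples = %d",
          sum(reference_sizes), n)
  }
  coords <- sample_coords(samples)
  k <- length(reference_sizes)
  with_seed(seed, {
    lapply(seq_len(n_sets), function(s) {
      centers <- sample.int(n, k)
      lab <- grow_clusters(coords, centers, reference_sizes)
      ifelse(lab == 0L, "none", paste0("cluster_", lab))
    })
  })
}

#' Sizes of the observed (non-"none") network labels
#'
#' @param samples A sample table.
#' @return Named integer vector of label counts, alphabetical by label.
#' @export
network_sizes <- function(samples) {
  samples <- validate_samples(samples)
  tab <- table(samples$network[samples$network != "none"])
  stats::setNames(as.integer(tab), names(tab))
}

#' Null-network experiment: are randomly placed clusters also "significant"?
#'
#' Repeats the SF permutation test after replacing the real network labels
#' with each of `n_sets` randomly placed, size-matched contiguous cluster
#' sets, keeping the edge weights, distances, and inclusion filters of the
#' real analysis fixed. Each set gets its own permutation null. The report
#' gives the fraction of sets significant at 0.05 and at 0.001. If spatial
#' proximity alone drove the real result, random contiguous clusters are
#' just as "significant" as the real networks — the experiment's point. SF
#' magnitudes are deliberately not compared across sets: SF is a function
#' of the number of Wi edges, which varies with cluster placement.
#'
#' @param edges An `edge_table` built from the real analysis, with whatever
#'   filters the real analysis used already applied.
#' @param samples The sample table (its coordinates place the clusters; its
#'   own network labels are only used for `reference_sizes` default).
#' @param n_sets Number of random cluster sets.
#' @param n_perm Permutations per set.
#' @param seed Integer seed.
#' @param positive_only Passed to the SF computation.
#' @param reference_sizes Cluster sizes; defaults to the observed
#'   [network_sizes()].
#' @return A list of class `null_network_report`: `p_values` (length
#'   `n_sets`, NA where degenerate), `sf` (observed SF per set),
#'   `frac_p05`, `frac_p001` (fractions over non-degenerate sets),
#'   `n_degenerate`, `n_sets`, `n_perm`.
#' @export
null_network_experiment <- function(edges, samples, n_sets = 100,
                                    n_perm = 1000, seed = NULL,
                                    positive_only = TRUE,
                                    reference_sizes = NULL) {
  stopifnot(inherits(edges, "edge_table"))
  samples <- validate_samples(samples)
  if (is.null(reference_sizes)) reference_sizes <- network_sizes(samples)
  if (!length(reference_sizes)) {
    stopf("no reference sizes: the sample table has no network labels")
  }
  sets <- random_cluster_sets(samples, reference_sizes, n_sets = n_sets,
                              seed = child_seed(seed, 7L))
  p_values <- rep(NA_real_, n_sets)
  sf_obs <- rep(NA_real_, n_sets)
  for (s in seq_len(n_sets)) {
    relabeled <- samples
    relabeled$network <- sets[[s]]
    net <- sets[[s]]
    ed <- edges
    ed$wi <- net[ed$i] == net[ed$j] & net[ed$i] != "none"
    res <- tryCatch(
      sf_test(ed, relabeled, n_perm = n_perm,
              seed = child_seed(seed, 1000L + s),
              positive_only = positive_only),
      error = function(e) NULL
    )
    if (!is.null(res)) {
      p_values[s] <- res$p_value
      sf_obs[s] <- res$sf
    }
  }
  ok <- !is.na(p_values)
  structure(
    list(
      p_values = p_values, sf = sf_obs,
      frac_p05 = mean(p_values[ok] < 0.05),
      frac_p001 = mean(p_values[ok] < 0.001),
      n_degenerate = sum(!ok), n_sets = n_sets, n_perm = n_perm,
      reference_sizes = reference_sizes
    ),
    class = "null_network_report"
  )
}

#' @export
print.null_network_report <- function(x, ...) {
  cat(sprintf(
    paste0("<null_network_report> %d size-matched random cluster sets ",
           "(%d permutations each)\n  significant at 0.05: %.1f%%   ",
           "at 0.001: %.1f%%   degenerate sets: %d\n"),
    x$n_sets, x$n_perm, 100 * x$frac_p05, 100 * x$frac_p001, x$n_degenerate
  ))
  invisible(x)
}
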