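#' Within-network strength fraction (SF)
#'
#' The strength fraction is the sum of edge weights over included
#' within-network (Wi) edges divided by the sum over all included edges.
#' With `positive_only = TRUE` (the default, matching the original
#' analysis) only edges with strictly positive weight contribute to either
#' sum, so SF lies in \[0, 1\]. With `positive_only = FALSE` signed weights
#' are summed as-is, which permits SF outside \[0, 1\] — in particular the
#' large negative SF that appears after distance residualization, when
#' roughly half the weights are negative.
#'
#' @param edges An `edge_table` (see [build_edge_table()]); if it has been
#'   through [residualize_distance()], residual weights are used.
#' @param positive_only Restrict both sums to edges with weight > 0.
#' @return A single numeric SF value.
#' @export
strength_fraction <- function(edges, positive_only = TRUE) {
  stopifnot(inherits(edges, "edge_table"))
  w <- edge_weights(edges)
  inc <- edges$included & !is.na(w)
  if (!any(inc)) stopf("no included edges: the denominator is empty")
  if (positive_only) {
    contrib <- inc & w > 0
    if (!any(contrib)) {
      stopf("no included edge has positive weight: the denominator is empty")
    }
  } else {
    contrib <- inc
  }
  denom <- sum(w[contrib])
  if (!positive_only && abs(denom) < .Machine$double.eps) {
    stopf("signed weights sum to zero over included edges; SF undefined")
  }
  sum(w[contrib & edges$wi]) / denom
}

# Shared fast path for the permutation null. Precomputes the contributing
# edge set (fixed across permutations: the included mask and any positivity
# cutoff depend on weights and filters, not on network labels) and integer
# label codes (0 = "none"), then shuffles labels and re-sums the Wi
# numerator; the denominator never changes under shuffling.
perm_null_engine <- function(edges, networks, n_perm, seed, positive_only) {
  w <- edge_weights(edges)
  inc <- edges$included & !is.na(w)
  if (!any(inc)) stopf("no included edges: the denominator is empty")
  contrib <- if (positive_only) inc & w > 0 else inc
  if (!any(contrib)) {
    stopf("no included edge has positive weight: the denominator is empty")
  }
  denom <- sum(w[contrib])
  if (!positive_only && abs(denom) < .Machine$double.eps) {
    stopf("signed weights sum to zero over included edges; SF undefined")
  }
  ei <- edges$i[contrib]
  ej <- edges$j[contrib]
  wc <- w[contrib]
  net_levels <- setdiff(unique(networks), "none")
  lab <- match(networks, net_levels)
  lab[is.na(lab)] <- 0L
  lab <- as.integer(lab)
  n <- length(networks)
  with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      nl <- lab[sample.int(n)]
      a <- nl[ei]
      sum(wc[a == nl[ej] & a > 0L]) / denom
    }, numeric(1))
  })
}

#' Label-permutation null distribution of the SF
#'
#' For each permutation the per-sample network labels (including `"none"`)
#' are uniformly shuffled, the Wi flags recomputed, and SF recomputed with
#' the same positivity setting. The edge inclusion mask (tissue or distance
#' filters) stays fixed: filters depend on geometry and tissue class, not on
#' which samples carry a network label. Note what the shuffle does
#' physically: long out-of-network edges get relabeled Wi, so the null
#' predicts the SF a size-matched but spatially unstructured label
#' assignment would achieve. The test is exact only if samples are
#' exchangeable — which spatially autocorrelated expression violates, the
#' central point of the audit.
#'
#' @param edges An `edge_table`.
#' @param samples The sample table the edges were built from (its `network`
#'   column is what gets shuffled).
#' @param n_perm Number of permutations (>= 1).
#' @param seed Integer seed; the null is a pure function of it.
#' @param positive_only Passed through to the SF computation.
#' @return Numeric vector of `n_perm` null SF values.
#' @export
permutation_null <- function(edges, samples, n_perm = 1000, seed = NULL,
                             positive_only = TRUE) {
  stopifnot(inherits(edges, "edge_table"))
  samples <- validate_samples(samples)
  if (n_perm < 1) stopf("`n_perm` must be >= 1")
  perm_null_engine(edges, samples$network, as.integer(n_perm), seed,
                   positive_only)
}

#' One-sided permutation p-value with add-one correction
#'
#' `p = (1 + #\{null_sf >= sf\}) / (1 + n_perm)`; ties count against the
#' observed value. The add-one correction keeps the p-value strictly
#' positive — an observed SF above every null value yields
#' `p = 1 / (n_perm + 1)`, reported downstream as a bound, never as 0.
#'
#' @param sf Observed SF.
#' @param null_sf Numeric vector of null SF values.
#' @return p-value in (0, 1].
#' @export
sf_pvalue <- function(sf, null_sf) {
  if (!length(null_sf)) stopf("empty null distribution")
  (1 + sum(null_sf >= sf)) / (1 + length(null_sf))
}

#' Strength-fraction permutation test
#'
#' Computes the observed SF, its label-permutation null, and the one-sided
#' p-value, and records the edge counts the SF was computed over (SF is a
#' function of the number of Wi edges, so SF values are only comparable
#' between analyses with matched Wi edge counts).
#'
#' @inheritParams permutation_null
#' @param d_min Minimum-distance threshold already applied to `edges`, if
#'   any; recorded for reporting only.
#' @param correction Label for the proximity correction in effect: one of
#'   `"none"`, `"tissue"`, `"distance"`, `"regression"`.
#' @return An object of class `sf_result`: a list with `sf`, `null_sf`,
#'   `p_value`, `n_within_edges`, `n_total_edges`, `positive_only`,
#'   `d_min`, `correction`, `n_perm`, `degenerate`.
#' @export
sf_test <- function(edges, samples, n_perm = 1000, seed = NULL,
                    positive_only = TRUE, d_min = NULL,
                    correction = c("none", "tissue", "distance",
                                   "regression")) {
  correction <- match.arg(correction)
  sf <- strength_fraction(edges, positive_only = positive_only)
  null_sf <- permutation_null(edges, samples, n_perm = n_perm, seed = seed,
                              positive_only = positive_only)
  w <- edge_weights(edges)
  inc <- edges$included & !is.na(w)
  contrib <- if (positive_only) inc & w > 0 else inc
  structure(
    list(
      sf = sf, null_sf = null_sf, p_value = sf_pvalue(sf, null_sf),
      n_within_edges = sum(contrib & edges$wi),
      n_total_edges = sum(contrib),
      positive_only = positive_only,
      d_min = d_min, correction = correction,
      n_perm = length(null_sf), degenerate = FALSE
    ),
    class = "sf_result"
  )
}

degenerate_sf_result <- function(message, positive_only, d_min, correction) {
  structure(
    list(sf = NA_real_, null_sf = numeric(0), p_value = NA_real_,
         n_within_edges = 0L, n_total_edges = 0L,
         positive_only = positive_only, d_min = d_min,
         correction = correction, n_perm = 0L, degenerate = TRUE,
         message = message),
    class = "sf_result"
  )
}

#' @export
print.sf_result <- function(x, ...) {
  lab <- if (!is.null(x$d_min)) sprintf("d >= %g mm", x$d_min) else x$correction
  if (x$degenerate) {
    cat(sprintf("<sf_result> [%s] degenerate: %s\n", lab, x$message))
    return(invisible(x))
  }
  p_lab <- if (x$p_value <= 1 / (x$n_perm + 1)) {
    sprintf("p < %g", 1 / x$n_perm)
  } else {
    sprintf("p = %.4g", x$p_value)
  }
  cat(sprintf(
    "<sf_result> [%s] SF = %.4f, %s (%d permutations; %d Wi / %d edges%s)\n",
    lab, x$sf, p_lab, x$n_perm, x$n_within_edges, x$n_total_edges,
    if (x$positive_only) ", positive weights only" else ", signed weights"
  ))
  invisible(x)
}

#' Distance-threshold SF sweep
#'
#' Recomputes the SF test after removing edges shorter than each threshold
#' in turn, each with its own permutation null on the filtered edge set
#' (the edge universe changes, so nulls are never reused across
#' thresholds). When `include_tissue = TRUE` the sweep is prefixed by the
#' label-based condition — same-tissue edges removed, no distance filter —
#' under the name `"tissue"`, the proximity control the audited study used.
#' A threshold that empties the denominator yields a degenerate, flagged
#' result rather than aborting the sweep.
#'
#' @inheritParams permutation_null
#' @param thresholds Ascending numeric vector of minimum distances in mm.
#' @param include_tissue Prepend the same-tissue-filter condition.
#' @return A list of [sf_test()] results, named `"tissue"` (optional) and
#'   `"d<threshold>"`.
#' @export
distance_sweep <- function(edges, samples, thresholds, n_perm = 1000,
                           seed = NULL, positive_only = TRUE,
                           include_tissue = TRUE) {
  stopifnot(inherits(edges, "edge_table"))
  if (is.unsorted(thresholds)) {
    stopf("`thresholds` must be sorted ascending")
  }
  conditions <- list()
  if (include_tissue) {
    conditions[["tissue"]] <- list(table = filter_same_tissue(edges),
                                   d_min = NULL, correction = "tissue")
  }
  for (t_mm in thresholds) {
    conditions[[sprintf("d%g", t_mm)]] <- list(
      table = filter_min_distance(edges, t_mm),
      d_min = t_mm, correction = "distance"
    )
  }
  results <- vector("list", length(conditions))
  names(results) <- names(conditions)
  for (k in seq_along(conditions)) {
    cond <- conditions[[k]]
    results[[k]] <- tryCatch(
      sf_test(cond$table, samples, n_perm = n_perm,
              seed = child_seed(seed, 100L + k),
              positive_only = positive_only,
              d_min = cond$d_min,
              correction = if (is.null(cond$d_min)) "tissue" else "distance"),
      error = function(e) {
        degenerate_sf_result(conditionMessage(e), positive_only,
                             cond$d_min,
                             if (is.null(cond$d_min)) "tissue" else "distance")
      }
    )
  }
  results
}
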