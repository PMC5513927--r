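#' Correlation between edge weight and edge distance
#'
#' Pearson correlation between the tissue-tissue correlation `r` and the
#' Euclidean distance `d` over the currently included edges, with the
#' standard t-distribution p-value. A clearly negative R is the signature
#' of the spatial confound: nearby samples have more similar expression.
#' Whether the same-tissue filter is applied first is the caller's choice —
#' the confound typically survives it.
#'
#' @param edges An `edge_table` with >= 3 included edges.
#' @return A list with `R` (Pearson correlation), `p` (two-sided), and `n`
#'   (number of included edges).
#' @export
distance_correlation_test <- function(edges) {
  stopifnot(inherits(edges, "edge_table"))
  inc <- edges$included
  if (sum(inc) < 3) stopf("need >= 3 included edges")
  r <- edges$r[inc]
  d <- edges$d[inc]
  if (stats::sd(r) == 0) stopf("edge weights are constant; R undefined")
  if (stats::sd(d) == 0) stopf("edge distances are constant; R undefined")
  ct <- stats::cor.test(r, d, method = "pearson")
  list(R = unname(ct$estimate), p = ct$p.value, n = sum(inc))
}

#' Two-sample t-test of within- vs out-of-network edge distances
#'
#' Compares the Euclidean distances of included within-network (Wi) edges
#' against included out-of-network (T-W) edges. Pooled-variance by default,
#' with `df = n_wi + n_tw - 2`; Welch is available behind `pooled = FALSE`.
#' The sign convention is Wi minus T-W: negative t means Wi edges are
#' shorter on average, i.e. the network labels are spatially clustered and
#' the permutation null (which hands Wi status to long T-W edges) is biased
#' against the observed SF.
#'
#' @param edges An `edge_table` with >= 2 included edges in each group.
#' @param pooled Use the pooled-variance t-test (default); `FALSE` for
#'   Welch.
#' @return A list with `t`, `df`, `mean_wi` (mm), `mean_tw` (mm), `p`
#'   (two-sided), `n_wi`, `n_tw`.
#' @export
within_out_distance_ttest <- function(edges, pooled = TRUE) {
  stopifnot(inherits(edges, "edge_table"))
  inc <- edges$included
  d_wi <- edges$d[inc & edges$wi]
  d_tw <- edges$d[inc & !edges$wi]
  if (length(d_wi) < 2 || length(d_tw) < 2) {
    stopf("need >= 2 included edges in each of the Wi and T-W groups")
  }
  tt <- stats::t.test(d_wi, d_tw, var.equal = pooled)
  list(
    t = unname(tt$statistic), df = unname(tt$parameter),
    mean_wi = mean(d_wi), mean_tw = mean(d_tw), p = tt$p.value,
    n_wi = length(d_wi), n_tw = length(d_tw)
  )
}

#' Binned mean edge weight by distance
#'
#' A visualization aid: mean edge weight within equal-width distance bins
#' over the included edges. Makes the shape of the decay visible without
#' committing to a parametric curve.
#'
#' @param edges An `edge_table`.
#' @param n_bins Number of equal-width distance bins.
#' @return A data.frame with `bin_mid_mm`, `mean_r`, `n_edges`.
#' @export
binned_distance_profile <- function(edges, n_bins = 20) {
  stopifnot(inherits(edges, "edge_table"))
  inc <- edges$included
  if (!any(inc)) stopf("no included edges")
  d <- edges$d[inc]
  r <- edges$r[inc]
  breaks <- seq(min(d), max(d), length.out = n_bins + 1)
  bin <- cut(d, breaks, include.lowest = TRUE)
  data.frame(
    bin_mid_mm = (breaks[-1] + breaks[-length(breaks)]) / 2,
    mean_r = as.numeric(tapply(r, bin, mean)),
    n_edges = as.integer(table(bin))
  )
}
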