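#' Validate a sample annotation table
#'
#' Checks the sample table contract used throughout the package: unique
#' sample IDs, finite 3D coordinates in mm, and character tissue-class and
#' network labels (an empty or missing network is normalized to `"none"`).
#'
#' @param samples A data.frame with columns `sample_id`, `x_mm`, `y_mm`,
#'   `z_mm`, `tissue_class`, `network`.
#' @return The validated (and normalized) data.frame.
#' @export
validate_samples <- function(samples) {
  required <- c("sample_id", "x_mm", "y_mm", "z_mm", "tissue_class", "network")
  missing_cols <- setdiff(required, names(samples))
  if (length(missing_cols)) {
    stopf("sample table is missing column(s): %s",
          paste(missing_cols, collapse = ", "))
  }
  samples$sample_id <- as.character(samples$sample_id)
  if (anyDuplicated(samples$sample_id)) {
    dup <- unique(samples$sample_id[duplicated(samples$sample_id)])
    stopf("duplicate sample_id(s): %s", paste(dup, collapse = ", "))
  }
  for (col in c("x_mm", "y_mm", "z_mm")) {
    v <- suppressWarnings(as.numeric(samples[[col]]))
    if (any(!is.finite(v))) {
      stopf("non-finite or non-numeric values in coordinate column `%s`", col)
    }
    samples[[col]] <- v
  }
  samples$tissue_class <- as.character(samples$tissue_class)
  net <- as.character(samples$network)
  net[is.na(net) | net == ""] <- "none"
  samples$network <- net
  samples
}

sample_coords <- function(samples) {
  m <- as.matrix(samples[, c("x_mm", "y_mm", "z_mm")])
  rownames(m) <- samples$sample_id
  m
}

#' Tissue-tissue correlation matrix
#'
#' Pearson correlation between every pair of samples' expression profiles,
#' computed across genes. With `standardize = TRUE` (the default) each gene
#' is z-scored across samples first, so no single high-mean or high-variance
#' gene dominates the sample-sample correlations; genes that are constant
#' across samples cannot be z-scored and are dropped with a warning.
#'
#' @param expr A genes x samples numeric matrix (>= 2 genes).
#' @param standardize Z-score each gene across samples before correlating.
#' @return A samples x samples symmetric correlation matrix with unit
#'   diagonal.
#' @export
tissue_correlation <- function(expr, standardize = TRUE) {
  if (!is.matrix(expr) || nrow(expr) < 2) {
    stopf("`expr` must be a genes x samples matrix with >= 2 genes")
  }
  if (any(!is.finite(expr))) {
    stopf("`expr` contains non-finite values; clean it first")
  }
  if (standardize) {
    gene_sd <- apply(expr, 1, stats::sd)
    if (any(gene_sd == 0)) {
      warning(sprintf("dropping %d constant gene(s) before standardization",
                      sum(gene_sd == 0)), call. = FALSE)
      expr <- expr[gene_sd > 0, , drop = FALSE]
      if (nrow(expr) < 2) stopf("fewer than 2 non-constant genes remain")
    }
    expr <- t(scale(t(expr)))
  }
  profile_sd <- apply(expr, 2, stats::sd)
  if (any(profile_sd == 0)) {
    bad <- colnames(expr)[profile_sd == 0]
    stopf("zero-variance expression profile for sample(s): %s",
          paste(bad, collapse = ", "))
  }
  r <- stats::cor(expr)
  diag(r) <- 1
  r
}

#' Pairwise Euclidean distances between samples
#'
#' @param samples A validated sample table (see [validate_samples()]).
#' @return A samples x samples symmetric matrix of Euclidean distances in mm
#'   with zero diagonal. Distances are computed in the 3D coordinate frame
#'   of the annotation (MNI-style mm).
#' @export
pairwise_distance <- function(samples) {
  samples <- validate_samples(samples)
  as.matrix(stats::dist(sample_coords(samples)))
}

#' Build the tissue-tissue correlation edge table
#'
#' One row per unordered sample pair (i < j) holding the correlation weight
#' `r`, the Euclidean distance `d` in mm, the within-network flag `wi`
#' (both endpoints share the same non-`"none"` network label; pairs in two
#' different networks count as out-of-network, T-W), the `same_tissue` flag,
#' and the `included` mask (initially all `TRUE`). Weights are stored
#' signed; any positivity cutoff is applied downstream by the strength
#' fraction itself.
#'
#' @param samples A sample table; see [validate_samples()].
#' @param expr A genes x samples matrix aligned to `samples` (same sample
#'   IDs; any column order).
#' @param standardize Passed to [tissue_correlation()].
#' @return A data.frame of class `edge_table` with columns `i`, `j`
#'   (sample indices), `sample_i`, `sample_j`, `r`, `d`, `wi`,
#'   `same_tissue`, `included`.
#' @export
build_edge_table <- function(samples, expr, standardize = TRUE) {
  samples <- validate_samples(samples)
  if (is.null(colnames(expr))) {
    if (ncol(expr) != nrow(samples)) {
      stopf("expression has %d columns but there are %d samples",
            ncol(expr), nrow(samples))
    }
    colnames(expr) <- samples$sample_id
  }
  missing_samples <- setdiff(samples$sample_id, colnames(expr))
  if (length(missing_samples)) {
    stopf("sample(s) missing from expression matrix: %s",
          paste(missing_samples, collapse = ", "))
  }
  expr <- expr[, samples$sample_id, drop = FALSE]

  n <- nrow(samples)
  rmat <- tissue_correlation(expr, standardize = standardize)
  dmat <- pairwise_distance(samples)

  idx <- which(upper.tri(rmat), arr.ind = TRUE)
  # order rows by (i, j), i < j
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  i <- idx[, 1]
  j <- idx[, 2]
  net <- samples$network
  edges <- data.frame(
    i = i, j = j,
    sample_i = samples$sample_id[i],
    sample_j = samples$sample_id[j],
    r = rmat[idx],
    d = dmat[idx],
    wi = net[i] == net[j] & net[i] != "none",
    same_tissue = samples$tissue_class[i] == samples$tissue_class[j],
    included = TRUE,
    stringsAsFactors = FALSE
  )
  structure(edges, class = c("edge_table", "data.frame"),
            n_samples = n, residualized = FALSE)
}

#' @export
print.edge_table <- function(x, ...) {
  cat(sprintf(
    "<edge_table> %d edges over %d samples (%d included, %d Wi%s)\n",
    nrow(x), attr(x, "n_samples"), sum(x$included), sum(x$wi),
    if (isTRUE(attr(x, "residualized"))) ", distance-residualized" else ""
  ))
  utils::str(as.data.frame(utils::head(x, 3)))
  invisible(x)
}

#' Exclude edges whose endpoints share a tissue class
#'
#' The label-based proximity control: `included` becomes
#' `included & !same_tissue`. The input table is not modified; a new table
#' with the updated mask is returned. Because parcel boundaries are
#' arbitrary, this keeps short cross-parcel edges while discarding long
#' within-parcel ones — the pathology the distance-based filters address.
#'
#' @param edges An `edge_table`.
#' @return The edge table with its `included` mask narrowed.
#' @export
filter_same_tissue <- function(edges) {
  stopifnot(inherits(edges, "edge_table"))
  edges$included <- edges$included & !edges$same_tissue
  edges
}

#' Exclude edges shorter than a minimum distance
#'
#' Removal is strict: an edge is dropped iff `d < d_min`, so an edge at
#' exactly `d_min` mm is retained (a "< 16 mm" condition removes edges
#' strictly shorter than 16 mm).
#'
#' @param edges An `edge_table`.
#' @param d_min Minimum retained distance in mm (>= 0).
#' @return The edge table with its `included` mask narrowed.
#' @export
filter_min_distance <- function(edges, d_min) {
  stopifnot(inherits(edges, "edge_table"))
  if (!is.finite(d_min) || d_min < 0) stopf("`d_min` must be >= 0")
  edges$included <- edges$included & (edges$d >= d_min)
  edges
}

#' Residualize edge weights on distance
#'
#' Fits ordinary least squares of the correlation weight `r` on distance `d`
#' over the currently included edges and replaces the working weight with
#' the residual (stored in a new `weight` column; `r` is kept). This is the
#' linear regression-based distance adjustment: after it, roughly half the
#' included weights are negative by construction (mean-centering), which is
#' why the downstream positivity cutoff becomes consequential.
#'
#' @param edges An `edge_table` with >= 2 included edges at distinct
#'   distances.
#' @return The edge table with a `weight` column of residuals (NA on
#'   excluded edges) and attribute `residualized = TRUE`.
#' @export
residualize_distance <- function(edges) {
  stopifnot(inherits(edges, "edge_table"))
  inc <- edges$included
  if (sum(inc) < 2) stopf("need >= 2 included edges to fit the regression")
  d <- edges$d[inc]
  if (length(unique(d)) < 2) {
    stopf("distance is constant among included edges; slope unidentifiable")
  }
  fit <- stats::lm.fit(cbind(1, d), edges$r[inc])
  edges$weight <- NA_real_
  edges$weight[inc] <- fit$residuals
  attr(edges, "residualized") <- TRUE
  edges
}

# Working weight of an edge table: residualized weight if present, else r.
edge_weights <- function(edges) {
  if (isTRUE(attr(edges, "residualized"))) edges$weight else edges$r
}
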