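# Serialize an sf_result for JSON output: the full null vector is summarized
# (its seed makes it reproducible) and a p-value at the add-one floor is
# additionally reported as the bound "p < 1/n_perm".
sf_report <- function(res) {
  if (res$degenerate) {
    return(list(degenerate = TRUE, message = res$message,
                d_min = res$d_min, correction = res$correction))
  }
  list(
    sf = res$sf,
    p_value = res$p_value,
    p_at_floor = res$p_value <= 1 / (res$n_perm + 1),
    n_within_edges = res$n_within_edges,
    n_total_edges = res$n_total_edges,
    positive_only = res$positive_only,
    d_min = res$d_min,
    correction = res$correction,
    n_perm = res$n_perm,
    null_mean = mean(res$null_sf),
    null_sd = stats::sd(res$null_sf),
    null_q95 = unname(stats::quantile(res$null_sf, 0.95)),
    degenerate = FALSE
  )
}

write_stage_json <- function(x, out_dir, name) {
  path <- file.path(out_dir, paste0(name, ".json"))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  path
}

#' Run the full strength-fraction audit
#'
#' Chains the package's stages into the complete audit of a within-network
#' SF analysis: build the tissue-tissue correlation edge table; run the SF
#' permutation test under the label-based (same-tissue) proximity control;
#' diagnose the spatial confound (weight-vs-distance correlation, Wi vs T-W
#' edge-distance t-test, binned decay profile); sweep minimum-distance edge
#' filters; apply the linear distance-residualization correction in both
#' signed and positive-only modes; and run the null-network experiment with
#' randomly placed size-matched cluster sets. Results are written as an
#' edge-table TSV, one JSON file per stage, and a plain-text summary. Every
#' stochastic stage derives its own seed from `seed` and logs it.
#'
#' @param config A named list (or the result of [read_audit_config()]) with
#'   either a `simulate` block of [synthetic_config()] arguments or
#'   `samples` / `expression` file paths, plus optional `out_dir`,
#'   `n_perm`, `thresholds`, `n_sets`, `seed`, `positive_only`,
#'   `tissue_filter`, `standardize`.
#' @return Invisibly, a list with every stage's in-memory result and the
#'   paths written.
#' @export
run_audit <- function(config) {
  out_dir <- config$out_dir %||% "."
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  n_perm <- as.integer(config$n_perm %||% 1000L)
  n_sets <- as.integer(config$n_sets %||% 100L)
  thresholds <- as.numeric(config$thresholds %||% seq(0, 72, by = 8))
  positive_only <- isTRUE(config$positive_only %||% TRUE)
  tissue_filter <- isTRUE(config$tissue_filter %||% TRUE)
  standardize <- isTRUE(config$standardize %||% TRUE)

  # --- inputs -------------------------------------------------------------
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    sim_args$seed <- as.integer(sim_args$seed %||% seed)
    cfg <- do.call(synthetic_config, sim_args)
    message(sprintf("simulating dataset (seed %d)", cfg$seed))
    ds <- simulate_dataset(cfg)
    samples <- ds$samples
    expr <- ds$expression
    write_samples(samples, file.path(out_dir, "samples.csv"))
    write_expression(expr, file.path(out_dir, "expression.tsv"))
  } else {
    if (is.null(config$samples) || is.null(config$expression)) {
      stopf(paste("config must provide either a `simulate` block or",
                  "`samples` and `expression` paths"))
    }
    samples <- read_samples(config$samples)
    expr <- read_expression(config$expression, samples)
  }

  # --- edge table ---------------------------------------------------------
  edges <- build_edge_table(samples, expr, standardize = standardize)
  base_edges <- if (tissue_filter) filter_same_tissue(edges) else edges
  edge_df <- as.data.frame(base_edges)
  utils::write.table(edge_df, file.path(out_dir, "edges.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)

  # --- naive SF under the label-based control -----------------------------
  sf_seed <- child_seed(seed, 11L)
  message(sprintf("SF permutation test (seed %d, %d permutations)",
                  sf_seed, n_perm))
  naive <- sf_test(base_edges, samples, n_perm = n_perm, seed = sf_seed,
                   positive_only = positive_only,
                   correction = if (tissue_filter) "tissue" else "none")
  write_stage_json(sf_report(naive), out_dir, "sf")

  # --- confound diagnostics -----------------------------------------------
  diag_raw <- distance_correlation_test(edges)
  diag_filt <- distance_correlation_test(base_edges)
  tt <- within_out_distance_ttest(base_edges)
  profile <- binned_distance_profile(base_edges)
  diagnostics <- list(
    distance_correlation_all_edges = diag_raw,
    distance_correlation_after_filter = diag_filt,
    within_out_distance_ttest = tt,
    binned_profile = profile
  )
  write_stage_json(diagnostics, out_dir, "diagnostics")

  # --- distance sweep -----------------------------------------------------
  sweep_seed <- child_seed(seed, 13L)
  message(sprintf("distance sweep (seed %d)", sweep_seed))
  sweep <- distance_sweep(edges, samples, thresholds, n_perm = n_perm,
                          seed = sweep_seed, positive_only = positive_only,
                          include_tissue = TRUE)
  write_stage_json(lapply(sweep, sf_report), out_dir, "sweep")

  # --- regression correction ----------------------------------------------
  reg_seed <- child_seed(seed, 17L)
  message(sprintf("regression correction (seed %d)", reg_seed))
  # The regression is fit over all edges; the same-tissue filter is applied
  # afterwards. Residuals of an intercept model sum to zero over the fitted
  # set, so a signed SF is only well defined on a proper subset of it.
  resid_edges <- residualize_distance(edges)
  if (tissue_filter) resid_edges <- filter_same_tissue(resid_edges)
  reg_signed <- sf_test(resid_edges, samples, n_perm = n_perm,
                        seed = reg_seed, positive_only = FALSE,
                        correction = "regression")
  reg_pos <- sf_test(resid_edges, samples, n_perm = n_perm,
                     seed = child_seed(seed, 19L), positive_only = TRUE,
                     correction = "regression")
  write_stage_json(list(signed = sf_report(reg_signed),
                        positive_only = sf_report(reg_pos)),
                   out_dir, "regression")

  # --- null networks ------------------------------------------------------
  nn_seed <- child_seed(seed, 23L)
  message(sprintf("null-network experiment (seed %d, %d sets)",
                  nn_seed, n_sets))
  nullnets <- null_network_experiment(base_edges, samples, n_sets = n_sets,
                                      n_perm = n_perm, seed = nn_seed,
                                      positive_only = positive_only)
  write_stage_json(
    list(n_sets = nullnets$n_sets, n_perm = nullnets$n_perm,
         frac_p05 = nullnets$frac_p05, frac_p001 = nullnets$frac_p001,
         n_degenerate = nullnets$n_degenerate,
         p_values = nullnets$p_values),
    out_dir, "nullnets"
  )

  # --- text summary -------------------------------------------------------
  fmt_p <- function(res) {
    if (res$p_value <= 1 / (res$n_perm + 1)) {
      sprintf("p < %g", 1 / res$n_perm)
    } else {
      sprintf("p = %.4g", res$p_value)
    }
  }
  summary_lines <- c(
    "Strength-fraction spatial-confound audit",
    sprintf("samples: %d  genes: %d  edges: %d (%d included)",
            nrow(samples), nrow(expr), nrow(edges), sum(base_edges$included)),
    sprintf("networks: %s", paste(sprintf("%s=%d", names(network_sizes(samples)),
                                          network_sizes(samples)),
                                  collapse = " ")),
    "",
    sprintf("SF under %s correction: SF = %.4f, %s (%d Wi / %d edges)",
            naive$correction, naive$sf, fmt_p(naive),
            naive$n_within_edges, naive$n_total_edges),
    sprintf("weight-vs-distance: R = %.4f (p = %.3g) on all edges; R = %.4f (p = %.3g) after filter",
            diag_raw$R, diag_raw$p, diag_filt$R, diag_filt$p),
    sprintf("Wi vs T-W edge distance: t(%d) = %.2f, mean Wi = %.1f mm, mean T-W = %.1f mm",
            round(tt$df), tt$t, tt$mean_wi, tt$mean_tw),
    "",
    "distance sweep:",
    vapply(names(sweep), function(nm) {
      res <- sweep[[nm]]
      if (res$degenerate) {
        sprintf("  %-8s degenerate (%s)", nm, res$message)
      } else {
        sprintf("  %-8s SF = %.4f, %s", nm, res$sf, fmt_p(res))
      }
    }, character(1)),
    "",
    sprintf("regression correction, signed:        SF = %.4f, %s",
            reg_signed$sf, fmt_p(reg_signed)),
    sprintf("regression correction, positive-only: SF = %.4f, %s",
            reg_pos$sf, fmt_p(reg_pos)),
    "",
    sprintf("null networks: %d/%d sets (%.1f%%) significant at 0.05; %.1f%% at 0.001",
            sum(nullnets$p_values < 0.05, na.rm = TRUE), nullnets$n_sets,
            100 * nullnets$frac_p05, 100 * nullnets$frac_p001)
  )
  writeLines(unlist(summary_lines), file.path(out_dir, "summary.txt"))

  invisible(list(
    samples = samples, expression = expr, edges = edges,
    base_edges = base_edges, naive = naive, diagnostics = diagnostics,
    sweep = sweep, regression = list(signed = reg_signed,
                                     positive_only = reg_pos),
    nullnets = nullnets, out_dir = out_dir
  ))
}
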