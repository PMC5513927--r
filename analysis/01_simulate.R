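#!/usr/bin/env Rscript
# Stage 1 — generate the standard synthetic dataset.
#
# 500 cortical-like samples drawn uniformly in a 140 x 170 x 120 mm box,
# 500 genes from a zero-mean Gaussian process with exponential spatial
# covariance (20 mm length scale, unit signal and unit nugget variance),
# 4 contiguous "functional networks" of 25 samples each, and 32 Voronoi
# tissue parcels standing in for atlas tissue-class labels.

suppressPackageStartupMessages(library(sfaudit))
dir.create("results", showWarnings = FALSE)

cfg <- synthetic_config(seed = 1)
ds <- simulate_dataset(cfg)

write_samples(ds$samples, "results/samples.csv")
write_expression(ds$expression, "results/expression.tsv")

cat(sprintf("wrote %d samples, %d genes\n",
            nrow(ds$samples), nrow(ds$expression)))
cat("network sizes:",
    paste(sprintf("%s=%d", names(network_sizes(ds$samples)),
                  network_sizes(ds$samples)), collapse = " "), "\n")
cat(sprintf("tissue parcels: %d\n", length(unique(ds$samples$tissue_class))))
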