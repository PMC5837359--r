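#!/usr/bin/env Rscript
# Stage 2: build Fisher-z association matrices and thresholded graphs.
#
# Reads the cohort written by 01_simulate.R, computes per-subject association
# matrices, the group averages, their pairwise differences, and thresholds
# each subject's matrix at 6% density over a maximum-spanning-tree backbone.
# Writes group-average matrices, difference matrices and per-subject edge
# lists under results/connectome/.
#
# Usage: Rscript analysis/02_connectome.R [--cohort <dir>] [--out <dir>]

suppressPackageStartupMessages(library(tauconnect))
args <- commandArgs(trailingOnly = TRUE)
get_arg <- function(flag, default) {
  hit <- which(args == flag)
  if (length(hit) == 1 && hit < length(args)) args[hit + 1] else default
}
cohort_dir <- get_arg("--cohort", "results/cohort")
out_dir <- get_arg("--out", "results/connectome")
density <- as.numeric(get_arg("--density", "0.06"))
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

bundle <- read_cohort(cohort_dir)
message("Computing association matrices for ", nrow(bundle$subjects),
        " subjects ...")
assoc <- cohort_association_matrices(bundle)

groups <- unique(bundle$subjects$group)
avg <- lapply(setNames(groups, groups), function(g) {
  group_average_matrix(assoc[bundle$subjects$group == g])
})
for (g in groups) {
  write_matrix_tsv(avg[[g]], file.path(out_dir, paste0("avg_", g, ".tsv")))
}
pairs <- combn(groups, 2, simplify = FALSE)
for (pr in pairs) {
  d <- matrix_difference(avg[[pr[1]]], avg[[pr[2]]])
  write_matrix_tsv(d, file.path(out_dir,
                                paste0("diff_", pr[1], "_", pr[2], ".tsv")))
  message(sprintf("  mean |z difference| %s - %s: %.4f",
                  pr[1], pr[2], mean(abs(d[upper.tri(d)]))))
}

message("Thresholding at ", density * 100, "% density ...")
n_edges <- NULL
for (id in bundle$subjects$subject_id) {
  g <- threshold_graph(assoc[[id]], density = density)
  write_edge_list_tsv(g, file.path(out_dir, paste0("edges_", id, ".tsv")))
  n_edges <- c(n_edges, g$n_edges)
}
message("All graphs connected with ", unique(n_edges), " edges each.")
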