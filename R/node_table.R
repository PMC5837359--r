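#' Build a synthetic brain parcellation table
#'
#' Creates the static per-node metadata used throughout the pipeline: node
#' identity, a centroid in mm, a lobe label, subcortical and cerebellar flags,
#' and a planted community assignment. The layout emulates an equal-volume
#' whole-brain parcellation in which cortical nodes split into functional
#' communities, subcortical/deep nodes form their own community, and cerebellar
#' nodes act as the PET reference region.
#'
#' Cortical nodes are partitioned across `n_communities` as evenly as possible
#' (sizes differ by at most one). All non-cortical nodes (subcortical plus
#' cerebellar), when present, share one additional "deep" community. Centroids
#' are drawn uniformly inside disjoint axis-aligned blocks, one block per lobe,
#' so that lobes occupy separate regions of space.
#'
#' @param n_cortical number of cortical nodes (>= `n_communities`)
#' @param n_communities number of cortical communities
#' @param n_subcortical number of subcortical (deep grey/brainstem) nodes
#' @param n_cerebellar number of cerebellar reference-region nodes
#' @param seed integer seed for the centroid draw
#' @return a `data.frame` with columns `node_id` (0-based, contiguous), `x`,
#'   `y`, `z` (mm), `lobe`, `is_subcortical`, `is_cerebellar`, `community`
#'   (0-based), and `networks` (comma-separated labels, empty by default)
#' @export
make_node_table <- function(n_cortical, n_communities, n_subcortical = 0,
                            n_cerebellar = 0, seed = 1) {
  counts <- c(n_cortical, n_communities, n_subcortical, n_cerebellar)
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop_arg("all counts must be non-negative integers")
  }
  if (n_cortical < n_communities) {
    stop_arg("n_cortical must be at least n_communities")
  }
  n <- n_cortical + n_subcortical + n_cerebellar
  if (n == 0) stop_arg("node table must contain at least one node")

  community <- integer(n)
  lobe <- character(n)
  is_subcortical <- logical(n)
  is_cerebellar <- logical(n)

  cortical_lobes <- c("frontal", "parietal", "temporal", "occipital",
                      "cingulate", "insular")
  if (n_cortical > 0) {
    # block partition: community sizes differ by at most one
    sizes <- rep(n_cortical %/% n_communities, n_communities)
    extra <- n_cortical %% n_communities
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
    community[seq_len(n_cortical)] <- rep(seq_len(n_communities) - 1L, times = sizes)
    lobe[seq_len(n_cortical)] <-
      cortical_lobes[(community[seq_len(n_cortical)] %% length(cortical_lobes)) + 1L]
  }
  deep_community <- if (n_cortical > 0) n_communities else 0L
  if (n_subcortical > 0) {
    idx <- n_cortical + seq_len(n_subcortical)
    community[idx] <- deep_community
    lobe[idx] <- "subcortical"
    is_subcortical[idx] <- TRUE
  }
  if (n_cerebellar > 0) {
    idx <- n_cortical + n_subcortical + seq_len(n_cerebellar)
    community[idx] <- deep_community
    lobe[idx] <- "cerebellum"
    is_cerebellar[idx] <- TRUE
  }

  # disjoint 30 mm blocks per lobe along x; uniform centroids within each block
  lobe_levels <- unique(lobe)
  centroids <- with_seed(seed, {
    out <- matrix(0, n, 3)
    for (li in seq_along(lobe_levels)) {
      idx <- which(lobe == lobe_levels[li])
      x0 <- (li - 1) * 40
      out[idx, 1] <- stats::runif(length(idx), x0, x0 + 30)
      out[idx, 2] <- stats::runif(length(idx), 0, 30)
      out[idx, 3] <- stats::runif(length(idx), 0, 30)
    }
    out
  })

  data.frame(
    node_id = seq_len(n) - 1L,
    x = centroids[, 1],
    y = centroids[, 2],
    z = centroids[, 3],
    lobe = lobe,
    is_subcortical = is_subcortical,
    is_cerebellar = is_cerebellar,
    community = community,
    networks = "",
    stringsAsFactors = FALSE
  )
}

validate_node_table <- function(node_table) {
  needed <- c("node_id", "x", "y", "z", "lobe", "is_subcortical",
              "is_cerebellar", "community")
  missing <- setdiff(needed, names(node_table))
  if (length(missing) > 0) {
    stop_arg("node table missing columns: ", paste(missing, collapse = ", "))
  }
  if (any(duplicated(node_table$node_id)) ||
      !identical(sort(as.integer(node_table$node_id)),
                 seq_len(nrow(node_table)) - 1L)) {
    stop_arg("node_id must be unique and contiguous from 0")
  }
  if (any(node_table$is_subcortical & node_table$is_cerebellar)) {
    stop_arg("a node cannot be both subcortical and cerebellar")
  }
  invisible(node_table)
}

cortical_mask <- function(node_table) {
  !node_table$is_subcortical & !node_table$is_cerebellar
}
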