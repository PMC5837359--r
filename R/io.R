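# TSV readers/writers and cohort (de)serialization. All on-disk formats are
# plain text: square matrices as TSV with a node-id header row, cohorts as one
# time-series TSV per subject plus tau/node/subject tables and a JSON truth
# record.

#' Write a square matrix as TSV with a node-id header
#'
#' @param m numeric matrix
#' @param path output path
#' @export
write_matrix_tsv <- function(m, path) {
  ids <- colnames(m)
  if (is.null(ids)) ids <- as.character(seq_len(ncol(m)) - 1L)
  utils::write.table(
    stats::setNames(as.data.frame(m), ids), path,
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = TRUE
  )
}

#' Read a square matrix from TSV
#'
#' @param path input path
#' @param node_ids optional character vector; the header must match exactly
#' @param check_symmetric verify symmetry within 1e-10
#' @return numeric matrix with the header as dimnames
#' @export
read_matrix_tsv <- function(path, node_ids = NULL, check_symmetric = FALSE) {
  if (!file.exists(path)) stop_arg("file not found: ", path)
  lines <- readLines(path)
  if (length(lines) < 2) stop_arg("parse error: ", path, " has no data rows")
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  n <- length(header)
  body <- strsplit(lines[-1], "\t", fixed = TRUE)
  m <- matrix(NA_real_, length(body), n)
  for (i in seq_along(body)) {
    row <- body[[i]]
    if (length(row) != n) {
      stop_arg("parse error: row ", i + 1, " has ", length(row),
               " fields, expected ", n)
    }
    vals <- suppressWarnings(as.numeric(row))
    if (any(is.na(vals) & !row %in% c("NA", "NaN"))) {
      stop_arg("parse error: non-numeric cell in row ", i + 1)
    }
    m[i, ] <- vals
  }
  if (nrow(m) != n) stop_arg("matrix is not square: ", nrow(m), " x ", n)
  if (!is.null(node_ids) && !identical(header, as.character(node_ids))) {
    stop_arg("header does not match the expected node ids")
  }
  dimnames(m) <- list(header, header)
  if (check_symmetric) check_square_symmetric(m, what = basename(path))
  m
}

#' Export a thresholded graph as an edge list
#'
#' Writes the retained edges as a three-column TSV (`node_i`, `node_j`, `z`)
#' with 0-based node ids.
#'
#' @param g a `thresholded_graph`
#' @param path output path
#' @export
write_edge_list_tsv <- function(g, path) {
  idx <- which(upper.tri(g$binary) & g$binary == 1, arr.ind = TRUE)
  df <- data.frame(node_i = idx[, 1] - 1L, node_j = idx[, 2] - 1L,
                   z = g$weighted[idx])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write a synthetic cohort to disk
#'
#' Emits one node x time TSV per subject (`timeseries_<id>.tsv`), the tau
#' matrix (`tau.tsv`, subjects x nodes), the node table (`nodes.tsv`), the
#' subject table (`subjects.tsv`) and the truth record (`truth.json`).
#'
#' @param bundle a `cohort_bundle`
#' @param dir output directory (created if absent)
#' @return `dir`, invisibly
#' @export
write_cohort <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.table(bundle$node_table, file.path(dir, "nodes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$subjects, file.path(dir, "subjects.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  tau_df <- data.frame(subject_id = rownames(bundle$tau),
                       bundle$tau, check.names = FALSE)
  utils::write.table(tau_df, file.path(dir, "tau.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (id in names(bundle$timeseries)) {
    utils::write.table(bundle$timeseries[[id]],
                       file.path(dir, paste0("timeseries_", id, ".tsv")),
                       sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  jsonlite::write_json(bundle$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a synthetic cohort from disk
#'
#' @param dir directory written by [write_cohort()]
#' @return a `cohort_bundle`
#' @export
read_cohort <- function(dir) {
  nodes_path <- file.path(dir, "nodes.tsv")
  if (!file.exists(nodes_path)) stop_arg("no cohort found in ", dir)
  node_table <- utils::read.table(nodes_path, sep = "\t", header = TRUE,
                                  stringsAsFactors = FALSE)
  node_table$networks[is.na(node_table$networks)] <- ""
  subjects <- utils::read.table(file.path(dir, "subjects.tsv"), sep = "\t",
                                header = TRUE, stringsAsFactors = FALSE)
  tau_df <- utils::read.table(file.path(dir, "tau.tsv"), sep = "\t",
                              header = TRUE, check.names = FALSE,
                              stringsAsFactors = FALSE)
  tau <- as.matrix(tau_df[, -1, drop = FALSE])
  rownames(tau) <- tau_df$subject_id
  timeseries <- lapply(subjects$subject_id, function(id) {
    path <- file.path(dir, paste0("timeseries_", id, ".tsv"))
    if (!file.exists(path)) stop_arg("missing time series for subject ", id)
    as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  })
  names(timeseries) <- subjects$subject_id
  truth_path <- file.path(dir, "truth.json")
  truth <- if (file.exists(truth_path)) {
    jsonlite::read_json(truth_path, simplifyVector = TRUE)
  } else {
    NULL
  }
  structure(
    list(node_table = node_table, subjects = subjects, timeseries = timeseries,
         tau = tau, truth = truth),
    class = "cohort_bundle"
  )
}

#' Read a run configuration from YAML or JSON
#'
#' Unknown fields raise an error; missing fields take the [cohort_config()]
#' defaults.
#'
#' @param path YAML or JSON file of generator/analysis settings
#' @return a config list
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_arg("config file not found: ", path)
  raw <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.null(raw$group_sizes)) raw$group_sizes <- unlist(raw$group_sizes)
  if (!is.null(raw$burden_range)) {
    raw$burden_range <- lapply(raw$burden_range, as.numeric)
  }
  do.call(cohort_config, raw)
}

#' Run manifest for reproducibility auditing
#'
#' @param config the run configuration
#' @param outputs character vector of output file paths to checksum
#' @return list with the config hash (md5 of its canonical JSON), package
#'   version, timestamp, and per-file md5 checksums
#' @export
run_manifest <- function(config, outputs = character(0)) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config[order(names(config))], tmp, auto_unbox = TRUE,
                       digits = NA)
  existing <- outputs[file.exists(outputs)]
  list(
    config_hash = unname(tools::md5sum(tmp)),
    package_version = as.character(utils::packageVersion("tauconnect")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    checksums = as.list(tools::md5sum(existing))
  )
}
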