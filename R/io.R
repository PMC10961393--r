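#' Write a subject bundle to disk
#'
#' One tab-delimited matrix file per run (time x vertex), a JSON metadata
#' sidecar (TR, seed, schedule, effect preset), and the vertex table as TSV.
#'
#' @param dataset a subject element of a [simulate_cohort()] result.
#' @param map the cohort's retinotopic map.
#' @param schedule the cohort's block schedule.
#' @param dir output directory (created if missing).
#' @return Invisibly, the directory path.
#' @export
write_subject_bundle <- function(dataset, map, schedule, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (r in seq_along(dataset$runs)) {
    utils::write.table(dataset$runs[[r]]$bold,
                       file.path(dir, sprintf("run%02d_bold.tsv", r)),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
    utils::write.table(dataset$runs[[r]]$confounds,
                       file.path(dir, sprintf("run%02d_confounds.tsv", r)),
                       sep = "\t", row.names = FALSE, col.names = TRUE)
  }
  meta <- list(subject_id = dataset$subject_id,
               TR = dataset$runs[[1]]$TR,
               n_runs = length(dataset$runs),
               seed = dataset$seed,
               schedule = as.data.frame(schedule))
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.table(as.data.frame(map), file.path(dir, "vertices.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Read a subject bundle written by [write_subject_bundle()]
#'
#' @param dir bundle directory.
#' @return list(dataset, map, schedule-as-data.frame, meta).
#' @export
read_subject_bundle <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  runs <- lapply(seq_len(meta$n_runs), function(r) {
    bold <- as.matrix(utils::read.table(
      file.path(dir, sprintf("run%02d_bold.tsv", r)), sep = "\t"))
    dimnames(bold) <- NULL
    conf <- as.matrix(utils::read.table(
      file.path(dir, sprintf("run%02d_confounds.tsv", r)), sep = "\t",
      header = TRUE))
    list(bold = bold, TR = meta$TR, confounds = conf)
  })
  map <- utils::read.table(file.path(dir, "vertices.tsv"), sep = "\t",
                           header = TRUE, stringsAsFactors = FALSE)
  class(map) <- c("retinotopic_map", "data.frame")
  dataset <- structure(list(subject_id = meta$subject_id, runs = runs,
                            seed = meta$seed),
                       class = "subject_dataset")
  list(dataset = dataset, map = map, schedule = meta$schedule, meta = meta)
}

#' Write / read fixation tables
#'
#' The de facto eye-tracker export shape: one row per fixation with trial,
#' onset, duration and pixel coordinates (plus optional participant and
#' condition columns).
#'
#' @param fixations data.frame with at least trial, onset_ms, duration_ms,
#'   x_px, y_px.
#' @param path TSV file path.
#' @return \code{write_fixations}: the path, invisibly;
#'   \code{read_fixations}: the data.frame.
#' @export
write_fixations <- function(fixations, path) {
  utils::write.table(fixations, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_fixations
#' @export
read_fixations <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Edge table of a weight-map summary
#'
#' One row per edge: endpoints, sub-network label, median transformed weight,
#' significance flag and the level the edge supports.
#'
#' @param summary a [summarize_maps()] result.
#' @param map the retinotopic map.
#' @param path optional TSV path to write to.
#' @return The edge table data.frame (invisibly when written).
#' @export
edge_table <- function(summary, map, path = NULL) {
  part <- partition_subnetworks(map)
  ei <- attr(part, "edge_index")
  sig <- summary$significant_edges
  flag <- integer(nrow(ei))
  supported <- rep(NA_character_, nrow(ei))
  flag[sig$positive] <- 1L
  supported[sig$positive] <- summary$positive_level
  flag[sig$negative] <- 1L
  supported[sig$negative] <- paste0("not_", summary$positive_level)
  tab <- data.frame(edge_id = seq_len(nrow(ei)),
                    vertex_i = ei[, 1], vertex_j = ei[, 2],
                    subnetwork = as.character(part),
                    median_weight = summary$median_map,
                    significant = flag, supported_level = supported,
                    stringsAsFactors = FALSE)
  if (!is.null(path)) {
    utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
    return(invisible(tab))
  }
  tab
}

#' Write / read a square connectivity matrix as TSV
#'
#' @param matrix a \code{"connectivity_matrix"} (or any square matrix).
#' @param path TSV file path.
#' @return \code{write_matrix_tsv}: the path, invisibly;
#'   \code{read_matrix_tsv}: the matrix.
#' @export
write_matrix_tsv <- function(matrix, path) {
  utils::write.table(unclass(matrix), path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  dimnames(m) <- NULL
  m
}
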