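# Plain-text interchange: everything the pipeline consumes or emits travels
# as TSV so runs can be archived and inspected without binary formats.

#' Write / read a subject's ROI time series
#'
#' Frames x ROIs TSV with ROI labels as header.
#' @param ts `subject_ts`.
#' @param path output file.
#' @export
write_subject_ts <- function(ts, path) {
  utils::write.table(ts$data, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_subject_ts
#' @param tr_seconds,subject_id metadata to attach on read.
#' @param fd,dvars optional motion vectors to attach on read.
#' @export
read_subject_ts <- function(path, tr_seconds, subject_id = basename(path),
                            fd = NULL, dvars = NULL) {
  x <- as.matrix(utils::read.delim(path, check.names = FALSE))
  structure(list(subject_id = subject_id, data = x, tr_seconds = tr_seconds,
                 fd = fd %||% rep(0, nrow(x)),
                 dvars = dvars %||% rep(0, nrow(x))),
            class = "subject_ts")
}

#' Write a motion trace as two-column TSV (fd, dvars)
#' @param motion list with `fd`, `dvars`.
#' @param path output file.
#' @export
write_motion_trace <- function(motion, path) {
  utils::write.table(data.frame(fd = motion$fd, dvars = motion$dvars),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a square labeled matrix (FC, co-classification, allegiance)
#' @param m square matrix.
#' @param path output file.
#' @export
write_matrix_tsv <- function(m, path) {
  utils::write.table(m, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  m <- as.matrix(utils::read.delim(path, check.names = FALSE))
  dimnames(m) <- list(colnames(m), colnames(m))
  m
}

#' Write a connectivity matrix in long edge-list form
#'
#' TSV with columns node_i, node_j, weight (upper triangle, positive edges).
#' @param fc connectivity matrix.
#' @param path output file.
#' @export
write_fc_long <- function(fc, path) {
  iu <- which(upper.tri(fc) & fc > 0, arr.ind = TRUE)
  utils::write.table(
    data.frame(node_i = iu[, 1] - 1L, node_j = iu[, 2] - 1L,
               weight = fc[iu]),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a partition as TSV (node_id, label, community)
#' @param part `partition` or label vector.
#' @param atlas atlas supplying node labels.
#' @param path output file.
#' @export
write_partition_tsv <- function(part, atlas, path) {
  labels <- if (inherits(part, "partition")) part$labels else part
  utils::write.table(
    data.frame(node_id = atlas$node_id, label = atlas$label,
               community = labels),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a simulation configuration as a flat key-value file
#' @param config `sim_config`.
#' @param path output file.
#' @export
write_config <- function(config, path) {
  kv <- c(n_nodes = config$n_nodes, n_frames = config$n_frames,
          tr_seconds = config$tr_seconds, seed = config$seed,
          groups = paste(names(config$group_specs), collapse = ","),
          group_sizes = paste(vapply(config$group_specs, `[[`, 1L,
                                     "n_subjects"), collapse = ","))
  writeLines(paste(names(kv), kv, sep = "="), path)
  invisible(path)
}
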