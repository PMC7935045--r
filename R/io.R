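# Delimited-table persistence. Every matrix artifact is written as a plain
# TSV, with run/session identity carried in a sidecar TSV next to it, so a
# dataset survives as text and round-trips without loss of metadata.

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path),
                                      ".meta.tsv")

#' Write / read node time series runs
#'
#' Each run is a TSV of timepoints x nodes; a single sidecar table
#' (`<prefix>.meta.tsv`) records file, subject, session, run and TR.
#'
#' @param ts_list List of [node_timeseries()] objects.
#' @param prefix Path prefix; run `i` goes to `<prefix>_run<i>.tsv`.
#' @return `write_timeseries` returns the sidecar path invisibly;
#'   `read_timeseries` returns a list of `node_timeseries`.
#' @export
write_timeseries <- function(ts_list, prefix) {
  meta <- data.frame(file = character(0), subject = character(0),
                     session = integer(0), run = integer(0),
                     tr = numeric(0))
  for (i in seq_along(ts_list)) {
    ts <- ts_list[[i]]
    f <- sprintf("%s_run%03d.tsv", prefix, i)
    utils::write.table(ts$data, f, sep = "\t", row.names = FALSE,
                       col.names = FALSE)
    meta[i, ] <- list(basename(f), ts$subject, ts$session, ts$run, ts$tr)
  }
  mf <- paste0(prefix, ".meta.tsv")
  utils::write.table(meta, mf, sep = "\t", row.names = FALSE)
  invisible(mf)
}

#' @rdname write_timeseries
#' @param prefix Path prefix used when writing.
#' @export
read_timeseries <- function(prefix) {
  meta <- utils::read.table(paste0(prefix, ".meta.tsv"), header = TRUE,
                            sep = "\t", stringsAsFactors = FALSE)
  lapply(seq_len(nrow(meta)), function(i) {
    data <- as.matrix(utils::read.table(
      file.path(dirname(prefix), meta$file[i]), sep = "\t"))
    dimnames(data) <- NULL
    node_timeseries(data, meta$subject[i], meta$session[i], meta$run[i],
                    meta$tr[i])
  })
}

#' Write / read a behavior table
#'
#' Plain TSV with a header naming the measures and the `subject`/`session`
#' identifier columns.
#'
#' @param behavior data.frame from [generate_behavior()] (or like it).
#' @param path File path.
#' @export
write_behavior <- function(behavior, path) {
  utils::write.table(behavior, path, sep = "\t", row.names = FALSE)
  invisible(path)
}

#' @rdname write_behavior
#' @export
read_behavior <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Write a feature matrix with its block identity
#'
#' @param features Subject-sessions x features matrix (e.g. from
#'   [state_features()] or [static_edge_features()]).
#' @param blocks data.frame with `subject`, `session` per row.
#' @param path File path.
#' @export
write_features <- function(features, blocks, path) {
  utils::write.table(cbind(blocks, as.data.frame(features)), path,
                     sep = "\t", row.names = FALSE)
  invisible(path)
}
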