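#' Read and write sensor layouts as JSON
#'
#' @param layout A [make_sensor_layout()] layout.
#' @param path Output/input file path.
#' @return `read_layout_json` returns a `sensor_layout`;
#'   `write_layout_json` returns `path` invisibly.
#' @export
write_layout_json <- function(layout, path) {
  validate_layout(layout)
  obj <- list(channel_ids = layout$channel_ids,
              positions = unname(apply(layout$positions, 1, c,
                                       simplify = FALSE)),
              regions = unname(layout$regions))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_layout_json
#' @export
read_layout_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  pos <- do.call(rbind, lapply(seq_along(obj$channel_ids), function(i)
    as.numeric(if (is.list(obj$positions)) obj$positions[[i]]
               else obj$positions[i, ])))
  colnames(pos) <- c("x", "y", "z")
  rownames(pos) <- obj$channel_ids
  layout <- structure(list(channel_ids = obj$channel_ids, positions = pos,
                           regions = setNames(obj$regions, obj$channel_ids)),
                      class = "sensor_layout")
  validate_layout(layout)
  layout
}

#' Read and write recordings as delimited text
#'
#' The signal block is a tab-separated matrix (one row per channel); the
#' sampling rate, channel ids, unit, subject id, QC flags and band live in
#' a JSON sidecar at `<path>.json`.
#'
#' @param rec A [meg_recording()].
#' @param path Signal matrix path (the sidecar is derived from it).
#' @return `read_recording_txt` returns a `meg_recording`;
#'   `write_recording_txt` returns `path` invisibly.
#' @export
write_recording_txt <- function(rec, path) {
  stopifnot(inherits(rec, "meg_recording"))
  write.table(rec$signals, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  meta <- list(subject_id = rec$subject_id,
               sampling_rate = rec$sampling_rate,
               channel_ids = rec$channel_ids, unit = "fT",
               qc_flags = rec$qc_flags)
  if (!is.null(rec$band))
    meta$band <- list(name = rec$band$name, lo = rec$band$lo,
                      hi = rec$band$hi)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_recording_txt
#' @export
read_recording_txt <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  sig <- as.matrix(read.table(path, sep = "\t", header = FALSE))
  dimnames(sig) <- NULL
  band <- if (!is.null(meta$band))
    as_band(list(name = meta$band$name, lo = meta$band$lo,
                 hi = meta$band$hi))
  meg_recording(sig, meta$sampling_rate, channel_ids = meta$channel_ids,
                subject_id = meta$subject_id,
                qc_flags = unlist(meta$qc_flags), band = band)
}

#' Read and write connectivity matrices as TSV
#'
#' Channel ids form the header row and first column.
#'
#' @param cm A [connectivity_matrix()].
#' @param path File path.
#' @param subject_id,band Metadata restored on read (the TSV itself only
#'   stores the weights).
#' @return `read_connectivity_tsv` returns a `connectivity_matrix`;
#'   `write_connectivity_tsv` returns `path` invisibly.
#' @export
write_connectivity_tsv <- function(cm, path) {
  stopifnot(inherits(cm, "connectivity_matrix"))
  df <- data.frame(channel = rownames(cm$weights), cm$weights,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_connectivity_tsv
#' @export
read_connectivity_tsv <- function(path, subject_id = "subject",
                                  band = NULL) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  w <- as.matrix(df[, -1, drop = FALSE])
  rownames(w) <- df[[1]]
  w[lower.tri(w)] <- t(w)[lower.tri(w)]   # guard against print round-trip
  diag(w) <- 0
  connectivity_matrix(w, subject_id = subject_id, band = band)
}

#' Write a thresholded network as an edge-list TSV
#'
#' @param net An [apply_threshold()] network.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_edges_tsv <- function(net, path) {
  stopifnot(inherits(net, "thresholded_network"))
  write.table(net$edges[, c("chan_i", "chan_j", "weight", "sign")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write cohort metadata as TSV
#'
#' One row per subject, columns exactly the subject-metadata fields.
#'
#' @param meta Data frame from [cohort_metadata()].
#' @param path File path.
#' @return `read_cohort_meta_tsv` returns the data frame;
#'   `write_cohort_meta_tsv` returns `path` invisibly.
#' @export
write_cohort_meta_tsv <- function(meta, path) {
  write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_meta_tsv
#' @export
read_cohort_meta_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
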