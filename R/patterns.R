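# Regions and region pairs whose excitatory/inhibitory presence the
# topographic pattern analysis counts.
pattern_rois <- function() {
  list(
    frontal = c("frontal", "frontal"),
    temporal_L = c("temporal_L", "temporal_L"),
    temporal_R = c("temporal_R", "temporal_R"),
    occipital_L = c("occipital_L", "occipital_L"),
    occipital_R = c("occipital_R", "occipital_R"),
    temporal_bilateral = c("temporal_L", "temporal_R"),
    occipital_bilateral = c("occipital_L", "occipital_R")
  )
}

#' Classify a thresholded network into a regional pattern
#'
#' Reduces a subject-band network to the booleans counted in the group
#' comparison: for each region of interest (frontal, left/right temporal,
#' left/right occipital) and for the two cross-hemisphere pairs (bilateral
#' temporal, bilateral occipital), whether at least `min_edges` retained
#' positive ("excitatory") and negative ("inhibitory") edges connect the
#' region's sensors (respectively one sensor in each region of a pair).
#'
#' @param net A [apply_threshold()] network.
#' @param layout The [make_sensor_layout()] layout sharing the network's
#'   channel ids.
#' @param min_edges Minimum suprathreshold edges for a presence call
#'   (default 1).
#' @return A `regional_pattern` data frame: `subject_id`, `band`, `roi`,
#'   `excitatory`, `inhibitory`.
#' @export
classify_pattern <- function(net, layout, min_edges = 1L) {
  stopifnot(inherits(net, "thresholded_network"))
  validate_layout(layout)
  if (!identical(net$channel_ids, layout$channel_ids))
    stop("network and layout channel ids differ")
  if (min_edges < 1) stop("min_edges must be >= 1")
  reg <- layout$regions
  e <- net$edges
  ri <- reg[e$chan_i]
  rj <- reg[e$chan_j]
  rois <- pattern_rois()
  out <- data.frame(
    subject_id = net$subject_id,
    band = if (is.null(net$band)) NA_character_ else net$band$name,
    roi = names(rois),
    excitatory = FALSE, inhibitory = FALSE,
    stringsAsFactors = FALSE
  )
  for (k in seq_along(rois)) {
    a <- rois[[k]][1]; b <- rois[[k]][2]
    hit <- if (a == b) ri == a & rj == a
           else (ri == a & rj == b) | (ri == b & rj == a)
    out$excitatory[k] <- sum(hit & e$sign > 0) >= min_edges
    out$inhibitory[k] <- sum(hit & e$sign < 0) >= min_edges
  }
  class(out) <- c("regional_pattern", "data.frame")
  out
}

#' Export a topographic contour map of a thresholded network
#'
#' Projects the 3D sensor positions to the plane with an
#' azimuthal-equidistant projection (nose up) and draws every retained
#' connection between its sensor positions: red for positive (excitatory)
#' edges, blue for negative (inhibitory) ones.  Alongside the figure a
#' machine-readable edge manifest (`<path>.manifest.tsv`) is written, so
#' the drawn content is testable without pixel comparison.  Output is
#' deterministic given its inputs.
#'
#' @param cm A [connectivity_matrix()].
#' @param layout Matching [make_sensor_layout()] layout.
#' @param tau Display threshold in `(0, 1)`.
#' @param path Output figure path; `.pdf` or `.png` decides the device.
#' @return Invisibly, list with `file`, `manifest` (path) and `edges`.
#' @export
export_contour_map <- function(cm, layout, tau, path) {
  stopifnot(inherits(cm, "connectivity_matrix"))
  validate_layout(layout)
  if (!identical(rownames(cm$weights), layout$channel_ids))
    stop("matrix and layout channel ids differ")
  net <- apply_threshold(cm, tau)
  xy <- project_azimuthal(layout$positions)
  manifest <- paste0(path, ".manifest.tsv")

  ok <- tryCatch({
    if (grepl("\\.png$", path)) grDevices::png(path, 600, 600)
    else grDevices::pdf(path, width = 6, height = 6)
    TRUE
  }, error = function(e) stop("cannot open output device for ", path))
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::plot.new()
  lim <- range(xy) + c(-0.1, 0.1)
  graphics::plot.window(xlim = lim, ylim = lim, asp = 1)
  graphics::title(main = paste0(cm$subject_id,
                                if (!is.null(cm$band))
                                  paste0(" - ", cm$band$name),
                                " (tau = ", tau, ")"))
  e <- net$edges
  if (nrow(e)) {
    col <- ifelse(e$sign > 0, "red", "blue")
    graphics::segments(xy[e$i, 1], xy[e$i, 2], xy[e$j, 1], xy[e$j, 2],
                       col = col, lwd = 1.2)
  }
  graphics::points(xy, pch = 16, cex = 0.6, col = "grey30")

  write.table(e[, c("chan_i", "chan_j", "weight", "sign")], manifest,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(file = path, manifest = manifest, edges = e))
}

# Azimuthal-equidistant projection of unit-hemisphere positions, nose
# (+x) up, left (+y) on the left of the plot.
project_azimuthal <- function(pos) {
  elev <- asin(pmin(1, pmax(-1, pos[, 3] / sqrt(rowSums(pos^2)))))
  az <- atan2(pos[, 2], pos[, 1])
  r <- pi / 2 - elev
  cbind(px = -r * sin(az), py = r * cos(az))
}
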