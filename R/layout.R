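#' Generate a quasi-uniform hemispheric sensor layout
#'
#' Places `n_channels` sensors on the upper unit hemisphere with a
#' golden-angle spiral plus a small seeded positional jitter, and assigns
#' each sensor an anatomical region label from its angular position
#' (anterior sensors are frontal, lateral ones temporal, posterior ones
#' occipital split by hemisphere, with parietal/central covering the upper
#' posterior and vertex).  The five region groups used by the topographic
#' pattern analysis (frontal, bilateral temporal, bilateral occipital) are
#' guaranteed to be non-empty: if an angular rule leaves one empty, the
#' sensor closest to that region's prototype direction is re-labelled.
#'
#' Coordinates are head-centred with +x anterior, +y left, +z superior,
#' in arbitrary (unit-sphere) length units.
#'
#' @param n_channels Number of sensors, at least 8.
#' @param seed Integer seed; the same seed yields an identical layout.
#' @return A `sensor_layout` object: list with `channel_ids` (character),
#'   `positions` (`n x 3` matrix) and `regions` (named character vector).
#' @examples
#' layout <- make_sensor_layout(275, seed = 7)
#' table(layout$regions)
#' @export
make_sensor_layout <- function(n_channels, seed = 1L) {
  if (!is.numeric(n_channels) || length(n_channels) != 1L ||
      n_channels < 8 || n_channels != round(n_channels))
    stop("n_channels must be a single integer >= 8")
  n <- as.integer(n_channels)
  set.seed(as.integer(seed))

  golden <- pi * (3 - sqrt(5))
  i <- seq_len(n)
  z <- (i - 0.5) / n             # heights in (0, 1): upper hemisphere
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- i * golden
  pos <- cbind(x = r * cos(phi), y = r * sin(phi), z = z)
  pos <- pos + matrix(rnorm(3L * n, sd = 0.02), ncol = 3)
  pos <- pos / sqrt(rowSums(pos^2))
  pos[, "z"] <- pmax(pos[, "z"], 0.01)
  pos <- pos / sqrt(rowSums(pos^2))

  regions <- region_from_angles(pos)
  regions <- ensure_mandatory_regions(pos, regions)

  ids <- sprintf("MEG%03d", i)
  rownames(pos) <- ids
  names(regions) <- ids
  structure(list(channel_ids = ids, positions = pos, regions = regions),
            class = "sensor_layout")
}

# Deterministic angular labelling rules.
region_from_angles <- function(pos) {
  elev <- asin(pmin(1, pmax(-1, pos[, "z"]))) * 180 / pi
  az <- atan2(pos[, "y"], pos[, "x"]) * 180 / pi
  out <- character(nrow(pos))
  for (k in seq_len(nrow(pos))) {
    out[k] <-
      if (elev[k] > 70) "central"
      else if (abs(az[k]) <= 45) "frontal"
      else if (az[k] > 45 && az[k] <= 110) "temporal_L"
      else if (az[k] < -45 && az[k] >= -110) "temporal_R"
      else if (elev[k] > 45) "parietal"
      else if (az[k] > 0) "occipital_L"
      else "occipital_R"
  }
  out
}

# Re-label the nearest sensor towards any empty mandatory region, drawing
# only from regions that keep at least two members (so one fix cannot
# empty another mandatory group).
ensure_mandatory_regions <- function(pos, regions) {
  prototypes <- rbind(
    frontal     = c(1, 0, 0.35),
    temporal_L  = c(0.1, 0.95, 0.15),
    temporal_R  = c(0.1, -0.95, 0.15),
    occipital_L = c(-0.9, 0.35, 0.2),
    occipital_R = c(-0.9, -0.35, 0.2)
  )
  prototypes <- prototypes / sqrt(rowSums(prototypes^2))
  for (reg in MANDATORY_REGIONS) {
    if (any(regions == reg)) next
    donors <- names(which(table(regions) >= 2))
    cand <- which(regions %in% donors)
    d <- colSums((t(pos[cand, , drop = FALSE]) - prototypes[reg, ])^2)
    regions[cand[which.min(d)]] <- reg
  }
  regions
}

#' Validate a sensor layout
#'
#' Checks the structural invariants: unique channel ids, finite 3D
#' positions, one known region label per channel, at least 8 channels, and
#' non-empty frontal, bilateral temporal and bilateral occipital groups.
#'
#' @param layout A `sensor_layout`.
#' @return The layout, invisibly; errors describe the first violation.
#' @export
validate_layout <- function(layout) {
  if (!inherits(layout, "sensor_layout")) stop("not a sensor_layout")
  ids <- layout$channel_ids
  if (length(ids) < 8) stop("layout must have at least 8 channels")
  if (anyDuplicated(ids)) stop("channel ids must be unique")
  if (!is.matrix(layout$positions) || ncol(layout$positions) != 3 ||
      nrow(layout$positions) != length(ids) ||
      !all(is.finite(layout$positions)))
    stop("positions must be a finite n x 3 matrix")
  if (length(layout$regions) != length(ids))
    stop("every channel needs exactly one region label")
  unknown <- setdiff(unique(layout$regions), REGIONS)
  if (length(unknown))
    stop("unknown region label(s): ", paste(unknown, collapse = ", "))
  missing <- setdiff(MANDATORY_REGIONS, unique(layout$regions))
  if (length(missing))
    stop("mandatory region(s) empty: ", paste(missing, collapse = ", "))
  invisible(layout)
}

#' @export
print.sensor_layout <- function(x, ...) {
  cat("<sensor_layout> ", length(x$channel_ids), " channels\n", sep = "")
  print(table(x$regions))
  invisible(x)
}
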