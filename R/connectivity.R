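#' Construct a connectivity matrix object
#'
#' Mostly used internally and in tests; [pairwise_connectivity()] is the
#' estimator.  Enforces the structural invariants: symmetry, zero
#' diagonal, entries in `[-1, 1]`.
#'
#' @param weights Square numeric matrix of signed edge weights.
#' @param subject_id,band,segment_s,overlap Estimator metadata.
#' @return A `connectivity_matrix` object.
#' @export
connectivity_matrix <- function(weights, subject_id = "subject",
                                band = NULL, segment_s = NA_real_,
                                overlap = NA_real_) {
  if (!is.matrix(weights) || nrow(weights) != ncol(weights))
    stop("weights must be a square matrix")
  if (max(abs(weights - t(weights))) > 1e-12)
    stop("weights must be symmetric")
  if (any(abs(diag(weights)) > 0)) stop("diagonal must be zero")
  if (max(abs(weights)) > 1 + 1e-12) stop("entries must lie in [-1, 1]")
  if (is.null(rownames(weights)))
    rownames(weights) <- colnames(weights) <-
      sprintf("MEG%03d", seq_len(nrow(weights)))
  if (!is.null(band)) band <- as_band(band)
  structure(list(subject_id = subject_id, band = band, weights = weights,
                 segment_s = segment_s, overlap = overlap),
            class = "connectivity_matrix")
}

#' All-pairs signed band connectivity
#'
#' For every sensor pair the connection magnitude is the square root of
#' the Welch magnitude-squared coherence averaged over the in-band
#' frequency bins (Hann taper), which puts it on a correlation-like
#' `[0, 1]` scale; the connection sign is the sign of the zero-lag Pearson
#' correlation of the band-filtered signals, so positively co-fluctuating
#' ("excitatory") pairs get positive weights and anti-correlated
#' ("inhibitory") pairs negative ones.
#'
#' @param rec A band-filtered [meg_recording()] (see [bandpass()]).
#' @param band Band specification; defaults to the band recorded on `rec`.
#' @param segment_s Welch segment length in seconds (default 4).
#' @param overlap Segment overlap fraction in `[0, 1)` (default 0.5).
#' @return A [connectivity_matrix()].
#' @examples
#' rec <- meg_recording(matrix(rnorm(2 * 4800), 2), 600)
#' cm <- pairwise_connectivity(bandpass(rec, "theta"))
#' cm$weights
#' @export
pairwise_connectivity <- function(rec, band = NULL, segment_s = 4,
                                  overlap = 0.5) {
  stopifnot(inherits(rec, "meg_recording"))
  if (is.null(band)) band <- rec$band
  if (is.null(band))
    stop("rec carries no band; band-filter it first or pass `band`")
  band <- as_band(band)
  fs <- rec$sampling_rate
  n <- ncol(rec$signals)
  if (n / fs < 2 * segment_s)
    stop("recording too short: need at least 2 x segment_s = ",
         2 * segment_s, " s")
  if (overlap < 0 || overlap >= 1) stop("overlap must be in [0, 1)")

  # A band-filtered signal carries no information above band$hi, so it can
  # be decimated to >= 4 x the upper band edge before the Welch stage;
  # frequency resolution (1 / segment_s) and segment count are unchanged.
  dec <- max(1L, as.integer(floor(fs / (4 * band$hi))))
  sig <- if (dec > 1L)
    rec$signals[, seq(1L, n, by = dec), drop = FALSE]
  else rec$signals
  fs_d <- fs / dec
  nper <- round(segment_s * fs_d)
  step <- max(1L, as.integer(round(nper * (1 - overlap))))

  zerovar <- apply(sig, 1, function(v) all(v == v[1]))
  if (any(zerovar))
    warning("zero-variance channel(s) ",
            paste(rec$channel_ids[zerovar], collapse = ", "),
            "; their connectivity is set to 0")

  coh <- welch_band_coherence(t(sig), fs_d, nper, step, band$lo, band$hi)
  xc <- sig - rowMeans(sig)
  sgn <- sign(tcrossprod(xc))                  # sign of zero-lag covariance
  sgn[!is.finite(sgn)] <- 0
  w <- sgn * coh
  w[zerovar, ] <- 0
  w[, zerovar] <- 0
  diag(w) <- 0
  w[lower.tri(w)] <- t(w)[lower.tri(w)]        # exact symmetry
  w <- pmin(pmax(w, -1), 1)
  dimnames(w) <- list(rec$channel_ids, rec$channel_ids)
  connectivity_matrix(w, subject_id = rec$subject_id, band = band,
                      segment_s = segment_s, overlap = overlap)
}

#' Threshold a connectivity matrix into an edge set
#'
#' Retains exactly the sensor pairs with `|weight| >= tau`, each tagged
#' with its sign; the same fixed threshold is applied to every subject so
#' topographic patterns are comparable across the cohort.
#'
#' @param cm A [connectivity_matrix()].
#' @param tau Threshold in `(0, 1)`.
#' @return A `thresholded_network`: list with `tau`, `channel_ids` and an
#'   `edges` data frame (`i`, `j`, `chan_i`, `chan_j`, `weight`, `sign`).
#' @export
apply_threshold <- function(cm, tau) {
  stopifnot(inherits(cm, "connectivity_matrix"))
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0 || tau >= 1)
    stop("tau must lie strictly between 0 and 1")
  w <- cm$weights
  idx <- which(upper.tri(w) & abs(w) >= tau, arr.ind = TRUE)
  ids <- rownames(w)
  edges <- data.frame(
    i = idx[, 1], j = idx[, 2],
    chan_i = ids[idx[, 1]], chan_j = ids[idx[, 2]],
    weight = w[idx], sign = as.integer(sign(w[idx])),
    stringsAsFactors = FALSE
  )
  edges <- edges[order(edges$i, edges$j), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(subject_id = cm$subject_id, band = cm$band, tau = tau,
                 n_nodes = nrow(w), channel_ids = ids, edges = edges),
            class = "thresholded_network")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat("<connectivity_matrix> ", x$subject_id,
      if (!is.null(x$band)) paste0(" [", x$band$name, "]"),
      ": ", nrow(x$weights), " nodes, |w| in [",
      sprintf("%.3f", min(abs(x$weights[upper.tri(x$weights)]))), ", ",
      sprintf("%.3f", max(abs(x$weights))), "]\n", sep = "")
  invisible(x)
}
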