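#' Average connection strength
#'
#' Mean of `|w_ij|` over all `n(n-1)/2` unordered sensor pairs of the full
#' weighted matrix -- the global functional-connectivity level of the
#' array.  Sign is ignored; the network comparison uses a single scalar
#' per band.
#'
#' @param cm A [connectivity_matrix()].
#' @return Scalar in `[0, 1]`.
#' @export
mean_strength <- function(cm) {
  w <- connectivity_weights(cm)
  if (nrow(w) < 2) stop("need at least 2 nodes")
  mean(abs(w[upper.tri(w)]))
}

#' Characteristic path length
#'
#' On the graph keeping edges with `|w_ij| >= tau`, each retained edge has
#' length `1/|w_ij|` (stronger connections are shorter).  Returns the mean
#' shortest-path length over all connected ordered node pairs; when the
#' graph is disconnected, unreachable pairs are excluded from the mean and
#' the `connected` attribute is `FALSE`.  `Inf` is returned if no pair is
#' connected.
#'
#' @param cm A [connectivity_matrix()].
#' @param tau Edge threshold in `(0, 1)`.
#' @return Scalar path length (attribute `connected` reports whether every
#'   pair was reachable).
#' @export
char_path_length <- function(cm, tau) {
  w <- connectivity_weights(cm)
  if (nrow(w) < 2) stop("need at least 2 nodes")
  check_tau(tau)
  absw <- abs(w)
  d <- ifelse(absw >= tau, 1 / absw, Inf)
  diag(d) <- 0
  for (k in seq_len(nrow(d)))                 # Floyd-Warshall relaxation
    d <- pmin(d, outer(d[, k], d[k, ], `+`))
  off <- d[upper.tri(d)]
  reachable <- is.finite(off)
  out <- if (!any(reachable)) Inf else mean(off[reachable])
  attr(out, "connected") <- all(reachable)
  out
}

#' Average weighted clustering coefficient
#'
#' Onnela weighted clustering on the `tau`-thresholded graph: retained
#' weights are normalised by the network's maximum `|w|`, each node's
#' coefficient is the mean geometric triangle intensity over its
#' `k(k-1)/2` neighbour pairs, nodes with degree < 2 contribute 0, and the
#' network value is the mean over all nodes.  With binary weights this
#' reduces to the classic unweighted clustering coefficient (the fraction
#' of closed neighbour pairs).
#'
#' @param cm A [connectivity_matrix()].
#' @param tau Edge threshold in `(0, 1)`.
#' @return Scalar in `[0, 1]`.
#' @export
avg_clustering <- function(cm, tau) {
  w <- connectivity_weights(cm)
  n <- nrow(w)
  if (n < 2) stop("need at least 2 nodes")
  check_tau(tau)
  absw <- abs(w)
  adj <- absw >= tau
  diag(adj) <- FALSE
  wthr <- absw * adj
  mx <- max(wthr)
  if (mx == 0) return(0)
  w3 <- (wthr / mx)^(1 / 3)
  tri <- diag(w3 %*% w3 %*% w3) / 2           # triangle intensity per node
  k <- rowSums(adj)
  ci <- ifelse(k >= 2, 2 * tri / (k * (k - 1)), 0)
  mean(ci)
}

#' All three network metrics for one subject-band network
#'
#' @param cm A [connectivity_matrix()].
#' @param tau Edge threshold for path length and clustering.
#' @return One-row data frame: `subject_id`, `band`, `n_nodes`,
#'   `strength`, `path_length`, `clustering`, `connected`.
#' @export
network_metrics <- function(cm, tau = 0.5) {
  pl <- char_path_length(cm, tau)
  data.frame(
    subject_id = cm$subject_id,
    band = if (is.null(cm$band)) NA_character_ else cm$band$name,
    n_nodes = nrow(cm$weights),
    strength = mean_strength(cm),
    path_length = as.numeric(pl),
    clustering = avg_clustering(cm, tau),
    connected = isTRUE(attr(pl, "connected")),
    stringsAsFactors = FALSE
  )
}

connectivity_weights <- function(cm) {
  if (inherits(cm, "connectivity_matrix")) cm$weights
  else if (is.matrix(cm)) cm
  else stop("expected a connectivity_matrix or a matrix")
}

check_tau <- function(tau) {
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0 || tau >= 1)
    stop("tau must lie strictly between 0 and 1")
  invisible(tau)
}
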