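#' Significant-persistence list of a diagram
#'
#' The descending-sorted list of persistences (death - birth) of features
#' with persistence at least \code{eps}. Infinite persistences (classes alive
#' at the computed threshold) are capped at \code{tau - birth} before list
#' construction, since diagrams are compared as truncated at their
#' PH-threshold.
#'
#' @param x a \code{ph_diagram}, a records data frame, or a numeric vector of
#'   persistences.
#' @param eps minimum persistence retained.
#' @param dim restrict to one homology dimension (default: all).
#' @param tau threshold for capping infinite persistence; defaults to the
#'   diagram's own parameters when available.
#' @return numeric vector sorted in decreasing order, class
#'   \code{persistence_list}.
#' @export
persistence_list <- function(x, eps = 0, dim = NULL, tau = NULL) {
  if (inherits(x, "ph_diagram")) {
    if (is.null(tau) && !is.null(x$params)) tau <- x$params$tau
    x <- x$records
  }
  if (is.data.frame(x)) {
    if (!is.null(dim)) x <- x[x$dim == dim, , drop = FALSE]
    pers <- x$death - x$birth
    inf <- is.infinite(pers)
    if (any(inf)) {
      if (is.null(tau)) stop("tau is required to cap infinite persistence")
      pers[inf] <- tau - x$birth[inf]
    }
  } else pers <- as.numeric(x)
  out <- sort(pers[pers >= eps], decreasing = TRUE)
  structure(out, class = "persistence_list", eps = eps)
}

#' L0 distance between two persistence diagrams
#'
#' Both diagrams are reduced to their significant-persistence lists (sorted
#' decreasing, persistence >= eps), the shorter list is padded with zeros to
#' equal length, and the maximum absolute element-wise difference is
#' returned. This is an L-infinity norm on zero-padded sorted vectors, hence
#' a pseudometric.
#'
#' @param a,b \code{ph_diagram}s, records data frames, or numeric persistence
#'   vectors.
#' @param eps significance threshold applied to both lists.
#' @param dim,tau passed to \code{\link{persistence_list}}.
#' @export
l0_distance <- function(a, b, eps = 0, dim = NULL, tau = NULL) {
  la <- as.numeric(persistence_list(a, eps = eps, dim = dim, tau = tau))
  lb <- as.numeric(persistence_list(b, eps = eps, dim = dim, tau = tau))
  n <- max(length(la), length(lb))
  if (n == 0L) return(0)
  la <- c(la, rep(0, n - length(la)))
  lb <- c(lb, rep(0, n - length(lb)))
  max(abs(la - lb))
}

#' Are two diagrams significantly different?
#'
#' Two diagrams, at least one containing a significant feature, are
#' classified as significantly different when their L0 distance is strictly
#' greater than \code{threshold}.
#'
#' @inheritParams l0_distance
#' @param threshold strict decision boundary (default 3).
#' @export
significantly_different <- function(a, b, eps = 0, threshold = 3,
                                    dim = NULL, tau = NULL) {
  la <- persistence_list(a, eps = eps, dim = dim, tau = tau)
  lb <- persistence_list(b, eps = eps, dim = dim, tau = tau)
  if (length(la) == 0L && length(lb) == 0L) {
    warning("neither diagram has a significant feature; returning FALSE")
    return(FALSE)
  }
  l0_distance(la, lb, eps = eps) > threshold
}

#' Pairwise L0 distance matrix
#'
#' @param diagrams named list of diagrams (any input accepted by
#'   \code{\link{l0_distance}}).
#' @inheritParams l0_distance
#' @return symmetric numeric matrix with zero diagonal.
#' @export
l0_matrix <- function(diagrams, eps = 0, dim = NULL, tau = NULL) {
  k <- length(diagrams)
  lists <- lapply(diagrams, persistence_list, eps = eps, dim = dim, tau = tau)
  m <- matrix(0, k, k, dimnames = list(names(diagrams), names(diagrams)))
  if (k >= 2L)
    for (a in seq_len(k - 1L)) for (b in seq(a + 1L, k))
      m[a, b] <- m[b, a] <- l0_distance(lists[[a]], lists[[b]])
  m
}
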