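#' Sparse pairwise-distance model
#'
#' Builds the distance model backing a Vietoris-Rips filtration. Only pairs
#' with distance at most \code{tau} are stored; an absent pair means the
#' distance is infinite and the edge never enters the filtration (the Hi-C
#' convention for zero or NaN contact counts). Distances from an embedding are
#' Euclidean.
#'
#' @param x a numeric matrix of point coordinates (one point per row), a
#'   square symmetric distance matrix (\code{NA}/\code{NaN} entries are
#'   treated as absent), or a data frame of COO triples with columns
#'   \code{i}, \code{j}, \code{value} holding 0-based point indices.
#' @param tau truncation threshold (must be positive).
#' @param type how to interpret \code{x}; \code{"auto"} treats a data frame as
#'   COO triples, a square matrix with zero diagonal as distances, and any
#'   other matrix as an embedding.
#' @param n_points number of points, required for COO input.
#' @return an object of class \code{sparse_dist} with fields \code{n_points},
#'   \code{i}, \code{j} (0-based, \code{i < j}), \code{d}, \code{tau} and
#'   \code{source}.
#' @export
build_distance_model <- function(x, tau,
                                 type = c("auto", "embedding", "distances", "coo"),
                                 n_points = NULL) {
  type <- match.arg(type)
  stopifnot(is.numeric(tau), length(tau) == 1L, tau > 0)
  if (type == "auto") {
    if (is.data.frame(x)) type <- "coo"
    else if (is.matrix(x) && nrow(x) == ncol(x) && nrow(x) > 1 &&
             all(abs(diag(x)) < .Machine$double.eps^0.5, na.rm = TRUE) &&
             isTRUE(all.equal(x, t(x), check.attributes = FALSE)))
      type <- "distances"
    else type <- "embedding"
  }
  switch(type,
    embedding = dist_from_embedding(x, tau),
    distances = dist_from_matrix(x, tau),
    coo = dist_from_coo(x, n_points, tau))
}

dist_from_embedding <- function(coords, tau) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (any(!is.finite(coords))) stop("embedding coordinates must be finite")
  if (ncol(coords) < 1L) stop("embedding must have at least one coordinate")
  n <- nrow(coords)
  d <- as.matrix(dist(coords))
  ut <- which(upper.tri(d), arr.ind = TRUE)
  keep <- d[ut] <= tau
  new_sparse_dist(n, ut[keep, 1L] - 1L, ut[keep, 2L] - 1L, d[ut][keep],
                  tau, "embedding")
}

dist_from_matrix <- function(m, tau) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("distance matrix must be square")
  if (any(m < 0, na.rm = TRUE)) stop("distances must be non-negative")
  n <- nrow(m)
  ut <- which(upper.tri(m), arr.ind = TRUE)
  v <- m[ut]
  keep <- is.finite(v) & v <= tau
  new_sparse_dist(n, ut[keep, 1L] - 1L, ut[keep, 2L] - 1L, v[keep],
                  tau, "matrix")
}

dist_from_coo <- function(df, n_points, tau) {
  stopifnot(all(c("i", "j", "value") %in% names(df)))
  if (is.null(n_points)) n_points <- max(df$i, df$j) + 1L
  i <- as.integer(pmin(df$i, df$j))
  j <- as.integer(pmax(df$i, df$j))
  v <- as.numeric(df$value)
  ok <- i != j & !is.na(v) & is.finite(v)
  i <- i[ok]; j <- j[ok]; v <- v[ok]
  if (any(v < 0)) stop("distances must be non-negative")
  # duplicates (i, j) keep the smallest distance
  o <- order(i, j, v)
  i <- i[o]; j <- j[o]; v <- v[o]
  dup <- duplicated(paste(i, j))
  i <- i[!dup]; j <- j[!dup]; v <- v[!dup]
  keep <- v <= tau
  new_sparse_dist(as.integer(n_points), i[keep], j[keep], v[keep], tau, "matrix")
}

new_sparse_dist <- function(n, i, j, d, tau, source) {
  structure(list(n_points = as.integer(n), i = as.integer(i),
                 j = as.integer(j), d = as.numeric(d), tau = tau,
                 source = source),
            class = "sparse_dist")
}

#' @export
print.sparse_dist <- function(x, ...) {
  cat(sprintf("<sparse_dist> %d points, %d pairs with distance <= %g (%s)\n",
              x$n_points, length(x$d), x$tau, x$source))
  invisible(x)
}

#' Number of stored pairs in a distance model
#' @param dm a \code{sparse_dist} object.
#' @export
n_pairs <- function(dm) length(dm$d)

# Environment-based pair lookup: key i*n + j (i < j), value distance.
dist_lookup <- function(dm) {
  keys <- dm$i * as.numeric(dm$n_points) + dm$j
  function(a, b) {
    i <- pmin(a, b); j <- pmax(a, b)
    out <- dm$d[match(i * as.numeric(dm$n_points) + j, keys)]
    out[i == j] <- 0
    out[is.na(out)] <- Inf
    out
  }
}

#' Read a point embedding from a delimited text file
#'
#' Whitespace- or comma-delimited table, one point per row, columns are
#' coordinates; an optional non-numeric header row is skipped.
#' @param path file path.
#' @return numeric matrix of coordinates.
#' @export
read_embedding <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first)) "," else ""
  hdr <- suppressWarnings(any(is.na(as.numeric(strsplit(trimws(first),
                              if (sep == ",") "," else "[[:space:]]+")[[1]]))))
  as.matrix(read.table(path, header = hdr, sep = sep))
}

#' Read COO triples (i, j, value) from a delimited text file
#' @param path file path.
#' @return data frame with columns \code{i}, \code{j}, \code{value}.
#' @export
read_coo <- function(path) {
  df <- read.table(path, header = FALSE, col.names = c("i", "j", "value"))
  df$i <- as.integer(df$i); df$j <- as.integer(df$j)
  df
}
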