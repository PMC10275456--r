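#' Build a Vietoris-Rips filtration
#'
#' Enumerates all cliques of the truncated distance graph with up to
#' \code{max_dim + 1} vertices, ordered by diameter ascending, then dimension
#' ascending, then vertex-lexicographic. Every face of an included simplex is
#' included and precedes it. The lexicographic tie-break among simplices of
#' equal diameter and dimension can be replaced by a seeded random order via
#' \code{perm_seed}; this is the degree of freedom the stochastic
#' re-tightening stage permutes.
#'
#' @param dm a \code{sparse_dist} model (already truncated at \code{tau}).
#' @param tau filtration threshold; defaults to the model's own threshold.
#' @param max_dim largest simplex dimension (1 to 3; homology is computed up
#'   to \code{max_dim - 1}).
#' @param perm_seed \code{NULL} for the lexicographic tie-break, or an integer
#'   seed for a random permutation of equal-diameter, equal-dimension runs.
#' @return a \code{vr_filtration}: list with \code{verts} (m x 4 matrix of
#'   0-based vertex ids, -1 padded), \code{dim}, \code{diam}, \code{n_points},
#'   \code{tau}, \code{max_dim}.
#' @export
build_vr_filtration <- function(dm, tau = dm$tau, max_dim = 3, perm_seed = NULL) {
  stopifnot(inherits(dm, "sparse_dist"))
  if (max_dim > 3) stop("max_dim > 3 is unsupported (homology is reported up to H2)")
  if (max_dim < 1) stop("max_dim must be at least 1")
  if (tau > dm$tau + 1e-12) stop("tau exceeds the distance model's truncation")
  keep <- dm$d <= tau
  f <- vr_filtration_cpp(dm$n_points, dm$i[keep], dm$j[keep], dm$d[keep],
                         tau, as.integer(max_dim),
                         if (is.null(perm_seed)) -1L else as.integer(perm_seed))
  class(f) <- "vr_filtration"
  f
}

#' @export
print.vr_filtration <- function(x, ...) {
  tab <- tabulate(x$dim + 1L, nbins = 4L)
  cat(sprintf("<vr_filtration> %d points, tau = %g: %d vertices, %d edges, %d triangles, %d tetrahedra\n",
              x$n_points, x$tau, tab[1], tab[2], tab[3], tab[4]))
  invisible(x)
}

#' Number of simplices in a filtration
#' @param filt a \code{vr_filtration}.
#' @export
n_simplices <- function(filt) length(filt$dim)

#' Vertex tuples of simplices
#'
#' @param filt a \code{vr_filtration}.
#' @param idx 1-based filtration indices.
#' @return integer matrix, one row per simplex, -1 padded, 0-based vertex ids.
#' @export
simplex_vertices <- function(filt, idx) {
  filt$verts[idx, , drop = FALSE]
}

#' Find filtration indices of vertex tuples
#'
#' @param filt a \code{vr_filtration}.
#' @param verts integer matrix of 0-based vertex ids, one simplex per row
#'   (pad unused columns with -1), or a vector for a single simplex.
#' @return 1-based filtration indices (NA when the simplex is absent).
#' @export
simplex_index <- function(filt, verts) {
  if (!is.matrix(verts)) verts <- matrix(verts, nrow = 1L)
  if (ncol(verts) < 4L)
    verts <- cbind(verts, matrix(-1L, nrow(verts), 4L - ncol(verts)))
  storage.mode(verts) <- "integer"
  out <- simplex_index_cpp(filt$verts, filt$dim, filt$diam, filt$n_points, verts)
  out <- out + 1L
  out[out == 0L] <- NA_integer_
  out
}

# ---- chains over Z2 ----

#' Construct a chain
#'
#' A chain is a set of same-dimension simplices with Z2 (symmetric
#' difference) arithmetic; adding a simplex twice removes it. Chains store
#' 1-based filtration indices.
#'
#' @param idx integer vector of 1-based filtration indices.
#' @param dim chain dimension.
#' @export
new_chain <- function(idx, dim) {
  idx <- sort(unique(as.integer(idx)))
  structure(list(dim = as.integer(dim), idx = idx), class = "tph_chain")
}

#' @export
print.tph_chain <- function(x, ...) {
  cat(sprintf("<chain> dim %d, %d simplices\n", x$dim, length(x$idx)))
  invisible(x)
}

#' Chain length (number of simplices)
#' @param chain a \code{tph_chain}.
#' @export
chain_length <- function(chain) length(chain$idx)

#' Z2 sum of two chains
#' @param a,b chains of equal dimension.
#' @export
chain_xor <- function(a, b) {
  stopifnot(a$dim == b$dim)
  both <- c(a$idx, b$idx)
  keep <- both[!(both %in% both[duplicated(both)])]
  new_chain(keep, a$dim)
}

#' Z2 boundary of a chain
#'
#' @param chain a \code{tph_chain} of dimension 1 to 3.
#' @param filt the filtration the chain lives in.
#' @return the (dim - 1)-chain of facets appearing an odd number of times;
#'   the empty chain when \code{chain} is a cycle.
#' @export
chain_boundary <- function(chain, filt) {
  stopifnot(chain$dim >= 1L, chain$dim <= 3L)
  if (length(chain$idx) == 0L) return(new_chain(integer(), chain$dim - 1L))
  out <- chain_boundary_cpp(filt$verts, filt$dim, filt$diam, filt$n_points,
                            chain$idx - 1L)
  new_chain(out + 1L, chain$dim - 1L)
}

#' Is the chain a cycle?
#' @inheritParams chain_boundary
#' @export
is_cycle <- function(chain, filt) chain_length(chain_boundary(chain, filt)) == 0L

#' Vertex tuples of a chain's simplices
#' @inheritParams chain_boundary
#' @return integer matrix with \code{dim + 1} columns of 0-based vertex ids.
#' @export
chain_vertices <- function(chain, filt) {
  v <- simplex_vertices(filt, chain$idx)
  v[, seq_len(chain$dim + 1L), drop = FALSE]
}

# A chain expressed as global vertex tuples, detached from any filtration;
# used for final representatives whose covers were re-filtered independently.
new_vertex_chain <- function(verts, dim) {
  verts <- verts[, seq_len(dim + 1L), drop = FALSE]
  verts <- t(apply(verts, 1L, sort))
  if (dim == 0L) verts <- matrix(verts, ncol = 1L)
  o <- do.call(order, as.data.frame(verts))
  structure(list(dim = as.integer(dim), verts = verts[o, , drop = FALSE]),
            class = "vertex_chain")
}

#' @export
print.vertex_chain <- function(x, ...) {
  cat(sprintf("<vertex_chain> dim %d, %d simplices\n", x$dim, nrow(x$verts)))
  invisible(x)
}

#' Convert a filtration-indexed chain to global vertex tuples
#'
#' @param chain a \code{tph_chain}.
#' @param filt its filtration.
#' @param vmap optional map from the filtration's 0-based local vertex ids to
#'   global point ids (1-based positions into \code{vmap}).
#' @export
as_vertex_chain <- function(chain, filt, vmap = NULL) {
  v <- chain_vertices(chain, filt)
  if (!is.null(vmap)) v[] <- vmap[v + 1L]
  new_vertex_chain(v, chain$dim)
}
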