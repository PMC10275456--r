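#' Greedy pairwise shortening of a set of representative cycles
#'
#' Repeatedly computes the steepest attainable decrease d* = max over ordered
#' pairs (i, j), i != j, of |Ci| - |Ci xor Cj|, and while d* > 0 replaces Ci
#' by Ci xor Cj for every pair achieving it, scanning pairs in ascending
#' (i, j) order with immediate visibility of earlier replacements. Each
#' replacement is an elementary basis operation, so the Z2 span of the set
#' modulo boundaries is preserved, the total length strictly decreases, and
#' the fixed point has no pair that could shorten any cycle. The optimized
#' search (default) only examines pairs sharing at least one simplex -- a
#' disjoint pair can never shorten -- and produces the identical result to
#' the all-pairs scan.
#'
#' @param cycles list of \code{tph_chain}s of one dimension.
#' @param optimized use the shared-simplex candidate index for the d* search.
#' @return list of shortened chains; attributes \code{n_passes} and
#'   \code{n_applied} report the work done.
#' @export
greedy_shorten <- function(cycles, optimized = TRUE) {
  if (length(cycles) == 0L) return(cycles)
  d <- unique(vapply(cycles, function(c) c$dim, integer(1)))
  if (length(d) != 1L) stop("all cycles must have the same dimension")
  res <- greedy_shorten_cpp(lapply(cycles, function(c) c$idx), optimized)
  out <- lapply(res$cycles, new_chain, dim = d)
  attr(out, "n_passes") <- res$n_passes
  attr(out, "n_applied") <- res$n_applied
  out
}

#' Split a cycle into connected components
#'
#' Pairwise Z2 addition can produce disconnected cycles. Two d-simplices are
#' connected when they share a (d-1)-face; the components of that face-sharing
#' graph are returned as separate cycles (each component of a cycle is itself
#' a cycle, and components share no face).
#'
#' @param chain a \code{tph_chain} cycle.
#' @param filt its filtration.
#' @return list of \code{tph_chain}s, one per component.
#' @export
split_disconnected <- function(chain, filt) {
  k <- chain_length(chain)
  if (k <= 1L) return(list(chain))
  fac <- facets_list_cpp(filt$verts, filt$dim, filt$diam, filt$n_points,
                         chain$idx - 1L)
  # union-find over simplices sharing a facet
  parent <- seq_len(k)
  findr <- function(v) { while (parent[v] != v) { parent[v] <<- parent[parent[v]]; v <- parent[v] }; v }
  seenf <- new.env(hash = TRUE)
  for (q in seq_len(k)) {
    for (f in fac[[q]]) {
      key <- as.character(f)
      prev <- seenf[[key]]
      if (is.null(prev)) assign(key, q, envir = seenf)
      else { a <- findr(prev); b <- findr(q); if (a != b) parent[a] <- b }
    }
  }
  comp <- vapply(seq_len(k), findr, integer(1))
  lapply(split(chain$idx, comp), new_chain, dim = chain$dim)
}

#' Locally smooth cycles with trivial simplices
#'
#' Reduces H1 representatives with triangles and H2 representatives with
#' tetrahedra: the cycle is XORed with the boundary of a cofacet whenever
#' that strictly shortens it, iterating over only the trivial simplices that
#' share a face with the current cycle, until a fixed point with respect to
#' single-simplex moves. The difference between input and output is a sum of
#' boundaries, so the homology class is unchanged.
#'
#' @param cycles list of \code{tph_chain} cycles (or a single chain).
#' @param filt their filtration.
#' @return list of smoothed chains (or a single chain if one was given).
#' @export
smooth_cycles <- function(cycles, filt) {
  single <- inherits(cycles, "tph_chain")
  if (single) cycles <- list(cycles)
  if (length(cycles) == 0L) return(cycles)
  res <- smooth_cycles_cpp(filt$verts, filt$dim, filt$diam, filt$n_points,
                           lapply(cycles, function(c) c$idx - 1L))
  out <- Map(function(ix, c0) new_chain(ix + 1L, c0$dim), res, cycles)
  if (single) out[[1L]] else out
}

#' Drop degenerate cycles
#'
#' Smoothing can reduce a cycle to a degenerate chain of length two (or
#' less); such chains localize nothing and are removed before further
#' analysis.
#'
#' @param cycles list of \code{tph_chain}s.
#' @param max_len largest length considered degenerate.
#' @return the surviving cycles; attribute \code{n_dropped} counts removals.
#' @export
drop_degenerate <- function(cycles, max_len = 2L) {
  keep <- vapply(cycles, chain_length, integer(1)) > max_len
  out <- cycles[keep]
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Tighten the birth-cycles of a diagram (stages I-III)
#'
#' Extracts birth-cycles for every nontrivial feature of the requested
#' dimension born at scale at most \code{birth_max}, then applies greedy
#' shortening, connectedness splitting, local smoothing, and degenerate
#' filtering.
#'
#' @param pd a \code{ph_diagram}.
#' @param dim homology dimension to tighten (1 or 2).
#' @param params \code{ph_params}; defaults to the diagram's.
#' @param birth_max only features born at scale <= \code{birth_max} seed the
#'   cycle set; defaults to the birth-threshold \code{tau_u}.
#' @param optimized passed to \code{\link{greedy_shorten}}.
#' @return a list with \code{cycles} (tight \code{tph_chain}s),
#'   \code{records} (the seeding records), and \code{log} (lengths per stage
#'   and the degenerate count).
#' @export
tighten_cycles <- function(pd, dim = 1L, params = pd$params,
                           birth_max = params$tau_u, optimized = TRUE) {
  stopifnot(inherits(pd, "ph_diagram"))
  filt <- pd$state$filt
  rec <- pd$records[pd$records$dim == dim & pd$records$birth <= birth_max, ,
                    drop = FALSE]
  if (nrow(rec) == 0L)
    return(list(cycles = list(), records = rec,
                log = list(n_birth = 0L, n_degenerate = 0L)))
  bc <- birth_cycles(pd, rec$id)
  len0 <- vapply(bc, chain_length, integer(1))
  sh <- greedy_shorten(bc, optimized = optimized)
  sp <- unlist(lapply(sh, split_disconnected, filt = filt), recursive = FALSE)
  sm <- smooth_cycles(sp, filt)
  out <- drop_degenerate(sm)
  list(cycles = out, records = rec,
       log = list(n_birth = length(bc),
                  birth_lengths = len0,
                  shortened_lengths = vapply(sh, chain_length, integer(1)),
                  smoothed_lengths = vapply(sm, chain_length, integer(1)),
                  n_split = length(sp) - length(sh),
                  n_degenerate = attr(out, "n_dropped")))
}
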