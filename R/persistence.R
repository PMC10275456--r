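#' Significance parameters for persistent homology
#'
#' \code{tau_u} (birth-threshold) is the upper limit on the birth of cycles,
#' \code{eps} the lower limit on persistence; persistence is computed up to
#' the PH-threshold \code{tau = tau_u + eps}, which is always derived and
#' never set independently.
#'
#' @param tau_u birth-threshold (> 0); same units as the input distances.
#' @param eps minimum persistence for significance (>= 0).
#' @export
ph_params <- function(tau_u, eps) {
  stopifnot(is.numeric(tau_u), tau_u > 0, is.numeric(eps), eps >= 0)
  structure(list(tau_u = tau_u, eps = eps, tau = tau_u + eps),
            class = "ph_params")
}

#' Protein-backbone preset: birth-threshold 10 A, persistence threshold 3.5 A
#'
#' Chosen against typical protein bond lengths of roughly 1.5 to 3 A.
#' @export
ph_params_protein <- function() ph_params(10, 3.5)

#' @export
print.ph_params <- function(x, ...) {
  cat(sprintf("<ph_params> tau_u = %g, eps = %g, tau = %g\n",
              x$tau_u, x$eps, x$tau))
  invisible(x)
}

#' Compute persistent homology of a Vietoris-Rips filtration
#'
#' Persistence pairs for dimensions 1 to \code{max_dim - 1} (H0 is computed
#' internally but not reported), truncated at the filtration threshold:
#' classes alive at tau have death +Inf. The default route reduces the
#' coboundary matrix (with clearing) and maps pivots back through the
#' bijection between coboundary and boundary pivots; \code{route =
#' "boundary"} reduces the boundary matrix directly. Both routes yield the
#' same diagram.
#'
#' @param filt a \code{vr_filtration}.
#' @param params optional \code{ph_params}, attached for downstream stages.
#' @param route reduction route.
#' @return a \code{ph_diagram}: list with \code{records} (data frame: id,
#'   dim, birth, death, persistence, creator, destroyer as 1-based filtration
#'   indices), and a \code{state} holding the filtration and the complete
#'   pivot maps (including zero-persistence pairs) used for birth-cycle
#'   extraction.
#' @export
compute_persistence <- function(filt, params = NULL,
                                route = c("coboundary", "boundary")) {
  route <- match.arg(route)
  stopifnot(inherits(filt, "vr_filtration"))
  maxhom <- filt$max_dim - 1L
  pairs <- vector("list", filt$max_dim)
  if (n_simplices(filt) == 0L) {
    for (d in 0:maxhom) pairs[[d + 1L]] <- list(creator = integer(), destroyer = integer())
  } else if (route == "coboundary") {
    raw <- ph_pairs_cpp(filt$verts, filt$dim, filt$diam, filt$n_points,
                        as.integer(filt$max_dim))
    for (d in 0:maxhom)
      pairs[[d + 1L]] <- list(creator = raw[[d + 1L]]$creator + 1L,
                              destroyer = ifelse(raw[[d + 1L]]$destroyer < 0L,
                                                 NA_integer_,
                                                 raw[[d + 1L]]$destroyer + 1L))
  } else {
    raw <- boundary_pairs_cpp(filt$verts, filt$dim, filt$diam, filt$n_points, FALSE)
    for (d in 0:maxhom) {
      sel <- raw$dim == d
      pairs[[d + 1L]] <- list(creator = raw$creator[sel] + 1L,
                              destroyer = ifelse(raw$destroyer[sel] < 0L,
                                                 NA_integer_,
                                                 raw$destroyer[sel] + 1L))
    }
  }
  rec <- do.call(rbind, lapply(seq_len(maxhom), function(d) {
    p <- pairs[[d + 1L]]
    if (length(p$creator) == 0L)
      return(data.frame(dim = integer(), birth = numeric(), death = numeric(),
                        creator = integer(), destroyer = integer()))
    data.frame(dim = d, birth = filt$diam[p$creator],
               death = ifelse(is.na(p$destroyer), Inf, filt$diam[p$destroyer]),
               creator = p$creator, destroyer = p$destroyer)
  }))
  rec <- rec[rec$death > rec$birth, , drop = FALSE]
  rec <- rec[order(rec$dim, rec$birth, rec$death), , drop = FALSE]
  if (nrow(rec)) rec$id <- seq_len(nrow(rec)) else rec$id <- integer()
  rec$persistence <- rec$death - rec$birth
  rownames(rec) <- NULL
  rec <- rec[, c("id", "dim", "birth", "death", "persistence", "creator", "destroyer")]
  structure(list(records = rec,
                 state = list(filt = filt, pairs = pairs, route = route),
                 params = params),
            class = "ph_diagram")
}

#' @export
print.ph_diagram <- function(x, ...) {
  cat(sprintf("<ph_diagram> %d nontrivial records (route: %s)\n",
              nrow(x$records), x$state$route))
  if (nrow(x$records)) print(table(dim = x$records$dim))
  invisible(x)
}

#' Filter records to significant features
#'
#' A feature is significant when its birth is at most \code{tau_u} and its
#' persistence at least \code{eps}; death beyond the computed threshold
#' (reported as +Inf) always qualifies.
#'
#' @param x a \code{ph_diagram} or its records data frame.
#' @param params a \code{ph_params}.
#' @export
significant <- function(x, params = NULL) {
  rec <- if (inherits(x, "ph_diagram")) x$records else x
  if (is.null(params) && inherits(x, "ph_diagram")) params <- x$params
  stopifnot(inherits(params, "ph_params"))
  keep <- rec$birth <= params$tau_u &
    (is.infinite(rec$death) | rec$death - rec$birth >= params$eps)
  rec[keep, , drop = FALSE]
}

# owner map (pivot bijection one dimension down) for birth-cycle recursion:
# (d-1)-simplex filtration index -> destroyer d-simplex index, 0-based.
.owner_map <- function(pd, d) {
  p <- pd$state$pairs[[d]]  # dim d-1 pairs
  fin <- !is.na(p$destroyer)
  list(keys = p$creator[fin] - 1L, vals = p$destroyer[fin] - 1L)
}

#' Extract birth-cycles
#'
#' The reduction operations of the boundary matrix form a comprehensive set
#' of representative boundaries, one per nontrivial class: the birth-cycle,
#' the column V(sigma) of reduction operations of the creator simplex. The
#' default method rebuilds each needed column recursively on the fly, caching
#' a reduced column only after its recursion has been re-entered more than
#' \code{cache_limit} times; \code{method = "stored"} instead runs the full
#' boundary reduction keeping every V column, and is used as the in-package
#' cross-check.
#'
#' @param pd a \code{ph_diagram}.
#' @param ids record ids (rows of \code{pd$records}); defaults to all.
#' @param method on-the-fly recursion or full stored-V reduction.
#' @param cache_limit selective-caching threshold for the on-the-fly route.
#' @return list of \code{tph_chain} cycles, one per requested record, each
#'   containing its creator simplex and with zero boundary.
#' @export
birth_cycles <- function(pd, ids = pd$records$id,
                         method = c("on_the_fly", "stored"),
                         cache_limit = 2L) {
  method <- match.arg(method)
  stopifnot(inherits(pd, "ph_diagram"))
  rec <- pd$records[match(ids, pd$records$id), , drop = FALSE]
  if (anyNA(rec$id)) stop("unknown record id")
  filt <- pd$state$filt
  out <- vector("list", nrow(rec))
  if (method == "stored") {
    raw <- boundary_pairs_cpp(filt$verts, filt$dim, filt$diam, filt$n_points, TRUE)
    pos <- match(rec$creator - 1L, raw$creator)
    if (anyNA(pos)) stop("record is not a creator of this filtration")
    for (q in seq_len(nrow(rec)))
      out[[q]] <- new_chain(raw$v[[pos[q]]] + 1L, rec$dim[q])
  } else {
    for (d in sort(unique(rec$dim))) {
      sel <- which(rec$dim == d)
      own <- .owner_map(pd, d)
      cyc <- birth_cycles_cpp(filt$verts, filt$dim, filt$diam, filt$n_points,
                              rec$creator[sel] - 1L,
                              own$keys, own$vals, as.integer(cache_limit))
      for (q in seq_along(sel)) out[[sel[q]]] <- new_chain(cyc[[q]] + 1L, d)
    }
  }
  names(out) <- rec$id
  out
}

#' @rdname birth_cycles
#' @param id a single record id.
#' @export
birth_cycle <- function(pd, id, method = c("on_the_fly", "stored"),
                        cache_limit = 2L) {
  birth_cycles(pd, id, method = method, cache_limit = cache_limit)[[1L]]
}
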