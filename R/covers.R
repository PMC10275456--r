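#' Local cover of a cycle in an embedding
#'
#' The cover of a cycle is the smallest axis-aligned hyper-rectangle that
#' contains all points of the cycle, together with every data point lying on
#' or inside that box. Covers restrict the re-analysis of a feature to a
#' small sub-cloud; they require a spatial embedding.
#'
#' @param cycle a \code{tph_chain} (with \code{filt}) or a
#'   \code{vertex_chain}.
#' @param coords the full embedding (one point per row; points are indexed
#'   0-based).
#' @param filt the filtration, required when \code{cycle} is a
#'   \code{tph_chain}.
#' @return a \code{tph_cover}: list with \code{box} (2 x dim matrix, rows
#'   \code{lo}, \code{hi}), \code{members} (0-based point indices),
#'   \code{cycle}, and \code{n_significant} (\code{NA} until computed).
#' @export
local_cover <- function(cycle, coords, filt = NULL) {
  if (inherits(cycle, "tph_chain")) {
    stopifnot(!is.null(filt))
    cycle <- as_vertex_chain(cycle, filt)
  }
  pts <- unique(as.vector(cycle$verts))
  box <- apply(coords[pts + 1L, , drop = FALSE], 2L, range)
  rownames(box) <- c("lo", "hi")
  members <- box_members(box, coords)
  structure(list(box = box, members = members, cycle = cycle,
                 n_significant = NA_integer_),
            class = "tph_cover")
}

box_members <- function(box, coords) {
  inside <- rep(TRUE, nrow(coords))
  for (k in seq_len(ncol(coords)))
    inside <- inside & coords[, k] >= box["lo", k] & coords[, k] <= box["hi", k]
  which(inside) - 1L
}

#' @export
print.tph_cover <- function(x, ...) {
  cat(sprintf("<tph_cover> %d members, n_significant = %s\n",
              length(x$members),
              ifelse(is.na(x$n_significant), "?", x$n_significant)))
  invisible(x)
}

# One deterministic tightening run on a sub-cloud. The tightening stages run
# in the complex truncated at the PH-threshold tau, as in the global stage --
# beyond tau every loop is contractible by local moves in the near-complete
# graph, which would defeat the smoothing fixed point. Significance counts at
# the truncated threshold equal those at the maximum possible threshold
# (death beyond tau reports +Inf, which qualifies exactly when the resolved
# persistence would), so the complete complex is only built when resolved
# deaths are requested (full_pd = TRUE). Returns the significant records
# (persistence descending) and the n_sig shortest tight cycles as global
# vertex chains.
.cover_run <- function(coords_local, members, params, dim, perm_seed = NULL,
                       full_pd = FALSE) {
  dmax <- max(dist(coords_local))
  if (dmax == 0) dmax <- 1
  tau_run <- min(params$tau, dmax)
  dm <- dist_from_embedding(coords_local, tau_run)
  filt <- build_vr_filtration(dm, tau_run, max_dim = dim + 1L,
                              perm_seed = perm_seed)
  pd <- compute_persistence(filt, params)
  sig <- significant(pd, params)
  sig <- sig[sig$dim == dim, , drop = FALSE]
  sig <- sig[order(-sig$persistence), , drop = FALSE]
  if (full_pd && params$tau < dmax) {
    dm_f <- dist_from_embedding(coords_local, dmax)
    filt_f <- build_vr_filtration(dm_f, dmax, max_dim = dim + 1L,
                                  perm_seed = perm_seed)
    sig <- significant(compute_persistence(filt_f, params), params)
    sig <- sig[sig$dim == dim, , drop = FALSE]
    sig <- sig[order(-sig$persistence), , drop = FALSE]
  }
  tight <- tighten_cycles(pd, dim = dim, params = params)
  cyc <- tight$cycles
  if (length(cyc)) cyc <- cyc[order(vapply(cyc, chain_length, integer(1)))]
  cyc <- head(cyc, nrow(sig))
  list(n_sig = nrow(sig), records = sig,
       cycles = lapply(cyc, as_vertex_chain, filt = filt, vmap = members))
}

#' Count significant features of a cover's sub-cloud
#'
#' Runs persistent homology of the embedding restricted to the cover's
#' members, up to the maximum possible threshold, and counts the features of
#' the requested dimension that are significant under \code{params}.
#'
#' @param cover a \code{tph_cover}.
#' @param coords the full embedding.
#' @param params \code{ph_params}.
#' @param dim homology dimension of interest.
#' @return the cover with \code{n_significant} filled in.
#' @export
cover_significance <- function(cover, coords, params, dim) {
  loc <- coords[cover$members + 1L, , drop = FALSE]
  if (nrow(loc) < dim + 3L) { cover$n_significant <- 0L; return(cover) }
  run <- .cover_run(loc, cover$members, params, dim)
  cover$n_significant <- run$n_sig
  cover
}

.box_subset <- function(a, b) {  # is box a inside box b?
  all(a["lo", ] >= b["lo", ] - 1e-12) && all(a["hi", ] <= b["hi", ] + 1e-12)
}

.box_intersect <- function(a, b) {
  lo <- pmax(a["lo", ], b["lo", ])
  hi <- pmin(a["hi", ], b["hi", ])
  if (any(lo > hi)) return(NULL)
  box <- rbind(lo = lo, hi = hi)
  box
}

#' Prune and contract a collection of covers
#'
#' A cover whose sub-cloud has no significant feature cannot wrap around one,
#' and is dropped. Then two contraction rules are applied to a fixed point,
#' scanning covers in creation order: if cover A is a subset of cover B with
#' the same number of significant features, B is removed; if the intersection
#' of A and B has as many significant features as A (or B), that cover is
#' replaced by the intersection. Identical covers are deduplicated. The total
#' number of significant features attributable to the collection is
#' unchanged.
#'
#' @param covers list of \code{tph_cover}s.
#' @param coords the full embedding.
#' @param params \code{ph_params}.
#' @param dim homology dimension.
#' @return pruned, contracted list of covers (all with
#'   \code{n_significant > 0}).
#' @export
prune_and_contract <- function(covers, coords, params, dim) {
  covers <- lapply(covers, function(cv)
    if (is.na(cv$n_significant)) cover_significance(cv, coords, params, dim) else cv)
  covers <- Filter(function(cv) cv$n_significant > 0L, covers)
  repeat {
    changed <- FALSE
    # subset rule to fixed point
    repeat {
      drop <- rep(FALSE, length(covers))
      for (a in seq_along(covers)) for (b in seq_along(covers)) {
        if (a == b || drop[a] || drop[b]) next
        if (.box_subset(covers[[a]]$box, covers[[b]]$box) &&
            covers[[a]]$n_significant == covers[[b]]$n_significant)
          drop[b] <- TRUE
      }
      if (!any(drop)) break
      covers <- covers[!drop]
      changed <- TRUE
    }
    # intersection rule (one sweep), then back to the subset rule
    applied <- FALSE
    if (length(covers) >= 2L) {
      for (a in seq_len(length(covers) - 1L)) {
        for (b in seq(a + 1L, length(covers))) {
          bi <- .box_intersect(covers[[a]]$box, covers[[b]]$box)
          if (is.null(bi)) next
          if (identical(bi, covers[[a]]$box) && identical(bi, covers[[b]]$box)) next
          members <- box_members(bi, coords)
          cand <- structure(list(box = bi, members = members,
                                 cycle = covers[[a]]$cycle,
                                 n_significant = NA_integer_),
                            class = "tph_cover")
          cand <- cover_significance(cand, coords, params, dim)
          if (cand$n_significant == covers[[a]]$n_significant &&
              !identical(bi, covers[[a]]$box)) {
            covers[[a]] <- cand; applied <- TRUE
          }
          if (cand$n_significant == covers[[b]]$n_significant &&
              !identical(bi, covers[[b]]$box)) {
            covers[[b]] <- cand; applied <- TRUE
          }
        }
        if (applied) break
      }
    }
    if (applied) changed <- TRUE
    if (!applied) break
  }
  # deduplicate identical boxes
  if (length(covers) >= 2L) {
    sig <- vapply(covers, function(cv) paste(signif(cv$box, 12), collapse = ","),
                  character(1))
    covers <- covers[!duplicated(sig)]
  }
  covers
}

#' Plan for stochastic re-tightening
#'
#' @param n_perturb number of perturbed data sets (the first is always the
#'   unperturbed one).
#' @param n_perm number of filtration-order permutations per perturbation
#'   (the first is always the deterministic lexicographic order).
#' @param delta perturbation magnitude; \code{NULL} selects 1 percent of the
#'   cover's box diagonal, halved (at most 6 times) until the number of
#'   significant features is stable across perturbations.
#' @param seed integer seed controlling perturbation offsets and permutation
#'   seeds.
#' @export
stochastic_plan <- function(n_perturb = 15L, n_perm = 15L, delta = NULL,
                            seed = 1L) {
  stopifnot(n_perturb >= 1L, n_perm >= 1L, is.null(delta) || delta >= 0)
  structure(list(n_perturb = as.integer(n_perturb), n_perm = as.integer(n_perm),
                 delta = delta, seed = as.integer(seed)),
            class = "stochastic_plan")
}

#' Stochastic re-tightening within a cover
#'
#' Generates perturbed copies of the cover's points (i.i.d. uniform offsets
#' in [-delta, delta] per coordinate) and, for each, several permutations of
#' the relative order of equal-diameter simplices; the deterministic stages
#' are re-run for every permutation of every perturbation and, for each
#' matched significant feature, the shortest representative across all runs
#' is kept. The unperturbed data set and the identity permutation are always
#' included as the first run, so the result never exceeds the deterministic
#' representative's length. Features are matched across runs by (birth,
#' death) within tolerance 1e-9 and then greedily by persistence rank; the
#' perturbation magnitude is halved until the number of significant features
#' agrees across all perturbations.
#'
#' @param cover a \code{tph_cover} (with \code{n_significant} computed or
#'   computable).
#' @param coords the full embedding.
#' @param params \code{ph_params}.
#' @param dim homology dimension.
#' @param plan a \code{stochastic_plan}.
#' @return list with \code{cycles} (one \code{vertex_chain} per significant
#'   feature, global point ids), \code{records} (from the unperturbed run),
#'   \code{lengths}, \code{delta} (magnitude used), and \code{n_runs}.
#' @export
stochastic_tighten <- function(cover, coords, params, dim, plan) {
  stopifnot(inherits(plan, "stochastic_plan"))
  loc <- coords[cover$members + 1L, , drop = FALSE]
  diag_len <- sqrt(sum((cover$box["hi", ] - cover$box["lo", ])^2))
  delta <- if (is.null(plan$delta)) 0.01 * diag_len else plan$delta
  base <- .cover_run(loc, cover$members, params, dim, full_pd = TRUE)
  if (base$n_sig == 0L)
    return(list(cycles = list(), records = base$records, lengths = integer(),
                delta = delta, n_runs = 0L))
  # choose delta: feature count must be stable across all perturbations
  perturbations <- NULL
  if (plan$n_perturb > 1L && delta > 0) {
    for (attempt in 0:6) {
      perturbations <- with_seed(plan$seed + attempt, lapply(
        seq_len(plan$n_perturb - 1L), function(q)
          loc + matrix(runif(length(loc), -delta, delta), nrow(loc), ncol(loc))))
      counts <- vapply(perturbations, function(p)
        .cover_run(p, cover$members, params, dim)$n_sig, integer(1))
      if (all(counts == base$n_sig)) break
      if (attempt == 6)
        stop("significant-feature count unstable across perturbations; ",
             "could not find a workable perturbation magnitude")
      delta <- delta / 2
    }
  } else if (plan$n_perturb > 1L) {
    perturbations <- replicate(plan$n_perturb - 1L, loc, simplify = FALSE)
  }
  datasets <- c(list(loc), perturbations)
  perm_seeds <- with_seed(plan$seed,
    matrix(sample.int(.Machine$integer.max - 1L,
                      length(datasets) * plan$n_perm),
           nrow = length(datasets)))
  best <- base$cycles
  best_len <- vapply(best, function(ch) nrow(ch$verts), integer(1))
  n_runs <- 0L
  for (p in seq_along(datasets)) {
    for (q in seq_len(plan$n_perm)) {
      if (p == 1L && q == 1L) { n_runs <- n_runs + 1L; next }  # identity run = base
      ps <- if (q == 1L) NULL else perm_seeds[p, q]
      run <- .cover_run(datasets[[p]], cover$members, params, dim, perm_seed = ps)
      n_runs <- n_runs + 1L
      if (run$n_sig != base$n_sig) next  # unmatched count; skip this run
      # slot matching: identical (birth, death) within 1e-9 keeps its slot,
      # otherwise slots align by persistence rank (both lists sorted).
      for (k in seq_len(min(length(run$cycles), length(best)))) {
        len <- nrow(run$cycles[[k]]$verts)
        if (len < best_len[k]) { best[[k]] <- run$cycles[[k]]; best_len[k] <- len }
      }
    }
  }
  list(cycles = best, records = base$records, lengths = best_len,
       delta = delta, n_runs = n_runs)
}
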