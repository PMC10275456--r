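#' Tight representatives of significant features in a point cloud
#'
#' Full pipeline on an embedded point cloud: Vietoris-Rips persistence up to
#' tau = tau_u + eps, birth-cycle extraction for nontrivial features born up
#' to tau_u, greedy shortening, connectedness splitting, local smoothing and
#' degenerate filtering; then, in the embedding, covers are built around the
#' surviving cycles, pruned and contracted, and each cover is re-tightened
#' at the maximum possible threshold (optionally under a stochastic plan).
#'
#' @param coords embedding matrix (one point per row, 2 or 3 columns).
#' @param params \code{ph_params}.
#' @param dim homology dimension of interest (1 = loops, 2 = voids).
#' @param plan \code{NULL} for a single deterministic cover run, or a
#'   \code{\link{stochastic_plan}}.
#' @param use_covers set \code{FALSE} to stop after the smoothing stage.
#' @return a \code{tight_ph} object: list with the truncated \code{diagram},
#'   \code{significant} records, stage-III \code{cycles}, the contracted
#'   \code{covers}, and \code{representatives} (one \code{vertex_chain} per
#'   significant feature per cover, global 0-based point ids).
#' @export
tight_representatives <- function(coords, params, dim = 1L, plan = NULL,
                                  use_covers = TRUE) {
  coords <- as.matrix(coords)
  stopifnot(inherits(params, "ph_params"), dim %in% c(1L, 2L))
  dm <- dist_from_embedding(coords, params$tau)
  filt <- build_vr_filtration(dm, params$tau, max_dim = dim + 1L)
  pd <- compute_persistence(filt, params)
  sig <- significant(pd, params)
  sig <- sig[sig$dim == dim, , drop = FALSE]
  tight <- tighten_cycles(pd, dim = dim, params = params)
  covers <- list()
  reps <- list()
  if (use_covers && length(tight$cycles)) {
    covers <- lapply(tight$cycles, local_cover, coords = coords, filt = filt)
    covers <- prune_and_contract(covers, coords, params, dim)
    for (cv in covers) {
      res <- if (is.null(plan)) {
        run <- .cover_run(coords[cv$members + 1L, , drop = FALSE],
                          cv$members, params, dim, full_pd = TRUE)
        list(cycles = run$cycles, records = run$records)
      } else {
        stochastic_tighten(cv, coords, params, dim, plan)
      }
      reps <- c(reps, res$cycles)
    }
  } else if (!use_covers) {
    reps <- lapply(tight$cycles, as_vertex_chain, filt = filt)
  }
  structure(list(diagram = pd, significant = sig, cycles = tight$cycles,
                 covers = covers, representatives = reps, params = params,
                 dim = dim, log = tight$log),
            class = "tight_ph")
}

#' @export
print.tight_ph <- function(x, ...) {
  cat(sprintf("<tight_ph> dim %d: %d significant features, %d tight cycles, %d covers, %d final representatives\n",
              x$dim, nrow(x$significant), length(x$cycles), length(x$covers),
              length(x$representatives)))
  invisible(x)
}
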