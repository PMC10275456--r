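#' Bin map for Hi-C matrices
#'
#' Chromosomes are partitioned into fixed-length segments of \code{resolution}
#' base pairs (bins); bins are indexed 0-based, concatenated in the order the
#' chromosomes are given.
#'
#' @param n_bins named integer vector: number of bins per chromosome.
#' @param resolution bin size in base pairs.
#' @return data frame with columns \code{bin}, \code{chrom}, \code{start};
#'   attribute \code{resolution}.
#' @export
make_bin_map <- function(n_bins, resolution) {
  stopifnot(!is.null(names(n_bins)), all(n_bins > 0))
  chrom <- rep(names(n_bins), n_bins)
  start <- unlist(lapply(n_bins, function(k) (seq_len(k) - 1L) * resolution),
                  use.names = FALSE)
  structure(data.frame(bin = seq_len(sum(n_bins)) - 1L, chrom = chrom,
                       start = start, stringsAsFactors = FALSE),
            resolution = resolution)
}

#' Read a bin-table sidecar (chrom, start, end per bin)
#'
#' Bins must be listed in index order; the resolution is taken from the first
#' row.
#'
#' @param path TSV file with columns chrom, start, end (header optional).
#' @return a bin map as from \code{\link{make_bin_map}}.
#' @export
read_bin_table <- function(path) {
  first <- strsplit(readLines(path, n = 1L), "\t")[[1L]]
  hdr <- suppressWarnings(is.na(as.numeric(first[2L])))
  df <- read.table(path, sep = "\t", header = hdr,
                   col.names = c("chrom", "start", "end"))
  structure(data.frame(bin = seq_len(nrow(df)) - 1L, chrom = df$chrom,
                       start = df$start, stringsAsFactors = FALSE),
            resolution = df$end[1L] - df$start[1L])
}

#' Write a bin-table sidecar
#' @param bin_map a bin map.
#' @param path output TSV.
#' @export
write_bin_table <- function(bin_map, path) {
  res <- attr(bin_map, "resolution")
  write.table(data.frame(chrom = bin_map$chrom, start = bin_map$start,
                         end = bin_map$start + res),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Estimate pairwise spatial distances from balanced Hi-C counts
#'
#' The distance estimate is the multiplicative inverse of the non-zero
#' balanced contact frequency, d_ij = 1 / m_ij. Zero and NaN counts give an
#' infinite distance: the corresponding edge is never added to the simplicial
#' complex, regardless of the threshold.
#'
#' @param counts square balanced contact matrix, or a COO data frame with
#'   columns \code{i}, \code{j}, \code{value} (0-based bins).
#' @param n_bins number of bins (required for COO input when it cannot be
#'   inferred).
#' @param tau truncation threshold for the resulting model (default keeps
#'   all finite estimates).
#' @return a \code{sparse_dist} model.
#' @export
distances_from_counts <- function(counts, n_bins = NULL, tau = Inf) {
  if (is.data.frame(counts)) {
    if (any(counts$value < 0, na.rm = TRUE)) stop("contact counts must be non-negative")
    pos <- !is.na(counts$value) & counts$value > 0
    df <- data.frame(i = counts$i[pos], j = counts$j[pos],
                     value = 1 / counts$value[pos])
    dist_from_coo(df, n_bins, tau)
  } else {
    m <- as.matrix(counts)
    if (nrow(m) != ncol(m)) stop("contact matrix must be square")
    if (any(m < 0, na.rm = TRUE)) stop("contact counts must be non-negative")
    d <- 1 / m
    d[!is.finite(d)] <- NA  # zero or NaN counts: edge absent
    diag(d) <- 0
    dist_from_matrix(d, tau)
  }
}

#' Truncate a distance model at a smaller threshold
#' @param dm a \code{sparse_dist}.
#' @param tau new threshold (must not exceed the current one).
#' @export
truncate_distances <- function(dm, tau) {
  stopifnot(tau <= dm$tau)
  keep <- dm$d <= tau
  new_sparse_dist(dm$n_points, dm$i[keep], dm$j[keep], dm$d[keep], tau, dm$source)
}

# gap in bins for each stored pair; NA for trans pairs when a bin map is given
.pair_gaps <- function(dm, bin_map = NULL) {
  gap <- dm$j - dm$i
  if (!is.null(bin_map)) {
    cis <- bin_map$chrom[dm$i + 1L] == bin_map$chrom[dm$j + 1L]
    gap[!cis] <- NA_integer_
  }
  gap
}

#' Standardize and rescale distance estimates across protocols
#'
#' The mean and standard deviation (population convention) of the estimates
#' at bin-distance 1 are computed with the top \code{trim} fraction excluded
#' as experimental outliers; all estimates are standardized by
#' \eqn{(x - \mu)/\sigma}, made positive by adding \eqn{|min|}, and then
#' shifted and power-scaled as \eqn{\hat x = \tilde x_+^p + c}. The exponent
#' and shift align the 5- and 95-percentiles across experiments; presets for
#' the five protocol experiments are available via
#' \code{\link{hic_protocol_scaling}}.
#'
#' @param dm an untruncated \code{sparse_dist} of estimates.
#' @param bin_map optional bin map (restricts bin-distance-1 pairs to cis).
#' @param p power applied to the positivized standardized estimates.
#' @param c shift added after the power.
#' @param trim fraction of the largest bin-distance-1 estimates ignored when
#'   computing the mean and standard deviation (default the top 0.1 percent).
#' @return the model with rescaled distances.
#' @export
scale_estimates <- function(dm, bin_map = NULL, p = 1, c = 0, trim = 0.001) {
  gap <- .pair_gaps(dm, bin_map)
  x1 <- dm$d[!is.na(gap) & gap == 1L]
  if (length(x1) == 0L) stop("no bin-distance-1 estimates present")
  x1 <- x1[x1 <= quantile(x1, 1 - trim)]
  mu <- mean(x1)
  sigma <- sqrt(mean((x1 - mu)^2))
  if (sigma == 0) stop("degenerate bin-distance-1 distribution (sigma = 0)")
  xt <- (dm$d - mu) / sigma
  xt <- xt + abs(min(xt))
  out <- dm
  out$d <- xt^p + c
  out
}

#' Scaling presets for the five cross-protocol Hi-C experiments
#'
#' Exponents 1.18, 1.05, 0.98, 1.05 and 0.84 (shift 0) for experiments 1-5:
#' FA+DpnII, FA+DSG+DdeI, FA+DSG+DpnII+DdeI, FA+DSG+DpnII, FA+DSG+MNase.
#'
#' @param experiment experiment index, 1 to 5.
#' @return list with elements \code{p} and \code{c}.
#' @export
hic_protocol_scaling <- function(experiment) {
  p <- c(1.18, 1.05, 0.98, 1.05, 0.84)
  stopifnot(experiment %in% seq_along(p))
  list(p = p[experiment], c = 0)
}

#' Percentiles of spatial-estimate distributions by bin distance
#'
#' D_k is the distribution of estimates over pairs at bin-distance k; its
#' percentiles (default the 95th) provide the birth- and PH-thresholds for
#' loop computation.
#'
#' @param dm a \code{sparse_dist} of estimates.
#' @param bin_map optional bin map restricting pairs to cis.
#' @param k bin distances wanted.
#' @param prob percentile.
#' @return named numeric vector \code{p_k}.
#' @export
bin_distance_percentiles <- function(dm, bin_map = NULL, k = 1:5, prob = 0.95) {
  gap <- .pair_gaps(dm, bin_map)
  out <- vapply(k, function(kk) {
    x <- dm$d[!is.na(gap) & gap == kk]
    if (length(x) == 0L) NA_real_ else unname(quantile(x, prob))
  }, numeric(1))
  names(out) <- k
  out
}

# ---- loops ----

#' Construct a genomic H1 loop
#'
#' A loop is an ordered set of bins [b_0, ..., b_n] where consecutive bins
#' (and the closing pair (b_n, b_0)) are edges of the cycle.
#'
#' @param bins ordered 0-based bin indices.
#' @param edges optional explicit edge matrix (two columns of bins); default
#'   consecutive pairs plus the closing edge.
#' @param est_birth,est_death estimated birth and death scales.
#' @export
genomic_loop <- function(bins, edges = NULL, est_birth = NA_real_,
                         est_death = NA_real_) {
  bins <- as.integer(bins)
  if (is.null(edges) && length(bins) >= 2L)
    edges <- cbind(bins, c(bins[-1L], bins[1L]))
  structure(list(bins = bins, edges = edges, est_birth = est_birth,
                 est_death = est_death),
            class = "genomic_loop")
}

#' @export
print.genomic_loop <- function(x, ...) {
  cat(sprintf("<genomic_loop> %d bins [%s]%s\n", length(x$bins),
              paste(head(x$bins, 8L), collapse = ","),
              if (length(x$bins) > 8L) ",..." else ""))
  invisible(x)
}

#' Convert a tightened H1 chain into a genomic loop
#'
#' If every bin of the cycle has exactly two incident edges the bins are
#' reported in traversal order; otherwise the edge set is kept and bins are
#' listed sorted.
#'
#' @param chain a 1-dimensional \code{tph_chain}.
#' @param filt its filtration (vertex ids are bin indices).
#' @export
loop_from_chain <- function(chain, filt) {
  stopifnot(chain$dim == 1L)
  ev <- chain_vertices(chain, filt)
  bins <- sort(unique(as.vector(ev)))
  deg <- table(factor(as.vector(ev), levels = bins))
  ordered <- all(deg == 2L)
  if (ordered) {
    adj <- split(c(ev[, 2L], ev[, 1L]), c(ev[, 1L], ev[, 2L]))
    walk <- integer(nrow(ev))
    walk[1L] <- bins[1L]
    prev <- -1L
    for (q in seq_len(nrow(ev))[-1L]) {
      nb <- adj[[as.character(walk[q - 1L])]]
      nxt <- nb[nb != prev][1L]
      prev <- walk[q - 1L]
      walk[q] <- nxt
    }
    ordered <- length(unique(walk)) == length(bins)
    if (ordered) bins <- walk
  }
  genomic_loop(bins, edges = ev)
}

#' Estimate the persistence a loop can wrap around
#'
#' After greedy shortening the persistence of the underlying feature is no
#' longer tracked; the theoretical maximum is estimated with birth = the
#' longest edge in the boundary and death = the maximum over all pairwise
#' distances between the loop's bins. A missing pairwise estimate gives an
#' infinite death. Loops with estimated persistence below \code{eps} are
#' flagged for removal.
#'
#' @param loop a \code{genomic_loop}.
#' @param dm the (untruncated) distance model.
#' @param eps persistence threshold; \code{NULL} skips the flag.
#' @return the loop with \code{est_birth}, \code{est_death} filled and
#'   attribute \code{keep} when \code{eps} is given.
#' @export
estimate_loop_persistence <- function(loop, dm, eps = NULL) {
  lk <- dist_lookup(dm)
  loop$est_birth <- max(lk(loop$edges[, 1L], loop$edges[, 2L]))
  pr <- utils::combn(loop$bins, 2L)
  loop$est_death <- max(lk(pr[1L, ], pr[2L, ]))
  if (!is.null(eps))
    attr(loop, "keep") <- (loop$est_death - loop$est_birth) >= eps
  loop
}

#' Classify a loop as cis- or trans-chromosomal
#'
#' @param loop a \code{genomic_loop} (or vector of bins).
#' @param bin_map a bin map.
#' @return \code{"cis"} when all bins are on one chromosome, else
#'   \code{"trans"}.
#' @export
classify_cis_trans <- function(loop, bin_map) {
  bins <- if (inherits(loop, "genomic_loop")) loop$bins else as.integer(loop)
  ch <- unique(bin_map$chrom[bins + 1L])
  if (length(ch) == 1L) "cis" else "trans"
}

.loop_bins <- function(x) {
  if (inherits(x, "genomic_loop")) x$bins else as.integer(x)
}

#' Distance between two loops
#'
#' d(A, B) = max over a in A of min over b in B of |a - b|, symmetrized by
#' taking the larger of d(A, B) and d(B, A); units are bins.
#'
#' @param a,b loops (or bin vectors).
#' @export
loop_distance <- function(a, b) {
  ba <- .loop_bins(a); bb <- .loop_bins(b)
  d1 <- max(vapply(ba, function(x) min(abs(x - bb)), numeric(1)))
  d2 <- max(vapply(bb, function(x) min(abs(x - ba)), numeric(1)))
  max(d1, d2)
}

#' Distance between a loop and a peak (bin pair)
#'
#' d(L, H) = max of the distances from each peak anchor to the nearest bin
#' of the loop.
#'
#' @param loop a loop (or bin vector).
#' @param peak numeric vector (b1, b2).
#' @export
peak_distance <- function(loop, peak) {
  bins <- .loop_bins(loop)
  max(min(abs(bins - peak[1L])), min(abs(bins - peak[2L])))
}

#' Does a loop match a peak?
#'
#' A loop and a peak are matched when their distance is at most
#' \code{threshold} bins (default 2, the 20 kb clustering radius at 10 kb
#' resolution).
#'
#' @inheritParams peak_distance
#' @param threshold matching radius in bins.
#' @export
match_peak <- function(loop, peak, threshold = 2) {
  peak_distance(loop, peak) <= threshold
}

#' Matching report between loops and peaks
#'
#' @param loops list of loops.
#' @param peaks data frame or matrix with two columns of anchor bins.
#' @param threshold matching radius in bins.
#' @return data frame: loop, peak, distance, matched.
#' @export
match_peaks <- function(loops, peaks, threshold = 2) {
  peaks <- as.matrix(peaks)
  out <- expand.grid(loop = seq_along(loops), peak = seq_len(nrow(peaks)))
  out$distance <- mapply(function(l, p) peak_distance(loops[[l]], peaks[p, 1:2]),
                         out$loop, out$peak)
  out$matched <- out$distance <= threshold
  out
}

.interaction_gaps <- function(x) {
  if (inherits(x, "genomic_loop")) {
    if (!is.null(x$edges)) abs(x$edges[, 1L] - x$edges[, 2L])
    else { b <- x$bins; abs(b - c(b[-1L], b[1L])) }
  } else abs(x[1L] - x[2L])  # a peak
}

#' Maximum range of interaction
#'
#' For a loop, the largest bin gap between contiguous bins (including the
#' closing edge); for a peak, the gap between its anchors. Reported in base
#' pairs.
#'
#' @param x a \code{genomic_loop} or a peak (b1, b2).
#' @param resolution bin size in base pairs.
#' @export
max_interaction_range <- function(x, resolution) {
  max(.interaction_gaps(x)) * resolution
}

#' Classify the range of interaction
#'
#' Short-range: below 100 kb; mid-range: at least 100 kb but below 1 Mb;
#' long-range: at least 1 Mb.
#'
#' @inheritParams max_interaction_range
#' @export
interaction_range_class <- function(x, resolution) {
  r <- max_interaction_range(x, resolution)
  if (r < 1e5) "short" else if (r < 1e6) "mid" else "long"
}

#' Single versus multiple mid-range interactions
#'
#' A loop's mid-range interactions are its bin gaps of at least 100 kb and
#' below 1 Mb. Bins are mid-range when they lie in at least one mid-range
#' loop and in no long-range loop; mid-range bins are multiple mid-range when
#' they lie in at least one loop with more than one mid-range interaction,
#' and single mid-range otherwise.
#'
#' @param loops list of \code{genomic_loop}s.
#' @param resolution bin size in base pairs.
#' @return list with \code{loops} (data frame: loop, range_class,
#'   n_mid_interactions, multiplicity) and \code{bins} (data frame: bin,
#'   class in single/multiple).
#' @export
mid_range_multiplicity <- function(loops, resolution) {
  info <- lapply(loops, function(l) {
    g <- .interaction_gaps(l) * resolution
    list(class = interaction_range_class(l, resolution),
         n_mid = sum(g >= 1e5 & g < 1e6))
  })
  ldf <- data.frame(loop = seq_along(loops),
                    range_class = vapply(info, `[[`, character(1), "class"),
                    n_mid_interactions = vapply(info, `[[`, numeric(1), "n_mid"))
  ldf$multiplicity <- ifelse(ldf$n_mid_interactions >= 2, "multiple",
                             ifelse(ldf$n_mid_interactions == 1, "single", "none"))
  mid_bins <- unique(unlist(lapply(which(ldf$range_class == "mid"),
                                   function(q) loops[[q]]$bins)))
  long_bins <- unique(unlist(lapply(which(ldf$range_class == "long"),
                                    function(q) loops[[q]]$bins)))
  mid_bins <- setdiff(mid_bins, long_bins)
  multi_bins <- unique(unlist(lapply(which(ldf$multiplicity == "multiple"),
                                     function(q) loops[[q]]$bins)))
  bdf <- data.frame(bin = sort(mid_bins))
  bdf$class <- ifelse(bdf$bin %in% multi_bins, "multiple", "single")
  list(loops = ldf, bins = bdf)
}

#' Consensus loops across experiments
#'
#' Builds the graph whose nodes are (experiment, loop) with an edge between
#' loops of different experiments at loop-distance at most
#' \code{dist_threshold}, enumerates all maximal cliques with one loop from
#' every experiment, and picks a deterministic representative per clique
#' (lowest experiment index, then first loop).
#'
#' @param per_experiment_loops list (one entry per experiment) of lists of
#'   loops.
#' @param dist_threshold matching radius in bins.
#' @param clique_size required clique size; defaults to the number of
#'   experiments.
#' @return list of representative loops; attribute \code{n_cliques}.
#' @export
consensus_loops <- function(per_experiment_loops, dist_threshold = 2,
                            clique_size = length(per_experiment_loops)) {
  ne <- length(per_experiment_loops)
  if (ne < 2L) stop("at least two experiments are required")
  tags <- do.call(rbind, lapply(seq_len(ne), function(e) {
    k <- length(per_experiment_loops[[e]])
    if (k == 0L) return(NULL)
    data.frame(exp = e, loop = seq_len(k))
  }))
  if (is.null(tags) || nrow(tags) == 0L)
    return(structure(list(), n_cliques = 0L))
  nodes <- nrow(tags)
  getl <- function(q) per_experiment_loops[[tags$exp[q]]][[tags$loop[q]]]
  ed <- NULL
  for (a in seq_len(nodes - 1L)) for (b in seq(a + 1L, nodes)) {
    if (tags$exp[a] == tags$exp[b]) next
    if (loop_distance(getl(a), getl(b)) <= dist_threshold)
      ed <- rbind(ed, c(a, b))
  }
  if (is.null(ed)) return(structure(list(), n_cliques = 0L))
  g <- igraph::graph_from_edgelist(ed, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nodes - igraph::vcount(g)))
  cl <- igraph::max_cliques(g, min = clique_size)
  cl <- Filter(function(x) length(x) >= clique_size, cl)
  reps <- lapply(cl, function(x) {
    q <- as.integer(x)
    q <- q[order(tags$exp[q], tags$loop[q])][1L]
    getl(q)
  })
  # deduplicate representatives shared by several cliques
  key <- vapply(reps, function(l) paste(.loop_bins(l), collapse = ","), character(1))
  structure(reps[!duplicated(key)], n_cliques = length(cl))
}

#' Compute tight H1 chromatin loops from a balanced Hi-C matrix
#'
#' End-to-end Hi-C layer: distance estimation (inverse counts), Vietoris-Rips
#' persistence up to tau = tau_u + eps, birth-cycle extraction for features
#' born up to tau_u, greedy shortening, connectedness splitting, local
#' smoothing, degenerate filtering, persistence re-estimation against the
#' untruncated estimates, and classification (cis/trans, interaction range).
#' Covers are not used here: a contact matrix provides no spatial embedding.
#'
#' @param counts balanced contact matrix or COO data frame (see
#'   \code{\link{distances_from_counts}}).
#' @param bin_map a bin map from \code{\link{make_bin_map}}.
#' @param params \code{ph_params} in estimate units.
#' @param scale optional list(p, c) applied via \code{\link{scale_estimates}}.
#' @param cis_only drop trans edges before the filtration.
#' @return a \code{hic_loops} object: list with \code{loops} (each a
#'   \code{genomic_loop} with estimates, chromosome class and range class),
#'   \code{diagram}, \code{records} and a \code{log} of stage counts.
#' @export
hic_loops <- function(counts, bin_map, params, scale = NULL, cis_only = FALSE) {
  resolution <- attr(bin_map, "resolution")
  dm_full <- distances_from_counts(counts, n_bins = nrow(bin_map))
  if (!is.null(scale))
    dm_full <- scale_estimates(dm_full, bin_map, p = scale$p, c = scale$c)
  if (cis_only) {
    cis <- bin_map$chrom[dm_full$i + 1L] == bin_map$chrom[dm_full$j + 1L]
    dm_full <- new_sparse_dist(dm_full$n_points, dm_full$i[cis], dm_full$j[cis],
                               dm_full$d[cis], dm_full$tau, dm_full$source)
  }
  dm <- truncate_distances(dm_full, params$tau)
  filt <- build_vr_filtration(dm, params$tau, max_dim = 2L)
  pd <- compute_persistence(filt, params)
  tight <- tighten_cycles(pd, dim = 1L, params = params)
  loops <- lapply(tight$cycles, loop_from_chain, filt = filt)
  loops <- lapply(loops, estimate_loop_persistence, dm = dm_full,
                  eps = params$eps)
  keep <- vapply(loops, function(l) isTRUE(attr(l, "keep")), logical(1))
  n_est_dropped <- sum(!keep)
  loops <- loops[keep]
  for (q in seq_along(loops)) {
    attr(loops[[q]], "chrom_class") <- classify_cis_trans(loops[[q]], bin_map)
    attr(loops[[q]], "range_class") <-
      interaction_range_class(loops[[q]], resolution)
  }
  structure(list(loops = loops, diagram = pd, records = tight$records,
                 bin_map = bin_map,
                 log = c(tight$log, list(n_est_dropped = n_est_dropped))),
            class = "hic_loops")
}

#' @export
print.hic_loops <- function(x, ...) {
  cc <- vapply(x$loops, function(l) attr(l, "chrom_class"), character(1))
  cat(sprintf("<hic_loops> %d loops (%d cis, %d trans); %d birth-cycles, %d degenerate, %d below estimated persistence\n",
              length(x$loops), sum(cc == "cis"), sum(cc == "trans"),
              x$log$n_birth, x$log$n_degenerate, x$log$n_est_dropped))
  invisible(x)
}
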