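# Greedy shortening, connectedness splitting, smoothing, degenerate filtering.

test_that("hexagon with a chord: greedy replaces the outer cycle", {
  hx <- fixture_hexagon_chord()
  out <- greedy_shorten(list(hx$left, hx$outer))
  expect_equal(vapply(out, chain_length, integer(1)), c(4L, 4L))
  expect_identical(out[[1L]]$idx, hx$left$idx)
  expect_identical(out[[2L]]$idx, hx$right$idx)  # outer xor left = right 4-cycle
})

test_that("a single cycle and an empty set pass through greedy unchanged", {
  hx <- fixture_hexagon_chord()
  out <- greedy_shorten(list(hx$outer))
  expect_identical(out[[1L]]$idx, hx$outer$idx)
  expect_length(greedy_shorten(list()), 0L)
})

test_that("optimized greedy equals the naive all-pairs greedy on birth cycles", {
  x <- unclass(fixture_two_circles(n = 60L, noise = 0.08, seed = 4L))
  p <- attr(fixture_two_circles(), "ground_truth")$params
  filt <- build_vr_filtration(build_distance_model(x, p$tau), p$tau, max_dim = 2)
  pd <- compute_persistence(filt, p)
  rec <- pd$records[pd$records$dim == 1L & pd$records$birth <= p$tau_u, ]
  bc <- birth_cycles(pd, rec$id)
  expect_gt(length(bc), 3L)
  opt <- greedy_shorten(bc, optimized = TRUE)
  naive <- greedy_shorten(bc, optimized = FALSE)
  expect_identical(lapply(opt, `[[`, "idx"), lapply(naive, `[[`, "idx"))
  # monotone: every cycle no longer than its birth cycle; total strictly less
  l0 <- vapply(bc, chain_length, integer(1))
  l1 <- vapply(opt, chain_length, integer(1))
  expect_true(all(l1 <= l0))
  # fixed point: no pair can shorten any cycle further
  for (i in seq_along(opt)) for (j in seq_along(opt)) {
    if (i == j) next
    expect_gte(chain_length(chain_xor(opt[[i]], opt[[j]])),
               chain_length(opt[[i]]))
  }
})

test_that("greedy and smoothing preserve the span modulo boundaries", {
  x <- random_cloud(20L, 2L, 2L)
  tau <- unname(quantile(dist(x), 0.8))
  filt <- build_vr_filtration(build_distance_model(x, tau), tau, max_dim = 2)
  pd <- compute_persistence(filt)
  rec <- pd$records[pd$records$dim == 1L, ]
  expect_gt(nrow(rec), 0L)
  bc <- birth_cycles(pd, rec$id)
  sh <- greedy_shorten(bc)
  sm <- smooth_cycles(sh, filt)
  B <- boundary_matrix_of(filt, 2L)  # triangle boundaries as edge vectors
  base_rank <- gf2_rank(B)
  V0 <- do.call(cbind, lapply(bc, chain_vector_of, filt = filt))
  V2 <- do.call(cbind, lapply(sm, chain_vector_of, filt = filt))
  expect_equal(gf2_rank(cbind(B, V0)) - base_rank,
               gf2_rank(cbind(B, V2)) - base_rank)
  expect_equal(gf2_rank(cbind(B, V0, V2)), gf2_rank(cbind(B, V0)))
  # each smoothing difference is a sum of triangle boundaries
  for (q in seq_along(sh)) {
    diff <- chain_xor(sh[[q]], sm[[q]])
    expect_true(gf2_in_span(B, chain_vector_of(diff, filt)))
  }
})

test_that("disconnected cycles split into their face-connected components", {
  # two vertex-disjoint triangles, far apart
  x <- rbind(c(0, 0), c(1, 0), c(0.5, 0.9),
             c(10, 0), c(11, 0), c(10.5, 0.9))
  tau <- 1.2
  filt <- build_vr_filtration(build_distance_model(x, tau), tau, max_dim = 2)
  e <- function(a, b) simplex_index(filt, c(a, b, -1L, -1L))
  both <- new_chain(c(e(0, 1), e(1, 2), e(0, 2), e(3, 4), e(4, 5), e(3, 5)), 1L)
  parts <- split_disconnected(both, filt)
  expect_length(parts, 2L)
  expect_setequal(vapply(parts, chain_length, integer(1)), c(3L, 3L))
  single <- new_chain(c(e(0, 1), e(1, 2), e(0, 2)), 1L)
  expect_length(split_disconnected(single, filt), 1L)
})

test_that("xor of two planted disjoint loops is split back into both", {
  x <- unclass(fixture_two_circles(n = 40L, seed = 9L))
  gt <- attr(fixture_two_circles(n = 40L, seed = 9L), "ground_truth")
  filt <- build_vr_filtration(build_distance_model(x, gt$params$tau),
                              gt$params$tau, max_dim = 2)
  pd <- compute_persistence(filt, gt$params)
  tight <- tighten_cycles(pd, 1L, gt$params)
  expect_equal(length(tight$cycles), 2L)
  merged <- chain_xor(tight$cycles[[1L]], tight$cycles[[2L]])
  parts <- split_disconnected(merged, filt)
  expect_length(parts, 2L)
  key <- function(ch) paste(ch$idx, collapse = ",")
  expect_setequal(vapply(parts, key, character(1)),
                  vapply(tight$cycles, key, character(1)))
})

test_that("smoothing shortens with triangle boundaries and reaches a fixed point", {
  # pentagon with one short-cut chord (0,2): only triangle 012 is in the
  # complex, so smoothing decimates vertex 1 and then stops
  x <- rbind(c(0, 0), c(1, 0.3), c(2, 0), c(2, -2), c(0, -2))
  tau <- 2.1
  filt <- build_vr_filtration(build_distance_model(x, tau), tau, max_dim = 2)
  expect_equal(sum(filt$dim == 2L), 1L)
  e <- function(a, b) simplex_index(filt, c(a, b, -1L, -1L))
  cyc <- new_chain(c(e(0, 1), e(1, 2), e(2, 3), e(3, 4), e(0, 4)), 1L)
  sm <- smooth_cycles(cyc, filt)
  expect_equal(chain_length(sm), 4L)  # v1 decimated via triangle 0,1,2
  expect_setequal(sm$idx, c(e(0, 2), e(2, 3), e(3, 4), e(0, 4)))
  expect_true(is_cycle(sm, filt))
  sm2 <- smooth_cycles(sm, filt)
  expect_identical(sm2$idx, sm$idx)   # already locally minimal
})

test_that("degenerate cycles of length <= 2 are dropped and counted", {
  cs <- list(new_chain(1:2, 1L), new_chain(1:5, 1L))
  out <- drop_degenerate(cs)
  expect_length(out, 1L)
  expect_equal(attr(out, "n_dropped"), 1L)
  allgone <- drop_degenerate(list(new_chain(1:2, 1L), new_chain(3:4, 1L)))
  expect_length(allgone, 0L)
  expect_equal(attr(allgone, "n_dropped"), 2L)
})

test_that("noisy circle: tightening shrinks the representative monotonically", {
  x <- fixture_noisy_circle()
  gt <- attr(x, "ground_truth")
  filt <- build_vr_filtration(build_distance_model(unclass(x), gt$params$tau),
                              gt$params$tau, max_dim = 2)
  pd <- compute_persistence(filt, gt$params)
  tight <- tighten_cycles(pd, 1L, gt$params)
  expect_equal(length(tight$cycles), 1L)
  lg <- tight$log
  expect_true(all(lg$shortened_lengths <= lg$birth_lengths))
  expect_lt(chain_length(tight$cycles[[1L]]), max(lg$birth_lengths))
  # the loop stays inside the generating annulus
  v <- unique(as.vector(chain_vertices(tight$cycles[[1L]], filt)))
  rad <- sqrt(rowSums(unclass(x)[v + 1L, ]^2))
  expect_true(all(rad >= gt$annulus[1L] & rad <= gt$annulus[2L]))
})
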