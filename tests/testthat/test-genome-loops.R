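# Hi-C layer: distance estimation, scaling, loop operations, consensus.

test_that("inverse-count distances drop zero and NaN counts", {
  m <- matrix(c(0, 2, 0, 2, 0, NaN, 0, NaN, 0), 3, 3)
  dm <- distances_from_counts(m)
  expect_equal(n_pairs(dm), 1L)
  expect_equal(dm$d, 0.5)           # m = 2 -> d = 1/2
  expect_error(distances_from_counts(matrix(c(0, -1, -1, 0), 2, 2)),
               "non-negative")
  coo <- data.frame(i = c(0L, 0L, 1L), j = c(1L, 2L, 2L), value = c(4, 0, NA))
  dm2 <- distances_from_counts(coo, n_bins = 3L)
  expect_equal(dm2$d, 0.25)
})

test_that("scaling standardizes on bin-distance-1 estimates (population sd)", {
  # direct-formula oracle: x = [1,2,3] at gap 1 plus one gap-2 estimate
  coo <- data.frame(i = c(0L, 1L, 2L, 0L), j = c(1L, 2L, 3L, 2L),
                    value = c(1, 2, 3, 5))
  dm <- build_distance_model(coo, Inf, type = "coo", n_points = 4L)
  out <- scale_estimates(dm, p = 1, c = 0, trim = 0)
  x1 <- c(1, 2, 3)
  mu <- mean(x1); sigma <- sqrt(mean((x1 - mu)^2))
  xt <- (dm$d - mu) / sigma
  expect_equal(out$d, xt + abs(min(xt)))
  # power and shift applied after positivization
  out2 <- scale_estimates(dm, p = 2, c = 1, trim = 0)
  expect_equal(out2$d, (xt + abs(min(xt)))^2 + 1)
  # degenerate sigma rejected
  same <- build_distance_model(data.frame(i = 0:1, j = 1:2, value = c(2, 2)),
                               Inf, type = "coo", n_points = 3L)
  expect_error(scale_estimates(same, trim = 0), "sigma")
  # protocol presets
  expect_equal(hic_protocol_scaling(1)$p, 1.18)
  expect_equal(hic_protocol_scaling(5)$p, 0.84)
  expect_equal(hic_protocol_scaling(3)$c, 0)
})

test_that("loop persistence estimates follow the max-edge / max-pair rule", {
  sq <- unclass(fixture_square4())
  dm <- build_distance_model(sq, Inf)
  loop <- genomic_loop(c(0L, 1L, 2L, 3L))
  est <- estimate_loop_persistence(loop, dm, eps = 0.2)
  expect_equal(est$est_birth, 1)
  expect_equal(est$est_death, sqrt(2))
  expect_true(attr(est, "keep"))
  # equilateral triangle: persistence 0, filtered for any eps > 0
  tri <- matrix(c(0, 0, 1, 0, 0.5, sqrt(3) / 2), 3, 2, byrow = TRUE)
  dmt <- build_distance_model(tri, Inf)
  lt <- estimate_loop_persistence(genomic_loop(0:2), dmt, eps = 1e-6)
  expect_equal(lt$est_birth, lt$est_death)
  expect_false(attr(lt, "keep"))
  # missing pairwise distance means infinite death
  part <- build_distance_model(data.frame(i = c(0L, 1L, 0L), j = c(1L, 2L, 2L),
                                          value = c(1, 1, 1)),
                               Inf, type = "coo", n_points = 4L)
  l4 <- genomic_loop(c(0L, 1L, 2L, 3L),
                     edges = rbind(c(0L, 1L), c(1L, 2L)))
  e4 <- estimate_loop_persistence(l4, part)
  expect_equal(e4$est_death, Inf)
})

test_that("cis/trans classification uses the bin map", {
  bm <- make_bin_map(c(chr1 = 10L, chr2 = 10L), 1e4)
  expect_equal(classify_cis_trans(c(0L, 3L, 7L), bm), "cis")
  expect_equal(classify_cis_trans(c(0L, 3L, 12L), bm), "trans")
  # chromosome-pair incidence over a toy loop set equals a hand count
  loops <- list(genomic_loop(c(0L, 12L, 3L)), genomic_loop(c(11L, 15L)),
                genomic_loop(c(1L, 2L, 14L)))
  cls <- vapply(loops, classify_cis_trans, character(1), bin_map = bm)
  expect_equal(unname(cls), c("trans", "cis", "trans"))
})

test_that("loop distance is symmetric and equals the brute-force definition", {
  expect_equal(loop_distance(c(1, 2, 3), c(2, 3, 4)), 1)
  expect_equal(loop_distance(c(5, 9), c(5, 9)), 0)
  brute <- function(a, b) {
    d1 <- max(sapply(a, function(x) min(abs(x - b))))
    d2 <- max(sapply(b, function(x) min(abs(x - a))))
    max(d1, d2)
  }
  for (s in 1:20) {
    ab <- tightph:::with_seed(s, list(sample(100L, sample(2:8, 1)),
                                      sample(100L, sample(2:8, 1))))
    expect_equal(loop_distance(ab[[1]], ab[[2]]), brute(ab[[1]], ab[[2]]))
    expect_equal(loop_distance(ab[[1]], ab[[2]]),
                 loop_distance(ab[[2]], ab[[1]]))
  }
})

test_that("peak matching uses the <= 2 bin rule including the boundary", {
  expect_true(match_peak(c(10, 11, 50), c(11, 49)))    # d = 1
  expect_false(match_peak(c(10, 11, 50), c(11, 60)))   # d = 10
  expect_equal(peak_distance(c(10, 11, 50), c(11, 60)), 10)
  expect_true(match_peak(c(10, 50), c(12, 50)))        # d = 2 exactly
  rep <- match_peaks(list(genomic_loop(c(10L, 11L, 50L))),
                     rbind(c(11, 49), c(11, 60)))
  expect_equal(rep$matched, c(TRUE, FALSE))
  expect_equal(rep$distance, c(1, 10))
})

test_that("interaction range classes use closed 100 kb and 1 Mb bounds", {
  res <- 1e4
  short <- genomic_loop(c(0L, 2L, 5L))           # max gap 5 bins = 50 kb
  expect_equal(interaction_range_class(short, res), "short")
  expect_equal(interaction_range_class(c(100, 250), res), "long")  # 1.5 Mb
  exact <- genomic_loop(c(0L, 10L))              # 100 kb exactly -> mid
  expect_equal(interaction_range_class(exact, res), "mid")
  expect_equal(interaction_range_class(c(0, 100), res), "long")    # 1 Mb
})

test_that("mid-range multiplicity classifies loops and bins as quoted", {
  res <- 1e4
  multi <- genomic_loop(c(0L, 15L, 30L))   # gaps 15,15,30 bins: three mid
  single <- genomic_loop(c(40L, 52L, 48L, 44L))  # gaps 12,4,4,4: one mid
  longl <- genomic_loop(c(60L, 175L, 176L))  # gap 115 bins = 1.15 Mb: long
  out <- mid_range_multiplicity(list(multi, single, longl), res)
  expect_equal(out$loops$multiplicity[1:2], c("multiple", "single"))
  expect_equal(out$loops$range_class, c("mid", "mid", "long"))
  expect_true(all(c(0, 15, 30) %in% out$bins$bin))
  expect_equal(out$bins$class[out$bins$bin %in% c(0, 15, 30)],
               rep("multiple", 3))
  expect_equal(out$bins$class[out$bins$bin %in% c(40, 52, 48, 44)],
               rep("single", 4))
  # a bin in both a mid- and a long-range loop is excluded
  both <- mid_range_multiplicity(list(single, genomic_loop(c(40L, 160L))), res)
  expect_false(40 %in% both$bins$bin)
})

test_that("consensus loops are maximal 5-cliques with planted recovery", {
  mkexp <- function(shift) list(genomic_loop(c(10L, 11L, 12L) + shift),
                                genomic_loop(c(70L, 75L, 80L) + shift))
  exps <- lapply(c(0L, 1L, -1L, 1L, 0L), mkexp)
  exps[[1L]] <- c(exps[[1L]], list(genomic_loop(c(50L))))  # exp1-only loop
  cons <- consensus_loops(exps)
  expect_equal(attr(cons, "n_cliques"), 2L)
  expect_length(cons, 2L)
  starts <- sort(vapply(cons, function(l) l$bins[1L], integer(1)))
  expect_equal(starts, c(10L, 70L))
  # no cross-experiment matches
  far <- lapply(0:4, function(q) list(genomic_loop(c(100L * q + 1L, 100L * q + 2L))))
  none <- consensus_loops(far)
  expect_length(none, 0L)
  expect_error(consensus_loops(far[1]), "two experiments")
  # exhaustive clique oracle on a random instance
  tightph:::with_seed(42L, {
    rnd <- lapply(1:5, function(e)
      lapply(1:3, function(q) genomic_loop(sample(60L, 3L))))
  })
  cons2 <- consensus_loops(rnd)
  # brute force: all 3^5 combinations, one loop per experiment, all pairs <= 2
  combos <- expand.grid(rep(list(1:3), 5))
  hits <- 0L
  for (rw in seq_len(nrow(combos))) {
    sel <- lapply(1:5, function(e) rnd[[e]][[combos[rw, e]]])
    okk <- TRUE
    for (a in 1:4) for (b in (a + 1):5)
      if (loop_distance(sel[[a]], sel[[b]]) > 2) okk <- FALSE
    hits <- hits + okk
  }
  expect_equal(attr(cons2, "n_cliques"), hits)
})

test_that("planted Hi-C matrix yields exactly one loop through the anchors", {
  h <- fixture_planted_hic()
  res <- hic_loops(h$counts, h$bin_map, h$params)
  expect_length(res$loops, 1L)
  loop <- res$loops[[1L]]
  expect_equal(attr(loop, "chrom_class"), "cis")
  # the loop passes within the anchor block half-width of both anchors
  expect_lte(min(abs(loop$bins - h$anchors$bin1)), 1L)
  expect_lte(min(abs(loop$bins - h$anchors$bin2)), 1L)
  expect_gte(loop$est_death - loop$est_birth, h$params$eps)
  # trans variant
  ht <- fixture_planted_hic(trans = TRUE)
  rest <- hic_loops(ht$counts, ht$bin_map, ht$params)
  expect_length(rest$loops, 1L)
  expect_equal(attr(rest$loops[[1L]], "chrom_class"), "trans")
})

test_that("bin-distance percentiles come from the right gap classes", {
  coo <- data.frame(i = c(0L, 1L, 2L, 0L, 1L), j = c(1L, 2L, 3L, 2L, 3L),
                    value = c(1, 2, 3, 10, 20))
  dm <- build_distance_model(coo, Inf, type = "coo", n_points = 4L)
  p50 <- bin_distance_percentiles(dm, k = 1:2, prob = 0.5)
  expect_equal(unname(p50["1"]), 2)
  expect_equal(unname(p50["2"]), 15)
})
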