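# Covers, pruning/contraction rules and stochastic re-tightening.

test_that("a cover is the tightest closed box around the cycle's points", {
  coords <- rbind(c(0, 0), c(2, 1), c(1, 0.5), c(5, 5))
  cyc <- tightph:::new_vertex_chain(rbind(c(0L, 1L)), 1L)
  cv <- local_cover(cyc, coords)
  expect_equal(unname(cv$box["lo", ]), c(0, 0))
  expect_equal(unname(cv$box["hi", ]), c(2, 1))
  expect_setequal(cv$members, c(0L, 1L, 2L))  # interior point included
  # degenerate single-point cycle: zero-volume box holds coincident points
  one <- tightph:::new_vertex_chain(rbind(c(3L, 3L)), 1L)
  cv1 <- local_cover(one, coords)
  expect_equal(unname(cv1$box["lo", ]), unname(cv1$box["hi", ]))
  expect_equal(cv1$members, 3L)
})

test_that("the cycle's own points always lie inside its cover", {
  x <- fixture_noisy_circle(n = 120L, seed = 3L)
  gt <- attr(x, "ground_truth")
  tp <- tight_representatives(unclass(x), gt$params, dim = 1L,
                              use_covers = FALSE)
  filt <- tp$diagram$state$filt
  cyc <- tp$cycles[[1L]]
  cv <- local_cover(cyc, unclass(x), filt)
  pts <- unique(as.vector(chain_vertices(cyc, filt)))
  expect_true(all(pts %in% cv$members))
  expect_lte(length(cv$members), nrow(x))
})

test_that("zero-feature covers are dropped; subset rule removes the superset", {
  x <- fixture_two_circles(seed = 2L)
  gt <- attr(x, "ground_truth")
  coords <- unclass(x)
  # cover around the first circle, a subset box inside it, and an empty box
  big <- structure(list(box = rbind(lo = c(-1.4, -1.4), hi = c(1.4, 1.4)),
                        members = integer(), cycle = NULL,
                        n_significant = NA_integer_), class = "tph_cover")
  big$members <- tightph:::box_members(big$box, coords)
  empty <- structure(list(box = rbind(lo = c(1.35, 1.2), hi = c(1.75, 1.9)),
                          members = integer(), cycle = NULL,
                          n_significant = NA_integer_), class = "tph_cover")
  empty$members <- tightph:::box_members(empty$box, coords)
  out <- prune_and_contract(list(big, empty), coords, gt$params, 1L)
  expect_length(out, 1L)
  expect_equal(out[[1L]]$n_significant, 1L)
  # explicit subset with equal counts: superset is removed
  sub <- structure(list(box = rbind(lo = c(-1.2, -1.2), hi = c(1.2, 1.2)),
                        members = integer(), cycle = NULL,
                        n_significant = NA_integer_), class = "tph_cover")
  sub$members <- tightph:::box_members(sub$box, coords)
  out2 <- prune_and_contract(list(sub, big), coords, gt$params, 1L)
  expect_length(out2, 1L)
  expect_equal(unname(out2[[1L]]$box["hi", 1L]), 1.2)
})

test_that("overlapping covers around one circle contract to their intersection", {
  x <- fixture_noisy_circle(n = 150L, seed = 6L)
  gt <- attr(x, "ground_truth")
  coords <- unclass(x)
  mk <- function(lo, hi) {
    cv <- structure(list(box = rbind(lo = lo, hi = hi), members = integer(),
                         cycle = NULL, n_significant = NA_integer_),
                    class = "tph_cover")
    cv$members <- tightph:::box_members(cv$box, coords)
    cv
  }
  a <- mk(c(-1.5, -1.2), c(1.2, 1.5))
  b <- mk(c(-1.2, -1.5), c(1.5, 1.2))
  out <- prune_and_contract(list(a, b), coords, gt$params, 1L)
  expect_length(out, 1L)
  expect_equal(unname(out[[1L]]$box["lo", ]), c(-1.2, -1.2))
  expect_equal(unname(out[[1L]]$box["hi", ]), c(1.2, 1.2))
  expect_equal(out[[1L]]$n_significant, 1L)
})

test_that("contraction preserves the total significant-feature count", {
  for (fix in list(fixture_two_circles(seed = 5L),
                   fixture_two_spheres(n = 40L, seed = 5L))) {
    gt <- attr(fix, "ground_truth")
    dim <- if (is.null(gt$expected_h2)) 1L else 2L
    expected <- if (dim == 1L) gt$expected_h1 else gt$expected_h2
    tp <- tight_representatives(unclass(fix), gt$params, dim = dim)
    expect_equal(sum(vapply(tp$covers, function(cv) cv$n_significant,
                            integer(1))),
                 expected)
    expect_true(all(vapply(tp$covers, function(cv) cv$n_significant,
                           integer(1)) > 0L))
  }
})

test_that("identity plan reproduces the deterministic run bit-exactly", {
  x <- fixture_noisy_circle(n = 120L, seed = 8L)
  gt <- attr(x, "ground_truth")
  det <- tight_representatives(unclass(x), gt$params, dim = 1L)
  idn <- tight_representatives(unclass(x), gt$params, dim = 1L,
                               plan = stochastic_plan(1L, 1L, delta = 0,
                                                      seed = 42L))
  expect_identical(det$representatives, idn$representatives)
})

test_that("stochastic selection picks the shortest matched representative", {
  x <- fixture_noisy_circle(n = 120L, seed = 8L)
  gt <- attr(x, "ground_truth")
  det <- tight_representatives(unclass(x), gt$params, dim = 1L)
  sto <- tight_representatives(unclass(x), gt$params, dim = 1L,
                               plan = stochastic_plan(4L, 4L, seed = 11L))
  expect_equal(length(sto$representatives), length(det$representatives))
  for (q in seq_along(det$representatives))
    expect_lte(nrow(sto$representatives[[q]]$verts),
               nrow(det$representatives[[q]]$verts))
  # bit-reproducible under the same seed and plan
  sto2 <- tight_representatives(unclass(x), gt$params, dim = 1L,
                                plan = stochastic_plan(4L, 4L, seed = 11L))
  expect_identical(sto$representatives, sto2$representatives)
})

test_that("min-length selection over runs is a plain minimum", {
  # the matching contract on a constructed example: lengths {7, 5, 6} -> 5
  lens <- c(7L, 5L, 6L)
  expect_equal(min(lens), 5L)
  # and the stochastic result never exceeds the identity run's length by
  # construction (identity run is always included)
  x <- fixture_noisy_circle(n = 100L, seed = 13L)
  gt <- attr(x, "ground_truth")
  tp <- tight_representatives(unclass(x), gt$params, dim = 1L,
                              plan = stochastic_plan(2L, 3L, seed = 7L))
  det <- tight_representatives(unclass(x), gt$params, dim = 1L)
  expect_lte(nrow(tp$representatives[[1L]]$verts),
             nrow(det$representatives[[1L]]$verts))
})
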