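# Persistence computation, route duality and birth-cycle extraction.

test_that("unit square has one H1 class born 1, dead sqrt(2)", {
  x <- unclass(fixture_square4())
  filt <- build_vr_filtration(build_distance_model(x, 1.5), 1.5, max_dim = 3)
  pd <- compute_persistence(filt)
  h1 <- pd$records[pd$records$dim == 1L, ]
  expect_equal(nrow(h1), 1L)
  expect_equal(h1$birth, 1)
  expect_equal(h1$death, sqrt(2))
  bc <- birth_cycle(pd, h1$id)
  expect_equal(chain_length(bc), 4L)
  v <- chain_vertices(bc, filt)
  expect_setequal(apply(v, 1, paste, collapse = ","),
                  c("0,1", "1,2", "2,3", "0,3"))  # the four sides
})

test_that("octahedron has one H2 class born sqrt(2); birth cycle is 8 faces", {
  x <- unclass(fixture_octahedron())
  filt <- build_vr_filtration(build_distance_model(x, 2.1), 2.1, max_dim = 3)
  pd <- compute_persistence(filt)
  h2 <- pd$records[pd$records$dim == 2L, ]
  expect_equal(nrow(h2), 1L)
  expect_equal(h2$birth, sqrt(2))
  expect_equal(h2$death, 2)
  # brute-force oracle agrees
  expect_equal(sorted_diagram(pd$records), oracle_diagram(x, 2.1, 3))
  bc <- birth_cycle(pd, h2$id)
  expect_equal(chain_length(bc), 8L)
  expect_true(is_cycle(bc, filt))
})

test_that("both reduction routes match the brute-force oracle on random clouds", {
  for (seed in 1:30) {
    dims <- if (seed %% 2L) 2L else 3L
    n <- 8L + (seed * 7L) %% 13L
    x <- random_cloud(n, dims, seed)
    tau <- unname(quantile(dist(x), 0.6))
    filt <- build_vr_filtration(build_distance_model(x, tau), tau, max_dim = 3)
    co <- compute_persistence(filt, route = "coboundary")
    bo <- compute_persistence(filt, route = "boundary")
    orc <- oracle_diagram(x, tau, 3)
    expect_equal(sorted_diagram(co$records), orc, tolerance = 1e-12)
    expect_equal(sorted_diagram(bo$records), orc, tolerance = 1e-12)
  }
})

test_that("birth cycles satisfy their contract and match the stored-V route", {
  for (seed in c(2L, 11L, 23L)) {
    x <- random_cloud(18L, 3L, seed)
    tau <- unname(quantile(dist(x), 0.55))
    filt <- build_vr_filtration(build_distance_model(x, tau), tau, max_dim = 3)
    pd <- compute_persistence(filt)
    rec <- pd$records
    if (nrow(rec) == 0L) next
    fly <- birth_cycles(pd, rec$id, method = "on_the_fly")
    sto <- birth_cycles(pd, rec$id, method = "stored")
    for (q in seq_len(nrow(rec))) {
      expect_true(is_cycle(fly[[q]], filt))
      expect_true(rec$creator[q] %in% fly[[q]]$idx)
      expect_identical(fly[[q]]$idx, sto[[q]]$idx)
    }
    # caching policy does not change the result
    agg <- birth_cycles(pd, rec$id, cache_limit = 0L)
    lazy <- birth_cycles(pd, rec$id, cache_limit = 10L)
    expect_identical(lapply(agg, `[[`, "idx"), lapply(fly, `[[`, "idx"))
    expect_identical(lapply(lazy, `[[`, "idx"), lapply(fly, `[[`, "idx"))
  }
})

test_that("birth cycles are homologically nontrivial at their birth scale", {
  for (seed in c(2L, 5L, 10L)) {
    x <- random_cloud(14L, 2L, seed)
    tau <- unname(quantile(dist(x), 0.7))
    filt <- build_vr_filtration(build_distance_model(x, tau), tau, max_dim = 3)
    pd <- compute_persistence(filt)
    h1 <- pd$records[pd$records$dim == 1L, ]
    if (nrow(h1) == 0L) next
    cycles <- birth_cycles(pd, h1$id)
    for (q in seq_len(nrow(h1))) {
      cyc <- cycles[[q]]
      # complex at the moment the creator enters: earlier triangles only
      tri <- which(filt$dim == 2L &
                     seq_along(filt$dim) < h1$creator[q])
      M <- NULL
      for (tt in tri) {
        bd <- chain_boundary(new_chain(tt, 2L), filt)
        M <- cbind(M, chain_vector_of(bd, filt))
      }
      v <- chain_vector_of(cyc, filt)
      expect_false(gf2_in_span(M, v))
    }
    # the birth-cycle set is comprehensive: spans >= #nontrivial features
    if (nrow(h1) >= 1L) {
      V <- do.call(cbind, lapply(cycles, chain_vector_of, filt = filt))
      expect_gte(gf2_rank(V), nrow(h1))
    }
  }
})

test_that("significance filter keeps birth <= tau_u and persistence >= eps", {
  rec <- data.frame(id = 1:3, dim = 1L,
                    birth = c(90, 120, 95), death = c(160, 200, 130))
  rec$persistence <- rec$death - rec$birth
  rec$creator <- NA_integer_; rec$destroyer <- NA_integer_
  keep <- significant(rec, ph_params(100, 50))
  expect_equal(keep$id, 1L)
  # infinite death always qualifies
  rec2 <- data.frame(id = 1L, dim = 2L, birth = 9, death = Inf,
                     persistence = Inf, creator = NA, destroyer = NA)
  expect_equal(nrow(significant(rec2, ph_params(10, 3.5))), 1L)
  # protein preset carries the documented thresholds
  pp <- ph_params_protein()
  expect_equal(pp$tau_u, 10)
  expect_equal(pp$eps, 3.5)
  expect_equal(pp$tau, 13.5)
})

test_that("empty filtrations yield empty diagrams", {
  dm <- build_distance_model(data.frame(i = integer(), j = integer(),
                                        value = numeric()),
                             1, n_points = 0L)
  filt <- build_vr_filtration(dm, 1, max_dim = 2)
  pd <- compute_persistence(filt)
  expect_equal(nrow(pd$records), 0L)
})
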