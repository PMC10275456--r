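#' Synthetic fixtures for every pipeline
#'
#' Deterministic, seeded generators covering all input classes: small worked
#' examples (unit square, hexagon with a chord, octahedron), noisy embedded
#' shapes (circles, sphere shells), planted-loop Hi-C contact matrices, and
#' toy PDB files. Each fixture carries a \code{ground_truth} attribute with
#' the planted structure and suggested significance parameters. The same
#' (kind, parameters, seed) always produces byte-identical output.
#'
#' @param kind one of \code{"square4"}, \code{"hexagon_chord"},
#'   \code{"noisy_circle"}, \code{"two_circles"}, \code{"sphere_shell"},
#'   \code{"two_spheres"}, \code{"octahedron"}, \code{"planted_hic"},
#'   \code{"toy_pdb"}.
#' @param ... passed to the specific generator.
#' @export
generate_fixture <- function(kind, ...) {
  switch(kind,
    square4 = fixture_square4(),
    hexagon_chord = fixture_hexagon_chord(),
    noisy_circle = fixture_noisy_circle(...),
    two_circles = fixture_two_circles(...),
    sphere_shell = fixture_sphere_shell(...),
    two_spheres = fixture_two_spheres(...),
    octahedron = fixture_octahedron(),
    planted_hic = fixture_planted_hic(...),
    toy_pdb = fixture_toy_pdb(...),
    stop("unknown fixture kind: ", kind))
}

#' @rdname generate_fixture
#' @export
fixture_square4 <- function() {
  x <- matrix(c(0, 0, 1, 0, 1, 1, 0, 1), ncol = 2, byrow = TRUE)
  structure(x, ground_truth = list(expected_h1 = 1L, birth = 1, death = sqrt(2)))
}

#' @rdname generate_fixture
#' @export
fixture_octahedron <- function() {
  x <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
             c(0, 0, 1), c(0, 0, -1))
  structure(x, ground_truth = list(expected_h2 = 1L, birth = sqrt(2), death = 2))
}

#' Hexagon with a chord: two overlapping cycles for the greedy stage
#'
#' An abstract metric graph: six unit sides v0..v5 and the chord v0-v3, all
#' of length 1. Returns the filtration together with two chains: the outer
#' 6-cycle and the left 4-cycle through the chord.
#' @rdname generate_fixture
#' @export
fixture_hexagon_chord <- function() {
  edges <- rbind(c(0, 1), c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(0, 5), c(0, 3))
  dm <- dist_from_coo(data.frame(i = edges[, 1], j = edges[, 2], value = 1),
                      6, 1.5)
  filt <- build_vr_filtration(dm, 1.5, max_dim = 2)
  eidx <- function(a, b) simplex_index(filt, c(a, b, -1L, -1L))
  left <- new_chain(c(eidx(0, 1), eidx(1, 2), eidx(2, 3), eidx(0, 3)), 1L)
  outer <- new_chain(c(eidx(0, 1), eidx(1, 2), eidx(2, 3), eidx(3, 4),
                       eidx(4, 5), eidx(0, 5)), 1L)
  right <- new_chain(c(eidx(3, 4), eidx(4, 5), eidx(0, 5), eidx(0, 3)), 1L)
  structure(list(filt = filt, left = left, outer = outer, right = right),
            ground_truth = list(final_lengths = c(4L, 4L)))
}

#' @rdname generate_fixture
#' @param n number of points.
#' @param r radius.
#' @param noise Gaussian coordinate noise (standard deviation).
#' @param seed RNG seed.
#' @export
fixture_noisy_circle <- function(n = 200L, r = 1, noise = 0.03, seed = 1L) {
  x <- with_seed(seed, {
    th <- 2 * pi * (seq_len(n) - 1 + runif(n, -0.3, 0.3)) / n
    cbind(r * cos(th), r * sin(th)) + matrix(rnorm(2L * n, 0, noise), n, 2L)
  })
  structure(x, ground_truth = list(
    expected_h1 = 1L, center = c(0, 0),
    annulus = c(r - 0.3 * r, r + 0.3 * r),
    params = ph_params(0.35 * r, 0.15 * r)))
}

#' @rdname generate_fixture
#' @param centers list of circle centres.
#' @export
fixture_two_circles <- function(n = 100L, r = 1, noise = 0.03, seed = 1L,
                                centers = list(c(0, 0), c(3, 0))) {
  parts <- lapply(seq_along(centers), function(q)
    sweep(unclass(fixture_noisy_circle(n, r, noise, seed + q - 1L)), 2L,
          centers[[q]], "+"))
  x <- do.call(rbind, parts)
  structure(x, ground_truth = list(
    expected_h1 = length(centers), centers = centers,
    params = ph_params(0.35 * r, 0.15 * r)))
}

# deterministic near-uniform sphere sampling (golden-angle lattice)
.fib_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  rho <- sqrt(pmax(0, 1 - z^2))
  th <- pi * (1 + sqrt(5)) * i
  cbind(rho * cos(th), rho * sin(th), z)
}

#' @rdname generate_fixture
#' @export
fixture_sphere_shell <- function(n = 48L, r = 6, noise = 0.2, seed = 1L) {
  x <- r * .fib_sphere(n)
  x <- x + with_seed(seed, matrix(rnorm(3L * n, 0, noise), n, 3L))
  structure(x, ground_truth = list(
    expected_h2 = 1L, center = c(0, 0, 0), radius = r,
    params = ph_params_protein()))
}

#' @rdname generate_fixture
#' @export
fixture_two_spheres <- function(n = 48L, r = 6, noise = 0.2, seed = 1L,
                                centers = list(c(0, 0, 0), c(20, 0, 0))) {
  parts <- lapply(seq_along(centers), function(q)
    sweep(unclass(fixture_sphere_shell(n, r, noise, seed + q - 1L)), 2L,
          centers[[q]], "+"))
  x <- do.call(rbind, parts)
  structure(x, ground_truth = list(
    expected_h2 = length(centers), centers = centers,
    params = ph_params_protein()))
}

#' Planted-loop Hi-C contact matrix
#'
#' Balanced-count surrogate with a distance-decay background: same-chromosome
#' counts are Poisson with mean \code{scale / (1 + gap)}, so inverse-count
#' distance estimates grow with bin distance; chromosomes share no background
#' contacts. An anchor block of elevated counts (\code{anchor_rate * scale}
#' within \code{width} bins of each anchor pair) plants a chromatin loop
#' through the anchors. With \code{trans = TRUE} two cross-chromosome anchor
#' pairs plant a trans loop instead.
#'
#' @param n_bins named vector of bins per chromosome.
#' @param anchors data frame with columns \code{bin1}, \code{bin2}.
#' @param scale background count scale.
#' @param anchor_rate anchor block mean as a fraction of \code{scale}.
#' @param width anchor block half-width in bins.
#' @param resolution bin size in bp.
#' @param trans plant a trans loop via two cross-chromosome anchors.
#' @param seed RNG seed.
#' @rdname generate_fixture
#' @export
fixture_planted_hic <- function(n_bins = c(chr1 = 220L, chr2 = 80L),
                                anchors = data.frame(bin1 = 40L, bin2 = 160L),
                                scale = 1000, anchor_rate = 0.5, width = 1L,
                                resolution = 10000L, trans = FALSE,
                                seed = 1L) {
  bm <- make_bin_map(n_bins, resolution)
  if (trans)
    anchors <- data.frame(bin1 = c(40L, 160L),
                          bin2 = n_bins[[1L]] + c(20L, 60L))
  n <- nrow(bm)
  ii <- jj <- integer(0); lam <- numeric(0)
  for (ch in unique(bm$chrom)) {
    b <- bm$bin[bm$chrom == ch]
    pr <- utils::combn(b, 2L)
    ii <- c(ii, pr[1L, ]); jj <- c(jj, pr[2L, ])
    lam <- c(lam, scale / (1 + pr[2L, ] - pr[1L, ]))
  }
  key <- ii * n + jj
  for (q in seq_len(nrow(anchors))) {
    a1 <- anchors$bin1[q]; a2 <- anchors$bin2[q]
    blk <- expand.grid(i = a1 + (-width):width, j = a2 + (-width):width)
    blk <- blk[blk$i >= 0 & blk$j >= 0 & blk$i < n & blk$j < n & blk$i != blk$j, ]
    bi <- pmin(blk$i, blk$j); bj <- pmax(blk$i, blk$j)
    bkey <- bi * n + bj
    hit <- match(bkey, key)
    new <- is.na(hit)
    lam[hit[!new]] <- pmax(lam[hit[!new]], anchor_rate * scale)
    if (any(new)) {
      ii <- c(ii, bi[new]); jj <- c(jj, bj[new])
      lam <- c(lam, rep(anchor_rate * scale, sum(new)))
      key <- c(key, bkey[new])
    }
  }
  counts <- with_seed(seed, rpois(length(lam), lam))
  coo <- data.frame(i = ii, j = jj, value = counts)
  coo <- coo[coo$value > 0, , drop = FALSE]
  rownames(coo) <- NULL
  structure(list(counts = coo, bin_map = bm,
                 params = ph_params(0.005, 0.02), anchors = anchors),
            ground_truth = list(
                 expected_loops = if (trans) 1L else nrow(anchors),
                 chrom_class = if (trans) "trans" else "cis",
                 anchors = anchors))
}

#' Toy PDB text fixtures
#'
#' \code{kind = "helix"} writes a small idealized backbone (4 atoms per
#' residue), optionally with a HETATM ligand or a non-standard residue;
#' \code{kind = "cage"} writes a synthetic spherical cage of backbone atoms
#' of radius \code{r} enclosing a central void (a geometry stand-in, not a
#' real protein fold).
#'
#' @param kind \code{"helix"} or \code{"cage"}.
#' @param n_res number of residues (helix).
#' @param ligand append a HETATM ligand record.
#' @param bad_residue use residue name "XYZ" for the last residue.
#' @param path optional file to write; the PDB text lines are returned
#'   invisibly in any case.
#' @rdname generate_fixture
#' @export
fixture_toy_pdb <- function(kind = c("helix", "cage"), n_res = 2L,
                            n = 48L, r = 6, noise = 0.2, seed = 1L,
                            ligand = FALSE, bad_residue = FALSE,
                            path = NULL) {
  kind <- match.arg(kind)
  if (kind == "helix") {
    offs <- list(N = c(0.0, 0.0, 0.0), CA = c(1.0, 0.8, 0.0),
                 C = c(2.2, 0.3, 0.4), O = c(2.5, -0.8, 0.6))
    rows <- list()
    serial <- 0L
    for (res in seq_len(n_res)) {
      base <- c(2.8 * (res - 1L), 1.2 * ((res - 1L) %% 2L), 0.9 * (res - 1L))
      resname <- if (bad_residue && res == n_res) "XYZ" else "ALA"
      for (a in names(offs)) {
        serial <- serial + 1L
        xyz <- base + offs[[a]]
        rows[[serial]] <- .pdb_atom_line("ATOM", serial, a, resname, "A",
                                         res, xyz)
      }
    }
    lines <- unlist(rows)
    if (ligand)
      lines <- c(lines, .pdb_atom_line("HETATM", serial + 1L, "ZN", "ZN", "A",
                                       n_res + 1L, c(1.0, 3.0, 1.0)))
    lines <- c(lines, "END")
    truth <- list(n_backbone_atoms = 4L * n_res)
  } else {
    xyz <- unclass(fixture_sphere_shell(n, r, noise, seed))
    names4 <- rep(c("N", "CA", "C", "O"), length.out = n)
    lines <- vapply(seq_len(n), function(q)
      .pdb_atom_line("ATOM", q, names4[q], "GLY", "A",
                     (q - 1L) %/% 4L + 1L, xyz[q, ]), character(1))
    lines <- c(lines, "END")
    truth <- list(expected_h2 = 1L, center = c(0, 0, 0), radius = r)
  }
  if (!is.null(path)) writeLines(lines, path)
  structure(lines, ground_truth = truth)
}

.pdb_atom_line <- function(rec, serial, name, resname, chain, resno, xyz) {
  elem <- substr(name, 1L, 1L)
  sprintf("%-6s%5d  %-3s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rec, serial, name, resname, chain, resno,
          xyz[1L], xyz[2L], xyz[3L], 1.00, 0.00, elem)
}
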