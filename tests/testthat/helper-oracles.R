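# Independent pure-R oracles: brute-force Vietoris-Rips enumeration, the
# standard left-to-right boundary matrix reduction over Z2, GF(2) linear
# algebra, and a bottleneck distance computed by binary search over matching
# feasibility. These never call into the package's C++ engine.

# ---- brute-force VR filtration ----

# All vertex subsets of size <= max_dim+1 with diameter <= tau, ordered by
# (diameter, dimension, lexicographic vertex tuple). Vertices 0-based.
oracle_vr <- function(coords, tau, max_dim = 3) {
  D <- as.matrix(dist(coords))
  n <- nrow(D)
  verts <- lapply(seq_len(n) - 1L, function(v) v)
  diam <- rep(0, n)
  for (k in seq(2L, max_dim + 1L)) {
    if (k > n) break
    cmb <- utils::combn(n, k)
    dm <- rep(0, ncol(cmb))
    for (a in seq_len(k - 1L)) for (b in seq(a + 1L, k))
      dm <- pmax(dm, D[cbind(cmb[a, ], cmb[b, ])])
    keep <- dm <= tau
    verts <- c(verts, lapply(which(keep), function(q) cmb[, q] - 1L))
    diam <- c(diam, dm[keep])
  }
  dims <- vapply(verts, length, integer(1)) - 1L
  lex <- vapply(verts, function(v) paste(sprintf("%06d", v), collapse = ""),
                character(1))
  o <- order(diam, dims, lex)
  list(verts = verts[o], diam = diam[o], dim = dims[o])
}

# ---- standard reduction oracle ----

.z2_xor <- function(a, b) sort(c(setdiff(a, b), setdiff(b, a)))

# Left-to-right column reduction of the boundary matrix of an oracle_vr
# filtration. Returns all (creator, destroyer) pairs (1-based positions into
# the filtration; destroyer NA = essential).
oracle_reduce <- function(filt) {
  m <- length(filt$verts)
  key <- vapply(filt$verts, paste, character(1), collapse = ",")
  idx <- seq_len(m)
  names(idx) <- key
  owner <- integer(0)   # pivot -> column
  R <- vector("list", m)
  creator <- integer(0); destroyer <- integer(0); cdim <- integer(0)
  for (j in seq_len(m)) {
    v <- filt$verts[[j]]
    d <- length(v) - 1L
    c0 <- integer(0)
    if (d > 0) {
      c0 <- sort(vapply(seq_along(v), function(drop)
        idx[[paste(v[-drop], collapse = ",")]], integer(1)))
    }
    repeat {
      if (length(c0) == 0L) break
      p <- max(c0)
      k <- owner[as.character(p)]
      if (is.na(k) || length(k) == 0L) break
      c0 <- .z2_xor(c0, R[[k]])
    }
    if (length(c0) == 0L) {
      creator <- c(creator, j); destroyer <- c(destroyer, NA_integer_)
      cdim <- c(cdim, d)
    } else {
      p <- max(c0)
      owner[as.character(p)] <- j
      R[[j]] <- c0
    }
  }
  # fill destroyers of paired creators
  for (p in names(owner)) {
    pi <- as.integer(p)
    hit <- match(pi, creator)
    if (!is.na(hit)) destroyer[hit] <- owner[[p]]
  }
  data.frame(creator = creator, destroyer = destroyer, dim = cdim)
}

# Diagram (dims 1..max_dim-1, nonzero persistence) from the oracle, as a
# sorted data frame comparable with compute_persistence()$records.
oracle_diagram <- function(coords, tau, max_dim = 3) {
  filt <- oracle_vr(coords, tau, max_dim)
  red <- oracle_reduce(filt)
  birth <- filt$diam[red$creator]
  death <- ifelse(is.na(red$destroyer), Inf, filt$diam[red$destroyer])
  df <- data.frame(dim = red$dim, birth = birth, death = death)
  df <- df[df$dim >= 1 & df$dim <= max_dim - 1 & df$death > df$birth, ]
  df <- df[order(df$dim, df$birth, df$death), c("dim", "birth", "death")]
  rownames(df) <- NULL
  df
}

sorted_diagram <- function(rec) {
  df <- rec[, c("dim", "birth", "death")]
  df <- df[order(df$dim, df$birth, df$death), ]
  rownames(df) <- NULL
  df
}

# ---- GF(2) linear algebra ----

gf2_rank <- function(M) {
  if (is.null(M) || length(M) == 0L) return(0L)
  M <- (M %% 2L) != 0L
  r <- 0L
  for (col in seq_len(ncol(M))) {
    piv <- which(M[, col])
    piv <- piv[piv > r]
    if (length(piv) == 0L) next
    r <- r + 1L
    if (piv[1L] != r) M[c(r, piv[1L]), ] <- M[c(piv[1L], r), ]
    hit <- which(M[, col] & seq_len(nrow(M)) != r)
    if (length(hit)) M[hit, ] <- xor(M[hit, , drop = FALSE],
                                     matrix(M[r, ], length(hit), ncol(M),
                                            byrow = TRUE))
  }
  r
}

# is v in the GF(2) column span of M?
gf2_in_span <- function(M, v) {
  if (all(v == 0)) return(TRUE)
  if (is.null(M) || ncol(M) == 0L) return(FALSE)
  gf2_rank(cbind(M, v)) == gf2_rank(M)
}

# 0/1 matrix of the boundaries of all dim-d simplices of a filtration,
# rows = (d-1)-simplices, columns = d-simplices (package filtration object).
boundary_matrix_of <- function(filt, d) {
  rows <- which(filt$dim == d - 1L)
  cols <- which(filt$dim == d)
  if (length(cols) == 0L) return(NULL)
  M <- matrix(0L, length(rows), length(cols))
  rowpos <- integer(length(filt$dim))
  rowpos[rows] <- seq_along(rows)
  for (q in seq_along(cols)) {
    ch <- new_chain(cols[q], d)
    bd <- chain_boundary(ch, filt)
    M[rowpos[bd$idx], q] <- 1L
  }
  M
}

# indicator vector of a d-chain over the dim-d simplices of filt
chain_vector_of <- function(chain, filt) {
  rows <- which(filt$dim == chain$dim)
  v <- integer(length(rows))
  v[match(chain$idx, rows)] <- 1L
  v
}

# ---- bottleneck distance oracle ----

# diagrams: data frames with finite birth/death columns.
bottleneck_oracle <- function(A, B) {
  na <- nrow(A); nb <- nrow(B)
  if (na == 0L && nb == 0L) return(0)
  costAB <- matrix(Inf, max(na, 1L), max(nb, 1L))
  if (na > 0L && nb > 0L)
    for (i in seq_len(na)) for (j in seq_len(nb))
      costAB[i, j] <- max(abs(A$birth[i] - B$birth[j]),
                          abs(A$death[i] - B$death[j]))
  dA <- if (na) (A$death - A$birth) / 2 else numeric(0)
  dB <- if (nb) (B$death - B$birth) / 2 else numeric(0)
  cand <- sort(unique(c(0, costAB[is.finite(costAB)], dA, dB)))
  feasible <- function(t) {
    # bipartite: left = A points + nb diagonal slots, right = B points + na
    # diagonal slots; perfect matching must exist with all costs <= t
    nl <- na + nb; nr <- nb + na
    el <- NULL
    for (i in seq_len(na)) {
      for (j in seq_len(nb)) if (costAB[i, j] <= t) el <- rbind(el, c(i, j))
      if (dA[i] <= t) el <- rbind(el, c(i, nb + i))
    }
    for (j in seq_len(nb)) if (dB[j] <= t) el <- rbind(el, c(na + j, j))
    for (j in seq_len(nb)) for (i in seq_len(na))
      el <- rbind(el, c(na + j, nb + i))
    if (is.null(el)) return(FALSE)
    g <- igraph::make_bipartite_graph(
      types = c(rep(FALSE, nl), rep(TRUE, nr)),
      edges = as.vector(t(cbind(el[, 1L], nl + el[, 2L]))))
    igraph::max_bipartite_match(g)$matching_size == nl
  }
  for (t in cand) if (feasible(t)) return(t)
  max(cand)
}

# ---- misc ----

random_cloud <- function(n, dimension = 2L, seed = 1L) {
  tightph:::with_seed(seed, matrix(runif(n * dimension), n, dimension))
}
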