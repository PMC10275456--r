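#' Extract a protein backbone point cloud from a PDB file
#'
#' Reads ATOM records (HETATM ligands and waters are ignored) and keeps the
#' backbone atoms N, C, CA and O of the first model, alternate location ''
#' or 'A'. Entries with a residue outside the 20 standard amino acids can be
#' rejected with \code{strict = TRUE}. Structures with fewer than
#' \code{min_atoms} backbone atoms are rejected.
#'
#' @param path PDB file path.
#' @param atoms atom names retained.
#' @param strict reject entries containing non-standard residues.
#' @param min_atoms floor on the backbone size (default 10).
#' @return a \code{backbone}: list with \code{xyz} (n x 3 matrix, Angstrom)
#'   and \code{atom} (data frame with elety, resid, resno, chain).
#' @export
extract_backbone <- function(path, atoms = c("N", "C", "CA", "O"),
                             strict = FALSE, min_atoms = 10L) {
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  at <- at[is.na(at$alt) | at$alt %in% c("", "A"), , drop = FALSE]
  if (strict) {
    bad <- setdiff(unique(at$resid), aa_three_letter)
    if (length(bad))
      stop("non-standard residue(s): ", paste(bad, collapse = ", "))
  }
  at <- at[at$elety %in% atoms, , drop = FALSE]
  if (nrow(at) < min_atoms)
    stop(sprintf("backbone has %d atoms; at least %d required", nrow(at), min_atoms))
  xyz <- as.matrix(at[, c("x", "y", "z")])
  rownames(xyz) <- NULL
  structure(list(xyz = xyz,
                 atom = at[, c("elety", "resid", "resno", "chain")]),
            class = "backbone")
}

#' The 20 standard amino acids (three-letter codes)
#' @export
aa_three_letter <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                     "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                     "THR", "TRP", "TYR", "VAL")

#' @export
print.backbone <- function(x, ...) {
  cat(sprintf("<backbone> %d atoms, %d residues\n", nrow(x$xyz),
              length(unique(paste(x$atom$chain, x$atom$resno)))))
  invisible(x)
}

#' Find voids (significant H2 features) in a protein backbone
#'
#' Runs the full tightening pipeline on the backbone point cloud with the
#' protein defaults (birth-threshold 10 A, persistence threshold 3.5 A) and,
#' by default, stochastic re-tightening with 15 perturbations and 15
#' permutations per perturbation within each contracted cover.
#'
#' @param x a \code{backbone}, or a coordinate matrix.
#' @param params \code{ph_params} (protein preset by default).
#' @param plan stochastic plan; \code{NULL} for a deterministic cover run.
#' @return a \code{protein_voids} object wrapping the \code{tight_ph} result:
#'   \code{records} are the significant H2 features, \code{surfaces} the
#'   tight representative 2-cycles (vertex triangle lists).
#' @export
find_voids <- function(x, params = ph_params_protein(),
                       plan = stochastic_plan(15L, 15L, seed = 1L)) {
  coords <- if (inherits(x, "backbone")) x$xyz else as.matrix(x)
  tp <- tight_representatives(coords, params, dim = 2L, plan = plan)
  structure(list(records = tp$significant, surfaces = tp$representatives,
                 covers = tp$covers, pipeline = tp, coords = coords,
                 params = params),
            class = "protein_voids")
}

#' @export
print.protein_voids <- function(x, ...) {
  cat(sprintf("<protein_voids> %d significant H2 features, %d tight surfaces\n",
              nrow(x$records), length(x$surfaces)))
  if (nrow(x$records))
    print(x$records[, c("birth", "death", "persistence")])
  invisible(x)
}

#' Does a closed surface enclose a point?
#'
#' Ray-crossing parity test: a ray from \code{point} in a fixed direction is
#' intersected with every triangle of the 2-chain; an odd crossing count
#' means the point is inside. Degenerate grazing hits are avoided by
#' retrying with a rotated direction.
#'
#' @param surface a \code{vertex_chain} of dimension 2 (triangles as 0-based
#'   point ids).
#' @param coords the embedding the ids refer to.
#' @param point numeric length-3 position.
#' @export
surface_encloses <- function(surface, coords, point) {
  stopifnot(surface$dim == 2L, length(point) == 3L)
  tri <- surface$verts
  dirs <- rbind(c(1, 0.2343, 0.5672), c(0.1213, 1, 0.3421), c(0.771, 0.345, 1))
  for (t in seq_len(nrow(dirs))) {
    dir <- dirs[t, ] / sqrt(sum(dirs[t, ]^2))
    hits <- 0L
    ok <- TRUE
    for (q in seq_len(nrow(tri))) {
      a <- coords[tri[q, 1L] + 1L, ]
      b <- coords[tri[q, 2L] + 1L, ]
      cc <- coords[tri[q, 3L] + 1L, ]
      # Moeller-Trumbore
      e1 <- b - a; e2 <- cc - a
      h <- c(dir[2] * e2[3] - dir[3] * e2[2],
             dir[3] * e2[1] - dir[1] * e2[3],
             dir[1] * e2[2] - dir[2] * e2[1])
      det <- sum(e1 * h)
      if (abs(det) < 1e-12) next
      s <- point - a
      u <- sum(s * h) / det
      qv <- c(s[2] * e1[3] - s[3] * e1[2],
              s[3] * e1[1] - s[1] * e1[3],
              s[1] * e1[2] - s[2] * e1[1])
      v <- sum(dir * qv) / det
      tt <- sum(e2 * qv) / det
      eps <- 1e-9
      if (u > -eps && u < eps || v > -eps && v < eps ||
          (u + v) > 1 - eps && (u + v) < 1 + eps || abs(tt) < eps) {
        if (u > -1e-6 && v > -1e-6 && u + v < 1 + 1e-6 && tt > -1e-6) {
          ok <- FALSE; break  # grazing hit: retry with another direction
        }
      }
      if (u >= 0 && v >= 0 && u + v <= 1 && tt > 0) hits <- hits + 1L
    }
    if (ok) return(hits %% 2L == 1L)
  }
  stop("ray-parity test degenerate in all probe directions")
}

#' Compare the H2 diagrams of a homolog set
#'
#' Pairwise L0 distances between the significant-persistence lists of the
#' diagrams, with significance calls at the strict threshold.
#'
#' @param diagrams named list of \code{ph_diagram}s (or persistence vectors).
#' @param eps significance threshold on persistence (default 3.5 A).
#' @param threshold L0 distance above which a pair is significantly
#'   different (default 3).
#' @param tau cap for infinite persistences (see
#'   \code{\link{persistence_list}}).
#' @return list with \code{l0} (symmetric matrix) and \code{pairs} (data
#'   frame: a, b, l0, significant).
#' @export
compare_homolog_set <- function(diagrams, eps = 3.5, threshold = 3,
                                tau = NULL) {
  stopifnot(length(diagrams) >= 2L)
  m <- l0_matrix(diagrams, eps = eps, dim = 2L, tau = tau)
  idx <- which(upper.tri(m), arr.ind = TRUE)
  nm <- if (is.null(names(diagrams))) as.character(seq_along(diagrams))
        else names(diagrams)
  pairs <- data.frame(a = nm[idx[, 1L]], b = nm[idx[, 2L]],
                      l0 = m[idx], significant = m[idx] > threshold)
  list(l0 = m, pairs = pairs)
}
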