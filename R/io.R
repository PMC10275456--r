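#' Write a persistence diagram to TSV
#'
#' Columns: dim, birth, death ("inf" for classes alive at the threshold),
#' creator (comma-separated sorted vertex ids).
#'
#' @param pd a \code{ph_diagram} or records data frame.
#' @param path output file.
#' @param filt filtration for creator vertices (taken from the diagram when
#'   available).
#' @export
write_diagram <- function(pd, path, filt = NULL) {
  if (inherits(pd, "ph_diagram")) { filt <- pd$state$filt; rec <- pd$records }
  else rec <- pd
  creator <- rep(NA_character_, nrow(rec))
  if (!is.null(filt) && nrow(rec)) {
    v <- simplex_vertices(filt, rec$creator)
    creator <- apply(v, 1L, function(r) paste(r[r >= 0], collapse = ","))
  }
  df <- data.frame(dim = rec$dim, birth = rec$birth,
                   death = ifelse(is.infinite(rec$death), "inf", rec$death),
                   creator = creator)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a persistence diagram written by \code{\link{write_diagram}}
#' @param path file path.
#' @return records data frame (death "inf" becomes +Inf).
#' @export
read_diagram <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE,
                   colClasses = c("integer", "numeric", "character", "character"))
  df$death <- ifelse(df$death == "inf", Inf, as.numeric(df$death))
  df$persistence <- df$death - df$birth
  df
}

.chain_line_simplices <- function(verts) {
  paste(apply(verts, 1L, function(r) paste(r[r >= 0], collapse = ",")),
        collapse = ";")
}

#' Write representative cycles
#'
#' One cycle per line: dim, then the simplices as semicolon-separated sorted
#' vertex tuples. With estimates (\code{est}), two extra columns est_birth
#' and est_death precede the simplices.
#'
#' @param cycles list of \code{tph_chain} (needs \code{filt}) or
#'   \code{vertex_chain}.
#' @param path output file.
#' @param filt filtration for index-based chains.
#' @param est optional data frame / matrix with columns est_birth, est_death.
#' @export
write_cycles <- function(cycles, path, filt = NULL, est = NULL) {
  lines <- vapply(seq_along(cycles), function(q) {
    ch <- cycles[[q]]
    v <- if (inherits(ch, "tph_chain")) chain_vertices(ch, filt) else ch$verts
    lead <- if (!is.null(est))
      sprintf("%d\t%.12g\t%.12g", ch$dim, est[q, 1L], est[q, 2L])
    else sprintf("%d", ch$dim)
    paste0(lead, "\t", .chain_line_simplices(v))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read cycles written by \code{\link{write_cycles}}
#' @param path file path.
#' @return list of \code{vertex_chain}s; est columns, when present, are
#'   attached as attributes.
#' @export
read_cycles <- function(path) {
  lines <- readLines(path)
  lapply(lines, function(ln) {
    parts <- strsplit(ln, "\t")[[1L]]
    d <- as.integer(parts[1L])
    simp <- parts[length(parts)]
    v <- do.call(rbind, lapply(strsplit(simp, ";")[[1L]], function(s)
      as.integer(strsplit(s, ",")[[1L]])))
    ch <- new_vertex_chain(v, d)
    if (length(parts) == 4L) {
      attr(ch, "est_birth") <- as.numeric(parts[2L])
      attr(ch, "est_death") <- as.numeric(parts[3L])
    }
    ch
  })
}

#' Write a cover report to TSV
#'
#' One row per cover: box bounds (lo/hi per coordinate), member count and
#' number of significant features.
#'
#' @param covers list of \code{tph_cover}s.
#' @param path output file.
#' @export
write_cover_report <- function(covers, path) {
  rows <- lapply(covers, function(cv) {
    b <- as.vector(cv$box)
    names(b) <- paste0(rep(c("lo", "hi"), ncol(cv$box)),
                       rep(seq_len(ncol(cv$box)), each = 2L))
    c(as.list(b), n_members = length(cv$members),
      n_significant = cv$n_significant)
  })
  df <- do.call(rbind, lapply(rows, as.data.frame))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a pairwise L0 matrix to TSV
#' @param m symmetric matrix from \code{\link{l0_matrix}}.
#' @param path output file.
#' @export
write_l0_matrix <- function(m, path) {
  write.table(data.frame(id = rownames(m), m, check.names = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write loops as BEDPE-like TSV
#'
#' One row per loop edge: chrom/start/end for both anchor bins plus the loop
#' id.
#'
#' @param loops list of \code{genomic_loop}s.
#' @param bin_map the bin map.
#' @param path output file.
#' @export
write_loops_bedpe <- function(loops, bin_map, path) {
  res <- attr(bin_map, "resolution")
  rows <- do.call(rbind, lapply(seq_along(loops), function(q) {
    e <- loops[[q]]$edges
    data.frame(chrom1 = bin_map$chrom[e[, 1L] + 1L],
               start1 = bin_map$start[e[, 1L] + 1L],
               end1 = bin_map$start[e[, 1L] + 1L] + res,
               chrom2 = bin_map$chrom[e[, 2L] + 1L],
               start2 = bin_map$start[e[, 2L] + 1L],
               end2 = bin_map$start[e[, 2L] + 1L] + res,
               loop_id = q)
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write loops as JSON lines (full bin lists)
#'
#' @param loops list of \code{genomic_loop}s.
#' @param path output file.
#' @export
write_loops_jsonl <- function(loops, path) {
  lines <- vapply(seq_along(loops), function(q) {
    l <- loops[[q]]
    jsonlite::toJSON(list(loop_id = q, bins = l$bins,
                          est_birth = l$est_birth, est_death = l$est_death,
                          chrom_class = attr(l, "chrom_class"),
                          range_class = attr(l, "range_class")),
                     auto_unbox = TRUE, digits = NA, null = "null")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a loop/peak matching report to TSV
#' @param report data frame from \code{\link{match_peaks}}.
#' @param path output file.
#' @export
write_match_report <- function(report, path) {
  write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a tight H2 surface as an OFF mesh
#'
#' @param surface a \code{vertex_chain} of dimension 2.
#' @param coords the embedding its point ids refer to.
#' @param path output file.
#' @export
write_off <- function(surface, coords, path) {
  stopifnot(surface$dim == 2L)
  pts <- sort(unique(as.vector(surface$verts)))
  remap <- match(surface$verts, pts) - 1L
  dim(remap) <- dim(surface$verts)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", length(pts), nrow(surface$verts)), con)
  writeLines(apply(coords[pts + 1L, , drop = FALSE], 1L, paste, collapse = " "), con)
  writeLines(apply(remap, 1L, function(r) paste(c(3L, r), collapse = " ")), con)
  invisible(path)
}
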