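#' T-cell epitope interval set
#'
#' Epitope intervals are given in full-protein numbering (1-based, inclusive)
#' and may overlap one another. Coordinates are user-supplied: published
#' epitope tables use full-protein numbering, and the package converts
#' construct-relative fragment intervals via the construct's numbering offset
#' before intersecting.
#'
#' @param name Character vector of epitope names.
#' @param start,end Integer vectors of interval bounds (full-protein,
#'   1-based inclusive; `start <= end`).
#' @return An object of class `epitope_set` (a tibble).
#' @export
epitope_set <- function(name, start, end) {
  start <- as.integer(start); end <- as.integer(end)
  if (any(start > end)) stop("epitope intervals need start <= end", call. = FALSE)
  if (any(start < 1L)) stop("epitope coordinates are 1-based", call. = FALSE)
  structure(tibble::tibble(name = as.character(name), start = start, end = end),
            class = c("epitope_set", "tbl_df", "tbl", "data.frame"))
}

#' Read an epitope table from TSV
#'
#' Expected columns: `name`, `start`, `end` (full-protein numbering,
#' 1-based inclusive).
#'
#' @param path TSV file path.
#' @return An [epitope_set()].
#' @export
read_epitopes <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("name", "start", "end") %in% names(df))) {
    stop("epitope table needs columns name, start, end", call. = FALSE)
  }
  epitope_set(df$name, df$start, df$end)
}

#' Overlap digestion fragments with T-cell epitope intervals
#'
#' Converts fragment intervals from construct-relative to full-protein
#' coordinates using the construct's numbering offset, then reports every
#' (fragment, epitope) pair sharing at least one residue. Adjacent intervals
#' do not overlap under inclusive coordinates.
#'
#' @param fragments Fragment table from [enumerate_fragments()] or the
#'   `pairs` component of [match_pairs()] (needs columns `start`, `end`).
#' @param construct The [protein_construct()] providing `numbering_offset`.
#' @param epitopes An [epitope_set()].
#' @return A tibble with one row per overlapping pair: fragment coordinates in
#'   both numbering systems, `epitope`, epitope bounds, `overlap_residues`
#'   (size of the intersection) and `fragment_coverage` (overlap divided by
#'   fragment length, in (0, 1]).
#' @export
overlap_report <- function(fragments, construct, epitopes) {
  stopifnot(inherits(construct, "protein_construct"))
  empty <- tibble::tibble(
    start = integer(), end = integer(),
    full_start = integer(), full_end = integer(), sequence = character(),
    epitope = character(), epitope_start = integer(), epitope_end = integer(),
    overlap_residues = integer(), fragment_coverage = numeric()
  )
  if (nrow(fragments) == 0L || nrow(epitopes) == 0L) return(empty)
  off <- construct$numbering_offset
  frag_rng <- IRanges::IRanges(start = fragments$start + off - 1L,
                               end = fragments$end + off - 1L)
  epi_rng <- IRanges::IRanges(start = epitopes$start, end = epitopes$end)
  hits <- IRanges::findOverlaps(frag_rng, epi_rng)
  if (length(hits) == 0L) return(empty)
  fi <- S4Vectors::queryHits(hits)
  ei <- S4Vectors::subjectHits(hits)
  inter <- IRanges::pintersect(frag_rng[fi], epi_rng[ei])
  ov <- IRanges::width(inter)
  flen <- fragments$end[fi] - fragments$start[fi] + 1L
  tibble::tibble(
    start = fragments$start[fi],
    end = fragments$end[fi],
    full_start = fragments$start[fi] + off - 1L,
    full_end = fragments$end[fi] + off - 1L,
    sequence = if ("sequence" %in% names(fragments)) fragments$sequence[fi]
               else NA_character_,
    epitope = epitopes$name[ei],
    epitope_start = epitopes$start[ei],
    epitope_end = epitopes$end[ei],
    overlap_residues = as.integer(ov),
    fragment_coverage = ov / flen
  )
}
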