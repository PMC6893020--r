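#' Run the quantified-digestion pipeline end to end
#'
#' Orchestrates the full isotope-pair quantification workflow: enumerate
#' candidate fragments from the construct sequence, match NA/15N peak pairs
#' in every timepoint's pooled spectrum, build per-fragment ratio
#' time-courses, summarize the digest, and (when an epitope table is
#' supplied) map observed fragments onto known T-cell epitope intervals.
#' The pipeline involves no randomness: its output is a deterministic
#' function of the inputs and configuration.
#'
#' @param sequence A [protein_construct()] or path to a single-record FASTA.
#' @param peaks A list of [peak_list()] objects or path to a manifest CSV
#'   (columns `path`, `timepoint`; see [read_peak_manifest()]).
#' @param epitopes An [epitope_set()], path to an epitope TSV, or NULL. A
#'   missing epitope file degrades gracefully: digestion and ratio outputs
#'   are still produced and the overlap step is skipped with a warning.
#' @param numbering_offset Used when `sequence` is a FASTA path.
#' @param digest A [digest_config()].
#' @param match A [match_config()].
#' @param out_dir Optional output directory; when given, all result tables
#'   are written as TSV together with a run log echoing the configuration.
#'   On error any partially written outputs are removed.
#' @return A list with class `digest_run`: `construct`, `candidates`,
#'   `matches` (per timepoint), `summary` ([summarize_digest()] result),
#'   `timecourses` (per-fragment ratio time-courses, paired fragments only)
#'   and `overlaps` (NULL when no epitopes were available).
#' @export
run_quantified_digest <- function(sequence, peaks, epitopes = NULL,
                                  numbering_offset = 1L,
                                  digest = digest_config(),
                                  match = match_config(),
                                  out_dir = NULL) {
  construct <- if (inherits(sequence, "protein_construct")) sequence else {
    if (!file.exists(sequence)) {
      stop("[sequence] FASTA file not found: ", sequence, call. = FALSE)
    }
    read_construct(sequence, numbering_offset = numbering_offset)
  }

  series <- if (is.list(peaks) && all(vapply(peaks, inherits, logical(1),
                                             "peak_list"))) {
    peaks
  } else {
    if (!file.exists(peaks)) {
      stop("[peaks] manifest not found: ", peaks, call. = FALSE)
    }
    read_peak_manifest(peaks)
  }

  epi <- NULL
  if (!is.null(epitopes)) {
    if (inherits(epitopes, "epitope_set")) {
      epi <- epitopes
    } else if (file.exists(epitopes)) {
      epi <- read_epitopes(epitopes)
    } else {
      warning("epitope table not found (", epitopes,
              "); overlap step skipped", call. = FALSE)
    }
  }

  candidates <- enumerate_fragments(construct, digest)
  matches <- lapply(series, match_pairs, candidates = candidates,
                    config = match)
  summary <- summarize_digest(matches)

  paired_frags <- summary$fragments[summary$fragments$n_paired > 0, ,
                                    drop = FALSE]
  timecourses <- lapply(seq_len(nrow(paired_frags)), function(i) {
    frag <- candidates[candidates$start == paired_frags$start[i] &
                       candidates$end == paired_frags$end[i], , drop = FALSE]
    tc <- ratio_timecourse(series, frag, match)
    tc$start <- paired_frags$start[i]
    tc$end <- paired_frags$end[i]
    tc
  })
  timecourses <- if (length(timecourses)) dplyr::bind_rows(timecourses) else
    NULL

  overlaps <- if (!is.null(epi)) {
    observed <- summary$fragments
    overlap_report(observed, construct, epi)
  } else NULL

  result <- structure(
    list(construct = construct, candidates = candidates, matches = matches,
         summary = summary, timecourses = timecourses, overlaps = overlaps),
    class = "digest_run"
  )

  if (!is.null(out_dir)) .write_digest_run(result, match, digest, out_dir)
  result
}

.write_digest_run <- function(result, match, digest, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  on_fail <- function(e) {
    unlink(written)
    stop("[output] failed while writing reports: ", conditionMessage(e),
         call. = FALSE)
  }
  tryCatch({
    emit <- function(df, name) {
      p <- file.path(out_dir, name)
      utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
      written <<- c(written, p)
    }
    emit(result$candidates, "candidate_fragments.tsv")
    pairs <- dplyr::bind_rows(lapply(result$matches, function(m) {
      if (nrow(m$pairs)) dplyr::mutate(m$pairs, timepoint = m$timepoint)
      else NULL
    }))
    emit(pairs, "pairs.tsv")
    emit(result$summary$fragments, "digest_summary.tsv")
    if (!is.null(result$timecourses)) emit(result$timecourses,
                                           "ratio_timecourses.tsv")
    if (!is.null(result$overlaps)) emit(result$overlaps,
                                        "epitope_overlaps.tsv")
    log_path <- file.path(out_dir, "run_log.txt")
    writeLines(c(
      sprintf("allerquant %s", as.character(utils::packageVersion("allerquant"))),
      sprintf("R %s", as.character(getRversion())),
      sprintf("date: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
      sprintf("construct: %s (%d residues, offset %d)",
              result$construct$id, nchar(result$construct$sequence),
              result$construct$numbering_offset),
      sprintf("digest: lengths %d-%d, window %g-%g Da, %s, enrichment %g, %s masses",
              digest$min_length, digest$max_length, digest$mz_min,
              digest$mz_max, digest$specificity, digest$enrichment,
              digest$mass_type),
      sprintf("match: tolerance %g %s, policy %s", match$tolerance,
              match$unit, match$ambiguity_policy),
      sprintf("timepoints: %s",
              paste(vapply(result$matches, function(m) m$timepoint,
                           numeric(1)), collapse = ", ")),
      sprintf("tallies: %d paired, %d NA-only, %d 15N-only",
              result$summary$tallies["paired"],
              result$summary$tallies["na_only"],
              result$summary$tallies["n15_only"])
    ), log_path)
    written <- c(written, log_path)
  }, error = on_fail)
  invisible(out_dir)
}

#' @export
print.digest_run <- function(x, ...) {
  cat(sprintf(
    "<digest_run> %s: %d candidates, %d timepoints; %d paired / %d NA-only / %d 15N-only fragments\n",
    x$construct$id, nrow(x$candidates), length(x$matches),
    x$summary$tallies["paired"], x$summary$tallies["na_only"],
    x$summary$tallies["n15_only"]))
  if (!is.null(x$overlaps)) {
    cat(sprintf("  %d fragment-epitope overlaps\n", nrow(x$overlaps)))
  }
  invisible(x)
}
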