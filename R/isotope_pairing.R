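#' Centroided MALDI peak list for one digestion timepoint
#'
#' @param mz Numeric vector of centroid m/z values in Da, sorted ascending.
#' @param intensity Non-negative intensities (arbitrary units, internally
#'   comparable within one pooled spectrum).
#' @param timepoint Digestion time in minutes (>= 0).
#' @return An object of class `peak_list` with fields `timepoint` and `peaks`
#'   (a tibble with columns `mz`, `intensity`).
#' @export
peak_list <- function(mz, intensity, timepoint = 0) {
  stopifnot(length(mz) == length(intensity))
  if (is.unsorted(mz, strictly = FALSE)) {
    stop("peak m/z values must be sorted ascending", call. = FALSE)
  }
  if (any(intensity < 0)) stop("intensities must be non-negative", call. = FALSE)
  if (timepoint < 0) stop("timepoint must be >= 0", call. = FALSE)
  structure(
    list(timepoint = as.numeric(timepoint),
         peaks = tibble::tibble(mz = as.numeric(mz),
                                intensity = as.numeric(intensity))),
    class = "peak_list"
  )
}

#' @export
print.peak_list <- function(x, ...) {
  cat(sprintf("<peak_list> t = %g min, %d peaks (m/z %.1f-%.1f)\n",
              x$timepoint, nrow(x$peaks),
              if (nrow(x$peaks)) min(x$peaks$mz) else NA,
              if (nrow(x$peaks)) max(x$peaks$mz) else NA))
  invisible(x)
}

#' Read a peak list from a two-column (mz, intensity) CSV/TSV file
#'
#' @param path File path; tab- or comma-separated, with or without a header
#'   line naming the columns `mz` and `intensity`.
#' @param timepoint Digestion time in minutes attached to the list.
#' @return A [peak_list()].
#' @export
read_peak_list <- function(path, timepoint = 0) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  header <- grepl("[A-Za-z]", first)
  df <- utils::read.table(path, sep = sep, header = header,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("peak list needs two columns (mz, intensity)",
                          call. = FALSE)
  names(df)[1:2] <- c("mz", "intensity")
  ord <- order(df$mz)
  peak_list(df$mz[ord], df$intensity[ord], timepoint = timepoint)
}

#' Read a manifest of peak-list files
#'
#' The manifest is a CSV/TSV with columns `path` and `timepoint` (minutes);
#' relative paths are resolved against the manifest's directory.
#'
#' @param path Manifest file path.
#' @return A list of [peak_list()] objects sorted by timepoint.
#' @export
read_peak_manifest <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE)
  if (!all(c("path", "timepoint") %in% names(df))) {
    stop("manifest needs columns 'path' and 'timepoint'", call. = FALSE)
  }
  base <- dirname(path)
  df <- df[order(df$timepoint), , drop = FALSE]
  lapply(seq_len(nrow(df)), function(i) {
    p <- df$path[i]
    if (!file.exists(p)) p <- file.path(base, p)
    read_peak_list(p, timepoint = df$timepoint[i])
  })
}

#' Peak-matching settings
#'
#' @param tolerance Match tolerance (> 0); the default 0.3 Da reflects
#'   reflector-MALDI accuracy on 1-4 kDa peptides.
#' @param unit `"da"` for an absolute window or `"ppm"` for a relative one.
#' @param ambiguity_policy `"report_all"` emits every candidate-peak match and
#'   flags peaks shared between candidates; `"nearest"` greedily consumes each
#'   peak by its closest-mass candidate so every peak supports at most one.
#' @return An object of class `match_config`.
#' @export
match_config <- function(tolerance = 0.3, unit = c("da", "ppm"),
                         ambiguity_policy = c("report_all", "nearest")) {
  unit <- match.arg(unit)
  ambiguity_policy <- match.arg(ambiguity_policy)
  if (!(tolerance > 0)) stop("tolerance must be > 0", call. = FALSE)
  structure(list(tolerance = tolerance, unit = unit,
                 ambiguity_policy = ambiguity_policy),
            class = "match_config")
}

.tol_da <- function(mass, config) {
  if (config$unit == "ppm") mass * config$tolerance / 1e6 else config$tolerance
}

# indices of peaks within tolerance of a theoretical mass, closest first
.matching_peaks <- function(mass, peaks, config) {
  tol <- .tol_da(mass, config)
  d <- abs(peaks$mz - mass)
  idx <- which(d <= tol)
  idx[order(d[idx])]
}

#' Match natural-abundance/15N isotope pairs against candidate fragments
#'
#' In a pooled spectrum of separately digested natural-abundance (apo) and
#' uniformly 15N-labeled (cargo-loaded) protein, each peptide that is produced
#' in both reactions appears as a peak pair separated by
#' `enrichment * n_count * 0.9970349` Da; the intensity ratio of the pair
#' measures the relative digestion of the two states. A candidate whose two
#' label masses both match (distinct) peaks within tolerance is emitted as a
#' pair; candidates matching only one channel are reported as `na_only` or
#' `n15_only` rather than silently dropped.
#'
#' @param peaklist A [peak_list()].
#' @param candidates Fragment table from [enumerate_fragments()] (must carry
#'   `mass_na` and `mass_15n`).
#' @param config A [match_config()].
#' @return A list with class `pair_match`: `pairs` (tibble with observed m/z,
#'   intensities, `ratio` = intensity_15n / intensity_na, NA when the
#'   denominator is zero, and an `ambiguous` flag), `na_only`, `n15_only`,
#'   and `timepoint`.
#' @export
match_pairs <- function(peaklist, candidates, config = match_config()) {
  stopifnot(inherits(peaklist, "peak_list"), inherits(config, "match_config"))
  peaks <- peaklist$peaks
  if (is.unsorted(peaks$mz)) {
    stop("peak list must be sorted ascending by m/z", call. = FALSE)
  }
  if (nrow(candidates) == 0L) {
    return(.pair_match(.empty_pairs(), .empty_single(), .empty_single(),
                       peaklist$timepoint))
  }

  if (config$ambiguity_policy == "nearest") {
    return(.match_pairs_nearest(peaklist, candidates, config))
  }

  na_hits <- lapply(candidates$mass_na, .matching_peaks, peaks = peaks,
                    config = config)
  n15_hits <- lapply(candidates$mass_15n, .matching_peaks, peaks = peaks,
                     config = config)
  # how many candidates claim each peak (for the ambiguity flag)
  usage <- tabulate(unlist(c(na_hits, n15_hits)), nbins = nrow(peaks))

  pair_rows <- list(); na_rows <- list(); n15_rows <- list()
  for (i in seq_len(nrow(candidates))) {
    na_i <- na_hits[[i]]; n15_i <- n15_hits[[i]]
    combos <- expand.grid(na = na_i, n15 = n15_i)
    combos <- combos[combos$na != combos$n15, , drop = FALSE]
    if (nrow(combos) > 0L) {
      amb <- usage[combos$na] > 1L | usage[combos$n15] > 1L | nrow(combos) > 1L
      pair_rows[[length(pair_rows) + 1L]] <- tibble::tibble(
        candidates[rep(i, nrow(combos)), , drop = FALSE],
        mz_na_obs = peaks$mz[combos$na],
        mz_15n_obs = peaks$mz[combos$n15],
        intensity_na = peaks$intensity[combos$na],
        intensity_15n = peaks$intensity[combos$n15],
        ratio = ifelse(peaks$intensity[combos$na] > 0,
                       peaks$intensity[combos$n15] / peaks$intensity[combos$na],
                       NA_real_),
        ambiguous = amb
      )
    } else if (length(na_i) > 0L) {
      na_rows[[length(na_rows) + 1L]] <- tibble::tibble(
        candidates[i, , drop = FALSE],
        mz_obs = peaks$mz[na_i[1]],
        intensity = peaks$intensity[na_i[1]]
      )
    } else if (length(n15_i) > 0L) {
      n15_rows[[length(n15_rows) + 1L]] <- tibble::tibble(
        candidates[i, , drop = FALSE],
        mz_obs = peaks$mz[n15_i[1]],
        intensity = peaks$intensity[n15_i[1]]
      )
    }
  }
  .pair_match(
    if (length(pair_rows)) dplyr::bind_rows(pair_rows) else .empty_pairs(),
    if (length(na_rows)) dplyr::bind_rows(na_rows) else .empty_single(),
    if (length(n15_rows)) dplyr::bind_rows(n15_rows) else .empty_single(),
    peaklist$timepoint
  )
}

# greedy nearest assignment: every (candidate-channel, peak) match sorted by
# mass error; each peak consumed once, each candidate channel filled once
.match_pairs_nearest <- function(peaklist, candidates, config) {
  peaks <- peaklist$peaks
  edges <- list()
  for (i in seq_len(nrow(candidates))) {
    for (channel in c("na", "n15")) {
      mass <- if (channel == "na") candidates$mass_na[i] else candidates$mass_15n[i]
      idx <- .matching_peaks(mass, peaks, config)
      if (length(idx)) {
        edges[[length(edges) + 1L]] <- data.frame(
          cand = i, channel = channel, peak = idx,
          err = abs(peaks$mz[idx] - mass)
        )
      }
    }
  }
  assign_na <- rep(NA_integer_, nrow(candidates))
  assign_n15 <- rep(NA_integer_, nrow(candidates))
  if (length(edges)) {
    edges <- do.call(rbind, edges)
    edges <- edges[order(edges$err), , drop = FALSE]
    used <- logical(nrow(peaks))
    for (j in seq_len(nrow(edges))) {
      e <- edges[j, ]
      if (used[e$peak]) next
      if (e$channel == "na" && is.na(assign_na[e$cand])) {
        assign_na[e$cand] <- e$peak; used[e$peak] <- TRUE
      } else if (e$channel == "n15" && is.na(assign_n15[e$cand])) {
        assign_n15[e$cand] <- e$peak; used[e$peak] <- TRUE
      }
    }
  }
  both <- which(!is.na(assign_na) & !is.na(assign_n15))
  na_only <- which(!is.na(assign_na) & is.na(assign_n15))
  n15_only <- which(is.na(assign_na) & !is.na(assign_n15))
  pairs <- if (length(both)) {
    tibble::tibble(
      candidates[both, , drop = FALSE],
      mz_na_obs = peaks$mz[assign_na[both]],
      mz_15n_obs = peaks$mz[assign_n15[both]],
      intensity_na = peaks$intensity[assign_na[both]],
      intensity_15n = peaks$intensity[assign_n15[both]],
      ratio = ifelse(peaks$intensity[assign_na[both]] > 0,
                     peaks$intensity[assign_n15[both]] /
                       peaks$intensity[assign_na[both]],
                     NA_real_),
      ambiguous = FALSE
    )
  } else .empty_pairs()
  single <- function(ids, assign) {
    if (!length(ids)) return(.empty_single())
    tibble::tibble(candidates[ids, , drop = FALSE],
                   mz_obs = peaks$mz[assign[ids]],
                   intensity = peaks$intensity[assign[ids]])
  }
  .pair_match(pairs, single(na_only, assign_na), single(n15_only, assign_n15),
              peaklist$timepoint)
}

.pair_match <- function(pairs, na_only, n15_only, timepoint) {
  structure(list(pairs = pairs, na_only = na_only, n15_only = n15_only,
                 timepoint = timepoint),
            class = "pair_match")
}

#' @export
print.pair_match <- function(x, ...) {
  cat(sprintf("<pair_match> t = %g min: %d pairs, %d NA-only, %d 15N-only\n",
              x$timepoint, nrow(x$pairs), nrow(x$na_only), nrow(x$n15_only)))
  invisible(x)
}

.empty_pairs <- function() {
  tibble::tibble(
    .empty_fragment_table(),
    mz_na_obs = numeric(), mz_15n_obs = numeric(),
    intensity_na = numeric(), intensity_15n = numeric(),
    ratio = numeric(), ambiguous = logical()
  )
}

.empty_single <- function() {
  tibble::tibble(.empty_fragment_table(),
                 mz_obs = numeric(), intensity = numeric())
}

#' 15N:NA intensity ratio of one fragment over a digestion time-course
#'
#' Follows a single isotope pair (e.g. the 981.6/991.6 epitope fragment)
#' across timepoints. Timepoints where either partner is missing within
#' tolerance are reported as censored entries, never dropped or zero-imputed.
#'
#' @param series List of [peak_list()] objects (one per timepoint).
#' @param fragment One-row fragment table (or any list with `mass_na` and
#'   `mass_15n`).
#' @param config A [match_config()].
#' @return A tibble with columns `timepoint`, `intensity_na`,
#'   `intensity_15n`, `ratio`, `censored`.
#' @export
ratio_timecourse <- function(series, fragment, config = match_config()) {
  stopifnot(length(series) >= 1L)
  if (is.data.frame(fragment)) {
    stopifnot(nrow(fragment) == 1L)
    fragment <- as.list(fragment)
  }
  rows <- lapply(series, function(pl) {
    stopifnot(inherits(pl, "peak_list"))
    peaks <- pl$peaks
    na_i <- .matching_peaks(fragment$mass_na, peaks, config)
    n15_i <- .matching_peaks(fragment$mass_15n, peaks, config)
    if (length(na_i) && length(n15_i) && na_i[1] != n15_i[1]) {
      ina <- peaks$intensity[na_i[1]]
      i15 <- peaks$intensity[n15_i[1]]
      tibble::tibble(timepoint = pl$timepoint, intensity_na = ina,
                     intensity_15n = i15,
                     ratio = if (ina > 0) i15 / ina else NA_real_,
                     censored = FALSE)
    } else {
      tibble::tibble(timepoint = pl$timepoint, intensity_na = NA_real_,
                     intensity_15n = NA_real_, ratio = NA_real_,
                     censored = TRUE)
    }
  })
  dplyr::arrange(dplyr::bind_rows(rows), .data$timepoint)
}

#' Summarize a digestion time-course of pair matches
#'
#' Aggregates [match_pairs()] results over timepoints into a per-fragment
#' table (keyed by construct interval) of mean ratio and censoring counts,
#' plus overall tallies of fragments observed as pairs, NA-only (present in
#' the apo digestion only), and 15N-only.
#'
#' @param pairs_by_time List of `pair_match` objects from [match_pairs()],
#'   one per timepoint.
#' @return An object of class `digest_summary`: `fragments` (tibble with
#'   `start`, `end`, `sequence`, `n_paired`, `n_censored`, `n_na_only`,
#'   `n_n15_only`, `mean_ratio`), `tallies` (named vector `paired`,
#'   `na_only`, `n15_only` counting distinct fragments by their best
#'   observation status), and `n_timepoints`.
#' @export
summarize_digest <- function(pairs_by_time) {
  stopifnot(length(pairs_by_time) >= 1L)
  n_t <- length(pairs_by_time)
  paired <- dplyr::bind_rows(lapply(pairs_by_time, function(m) m$pairs))
  naonly <- dplyr::bind_rows(lapply(pairs_by_time, function(m) m$na_only))
  n15only <- dplyr::bind_rows(lapply(pairs_by_time, function(m) m$n15_only))

  key <- function(df) if (nrow(df)) paste(df$start, df$end) else character()
  all_keys <- unique(c(key(paired), key(naonly), key(n15only)))
  seqs <- c(paired$sequence, naonly$sequence, n15only$sequence)
  names(seqs) <- c(key(paired), key(naonly), key(n15only))

  rows <- lapply(all_keys, function(k) {
    se <- as.integer(strsplit(k, " ")[[1]])
    in_pair <- key(paired) == k
    ratios <- paired$ratio[in_pair]
    ratios <- ratios[!is.na(ratios)]
    n_p <- sum(in_pair)
    tibble::tibble(
      start = se[1], end = se[2],
      sequence = unname(seqs[k]),
      n_paired = n_p,
      n_censored = n_t - n_p,
      n_na_only = sum(key(naonly) == k),
      n_n15_only = sum(key(n15only) == k),
      mean_ratio = if (length(ratios)) mean(ratios) else NA_real_
    )
  })
  fragments <- dplyr::arrange(dplyr::bind_rows(rows), .data$start, .data$end)

  status <- with(fragments, ifelse(n_paired > 0, "paired",
                            ifelse(n_na_only > 0, "na_only", "n15_only")))
  tallies <- c(paired = sum(status == "paired"),
               na_only = sum(status == "na_only"),
               n15_only = sum(status == "n15_only"))
  structure(list(fragments = fragments, tallies = tallies,
                 n_timepoints = n_t),
            class = "digest_summary")
}

#' @export
print.digest_summary <- function(x, ...) {
  cat(sprintf(
    "<digest_summary> %d timepoints: %d paired, %d NA-only, %d 15N-only fragments\n",
    x$n_timepoints, x$tallies["paired"], x$tallies["na_only"],
    x$tallies["n15_only"]))
  invisible(x)
}
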