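# Seeded generators for every input the pipeline consumes. Each generator is
# a pure function of its arguments (including the seed): identical calls give
# identical output, and noiseless settings admit exact closed-loop recovery.

#' Configuration for a simulated paired-label digestion experiment
#'
#' Defines a ground-truth digestion time-course in the two-channel
#' (natural-abundance apo / uniformly 15N-labeled cargo-loaded) design. Each
#' true fragment appears with first-order kinetics: the NA channel intensity
#' is `A * (1 - exp(-k t))` and the 15N channel `A * (1 - exp(-rho k t))`,
#' where `rho` in (0, 1] is the loaded-state rate multiplier (cargo loading
#' slows proteolysis). A configurable subset of fragments is cleavable only
#' in the apo channel (NA-only), mirroring cryptic cut sites accessible only
#' in the unloaded protein. The default design has 20 paired and 6 NA-only
#' fragments — the fragment-assignment pattern observed in the 4 h cathepsin S
#' digest of Bla g 1 — with a rate multiplier of 0.7 and a digestion rate
#' constant (0.002 min^-1) that places the 4 h timepoint mid-course, so the
#' 15N products trail their NA counterparts by roughly 20-40% at 4 h and the
#' ratio converges toward (but not to) 1 by 24 h.
#'
#' @param construct A [protein_construct()] from which true fragments are
#'   drawn.
#' @param digest A [digest_config()] defining the candidate space and the
#'   acquisition window.
#' @param true_fragments,na_only_fragments Optional two-column matrices or
#'   data frames of construct-relative (start, end) intervals. When NULL,
#'   `n_paired` + `n_na_only` fragments are drawn (seeded) from the candidate
#'   space with all label masses mutually separated by
#'   `min_mass_separation` Da so that noiseless matching is unambiguous.
#' @param n_paired,n_na_only Number of paired / NA-only fragments to draw.
#' @param k First-order digestion rate constant(s), min^-1 (recycled).
#' @param rho Loaded-state rate multiplier in (0, 1].
#' @param plateaus Per-fragment plateau intensities (recycled).
#' @param timepoints Sampling times in minutes.
#' @param mz_jitter_sd Gaussian m/z jitter SD in Da.
#' @param intensity_noise_cv Lognormal intensity noise CV (fraction).
#' @param n_decoys Unassignable decoy peaks per spectrum, uniform in the
#'   acquisition window.
#' @param min_mass_separation Minimum spacing (Da) enforced between all true
#'   label masses during automatic fragment selection.
#' @param seed Integer seed; the experiment is a pure function of
#'   (config, seed).
#' @return An object of class `digest_sim_config`.
#' @export
digest_sim_config <- function(construct, digest = digest_config(),
                              true_fragments = NULL,
                              na_only_fragments = NULL,
                              n_paired = 20L, n_na_only = 6L,
                              k = 0.002, rho = 0.7, plateaus = 1000,
                              timepoints = c(30, 60, 120, 240, 480, 1440),
                              mz_jitter_sd = 0.05,
                              intensity_noise_cv = 0.05,
                              n_decoys = 10L,
                              min_mass_separation = 2.5,
                              seed = 1L) {
  stopifnot(inherits(construct, "protein_construct"),
            inherits(digest, "digest_config"))
  if (!(rho > 0 && rho <= 1)) stop("rho must lie in (0, 1]", call. = FALSE)
  if (any(k <= 0)) stop("rate constants must be > 0", call. = FALSE)
  if (mz_jitter_sd < 0 || intensity_noise_cv < 0) {
    stop("jitter and noise must be >= 0", call. = FALSE)
  }

  fragments <- .resolve_sim_fragments(construct, digest, true_fragments,
                                      na_only_fragments, n_paired, n_na_only,
                                      min_mass_separation, seed)
  n_frag <- nrow(fragments)
  fragments$k <- rep_len(k, n_frag)
  fragments$plateau <- rep_len(plateaus, n_frag)

  structure(
    list(construct = construct, digest = digest, fragments = fragments,
         rho = rho, timepoints = as.numeric(timepoints),
         mz_jitter_sd = mz_jitter_sd,
         intensity_noise_cv = intensity_noise_cv,
         n_decoys = as.integer(n_decoys), seed = as.integer(seed)),
    class = "digest_sim_config"
  )
}

.resolve_sim_fragments <- function(construct, digest, true_fragments,
                                   na_only_fragments, n_paired, n_na_only,
                                   min_sep, seed) {
  if (!is.null(true_fragments)) {
    tf <- .intervals_to_fragments(construct, digest, true_fragments)
    tf$role <- "paired"
    if (!is.null(na_only_fragments)) {
      nf <- .intervals_to_fragments(construct, digest, na_only_fragments)
      nf$role <- "na_only"
      tf <- dplyr::bind_rows(tf, nf)
    }
    return(tf)
  }
  candidates <- enumerate_fragments(construct, digest)
  n_want <- n_paired + n_na_only
  if (nrow(candidates) < n_want) {
    stop("candidate space too small: ", nrow(candidates), " fragments for ",
         n_want, " requested", call. = FALSE)
  }
  sel <- withr::with_seed(seed, {
    perm <- sample.int(nrow(candidates))
    chosen <- integer(0)
    masses <- numeric(0)
    for (i in perm) {
      m <- c(candidates$mass_na[i], candidates$mass_15n[i])
      if (length(masses) == 0L || min(abs(outer(m, masses, "-"))) >= min_sep) {
        chosen <- c(chosen, i)
        masses <- c(masses, m)
        if (length(chosen) == n_want) break
      }
    }
    chosen
  })
  if (length(sel) < n_want) {
    stop("could not draw ", n_want, " fragments with label masses separated by ",
         min_sep, " Da; lower min_mass_separation or the fragment count",
         call. = FALSE)
  }
  out <- candidates[sel, , drop = FALSE]
  out$role <- rep(c("paired", "na_only"), c(n_paired, n_na_only))
  out
}

.intervals_to_fragments <- function(construct, digest, intervals) {
  intervals <- as.data.frame(intervals)
  names(intervals)[1:2] <- c("start", "end")
  seqs <- substring(construct$sequence, intervals$start, intervals$end)
  mass_na <- peptide_mass(seqs, digest, label = "na")
  outside <- mass_na < digest$mz_min | mass_na > digest$mz_max
  if (any(outside)) {
    stop(sprintf(
      "fragment [%d,%d] has mass %.2f Da outside the acquisition window [%g, %g]",
      intervals$start[which(outside)[1]], intervals$end[which(outside)[1]],
      mass_na[which(outside)[1]], digest$mz_min, digest$mz_max), call. = FALSE)
  }
  off <- construct$numbering_offset
  tibble::tibble(
    start = as.integer(intervals$start), end = as.integer(intervals$end),
    full_start = as.integer(intervals$start) + off - 1L,
    full_end = as.integer(intervals$end) + off - 1L,
    sequence = seqs,
    n_count = nitrogen_count(seqs),
    mass_na = mass_na,
    mass_15n = peptide_mass(seqs, digest, label = "n15")
  )
}

# lognormal multiplicative noise with unit mean and given CV
.lognoise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Expected 15N:NA ratio under first-order digestion kinetics
#'
#' With equal plateaus the noiseless intensity ratio of a paired fragment is
#' `(1 - exp(-rho k t)) / (1 - exp(-k t))`: close to `rho` at early times and
#' converging to 1 from below as both reactions reach completion.
#'
#' @param t Time in minutes (> 0).
#' @param k First-order rate constant, min^-1.
#' @param rho Loaded-state rate multiplier.
#' @return Numeric vector of expected ratios.
#' @export
expected_pair_ratio <- function(t, k, rho) {
  (1 - exp(-rho * k * t)) / (1 - exp(-k * t))
}

#' Simulate a paired-label MALDI digestion time-course
#'
#' Generates one pooled, centroided peak list per timepoint plus a
#' ground-truth manifest. Paired fragments contribute an NA peak and a
#' 15N-shifted peak with first-order appearance kinetics (loaded channel
#' slowed by `rho`); NA-only fragments contribute only their NA peak; decoy
#' peaks fall uniformly in the acquisition window. Intensities carry
#' lognormal noise with the configured CV and m/z values Gaussian jitter;
#' both default off for closed-loop tests. Zero-intensity peaks (t = 0) are
#' below detection and omitted.
#'
#' @param config A [digest_sim_config()].
#' @return A list with class `digest_experiment`: `peaklists` (list of
#'   [peak_list()], one per timepoint) and `manifest` (ground truth: the
#'   fragment table with roles, rates and plateaus, plus `rho`,
#'   `timepoints` and the generating seed).
#' @export
gen_digest_experiment <- function(config) {
  stopifnot(inherits(config, "digest_sim_config"))
  frag <- config$fragments
  rho <- config$rho
  peaklists <- withr::with_seed(config$seed + 1L, {
    lapply(config$timepoints, function(t) {
      na_int <- frag$plateau * (1 - exp(-frag$k * t)) *
        .lognoise(nrow(frag), config$intensity_noise_cv)
      n15_int <- frag$plateau * (1 - exp(-rho * frag$k * t)) *
        .lognoise(nrow(frag), config$intensity_noise_cv)
      n15_int[frag$role == "na_only"] <- 0
      mz <- c(frag$mass_na + stats::rnorm(nrow(frag), 0, config$mz_jitter_sd),
              frag$mass_15n + stats::rnorm(nrow(frag), 0, config$mz_jitter_sd))
      intensity <- c(na_int, n15_int)
      if (config$n_decoys > 0L) {
        mz <- c(mz, stats::runif(config$n_decoys, config$digest$mz_min,
                                 config$digest$mz_max))
        intensity <- c(intensity,
                       stats::runif(config$n_decoys, 0.05, 0.5) *
                         mean(frag$plateau))
      }
      keep <- intensity > 0
      ord <- order(mz[keep])
      peak_list(mz[keep][ord], intensity[keep][ord], timepoint = t)
    })
  })
  structure(
    list(peaklists = peaklists,
         manifest = list(fragments = frag, rho = rho,
                         timepoints = config$timepoints,
                         seed = config$seed)),
    class = "digest_experiment"
  )
}

#' Write a simulated digestion experiment to disk
#'
#' Emits one two-column CSV peak list per timepoint, a `manifest.csv`
#' (path, timepoint) indexing them, and a `ground_truth.json` with the
#' generating fragment table and kinetic parameters — the same dialects the
#' package's readers consume.
#'
#' @param experiment A [gen_digest_experiment()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_digest_experiment <- function(experiment, dir) {
  stopifnot(inherits(experiment, "digest_experiment"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(experiment$peaklists, function(pl) {
    fn <- sprintf("peaks_t%04d.csv", as.integer(pl$timepoint))
    utils::write.csv(pl$peaks, file.path(dir, fn), row.names = FALSE)
    data.frame(path = fn, timepoint = pl$timepoint)
  })
  utils::write.csv(do.call(rbind, rows), file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(fragments = experiment$manifest$fragments,
         rho = experiment$manifest$rho,
         timepoints = experiment$manifest$timepoints,
         seed = experiment$manifest$seed),
    file.path(dir, "ground_truth.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' Generate a synthetic two-state thermal melt curve
#'
#' Boltzmann signal over a temperature grid (default 25-95 degrees C, the
#' usual CD melt acquisition range) with multiplicative Gaussian noise.
#'
#' @param t_half Transition midpoint, degrees C.
#' @param width Transition width parameter, degrees C (> 0).
#' @param baseline_folded,baseline_unfolded Signal baselines (the defaults
#'   mimic negative 222 nm ellipticity shrinking in magnitude on unfolding).
#' @param noise_cv Multiplicative Gaussian noise CV (fraction).
#' @param n_points Number of points on the grid (>= 8).
#' @param t_min,t_max Temperature range, degrees C.
#' @param seed Integer seed.
#' @param label Curve label.
#' @return A [melt_curve()].
#' @export
gen_melt_curve <- function(t_half = 70, width = 3,
                           baseline_folded = -20, baseline_unfolded = -2,
                           noise_cv = 0.01, n_points = 60,
                           t_min = 25, t_max = 95, seed = 1L,
                           label = "synthetic") {
  stopifnot(width > 0, n_points >= 8)
  temp <- seq(t_min, t_max, length.out = n_points)
  f <- .boltzmann_f(temp, t_half, width)
  signal <- baseline_folded + (baseline_unfolded - baseline_folded) * f
  signal <- withr::with_seed(seed, {
    signal * (1 + stats::rnorm(n_points, 0, noise_cv))
  })
  melt_curve(temp, signal, label = label)
}

#' Generate a synthetic SDS-PAGE densitometry table
#'
#' Substrate band fractions decline linearly with time and concentration at
#' the true concentration-normalized rate: `band_fraction =
#' clamp(1 - true_slope * conc * t * (1 + noise), 0, 1)`, with a t = 0 anchor
#' row per concentration. Defaults follow the proteolysis assay design
#' (5-75 uM substrate, 30 and 60 min samples); the default rate keeps all
#' points inside the linear range.
#'
#' @param true_slope Substrate loss per minute per uM (>= 0).
#' @param concentrations Substrate concentrations, uM.
#' @param timepoints Sampling times, minutes (> 0; a t = 0 anchor is added).
#' @param noise_cv Gaussian noise CV on the loss term.
#' @param condition Condition label.
#' @param seed Integer seed.
#' @return A densitometry tibble (see [read_densitometry()]).
#' @export
gen_densitometry <- function(true_slope = 1e-4,
                             concentrations = c(5, 25, 75),
                             timepoints = c(30, 60),
                             noise_cv = 0.05, condition = "sample",
                             seed = 1L) {
  stopifnot(true_slope >= 0, all(timepoints > 0))
  grid <- expand.grid(concentration_uM = concentrations,
                      time_min = timepoints)
  loss <- withr::with_seed(seed, {
    true_slope * grid$concentration_uM * grid$time_min *
      (1 + stats::rnorm(nrow(grid), 0, noise_cv))
  })
  obs <- tibble::tibble(
    condition = condition,
    concentration_uM = grid$concentration_uM,
    time_min = grid$time_min,
    band_fraction = pmin(pmax(1 - loss, 0), 1)
  )
  anchor <- tibble::tibble(condition = condition,
                           concentration_uM = concentrations,
                           time_min = 0, band_fraction = 1)
  dplyr::arrange(dplyr::bind_rows(anchor, obs),
                 .data$concentration_uM, .data$time_min)
}

#' Generate a synthetic 31P standard-curve series with bound samples
#'
#' Linear standard intensities with multiplicative noise, plus replicate
#' sample intensities implied by a true binding stoichiometry:
#' `intensity = slope * (true_stoichiometry * protein_mM) + intercept`. The
#' default stoichiometry of 4.7 lipids per protein matches the measured
#' phospholipid occupancy of the Bla g 1 cavity; three replicates mirror the
#' three-independent-trials design.
#'
#' @param slope,intercept True standard-curve parameters (slope > 0).
#' @param concentrations Standard concentrations, mM.
#' @param noise_cv Multiplicative Gaussian noise CV.
#' @param true_stoichiometry True lipids-per-protein ratio.
#' @param protein_mM Protein concentration, mM.
#' @param n_replicates Number of sample replicates.
#' @param seed Integer seed.
#' @return A list: `standards` (tibble with `concentration`, `intensity`),
#'   `sample_intensities`, `true_stoichiometry`, `protein_mM`.
#' @export
gen_standard_series <- function(slope = 3, intercept = 0,
                                concentrations = c(2, 4, 6, 8, 10, 12),
                                noise_cv = 0.05,
                                true_stoichiometry = 4.7, protein_mM = 2,
                                n_replicates = 3L, seed = 1L) {
  stopifnot(slope > 0, protein_mM > 0)
  withr::with_seed(seed, {
    std_int <- (slope * concentrations + intercept) *
      (1 + stats::rnorm(length(concentrations), 0, noise_cv))
    samp <- (slope * true_stoichiometry * protein_mM + intercept) *
      (1 + stats::rnorm(n_replicates, 0, noise_cv))
    list(
      standards = tibble::tibble(concentration = concentrations,
                                 intensity = std_int),
      sample_intensities = samp,
      true_stoichiometry = true_stoichiometry,
      protein_mM = protein_mM
    )
  })
}

#' Generate a random protein construct
#'
#' Draws residues from the canonical alphabet weighted toward a typical
#' globular composition; useful for property tests over many constructs.
#'
#' @param length Number of residues.
#' @param seed Integer seed.
#' @param id Construct id.
#' @param numbering_offset Full-protein position of residue 1.
#' @return A [protein_construct()].
#' @export
gen_construct <- function(length, seed = 1L, id = "synthetic",
                          numbering_offset = 1L) {
  weights <- c(G = 7, A = 8, S = 6, P = 5, V = 7, T = 5, C = 2, L = 9,
               I = 6, N = 4, D = 5, Q = 4, K = 6, E = 6, M = 2, H = 2,
               F = 4, R = 5, Y = 3, W = 1)
  seq <- withr::with_seed(seed, {
    paste(sample(names(weights), length, replace = TRUE,
                 prob = weights / sum(weights)), collapse = "")
  })
  protein_construct(seq, id = id, numbering_offset = numbering_offset)
}
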