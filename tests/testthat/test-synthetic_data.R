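test_that("generators are pure functions of config and seed", {
  con <- synthetic_construct()
  cfg <- digest_sim_config(con, mz_jitter_sd = 0.05,
                           intensity_noise_cv = 0.05, n_decoys = 8, seed = 4)
  e1 <- gen_digest_experiment(cfg)
  e2 <- gen_digest_experiment(cfg)
  expect_identical(e1, e2)
  e3 <- gen_digest_experiment(digest_sim_config(con, mz_jitter_sd = 0.05,
                                                intensity_noise_cv = 0.05,
                                                n_decoys = 8, seed = 5))
  expect_false(identical(e1$peaklists, e3$peaklists))

  expect_identical(gen_melt_curve(seed = 3), gen_melt_curve(seed = 3))
  expect_identical(gen_densitometry(seed = 3), gen_densitometry(seed = 3))
  expect_identical(gen_standard_series(seed = 3), gen_standard_series(seed = 3))
  expect_identical(gen_construct(40, seed = 3), gen_construct(40, seed = 3))
})

test_that("noiseless digestion experiments are recovered exactly (closed loop)", {
  con <- synthetic_construct()
  cfg <- digest_sim_config(con, mz_jitter_sd = 0, intensity_noise_cv = 0,
                           n_decoys = 0, seed = 11)
  exp1 <- gen_digest_experiment(cfg)
  truth <- cfg$fragments
  for (pl in exp1$peaklists) {
    res <- match_pairs(pl, truth, match_config(tolerance = 0.3))
    paired_truth <- truth[truth$role == "paired", ]
    na_truth <- truth[truth$role == "na_only", ]
    # recall: every true paired fragment is found as a pair
    expect_setequal(paste(res$pairs$start, res$pairs$end),
                    paste(paired_truth$start, paired_truth$end))
    # precision: nothing else is called a pair, nothing is ambiguous
    expect_false(any(res$pairs$ambiguous))
    expect_setequal(paste(res$na_only$start, res$na_only$end),
                    paste(na_truth$start, na_truth$end))
    expect_equal(nrow(res$n15_only), 0L)
  }
})

test_that("noiseless pair ratios follow first-order kinetics (ODE oracle)", {
  con <- synthetic_construct()
  k <- 0.008; rho <- 0.5
  cfg <- digest_sim_config(con, k = k, rho = rho, plateaus = 500,
                           mz_jitter_sd = 0, intensity_noise_cv = 0,
                           n_decoys = 0, seed = 13)
  exp1 <- gen_digest_experiment(cfg)
  # independent oracle: integrate dP/dt = k (A - P) numerically rather than
  # reusing the generator's exponential form
  times <- c(0, cfg$timepoints)
  ode <- deSolve::ode(
    y = c(na = 0, n15 = 0), times = times,
    func = function(t, y, p) {
      list(c(p$k * (p$A - y["na"]), p$rho * p$k * (p$A - y["n15"])))
    },
    parms = list(k = k, rho = rho, A = 500)
  )
  oracle_ratio <- ode[-1, "n15"] / ode[-1, "na"]

  frag <- cfg$fragments[cfg$fragments$role == "paired", ][1, ]
  tc <- ratio_timecourse(exp1$peaklists, frag, match_config())
  expect_equal(tc$ratio, unname(oracle_ratio), tolerance = 1e-6)
  # early ratio near rho, late ratio approaching 1 from below, non-decreasing
  expect_lt(abs(tc$ratio[1] - rho), 0.1)
  expect_true(all(tc$ratio <= 1 + 1e-12))
  expect_true(all(diff(tc$ratio) >= -1e-12))
})

test_that("explicit fragment intervals are honored and window violations rejected", {
  con <- synthetic_construct()
  cfg <- digest_sim_config(con, true_fragments = rbind(c(23, 31), c(40, 52)),
                           na_only_fragments = rbind(c(90, 101)), seed = 2)
  expect_equal(nrow(cfg$fragments), 3L)
  expect_equal(cfg$fragments$role, c("paired", "paired", "na_only"))
  expect_equal(cfg$fragments$sequence[1], "LAVIPWAIV")

  # a dipeptide is far below the m/z 800 acquisition floor
  expect_error(
    digest_sim_config(con, true_fragments = rbind(c(1, 2)), seed = 2),
    "outside the acquisition window"
  )
})

test_that("noiseless melt curves reproduce the Boltzmann model exactly", {
  curve <- gen_melt_curve(t_half = 65, width = 2.5, noise_cv = 0, seed = 6)
  f <- 1 / (1 + exp((65 - curve$points$temperature) / 2.5))
  expect_equal(curve$points$signal, -20 + (-2 - -20) * f, tolerance = 1e-12)
  expect_equal(nrow(curve$points), 60L)
})

test_that("noiseless standard series imply the true stoichiometry", {
  ss <- gen_standard_series(slope = 5, intercept = 2, noise_cv = 0,
                            true_stoichiometry = 3.3, protein_mM = 1.5,
                            seed = 8)
  expect_equal(ss$standards$intensity, 5 * ss$standards$concentration + 2)
  expect_equal(unique(ss$sample_intensities), 5 * 3.3 * 1.5 + 2)
})

test_that("automatic fragment selection keeps label masses well separated", {
  con <- synthetic_construct()
  cfg <- digest_sim_config(con, n_paired = 15, n_na_only = 5,
                           min_mass_separation = 2.5, seed = 19)
  masses <- sort(c(cfg$fragments$mass_na, cfg$fragments$mass_15n))
  expect_true(all(diff(masses) >= 2.5 - 1e-9))
})
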