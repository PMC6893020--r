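test_that("a single clean isotope pair is matched and ratioed", {
  pl <- peak_list(c(981.60, 991.57), c(1000, 750), timepoint = 240)
  cand <- fake_fragment(981.60, n_count = 10)
  res <- match_pairs(pl, cand, match_config(tolerance = 0.3))
  expect_equal(nrow(res$pairs), 1L)
  expect_equal(res$pairs$ratio, 0.75)
  expect_false(res$pairs$ambiguous)
  expect_equal(nrow(res$na_only), 0L)
})

test_that("tight tolerance still matches when theory agrees to sub-mDa", {
  # theoretical 15N partner: 981.60 + 10 * 0.9970349 = 991.5703; the observed
  # 991.57 differs by 0.00035, inside a 0.01 Da window
  pl <- peak_list(c(981.60, 991.57), c(1000, 750), timepoint = 240)
  cand <- fake_fragment(981.60, n_count = 10)
  res <- match_pairs(pl, cand, match_config(tolerance = 0.01))
  expect_equal(nrow(res$pairs), 1L)
  expect_equal(res$pairs$ratio, 0.75)
})

test_that("a candidate with a missing partner is censored to na_only", {
  pl <- peak_list(981.60, 1000, timepoint = 60)
  cand <- fake_fragment(981.60, n_count = 10)
  res <- match_pairs(pl, cand, match_config(tolerance = 0.3))
  expect_equal(nrow(res$pairs), 0L)
  expect_equal(nrow(res$na_only), 1L)
  expect_equal(res$na_only$intensity, 1000)
})

test_that("zero NA intensity flags the ratio as undefined", {
  pl <- peak_list(c(981.60, 991.57), c(0, 750), timepoint = 60)
  cand <- fake_fragment(981.60, n_count = 10)
  res <- match_pairs(pl, cand, match_config(tolerance = 0.3))
  expect_equal(nrow(res$pairs), 1L)
  expect_true(is.na(res$pairs$ratio))
})

test_that("unsorted peak lists are rejected", {
  expect_error(peak_list(c(991.57, 981.60), c(750, 1000)), "sorted")
})

test_that("empty candidate list yields empty results", {
  pl <- peak_list(981.60, 1000, timepoint = 60)
  res <- match_pairs(pl, fake_fragment(1, 1)[0, ], match_config())
  expect_equal(nrow(res$pairs), 0L)
  expect_equal(nrow(res$na_only), 0L)
})

test_that("enlarging tolerance never decreases the number of pairs", {
  con <- synthetic_construct()
  cfg <- digest_sim_config(con, mz_jitter_sd = 0.15,
                           intensity_noise_cv = 0.05, n_decoys = 15,
                           seed = 21)
  exp1 <- gen_digest_experiment(cfg)
  pl <- exp1$peaklists[[4]]
  n_prev <- -1L
  for (tol in c(0.05, 0.1, 0.2, 0.4, 0.8)) {
    n <- nrow(match_pairs(pl, cfg$fragments,
                          match_config(tolerance = tol))$pairs)
    expect_gte(n, n_prev)
    n_prev <- n
  }
})

test_that("emitted pairs are self-consistent with the label-shift model", {
  con <- synthetic_construct()
  cfg <- digest_sim_config(con, mz_jitter_sd = 0.05,
                           intensity_noise_cv = 0.05, n_decoys = 10,
                           seed = 33)
  exp1 <- gen_digest_experiment(cfg)
  tol <- 0.3
  for (pl in exp1$peaklists) {
    pairs <- match_pairs(pl, cfg$fragments,
                         match_config(tolerance = tol))$pairs
    if (nrow(pairs) == 0) next
    gap <- pairs$mz_15n_obs - pairs$mz_na_obs
    expect_true(all(abs(gap - pairs$n_count * 0.9970349) <= 2 * tol))
  }
})

test_that("ambiguity is flagged under report_all and resolved under nearest", {
  # two candidates 0.1 Da apart share peaks at 0.3 Da tolerance
  c1 <- fake_fragment(1000.00, n_count = 10, start = 1, end = 9)
  c2 <- fake_fragment(1000.10, n_count = 10, start = 2, end = 10)
  cands <- dplyr::bind_rows(c1, c2)
  pl <- peak_list(c(1000.00, 1009.97), c(100, 80), timepoint = 60)
  all_res <- match_pairs(pl, cands, match_config(tolerance = 0.3,
                                                 ambiguity_policy = "report_all"))
  expect_equal(nrow(all_res$pairs), 2L)
  expect_true(all(all_res$pairs$ambiguous))
  near <- match_pairs(pl, cands, match_config(tolerance = 0.3,
                                              ambiguity_policy = "nearest"))
  expect_equal(nrow(near$pairs), 1L)
  expect_equal(near$pairs$start, 1L)  # closest-mass candidate wins the peaks
  expect_false(near$pairs$ambiguous)
})

test_that("ratio timecourse divides elementwise and censors missing partners", {
  cand <- fake_fragment(981.60, n_count = 10)
  mk <- function(t, ina, i15) {
    if (is.na(i15)) peak_list(981.60, ina, timepoint = t)
    else peak_list(c(981.60, 991.57), c(ina, i15), timepoint = t)
  }
  series <- list(mk(60, 100, 60), mk(120, 200, 140), mk(240, 300, 270))
  tc <- ratio_timecourse(series, cand, match_config(tolerance = 0.3))
  expect_equal(tc$ratio, c(0.60, 0.70, 0.90))
  expect_false(any(tc$censored))

  series2 <- list(mk(60, 100, 60), mk(120, 200, NA))
  tc2 <- ratio_timecourse(series2, cand, match_config(tolerance = 0.3))
  expect_equal(tc2$censored, c(FALSE, TRUE))
  expect_true(is.na(tc2$ratio[2]))
})

test_that("digest summary averages ratios and counts censoring", {
  cand <- fake_fragment(981.60, n_count = 10)
  mk <- function(t, i15) peak_list(c(981.60, 991.57), c(100, i15),
                                   timepoint = t)
  matches <- lapply(list(mk(60, 60), mk(120, 70), mk(240, 90)),
                    match_pairs, candidates = cand,
                    config = match_config(tolerance = 0.3))
  s <- summarize_digest(matches)
  expect_equal(nrow(s$fragments), 1L)
  expect_equal(s$fragments$mean_ratio, mean(c(0.6, 0.7, 0.9)),
               tolerance = 1e-12)
  expect_equal(unname(s$tallies), c(1, 0, 0))

  # fragment never paired: row present, mean undefined, fully censored
  lone <- lapply(list(peak_list(981.60, 100, timepoint = 60),
                      peak_list(981.60, 100, timepoint = 120)),
                 match_pairs, candidates = cand,
                 config = match_config(tolerance = 0.3))
  s2 <- summarize_digest(lone)
  expect_equal(nrow(s2$fragments), 1L)
  expect_true(is.na(s2$fragments$mean_ratio))
  expect_equal(s2$fragments$n_censored, 2L)
  expect_equal(unname(s2$tallies), c(0, 1, 0))
})

test_that("the 20-paired / 6-NA-only design is recovered on noiseless data", {
  con <- synthetic_construct()
  cfg <- digest_sim_config(con, n_paired = 20, n_na_only = 6,
                           mz_jitter_sd = 0, intensity_noise_cv = 0,
                           n_decoys = 0, seed = 7)
  exp1 <- gen_digest_experiment(cfg)
  matches <- lapply(exp1$peaklists, match_pairs,
                    candidates = cfg$fragments, config = match_config())
  s <- summarize_digest(matches)
  expect_equal(unname(s$tallies), c(20, 6, 0))
})

test_that("peak lists and manifests round-trip through files", {
  dir <- withr::local_tempdir()
  con <- synthetic_construct()
  cfg <- digest_sim_config(con, timepoints = c(30, 240), seed = 5)
  exp1 <- gen_digest_experiment(cfg)
  write_digest_experiment(exp1, dir)
  back <- read_peak_manifest(file.path(dir, "manifest.csv"))
  expect_equal(length(back), 2L)
  expect_equal(back[[2]]$timepoint, 240)
  expect_equal(back[[1]]$peaks$mz, exp1$peaklists[[1]]$peaks$mz,
               tolerance = 1e-9)
  truth <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$rho, cfg$rho)
  expect_equal(nrow(truth$fragments), nrow(cfg$fragments))
})
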