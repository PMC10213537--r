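test_that("log response ratio matches direct evaluation and sign convention", {
  expect_equal(log_response_ratio(5.21, 5.38), log(5.38 / 5.21))
  expect_equal(round(log_response_ratio(5.21, 5.38), 6), 0.032109)
  expect_equal(log_response_ratio(7.3, 7.3), 0)
  expect_equal(log_response_ratio(2, 1), -log(2))
  expect_error(log_response_ratio(0, 1), "positive")
  expect_error(log_response_ratio(2, -1), "positive")
})

test_that("sampling variance matches its term-by-term definition", {
  expect_equal(sampling_variance(5, 0.5, 3, 5, 0.5, 3),
               0.25 / (3 * 25) * 2)
  # one arm with zero SD drops its term
  expect_equal(sampling_variance(5, 0.5, 3, 5, 0, 3), 0.25 / (3 * 25))
  # v is inversely proportional to replicate counts, term by term
  expect_equal(sampling_variance(5, 0.5, 6, 5, 0.5, 6),
               sampling_variance(5, 0.5, 3, 5, 0.5, 3) / 2)
})

test_that("variance agrees with a literal transcription on random records", {
  recs <- random_records(200, seed = 7)
  eff <- effect_sizes(recs, var_floor = 0)
  expected <- oracle_variance(recs$sd_npkm, recs$n_npkm, recs$mean_npkm,
                              recs$sd_npk, recs$n_npk, recs$mean_npk)
  expect_lt(max(abs(eff$variance - expected) / expected), 1e-12)
})

test_that("swapping arms negates the effect and preserves its variance", {
  recs <- random_records(50, seed = 11)
  swapped <- dplyr::mutate(recs,
                           mean_npk = recs$mean_npkm, sd_npk = recs$sd_npkm,
                           n_npk = recs$n_npkm, mean_npkm = recs$mean_npk,
                           sd_npkm = recs$sd_npk, n_npkm = recs$n_npk)
  a <- effect_sizes(recs); b <- effect_sizes(swapped)
  expect_equal(b$rr, -a$rr)
  expect_equal(b$variance, a$variance)
})

test_that("effect size and variance are invariant to unit rescaling", {
  recs <- random_records(50, seed = 13)
  scaled <- dplyr::mutate(recs, dplyr::across(
    c("mean_npk", "sd_npk", "mean_npkm", "sd_npkm"), ~ .x * 17.3))
  a <- effect_sizes(recs); b <- effect_sizes(scaled)
  expect_equal(b$rr, a$rr)
  expect_equal(b$variance, a$variance)
})

test_that("weight times variance is exactly one for every effect", {
  eff <- effect_sizes(random_records(100, seed = 17))
  expect_equal(eff$weight * eff$variance, rep(1, 100))
})

test_that("fixed-cv imputation fills missing SDs and flags them", {
  rec <- make_record(mean_npkm = 8.0, sd_npkm = NA_real_)
  out <- impute_missing_sd(rec, cv = 0.1)
  expect_equal(out$sd_npkm, 0.8)
  expect_true(out$sd_imputed)
  # complete records are untouched
  full <- make_record()
  out2 <- impute_missing_sd(full, cv = 0.1)
  expect_equal(out2$sd_npk, full$sd_npk)
  expect_false(out2$sd_imputed)
})

test_that("average-cv policy uses the stratum mean CV with fixed fallback", {
  db <- dplyr::bind_rows(
    make_record(study_id = "a", mean_npk = 10, sd_npk = 0.5,
                mean_npkm = 10, sd_npkm = 0.5),              # CV 0.05
    make_record(study_id = "b", mean_npk = 10, sd_npk = 1.5,
                mean_npkm = 10, sd_npkm = 1.5),              # CV 0.15
    make_record(study_id = "c", mean_npk = 10, sd_npk = NA_real_,
                mean_npkm = 20, sd_npkm = NA_real_)
  )
  out <- impute_missing_sd(db, cv = 0.1, policy = "average-cv")
  expect_equal(out$sd_npk[3], 0.10 * 10)   # stratum CVs {0.05, 0.15} -> 0.10
  expect_equal(out$sd_npkm[3], 0.10 * 20)
  # no complete record in the stratum: fixed-cv fallback with a warning
  lone <- make_record(crop = "rice", sd_npk = NA_real_, sd_npkm = NA_real_)
  expect_warning(fb <- impute_missing_sd(lone, cv = 0.1,
                                         policy = "average-cv"),
                 "falling back")
  expect_equal(fb$sd_npk, 0.1 * lone$mean_npk)
})

test_that("zero SD in both arms is floored and flagged, not infinite-weighted", {
  rec <- make_record(sd_npk = 0, sd_npkm = 0)
  eff <- effect_sizes(rec)
  expect_equal(eff$variance, 1e-6)
  expect_true(eff$var_floored)
  expect_true(is.finite(eff$weight))
})
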