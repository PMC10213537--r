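test_that("noiseless polynomial data are recovered exactly", {
  x <- seq(2, 96, length.out = 60)
  quad <- tibble::tibble(x = x, rr = 0.056 - 1e-4 * (x - 44)^2)
  cq <- fit_response_curve(quad, "x", form = "auto")
  expect_identical(cq$model_form, "quadratic")
  expect_equal(cq$r_squared, 1, tolerance = 1e-10)
  true_cf <- c(0.056 - 1e-4 * 44^2, 2e-4 * 44, -1e-4)
  expect_lt(max(abs(cq$coefficients - true_cf) / abs(true_cf)), 1e-8)
  expect_equal(cq$optimum_x, 44, tolerance = 1e-8)

  lin <- tibble::tibble(x = x, rr = 2e-4 * (x - 161))
  cl <- fit_response_curve(lin, "x", form = "auto")
  expect_identical(cl$model_form, "linear")
  expect_equal(cl$zero_crossing_x, NA_real_)  # 161 beyond observed range
  cl2 <- fit_response_curve(
    tibble::tibble(x = seq(61, 261, 5), rr = 2e-4 * (seq(61, 261, 5) - 161)),
    "x", form = "linear")
  expect_equal(cl2$zero_crossing_x, 161, tolerance = 1e-8)
})

test_that("pure-noise data yield a non-significant curve", {
  withr::with_seed(42, {
    d <- tibble::tibble(x = runif(200, 0, 100), rr = rnorm(200, 0, 0.05))
  })
  cur <- fit_response_curve(d, "x")
  expect_gt(cur$p_value, 0.01)
  expect_false(cur$significant)
})

test_that("optimum extraction honours curvature and range contracts", {
  # vertex identity on exact coefficients
  d <- tibble::tibble(x = seq(0, 100, 2),
                      rr = (0.056 - 1e-4 * 44^2) + 2e-4 * 44 * seq(0, 100, 2) -
                        1e-4 * seq(0, 100, 2)^2)
  cur <- fit_response_curve(d, "x", form = "quadratic")
  expect_equal(extract_optimum(cur), 44, tolerance = 1e-8)
  # upward-opening quadratic has no interior maximum
  up <- fit_response_curve(tibble::tibble(x = seq(0, 100, 2),
                                          rr = 1e-4 * (seq(0, 100, 2) - 50)^2),
                           "x", form = "quadratic")
  expect_true(is.na(extract_optimum(up)))
  # vertex beyond the admissible range is reported as boundary, not a number
  expect_message(out <- extract_optimum(cur, x_range = c(0, 30)), "boundary")
  expect_true(is.na(out))
  # linear fits never have an optimum
  expect_true(is.na(extract_optimum(
    fit_response_curve(tibble::tibble(x = 1:20, rr = 0.001 * (1:20)), "x",
                       form = "linear"))))
})

test_that("zero-crossing extraction returns the smallest upward crossing", {
  x <- seq(61, 261, 4)
  cur <- fit_response_curve(tibble::tibble(x = x, rr = 2e-4 * (x - 161)),
                            "x", form = "linear")
  expect_equal(extract_zero_crossing(cur), 161, tolerance = 1e-8)
  # entirely positive curve: no crossing
  pos <- fit_response_curve(tibble::tibble(x = x, rr = 0.01 + 2e-5 * x),
                            "x", form = "linear")
  expect_true(is.na(extract_zero_crossing(pos)))
  # concave quadratic crossing up then down: smaller root, with a warning
  xq <- seq(0, 100, 2)
  two <- fit_response_curve(
    tibble::tibble(x = xq, rr = 0.05 - 1e-4 * (xq - 50)^2), "x",
    form = "quadratic")
  expect_warning(z <- extract_zero_crossing(two), "more than once")
  expect_equal(z, 50 - sqrt(500), tolerance = 1e-6)
})

test_that("regression output is invariant to row order", {
  gen <- make_fixture("dose_response", seed = 4)
  eff <- effect_sizes(gen$database)
  eff <- eff[eff$outcome == "yield", ]
  perm <- withr::with_seed(1, eff[sample.int(nrow(eff)), ])
  a <- fit_response_curve(eff, "substitution_rate", form = "quadratic")
  b <- fit_response_curve(perm, "substitution_rate", form = "quadratic")
  expect_equal(a$coefficients, b$coefficients)
  expect_equal(a$r_squared, b$r_squared)
})

test_that("forest importance is reproducible bit-wise for a fixed seed", {
  eff <- effect_sizes(make_fixture("importance", seed = 6)$database)
  a <- rf_importance(eff, n_trees = 100, seed = 42)
  b <- rf_importance(eff, n_trees = 100, seed = 42)
  expect_identical(tibble::as_tibble(a), tibble::as_tibble(b))
  c <- rf_importance(eff, n_trees = 100, seed = 43)
  expect_false(identical(a$pct_inc_mse, c$pct_inc_mse))
})

test_that("a constant response has (near-)zero importance everywhere", {
  eff <- effect_sizes(make_fixture("importance", seed = 9)$database)
  eff$rr <- 0.02
  imp <- suppressWarnings(rf_importance(eff, n_trees = 100, seed = 1))
  expect_true(all(abs(imp$pct_inc_mse) <= 2))
})

test_that("duplicating a noise moderator does not displace the signal", {
  eff <- effect_sizes(make_fixture("importance", seed = 12)$database)
  eff$aar_dup <- eff$aar_mm
  mods <- c("substitution_rate", "n_rate_total", "aar_mm", "aar_dup",
            "mat_c", "asd_h", "ffp_days", "som_gkg", "tn_gkg", "an_mgkg",
            "ap_mgkg", "ak_mgkg")
  imp <- rf_importance(eff, moderators = mods, seed = 7)
  expect_identical(imp$moderator[1], "substitution_rate")
})

test_that("moderators mostly missing are excluded with a warning", {
  eff <- effect_sizes(make_fixture("importance", seed = 15)$database)
  eff$som_gkg[seq_len(floor(nrow(eff) * 0.6))] <- NA
  expect_warning(imp <- rf_importance(eff, n_trees = 50, seed = 1),
                 "som_gkg")
  expect_false("som_gkg" %in% imp$moderator)
  small <- effect_sizes(make_record())
  expect_error(rf_importance(small, seed = 1), "at least 30")
})

test_that("tidy and glance methods expose fitted-object summaries", {
  x <- seq(61, 261, 4)
  cur <- fit_response_curve(tibble::tibble(x = x, rr = 2e-4 * (x - 161)),
                            "x", form = "linear")
  td <- tidy(cur)
  expect_named(td, c("term", "estimate", "std.error"))
  gl <- glance(cur)
  expect_true(all(c("model_form", "r.squared", "p.value",
                    "zero_crossing_x") %in% names(gl)))
  eff <- effect_sizes(make_fixture("importance", seed = 2)$database)
  expect_s3_class(tidy(rf_importance(eff, n_trees = 50, seed = 1)),
                  "tbl_df")
})
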