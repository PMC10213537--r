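# Independent oracles, transcribed literally from the estimator definitions
# and kept free of any package internals.

# delta-method variance of the log ratio of arm means, term by term
oracle_variance <- function(sd_t, n_t, m_t, sd_c, n_c, m_c) {
  sd_t^2 / (n_t * m_t^2) + sd_c^2 / (n_c * m_c^2)
}

# inverse-variance weighted mean with parametric 95% CI
oracle_pool <- function(rr, v) {
  w <- 1 / v
  est <- sum(w * rr) / sum(w)
  se <- sqrt(1 / sum(w))
  c(est = est, se = se, lo = est - 1.96 * se, hi = est + 1.96 * se)
}

# a minimal valid comparison row with overridable fields
make_record <- function(...) {
  base <- tibble::tibble(
    study_id = "S1", crop = "wheat", outcome = "yield",
    mean_npk = 5.0, sd_npk = 0.5, n_npk = 3L,
    mean_npkm = 5.2, sd_npkm = 0.5, n_npkm = 3L,
    n_rate_total = 200, substitution_rate = 50,
    climate_type = "NTM", aar_mm = 600, mat_c = 12, asd_h = 2400,
    ffp_days = 200, som_gkg = 22, tn_gkg = 1.2, an_mgkg = 90,
    ap_mgkg = 15, ak_mgkg = 180, ph = 6.8
  )
  dots <- list(...)
  for (nm in names(dots)) base[[nm]] <- dots[[nm]]
  base
}

# random valid records for property-style tests
random_records <- function(n, seed) {
  withr::with_seed(seed, {
    recs <- purrr::map_dfr(seq_len(n), function(i) {
      m1 <- runif(1, 1, 50); m2 <- runif(1, 1, 50)
      make_record(study_id = paste0("S", i),
                  mean_npk = m1, sd_npk = runif(1, 0.01, 0.3) * m1,
                  n_npk = sample(3:6, 1),
                  mean_npkm = m2, sd_npkm = runif(1, 0.01, 0.3) * m2,
                  n_npkm = sample(3:6, 1))
    })
    recs
  })
}
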