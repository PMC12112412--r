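test_that("treatment summaries match hand arithmetic", {
  mat <- matrix(c(2, 4), 1, 2, dimnames = list("A", c("e1", "e2")))
  s <- summarize_treatments(mat)
  expect_equal(s$mean, 3)
  expect_equal(s$sd, sqrt(2))
  expect_equal(s$cv, 100 * sqrt(2) / 3)  # ~47.1%
  expect_equal(s$m, log10(3))
  expect_equal(s$v, log10(2))
})

test_that("summaries reject degenerate treatments", {
  const <- matrix(3, 2, 3, dimnames = list(c("A", "B"), NULL))
  expect_error(summarize_treatments(const), "zero yield variance")
  expect_warning(s <- summarize_treatments(rbind(const[1, , drop = FALSE],
                                                 B = c(1, 2, 3)),
                                           on_zero_variance = "drop"),
                 "dropping")
  expect_equal(s$treatment_id, "B")
  single <- matrix(c(2, NA, NA), 1, 3, dimnames = list("A", NULL))
  expect_error(summarize_treatments(single), "fewer than 2")
  neg <- matrix(c(-2, 1, 0, 1), 2, 2, dimnames = list(c("A", "B"), NULL))
  expect_error(summarize_treatments(neg), "nonpositive")
})

test_that("Taylor regression recovers closed-form exponents", {
  means <- c(1, 2, 4, 8)
  # constant-CV family: sd proportional to mean implies slope exactly 2
  s <- summaries_from_moments(letters[1:4], means, sd = 0.2 * means)
  fit <- fit_taylor(s)
  expect_equal(fit$b, 2, tolerance = 1e-12)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  # equal variances across means: slope exactly 0
  s0 <- summaries_from_moments(letters[1:4], means, sd = rep(0.3, 4))
  expect_equal(fit_taylor(s0)$b, 0, tolerance = 1e-12)
  # degenerate design
  s1 <- summaries_from_moments(letters[1:3], c(2, 2, 2), c(0.1, 0.2, 0.3))
  expect_error(fit_taylor(s1), "singular")
  expect_error(fit_taylor(s[1:2, ]), "at least 3")
})

test_that("published rice summaries give Taylor slope near one and the
           expected adjusted CVs", {
  fx <- load_lte_stability("ndiaye_rice")
  s <- summaries_from_moments(fx$treatment_id, fx$mean_obs, fx$sd_obs, fx$n)
  fit <- fit_taylor(s)
  # independent oracle: direct OLS of log10(SD^2) on log10(mean)
  b_direct <- unname(coef(lm(log10(fx$sd_obs^2) ~ log10(fx$mean_obs)))[2])
  expect_equal(fit$b, b_direct, tolerance = 1e-12)
  expect_equal(fit$b, 0.99, tolerance = 0.01)
  acv <- adjusted_cv(s, fit)
  # hand evaluation of the formula for the 0-N hot-dry-season row; the
  # published table prints 27.1 from unrounded data, agreement ~1 point
  i <- which(fx$n_rate == 0 & fx$season == "HDS")
  by_hand <- 100 / fx$mean_obs[i] *
    sqrt(10^(log10(fx$sd_obs[i]^2) +
               (2 - fit$b) * (log10(fx$mean_obs[i]) - fit$m_bar)))
  expect_equal(unname(acv[i]), by_hand, tolerance = 1e-12)
  expect_lt(abs(unname(acv[i]) - 26.5), 0.05)
  # within ~1 percentage point of the printed 27.1 (rounded inputs)
  expect_lt(abs(unname(acv[i]) - fx$acv_obs[i]), 1.5)
})

test_that("adjusted CV grouping is enforced in strict mode", {
  s <- summaries_from_moments(letters[1:4], c(1, 2, 4, 8), c(0.2, 0.3, 0.5, 1))
  fit <- fit_taylor(s[1:3, ])
  expect_error(adjusted_cv(s, fit), "not in the Taylor fit group")
  expect_silent(adjusted_cv(s, fit, strict = FALSE))
})

test_that("SYI hits its closed-form anchor points", {
  expect_equal(sustainable_yield_index(5, 0, 5), 1)
  expect_equal(sustainable_yield_index(2, 2, 5), 0)
  expect_equal(sustainable_yield_index(6.6, 1.1, 8.46), (6.6 - 1.1) / 8.46)
  expect_error(sustainable_yield_index(1, 0.5, 0), "positive")
  # monotone in mean (up) and sd (down)
  expect_true(all(diff(sustainable_yield_index(1:5, 0.5, 6)) > 0))
  expect_true(all(diff(sustainable_yield_index(3, seq(0, 1, 0.2), 6)) < 0))
})

test_that("Finlay-Wilkinson regression recovers its defining cases", {
  omega <- c(1, 2, 3, 4)
  # treatments identical to the environment mean: slope 1, intercept 0
  mat <- make_fw_matrix(c(1, 1, 1), c(0, 0, 0), omega)
  fw <- finlay_wilkinson(mat)
  expect_equal(fw$coefficients$slope, rep(1, 3), tolerance = 1e-12)
  expect_equal(fw$coefficients$intercept, rep(0, 3), tolerance = 1e-12)
  # a constant-yield treatment: slope 0, intercept the constant
  mat2 <- rbind(make_fw_matrix(c(1.5, 0.5), c(0.3, -0.3), omega),
                T99 = rep(2.5, 4))
  fw2 <- finlay_wilkinson(mat2)
  expect_equal(fw2$coefficients$slope[3], 0)
  expect_equal(fw2$coefficients$intercept[3], 2.5)
  expect_error(finlay_wilkinson(mat[, 1:2]), "at least 3 environments")
})

test_that("mean F-W slope is 1 on complete matrices", {
  set.seed(11)
  for (rep in 1:10) {
    nt <- sample(3:8, 1)
    ne <- sample(4:12, 1)
    mat <- matrix(abs(rnorm(nt * ne, 3, 1)) + 0.1, nt, ne,
                  dimnames = list(paste0("T", 1:nt), paste0("E", 1:ne)))
    fw <- finlay_wilkinson(mat)
    expect_equal(mean(fw$coefficients$slope), 1, tolerance = 1e-10)
  }
})

test_that("stability_table combines all measures per source", {
  cfg <- panel_config(means = c(2, 3.5, 5, 6.5), n_environments = 8,
                      env_sd = 0.4, taylor_b = 1.8, taylor_c = 0.02,
                      seed = 3)
  st <- stability_table(generate_lte_panel(cfg))
  expect_equal(nrow(st), 8)
  expect_setequal(unique(st$source), c("observed", "predicted"))
  expect_true(all(c("acv", "syi", "fw_slope", "fw_intercept") %in% names(st)))
  expect_true(all(st$acv > 0))
  expect_true(all(st$syi <= 1))
  # identical sources give identical stability columns
  pan <- generate_lte_panel(cfg)
  df <- tibble::as_tibble(pan)
  obs <- df[df$source == "observed", ]
  dup <- obs
  dup$source <- "predicted"
  st2 <- stability_table(yield_panel(dplyr::bind_rows(obs, dup)))
  o <- st2[st2$source == "observed", c("acv", "syi", "fw_slope")]
  p <- st2[st2$source == "predicted", c("acv", "syi", "fw_slope")]
  expect_equal(o, p)
})
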