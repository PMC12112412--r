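# First 16 non-zero points of the 5-dimensional Sobol' sequence, frozen
# from an independent generator of the same Joe-Kuo direction numbers.
sobol_oracle_5d <- matrix(c(
  0.5000, 0.5000, 0.5000, 0.5000, 0.5000,
  0.7500, 0.2500, 0.2500, 0.2500, 0.7500,
  0.2500, 0.7500, 0.7500, 0.7500, 0.2500,
  0.3750, 0.3750, 0.6250, 0.8750, 0.3750,
  0.8750, 0.8750, 0.1250, 0.3750, 0.8750,
  0.6250, 0.1250, 0.8750, 0.6250, 0.6250,
  0.1250, 0.6250, 0.3750, 0.1250, 0.1250,
  0.1875, 0.3125, 0.9375, 0.4375, 0.5625,
  0.6875, 0.8125, 0.4375, 0.9375, 0.0625,
  0.9375, 0.0625, 0.6875, 0.1875, 0.3125,
  0.4375, 0.5625, 0.1875, 0.6875, 0.8125,
  0.3125, 0.1875, 0.3125, 0.5625, 0.9375,
  0.8125, 0.6875, 0.8125, 0.0625, 0.4375,
  0.5625, 0.4375, 0.0625, 0.8125, 0.1875,
  0.0625, 0.9375, 0.5625, 0.3125, 0.6875,
  0.09375, 0.46875, 0.46875, 0.65625, 0.28125
), nrow = 16, byrow = TRUE)

test_that("Sobol' sequence matches the frozen reference points", {
  expect_equal(sobol_sequence(16, 5), sobol_oracle_5d, tolerance = 1e-12)
  # first point under skip-zero is the cube midpoint
  expect_equal(sobol_sequence(1, 8)[1, ], rep(0.5, 8))
  # deterministic
  expect_identical(sobol_sequence(32, 3), sobol_sequence(32, 3))
  expect_error(sobol_sequence(4, 60), "at most")
})

test_that("LP-tau designs scale onto parameter ranges", {
  rice <- load_crop_parameter_ranges("rice")
  des <- lp_tau_design(rice, 400)
  expect_equal(dim(des$scaled_points), c(400, 7))
  for (j in seq_len(7)) {
    expect_true(all(des$scaled_points[, j] >= rice$min[j]))
    expect_true(all(des$scaled_points[, j] <= rice$max[j]))
  }
  # first design point is every parameter at its midpoint
  expect_equal(unname(des$scaled_points[1, ]), (rice$min + rice$max) / 2)
  # scaled = min + unit * (max - min)
  expect_equal(des$scaled_points,
               sweep(sweep(des$unit_points, 2, rice$max - rice$min, `*`),
                     2, rice$min, `+`))
})

test_that("Sobol' columns are more uniform than random sampling", {
  n <- 256
  ks_dist <- function(x) max(abs(sort(x) - (seq_along(x) - 0.5) / length(x)))
  des <- sobol_sequence(n, 4)
  sob_d <- mean(apply(des, 2, ks_dist))
  set.seed(7)
  rand_d <- mean(replicate(20, mean(apply(matrix(runif(n * 4), n, 4), 2,
                                          ks_dist))))
  expect_lt(sob_d, rand_d)
})

test_that("additive model gives equal main and total effects of one third", {
  specs <- parameter_ranges(data.frame(name = c("x1", "x2", "x3"),
                                       min = 0, max = 1))
  res <- saltelli_indices(function(p, ctx) c(y = sum(p)), specs,
                          n_base = 8192, seed = 1)
  expect_equal(res$s_i, rep(1 / 3, 3), tolerance = 0.02)
  expect_equal(res$st_i, rep(1 / 3, 3), tolerance = 0.02)
  expect_true(all(res$st_i >= res$s_i - 0.02))
  expect_lte(sum(res$s_i), 1.02)
})

test_that("Ishigami indices match the analytic variance decomposition", {
  a <- 7; b <- 0.1
  specs <- parameter_ranges(data.frame(name = c("x1", "x2", "x3"),
                                       min = -pi, max = pi))
  ish <- function(p, ctx) {
    c(y = sin(p[["x1"]]) + a * sin(p[["x2"]])^2 +
        b * p[["x3"]]^4 * sin(p[["x1"]]))
  }
  # closed forms derived from the variance decomposition of the function:
  # V1 = (1 + b pi^4/5)^2 / 2, V2 = a^2/8, V3 = 0,
  # V13 = b^2 pi^8 (1/18 - 1/50), V = V1 + V2 + V13
  v1 <- 0.5 * (1 + b * pi^4 / 5)^2
  v2 <- a^2 / 8
  v13 <- b^2 * pi^8 * (1 / 18 - 1 / 50)
  v <- v1 + v2 + v13
  res <- saltelli_indices(ish, specs, n_base = 8192, seed = 2)
  expect_equal(res$s_i[res$parameter == "x1"], v1 / v, tolerance = 0.02)
  expect_equal(res$s_i[res$parameter == "x2"], v2 / v, tolerance = 0.02)
  expect_equal(res$s_i[res$parameter == "x3"], 0, tolerance = 0.02)
  expect_gt(res$st_i[res$parameter == "x3"], 0.2)
  expect_true(all(res$st_i >= res$s_i - 0.02))
})

test_that("a single active input takes all the variance", {
  specs <- parameter_ranges(data.frame(name = c("x1", "x2", "x3"),
                                       min = 0, max = 1))
  res <- saltelli_indices(function(p, ctx) c(y = 3 * p[["x1"]]), specs,
                          n_base = 1024, seed = 3)
  expect_equal(res$s_i[res$parameter == "x1"], 1, tolerance = 0.03)
  expect_equal(res$st_i[res$parameter == "x1"], 1, tolerance = 0.03)
  expect_equal(res$s_i[res$parameter != "x1"], rep(0, 2), tolerance = 0.02)
})

test_that("Monte-Carlo error halves when the sample quadruples", {
  specs <- parameter_ranges(data.frame(name = c("x1", "x2", "x3"),
                                       min = 0, max = 1))
  err <- vapply(c(1024, 4096, 16384), function(nb) {
    res <- saltelli_indices(function(p, ctx) c(y = sum(p)), specs,
                            n_base = nb, seed = 4)
    mean(abs(c(res$s_i, res$st_i) - 1 / 3))
  }, numeric(1))
  # allow slack: QMC convergence is at least the MC rate
  expect_lt(err[2], err[1])
  expect_lt(err[3], err[2])
})

test_that("failed runs are discarded block-wise with sane reporting", {
  fA <- matrix(rnorm(20), 10, 2)
  fB <- matrix(rnorm(20), 10, 2)
  fAB <- list(matrix(rnorm(20), 10, 2))
  # no failures: identity
  out <- discard_failed(fA, fB, fAB)
  expect_equal(out$fraction, 0)
  expect_equal(out$fA, fA)
  # one NA anywhere removes the whole block
  fAB[[1]][4, 2] <- NA
  out2 <- discard_failed(fA, fB, fAB)
  expect_equal(out2$n_discarded, 1)
  expect_equal(nrow(out2$fA), 9)
  # all failures abort
  expect_error(discard_failed(fA * NA, fB, fAB), "unreliable")
})

test_that("toy crop failures stay below half and indices remain coherent", {
  res <- saltelli_indices(toy_crop_model, toy_crop_ranges(),
                          n_base = 1024, seed = 5)
  y <- res[res$output == "yield", ]
  frac <- y$n_discarded[1] / 1024
  expect_gt(frac, 0)
  expect_lt(frac, 0.5)
  expect_true(all(y$st_i >= y$s_i - 0.02))
})

test_that("index summaries give Tukey boxplot statistics", {
  specs <- parameter_ranges(data.frame(name = "p1", min = 0, max = 1))
  base <- tibble::tibble(context = c("y1", "y2", "y3"), output = "yield",
                         parameter = "p1", s_i = c(0.1, 0.2, 0.3),
                         st_i = c(0.15, 0.25, 0.35))
  s <- summarize_indices(base)
  s_main <- s[s$index == "s_i", ]
  expect_equal(s_main$median, 0.2)
  expect_equal(s_main$iqr, 0.1)
  # identical values collapse to a zero-IQR box
  same <- base
  same$s_i <- 0.4
  s2 <- summarize_indices(same)
  expect_equal(s2$iqr[s2$index == "s_i"], 0)
  expect_equal(s2$median[s2$index == "s_i"], 0.4)
  expect_error(summarize_indices(base[1, ]), "at least 2")
})

test_that("the designated toy-crop interaction shows up across years", {
  res <- saltelli_indices(toy_crop_model, toy_crop_ranges(),
                          n_base = 1024, seed = 6,
                          contexts = paste0("year", 1:8))
  s <- summarize_indices(res[res$output == "yield", ])
  med <- function(p, idx) s$median[s$parameter == p & s$index == idx]
  expect_gt(med("rue", "st_i"), med("rue", "s_i") + 0.05)
  expect_gt(med("tt_grainfill", "st_i"), med("tt_grainfill", "s_i") + 0.05)
})
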