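test_that("power-law fits are exact on noiseless data", {
  x <- seq(2, 200, length.out = 40)
  f <- fit_power_law(data.frame(x = x, y = 4 * x^1.5), x = "x", y = "y")
  expect_equal(f$exponent, 1.5, tolerance = 1e-12)
  expect_equal(f$amplitude, 4, tolerance = 1e-10)
  # contact-exponent convention: Pc ~ 1/s^alpha reports alpha positive
  fa <- fit_power_law(data.frame(s = x, Pc = x^-1.08), x = "s", y = "Pc",
                      target = "alpha_from_Pc")
  expect_equal(fa$exponent, 1.08, tolerance = 1e-12)
  # R2 profile convention: R2 ~ s^(2 nu) reports slope/2
  fn <- fit_power_law(data.frame(s = x, R2 = x^0.68), x = "s", y = "R2",
                      target = "nu_from_R2")
  expect_equal(fn$exponent, 0.34, tolerance = 1e-12)
})

test_that("noisy fits agree with an independent normal-equations solve", {
  set.seed(99)
  x <- exp(seq(log(2), log(500), length.out = 60))
  y <- 2.5 * x^-1.2 * exp(rnorm(60, sd = 0.1))
  f <- fit_power_law(data.frame(x = x, y = y), x = "x", y = "y")
  lx <- log10(x); ly <- log10(y)
  # closed-form least squares
  slope <- (mean(lx * ly) - mean(lx) * mean(ly)) /
    (mean(lx^2) - mean(lx)^2)
  expect_equal(f$exponent, slope, tolerance = 1e-10)
  # range restriction honours the bounds inclusively
  fr <- fit_power_law(data.frame(x = x, y = y), x = "x", y = "y",
                      range = c(10, 100))
  expect_identical(fr$n_points, sum(x >= 10 & x <= 100))
})

test_that("degenerate fit inputs raise configuration errors", {
  expect_error(fit_power_law(data.frame(x = 1:2, y = c(1, 2)),
                             x = "x", y = "y"),
               class = "csac_config_error")
  expect_error(fit_power_law(data.frame(x = 1:5, y = c(1, 2, 0, 4, 5)),
                             x = "x", y = "y"),
               class = "csac_config_error")
  expect_error(fit_power_law(data.frame(x = 1:5, y = 1:5)),
               class = "csac_config_error")  # no column hints
})

test_that("tidy and glance summarise fits in broom style", {
  x <- 2:50
  f <- fit_power_law(data.frame(x = x, y = x^0.6), x = "x", y = "y")
  td <- tidy(f)
  expect_named(td, c("term", "estimate", "conf.low", "conf.high"))
  expect_equal(td$estimate[td$term == "exponent"], 0.6, tolerance = 1e-10)
  gl <- glance(f)
  expect_identical(nrow(gl), 1L)
  expect_true(all(c("exponent", "r_squared", "n_points") %in% names(gl)))
})

test_that("plateau detection finds a constructed onset and ignores pure
           power laws", {
  s <- sort(unique(round(exp(seq(log(2), log(600), length.out = 60)))))
  pure <- tibble::tibble(s = s, R2 = s^0.68)
  expect_true(is.na(detect_plateau_onset(pure)))
  plateau_at <- 125
  piece <- tibble::tibble(
    s = s, R2 = ifelse(s <= plateau_at, s^0.68, plateau_at^0.68))
  onset <- detect_plateau_onset(piece)
  expect_gt(onset, 75)
  expect_lt(onset, 175)
  expect_error(detect_plateau_onset(pure[1:4, ]),
               class = "csac_config_error")
  expect_error(detect_plateau_onset(tibble::tibble(s = 10:18, R2 = 1)),
               class = "csac_config_error")  # less than a decade of s
})

test_that("bootstrap intervals behave like percentile bootstrap", {
  en <- grow_ensemble(40, 10, D_um = 1.5, seed = 77)
  # constant statistic -> zero-width interval
  ci <- bootstrap_ci(function(e) 5, en, n_boot = 100, seed = 1)
  expect_equal(unname(ci[1]), 5)
  expect_equal(unname(ci[2]), 5)
  # sample mean of iid normals vs closed form 2 * 1.96 * sd / sqrt(n)
  set.seed(11)
  n <- 200; sigma <- 2
  vals <- rnorm(n, sd = sigma)
  big <- subset_ensemble(en, rep(1, n))  # n dummy chains
  ci2 <- bootstrap_ci(function(e, idx) mean(vals[idx]), big,
                      n_boot = 2000, seed = 2)
  width <- ci2[2] - ci2[1]
  expect_lt(abs(width - 2 * 1.96 * sigma / sqrt(n)) / (2 * 1.96 * sigma / sqrt(n)),
            0.2)
  # interval contains the point estimate
  expect_lte(ci2[1], mean(vals))
  expect_gte(ci2[2], mean(vals))
  expect_error(bootstrap_ci(function(e) 1, subset_ensemble(en, 1),
                            n_boot = 100), class = "csac_config_error")
})

test_that("exponent report is identical for identical ensembles", {
  en <- grow_ensemble(40, 40, D_um = 1.5, seed = 13)
  rep <- exponent_report(list(`1.5` = list(en), `2.5` = list(en)),
                         nu_range = c(2, 20), alpha_range = c(2, 20),
                         min_contacts = 1)
  expect_equal(rep$nu[1], rep$nu[2])
  expect_equal(rep$alpha[1], rep$alpha[2])
  expect_true(attr(rep, "nu_monotone"))
  expect_true(attr(rep, "alpha_monotone"))
})

test_that("end-to-end scaling table carries one row per condition", {
  ens <- lapply(c(10, 20), function(N)
    grow_ensemble(15, N, D_um = Inf, seed = N))
  tab <- end_to_end_scaling(ens)
  expect_identical(tab$n_units, c(10L, 20L))
  expect_true(all(tab$e2e_nm > 0))
  expect_true(all(tab$ess <= tab$n_chains))
})
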