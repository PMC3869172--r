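make_toy_dataset <- function(with_sd = TRUE) {
  cfg <- fig_config(kappa_y = 40)
  pr <- parametrize_from_z(cfg$spec, cfg$params, 0.4, 0.2)
  tt <- c(0, 5, 10, 20, 40, 80)
  pro <- stimulus_protocol(steps = data.frame(time = 1e-6, input = 0.2))
  tr <- simulate_model(cfg$spec, pr$params, pro, times = tt)
  rec <- tibble::tibble(time = tt, observable = "resp", value = tr$z,
                        sd = if (with_sd) rep(0.05, length(tt)) else NA_real_,
                        condition = "c1")
  ts_dataset(rec, observable_map = list(resp = list(component = "z",
                                                    scale = FALSE)),
             protocols = list(c1 = pro))
}

test_that("weighted SSR is zero for a perfect fit and matches a brute-force oracle", {
  ds <- make_toy_dataset()
  cfg <- fig_config(kappa_y = 40)
  pr <- parametrize_from_z(cfg$spec, cfg$params, 0.4, 0.2)
  sims <- triloop:::simulate_conditions(cfg$spec, pr$params, ds)
  expect_lt(as.numeric(weighted_ssr(sims, ds)), 1e-8)

  # one point, residual 2, sd 2 -> (2/2)^2 = 1
  rec1 <- tibble::tibble(time = 1, observable = "resp", value = 3, sd = 2,
                         condition = "c1")
  d1 <- ts_dataset(rec1, list(resp = list(component = "z", scale = FALSE)),
                   list(c1 = stimulus_protocol()))
  sim1 <- list(c1 = list(time = c(0, 1), z = c(1, 1), x = c(0, 0), y = c(0, 0)))
  expect_equal(as.numeric(weighted_ssr(sim1, d1)), 1)

  # random data vs an independently coded double loop
  set.seed(31)
  df <- tibble::as_tibble(ds)
  noisy <- df
  noisy$value <- noisy$value + rnorm(nrow(noisy), sd = 0.2)
  d2 <- ts_dataset(noisy, attr(ds, "observable_map"), attr(ds, "protocols"))
  ssr <- as.numeric(weighted_ssr(sims, d2))
  brute <- 0
  for (i in seq_len(nrow(noisy))) {
    tr <- sims[[noisy$condition[i]]]
    sim_i <- approx(tr$time, tr$z, xout = noisy$time[i])$y
    brute <- brute + ((noisy$value[i] - sim_i) / noisy$sd[i])^2
  }
  expect_equal(ssr, brute, tolerance = 1e-12)
})

test_that("missing per-point sds fall back to mean-level weighting", {
  ds <- make_toy_dataset(with_sd = FALSE)
  expect_true(attr(ds, "sd_fallback"))
  cfg <- fig_config(kappa_y = 40)
  pr <- parametrize_from_z(cfg$spec, cfg$params, 0.4, 0.2)
  sims <- triloop:::simulate_conditions(cfg$spec, pr$params, ds)
  df <- tibble::as_tibble(ds)
  shifted <- df; shifted$value <- shifted$value + 0.1
  d2 <- ts_dataset(shifted, attr(ds, "observable_map"), attr(ds, "protocols"))
  w <- 1 / mean(shifted$value)^2
  expect_equal(as.numeric(weighted_ssr(sims, d2)),
               nrow(shifted) * w * 0.1^2, tolerance = 1e-6)
})

test_that("small-sample AIC reproduces its reference values", {
  expect_equal(round(aicc(15.3, 67, 6), 1), 104.6)
  expect_equal(round(aicc(16.3, 67, 8), 1), 113.9)
  # direct evaluation of the stated formula at simple arguments
  expect_equal(aicc(1, 10, 1),
               10 * log(2 * pi * 0.1) + 10 + 2 + 4 / 8, tolerance = 1e-12)
  expect_error(aicc(1, 5, 4), "n > k")
  expect_error(aicc(0, 10, 1), "ssr")
})

test_that("aicc increases with misfit and with model complexity", {
  ssrs <- c(1, 2, 5, 10)
  expect_true(all(diff(vapply(ssrs, aicc, numeric(1), n = 30, k = 4)) > 0))
  ks <- 1:6
  expect_true(all(diff(vapply(ks, function(k) aicc(3, 30, k), numeric(1))) > 0))
})

test_that("Akaike weights reproduce reference values and their invariances", {
  hog_aicc <- c(61.5, 64.4, 104.6, 107.2, 113.9, 175.9, 179.0, 184.2,
                184.1, 188.1, 189.1, 193.2)
  w <- akaike_weights(hog_aicc)
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_equal(round(w[1], 1), 0.8)
  expect_equal(round(w[2], 1), 0.2)

  p53_aicc <- c(-76.8, -68.8, -26.4, -31.1, -25.6, 7.3, 12.2, 14.2, 20.7,
                25.1, 30.3, 81.8, 91.6, 91.6, 99.9, 101.0, 123.1, 119.1,
                124.0, 136.7)
  wp <- akaike_weights(p53_aicc)
  expect_equal(round(wp[2], 2), 0.02)

  expect_equal(akaike_weights(42), 1)
  expect_equal(akaike_weights(c(10, 10)), c(0.5, 0.5))
  # translation invariance and monotone decrease in Delta
  expect_equal(akaike_weights(hog_aicc + 100), w, tolerance = 1e-12)
  expect_true(all(diff(akaike_weights(sort(hog_aicc))) <= 0))
})

test_that("an empty free set returns the objective at the given parameters", {
  ds <- make_toy_dataset()
  cfg <- fig_config(kappa_y = 40)
  pr <- parametrize_from_z(cfg$spec, cfg$params, 0.4, 0.2)
  f <- fit_model(cfg$spec, pr$params, ds, fit_config(free = character(0)))
  sims <- triloop:::simulate_conditions(cfg$spec, pr$params, ds)
  expect_equal(f$ssr, as.numeric(weighted_ssr(sims, ds)), tolerance = 1e-10)
  expect_equal(f$k, 0L)
})

test_that("a low-dimensional fit recovers perturbed parameters", {
  sc <- hog_scenario()
  ds <- generate_hog_dataset(sc)
  start <- sc$params
  start$k4 <- start$k4 * 3
  start$k1 <- start$k1 / 3
  f <- fit_model(sc$spec, start, ds,
                 fit_config(free = c("k1", "k4"), population = 16,
                            generations = 6, seed = 5))
  expect_lt(abs(f$estimates[["k4"]] - sc$params$k4) / sc$params$k4, 0.2)
  # the sensor turnover is only weakly constrained by y/z observations
  expect_lt(abs(f$estimates[["k1"]] - sc$params$k1) / sc$params$k1, 0.35)
  truth_ssr <- as.numeric(weighted_ssr(
    triloop:::simulate_conditions(sc$spec, sc$params, ds), ds))
  expect_lte(f$ssr, truth_ssr * 1.05)
})

test_that("tidy and glance expose fit results in rectangular form", {
  ds <- make_toy_dataset()
  cfg <- fig_config(kappa_y = 40)
  pr <- parametrize_from_z(cfg$spec, cfg$params, 0.4, 0.2)
  f <- fit_model(cfg$spec, pr$params, ds, fit_config(free = character(0)))
  td <- tidy(f)
  expect_true(all(c("term", "estimate") %in% names(td)))
  gl <- glance(f)
  expect_equal(gl$n, nrow(ds))
  expect_equal(gl$ssr, f$ssr)
})
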