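test_that("zero-order response removal makes the transducer steady state stimulus-independent", {
  spec <- model_spec("output_activation", f1 = "mass_action", f3 = "linear",
                     h = "michaelis_menten", mass_conservation = TRUE)
  p <- default_params(spec)
  p$k5 <- 0.1; p$k6 <- 0.02; p$Kz <- 1e-4; p$k2 <- 0.3; p$yT <- 1
  eq1 <- steady_state(spec, p, 1)
  eq10 <- steady_state(spec, p, 10)
  expect_equal(eq1$y, p$k6 / p$k5, tolerance = 1e-3)
  expect_equal(eq10$y, p$k6 / p$k5, tolerance = 1e-3)
  # perfect adaptation across a 100-fold stimulus range
  ys <- vapply(c(0.1, 1, 10), function(s) steady_state(spec, p, s)$y,
               numeric(1))
  expect_lt(diff(range(ys)) / mean(ys), 1e-6 + p$Kz * 100)
})

test_that("input-inhibition steady state satisfies xbar = s q(zbar) / k1", {
  spec <- model_spec("input_inhibition", h = "mass_action",
                     mass_conservation = TRUE)
  p <- default_params(spec)
  s <- 0.7
  eq <- steady_state(spec, p, s)
  expect_true(eq$exists)
  q <- 1 / (1 + (eq$z / p$Kq)^p$hq)
  expect_equal(eq$x, s * q / p$k1, tolerance = 1e-9)
})

test_that("forward simulation from a computed stable steady state stays on it", {
  set.seed(3)
  checked <- 0
  for (i in 1:12) {
    m <- random_model()
    eq <- steady_state(m$spec, m$params)
    if (!eq$exists) next
    cls <- classify_state(m$spec, m$params)
    if (cls != "stable") next
    tr <- simulate_model(m$spec, m$params, times = seq(0, 1000, 50),
                         init = c(eq$x, eq$y, eq$z), pre_equilibrate = FALSE)
    expect_lt(max(abs(tr$x - eq$x), abs(tr$y - eq$y), abs(tr$z - eq$z)), 1e-6)
    checked <- checked + 1
  }
  expect_gte(checked, 3)
})

test_that("steady-state parametrization reproduces the closed-form basal stimulus", {
  # zero-order f1 (f1(xbar) ~ 1), linear f3, q = 1, xbar arranged to be 1:
  # k0 = k1*xbar + k2*f3(zbar) = 0.2 + 0.3*0.4 = 0.32
  spec <- model_spec("output_activation", f1 = "michaelis_menten",
                     f3 = "linear", h = "mass_action",
                     mass_conservation = TRUE)
  p <- default_params(spec)
  p$Kx <- 1e-6; p$k5 <- 1; p$k6 <- 1; p$k3 <- 0.1; p$k4 <- 0.15
  p$k2 <- 0.3; p$yT <- 1
  pr <- parametrize_from_z(spec, p, z_bar = 0.4, k1 = 0.2)
  expect_equal(pr$eq$x, 1, tolerance = 1e-5)
  expect_equal(pr$k0, 0.32, tolerance = 1e-4)

  # input-inhibition rearrangement: k0 = k1*xbar / q(zbar)
  spec2 <- model_spec("input_inhibition", h = "mass_action",
                      mass_conservation = TRUE)
  p2 <- default_params(spec2)
  pr2 <- parametrize_from_z(spec2, p2, z_bar = 0.4, k1 = 0.2)
  q <- 1 / (1 + (0.4 / p2$Kq)^p2$hq)
  expect_equal(pr2$k0, 0.2 * pr2$eq$x / q, tolerance = 1e-12)
})

test_that("parametrization round-trips through the forward steady-state solver", {
  set.seed(11)
  done <- 0
  for (i in 1:15) {
    m <- random_model()
    z_bar <- runif(1, 0.05, 1)
    k1 <- runif(1, 0.05, 1)
    pr <- tryCatch(parametrize_from_z(m$spec, m$params, z_bar, k1),
                   error = function(e) NULL)
    if (is.null(pr) || pr$k0 <= 0) next
    eq <- steady_state(m$spec, pr$params, pr$k0)
    if (!eq$exists || eq$n_roots > 1) next
    expect_equal(c(eq$x, eq$y, eq$z), c(pr$eq$x, pr$eq$y, pr$eq$z),
                 tolerance = 1e-8)
    done <- done + 1
  }
  expect_gte(done, 5)
})

test_that("infeasible parametrization (ybar >= yT) is reported", {
  spec <- model_spec("output_activation", h = "mass_action",
                     mass_conservation = TRUE)
  p <- default_params(spec)
  p$k5 <- 0.01; p$k6 <- 1; p$yT <- 1   # ybar = 100 * zbar
  expect_error(parametrize_from_z(spec, p, z_bar = 0.5, k1 = 0.2),
               "infeasible")
})

test_that("Hurwitz coefficients match the characteristic polynomial", {
  # decoupled construction with eigenvalues -1, -2, -3:
  # (l+1)(l+2)(l+3) = l^3 + 6l^2 + 11l + 6
  spec <- model_spec("output_activation", f1 = "mass_action", f3 = "linear",
                     h = "mass_action", mass_conservation = FALSE)
  p <- default_params(spec)
  p$k2 <- 0; p$k3 <- 0; p$k5 <- 0; p$k1 <- 1; p$k4 <- 2; p$k6 <- 3
  hw <- hurwitz(spec, p, c(0.1, 0.1, 0.1))
  expect_equal(c(hw$a1, hw$a2, hw$a3), c(6, 11, 6))

  # random equilibria: compare against an eigendecomposition oracle
  set.seed(5)
  done <- 0
  for (i in 1:12) {
    m <- random_model()
    eq <- steady_state(m$spec, m$params)
    if (!eq$exists) next
    hw <- hurwitz(m$spec, m$params, eq)
    ev <- eigen(hw$jacobian, only.values = TRUE)$values
    expect_equal(hw$a1, -Re(sum(ev)), tolerance = 1e-8)
    expect_equal(hw$a2, Re(ev[1] * ev[2] + ev[1] * ev[3] + ev[2] * ev[3]),
                 tolerance = 1e-8)
    expect_equal(hw$a3, -Re(prod(ev)), tolerance = 1e-8)
    done <- done + 1
  }
  expect_gte(done, 5)
})

test_that("Hurwitz coefficients are positive at interior equilibria", {
  set.seed(13)
  done <- 0
  for (i in 1:15) {
    m <- random_model()
    eq <- steady_state(m$spec, m$params)
    if (!eq$exists || eq$z < 1e-6) next
    hw <- hurwitz(m$spec, m$params, eq)
    expect_gt(hw$a1, 0)
    expect_gt(hw$a2, 0)
    expect_gt(hw$a3, 0)
    done <- done + 1
  }
  expect_gte(done, 5)
})

test_that("destabilization in the reference configuration matches the eigenvalue picture", {
  cfg <- fig_config(kappa_y = 0)
  pr <- parametrize_from_z(cfg$spec, cfg$params, 0.4, 0.2)
  hw <- hurwitz(cfg$spec, pr$params, pr$eq)
  expect_lt(hw$discriminant, 0)
  ev <- eigen(hw$jacobian, only.values = TRUE)$values
  cplx <- ev[Im(ev) != 0]
  expect_length(cplx, 2)
  expect_true(all(Re(cplx) > 0))
  expect_lt(Re(ev[Im(ev) == 0][1]), 0)
})

test_that("the Hopf condition is exactly quadratic in k1", {
  set.seed(17)
  for (kappa in c(0, 10, 40)) {
    cfg <- fig_config(kappa_y = kappa)
    co <- triloop:::phi_quadratic(cfg$spec, cfg$params, z_bar = 0.4)
    phi_pred <- function(k1) co[["c0"]] + co[["c1"]] * k1 + co[["c2"]] * k1^2
    for (k1 in runif(10, 0, 3)) {
      expect_equal(triloop:::phi_of_k1(cfg$spec, cfg$params, 0.4, k1),
                   phi_pred(k1), tolerance = 1e-9)
    }
  }
})

test_that("hopf_k1 agrees with a brute-force sign scan and satisfies the Hopf identities", {
  cfg <- fig_config(kappa_y = 0)
  k1s <- hopf_k1(cfg$spec, cfg$params, 0.4)
  expect_gt(as.numeric(k1s), 0.2)   # (0.4, 0.2) lies in the oscillatory region

  # bracketing oracle on a dense grid
  grid <- seq(1e-4, 2, length.out = 4000)
  phi <- vapply(grid, function(k1)
    triloop:::phi_of_k1(cfg$spec, cfg$params, 0.4, k1), numeric(1))
  flip <- which(phi[-1] * phi[-length(phi)] < 0)
  root_bracket <- stats::uniroot(function(k1)
    triloop:::phi_of_k1(cfg$spec, cfg$params, 0.4, k1),
    c(grid[max(flip)], grid[max(flip) + 1]), tol = 1e-12)$root
  expect_equal(as.numeric(k1s), root_bracket, tolerance = 1e-6)

  # at the root: a1*a2 = a3 and the eigenvalues are {-a1, +-i sqrt(a2)}
  pr <- parametrize_from_z(cfg$spec, cfg$params, 0.4, as.numeric(k1s))
  hw <- hurwitz(cfg$spec, pr$params, pr$eq)
  expect_lt(abs(hw$discriminant), 1e-8)
  ev <- eigen(hw$jacobian, only.values = TRUE)$values
  re_ev <- Re(ev[Im(ev) == 0])
  cplx <- ev[Im(ev) != 0]
  expect_equal(re_ev[1], -hw$a1, tolerance = 1e-6)
  expect_lt(max(abs(Re(cplx))), 1e-6)
  expect_equal(sort(abs(Im(cplx))), rep(sqrt(hw$a2), 2), tolerance = 1e-6)
})

test_that("strong transducer autoinhibition moves the critical k1 below the operating point", {
  cfg <- fig_config(kappa_y = 40)
  k1s <- hopf_k1(cfg$spec, cfg$params, 0.4)
  expect_true(is.na(as.numeric(k1s)) || as.numeric(k1s) < 0.2)
})

test_that("autoinhibition shrinks the bifurcation curve pointwise", {
  zg <- seq(0.15, 0.9, length.out = 12)
  cfg0 <- fig_config(kappa_y = 0)
  b0 <- bifurcation_curve(cfg0$spec, cfg0$params, zg,
                          check_transversality = TRUE)
  b40 <- bifurcation_curve(cfg0$spec, cfg0$params, zg, kappa_y = 40,
                           check_transversality = FALSE)
  ok <- is.finite(b0$k1_star)
  expect_gt(sum(ok), 8)
  k40 <- ifelse(is.finite(b40$k1_star), b40$k1_star, 0)
  expect_true(all(k40[ok] <= b0$k1_star[ok] + 1e-9))
  # transversality at the sampled curve points
  expect_true(all(b0$transversal[!is.na(b0$transversal)]))
})

test_that("critical k1 is non-increasing in the autoinhibition strength", {
  # input-inhibition: shrinkage holds unconditionally
  spec <- model_spec("input_inhibition", h = "michaelis_menten",
                     auto_y = TRUE, mass_conservation = TRUE)
  p <- default_params(spec)
  p$Kz <- 1e-3; p$hq <- 4; p$mg <- 1
  for (z_bar in c(0.3, 0.6, 1.2)) {
    k1s <- vapply(c(0, 2, 10, 50), function(kap) {
      p$kappa_y <- kap
      r <- hopf_k1(spec, p, z_bar)
      if (is.na(as.numeric(r))) 0 else as.numeric(r)
    }, numeric(1))
    expect_true(all(diff(k1s) <= 1e-9))
  }
  # output-activation with effectively zero-order f1 at equilibrium
  cfg <- fig_config(kappa_y = 0)
  for (z_bar in c(0.3, 0.6)) {
    k1s <- vapply(c(0, 5, 20, 40), function(kap) {
      pp <- cfg$params; pp$kappa_y <- kap
      sp <- cfg$spec; sp$auto_y <- kap > 0
      r <- hopf_k1(sp, pp, z_bar)
      if (is.na(as.numeric(r))) 0 else as.numeric(r)
    }, numeric(1))
    expect_true(all(diff(k1s) <= 1e-9))
  }
})

test_that("a saturating-feedback loop admits Hopf points without high cooperativity", {
  # input-inhibition with Hill exponent 4, mass conservation and zero-order
  # response removal: the curve is non-empty, unlike the classical loop
  # which needs cooperativity >= 8
  spec <- model_spec("input_inhibition", h = "michaelis_menten",
                     mass_conservation = TRUE)
  p <- default_params(spec)
  p$Kz <- 1e-3; p$hq <- 4
  b <- bifurcation_curve(spec, p, seq(0.2, 2, length.out = 10),
                         check_transversality = FALSE)
  expect_gt(sum(is.finite(b$k1_star)), 0)
})

test_that("classification flips from oscillatory to stable across the critical k1", {
  cfg <- fig_config(kappa_y = 0)
  k1s <- as.numeric(hopf_k1(cfg$spec, cfg$params, 0.4))
  below <- parametrize_from_z(cfg$spec, cfg$params, 0.4, 0.8 * k1s)
  above <- parametrize_from_z(cfg$spec, cfg$params, 0.4, 1.2 * k1s)
  expect_equal(as.character(classify_state(cfg$spec, below$params, below$k0)),
               "oscillatory")
  expect_equal(as.character(classify_state(cfg$spec, above$params, above$k0)),
               "stable")
})

test_that("classify agrees with the simulation oracle away from boundaries", {
  cfg <- fig_config(kappa_y = 0)
  set.seed(23)
  agree <- 0; total <- 0
  for (i in 1:8) {
    z_bar <- runif(1, 0.2, 0.8)
    k1s <- as.numeric(hopf_k1(cfg$spec, cfg$params, z_bar))
    if (!is.finite(k1s)) next
    k1 <- k1s * sample(c(0.7, 1.4), 1)   # clearly inside one regime
    pr <- parametrize_from_z(cfg$spec, cfg$params, z_bar, k1)
    cls <- as.character(classify_state(cfg$spec, pr$params, pr$k0))
    tr <- simulate_model(cfg$spec, pr$params,
                         times = seq(0, 2500, 2.5),
                         init = c(pr$eq$x, pr$eq$y, pr$eq$z) * 1.02,
                         pre_equilibrate = FALSE)
    osc <- detect_oscillation(tr, "z", transient = 0.2)
    total <- total + 1
    if ((cls == "oscillatory") == isTRUE(osc$oscillating)) agree <- agree + 1
  }
  expect_gte(total, 5)
  expect_gte(agree / total, 0.95)
})

test_that("no-steady-state regimes are reported explicitly", {
  # saturable removal cannot absorb the inflow: z grows without bound
  spec <- model_spec("output_activation", f1 = "mass_action", f3 = "linear",
                     h = "michaelis_menten", mass_conservation = FALSE)
  p <- default_params(spec)
  p$k2 <- 0   # no feedback on the sensor
  p$k5 <- 1; p$k6 <- 0.01; p$Kz <- 0.05
  eq <- steady_state(spec, p, 1)
  expect_false(eq$exists)
  expect_equal(as.character(classify_state(spec, p, 1)), "no_steady_state")
})

test_that("stability regions shrink with autoinhibition and reduce to classify at 1x1", {
  cfg0 <- fig_config(kappa_y = 0)
  pr <- parametrize_from_z(cfg0$spec, cfg0$params, 0.4, 0.2)
  r1 <- stability_region(cfg0$spec, pr$params, "k1", "k2",
                         c(0.05, 0.4), c(0.1, 0.6), n = 6)
  cfg40 <- fig_config(kappa_y = 40)
  p40 <- cfg40$params; p40$k0 <- pr$params$k0
  r2 <- stability_region(cfg40$spec, p40, "k1", "k2",
                         c(0.05, 0.4), c(0.1, 0.6), n = 6)
  expect_lte(attr(r2, "oscillatory_fraction"),
             attr(r1, "oscillatory_fraction"))
  expect_gt(attr(r1, "oscillatory_fraction"), 0)

  single <- stability_region(cfg0$spec, pr$params, "k1", "k2",
                             c(0.2, 0.2), c(0.3, 0.3), n = 1)
  expect_equal(nrow(single), 1)
  expect_equal(single$class,
               as.character(classify_state(cfg0$spec, pr$params)))
})

test_that("the classical repression loop needs cooperativity 8 with equal rates and more otherwise", {
  m <- goodwin_min_hill(tol = 5e-3)
  expect_equal(m, 8, tolerance = 0.01)
  # unequal degradation rates raise the threshold strictly above 8
  spec <- model_spec("input_inhibition", f1 = "mass_action", f3 = "linear",
                     h = "mass_action", mass_conservation = FALSE)
  p <- default_params(spec)
  p$k2 <- 0; p$k3 <- 1; p$k5 <- 1; p$k4 <- 1; p$k6 <- 5; p$Kq <- 1
  admits <- function(hq) {
    p$hq <- hq
    any(vapply(10^seq(-1, 3, length.out = 25), function(z) {
      r <- tryCatch(hopf_k1(spec, p, z), error = function(e) NA_real_)
      length(attr(r, "roots")) > 0
    }, logical(1)))
  }
  expect_false(admits(8))
  expect_false(admits(9.5))   # threshold strictly above 8 for unequal rates
  expect_true(admits(16))
})
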