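#' Steady states of the feedback model
#'
#' At a constant stimulus `s` a steady state satisfies, component by
#' component, `ybar = k6 h(zbar) / (k5 H(zbar))` from the response equation,
#' `xbar = k4 ybar / (k3 G(ybar))` with `G(y) = (yT - y) g(y)` from the
#' transducer equation, and the remaining scalar condition
#' `s q(zbar) - k1 xbar - k2 f1(xbar) f3(zbar) = 0` in `zbar`. The solver
#' scans `zbar` on a log grid for sign changes, brackets each root with
#' `uniroot`, polishes with damped Newton steps on the full 3-d system, and
#' returns the root reached by relaxation from the unstimulated state when
#' several coexist. If no non-negative root exists (e.g. the response inflow
#' exceeds the saturable removal capacity) an explicit no-steady-state result
#' is returned.
#'
#' @inheritParams rhs
#' @param stimulus Constant total stimulus.
#' @param z_max Upper end of the `zbar` search interval.
#' @return A list of class `triloop_equilibrium`: `exists`, `x`, `y`, `z`,
#'   `stimulus`, `residual` (scaled max |rhs|), and `n_roots` found.
#' @export
steady_state <- function(spec, params, stimulus = params$k0, z_max = 1e6) {
  validate_model(spec, params)
  p <- params
  fns <- model_functions(spec, p)
  ybar_of_z <- function(z) {
    h <- if (spec$h == "mass_action") z else z / (p$Kz + z)
    H <- if (spec$auto_z) auto_inhibition(z, p$kappa_z, p$mH) else 1
    p$k6 * h / (p$k5 * H)
  }
  xbar_of_y <- function(y) {
    g <- if (spec$auto_y) auto_inhibition(y, p$kappa_y, p$mg) else 1
    G <- if (spec$mass_conservation) (p$yT - y) * g else g
    if (G <= 0) return(NA_real_)
    p$k4 * y / (p$k3 * G)
  }
  resid <- function(z) {
    y <- ybar_of_z(z)
    if (spec$mass_conservation && y >= p$yT) return(NA_real_)
    x <- xbar_of_y(y)
    if (!is.finite(x) || x < 0) return(NA_real_)
    # components 2 and 3 vanish by construction; component 1 is the residual
    fns$rhs(c(x, y, z), stimulus)[1]
  }
  none <- structure(list(exists = FALSE, x = NA_real_, y = NA_real_,
                         z = NA_real_, stimulus = stimulus,
                         residual = NA_real_, n_roots = 0L),
                    class = "triloop_equilibrium")
  if (stimulus <= 0) {
    # with no inflow the origin is the (unique) non-negative steady state
    out <- none; out$exists <- TRUE; out$x <- out$y <- out$z <- 0
    out$residual <- 0; out$n_roots <- 1L
    return(out)
  }
  zg <- 10^seq(-10, log10(z_max), length.out = 500)
  rv <- vapply(zg, resid, numeric(1))
  ok <- which(is.finite(rv))
  if (!length(ok)) return(none)
  roots <- numeric(0)
  sgn <- sign(rv[ok])
  flips <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  for (i in flips) {
    lo <- zg[ok[i]]; hi <- zg[ok[i + 1]]
    r <- tryCatch(stats::uniroot(resid, c(lo, hi), tol = 1e-14)$root,
                  error = function(e) NA_real_)
    if (is.finite(r)) roots <- c(roots, r)
  }
  # exact zeros on the grid
  roots <- c(roots, zg[ok][rv[ok] == 0])
  if (!length(roots)) return(none)
  roots <- sort(unique(roots))
  polish <- function(z) {
    st <- c(xbar_of_y(ybar_of_z(z)), ybar_of_z(z), z)
    for (it in 1:50) {
      f <- fns$rhs(st, stimulus)
      sc <- 1 + max(abs(st))
      if (max(abs(f)) / sc < 1e-13) break
      J <- fns$jac(st, stimulus)
      step <- tryCatch(solve(J, -f), error = function(e) NULL)
      if (is.null(step)) break
      lam <- 1
      repeat {
        st_new <- st + lam * step
        if (all(st_new >= 0) &&
            all(is.finite(fn <- fns$rhs(st_new, stimulus))) &&
            max(abs(fn)) <= max(abs(f))) { st <- st_new; break }
        lam <- lam / 2
        if (lam < 1e-6) break
      }
      if (lam < 1e-6) break
    }
    st
  }
  cand <- lapply(roots, polish)
  if (length(cand) > 1) {
    # continuation from the unstimulated state: short relaxation decides
    tr <- tryCatch(
      simulate_model(spec, p, times = seq(0, 2e3, length.out = 40),
                     init = c(0, 0, 0), pre_equilibrate = FALSE,
                     rtol = 1e-6, atol = 1e-8),
      error = function(e) NULL)
    pick <- 1L
    if (!is.null(tr)) {
      zf <- mean(utils::tail(tr$z, 10))
      pick <- which.min(vapply(cand, function(s) abs(s[3] - zf), numeric(1)))
    }
    cand <- cand[pick]
  }
  st <- cand[[1]]
  f <- fns$rhs(st, stimulus)
  res <- max(abs(f)) / (1 + max(abs(st)))
  if (!all(is.finite(st)) || res > 1e-6) return(none)
  structure(list(exists = TRUE, x = st[1], y = st[2], z = st[3],
                 stimulus = stimulus, residual = res,
                 n_roots = length(roots)),
            class = "triloop_equilibrium")
}

#' @export
print.triloop_equilibrium <- function(x, ...) {
  if (!x$exists) cat("<equilibrium> none (no non-negative steady state)\n")
  else cat(sprintf("<equilibrium> x=%.6g y=%.6g z=%.6g (stimulus %.4g, residual %.2g)\n",
                   x$x, x$y, x$z, x$stimulus, x$residual))
  invisible(x)
}

#' Parametrize the model from a chosen response steady state
#'
#' Instead of solving for the steady state at given parameters, one can pick
#' the equilibrium response level `zbar` and the sensor turnover `k1`, solve
#' `ybar` from the response equation and `xbar` from the transducer equation,
#' and then read off the basal stimulus that makes this an equilibrium:
#' `k0 = (k1 xbar + k2 f1(xbar) f3(zbar)) / q(zbar)`. This is the 1:1 map
#' between `zbar` and `k0` exploited by the bifurcation analysis.
#'
#' @inheritParams rhs
#' @param z_bar Chosen equilibrium response level (> 0).
#' @param k1 Sensor turnover rate to use.
#' @return List with `eq` (a `triloop_equilibrium`), `k0`, and `params`
#'   (the input parameters with `k0` and `k1` set).
#' @export
parametrize_from_z <- function(spec, params, z_bar, k1) {
  stopifnot(z_bar > 0, k1 >= 0)
  p <- params
  p$k1 <- k1
  h <- if (spec$h == "mass_action") z_bar else z_bar / (p$Kz + z_bar)
  H <- if (spec$auto_z) auto_inhibition(z_bar, p$kappa_z, p$mH) else 1
  y_bar <- p$k6 * h / (p$k5 * H)
  if (spec$mass_conservation && y_bar >= p$yT)
    stop("infeasible parametrization: solved ybar >= yT")
  g <- if (spec$auto_y) auto_inhibition(y_bar, p$kappa_y, p$mg) else 1
  G <- if (spec$mass_conservation) (p$yT - y_bar) * g else g
  if (G <= 0) stop("infeasible parametrization: G(ybar) <= 0")
  x_bar <- p$k4 * y_bar / (p$k3 * G)
  tm <- model_terms(spec, p, c(x_bar, y_bar, z_bar))
  k0 <- (k1 * x_bar + p$k2 * tm$f1 * tm$f3) / tm$q
  p$k0 <- k0
  f <- rhs(spec, p, c(x_bar, y_bar, z_bar), k0)
  eq <- structure(list(exists = TRUE, x = x_bar, y = y_bar, z = z_bar,
                       stimulus = k0,
                       residual = max(abs(f)) / (1 + max(abs(c(x_bar, y_bar, z_bar)))),
                       n_roots = 1L),
                  class = "triloop_equilibrium")
  list(eq = eq, k0 = k0, params = p)
}

#' Hurwitz coefficients of the characteristic polynomial
#'
#' For the 3x3 Jacobian `J` at an equilibrium, the characteristic polynomial
#' is `lambda^3 + a1 lambda^2 + a2 lambda + a3` with `a1 = -tr(J)`,
#' `a2 = sum of principal 2x2 minors`, `a3 = -det(J)`. At interior equilibria
#' of a valid structure all three are positive, so every real eigenvalue is
#' negative, and a single pure-imaginary pair exists exactly when
#' `a1 a2 = a3`, at frequency `omega = sqrt(a2)`.
#'
#' @param spec,params Model structure and parameters.
#' @param eq A `triloop_equilibrium` (or a state vector `c(x,y,z)`).
#' @param stimulus Stimulus at which the equilibrium holds; defaults to the
#'   equilibrium's own stimulus.
#' @return List of class `hurwitz_coefficients`: `a1`, `a2`, `a3`, `omega`,
#'   and `discriminant` (`a1*a2 - a3`; negative means an unstable complex
#'   pair).
#' @export
hurwitz <- function(spec, params, eq, stimulus = NULL) {
  st <- if (inherits(eq, "triloop_equilibrium")) c(eq$x, eq$y, eq$z) else eq
  if (is.null(stimulus))
    stimulus <- if (inherits(eq, "triloop_equilibrium")) eq$stimulus else params$k0
  J <- model_jacobian(spec, params, st, stimulus)
  a1 <- -sum(diag(J))
  a2 <- (J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1]) +
        (J[1, 1] * J[3, 3] - J[1, 3] * J[3, 1]) +
        (J[2, 2] * J[3, 3] - J[2, 3] * J[3, 2])
  a3 <- -det(J)
  structure(list(a1 = a1, a2 = a2, a3 = a3,
                 omega = if (a2 > 0) sqrt(a2) else NA_real_,
                 discriminant = a1 * a2 - a3, jacobian = J),
            class = "hurwitz_coefficients")
}

# Phi(k1) = a1*a2 - a3 along the z_bar-parametrization. Exactly quadratic in
# k1 (each Jacobian entry is affine in k1 once k0 is eliminated), so three
# evaluations at k1 = 0, 1, 2 recover it exactly.
phi_of_k1 <- function(spec, params, z_bar, k1) {
  pr <- parametrize_from_z(spec, params, z_bar, k1)
  hurwitz(spec, pr$params, pr$eq)$discriminant
}

phi_quadratic <- function(spec, params, z_bar) {
  ph <- vapply(c(0, 1, 2), function(k1) phi_of_k1(spec, params, z_bar, k1),
               numeric(1))
  c0 <- ph[1]
  c2 <- (ph[3] - 2 * ph[2] + ph[1]) / 2
  c1 <- ph[2] - c0 - c2
  c(c0 = c0, c1 = c1, c2 = c2)
}

#' Critical sensor turnover for a Hopf bifurcation at a chosen equilibrium
#'
#' With the basal stimulus eliminated through [parametrize_from_z()], the
#' Hopf condition `Phi(k1) = a1 a2 - a3 = 0` is exactly quadratic in `k1`.
#' The coefficients are recovered by evaluating `Phi` at `k1 = 0, 1, 2` and
#' interpolating; the function returns the largest positive real root (the
#' boundary below which the equilibrium is unstable and oscillations occur),
#' or `NA` when no positive root exists. For input-inhibition structures both
#' roots can be positive, in which case the oscillatory band is the interval
#' between them; all roots are attached as an attribute.
#'
#' @inheritParams parametrize_from_z
#' @return The critical `k1*` (largest positive root), or `NA_real_`;
#'   attributes `roots` (all real positive roots) and `coefficients`
#'   (`c0`, `c1`, `c2` of `Phi`).
#' @export
hopf_k1 <- function(spec, params, z_bar) {
  co <- phi_quadratic(spec, params, z_bar)
  c0 <- co[["c0"]]; c1 <- co[["c1"]]; c2 <- co[["c2"]]
  scale <- max(abs(co), 1e-300)
  roots <- numeric(0)
  if (abs(c2) / scale < 1e-12) {
    # degenerate quadratic: solve linearly
    if (abs(c1) / scale > 1e-12) roots <- -c0 / c1
  } else {
    disc <- c1^2 - 4 * c2 * c0
    if (disc >= 0) roots <- (-c1 + c(-1, 1) * sqrt(disc)) / (2 * c2)
  }
  roots <- sort(roots[is.finite(roots) & roots > 0])
  out <- if (length(roots)) roots[length(roots)] else NA_real_
  attr(out, "roots") <- roots
  attr(out, "coefficients") <- co
  out
}

#' Hopf bifurcation curve in the (zbar, k1) plane
#'
#' Applies [hopf_k1()] along a grid of equilibrium response levels,
#' optionally overriding the autoinhibition strengths. Transversality
#' (`d Re(lambda) / d k1 != 0` at the crossing) is checked by finite
#' differences at a subsample of curve points.
#'
#' @inheritParams parametrize_from_z
#' @param z_grid Increasing vector of `zbar` values.
#' @param kappa_y,kappa_z Optional autoinhibition strengths overriding
#'   `params`.
#' @param check_transversality Verify the eigenvalue crossing at up to 5
#'   curve points.
#' @return Tibble of class `triloop_bifurcation` with columns `z_bar`,
#'   `k1_star` (NA where no positive root), `transversal` (logical, NA where
#'   unchecked).
#' @export
bifurcation_curve <- function(spec, params, z_grid, kappa_y = NULL,
                              kappa_z = NULL, check_transversality = TRUE) {
  p <- params
  if (!is.null(kappa_y)) { p$kappa_y <- kappa_y; spec$auto_y <- kappa_y > 0 }
  if (!is.null(kappa_z)) { p$kappa_z <- kappa_z; spec$auto_z <- kappa_z > 0 }
  k1s <- vapply(z_grid, function(z)
    tryCatch(as.numeric(hopf_k1(spec, p, z)), error = function(e) NA_real_),
    numeric(1))
  tv <- rep(NA, length(z_grid))
  if (check_transversality) {
    idx <- which(is.finite(k1s))
    if (length(idx)) {
      for (i in idx[unique(round(seq(1, length(idx), length.out = min(5, length(idx)))))]) {
        k1c <- k1s[i]
        re_max <- function(k1) {
          pr <- parametrize_from_z(spec, p, z_grid[i], k1)
          ev <- eigen(hurwitz(spec, pr$params, pr$eq)$jacobian, only.values = TRUE)$values
          max(Re(ev[Im(ev) != 0]), -Inf)
        }
        dk <- max(1e-6, 1e-6 * k1c)
        slope <- (re_max(k1c + dk) - re_max(k1c - dk)) / (2 * dk)
        tv[i] <- is.finite(slope) && abs(slope) > 1e-10
      }
    }
  }
  out <- tibble::tibble(z_bar = z_grid, k1_star = k1s, transversal = tv)
  attr(out, "kappa_y") <- p$kappa_y
  attr(out, "kappa_z") <- p$kappa_z
  class(out) <- c("triloop_bifurcation", class(out))
  out
}

#' Classify the steady state at a constant stimulus
#'
#' `oscillatory` means an equilibrium exists but its Jacobian has eigenvalues
#' with positive real part (for this model class, a single complex pair, so
#' the instability is oscillatory); `stable` means all real parts are
#' negative; `no_steady_state` means no non-negative equilibrium exists.
#' Eigenvalues with `|Re| < tol` are classified `stable` but flagged
#' `marginal`.
#'
#' @inheritParams steady_state
#' @param tol Marginality tolerance on `Re(lambda)`.
#' @return Character scalar, one of `"stable"`, `"oscillatory"`,
#'   `"no_steady_state"`; attributes `eq`, `eigenvalues`, `marginal`.
#' @export
classify_state <- function(spec, params, stimulus = params$k0, tol = 1e-9) {
  eq <- steady_state(spec, params, stimulus)
  if (!eq$exists) {
    out <- "no_steady_state"
    attr(out, "eq") <- eq
    return(out)
  }
  ev <- eigen(model_jacobian(spec, params, c(eq$x, eq$y, eq$z), stimulus),
              only.values = TRUE)$values
  mre <- max(Re(ev))
  out <- if (mre > tol) "oscillatory" else "stable"
  attr(out, "eq") <- eq
  attr(out, "eigenvalues") <- ev
  attr(out, "marginal") <- abs(mre) <= tol
  out
}

#' Map stability classes over a two-parameter plane
#'
#' Classifies the steady state on a rectangular grid of two named parameters
#' and reports the fraction of the grid in the oscillatory class.
#'
#' @inheritParams steady_state
#' @param x_param,y_param Names of the two parameters to vary.
#' @param x_range,y_range Length-2 numeric ranges.
#' @param n Grid size per axis (scalar or length 2).
#' @param log_scale Place grid points log-uniformly.
#' @return Tibble of class `triloop_region` with the two parameter columns
#'   and `class`; attribute `oscillatory_fraction`.
#' @export
stability_region <- function(spec, params, x_param, y_param,
                             x_range, y_range, n = 20,
                             stimulus = NULL, log_scale = FALSE) {
  n <- rep(n, length.out = 2)
  gx <- if (log_scale) 10^seq(log10(x_range[1]), log10(x_range[2]), length.out = n[1])
        else seq(x_range[1], x_range[2], length.out = n[1])
  gy <- if (log_scale) 10^seq(log10(y_range[1]), log10(y_range[2]), length.out = n[2])
        else seq(y_range[1], y_range[2], length.out = n[2])
  grid <- expand.grid(vx = gx, vy = gy)
  cls <- character(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    p <- params
    p[[x_param]] <- grid$vx[i]
    p[[y_param]] <- grid$vy[i]
    s <- if (is.null(stimulus)) p$k0 else stimulus
    cls[i] <- tryCatch(as.character(classify_state(spec, p, s)),
                       error = function(e) "no_steady_state")
  }
  out <- tibble::tibble(!!x_param := grid$vx, !!y_param := grid$vy, class = cls)
  attr(out, "oscillatory_fraction") <- mean(cls == "oscillatory")
  attr(out, "axes") <- c(x_param, y_param)
  class(out) <- c("triloop_region", class(out))
  out
}

#' Minimal Hill cooperativity for oscillations in the classical Goodwin loop
#'
#' The classical Goodwin oscillator is the input-inhibition special case:
#' Hill-type repression of the sensor inflow, three linear first-order
#' degradations, no mass conservation and no autoinhibition. With equal
#' degradation rates, purely imaginary eigenvalues require the log-slope of
#' the repression function to reach 8 (the secant condition), so a Hopf
#' bifurcation first becomes possible at Hill exponent 8. This function finds
#' that threshold numerically: for each exponent it sweeps the equilibrium
#' response level and asks whether the quadratic Hopf condition admits a
#' positive root in `k1`, then bisects the admissibility boundary.
#'
#' Treating `k1` as free is equivalent to imposing equal rates here: the
#' critical point that minimises the required cooperativity has
#' `k1 = k4 = k6` exactly.
#'
#' @param k_deg Common degradation rate of transducer and response
#'   (`k4 = k6`).
#' @param lower,upper Bracketing interval for the exponent sweep.
#' @param tol Bisection tolerance on the exponent.
#' @param z_grid Equilibrium response levels swept per exponent.
#' @return The minimal Hill exponent (numeric scalar).
#' @export
goodwin_min_hill <- function(k_deg = 1, lower = 1, upper = 16, tol = 1e-3,
                             z_grid = 10^seq(-1, 4, length.out = 40)) {
  spec <- model_spec("input_inhibition", f1 = "mass_action", f3 = "linear",
                     h = "mass_action", auto_y = FALSE, auto_z = FALSE,
                     mass_conservation = FALSE)
  base <- default_params(spec)
  base$k2 <- 0; base$k3 <- 1; base$k5 <- 1
  base$k4 <- k_deg; base$k6 <- k_deg
  base$Kq <- 1
  admits <- function(hq) {
    p <- base; p$hq <- hq
    for (z in z_grid) {
      r <- tryCatch(hopf_k1(spec, p, z), error = function(e) NA_real_)
      if (length(attr(r, "roots"))) return(TRUE)
    }
    FALSE
  }
  if (admits(lower)) return(lower)
  if (!admits(upper)) return(NA_real_)
  lo <- lower; hi <- upper
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (admits(mid)) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}
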