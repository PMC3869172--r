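#' Define a structural variant of the three-variable feedback model
#'
#' The model describes a sensor `x`, a transducer `y` and a response `z`:
#' \deqn{x' = s\,q(z) - k_1 x - k_2 f_1(x) f_3(z)}
#' \deqn{y' = k_3\, x\, (y_T - y)\, g(y,\kappa_y) - k_4 y}
#' \deqn{z' = k_5\, y\, H(z,\kappa_z) - k_6 h(z)}
#' where `s = k0 + input` is the (possibly time-varying) stimulus. The overall
#' negative feedback acts either by *input-inhibition* (a decreasing `q(z)`
#' multiplying the inflow, with `k2 = 0`) or by *output-activation* (the
#' `k2 f1(x) f3(z)` outflow term, with `q = 1`); the two are mutually
#' exclusive. `g` and `H` are optional nested autoinhibitory feedbacks,
#' `1/(1 + (kappa v)^m)`, and the `(yT - y)` factor models mass conservation
#' of the transducer pool (e.g. a phosphorylation cycle).
#'
#' @param feedback `"output_activation"` or `"input_inhibition"`.
#' @param f1 Sensor-outflow kinetics in the feedback term: `"mass_action"`
#'   (`f1(x) = x`) or `"michaelis_menten"` (`f1(x) = x/(Kx + x)`; a small `Kx`
#'   gives effectively zero-order kinetics). Ignored under input-inhibition.
#' @param f3 Feedback kinetics of the response on the sensor:
#'   `"linear"` (`f3(z) = z`) or `"hill"`
#'   (`f3(z) = z^m/(Kf3^m + z^m)`). Ignored under input-inhibition.
#' @param h Response-removal kinetics: `"mass_action"` (`h(z) = z`) or
#'   `"michaelis_menten"` (`h(z) = z/(Kz + z)`; small `Kz` gives zero-order
#'   removal, i.e. an integrating response and perfect adaptation of `y`).
#' @param auto_y,auto_z Logical; include the nested autoinhibition `g(y)`
#'   resp. `H(z)`.
#' @param mass_conservation Logical; include the `(yT - y)` factor.
#' @param family Optional label (`"generic"`, `"hog"`, `"p53"`).
#' @param delta Optional integer vector of structural switches (used by the
#'   family enumerations; see [enumerate_hog()]).
#' @return An object of class `model_spec`.
#' @seealso [default_params()], [rhs()], [model_jacobian()], [simulate_model()]
#' @examples
#' spec <- model_spec("output_activation", f1 = "michaelis_menten")
#' p <- default_params(spec)
#' rhs(spec, p, c(x = 0.1, y = 0.2, z = 0.3))
#' @export
model_spec <- function(feedback = c("output_activation", "input_inhibition"),
                       f1 = c("mass_action", "michaelis_menten"),
                       f3 = c("linear", "hill"),
                       h = c("mass_action", "michaelis_menten"),
                       auto_y = FALSE, auto_z = FALSE,
                       mass_conservation = TRUE,
                       family = "generic", delta = NULL) {
  spec <- structure(list(
    feedback = match.arg(feedback),
    f1 = match.arg(f1),
    f3 = match.arg(f3),
    h = match.arg(h),
    auto_y = isTRUE(auto_y),
    auto_z = isTRUE(auto_z),
    mass_conservation = isTRUE(mass_conservation),
    family = family,
    delta = delta
  ), class = "model_spec")
  spec
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec>", x$family,
      if (!is.null(x$delta)) paste0("delta=(", paste(x$delta, collapse = ","), ")"),
      "\n")
  cat("  feedback:", x$feedback, "| f1:", x$f1, "| f3:", x$f3, "| h:", x$h, "\n")
  cat("  auto_y:", x$auto_y, "| auto_z:", x$auto_z,
      "| mass conservation:", x$mass_conservation, "\n")
  invisible(x)
}

#' Default parameter set for a model structure
#'
#' Returns a full named parameter list for `spec`. Rates are generic
#' order-of-magnitude placeholders meant as starting points; analyses in the
#' package always take explicit parameter values.
#'
#' Parameters: rates `k0..k6`; `yT` total transducer pool (mass conservation);
#' `kappa_y`, `kappa_z` autoinhibition strengths with exponents `mg`, `mH`;
#' `Kx`, `Kz` Michaelis constants of `f1`, `h`; `Kq`, `hq` half-saturation and
#' exponent of the Hill-type input-inhibition `q`; `Kf3`, `mf3` for Hill-type
#' `f3`. Structurally inactive entries are kept at neutral values (`k2 = 0`
#' under input-inhibition; `kappa = 0` means no autoinhibition).
#'
#' @param spec A [model_spec()].
#' @return Named list of parameters.
#' @export
default_params <- function(spec) {
  p <- list(
    k0 = 0.1, k1 = 0.2, k2 = 0.3, k3 = 0.1, k4 = 0.02, k5 = 0.1, k6 = 0.02,
    yT = 1, kappa_y = 0, kappa_z = 0, mg = 1, mH = 2,
    Kx = 1e-4, Kz = 0.05, Kq = 1, hq = 2, Kf3 = 1, mf3 = 2
  )
  if (spec$feedback == "input_inhibition") p$k2 <- 0
  if (spec$auto_y) p$kappa_y <- 1
  if (spec$auto_z) p$kappa_z <- 1
  p
}

# Structural consistency: input-inhibition and output-activation are mutually
# exclusive; autoinhibition switches must match kappa values.
validate_model <- function(spec, params) {
  stopifnot(inherits(spec, "model_spec"))
  need <- c("k0", "k1", "k2", "k3", "k4", "k5", "k6")
  miss <- setdiff(need, names(params))
  if (length(miss)) stop("missing parameters: ", paste(miss, collapse = ", "))
  if (spec$feedback == "input_inhibition" && params$k2 > 0)
    stop("structural error: input-inhibition requires k2 = 0 ",
         "(q(z) and the k2*f1*f3 term are mutually exclusive)")
  if (spec$mass_conservation && (is.null(params$yT) || params$yT <= 0))
    stop("mass conservation requires yT > 0")
  invisible(TRUE)
}

# Internal fast path: precompute structure flags and parameter scalars once,
# return lean rhs/jacobian closures for use inside ODE solvers and root
# finders (validation happens at the public entry points).
model_functions <- function(spec, params) {
  p <- params
  k1 <- p$k1; k2 <- p$k2; k3 <- p$k3; k4 <- p$k4; k5 <- p$k5; k6 <- p$k6
  yT <- if (is.null(p$yT)) 1 else p$yT
  Kx <- p$Kx; Kz <- p$Kz; Kq <- p$Kq; hq <- p$hq; Kf3 <- p$Kf3; mf3 <- p$mf3
  kap_y <- p$kappa_y; mg <- p$mg; kap_z <- p$kappa_z; mH <- p$mH
  f1_mm <- spec$f1 == "michaelis_menten"
  f3_hill <- spec$f3 == "hill"
  h_mm <- spec$h == "michaelis_menten"
  inp_inh <- spec$feedback == "input_inhibition"
  ay <- spec$auto_y && kap_y > 0
  az <- spec$auto_z && kap_z > 0
  mc <- spec$mass_conservation
  Kf3m <- if (f3_hill) Kf3^mf3 else NA_real_

  rhs_fn <- function(state, stimulus) {
    x <- state[1]; y <- state[2]; z <- state[3]
    q <- if (inp_inh) 1 / (1 + (z / Kq)^hq) else 1
    f1 <- if (f1_mm) x / (Kx + x) else x
    f3 <- if (f3_hill) { u <- z^mf3; u / (Kf3m + u) } else z
    h <- if (h_mm) z / (Kz + z) else z
    g <- if (ay) 1 / (1 + (kap_y * y)^mg) else 1
    H <- if (az) 1 / (1 + (kap_z * z)^mH) else 1
    G <- if (mc) (yT - y) * g else g
    c(stimulus * q - k1 * x - k2 * f1 * f3,
      k3 * x * G - k4 * y,
      k5 * y * H - k6 * h)
  }

  jac_fn <- function(state, stimulus) {
    x <- state[1]; y <- state[2]; z <- state[3]
    if (inp_inh) {
      uq <- (z / Kq)^hq
      q <- 1 / (1 + uq)
      dq <- if (z > 0) -hq * uq / (z * (1 + uq)^2) else
        if (hq > 1) 0 else if (hq == 1) -1 / Kq else -Inf
    } else { q <- 1; dq <- 0 }
    if (f1_mm) { f1 <- x / (Kx + x); df1 <- Kx / (Kx + x)^2 }
    else { f1 <- x; df1 <- 1 }
    if (f3_hill) {
      u <- z^mf3
      f3 <- u / (Kf3m + u)
      df3 <- if (z > 0) mf3 * Kf3m * u / (z * (Kf3m + u)^2) else
        if (mf3 > 1) 0 else if (mf3 == 1) 1 / Kf3 else Inf
    } else { f3 <- z; df3 <- 1 }
    if (h_mm) { dh <- Kz / (Kz + z)^2 } else { dh <- 1 }
    if (ay) {
      ug <- (kap_y * y)^mg
      g <- 1 / (1 + ug)
      dg <- if (y > 0) -mg * ug / (y * (1 + ug)^2) else
        if (mg > 1) 0 else if (mg == 1) -kap_y else -Inf
    } else { g <- 1; dg <- 0 }
    if (az) {
      uH <- (kap_z * z)^mH
      H <- 1 / (1 + uH)
      dH <- if (z > 0) -mH * uH / (z * (1 + uH)^2) else
        if (mH > 1) 0 else if (mH == 1) -kap_z else -Inf
    } else { H <- 1; dH <- 0 }
    if (mc) { G <- (yT - y) * g; dG <- -g + (yT - y) * dg }
    else { G <- g; dG <- dg }
    matrix(c(-k1 - k2 * df1 * f3, 0, stimulus * dq - k2 * f1 * df3,
             k3 * G, k3 * x * dG - k4, 0,
             0, k5 * H, k5 * y * dH - k6 * dh),
           3, 3, byrow = TRUE)
  }
  list(rhs = rhs_fn, jac = jac_fn)
}

# Pack structure + parameters + stimulus into the flat double vector expected
# by the compiled rhs/jacobian (see src/triloop.c for the layout).
pack_params <- function(spec, params, stimulus) {
  p <- params
  c(p$k0, p$k1, p$k2, p$k3, p$k4, p$k5, p$k6,
    if (is.null(p$yT)) 1 else p$yT,
    p$Kx, p$Kz, p$Kq, p$hq, p$Kf3, p$mf3,
    p$kappa_y, p$mg, p$kappa_z, p$mH,
    stimulus,
    as.numeric(spec$f1 == "michaelis_menten"),
    as.numeric(spec$f3 == "hill"),
    as.numeric(spec$h == "michaelis_menten"),
    as.numeric(spec$feedback == "input_inhibition"),
    as.numeric(spec$auto_y && p$kappa_y > 0),
    as.numeric(spec$auto_z && p$kappa_z > 0),
    as.numeric(spec$mass_conservation))
}

# Internal: evaluate all kinetic factors and their derivatives at a state.
model_terms <- function(spec, params, state) {
  x <- state[[1]]; y <- state[[2]]; z <- state[[3]]
  p <- params
  f1 <- if (spec$f1 == "mass_action") x else x / (p$Kx + x)
  df1 <- if (spec$f1 == "mass_action") 1 else p$Kx / (p$Kx + x)^2
  if (spec$f3 == "linear") {
    f3 <- z; df3 <- 1
  } else {
    u <- (z / p$Kf3)^p$mf3
    f3 <- u / (1 + u)
    df3 <- if (z > 0) p$mf3 * u / (z * (1 + u)^2) else
      if (p$mf3 > 1) 0 else if (p$mf3 == 1) 1 / p$Kf3 else Inf
  }
  if (spec$h == "mass_action") {
    h <- z; dh <- 1
  } else {
    h <- z / (p$Kz + z); dh <- p$Kz / (p$Kz + z)^2
  }
  if (spec$feedback == "input_inhibition") {
    uq <- (z / p$Kq)^p$hq
    q <- 1 / (1 + uq)
    dq <- if (z > 0) -p$hq * uq / (z * (1 + uq)^2) else
      if (p$hq > 1) 0 else if (p$hq == 1) -1 / p$Kq else -Inf
  } else {
    q <- 1; dq <- 0
  }
  g <- if (spec$auto_y) auto_inhibition(y, p$kappa_y, p$mg) else 1
  dg <- if (spec$auto_y) auto_inhibition_deriv(y, p$kappa_y, p$mg) else 0
  H <- if (spec$auto_z) auto_inhibition(z, p$kappa_z, p$mH) else 1
  dH <- if (spec$auto_z) auto_inhibition_deriv(z, p$kappa_z, p$mH) else 0
  if (spec$mass_conservation) {
    G <- (p$yT - y) * g
    dG <- -g + (p$yT - y) * dg
  } else {
    G <- g
    dG <- dg
  }
  list(f1 = f1, df1 = df1, f3 = f3, df3 = df3, h = h, dh = dh,
       q = q, dq = dq, g = g, dg = dg, H = H, dH = dH, G = G, dG = dG)
}

#' Right-hand side of the feedback model
#'
#' @param spec A [model_spec()].
#' @param params Named parameter list (see [default_params()]).
#' @param state Numeric vector `c(x, y, z)`, non-negative.
#' @param stimulus Total stimulus `s = k0 + external input`; defaults to the
#'   basal `params$k0`.
#' @return Numeric vector `c(x, y, z)` of time derivatives.
#' @export
rhs <- function(spec, params, state, stimulus = params$k0) {
  validate_model(spec, params)
  tm <- model_terms(spec, params, state)
  p <- params
  x <- state[[1]]; y <- state[[2]]; z <- state[[3]]
  c(x = stimulus * tm$q - p$k1 * x - p$k2 * tm$f1 * tm$f3,
    y = p$k3 * x * tm$G - p$k4 * y,
    z = p$k5 * y * tm$H - p$k6 * tm$h)
}

#' Analytic Jacobian of the feedback model
#'
#' At an interior equilibrium the Jacobian has the sign pattern of a monotone
#' cyclic negative-feedback system: zero entries at (1,2), (2,3) and (3,1),
#' positive couplings (2,1) and (3,2), and a negative feedback entry (1,3).
#'
#' @inheritParams rhs
#' @return A 3x3 numeric matrix.
#' @export
model_jacobian <- function(spec, params, state, stimulus = params$k0) {
  validate_model(spec, params)
  tm <- model_terms(spec, params, state)
  p <- params
  x <- state[[1]]; y <- state[[2]]; z <- state[[3]]
  J <- matrix(0, 3, 3, dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  J[1, 1] <- -p$k1 - p$k2 * tm$df1 * tm$f3
  J[1, 3] <- stimulus * tm$dq - p$k2 * tm$f1 * tm$df3
  J[2, 1] <- p$k3 * tm$G
  J[2, 2] <- p$k3 * x * tm$dG - p$k4
  J[3, 2] <- p$k5 * tm$H
  J[3, 3] <- p$k5 * y * tm$dH - p$k6 * tm$dh
  if (any(!is.finite(J))) stop("Jacobian not finite: state on a non-differentiable point")
  J
}
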