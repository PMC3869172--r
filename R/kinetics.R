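#' Kinetic rate-law building blocks
#'
#' The generic feedback model is assembled from a small set of scalar kinetic
#' functions: mass-action (linear), Michaelis-Menten saturation, activating and
#' inhibitory Hill functions, and the trivial constant. Each form is
#' represented as a list with a `tag` and its shape constants, and can be
#' evaluated together with its first derivative (needed for analytic
#' Jacobians).
#'
#' Invariants honoured by the forms:
#' * `michaelis_menten(v; K) = v/(K+v)` lies in `[0, 1)` for `v >= 0` and is
#'   strictly increasing; small `K` approximates zero-order (saturated)
#'   kinetics.
#' * `hill_inhibitory(v; K, n) = 1/(1 + (v/K)^n)` equals 1 at `v = 0` and is
#'   strictly decreasing.
#' * `constant_one` returns 1 for any argument.
#'
#' @param tag One of `"constant_one"`, `"linear"`, `"mass_action"`,
#'   `"michaelis_menten"`, `"hill_activating"`, `"hill_inhibitory"`.
#'   `"linear"` and `"mass_action"` are synonyms (the rate constant lives
#'   outside the form).
#' @param K Half-saturation constant (Michaelis or Hill forms).
#' @param n Hill exponent (Hill forms).
#' @return An object of class `kinetic_form`.
#' @examples
#' f <- kinetic_form("michaelis_menten", K = 0.1)
#' kin_eval(f, 1)      # 1/(0.1 + 1)... times 1 -> ~0.909
#' kin_deriv(f, 1)
#' @export
kinetic_form <- function(tag = c("constant_one", "linear", "mass_action",
                                 "michaelis_menten", "hill_activating",
                                 "hill_inhibitory"),
                         K = NULL, n = NULL) {
  tag <- match.arg(tag)
  if (tag %in% c("michaelis_menten", "hill_activating", "hill_inhibitory")) {
    if (is.null(K) || K <= 0) stop("kinetic form '", tag, "' needs K > 0")
  }
  if (tag %in% c("hill_activating", "hill_inhibitory")) {
    if (is.null(n) || n <= 0) stop("kinetic form '", tag, "' needs n > 0")
  }
  structure(list(tag = tag, K = K, n = n), class = "kinetic_form")
}

#' @rdname kinetic_form
#' @param form A `kinetic_form`.
#' @param v Non-negative argument (scalar or vector).
#' @export
kin_eval <- function(form, v) {
  switch(form$tag,
    constant_one = rep(1, length(v)),
    linear = ,
    mass_action = v,
    michaelis_menten = v / (form$K + v),
    hill_activating = {
      u <- (v / form$K)^form$n
      u / (1 + u)
    },
    hill_inhibitory = 1 / (1 + (v / form$K)^form$n)
  )
}

#' @rdname kinetic_form
#' @export
kin_deriv <- function(form, v) {
  switch(form$tag,
    constant_one = rep(0, length(v)),
    linear = ,
    mass_action = rep(1, length(v)),
    michaelis_menten = form$K / (form$K + v)^2,
    hill_activating = {
      # d/dv u/(1+u), u = (v/K)^n; at v = 0 the derivative is 0 for n > 1,
      # 1/K for n = 1, and divergent for n < 1 (reported as Inf).
      n <- form$n; K <- form$K
      u <- (v / K)^n
      ifelse(v > 0, n * u / (v * (1 + u)^2),
             ifelse(n > 1, 0, ifelse(n == 1, 1 / K, Inf)))
    },
    hill_inhibitory = {
      n <- form$n; K <- form$K
      u <- (v / K)^n
      ifelse(v > 0, -n * u / (v * (1 + u)^2),
             ifelse(n > 1, 0, ifelse(n == 1, -1 / K, -Inf)))
    }
  )
}

# Autoinhibition factor 1/(1 + (kappa*v)^m): smooth, positive, equal to 1 at
# kappa = 0 or v = 0, decreasing in both arguments. Used for g(y, kappa_y)
# and H(z, kappa_z).
auto_inhibition <- function(v, kappa, m) {
  if (kappa <= 0) return(rep(1, length(v)))
  1 / (1 + (kappa * v)^m)
}

auto_inhibition_deriv <- function(v, kappa, m) {
  if (kappa <= 0) return(rep(0, length(v)))
  u <- (kappa * v)^m
  ifelse(v > 0, -m * u / (v * (1 + u)^2),
         ifelse(m > 1, 0, ifelse(m == 1, -kappa, -Inf)))
}
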