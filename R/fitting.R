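#' Weighted sum of squared residuals
#'
#' `sum_i w_i (obs_i - s_o sim_i)^2`, with weights `1/sd_i^2` where per-point
#' sds are available and `1/mean(value)^2` per observable otherwise, and one
#' optional multiplicative scale `s_o` per relative-scale observable
#' (profiled analytically to its weighted least-squares optimum unless given).
#'
#' @param sims Named list of trajectories (one per condition, as returned by
#'   [simulate_model()]), each covering the data times of its condition.
#' @param data A [ts_dataset()].
#' @param scales Optional named numeric vector of observable scales; when
#'   `NULL`, scales flagged in the observable map are profiled out.
#' @return The scalar weighted SSR; attributes `scales` and `residuals`
#'   (the weighted residual vector).
#' @export
weighted_ssr <- function(sims, data, scales = NULL) {
  map <- attr(data, "observable_map")
  df <- tibble::as_tibble(data)
  miss <- setdiff(unique(df$condition), names(sims))
  if (length(miss)) stop("simulations missing conditions: ", paste(miss, collapse = ", "))
  # weights
  w <- 1 / df$sd^2
  if (anyNA(w)) {
    for (o in unique(df$observable)) {
      sel <- df$observable == o & is.na(df$sd)
      if (any(sel)) w[sel] <- 1 / mean(df$value[df$observable == o])^2
    }
  }
  # simulated values at data points
  simv <- numeric(nrow(df))
  for (cond in unique(df$condition)) {
    tr <- sims[[cond]]
    sel <- which(df$condition == cond)
    for (o in unique(df$observable[sel])) {
      comp <- map[[o]]$component
      oi <- sel[df$observable[sel] == o]
      simv[oi] <- stats::approx(tr$time, tr[[comp]], xout = df$time[oi],
                                rule = 2)$y
    }
  }
  # scales: profiled per observable where flagged
  sc <- stats::setNames(rep(1, length(map)), names(map))
  for (o in names(map)) {
    if (!is.null(scales) && o %in% names(scales)) {
      sc[o] <- scales[[o]]
    } else if (isTRUE(map[[o]]$scale)) {
      sel <- df$observable == o
      den <- sum(w[sel] * simv[sel]^2)
      sc[o] <- if (den > 0) sum(w[sel] * df$value[sel] * simv[sel]) / den else 1
    }
  }
  r <- sqrt(w) * (df$value - sc[df$observable] * simv)
  out <- sum(r^2)
  attr(out, "scales") <- sc
  attr(out, "residuals") <- r
  out
}

#' Small-sample corrected Akaike information criterion
#'
#' For a Gaussian least-squares fit with `n` data points, `k` parameters and
#' weighted residual sum `ssr`:
#' `AICc = n ln(2 pi ssr / n) + n + 2k + 2k(k+1)/(n - k - 1)`
#' (the full Gaussian log-likelihood, constants included).
#'
#' @param ssr Weighted sum of squared residuals (> 0).
#' @param n Number of data points.
#' @param k Number of fitted parameters (including observable scales).
#' @return AICc value.
#' @examples
#' aicc(15.3, 67, 6)  # 104.6
#' @export
aicc <- function(ssr, n, k) {
  if (n <= k + 1) stop("AICc undefined: need n > k + 1 (n = ", n, ", k = ", k, ")")
  if (ssr <= 0) stop("AICc undefined for ssr <= 0")
  n * log(2 * pi * ssr / n) + n + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Akaike weights
#'
#' `w_i = exp(-Delta_i/2) / sum_j exp(-Delta_j/2)` with
#' `Delta_i = AICc_i - min(AICc)`: the weight of evidence in favour of each
#' model in the compared set.
#'
#' @param aicc_values Numeric vector of AICc values.
#' @return Numeric vector of weights summing to 1.
#' @export
akaike_weights <- function(aicc_values) {
  stopifnot(length(aicc_values) >= 1)
  d <- aicc_values - min(aicc_values)
  w <- exp(-d / 2)
  w / sum(w)
}

#' Fitting configuration
#'
#' Defaults follow the evolutionary-programming protocol: population and
#' generation counts of 10 times the number of free parameters. Reduced
#' budgets (for quick exploratory fits) are set explicitly.
#'
#' @param free Character vector of free parameter names (default: the
#'   structurally active set from [free_parameters()]).
#' @param fixed Parameter names excluded from the free set (e.g. to fix the
#'   gauge of an unobserved component whose unit is not identifiable).
#' @param lower,upper Named numeric bounds (natural scale); defaults span
#'   three decades around the base parameter values.
#' @param population,generations Evolutionary-programming budget; `NULL`
#'   means 10 x number of free parameters each.
#' @param seed Mandatory RNG seed.
#' @param sigma_init Initial log10 mutation step size.
#' @param polish Run a Levenberg-Marquardt polish after the global search.
#' @param boundary_rounds Max rounds of bound widening + re-polish when the
#'   optimum sits on a bound.
#' @return List of class `fit_config`.
#' @export
fit_config <- function(free = NULL, fixed = NULL, lower = NULL, upper = NULL,
                       population = NULL, generations = NULL, seed = 1,
                       sigma_init = 0.25, polish = TRUE, boundary_rounds = 2) {
  structure(list(free = free, fixed = fixed, lower = lower, upper = upper,
                 population = population, generations = generations,
                 seed = seed, sigma_init = sigma_init, polish = polish,
                 boundary_rounds = boundary_rounds),
            class = "fit_config")
}

# Lean piecewise integration for the fitting objective: same solver and event
# handling as simulate_model, but returns bare vectors without result
# packaging (called thousands of times per fit).
integrate_piecewise_raw <- function(spec, params, proto, times, init,
                                    rtol = 1e-6, atol = 1e-8) {
  ev <- sort(unique(c(proto$steps$time, proto$inhibitors$time)))
  ev <- ev[ev > times[1] & ev < times[length(times)]]
  bounds <- c(times[1], ev, times[length(times)])
  out_t <- numeric(0); out_m <- NULL
  state <- init
  for (i in seq_len(length(bounds) - 1)) {
    env <- protocol_at(proto, params, bounds[i])
    stim <- env$params$k0 + env$input
    seg <- sort(unique(c(bounds[i], times[times > bounds[i] & times <= bounds[i + 1]],
                         bounds[i + 1])))
    sol <- deSolve::lsoda(state, seg, func = "tl_derivs",
                          parms = pack_params(spec, env$params, stim),
                          dllname = "triloop", initfunc = "tl_initmod",
                          jacfunc = "tl_jac", jactype = "fullusr",
                          rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1] < 0) stop("solver failure")
    state <- sol[nrow(sol), 2:4]
    keep <- sol[, 1] %in% times
    if (i > 1) keep[1] <- FALSE
    out_t <- c(out_t, sol[keep, 1])
    out_m <- rbind(out_m, sol[keep, 2:4, drop = FALSE])
  }
  list(time = out_t, x = out_m[, 1], y = out_m[, 2], z = out_m[, 3])
}

# Simulate all dataset conditions for one parameter set; shared
# pre-equilibration at the basal stimulus.
simulate_conditions <- function(spec, params, data, rtol = 1e-6, atol = 1e-8,
                                raw = FALSE) {
  protos <- attr(data, "protocols")
  df <- tibble::as_tibble(data)
  eq <- steady_state(spec, params, params$k0)
  init <- if (eq$exists) c(eq$x, eq$y, eq$z) else c(0, 0, 0)
  sims <- list()
  for (cond in unique(df$condition)) {
    tt <- sort(unique(c(0, df$time[df$condition == cond])))
    if (length(tt) < 2) tt <- c(tt, tt + 1)
    sims[[cond]] <- if (raw)
      integrate_piecewise_raw(spec, params, protos[[cond]], tt, init,
                              rtol = rtol, atol = atol)
    else
      simulate_model(spec, params, protos[[cond]], times = tt,
                     init = init, pre_equilibrate = FALSE,
                     rtol = rtol, atol = atol)
  }
  sims
}

default_bounds <- function(base, free) {
  lo <- up <- stats::setNames(numeric(length(free)), free)
  for (nm in free) {
    v <- base[[nm]]
    if (nm %in% c("hq", "mf3")) { lo[nm] <- 1; up[nm] <- 8 }
    else if (startsWith(nm, "kappa")) { lo[nm] <- 1e-3; up[nm] <- 1e3 }
    else { lo[nm] <- max(v / 10^1.5, 1e-8); up[nm] <- v * 10^1.5 }
  }
  list(lower = lo, upper = up)
}

#' Fit a model variant to a dataset
#'
#' Global search by evolutionary programming (Gaussian mutation with
#' self-adaptive step sizes, truncation selection, parameters searched in
#' log10 space within bounds), followed by a Levenberg-Marquardt polish of
#' the weighted residuals. When the optimum lands on a parameter bound, the
#' bound is relaxed and the model refitted (up to
#' `config$boundary_rounds` times). Observable scale factors are profiled
#' analytically and counted as fitted parameters.
#'
#' @param spec A [model_spec()].
#' @param params Base parameter list (values for fixed parameters and
#'   starting magnitudes for free ones).
#' @param data A [ts_dataset()].
#' @param config A [fit_config()].
#' @return Object of class `triloop_fit`: fitted `params`, free-parameter
#'   `estimates`, `scales`, `ssr`, `n`, `k`, `aicc`, plus search diagnostics.
#' @export
fit_model <- function(spec, params, data, config = fit_config()) {
  validate_model(spec, params)
  df <- tibble::as_tibble(data)
  map <- attr(data, "observable_map")
  free <- config$free %||% free_parameters(spec)
  free <- setdiff(intersect(free, names(params)), config$fixed)
  n_scales <- sum(vapply(map, function(m) isTRUE(m$scale), logical(1)))
  n <- nrow(df)
  k <- length(free) + n_scales
  objective <- function(theta) {  # theta on log10 scale
    p <- params
    for (i in seq_along(free)) p[[free[i]]] <- 10^theta[i]
    val <- tryCatch({
      sims <- simulate_conditions(spec, p, data, raw = TRUE)
      weighted_ssr(sims, data)
    }, error = function(e) NULL)
    if (is.null(val) || !is.finite(val)) {
      out <- 1e10
      attr(out, "scales") <- NULL
      attr(out, "residuals") <- rep(1e5 / sqrt(n), n)
      return(out)
    }
    val
  }

  if (length(free) == 0) {
    ssr <- objective(numeric(0))
    return(structure(list(spec = spec, params = params,
                          estimates = stats::setNames(numeric(0), character(0)),
                          scales = attr(ssr, "scales"), ssr = as.numeric(ssr),
                          n = n, k = n_scales,
                          aicc = aicc(as.numeric(ssr), n, n_scales),
                          generations = 0L, seed = config$seed,
                          boundary_hits = character(0)),
                     class = "triloop_fit"))
  }

  bb <- default_bounds(params, free)
  lower <- bb$lower; upper <- bb$upper
  if (!is.null(config$lower)) lower[names(config$lower)] <- config$lower
  if (!is.null(config$upper)) upper[names(config$upper)] <- config$upper
  P <- config$population %||% (10L * length(free))
  G <- config$generations %||% (10L * length(free))

  best <- NULL
  with_seed(config$seed, for (round in seq_len(config$boundary_rounds + 1)) {
    llo <- log10(lower); lup <- log10(upper)
    # initial population: log-uniform + the base point
    pop <- matrix(stats::runif(P * length(free)), P) %*% diag(lup - llo, length(free)) +
      matrix(llo, P, length(free), byrow = TRUE)
    pop[1, ] <- pmin(pmax(log10(unlist(params[free])), llo), lup)
    if (!is.null(best)) pop[2, ] <- pmin(pmax(best$theta, llo), lup)
    sig <- matrix(config$sigma_init, P, length(free))
    fit <- apply(pop, 1, function(th) as.numeric(objective(th)))
    for (g in seq_len(G)) {
      off <- pop + sig * matrix(stats::rnorm(P * length(free)), P)
      off <- pmin(pmax(off, matrix(llo, P, length(free), byrow = TRUE)),
                  matrix(lup, P, length(free), byrow = TRUE))
      sig_off <- sig * exp(0.2 * matrix(stats::rnorm(P * length(free)), P))
      sig_off <- pmin(pmax(sig_off, 1e-3), 1)
      fit_off <- apply(off, 1, function(th) as.numeric(objective(th)))
      keep <- order(c(fit, fit_off))[seq_len(P)]
      allpop <- rbind(pop, off); allsig <- rbind(sig, sig_off)
      pop <- allpop[keep, , drop = FALSE]
      sig <- allsig[keep, , drop = FALSE]
      fit <- c(fit, fit_off)[keep]
    }
    theta <- pop[1, ]
    if (config$polish) {
      resid_fn <- function(th) attr(objective(th), "residuals") %||%
        rep(1e5 / sqrt(n), n)
      nls <- tryCatch(
        minpack.lm::nls.lm(par = theta, fn = resid_fn, lower = llo,
                           upper = lup,
                           control = minpack.lm::nls.lm.control(maxiter = 60)),
        error = function(e) NULL)
      if (!is.null(nls) && sum(nls$fvec^2) < fit[1]) theta <- nls$par
    }
    obj <- objective(theta)
    best <- list(theta = theta, ssr = as.numeric(obj),
                 scales = attr(obj, "scales"))
    on_bound <- free[abs(theta - llo) < 1e-3 | abs(lup - theta) < 1e-3]
    on_bound <- setdiff(on_bound, c("hq", "mf3"))  # exponents keep hard bounds
    if (!length(on_bound) || round > config$boundary_rounds) break
    lower[on_bound] <- lower[on_bound] / 10^0.5
    upper[on_bound] <- upper[on_bound] * 10^0.5
  })

  p_hat <- params
  for (i in seq_along(free)) p_hat[[free[i]]] <- 10^best$theta[i]
  structure(list(spec = spec, params = p_hat,
                 estimates = stats::setNames(10^best$theta, free),
                 scales = best$scales, ssr = best$ssr, n = n, k = k,
                 aicc = aicc(best$ssr, n, k),
                 generations = G, population = P, seed = config$seed,
                 boundary_hits = if (exists("on_bound")) on_bound else character(0)),
            class = "triloop_fit")
}

#' @export
print.triloop_fit <- function(x, ...) {
  cat(sprintf("<triloop_fit> %s delta=(%s): SSR %.4g, n %d, k %d, AICc %.2f\n",
              x$spec$family, paste(x$spec$delta, collapse = ","),
              x$ssr, x$n, x$k, x$aicc))
  invisible(x)
}

#' Fit and rank a family of candidate models
#'
#' Fits every structure in the family to the same dataset and assembles a
#' ranking table with AICc and Akaike weights, flagging the
#' best-approximating set by a weight threshold.
#'
#' @param family A `model_family` (or list of [model_spec()]s).
#' @param params_fn Function `spec -> base parameter list` (default
#'   [default_params()]).
#' @param data A [ts_dataset()].
#' @param config A [fit_config()] applied to every model (population /
#'   generations `NULL` scale with each model's own parameter count).
#' @param weight_threshold Akaike-weight cutoff for the best-approximating
#'   set.
#' @return Tibble of class `triloop_ranking`, sorted by AICc, with columns
#'   `rank`, `model`, `delta`, `n`, `k`, `SSR`, `AICc`, `AICw`, `best` and
#'   `error` (fit failures recorded, row retained). Fits attached as
#'   attribute `fits`.
#' @export
rank_models <- function(family, data, params_fn = default_params,
                        config = fit_config(), weight_threshold = 0.05) {
  fits <- vector("list", length(family))
  rows <- vector("list", length(family))
  for (i in seq_along(family)) {
    sp <- family[[i]]
    f <- tryCatch(fit_model(sp, params_fn(sp), data, config),
                  error = function(e) e)
    fits[[i]] <- f
    if (inherits(f, "error")) {
      rows[[i]] <- tibble::tibble(
        model = sp$model %||% i,
        delta = paste0("(", paste(sp$delta, collapse = ","), ")"),
        n = nrow(data), k = NA_integer_, SSR = NA_real_, AICc = NA_real_,
        error = conditionMessage(f))
    } else {
      rows[[i]] <- tibble::tibble(
        model = sp$model %||% i,
        delta = paste0("(", paste(sp$delta, collapse = ","), ")"),
        n = f$n, k = f$k, SSR = f$ssr, AICc = f$aicc, error = NA_character_)
    }
  }
  tab <- dplyr::bind_rows(rows)
  okv <- !is.na(tab$AICc)
  tab$AICw <- NA_real_
  tab$AICw[okv] <- akaike_weights(tab$AICc[okv])
  tab <- dplyr::arrange(tab, dplyr::desc(!is.na(.data$AICc)), .data$AICc)
  tab$rank <- seq_len(nrow(tab))
  tab$best <- !is.na(tab$AICw) & tab$AICw >= weight_threshold
  tab <- dplyr::select(tab, "rank", "model", "delta", "n", "k", "SSR",
                       "AICc", "AICw", "best", "error")
  attr(tab, "fits") <- fits
  class(tab) <- c("triloop_ranking", class(tab))
  tab
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Broom-style accessors for fits and rankings
#'
#' `tidy()` returns one row per fitted quantity (free parameters and
#' profiled observable scales); `glance()` returns the one-row fit summary.
#'
#' @param x A `triloop_fit` or `triloop_ranking`.
#' @param ... Unused.
#' @method tidy triloop_fit
#' @export
tidy.triloop_fit <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(term = names(x$estimates), estimate = unname(x$estimates),
                   type = "parameter"),
    tibble::tibble(term = paste0("scale_", names(x$scales)),
                   estimate = unname(x$scales), type = "scale"))
}

#' @rdname tidy.triloop_fit
#' @method glance triloop_fit
#' @export
glance.triloop_fit <- function(x, ...) {
  tibble::tibble(ssr = x$ssr, n = x$n, k = x$k, AICc = x$aicc,
                 population = x$population %||% NA_integer_,
                 generations = x$generations)
}

#' @rdname tidy.triloop_fit
#' @method tidy triloop_ranking
#' @export
tidy.triloop_ranking <- function(x, ...) {
  out <- tibble::as_tibble(x)
  attr(out, "fits") <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
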