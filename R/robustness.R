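#' Monte-Carlo parameter perturbation
#'
#' Draws each free parameter independently from a uniform distribution on
#' `[p/2, 2p]` around its reference value (the half-to-double protocol).
#'
#' @param params Reference parameter list.
#' @param free Character vector of parameter names to perturb.
#' @param n Number of samples.
#' @param seed RNG seed (reproducible draws).
#' @param range Multiplicative range, default `c(0.5, 2)`.
#' @return Tibble with a `sample` id column and one column per perturbed
#'   parameter.
#' @export
perturb_parameters <- function(params, free, n, seed = 1, range = c(0.5, 2)) {
  stopifnot(n >= 1, all(free %in% names(params)))
  draws <- with_seed(seed, lapply(free, function(nm) {
    p <- params[[nm]]
    stats::runif(n, min = range[1] * p, max = range[2] * p)
  }))
  names(draws) <- free
  tibble::as_tibble(c(list(sample = seq_len(n)), draws))
}

#' Steady-state distances under parameter perturbation
#'
#' For each perturbed parameter sample, computes the steady state under the
#' given stimulus and its per-component absolute distance to the reference
#' steady state, plus the Euclidean distance across components. Samples
#' without a steady state are flagged and excluded from distances, with the
#' count reported as an attribute.
#'
#' @param spec A [model_spec()].
#' @param samples Tibble from [perturb_parameters()].
#' @param params Reference parameter list (entries overridden per sample by
#'   the sample columns).
#' @param stimulus Constant stimulus at which steady states are computed
#'   (e.g. basal + shock dose).
#' @return Tibble of class `triloop_mc` with `sample`, `ok`, steady-state
#'   components, `dist_x`, `dist_y`, `dist_z`, `dist_euclid`; attributes
#'   `reference` (the reference equilibrium) and `n_no_steady_state`.
#' @export
steady_state_distances <- function(spec, samples, params,
                                   stimulus = params$k0) {
  ref <- steady_state(spec, params, stimulus)
  if (!ref$exists) stop("reference parameters admit no steady state")
  pert_names <- setdiff(names(samples), "sample")
  out <- vector("list", nrow(samples))
  for (i in seq_len(nrow(samples))) {
    p <- params
    for (nm in pert_names) p[[nm]] <- samples[[nm]][i]
    s <- if ("k0" %in% pert_names && stimulus != params$k0)
      p$k0 + (stimulus - params$k0) else stimulus
    eq <- tryCatch(steady_state(spec, p, s),
                   error = function(e) list(exists = FALSE))
    if (eq$exists) {
      out[[i]] <- tibble::tibble(
        sample = samples$sample[i], ok = TRUE,
        x = eq$x, y = eq$y, z = eq$z,
        dist_x = abs(eq$x - ref$x), dist_y = abs(eq$y - ref$y),
        dist_z = abs(eq$z - ref$z),
        dist_euclid = sqrt((eq$x - ref$x)^2 + (eq$y - ref$y)^2 +
                             (eq$z - ref$z)^2))
    } else {
      out[[i]] <- tibble::tibble(sample = samples$sample[i], ok = FALSE,
                                 x = NA_real_, y = NA_real_, z = NA_real_,
                                 dist_x = NA_real_, dist_y = NA_real_,
                                 dist_z = NA_real_, dist_euclid = NA_real_)
    }
  }
  res <- dplyr::bind_rows(out)
  attr(res, "reference") <- ref
  attr(res, "n_no_steady_state") <- sum(!res$ok)
  class(res) <- c("triloop_mc", class(res))
  res
}

#' Compare the variability of two distance distributions
#'
#' Tests whether two steady-state distance distributions differ in spread.
#' Default is Levene's test on absolute deviations from the median
#' (Brown-Forsythe variant; robust to the skewness typical of distance
#' distributions); the classical F ratio test is available with
#' `method = "f"`.
#'
#' @param dist_a,dist_b Numeric vectors of distances (NA dropped).
#' @param method `"levene"` or `"f"`.
#' @return List with `statistic`, `p_value`, `var_a`, `var_b`, `direction`
#'   (`"a_smaller"`, `"b_smaller"` or `"equal"`) and `method`.
#' @export
compare_variances <- function(dist_a, dist_b, method = c("levene", "f")) {
  method <- match.arg(method)
  a <- dist_a[is.finite(dist_a)]
  b <- dist_b[is.finite(dist_b)]
  stopifnot(length(a) >= 2, length(b) >= 2)
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0)
    return(list(statistic = NA_real_, p_value = 1, var_a = va, var_b = vb,
                direction = "equal", method = method,
                degenerate = TRUE))
  if (method == "levene") {
    g <- factor(rep(c("a", "b"), c(length(a), length(b))))
    lt <- car::leveneTest(c(a, b), g)
    stat <- lt[1, "F value"]; pv <- lt[1, "Pr(>F)"]
  } else {
    ft <- stats::var.test(a, b)
    stat <- unname(ft$statistic); pv <- ft$p.value
  }
  list(statistic = stat, p_value = pv, var_a = va, var_b = vb,
       direction = if (va < vb) "a_smaller" else if (vb < va) "b_smaller" else "equal",
       method = method, degenerate = FALSE)
}

#' Full robustness study for a pair of model variants
#'
#' Runs the half-to-double Monte-Carlo perturbation for two structures
#' (typically with vs. without autoinhibition), computes post-stimulus
#' steady-state distances, and compares per-component variances.
#'
#' @param spec_a,spec_b The two model structures.
#' @param params_a,params_b Their reference parameters.
#' @param free_a,free_b Parameters perturbed in each (default: the
#'   structurally free sets).
#' @param n Number of Monte-Carlo samples per model.
#' @param stimulus Stimulus at which steady states are evaluated.
#' @param seed RNG seed.
#' @param method Variance test passed to [compare_variances()].
#' @return List with the two distance tibbles (`mc_a`, `mc_b`) and a tibble
#'   `comparison` with one row per component (x, y, z, euclid).
#' @export
robustness_study <- function(spec_a, params_a, spec_b, params_b,
                             free_a = free_parameters(spec_a),
                             free_b = free_parameters(spec_b),
                             n = 250, stimulus = params_a$k0, seed = 1,
                             method = "levene") {
  sa <- perturb_parameters(params_a, free_a, n, seed = seed)
  sb <- perturb_parameters(params_b, free_b, n, seed = seed + 1)
  mca <- steady_state_distances(spec_a, sa, params_a, stimulus)
  mcb <- steady_state_distances(spec_b, sb, params_b, stimulus)
  comp <- lapply(c(x = "dist_x", y = "dist_y", z = "dist_z",
                   euclid = "dist_euclid"), function(col) {
    cv <- compare_variances(mca[[col]], mcb[[col]], method = method)
    tibble::tibble(var_a = cv$var_a, var_b = cv$var_b,
                   statistic = cv$statistic, p_value = cv$p_value,
                   direction = cv$direction)
  })
  comparison <- dplyr::bind_rows(comp, .id = "component")
  list(mc_a = mca, mc_b = mcb, comparison = comparison,
       n = n, seed = seed, stimulus = stimulus, method = method)
}
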