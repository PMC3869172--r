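#' Enumerate the HOG candidate-model family
#'
#' Candidate models for yeast osmoadaptation (sensor `x` = volume/turgor
#' signal, `y` = phosphorylated Hog1, `z` = glycerol) are structural variants
#' of the generic loop indexed by a switch vector
#' `delta = (d1, d2, d3, d4)`:
#' * `d1` feedback type: 1 = input-inhibition (Hill `q(z)`, `k2 = 0`),
#'   0 = output-activation (`k2 f1(x) f3(z)` with `f3(z) = z`);
#' * `d2` sensor-outflow kinetics `f1`: 0 = mass action, 1 =
#'   Michaelis-Menten (zero-order for small `Kx`); inactive (fixed 0) under
#'   input-inhibition, where the `f1` term is absent;
#' * `d3` autoinhibition `g(y, kappa_y)` on Hog1: 0 = absent, 1 = present;
#' * `d4` glycerol-removal kinetics `h`: 0 = mass action, 1 =
#'   Michaelis-Menten (perfect adaptation in the small-`Kz` limit).
#'
#' All HOG variants keep mass conservation on `y`, `f3(z) = z` and
#' `H(z) == 1`. The admissible combinations give 8 output-activation plus 4
#' input-inhibition structures: 12 models.
#'
#' @return A list of [model_spec()] objects (class `model_family`), each with
#'   its `delta` and a `model` id.
#' @seealso [enumerate_p53()], [family_table()]
#' @export
enumerate_hog <- function() {
  specs <- list()
  id <- 0L
  for (d1 in 0:1) for (d2 in 0:1) for (d3 in 0:1) for (d4 in 0:1) {
    if (d1 == 1 && d2 == 1) next  # f1 switch multiplies an absent term
    id <- id + 1L
    sp <- model_spec(
      feedback = if (d1 == 1) "input_inhibition" else "output_activation",
      f1 = if (d2 == 1) "michaelis_menten" else "mass_action",
      f3 = "linear",
      h = if (d4 == 1) "michaelis_menten" else "mass_action",
      auto_y = d3 == 1, auto_z = FALSE,
      mass_conservation = TRUE,
      family = "hog", delta = c(d1, d2, d3, d4))
    sp$model <- id
    specs[[id]] <- sp
  }
  structure(specs, class = "model_family", family = "hog")
}

#' Enumerate the p53 candidate-model family
#'
#' Candidate models for the p53-Mdm2 negative feedback (`x` = active p53,
#' `y` = Mdm2 RNA, `z` = Mdm2 protein) indexed by
#' `delta = (d1, d2, d3, d4, d5)`:
#' * `d1` feedback type (1 = input-inhibition, 0 = output-activation);
#' * `d2` `f1` kinetics (0 = mass action, 1 = Michaelis-Menten); inactive
#'   under input-inhibition;
#' * `d3` feedback kinetics `f3` (0 = mass action/linear, 1 = Hill);
#'   inactive under input-inhibition;
#' * `d4` autoinhibition `H(z, kappa_z)` on Mdm2 protein (0/1);
#' * `d5` `h` kinetics (0 = mass action, 1 = Michaelis-Menten, i.e.
#'   zero-order removal for small `Kz`).
#'
#' `y` is an RNA, so no mass conservation and `g(y) == 1`. Admissible
#' combinations: 16 output-activation plus 4 input-inhibition structures:
#' 20 models.
#'
#' @return A list of [model_spec()] objects (class `model_family`).
#' @export
enumerate_p53 <- function() {
  specs <- list()
  id <- 0L
  for (d1 in 0:1) for (d2 in 0:1) for (d3 in 0:1) for (d4 in 0:1) for (d5 in 0:1) {
    if (d1 == 1 && (d2 == 1 || d3 == 1)) next  # switches on absent terms
    id <- id + 1L
    sp <- model_spec(
      feedback = if (d1 == 1) "input_inhibition" else "output_activation",
      f1 = if (d2 == 1) "michaelis_menten" else "mass_action",
      f3 = if (d3 == 1) "hill" else "linear",
      h = if (d5 == 1) "michaelis_menten" else "mass_action",
      auto_y = FALSE, auto_z = d4 == 1,
      mass_conservation = FALSE,
      family = "p53", delta = c(d1, d2, d3, d4, d5))
    sp$model <- id
    specs[[id]] <- sp
  }
  structure(specs, class = "model_family", family = "p53")
}

#' Names of the structurally free parameters of a model variant
#'
#' Derived mechanically from the structure: the rate constants of active
#' terms plus the kinetic constants of the active saturating forms.
#' Observable scaling factors (one per relative-scale observable) are added
#' at fit time and counted in the AICc `k` separately.
#'
#' @param spec A [model_spec()].
#' @param include_k0 Count the basal stimulus `k0` as free.
#' @return Character vector of parameter names.
#' @export
free_parameters <- function(spec, include_k0 = TRUE) {
  out <- c(if (include_k0) "k0", "k1", "k3", "k4", "k5", "k6")
  if (spec$feedback == "output_activation") out <- c(out, "k2")
  if (spec$feedback == "input_inhibition") out <- c(out, "Kq", "hq")
  if (spec$f1 == "michaelis_menten" && spec$feedback == "output_activation")
    out <- c(out, "Kx")
  if (spec$f3 == "hill" && spec$feedback == "output_activation")
    out <- c(out, "Kf3", "mf3")
  if (spec$h == "michaelis_menten") out <- c(out, "Kz")
  if (spec$auto_y) out <- c(out, "kappa_y")
  if (spec$auto_z) out <- c(out, "kappa_z")
  out
}

#' Tabulate a model family
#'
#' @param family A `model_family` from [enumerate_hog()] or
#'   [enumerate_p53()].
#' @return Tibble with `model`, `delta` (string), `feedback`, kinetic
#'   choices and the mechanical free-parameter count `k_struct`.
#' @export
family_table <- function(family) {
  tibble::tibble(
    model = vapply(family, function(s) s$model, integer(1)),
    delta = vapply(family, function(s) paste0("(", paste(s$delta, collapse = ","), ")"),
                   character(1)),
    feedback = vapply(family, function(s) s$feedback, character(1)),
    f1 = vapply(family, function(s) s$f1, character(1)),
    f3 = vapply(family, function(s) s$f3, character(1)),
    h = vapply(family, function(s) s$h, character(1)),
    auto = vapply(family, function(s) s$auto_y || s$auto_z, logical(1)),
    k_struct = vapply(family, function(s) length(free_parameters(s)), integer(1))
  )
}

# Find the spec with a given delta vector in a family.
family_get <- function(family, delta) {
  hit <- Filter(function(s) identical(as.integer(s$delta), as.integer(delta)), family)
  if (!length(hit)) stop("no model with delta (", paste(delta, collapse = ","), ")")
  hit[[1]]
}
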