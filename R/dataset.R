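#' Time-series datasets for model fitting
#'
#' A dataset couples observation records with the mapping from observables to
#' model components and the experimental protocol per condition. Records are
#' tidy: one row per measured point.
#'
#' @param records Data frame with columns `time`, `observable`, `value`,
#'   `sd` (optional; per-point standard deviation, > 0 where present) and
#'   `condition`.
#' @param observable_map Named list: for each observable, a list with
#'   `component` (`"x"`, `"y"` or `"z"`) and `scale` (logical; TRUE when the
#'   observable is on an arbitrary relative scale and a multiplicative scale
#'   factor should be fitted).
#' @param protocols Named list of [stimulus_protocol()]s, one per condition
#'   label appearing in `records`.
#' @return Tibble of records with class `triloop_dataset`; the map and
#'   protocols are carried as attributes.
#' @export
ts_dataset <- function(records, observable_map, protocols) {
  records <- tibble::as_tibble(records)
  need <- c("time", "observable", "value", "condition")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records missing columns: ", paste(miss, collapse = ", "))
  if (!"sd" %in% names(records)) records$sd <- NA_real_
  if (any(!is.na(records$sd) & records$sd <= 0))
    stop("per-point sds must be > 0 where present")
  obs <- unique(records$observable)
  unmapped <- setdiff(obs, names(observable_map))
  if (length(unmapped))
    stop("unmapped observables: ", paste(unmapped, collapse = ", "))
  conds <- unique(records$condition)
  missing_proto <- setdiff(conds, names(protocols))
  if (length(missing_proto))
    stop("conditions without protocol: ", paste(missing_proto, collapse = ", "))
  out <- records
  attr(out, "observable_map") <- observable_map
  attr(out, "protocols") <- protocols
  attr(out, "sd_fallback") <- anyNA(records$sd)
  class(out) <- c("triloop_dataset", class(out))
  out
}

#' Read / write tidy time-series CSV
#'
#' The CSV schema is `time, observable, value, sd, condition`; `sd` may be
#' absent, in which case weighting falls back to `1/mean(observable)^2` and
#' the dataset is flagged. Malformed rows are rejected with the offending
#' line numbers.
#'
#' @param path File path.
#' @param observable_map,protocols As in [ts_dataset()]; when `NULL`, every
#'   observable is mapped to the like-named component with a fitted scale and
#'   every condition gets an empty protocol (constant basal stimulus).
#' @return A `triloop_dataset`.
#' @export
read_timeseries_csv <- function(path, observable_map = NULL, protocols = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("time", "observable", "value", "condition")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("CSV missing columns: ", paste(miss, collapse = ", "))
  bad <- which(!is.finite(df$time) | !is.finite(df$value))
  if (length(bad))
    stop("malformed rows (non-numeric time/value) at lines: ",
         paste(bad + 1, collapse = ", "))
  if (is.null(observable_map))
    observable_map <- stats::setNames(
      lapply(unique(df$observable), function(o)
        list(component = substr(o, 1, 1), scale = TRUE)),
      unique(df$observable))
  if (is.null(protocols))
    protocols <- stats::setNames(
      replicate(length(unique(df$condition)), stimulus_protocol(),
                simplify = FALSE),
      unique(df$condition))
  ts_dataset(df, observable_map, protocols)
}

#' @rdname read_timeseries_csv
#' @param dataset A `triloop_dataset`.
#' @export
write_timeseries_csv <- function(dataset, path) {
  readr::write_csv(tibble::as_tibble(dataset), path)
  invisible(path)
}

#' Serialize a model structure and parameters to YAML
#'
#' @param spec A [model_spec()].
#' @param params Named parameter list.
#' @param path File path.
#' @export
write_model_yaml <- function(spec, params, path) {
  yaml::write_yaml(list(
    family = spec$family,
    delta = as.integer(spec$delta),
    feedback = spec$feedback,
    f1 = spec$f1, f3 = spec$f3, h = spec$h,
    auto_y = spec$auto_y, auto_z = spec$auto_z,
    mass_conservation = spec$mass_conservation,
    params = params), path)
  invisible(path)
}

#' @rdname write_model_yaml
#' @return `read_model_yaml`: list with `spec` and `params`.
#' @export
read_model_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  spec <- model_spec(feedback = x$feedback, f1 = x$f1, f3 = x$f3, h = x$h,
                     auto_y = x$auto_y, auto_z = x$auto_z,
                     mass_conservation = x$mass_conservation,
                     family = x$family,
                     delta = if (length(x$delta)) as.integer(x$delta) else NULL)
  list(spec = spec, params = x$params)
}
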