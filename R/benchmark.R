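#' Normalize an observable table by a reference variant
#'
#' Divides each observable value by the value of the reference variant,
#' independently within each `source` group (so simulation and experiment
#' are each normalized by their own reference), the convention used when
#' comparing relative condensate observables across models.
#'
#' @param table data.frame with columns `variant`, `value` and optionally
#'   `source`; missing `source` is treated as a single group.
#' @param reference_variant reference variant id (must be present in every
#'   source group with a nonzero value).
#' @return the table with an added `normalized` column.
#' @export
normalize_by_reference <- function(table, reference_variant) {
  stopifnot(is.data.frame(table),
            all(c("variant", "value") %in% names(table)))
  if (!"source" %in% names(table)) table$source <- "all"
  table$normalized <- NA_real_
  for (s in unique(table$source)) {
    idx <- table$source == s
    ref <- table$value[idx & table$variant == reference_variant]
    if (length(ref) != 1 || is.na(ref) || ref == 0) {
      stop("reference variant '", reference_variant,
           "' missing (or zero) in source '", s, "'")
    }
    table$normalized[idx] <- table$value[idx] / ref
  }
  table
}

#' Mean relative log-deviation for saturation concentrations
#'
#' D = (1/n) sum |log10(exp_i) - log10(sim_i)| / log10(exp_i).  Decimal
#' logarithms; the per-point denominator makes the metric units-dependent
#' (values are expected in mM) and undefined where an experimental value
#' equals 1, which is rejected explicitly.  Note the denominator is signed:
#' experimental values below 1 contribute with a negative weight.
#'
#' @param sim,exp positive numeric vectors of equal length.
#' @return deviation D (dimensionless).
#' @export
deviation_csat <- function(sim, exp) {
  stopifnot(length(sim) == length(exp), all(sim > 0), all(exp > 0))
  lz <- which(log10(exp) == 0)
  if (length(lz) > 0) {
    stop("experimental value equal to 1 (log10 = 0) at point ", lz[1],
         "; the per-point denominator is undefined there")
  }
  mean(abs(log10(exp) - log10(sim)) / log10(exp))
}

#' Root-mean-square log-deviation for viscosities
#'
#' D = sqrt((1/n) sum (log10(exp_i) - log10(sim_i))^2), decimal logs.
#'
#' @param sim,exp positive numeric vectors of equal length.
#' @return deviation D (dimensionless, >= 0).
#' @export
deviation_viscosity <- function(sim, exp) {
  stopifnot(length(sim) == length(exp))
  if (any(sim <= 0) || any(exp <= 0)) {
    stop("all values must be positive for the log deviation")
  }
  sqrt(mean((log10(exp) - log10(sim))^2))
}

#' Ordinary least-squares line and Pearson correlation
#'
#' @param x,y numeric vectors (n >= 2, nonzero variance each).
#' @return list with slope `m`, intercept `b` and Pearson `r`.
#' @export
linear_correlation <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  if (var(x) == 0 || var(y) == 0) {
    stop("zero variance in x or y; no line can be fitted")
  }
  fit <- lm(y ~ x)
  list(m = unname(coef(fit)[2]), b = unname(coef(fit)[1]),
       r = stats::cor(x, y))
}
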