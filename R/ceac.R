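#' Probability of cost-effectiveness from a regression p-value
#'
#' Converts the two-sided p-value on the treatment coefficient of a
#' net-benefit regression into the probability that the intervention is
#' cost-effective at that ceiling ratio. Only a one-sided test of whether
#' the incremental net benefit is positive is needed, so the one-sided
#' p-value is half the two-sided one; the probability is
#' \eqn{1 - p/2} when \eqn{\delta > 0}, \eqn{p/2} when \eqn{\delta < 0},
#' and exactly 0.5 when \eqn{\delta = 0} (the continuous limit from both
#' sides).
#'
#' @param delta incremental net benefit (treatment coefficient).
#' @param two_sided_p its two-sided p-value, in \[0, 1\].
#' @return probability in \[0, 1\] (vectorised).
#' @export
#' @examples
#' prob_cost_effective(37664, 0.041)   # 0.9795
#' prob_cost_effective(-4466, 0.671)   # 0.3355
prob_cost_effective <- function(delta, two_sided_p) {
  if (any(!is.na(two_sided_p) & (two_sided_p < 0 | two_sided_p > 1)))
    stop("two-sided p-values must lie in [0, 1]", call. = FALSE)
  one_sided <- two_sided_p / 2
  ifelse(delta > 0, 1 - one_sided, ifelse(delta < 0, one_sided, 0.5))
}

new_ceac_curve <- function(points, label, model) {
  structure(points, label = label, model = model,
            class = c("ceac_curve", "data.frame"))
}

#' Cost-effectiveness acceptability curve
#'
#' Fits a net-benefit regression at every ceiling ratio of a grid and
#' converts each fit's treatment coefficient and two-sided p-value into a
#' probability of cost-effectiveness, giving the CEAC: the probability
#' that the intervention is preferred over the comparator as a function
#' of the maximum a decision maker is willing to pay per unit effect.
#'
#' @param dataset a [cea_dataset].
#' @param grid a [ceiling_grid] (or numeric vector of ceiling ratios).
#' @param covariates optional covariates for an adjusted curve (see
#'   [fit_nb_adjusted()]).
#' @param interactions include treatment-by-covariate interactions.
#' @param robust heteroskedasticity-robust standard errors.
#' @param label curve label, e.g. `"overall"`, `"place=1"`, `"adjusted"`.
#' @return object of class `ceac_curve`: a data frame with columns
#'   `lambda`, `delta`, `se`, `two_sided_p`, `one_sided_p`,
#'   `prob_cost_effective`, ordered by `lambda`.
#' @export
#' @examples
#' d <- generate_cea(default_nouna_config(exact_moments = TRUE))
#' ceac <- build_ceac(d, ceiling_grid(0, 1e6, 1e5))
#' icer_from_ceac(ceac)
build_ceac <- function(dataset, grid, covariates = NULL,
                       interactions = FALSE, robust = FALSE,
                       label = if (length(covariates)) "adjusted" else "overall") {
  if (!inherits(grid, "ceiling_grid")) grid <- ceiling_grid(values = grid)
  rows <- lapply(as.numeric(grid), function(lam) {
    fit <- tryCatch(
      fit_nb(dataset, lam, covariates = covariates,
             interactions = interactions, robust = robust),
      error = function(e)
        stop(sprintf("net-benefit fit failed at lambda = %s: %s",
                     format(lam, big.mark = ","), conditionMessage(e)),
             call. = FALSE))
    data.frame(lambda = lam, delta = fit$delta, se = fit$delta_se,
               two_sided_p = fit$delta_p,
               one_sided_p = fit$delta_p / 2,
               prob_cost_effective =
                 prob_cost_effective(fit$delta, fit$delta_p))
  })
  model <- if (!length(covariates)) "simple"
           else if (interactions) "adjusted_with_interactions"
           else "adjusted"
  new_ceac_curve(do.call(rbind, rows), label = label, model = model)
}

#' @export
as.data.frame.ceac_curve <- function(x, ...) {
  attr(x, "label") <- NULL
  attr(x, "model") <- NULL
  class(x) <- "data.frame"
  x
}

#' @export
print.ceac_curve <- function(x, ...) {
  cat(sprintf("<ceac_curve> '%s' (%s model), %d ceiling ratios in [%s, %s]\n",
              attr(x, "label"), attr(x, "model"), nrow(x),
              format(min(x$lambda), big.mark = ","),
              format(max(x$lambda), big.mark = ",")))
  print(utils::head(as.data.frame(x), 8))
  if (nrow(x) > 8) cat("  ...", nrow(x) - 8, "more rows\n")
  invisible(x)
}

# First crossing of `threshold` by prob_cost_effective in grid order,
# linearly interpolated on (lambda, P). NA when no crossing.
first_crossing <- function(curve, threshold) {
  p <- curve$prob_cost_effective
  lam <- curve$lambda
  if (anyNA(p)) {
    keep <- !is.na(p)
    p <- p[keep]; lam <- lam[keep]
  }
  if (!length(p)) return(NA_real_)
  if (p[1] == threshold) return(lam[1])
  for (i in seq_len(length(p) - 1L)) {
    lo <- p[i]; hi <- p[i + 1L]
    if ((lo < threshold && hi >= threshold) ||
        (lo > threshold && hi <= threshold)) {
      if (hi == lo) return(lam[i + 1L])
      return(lam[i] + (threshold - lo) / (hi - lo) * (lam[i + 1L] - lam[i]))
    }
  }
  NA_real_
}

#' CEAC-based ICER
#'
#' The ceiling ratio at which the probability of cost-effectiveness first
#' crosses 50% — for the simple model this is the sample ICER, since the
#' incremental net benefit \eqn{\delta(\lambda) = \lambda\Delta E - \Delta C}
#' is zero exactly at \eqn{\lambda = \Delta C/\Delta E}. Linear
#' interpolation between adjacent grid points; no smoothing.
#'
#' @param curve a `ceac_curve`.
#' @return the crossing ceiling ratio, or `NA` if the curve never crosses
#'   0.5 within the grid.
#' @export
icer_from_ceac <- function(curve) {
  stopifnot(inherits(curve, "ceac_curve"))
  first_crossing(curve, 0.5)
}

#' CEAC-based confidence interval for the ICER
#'
#' Reads an equal-tailed confidence interval for the ICER off the CEAC:
#' the ceiling ratios at which the probability of cost-effectiveness
#' first crosses \eqn{(1-level)/2} and \eqn{1-(1-level)/2}. A bound whose
#' threshold is never crossed inside the grid is reported open (`NA`).
#'
#' @param curve a `ceac_curve`.
#' @param level confidence level in (0, 1), default 0.95.
#' @return named numeric vector `c(lower, upper)`; `NA` marks an open
#'   bound.
#' @export
ci_from_ceac <- function(curve, level = 0.95) {
  stopifnot(inherits(curve, "ceac_curve"))
  if (length(level) != 1 || is.na(level) || level <= 0 || level >= 1)
    stop("level must lie strictly between 0 and 1", call. = FALSE)
  alpha <- (1 - level) / 2
  c(lower = first_crossing(curve, alpha),
    upper = first_crossing(curve, 1 - alpha))
}

#' Subgroup acceptability curves
#'
#' One simple-model CEAC per level of a stratifying covariate, each fit on
#' the stratum's records only. Levels missing either arm raise an error
#' naming the stratum.
#'
#' @param dataset a [cea_dataset].
#' @param grid a [ceiling_grid].
#' @param by covariate column to stratify on.
#' @param robust heteroskedasticity-robust standard errors.
#' @return named list of `ceac_curve` objects, labelled `<by>=<level>`.
#' @export
subgroup_ceacs <- function(dataset, grid, by, robust = FALSE) {
  stopifnot(inherits(dataset, "cea_dataset"))
  if (!by %in% names(dataset))
    stop("covariate not found: ", by, call. = FALSE)
  levels <- sort(unique(dataset[[by]][!is.na(dataset[[by]])]))
  if (!length(levels)) stop("covariate ", by, " has no observed levels",
                            call. = FALSE)
  out <- lapply(levels, function(lv) {
    sub <- dataset[!is.na(dataset[[by]]) & dataset[[by]] == lv, ,
                   drop = FALSE]
    check_two_arms(sub, sprintf("stratum %s = %s", by, format(lv)))
    build_ceac(sub, grid, robust = robust,
               label = sprintf("%s=%s", by, format(lv)))
  })
  stats::setNames(out, sprintf("%s=%s", by, format(levels)))
}

#' Covariate-adjusted acceptability curve
#'
#' CEAC built from the treatment coefficient and p-value of the
#' covariate-adjusted net-benefit regression at each ceiling ratio.
#'
#' @inheritParams build_ceac
#' @return a `ceac_curve` labelled `"adjusted"`.
#' @export
adjusted_ceac <- function(dataset, grid, covariates,
                          interactions = FALSE, robust = FALSE) {
  build_ceac(dataset, grid, covariates = covariates,
             interactions = interactions, robust = robust,
             label = "adjusted")
}

#' Export one or more CEAC curves as a delimited table
#'
#' Writes curves to CSV with columns `lambda`, `delta`, `se`,
#' `two_sided_p`, `one_sided_p`, `prob_cost_effective`, `label`.
#'
#' @param curves a `ceac_curve` or list of them.
#' @param path destination CSV path.
#' @return `path`, invisibly.
#' @export
write_ceac <- function(curves, path) {
  utils::write.csv(ceac_table(curves), path, row.names = FALSE, na = "")
  invisible(path)
}

ceac_table <- function(curves) {
  if (inherits(curves, "ceac_curve")) curves <- list(curves)
  do.call(rbind, lapply(curves, function(cv) {
    df <- as.data.frame(cv)
    df$label <- attr(cv, "label")
    df
  }))
}

#' Plot acceptability curves
#'
#' Probability of cost-effectiveness against the ceiling ratio, one line
#' per curve, with the ceiling axis in thousands of currency units and a
#' dashed reference line at 50%.
#'
#' @param curves a `ceac_curve` or list of them.
#' @param currency currency label for the x axis.
#' @return a ggplot object.
#' @export
plot_ceac <- function(curves, currency = "XOF") {
  df <- ceac_table(curves)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lambda / 1000,
                                   y = .data$prob_cost_effective,
                                   colour = .data$label)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = sprintf("Ceiling ratio (thousands of %s per unit effect)",
                              currency),
                  y = "Probability cost-effective", colour = NULL) +
    ggplot2::theme_minimal()
}
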