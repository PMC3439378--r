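#' Per-record net monetary benefits
#'
#' For a willingness-to-pay ceiling ratio \eqn{\lambda} (currency per unit
#' effect), each record's net monetary benefit is
#' \eqn{NB_i = \lambda E_i - C_i}: the effect monetised at \eqn{\lambda}
#' minus the cost. Order is preserved.
#'
#' @param dataset a [cea_dataset].
#' @param lambda ceiling ratio, a single value \eqn{\ge 0}.
#' @return numeric vector, one value per record.
#' @export
#' @examples
#' d <- cea_dataset(data.frame(household_id = 1, treated = 1,
#'                             cost = 70253, effect = 1))
#' net_benefit(d, 700000)   # 629747
net_benefit <- function(dataset, lambda) {
  stopifnot(inherits(dataset, "cea_dataset"))
  if (length(lambda) != 1 || is.na(lambda) || lambda < 0)
    stop("lambda must be a single non-negative ceiling ratio", call. = FALSE)
  lambda * dataset$effect - dataset$cost
}

#' Build a grid of ceiling ratios
#'
#' Either a regular sequence `seq(start, stop, step)` or an explicit value
#' list; values are sorted, de-duplicated and validated to be
#' non-negative. The default grid spans 0 to 2,500,000 XOF in steps of
#' 100,000, bracketing plausible willingness-to-pay per unit utilisation.
#'
#' @param start,stop,step regular-grid specification (`step > 0`).
#' @param values explicit ceiling ratios (overrides the regular spec).
#' @return object of class `ceiling_grid` (a sorted numeric vector).
#' @export
#' @examples
#' ceiling_grid(0, 1e6, 5e5)        # 0, 500000, 1000000
#' ceiling_grid(values = c(5, 5, 1)) # 1, 5
ceiling_grid <- function(start = 0, stop = 2.5e6, step = 1e5,
                         values = NULL) {
  if (is.null(values)) {
    if (step <= 0) stop("step must be positive", call. = FALSE)
    values <- seq(start, stop, by = step)
  }
  if (!length(values)) stop("empty ceiling-ratio grid", call. = FALSE)
  if (any(is.na(values) | values < 0))
    stop("ceiling ratios must be non-negative", call. = FALSE)
  structure(sort(unique(as.numeric(values))), class = "ceiling_grid")
}

#' Net-benefit regression at one ceiling ratio
#'
#' Ordinary-least-squares fit of the per-record net benefit
#' \eqn{NB_i(\lambda)} on the treatment dummy — the simple model
#' \eqn{NB_i = \alpha + \delta t_i + \epsilon_i}, in which \eqn{\delta} is
#' the incremental net benefit and equals the between-arm difference in
#' mean net benefit exactly — or, via [fit_nb_adjusted()], on treatment
#' plus covariate main effects and optional treatment-by-covariate
#' interactions. Standard errors are homoskedastic OLS by default
#' (heteroskedasticity-robust HC1 behind `robust = TRUE`); p-values are
#' two-sided from the t distribution on the residual degrees of freedom.
#'
#' @param dataset a [cea_dataset] with at least two records per arm.
#' @param lambda ceiling ratio \eqn{\ge 0}.
#' @param robust use HC1 heteroskedasticity-robust standard errors.
#' @return object of class `nb_fit`: list with `lambda`, `model`, `n`,
#'   `n_dropped`, `coefficients` (data frame: `term`, `estimate`, `se`,
#'   `p_value`), `delta`, `delta_se`, `delta_p` (the intervention row),
#'   `sigma` (residual SD), `adj_r_squared`, `f_statistic`, `df`
#'   (regression and residual degrees of freedom), `degenerate` (TRUE when
#'   the residual variance is zero, in which case p-values are `NA`).
#' @export
#' @examples
#' d <- generate_cea(default_nouna_config(exact_moments = TRUE))
#' fit_nb_simple(d, 700000)
fit_nb_simple <- function(dataset, lambda, robust = FALSE) {
  fit_nb(dataset, lambda, covariates = NULL, interactions = FALSE,
         robust = robust)
}

#' Covariate-adjusted net-benefit regression at one ceiling ratio
#'
#' @param covariates character vector of covariate column names entering
#'   as main effects (`asset_quintile` enters as a single ordinal numeric
#'   term unless `quintile_indicators = TRUE`). Empty means the simple
#'   model.
#' @param interactions also include treatment-by-covariate product terms,
#'   whose coefficients show how the incremental net benefit varies at the
#'   margin of each covariate.
#' @param quintile_indicators code `asset_quintile` as four indicator
#'   contrasts instead of one ordinal term.
#' @inheritParams fit_nb_simple
#' @return an `nb_fit`; `delta` is the adjusted incremental net benefit
#'   (at covariates zero when interactions are present).
#' @rdname fit_nb_simple
#' @export
fit_nb_adjusted <- function(dataset, lambda, covariates,
                            interactions = FALSE, robust = FALSE,
                            quintile_indicators = FALSE) {
  fit_nb(dataset, lambda, covariates = covariates,
         interactions = interactions, robust = robust,
         quintile_indicators = quintile_indicators)
}

fit_nb <- function(dataset, lambda, covariates = NULL,
                   interactions = FALSE, robust = FALSE,
                   quintile_indicators = FALSE) {
  stopifnot(inherits(dataset, "cea_dataset"))
  if (length(lambda) != 1 || is.na(lambda) || lambda < 0)
    stop("lambda must be a single non-negative ceiling ratio", call. = FALSE)
  covariates <- covariates[nzchar(covariates)]
  missing_cov <- setdiff(covariates, names(dataset))
  if (length(missing_cov))
    stop("covariate(s) not in dataset: ",
         paste(missing_cov, collapse = ", "), call. = FALSE)
  cc <- complete_cases_on(dataset, covariates)
  d <- as.data.frame(cc$data)
  check_two_arms(d)
  if (sum(d$treated == 1) < 2 || sum(d$treated == 0) < 2)
    stop("each arm needs at least two records to estimate the residual variance",
         call. = FALSE)
  d$.nb <- lambda * d$effect - d$cost
  terms <- "treated"
  if (length(covariates)) {
    cov_terms <- vapply(covariates, function(v) {
      if (v == "asset_quintile" && quintile_indicators)
        "factor(asset_quintile)" else v
    }, character(1))
    terms <- c(terms, cov_terms)
    if (interactions) terms <- c(terms, paste0("treated:", cov_terms))
  }
  form <- stats::as.formula(paste(".nb ~", paste(terms, collapse = " + ")))
  fit <- stats::lm(form, data = d)
  n <- nrow(d)
  p_model <- fit$rank
  if (n < p_model + 2)
    stop("too few complete cases for the requested model", call. = FALSE)
  aliased <- is.na(stats::coef(fit))
  if (any(aliased))
    stop("collinear design; drop column(s): ",
         paste(names(stats::coef(fit))[aliased], collapse = ", "),
         call. = FALSE)
  est <- stats::coef(fit)
  df_res <- fit$df.residual
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / df_res
  degenerate <- sigma2 <= .Machine$double.eps * mean(d$.nb^2 + 1)
  # vcov/summary warn on a perfect fit; degeneracy is flagged explicitly instead
  vc <- suppressWarnings(
    if (robust) sandwich::vcovHC(fit, type = "HC1") else stats::vcov(fit))
  se <- sqrt(pmax(diag(vc), 0))  # guard tiny negative fp diagonals (HC on a degenerate arm)
  names(se) <- names(est)
  tval <- est / se
  pval <- if (degenerate) rep(NA_real_, length(est))
          else 2 * stats::pt(-abs(tval), df_res)
  coefs <- data.frame(term = names(est), estimate = unname(est),
                      se = unname(se), p_value = unname(pval),
                      stringsAsFactors = FALSE)
  sm <- suppressWarnings(summary(fit))
  fstat <- if (!is.null(sm$fstatistic)) unname(sm$fstatistic[1]) else NA_real_
  model <- if (!length(covariates)) "simple"
           else if (interactions) "adjusted_with_interactions"
           else "adjusted"
  structure(list(lambda = lambda, model = model, n = n,
                 n_dropped = cc$n_dropped, coefficients = coefs,
                 delta = unname(est["treated"]),
                 delta_se = unname(se["treated"]),
                 delta_p = coefs$p_value[coefs$term == "treated"],
                 sigma = sqrt(sigma2),
                 adj_r_squared = sm$adj.r.squared,
                 f_statistic = fstat,
                 df = c(regression = p_model - 1L, residual = df_res),
                 degenerate = degenerate,
                 robust = robust),
            class = "nb_fit")
}

#' @export
print.nb_fit <- function(x, ...) {
  cat(sprintf("<nb_fit> %s model at lambda = %s (n = %d%s)\n", x$model,
              format(x$lambda, big.mark = ","), x$n,
              if (x$n_dropped) sprintf(", %d dropped", x$n_dropped) else ""))
  cat(sprintf("  incremental net benefit (delta): %.1f (SE %.1f, p = %s)\n",
              x$delta, x$delta_se,
              if (is.na(x$delta_p)) "NA" else format.pval(x$delta_p, digits = 3)))
  cat(sprintf("  adj R-squared %.4f; F = %.2f on %d and %d df\n",
              x$adj_r_squared, x$f_statistic, x$df[["regression"]],
              x$df[["residual"]]))
  if (x$degenerate) cat("  note: zero residual variance; p-values degenerate\n")
  invisible(x)
}
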