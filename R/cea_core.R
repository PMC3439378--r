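#' Per-arm summary statistics
#'
#' Means, standard deviations and standard errors of cost and effect for
#' each arm, optionally within one stratum of a covariate. SDs use the
#' n-1 denominator; SEs are sd/sqrt(n). A single-record arm reports SD and
#' SE as `NA` (undefined with the n-1 denominator).
#'
#' @param dataset a [cea_dataset].
#' @param by optional covariate name to stratify on.
#' @param level stratum level (required with `by`).
#' @return object of class `cea_group_summary`: a data frame with one row
#'   per arm and columns `arm`, `n`, `mean_cost`, `sd_cost`, `se_cost`,
#'   `mean_effect`, `sd_effect`, `se_effect`.
#' @export
#' @examples
#' d <- generate_cea(default_nouna_config(exact_moments = TRUE))
#' summarize_groups(d)
summarize_groups <- function(dataset, by = NULL, level = NULL) {
  stopifnot(inherits(dataset, "cea_dataset"))
  label <- "dataset"
  if (!is.null(by)) {
    if (is.null(level)) stop("'level' is required when 'by' is given",
                             call. = FALSE)
    if (!by %in% names(dataset))
      stop("covariate not found: ", by, call. = FALSE)
    dataset <- dataset[!is.na(dataset[[by]]) & dataset[[by]] == level, ,
                       drop = FALSE]
    label <- sprintf("stratum %s = %s", by, format(level))
  }
  check_two_arms(dataset, label)
  one <- function(t) {
    d <- dataset[dataset$treated == t, ]
    n <- nrow(d)
    sdc <- if (n > 1) stats::sd(d$cost) else NA_real_
    sde <- if (n > 1) stats::sd(d$effect) else NA_real_
    data.frame(arm = if (t == 1) "intervention" else "comparison",
               n = n,
               mean_cost = mean(d$cost), sd_cost = sdc,
               se_cost = sdc / sqrt(n),
               mean_effect = mean(d$effect), sd_effect = sde,
               se_effect = sde / sqrt(n))
  }
  out <- rbind(one(0), one(1))
  attr(out, "stratum") <- if (is.null(by)) NULL else c(by = by, level = level)
  class(out) <- c("cea_group_summary", "data.frame")
  out
}

#' Incremental cost, effect and the ICER
#'
#' Differences in mean cost and mean effect (intervention minus
#' comparison), the pooled homoskedastic standard error of the cost
#' difference, the incremental cost-effectiveness ratio
#' \eqn{\Delta C / \Delta E} and its cost-effectiveness-plane quadrant.
#' The ICER is reported on the per-unit effect scale and, for a binary
#' effect, also per percentage point (`icer / 100`).
#'
#' @param summaries a `cea_group_summary` from [summarize_groups()].
#' @return object of class `cea_incremental`: list with elements
#'   `delta_cost`, `delta_effect`, `se_delta_cost`, `icer` (NA when
#'   \eqn{\Delta E = 0}), `icer_per_point`, `icer_defined`, `quadrant`.
#' @export
#' @examples
#' d <- generate_cea(default_nouna_config(exact_moments = TRUE))
#' incremental(summarize_groups(d))
incremental <- function(summaries) {
  stopifnot(inherits(summaries, "cea_group_summary"))
  s1 <- summaries[summaries$arm == "intervention", ]
  s0 <- summaries[summaries$arm == "comparison", ]
  dC <- s1$mean_cost - s0$mean_cost
  dE <- s1$mean_effect - s0$mean_effect
  n1 <- s1$n; n0 <- s0$n
  se <- if (n1 > 1 && n0 > 1) {
    sp2 <- ((n1 - 1) * s1$sd_cost^2 + (n0 - 1) * s0$sd_cost^2) /
      (n1 + n0 - 2)
    sqrt(sp2 * (1 / n1 + 1 / n0))
  } else NA_real_
  defined <- dE != 0
  icer <- if (defined) dC / dE else NA_real_
  structure(list(delta_cost = dC, delta_effect = dE, se_delta_cost = se,
                 icer = icer, icer_per_point = icer / 100,
                 icer_defined = defined,
                 quadrant = classify_quadrant(dC, dE)),
            class = "cea_incremental")
}

#' @export
print.cea_incremental <- function(x, ...) {
  cat("<cea_incremental>\n")
  cat(sprintf("  delta cost   : %12.1f (SE %.1f)\n", x$delta_cost,
              x$se_delta_cost))
  cat(sprintf("  delta effect : %12.4f\n", x$delta_effect))
  if (x$icer_defined)
    cat(sprintf("  ICER         : %12.1f per unit effect (%.1f per percentage point)\n",
                x$icer, x$icer_per_point))
  else cat("  ICER         : undefined (delta effect = 0)\n")
  cat("  quadrant     :", x$quadrant, "\n")
  invisible(x)
}

#' Classify an intervention on the cost-effectiveness plane
#'
#' Quadrant of the (incremental effect, incremental cost) plane:
#' `dominant` (cheaper and more effective), `dominated` (costlier and less
#' effective), `northeast_tradeoff` (costlier and more effective, the
#' usual case for new interventions), `southwest_tradeoff` (cheaper and
#' less effective), or `on_axis` when either increment is zero.
#'
#' @param delta_cost,delta_effect increments (intervention minus
#'   comparison).
#' @return character scalar (vectorised over the inputs).
#' @export
#' @examples
#' classify_quadrant(60623, 0.14)   # "northeast_tradeoff"
classify_quadrant <- function(delta_cost, delta_effect) {
  out <- ifelse(delta_cost == 0 | delta_effect == 0, "on_axis",
         ifelse(delta_cost < 0 & delta_effect > 0, "dominant",
         ifelse(delta_cost > 0 & delta_effect < 0, "dominated",
         ifelse(delta_cost > 0, "northeast_tradeoff",
                "southwest_tradeoff"))))
  out
}
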