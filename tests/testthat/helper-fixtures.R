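# Shared fixtures and independent oracles.

# Exact-moment two-arm cohort via the generator: k1/n1 users in the
# intervention arm (costs with exact mean m1, SD s1, uncorrelated with the
# effect), k0/n0 users in the comparison arm at constant cost c0.
exact_cohort <- function(n1, k1, m1, s1, n0, k0, c0 = 9630, seed = 7L) {
  generate_cea(synthetic_config(
    n_members = n1, n_nonmembers = n0,
    p_effect_member = k1 / n1, p_effect_nonmember = k0 / n0,
    cost_nonmember = c0, cost_member_mean = m1, cost_member_sd = s1,
    seed = seed, exact_moments = TRUE))
}

# The overall cohort built from the published arm sizes and use counts
# (363 members with 310 users; 981 non-members with 700 users) and the
# published cost moments.
nouna_exact <- function(seed = 7L) {
  exact_cohort(363, 310, 70253, 11658, 981, 700, 9630, seed = seed)
}

# Independent least-squares oracle: normal equations, homoskedastic
# t-based inference. Never calls lm().
ols_oracle <- function(X, y) {
  XtX <- crossprod(X)
  b <- solve(XtX, crossprod(X, y))
  res <- y - X %*% b
  df <- nrow(X) - ncol(X)
  s2 <- sum(res^2) / df
  se <- sqrt(diag(s2 * solve(XtX)))
  tt <- drop(b) / se
  list(coef = drop(b), se = se, p = 2 * pt(-abs(tt), df), sigma2 = s2,
       df = df)
}

# Closed-form two-group oracle for exact-moment cohorts (cost independent
# of effect within arm, comparison cost constant): coefficient, SE,
# two-sided p, probability cost-effective (%), adjusted R-squared.
closed_form_fit <- function(lambda, n1, k1, m1, s1, n0, k0, c0) {
  p1 <- k1 / n1; p0 <- k0 / n0
  delta <- lambda * (p1 - p0) - (m1 - c0)
  ssw_e1 <- k1 * (1 - p1)^2 + (n1 - k1) * p1^2
  ssw_e0 <- k0 * (1 - p0)^2 + (n0 - k0) * p0^2
  ss1 <- lambda^2 * ssw_e1 + (n1 - 1) * s1^2
  ss0 <- lambda^2 * ssw_e0
  n <- n1 + n0
  sig2 <- (ss1 + ss0) / (n - 2)
  se <- sqrt(sig2 * (1 / n1 + 1 / n0))
  p2 <- 2 * pt(-abs(delta / se), n - 2)
  prob <- if (delta > 0) 1 - p2 / 2 else if (delta < 0) p2 / 2 else 0.5
  y1 <- lambda * p1 - m1; y0 <- lambda * p0 - c0
  ybar <- (n1 * y1 + n0 * y0) / n
  ssb <- n1 * (y1 - ybar)^2 + n0 * (y0 - ybar)^2
  r2 <- ssb / (ssb + ss1 + ss0)
  list(delta = delta, se = se, p2 = p2, prob_pct = 100 * prob,
       adj_r2 = 1 - (1 - r2) * (n - 1) / (n - 2))
}

# Small random but valid dataset for property-style tests.
random_dataset <- function(n1 = 40, n0 = 60, seed = 1) {
  set.seed(seed)
  cea_dataset(data.frame(
    household_id = sprintf("r%03d", seq_len(n1 + n0)),
    treated = rep(c(1, 0), c(n1, n0)),
    cost = c(rnorm(n1, 60000, 9000), rnorm(n0, 12000, 3000)),
    effect = rbinom(n1 + n0, 1, rep(c(0.8, 0.6), c(n1, n0))),
    education = rbinom(n1 + n0, 1, 0.5),
    place = rbinom(n1 + n0, 1, 0.45),
    asset_quintile = sample(1:5, n1 + n0, replace = TRUE)))
}

# Swap arm labels.
swap_arms <- function(dataset) {
  dataset$treated <- 1 - dataset$treated
  dataset
}
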