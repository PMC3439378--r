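test_that("the p-value sign rule is a pure transformation", {
  # published transformation rows: (37664, 0.041) -> 98%; (-4466, 0.671) -> 33.5%
  expect_equal(prob_cost_effective(37664, 0.041), 0.9795)
  expect_equal(round(100 * prob_cost_effective(37664, 0.041)), 98)
  expect_equal(prob_cost_effective(-4466, 0.671), 0.3355)
  expect_equal(100 * prob_cost_effective(-4466, 0.671), 33.5,
               tolerance = 0.005)  # published table prints 33.5
  expect_equal(prob_cost_effective(0, 1.0), 0.5)
  expect_equal(prob_cost_effective(0, 0.2), 0.5)
  expect_error(prob_cost_effective(1, 1.2), "\\[0, 1\\]")
  expect_error(prob_cost_effective(1, -0.1), "\\[0, 1\\]")
  # vectorised, symmetric in the sign of delta
  expect_equal(prob_cost_effective(c(5, -5), c(0.2, 0.2)), c(0.9, 0.1))
})

test_that("the overall CEAC crosses 50% between 400k and 500k on the fixture", {
  d <- nouna_exact()
  curve <- build_ceac(d, ceiling_grid(0, 1e6, 1e5))
  expect_s3_class(curve, "ceac_curve")
  expect_equal(curve$one_sided_p, curve$two_sided_p / 2)
  expect_true(all(diff(curve$lambda) > 0))
  p4 <- curve$prob_cost_effective[curve$lambda == 4e5]
  p5 <- curve$prob_cost_effective[curve$lambda == 5e5]
  expect_lt(p4, 0.5)
  expect_gt(p5, 0.5)
  cross <- icer_from_ceac(curve)
  expect_gt(cross, 4e5)
  expect_lt(cross, 5e5)
  expect_error(build_ceac(d, numeric()), "empty")
})

test_that("large samples are nearly certain at five times the ICER", {
  cfg <- default_nouna_config(seed = 3)
  cfg$n_members <- 5000L
  cfg$n_nonmembers <- 5000L
  d <- generate_cea(do.call(synthetic_config, unclass(cfg)))
  icer <- incremental(summarize_groups(d))$icer
  curve <- build_ceac(d, ceiling_grid(values = 5 * icer))
  expect_gt(curve$prob_cost_effective, 0.99)
})

test_that("the 50% crossing recovers the sample ICER", {
  for (seed in c(4, 12, 29)) {
    d <- random_dataset(seed = seed)
    inc <- incremental(summarize_groups(d))
    grid <- ceiling_grid(0, ceiling(2.5 * inc$icer / 1e4) * 1e4, 1e4)
    cross <- icer_from_ceac(build_ceac(d, grid))
    # delta(lambda) = 0 exactly at the sample ICER; interpolation is on P,
    # so allow one grid step of slack
    expect_lt(abs(cross - inc$icer), 1e4)
    # P at the exact sample ICER is 0.5 by construction
    at <- build_ceac(d, ceiling_grid(values = inc$icer))
    expect_equal(at$prob_cost_effective, 0.5, tolerance = 1e-9)
  }
})

test_that("a curve that never crosses a threshold reports an open bound", {
  d <- nouna_exact()
  high <- build_ceac(d, ceiling_grid(7e5, 1e6, 1e5))  # entirely above 0.5
  expect_true(is.na(icer_from_ceac(high)))
  ci <- ci_from_ceac(build_ceac(d, ceiling_grid(3e5, 6e5, 5e4)))
  expect_true(is.na(ci[["upper"]]))  # 0.975 not reached inside this grid
  expect_error(ci_from_ceac(high, level = 1.5), "level")
})

test_that("confidence bounds collapse to the 50% crossing as level -> 0", {
  d <- nouna_exact()
  curve <- build_ceac(d, ceiling_grid(0, 1.5e6, 2.5e4))
  cross <- icer_from_ceac(curve)
  ci <- ci_from_ceac(curve, level = 1e-6)
  expect_equal(ci[["lower"]], cross, tolerance = 1e-3)
  expect_equal(ci[["upper"]], cross, tolerance = 1e-3)
  # nominal-level interval brackets the crossing
  ci95 <- ci_from_ceac(curve, level = 0.95)
  expect_lt(ci95[["lower"]], cross)
  expect_gt(ci95[["upper"]], cross)
})

test_that("subgroup curves equal filter-and-fit and town dominates at low ceilings", {
  town <- exact_cohort(230, 209, 68165.5, 11658, 394, 281, seed = 8)
  town$place <- 1
  villages <- exact_cohort(134, 112, 73837, 11658, 588, 420, seed = 9)
  villages$place <- 0
  villages$household_id <- paste0("v", villages$household_id)
  d <- cea_dataset(rbind(as.data.frame(town), as.data.frame(villages)))
  grid <- ceiling_grid(0, 8e5, 1e5)
  curves <- subgroup_ceacs(d, grid, "place")
  expect_named(curves, c("place=0", "place=1"))
  # oracle: manually filtered subset
  manual <- build_ceac(cea_dataset(as.data.frame(d)[d$place == 1, ]), grid)
  expect_equal(as.data.frame(curves[["place=1"]]), as.data.frame(manual))
  # town curve dominates the villages curve at every ceiling <= 800k
  expect_true(all(curves[["place=1"]]$prob_cost_effective >=
                    curves[["place=0"]]$prob_cost_effective))
  # stratifying on a constant covariate returns the overall curve
  d$education <- 1
  const <- subgroup_ceacs(d, grid, "education")
  expect_length(const, 1)
  expect_equal(const[[1]]$prob_cost_effective,
               build_ceac(d, grid)$prob_cost_effective)
  # a stratum missing an arm is an error naming the stratum
  d2 <- d
  d2$place[d2$treated == 1] <- 1
  expect_error(subgroup_ceacs(d2, grid, "place"), "place = 0")
})

test_that("the adjusted curve nests the unadjusted one and matches the oracle", {
  d <- random_dataset(seed = 61)
  grid <- ceiling_grid(0, 6e5, 2e5)
  expect_equal(as.data.frame(adjusted_ceac(d, grid, character())),
               as.data.frame(build_ceac(d, grid)))
  adj <- adjusted_ceac(d, grid, c("education", "place"))
  X <- cbind(1, d$treated, d$education, d$place)
  for (i in seq_len(nrow(adj))) {
    orc <- ols_oracle(X, net_benefit(d, adj$lambda[i]))
    expect_equal(adj$delta[i], orc$coef[2])
    expect_equal(adj$two_sided_p[i], unname(orc$p[2]))
  }
})

test_that("adjusting for an informative covariate moves the 50% crossing", {
  # members concentrated in town, town cheaper to move: place confounds
  town <- exact_cohort(230, 209, 68165.5, 11658, 394, 281, seed = 18)
  town$place <- 1
  villages <- exact_cohort(134, 112, 73837, 11658, 588, 420, seed = 19)
  villages$place <- 0
  villages$household_id <- paste0("v", villages$household_id)
  d <- cea_dataset(rbind(as.data.frame(town), as.data.frame(villages)))
  grid <- ceiling_grid(0, 1.5e6, 2.5e4)
  unadj <- icer_from_ceac(build_ceac(d, grid))
  adj <- icer_from_ceac(adjusted_ceac(d, grid, "place"))
  expect_false(isTRUE(all.equal(adj, unadj, tolerance = 1e-6)))
})

test_that("probabilities are antisymmetric under arm swap and cost-scale invariant", {
  d <- random_dataset(seed = 71)
  grid <- ceiling_grid(0, 1e6, 2e5)
  p <- build_ceac(d, grid)$prob_cost_effective
  p_swapped <- build_ceac(swap_arms(d), grid)$prob_cost_effective
  expect_equal(p_swapped, 1 - p)
  dk <- d
  k <- 655.957
  dk$cost <- dk$cost * k
  p_scaled <- build_ceac(dk, ceiling_grid(values = as.numeric(grid) * k)
                         )$prob_cost_effective
  expect_equal(p_scaled, p)
})

test_that("the curve's asymptote is the effect-only regression probability", {
  d <- random_dataset(seed = 81)
  far <- build_ceac(d, ceiling_grid(values = 1e12))
  eff_fit <- summary(lm(effect ~ treated, data = d))$coefficients
  p_eff <- prob_cost_effective(eff_fit["treated", "Estimate"],
                               eff_fit["treated", "Pr(>|t|)"])
  expect_equal(far$prob_cost_effective, p_eff, tolerance = 1e-4)
  expect_lt(far$prob_cost_effective, 1)
})

test_that("curves export to a delimited table mirroring the published layout", {
  d <- nouna_exact()
  curve <- build_ceac(d, ceiling_grid(0, 4e5, 2e5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_ceac(list(overall = curve), path)
  back <- read.csv(path)
  expect_identical(names(back),
                   c("lambda", "delta", "se", "two_sided_p", "one_sided_p",
                     "prob_cost_effective", "label"))
  expect_equal(back$delta, curve$delta)
  expect_identical(unique(back$label), "overall")
  gg <- plot_ceac(curve)
  expect_s3_class(gg, "ggplot")
})
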