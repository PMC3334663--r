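test_that("normality screening behaves on normal, bimodal and degenerate input", {
  with_seed <- bonemorph:::with_seed
  hits <- vapply(1:200, function(s)
    with_seed(s, check_normality(rnorm(12))) > 0.05, logical(1))
  expect_gte(mean(hits), 0.9)

  bimodal <- rep(c(0, 10), 6) + rep(c(-0.01, 0.01), each = 6)
  expect_lt(check_normality(bimodal), 0.05)
  expect_error(check_normality(rep(3, 12)), "zero-variance")
  expect_error(check_normality(c(1, 2)), "3 <= n")
})

test_that("rm_anova matches hand-computed sums of squares and aov", {
  # 3 animals x 2 limbs x 2 timepoints toy table
  toy <- expand.grid(animal = 1:3, limb = c("MIA", "control"), week = c(2, 6),
                     stringsAsFactors = FALSE)
  toy$compartment <- "total"; toy$parameter <- "p"
  toy$value <- c(10, 12, 14, 11, 14, 18, 13, 15, 16, 12, 16, 21)
  class(toy) <- c("longitudinal_dataset", "data.frame")
  res <- rm_anova(toy, "p", "total")

  # independent oracle: brute-force sums of squares over all cells
  y <- array(NA_real_, c(3, 2, 2))
  for (i in seq_len(nrow(toy)))
    y[toy$animal[i], match(toy$limb[i], c("MIA", "control")),
      match(toy$week[i], c(2, 6))] <- toy$value[i]
  M <- mean(y)
  ssb <- 0; ssbs <- 0; ssa <- 0; ssas <- 0; ssab <- 0; ssabs <- 0
  for (k in 1:2) ssb <- ssb + 3 * 2 * (mean(y[, , k]) - M)^2
  for (j in 1:2) ssa <- ssa + 3 * 2 * (mean(y[, j, ]) - M)^2
  for (i in 1:3) for (k in 1:2)
    ssbs <- ssbs + 2 * (mean(y[i, , k]) - mean(y[i, , ]) - mean(y[, , k]) + M)^2
  for (i in 1:3) for (j in 1:2)
    ssas <- ssas + 2 * (mean(y[i, j, ]) - mean(y[i, , ]) - mean(y[, j, ]) + M)^2
  for (j in 1:2) for (k in 1:2)
    ssab <- ssab + 3 * (mean(y[, j, k]) - mean(y[, j, ]) - mean(y[, , k]) + M)^2
  for (i in 1:3) for (j in 1:2) for (k in 1:2)
    ssabs <- ssabs + (y[i, j, k] - mean(y[i, j, ]) - mean(y[i, , k]) -
                        mean(y[, j, k]) + mean(y[i, , ]) + mean(y[, j, ]) +
                        mean(y[, , k]) - M)^2
  f_time <- (ssb / 1) / (ssbs / 2)
  f_group <- (ssa / 1) / (ssas / 2)
  f_inter <- (ssab / 1) / (ssabs / 2)
  expect_equal(res$F[res$effect == "time"], f_time, tolerance = 1e-6)
  expect_equal(res$F[res$effect == "group"], f_group, tolerance = 1e-6)
  expect_equal(res$F[res$effect == "time_x_group"], f_inter, tolerance = 1e-6)

  # cross-check against the standard error-stratified fit
  df <- transform(toy, animal = factor(animal), limb = factor(limb),
                  week = factor(week))
  fit <- summary(stats::aov(value ~ limb * week + Error(animal / (limb * week)),
                            data = df))
  f_aov_limb <- fit[["Error: animal:limb"]][[1]]["limb", "F value"]
  f_aov_week <- fit[["Error: animal:week"]][[1]]["week", "F value"]
  f_aov_int <- fit[["Error: animal:limb:week"]][[1]]["limb:week", "F value"]
  expect_equal(res$F[res$effect == "group"], f_aov_limb, tolerance = 1e-8)
  expect_equal(res$F[res$effect == "time"], f_aov_week, tolerance = 1e-8)
  expect_equal(res$F[res$effect == "time_x_group"], f_aov_int,
               tolerance = 1e-8)
})

test_that("rm_anova degenerates cleanly and refuses bad designs", {
  toy <- expand.grid(animal = 1:4, limb = c("MIA", "control"),
                     week = c(2, 6, 10), stringsAsFactors = FALSE)
  toy$compartment <- "total"; toy$parameter <- "p"
  base <- rep(c(10, 12, 9, 14), times = 6)
  toy$value <- base + rep(c(0, 1, 2), each = 8)     # pure time trend, limbs equal
  class(toy) <- c("longitudinal_dataset", "data.frame")
  res <- rm_anova(toy, "p", "total")
  expect_equal(res$SS[res$effect == "group"], 0)
  expect_equal(res$SS[res$effect == "time_x_group"], 0)
  expect_gt(res$SS[res$effect == "time"], 0)

  expect_error(rm_anova(toy[-1, ], "p", "total"), "incomplete")
  one_week <- toy[toy$week == 2, ]
  class(one_week) <- c("longitudinal_dataset", "data.frame")
  expect_error(rm_anova(one_week, "p", "total"), "2 timepoints")
})

test_that("paired tests reproduce the closed-form t and honour gating", {
  ds <- expand.grid(animal = 1:5, limb = c("MIA", "control"), week = 2,
                    stringsAsFactors = FALSE)
  ds$compartment <- "total"; ds$parameter <- "p"
  ctl <- c(10, 20, 30, 40, 50)
  ds$value <- ifelse(ds$limb == "control", ctl[ds$animal],
                     ctl[ds$animal] + ds$animal)    # differences 1..5
  class(ds) <- c("longitudinal_dataset", "data.frame")
  pt <- paired_tests(ds, "p", "total", gate = "none")
  t_expected <- 3 / (sd(1:5) / sqrt(5))             # 4.2426
  expect_equal(round(t_expected, 4), 4.2426)
  expect_equal(pt$p_raw, 2 * pt(-t_expected, df = 4))
  expect_equal(pt$p_holm, pt$p_raw)                 # single comparison family

  # all-zero differences
  ds0 <- ds; ds0$value <- ctl[ds0$animal]
  class(ds0) <- c("longitudinal_dataset", "data.frame")
  p0 <- paired_tests(ds0, "p", "total", gate = "none")
  expect_equal(p0$p_raw, 1)
  expect_equal(p0$pct_diff, 0)

  # gated out: null three-week cohort with no effects
  des <- one_cell_design(c(2, 6, 10), 250, 10, 250, 10, n_animals = 12L,
                         seed = 5L)
  null_ds <- simulate_cohort(des)
  an <- rm_anova(null_ds, "par", "total")
  if (all(an$p >= 0.05)) {
    gated <- paired_tests(null_ds, "par", "total", gate = "any")
    expect_true(all(is.na(gated$p_raw)))
    expect_false(any(gated$significant))
  }
  ungated <- paired_tests(null_ds, "par", "total", gate = "none")
  expect_true(all(is.finite(ungated$p_raw)))
  expect_equal(nrow(ungated), 3L)
})

test_that("holm_adjust implements the stepdown and its dominance bounds", {
  expect_equal(holm_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.04, 0.04))
  expect_equal(holm_adjust(0.2), 0.2)
  expect_equal(holm_adjust(c(0.5, 0.5, 0.5)), c(1, 1, 1))
  expect_error(holm_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(31)
  for (i in 1:50) {
    p <- runif(sample(1:6, 1))
    adj <- holm_adjust(p)
    expect_equal(adj, p.adjust(p, "holm"))          # independent oracle
    expect_true(all(adj >= p))
    expect_true(all(adj <= pmin(1, length(p) * p)))
  }
})

test_that("percent differences match the published worked cells", {
  expect_equal(round(percent_difference(1260, 1456), 1), -13.5)
  expect_equal(round(percent_difference(271, 250), 1), 8.4)
  expect_equal(percent_difference(7, 7), 0)
  expect_error(percent_difference(5, 0), "zero")
  # sign antisymmetry up to the ratio of the two roles
  for (pair in list(c(1260, 1456), c(271, 250), c(3, 11)))
    expect_equal(percent_difference(pair[1], pair[2]),
                 -percent_difference(pair[2], pair[1]) * pair[1] / pair[2])
})

test_that("timepoint comparisons pair within limb across weeks", {
  des <- one_cell_design(c(2, 6, 10), c(250, 240, 230), 10,
                         c(250, 248, 246), 10, n_animals = 12L, seed = 2L)
  ds <- simulate_cohort(des)
  tt <- timepoint_tests(ds, "par", "total", limb = "MIA")
  expect_equal(nrow(tt), 3L)                        # 3 week pairs
  expect_equal(tt$p_holm, holm_adjust(tt$p_raw))
  expect_true(all(tt$week_from < tt$week_to))
})

test_that("build_tables produces the full comparison grid with correct rounding", {
  des <- cohort_design(mia_table_design(), n_animals = 12L, seed = 3L)
  ds <- simulate_cohort(des)
  tabs <- build_tables(ds, gate = "none")
  expect_equal(nrow(tabs$comparisons), 6 * 3 * 3)   # parameters x compartments x weeks
  expect_equal(nrow(tabs$anova), 6 * 3 * 3)         # three effects per cell
  expect_true(all(c("pct_diff", "p_raw", "p_holm", "significant") %in%
                    names(tabs$comparisons)))
  # Holm within each parameter-compartment family
  fam <- tabs$comparisons[tabs$comparisons$parameter == "BV" &
                            tabs$comparisons$compartment == "total", ]
  expect_equal(fam$p_holm, holm_adjust(fam$p_raw))
  # rounded view: micrometre parameters as integers, Tb.N to one decimal
  r <- tabs$comparisons_rounded
  expect_true(all(r$mia_mean[r$parameter == "Tb.Sp"] ==
                    round(r$mia_mean[r$parameter == "Tb.Sp"])))
  tbn <- r$mia_mean[r$parameter == "Tb.N"]
  expect_true(all(abs(tbn * 10 - round(tbn * 10)) < 1e-9))
  expect_error(build_tables(ds[0, ]), "empty")
})

test_that("summary means track the design at large n", {
  sub <- mia_table_design()
  sub <- sub[sub$compartment == "total", ]
  des <- cohort_design(sub, n_animals = 10000L, seed = 11L)
  tabs <- build_tables(simulate_cohort(des), gate = "none")
  got <- tabs$comparisons
  for (i in seq_len(nrow(sub))) {
    row <- got[got$parameter == sub$parameter[i] & got$week == sub$week[i], ]
    expect_lt(abs(row$mia_mean - sub$mia_mean[i]) / sub$mia_mean[i], 0.01)
    expect_lt(abs(row$ctl_mean - sub$ctl_mean[i]) / sub$ctl_mean[i], 0.01)
  }
})
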