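test_that("two-way ANOVA matches the balanced cell-means oracle", {
  means <- list(X = c(MA.light = 50, MA.dark = 30, SAL.light = 25,
                      SAL.dark = 20))
  tab <- make_balanced_table(5, means, sd = 4, seed = 11)
  fit <- two_way_anova(tab, "X")
  d <- data.frame(y = tab$X, treatment = tab$treatment, phase = tab$phase)
  orc <- oracle_balanced_anova(d)
  expect_equal(fit$F[["treatment"]], orc$F_treatment, tolerance = 1e-10)
  expect_equal(fit$F[["time"]], orc$F_time, tolerance = 1e-10)
  expect_equal(fit$F[["interaction"]], orc$F_interaction, tolerance = 1e-10)
  expect_equal(fit$df$residual, orc$df_residual)
  expect_equal(fit$df$numerator[["treatment"]], 1)
  # p follows from F and the dfs
  expect_equal(fit$p[["treatment"]],
               pf(orc$F_treatment, 1, orc$df_residual, lower.tail = FALSE))
})

test_that("additive cell means with cell-mean-preserving noise give zero interaction F", {
  # residuals sum to zero within each cell, so realized cell means equal the
  # configured additive structure and the interaction contrast vanishes
  means <- list(X = c(MA.light = 40, MA.dark = 30, SAL.light = 25,
                      SAL.dark = 15))
  grid <- expand.grid(phase = c("light", "dark"), treatment = c("MA", "SAL"),
                      stringsAsFactors = FALSE)
  set.seed(1)
  res <- c(-2, -1, 0, 1, 2)
  rows <- grid[rep(1:4, each = 5), ]
  key <- paste(rows$treatment, rows$phase, sep = ".")
  df <- data.frame(animal_id = sprintf("a%02d", 1:20),
                   treatment = rows$treatment, phase = rows$phase,
                   X = means$X[key] + rep(res, 4),
                   Y = rnorm(20, 30),
                   stringsAsFactors = FALSE)
  tab <- cofosnet:::as_cfos_table(df)
  fit <- two_way_anova(tab, "X")
  expect_equal(fit$F[["interaction"]], 0, tolerance = 1e-12)
  expect_gt(fit$F[["treatment"]], 0)
})

test_that("the 40-animal design has denominator df 36", {
  tab <- simulate_cfos(cfos_sim_config(seed = 5))
  fit <- two_way_anova(tab, "SCN")
  expect_equal(fit$df$residual, 36)
})

test_that("degenerate designs are rejected with informative errors", {
  tab <- simulate_cfos(cfos_sim_config(n_per_cell = 4, seed = 2))
  madark <- which(tab$treatment == "MA" & tab$phase == "dark")
  keep <- setdiff(seq_len(nrow(tab)), madark[-1])  # leave 1 MA/dark animal
  expect_error(two_way_anova(tab[keep, ], "SCN"), "MA x dark")
  const <- tab
  const$SCN <- 7
  expect_error(two_way_anova(const, "SCN"), "degenerate")
  expect_error(two_way_anova(tab, "NOPE"), "unknown region")
})

test_that("pattern classification implements the full truth table", {
  cases <- list(
    list(flags = c(TRUE, FALSE, FALSE), pattern = "1"),
    list(flags = c(FALSE, TRUE, FALSE), pattern = "2"),
    list(flags = c(TRUE, FALSE, TRUE), pattern = "3"),
    list(flags = c(TRUE, TRUE, TRUE), pattern = "3"),
    list(flags = c(TRUE, TRUE, FALSE), pattern = "4"),
    list(flags = c(FALSE, FALSE, FALSE), pattern = "5"),
    list(flags = c(FALSE, TRUE, TRUE), pattern = "other"),
    list(flags = c(FALSE, FALSE, TRUE), pattern = "other")
  )
  for (cs in cases) {
    expect_equal(classify_pattern(cs$flags)$pattern, cs$pattern,
                 label = paste(cs$flags, collapse = ","))
  }
  # classification is a pure function of the flags at the chosen alpha
  fake <- structure(list(region = "X",
                         p = c(treatment = 0.01, time = 0.2,
                               interaction = 0.04)),
                    class = "cfos_aov")
  expect_equal(classify_pattern(fake, alpha = 0.05)$pattern, "3")
  expect_equal(classify_pattern(fake, alpha = 0.001)$pattern, "5")
})

test_that("simple effects use the pooled error and Bonferroni x4", {
  # no differences anywhere: all adjusted p capped at 1
  flat <- make_balanced_table(5, list(X = c(MA.light = 30, MA.dark = 30,
                                            SAL.light = 30, SAL.dark = 30)),
                              sd = 5, seed = 21)
  # force identical cell means by centering residuals within cells
  key <- paste(flat$treatment, flat$phase, sep = ".")
  flat$X <- flat$X - ave(flat$X, key) + 30
  ph <- simple_effects(flat, "X")
  expect_equal(ph$estimate, rep(0, 4), tolerance = 1e-12)
  expect_equal(ph$p_adj, rep(1, 4))

  # adjusted p is exactly min(1, 4 * raw p)
  tab <- simulate_cfos(cfos_sim_config(seed = 31))
  ph2 <- simple_effects(tab, "PVN")
  expect_equal(ph2$p_adj, pmin(1, 4 * ph2$p))
  expect_true(all(ph2$p_adj >= ph2$p))
})

test_that("a light-phase-only treatment effect shows in the right contrast", {
  means <- list(X = c(MA.light = 60, MA.dark = 30, SAL.light = 30,
                      SAL.dark = 30))
  tab <- make_balanced_table(10, means, sd = 8, seed = 41)
  ph <- simple_effects(tab, "X")
  light <- ph[ph$contrast == "MA - SAL | light", ]
  dark <- ph[ph$contrast == "MA - SAL | dark", ]
  expect_lt(light$p_adj, 0.05)
  expect_gt(dark$p_adj, 0.05)
  # oracle check of the light contrast via the t distribution
  fit <- two_way_anova(tab, "X")
  est <- fit$cell_means["MA", "light"] - fit$cell_means["SAL", "light"]
  tstat <- est / sqrt(fit$mse * (1 / 10 + 1 / 10))
  expect_equal(light$p, 2 * pt(-abs(tstat), 36), tolerance = 1e-12)
})

test_that("activation_patterns labels every region once and annotates trends", {
  tab <- simulate_cfos(cfos_sim_config(seed = 8))
  ap <- activation_patterns(tab)
  expect_equal(nrow(ap), 17)
  expect_setequal(ap$region, cfos_regions())
  expect_true(all(ap$pattern %in% c("1", "2", "3", "4", "5", "other")))
  expect_true(all(ap$df2 == 36))
})
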