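test_that("identical groups give zero difference, p near 1, Z near 0", {
  half <- simulate_cfos(cfos_sim_config(regions = paste0("R", 1:5),
                                        cell_means = flat_means(paste0("R", 1:5)),
                                        n_per_cell = 5, seed = 2))
  # group B is a byte-for-byte copy of group A's data
  tab <- rbind(half, half)
  tab$animal_id <- sprintf("a%02d", seq_len(nrow(tab)))
  g <- rep(c("A", "B"), each = nrow(half))
  dk <- connectivity_difference(tab, g)
  expect_equal(as.numeric(dk), rep(0, 5), tolerance = 1e-12)
  nd <- bootstrap_compare(tab, g, n_boot = 300, seed = 3)
  expect_equal(nd$delta_k, rep(0, 5), tolerance = 1e-12)
  expect_true(all(nd$p > 0.9))
  expect_true(all(abs(nd$z) < 0.5))
})

test_that("swapping group labels negates every difference, p unchanged", {
  tab <- simulate_cfos(cfos_sim_config(seed = 12))
  g1 <- factor(tab$treatment, levels = c("MA", "SAL"))
  g2 <- factor(tab$treatment, levels = c("SAL", "MA"))
  d1 <- connectivity_difference(tab, g1)
  d2 <- connectivity_difference(tab, g2)
  expect_equal(as.numeric(d1), -as.numeric(d2), tolerance = 1e-12)

  n1 <- bootstrap_compare(tab, g1, n_boot = 400, seed = 5)
  n2 <- bootstrap_compare(tab, g2, n_boot = 400, seed = 5)
  expect_equal(n1$delta_k, -n2$delta_k, tolerance = 1e-12)
  # |observed| is what the two-sided p sees; the relabelling null is
  # symmetric so p agrees up to Monte-Carlo noise
  expect_equal(n1$p, n2$p, tolerance = 0.05)
})

test_that("bootstrap output is deterministic, p in (0, 1], null symmetric", {
  tab <- simulate_cfos(cfos_sim_config(seed = 9))
  a <- bootstrap_compare(tab, n_boot = 300, seed = 7)
  b <- bootstrap_compare(tab, n_boot = 300, seed = 7)
  expect_identical(a, b)
  expect_true(all(a$p > 0 & a$p <= 1))
  # relabelling null is symmetric about zero: its mean stays within
  # 3 Monte-Carlo standard errors of 0
  expect_true(all(abs(a$null_mean) <= 3 * a$null_sd / sqrt(300) + 1e-12))
})

test_that("small groups are rejected", {
  tab <- simulate_cfos(cfos_sim_config(regions = c("A", "B", "C"),
                                       cell_means = flat_means(c("A", "B", "C")),
                                       n_per_cell = 3, seed = 1))
  g <- rep(c("x", "y"), c(3, 9))
  expect_error(bootstrap_compare(tab, g, n_boot = 100, seed = 1),
               "at least 4")
  expect_error(bootstrap_compare(tab, n_boot = 10, seed = 1), ">= 100")
})

test_that("tiny-instance bootstrap null matches exhaustive split enumeration", {
  set.seed(10)
  m <- matrix(rnorm(24, 40, 9), 8, 3, dimnames = list(NULL, c("A", "B", "C")))
  df <- data.frame(animal_id = sprintf("a%d", 1:8),
                   treatment = rep(c("MA", "SAL"), each = 4),
                   phase = rep(c("light", "dark"), 4),
                   m, stringsAsFactors = FALSE)
  tab <- cofosnet:::as_cfos_table(df)

  # exhaustive: all 70 equal-size splits of the pooled 8 animals
  splits <- combn(8, 4)
  dks <- apply(splits, 2, function(idx) {
    kA <- connectivity_profile(correlation_matrix(m[idx, , drop = FALSE]))
    kB <- connectivity_profile(correlation_matrix(m[-idx, , drop = FALSE]))
    kA - kB
  })
  ex_mean <- rowMeans(dks)
  ex_sd <- apply(dks, 1, function(v) sqrt(mean((v - mean(v))^2)))

  nb <- 4000
  nd <- bootstrap_compare(tab, n_boot = nb, seed = 77)
  se_mean <- ex_sd / sqrt(nb)
  expect_true(all(abs(nd$null_mean - ex_mean) <= 3 * se_mean))
  # SE of a Monte-Carlo sd via the fourth moment (delta method)
  m4 <- apply(dks, 1, function(v) mean((v - mean(v))^4))
  se_sd <- sqrt(pmax(m4 - ex_sd^4, 0) / nb) / (2 * ex_sd)
  expect_true(all(abs(nd$null_sd - ex_sd) <= 3 * se_sd + 1e-9))
})

test_that("a group-specific hub attains the maximal connectivity difference", {
  regions <- paste0("R", 1:8)
  hits <- 0L
  n_seeds <- 40
  for (s in seq_len(n_seeds)) {
    cfg <- cfos_sim_config(regions = regions, n_per_cell = 10,
                           cell_means = flat_means(regions, 40),
                           dispersion = 0.3, base_r = 0,
                           hub = list(region = "R1",
                                      partners = c("R2", "R3", "R4"),
                                      r = 0.7),
                           seed = 1000 + s)
    tab <- simulate_cfos(cfg)
    dk <- connectivity_difference(tab)   # MA - SAL
    if (names(which.max(dk)) == "R1") hits <- hits + 1L
  }
  expect_gt(hits / n_seeds, 0.5)
})
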