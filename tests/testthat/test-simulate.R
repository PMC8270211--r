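# Ascertained trio simulator: parameter validation, transmission law,
# fast-path equivalence, null panels.

test_that("invalid simulation parameters are rejected", {
  expect_error(simulate_trios(10, maf = 0), "maf")
  expect_error(simulate_trios(10, maf = 1), "maf")
  expect_error(simulate_trios(10, maf = 0.2, rr = 0), "rr")
  expect_error(simulate_trios(0, maf = 0.2), "'n'")
  expect_error(simulate_transmission_counts(0, maf = 0.2), "'n'")
  expect_error(simulate_transmission_counts(10, maf = -0.1), "maf")
})

test_that("simulated trios are Mendelian-consistent and reproducible", {
  tr <- simulate_trios(2000, maf = 0.25, rr = 1.4, seed = 11)
  expect_equal(nrow(tr), 2000)
  expect_true(all(as.matrix(tr[c("g_child", "g_mother", "g_father")]) %in% 0:2))
  expect_equal(mendelian_filter(tr)$n_removed, 0)
  tr2 <- simulate_trios(2000, maf = 0.25, rr = 1.4, seed = 11)
  expect_identical(tr, tr2)
})

test_that("heterozygous parents transmit the effect allele with probability rr/(1+rr)", {
  # trio-level path at the null and at rr = 1.5
  for (case in list(list(rr = 1.0, maf = 0.3), list(rr = 1.5, maf = 0.1))) {
    tr <- simulate_trios(1e5, maf = case$maf, rr = case$rr, seed = 21)
    cnt <- trioverlap:::.count_transmissions(tr)
    expected <- case$rr / (1 + case$rr)
    n <- cnt$t + cnt$u
    mc_se <- sqrt(expected * (1 - expected) / n)
    expect_lt(abs(cnt$t / n - expected), 3 * mc_se)
  }
  # sufficient-statistic path over a grid of relative risks
  for (rr in c(0.5, 1, 1.5, 2)) {
    s <- simulate_transmission_counts(5e4, maf = 0.3, rr = rr, seed = 31)
    expected <- rr / (1 + rr)
    n <- s$t + s$u
    mc_se <- sqrt(expected * (1 - expected) / n)
    expect_lt(abs(s$t / n - expected), 3 * mc_se)
  }
})

test_that("fast count path matches the trio-level path in distribution", {
  # gTDT Z from 1000 replicates of 2000 trios down each path
  set.seed(41)
  s <- trioverlap:::.sim_counts_engine(1000, 2000L, 0.2, rep(1.3, 1000))
  z_fast <- trioverlap:::.z_from_counts(s$t, s$u)
  z_trio <- vapply(seq_len(1000), function(i)
    gtdt_additive(simulate_trios(2000, 0.2, 1.3))$z, 0)
  ks <- suppressWarnings(ks.test(z_fast, z_trio))
  expect_gt(ks$p.value, 0.01)
  # T + U equals the heterozygous-parent count bookkeeping
  one <- simulate_transmission_counts(500, 0.2, 1.3, seed = 42)
  expect_true(one$t + one$u >= one$n_informative)
  expect_lte(one$n_informative, 500)
})

test_that("scenario configuration is validated", {
  expect_error(scenario_config(mixture = c(0.5, 0.5, 0.5)), "mixture")
  expect_error(scenario_config(maf = 1.2), "frequencies")
  expect_error(scenario_config(rr1 = -1), "positive")
  expect_error(scenario_config(n1 = 0), "sample sizes")
  expect_error(scenario_config(ethnic_fractions = c(0.6, 0.6)), "ethnic_fractions")
  cfg <- scenario_config(n1 = 100, n2 = 50, maf = 0.2, n_variants = 10)
  expect_s3_class(cfg, "scenario_config")
  expect_equal(length(cfg$maf), 2)   # recycled over strata
})

test_that("scenario config round-trips through the flat key=value format", {
  path <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("# scenario", "n1 = 300", "n2 = 100",
               "maf = 0.1, 0.3", "mixture = 0.998, 0.001, 0.001",
               "rr1 = 1.15", "rr2 = 1.15", "n_variants = 50"), path)
  cfg <- read_scenario_config(path)
  expect_equal(cfg$n1, 300L)
  expect_equal(cfg$maf, c(0.1, 0.3))
  expect_equal(cfg$mixture, c(0.998, 0.001, 0.001))
  writeLines("bogus_key = 1", path)
  expect_error(read_scenario_config(path), "unknown config keys")
})

test_that("global-null panel yields standard-normal Z and calibrated p-values", {
  cfg <- scenario_global_null(n1 = 1200, n2 = 1200, n_variants = 1e5)
  panel <- simulate_null_panel(cfg, seed = 51)
  expect_equal(nrow(panel), 1e5)
  expect_true(all(panel$component == "00"))
  # moments of Z match the standard normal on the full panel
  expect_lt(abs(mean(panel$z1)), 3 / sqrt(1e5))
  expect_lt(abs(var(panel$z1) - 1), 3 * sqrt(2 / 1e5))
  expect_lt(abs(var(panel$z2) - 1), 3 * sqrt(2 / 1e5))
  # calibration of the p-values at two levels (99% binomial bands)
  for (a in c(0.05, 1e-3)) {
    for (p in list(panel$p1, panel$p2)) {
      k <- sum(p < a)
      expect_gte(k, qbinom(0.005, 1e5, a))
      expect_lte(k, qbinom(0.995, 1e5, a))
    }
  }
  # distributional shape by KS at a scale where the count lattice is
  # undetectable (Z and p carry the same discreteness, being monotone
  # transforms of the transmission counts)
  set.seed(1)
  idx <- sample(1e5, 2000)
  expect_gt(suppressWarnings(ks.test(panel$z1[idx], "pnorm"))$p.value, 0.01)
  expect_gt(suppressWarnings(ks.test(panel$p1[idx], "punif"))$p.value, 0.01)
})

test_that("random-effect sub-null panel inflates only the affected subgroup's Z variance", {
  cfg <- scenario_random_subnull(n1 = 1800, n2 = 600, n_variants = 2e4)
  panel <- simulate_null_panel(cfg, seed = 61)
  expect_true(all(panel$component == "01"))
  expect_gt(var(panel$z1), 1.5)           # inflated by the random effect
  expect_lt(abs(var(panel$z2) - 1), 0.05) # unaffected subgroup stays standard
})

test_that("null panels are seed-reproducible and mixture components match proportions", {
  cfg <- scenario_fixed_subnull(n1 = 600, n2 = 200, n_variants = 2e4)
  p1 <- simulate_null_panel(cfg, seed = 71)
  p2 <- simulate_null_panel(cfg, seed = 71)
  expect_identical(p1, p2)
  tab <- table(p1$component)
  expect_gt(tab[["00"]] / 2e4, 0.99)      # mixture dominated by global null
  expect_true(all(c("01", "02") %in% names(tab)))
})

test_that("panel TSV round-trips", {
  cfg <- scenario_global_null(n1 = 200, n2 = 200, n_variants = 50)
  panel <- simulate_null_panel(cfg, seed = 81)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_null_panel(panel, path)
  back <- read_null_panel(path)
  expect_equal(back$z1, panel$z1, tolerance = 1e-15)
  expect_identical(back$component, panel$component)
})
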