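# Additive gTDT: closed form vs conditional-logistic oracles, degenerate
# handling, founder MAF, Mendelian screening, sex interaction.

test_that("balanced transmission gives a null estimate", {
  s <- gtdt_from_counts(20, 20)
  expect_equal(s$beta, 0)
  expect_equal(s$z, 0)
  expect_equal(s$p, 1)
  expect_equal(s$status, "ok")
})

test_that("closed form matches the hand-derived 30/10 example", {
  s <- gtdt_from_counts(30, 10)
  expect_equal(s$beta, log(3), tolerance = 1e-12)
  expect_equal(s$se, sqrt(1 / 30 + 1 / 10), tolerance = 1e-12)
  expect_equal(s$z, log(3) / sqrt(1 / 30 + 1 / 10), tolerance = 1e-12)
})

test_that("closed form equals generic conditional-logistic maximization", {
  set.seed(101)
  for (i in 1:25) {
    tr <- random_informative_trios(sample(15:50, 1), runif(1, 0.15, 0.5))
    s <- gtdt_additive(tr)
    o <- clogit_oracle(tr)
    expect_equal(s$beta, o$beta, tolerance = 1e-8)
    expect_equal(s$se, o$se, tolerance = 1e-8)
  }
})

test_that("closed form agrees with survival::clogit on expanded pseudo-controls", {
  skip_if_not_installed("survival")
  set.seed(102)
  tr <- random_informative_trios(60, 0.3)
  rows <- do.call(rbind, lapply(seq_len(nrow(tr)), function(i) {
    g <- pseudo_children(tr$g_mother[i], tr$g_father[i])
    # observed child + remaining three transmission combinations
    hit <- match(tr$g_child[i], g)
    data.frame(id = i, g = c(g[hit], g[-hit]), y = c(1, 0, 0, 0))
  }))
  fit <- survival::coxph(survival::Surv(rep(1, nrow(rows)), rows$y) ~ g +
                           survival::strata(id), data = rows,
                         method = "exact")
  s <- gtdt_additive(tr)
  expect_equal(unname(coef(fit)), s$beta, tolerance = 1e-6)
  expect_equal(unname(sqrt(vcov(fit)[1, 1])), s$se, tolerance = 1e-6)
})

test_that("degenerate and non-estimable transmissions are flagged", {
  s <- gtdt_from_counts(12, 0)
  expect_equal(s$status, "degenerate")
  expect_equal(s$beta, Inf)
  expect_equal(s$p, binom.test(12, 12, 0.5)$p.value)
  # all parents homozygous: no informative trios
  tr <- data.frame(g_child = c(1L, 2L), g_mother = c(0L, 2L),
                   g_father = c(2L, 2L))
  expect_equal(gtdt_additive(tr)$status, "not_estimable")
})

test_that("swapping the effect allele negates beta and preserves |z| and p", {
  tr <- simulate_trios(800, maf = 0.3, rr = 1.5, seed = 103)
  swapped <- data.frame(g_child = 2L - tr$g_child,
                        g_mother = 2L - tr$g_mother,
                        g_father = 2L - tr$g_father)
  a <- gtdt_additive(tr); b <- gtdt_additive(swapped)
  expect_equal(b$beta, -a$beta, tolerance = 1e-12)
  expect_equal(abs(b$z), abs(a$z), tolerance = 1e-12)
  expect_equal(b$p, a$p, tolerance = 1e-12)
})

test_that("gTDT p-values are uniform under the null", {
  set.seed(104)
  s <- trioverlap:::.sim_counts_engine(1e4, 5000L, 0.3, rep(1, 1e4))
  z <- trioverlap:::.z_from_counts(s$t, s$u)
  p <- 2 * pnorm(-abs(z))
  expect_gt(suppressWarnings(ks.test(p, "punif"))$p.value, 0.01)
})

test_that("founder MAF uses parents only", {
  tr <- data.frame(g_child = c(0L, 2L), g_mother = c(0L, 1L),
                   g_father = c(1L, 2L))
  expect_equal(founder_maf(tr)$eaf, 4 / 8)
  # all-heterozygous parents
  tr2 <- data.frame(g_child = c(1L, 1L), g_mother = c(1L, 1L),
                    g_father = c(1L, 1L))
  expect_equal(founder_maf(tr2)$maf, 0.5)
  # perturbing children leaves the founder frequency unchanged
  tr$g_child <- c(1L, 1L)
  expect_equal(founder_maf(tr)$eaf, 0.5)
  expect_error(founder_maf(tr[0, ]), "no trios")
})

test_that("Mendelian filter removes impossible trios and counts them", {
  tr <- data.frame(g_child = c(1L, 1L, 2L, 0L),
                   g_mother = c(0L, 1L, 0L, 1L),
                   g_father = c(0L, 1L, 1L, 1L))
  out <- mendelian_filter(tr)
  expect_equal(out$n_removed, 2)           # rows 1 (0x0 -> 1) and 3 (0x1 -> 2)
  expect_equal(out$violation_rate, 0.5)
  expect_equal(nrow(out$trios), 2)
  clean <- simulate_trios(200, 0.3, 1, seed = 105)
  expect_equal(mendelian_filter(clean)$n_removed, 0)
})

test_that("sex-interaction gTDT factorizes into stratum difference", {
  # identical strata: zero interaction
  mk <- function(t_cnt, u_cnt, sex) {
    # t_cnt transmissions / u_cnt non-transmissions from single-het-parent trios
    data.frame(g_child = c(rep(1L, t_cnt), rep(0L, u_cnt)),
               g_mother = 1L, g_father = 0L,
               sex_child = sex)
  }
  tr <- rbind(mk(30, 10, 0L), mk(30, 10, 1L))
  s <- gtdt_sex_interaction(tr)
  expect_equal(s$beta, 0)
  expect_equal(s$p, 1)
  # opposite strata: beta_GE = -2 log 3 with pooled variance
  tr2 <- rbind(mk(30, 10, 0L), mk(10, 30, 1L))
  s2 <- gtdt_sex_interaction(tr2)
  expect_equal(s2$beta, -2 * log(3), tolerance = 1e-12)
  expect_equal(s2$se, sqrt(2 * (1 / 30 + 1 / 10)), tolerance = 1e-12)
  expect_equal(s2$z, -2 * log(3) / sqrt(2 * (1 / 30 + 1 / 10)),
               tolerance = 1e-12)
  expect_error(gtdt_sex_interaction(tr2, sex = c(0, 1)), "one entry per trio")
})

test_that("sex-interaction closed form matches joint conditional-logistic fit", {
  skip_if_not_installed("survival")
  set.seed(106)
  tr <- rbind(cbind(random_informative_trios(80, 0.3), sex_child = 0L),
              cbind(random_informative_trios(80, 0.3), sex_child = 1L))
  rows <- do.call(rbind, lapply(seq_len(nrow(tr)), function(i) {
    g <- pseudo_children(tr$g_mother[i], tr$g_father[i])
    hit <- match(tr$g_child[i], g)
    data.frame(id = i, g = c(g[hit], g[-hit]), y = c(1, 0, 0, 0),
               sex = tr$sex_child[i])
  }))
  fit <- survival::coxph(survival::Surv(rep(1, nrow(rows)), rows$y) ~ g +
                           g:sex + survival::strata(id), data = rows,
                         method = "exact")
  s <- gtdt_sex_interaction(tr)
  expect_equal(unname(coef(fit)["g:sex"]), s$beta, tolerance = 1e-6)
  expect_equal(unname(sqrt(vcov(fit)["g:sex", "g:sex"])), s$se,
               tolerance = 1e-6)
})
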