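# Ascertained case-parent trio simulator.
#
# Model: parental genotypes in Hardy-Weinberg proportions at effect-allele
# frequency `maf`; the child's disease risk is multiplicative in the
# effect-allele dosage, P(affected | g) = K * rr^g; trios are ascertained
# on an affected child. Under this model the ascertained trio likelihood
# factorizes per parent: each parent's genotype is tilted to
#   w(0) = q^2,  w(1) = 2pq (1+rr)/2,  w(2) = p^2 rr,
# and, independently, a heterozygous parent transmits the effect allele
# with probability rr / (1 + rr) (homozygous parents transmit
# deterministically). The baseline K (the stratum prevalence) cancels.

# tilted parental genotype distribution under child-affected ascertainment
.tilted_parent_dist <- function(maf, rr) {
  p <- maf; q <- 1 - p
  w <- c(q^2, p * q * (1 + rr), p^2 * rr)
  w / sum(w)
}

.check_sim_args <- function(n, maf, rr) {
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n < 1)
    stop("'n' must be a single integer >= 1")
  if (!is.numeric(maf) || length(maf) != 1L || !is.finite(maf) ||
      maf <= 0 || maf >= 1)
    stop("'maf' must be a single frequency in (0, 1)")
  if (!is.numeric(rr) || length(rr) != 1L || !is.finite(rr) || rr <= 0)
    stop("'rr' must be a single positive relative risk")
}

#' Simulate ascertained case-parent trios at one variant
#'
#' Draws `n` trios ascertained on an affected child under the
#' multiplicative genotype relative-risk model, by rejection sampling:
#' parents are drawn from Hardy-Weinberg proportions at frequency `maf`,
#' the child by Mendelian transmission, and the trio is accepted with
#' probability proportional to `rr^g_child` (the rare-disease ascertainment
#' weight). A consequence of the model is that, conditional on a
#' heterozygous parent, the effect allele is transmitted with probability
#' `rr / (1 + rr)` — the transmission distortion the gTDT measures.
#'
#' @param n number of trios to return.
#' @param maf effect-allele frequency in (0, 1).
#' @param rr genotype relative risk per effect-allele copy (> 0).
#' @param seed optional integer seed (set once at entry).
#' @param subgroup,ethnicity optional labels attached to every trio.
#' @return a `data.frame` with one row per trio: `g_child`, `g_mother`,
#'   `g_father` (effect-allele dosages in 0:2), `sex_child` (0/1,
#'   Bernoulli(1/2)), plus `subgroup` and `ethnicity` labels.
#' @examples
#' trios <- simulate_trios(500, maf = 0.3, rr = 1.5, seed = 1)
#' gtdt_additive(trios)
#' @export
simulate_trios <- function(n, maf, rr = 1, seed = NULL,
                           subgroup = NA_character_,
                           ethnicity = NA_character_) {
  .check_sim_args(n, maf, rr)
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n)
  accept_scale <- max(1, rr)^2        # makes rr^g_child / scale a probability
  gm <- gf <- gc <- integer(0)
  need <- n
  while (need > 0L) {
    # over-draw to keep the number of rejection rounds small
    m <- max(100L, ceiling(need / max(0.2, 1 / accept_scale)))
    m_gm <- rbinom(m, 2L, maf)
    m_gf <- rbinom(m, 2L, maf)
    tm <- rbinom(m, 1L, m_gm / 2)     # allele transmitted by mother
    tf <- rbinom(m, 1L, m_gf / 2)
    m_gc <- tm + tf
    keep <- runif(m) < rr^m_gc / accept_scale
    gm <- c(gm, m_gm[keep]); gf <- c(gf, m_gf[keep]); gc <- c(gc, m_gc[keep])
    need <- n - length(gc)
  }
  data.frame(g_child = gc[seq_len(n)], g_mother = gm[seq_len(n)],
             g_father = gf[seq_len(n)],
             sex_child = rbinom(n, 1L, 0.5),
             subgroup = subgroup, ethnicity = ethnicity,
             stringsAsFactors = FALSE)
}

# vectorized sufficient-statistic engine: for m variants simulated at the
# same (n, maf) with per-variant relative risks rr (vector), return
# transmitted / untransmitted counts and informative-trio counts.
.sim_counts_engine <- function(m, n, maf, rr) {
  p <- maf; q <- 1 - p
  w1 <- p * q * (1 + rr)
  ph <- w1 / (q^2 + w1 + p^2 * rr)    # tilted P(parent heterozygous)
  n2 <- rbinom(m, n, ph^2)            # trios with both parents het
  pr1 <- 2 * ph * (1 - ph) / (1 - ph^2)
  n1 <- rbinom(m, n - n2, pr1)        # trios with exactly one het parent
  het <- n1 + 2L * n2                 # heterozygous parents overall
  t_cnt <- rbinom(m, het, rr / (1 + rr))
  list(t = t_cnt, u = het - t_cnt, n_informative = n1 + n2)
}

#' Simulate transmission counts directly (fast sufficient-statistic path)
#'
#' Equivalent in distribution to [simulate_trios()] followed by counting,
#' but draws only the sufficient statistics of the additive gTDT: the
#' numbers of effect alleles transmitted (`t`) and untransmitted (`u`) by
#' heterozygous parents, and the number of informative trios. The
#' factorized form of the ascertained trio likelihood makes the per-parent
#' heterozygosity indicator and the per-parent transmission independent,
#' so three binomial draws suffice.
#'
#' @inheritParams simulate_trios
#' @return a list with integer elements `t`, `u` and `n_informative`
#'   (`t + u` equals the number of heterozygous parents among the `n`
#'   trios).
#' @examples
#' simulate_transmission_counts(1000, maf = 0.2, rr = 1.3, seed = 1)
#' @export
simulate_transmission_counts <- function(n, maf, rr = 1, seed = NULL) {
  .check_sim_args(n, maf, rr)
  if (!is.null(seed)) set.seed(seed)
  s <- .sim_counts_engine(1L, as.integer(n), maf, rr)
  list(t = s$t, u = s$u, n_informative = s$n_informative)
}

# counts for one subgroup across ethnic strata; rr is per-variant
.sim_subgroup_counts <- function(m, n, config, rr) {
  fr <- config$ethnic_fractions
  sizes <- diff(round(cumsum(c(0, fr)) * n))   # stratum sizes summing to n
  tot_t <- integer(m); tot_u <- integer(m); tot_inf <- integer(m)
  for (s in seq_along(fr)) {
    if (sizes[s] == 0L) next
    cnt <- .sim_counts_engine(m, sizes[s], config$maf[s], rr)
    tot_t <- tot_t + cnt$t; tot_u <- tot_u + cnt$u
    tot_inf <- tot_inf + cnt$n_informative
  }
  list(t = tot_t, u = tot_u, n_informative = tot_inf)
}

# Wald Z from counts; degenerate (t or u zero) -> NA
.z_from_counts <- function(t, u) {
  z <- suppressWarnings(log(t / u) / sqrt(1 / t + 1 / u))
  z[t == 0L | u == 0L] <- NA_real_
  z
}

#' Simulate a genome-scale null panel of subgroup summary statistics
#'
#' Generates `config$n_variants` independent variants. Each variant is
#' assigned to a mixture component: global null (`"00"`, no effect), sub-null
#' with an effect on subgroup 1 only (`"01"`), or on subgroup 2 only
#' (`"02"`). Sub-null effects are the fixed `rr1`/`rr2` of the scenario, or
#' random with log-RR ~ Normal(0, `effect_sd`^2) when the corresponding
#' `effect_sd` is positive. Both subgroups' trios are simulated per variant
#' (via the fast sufficient-statistic path, pooled over ethnic strata) and
#' reduced to additive gTDT Z-scores and p-values.
#'
#' Variants whose transmission counts are degenerate (all transmitted or
#' all untransmitted; essentially impossible at realistic sizes) get `NA`
#' statistics.
#'
#' @param config a [scenario_config()]; its `mixture` must sum to 1.
#' @param seed optional integer seed; defaults to `config$seed`.
#' @return a `data.frame` with columns `variant_id`, `component` (one of
#'   `"00"`, `"01"`, `"02"`), `z1`, `z2`, `p1`, `p2`, and the transmission
#'   counts `t1`, `u1`, `t2`, `u2` (useful for pooled-trio analyses).
#' @examples
#' cfg <- scenario_global_null(n1 = 300, n2 = 300, n_variants = 200)
#' panel <- simulate_null_panel(cfg, seed = 1)
#' head(panel)
#' @export
simulate_null_panel <- function(config, seed = config$seed) {
  if (!inherits(config, "scenario_config"))
    stop("'config' must be a scenario_config")
  if (!is.null(seed)) set.seed(seed)
  m <- config$n_variants
  comp <- sample.int(3L, m, replace = TRUE, prob = config$mixture)
  # per-variant relative risks
  rr1 <- rep(1, m); rr2 <- rep(1, m)
  on1 <- comp == 2L; on2 <- comp == 3L
  if (any(on1)) {
    rr1[on1] <- if (config$effect_sd1 > 0)
      exp(rnorm(sum(on1), 0, config$effect_sd1)) else config$rr1
  }
  if (any(on2)) {
    rr2[on2] <- if (config$effect_sd2 > 0)
      exp(rnorm(sum(on2), 0, config$effect_sd2)) else config$rr2
  }
  g1 <- .sim_subgroup_counts(m, config$n1, config, rr1)
  g2 <- .sim_subgroup_counts(m, config$n2, config, rr2)
  z1 <- .z_from_counts(g1$t, g1$u)
  z2 <- .z_from_counts(g2$t, g2$u)
  data.frame(variant_id = sprintf("var%07d", seq_len(m)),
             component = c("00", "01", "02")[comp],
             z1 = z1, z2 = z2,
             p1 = 2 * pnorm(-abs(z1)), p2 = 2 * pnorm(-abs(z2)),
             t1 = g1$t, u1 = g1$u, t2 = g2$t, u2 = g2$u,
             stringsAsFactors = FALSE)
}

#' Write / read a null panel as TSV
#'
#' The on-disk dialect has the columns `variant_id`, `component`, `z1`,
#' `z2`, `p1`, `p2` (tab-separated, full double precision).
#'
#' @param panel a data.frame from [simulate_null_panel()].
#' @param path output file path.
#' @return `write_null_panel()` returns `path` invisibly;
#'   `read_null_panel()` returns the panel data.frame.
#' @export
write_null_panel <- function(panel, path) {
  cols <- c("variant_id", "component", "z1", "z2", "p1", "p2")
  stopifnot(all(cols %in% names(panel)))
  out <- panel[cols]
  for (nm in c("z1", "z2", "p1", "p2"))
    out[[nm]] <- sprintf("%.17g", out[[nm]])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_null_panel
#' @export
read_null_panel <- function(path) {
  read.table(path, header = TRUE, sep = "\t",
             colClasses = c("character", "character", rep("numeric", 4)),
             stringsAsFactors = FALSE)
}
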