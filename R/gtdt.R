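# Genotypic transmission disequilibrium test (gTDT), additive coding.
#
# The conditional-logistic likelihood compares the affected child's
# genotype to the three pseudo-sibling genotypes constructible from the
# parents. Under additive dosage coding the MLE has a closed form in the
# transmitted / untransmitted effect-allele counts from heterozygous
# parents: beta = log(T/U), se = sqrt(1/T + 1/U).

.check_trios <- function(trios) {
  need <- c("g_child", "g_mother", "g_father")
  if (!is.data.frame(trios) || !all(need %in% names(trios)))
    stop("'trios' must be a data.frame with columns ",
         paste(need, collapse = ", "))
  g <- as.matrix(trios[need])
  if (nrow(g) && (any(!g %in% 0:2)))
    stop("genotype dosages must be in {0, 1, 2}")
  invisible(trios)
}

# transmitted / untransmitted effect alleles from heterozygous parents
.count_transmissions <- function(trios) {
  gm <- trios$g_mother; gf <- trios$g_father; gc <- trios$g_child
  n_het <- (gm == 1L) + (gf == 1L)
  n_hom2 <- (gm == 2L) + (gf == 2L)
  t_per <- gc - n_hom2                 # alleles transmitted by het parents
  u_per <- n_het - t_per
  if (any(t_per < 0 | u_per < 0))
    stop("Mendelian-inconsistent trio encountered; run mendelian_filter() first")
  list(t = sum(t_per), u = sum(u_per), n_informative = sum(n_het > 0L),
       n_trios = nrow(trios))
}

.gtdt_stat <- function(beta, se, z, p, n_informative, t, u, status,
                       effect_allele = NA_character_) {
  structure(list(beta = beta, se = se, z = z, p = p,
                 n_informative = n_informative,
                 t_count = t, u_count = u, status = status,
                 effect_allele = effect_allele),
            class = "gtdt_stat")
}

#' @export
print.gtdt_stat <- function(x, ...) {
  cat(sprintf(
    "gTDT (additive): beta = %.4g (RR = %.4g), se = %.4g, z = %.4g, p = %.3g\n",
    x$beta, exp(x$beta), x$se, x$z, x$p))
  cat(sprintf("  T/U = %d/%d over %d informative trios [%s]\n",
              x$t_count, x$u_count, x$n_informative, x$status))
  invisible(x)
}

#' Additive gTDT from transmission counts
#'
#' The additive conditional-logistic MLE depends on the trios only through
#' the effect alleles transmitted (`t`) and untransmitted (`u`) by
#' heterozygous parents: `beta = log(t/u)`, `se = sqrt(1/t + 1/u)`,
#' `z = beta/se`, `p = 2 * pnorm(-|z|)`.
#'
#' Degenerate counts (`t == 0` or `u == 0` with `t + u > 0`) yield an
#' infinite `beta`; the p-value then falls back to the exact binomial
#' test of transmission probability 1/2 and the result is flagged
#' `status = "degenerate"`. With no informative transmissions the result
#' is flagged `"not_estimable"`. Flagged variants should be excluded from
#' downstream composite-null testing.
#'
#' @param t,u transmitted / untransmitted effect-allele counts.
#' @param n_informative number of informative trios (metadata; defaults to
#'   `NA`).
#' @param effect_allele optional allele label carried through.
#' @return an object of class `"gtdt_stat"`: a list with `beta`, `se`,
#'   `z`, `p`, `n_informative`, `t_count`, `u_count`, `status`,
#'   `effect_allele`.
#' @export
gtdt_from_counts <- function(t, u, n_informative = NA_integer_,
                             effect_allele = NA_character_) {
  stopifnot(length(t) == 1L, length(u) == 1L, t >= 0, u >= 0)
  t <- as.integer(t); u <- as.integer(u)
  if (t + u == 0L)
    return(.gtdt_stat(NA_real_, NA_real_, NA_real_, NA_real_,
                      n_informative, t, u, "not_estimable", effect_allele))
  if (t == 0L || u == 0L) {
    p <- binom.test(t, t + u, 0.5)$p.value
    beta <- if (t == 0L) -Inf else Inf
    return(.gtdt_stat(beta, Inf, sign(beta) * Inf, p,
                      n_informative, t, u, "degenerate", effect_allele))
  }
  beta <- log(t / u)
  se <- sqrt(1 / t + 1 / u)
  z <- beta / se
  .gtdt_stat(beta, se, z, 2 * pnorm(-abs(z)), n_informative, t, u,
             "ok", effect_allele)
}

#' Additive genotypic TDT for case-parent trios
#'
#' Maximizes the conditional-logistic likelihood of the affected child's
#' genotype versus the three pseudo-sibling genotypes given the parents,
#' under additive dosage coding. The closed form in transmission counts is
#' used (see [gtdt_from_counts()]); it matches generic conditional-logistic
#' maximization to numerical precision.
#'
#' @param trios a data.frame of Mendelian-consistent trios with columns
#'   `g_child`, `g_mother`, `g_father` (effect-allele dosages, 0:2).
#' @param effect_allele optional allele label carried through.
#' @return a `"gtdt_stat"` object (see [gtdt_from_counts()]).
#' @examples
#' trios <- simulate_trios(400, maf = 0.3, rr = 1.4, seed = 2)
#' gtdt_additive(trios)
#' @export
gtdt_additive <- function(trios, effect_allele = NA_character_) {
  .check_trios(trios)
  cnt <- .count_transmissions(trios)
  gtdt_from_counts(cnt$t, cnt$u, cnt$n_informative, effect_allele)
}

#' 1-df SNP-by-sex interaction gTDT
#'
#' Fits the gene-environment conditional-logistic model with dosage and
#' dosage-by-sex terms. Because the child's sex is constant within a trio,
#' the conditional likelihood factorizes by sex stratum, so the
#' interaction MLE is the difference of the stratum-specific additive
#' estimates: `beta_GE = beta(sex = 1) - beta(sex = 0)`,
#' `se_GE = sqrt(se0^2 + se1^2)`, with a 1-df Wald test.
#'
#' @param trios trio data.frame as in [gtdt_additive()].
#' @param sex per-trio child sex coded 0/1 (0 = reference category);
#'   defaults to the `sex_child` column of `trios`.
#' @return a `"gtdt_stat"` for the interaction effect; flagged
#'   `"not_estimable"` if either stratum lacks informative transmissions.
#' @export
gtdt_sex_interaction <- function(trios, sex = trios$sex_child) {
  .check_trios(trios)
  if (is.null(sex)) stop("'sex' must be supplied (or a sex_child column)")
  if (length(sex) != nrow(trios))
    stop("'sex' must have one entry per trio")
  if (!all(sex %in% 0:1)) stop("'sex' must be coded 0/1")
  s0 <- gtdt_additive(trios[sex == 0L, , drop = FALSE])
  s1 <- gtdt_additive(trios[sex == 1L, , drop = FALSE])
  n_inf <- s0$n_informative + s1$n_informative
  if (s0$status != "ok" || s1$status != "ok")
    return(.gtdt_stat(NA_real_, NA_real_, NA_real_, NA_real_, n_inf,
                      s0$t_count + s1$t_count, s0$u_count + s1$u_count,
                      "not_estimable"))
  beta <- s1$beta - s0$beta
  se <- sqrt(s0$se^2 + s1$se^2)
  z <- beta / se
  .gtdt_stat(beta, se, z, 2 * pnorm(-abs(z)), n_inf,
             s0$t_count + s1$t_count, s0$u_count + s1$u_count, "ok")
}

#' Effect-allele frequency among founders
#'
#' Allele frequency computed from the parents (founders) only, as used for
#' the MAF >= 5% analysis filter; children are ignored so the estimate is
#' unaffected by ascertainment-driven transmission distortion in the
#' offspring.
#'
#' @param trios trio data.frame (see [gtdt_additive()]).
#' @return a list with `eaf` (effect-allele frequency among parents) and
#'   `maf` (`min(eaf, 1 - eaf)`).
#' @export
founder_maf <- function(trios) {
  .check_trios(trios)
  if (nrow(trios) == 0L) stop("no trios supplied")
  eaf <- sum(trios$g_mother + trios$g_father) / (4 * nrow(trios))
  list(eaf = eaf, maf = min(eaf, 1 - eaf))
}

#' Remove Mendelian-inconsistent trios at a variant
#'
#' A trio is inconsistent when the child's genotype cannot arise from the
#' parents (e.g. child dosage 1 from two homozygous-reference parents).
#' The per-variant violation rate supports the usual <= 5% variant screen.
#'
#' @param trios trio data.frame (see [gtdt_additive()]).
#' @return a list with `trios` (consistent rows), `n_removed` and
#'   `violation_rate` (fraction of input trios removed; 0 for empty input).
#' @export
mendelian_filter <- function(trios) {
  .check_trios(trios)
  gm <- trios$g_mother; gf <- trios$g_father; gc <- trios$g_child
  n_het <- (gm == 1L) + (gf == 1L)
  n_hom2 <- (gm == 2L) + (gf == 2L)
  t_per <- gc - n_hom2
  ok <- t_per >= 0L & t_per <= n_het
  n_bad <- sum(!ok)
  list(trios = trios[ok, , drop = FALSE], n_removed = n_bad,
       violation_rate = if (nrow(trios)) n_bad / nrow(trios) else 0)
}
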