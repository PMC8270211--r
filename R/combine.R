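# Cross-study combination and global-null competitor methods.

.est_ok <- function(s) {
  inherits(s, "gtdt_stat") && s$status == "ok" && is.finite(s$beta) &&
    is.finite(s$se) && s$se > 0
}

#' Inverse-variance weighted fixed-effects meta-analysis
#'
#' Combines per-study gTDT estimates of the same variant:
#' `beta = sum(w_i beta_i) / sum(w_i)` with `w_i = 1/se_i^2`, and
#' `se = 1/sqrt(sum(w_i))`. All studies must refer to the same effect
#' allele. Non-estimable or degenerate studies are dropped with a warning;
#' a variant present in a single study is returned as that study's result.
#' Cochran's Q heterogeneity statistic is reported but not used for
#' filtering (the analysis is fixed-effects throughout).
#'
#' @param stats a list of `"gtdt_stat"` objects (see [gtdt_additive()]),
#'   or a data.frame with columns `beta` and `se` (optionally
#'   `effect_allele`, `n_informative`).
#' @return an object of class `"meta_stat"`: `beta`, `se`, `z`, `p`,
#'   `k_studies`, `q`, `q_df`, `q_p`, `effect_allele`.
#' @examples
#' a <- gtdt_from_counts(30, 10)
#' b <- gtdt_from_counts(25, 15)
#' ivw_meta(list(a, b))
#' @export
ivw_meta <- function(stats) {
  if (is.data.frame(stats)) {
    stopifnot(all(c("beta", "se") %in% names(stats)))
    ea <- if ("effect_allele" %in% names(stats)) stats$effect_allele
          else rep(NA_character_, nrow(stats))
    stats <- lapply(seq_len(nrow(stats)), function(i)
      .gtdt_stat(stats$beta[i], stats$se[i], NA, NA, NA_integer_,
                 NA_integer_, NA_integer_, "ok", ea[i]))
  }
  if (!is.list(stats) || !length(stats)) stop("'stats' must be a non-empty list")
  ea <- unique(stats[[1]]$effect_allele)
  alleles <- unlist(lapply(stats, `[[`, "effect_allele"))
  if (length(unique(alleles[!is.na(alleles)])) > 1L)
    stop("studies disagree on the effect allele; harmonize before meta-analysis")
  usable <- vapply(stats, .est_ok, logical(1))
  if (sum(!usable))
    warning(sum(!usable), " non-estimable/degenerate stat(s) dropped from meta-analysis")
  stats <- stats[usable]
  if (!length(stats))
    return(structure(list(beta = NA_real_, se = NA_real_, z = NA_real_,
                          p = NA_real_, k_studies = 0L, q = NA_real_,
                          q_df = NA_integer_, q_p = NA_real_,
                          effect_allele = ea, status = "not_estimable"),
                     class = "meta_stat"))
  b <- vapply(stats, `[[`, 0, "beta")
  se <- vapply(stats, `[[`, 0, "se")
  w <- 1 / se^2
  beta <- sum(w * b) / sum(w)
  se_m <- 1 / sqrt(sum(w))
  z <- beta / se_m
  k <- length(stats)
  q <- sum(w * (b - beta)^2)
  q_df <- k - 1L
  structure(list(beta = beta, se = se_m, z = z, p = 2 * pnorm(-abs(z)),
                 k_studies = k, q = q, q_df = q_df,
                 q_p = if (q_df > 0) pchisq(q, q_df, lower.tail = FALSE)
                       else NA_real_,
                 effect_allele = ea, status = "ok"),
            class = "meta_stat")
}

#' @export
print.meta_stat <- function(x, ...) {
  cat(sprintf("IVW fixed-effects meta (%d studies): beta = %.4g, se = %.4g, z = %.4g, p = %.3g\n",
              x$k_studies, x$beta, x$se, x$z, x$p))
  if (!is.na(x$q) && x$q_df > 0)
    cat(sprintf("  heterogeneity: Q = %.3g on %d df (p = %.3g)\n",
                x$q, x$q_df, x$q_p))
  invisible(x)
}

#' Pooled-trio analysis (global-null comparator)
#'
#' Concatenates the trios of both subgroups and runs one additive gTDT on
#' the union. This "pooled" analysis tests the *global* null (no effect on
#' either subgroup), not the composite null of overlap: opposite-direction
#' effects cancel, and a strong effect confined to one subgroup can reject
#' it even though there is no overlap.
#'
#' @param trios_subgroup1,trios_subgroup2 trio data.frames at the same
#'   variant, coded on the same effect allele.
#' @return a `"gtdt_stat"` for the pooled panel.
#' @export
pooled_gtdt <- function(trios_subgroup1, trios_subgroup2) {
  .check_trios(trios_subgroup1); .check_trios(trios_subgroup2)
  cols <- c("g_child", "g_mother", "g_father")
  gtdt_additive(rbind(trios_subgroup1[cols], trios_subgroup2[cols]))
}

#' Fisher's combination of two p-values
#'
#' `X = -2 (log p1 + log p2)` referred to a chi-squared distribution with
#' 4 degrees of freedom. Like the pooled analysis this tests the global
#' null, not genetic overlap.
#'
#' @param p1,p2 p-values in (0, 1] (vectors recycled to a common length).
#' @return numeric vector of combined p-values.
#' @examples
#' fisher_combine(0.05, 0.05)
#' @export
fisher_combine <- function(p1, p2) {
  if (any(!is.finite(p1)) || any(!is.finite(p2)) ||
      any(p1 <= 0 | p1 > 1) || any(p2 <= 0 | p2 > 1))
    stop("p-values must lie in (0, 1]")
  x <- -2 * (log(p1) + log(p2))
  pchisq(x, df = 4, lower.tail = FALSE)
}

#' Dual-threshold ("naive") overlap criterion
#'
#' Declares overlap when the subgroup-1 p-value falls below `thr1` *and*
#' the subgroup-2 p-value falls below `thr2`. The criterion is asymmetric:
#' by convention the genome-wide threshold applies to the larger subgroup
#' (subgroup 1). Standard presets: "Naive-1" uses
#' `thr1 = 5e-8, thr2 = 1e-5` (the default); "Naive-2" relaxes the second
#' threshold to `thr2 = 1e-3`.
#'
#' @param p1,p2 p-values in (0, 1] (recycled).
#' @param thr1,thr2 significance thresholds in (0, 1).
#' @return logical vector: does the pair meet the criterion?
#' @examples
#' naive_criterion(1e-9, 1e-4)                # Naive-1: FALSE
#' naive_criterion(1e-9, 1e-4, thr2 = 1e-3)   # Naive-2: TRUE
#' @export
naive_criterion <- function(p1, p2, thr1 = 5e-8, thr2 = 1e-5) {
  if (any(!is.finite(p1)) || any(!is.finite(p2)) ||
      any(p1 <= 0 | p1 > 1) || any(p2 <= 0 | p2 > 1))
    stop("p-values must lie in (0, 1]")
  stopifnot(thr1 > 0, thr1 < 1, thr2 > 0, thr2 < 1)
  p1 < thr1 & p2 < thr2
}
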