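# Type-I-error and power studies, genomic inflation, QQ coordinates.

.known_methods <- c("placo", "pooled", "fisher", "naive1", "naive2")

#' Wilson score confidence interval for a binomial proportion
#'
#' @param k number of successes.
#' @param n number of trials.
#' @param conf confidence level (default 0.99, the level used for
#'   calibration pass/fail decisions).
#' @return a list with `estimate`, `lower`, `upper`.
#' @export
wilson_ci <- function(k, n, conf = 0.99) {
  stopifnot(n >= 1, k >= 0, k <= n)
  z <- qnorm(1 - (1 - conf) / 2)
  ph <- k / n
  den <- 1 + z^2 / n
  ctr <- (ph + z^2 / (2 * n)) / den
  hw <- z * sqrt(ph * (1 - ph) / n + z^2 / (4 * n^2)) / den
  list(estimate = ph, lower = max(0, ctr - hw), upper = min(1, ctr + hw))
}

# simulate n_reps single-variant replicates of both subgroups and return
# the per-replicate summary statistics needed by every method
.sim_power_reps <- function(config, n_reps) {
  g1 <- .sim_subgroup_counts(n_reps, config$n1, config, rep(config$rr1, n_reps))
  g2 <- .sim_subgroup_counts(n_reps, config$n2, config, rep(config$rr2, n_reps))
  z1 <- .z_from_counts(g1$t, g1$u)
  z2 <- .z_from_counts(g2$t, g2$u)
  tp <- g1$t + g2$t; up <- g1$u + g2$u
  list(z1 = z1, z2 = z2,
       p1 = 2 * pnorm(-abs(z1)), p2 = 2 * pnorm(-abs(z2)),
       zp = .z_from_counts(tp, up))
}

.method_rejections <- function(sim, method, alpha) {
  switch(method,
    placo = {
      # single-variant replicates provide no genome-wide panel, so the
      # marginal variances are fixed at 1 and the test reduces to the
      # plain normal-product tail; invert once
      u_a <- .npt_quantile(alpha)
      abs(sim$z1 * sim$z2) >= u_a
    },
    pooled = 2 * pnorm(-abs(sim$zp)) < alpha,
    fisher = fisher_combine(pmax(sim$p1, 1e-300), pmax(sim$p2, 1e-300)) < alpha,
    naive1 = sim$p1 < alpha & sim$p2 < 1e-5,
    naive2 = sim$p1 < alpha & sim$p2 < 1e-3,
    stop("unknown method: ", method)
  )
}

#' Power study over single-variant replicates
#'
#' Simulates `n_reps` independent replicates of one variant carrying the
#' scenario's `rr1` / `rr2` effects on the two subgroups, computes the
#' additive gTDT Z-score per subgroup per replicate, applies each requested
#' method and tallies rejections at `alpha`.
#'
#' Methods: `"placo"` (product test, marginal variances fixed at 1 since a
#' single-variant design offers no genome-wide panel for estimation),
#' `"pooled"` (gTDT on the concatenated trios), `"fisher"` (chi-squared-4
#' combination), `"naive1"` / `"naive2"` (dual-threshold criteria
#' `p1 < alpha` and `p2 < 1e-5` / `1e-3`).
#'
#' @param config a [scenario_config()]; `rr1`, `rr2` are the alternative
#'   relative risks (set both to 1 to check size).
#' @param methods subset of the method names above.
#' @param alpha significance level (the first threshold of the naive
#'   criteria).
#' @param n_reps number of replicates (>= 100).
#' @param seed optional integer seed.
#' @return a data.frame of class `"eval_report"` with columns `method`,
#'   `alpha`, `n_reps`, `n_reject`, `rate`, `mc_se`
#'   (`sqrt(rate (1-rate) / n_reps)`); the scenario and seed are attached
#'   as attributes.
#' @examples
#' cfg <- scenario_config(n1 = 300, n2 = 300, maf = 0.1, rr1 = 1.5, rr2 = 1.5)
#' power_study(cfg, methods = "placo", alpha = 1e-4, n_reps = 200, seed = 1)
#' @export
power_study <- function(config, methods = c("placo", "pooled", "naive1", "naive2"),
                        alpha = 5e-8, n_reps = 3000, seed = NULL) {
  if (!inherits(config, "scenario_config"))
    stop("'config' must be a scenario_config")
  bad <- setdiff(methods, .known_methods)
  if (length(bad)) stop("unknown method(s): ", paste(bad, collapse = ", "))
  stopifnot(alpha > 0, alpha < 1)
  if (n_reps < 100) stop("'n_reps' must be >= 100")
  if (!is.null(seed)) set.seed(seed)
  sim <- .sim_power_reps(config, n_reps)
  rows <- lapply(methods, function(m) {
    rej <- .method_rejections(sim, m, alpha)
    k <- sum(rej, na.rm = TRUE)
    r <- k / n_reps
    data.frame(method = m, alpha = alpha, n_reps = n_reps,
               n_reject = k, rate = r,
               mc_se = sqrt(r * (1 - r) / n_reps),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "config") <- config
  attr(out, "seed") <- seed
  class(out) <- c("eval_report", class(out))
  out
}

#' Type-I error study on a genome-scale null panel
#'
#' Builds (or accepts) a null panel from the scenario, applies each method
#' per variant, and reports empirical rejection rates at each `alpha` with
#' 99% Wilson confidence intervals. PLACO fits its composite-null model on
#' the panel with [estimate_var_z()] and then counts rejections by
#' threshold inversion ([placo_threshold()]), which is exact and avoids a
#' per-variant tail evaluation.
#'
#' @param config a [scenario_config()] describing a null panel (its
#'   `mixture` places no variant under the non-null).
#' @param methods subset of `"placo"`, `"pooled"`, `"fisher"`.
#' @param alphas significance levels to evaluate.
#' @param seed optional integer seed.
#' @param panel optionally, a pre-computed panel from
#'   [simulate_null_panel()] (then `config`/`seed` are used only for
#'   metadata).
#' @param p_screen,method_var variance-estimation settings for PLACO.
#' @return an `"eval_report"` data.frame with columns `method`, `alpha`,
#'   `n_variants`, `n_reject`, `rate`, `mc_se`, `ci_lower`, `ci_upper`
#'   (99% Wilson); the fitted composite-null model is attached as
#'   attribute `"model"`.
#' @export
type1_study <- function(config, methods = c("placo", "pooled"),
                        alphas = c(1e-3, 1e-4), seed = NULL, panel = NULL,
                        p_screen = 1e-4,
                        method_var = c("truncated", "naive")) {
  method_var <- match.arg(method_var)
  bad <- setdiff(methods, c("placo", "pooled", "fisher"))
  if (length(bad)) stop("unknown method(s): ", paste(bad, collapse = ", "))
  if (is.null(panel)) {
    if (!inherits(config, "scenario_config"))
      stop("'config' must be a scenario_config")
    if (config$n_variants < 1) stop("panel must contain at least one variant")
    panel <- simulate_null_panel(config, seed = seed)
  }
  ok <- is.finite(panel$z1) & is.finite(panel$z2)
  n_drop <- sum(!ok)
  if (n_drop) warning(n_drop, " variant(s) with degenerate counts excluded")
  panel <- panel[ok, , drop = FALSE]
  m <- nrow(panel)
  if (m == 0L) stop("no usable variants in panel")

  model <- NULL
  if ("placo" %in% methods) {
    v1 <- estimate_var_z(panel$z1, p_screen = p_screen, method = method_var)
    v2 <- estimate_var_z(panel$z2, p_screen = p_screen, method = method_var)
    model <- composite_null_model(v1$var_z, v2$var_z, p_screen = p_screen)
  }
  tprod <- abs(panel$z1 * panel$z2)
  zp <- if ("pooled" %in% methods)
    .z_from_counts(panel$t1 + panel$t2, panel$u1 + panel$u2) else NULL

  rows <- list()
  for (a in alphas) {
    for (mth in methods) {
      k <- switch(mth,
        placo = sum(tprod >= placo_threshold(a, model)),
        pooled = sum(2 * pnorm(-abs(zp)) < a, na.rm = TRUE),
        fisher = sum(fisher_combine(pmax(panel$p1, 1e-300),
                                    pmax(panel$p2, 1e-300)) < a))
      ci <- wilson_ci(k, m, conf = 0.99)
      rows[[length(rows) + 1L]] <- data.frame(
        method = mth, alpha = a, n_variants = m, n_reject = k,
        rate = k / m, mc_se = sqrt(a * (1 - a) / m),
        ci_lower = ci$lower, ci_upper = ci$upper,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "config") <- config
  attr(out, "seed") <- seed
  attr(out, "model") <- model
  class(out) <- c("eval_report", class(out))
  out
}

#' Genomic inflation factor at a percentile
#'
#' Maps p-values to 1-df chi-squared statistics via the inverse survival
#' function and returns the ratio of the empirical `100(1-x)`-th
#' percentile of those statistics to the corresponding theoretical 1-df
#' chi-squared percentile. `x = 0.5` (the median, bulk inflation) and
#' `x = 0.001` (tail inflation) are the conventional choices; a value near
#' 1 indicates calibration.
#'
#' @param pvals p-values in (0, 1].
#' @param x percentile fraction in (0, 1).
#' @return the scalar inflation factor \eqn{\lambda_x}.
#' @examples
#' genomic_lambda(runif(1e4))        # ~ 1
#' @export
genomic_lambda <- function(pvals, x = 0.5) {
  if (length(pvals) == 0L) stop("'pvals' must be non-empty")
  if (any(!is.finite(pvals)) || any(pvals <= 0 | pvals > 1))
    stop("p-values must lie in (0, 1]")
  if (!is.numeric(x) || length(x) != 1L || x <= 0 || x >= 1)
    stop("'x' must be a fraction in (0, 1)")
  chi <- qchisq(pvals, df = 1, lower.tail = FALSE)
  quantile(chi, probs = 1 - x, names = FALSE) /
    qchisq(1 - x, df = 1)
}

#' QQ-plot coordinates with pointwise confidence band
#'
#' Sorted observed p-values against uniform order-statistic expectations
#' `(i - 0.5)/n`, on the -log10 scale, with a pointwise beta-distribution
#' band (the i-th uniform order statistic is Beta(i, n - i + 1)).
#'
#' @param pvals p-values in (0, 1].
#' @param band pointwise band coverage (default 0.95).
#' @return a data.frame with columns `expected`, `observed`, `lower`,
#'   `upper` (all -log10 scale), ordered from most to least significant.
#' @export
qq_coordinates <- function(pvals, band = 0.95) {
  if (length(pvals) == 0L) stop("'pvals' must be non-empty")
  if (any(!is.finite(pvals)) || any(pvals <= 0 | pvals > 1))
    stop("p-values must lie in (0, 1]")
  n <- length(pvals)
  i <- seq_len(n)
  a <- (1 - band) / 2
  data.frame(expected = -log10((i - 0.5) / n),
             observed = -log10(sort(pvals)),
             lower = -log10(qbeta(1 - a, i, n - i + 1)),
             upper = -log10(qbeta(a, i, n - i + 1)))
}
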