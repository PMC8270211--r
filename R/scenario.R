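# Simulation scenario configuration.
#
# A scenario describes two case-parent trio studies (one per disease
# subgroup), each split over two ethnic strata with their own effect-allele
# frequency and baseline prevalence, plus the genetic effects to simulate:
# fixed relative risks and/or random log-RR effects, and the mixture of
# null components for genome-scale null panels.

#' Simulation scenario for bi-ethnic case-parent trio studies
#'
#' @param n1,n2 number of ascertained trios for subgroup 1 and subgroup 2
#'   (the default 1,800 / 600 is the unbalanced 3:1 split of 2,400 trios;
#'   use 1200/1200 or 2100/300 for the 1:1 and 7:1 designs).
#' @param ethnic_fractions fractions of each subgroup's trios drawn from
#'   each ethnic stratum; must sum to 1 (default: equal split).
#' @param maf effect-allele frequency per ethnic stratum, each in (0, 1).
#'   Recycled to the number of strata.
#' @param prevalence baseline disease prevalence per stratum, in (0, 1).
#'   Under the multiplicative model the prevalence cancels from the
#'   retrospective trio likelihood; it is carried for completeness and
#'   used only to label strata as differing in baseline risk.
#' @param rr1,rr2 fixed genotype relative risk per effect-allele copy for
#'   subgroup 1 / subgroup 2 (positive; 1 = no effect). Used for power
#'   scenarios and for fixed-effect sub-null components of null panels.
#' @param effect_sd1,effect_sd2 standard deviation of a *random* log-RR
#'   effect (0 = fixed effects). When positive, a sub-null variant for
#'   that subgroup draws log-RR ~ Normal(0, effect_sd^2).
#' @param mixture proportions `c(pi00, pi01, pi02)` of null-panel variants
#'   under the global null, under "effect on subgroup 1 only", and under
#'   "effect on subgroup 2 only"; must sum to 1.
#' @param n_variants number of variants in a null panel.
#' @param seed optional integer seed stored with the scenario.
#' @return an object of class `"scenario_config"` (a validated list).
#' @seealso [scenario_global_null()], [scenario_fixed_subnull()],
#'   [scenario_random_subnull()] for the standard null-panel presets.
#' @export
scenario_config <- function(n1 = 1800, n2 = 600,
                            ethnic_fractions = c(0.5, 0.5),
                            maf = c(0.10, 0.20),
                            prevalence = c(0.001, 0.002),
                            rr1 = 1, rr2 = 1,
                            effect_sd1 = 0, effect_sd2 = 0,
                            mixture = c(1, 0, 0),
                            n_variants = 1e6,
                            seed = NULL) {
  stopifnot(length(n1) == 1L, length(n2) == 1L)
  if (!is.numeric(n1) || !is.numeric(n2) || n1 < 1 || n2 < 1)
    stop("sample sizes must be >= 1")
  if (!is.numeric(ethnic_fractions) || any(ethnic_fractions < 0) ||
      abs(sum(ethnic_fractions) - 1) > 1e-8)
    stop("'ethnic_fractions' must be non-negative and sum to 1")
  k <- length(ethnic_fractions)
  maf <- rep_len(maf, k)
  prevalence <- rep_len(prevalence, k)
  if (any(maf <= 0 | maf >= 1)) stop("allele frequencies must be in (0, 1)")
  if (any(prevalence <= 0 | prevalence >= 1))
    stop("prevalences must be in (0, 1)")
  if (rr1 <= 0 || rr2 <= 0) stop("relative risks must be positive")
  if (effect_sd1 < 0 || effect_sd2 < 0) stop("effect SDs must be >= 0")
  if (length(mixture) != 3L || any(mixture < 0 | mixture > 1) ||
      abs(sum(mixture) - 1) > 1e-8)
    stop("'mixture' must be 3 proportions in [0, 1] summing to 1")
  if (n_variants < 1) stop("'n_variants' must be >= 1")
  structure(list(n1 = as.integer(n1), n2 = as.integer(n2),
                 ethnic_fractions = ethnic_fractions,
                 maf = maf, prevalence = prevalence,
                 rr1 = rr1, rr2 = rr2,
                 effect_sd1 = effect_sd1, effect_sd2 = effect_sd2,
                 mixture = mixture,
                 n_variants = as.integer(n_variants),
                 seed = seed),
            class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("Trio simulation scenario\n")
  cat("  trios: subgroup1 =", x$n1, " subgroup2 =", x$n2, "\n")
  cat("  strata: fractions", paste(x$ethnic_fractions, collapse = "/"),
      " maf", paste(x$maf, collapse = "/"),
      " prevalence", paste(x$prevalence, collapse = "/"), "\n")
  cat("  effects: rr1 =", x$rr1, " rr2 =", x$rr2,
      " effect_sd1 =", x$effect_sd1, " effect_sd2 =", x$effect_sd2, "\n")
  cat("  null mixture (00/01/02):", paste(x$mixture, collapse = "/"),
      " n_variants =", x$n_variants, "\n")
  invisible(x)
}

#' Standard null-panel scenario presets
#'
#' Three genome-scale null-panel designs used to assess type-I error of
#' overlap tests, all with 2,400 trios split `n1`:`n2` between subgroups:
#'
#' * `scenario_global_null()`: every variant has no effect on either
#'   subgroup.
#' * `scenario_fixed_subnull()`: a mixture in which almost all variants
#'   (99.8%) are under the global null and 0.1% each carry a *fixed*
#'   relative risk of 1.15 on exactly one subgroup.
#' * `scenario_random_subnull()`: every variant carries a *random* effect
#'   on subgroup 1 only, log-RR ~ Normal(0, 0.1^2); subgroup 2 is null.
#'
#' All remain null panels for the composite null of overlap (no variant
#' affects both subgroups), while the sub-null designs are alternatives
#' for global-null tests such as the pooled analysis.
#'
#' @param n1,n2 trios per subgroup.
#' @param n_variants panel size.
#' @param ... further arguments passed to [scenario_config()].
#' @return a [scenario_config()].
#' @export
scenario_global_null <- function(n1 = 1200, n2 = 1200, n_variants = 1e6, ...) {
  scenario_config(n1 = n1, n2 = n2, mixture = c(1, 0, 0),
                  n_variants = n_variants, ...)
}

#' @rdname scenario_global_null
#' @export
scenario_fixed_subnull <- function(n1 = 1800, n2 = 600, n_variants = 1e6, ...) {
  scenario_config(n1 = n1, n2 = n2, mixture = c(0.998, 0.001, 0.001),
                  rr1 = 1.15, rr2 = 1.15, n_variants = n_variants, ...)
}

#' @rdname scenario_global_null
#' @export
scenario_random_subnull <- function(n1 = 1800, n2 = 600, n_variants = 1e6, ...) {
  scenario_config(n1 = n1, n2 = n2, mixture = c(0, 1, 0),
                  effect_sd1 = 0.1, n_variants = n_variants, ...)
}

#' Read a scenario from a flat key=value configuration file
#'
#' Lines of the form `key = value` (comments with `#`). Vector-valued keys
#' (`ethnic_fractions`, `maf`, `prevalence`, `mixture`) take
#' comma-separated values. Unknown keys are an error.
#'
#' @param path path to the configuration file.
#' @return a [scenario_config()].
#' @export
read_scenario_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!all(grepl("=", lines, fixed = TRUE)))
    stop("malformed config: every non-comment line must be 'key = value'")
  keys <- trimws(sub("=.*$", "", lines))
  vals <- trimws(sub("^[^=]*=", "", lines))
  known <- names(formals(scenario_config))
  bad <- setdiff(keys, known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  args <- lapply(vals, function(v) {
    as.numeric(strsplit(v, ",", fixed = TRUE)[[1]])
  })
  names(args) <- keys
  do.call(scenario_config, args)
}
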