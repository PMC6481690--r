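#' Clinical treatment-characteristics table
#'
#' The ten-patient prostate IRE cohort shipped with the package: per
#' patient, pre-treatment PSA (ng/mL), maximum applied voltage (V),
#' maximum electrode spacing (cm), change in delivered current (A),
#' dynamic-model lethal threshold (V/cm), and ablation volume (cm^3).
#'
#' @return A data frame with 10 rows.
#' @examples
#' tab <- load_clinical_cohort()
#' round(mean(tab$threshold_dynamic))  # 506
#' @export
load_clinical_cohort <- function() {
  path <- system.file("extdata", "clinical_cohort.csv",
                      package = "irethreshold", mustWork = TRUE)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  num <- tab[setdiff(names(tab), "patient_id")]
  stopifnot(nrow(tab) == 10, all(unlist(num) > 0), all(tab$max_voltage <= 3000))
  tab
}

#' Pearson correlation with two-sided p-value
#'
#' Sample Pearson r with the exact t-transform p-value
#' (t = r sqrt((n-2)/(1-r^2)) on n-2 degrees of freedom).
#'
#' @param x,y Numeric vectors of equal length (n >= 3) with non-zero
#'   variance.
#' @return List with `r`, `p`, `n`.
#' @export
pearson <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  if (length(x) < 3) stop("at least 3 observations are required")
  if (sd(x) == 0 || sd(y) == 0)
    stop("correlation undefined: zero variance input")
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Post-hoc power of the Pearson correlation test
#'
#' Two-sided power at significance `alpha` when the population correlation
#' is taken equal to the observed `r` (retrospective power). The default
#' method evaluates the noncentral-t distribution of the test statistic at
#' noncentrality |r| sqrt((n-2)/(1-r^2)); `"fisher_z"` uses the normal
#' approximation with SE 1/sqrt(n-3).
#'
#' @param r Observed correlation, |r| < 1.
#' @param n Sample size (>= 4).
#' @param alpha Two-sided significance level.
#' @param method `"noncentral_t"` (default) or `"fisher_z"`.
#' @return Power as a fraction in (0, 1).
#' @examples
#' posthoc_power(-0.624, 10)  # ~0.51
#' @export
posthoc_power <- function(r, n, alpha = 0.05,
                          method = c("noncentral_t", "fisher_z")) {
  method <- match.arg(method)
  if (!is.numeric(r) || abs(r) >= 1) stop("'r' must satisfy |r| < 1")
  if (n < 4) stop("'n' must be at least 4")
  stopifnot(alpha > 0, alpha < 1)
  if (method == "noncentral_t") {
    df <- n - 2
    ncp <- abs(r) * sqrt(df / (1 - r^2))
    tc <- qt(1 - alpha / 2, df)
    pt(tc, df, ncp = ncp, lower.tail = FALSE) + pt(-tc, df, ncp = ncp)
  } else {
    lam <- atanh(abs(r)) * sqrt(n - 3)
    zc <- qnorm(1 - alpha / 2)
    pnorm(lam - zc) + pnorm(-lam - zc)
  }
}

#' Reproduce the cohort correlation table
#'
#' Computes the correlation, p-value, and post-hoc power for the variable
#' pairs recoverable from the treatment-characteristics table: PSA vs
#' threshold, PSA vs change in current, PSA vs ablation volume, and
#' threshold vs ablation volume. The change-in-PSA row of the published
#' analysis cannot be recomputed (post-treatment PSA is not part of the
#' record) and is reported in the `omitted` attribute.
#'
#' @param records Data frame in the layout of [load_clinical_cohort()].
#' @param power_method Passed to [posthoc_power()].
#' @return Data frame with columns `var1`, `var2`, `r`, `p`, `power_pct`,
#'   `n`, plus an `omitted` attribute naming the unrecoverable row.
#' @export
cohort_correlations <- function(records = load_clinical_cohort(),
                                power_method = "noncentral_t") {
  need <- c("psa_pre", "delta_current", "threshold_dynamic", "ablation_volume")
  stopifnot(all(need %in% names(records)))
  pairs <- list(
    c("psa_pre", "threshold_dynamic"),
    c("psa_pre", "delta_current"),
    c("psa_pre", "ablation_volume"),
    c("threshold_dynamic", "ablation_volume"))
  labels <- c(psa_pre = "Pre-treatment PSA",
              delta_current = "Change in current",
              threshold_dynamic = "Electric field threshold",
              ablation_volume = "Ablation volume")
  out <- do.call(rbind, lapply(pairs, function(pr) {
    ct <- pearson(records[[pr[1]]], records[[pr[2]]])
    data.frame(var1 = labels[pr[1]], var2 = labels[pr[2]],
               r = ct$r, p = ct$p,
               power_pct = 100 * posthoc_power(ct$r, ct$n,
                                               method = power_method),
               n = ct$n, row.names = NULL)
  }))
  attr(out, "omitted") <-
    "Change in PSA ~ ablation volume: post-treatment PSA is not part of the shipped record"
  out
}

#' Maximum induced transmembrane potential (Schwan equation)
#'
#' Steady-state peak transmembrane potential of a spherical cell in a
#' uniform field: TMP_max = 1.5 E r. Larger cells reach a critical TMP
#' (~1 V for electroporation) at lower fields, which is the candidate
#' mechanism linking cell size to the lethal threshold.
#'
#' @param e_field Field magnitude (V/m), non-negative; vectorized.
#' @param radius Cell radius (m), positive.
#' @return TMP (V).
#' @examples
#' tmp_max(66667, 10e-6)  # ~1 V at 666.7 V/cm for a 10 um cell
#' @export
tmp_max <- function(e_field, radius) {
  if (any(e_field < 0)) stop("'e_field' must be non-negative (V/m)")
  if (any(radius <= 0)) stop("'radius' must be positive (m)")
  1.5 * e_field * radius
}
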