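# Retention scores and significance calls.
#
# RS = IES+ / (IES+ + IES-). Significantly retained IESs are called against
# a control sample: the upper bound of the exact (Clopper-Pearson) confidence
# interval of the control RS becomes the null proportion of a one-sided
# binomial test on the experimental counts; p-values are Benjamini-Hochberg
# adjusted and called at adjusted p < 0.05.

#' Test configuration
#'
#' @param confidence Two-sided confidence level of the control interval
#'   (0.95 = the conventional 95\% exact interval).
#' @param fdr_threshold Adjusted-p cutoff for calling significant retention.
#' @return A list of class `ies_test_config`.
#' @export
test_config <- function(confidence = 0.95, fdr_threshold = 0.05) {
  if (confidence <= 0 || confidence >= 1) {
    stop("confidence must lie in (0, 1)", call. = FALSE)
  }
  if (fdr_threshold <= 0 || fdr_threshold >= 1) {
    stop("fdr_threshold must lie in (0, 1)", call. = FALSE)
  }
  structure(list(confidence = confidence, fdr_threshold = fdr_threshold),
            class = "ies_test_config")
}

#' Retention score
#'
#' `RS = ies_plus / (ies_plus + ies_minus)`, `NA` when no read was
#' classified.
#'
#' @param ies_plus,ies_minus Non-negative counts (vectorized).
#' @return Numeric vector in `[0, 1]`, `NA` where `n = 0`.
#' @export
retention_score <- function(ies_plus, ies_minus) {
  stopifnot(all(ies_plus >= 0), all(ies_minus >= 0))
  n <- ies_plus + ies_minus
  ifelse(n > 0, ies_plus / n, NA_real_)
}

#' Upper Clopper-Pearson bound
#'
#' Upper endpoint of the exact two-sided binomial confidence interval,
#' obtained by beta-quantile inversion of the binomial CDF:
#' `qbeta(1 - (1 - confidence)/2, k + 1, n - k)`, with `k = n` giving 1.
#'
#' @param k Successes (vectorized).
#' @param n Trials, `n >= 1`.
#' @param confidence Two-sided confidence level.
#' @return Upper bound(s) in `[0, 1]`.
#' @export
clopper_pearson_upper <- function(k, n, confidence = 0.95) {
  if (any(n < 1)) stop("n must be >= 1", call. = FALSE)
  if (any(k < 0) || any(k > n)) stop("need 0 <= k <= n", call. = FALSE)
  alpha2 <- (1 - confidence) / 2
  ifelse(k == n, 1, stats::qbeta(1 - alpha2, k + 1, n - k))
}

#' One-sided binomial exceedance p-value
#'
#' `P(X >= k)` for `X ~ Binomial(n, p0)`; the frequency-comparison test of
#' experimental counts against the control's upper confidence bound.
#'
#' @param k Observed successes (vectorized).
#' @param n Trials.
#' @param p0 Null proportion.
#' @return p-value(s); `k = 0` gives 1.
#' @export
binomial_greater_pvalue <- function(k, n, p0) {
  stopifnot(all(k >= 0), all(k <= n), all(p0 >= 0), all(p0 <= 1))
  ifelse(k <= 0, 1, stats::pbinom(k - 1, n, p0, lower.tail = FALSE))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjustment with enforced monotonicity, capped at 1; `NA` entries
#' are excluded from the number of tests and returned as `NA`. Input order is
#' preserved.
#'
#' @param pvalues Numeric vector in `[0, 1]` (NA allowed).
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  out <- rep(NA_real_, length(pvalues))
  m <- sum(ok)
  if (m == 0L) return(out)
  p <- pvalues[ok]
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  out[ok] <- pmin(1, cummin(m / (m:1) * p[o]))[ro]
  out
}

#' Call significantly retained IESs against a control
#'
#' Per IES with classified reads in both samples: the control counts give the
#' upper Clopper-Pearson bound of the control RS; the experimental counts are
#' tested one-sided against that bound; p-values are BH-adjusted over all
#' tested IESs. IESs with `n = 0` in either sample (or absent from the
#' control) get `NA` and are excluded from the number of tests.
#'
#' @param experiment,control Count tables (`ies_id`, `ies_plus`,
#'   `ies_minus`).
#' @param cfg A [test_config()].
#' @param pooled_control Use a single control bound computed from the summed
#'   control counts instead of per-IES bounds.
#' @return `data.frame`: `ies_id`, `ies_plus`, `ies_minus`, `rs`,
#'   `control_upper`, `pvalue`, `padj`, `significant`.
#' @export
call_significant <- function(experiment, control, cfg = test_config(),
                             pooled_control = FALSE) {
  stopifnot(is.data.frame(experiment), is.data.frame(control))
  needed <- c("ies_id", "ies_plus", "ies_minus")
  stopifnot(all(needed %in% names(experiment)),
            all(needed %in% names(control)))
  idx <- match(experiment$ies_id, control$ies_id)
  if (anyNA(idx)) {
    warning(sum(is.na(idx)), " IES(s) absent from the control table; ",
            "returned as NA", call. = FALSE)
  }
  n_exp <- experiment$ies_plus + experiment$ies_minus
  ctl_plus <- control$ies_plus[idx]
  n_ctl <- ctl_plus + control$ies_minus[idx]
  rs <- retention_score(experiment$ies_plus, experiment$ies_minus)

  control_upper <- rep(NA_real_, nrow(experiment))
  testable <- !is.na(idx) & n_exp > 0 & !is.na(n_ctl) & n_ctl > 0
  if (pooled_control) {
    tot_plus <- sum(control$ies_plus)
    tot_n <- tot_plus + sum(control$ies_minus)
    if (tot_n > 0) {
      control_upper[testable] <- clopper_pearson_upper(tot_plus, tot_n,
                                                       cfg$confidence)
    }
  } else {
    control_upper[testable] <- clopper_pearson_upper(
      ctl_plus[testable], n_ctl[testable], cfg$confidence)
  }
  pvalue <- rep(NA_real_, nrow(experiment))
  pvalue[testable] <- binomial_greater_pvalue(
    experiment$ies_plus[testable], n_exp[testable],
    control_upper[testable])
  padj <- bh_adjust(pvalue)
  data.frame(
    ies_id = experiment$ies_id,
    ies_plus = experiment$ies_plus,
    ies_minus = experiment$ies_minus,
    rs = rs,
    control_upper = control_upper,
    pvalue = pvalue,
    padj = padj,
    significant = !is.na(padj) & padj < cfg$fdr_threshold,
    stringsAsFactors = FALSE
  )
}

#' Write retention records as TSV
#'
#' RS and interval/p columns are written at full precision except `rs`,
#' rounded to 3 decimals for readability.
#'
#' @param records Output of [call_significant()].
#' @param path Output file.
#' @export
write_retention_records <- function(records, path) {
  records$rs <- round(records$rs, 3)
  write_tsv(records, path)
}
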