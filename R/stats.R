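#' Descriptive phase statistics
#'
#' Median and quartiles (linear-interpolation convention,
#' `stats::quantile` type 7) of phase lengths, per phase.
#'
#' @param lengths A named list or data.frame of numeric phase-length
#'   vectors in hours (e.g. columns `G1_h`, `S_h`, `G2M_h`, `total_h`).
#' @return A data.frame with one row per phase: `phase`, `n`, `q1`,
#'   `median`, `q3` (hours).
#' @export
describe_phases <- function(lengths) {
  if (is.data.frame(lengths))
    lengths <- as.list(lengths[vapply(lengths, is.numeric, TRUE)])
  rows <- lapply(names(lengths), function(nm) {
    x <- lengths[[nm]]
    x <- x[!is.na(x)]
    if (length(x) < 1) stop("phase ", nm, " has no values")
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    data.frame(phase = nm, n = length(x), q1 = q[1], median = q[2],
               q3 = q[3], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Normality-gated two-group comparison
#'
#' Shapiro-Wilk is run on each group at alpha = 0.05; when both groups
#' are consistent with normality a two-sample t test is used (pooled
#' variance by default, the classical Student form; set `welch = TRUE`
#' for the Welch form), otherwise a two-tailed Wilcoxon-Mann-Whitney.
#' Stars follow the convention * P < 0.05, ** P < 0.005, *** P < 0.0005.
#'
#' @param a,b Numeric samples, each n >= 3.
#' @param alpha Normality-gate level (default 0.05).
#' @param welch Use Welch's t instead of pooled.
#' @return List: `shapiro_p` (length 2), `test` (`"t"` or
#'   `"wilcoxon"`), `statistic`, `p`, `stars`.
#' @export
compare_groups <- function(a, b, alpha = 0.05, welch = FALSE) {
  if (length(a) < 3 || length(b) < 3)
    stop("each group needs n >= 3 (Shapiro-Wilk is undefined below that)")
  sw <- c(stats::shapiro.test(a)$p.value, stats::shapiro.test(b)$p.value)
  if (all(sw > alpha)) {
    ht <- stats::t.test(a, b, var.equal = !welch,
                        alternative = "two.sided")
    test <- "t"
  } else {
    ht <- stats::wilcox.test(a, b, alternative = "two.sided", exact = FALSE)
    test <- "wilcoxon"
  }
  list(shapiro_p = sw, test = test,
       statistic = unname(ht$statistic), p = ht$p.value,
       stars = significance_stars(ht$p.value))
}

#' @rdname compare_groups
#' @param p A p-value.
#' @export
significance_stars <- function(p) {
  if (is.na(p)) return(NA_character_)
  if (p < 0.0005) "***" else if (p < 0.005) "**" else if (p < 0.05) "*"
  else "ns"
}

#' Pairwise phase-length regressions
#'
#' Ordinary least squares for each unordered pair of phases (G1~S,
#' G1~G2M, S~G2M) across cells, reporting the slope, R-squared and the
#' p-value for the slope differing from zero -- a correlation screen for
#' coupling between phase lengths within single cells.
#'
#' @param phases A data.frame with numeric columns `G1_h`, `S_h`,
#'   `G2M_h` (one row per cell); rows with any NA are dropped.
#' @return A data.frame: `response`, `predictor`, `slope`, `r_squared`,
#'   `p_slope`, `n`.
#' @export
phase_regressions <- function(phases) {
  cols <- c("G1_h", "S_h", "G2M_h")
  stopifnot(all(cols %in% names(phases)))
  d <- phases[stats::complete.cases(phases[, cols]), cols]
  if (nrow(d) < 3) stop("need >= 3 cells with all phases called")
  pairs <- list(c("G1_h", "S_h"), c("G1_h", "G2M_h"), c("S_h", "G2M_h"))
  rows <- lapply(pairs, function(p) {
    fit <- stats::lm(d[[p[1]]] ~ d[[p[2]]])
    s <- summary(fit)
    data.frame(response = p[1], predictor = p[2],
               slope = unname(stats::coef(fit)[2]),
               r_squared = s$r.squared,
               p_slope = s$coefficients[2, 4],
               n = nrow(d), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cohen's d from summary statistics
#'
#' `d = |mean1 - mean2| / sd` for a common within-group standard
#' deviation.
#'
#' @param mean1,mean2 Group means.
#' @param sd Common standard deviation (> 0).
#' @return The effect size d.
#' @export
cohens_d <- function(mean1, mean2, sd) {
  if (sd <= 0) stop("sd must be positive")
  abs(mean1 - mean2) / sd
}

#' A-priori sample size per group
#'
#' For the t family, the smallest per-group n whose two-sided two-sample
#' t test at level `alpha` reaches the target power for effect size `d`
#' (noncentral-t iteration, noncentrality `d * sqrt(n/2)`, df `2n - 2`).
#' For the Wilcoxon-Mann-Whitney family, the t-family n divided by the
#' asymptotic relative efficiency of the WMW test under a normal parent
#' (3/pi), rounded up -- the classical normal-A.R.E. correction.
#'
#' @param d Effect size (> 0).
#' @param alpha Significance level (default 0.05).
#' @param power Target power (default 0.95).
#' @param family `"wilcoxon"` (default) or `"t"`.
#' @return Integer sample size per group (minimum 2).
#' @export
a_priori_n <- function(d, alpha = 0.05, power = 0.95,
                       family = c("wilcoxon", "t")) {
  family <- match.arg(family)
  if (d <= 0) stop("effect size d must be positive")
  if (!(alpha > 0 && alpha < 1 && power > 0 && power < 1))
    stop("alpha and power must be in (0, 1)")
  pow <- function(n) {
    df <- 2 * n - 2
    ncp <- d * sqrt(n / 2)
    tc <- stats::qt(1 - alpha / 2, df)
    1 - stats::pt(tc, df, ncp) + stats::pt(-tc, df, ncp)
  }
  n <- 2L
  while (pow(n) < power) {
    n <- n + 1L
    if (n > 1e7) stop("sample size search did not converge")
  }
  if (family == "wilcoxon") n <- as.integer(ceiling(n / (3 / pi)))
  n
}

#' Percent change between two medians
#'
#' `100 * (treated - control) / control`, as used to report e.g. "the
#' median G1 phase lengthened 94%, from 6.7 h to 13 h".
#'
#' @param control,treated Control and treated values; `control > 0`.
#' @param digits Rounding for the reported value (default 0, integer
#'   percent).
#' @return The percent change.
#' @export
percent_change <- function(control, treated, digits = 0) {
  if (any(control <= 0)) stop("control value must be positive")
  round(100 * (treated - control) / control, digits)
}

#' Percentage-point change between two fractions
#'
#' Plain difference of two percentages (e.g. a G1/G0 fraction moving
#' from 73.3\% to 82.8\% is a 9.5 percentage-point increase).
#'
#' @param control,treated Percentages.
#' @return `treated - control`.
#' @export
percentage_point_change <- function(control, treated) treated - control
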