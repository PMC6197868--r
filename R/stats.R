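# Rank-based statistical cores shared by marker discovery and the
# differential-expression rule.

# Mann-Whitney U for x vs y from pooled midranks; tie-run lengths are
# only computed when the caller needs the tie-corrected variance.
mw_u <- function(x, y, ties = TRUE) {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  tl <- if (ties) rle(sort.int(c(x, y), method = "quick"))$lengths else NULL
  list(u = u, nx = nx, ny = ny, tie_lengths = tl)
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Uses exact enumeration of all rank assignments when the pooled sample
#' has at most `exact_max` observations and no ties, and otherwise the
#' normal approximation with tie correction and continuity correction.
#'
#' @param x,y Non-empty numeric samples.
#' @param exact_max Largest pooled size for the exact path (default 10).
#' @return List with `statistic` (Mann-Whitney U for `x`) and `p.value`.
#' @export
wilcoxon_rank_sum <- function(x, y, exact_max = 10) {
  if (length(x) == 0 || length(y) == 0) stop("both samples must be non-empty")
  s <- mw_u(x, y)
  ties <- any(s$tie_lengths > 1)
  if (s$nx + s$ny <= exact_max && !ties) {
    p <- wilcox_exact_p(s$u, s$nx, s$ny)
  } else {
    p <- wilcox_normal_p(s$u, s$nx, s$ny, s$tie_lengths)
  }
  list(statistic = s$u, p.value = p)
}

# Exact two-sided p: twice the smaller tail of the null U distribution,
# capped at 1.
wilcox_exact_p <- function(u, nx, ny) {
  d <- wilcox_u_distribution(nx, ny)
  lower <- sum(d$prob[d$u <= u])
  upper <- sum(d$prob[d$u >= u])
  min(1, 2 * min(lower, upper))
}

wilcox_u_distribution <- function(nx, ny) {
  # direct enumeration over rank combinations; trivial at pooled n <= 10
  ranks <- seq_len(nx + ny)
  cmb <- utils::combn(ranks, nx)
  us <- colSums(cmb) - nx * (nx + 1) / 2
  tab <- table(us)
  tibble::tibble(u = as.numeric(names(tab)),
                 prob = as.numeric(tab) / ncol(cmb))
}

wilcox_normal_p <- function(u, nx, ny, tie_lengths) {
  n <- nx + ny
  mu <- nx * ny / 2
  tie_term <- sum(tie_lengths^3 - tie_lengths)
  sigma2 <- nx * ny / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  z <- u - mu
  z <- (z - sign(z) * 0.5) / sqrt(sigma2)   # continuity correction
  2 * stats::pnorm(-abs(z))
}

#' Area under the ROC curve and classification power
#'
#' `AUC = P(in > out) + 0.5 P(tie)` for a random in-group / out-group
#' value pair; `power = 2 |AUC - 0.5|` so both up- and down-markers score
#' highly.
#'
#' @param x_in,x_out Non-empty numeric samples.
#' @return List with `auc` and `power`.
#' @export
roc_power <- function(x_in, x_out) {
  if (length(x_in) == 0 || length(x_out) == 0) stop("both samples must be non-empty")
  s <- mw_u(x_in, x_out, ties = FALSE)
  auc <- s$u / (s$nx * s$ny)
  list(auc = auc, power = 2 * abs(auc - 0.5))
}

#' Pseudocounted fold change between two group means
#'
#' Returns `(pseudocount + mean_a) / (pseudocount + mean_b)`; the
#' pseudocount (default 0.01) keeps the ratio defined when either mean is
#' zero.  The direction-free fold used by the decision rule is
#' `max(ratio, 1/ratio)` (see [de_test()]).
#'
#' @param mean_a,mean_b Non-negative group means (vectorized).
#' @param pseudocount Additive pseudocount.
#' @return Numeric ratio(s).
#' @export
fold_change <- function(mean_a, mean_b, pseudocount = 0.01) {
  if (any(mean_a < 0) || any(mean_b < 0)) stop("means must be >= 0")
  (pseudocount + mean_a) / (pseudocount + mean_b)
}

#' Cohen's d standardized mean difference
#'
#' `d = (mean_a - mean_b) / s_pooled` with
#' `s_pooled = sqrt(((n_a-1) s_a^2 + (n_b-1) s_b^2) / (n_a + n_b - 2))`.
#' When the pooled deviation is zero, `d` is 0 for equal means and
#' `±Inf` otherwise (a degenerate perfectly-separated case, which passes
#' any magnitude threshold).
#'
#' @param mean_a,mean_b Group means (vectorized).
#' @param sd_a,sd_b Group standard deviations (n-1 denominator).
#' @param n_a,n_b Group sizes; `n_a + n_b` must be at least 3.
#' @return Numeric effect size(s).
#' @export
cohens_d <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b) {
  if (any(n_a + n_b < 3)) stop("need at least 3 observations in total")
  pooled <- sqrt(((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / (n_a + n_b - 2))
  diff <- mean_a - mean_b
  ifelse(pooled > 0, diff / pooled, ifelse(diff == 0, 0, sign(diff) * Inf))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values (monotone in rank, capped at 1).
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
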