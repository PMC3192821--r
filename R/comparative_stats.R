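# Comparison machinery used throughout the analyses. Conventions (fixed so
# p-values are reproducible bit-for-bit): average ranks for ties,
# tie-corrected variance, continuity correction in the normal approximation,
# exact enumeration for small samples without ties; all tests two-sided.

# exact null distribution of the Mann-Whitney U statistic by subset-sum DP:
# dp[m+1, s+1] = number of size-m subsets of ranks 1..N with rank sum s
.exact_ranksum_dist <- function(n1, n2) {
  N <- n1 + n2
  maxs <- n1 * N
  dp <- matrix(0, nrow = n1 + 1L, ncol = maxs + 1L)
  dp[1L, 1L] <- 1
  for (r in seq_len(N)) {
    for (m in rev(seq_len(min(r, n1)))) {
      cols <- (r + 1L):(maxs + 1L)
      dp[m + 1L, cols] <- dp[m + 1L, cols] + dp[m, cols - r]
    }
  }
  dp[n1 + 1L, ]  # index s+1 = count of W = s (W = rank sum of sample 1)
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Tests for a location shift between two independent samples. Exact
#' enumeration of the rank-sum distribution when the combined sample size is
#' at most `exact_max` and there are no ties; otherwise the normal
#' approximation with tie-corrected variance and continuity correction.
#' `NA` values are dropped. Completely tied data yield p = 1.
#'
#' @param x,y Numeric vectors.
#' @param exact_max Largest combined sample size for the exact test
#'   (default 20).
#' @return Two-sided p-value.
#' @export
#' @examples
#' rank_sum_test(c(1, 2, 3), c(4, 5, 6))  # exact p = 0.1
rank_sum_test <- function(x, y, exact_max = 20L) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (!length(x) || !length(y)) {
    stop("both samples must be non-empty after dropping NA", call. = FALSE)
  }
  n1 <- length(x)
  n2 <- length(y)
  all_v <- c(x, y)
  if (length(unique(all_v)) == 1L) return(1)
  r <- rank(all_v)
  W <- sum(r[seq_len(n1)])
  ties <- table(r)  # tie groups from ranks (not raw doubles)
  has_ties <- any(ties > 1L)
  if (!has_ties && (n1 + n2) <= exact_max) {
    dist <- .exact_ranksum_dist(n1, n2)
    tot <- sum(dist)
    lo <- sum(dist[1:(W + 1L)])  # W is integer here (no ties)
    hi <- sum(dist[(W + 1L):length(dist)])
    return(min(1, 2 * min(lo, hi) / tot))
  }
  N <- n1 + n2
  mu <- n1 * (N + 1) / 2
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
  if (sigma2 <= 0) return(1)
  z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

# exact null distribution of the signed-rank statistic V (sum over subsets)
.exact_signedrank_dist <- function(n) {
  maxs <- n * (n + 1) / 2
  dp <- numeric(maxs + 1L)
  dp[1L] <- 1
  for (r in seq_len(n)) {
    cols <- (r + 1L):(maxs + 1L)
    dp[cols] <- dp[cols] + dp[cols - r]
  }
  dp
}

#' Two-sided Wilcoxon signed-rank test for paired data
#'
#' Differences of exactly zero are dropped (Wilcoxon's convention). Exact
#' when at most `exact_max` differences, none zero and with untied
#' magnitudes; otherwise normal approximation with tie correction and
#' continuity correction.
#'
#' @param x Numeric vector of first measurements, or of differences if `y`
#'   is `NULL`.
#' @param y Optional paired second measurements.
#' @param exact_max Largest n for the exact test (default 20).
#' @return Two-sided p-value (1 when all differences are zero).
#' @export
signed_rank_test <- function(x, y = NULL, exact_max = 20L) {
  d <- if (is.null(y)) x else x - y
  d <- d[!is.na(d)]
  had_zeros <- any(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) return(1)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  ties <- table(r)  # tie groups from ranks (not raw doubles)
  has_ties <- any(ties > 1L)
  # dropped zeros disable the exact distribution (reference convention)
  if (!has_ties && !had_zeros && n <= exact_max) {
    dist <- .exact_signedrank_dist(n)
    tot <- sum(dist)
    lo <- sum(dist[1:(V + 1L)])
    hi <- sum(dist[(V + 1L):length(dist)])
    return(min(1, 2 * min(lo, hi) / tot))
  }
  mu <- n * (n + 1) / 4
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  if (sigma2 <= 0) return(1)
  z <- (V - mu - sign(V - mu) * 0.5) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Two-sided exact sign (binomial) test for paired data
#'
#' Pairs with zero difference are excluded; the remaining signs are tested
#' against theta = 1/2 with the exact binomial two-sided convention (sum of
#' all outcome probabilities not exceeding that of the observed outcome).
#'
#' @param x Numeric vector of first measurements, or of differences if `y`
#'   is `NULL`.
#' @param y Optional paired second measurements.
#' @return Two-sided p-value (1 when all differences are zero).
#' @export
#' @examples
#' sign_test(c(rep(1, 9), -1))  # 9/10 positive: p = 0.021484375
sign_test <- function(x, y = NULL) {
  d <- if (is.null(y)) x else x - y
  d <- d[!is.na(d)]
  d <- d[d != 0]
  m <- length(d)
  if (m == 0L) return(1)
  k <- sum(d > 0)
  binom_two_sided(k, m, 0.5)
}

#' Exact two-sided binomial test probability
#'
#' Probability under Binomial(n, p) of any outcome whose point probability
#' does not exceed that of `k` (the standard two-sided convention, with a
#' small relative tolerance on the comparison).
#'
#' @param k Observed successes.
#' @param n Trials.
#' @param p Null success probability.
#' @return Two-sided p-value.
#' @export
binom_two_sided <- function(k, n, p = 0.5) {
  dk <- stats::dbinom(k, n, p)
  probs <- stats::dbinom(0:n, n, p)
  min(1, sum(probs[probs <= dk * (1 + 1e-7)]))
}

#' Spearman correlation with a Fisher-z confidence interval
#'
#' Rank correlation with average ranks for ties; p-value from the
#' t approximation; the confidence interval from the Fisher z transform with
#' standard error 1/sqrt(n - 3).
#'
#' @param x,y Numeric vectors (pairwise-complete observations are used;
#'   n >= 4 required).
#' @param conf Confidence level (default 0.95).
#' @param bin_label Optional label carried into the result.
#' @return A list of class `"correlation_by_bin"`: `bin_label`, `n`, `rho`,
#'   `ci_low`, `ci_high`, `p_value`, `flags` (`"constant_input"` when a
#'   vector is constant, in which case `rho` is `NA`).
#' @export
spearman_ci <- function(x, y, conf = 0.95, bin_label = NA_character_) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 4L) stop("need at least 4 complete pairs", call. = FALSE)
  flags <- character(0)
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    return(structure(list(bin_label = bin_label, n = n, rho = NA_real_,
                          ci_low = NA_real_, ci_high = NA_real_,
                          p_value = NA_real_, flags = "constant_input"),
                     class = "correlation_by_bin"))
  }
  rho <- stats::cor(rank(x), rank(y))
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  z <- atanh(min(max(rho, -1 + 1e-15), 1 - 1e-15))
  se <- 1 / sqrt(n - 3)
  q <- stats::qnorm(1 - (1 - conf) / 2)
  structure(list(bin_label = bin_label, n = n, rho = rho,
                 ci_low = tanh(z - q * se), ci_high = tanh(z + q * se),
                 p_value = p, flags = flags),
            class = "correlation_by_bin")
}

#' @export
print.correlation_by_bin <- function(x, ...) {
  cat(sprintf("%s: rho = %s [%s, %s], n = %d, p = %s%s\n",
              if (is.na(x$bin_label)) "correlation" else x$bin_label,
              format(x$rho), format(x$ci_low), format(x$ci_high), x$n,
              format(x$p_value),
              if (length(x$flags))
                paste0(" [", paste(x$flags, collapse = ","), "]") else ""))
  invisible(x)
}

#' Assign values to empirical quantile bins
#'
#' Bin edges are the empirical quantiles of the pooled values; a value equal
#' to an edge goes to the lower bin. When edges coincide (fewer distinct
#' values than bins) the affected bins are merged with a warning.
#'
#' @param values Finite numeric vector (length >= k).
#' @param k Number of bins (default 4: quartiles Q1..Q4).
#' @return Factor of bin labels `Q1` (lowest) .. `Qk` (highest), one per
#'   value; merged bins keep the label of their lowest member.
#' @export
#' @examples
#' table(quartile_bin(1:8))
quartile_bin <- function(values, k = 4L) {
  stopifnot(all(is.finite(values)), length(values) >= k)
  edges <- stats::quantile(values, probs = seq_len(k - 1L) / k, names = FALSE)
  if (anyDuplicated(edges)) {
    warning("duplicate bin edges: bins merged", call. = FALSE)
    edges <- unique(edges)
  }
  idx <- rep(1L, length(values))
  for (e in edges) idx <- idx + (values > e)
  factor(paste0("Q", idx), levels = paste0("Q", seq_len(length(edges) + 1L)))
}

#' Summaries of a metric by group, relative to a reference group
#'
#' For each group: n (defined records), median, first and third quartiles,
#' two-sided rank-sum p-value versus the reference group, and the ratio of
#' the group median to the reference median. `NA` (UNDEFINED) records are
#' dropped and counted.
#'
#' @param values Numeric vector (may contain `NA` for undefined records).
#' @param groups Character/factor vector of group labels, same length.
#' @param reference Label of the reference group (must be present).
#' @return data.frame with one row per group (reference first): columns
#'   `group`, `n`, `median`, `q1`, `q3`, `p_value` (NA for the reference),
#'   `ratio`, `n_undefined_dropped`.
#' @export
summarize_groups <- function(values, groups, reference) {
  groups <- as.character(groups)
  if (!reference %in% groups) {
    stop("reference group '", reference, "' not present", call. = FALSE)
  }
  labs <- unique(groups)
  labs <- c(reference, setdiff(labs, reference))
  ref_vals <- values[groups == reference & !is.na(values)]
  rows <- list()
  for (g in labs) {
    v_all <- values[groups == g]
    v <- v_all[!is.na(v_all)]
    if (!length(v)) {
      warning("group '", g, "' has no defined records; omitted",
              call. = FALSE)
      next
    }
    qs <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    rows[[g]] <- data.frame(
      group = g, n = length(v), median = qs[2], q1 = qs[1], q3 = qs[3],
      p_value = if (g == reference) NA_real_ else rank_sum_test(v, ref_vals),
      ratio = qs[2] / stats::median(ref_vals),
      n_undefined_dropped = sum(is.na(v_all)),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
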