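# Group-comparison statistics used throughout the sex-differential analyses.
# Small-sample paths are exact by enumeration (valid under ties); large-sample
# paths use the standard tie-corrected approximations.

#' Mann-Whitney U test (two-sided)
#'
#' Rank-sum comparison of two groups. For small pooled sizes
#' (`nA + nB <= exact_max_n`) the two-sided P-value is computed exactly by
#' enumerating every assignment of the pooled values to the two groups, which
#' remains valid in the presence of ties. Larger samples use the normal
#' approximation with tie correction and no continuity correction.
#'
#' @param a,b Numeric vectors, one per group; each must be non-empty.
#' @param exact_max_n Pooled-size cutoff below which the exact enumeration
#'   path is used.
#' @return A list with elements `statistic` (`"MannWhitneyU"`), `value`
#'   (the U statistic of group `a`), `p` (two-sided P-value), `n` (group
#'   sizes) and `method` (`"exact"` or `"normal"`).
#' @export
mann_whitney <- function(a, b, exact_max_n = 12L) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0L || length(b) == 0L) stop("both groups must be non-empty")
  if (anyNA(a) || anyNA(b)) stop("NA values not allowed")
  na <- length(a); nb <- length(b); n <- na + nb
  pooled <- c(a, b)
  u_of <- function(idx_a) {
    r <- rank(pooled)
    sum(r[idx_a]) - na * (na + 1) / 2
  }
  u_obs <- u_of(seq_len(na))
  if (n <= exact_max_n) {
    combs <- utils::combn(n, na)
    r <- rank(pooled)
    u_all <- colSums(matrix(r[combs], nrow = na)) - na * (na + 1) / 2
    eps <- 1e-9
    p_lo <- mean(u_all <= u_obs + eps)
    p_hi <- mean(u_all >= u_obs - eps)
    p <- min(1, 2 * min(p_lo, p_hi))
    method <- "exact"
  } else {
    wt <- stats::wilcox.test(a, b, exact = FALSE, correct = FALSE)
    p <- wt$p.value
    method <- "normal"
  }
  list(statistic = "MannWhitneyU", value = u_obs, p = p,
       n = c(length(a), length(b)), method = method)
}

#' Pearson chi-square test on a 2x2 table, without continuity correction
#'
#' @param a,b,c,d Non-negative integer counts filling the table by rows:
#'   `rbind(c(a, b), c(c, d))`. All row and column margins must be positive.
#' @return A list with `statistic` (`"ChiSquare"`), `value`, `p`, and `n`
#'   (the row totals).
#' @export
chi_square_2x2 <- function(a, b, c, d) {
  x <- c(a, b, c, d)
  if (any(x < 0) || any(x != round(x))) stop("counts must be non-negative integers")
  tab <- matrix(x, nrow = 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("all margins of the 2x2 table must be positive")
  }
  ct <- stats::chisq.test(tab, correct = FALSE)
  list(statistic = "ChiSquare", value = unname(ct$statistic),
       p = ct$p.value, n = rowSums(tab))
}

# All permutations of 1..n as an (n! x n) integer matrix.
.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permutations(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  for (i in seq_len(n)) {
    rows <- (i - 1L) * nrow(sub) + seq_len(nrow(sub))
    out[rows, 1L] <- i
    rest <- seq_len(n)[-i]
    out[rows, -1L] <- matrix(rest[sub], nrow = nrow(sub))
  }
  out
}

#' Spearman rank correlation with small-sample exact P-value
#'
#' Computes Spearman's rho as the Pearson correlation of mid-ranks. For
#' `n <= exact_max_n` the two-sided P-value is exact, by enumerating all
#' permutations of one rank vector (valid under ties); otherwise the
#' t-distribution approximation is used.
#'
#' @param x,y Numeric vectors of equal length (`n >= 3` for a defined P).
#' @param exact_max_n Sample-size cutoff for the exact enumeration path.
#' @return A list with `statistic` (`"Spearman"`), `value` (rho), `p`, `n`
#'   and `method`. A constant input vector yields `value = NA` with
#'   `method = "undefined"`.
#' @export
spearman_test <- function(x, y, exact_max_n = 9L) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) {
    return(list(statistic = "Spearman", value = NA_real_, p = NA_real_,
                n = n, method = "insufficient_n"))
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(statistic = "Spearman", value = NA_real_, p = NA_real_,
                n = n, method = "undefined"))
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= exact_max_n) {
    perms <- .permutations(n)
    # correlations of rx against every permutation of ry, vectorised
    rxc <- rx - mean(rx)
    ryp <- matrix(ry[perms], nrow = nrow(perms))
    rypc <- ryp - rowMeans(ryp)
    num <- as.vector(rypc %*% rxc)
    den <- sqrt(sum(rxc^2)) * sqrt(rowSums(rypc^2))
    rho_all <- num / den
    p <- mean(abs(rho_all) >= abs(rho) - 1e-12)
    method <- "exact"
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    method <- "t_approx"
  }
  list(statistic = "Spearman", value = rho, p = p, n = n, method = method)
}
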