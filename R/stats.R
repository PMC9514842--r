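# Rank-based statistics with the reporting conventions used throughout the
# analysis: Spearman rank correlation with df = n - 2, Mann-Whitney U as
# min(Ua, Ub) with both group sizes reported, exact permutation p-values at
# small n, and semi-log linear trends. Ties are handled by midranks. All
# p-values are two-sided; significance convention is p < 0.05.

#' Spearman rank correlation
#'
#' Spearman's rho on midranks. The two-sided p-value is exact — computed by
#' full enumeration of the `n!` rank permutations — for `n <= exact_max`,
#' and from the t approximation `t = rho * sqrt((n-2)/(1-rho^2))` on n - 2
#' degrees of freedom otherwise. Degrees of freedom are reported as n - 2,
#' following the parenthetical convention (e.g. rho(104) for n = 106).
#'
#' rho is invariant under strictly monotone transforms of either variable.
#'
#' @param x,y Numeric vectors of equal length, n >= 4.
#' @param exact_max Largest n at which the permutation p is enumerated.
#' @return A `correlation_result`: list with `rho`, `df` (= n - 2), `n`,
#'   `p` (two-sided) and `method` (`"exact"` or `"t-approximation"`).
#' @examples
#' spearman_rank(1:4, c(10, 20, 30, 40))$rho # 1
#' @export
spearman_rank <- function(x, y, exact_max = 8L) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 4L) stop("Spearman rank test requires n >= 4")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop("ranks are constant; correlation undefined")
  rho <- stats::cor(rx, ry)
  if (n <= exact_max) {
    perms <- all_permutations(n)
    rhos <- apply(perms, 1L, function(p) stats::cor(rx, ry[p]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    method <- "exact"
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
    method <- "t-approximation"
  }
  structure(list(rho = rho, df = n - 2L, n = n, p = min(p, 1), method = method),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Spearman rho(%d) = %.3f, p = %.4g, n = %d (%s)\n",
              x$df, x$rho, x$p, x$n, x$method))
  invisible(x)
}

# all n! permutations of 1..n, one per row (n <= 8 in practice)
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (k in seq_len(n)) {
    rows <- seq_len(nrow(sub)) + r
    out[rows, 1L] <- k
    out[rows, -1L] <- ifelse(sub >= k, sub + 1L, sub)
    r <- r + nrow(sub)
  }
  out
}

#' Mann-Whitney U test
#'
#' Two-sample rank-sum test with midrank tie handling. The reported U is
#' `min(Ua, Ub)`, so 0 indicates complete separation and `n1*n2/2` complete
#' overlap. The two-sided p-value is exact — enumerating all
#' `choose(n1+n2, n1)` group assignments of the pooled midranks — when
#' `n1 + n2 <= exact_max`, and a normal approximation with tie correction
#' and continuity correction otherwise. Both group sizes are reported.
#'
#' @param a,b Numeric vectors (both non-empty).
#' @param exact_max Largest pooled size at which the exact p is enumerated.
#' @return A `utest_result`: list with `U`, `n1`, `n2`, `p` (two-sided) and
#'   `method`.
#' @examples
#' mann_whitney_u(1:3, 4:6)$U # 0, complete separation
#' @export
mann_whitney_u <- function(a, b, exact_max = 12L) {
  n1 <- length(a); n2 <- length(b)
  if (n1 == 0L || n2 == 0L) stop("both groups must be non-empty")
  pooled <- c(a, b)
  r <- rank(pooled)
  ua <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u <- min(ua, n1 * n2 - ua)
  N <- n1 + n2
  if (N <= exact_max) {
    sel <- utils::combn(N, n1)
    us <- apply(sel, 2L, function(idx) {
      s <- sum(r[idx]) - n1 * (n1 + 1) / 2
      min(s, n1 * n2 - s)
    })
    p <- mean(us <= u + 1e-12)
    method <- "exact"
  } else {
    tie_tab <- table(r)
    tie_corr <- sum(tie_tab^3 - tie_tab) / (N * (N - 1))
    sigma <- sqrt(n1 * n2 / 12 * ((N + 1) - tie_corr))
    z <- (abs(ua - n1 * n2 / 2) - 0.5) / sigma
    p <- 2 * stats::pnorm(-z)
    method <- "normal-approximation"
  }
  structure(list(U = u, n1 = n1, n2 = n2, p = min(max(p, 0), 1),
                 method = method),
            class = "utest_result")
}

#' @export
print.utest_result <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %g, p = %.4g (n1 = %d, n2 = %d, %s)\n",
              x$U, x$p, x$n1, x$n2, x$method))
  invisible(x)
}

#' Semi-log linear trend
#'
#' Ordinary least squares of `y` against `log10(x)`, the standard way of
#' displaying trends that span orders of magnitude in the predictor (e.g.
#' input resistance).
#'
#' @param x Positive predictor values.
#' @param y Response values.
#' @return List with `slope`, `intercept` (units of y per decade of x) and
#'   the underlying `lm` fit.
#' @export
semilog_trend <- function(x, y) {
  if (any(x <= 0)) stop("semi-log trend requires strictly positive x")
  fit <- stats::lm(y ~ log10(x))
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]), fit = fit)
}
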