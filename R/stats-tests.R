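#' Two-sided test result
#'
#' Lightweight container returned by the statistical tests in this package.
#' All tests are two-sided and deterministic for a fixed input.
#'
#' @param statistic test statistic.
#' @param p_value two-sided p-value in (0, 1].
#' @param method short description of the test variant actually used.
#' @param n_per_group integer vector of per-group sample sizes.
#' @return An object of class `primet_test`: a list with elements
#'   `statistic`, `p_value`, `method`, `sided` and `n_per_group`.
#' @keywords internal
new_test_result <- function(statistic, p_value, method, n_per_group) {
  structure(
    list(
      statistic = unname(statistic),
      p_value = min(1, unname(p_value)),
      method = method,
      sided = "two-sided",
      n_per_group = unname(n_per_group)
    ),
    class = "primet_test"
  )
}

#' @export
print.primet_test <- function(x, ...) {
  cat(x$method, " (", x$sided, ")\n", sep = "")
  cat("statistic = ", format(x$statistic), ", p = ", format(x$p_value),
    ", n = ", paste(x$n_per_group, collapse = "/"), "\n",
    sep = ""
  )
  invisible(x)
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact test of association in a 2x2 contingency table
#' `rbind(c(a, b), c(c, d))`. The two-sided p-value follows the
#' probability-mass rule: the sum of hypergeometric probabilities of all
#' tables with the observed margins whose point probability does not exceed
#' the observed table's (a relative tolerance of 1e-7 guards against
#' floating-point ties).
#'
#' @param a,b,c,d nonnegative integer cell counts; rows are groups, columns
#'   are outcome present/absent.
#' @return A [new_test_result()] object; `statistic` is the sample odds
#'   ratio `(a*d)/(b*c)`.
#' @examples
#' fisher_exact_2x2(1, 23, 6, 12) # p ~ 0.0305
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != round(counts))) {
    stop("cell counts must be nonnegative integers")
  }
  r1 <- a + b
  n <- a + b + c + d
  k <- a + c # first-column margin; a ranges over the support
  support <- max(0, k - (n - r1)):min(r1, k)
  logp <- stats::dhyper(support, r1, n - r1, k, log = TRUE)
  obs <- stats::dhyper(a, r1, n - r1, k, log = TRUE)
  p <- sum(exp(logp[logp <= obs + 1e-7]))
  new_test_result(
    statistic = (a * d) / (b * c),
    p_value = p,
    method = "Fisher's exact test (probability-mass rule)",
    n_per_group = c(r1, c + d)
  )
}

#' Two-sided Mann-Whitney U test
#'
#' Rank-sum comparison of two independent samples. The p-value is exact (by
#' full enumeration of the null U distribution) when both groups have at
#' most `exact_max_n` observations and there are no ties; otherwise the
#' normal approximation with tie correction and continuity correction is
#' used.
#'
#' @param x,y numeric vectors, both nonempty.
#' @param exact_max_n largest per-group size for which the exact null
#'   distribution is enumerated.
#' @return A [new_test_result()] object; `statistic` is U for the first
#'   sample (number of (x, y) pairs with x > y, ties counted 1/2).
#' @export
mann_whitney_u <- function(x, y, exact_max_n = 8) {
  if (length(x) == 0 || length(y) == 0) stop("both samples must be nonempty")
  nx <- length(x)
  ny <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- any(duplicated(c(x, y)))
  if (nx <= exact_max_n && ny <= exact_max_n && !ties) {
    counts <- u_null_counts(nx, ny)
    total <- sum(counts)
    # two-sided: double the smaller tail (U is symmetric about nx*ny/2)
    lo <- sum(counts[seq_len(u + 1)]) # P(U <= u); U support is 0..nx*ny
    hi <- sum(counts[(u + 1):length(counts)])
    p <- min(1, 2 * min(lo, hi) / total)
    method <- "Mann-Whitney U test (exact)"
  } else {
    mu <- nx * ny / 2
    tie_tab <- table(c(x, y))
    n <- nx + ny
    sigma2 <- nx * ny / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    if (sigma2 <= 0) {
      return(new_test_result(u, 1, "Mann-Whitney U test (degenerate)", c(nx, ny)))
    }
    z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "Mann-Whitney U test (normal approximation)"
  }
  new_test_result(u, p, method, c(nx, ny))
}

# Number of rank configurations giving each U value (Gaussian binomial
# coefficients), by the standard recurrence on the largest observation:
# c(u; m, n) = c(u - n; m - 1, n) + c(u; m, n - 1).
u_null_counts <- function(m, n) {
  # prev[[j + 1]] holds the counts vector for (m' - 1, j)
  prev <- lapply(0:n, function(j) 1) # m' = 0: U is always 0
  for (mp in seq_len(m)) {
    cur <- vector("list", n + 1)
    cur[[1]] <- 1 # n' = 0: U is always 0
    for (j in seq_len(n)) {
      len <- mp * j + 1
      a <- c(rep(0, j), prev[[j + 1]], rep(0, len))[seq_len(len)] # x largest: U gains j
      b <- c(cur[[j]], rep(0, len))[seq_len(len)] # y largest
      cur[[j + 1]] <- a + b
    }
    prev <- cur
  }
  prev[[n + 1]]
}

#' Two-sided Wilcoxon signed-rank test
#'
#' One-sample signed-rank test on paired differences. Zero differences are
#' dropped (Wilcoxon convention). Exact p by enumeration of all sign
#' assignments for up to 12 nonzero differences, otherwise the normal
#' approximation with tie correction and continuity correction.
#'
#' @param diffs numeric vector of paired differences, at least one nonzero.
#' @return A [new_test_result()] object; `statistic` is V, the sum of ranks
#'   of positive differences.
#' @export
wilcoxon_signed_rank <- function(diffs) {
  d <- diffs[diffs != 0]
  n <- length(d)
  if (n == 0) stop("all differences are zero")
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  ties <- any(duplicated(abs(d)))
  if (n <= 12 && !ties) {
    # enumerate all 2^n sign assignments of ranks 1..n
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    vs <- as.vector(signs %*% seq_len(n))
    total <- 2^n
    lo <- sum(vs <= v)
    hi <- sum(vs >= v)
    p <- min(1, 2 * min(lo, hi) / total)
    method <- "Wilcoxon signed-rank test (exact)"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
    z <- (v - mu - sign(v - mu) * 0.5) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "Wilcoxon signed-rank test (normal approximation)"
  }
  new_test_result(v, p, method, n)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement.
#'
#' @param p_values numeric vector of p-values in \[0, 1\]; NAs propagate.
#' @return q-values in the input order.
#' @export
benjamini_hochberg <- function(p_values) {
  p <- p_values
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  pv <- p[ok]
  m <- length(pv)
  if (m == 0) return(q)
  o <- order(pv, decreasing = TRUE)
  qv <- pmin(1, cummin(pv[o] * m / (m:1)))[order(o)]
  q[ok] <- qv
  q
}
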