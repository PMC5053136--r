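#' Exact p-value of the longest-run statistic
#'
#' Probability that the longest run of identical outcomes in n fair coin
#' flips is at least C. Uses the composition-counting recurrence: the
#' number of binary sequences of length n whose longest run is at most m
#' equals twice the number of compositions of n into parts of size at most
#' m. The recurrence is evaluated on the probability scale
#' (\code{r(n) = sum_{j<=m} r(n-j)/2^j}), which is exact in double
#' precision for the sequence counts representable below 2^53 and
#' numerically stable beyond.
#'
#' @param C smallest run length of interest (1 <= C <= n).
#' @param n number of points.
#' @return \code{Pr(longest run >= C)}.
#' @export
cormap_pvalue <- function(C, n) {
  if (C < 1 || C > n) stop("C must lie in 1..n")
  if (C == 1) return(1)
  m <- C - 1L
  # With r(k) = (# compositions of k into parts <= m) / 2^k, the p-value is
  # 1 - 2 r(n). Computing r directly cancels catastrophically for tiny
  # p-values, so track the deficit t(k) = 1/2 - r(k) instead, which obeys
  #   t(k) = 2^-(m+1) + sum_{j=1..m} t(k-j) / 2^j   for k > m,
  # with t(k) = 0 for 1 <= k <= m; then p = 2 t(n). All terms are positive,
  # so the recurrence is exact for enumerable n and stable beyond.
  if (n <= m) return(0)
  t <- numeric(n + 1L)   # t[k+1] = t(k); t(0) unused for k > m
  for (k in (m + 1L):n) {
    j <- seq_len(m)
    t[k + 1L] <- 2^-(m + 1) + sum(t[k + 1L - j] * 0.5^j)
  }
  max(0, min(1, 2 * t[n + 1L]))
}

longest_same_sign_run <- function(d) {
  s <- sign(d)
  best <- 0L; cur <- 0L; prev <- 0
  for (v in s) {
    if (v != 0 && v == prev) cur <- cur + 1L
    else cur <- if (v != 0) 1L else 0L  # zeros carry no sign and break runs
    prev <- v
    if (cur > best) best <- cur
  }
  best
}

#' CORMAP comparison of two curves
#'
#' Longest-run similarity test: the differences \code{a - b} over a shared
#' q range are reduced to signs; the longest run C of identical sign is
#' compared with its exact distribution under the fair-coin null (two
#' statistically identical noisy curves). Exact zeros carry no sign and
#' break runs; all-zero differences short-circuit to an "identical
#' curves" result with C = n and p = 1.
#'
#' @param a,b [saxs_curve] objects on one grid.
#' @param q_range optional \code{c(q_lo, q_hi)} restriction, nm^-1.
#' @return object of class \code{cormap_result}: \code{n_points},
#'   \code{C}, \code{p_value}, \code{adjusted_p} (NA until set by
#'   [adjusted_pvalues()]), \code{identical_flag}.
#' @export
cormap_compare <- function(a, b, q_range = NULL) {
  check_same_grid(a, b, what = "cormap inputs")
  keep <- rep(TRUE, length(a$q))
  if (!is.null(q_range))
    keep <- a$q >= q_range[1] & a$q <= q_range[2]
  if (sum(keep) < 10) stop("cormap needs at least 10 shared points")
  d <- a$I[keep] - b$I[keep]
  n <- length(d)
  if (all(d == 0))
    return(structure(list(n_points = n, C = n, p_value = 1,
                          adjusted_p = NA_real_, identical_flag = TRUE),
                     class = "cormap_result"))
  C <- longest_same_sign_run(d)
  structure(list(n_points = n, C = C,
                 p_value = cormap_pvalue(C, n),
                 adjusted_p = NA_real_, identical_flag = FALSE),
            class = "cormap_result")
}

#' @export
print.cormap_result <- function(x, ...) {
  cat(sprintf("<cormap: n = %d, C = %d, p = %.4g%s%s>\n",
              x$n_points, x$C, x$p_value,
              if (is.na(x$adjusted_p)) "" else
                sprintf(", adjusted p = %.4g", x$adjusted_p),
              if (x$identical_flag) " [identical curves]" else ""))
  invisible(x)
}

#' Multiple-comparison adjustment for a set of CORMAP tests
#'
#' Bonferroni: \code{adjusted_p = min(1, p * k)} over k comparisons. The
#' adjustment method is swappable via \code{method} (any method accepted
#' by [stats::p.adjust()]).
#'
#' @param results list of \code{cormap_result} objects.
#' @param method adjustment method, default \code{"bonferroni"}.
#' @return the list with \code{adjusted_p} filled in.
#' @export
adjusted_pvalues <- function(results, method = "bonferroni") {
  if (length(results) == 0) stop("empty result list")
  p <- vapply(results, function(r) r$p_value, numeric(1))
  adj <- stats::p.adjust(p, method = method)
  for (i in seq_along(results)) results[[i]]$adjusted_p <- adj[i]
  results
}
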