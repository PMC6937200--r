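#' Kruskal-Wallis rank-sum test
#'
#' H statistic with the standard tie correction,
#' `H = [ (12 / (N(N+1))) * sum R_g^2 / n_g - 3(N+1) ] / C` with
#' `C = 1 - sum(t^3 - t) / (N^3 - N)` over tie groups; p from the
#' chi-square distribution with k - 1 degrees of freedom.
#'
#' @param values numeric observations.
#' @param groups factor (or coercible) of the same length.
#' @return list of class `kruskal_wallis`: `H`, `df`, `p`, `n`.
#' @export
kruskal_wallis <- function(values, groups) {
  g <- factor(groups)
  stopifnot(length(values) == length(g))
  ok <- is.finite(values) & !is.na(g)
  values <- values[ok]; g <- droplevels(g[ok])
  N <- length(values)
  if (nlevels(g) < 2) stop_validation("kruskal_wallis: need >= 2 groups")
  if (N < 2) stop_validation("kruskal_wallis: need >= 2 observations")
  r <- rank(values)
  Rg <- tapply(r, g, sum)
  ng <- tabulate(g)
  H <- 12 / (N * (N + 1)) * sum(Rg^2 / ng) - 3 * (N + 1)
  ties <- table(values)
  Cf <- 1 - sum(ties^3 - ties) / (N^3 - N)
  H <- if (Cf > 0) H / Cf else 0
  df <- nlevels(g) - 1L
  structure(list(H = H, df = df, p = pchisq(H, df, lower.tail = FALSE),
                 n = N),
            class = "kruskal_wallis")
}

#' @export
print.kruskal_wallis <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H = %.4g, df = %d, p = %.4g (n = %d)\n",
              x$H, x$df, x$p, x$n))
  invisible(x)
}

#' Dunn's post hoc test
#'
#' Pairwise z statistics on mean ranks after a Kruskal-Wallis test, with
#' the usual tie correction in the standard error:
#' `z = (Rbar_i - Rbar_j) / sqrt( (N(N+1)/12 - sum(t^3 - t)/(12(N-1))) *
#' (1/n_i + 1/n_j) )`. Two-sided p-values, unadjusted by default.
#'
#' @param values numeric observations.
#' @param groups factor of the same length.
#' @param adjust `"none"` (default) or `"bonferroni"`.
#' @return data.frame of class `dunn_test`: one row per pair with
#'   `z`, `p` (and `p_adjusted` when requested).
#' @export
dunns_posthoc <- function(values, groups, adjust = c("none", "bonferroni")) {
  adjust <- match.arg(adjust)
  g <- factor(groups)
  stopifnot(length(values) == length(g))
  ok <- is.finite(values) & !is.na(g)
  values <- values[ok]; g <- droplevels(g[ok])
  N <- length(values)
  if (nlevels(g) < 2) stop_validation("dunns_posthoc: need >= 2 groups")
  r <- rank(values)
  rbar <- tapply(r, g, mean)
  ng <- tabulate(g)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  pairs <- combn(levels(g), 2)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    i <- match(pairs[1, k], levels(g)); j <- match(pairs[2, k], levels(g))
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / ng[i] + 1 / ng[j]))
    z <- if (se > 0) (rbar[i] - rbar[j]) / se else 0
    data.frame(group1 = pairs[1, k], group2 = pairs[2, k], z = unname(z),
               p = unname(2 * pnorm(-abs(z))), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (adjust == "bonferroni") out$p_adjusted <- pmin(1, out$p * nrow(out))
  structure(out, class = c("dunn_test", "data.frame"), adjust = adjust)
}
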