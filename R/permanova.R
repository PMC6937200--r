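# Distance-based permutational ANOVA, implemented from scratch.
#
# Sums of squares follow Anderson's formulation: with d_ij the
# dissimilarity between samples i and j,
#   SS_total  = (1/N) * sum_{i<j} d_ij^2
#   SS_within = sum_g (1/n_g) * sum_{i<j in g} d_ij^2
# so that with Euclidean d on univariate data the pseudo-F equals the
# classical ANOVA F. Significance comes from permuting sample labels.

# sum over groups of within-group squared-distance block sums / group size,
# for a label vector g. rowsum twice gives per-block sums fast.
ss_within_groups <- function(D2, g) {
  g <- as.character(g)
  # B[a, b] = sum of D2 over the (rows in b) x (cols in a) block; rowsum
  # and table both order groups by sort(unique(g)), so diag lines up.
  B <- rowsum(t(rowsum(D2, g)), g)
  ng <- as.vector(table(g))
  sum(diag(B) / (2 * ng))
}

#' One-way PERMANOVA
#'
#' Permutational multivariate analysis of variance on a dissimilarity
#' matrix for a single grouping factor. The pseudo-F statistic is
#' `(SS_between / (a - 1)) / (SS_within / (N - a))`; its null distribution
#' is built by randomly relabelling samples. When the number of distinct
#' relabellings is at most `n_perm`, the exact permutation distribution is
#' enumerated instead of sampled.
#'
#' @param D dissimilarity matrix (square symmetric; `dist` accepted).
#' @param groups factor (or coercible) of length `nrow(D)`; every level
#'   needs at least 2 members.
#' @param n_perm number of random permutations (default 9999).
#' @param seed integer seed for the permutation stream (required for a
#'   stochastic p-value; the caller's RNG state is left untouched).
#' @return object of class `permanova`: data.frame of terms
#'   (`df`, `SS`, `MS`, `pseudo_F`, `p`) plus attributes
#'   `n_permutations`, `scheme`, `seed`, `degenerate`.
#' @export
permanova_oneway <- function(D, groups, n_perm = 9999, seed = 1) {
  D <- as_distance_matrix(D)
  g <- factor(groups)
  N <- nrow(D)
  if (length(g) != N) stop_validation("groups length must match nrow(D)")
  if (nlevels(g) < 2) stop_validation("need at least 2 groups")
  sizes <- table(g)
  if (any(sizes < 2))
    stop_validation("group(s) with fewer than 2 members: %s",
                    paste(names(sizes)[sizes < 2], collapse = ", "))
  if (n_perm < 1) stop_validation("n_perm must be >= 1")
  a <- nlevels(g)
  D2 <- D^2
  ss_total <- sum(D2[upper.tri(D2)]) / N
  stat <- function(gg) {
    ssw <- ss_within_groups(D2, gg)
    ssb <- ss_total - ssw
    (ssb / (a - 1)) / (ssw / (N - a))
  }
  ssw_obs <- ss_within_groups(D2, g)
  ssb_obs <- ss_total - ssw_obs
  degenerate <- ss_total < 1e-14
  f_obs <- if (degenerate) NA_real_ else
    (ssb_obs / (a - 1)) / (ssw_obs / (N - a))

  n_distinct <- distinct_relabellings(sizes)
  if (degenerate) {
    p <- NA_real_
    scheme <- "degenerate"
    n_used <- 0L
  } else if (!is.na(n_distinct) && n_distinct <= n_perm) {
    fs <- enumerate_stats(g, stat)
    p <- mean(fs >= f_obs - 1e-12)
    scheme <- "exact enumeration"
    n_used <- length(fs)
  } else {
    fs <- with_seed(seed, vapply(seq_len(n_perm),
                                 function(k) stat(g[sample.int(N)]),
                                 numeric(1)))
    p <- (sum(fs >= f_obs - 1e-12) + 1) / (n_perm + 1)
    scheme <- "free permutation of labels"
    n_used <- n_perm
  }
  tab <- data.frame(
    term = c(deparse1(substitute(groups)), "Residual", "Total"),
    df = c(a - 1L, N - a, N - 1L),
    SS = c(ssb_obs, ssw_obs, ss_total),
    MS = c(ssb_obs / (a - 1), ssw_obs / (N - a), NA_real_),
    pseudo_F = c(f_obs, NA_real_, NA_real_),
    p = c(p, NA_real_, NA_real_),
    stringsAsFactors = FALSE)
  structure(tab, class = c("permanova", "data.frame"),
            n_permutations = n_used, scheme = scheme, seed = seed,
            degenerate = degenerate)
}

# number of distinct label arrangements N! / prod(n_g!); NA on overflow
distinct_relabellings <- function(sizes) {
  lg <- lgamma(sum(sizes) + 1) - sum(lgamma(sizes + 1))
  if (lg > log(1e15)) return(NA_real_)
  round(exp(lg))
}

# evaluate `stat` on every distinct relabelling (deduplicated full
# permutations for small N; pure combinations for 2 groups)
enumerate_stats <- function(g, stat) {
  N <- length(g)
  if (nlevels(g) == 2L) {
    lev <- levels(g)
    n1 <- sum(g == lev[1])
    picks <- combn(N, n1)
    apply(picks, 2, function(ix) {
      gg <- factor(rep(lev[2], N), levels = lev)
      gg[ix] <- lev[1]
      stat(gg)
    })
  } else {
    perms <- all_permutations(N)
    labs <- apply(perms, 1, function(ix) paste(g[ix], collapse = "\r"))
    keep <- !duplicated(labs)
    apply(perms[keep, , drop = FALSE], 1, function(ix) stat(g[ix]))
  }
}

all_permutations <- function(n) {
  if (n > 8) stop_validation("exact enumeration limited to n <= 8 for >2 groups")
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

#' Two-way additive PERMANOVA
#'
#' Partitions the total sum of squared dissimilarities into two crossed
#' main effects and a residual (no interaction term), using the
#' Gower-centred inner-product matrix and sequential (type-I) projections,
#' so term order matters for unbalanced designs and is reported.
#' Pseudo-F per term is `MS_term / MS_residual`; p-values come from
#' unrestricted permutation of the raw observations (rows of `D`), or from
#' permutation within the levels of the other factor when
#' `scheme = "within_blocks"`.
#'
#' @param D dissimilarity matrix.
#' @param factorA,factorB factors of length `nrow(D)`; `factorA` enters
#'   the sequential decomposition first.
#' @param n_perm permutations (default 9999).
#' @param seed integer seed.
#' @param scheme `"unrestricted"` (default) or `"within_blocks"`
#'   (permute within levels of the other factor).
#' @return a `permanova` object with terms A, B, Residual, Total.
#' @export
permanova_twoway <- function(D, factorA, factorB, n_perm = 9999, seed = 1,
                             scheme = c("unrestricted", "within_blocks")) {
  scheme <- match.arg(scheme)
  D <- as_distance_matrix(D)
  N <- nrow(D)
  fA <- factor(factorA); fB <- factor(factorB)
  if (length(fA) != N || length(fB) != N)
    stop_validation("factor lengths must match nrow(D)")
  nameA <- deparse1(substitute(factorA))
  nameB <- deparse1(substitute(factorB))
  if (any(table(fA, fB) == 0))
    warning("empty cell(s) in the A x B design; sequential SS depends on term order",
            call. = FALSE)
  # Gower-centred matrix G = -1/2 J A J with A = d^2, J the centring matrix
  A <- -0.5 * D^2
  G <- sweep(A, 1, rowMeans(A))
  G <- sweep(G, 2, colMeans(G))  # double centring: G = J A J
  ss_total <- sum(diag(G))
  hatmat <- function(X) {
    q <- qr(X)
    Q <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
    tcrossprod(Q)
  }
  mmA <- model.matrix(~fA)
  mmAB <- if (nlevels(fB) > 1) model.matrix(~fA + fB) else mmA
  HA <- hatmat(mmA)
  HAB <- hatmat(mmAB)
  dfA <- nlevels(fA) - 1L
  dfB <- qr(mmAB)$rank - qr(mmA)$rank
  dfR <- N - 1L - dfA - dfB
  if (dfA < 1) stop_validation("factorA has a single level")
  part <- function(Gm) {
    ssA <- sum(HA * Gm)            # tr(HA G) since HA symmetric
    ssAB <- sum(HAB * Gm)
    ssB <- ssAB - ssA
    ssR <- sum(diag(Gm)) - ssAB
    c(ssA, ssB, ssR)
  }
  obs <- part(G)
  msR <- obs[3] / dfR
  # constant / aliased factorB: the model collapses to the one-way layout
  f_obs <- c(obs[1] / dfA,
             if (dfB > 0) obs[2] / dfB else NA_real_) / msR
  perm_index <- function() {
    if (scheme == "unrestricted") return(sample.int(N))
    # within-blocks: permute within levels of the *other* factor for both
    # terms at once is impossible; use blocks of B for testing A and vice
    # versa would need two runs. Default to blocks of the crossed cells.
    ix <- seq_len(N)
    for (lev in levels(fB)) {
      w <- which(fB == lev)
      ix[w] <- w[sample.int(length(w))]
    }
    ix
  }
  fs <- with_seed(seed, {
    t(vapply(seq_len(n_perm), function(k) {
      ix <- perm_index()
      p <- part(G[ix, ix])
      c(p[1] / dfA,
        if (dfB > 0) p[2] / dfB else NA_real_) / (p[3] / dfR)
    }, numeric(2)))
  })
  pA <- (sum(fs[, 1] >= f_obs[1] - 1e-12) + 1) / (n_perm + 1)
  pB <- if (dfB > 0)
    (sum(fs[, 2] >= f_obs[2] - 1e-12) + 1) / (n_perm + 1) else NA_real_
  tab <- data.frame(
    term = c(nameA, nameB, "Residual", "Total"),
    df = c(dfA, dfB, dfR, N - 1L),
    SS = c(obs, ss_total),
    MS = c(obs[1] / dfA, if (dfB > 0) obs[2] / dfB else NA_real_, msR,
           NA_real_),
    pseudo_F = c(f_obs, NA_real_, NA_real_),
    p = c(pA, pB, NA_real_, NA_real_),
    stringsAsFactors = FALSE)
  structure(tab, class = c("permanova", "data.frame"),
            n_permutations = n_perm,
            scheme = paste0(scheme, " permutation, sequential SS (", nameA,
                            " then ", nameB, ")"),
            seed = seed, degenerate = ss_total < 1e-14)
}

#' Pairwise one-way PERMANOVA
#'
#' One-way PERMANOVA restricted to each pair of group levels; reported
#' unadjusted by default (matching how pairwise permutation tables are
#' usually printed), with optional Bonferroni adjustment.
#'
#' @param D dissimilarity matrix.
#' @param groups factor of length `nrow(D)`.
#' @param n_perm,seed as in [permanova_oneway()].
#' @param adjust `"none"` (default) or `"bonferroni"`.
#' @return data.frame of class `pairwise_permanova`: one row per pair with
#'   `pseudo_F`, `p` (and `p_adjusted` when requested).
#' @export
permanova_pairwise <- function(D, groups, n_perm = 9999, seed = 1,
                               adjust = c("none", "bonferroni")) {
  adjust <- match.arg(adjust)
  D <- as_distance_matrix(D)
  g <- factor(groups)
  if (nlevels(g) < 2) stop_validation("need at least 2 groups")
  pairs <- combn(levels(g), 2)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    lev <- pairs[, k]
    keep <- g %in% lev
    res <- permanova_oneway(D[keep, keep, drop = FALSE], droplevels(g[keep]),
                            n_perm = n_perm, seed = seed + k - 1L)
    data.frame(group1 = lev[1], group2 = lev[2],
               pseudo_F = res$pseudo_F[1], p = res$p[1],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (adjust == "bonferroni")
    out$p_adjusted <- pmin(1, out$p * nrow(out))
  structure(out, class = c("pairwise_permanova", "data.frame"),
            n_permutations = n_perm, seed = seed, adjust = adjust)
}

#' @export
print.permanova <- function(x, ...) {
  cat(sprintf("Permutational multivariate ANOVA (%s; %d permutations)\n",
              attr(x, "scheme"), attr(x, "n_permutations")))
  y <- as.data.frame(x)
  y$SS <- round(y$SS, 4); y$MS <- round(y$MS, 4)
  y$pseudo_F <- round(y$pseudo_F, 3)
  print.data.frame(y, row.names = FALSE)
  if (isTRUE(attr(x, "degenerate")))
    cat("note: total sum of squares is zero; statistics undefined\n")
  invisible(x)
}
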