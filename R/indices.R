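#' Vacuity index
#'
#' Percentage of sampled stomachs that are empty, an inverse indicator of
#' feeding intensity: `Vi = 100 * Es / Ts` with `Es` empty and `Ts` total
#' stomachs.
#'
#' @param n_empty number of empty stomachs.
#' @param n_total total number of stomachs (> 0).
#' @return percentage in \[0, 100\].
#' @export
vacuity_index <- function(n_empty, n_total) {
  if (!is_number(n_total) || n_total <= 0)
    stop_validation("vacuity_index: n_total must be positive")
  if (!is_number(n_empty) || n_empty < 0 || n_empty > n_total)
    stop_validation("vacuity_index: need 0 <= n_empty <= n_total")
  100 * n_empty / n_total
}

#' Numerical or gravimetric diet composition (%N / %W)
#'
#' Share of the pooled total count (`basis = "count"`, %N) or wet weight
#' (`basis = "weight"`, %W) contributed by each prey group, over all
#' stomachs. Sums to 100 over the matrix columns.
#'
#' @param matrix a [build_diet_matrix()] result.
#' @param basis `"weight"` or `"count"`.
#' @return named numeric vector of percentages.
#' @export
composition <- function(matrix, basis = c("weight", "count")) {
  basis <- match.arg(basis)
  X <- matrix[[basis]]
  total <- sum(X)
  if (total <= 0)
    stop_validation("composition: all stomachs empty (grand total is zero)")
  100 * colSums(X) / total
}

#' Frequency of occurrence (FOi)
#'
#' Percentage of stomachs in which prey group i is present. By default the
#' denominator is every stomach, empty ones included (vacuity is reported
#' separately); set `include_empty = FALSE` to restrict to non-empty
#' stomachs.
#'
#' @param matrix a `diet_matrix`.
#' @param include_empty keep empty stomachs in the denominator (default).
#' @return named numeric vector of percentages.
#' @export
frequency_of_occurrence <- function(matrix, include_empty = TRUE) {
  present <- matrix$weight > 0 | matrix$count > 0
  if (!include_empty) {
    keep <- rowSums(present) > 0
    present <- present[keep, , drop = FALSE]
  }
  if (nrow(present) == 0)
    stop_validation("frequency_of_occurrence: no stomachs")
  100 * colMeans(present)
}

#' Prey-specific abundance by weight and number (PWi, PNi)
#'
#' For each prey group i, restricted to the stomachs that contain i.
#' Two conventions are implemented:
#' \describe{
#'   \item{`"mean_ratio"` (default)}{the mean over those stomachs of the
#'     per-stomach percentage `100 * w_i / total`, the form used to define
#'     PSIRI — it is what makes PSIRI sum to 100 over exhaustive,
#'     mutually exclusive prey groups on complete data.}
#'   \item{`"pooled"`}{the ratio of pooled sums,
#'     `100 * sum(w_i) / sum(totals)`, the form often written as
#'     `sum(Wi) / sum(SWi)`; it weights stomachs by their content mass and
#'     does not preserve the PSIRI sum property.}
#' }
#' Groups never observed are returned as `NA` (absent, not zero).
#'
#' @param matrix a `diet_matrix`.
#' @param method `"mean_ratio"` or `"pooled"`.
#' @return list with numeric vectors `PW` and `PN` (percent).
#' @export
prey_specific_ratios <- function(matrix,
                                 method = c("mean_ratio", "pooled")) {
  method <- match.arg(method)
  W <- matrix$weight; N <- matrix$count
  present <- W > 0 | N > 0
  tw <- rowSums(W); tn <- rowSums(N)
  PW <- PN <- setNames(rep(NA_real_, ncol(W)), colnames(W))
  for (j in seq_len(ncol(W))) {
    rows <- present[, j]
    if (!any(rows)) next
    rw <- rows & tw > 0; rn <- rows & tn > 0  # guard weight- or count-less rows
    if (method == "pooled") {
      if (any(rw)) PW[j] <- 100 * sum(W[rw, j]) / sum(tw[rw])
      if (any(rn)) PN[j] <- 100 * sum(N[rn, j]) / sum(tn[rn])
    } else {
      if (any(rw)) PW[j] <- 100 * mean(W[rw, j] / tw[rw])
      if (any(rn)) PN[j] <- 100 * mean(N[rn, j] / tn[rn])
    }
  }
  list(PW = PW, PN = PN)
}

#' Prey-specific index of relative importance (PSIRI)
#'
#' `PSIRI = FO * (PW + PN) / 2 / 100`, reported in percent. Over an
#' exhaustive set of mutually exclusive prey groups computed from complete
#' data, PSIRI sums to 100.
#'
#' @param FO frequency of occurrence, percent.
#' @param PW,PN prey-specific abundance by weight / number, percent.
#' @return PSIRI, percent (vectorised).
#' @export
psiri <- function(FO, PW, PN) {
  ok <- function(x) all(is.na(x) | (x >= 0 & x <= 100))
  if (!ok(FO) || !ok(PW) || !ok(PN))
    stop_validation("psiri: FO, PW and PN must lie in [0, 100]")
  FO * (PW + PN) / 2 / 100
}

#' Prey-specific abundance for the feeding-strategy plot (Pi)
#'
#' Amundsen's weight-based prey-specific abundance: the percentage a prey
#' group makes up of all prey weight in only those stomachs where it
#' occurs. Identical by construction to the `PW` component of
#' [prey_specific_ratios()] under the same convention; both routes are
#' computed and asserted equal.
#'
#' @param matrix a `diet_matrix`.
#' @param method convention passed to [prey_specific_ratios()].
#' @return named numeric vector of percentages (`NA` for unobserved groups).
#' @export
prey_specific_abundance <- function(matrix,
                                    method = c("mean_ratio", "pooled")) {
  method <- match.arg(method)
  W <- matrix$weight
  present <- W > 0 | matrix$count > 0
  tw <- rowSums(W)
  Pi <- setNames(rep(NA_real_, ncol(W)), colnames(W))
  for (j in seq_len(ncol(W))) {
    rows <- present[, j] & tw > 0
    if (!any(rows)) next
    Pi[j] <- if (method == "pooled") 100 * sum(W[rows, j]) / sum(tw[rows])
             else 100 * mean(W[rows, j] / tw[rows])
  }
  PW <- prey_specific_ratios(matrix, method = method)$PW
  stopifnot(all(abs(Pi - PW) < 1e-9, na.rm = TRUE))
  Pi
}

#' Full diet index table
#'
#' Computes %N, %W, FO, PW, PN and PSIRI for every observed prey group on
#' one common stomach set — the shape of a classical diet-composition
#' table. Groups never observed are omitted (absent rows, not zeros).
#'
#' @param matrix a `diet_matrix`.
#' @param include_empty_in_fo denominator convention for FO; see
#'   [frequency_of_occurrence()].
#' @param method prey-specific abundance convention; see
#'   [prey_specific_ratios()].
#' @return data.frame of class `index_table` with one row per observed
#'   group and attributes `n_stomachs` and `vacuity`.
#' @export
index_table <- function(matrix, include_empty_in_fo = TRUE,
                        method = c("mean_ratio", "pooled")) {
  if (sum(matrix$weight) <= 0 && sum(matrix$count) <= 0)
    stop_validation("index_table: all stomachs empty")
  pN <- composition(matrix, "count")
  pW <- composition(matrix, "weight")
  FO <- frequency_of_occurrence(matrix, include_empty = include_empty_in_fo)
  ps <- prey_specific_ratios(matrix, method = method)
  n_with <- colSums(matrix$weight > 0 | matrix$count > 0)
  out <- data.frame(prey_group = colnames(matrix$weight),
                    percent_N = pN, percent_W = pW, FO = FO,
                    PW = ps$PW, PN = ps$PN,
                    PSIRI = psiri(FO, ps$PW, ps$PN),
                    n_stomachs_with_group = n_with,
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[n_with > 0, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_stomachs") <- nrow(matrix$weight)
  empties <- rowSums(matrix$weight) == 0 & rowSums(matrix$count) == 0
  attr(out, "vacuity") <- vacuity_index(sum(empties), nrow(matrix$weight))
  class(out) <- c("index_table", "data.frame")
  out
}

#' @export
print.index_table <- function(x, digits = 1, ...) {
  cat(sprintf("Diet index table (%d stomachs, vacuity %.1f%%)\n",
              attr(x, "n_stomachs"), attr(x, "vacuity")))
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], round, digits = digits)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

#' Amundsen feeding-strategy coordinates
#'
#' One point per observed prey group: frequency of occurrence on the x
#' axis, weight-based prey-specific abundance (Pi) on the y axis. Quadrant
#' labels (relative to the 50/50 midlines, half-open so a point exactly on
#' a midline falls in the upper/right quadrant) summarise prey importance
#' and the predator's feeding strategy: high FO and high Pi = dominant
#' prey taken by a specialised population; low FO and high Pi =
#' specialisation by individual phenotypes; high FO, low Pi =
#' generalisation; low FO and low Pi = rare prey.
#'
#' @param matrix a `diet_matrix`.
#' @param method prey-specific abundance convention; see
#'   [prey_specific_ratios()].
#' @return data.frame of class `strategy_points` with columns
#'   `prey_group`, `FO`, `Pi`, `quadrant`.
#' @export
amundsen_points <- function(matrix, method = c("mean_ratio", "pooled")) {
  FO <- frequency_of_occurrence(matrix)
  Pi <- prey_specific_abundance(matrix, method = method)
  keep <- !is.na(Pi)
  if (!any(keep)) stop_validation("amundsen_points: no prey group present")
  quadrant <- ifelse(FO[keep] >= 50 & Pi[keep] >= 50, "dominant/specialised",
              ifelse(FO[keep] < 50 & Pi[keep] >= 50, "specialised (high BPC)",
              ifelse(FO[keep] >= 50, "generalised (high WPC)",
                     "rare/generalised")))
  structure(data.frame(prey_group = names(FO)[keep], FO = FO[keep],
                       Pi = Pi[keep], quadrant = quadrant,
                       row.names = NULL, stringsAsFactors = FALSE),
            class = c("strategy_points", "data.frame"))
}

#' Plot the Amundsen feeding-strategy diagram
#'
#' @param x a `strategy_points` data.frame from [amundsen_points()].
#' @param ... passed to [plot.default()].
#' @return `x`, invisibly.
#' @export
plot.strategy_points <- function(x, ...) {
  plot.default(x$FO, x$Pi, xlim = c(0, 100), ylim = c(0, 100),
               xlab = "Frequency of occurrence (FO, %)",
               ylab = "Prey-specific abundance (Pi, %)",
               pch = 19, ...)
  abline(h = 50, v = 50, lty = 3, col = "grey50")
  text(x$FO, x$Pi, labels = x$prey_group, pos = 3, cex = 0.7)
  invisible(x)
}
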