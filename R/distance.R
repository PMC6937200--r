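#' Bray-Curtis dissimilarity matrix
#'
#' `d(x, y) = sum(|x - y|) / sum(x + y)` on non-negative sample rows; 0 for
#' identical compositions, 1 for disjoint ones. A pair of all-zero rows has
#' an undefined ratio; it is defined as 0 here (identical emptiness) with a
#' warning, so vacuous stomach pairs do not poison downstream clustering.
#'
#' @param X samples x variables matrix of non-negative values (or a
#'   `diet_matrix`, whose weight matrix is used).
#' @param similarity return `1 - d` instead of `d`.
#' @return object of class `dist_matrix`: symmetric n x n matrix with zero
#'   diagonal and the sample labels as dimnames.
#' @export
bray_curtis <- function(X, similarity = FALSE) {
  if (inherits(X, "diet_matrix")) X <- X$weight
  X <- as.matrix(X)
  if (any(X < 0)) stop_validation("bray_curtis: negative entries")
  if (nrow(X) < 2) stop_validation("bray_curtis: need at least 2 samples")
  n <- nrow(X)
  num <- matrix(0, n, n)
  for (j in seq_len(ncol(X))) {
    num <- num + abs(outer(X[, j], X[, j], "-"))
  }
  rs <- rowSums(X)
  den <- outer(rs, rs, "+")
  zero_pair <- den == 0
  if (any(zero_pair & upper.tri(zero_pair))) {
    warning("bray_curtis: pair(s) of all-zero samples; distance set to 0",
            call. = FALSE)
    den[zero_pair] <- 1  # numerator is 0 there as well
  }
  D <- num / den
  diag(D) <- 0
  if (similarity) D <- 1 - D
  labs <- rownames(X) %||% as.character(seq_len(n))
  dimnames(D) <- list(labs, labs)
  structure(D, class = c("dist_matrix", "matrix"))
}

# Validate and coerce anything distance-like to a plain symmetric matrix.
as_distance_matrix <- function(D, what = "distance matrix") {
  if (inherits(D, "dist")) D <- as.matrix(D)
  D <- unclass(as.matrix(D))
  if (nrow(D) != ncol(D)) stop_validation("%s must be square", what)
  if (any(is.na(D))) stop_validation("%s contains NA/NaN", what)
  if (max(abs(D - t(D))) > 1e-12) stop_validation("%s must be symmetric", what)
  if (any(abs(diag(D)) > 1e-12)) stop_validation("%s must have zero diagonal", what)
  if (is.null(rownames(D))) {
    labs <- as.character(seq_len(nrow(D)))
    dimnames(D) <- list(labs, labs)
  }
  D
}

#' Write / read a square distance matrix as labelled CSV
#'
#' @param D distance matrix (square symmetric; `dist` accepted).
#' @param path CSV path.
#' @return `path` (write) or a `dist_matrix` (read).
#' @export
write_distance_csv <- function(D, path) {
  D <- as_distance_matrix(D)
  df <- data.frame(label = rownames(D), D, check.names = FALSE)
  write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
            path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_distance_csv
#' @export
read_distance_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  labs <- as.character(df[[1]])
  D <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(D) <- "double"
  dimnames(D) <- list(labs, labs)
  structure(as_distance_matrix(D), class = c("dist_matrix", "matrix"))
}
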