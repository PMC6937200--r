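#' UPGMA (group-average) agglomerative clustering
#'
#' Classic unweighted pair-group clustering: at each step the two closest
#' clusters merge, and the distance from the merged cluster to any other is
#' the size-weighted mean of the member distances (equivalently, the mean
#' over all cross-pairs of leaves). Ties are broken deterministically by
#' the lexicographically smallest label-sorted pair, so the result is
#' invariant to input row order.
#'
#' @param D distance matrix (square symmetric, zero diagonal; a `dist` or
#'   `dist_matrix` also works).
#' @return object of class `merge_tree`: list with `merges` (data.frame of
#'   cluster ids and heights, `hclust`-style negative leaf indexing),
#'   `labels`, and `linkage = "average"`.
#' @export
upgma <- function(D) {
  D <- as_distance_matrix(D)
  n <- nrow(D)
  if (n < 2) stop_validation("upgma: need at least 2 leaves")
  labs <- rownames(D)
  # active cluster bookkeeping: id < 0 => leaf -id, id > 0 => merge row id
  ids <- -seq_len(n)
  sizes <- rep(1L, n)
  members <- lapply(seq_len(n), function(i) labs[i])
  d <- D
  merges <- data.frame(a = integer(n - 1L), b = integer(n - 1L),
                       height = numeric(n - 1L))
  for (step in seq_len(n - 1L)) {
    m <- length(ids)
    # find minimum off-diagonal distance; ties -> smallest sorted label pair
    best <- NULL; best_d <- Inf; best_key <- NULL
    for (i in seq_len(m - 1L)) {
      for (j in (i + 1L):m) {
        key <- paste(sort(c(min(members[[i]]), min(members[[j]]))),
                     collapse = "\r")
        if (d[i, j] < best_d - 1e-15 ||
            (abs(d[i, j] - best_d) <= 1e-15 && !is.null(best_key) &&
             key < best_key)) {
          best <- c(i, j); best_d <- d[i, j]; best_key <- key
        }
      }
    }
    i <- best[1]; j <- best[2]
    merges$a[step] <- ids[i]; merges$b[step] <- ids[j]
    merges$height[step] <- best_d
    # group-average update: weighted mean by cluster sizes
    ni <- sizes[i]; nj <- sizes[j]
    new_d <- (ni * d[i, ] + nj * d[j, ]) / (ni + nj)
    keep <- setdiff(seq_len(m), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], new_d[keep]),
               c(new_d[keep], 0))
    ids <- c(ids[keep], step)
    sizes <- c(sizes[keep], ni + nj)
    members <- c(members[keep], list(sort(c(members[[i]], members[[j]]))))
  }
  if (any(diff(merges$height) < -1e-12))
    stop("upgma: merge heights decreased (internal error)")  # UPGMA is monotone
  structure(list(merges = merges, labels = labs, linkage = "average"),
            class = "merge_tree")
}

#' @export
print.merge_tree <- function(x, ...) {
  cat(sprintf("<merge_tree> UPGMA, %d leaves, heights %.4g .. %.4g\n",
              length(x$labels), min(x$merges$height), max(x$merges$height)))
  invisible(x)
}

#' Convert a merge tree to an hclust object
#'
#' @param tree a `merge_tree`.
#' @return an object of class `hclust` (for plotting/cophenetic use).
#' @export
as_hclust <- function(tree) {
  stopifnot(inherits(tree, "merge_tree"))
  m <- cbind(tree$merges$a, tree$merges$b)
  hc <- list(merge = m, height = tree$merges$height,
             order = hclust_order(m), labels = tree$labels,
             method = "average", call = match.call(),
             dist.method = "user-supplied")
  class(hc) <- "hclust"
  hc
}

# Leaf ordering for plotting: depth-first left-to-right.
hclust_order <- function(m) {
  walk <- function(id) {
    if (id < 0) return(-id)
    c(walk(m[id, 1]), walk(m[id, 2]))
  }
  walk(nrow(m))
}

#' Cophenetic distances implied by a merge tree
#'
#' @param tree a `merge_tree`.
#' @return symmetric matrix of cophenetic distances (merge height at which
#'   each leaf pair first shares a cluster).
#' @export
cophenetic_matrix <- function(tree) {
  n <- length(tree$labels)
  C <- matrix(0, n, n, dimnames = list(tree$labels, tree$labels))
  members <- lapply(seq_len(n), identity)
  for (k in seq_len(n - 1L)) {
    ga <- tree$merges$a[k]; gb <- tree$merges$b[k]
    la <- if (ga < 0) -ga else members[[n + ga]]
    lb <- if (gb < 0) -gb else members[[n + gb]]
    C[la, lb] <- tree$merges$height[k]
    C[lb, la] <- tree$merges$height[k]
    members[[n + k]] <- c(la, lb)
  }
  C
}

quote_newick_label <- function(x) {
  if (grepl("[\\s()\\[\\]:;,'\"]", x, perl = TRUE)) {
    paste0("'", gsub("'", "''", x), "'")
  } else x
}

#' Export a merge tree as a Newick string
#'
#' The tree is written ultrametrically: every node sits at half its merge
#' height (so the leaf-to-leaf path length through a node equals the merge
#' height, i.e. the cophenetic distance), and branch lengths are the
#' differences between parent and child node heights. Labels containing
#' Newick-reserved characters are quoted.
#'
#' @param tree a `merge_tree`.
#' @param digits significant digits for branch lengths.
#' @return a single Newick string, terminated by `;`.
#' @export
to_newick <- function(tree, digits = 10) {
  stopifnot(inherits(tree, "merge_tree"))
  fmt <- function(x) format(x, digits = digits, trim = TRUE, scientific = FALSE)
  node_str <- function(id, parent_age) {
    if (id < 0) {
      lab <- quote_newick_label(tree$labels[-id])
      return(paste0(lab, ":", fmt(parent_age)))
    }
    age <- tree$merges$height[id] / 2
    inner <- paste(node_str(tree$merges$a[id], age),
                   node_str(tree$merges$b[id], age), sep = ",")
    paste0("(", inner, "):", fmt(parent_age - age))
  }
  root <- nrow(tree$merges)
  root_age <- tree$merges$height[root] / 2
  inner <- paste(node_str(tree$merges$a[root], root_age),
                 node_str(tree$merges$b[root], root_age), sep = ",")
  paste0("(", inner, ");")
}
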