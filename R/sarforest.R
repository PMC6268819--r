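# Descriptor-based classifier: Shannon-entropy filtering of molecular
# descriptors followed by a decision forest of five Gini-split trees with
# pairwise-disjoint descriptor sets. The forest prediction is the
# unweighted mean of per-tree leaf class fractions.

#' Shannon entropy of a descriptor column
#'
#' Entropy in bits of the column after discretization. Columns with few
#' distinct values are used as-is; continuous columns are discretized into
#' `n_bins` equal-width bins.
#'
#' @param x numeric vector.
#' @param n_bins number of equal-width bins for continuous values.
#' @return entropy in bits (0 for a constant column).
#' @export
shannon_entropy <- function(x, n_bins = 10) {
  ux <- unique(x)
  if (length(ux) <= 1) return(0)
  lev <- if (length(ux) <= n_bins) {
    factor(x)
  } else {
    cut(x, breaks = seq(min(x), max(x), length.out = n_bins + 1),
        include.lowest = TRUE)
  }
  p <- tabulate(lev) / length(x)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Filter descriptors by information content
#'
#' Drops descriptor columns whose Shannon entropy falls below a threshold;
#' constant columns are always dropped (entropy 0).
#'
#' @param m descriptor matrix, compounds in rows.
#' @param min_entropy entropy threshold in bits.
#' @param n_bins discretization bins for [shannon_entropy()].
#' @return filtered matrix; retained and dropped column names in
#'   `attr(, "entropy_filter")`.
#' @export
filter_descriptors <- function(m, min_entropy = 0.5, n_bins = 10) {
  h <- apply(m, 2, shannon_entropy, n_bins = n_bins)
  keep <- if (min_entropy > 0) h >= min_entropy else rep(TRUE, ncol(m))
  if (!any(keep)) stop("entropy filter removed every descriptor")
  out <- m[, keep, drop = FALSE]
  attr(out, "entropy_filter") <- list(entropy = h,
                                      retained = colnames(m)[keep],
                                      dropped = colnames(m)[!keep],
                                      min_entropy = min_entropy)
  out
}

# Gini impurity of a count pair
.gini <- function(n_p, n_w) {
  n <- n_p + n_w
  if (n == 0) return(0)
  1 - (n_p / n)^2 - (n_w / n)^2
}

# Best (threshold, decrease) for one descriptor at one node; candidate
# thresholds are midpoints of adjacent sorted unique values. Vectorized
# over split positions via cumulative class counts.
.best_split_column <- function(x, y, min_leaf) {
  ord <- order(x)
  xs <- x[ord]
  ys <- y[ord]  # 1 = potent
  n <- length(ys)
  cum_p <- cumsum(ys)
  n_p <- cum_p[n]
  # split after position i: left = 1..i
  i <- seq_len(n - 1)
  valid <- xs[i] != xs[i + 1] & i >= min_leaf & (n - i) >= min_leaf
  if (!any(valid)) return(NULL)
  i <- i[valid]
  lp <- cum_p[i]
  lw <- i - lp
  rp <- n_p - lp
  rw <- (n - i) - rp
  parent <- .gini(n_p, n - n_p)
  child <- (i / n) * (1 - (lp / i)^2 - (lw / i)^2) +
    ((n - i) / n) * (1 - (rp / (n - i))^2 - (rw / (n - i))^2)
  dec <- parent - child
  best <- which.max(dec)
  list(threshold = (xs[i[best]] + xs[i[best] + 1]) / 2,
       decrease = dec[best])
}

#' Grow a single Gini decision tree
#'
#' Binary CART-style tree: each node takes the (descriptor, threshold)
#' pair with the largest Gini-impurity decrease, thresholds being midpoints
#' of adjacent sorted unique values; left branch is `x <= threshold`.
#' Growth stops at class purity, at `min_leaf` compounds per child, or when
#' no split yields a positive decrease. Descriptors in
#' `excluded_descriptors` are unavailable to this tree.
#'
#' @param m descriptor matrix.
#' @param labels `"P"`/`"W"` per row.
#' @param excluded_descriptors column names this tree must not use.
#' @param min_leaf minimum compounds in each child.
#' @param max_depth safety cap on depth.
#' @return list of class `"gini_tree"` with the recursive `node` structure
#'   and `descriptors` (the ones actually used).
#' @export
build_tree <- function(m, labels, excluded_descriptors = character(),
                       min_leaf = 5, max_depth = 12) {
  labels <- .check_labels(labels)
  avail <- setdiff(colnames(m), excluded_descriptors)
  if (!length(avail)) stop("no descriptors available for this tree")
  y <- as.numeric(labels == "P")
  used <- character()

  grow <- function(idx, depth) {
    n_p <- sum(y[idx])
    n_w <- length(idx) - n_p
    leaf <- list(leaf = TRUE, n_p = n_p, n_w = n_w,
                 p_potent = if (length(idx)) n_p / length(idx) else 0.5)
    if (n_p == 0 || n_w == 0 || length(idx) < 2 * min_leaf ||
        depth >= max_depth) {
      return(leaf)
    }
    best <- NULL
    for (d in avail) {
      s <- .best_split_column(m[idx, d], y[idx], min_leaf)
      if (!is.null(s) && s$decrease > 1e-12 &&
          (is.null(best) || s$decrease > best$decrease + 1e-12)) {
        best <- c(s, descriptor = d)
      }
    }
    if (is.null(best)) return(leaf)
    used <<- union(used, best$descriptor)
    left_idx <- idx[m[idx, best$descriptor] <= best$threshold]
    right_idx <- setdiff(idx, left_idx)
    list(leaf = FALSE, descriptor = best$descriptor,
         threshold = best$threshold, decrease = best$decrease,
         n_p = n_p, n_w = n_w,
         left = grow(left_idx, depth + 1),
         right = grow(right_idx, depth + 1))
  }

  root <- grow(seq_len(nrow(m)), 0)
  structure(list(node = root, descriptors = used, min_leaf = min_leaf),
            class = "gini_tree")
}

.tree_prob <- function(node, row) {
  while (!node$leaf) {
    node <- if (row[[node$descriptor]] <= node$threshold) node$left else
      node$right
  }
  node$p_potent
}

#' Predict potent-class probabilities from one tree
#' @param tree `"gini_tree"`.
#' @param m descriptor matrix.
#' @return numeric vector of leaf potent fractions.
#' @export
predict_tree <- function(tree, m) {
  vapply(seq_len(nrow(m)), function(r) .tree_prob(tree$node, m[r, ]), 0)
}

#' Train a five-tree descriptor-disjoint decision forest
#'
#' Trees are grown sequentially; every descriptor used by an earlier tree
#' is excluded from later trees, making the trees' descriptor sets pairwise
#' disjoint ("distinct but comparable"). Prediction averages the five
#' trees' leaf class fractions; a compound is called potent when the mean
#' reaches 0.5. If a later tree finds no usable split the forest is
#' returned short, with a flag.
#'
#' @param m (entropy-filtered) descriptor matrix.
#' @param labels `"P"`/`"W"` per row.
#' @param n_trees number of trees (default 5).
#' @param min_leaf minimum compounds per leaf child.
#' @return object of class `"decision_forest"`: `trees`, `descriptor_sets`,
#'   `complete` (got all `n_trees` informative trees?).
#' @export
train_forest <- function(m, labels, n_trees = 5, min_leaf = 5) {
  labels <- .check_labels(labels)
  trees <- list()
  excluded <- character()
  for (t in seq_len(n_trees)) {
    tree <- tryCatch(build_tree(m, labels, excluded, min_leaf = min_leaf),
                     error = function(e) NULL)
    if (is.null(tree) || !length(tree$descriptors)) break
    trees[[t]] <- tree
    excluded <- c(excluded, tree$descriptors)
  }
  structure(list(trees = trees,
                 descriptor_sets = lapply(trees, `[[`, "descriptors"),
                 complete = length(trees) == n_trees,
                 n_trees_requested = n_trees),
            class = "decision_forest")
}

#' Classify compounds with a decision forest
#' @param forest `"decision_forest"`.
#' @param m descriptor matrix.
#' @param cutoff potent call threshold on the mean probability.
#' @return data.frame with `id`, `probability`, `call`.
#' @export
classify_forest <- function(forest, m, cutoff = 0.5) {
  if (!length(forest$trees)) stop("empty forest")
  probs <- vapply(forest$trees, predict_tree, numeric(nrow(m)), m = m)
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = nrow(m))
  p <- rowMeans(probs)
  data.frame(id = rownames(m) %||% seq_len(nrow(m)),
             probability = p,
             call = ifelse(p >= cutoff, "P", "W"),
             stringsAsFactors = FALSE)
}

#' Tally descriptor usage across forests
#'
#' For each descriptor, the number of trees (across all supplied forests)
#' in which it was used. Within one forest counts are 0 or 1 per descriptor
#' because trees are descriptor-disjoint.
#'
#' @param forests list of `"decision_forest"` objects (or a single one).
#' @param descriptors optional universe of descriptor names to report
#'   zeros for.
#' @return named integer vector of tree counts.
#' @export
usage_tally <- function(forests, descriptors = NULL) {
  if (inherits(forests, "decision_forest")) forests <- list(forests)
  used <- unlist(lapply(forests, function(f)
    unlist(f$descriptor_sets, use.names = FALSE)))
  tal <- table(used)
  out <- stats::setNames(as.integer(tal), names(tal))
  if (!is.null(descriptors)) {
    full <- stats::setNames(integer(length(descriptors)), descriptors)
    full[names(out)] <- out
    out <- full
  }
  out
}
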