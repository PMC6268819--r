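make_descriptor_data <- function(n = 120, n_desc = 20, n_info = 5,
                                 effect = 2.5, seed = 1) {
  set.seed(seed)
  labels <- rep(c("P", "W"), length.out = n)
  m <- matrix(rnorm(n * n_desc), nrow = n,
              dimnames = list(sprintf("c%03d", 1:n),
                              sprintf("d%02d", 1:n_desc)))
  m[labels == "P", seq_len(n_info)] <-
    m[labels == "P", seq_len(n_info)] + effect
  list(m = m, labels = labels)
}

test_that("Shannon entropy of discretized columns", {
  expect_equal(shannon_entropy(rep(3.2, 50)), 0)
  expect_equal(shannon_entropy(rep(c(0, 1), 25)), 1)
  expect_equal(shannon_entropy(rep(1:8, 10)), 3)
  # ten equal-width bins cap the entropy at log2(10)
  expect_lte(shannon_entropy(runif(10000)), log2(10))
})

test_that("entropy filter drops constant columns and honors thresholds", {
  set.seed(2)
  m <- cbind(a = rnorm(40), b = rep(1, 40), c = runif(40))
  f <- filter_descriptors(m, min_entropy = 0.5)
  expect_false("b" %in% colnames(f))
  expect_equal(ncol(filter_descriptors(m, min_entropy = 0)), 3)
  expect_error(filter_descriptors(m[, "b", drop = FALSE], 0.5), "every")
})

test_that("the bundled synthetic descriptor table passes 327 columns", {
  cmp <- gen_compounds(121, seed = 8)
  desc <- gen_descriptors(cmp, seed = 9)
  expect_equal(ncol(desc), 777)
  f <- filter_descriptors(desc)
  expect_equal(ncol(f), 327)
  expect_true(all(attr(desc, "informative") %in% colnames(f)))
})

test_that("tree growth matches an exhaustive split-search oracle", {
  set.seed(12)
  m <- matrix(rnorm(12 * 3), nrow = 12,
              dimnames = list(NULL, c("d1", "d2", "d3")))
  labels <- ifelse(m[, 2] > 0.2, "P", "W")
  if (length(unique(labels)) < 2) labels[1:2] <- c("P", "W")
  tree <- build_tree(m, labels, min_leaf = 2)

  # brute force: every descriptor, every midpoint threshold
  gini <- function(y) 1 - mean(y)^2 - (1 - mean(y))^2
  y <- as.numeric(labels == "P")
  best <- list(dec = -Inf)
  for (d in colnames(m)) {
    v <- sort(unique(m[, d]))
    for (t in (v[-1] + v[-length(v)]) / 2) {
      l <- m[, d] <= t
      if (sum(l) < 2 || sum(!l) < 2) next
      dec <- gini(y) - mean(l) * gini(y[l]) - mean(!l) * gini(y[!l])
      if (dec > best$dec + 1e-12) best <- list(dec = dec, d = d, t = t)
    }
  }
  expect_equal(tree$node$descriptor, best$d)
  expect_equal(tree$node$threshold, best$t)
  expect_equal(tree$node$decrease, best$dec, tolerance = 1e-12)
})

test_that("degenerate nodes and perfect separators behave", {
  m <- matrix(rnorm(20), ncol = 2, dimnames = list(NULL, c("a", "b")))

  # one perfectly separating descriptor gives a depth-1 tree whose pure
  # children are leaves with zero impurity
  sep <- cbind(split = c(rep(0, 10), rep(1, 10)), noise = rnorm(20))
  labels <- rep(c("P", "W"), each = 10)
  t2 <- build_tree(sep, labels, min_leaf = 2)
  expect_equal(t2$node$descriptor, "split")
  expect_true(t2$node$left$leaf && t2$node$right$leaf)
  expect_equal(sort(c(t2$node$left$p_potent, t2$node$right$p_potent)),
               c(0, 1))
  expect_equal(predict_tree(t2, sep), as.numeric(labels == "P"))

  expect_error(build_tree(m, labels, excluded_descriptors = c("a", "b")),
               "no descriptors")
})

test_that("gini decrease is positive at every accepted split", {
  d <- make_descriptor_data(seed = 3)
  tree <- build_tree(d$m, d$labels)
  walk <- function(node) {
    if (node$leaf) return(invisible())
    expect_gt(node$decrease, 0)
    walk(node$left)
    walk(node$right)
  }
  walk(tree$node)
})

test_that("forest trees use pairwise-disjoint descriptor sets", {
  for (s in 1:3) {
    d <- make_descriptor_data(seed = s)
    forest <- train_forest(d$m, d$labels)
    sets <- forest$descriptor_sets
    for (i in seq_along(sets)) for (j in seq_along(sets)) {
      if (i < j) expect_length(intersect(sets[[i]], sets[[j]]), 0)
    }
    # single model: usage counts are zero or one by disjointness
    tal <- usage_tally(forest, descriptors = colnames(d$m))
    expect_true(all(tal %in% 0:1))
  }
})

test_that("forest training accuracy is high on separable data", {
  accs <- numeric(3)
  for (s in 1:3) {
    d <- make_descriptor_data(seed = 10 + s)
    forest <- train_forest(d$m, d$labels)
    accs[s] <- mean(classify_forest(forest, d$m)$call == d$labels)
  }
  expect_true(all(accs >= 0.95))
})

test_that("forest prediction is invariant to tree order", {
  d <- make_descriptor_data(seed = 17)
  forest <- train_forest(d$m, d$labels)
  shuffled <- forest
  shuffled$trees <- rev(forest$trees)
  expect_equal(classify_forest(shuffled, d$m)$probability,
               classify_forest(forest, d$m)$probability)
})

test_that("shuffling informative columns degrades held-out accuracy", {
  set.seed(23)
  d <- make_descriptor_data(n = 240, seed = 23)
  train_idx <- 1:160
  test_idx <- 161:240
  forest <- train_forest(d$m[train_idx, ], d$labels[train_idx])
  acc <- mean(classify_forest(forest, d$m[test_idx, ])$call ==
                d$labels[test_idx])

  m_shuf <- d$m
  m_shuf[, 1:5] <- m_shuf[sample(nrow(m_shuf)), 1:5]
  forest_s <- train_forest(m_shuf[train_idx, ], d$labels[train_idx])
  acc_s <- mean(classify_forest(forest_s, m_shuf[test_idx, ])$call ==
                  d$labels[test_idx])
  expect_gt(acc, acc_s)
  expect_gt(acc, 0.8)
})

test_that("usage tallies accumulate across repeated models", {
  d <- make_descriptor_data(seed = 31)
  forests <- lapply(1:4, function(s) {
    set.seed(s)
    idx <- sample(nrow(d$m), 100)
    train_forest(d$m[idx, ], d$labels[idx])
  })
  tal <- usage_tally(forests, descriptors = colnames(d$m))
  expect_length(tal, ncol(d$m))
  expect_true(all(tal <= 4 * 5))
  expect_equal(sum(tal), length(unlist(lapply(forests,
                                              `[[`, "descriptor_sets"))))
  unused <- names(tal)[tal == 0]
  for (f in forests) {
    expect_false(any(unused %in% unlist(f$descriptor_sets)))
  }
})

test_that("a forest short of five informative trees is flagged", {
  # two binary descriptors cannot feed five disjoint trees
  m <- cbind(a = rep(c(0, 1), each = 10), b = rep(c(0, 1), 10))
  labels <- rep(c("P", "W"), each = 10)
  forest <- train_forest(m, labels, min_leaf = 2)
  expect_false(forest$complete)
  expect_lt(length(forest$trees), 5)
})
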