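no_prune <- function(min_leaf = 1) fdt_params(min_leaf = min_leaf,
                                              prune_fraction = 0)

test_that("degenerate inputs behave as specified", {
  df <- data.frame(x = rnorm(10), label = "NORMAL",
                   stringsAsFactors = FALSE)
  tree <- learn_tree(df, no_prune())
  expect_equal(tree$root$type, "leaf")
  expect_equal(tree$root$label, "NORMAL")
  expect_equal(tree$root$support, 10)
  expect_error(learn_tree(df["label"], no_prune()), "no feature")
  expect_error(learn_tree(df[0, ], no_prune()), "at least one instance")
})

test_that("the root split matches exhaustive candidate search in 1-D", {
  df <- data.frame(x = c(1, 1.5, 3, 4),
                   label = c("A", "A", "B", "B"), stringsAsFactors = FALSE)
  tree <- learn_tree(df, no_prune())
  expect_equal(tree$root$type, "internal")
  expect_gt(tree$root$threshold, 1.5)
  expect_lt(tree$root$threshold, 3)
  expect_equal(tree$root$threshold, (1.5 + 3) / 2) # midpoint convention
  expect_equal(predict(tree, df), df$label)
  kids <- tree$root$children
  expect_true(all(vapply(kids, function(k) max(k$counts) == k$support,
                         logical(1))))
})

test_that("root information gain is optimal on small random tables", {
  for (seed in 1:20) {
    set.seed(100 + seed)
    n <- sample(6:12, 1)
    df <- data.frame(a = round(stats::runif(n, 0, 10), 1),
                     b = round(stats::runif(n, -5, 5), 1),
                     c = sample(0:3, n, replace = TRUE),
                     label = sample(c("X", "Y"), n, replace = TRUE),
                     stringsAsFactors = FALSE)
    tree <- learn_tree(df, no_prune())
    best <- oracle_best_gain(df)
    if (tree$root$type == "leaf") {
      expect_lt(best, 1e-9)
    } else {
      x <- df[[tree$root$attr]]
      thr <- tree$root$threshold
      l <- df$label[x < thr]; r <- df$label[x >= thr]
      got <- oracle_entropy(df$label) -
        (length(l) * oracle_entropy(l) + length(r) * oracle_entropy(r)) / n
      expect_equal(got, best, tolerance = 1e-10, info = paste("seed", seed))
    }
  }
})

test_that("trees are deterministic and recover planted rules exactly", {
  pl <- planted_emergency("EMERGENCY", list(c("Perf", "<", "0.5"),
                                            c("NBP_Sys", "<", "105")),
                          margin = 0.2)
  df <- generate_training_fixture(pl, n_per_class = 1000, seed = 11)
  t1 <- learn_tree(df, no_prune())
  t2 <- learn_tree(df, no_prune())
  expect_identical(tree_to_json(t1), tree_to_json(t2))
  expect_equal(sum(predict(t1, df) != df$label), 0) # zero training errors
})

test_that("prediction follows the documented routing conventions", {
  # unbalanced split: left leaf A (support 2), right leaf B (support 4)
  df <- data.frame(x = c(1, 2, 3, 4, 5, 6),
                   label = c("A", "A", "B", "B", "B", "B"),
                   stringsAsFactors = FALSE)
  tree <- learn_tree(df, no_prune())
  expect_equal(tree$root$attr, "x")
  # boundary value routes to the >= branch
  expect_equal(predict(tree, data.frame(x = tree$root$threshold)), "B")
  # missing value routes to the larger-support child
  expect_equal(predict(tree, data.frame(x = NA_real_)), "B")
  # support tie routes to the "<" child
  bal <- learn_tree(data.frame(x = c(1, 2, 3, 4),
                               label = c("A", "A", "B", "B"),
                               stringsAsFactors = FALSE), no_prune())
  expect_equal(predict(bal, data.frame(x = NA_real_)), "A")
})

test_that("predictions agree with an independent recursive tracer", {
  pl <- planted_emergency("E", list(c("Perf", "<", "0.5"),
                                    c("AWF", "<", "10.4")), margin = 0.2)
  df <- generate_training_fixture(pl, n_per_class = 150, noise_label_rate = 0.1,
                                  seed = 23)
  tree <- learn_tree(df, fdt_params(min_leaf = 2, prune_fraction = 0.25,
                                    seed = 3))
  set.seed(99)
  probe <- df[sample(nrow(df), 100), ]
  probe$Perf[sample(100, 10)] <- NA
  expect_equal(predict(tree, probe),
               vapply(seq_len(100), function(i)
                 oracle_trace(tree$root, as.list(probe[i, ])), character(1)))
})

test_that("reduced-error pruning collapses overfit subtrees and never hurts", {
  # six instances, one noise point at x = 2.5 forces an extra split
  grow <- data.frame(x = c(1, 2, 2.5, 3, 4, 5),
                     label = c("A", "A", "B", "A", "B", "B"),
                     stringsAsFactors = FALSE)
  tree <- learn_tree(grow, no_prune())
  expect_gt(vitalwatch:::tree_n_leaves(tree$root), 2)
  prune_set <- data.frame(x = c(1.5, 2.2, 3.5, 4.5),
                          label = c("A", "A", "B", "B"),
                          stringsAsFactors = FALSE)
  pruned <- prune_tree(tree, prune_set)
  expect_equal(vitalwatch:::tree_n_leaves(pruned$root), 2)
  expect_equal(predict(pruned, prune_set), prune_set$label)

  # a pure single leaf is untouched; an empty pruning set warns
  leaf <- learn_tree(data.frame(x = 1:5, label = "A",
                                stringsAsFactors = FALSE), no_prune())
  expect_identical(tree_to_json(prune_tree(leaf, prune_set)),
                   tree_to_json(leaf))
  expect_warning(prune_tree(tree, grow[0, ]), "empty pruning set")

  # pruning-set error never increases, across random trees and sets
  for (seed in 1:10) {
    pl <- planted_emergency("E", list(c("Perf", "<", "0.5")), margin = 0.2)
    df <- generate_training_fixture(pl, n_per_class = 60,
                                    noise_label_rate = 0.2, seed = seed)
    half <- seq_len(60)
    tr <- learn_tree(df[half, ], no_prune())
    ps <- df[-half, ]
    pr <- prune_tree(tr, ps)
    err <- function(tt) sum(predict(tt, ps) != ps$label)
    expect_lte(err(pr), err(tr), label = paste("seed", seed))
  }
})

test_that("path extraction simplifies, filters and sorts by support", {
  pl <- planted_emergency("EMERGENCY", list(c("Perf", "<", "0.5"),
                                            c("NBP_Sys", "<", "105")),
                          margin = 0.2)
  df <- generate_training_fixture(pl, n_per_class = 500, seed = 31)
  tree <- learn_tree(df, no_prune())
  paths <- extract_paths(tree, label_filter = "EMERGENCY")
  expect_gte(length(paths), 1)
  p <- paths[[1]]
  expect_equal(p$label, "EMERGENCY")
  expect_equal(p$purity, 1)
  # region inclusion: the emergency paths jointly cover every labelled
  # in-episode point and exclude every normal point
  satisfies <- function(row, cond) {
    all(vapply(seq_len(nrow(cond)), function(i) {
      v <- row[[cond$attribute[i]]]
      if (cond$op[i] == "<") v < as.numeric(cond$value[i]) else
        v >= as.numeric(cond$value[i])
    }, logical(1)))
  }
  covered <- vapply(seq_len(nrow(df)), function(i)
    any(vapply(paths, function(pp) satisfies(df[i, ], pp$conditions),
               logical(1))), logical(1))
  expect_true(all(covered[df$label == "EMERGENCY"]))
  expect_false(any(covered[df$label == "NORMAL"]))
  # support ordering and threshold filters
  all_paths <- extract_paths(tree)
  sup <- vapply(all_paths, `[[`, 0, "support")
  expect_true(all(diff(sup) <= 0))
  expect_length(extract_paths(tree, min_support = nrow(df) + 1), 0)

  # per-attribute simplification keeps the tightest bound
  conds <- list(list(attribute = "x", op = "<", value = 5),
                list(attribute = "x", op = "<", value = 3),
                list(attribute = "x", op = ">=", value = 1))
  simp <- vitalwatch:::simplify_conditions(conds)
  expect_equal(simp$value[simp$op == "<"], "3")
  expect_equal(simp$value[simp$op == ">="], "1")
})

test_that("tree JSON round trip is lossless", {
  pl <- planted_emergency("E", list(c("Perf", "<", "0.5")), margin = 0.2)
  df <- generate_training_fixture(pl, n_per_class = 100,
                                  noise_label_rate = 0.05, seed = 41)
  df$shape <- sample(c("round", "flat"), nrow(df), replace = TRUE)
  tree <- learn_tree(df, fdt_params(prune_fraction = 0.25, seed = 7))
  back <- tree_from_json(tree_to_json(tree))
  expect_identical(tree_to_json(back), tree_to_json(tree))
  expect_equal(predict(back, df), predict(tree, df))
})

test_that("threshold recovery lands inside the planted margin band over seeds", {
  pl <- planted_emergency("EMERGENCY", list(c("Perf", "<", "0.5")),
                          margin = 0.2)
  for (seed in 1:20) {
    df <- generate_training_fixture(pl, n_per_class = 500, seed = seed)
    tree <- learn_tree(df, no_prune())
    paths <- extract_paths(tree, label_filter = "EMERGENCY")
    thr <- as.numeric(paths[[1]]$conditions$value[
      paths[[1]]$conditions$attribute == "Perf"])
    expect_gt(thr, 0.3); expect_lt(thr, 0.7)
  }
})
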