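# Fast decision-tree learner: information-gain splits with candidate
# thresholds at midpoints between consecutive distinct sorted values,
# multiway splits on nominal attributes, and reduced-error pruning on a
# seeded held-out fraction. Deterministic given (data, params): equal-gain
# splits resolve to the lower attribute index, then the smaller threshold.

#' Learner parameters
#'
#' @param min_leaf minimum training instances per child of a split.
#' @param max_depth maximum tree depth (root = depth 0); `Inf` = unlimited.
#' @param prune_fraction fraction of instances held out (seeded) for
#'   reduced-error pruning; 0 disables pruning.
#' @param seed integer seed for the grow/prune split.
#' @return a `vw_fdt_params` list.
#' @export
fdt_params <- function(min_leaf = 2L, max_depth = Inf,
                       prune_fraction = 0.25, seed = 1L) {
  stopifnot(min_leaf >= 1, prune_fraction >= 0, prune_fraction < 1)
  structure(list(min_leaf = as.integer(min_leaf), max_depth = max_depth,
                 prune_fraction = prune_fraction, seed = as.integer(seed)),
            class = "vw_fdt_params")
}

entropy_counts <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(0)
  p <- counts[counts > 0] / n
  -sum(p * log2(p))
}

feature_columns <- function(instances, label_col = "label") {
  nm <- names(instances)
  nm[nm != label_col & !startsWith(nm, ".")]
}

#' Learn a decision tree
#'
#' @param instances labelled instance table: feature columns (numeric or
#'   character/factor), a `label` column, optional `.`-prefixed provenance
#'   columns (ignored).
#' @param params [fdt_params()].
#' @param label_col name of the label column.
#' @return a `vw_fdt` tree. With `min_leaf = 1`, `prune_fraction = 0` and
#'   unlimited depth, training error is 0 whenever greedy axis-aligned
#'   splitting can separate the classes.
#' @export
learn_tree <- function(instances, params = fdt_params(), label_col = "label") {
  feats <- feature_columns(instances, label_col)
  if (length(feats) == 0) vw_stop("no feature columns")
  if (nrow(instances) == 0) vw_stop("at least one instance required")
  labels <- as.character(instances[[label_col]])
  if (anyNA(labels)) vw_stop("labels must be non-missing")
  classes <- sort(unique(labels))
  kinds <- vapply(feats, function(f)
    if (is.numeric(instances[[f]])) "real" else "nominal", "")
  X <- instances[feats]
  for (f in feats[kinds == "nominal"]) X[[f]] <- as.character(X[[f]])

  n <- nrow(X)
  prune_idx <- integer()
  if (params$prune_fraction > 0) {
    k <- floor(n * params$prune_fraction)
    if (k >= 1 && n - k >= 1) {
      prune_idx <- with_seed(params$seed, sort(sample.int(n, k)))
    } else {
      vw_warn("too few instances to hold out a pruning set; growing on all")
    }
  }
  grow_idx <- setdiff(seq_len(n), prune_idx)
  root <- grow_node(X, labels, grow_idx, classes, kinds, params, depth = 0L)
  tree <- structure(list(root = root, params = params, classes = classes,
                         features = kinds, label_col = label_col),
                    class = "vw_fdt")
  if (length(prune_idx)) {
    tree <- prune_tree(tree, instances[prune_idx, , drop = FALSE])
  }
  tree
}

class_counts <- function(labels, idx, classes) {
  tab <- table(factor(labels[idx], levels = classes))
  stats::setNames(as.integer(tab), classes)
}

make_leaf <- function(counts) {
  support <- sum(counts)
  label <- names(counts)[which.max(counts)] # ties: first class in sort order
  list(type = "leaf", label = label, counts = counts, support = support)
}

grow_node <- function(X, labels, idx, classes, kinds, params, depth) {
  counts <- class_counts(labels, idx, classes)
  if (sum(counts > 0) <= 1 || length(idx) < 2 * params$min_leaf ||
      depth >= params$max_depth) {
    return(make_leaf(counts))
  }
  best <- find_best_split(X, labels, idx, classes, kinds, params$min_leaf)
  if (is.null(best)) return(make_leaf(counts))

  if (best$kind == "real") {
    x <- X[[best$attr]][idx]
    miss <- is.na(x)
    left_sel <- !miss & x < best$threshold
    right_sel <- !miss & x >= best$threshold
    # missing values route to the child with larger support (tie: left)
    if (any(miss)) {
      if (sum(left_sel) >= sum(right_sel)) left_sel <- left_sel | miss
      else right_sel <- right_sel | miss
    }
    node <- list(type = "internal", attr = best$attr, kind = "real",
                 threshold = best$threshold, counts = counts,
                 support = length(idx),
                 majority = names(counts)[which.max(counts)],
                 children = list(
                   left = grow_node(X, labels, idx[left_sel], classes, kinds,
                                    params, depth + 1L),
                   right = grow_node(X, labels, idx[right_sel], classes, kinds,
                                     params, depth + 1L)))
  } else {
    x <- X[[best$attr]][idx]
    miss <- is.na(x)
    vals <- best$values
    if (any(miss)) {
      sizes <- vapply(vals, function(v) sum(x == v, na.rm = TRUE), integer(1))
      x[miss] <- vals[which.max(sizes)]
    }
    kids <- lapply(vals, function(v)
      grow_node(X, labels, idx[x == v], classes, kinds, params, depth + 1L))
    names(kids) <- vals
    node <- list(type = "internal", attr = best$attr, kind = "nominal",
                 threshold = NA_real_, counts = counts, support = length(idx),
                 majority = names(counts)[which.max(counts)],
                 children = kids)
  }
  node
}

find_best_split <- function(X, labels, idx, classes, kinds, min_leaf) {
  parent_h <- entropy_counts(class_counts(labels, idx, classes))
  best <- NULL
  best_gain <- 1e-12
  y <- factor(labels[idx], levels = classes)
  for (f in names(kinds)) { # column order = tie-break order
    x <- X[[f]][idx]
    ok <- !is.na(x)
    if (sum(ok) < 2 * min_leaf) next
    if (kinds[[f]] == "real") {
      xs <- x[ok]; ys <- y[ok]
      ord <- order(xs)
      xs <- xs[ord]; ys <- ys[ord]
      m <- length(xs)
      cum <- vapply(levels(ys), function(cl) cumsum(ys == cl),
                    numeric(m))
      if (m == 1) cum <- matrix(cum, nrow = 1)
      total <- cum[m, ]
      boundaries <- which(xs[-m] < xs[-1]) # split between position i and i+1
      for (i in boundaries) {
        nl <- i; nr <- m - i
        if (nl < min_leaf || nr < min_leaf) next
        hl <- entropy_counts(cum[i, ])
        hr <- entropy_counts(total - cum[i, ])
        gain <- parent_h - (nl * hl + nr * hr) / m
        thr <- xs[i] + (xs[i + 1] - xs[i]) / 2
        # strict improvement only: candidates are visited in attribute
        # order then ascending threshold, so equal-gain ties resolve to
        # the lower attribute index, then the smaller threshold
        if (gain > best_gain + 1e-12) {
          best_gain <- gain
          best <- list(attr = f, kind = "real", threshold = thr)
        }
      }
    } else {
      vals <- sort(unique(x[ok]))
      if (length(vals) < 2) next
      sizes <- vapply(vals, function(v) sum(x == v, na.rm = TRUE), integer(1))
      if (any(sizes < min_leaf)) next
      h <- 0
      for (v in vals) {
        cc <- table(y[ok][x[ok] == v])
        h <- h + sum(cc) * entropy_counts(as.integer(cc))
      }
      gain <- parent_h - h / sum(ok)
      if (gain > best_gain + 1e-12) {
        best_gain <- gain
        best <- list(attr = f, kind = "nominal", values = vals)
      }
    }
  }
  best
}

# ---- prediction ------------------------------------------------------------

route_child <- function(node, value) {
  if (node$kind == "real") {
    if (is.na(value)) {
      ls <- node$children$left$support
      rs <- node$children$right$support
      return(if (ls >= rs) node$children$left else node$children$right)
    }
    # boundary value x == t routes to the ">=" branch
    if (value < node$threshold) node$children$left else node$children$right
  } else {
    if (!is.na(value) && value %in% names(node$children))
      return(node$children[[value]])
    sup <- vapply(node$children, `[[`, 0, "support")
    node$children[[which.max(sup)]]
  }
}

node_support <- function(node) node$support %||% sum(node$counts)

predict_one <- function(node, row) {
  while (node$type == "internal") {
    v <- row[[node$attr]]
    if (!is.null(v) && node$kind == "nominal") v <- as.character(v)
    node <- route_child(node, if (is.null(v)) NA else v)
  }
  node$label
}

#' Predict labels with a decision tree
#'
#' Missing attribute values route to the child with larger training
#' support (tie: the `<` child); a value exactly on a threshold routes to
#' the `>=` branch.
#'
#' @param object a `vw_fdt` tree.
#' @param newdata data.frame of instances.
#' @param ... unused.
#' @return character vector of predicted labels.
#' @export
predict.vw_fdt <- function(object, newdata, ...) {
  vapply(seq_len(nrow(newdata)), function(i)
    predict_one(object$root, as.list(newdata[i, , drop = FALSE])),
    character(1))
}

# ---- reduced-error pruning -------------------------------------------------

#' Reduced-error pruning
#'
#' Bottom-up: a subtree is replaced by its majority leaf whenever the
#' pruning-set error does not increase; nodes reached by no pruning
#' instance are left intact. The pruned tree's pruning-set error never
#' exceeds the unpruned tree's.
#'
#' @param tree a `vw_fdt`.
#' @param pruning_set data.frame with the tree's feature and label columns.
#' @return the pruned `vw_fdt`.
#' @export
prune_tree <- function(tree, pruning_set) {
  if (is.null(pruning_set) || nrow(pruning_set) == 0) {
    vw_warn("empty pruning set: tree returned unchanged")
    return(tree)
  }
  labels <- as.character(pruning_set[[tree$label_col]])
  rec <- function(node, idx) {
    if (node$type == "leaf" || length(idx) == 0) return(node)
    # split pruning rows among children with the prediction routing
    parts <- split_indices(node, pruning_set, idx)
    kids <- node$children
    for (k in names(kids)) kids[[k]] <- rec(kids[[k]], parts[[k]])
    node$children <- kids
    err_sub <- sum(vapply(idx, function(i)
      predict_one(node, as.list(pruning_set[i, , drop = FALSE])) != labels[i],
      logical(1)))
    err_leaf <- sum(labels[idx] != node$majority)
    if (err_leaf <= err_sub) {
      return(list(type = "leaf", label = node$majority, counts = node$counts,
                  support = node$support))
    }
    node
  }
  tree$root <- rec(tree$root, seq_len(nrow(pruning_set)))
  tree
}

split_indices <- function(node, data, idx) {
  x <- data[[node$attr]][idx]
  if (node$kind == "real") {
    miss <- is.na(x)
    left <- !miss & x < node$threshold
    right <- !miss & x >= node$threshold
    if (any(miss)) {
      if (node$children$left$support >= node$children$right$support)
        left <- left | miss
      else right <- right | miss
    }
    list(left = idx[left], right = idx[right])
  } else {
    x <- as.character(x)
    vals <- names(node$children)
    sup <- vapply(node$children, `[[`, 0, "support")
    fallback <- vals[which.max(sup)]
    x[is.na(x) | !(x %in% vals)] <- fallback
    stats::setNames(lapply(vals, function(v) idx[x == v]), vals)
  }
}

# ---- path extraction -------------------------------------------------------

#' Extract qualifying root-to-leaf paths
#'
#' One path per leaf whose label passes `label_filter`, whose support is at
#' least `min_support` and whose purity (majority count / support) is at
#' least `min_purity`. Conditions are simplified per attribute (tightest
#' bound kept per direction) and paths are sorted by support, descending.
#'
#' @param tree a `vw_fdt`.
#' @param label_filter labels to keep (`NULL` = all).
#' @param min_support minimum leaf support (count, >= 1).
#' @param min_purity minimum leaf purity in (0, 1].
#' @return list of `vw_tree_path` objects with fields `conditions`
#'   (data.frame `attribute`, `op`, `value`), `label`, `support`, `purity`.
#' @export
extract_paths <- function(tree, label_filter = NULL, min_support = 1,
                          min_purity = 0) {
  stopifnot(min_support >= 1, min_purity <= 1)
  paths <- list()
  walk <- function(node, conds) {
    if (node$type == "leaf") {
      if (node$support == 0) return()
      purity <- max(node$counts) / node$support
      if ((!is.null(label_filter) && !node$label %in% label_filter) ||
          node$support < min_support || purity < min_purity) return()
      cond <- simplify_conditions(conds)
      if (is.null(cond)) return() # infeasible (cannot arise from a tree)
      paths[[length(paths) + 1]] <<- structure(
        list(conditions = cond, label = node$label,
             support = node$support, purity = purity),
        class = "vw_tree_path")
      return()
    }
    if (node$kind == "real") {
      walk(node$children$left,
           c(conds, list(list(attribute = node$attr, op = "<",
                              value = node$threshold))))
      walk(node$children$right,
           c(conds, list(list(attribute = node$attr, op = ">=",
                              value = node$threshold))))
    } else {
      for (v in names(node$children)) {
        walk(node$children[[v]],
             c(conds, list(list(attribute = node$attr, op = "=", value = v))))
      }
    }
  }
  walk(tree$root, list())
  if (length(paths) > 1) {
    paths <- paths[order(vapply(paths, `[[`, 0, "support"),
                         decreasing = TRUE)]
  }
  paths
}

simplify_conditions <- function(conds) {
  if (length(conds) == 0) {
    return(data.frame(attribute = character(), op = character(),
                      value = character(), stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, lapply(conds, function(cc)
    data.frame(attribute = cc$attribute, op = cc$op,
               value = as.character(cc$value), stringsAsFactors = FALSE)))
  out <- list()
  for (a in unique(df$attribute)) {
    sub <- df[df$attribute == a, , drop = FALSE]
    eqs <- unique(sub$value[sub$op == "="])
    if (length(eqs) > 1) return(NULL)
    if (length(eqs) == 1) {
      out[[length(out) + 1]] <- data.frame(attribute = a, op = "=",
                                           value = eqs,
                                           stringsAsFactors = FALSE)
      next
    }
    lo <- suppressWarnings(max(as.numeric(sub$value[sub$op == ">="]), -Inf))
    hi <- suppressWarnings(min(as.numeric(sub$value[sub$op == "<"]), Inf))
    if (lo >= hi) return(NULL)
    if (is.finite(lo))
      out[[length(out) + 1]] <- data.frame(attribute = a, op = ">=",
                                           value = as.character(lo),
                                           stringsAsFactors = FALSE)
    if (is.finite(hi))
      out[[length(out) + 1]] <- data.frame(attribute = a, op = "<",
                                           value = as.character(hi),
                                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' @export
print.vw_tree_path <- function(x, ...) {
  conds <- apply(x$conditions, 1, function(r)
    paste(r[["attribute"]], r[["op"]], r[["value"]]))
  cat(sprintf("<path -> %s (support %d, purity %.3f)>\n  %s\n", x$label,
              x$support, x$purity, paste(conds, collapse = " and ")))
  invisible(x)
}

# ---- serialization ---------------------------------------------------------

node_to_list <- function(node) {
  if (node$type == "leaf") {
    list(type = "leaf", label = node$label,
         counts = as.list(node$counts), support = node$support)
  } else {
    list(type = "internal", attr = node$attr, kind = node$kind,
         threshold = node$threshold, counts = as.list(node$counts),
         support = node$support, majority = node$majority,
         children = lapply(node$children, node_to_list))
  }
}

node_from_list <- function(x) {
  counts <- stats::setNames(vapply(x$counts, as.integer, 0L), names(x$counts))
  if (x$type == "leaf") {
    list(type = "leaf", label = x$label, counts = counts,
         support = as.integer(x$support))
  } else {
    list(type = "internal", attr = x$attr, kind = x$kind,
         threshold = if (is.null(x$threshold)) NA_real_ else
           as.numeric(x$threshold),
         counts = counts, support = as.integer(x$support),
         majority = x$majority,
         children = lapply(x$children, node_from_list))
  }
}

#' Serialize a tree to / from JSON (lossless)
#'
#' @param tree a `vw_fdt`.
#' @param path optional output file.
#' @return `tree_to_json`: JSON text; `tree_from_json`: the tree.
#' @export
tree_to_json <- function(tree, path = NULL) {
  txt <- jsonlite::toJSON(list(
    root = node_to_list(tree$root),
    params = unclass(tree$params), classes = tree$classes,
    features = as.list(tree$features), label_col = tree$label_col),
    auto_unbox = TRUE, digits = NA, null = "null", na = "null", pretty = TRUE)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' @rdname tree_to_json
#' @param x JSON text or file path.
#' @export
tree_from_json <- function(x) {
  if (length(x) == 1 && !grepl("\n", x) && file.exists(x))
    x <- paste(readLines(x), collapse = "\n")
  p <- jsonlite::fromJSON(x, simplifyVector = FALSE)
  pp <- p$params
  structure(list(
    root = node_from_list(p$root),
    params = fdt_params(pp$min_leaf,
                        if (is.null(pp$max_depth)) Inf else pp$max_depth,
                        pp$prune_fraction, pp$seed),
    classes = as.character(unlist(p$classes)),
    features = stats::setNames(vapply(p$features, as.character, ""),
                               names(p$features)),
    label_col = p$label_col), class = "vw_fdt")
}

tree_text_lines <- function(node, indent = "") {
  leaf_txt <- function(nd) sprintf(": %s (%d/%d)", nd$label,
                                   max(nd$counts), nd$support)
  if (node$type == "leaf") return(paste0(indent, leaf_txt(node)))
  branches <- if (node$kind == "real") {
    list(list(txt = sprintf("%s < %s", node$attr, format(node$threshold)),
              child = node$children$left),
         list(txt = sprintf("%s >= %s", node$attr, format(node$threshold)),
              child = node$children$right))
  } else {
    lapply(names(node$children), function(v)
      list(txt = sprintf("%s = %s", node$attr, v),
           child = node$children[[v]]))
  }
  unlist(lapply(branches, function(b) {
    if (b$child$type == "leaf") {
      paste0(indent, b$txt, leaf_txt(b$child))
    } else {
      c(paste0(indent, b$txt), tree_text_lines(b$child, paste0(indent, "|   ")))
    }
  }))
}

#' @export
print.vw_fdt <- function(x, ...) {
  cat(sprintf("<fdt tree: %d leaves, depth %d>\n", tree_n_leaves(x$root),
              tree_depth(x$root)))
  cat(tree_text_lines(x$root), sep = "\n")
  invisible(x)
}

tree_n_leaves <- function(node) {
  if (node$type == "leaf") return(1L)
  sum(vapply(node$children, tree_n_leaves, integer(1)))
}

tree_depth <- function(node) {
  if (node$type == "leaf") return(0L)
  1L + max(vapply(node$children, tree_depth, integer(1)))
}

tree_n_nodes <- function(node) {
  if (node$type == "leaf") return(1L)
  1L + sum(vapply(node$children, tree_n_nodes, integer(1)))
}
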