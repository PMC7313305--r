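# Closing the loop: alarm history -> training set -> tree -> emergency
# paths -> (a) conjunctive alarm rules and (b) per-sign abnormal-range
# axioms, upserted into the knowledge base so the generic abnormal-range
# rule (gm_rule) fires on future data.

#' Convert a tree path into a learned alarm rule
#'
#' @param path a `vw_tree_path` from [extract_paths()] whose conditions are
#'   all numeric threshold conditions over catalog signs; nominal
#'   (equality) conditions are unsupported and rejected.
#' @param label alarm label; defaults to the path's leaf label.
#' @return a `vw_rule` with provenance `"learned"`.
#' @export
path_to_rule <- function(path, label = path$label) {
  cond <- path$conditions
  if (nrow(cond) == 0) vw_stop("path has no conditions")
  if (any(cond$op == "="))
    vw_stop("nominal-attribute conditions are unsupported for rule synthesis")
  emergency_rule_from_conditions(
    label,
    data.frame(sign_code = cond$attribute, op = cond$op,
               value = as.numeric(cond$value), stringsAsFactors = FALSE),
    provenance = "learned")
}

#' Derive abnormal-range axioms from a rule's threshold conditions
#'
#' Per comparison condition, one axiom named `<Sign>AN` whose region is the
#' half-line the operator denotes: `< c` gives `(-Inf, c)` (open at `c`,
#' matching the strict bound of learned conditions), `<= c` gives
#' `(-Inf, c]`, and symmetrically for `>` / `>=`. Equality conditions are
#' rejected.
#'
#' @param rule a `vw_rule` in emergency form (see
#'   [emergency_rule_from_conditions()]).
#' @param created_at creation instant recorded on new axioms.
#' @return list of [abnormal_range_axiom()] with provenance `"learned"`
#'   (two conditions on one sign yield two axioms with the same class name;
#'   [upsert_abnormal_range()] unions them).
#' @export
conditions_to_axioms <- function(rule, created_at = "2024-01-01T00:00:00Z") {
  cond <- decode_emergency_conditions(rule)
  if (is.null(cond))
    vw_stop("rule '%s' is not in emergency (threshold-condition) form",
            rule$rule_id)
  lapply(seq_len(nrow(cond)), function(i) {
    op <- cond$op[i]; c0 <- cond$value[i]
    if (op == "=") vw_stop("equality conditions cannot form a range axiom")
    region <- switch(op,
      "<"  = interval_set(-Inf, c0, upper_closed = FALSE),
      "<=" = interval_set(-Inf, c0, upper_closed = TRUE),
      ">"  = interval_set(c0, Inf, lower_closed = FALSE),
      ">=" = interval_set(c0, Inf, lower_closed = TRUE))
    abnormal_range_axiom(axiom_class_name(cond$sign_code[i]),
                         cond$sign_code[i], region, provenance = "learned",
                         created_at = created_at)
  })
}

#' Learning-loop parameters
#'
#' @param window co-occurrence / feature look-back window, seconds.
#' @param neg_ratio negatives per positive in the training set.
#' @param neg_exclusion post-alert exclusion for negative sampling, seconds.
#' @param min_support minimum leaf support for an accepted path.
#' @param min_purity minimum leaf purity for an accepted path.
#' @param learner [fdt_params()] for the tree.
#' @param seed master seed (drives negative sampling and the grow/prune
#'   split).
#' @return a `vw_learn_params` list.
#' @export
learn_params <- function(window = 60, neg_ratio = 1, neg_exclusion = 300,
                         min_support = 30, min_purity = 0.95,
                         learner = fdt_params(), seed = 1L) {
  learner$seed <- as.integer(seed)
  structure(list(window = window, neg_ratio = neg_ratio,
                 neg_exclusion = neg_exclusion, min_support = min_support,
                 min_purity = min_purity, learner = learner,
                 seed = as.integer(seed)),
            class = "vw_learn_params")
}

#' Mine alarm history and update the knowledge base
#'
#' Runs the full closed loop: [build_training_set()] on the KB's alert log,
#' [learn_tree()] (with reduced-error pruning), [extract_paths()] over
#' non-`NORMAL` leaves, then [path_to_rule()] and [conditions_to_axioms()]
#' for each accepted path, upserting the learned rules and axioms through
#' the knowledge base's public operations. After the update, an observation
#' whose value lies in any newly learned region derives `AbnormalVitalSign`
#' through [gm_rule()] in [apply_all()]. Deterministic given `kb` and the
#' seed in `params`.
#'
#' @param kb knowledge base with alert history.
#' @param params [learn_params()].
#' @param dry_run when `TRUE`, compute the report but leave the KB
#'   untouched.
#' @return list with `kb` (updated) and `report` (a `vw_learning_report`).
#' @export
learn_and_update <- function(kb, params = learn_params(), dry_run = FALSE) {
  run_at <- Sys.time()
  report <- structure(list(
    run_at = format_instant(run_at), params = params,
    instance_counts = integer(), tree_size = NA_integer_,
    tree_depth = NA_integer_, accepted_paths = list(),
    rejected_paths = list(), rule_ids = character(),
    axiom_classes = character(), dry_run = dry_run),
    class = "vw_learning_report")

  instances <- build_training_set(kb, window = params$window,
                                  neg_ratio = params$neg_ratio,
                                  neg_exclusion = params$neg_exclusion,
                                  seed = params$seed)
  report$instance_counts <- if (nrow(instances))
    vapply(split(seq_len(nrow(instances)), instances$label), length, 0L)
  else integer()
  n_pos <- sum(instances$label != "NORMAL")
  if (n_pos == 0) {
    if (!dry_run) kb <- kb_bump(kb, "learning run: no positive instances")
    return(list(kb = kb, report = report))
  }

  tree <- learn_tree(instances, params$learner)
  report$tree_size <- tree_n_nodes(tree$root)
  report$tree_depth <- tree_depth(tree$root)

  alarm_labels <- setdiff(unique(instances$label), "NORMAL")
  all_paths <- extract_paths(tree, label_filter = alarm_labels,
                             min_support = 1, min_purity = 0)
  new_axioms <- list()
  for (p in all_paths) {
    reason <- NULL
    if (p$support < params$min_support) {
      reason <- sprintf("support %d < %d", p$support, params$min_support)
    } else if (p$purity < params$min_purity) {
      reason <- sprintf("purity %.3f < %.3f", p$purity, params$min_purity)
    } else if (any(p$conditions$op == "=")) {
      reason <- "nominal conditions unsupported"
    } else if (nrow(p$conditions) == 0) {
      reason <- "empty condition set"
    }
    if (!is.null(reason)) {
      report$rejected_paths[[length(report$rejected_paths) + 1]] <-
        list(path = p, reason = reason)
      next
    }
    rule <- path_to_rule(p)
    axs <- conditions_to_axioms(rule, created_at = run_at)
    report$accepted_paths[[length(report$accepted_paths) + 1]] <- p
    report$rule_ids <- c(report$rule_ids, rule$rule_id)
    report$axiom_classes <- union(report$axiom_classes,
                                  vapply(axs, `[[`, "", "class_name"))
    if (!dry_run) {
      kb <- kb_upsert_rule(kb, rule)
      for (ax in axs) kb <- upsert_abnormal_range(kb, ax)
    }
  }
  list(kb = kb, report = report)
}

#' @export
print.vw_learning_report <- function(x, ...) {
  cat(sprintf("<learning report %s%s>\n", x$run_at,
              if (isTRUE(x$dry_run)) " (dry run)" else ""))
  cat("  instances:",
      if (length(x$instance_counts))
        paste(names(x$instance_counts), x$instance_counts, sep = "=",
              collapse = ", ")
      else "none", "\n")
  if (!is.na(x$tree_size))
    cat(sprintf("  tree: %d nodes, depth %d\n", x$tree_size, x$tree_depth))
  cat(sprintf("  accepted paths: %d  rejected: %d\n",
              length(x$accepted_paths), length(x$rejected_paths)))
  for (p in x$accepted_paths) print(p)
  for (rp in x$rejected_paths)
    cat(sprintf("  rejected (%s): -> %s, support %d\n", rp$reason,
                rp$path$label, rp$path$support))
  if (length(x$rule_ids)) cat("  new rules:", paste(x$rule_ids, collapse = "; "),
                              "\n")
  if (length(x$axiom_classes))
    cat("  axioms touched:", paste(x$axiom_classes, collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a learning report to JSON
#' @param report a `vw_learning_report`.
#' @param path optional output file.
#' @return JSON text.
#' @export
report_to_json <- function(report, path = NULL) {
  x <- unclass(report)
  x$params <- lapply(unclass(x$params), function(v)
    if (inherits(v, "vw_fdt_params")) unclass(v) else v)
  x$accepted_paths <- lapply(x$accepted_paths, unclass)
  x$rejected_paths <- lapply(x$rejected_paths, function(rp)
    list(reason = rp$reason, path = unclass(rp$path)))
  x$instance_counts <- as.list(x$instance_counts)
  txt <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null",
                          na = "null", pretty = TRUE, force = TRUE)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}
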