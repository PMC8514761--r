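# Fitting a gate tree to a sample, assigning events, and evaluating against
# ground truth.

clause_pass <- function(values, clause) {
  v <- clause$value
  switch(clause$op,
         ">" = values > v,
         ">=" = values >= v,
         "<" = values < v,
         "<=" = values <= v,
         between = values >= v[1] & values < v[2])
}

#' Fit a gating tree's thresholds on a sample
#'
#' Thresholds are placed per node scope: each clause is fitted on the values
#' of the events that pass all ancestor gates, mirroring how a manual gater
#' draws each gate inside its parent. Sibling nodes that cut the same marker
#' with the same method therefore receive identical thresholds, which makes
#' complementary sibling gates (cTEC/mTEC) exactly disjoint.
#'
#' @param tree A `GatingTree`.
#' @param table A transformed `EventTable`.
#' @return A fitted `GatingTree` (every clause carries a numeric threshold).
#' @export
fit_gating_tree <- function(tree, table) {
  stopifnot(inherits(tree, "GatingTree"), inherits(table, "EventTable"))
  if (table$scale_state != "transformed") {
    stop("state error: gating requires an asinh-transformed table", call. = FALSE)
  }
  ev <- table$events
  mk <- colnames(ev)
  member <- list(root = rep(TRUE, nrow(ev)))
  cache <- new.env(parent = emptyenv())
  for (nm in names(tree$nodes)) {   # nodes are stored parents-first
    nd <- tree$nodes[[nm]]
    scope <- member[[nd$parent]]
    for (i in seq_along(nd$clauses)) {
      clz <- nd$clauses[[i]]
      if (!clz$marker %in% mk) {
        stop(sprintf("fitting error at node '%s': marker '%s' absent from table",
                     nm, clz$marker), call. = FALSE)
      }
      if (is.null(clz$value)) {
        meths <- clz$method
        vals <- ev[scope, clz$marker]
        fitted <- vapply(meths, function(m) {
          key <- paste(nd$parent, clz$marker, m, sep = "\r")
          if (!is.null(cache[[key]])) return(cache[[key]])
          if (!grepl("^fixed", m) && length(vals) < 1L) {
            stop(sprintf("fitting error at node '%s': no events in scope", nm),
                 call. = FALSE)
          }
          th <- tryCatch(fit_cut(vals, m), error = function(e) {
            stop(sprintf("fitting error at node '%s' (%s %s): %s",
                         nm, clz$marker, m, conditionMessage(e)), call. = FALSE)
          })
          cache[[key]] <- th
          th
        }, numeric(1))
        if (clz$op == "between" && fitted[1] >= fitted[2]) {
          stop(sprintf("fitting error at node '%s': between bounds not increasing on %s",
                       nm, clz$marker), call. = FALSE)
        }
        nd$clauses[[i]]$value <- unname(fitted)
        tree$nodes[[nm]] <- nd
      }
    }
    pass <- lapply(nd$clauses, function(clz) clause_pass(ev[, clz$marker], clz))
    agg <- if (nd$combine == "or") Reduce(`|`, pass) else Reduce(`&`, pass)
    member[[nm]] <- scope & agg
  }
  tree$fitted <- TRUE
  tree
}

node_membership <- function(table, tree) {
  ev <- table$events
  member <- list(root = rep(TRUE, nrow(ev)))
  for (nm in names(tree$nodes)) {
    nd <- tree$nodes[[nm]]
    pass <- lapply(nd$clauses, function(clz) clause_pass(ev[, clz$marker], clz))
    agg <- if (nd$combine == "or") Reduce(`|`, pass) else Reduce(`&`, pass)
    member[[nm]] <- member[[nd$parent]] & agg
  }
  member
}

node_path <- function(tree, nm) {
  path <- nm
  while (tree$nodes[[nm]]$parent != "root") {
    nm <- tree$nodes[[nm]]$parent
    path <- c(nm, path)
  }
  paste(c("root", path), collapse = "/")
}

#' Apply a gating tree to a sample
#'
#' Assigns each event to the deepest gate whose full ancestor chain it
#' satisfies (`"ungated"` if it satisfies none) and tabulates per-population
#' counts and frequencies. If the tree is unfitted its thresholds are first
#' fitted on this table.
#'
#' @param table A transformed `EventTable`.
#' @param tree A `GatingTree`.
#' @return List with `assignment` (data.frame: event, population, path),
#'   `stats` (data.frame: population, parent, count, freq_of_parent,
#'   freq_of_total; attribute `empty` flags a zero-event table, attribute
#'   `n_ungated` counts unassigned events) and `tree` (the fitted tree).
#' @export
apply_gating <- function(table, tree) {
  stopifnot(inherits(table, "EventTable"), inherits(tree, "GatingTree"))
  if (table$scale_state != "transformed") {
    stop("state error: gating requires an asinh-transformed table", call. = FALSE)
  }
  if (!tree$fitted) tree <- fit_gating_tree(tree, table)
  n <- nrow(table$events)
  member <- node_membership(table, tree)
  nms <- names(tree$nodes)
  assigned <- rep("ungated", n)
  depth_cur <- rep(0L, n)
  for (nm in nms) {   # parents-first; later (deeper) nodes overwrite
    d <- tree$depth[nm]
    hit <- member[[nm]] & d > depth_cur
    assigned[hit] <- nm
    depth_cur[hit] <- d
  }
  paths <- vapply(nms, function(nm) node_path(tree, nm), character(1))
  paths <- c(paths, ungated = "root")
  assignment <- data.frame(event = seq_len(n), population = assigned,
                           path = unname(paths[assigned]),
                           stringsAsFactors = FALSE)
  counts <- vapply(nms, function(nm) sum(member[[nm]]), numeric(1))
  parent_counts <- vapply(nms, function(nm) {
    p <- tree$nodes[[nm]]$parent
    if (p == "root") n else sum(member[[p]])
  }, numeric(1))
  stats <- data.frame(
    population = nms,
    parent = vapply(tree$nodes, `[[`, character(1), "parent"),
    count = as.integer(counts),
    freq_of_parent = ifelse(parent_counts > 0, counts / parent_counts, 0),
    freq_of_total = if (n > 0) counts / n else rep(0, length(counts)),
    row.names = NULL, stringsAsFactors = FALSE)
  attr(stats, "empty") <- n == 0L
  attr(stats, "n_ungated") <- sum(assigned == "ungated")
  attr(stats, "n_total") <- n
  list(assignment = assignment, stats = stats, tree = tree)
}

#' Default mapping from simulator truth labels to gate nodes
#'
#' Immature thymocytes stop at the `thymocyte` gate, single-positive subsets
#' at `CD4SP`/`CD8SP`; B cells carry no dedicated gate and stop at the
#' hematopoietic gate; the unmodeled remainder is expected ungated.
#'
#' @return Named character vector truth label -> expected node.
#' @export
default_truth_map <- function() {
  c(cTEC = "cTEC", mTEC = "mTEC", FB = "FB", EC = "EC", LEC = "LEC",
    DC = "DC", MP = "MP",
    thymocyte_immature = "thymocyte",
    thymocyte_CD4SP = "CD4SP", thymocyte_CD8SP = "CD8SP",
    B = "hematopoietic", other = "ungated")
}

#' Evaluate a gate assignment against ground truth
#'
#' Computes per-population confusion counts, precision, recall and F1.
#' Predicted membership of a truth class is "assigned exactly the mapped
#' node" (the deepest-gate assignment), so an immature thymocyte gated down
#' to `matureSP` counts as an error.
#'
#' @param assignment Assignment data.frame from [apply_gating()].
#' @param truth_labels Character vector of per-event truth labels.
#' @param map Named vector truth label -> expected node name
#'   (default [default_truth_map()] completed with identity for unknown
#'   labels).
#' @return Data.frame with one row per truth class: tp/fp/fn counts,
#'   precision, recall, F1 (NA where undefined, e.g. recall of a class
#'   absent from the truth).
#' @export
evaluate_gating <- function(assignment, truth_labels, map = NULL) {
  pred <- assignment$population
  if (length(pred) != length(truth_labels)) {
    stop("alignment error: assignment and truth labels differ in length",
         call. = FALSE)
  }
  if (is.null(map)) map <- default_truth_map()
  classes <- union(names(map), unique(truth_labels))
  full_map <- stats::setNames(ifelse(classes %in% names(map),
                                     unname(map[classes]), classes), classes)
  rows <- lapply(classes, function(cls) {
    node <- full_map[[cls]]
    tp <- sum(pred == node & truth_labels == cls)
    fp <- sum(pred == node & truth_labels != cls)
    fn <- sum(pred != node & truth_labels == cls)
    n_truth <- sum(truth_labels == cls)
    precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    recall <- if (n_truth > 0) tp / n_truth else NA_real_
    f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_
    if (n_truth == 0) f1 <- NA_real_
    data.frame(truth_class = cls, node = node, tp = tp, fp = fp, fn = fn,
               n_truth = n_truth, precision = precision, recall = recall,
               f1 = f1, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
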