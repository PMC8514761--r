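# Gate-tree construction and automatic threshold placement.
#
# The published gating is manual; here thresholds are placed automatically on
# the asinh scale from kernel-density estimates of each node's parent scope.
# Three placement flavours cover the scheme's needs:
#   valley     - KDE minimum between the two largest density modes (bimodal
#                markers such as CD45, CD31, CD200);
#   valley_pos - KDE minimum between the two lowest-lying modes, i.e. the
#                negative/positive boundary of a multimodal marker;
#   valley_hi  - positivity cut first, then the valley separating the lowest
#                positive mode from the dominant brighter mode (the upper of
#                the "up to two thresholds" of tri-level markers like pdpn).

find_density_modes <- function(values, min_rel_height = 0.01) {
  d <- stats::density(values, n = 512)
  y <- d$y
  ix <- which(diff(sign(diff(y))) == -2) + 1L
  ix <- ix[y[ix] >= min_rel_height * max(y)]
  list(d = d, x = d$x[ix], y = y[ix])
}

valley_between <- function(d, x1, x2) {
  lo <- min(x1, x2); hi <- max(x1, x2)
  sel <- which(d$x > lo & d$x < hi)
  d$x[sel[which.min(d$y[sel])]]
}

#' Place a gating threshold on a 1-D intensity distribution
#'
#' @param values Numeric vector of (transformed) intensities.
#' @param method `"valley"` (KDE minimum between the two largest density
#'   modes; requires >= 50 values), `"quantile"` (empirical quantile `q`) or
#'   `"fixed"` (returns `v` unchanged).
#' @param q Quantile for `method = "quantile"`.
#' @param v Value for `method = "fixed"`.
#' @return The threshold (a single number). Valley placement on effectively
#'   unimodal data falls back to the 0.99 quantile with a warning.
#' @export
place_threshold <- function(values, method = c("valley", "quantile", "fixed"),
                            q = 0.5, v = NULL) {
  method <- match.arg(method)
  if (method == "fixed") {
    if (is.null(v)) stop("fixed placement needs a value v", call. = FALSE)
    return(as.numeric(v))
  }
  if (length(values) < 1L) stop("empty input", call. = FALSE)
  if (method == "quantile") {
    return(unname(stats::quantile(values, q, names = FALSE)))
  }
  if (length(values) < 50L) {
    stop("valley placement requires at least 50 values", call. = FALSE)
  }
  m <- find_density_modes(values)
  if (length(m$x) < 2L) {
    warning("no interior density minimum between two modes; falling back to quantile(0.99)",
            call. = FALSE)
    return(unname(stats::quantile(values, 0.99, names = FALSE)))
  }
  top2 <- order(m$y, decreasing = TRUE)[1:2]
  valley_between(m$d, m$x[top2[1]], m$x[top2[2]])
}

# negative/positive boundary: valley between the two modes lowest in x
cut_valley_pos <- function(values) {
  if (length(values) < 50L) {
    stop("valley placement requires at least 50 values", call. = FALSE)
  }
  m <- find_density_modes(values)
  if (length(m$x) < 2L) {
    warning("unimodal distribution; falling back to quantile(0.99)",
            call. = FALSE)
    return(unname(stats::quantile(values, 0.99, names = FALSE)))
  }
  ord <- order(m$x)
  valley_between(m$d, m$x[ord[1]], m$x[ord[2]])
}

# upper cut of a tri-level marker: among positives, valley between the
# dimmest mode and the largest of the brighter modes
cut_valley_hi <- function(values) {
  t1 <- cut_valley_pos(values)
  pos <- values[values > t1]
  if (length(pos) < 50L) {
    warning("too few positive events for an upper cut; falling back to quantile(0.99)",
            call. = FALSE)
    return(unname(stats::quantile(values, 0.99, names = FALSE)))
  }
  m <- find_density_modes(pos)
  if (length(m$x) < 2L) {
    warning("positive fraction unimodal; falling back to quantile(0.99) of positives",
            call. = FALSE)
    return(unname(stats::quantile(pos, 0.99, names = FALSE)))
  }
  ord <- order(m$x)
  rest <- ord[-1]
  big <- rest[which.max(m$y[rest])]
  valley_between(m$d, m$x[ord[1]], m$x[big])
}

fit_cut <- function(values, method) {
  if (grepl("^fixed\\(", method)) {
    return(as.numeric(sub("^fixed\\(([^)]+)\\)$", "\\1", method)))
  }
  if (grepl("^quantile\\(", method)) {
    q <- as.numeric(sub("^quantile\\(([^)]+)\\)$", "\\1", method))
    return(place_threshold(values, "quantile", q = q))
  }
  switch(method,
         valley = place_threshold(values, "valley"),
         valley_pos = cut_valley_pos(values),
         valley_hi = cut_valley_hi(values),
         stop(sprintf("unknown threshold method '%s'", method), call. = FALSE))
}

#' Gate clause
#'
#' One axis-aligned condition of a gate predicate.
#'
#' @param marker Marker name.
#' @param op One of `">"`, `">="`, `"<"`, `"<="`, `"between"`.
#' @param method Threshold method: `"valley"`, `"valley_pos"`, `"valley_hi"`,
#'   `"quantile(q)"` or `"fixed(v)"`. For `"between"` supply two methods
#'   `c(lo, hi)`.
#' @param value Optional pre-fitted numeric threshold(s).
#' @return A `GateClause` list.
#' @export
gate_clause <- function(marker, op = c(">=", ">", "<", "<=", "between"),
                        method = "valley", value = NULL) {
  op <- match.arg(op)
  if (op == "between" && length(method) != 2L && is.null(value)) {
    stop("a between clause needs two methods or two values", call. = FALSE)
  }
  structure(list(marker = marker, op = op, method = method,
                 value = if (is.null(value)) NULL else as.numeric(value)),
            class = "GateClause")
}

#' Gate node
#'
#' @param name Node (population) name.
#' @param parent Parent node name, or `"root"`.
#' @param clauses List of [gate_clause()]s.
#' @param combine `"and"` (all clauses must hold) or `"or"` (any clause).
#' @return A `GateNode`.
#' @export
gate_node <- function(name, parent, clauses, combine = c("and", "or")) {
  combine <- match.arg(combine)
  structure(list(name = name, parent = parent, clauses = clauses,
                 combine = combine), class = "GateNode")
}

#' Gating tree
#'
#' A rooted tree of [gate_node()]s. Validates that every non-root parent
#' exists, that there are no cycles and that node names are unique.
#'
#' @param nodes List of `GateNode`s.
#' @return A `GatingTree` (unfitted).
#' @export
gating_tree <- function(nodes) {
  nm <- vapply(nodes, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("gate node names must be unique", call. = FALSE)
  names(nodes) <- nm
  for (nd in nodes) {
    if (nd$parent != "root" && !nd$parent %in% nm) {
      stop(sprintf("unknown parent '%s' for node '%s'", nd$parent, nd$name),
           call. = FALSE)
    }
  }
  # depth computation doubles as the cycle check
  depth <- stats::setNames(rep(NA_integer_, length(nm)), nm)
  for (n in nm) {
    d <- 0L; cur <- n
    while (nodes[[cur]]$parent != "root") {
      cur <- nodes[[cur]]$parent
      d <- d + 1L
      if (d > length(nm)) stop("cycle detected in gating tree", call. = FALSE)
    }
    depth[n] <- d + 1L
  }
  structure(list(nodes = nodes[order(depth[nm])], depth = sort(depth),
                 fitted = FALSE), class = "GatingTree")
}

#' @export
print.GatingTree <- function(x, ...) {
  cat(sprintf("GatingTree: %d nodes [%s]\n", length(x$nodes),
              if (x$fitted) "fitted" else "unfitted"))
  for (nd in x$nodes) {
    cat(sprintf("  %s%s <- %s\n", strrep("  ", x$depth[nd$name] - 1L),
                nd$name, nd$parent))
  }
  invisible(x)
}

scheme_markers <- c("CD45", "EpCAM", "pdpn", "CD49f", "CD200", "CD31",
                    "HLA-DR", "CD11c", "CD11b", "CD3", "CD1a", "CD4", "CD8")

#' Build the thymic stromal gating tree
#'
#' Encodes the published hierarchy: TECs are gated pdpn-high/int with all
#' EpCAM levels admitted (EpCAM alone misses low-EpCAM TECs) and CD31+
#' lymphatic endothelium excluded upstream; cTEC = CD49f+CD200-,
#' mTEC = CD49f-low CD200+ (double-positive events match the LEC phenotype
#' and are assigned to neither subset). Accessory gates: vascular EC
#' (CD45-CD31+pdpn-), LEC (CD45-CD31+pdpn+CD49f-hi CD200-hi), fibroblasts
#' (CD45-EpCAM-HLA-DR-pdpn-int), DC (CD45+HLA-DR+CD11c+CD11b+), macrophages
#' (CD45+HLA-DR+CD11c-CD11b+), thymocytes (CD3+ and/or CD1a+), mature
#' single-positives (CD3-high CD1a-int/low) split into CD4SP/CD8SP. CD45 is
#' deliberately absent from the TEC path (it is dispensable there) but
#' retained for the accessory gates.
#'
#' @param panel A `PanelConfig` resolving all scheme markers.
#' @param overrides Optional named list `node -> marker -> threshold(s)`
#'   replacing automatic placement with fixed cuts (two values for a
#'   `between` clause).
#' @return An unfitted `GatingTree`.
#' @export
build_thymic_gating_tree <- function(panel = default_thymic_panel(),
                                     overrides = NULL) {
  have <- resolve_markers(panel$required_markers, panel)
  miss <- setdiff(scheme_markers, have)
  if (length(miss)) {
    stop(sprintf("build error: panel lacks marker(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  cl <- gate_clause
  nodes <- list(
    gate_node("hematopoietic", "root", list(cl("CD45", ">="))),
    gate_node("DC", "hematopoietic",
              list(cl("HLA-DR", ">="), cl("CD11c", ">="), cl("CD11b", ">="))),
    gate_node("MP", "hematopoietic",
              list(cl("HLA-DR", ">="), cl("CD11c", "<"), cl("CD11b", ">="))),
    gate_node("thymocyte", "hematopoietic",
              list(cl("CD3", ">=", "valley_pos"), cl("CD1a", ">=", "valley_pos")),
              combine = "or"),
    gate_node("matureSP", "thymocyte",
              list(cl("CD3", ">="), cl("CD1a", "<"))),
    gate_node("CD4SP", "matureSP", list(cl("CD4", ">="), cl("CD8", "<"))),
    gate_node("CD8SP", "matureSP", list(cl("CD8", ">="), cl("CD4", "<"))),
    gate_node("TEC", "root",
              list(cl("pdpn", ">=", "valley_hi"), cl("CD31", "<"))),
    gate_node("cTEC", "TEC", list(cl("CD49f", ">="), cl("CD200", "<"))),
    gate_node("mTEC", "TEC", list(cl("CD49f", "<"), cl("CD200", ">="))),
    gate_node("EC", "root",
              list(cl("CD45", "<"), cl("CD31", ">="),
                   cl("pdpn", "<", "valley_pos"))),
    gate_node("LEC", "root",
              list(cl("CD45", "<"), cl("CD31", ">="),
                   cl("pdpn", ">=", "valley_pos"),
                   cl("CD49f", ">=", "valley_hi"), cl("CD200", ">="))),
    gate_node("FB", "root",
              list(cl("CD45", "<"), cl("EpCAM", "<", "valley_pos"),
                   cl("HLA-DR", "<", "valley_pos"),
                   cl("pdpn", "between", c("valley_pos", "valley_hi"))))
  )
  tree <- gating_tree(nodes)
  if (!is.null(overrides)) tree <- apply_overrides(tree, overrides)
  tree
}

apply_overrides <- function(tree, overrides) {
  for (node in names(overrides)) {
    if (!node %in% names(tree$nodes)) {
      stop(sprintf("config error: override names unknown node '%s'", node),
           call. = FALSE)
    }
    for (mk in names(overrides[[node]])) {
      hit <- FALSE
      for (i in seq_along(tree$nodes[[node]]$clauses)) {
        if (tree$nodes[[node]]$clauses[[i]]$marker == mk) {
          v <- as.numeric(overrides[[node]][[mk]])
          tree$nodes[[node]]$clauses[[i]]$value <- v
          tree$nodes[[node]]$clauses[[i]]$method <-
            if (length(v) == 2L) sprintf("fixed(%g)", v) else sprintf("fixed(%g)", v[1])
          hit <- TRUE
        }
      }
      if (!hit) {
        stop(sprintf("config error: node '%s' has no clause on marker '%s'",
                     node, mk), call. = FALSE)
      }
    }
  }
  tree
}

#' Serialize a gating tree to YAML
#'
#' @param tree A `GatingTree`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gating_tree <- function(tree, path) {
  nodes <- lapply(unname(tree$nodes), function(nd) {
    list(name = nd$name, parent = nd$parent, combine = nd$combine,
         clauses = lapply(nd$clauses, function(cl) {
           out <- list(marker = cl$marker, op = cl$op,
                       method = as.list(cl$method))
           if (!is.null(cl$value)) out$value <- as.list(cl$value)
           out
         }))
  })
  yaml::write_yaml(list(fitted = tree$fitted, nodes = nodes), path)
  invisible(path)
}

#' Read a gating tree from YAML
#'
#' @param path YAML file written by [write_gating_tree()] (or hand-edited in
#'   the same structure).
#' @return A `GatingTree`.
#' @export
read_gating_tree <- function(path) {
  y <- yaml::read_yaml(path)
  nodes <- lapply(y$nodes, function(nd) {
    gate_node(nd$name, nd$parent,
              lapply(nd$clauses, function(cl) {
                gate_clause(cl$marker, cl$op,
                            method = unlist(cl$method),
                            value = if (is.null(cl$value)) NULL
                                    else unlist(cl$value))
              }),
              combine = nd$combine %||% "and")
  })
  tree <- gating_tree(nodes)
  tree$fitted <- isTRUE(y$fitted)
  tree
}
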