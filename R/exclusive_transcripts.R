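# Population-exclusive transcript analysis on a normalized FPKM matrix:
# expression calling, exclusivity, housekeeping exclusion and
# tissue-specificity categorization. Differential expression and FPKM
# computation are upstream of this module.

#' Expression matrix with population labels
#'
#' @param values Numeric genes x samples matrix of FPKM (non-negative, no
#'   missing values), with gene rownames and sample colnames.
#' @param sample_population Named character vector sample -> population;
#'   every sample must be mapped and every population needs >= 2 samples.
#' @return An `ExpressionMatrix`.
#' @export
expression_matrix <- function(values, sample_population) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("values needs gene rownames and sample colnames", call. = FALSE)
  }
  if (anyNA(values)) stop("FPKM matrix must not contain missing values",
                          call. = FALSE)
  if (any(values < 0)) stop("FPKM values must be non-negative", call. = FALSE)
  miss <- setdiff(colnames(values), names(sample_population))
  if (length(miss)) {
    stop(sprintf("unmapped sample(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  sample_population <- sample_population[colnames(values)]
  tab <- table(sample_population)
  if (any(tab < 2)) {
    stop(sprintf("population(s) with fewer than 2 samples: %s",
                 paste(names(tab)[tab < 2], collapse = ", ")), call. = FALSE)
  }
  structure(list(values = values, sample_population = sample_population),
            class = "ExpressionMatrix")
}

#' Expression-calling filter specification
#'
#' A gene counts as expressed in a population when strictly more than
#' `threshold` FPKM is observed in at least `min_samples` of that
#' population's samples. Defaults follow the published rule: > 0.5 FPKM in at
#' least 3 of 6 samples for cTEC and mTEC, 2 of 4 for FB and EC. The strict
#' comparison can be relaxed to `>=` for sensitivity analysis.
#'
#' @param threshold FPKM threshold (default 0.5).
#' @param min_samples Named integer vector population -> minimum number of
#'   above-threshold samples.
#' @param strict Use strict `>` (default TRUE) or `>=`.
#' @return An `ExpressionFilterSpec`.
#' @export
expression_filter_spec <- function(threshold = 0.5,
                                   min_samples = c(cTEC = 3L, mTEC = 3L,
                                                   FB = 2L, EC = 2L),
                                   strict = TRUE) {
  stopifnot(threshold >= 0, all(min_samples >= 1))
  structure(list(threshold = threshold, min_samples = min_samples,
                 strict = strict), class = "ExpressionFilterSpec")
}

#' Call gene expression per population
#'
#' @param matrix An `ExpressionMatrix`.
#' @param spec An `ExpressionFilterSpec` covering every population in the
#'   matrix.
#' @return Logical genes x populations matrix (`ExpressedMask`).
#' @export
expressed_mask <- function(matrix, spec = expression_filter_spec()) {
  stopifnot(inherits(matrix, "ExpressionMatrix"),
            inherits(spec, "ExpressionFilterSpec"))
  pops <- unique(unname(matrix$sample_population))
  miss <- setdiff(pops, names(spec$min_samples))
  if (length(miss)) {
    stop(sprintf("config error: no min_samples for population(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  above <- if (spec$strict) matrix$values > spec$threshold
           else matrix$values >= spec$threshold
  mask <- vapply(pops, function(p) {
    cols <- matrix$sample_population == p
    if (spec$min_samples[[p]] > sum(cols)) {
      stop(sprintf("config error: min_samples[%s] exceeds its %d samples",
                   p, sum(cols)), call. = FALSE)
    }
    rowSums(above[, cols, drop = FALSE]) >= spec$min_samples[[p]]
  }, logical(nrow(matrix$values)))
  mask <- matrix(mask, nrow = nrow(matrix$values),
                 dimnames = list(rownames(matrix$values), pops))
  class(mask) <- c("ExpressedMask", class(mask))
  mask
}

#' Population-exclusive genes
#'
#' A gene is exclusive to a population when it is called expressed there and
#' in no other population; genes expressed nowhere or in two or more
#' populations are exclusive nowhere.
#'
#' @param mask An `ExpressedMask` from [expressed_mask()].
#' @return List with `exclusive` (named list population -> gene ids),
#'   `counts` (named integer vector), `n_shared` (genes expressed in >= 2
#'   populations) and `n_silent` (genes expressed nowhere).
#' @export
exclusive_genes <- function(mask) {
  npop <- rowSums(mask)
  excl <- lapply(colnames(mask), function(p) {
    rownames(mask)[mask[, p] & npop == 1L]
  })
  names(excl) <- colnames(mask)
  list(exclusive = excl,
       counts = vapply(excl, length, integer(1)),
       n_shared = sum(npop >= 2L),
       n_silent = sum(npop == 0L))
}

#' Exclude housekeeping genes
#'
#' Case-sensitive exact-id set difference against a housekeeping list (as
#' curated, e.g., in a protein-atlas-style table supplied by the user).
#'
#' @param genes Character vector of gene ids.
#' @param housekeeping Character vector of housekeeping gene ids.
#' @return List with `kept` and `removed`.
#' @export
exclude_housekeeping <- function(genes, housekeeping) {
  removed <- genes[genes %in% housekeeping]
  list(kept = setdiff(genes, housekeeping), removed = removed)
}

#' Assign tissue-specificity categories
#'
#' Maps genes to the category (and, within the "tissue enriched" category,
#' the tissue) given by a user-supplied annotation table; genes absent from
#' the annotation are counted as unassigned, mirroring how a fraction of
#' exclusive transcripts cannot be matched to any category.
#'
#' @param genes Character vector of gene ids.
#' @param annotation Data.frame with columns `gene`, `category` and
#'   optionally `tissue`.
#' @return List with `category_counts` (named integer vector including
#'   `unassigned`), `tissue_counts` (within "tissue enriched"), `assignments`
#'   (data.frame gene/category/tissue) and `unassigned` (gene ids).
#' @export
assign_tissue_categories <- function(genes, annotation) {
  stopifnot(all(c("gene", "category") %in% names(annotation)))
  idx <- match(genes, annotation$gene)
  category <- ifelse(is.na(idx), "unassigned", annotation$category[idx])
  tissue <- if ("tissue" %in% names(annotation)) {
    ifelse(is.na(idx), NA_character_, annotation$tissue[idx])
  } else rep(NA_character_, length(genes))
  assignments <- data.frame(gene = genes, category = category, tissue = tissue,
                            stringsAsFactors = FALSE)
  cat_counts <- table(factor(category))
  te <- assignments[assignments$category == "tissue enriched" &
                      !is.na(assignments$tissue), ]
  list(category_counts = c(stats::setNames(as.integer(cat_counts),
                                           names(cat_counts))),
       tissue_counts = if (nrow(te)) {
         tc <- table(te$tissue)
         stats::setNames(as.integer(tc), names(tc))
       } else stats::setNames(integer(0), character(0)),
       assignments = assignments,
       unassigned = genes[is.na(idx)])
}

#' Full exclusive-transcript report
#'
#' Runs the published order of operations: expression calling -> exclusivity
#' -> housekeeping exclusion -> (optional) tissue categorization. The
#' housekeeping step can instead be applied before exclusivity via
#' `housekeeping_first = TRUE` (the published order is ambiguous).
#'
#' @param matrix An `ExpressionMatrix`.
#' @param spec An `ExpressionFilterSpec`.
#' @param housekeeping Character vector of housekeeping gene ids.
#' @param annotation Optional tissue annotation data.frame (see
#'   [assign_tissue_categories()]).
#' @param housekeeping_first Drop housekeeping genes before the exclusivity
#'   step instead of after.
#' @return An `ExclusiveReport` list: `exclusive`, `counts`,
#'   `housekeeping_excluded`, and per-population `categories` when an
#'   annotation is given.
#' @export
exclusive_report <- function(matrix, spec = expression_filter_spec(),
                             housekeeping = character(),
                             annotation = NULL,
                             housekeeping_first = FALSE) {
  mask <- expressed_mask(matrix, spec)
  if (housekeeping_first && length(housekeeping)) {
    mask <- mask[!rownames(mask) %in% housekeeping, , drop = FALSE]
  }
  ex <- exclusive_genes(mask)
  removed <- character(0)
  if (!housekeeping_first && length(housekeeping)) {
    for (p in names(ex$exclusive)) {
      hk <- exclude_housekeeping(ex$exclusive[[p]], housekeeping)
      ex$exclusive[[p]] <- hk$kept
      removed <- c(removed, hk$removed)
    }
    ex$counts <- vapply(ex$exclusive, length, integer(1))
  }
  out <- list(exclusive = ex$exclusive, counts = ex$counts,
              n_shared = ex$n_shared, n_silent = ex$n_silent,
              housekeeping_excluded = removed)
  if (!is.null(annotation)) {
    out$categories <- lapply(ex$exclusive, assign_tissue_categories,
                             annotation = annotation)
  }
  class(out) <- "ExclusiveReport"
  out
}

#' Read an FPKM matrix and sample->population map from TSV
#'
#' @param matrix_path TSV with genes in rows (first column = gene id) and
#'   samples in columns.
#' @param groups_path Two-column TSV (sample, population), with header.
#' @return An `ExpressionMatrix`.
#' @export
read_expression_matrix <- function(matrix_path, groups_path) {
  df <- utils::read.delim(matrix_path, check.names = FALSE)
  genes <- df[[1]]
  vals <- as.matrix(df[-1])
  rownames(vals) <- genes
  gr <- utils::read.delim(groups_path, check.names = FALSE)
  expression_matrix(vals, stats::setNames(as.character(gr[[2]]),
                                          as.character(gr[[1]])))
}
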