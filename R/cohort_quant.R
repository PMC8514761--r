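# Cohort-level quantitation: per-donor summaries, group comparisons,
# correlations, and qPCR 2^-ddCt relative quantification.

DAYS_PER_MONTH <- 30.44

#' Age group from age in days
#'
#' Bins follow the cohort's 0-3 / 3-6 / 6-12 month groups with
#' month = 30.44 days; older donors fall into `"other"`.
#'
#' @param age_days Non-negative integer vector.
#' @return Character vector of age groups.
#' @export
age_group_from_days <- function(age_days) {
  m <- age_days / DAYS_PER_MONTH
  ifelse(m < 3, "0-3m", ifelse(m < 6, "3-6m", ifelse(m <= 12, "6-12m", "other")))
}

#' Population statistics from per-population counts
#'
#' Convenience constructor used when counts come from a source other than
#' [apply_gating()] (e.g. the cohort simulator). Derives the composite TEC
#' (cTEC + mTEC) and matureSP (CD4SP + CD8SP) nodes when absent.
#'
#' @param counts Named vector of per-population event counts.
#' @param total Total acquired events (default `sum(counts)`).
#' @return A data.frame compatible with [summarize_donor()].
#' @export
population_stats_from_counts <- function(counts, total = sum(counts)) {
  counts <- stats::setNames(as.numeric(counts), names(counts))
  alias <- c(thymocyte_CD4SP = "CD4SP", thymocyte_CD8SP = "CD8SP")
  hit <- names(counts) %in% names(alias)
  names(counts)[hit] <- alias[names(counts)[hit]]
  if (!"TEC" %in% names(counts) && all(c("cTEC", "mTEC") %in% names(counts))) {
    counts["TEC"] <- counts["cTEC"] + counts["mTEC"]
  }
  if (!"matureSP" %in% names(counts) &&
      all(c("CD4SP", "CD8SP") %in% names(counts))) {
    counts["matureSP"] <- counts["CD4SP"] + counts["CD8SP"]
  }
  data.frame(population = names(counts), count = unname(counts),
             freq_of_total = if (total > 0) unname(counts) / total else 0,
             stringsAsFactors = FALSE)
}

REQUIRED_COHORT_NODES <- c("TEC", "cTEC", "mTEC", "matureSP", "CD4SP", "CD8SP")

#' Summarize one donor into a cohort-table row
#'
#' Frequencies are expressed as percent of total live single events; the
#' cTEC/mTEC and mature CD4SP/CD8SP ratios are derived. A zero mTEC (or
#' CD8SP) count leaves the corresponding ratio undefined (NA, flagged via
#' `ratio_defined`) while the row is retained for frequency analyses.
#'
#' @param stats A `PopulationStats` data.frame (from [apply_gating()] or
#'   [population_stats_from_counts()]) containing the TEC, cTEC, mTEC,
#'   matureSP, CD4SP and CD8SP nodes.
#' @param metadata List or one-row data.frame with `donor_id`, `age_days`,
#'   and optionally `sex`.
#' @param total Total event count; defaults to the `n_total` attribute of
#'   `stats` or, failing that, `sum` of top-level counts is required
#'   explicitly.
#' @return A one-row data.frame (cohort-table row).
#' @export
summarize_donor <- function(stats, metadata, total = NULL) {
  miss <- setdiff(REQUIRED_COHORT_NODES, stats$population)
  if (length(miss)) {
    stop(sprintf("missing required node(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  if (is.null(total)) {
    total <- attr(stats, "n_total")
    if (is.null(total)) {
      if (!"freq_of_total" %in% names(stats)) {
        stop("total event count required", call. = FALSE)
      }
      total <- NA_real_
    }
  }
  cnt <- function(p) stats$count[match(p, stats$population)]
  pct <- function(p) {
    if ("freq_of_total" %in% names(stats)) {
      100 * stats$freq_of_total[match(p, stats$population)]
    } else 100 * cnt(p) / total
  }
  ctec_mtec <- if (cnt("mTEC") > 0) cnt("cTEC") / cnt("mTEC") else NA_real_
  cd4_cd8 <- if (cnt("CD8SP") > 0) cnt("CD4SP") / cnt("CD8SP") else NA_real_
  if (is.na(ctec_mtec)) {
    message(sprintf("donor %s: zero mTEC count, cTEC/mTEC ratio undefined",
                    metadata$donor_id))
  }
  extra <- intersect(c("FB", "EC", "LEC", "DC", "MP"), stats$population)
  row <- data.frame(donor_id = metadata$donor_id,
                    age_days = metadata$age_days,
                    age_group = age_group_from_days(metadata$age_days),
                    sex = if (!is.null(metadata$sex)) metadata$sex else NA_character_,
                    n_total = total,
                    tec_pct = pct("TEC"), ctec_pct = pct("cTEC"),
                    mtec_pct = pct("mTEC"),
                    cd4sp_pct = pct("CD4SP"), cd8sp_pct = pct("CD8SP"),
                    ctec_mtec_ratio = ctec_mtec,
                    cd4sp_cd8sp_ratio = cd4_cd8,
                    ratio_defined = !is.na(ctec_mtec),
                    stringsAsFactors = FALSE)
  for (p in extra) row[[paste0(tolower(p), "_pct")]] <- pct(p)
  row
}

#' Summarize a whole simulated cohort
#'
#' Applies [summarize_donor()] to every row of a counts matrix (donors in
#' rows, populations in columns) with aligned metadata.
#'
#' @param counts Donors x populations count matrix (e.g.
#'   `simulate_cohort()$counts`).
#' @param metadata Data.frame with `donor_id`, `age_days`, `sex` per donor.
#' @return A cohort data.frame, one row per donor.
#' @export
summarize_cohort <- function(counts, metadata) {
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    summarize_donor(population_stats_from_counts(counts[i, ]),
                    metadata[i, , drop = FALSE], total = sum(counts[i, ]))
  })
  do.call(rbind, rows)
}

#' Linear correlation between two cohort metrics
#'
#' Ordinary least-squares fit of y on x; `r_squared` equals the squared
#' Pearson correlation and the two-sided p-value comes from the regression
#' F statistic.
#'
#' @param x,y Numeric vectors (n >= 3 complete pairs; neither constant).
#' @return A `CorrelationResult` list: slope, intercept, r_squared, p_value, n.
#' @export
correlate <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("correlation requires at least 3 complete pairs",
                          call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant input: correlation undefined", call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  f <- sm$fstatistic
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = sm$r.squared,
                 p_value = unname(stats::pf(f[1], f[2], f[3],
                                            lower.tail = FALSE)),
                 n = length(x)),
            class = "CorrelationResult")
}

#' Two-group comparison of a cohort metric
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test: exact when both groups
#' have at most 8 observations and there are no ties, otherwise the normal
#' approximation with tie correction. The effect size is the difference of
#' group medians (first group minus second, groups in sorted label order).
#' Rows with an undefined metric are dropped with a message.
#'
#' @param cohort Cohort data.frame (e.g. from [summarize_cohort()]).
#' @param metric Name of the metric column.
#' @param grouping Name of the grouping column (exactly 2 groups after
#'   dropping undefined rows).
#' @param test Only `"mann_whitney"` is available.
#' @return A `GroupComparison` list: groups, n, statistic (U), p_value,
#'   effect, exact.
#' @export
compare_groups <- function(cohort, metric, grouping, test = "mann_whitney") {
  test <- match.arg(test, "mann_whitney")
  vals <- cohort[[metric]]
  grp <- as.character(cohort[[grouping]])
  drop <- !is.finite(vals) | is.na(grp)
  if (any(drop)) {
    message(sprintf("dropping %d row(s) with undefined %s", sum(drop), metric))
    vals <- vals[!drop]; grp <- grp[!drop]
  }
  groups <- sort(unique(grp))
  if (length(groups) != 2L) {
    stop(sprintf("exactly 2 groups required, found %d", length(groups)),
         call. = FALSE)
  }
  x <- vals[grp == groups[1]]
  y <- vals[grp == groups[2]]
  if (length(x) < 2 || length(y) < 2) {
    stop("each group needs at least 2 observations", call. = FALSE)
  }
  exact <- length(x) <= 8 && length(y) <= 8 && !anyDuplicated(c(x, y))
  wt <- stats::wilcox.test(x, y, exact = exact, correct = !exact)
  structure(list(groups = groups, n = c(length(x), length(y)),
                 statistic = unname(wt$statistic), p_value = wt$p.value,
                 effect = stats::median(x) - stats::median(y),
                 exact = exact),
            class = "GroupComparison")
}

#' qPCR relative quantification (2^-ddCt)
#'
#' For each target gene and sample, dCt is the target Ct minus the
#' arithmetic mean Ct of the reference genes in that sample; ddCt subtracts
#' the calibrator sample's dCt; fold change is `2^(-ddCt)`. The calibrator's
#' fold is exactly 1 by construction.
#'
#' @param ct Data.frame with columns `gene`, `sample`, `ct` (one Ct per
#'   gene/sample pair).
#' @param targets Target gene names.
#' @param references Reference gene names (e.g. GAPDH, HPRT-1, RPLP13); each
#'   must be measured in every sample.
#' @param calibrator Sample id used as calibrator.
#' @return A `DdctResult` data.frame: gene, sample, dct, ddct, fold.
#' @export
ddct_fold_change <- function(ct, targets, references, calibrator) {
  stopifnot(all(c("gene", "sample", "ct") %in% names(ct)))
  samples <- unique(ct$sample)
  if (!calibrator %in% samples) {
    stop(sprintf("calibrator sample '%s' not present", calibrator), call. = FALSE)
  }
  get_ct <- function(g, s) {
    v <- ct$ct[ct$gene == g & ct$sample == s]
    if (length(v) != 1L) {
      stop(sprintf("missing or duplicated Ct for gene '%s' in sample '%s'",
                   g, s), call. = FALSE)
    }
    v
  }
  ref_mean <- vapply(samples, function(s) {
    mean(vapply(references, get_ct, numeric(1), s = s))
  }, numeric(1))
  names(ref_mean) <- samples
  rows <- expand.grid(gene = targets, sample = samples,
                      stringsAsFactors = FALSE)
  rows$dct <- mapply(function(g, s) get_ct(g, s) - ref_mean[[s]],
                     rows$gene, rows$sample)
  cal <- stats::setNames(rows$dct[rows$sample == calibrator],
                         rows$gene[rows$sample == calibrator])
  rows$ddct <- rows$dct - cal[rows$gene]
  rows$fold <- 2^(-rows$ddct)
  class(rows) <- c("DdctResult", "data.frame")
  rows
}
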