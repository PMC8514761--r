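# Surface-marker screen analytics: per-population MFI, two-population
# MFI-ratio ranking, top-N candidate selection with an absolute-MFI floor,
# and inter-donor reproducibility (CV) scoring.

#' Screen plate
#'
#' One antibody-screen plate: one well per marker, with the MFI of each
#' reference population measured in every well.
#'
#' @param mfi Numeric matrix, markers in rows (rownames = marker names),
#'   reference populations in columns.
#' @param donor_id Donor identifier.
#' @return A `ScreenPlate`.
#' @export
screen_plate <- function(mfi, donor_id = "donor") {
  mfi <- as.matrix(mfi)
  if (is.null(rownames(mfi)) || is.null(colnames(mfi))) {
    stop("mfi matrix needs marker rownames and population colnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(mfi))) {
    stop("marker names must be unique within a plate", call. = FALSE)
  }
  if (any(mfi < 0)) stop("MFIs must be non-negative", call. = FALSE)
  structure(list(donor_id = donor_id, mfi = mfi,
                 n_markers = nrow(mfi)), class = "ScreenPlate")
}

#' Population MFI from an event table
#'
#' The screen's summary statistic: mean (default), median or geometric mean
#' of a marker's raw-scale intensities over a selected event subset. MFIs are
#' computed on the raw instrument scale, matching how screen ratios are
#' reported.
#'
#' @param table A raw-scale `EventTable`.
#' @param member_mask Logical vector selecting at least one event.
#' @param marker Marker name.
#' @param statistic `"mean"`, `"median"` or `"geomean"`.
#' @return A single non-negative number.
#' @export
population_mfi <- function(table, member_mask, marker,
                           statistic = c("mean", "median", "geomean")) {
  statistic <- match.arg(statistic)
  stopifnot(inherits(table, "EventTable"))
  if (table$scale_state != "raw") {
    stop("state error: MFI is computed on the raw scale", call. = FALSE)
  }
  if (!marker %in% colnames(table$events)) {
    stop(sprintf("unknown marker '%s'", marker), call. = FALSE)
  }
  x <- table$events[member_mask, marker]
  if (length(x) == 0) stop("empty selection: no events in mask", call. = FALSE)
  switch(statistic,
         mean = mean(x),
         median = stats::median(x),
         geomean = exp(mean(log(pmax(x, .Machine$double.eps)))))
}

#' Rank screen markers by MFI ratio between two populations
#'
#' For every marker, ratio = MFI(pop_a) / MFI(pop_b); rows are sorted by
#' ratio descending with ties broken alphabetically by marker. A zero
#' denominator with a positive numerator yields an infinite ratio sorted
#' above all finite ones (flagged); markers with zero MFI in both populations
#' are excluded from the ranking (listed in the `excluded` attribute).
#'
#' @param plate A `ScreenPlate`.
#' @param pop_a,pop_b Reference population names (columns of the plate).
#' @return A `ScreenRanking` data.frame (marker, mfi_a, mfi_b, ratio,
#'   infinite, rank) with attributes `pop_a`, `pop_b`, `excluded`.
#' @export
rank_markers <- function(plate, pop_a, pop_b) {
  stopifnot(inherits(plate, "ScreenPlate"))
  for (p in c(pop_a, pop_b)) {
    if (!p %in% colnames(plate$mfi)) {
      stop(sprintf("data error: population '%s' absent from plate '%s'",
                   p, plate$donor_id), call. = FALSE)
    }
  }
  a <- plate$mfi[, pop_a]
  b <- plate$mfi[, pop_b]
  both_zero <- a == 0 & b == 0
  if (any(both_zero)) {
    message(sprintf("excluding %d marker(s) with zero MFI in both populations",
                    sum(both_zero)))
  }
  mk <- rownames(plate$mfi)[!both_zero]
  a <- a[!both_zero]; b <- b[!both_zero]
  ratio <- ifelse(b == 0, Inf, a / b)
  ord <- order(-ratio, mk)
  out <- data.frame(marker = mk[ord], mfi_a = unname(a[ord]),
                    mfi_b = unname(b[ord]), ratio = unname(ratio[ord]),
                    infinite = !is.finite(ratio[ord]),
                    rank = seq_along(ord), stringsAsFactors = FALSE)
  attr(out, "pop_a") <- pop_a
  attr(out, "pop_b") <- pop_b
  attr(out, "excluded") <- rownames(plate$mfi)[both_zero]
  class(out) <- c("ScreenRanking", "data.frame")
  out
}

#' Select candidate markers from a screen ranking
#'
#' Takes the top and bottom `top_n` markers by MFI ratio, then drops those
#' whose brighter-population MFI falls below an absolute floor (dim markers
#' are less practical for cytometry regardless of their ratio). The floor has
#' no published default and must be chosen by the analyst; `0` disables it.
#'
#' @param ranking A `ScreenRanking`.
#' @param top_n Number of markers taken from each end (default 30).
#' @param mfi_floor Minimum `max(mfi_a, mfi_b)` to retain a candidate.
#' @return A `CandidateSet` list: `high_end`, `low_end` (character vectors),
#'   `mfi_floor`, `excluded_by_floor` (data.frame marker/end/max_mfi).
#' @export
select_candidates <- function(ranking, top_n = 30L, mfi_floor = 0) {
  stopifnot(inherits(ranking, "ScreenRanking"), top_n >= 1)
  n <- nrow(ranking)
  if (top_n > n) {
    warning(sprintf("top_n = %d exceeds the %d ranked markers; clamped", top_n, n),
            call. = FALSE)
    top_n <- n
  }
  hi <- ranking[seq_len(top_n), ]
  lo <- ranking[seq(n, n - top_n + 1L), ]
  lo <- lo[!lo$marker %in% hi$marker, ]   # overlap possible when 2*top_n > n
  keep <- function(df) pmax(df$mfi_a, df$mfi_b) >= mfi_floor
  khi <- keep(hi); klo <- keep(lo)
  excl <- rbind(
    if (any(!khi)) data.frame(marker = hi$marker[!khi], end = "high",
                              max_mfi = pmax(hi$mfi_a, hi$mfi_b)[!khi]),
    if (any(!klo)) data.frame(marker = lo$marker[!klo], end = "low",
                              max_mfi = pmax(lo$mfi_a, lo$mfi_b)[!klo]))
  structure(list(high_end = hi$marker[khi], low_end = lo$marker[klo],
                 mfi_floor = mfi_floor,
                 excluded_by_floor = if (is.null(excl))
                   data.frame(marker = character(), end = character(),
                              max_mfi = numeric()) else excl),
            class = "CandidateSet")
}

#' Inter-donor reproducibility of candidate markers
#'
#' Coefficient of variation (sample sd / mean) of a population's MFI across
#' donors, per marker; the most reproducible markers rank first.
#'
#' @param plates List of at least two `ScreenPlate`s (one per donor).
#' @param markers Markers to score (must be present on every plate).
#' @param population Reference population whose MFI is compared.
#' @return A `ReproReport` data.frame (marker, mean_mfi, sd_mfi, cv,
#'   n_donors), sorted by CV ascending; CV is NA where the mean is 0.
#' @export
reproducibility_score <- function(plates, markers, population) {
  if (length(plates) < 2L) {
    stop("reproducibility requires plates from at least 2 donors", call. = FALSE)
  }
  vals <- vapply(plates, function(pl) {
    stopifnot(inherits(pl, "ScreenPlate"))
    miss <- setdiff(markers, rownames(pl$mfi))
    if (length(miss)) {
      stop(sprintf("data error: marker(s) %s missing from plate '%s'",
                   paste(miss, collapse = ", "), pl$donor_id), call. = FALSE)
    }
    if (!population %in% colnames(pl$mfi)) {
      stop(sprintf("data error: population '%s' absent from plate '%s'",
                   population, pl$donor_id), call. = FALSE)
    }
    pl$mfi[markers, population]
  }, numeric(length(markers)))
  vals <- matrix(vals, nrow = length(markers))
  m <- rowMeans(vals)
  s <- apply(vals, 1, stats::sd)
  cv <- ifelse(m > 0, s / m, NA_real_)
  out <- data.frame(marker = markers, mean_mfi = m, sd_mfi = s, cv = cv,
                    n_donors = length(plates), stringsAsFactors = FALSE)
  out <- out[order(out$cv), ]
  rownames(out) <- NULL
  class(out) <- c("ReproReport", "data.frame")
  out
}
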