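# Synthetic cytometry samples with known per-event ground truth.
#
# Intensities are log-normal per marker per population on the raw instrument
# scale; a population's "neg/low/int/high" phenotype levels are encoded as
# well-separated log-normal medians (>= 3 sd apart in asinh space for every
# decision boundary used by the default gating tree).

# run code under a fixed seed, restoring the caller's RNG state afterwards
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

#' Default population phenotype table
#'
#' Raw-scale log-normal medians for each of the 12 modeled thymic
#' populations across the 13-marker panel. Encodes the published marker
#' phenotypes: TECs are pdpn-high/int with cTEC CD49f+CD200- and mTEC
#' CD49f-low CD200+; vascular EC are CD31+pdpn-; lymphatic EC co-express high
#' CD49f, CD200, CD31 and pdpn; fibroblasts are CD45-EpCAM-HLA-DR-pdpn-int;
#' DC/MP are CD45+HLA-DR+ split on CD11c; thymocytes are CD3+ and/or CD1a+
#' with mature single-positives CD3-high CD1a-low. The table is read from a
#' plain-text file so alternative phenotypes can be supplied.
#'
#' @param path TSV file (population in first column, one column per marker);
#'   defaults to the table shipped with the package.
#' @return A data.frame of raw-scale medians, rownames = population names.
#' @export
thymic_phenotypes <- function(path = system.file("extdata",
                                                 "thymic_phenotypes.tsv",
                                                 package = "thymoflow")) {
  df <- utils::read.delim(path, check.names = FALSE)
  rownames(df) <- df[[1]]
  df[[1]] <- NULL
  df
}

#' Population intensity model
#'
#' @param name Population name.
#' @param frequency Mixture weight in `[0, 1]`.
#' @param medians Named numeric vector of raw-scale log-normal medians, one
#'   per marker.
#' @param sigma Log-scale standard deviation (shared across markers, or a
#'   named vector per marker).
#' @param truncate_sigma Truncate log-normal draws at this many standard
#'   deviations from the mean (Inf = no truncation). Useful to construct
#'   samples with strictly zero between-population overlap.
#' @return A `PopulationModel`.
#' @export
population_model <- function(name, frequency, medians, sigma = 0.35,
                             truncate_sigma = Inf) {
  stopifnot(is.numeric(frequency), frequency >= 0, frequency <= 1,
            all(sigma > 0), all(medians > 0))
  if (is.null(names(medians))) stop("medians must be named by marker",
                                    call. = FALSE)
  sig <- if (length(sigma) == 1L)
    stats::setNames(rep(sigma, length(medians)), names(medians))
  else sigma[names(medians)]
  structure(list(name = name, frequency = frequency,
                 mu = log(medians), sigma = sig,
                 truncate_sigma = truncate_sigma),
            class = "PopulationModel")
}

#' Default thymic population models
#'
#' Twelve populations with the phenotypes of [thymic_phenotypes()] and a
#' study-composition mixture in which every population is well represented
#' (thymocytes dominate, stromal subsets at a few percent). For realistic
#' rare-TEC compositions pass the cohort baselines instead.
#'
#' @param frequencies Optional named frequency vector (must sum to 1); the
#'   names select which phenotype rows are used.
#' @param sigma Log-scale sd per marker level (default 0.35).
#' @param truncate_sigma Passed to [population_model()].
#' @return List of `PopulationModel`s.
#' @export
default_population_models <- function(frequencies = NULL, sigma = 0.35,
                                      truncate_sigma = Inf) {
  ph <- thymic_phenotypes()
  if (is.null(frequencies)) {
    frequencies <- c(thymocyte_immature = 0.62, thymocyte_CD4SP = 0.06,
                     thymocyte_CD8SP = 0.03, B = 0.02, DC = 0.03, MP = 0.03,
                     cTEC = 0.04, mTEC = 0.06, FB = 0.04, EC = 0.04,
                     LEC = 0.01, other = 0.02)
  }
  miss <- setdiff(names(frequencies), rownames(ph))
  if (length(miss)) stop(sprintf("no phenotype for population(s): %s",
                                 paste(miss, collapse = ", ")), call. = FALSE)
  lapply(names(frequencies), function(p) {
    population_model(p, frequencies[[p]],
                     stats::setNames(as.numeric(ph[p, ]), colnames(ph)),
                     sigma = sigma, truncate_sigma = truncate_sigma)
  })
}

#' Sample specification
#'
#' @param populations List of `PopulationModel`s; frequencies must sum to 1
#'   (within 1e-9) and names must be unique.
#' @param n_events Number of events to draw.
#' @param seed RNG seed (identical seed gives bit-identical output).
#' @return A `SampleSpec`.
#' @export
sample_spec <- function(populations, n_events, seed = 1L) {
  nm <- vapply(populations, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("population names must be unique", call. = FALSE)
  fr <- vapply(populations, `[[`, numeric(1), "frequency")
  if (abs(sum(fr) - 1) > 1e-9) {
    stop(sprintf("population frequencies must sum to 1 (got %.12f)", sum(fr)),
         call. = FALSE)
  }
  if (n_events < 0) stop("n_events must be non-negative", call. = FALSE)
  mk <- lapply(populations, function(p) names(p$mu))
  if (length(unique(vapply(mk, paste, character(1), collapse = "|"))) != 1L) {
    stop("config error: all populations must parameterize the same markers",
         call. = FALSE)
  }
  structure(list(populations = populations, n_events = as.integer(n_events),
                 seed = seed), class = "SampleSpec")
}

#' Simulate a cytometry sample with ground-truth labels
#'
#' Each event's population is drawn from the mixture frequencies; its
#' intensities are drawn i.i.d. log-normal per marker from that population's
#' model. Output is deterministic given the spec's seed.
#'
#' @param spec A `SampleSpec`.
#' @return List with `table` (raw-scale `EventTable`) and `labels`
#'   (character vector of per-event population names).
#' @export
simulate_sample <- function(spec) {
  stopifnot(inherits(spec, "SampleSpec"))
  pops <- spec$populations
  nm <- vapply(pops, `[[`, character(1), "name")
  fr <- vapply(pops, `[[`, numeric(1), "frequency")
  mks <- names(pops[[1]]$mu)
  n <- spec$n_events
  with_seed(spec$seed, {
    labels <- if (n > 0) sample(nm, n, replace = TRUE, prob = fr) else character(0)
    ev <- matrix(0, nrow = n, ncol = length(mks), dimnames = list(NULL, mks))
    for (p in pops) {
      idx <- which(labels == p$name)
      k <- length(idx)
      if (k == 0) next
      for (m in mks) {
        z <- if (is.finite(p$truncate_sigma)) {
          lim <- stats::pnorm(c(-1, 1) * p$truncate_sigma)
          stats::qnorm(stats::runif(k, lim[1], lim[2]))
        } else stats::rnorm(k)
        ev[idx, m] <- exp(p$mu[[m]] + p$sigma[[m]] * z)
      }
    }
    list(table = event_table(ev, markers = mks,
                             sample_id = sprintf("sim_seed%s", spec$seed)),
         labels = labels)
  })
}

#' Enrichment specification
#'
#' Emulates stepwise stromal enrichment (density gradient plus CD45
#' depletion): each event is retained with the probability of its class.
#' Stromal classes are cTEC, mTEC, FB, EC, LEC; CD45+ classes are the
#' hematopoietic populations; remaining CD45- events (e.g. "other") use the
#' non-stromal CD45- retention.
#'
#' @param cd45_retention Retention probability for CD45+ events.
#' @param nonstromal_cd45neg_retention Retention for CD45- non-stromal events.
#' @param stromal_retention Retention for stromal events.
#' @param seed RNG seed.
#' @return An `EnrichmentSpec`.
#' @export
enrichment_spec <- function(cd45_retention = 0.004,
                            nonstromal_cd45neg_retention = 0.9,
                            stromal_retention = 0.9, seed = 1L) {
  r <- c(cd45_retention, nonstromal_cd45neg_retention, stromal_retention)
  if (any(r < 0 | r > 1)) stop("retentions must lie in [0, 1]", call. = FALSE)
  structure(list(cd45_retention = cd45_retention,
                 nonstromal_cd45neg_retention = nonstromal_cd45neg_retention,
                 stromal_retention = stromal_retention, seed = seed),
            class = "EnrichmentSpec")
}

STROMAL_POPULATIONS <- c("cTEC", "mTEC", "FB", "EC", "LEC")
CD45POS_POPULATIONS <- c("DC", "MP", "thymocyte_immature",
                         "thymocyte_CD4SP", "thymocyte_CD8SP", "B")

retention_class <- function(labels) {
  ifelse(labels %in% STROMAL_POPULATIONS, "stromal",
         ifelse(labels %in% CD45POS_POPULATIONS, "cd45pos", "cd45neg_other"))
}

#' Simulate stepwise stromal enrichment
#'
#' Subsamples events by class-specific retention probabilities; intensities
#' of retained events are unchanged. With the default retentions (CD45+
#' retention 0.004, stromal and other CD45- retention 0.9) a sample at
#' realistic TEC frequencies is enriched roughly 200-fold in TEC proportion.
#'
#' @param table An `EventTable`.
#' @param labels Ground-truth labels aligned with the table rows.
#' @param spec An `EnrichmentSpec`.
#' @return List with `table`, `labels` (the retained subset) and `kept`
#'   (logical index into the input).
#' @export
simulate_enrichment <- function(table, labels, spec) {
  stopifnot(inherits(table, "EventTable"), inherits(spec, "EnrichmentSpec"))
  if (length(labels) != n_events(table)) {
    stop("alignment error: labels must match table rows", call. = FALSE)
  }
  r <- c(stromal = spec$stromal_retention,
         cd45pos = spec$cd45_retention,
         cd45neg_other = spec$nonstromal_cd45neg_retention)
  with_seed(spec$seed, {
    keep <- stats::runif(length(labels)) < r[retention_class(labels)]
    if (!any(keep) && length(labels) > 0) {
      warning("enrichment retained no events", call. = FALSE)
    }
    out <- table
    out$events <- table$events[keep, , drop = FALSE]
    list(table = out, labels = labels[keep], kept = keep)
  })
}

#' Expected enrichment factor (closed form)
#'
#' For pre-enrichment class frequencies p_i and retentions r_i, the expected
#' post-enrichment proportion of a target class set is
#' `p' = sum(p_t * r_t) / sum(p_i * r_i)`; the enrichment factor is
#' `p' / p` with `p = sum(p_t)`.
#'
#' @param freqs Named frequency vector over populations (sums to 1).
#' @param spec An `EnrichmentSpec`.
#' @param target Population names whose combined proportion is tracked
#'   (default cTEC + mTEC, i.e. all TECs).
#' @return List with `expected_proportion` and `factor`.
#' @export
expected_enrichment <- function(freqs, spec, target = c("cTEC", "mTEC")) {
  r <- c(stromal = spec$stromal_retention,
         cd45pos = spec$cd45_retention,
         cd45neg_other = spec$nonstromal_cd45neg_retention)
  ret <- r[retention_class(names(freqs))]
  p0 <- sum(freqs[names(freqs) %in% target])
  p1 <- sum((freqs * ret)[names(freqs) %in% target]) / sum(freqs * ret)
  list(expected_proportion = p1, factor = p1 / p0)
}
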