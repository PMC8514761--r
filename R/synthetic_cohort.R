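# Synthetic donor cohorts with a planted male-infant cTEC deficit and a
# coupled CD4/CD8 mature-thymocyte shift.

#' Cohort specification
#'
#' Per-donor population frequencies are the age-adjusted baselines times
#' log-normal donor noise (coefficient of variation `donor_cv`); male donors
#' in the 0-3 month group additionally have their cTEC frequency multiplied
#' by `male_0_3m_ctec_multiplier`. The CD8 share of mature single-positive
#' thymocytes follows a logistic link on the log cTEC/mTEC ratio
#' (`plogis(qlogis(cd8sp_baseline_share) + coupling_slope * log(ratio))`),
#' so a positive slope plants an inverse CD4/CD8-vs-cTEC/mTEC coupling.
#' Baseline stromal frequencies default to the reported cohort medians (TEC
#' 0.067\% in the youngest group declining with age per
#' `tec_age_multipliers`; MP 0.044\%, DC 0.057\%, FB 0.06\%, EC 0.061\%,
#' LEC 0.0013\%); the remainder is thymocytes.
#'
#' @param n_donors Number of donors (>= 2).
#' @param age_group_probs Probabilities of the 0-3m / 3-6m / 6-12m age bins.
#' @param sex_probs Probabilities of F / M.
#' @param baseline_frequencies Named vector of per-population baseline
#'   fractions of total (stromal + accessory; must sum to < 1).
#' @param tec_age_multipliers Multipliers applied to cTEC and mTEC baselines
#'   per age group (defaults reproduce the 0.067/0.033/0.016\% TEC medians).
#' @param male_0_3m_ctec_multiplier cTEC multiplier for male 0-3m donors, in
#'   (0, 1].
#' @param coupling_slope Logistic-scale effect of log(cTEC/mTEC) on the CD8SP
#'   share of mature thymocytes.
#' @param cd8sp_baseline_share CD8SP share of mature thymocytes at
#'   cTEC/mTEC = 1 (default 1/3, i.e. CD4:CD8 of 2).
#' @param mature_fraction Fraction of thymocytes that are mature
#'   single-positives.
#' @param donor_cv Log-normal donor-to-donor CV of every baseline frequency.
#' @param n_events Events acquired per donor (drives the multinomial counting
#'   noise of the measured frequencies).
#' @param seed RNG seed.
#' @return A `CohortSpec`.
#' @export
cohort_spec <- function(n_donors = 31L,
                        age_group_probs = c("0-3m" = 0.4, "3-6m" = 0.3,
                                            "6-12m" = 0.3),
                        sex_probs = c(F = 0.5, M = 0.5),
                        baseline_frequencies = c(cTEC = 0.000335,
                                                 mTEC = 0.000335,
                                                 MP = 0.00044, DC = 0.00057,
                                                 FB = 0.0006, EC = 0.00061,
                                                 LEC = 0.000013,
                                                 B = 0.005, other = 0.002),
                        tec_age_multipliers = c("0-3m" = 1,
                                                "3-6m" = 0.033 / 0.067,
                                                "6-12m" = 0.016 / 0.067),
                        male_0_3m_ctec_multiplier = 0.5,
                        coupling_slope = 1,
                        cd8sp_baseline_share = 1 / 3,
                        mature_fraction = 0.12,
                        donor_cv = 0.5,
                        n_events = 5e5,
                        seed = 1L) {
  if (n_donors < 2) stop("a cohort needs at least 2 donors", call. = FALSE)
  if (abs(sum(age_group_probs) - 1) > 1e-9 || abs(sum(sex_probs) - 1) > 1e-9) {
    stop("probability maps must each sum to 1", call. = FALSE)
  }
  if (sum(baseline_frequencies) > 1) {
    stop("baseline frequencies must sum to <= 1", call. = FALSE)
  }
  stopifnot(male_0_3m_ctec_multiplier > 0, male_0_3m_ctec_multiplier <= 1,
            donor_cv >= 0)
  structure(as.list(environment()), class = "CohortSpec")
}

AGE_BIN_DAYS <- c("0-3m" = 0, "3-6m" = 91, "6-12m" = 183, top = 366)

#' Cohort table from ground-truth frequencies
#'
#' Builds the same per-donor metrics as [summarize_cohort()] directly from a
#' cohort's ground-truth frequency table, i.e. without the multinomial
#' counting noise of a finite acquisition.
#'
#' @param truth The `truth` data.frame of [simulate_cohort()].
#' @return A cohort data.frame with percent frequencies and derived ratios.
#' @export
cohort_from_truth <- function(truth) {
  data.frame(donor_id = truth$donor_id, age_days = truth$age_days,
             age_group = truth$age_group, sex = truth$sex,
             tec_pct = 100 * (truth$cTEC + truth$mTEC),
             ctec_pct = 100 * truth$cTEC, mtec_pct = 100 * truth$mTEC,
             cd4sp_pct = 100 * truth$thymocyte_CD4SP,
             cd8sp_pct = 100 * truth$thymocyte_CD8SP,
             ctec_mtec_ratio = truth$cTEC / truth$mTEC,
             cd4sp_cd8sp_ratio = truth$thymocyte_CD4SP / truth$thymocyte_CD8SP,
             ratio_defined = is.finite(truth$cTEC / truth$mTEC),
             stringsAsFactors = FALSE)
}

#' Simulate a donor cohort with ground truth
#'
#' Returns per-donor metadata, ground-truth population frequencies and
#' measured (multinomially sampled) event counts; full per-donor event tables
#' with intensities are generated on request.
#'
#' @param spec A `CohortSpec`.
#' @param generate_tables Also simulate a raw-scale `EventTable` (plus truth
#'   labels) per donor via [simulate_sample()]; off by default since counts
#'   are all the cohort statistics need.
#' @return List with `truth` (data.frame: donor metadata, true frequencies,
#'   true cTEC/mTEC ratio and CD8SP share), `counts` (donors x populations
#'   matrix of measured event counts at `n_events` per donor), `samples`
#'   (list of `simulate_sample()` outputs or `NULL`) and `spec`.
#' @export
simulate_cohort <- function(spec, generate_tables = FALSE) {
  stopifnot(inherits(spec, "CohortSpec"))
  pops <- c(names(spec$baseline_frequencies),
            "thymocyte_immature", "thymocyte_CD4SP", "thymocyte_CD8SP")
  with_seed(spec$seed, {
    n <- spec$n_donors
    age_group <- sample(names(spec$age_group_probs), n, replace = TRUE,
                        prob = spec$age_group_probs)
    lo <- AGE_BIN_DAYS[age_group]
    hi <- AGE_BIN_DAYS[match(age_group, names(AGE_BIN_DAYS)) + 1L]
    age_days <- floor(stats::runif(n, lo, hi))
    sex <- sample(names(spec$sex_probs), n, replace = TRUE,
                  prob = spec$sex_probs)
    sdl <- sqrt(log(1 + spec$donor_cv^2))
    freq <- matrix(0, n, length(pops), dimnames = list(NULL, pops))
    cd8_share <- numeric(n)
    for (i in seq_len(n)) {
      base <- spec$baseline_frequencies
      base[c("cTEC", "mTEC")] <- base[c("cTEC", "mTEC")] *
        spec$tec_age_multipliers[[age_group[i]]]
      if (sex[i] == "M" && age_group[i] == "0-3m") {
        base["cTEC"] <- base["cTEC"] * spec$male_0_3m_ctec_multiplier
      }
      noise <- exp(stats::rnorm(length(base), -sdl^2 / 2, sdl))
      f <- base * noise
      thym <- 1 - sum(f)
      mature <- thym * spec$mature_fraction
      ratio <- f[["cTEC"]] / f[["mTEC"]]
      s <- stats::plogis(stats::qlogis(spec$cd8sp_baseline_share) +
                           spec$coupling_slope * log(ratio))
      cd8_share[i] <- s
      freq[i, names(base)] <- f
      freq[i, "thymocyte_CD8SP"] <- mature * s
      freq[i, "thymocyte_CD4SP"] <- mature * (1 - s)
      freq[i, "thymocyte_immature"] <- thym - mature
    }
    counts <- t(vapply(seq_len(n), function(i) {
      as.integer(stats::rmultinom(1, spec$n_events, freq[i, ]))
    }, integer(length(pops))))
    colnames(counts) <- pops
    donor_id <- sprintf("D%02d", seq_len(n))
    rownames(counts) <- donor_id
    truth <- data.frame(donor_id = donor_id, age_days = age_days,
                        age_group = age_group, sex = sex,
                        freq, check.names = FALSE,
                        ctec_mtec_ratio = freq[, "cTEC"] / freq[, "mTEC"],
                        cd8sp_share = cd8_share,
                        row.names = NULL, stringsAsFactors = FALSE)
    samples <- NULL
    if (generate_tables) {
      ph <- thymic_phenotypes()
      samples <- lapply(seq_len(n), function(i) {
        fr <- freq[i, ]
        fr["thymocyte_immature"] <- fr["thymocyte_immature"] + (1 - sum(fr))
        mods <- lapply(names(fr), function(p) {
          population_model(p, fr[[p]],
                           stats::setNames(as.numeric(ph[p, ]), colnames(ph)))
        })
        simulate_sample(sample_spec(mods, spec$n_events,
                                    seed = (spec$seed %% 1000003L) * 1000L + i))
      })
    }
    list(truth = truth, counts = counts, samples = samples, spec = spec)
  })
}
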