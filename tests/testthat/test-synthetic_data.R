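test_that("a single population at frequency 1 labels every event", {
  mods <- default_population_models(frequencies = c(mTEC = 1))
  sim <- simulate_sample(sample_spec(mods, 500, seed = 1))
  expect_equal(unique(sim$labels), "mTEC")
  expect_equal(n_events(sim$table), 500L)
})

test_that("zero events yield an empty table and empty labels", {
  sim <- simulate_sample(sample_spec(default_population_models(), 0, seed = 1))
  expect_equal(n_events(sim$table), 0L)
  expect_length(sim$labels, 0L)
})

test_that("rare-population counts stay within the binomial tolerance", {
  p <- 0.0005
  fr <- c(cTEC = p, thymocyte_immature = 1 - p)
  sim <- simulate_sample(sample_spec(default_population_models(frequencies = fr),
                                     100000, seed = 3))
  n_ctec <- sum(sim$labels == "cTEC")
  expect_lt(abs(n_ctec - 50), 4 * sqrt(1e5 * p * (1 - p)))
})

test_that("simulated label frequencies converge to spec frequencies", {
  mods <- default_population_models()
  fr <- vapply(mods, `[[`, numeric(1), "frequency")
  names(fr) <- vapply(mods, `[[`, character(1), "name")
  sim <- simulate_sample(sample_spec(mods, 2e5, seed = 5))
  obs <- table(factor(sim$labels, levels = names(fr))) / 2e5
  se <- sqrt(fr * (1 - fr) / 2e5)
  expect_true(all(abs(as.numeric(obs) - fr) <= 3.5 * se + 1e-12))
})

test_that("generators are seed-deterministic and seed-sensitive", {
  spc <- sample_spec(default_population_models(), 300, seed = 9)
  a <- simulate_sample(spc)
  b <- simulate_sample(spc)
  expect_identical(a$table$events, b$table$events)
  expect_identical(a$labels, b$labels)
  c <- simulate_sample(sample_spec(default_population_models(), 300, seed = 10))
  expect_false(identical(a$table$events, c$table$events))

  e1 <- simulate_expression_matrix(small_expression_spec(200, seed = 4))
  e2 <- simulate_expression_matrix(small_expression_spec(200, seed = 4))
  expect_identical(e1$matrix$values, e2$matrix$values)

  p1 <- simulate_screen_plate(default_screen_spec(seed = 2))
  p2 <- simulate_screen_plate(default_screen_spec(seed = 2))
  expect_identical(p1$mfi, p2$mfi)
})

test_that("frequencies must sum to one and names be unique", {
  mods <- default_population_models(frequencies = c(cTEC = 0.6, mTEC = 0.3))
  expect_error(sample_spec(mods, 10), "sum to 1")
  dup <- default_population_models(frequencies = c(cTEC = 0.5, mTEC = 0.5))
  dup[[2]]$name <- "cTEC"
  expect_error(sample_spec(dup, 10), "unique")
})

test_that("enrichment with all retentions 1 keeps composition unchanged", {
  sim <- simulate_sample(separated_sample_spec(2000))
  en <- simulate_enrichment(sim$table, sim$labels,
                            enrichment_spec(1, 1, 1, seed = 1))
  expect_identical(en$labels, sim$labels)
  expect_identical(en$table$events, sim$table$events)
})

test_that("full CD45 depletion leaves the exact CD45-negative composition", {
  sim <- simulate_sample(separated_sample_spec(5000))
  en <- simulate_enrichment(sim$table, sim$labels,
                            enrichment_spec(0, 1, 1, seed = 1))
  keep_classes <- c("cTEC", "mTEC", "FB", "EC", "LEC", "other")
  expect_setequal(unique(en$labels), intersect(keep_classes, sim$labels))
  tec_expected <- sum(sim$labels %in% c("cTEC", "mTEC")) /
    sum(sim$labels %in% keep_classes)
  expect_equal(mean(en$labels %in% c("cTEC", "mTEC")), tec_expected)
})

test_that("enrichment never alters intensities, only membership", {
  sim <- simulate_sample(separated_sample_spec(3000))
  en <- simulate_enrichment(sim$table, sim$labels, enrichment_spec(seed = 8))
  expect_identical(en$table$events, sim$table$events[en$kept, , drop = FALSE])
})

test_that("realized enrichment matches the closed-form expectation", {
  fr <- c(thymocyte_immature = 0.9798, thymocyte_CD4SP = 0.01,
          thymocyte_CD8SP = 0.005, cTEC = 0.00025, mTEC = 0.00025,
          FB = 0.0006, EC = 0.0006, LEC = 0.0001, DC = 0.0006, MP = 0.0004,
          B = 0.002, other = 0.0004)
  spc <- sample_spec(default_population_models(frequencies = fr), 2e5, seed = 21)
  sim <- simulate_sample(spc)
  esp <- enrichment_spec(cd45_retention = 0.004, stromal_retention = 0.9,
                         nonstromal_cd45neg_retention = 0.9, seed = 0)
  expected <- expected_enrichment(prop.table(table(sim$labels)), esp)$factor
  factors <- vapply(1:10, function(s) {
    esp$seed <- s
    en <- simulate_enrichment(sim$table, sim$labels, esp)
    (mean(en$labels %in% c("cTEC", "mTEC"))) /
      mean(sim$labels %in% c("cTEC", "mTEC"))
  }, numeric(1))
  expect_true(all(abs(factors / expected - 1) < 0.15))
  expect_gt(expected, 100)  # stepwise enrichment is on the order of 200-fold
})

test_that("cohort generator honours its degenerate settings", {
  # no male effect, no donor noise: same-age-group donors share frequencies
  cc <- simulate_cohort(cohort_spec(n_donors = 20, donor_cv = 0,
                                    male_0_3m_ctec_multiplier = 1, seed = 2))
  for (g in unique(cc$truth$age_group)) {
    sub <- cc$truth[cc$truth$age_group == g, ]
    expect_equal(length(unique(round(sub$cTEC, 12))), 1L)
  }
  # zero coupling: CD8 share constant across donors
  cc2 <- simulate_cohort(cohort_spec(n_donors = 20, coupling_slope = 0, seed = 3))
  expect_equal(length(unique(round(cc2$truth$cd8sp_share, 12))), 1L)
  expect_error(simulate_cohort(cohort_spec(n_donors = 1)), "at least 2")
})

test_that("the planted male-infant cTEC deficit halves the true ratio", {
  med <- vapply(1:20, function(s) {
    cc <- simulate_cohort(cohort_spec(n_donors = 31, donor_cv = 0.2,
                                      male_0_3m_ctec_multiplier = 0.5,
                                      seed = 100 + s))
    sub <- cc$truth[cc$truth$age_group == "0-3m", ]
    stats::median(sub$ctec_mtec_ratio[sub$sex == "M"]) /
      stats::median(sub$ctec_mtec_ratio[sub$sex == "F"])
  }, numeric(1))
  expect_equal(stats::median(med), 0.5, tolerance = 0.25)
})

test_that("screen plates honour planted folds and noise settings", {
  # no effects, no noise: all ratios exactly 1
  spc <- screen_spec(n_markers = 20, well_noise_cv = 0, seed = 1)
  pl <- simulate_screen_plate(spc)
  rk <- rank_markers(pl, "EpCAMhigh", "EpCAMlow")
  expect_true(all(rk$ratio == 1))
  expect_identical(rk$marker, sort(rk$marker))  # alphabetical tie order
  # single planted fold-10 marker, zero noise: ratio exactly 10
  spc2 <- screen_spec(n_markers = 20, well_noise_cv = 0, seed = 1,
                      planted_effects = data.frame(marker = 7,
                                                   population = "EpCAMhigh",
                                                   fold = 10))
  rk2 <- rank_markers(simulate_screen_plate(spc2), "EpCAMhigh", "EpCAMlow")
  expect_equal(rk2$ratio[rk2$marker == "M007"], 10)
  expect_equal(rk2$rank[rk2$marker == "M007"], 1L)
})

test_that("duplicate planted wells and bad indices are rejected", {
  pe <- data.frame(marker = c(3, 3), population = "EpCAMhigh", fold = c(2, 5))
  expect_error(screen_spec(n_markers = 10, planted_effects = pe), "duplicate")
  pe2 <- data.frame(marker = 11, population = "EpCAMhigh", fold = 2)
  expect_error(screen_spec(n_markers = 10, planted_effects = pe2),
               "out of range")
})

test_that("expression simulator plants exactly what it reports", {
  se <- simulate_expression_matrix(
    expression_spec(n_genes = 500, seed = 6,
                    planted_exclusive = c(mTEC = 30, cTEC = 10, FB = 8, EC = 5)))
  rep <- exclusive_report(se$matrix)
  expect_identical(rep$counts[names(se$truth$exclusive)],
                   lengths(se$truth$exclusive))
  for (p in names(se$truth$exclusive)) {
    expect_setequal(rep$exclusive[[p]], se$truth$exclusive[[p]])
  }
  # nothing planted -> nothing recovered
  se0 <- simulate_expression_matrix(
    expression_spec(n_genes = 300, shared_prob = 1, housekeeping_count = 10L,
                    planted_exclusive = c(mTEC = 0L, cTEC = 0L, FB = 0L, EC = 0L),
                    seed = 7))
  expect_true(all(exclusive_report(se0$matrix)$counts == 0))
})

test_that("dropout only removes planted exclusives, never adds them", {
  se <- simulate_expression_matrix(small_expression_spec(500, seed = 8,
                                                         dropout_prob = 0.3))
  rep <- exclusive_report(se$matrix)
  for (p in names(se$truth$exclusive)) {
    recovered_planted <- intersect(rep$exclusive[[p]], se$truth$exclusive[[p]])
    expect_lte(length(recovered_planted), length(se$truth$exclusive[[p]]))
  }
})
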