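test_that("donor summaries derive frequencies, ratios and age groups", {
  counts <- c(cTEC = 200, mTEC = 100, thymocyte_CD4SP = 3000,
              thymocyte_CD8SP = 1500, thymocyte_immature = 995200)
  st <- population_stats_from_counts(counts, total = 1e6)
  row <- summarize_donor(st, list(donor_id = "D1", age_days = 40, sex = "M"),
                         total = 1e6)
  expect_equal(row$ctec_mtec_ratio, 2)
  expect_equal(row$cd4sp_cd8sp_ratio, 2)
  expect_equal(row$age_group, "0-3m")
  # 670 TEC in 1e6 events -> 0.067 percent of total
  st2 <- population_stats_from_counts(c(cTEC = 350, mTEC = 320,
                                        thymocyte_CD4SP = 10,
                                        thymocyte_CD8SP = 10,
                                        thymocyte_immature = 999310),
                                      total = 1e6)
  row2 <- summarize_donor(st2, list(donor_id = "D2", age_days = 200), total = 1e6)
  expect_equal(row2$tec_pct, 0.067)
  expect_equal(row2$age_group, "6-12m")
})

test_that("a zero mTEC count flags the ratio but keeps the row", {
  st <- population_stats_from_counts(c(cTEC = 10, mTEC = 0,
                                       thymocyte_CD4SP = 5,
                                       thymocyte_CD8SP = 5), total = 1000)
  expect_message(
    row <- summarize_donor(st, list(donor_id = "D3", age_days = 10), total = 1000),
    "undefined")
  expect_true(is.na(row$ctec_mtec_ratio))
  expect_false(row$ratio_defined)
  expect_equal(row$ctec_pct, 1)
})

test_that("missing required nodes are named", {
  st <- population_stats_from_counts(c(cTEC = 10, mTEC = 5), total = 100)
  expect_error(summarize_donor(st, list(donor_id = "D", age_days = 1),
                               total = 100), "matureSP")
})

test_that("summaries are invariant to sample duplication", {
  counts <- c(cTEC = 20, mTEC = 10, thymocyte_CD4SP = 300,
              thymocyte_CD8SP = 100, thymocyte_immature = 9570)
  r1 <- summarize_donor(population_stats_from_counts(counts),
                        list(donor_id = "a", age_days = 1),
                        total = sum(counts))
  r2 <- summarize_donor(population_stats_from_counts(counts * 2),
                        list(donor_id = "a", age_days = 1),
                        total = 2 * sum(counts))
  expect_equal(r1$tec_pct, r2$tec_pct)
  expect_equal(r1$ctec_mtec_ratio, r2$ctec_mtec_ratio)
})

test_that("correlation matches the closed-form OLS solution", {
  x <- c(0.8, 1.1, 1.9, 2.4, 3.0, 3.3, 4.1, 4.8, 5.5, 6.0)
  y <- c(2.1, 2.0, 3.2, 3.9, 4.1, 5.2, 5.0, 6.3, 6.8, 7.7)
  res <- correlate(x, y)
  # independent oracle: the textbook normal equations
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  r2 <- (sxy / sqrt(sxx * sum((y - mean(y))^2)))^2
  n <- length(x)
  fstat <- r2 / (1 - r2) * (n - 2)
  expect_equal(res$slope, slope, tolerance = 1e-12)
  expect_equal(res$intercept, intercept, tolerance = 1e-12)
  expect_equal(res$r_squared, r2, tolerance = 1e-12)
  expect_equal(res$p_value, pf(fstat, 1, n - 2, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("correlation handles perfect, null and degenerate inputs", {
  x <- 1:10
  # lm warns that a perfect fit makes the summary unreliable; expected here
  res <- suppressWarnings(correlate(x, 2 * x))
  expect_equal(res$r_squared, 1)
  expect_equal(res$slope, 2)
  set.seed(4)
  r2s <- vapply(1:20, function(i) {
    correlate(rnorm(1000), rnorm(1000))$r_squared
  }, numeric(1))
  expect_gte(mean(r2s < 0.01), 0.9)
  expect_error(correlate(rep(1, 5), 1:5), "constant")
  expect_error(correlate(1:2, 1:2), "at least 3")
  # symmetric r-squared under swapping x and y
  set.seed(5)
  a <- rnorm(30); b <- a + rnorm(30)
  expect_equal(correlate(a, b)$r_squared, correlate(b, a)$r_squared)
})

test_that("Mann-Whitney comparison reproduces the exact separated p-value", {
  co <- data.frame(v = c(1:5, 101:105), g = rep(c("a", "b"), each = 5))
  res <- compare_groups(co, "v", "g")
  expect_true(res$exact)
  expect_equal(res$p_value, 2 / 252, tolerance = 1e-12)
  expect_equal(res$effect, median(1:5) - median(101:105))
})

test_that("identical groups give a p-value near 1 and zero effect", {
  co <- data.frame(v = rep(c(1, 2, 3, 4), 2), g = rep(c("a", "b"), each = 4))
  res <- compare_groups(co, "v", "g")
  expect_gt(res$p_value, 0.9)
  expect_equal(res$effect, 0)
  expect_false(res$exact)  # ties force the normal approximation
})

test_that("comparison errors on empty/small groups and drops NA rows", {
  co <- data.frame(v = c(1, 2, NA, 4, 5, 6), g = rep(c("a", "b"), each = 3))
  expect_message(res <- compare_groups(co, "v", "g"), "dropping 1")
  expect_equal(res$n, c(2L, 3L))
  expect_error(compare_groups(data.frame(v = 1:4, g = "a"), "v", "g"),
               "2 groups")
  expect_error(compare_groups(data.frame(v = 1:4,
                                         g = c("a", "a", "a", "b")),
                              "v", "g"), "at least 2")
})

test_that("rank test p-values are invariant to monotone metric transforms", {
  set.seed(6)
  co <- data.frame(v = c(rlnorm(6, 0, 1), rlnorm(7, 1, 1)),
                   g = rep(c("a", "b"), c(6, 7)))
  p1 <- compare_groups(co, "v", "g")$p_value
  co$v <- log(co$v)
  expect_equal(compare_groups(co, "v", "g")$p_value, p1)
})

test_that("2^-ddCt folds match the hand-worked fixture", {
  ct <- ddct_fixture()
  res <- ddct_fold_change(ct, targets = "AIRE",
                          references = c("GAPDH", "HPRT-1", "RPLP13"),
                          calibrator = "cal")
  expect_equal(res$fold[res$sample == "cal"], 1)           # calibrator == 1
  expect_equal(res$ddct[res$sample == "s2"], -2.5)
  expect_equal(res$fold[res$sample == "s2"], 2^2.5, tolerance = 1e-12)
})

test_that("ddCt identities: zero shift and a clean 2-cycle shift", {
  ct <- data.frame(gene = rep(c("T", "R1"), 2),
                   sample = rep(c("cal", "s"), each = 2),
                   ct = c(25, 20, 23, 20))
  res <- ddct_fold_change(ct, "T", "R1", "cal")
  expect_equal(res$fold[res$sample == "cal"], 1)
  expect_equal(res$fold[res$sample == "s"], 4)  # 2 cycles earlier -> fold 4
  bad <- ct[-2, ]
  expect_error(ddct_fold_change(bad, "T", "R1", "cal"), "R1")
  expect_error(ddct_fold_change(ct, "T", "R1", "nope"), "nope")
})
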