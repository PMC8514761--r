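test_that("threshold placement matches its closed-form cases", {
  set.seed(1)
  x <- c(rnorm(5000, 1, 0.2), rnorm(5000, 4, 0.2))
  th <- place_threshold(x, "valley")
  expect_gt(th, 2)
  expect_lt(th, 3)
  expect_equal(place_threshold(c(1, 2, 3), "quantile", q = 0.5), 2)
  expect_equal(place_threshold(rnorm(10), "fixed", v = 1.7), 1.7)
  expect_error(place_threshold(numeric(0), "valley"), "empty")
  expect_error(place_threshold(rnorm(10), "valley"), "50")
})

test_that("valley placement on unimodal data falls back to quantile(0.99)", {
  set.seed(2)
  x <- rnorm(1000)
  expect_warning(th <- place_threshold(x, "valley"), "quantile")
  expect_equal(th, unname(quantile(x, 0.99)), tolerance = 1e-12)
})

test_that("threshold placement is deterministic given data and method", {
  set.seed(3)
  x <- c(rnorm(2000, 0, 0.3), rnorm(500, 3, 0.3))
  expect_identical(place_threshold(x, "valley"), place_threshold(x, "valley"))
})

test_that("the default tree contains the published populations", {
  tree <- build_thymic_gating_tree()
  expect_true(all(c("TEC", "cTEC", "mTEC", "EC", "LEC", "FB", "DC", "MP",
                    "thymocyte", "matureSP", "CD4SP", "CD8SP") %in%
                    names(tree$nodes)))
  expect_false(tree$fitted)
  # CD45 is deliberately absent from the TEC path
  tec_markers <- vapply(tree$nodes$TEC$clauses, `[[`, character(1), "marker")
  expect_false("CD45" %in% tec_markers)
  # cTEC and mTEC are siblings with complementary CD49f/CD200 clauses
  expect_equal(tree$nodes$cTEC$parent, "TEC")
  expect_equal(tree$nodes$mTEC$parent, "TEC")
})

test_that("tree YAML serialization round-trips structurally", {
  tree <- build_thymic_gating_tree()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_gating_tree(tree, path)
  back <- read_gating_tree(path)
  expect_equal(names(back$nodes), names(tree$nodes))
  for (nm in names(tree$nodes)) {
    expect_equal(back$nodes[[nm]]$parent, tree$nodes[[nm]]$parent)
    expect_equal(back$nodes[[nm]]$combine, tree$nodes[[nm]]$combine)
    expect_equal(lapply(back$nodes[[nm]]$clauses, unclass),
                 lapply(tree$nodes[[nm]]$clauses, unclass))
  }
})

test_that("building against an incomplete panel names the missing marker", {
  pan <- panel_config(setdiff(default_thymic_panel()$required_markers, "CD31"))
  expect_error(build_thymic_gating_tree(pan), "CD31")
})

test_that("overrides replace thresholds and reject unknown nodes", {
  tree <- build_thymic_gating_tree(overrides = list(TEC = list(CD31 = 2.5)))
  cl <- Filter(function(x) x$marker == "CD31", tree$nodes$TEC$clauses)[[1]]
  expect_equal(cl$value, 2.5)
  expect_error(build_thymic_gating_tree(overrides = list(nope = list(CD31 = 1))),
               "nope")
})

test_that("gating a zero-overlap sample recovers ground truth exactly", {
  sim <- simulate_sample(separated_sample_spec(20000, seed = 13))
  tt <- transform_events(sim$table)
  res <- apply_gating(tt, build_thymic_gating_tree())
  # every event lands exactly on its mapped node: recovery is exact
  expected_node <- unname(default_truth_map()[sim$labels])
  expect_identical(res$assignment$population, expected_node)
  ev <- evaluate_gating(res$assignment, sim$labels)
  expect_true(all(ev$f1[ev$n_truth > 0] == 1))
})

test_that("CD49f+CD200+ events inside the TEC gate join neither TEC subset", {
  sim <- simulate_sample(separated_sample_spec(20000, seed = 17))
  tt <- transform_events(sim$table)
  res <- apply_gating(tt, build_thymic_gating_tree())
  fitted <- res$tree
  # craft an event with the LEC-like CD49f+CD200+ phenotype but inside TEC
  ph <- thymic_phenotypes()
  ev <- asinh(matrix(as.numeric(ph["cTEC", ]), nrow = 1,
                     dimnames = list(NULL, colnames(ph))) / 150)
  ev[, "CD200"] <- asinh(20000 / 150)   # now CD49f-high AND CD200-high
  one <- event_table(sinh(ev) * 150) |> transform_events()
  res1 <- apply_gating(one, fitted)
  expect_equal(res1$assignment$population, "TEC")
})

test_that("an empty table gates to all-zero counts with an emptiness flag", {
  sim <- simulate_sample(separated_sample_spec(5000, seed = 23))
  fitted <- fit_gating_tree(build_thymic_gating_tree(),
                            transform_events(sim$table))
  empty <- transform_events(event_table(
    matrix(numeric(0), 0, ncol(sim$table$events),
           dimnames = list(NULL, markers(sim$table)))))
  res <- apply_gating(empty, fitted)
  expect_true(all(res$stats$count == 0))
  expect_true(all(res$stats$freq_of_total == 0))
  expect_true(attr(res$stats, "empty"))
})

test_that("gating requires a transformed table and fittable scopes", {
  sim <- simulate_sample(separated_sample_spec(1000, seed = 29))
  expect_error(apply_gating(sim$table, build_thymic_gating_tree()),
               "transformed")
  tiny <- transform_events(simulate_sample(separated_sample_spec(20, seed = 1))$table)
  expect_error(fit_gating_tree(build_thymic_gating_tree(), tiny),
               "fitting error")
})

test_that("hierarchy conservation holds: children never exceed parents", {
  sim <- simulate_sample(sample_spec(default_population_models(), 30000,
                                     seed = 31))
  res <- apply_gating(transform_events(sim$table), build_thymic_gating_tree())
  st <- res$stats
  for (nm in st$population) {
    kids <- st$count[st$parent == nm]
    if (length(kids)) expect_lte(max(kids), st$count[st$population == nm])
  }
  # deepest-assignment partition: assigned + ungated = total
  expect_equal(sum(res$assignment$population == "ungated") +
                 sum(res$assignment$population != "ungated"),
               n_events(sim$table))
  expect_equal(attr(st, "n_ungated"),
               sum(res$assignment$population == "ungated"))
})

test_that("gating is invariant to event order", {
  sim <- simulate_sample(sample_spec(default_population_models(), 20000,
                                     seed = 37))
  tt <- transform_events(sim$table)
  fitted <- fit_gating_tree(build_thymic_gating_tree(), tt)
  res <- apply_gating(tt, fitted)
  set.seed(1)
  perm <- sample.int(n_events(sim$table))
  tt2 <- tt
  tt2$events <- tt$events[perm, ]
  res2 <- apply_gating(tt2, fitted)
  expect_identical(res2$assignment$population, res$assignment$population[perm])
  expect_identical(res2$stats$count, res$stats$count)
})

test_that("evaluation matches a brute-force confusion computation", {
  set.seed(5)
  classes <- c("cTEC", "mTEC", "FB")
  truth <- sample(classes, 100, replace = TRUE)
  pred <- truth
  flip <- sample(100, 25)
  pred[flip] <- sample(classes, 25, replace = TRUE)
  assignment <- data.frame(event = 1:100, population = pred, path = "")
  ev <- evaluate_gating(assignment, truth,
                        map = setNames(classes, classes))
  for (cls in classes) {
    tp <- sum(pred == cls & truth == cls)
    fp <- sum(pred == cls & truth != cls)
    fn <- sum(pred != cls & truth == cls)
    row <- ev[ev$truth_class == cls, ]
    expect_equal(row$precision, tp / (tp + fp))
    expect_equal(row$recall, tp / (tp + fn))
    expect_equal(row$f1, 2 * tp / (2 * tp + fp + fn))
  }
})

test_that("evaluation handles perfect, permuted and absent classes", {
  truth <- rep(c("cTEC", "mTEC"), each = 10)
  perfect <- data.frame(event = 1:20, population = truth, path = "")
  ev <- evaluate_gating(perfect, truth, map = c(cTEC = "cTEC", mTEC = "mTEC"))
  expect_true(all(ev$f1[ev$n_truth > 0] == 1))
  worst <- data.frame(event = 1:20, population = rev(truth), path = "")
  ev2 <- evaluate_gating(worst, truth, map = c(cTEC = "cTEC", mTEC = "mTEC"))
  expect_true(all(ev2$f1[ev2$n_truth > 0] == 0))
  ev3 <- evaluate_gating(perfect, truth,
                         map = c(cTEC = "cTEC", mTEC = "mTEC", LEC = "LEC"))
  expect_true(is.na(ev3$recall[ev3$truth_class == "LEC"]))
  expect_error(evaluate_gating(perfect, truth[-1]), "alignment")
})
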