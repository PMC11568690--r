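test_that("split_training honors quotas, eligibility flags and seeds", {
  set.seed(12)
  n <- 2000
  labels <- sample(CLASS_LEVELS, n, replace = TRUE,
                   prob = c(0.2, 0.3, 0.15, 0.15, 0.2))
  prof <- data.frame(hem = rpois(n, 2), total = rpois(n, 3),
                     oversegmented = FALSE)
  prof$oversegmented[1:50] <- TRUE
  q <- c(CTC = 40L, PBMC = 100L, artefact = 20L, false_positive = 20L,
         negative = 20L)
  sp <- split_training(prof, labels, q, seed = 7)
  expect_length(sp$train_idx, sum(q))
  expect_identical(sort(c(sp$train_idx, sp$test_idx)), seq_len(n))
  tr_tab <- table(labels[sp$train_idx])
  for (cl in names(q)) expect_identical(unname(tr_tab[cl]), q[[cl]])
  # flagged cells never train
  expect_false(any(sp$train_idx %in% which(prof$oversegmented)))
  # deterministic under the seed
  expect_identical(split_training(prof, labels, q, seed = 7), sp)
  expect_false(identical(split_training(prof, labels, q, seed = 8), sp))
  # infeasible quota errors with the class and shortfall
  expect_error(split_training(prof, labels, c(CTC = 100000L), seed = 1),
               "CTC.*short")
})

test_that("quota_from_ratio reproduces the 2/5/1/1/1 split at n = 1000", {
  q <- quota_from_ratio(c(CTC = 2, PBMC = 5, artefact = 1,
                          false_positive = 1, negative = 1), 1000)
  expect_identical(q, c(CTC = 200L, PBMC = 500L, artefact = 100L,
                        false_positive = 100L, negative = 100L))
  expect_error(quota_from_ratio(c(a = 1, b = 2), 100), "divisible")
})

test_that("the forest separates well-separated classes and fails on one
           class", {
  cfg <- sim_config(n_cells_per_class = c(CTC = 400L, PBMC = 800L,
                                          artefact = 100L,
                                          false_positive = 200L,
                                          negative = 1500L), seed = 13L)
  tab <- simulate_feature_table(cfg)
  sp <- split_training(tab, tab$class,
                       quotas = c(CTC = 100L, PBMC = 200L, artefact = 50L,
                                  false_positive = 50L, negative = 50L),
                       seed = 2)
  rf <- train_classifier(tab[sp$train_idx, ], tab$class[sp$train_idx],
                         n_trees = 60L, seed = 5)
  pred <- predict(rf, tab[sp$test_idx, ])
  ev <- evaluate(pred, tab$class[sp$test_idx], positive_class = "CTC")
  ctc <- ev$per_class[ev$per_class$class == "CTC", ]
  expect_gte(ctc$recall, 0.95)
  expect_gte(ctc$specificity, 0.98)
  # permuted labels give |MCC| <= 0.05 on held-out data
  set.seed(31)
  perm <- sample(tab$class[sp$train_idx])
  rf_null <- train_classifier(tab[sp$train_idx, ], perm, n_trees = 60L,
                              seed = 5)
  pred_null <- predict(rf_null, tab[sp$test_idx, ])
  ev_null <- evaluate(pred_null, tab$class[sp$test_idx])
  expect_lte(abs(ev_null$mcc), 0.05)
  # single class refuses to train
  one <- tab[tab$class == "PBMC", ]
  expect_error(train_classifier(one, one$class), "2 classes")
  # forests serialize and predict identically after a round trip
  p <- withr::local_tempfile(fileext = ".json")
  write_forest(rf, p)
  rf2 <- read_forest(p)
  expect_identical(as.character(predict(rf2, tab[sp$test_idx[1:50], ])),
                   as.character(pred[1:50]))
})

test_that("evaluate reproduces metrics from known confusion counts", {
  # the published patient-set counts: 49 true CTCs, 37 recovered, 177
  # false positives among 17,707 non-CTCs
  truth <- c(rep("CTC", 49), rep("negative", 17707))
  predicted <- c(rep("CTC", 37), rep("negative", 12),
                 rep("CTC", 177), rep("negative", 17530))
  ev <- evaluate(predicted, truth, positive_class = "CTC")
  ctc <- ev$per_class[ev$per_class$class == "CTC", ]
  expect_equal(ctc$recall, 37 / 49, tolerance = 1e-12)
  expect_equal(ctc$specificity, 17530 / 17707, tolerance = 1e-12)
  expect_equal(ctc$precision, 37 / 214, tolerance = 1e-12)
  expect_identical(ctc$support, 49L)
  # confusion marginals equal class supports
  expect_identical(unname(rowSums(ev$confusion)),
                   unname(vapply(rownames(ev$confusion), function(cl)
                     sum(truth == cl), numeric(1))))
  # perfect prediction: MCC and F1 are 1
  ev2 <- evaluate(truth, truth)
  expect_equal(ev2$mcc, 1)
  expect_true(all(ev2$per_class$f1 == 1))
  expect_error(evaluate(truth[-1], truth), "length")
  # binary MCC agrees with the closed form on the patient counts
  tp <- 37; fn <- 12; fp <- 177; tn <- 17530
  mcc_closed <- (tp * tn - fp * fn) /
    sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  expect_equal(ev$mcc, mcc_closed, tolerance = 1e-12)
})

test_that("cohort_summary computes positivity and IQR per group", {
  prof <- data.frame(hem = c(0, 0, 1, 2, 3), KRT = 0,
                     total = c(0, 0, 1, 2, 3))
  s <- cohort_summary(prof, rep("g", 5))
  hem <- s[s$marker == "hem", ]
  expect_equal(hem$positivity, 60)
  expect_equal(hem$median, 1)
  # linear-interpolation quantiles, verified against the standard oracle
  expect_equal(hem$q1, unname(quantile(c(0, 0, 1, 2, 3), 0.25)))
  expect_equal(hem$q3, unname(quantile(c(0, 0, 1, 2, 3), 0.75)))
  krt <- s[s$marker == "KRT", ]
  expect_equal(c(krt$positivity, krt$median, krt$q1, krt$q3), c(0, 0, 0, 0))
  expect_true("total" %in% s$marker)
  # empty group flagged as NA, not silently zero
  s2 <- cohort_summary(prof[0, ], character(0))
  expect_identical(nrow(s2), 0L)
  # a declared-but-empty factor level yields flagged NA rows, not zeros
  s3 <- cohort_summary(prof, factor(rep("g", 5), levels = c("g", "h")))
  h <- s3[s3$group == "h", ]
  expect_true(nrow(h) > 0 && all(is.na(h$positivity)) && all(h$n == 0L))
})

test_that("a Table-1-parameterized cohort reproduces published positivity", {
  cfg <- sim_config(n_cells_per_class = c(CTC = 3000L, PBMC = 3000L,
                                          artefact = 0L,
                                          false_positive = 0L,
                                          negative = 0L), seed = 19L)
  tab <- simulate_feature_table(cfg)
  s <- cohort_summary(tab, tab$class)
  arfl <- s[s$group == "CTC" & s$marker == "AR-FL", ]
  expect_lt(abs(arfl$positivity - 99), 3)
  expect_lte(abs(arfl$median - 34), 2)
  hem <- s[s$group == "PBMC" & s$marker == "hem", ]
  expect_lt(abs(hem$positivity - 86), 5)
  expect_equal(hem$median, 3, tolerance = 1)
})
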