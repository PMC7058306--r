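# Records whose confusion matrix at cut-off 0.5 has the given counts.
records_from_counts <- function(tn, fp, fn, tp) {
  data.frame(
    score = c(rep(0.1, tn), rep(0.9, fp), rep(0.1, fn), rep(0.9, tp)),
    true_label = c(rep("benign", tn + fp), rep("malignant", fn + tp)),
    stringsAsFactors = FALSE)
}

test_that("the confusion matrix partitions prediction records", {
  recs <- records_from_counts(261, 45, 46, 268)
  cm <- confusion(recs, 0.5)
  expect_equal(c(cm$tn, cm$fp, cm$fn, cm$tp), c(261, 45, 46, 268))
  expect_equal(cm$tn + cm$fp + cm$fn + cm$tp, nrow(recs))

  perfect <- confusion(records_from_counts(10, 0, 0, 12), 0.5)
  expect_equal(perfect$fp + perfect$fn, 0)

  all_mal <- confusion(recs, 0)    # cut-off 0: everything called malignant
  expect_equal(all_mal$tn, 0)
  expect_equal(all_mal$fn, 0)

  bad <- recs
  bad$true_label[1] <- "atypical"
  expect_error(confusion(bad), "unknown label")
  expect_error(confusion(recs[0, ]), "non-empty")
})

test_that("summary metrics match their defining ratios", {
  m <- confusion_counts(tn = 261, fp = 45, fn = 46, tp = 268)
  s <- summary_metrics(m)
  expect_equal(round(s[["accuracy"]], 3), 0.853)
  expect_equal(s[["accuracy"]], 529 / 620)
  expect_equal(round(s[["sensitivity"]], 3), 0.854)   # 268 / 314
  expect_equal(round(s[["specificity"]], 3), 0.853)   # 261 / 306
  expect_equal(summary_metrics(confusion_counts(7, 0, 0, 9)),
               c(sensitivity = 1, specificity = 1, accuracy = 1))
  expect_error(summary_metrics(confusion_counts(0, 0, 3, 4)),
               "undefined metric")
  expect_error(confusion_counts(-1, 0, 0, 0), "non-negative")
})

test_that("accuracy is a prevalence-weighted mix of sensitivity and specificity", {
  set.seed(21)
  for (i in 1:10) {
    cm <- confusion_counts(tn = sample(5:50, 1), fp = sample(1:20, 1),
                           fn = sample(1:20, 1), tp = sample(5:50, 1))
    s <- summary_metrics(cm)
    expect_gte(s[["accuracy"]], min(s[["sensitivity"]], s[["specificity"]]))
    expect_lte(s[["accuracy"]], max(s[["sensitivity"]], s[["specificity"]]))
  }
})

test_that("the ROC curve is monotone from (0,0) to (1,1) with tie grouping", {
  sep <- data.frame(score = c(0.1, 0.2, 0.8, 0.9),
                    true_label = c("benign", "benign", "malignant",
                                   "malignant"))
  r <- roc_auc(sep)
  expect_equal(r$auc, 1.0)
  expect_equal(r$points$fpr[1], 0)
  expect_equal(r$points$tpr[1], 0)
  expect_equal(tail(r$points$fpr, 1), 1)
  expect_equal(tail(r$points$tpr, 1), 1)
  expect_true(all(diff(r$points$fpr) >= 0))
  expect_true(all(diff(r$points$tpr) >= 0))

  flat <- data.frame(score = rep(0.4, 10),
                     true_label = rep(c("benign", "malignant"), 5))
  expect_equal(roc_auc(flat)$auc, 0.5)
  expect_equal(nrow(roc_auc(flat)$points), 2L)   # one grouped tie step

  expect_error(roc_auc(data.frame(score = 0.2, true_label = "benign")),
               "both classes")
})

test_that("AUC equals the Mann-Whitney pairwise oracle", {
  for (s in 1:6) {
    recs <- random_records(50, seed = s, ties = s %% 2 == 0)
    expect_equal(roc_auc(recs)$auc, mann_whitney_auc(recs),
                 tolerance = 1e-9)
  }
})

test_that("AUC agrees with an established ROC implementation", {
  recs <- random_records(80, seed = 13)
  ours <- roc_auc(recs)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = recs$true_label, predictor = recs$score,
    levels = c("benign", "malignant"), direction = "<", quiet = TRUE)))
  expect_equal(ours, ref, tolerance = 1e-9)
})

test_that("the split plan carves a 173-patch holdout and three folds", {
  man <- fake_manifest(391, 402)        # the study's 793-patch accounting
  plan <- split_plan(holdout = 173, cv_folds = 3, grouping = "patch",
                     seed = 11)
  sp <- make_splits(man, plan)
  expect_equal(sum(sp$split == "validation"), 173L)
  pool <- sp$split[startsWith(sp$split, "fold")]
  expect_equal(length(pool), 620L)
  # folds partition the pool
  expect_setequal(unique(pool), c("fold1", "fold2", "fold3"))
  expect_equal(sum(table(pool)), 620L)
  # stratified: each fold contains both classes
  for (f in c("fold1", "fold2", "fold3")) {
    expect_setequal(unique(sp$label[sp$split == f]),
                    c("benign", "malignant"))
  }
  # deterministic given the seed
  expect_identical(make_splits(man, plan), sp)
  expect_error(make_splits(fake_manifest(50, 50), plan), "too few")
})

test_that("case grouping never splits a case across folds", {
  man <- fake_manifest(100, 100)
  sp <- make_splits(man, split_plan(holdout = 40, cv_folds = 3,
                                    grouping = "case", seed = 2))
  tab <- table(sp$case_id, sp$split)
  expect_true(all(rowSums(tab > 0) == 1L))
  # excluded rows stay excluded
  man2 <- fake_manifest(60, 60, 10)
  sp2 <- make_splits(man2, split_plan(holdout = 30, grouping = "case"))
  expect_true(all(sp2$split[sp2$label == "excluded"] == "excluded"))
})

test_that("pooled-fold confusion counts equal the sum over folds", {
  set.seed(31)
  recs <- random_records(90, seed = 31)
  recs$fold <- rep(1:3, 30)
  pooled <- confusion(recs, 0.5)
  per <- lapply(1:3, function(f) confusion(recs[recs$fold == f, ], 0.5))
  expect_equal(pooled$tp, sum(vapply(per, `[[`, numeric(1), "tp")))
  expect_equal(pooled$tn, sum(vapply(per, `[[`, numeric(1), "tn")))
  expect_equal(pooled$fp, sum(vapply(per, `[[`, numeric(1), "fp")))
  expect_equal(pooled$fn, sum(vapply(per, `[[`, numeric(1), "fn")))
})

test_that("the method comparison reports the study's deltas", {
  metrics <- list(
    ImageNet = c(sensitivity = 0.850, specificity = 0.768,
                 accuracy = 0.810, auc = 0.872),
    DCGAN = c(sensitivity = 0.793, specificity = 0.797,
              accuracy = 0.795, auc = 0.867),
    PGGAN = c(sensitivity = 0.854, specificity = 0.853,
              accuracy = 0.853, auc = 0.901))
  cmp <- method_comparison(metrics)
  pg <- cmp$deltas[cmp$deltas$method == "PGGAN", ]
  expect_equal(pg$accuracy, 0.043)
  expect_equal(pg$specificity, 0.085)
  expect_equal(cmp$deltas[cmp$deltas$method == "ImageNet", ]$accuracy, 0)
  expect_output(print(cmp), "PGGAN")
})

test_that("run_comparison pools folds and zeroes deltas for equal methods", {
  man <- fake_manifest(60, 60)
  man <- make_splits(man, split_plan(holdout = 20, cv_folds = 3,
                                     grouping = "patch", seed = 7))
  # trainer stub: deterministic scorer shared by both methods
  trainer <- function(method, train_man, seed) method
  predictor <- function(fitted, test_man) {
    set.seed(sum(utf8ToInt(paste(test_man$path, collapse = ""))) %% 1000)
    data.frame(score = ifelse(test_man$label == "malignant",
                              runif(nrow(test_man), 0.4, 1),
                              runif(nrow(test_man), 0, 0.6)),
               true_label = test_man$label, stringsAsFactors = FALSE)
  }
  cmp <- run_comparison(man, c("A", "B"), trainer, predictor,
                        reference = "A")
  expect_equal(nrow(cmp$table), 2L)
  expect_true(all(abs(as.matrix(cmp$deltas[-1])) < 1e-12))
  # pooled predictions cover every fold patch exactly once
  expect_equal(nrow(cmp$predictions$A),
               sum(startsWith(man$split, "fold")))
  expect_error(run_comparison(fake_manifest(5, 5), "A", trainer, predictor),
               "no folds")
})

test_that("the evaluation report rounds only at report time", {
  recs <- records_from_counts(261, 45, 46, 268)
  rep <- evaluation_report(recs)
  expect_equal(rep$metrics[["accuracy"]], 0.853)
  # two-point score distribution: AUC follows from the pair counts
  expect_equal(rep$auc, (268 * 261 + 0.5 * 268 * 45 + 0.5 * 46 * 261) /
                 (314 * 306))
  expect_s3_class(rep$roc, "data.frame")
})
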