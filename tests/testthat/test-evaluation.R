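test_that("confusion matrices count correctly", {
  y <- phase_factor(c("DS1", "SS", "SS", "SW", "DS2"))
  cm <- confusion(y, y)
  expect_true(all(cm[row(cm) != col(cm)] == 0))
  expect_equal(sum(cm), 5)
  cm2 <- confusion(c("DS1", "DS1"), c("DS1", "SW"))
  expect_equal(cm2["DS1", "SW"], 1)
  expect_equal(sum(cm2), 2)
  expect_error(confusion(character(0), character(0)), "empty")
  expect_error(confusion(c("DS1", "SS"), "DS1"), "length")
})

test_that("metrics reproduce the one-vs-rest definitions", {
  # binary reduction: TP=3, TN=4, FP=1, FN=2
  cm <- matrix(c(3, 1, 2, 4), 2, 2,
               dimnames = list(c("pos", "neg"), c("pos", "neg")))
  class(cm) <- c("confusion_matrix", class(cm))
  rep_ <- metrics(cm)
  expect_equal(rep_$accuracy, 0.7)
  expect_equal(rep_$per_class$precision[1], 0.75)
  expect_equal(rep_$per_class$recall[1], 0.6)
  expect_equal(rep_$per_class$f1[1], 2 * 0.75 * 0.6 / 1.35)
  expect_equal(rep_$per_class$tp[1], 3)
  expect_equal(rep_$per_class$tn[1], 4)
  # one-vs-rest bookkeeping: TP+FN = row sum, TP+FP = column sum
  y_t <- phase_factor(sample(gait_phases(), 60, TRUE))
  y_p <- phase_factor(sample(gait_phases(), 60, TRUE))
  cm4 <- confusion(y_t, y_p)
  r4 <- metrics(cm4)
  expect_equal(r4$per_class$tp + r4$per_class$fn, unname(rowSums(cm4)))
  expect_equal(r4$per_class$tp + r4$per_class$fp, unname(colSums(cm4)))
  # perfect predictions give all metrics 1
  perf <- metrics(confusion(y_t, y_t))
  expect_equal(c(perf$accuracy, perf$precision, perf$recall, perf$f1),
               rep(1, 4))
  expect_equal(metrics(cm4, times = c(2, 4))$avg_time_ms, 3)
})

test_that("empty predicted classes yield zero precision with a warning", {
  y_t <- phase_factor(rep(c("DS1", "SS"), 10))
  y_p <- phase_factor(rep("DS1", 20))
  w <- capture_warnings(rep_ <- metrics(confusion(y_t, y_p)))
  expect_true(any(grepl("undefined", w)))
  expect_equal(rep_$per_class$precision[rep_$per_class$class == "SS"], 0)
  expect_true(rep_$f1 <= 1)
})

test_that("stratified k-fold partitions the data evenly and reproducibly", {
  labs <- phase_factor(rep(gait_phases(), times = c(20, 80, 20, 80)))
  f1 <- kfold_split(labs, 5, seed = 3)
  f2 <- kfold_split(labs, 5, seed = 3)
  expect_identical(f1, f2)
  expect_setequal(unique(f1), 1:5)
  expect_equal(length(f1), 200L)
  for (cl in gait_phases()) {
    per_fold <- table(f1[labs == cl])
    expect_lte(max(per_fold) - min(per_fold), 1)
  }
  expect_error(kfold_split(phase_factor(c("DS1", "SS", "SS")), 5),
               "at least k")
})

test_that("k-fold cross-validation runs a generic trainer per fold", {
  fs <- small_feature_set()
  # nearest-centroid trainer on channel-mean features: cheap and accurate
  trainer <- function(x, y) {
    cm <- sapply(levels(y), function(cl) {
      colMeans(apply(x[y == cl, , , drop = FALSE], c(1, 2), mean))
    })
    list(centroids = cm, classes = levels(y))
  }
  predictor <- function(model, x) {
    proj <- apply(x, c(1, 2), mean)
    d <- as.matrix(stats::dist(rbind(t(model$centroids), proj)))
    k <- ncol(model$centroids)
    idx <- apply(d[-(1:k), 1:k, drop = FALSE], 1, which.min)
    factor(model$classes[idx], levels = model$classes)
  }
  cv <- kfold_cv(fs, k = 5, trainer = trainer, predictor = predictor,
                 seed = 2)
  expect_length(cv$reports, 5)
  accs <- vapply(cv$reports, `[[`, 0, "accuracy")
  expect_equal(cv$summary$mean_accuracy, mean(accs))
  expect_equal(cv$summary$sd_accuracy, sd(accs))
  expect_gte(cv$summary$mean_accuracy, 0.9)
  # folds form a partition
  expect_setequal(unique(cv$folds), 1:5)
  expect_length(cv$folds, dim(fs$features)[1L])
})

test_that("the ablation harness tabulates paired variants", {
  fs <- small_feature_set()
  set.seed(8)
  idx <- sample(dim(fs$features)[1L], 100)
  # 2-epoch models are deliberately undertrained; unpredicted classes
  # trigger the documented zero-division warnings
  tab <- suppressWarnings(
    ablation(fs$features[idx, , ], fs$labels[idx],
             variants = c("mcnn", "full"),
             config = tiny_model_config(),
             train = train_config(epochs = 2, batch_size = 64, seed = 1),
             seeds = 1:2))
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$variant, c("mcnn", "full"))
  expect_gt(tab$n_parameters[tab$variant == "full"],
            tab$n_parameters[tab$variant == "mcnn"])
  per_seed <- attr(tab, "per_seed")
  expect_equal(dim(per_seed), c(2L, 2L))
  expect_true(all(per_seed >= 0 & per_seed <= 1))
  expect_error(ablation(fs, variants = "full"), "2 variants")
})

test_that("multi-scene evaluation averages per-mode accuracies", {
  sets <- list(
    LW = cached("msc_lw", sim_feature_set("S01", "LW", 12, seed = 501)),
    SD = cached("msc_sd", sim_feature_set("S01", "SD", 12, seed = 502))
  )
  res <- suppressWarnings(
    multi_scene_eval(sets, config = tiny_model_config(),
                     train = train_config(epochs = 4, batch_size = 64,
                                          seed = 3)))
  expect_named(res$per_mode, c("LW", "SD"))
  accs <- vapply(res$per_mode, `[[`, 0, "accuracy")
  expect_equal(res$overall_accuracy, mean(accs))
  expect_equal(dim(res$confusions$LW), c(4L, 4L))
  one <- suppressWarnings(
    multi_scene_eval(sets["LW"], config = tiny_model_config(),
                     train = train_config(epochs = 2, batch_size = 64,
                                          seed = 3)))
  expect_equal(one$overall_accuracy, one$per_mode$LW$accuracy)
})

test_that("dataset bookkeeping reproduces the acquisition arithmetic", {
  plan <- dataset_plan(3200, 12, 5)
  expect_equal(plan$per_mode, 38400)
  expect_equal(plan$total, 192000)
  expect_equal(dataset_plan(10, 2, 3)$total, 60)
})
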