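# Subject-wise evaluation: fold rule, confusion matrices, cross-validation
# mechanics and cross-dataset transfer on a reduced-scale classifier.

test_that("the overlapping-window fold rule covers all 21 subjects", {
  subj <- paste0("S", 1:21)
  scheme <- make_folds(subj, 10L)
  expect_equal(scheme$folds[[1]], c("S1", "S2", "S3"))
  expect_equal(scheme$folds[[10]], c("S19", "S20", "S21"))
  expect_setequal(unique(unlist(scheme$folds)), subj)
  # consecutive folds overlap by construction
  expect_equal(intersect(scheme$folds[[1]], scheme$folds[[2]]), "S3")
  expect_error(make_folds(paste0("S", 1:20), 10L), "2 \\* n_folds")
})

test_that("confusion matrices report row percentages with undefined empty rows", {
  classes <- gait_types()
  perfect <- confusion_matrix(classes, classes, classes)
  expect_equal(unname(diag(perfect)), rep(100, 5))
  expect_equal(sum(perfect), 500)

  all_first <- confusion_matrix(rep("scissor", 10),
                                rep(classes, 2), classes)
  expect_true(all(all_first[, "scissor"] == 100))
  expect_true(all(all_first[, -1] == 0))

  # hand-counted toy set of 20 labelled pairs
  truths <- c(rep("scissor", 5), rep("spastic", 5), rep("steppage", 4),
              rep("normal", 3), rep("propulsive", 3))
  preds <- c("scissor", "scissor", "spastic", "scissor", "propulsive",
             "spastic", "spastic", "spastic", "scissor", "spastic",
             "steppage", "steppage", "steppage", "normal",
             "normal", "normal", "normal",
             "propulsive", "propulsive", "scissor")
  cm <- confusion_matrix(preds, truths, classes)
  expect_equal(unname(cm["scissor", ]), c(60, 20, 0, 0, 20))
  expect_equal(unname(cm["spastic", ]), c(20, 80, 0, 0, 0))
  expect_equal(unname(cm["steppage", ]), c(0, 0, 75, 25, 0))
  expect_equal(unname(cm["normal", ]), c(0, 0, 0, 100, 0))
  expect_equal(unname(cm["propulsive", ]), c(100 / 3, 0, 0, 0, 200 / 3))
  expect_equal(rowSums(cm), setNames(rep(100, 5), classes), tolerance = 1e-12)

  sparse <- confusion_matrix(c("scissor"), c("scissor"), classes)
  expect_true(all(is.na(sparse["normal", ])))
  expect_error(confusion_matrix(c("a", "b"), "a"), "length")
})

test_that("overall accuracy is the support-weighted mean of per-class recalls", {
  set.seed(7)
  classes <- gait_types()
  truths <- sample(classes, 60, replace = TRUE)
  preds <- ifelse(stats::runif(60) < 0.6, truths, sample(classes, 60, TRUE))
  rep_ <- gaitkit:::new_evaluation_report(preds, truths, classes)
  support <- table(factor(truths, classes))
  weighted <- sum(diag(rep_$confusion) * support) / sum(support)
  expect_equal(rep_$accuracy, weighted, tolerance = 1e-12)
})

test_that("cross-validation trains per fold, stays subject-disjoint and beats chance", {
  # reduced-scale experiment: 5 subjects x 5 classes x 2 repetitions of
  # 56 x 56 energy images through the same five-layer topology
  ds <- cv56_set()
  manifest <- data.frame(
    session_id = ds$subjects, subject_id = ds$subjects,
    gait_type = ds$labels, severity = 1L, direction = "left_to_right",
    repetition_index = 1L,
    sequence_uri = sprintf("seq%03d", seq_along(ds$labels)),
    stringsAsFactors = FALSE)
  reps <- stats::setNames(ds$representations, manifest$sequence_uri)
  cfg <- model_config(input_size = 56L, dense_units = c(64L, 5L),
                      batch_size = 16L, seed = 11L)
  scheme <- make_folds(unique(manifest$subject_id), 2L)
  report <- cross_validate(manifest, reps, cfg, scheme, epochs = 6L)
  expect_s3_class(report, "evaluation_report")
  expect_length(report$fold_accuracies, 2L)
  expect_true(all(abs(rowSums(report$confusion) - 100) < 1e-9))
  expect_gt(report$accuracy, 40)       # far above the 20% chance level
  expect_equal(report$fold_accuracy_mean, mean(report$fold_accuracies))

  # degenerate scheme with no training subjects is rejected
  bad <- structure(list(subjects = unique(manifest$subject_id),
                        folds = list(unique(manifest$subject_id))),
                   class = "fold_scheme")
  expect_error(cross_validate(manifest, reps, cfg, bad), "no training subjects")
  expect_error(cross_validate(manifest, reps[-1], cfg, scheme),
               "without representations")
})

test_that("cross-dataset evaluation maps labels and transfers above chance", {
  ds <- cv56_set()
  manifest <- data.frame(subject_id = ds$subjects, gait_type = ds$labels,
                         sequence_uri = sprintf("seq%03d", seq_along(ds$labels)),
                         stringsAsFactors = FALSE)
  reps <- stats::setNames(ds$representations, manifest$sequence_uri)
  # noisy at-home test domain: speckled masks, shifted body scale
  test_ds <- cv56_noisy_set()
  map <- gait_label_map()
  test_manifest <- data.frame(
    subject_id = test_ds$subjects + 100L,
    gait_type = unname(map[test_ds$labels]),
    sequence_uri = sprintf("t%03d", seq_along(test_ds$labels)),
    stringsAsFactors = FALSE)
  test_reps <- stats::setNames(test_ds$representations, test_manifest$sequence_uri)
  cfg <- model_config(input_size = 56L, dense_units = c(64L, 5L),
                      batch_size = 16L, seed = 19L)
  report <- cross_dataset_eval(manifest, reps, test_manifest, test_reps, cfg,
                               epochs = 6L)
  expect_setequal(rownames(report$confusion), unname(map))
  expect_gt(report$accuracy, 30)       # above the 20% chance level
  # unmappable test labels are refused
  bad_manifest <- test_manifest
  bad_manifest$gait_type[1] <- "limping"
  expect_error(cross_dataset_eval(manifest, reps, bad_manifest, test_reps, cfg),
               "not reachable")
})

test_that("identical train and test sets reach at least the final training accuracy", {
  ds <- tiny_image_set(n_per_class = 6L)
  manifest <- data.frame(subject_id = rep(1:6, 3), gait_type = ds$labels,
                         sequence_uri = sprintf("q%02d", seq_along(ds$labels)),
                         stringsAsFactors = FALSE)
  reps <- stats::setNames(ds$images, manifest$sequence_uri)
  cfg <- tiny_model_config(seed = 23L)
  map <- stats::setNames(cfg$classes, cfg$classes)  # identity vocabulary
  report <- cross_dataset_eval(manifest, reps, manifest, reps, cfg,
                               label_map = map, epochs = 8L)
  clf <- train_classifier(build_classifier(cfg), reps, manifest$gait_type,
                          validation_fraction = 0, epochs = 8L)
  final_train_acc <- 100 * clf$history$accuracy[nrow(clf$history)]
  expect_gte(report$accuracy, final_train_acc - 1e-9)
})
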