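# Subject-wise evaluation protocol.
#
# Folds follow the overlapping-window rule: the test set of fold k is
# V_k = {S_(2k-1), S_(2k), S_(2k+1)} over the ordered subject list, so with
# 21 subjects and 10 folds every subject is tested at least once while train
# and test subjects stay disjoint within each fold. Reports carry the pooled
# 5x5 confusion matrix in the canonical class order, rows = true class, as
# row percentages.

#' Build a subject-wise fold scheme
#'
#' Test set of fold `k` is the 3-subject window starting at position
#' `2k - 1` of the ordered subject list; the train set is the complement.
#'
#' @param subject_ids ordered vector of distinct subject identifiers; must
#'   hold at least `2 * n_folds + 1` subjects.
#' @param n_folds number of folds (default 10).
#' @return object of class `fold_scheme`: list with `subjects` and `folds`
#'   (per fold, the test-subject vector).
#' @export
make_folds <- function(subject_ids, n_folds = 10L) {
  subject_ids <- unique(subject_ids)
  m <- length(subject_ids)
  if (m < 2L * n_folds + 1L)
    stop("need at least 2 * n_folds + 1 subjects for the window rule",
         call. = FALSE)
  folds <- lapply(seq_len(n_folds), function(k) {
    i <- 2L * k - 1L
    subject_ids[i:(i + 2L)]
  })
  structure(list(subjects = subject_ids, folds = folds),
            class = "fold_scheme")
}

#' Row-percentage confusion matrix
#'
#' Entry (r, c) is `100 * count(true = r, predicted = c) / count(true = r)`.
#' Classes with zero support yield `NA` rows (undefined, not zero).
#'
#' @param predictions,truths equal-length label vectors.
#' @param classes class order for rows and columns.
#' @return numeric matrix of row percentages, rows = true class.
#' @export
confusion_matrix <- function(predictions, truths, classes = gait_types()) {
  if (length(predictions) != length(truths))
    stop("predictions and truths differ in length", call. = FALSE)
  predictions <- factor(as.character(predictions), levels = classes)
  truths <- factor(as.character(truths), levels = classes)
  counts <- table(truths, predictions)
  support <- rowSums(counts)
  pct <- 100 * counts / support
  pct[support == 0, ] <- NA_real_
  m <- matrix(as.numeric(pct), length(classes), length(classes),
              dimnames = list(true = classes, predicted = classes))
  m
}

new_evaluation_report <- function(predictions, truths, classes,
                                  fold_accuracies = NULL) {
  cm <- confusion_matrix(predictions, truths, classes)
  acc <- 100 * mean(predictions == truths)
  per_class <- diag(cm)
  structure(list(accuracy = acc, per_class_accuracy = per_class,
                 confusion = cm,
                 fold_accuracies = fold_accuracies,
                 fold_accuracy_mean = if (is.null(fold_accuracies)) NULL
                                      else mean(fold_accuracies),
                 n = length(truths)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("Evaluation over %d sequences: accuracy %.1f%%\n", x$n, x$accuracy))
  if (!is.null(x$fold_accuracy_mean))
    cat(sprintf("Mean per-fold accuracy: %.1f%% over %d folds\n",
                x$fold_accuracy_mean, length(x$fold_accuracies)))
  cat("Confusion matrix (row %):\n")
  print(round(x$confusion, 1))
  invisible(x)
}

# Sequence-level scoring: a sequence's label is the argmax of its
# whole-sequence representation's class probabilities.
score_sequences <- function(classifier, reps) {
  predict(classifier, reps, type = "class")
}

#' Subject-wise cross-validation
#'
#' For every fold, trains a fresh classifier on the representations of the
#' non-test subjects and scores the test subjects' sequences. Fold
#' disjointness (train and test subjects never overlap) is asserted on every
#' fold. Scoring is sequence-level: each sequence contributes its
#' whole-sequence representation.
#'
#' @param manifest dataset manifest (as from [generate_manifest()]); labels
#'   are taken from its `gait_type` column.
#' @param representations named list of `gait_representation`s keyed by
#'   `sequence_uri`; every manifest row must have one.
#' @param config a `model_config`.
#' @param scheme a `fold_scheme` over the manifest's subjects.
#' @param epochs,validation_fraction training overrides per fold (the
#'   default trains for the configured epochs without an inner validation
#'   split, keeping folds deterministic).
#' @param verbose print per-fold progress.
#' @return an `evaluation_report` with pooled accuracy/confusion and
#'   per-fold accuracies.
#' @export
cross_validate <- function(manifest, representations, config, scheme,
                           epochs = NULL, validation_fraction = 0,
                           verbose = FALSE) {
  stopifnot(inherits(scheme, "fold_scheme"))
  missing_reps <- setdiff(manifest$sequence_uri, names(representations))
  if (length(missing_reps))
    stop("manifest sequences without representations: ",
         paste(utils::head(missing_reps, 3), collapse = ", "), call. = FALSE)
  pooled_pred <- character(0); pooled_true <- character(0)
  fold_acc <- numeric(0)
  for (k in seq_along(scheme$folds)) {
    test_subj <- scheme$folds[[k]]
    train_subj <- setdiff(scheme$subjects, test_subj)
    if (length(intersect(train_subj, test_subj)))
      stop("train and test subjects overlap in fold ", k, call. = FALSE)
    if (length(train_subj) == 0L)
      stop("fold ", k, " leaves no training subjects", call. = FALSE)
    tr <- manifest[manifest$subject_id %in% train_subj, , drop = FALSE]
    te <- manifest[manifest$subject_id %in% test_subj, , drop = FALSE]
    if (nrow(te) == 0L) stop("fold ", k, " has no test sequences", call. = FALSE)
    cfg_k <- config
    cfg_k$seed <- config$seed + k
    clf <- build_classifier(cfg_k)
    clf <- train_classifier(clf, representations[tr$sequence_uri],
                            tr$gait_type,
                            validation_fraction = validation_fraction,
                            epochs = epochs)
    pred <- score_sequences(clf, representations[te$sequence_uri])
    acc <- 100 * mean(pred == te$gait_type)
    fold_acc <- c(fold_acc, acc)
    if (verbose) message(sprintf("fold %d: accuracy %.1f%%", k, acc))
    pooled_pred <- c(pooled_pred, pred)
    pooled_true <- c(pooled_true, te$gait_type)
  }
  new_evaluation_report(pooled_pred, pooled_true, config$classes, fold_acc)
}

#' Canonical gait-type to pathology label mapping
#'
#' Maps the studio gait-type vocabulary onto the pathology names used by
#' at-home capture datasets: scissor = diplegic, spastic = hemiplegic,
#' steppage = neuropathic, propulsive = Parkinsonian, normal = healthy.
#'
#' @return named character vector (names = gait types, values = pathology
#'   labels).
#' @export
gait_label_map <- function() {
  c(scissor = "diplegic", spastic = "hemiplegic", steppage = "neuropathic",
    normal = "healthy", propulsive = "parkinsonian")
}

#' Cross-dataset evaluation
#'
#' Trains once on every sequence of the training manifest and evaluates on
#' every sequence of the test manifest, whose labels may use a different
#' vocabulary related 1-to-1 by `label_map`. The returned report uses the
#' test-domain class names.
#'
#' @param train_manifest,test_manifest dataset manifests.
#' @param train_representations,test_representations named representation
#'   lists keyed by each manifest's `sequence_uri`.
#' @param config a `model_config`.
#' @param label_map named character vector mapping train-domain class names
#'   to test-domain names; every test label must be reachable.
#' @param epochs,validation_fraction training overrides.
#' @return an `evaluation_report` in the test-domain vocabulary.
#' @export
cross_dataset_eval <- function(train_manifest, train_representations,
                               test_manifest, test_representations,
                               config, label_map = gait_label_map(),
                               epochs = NULL, validation_fraction = 0) {
  unmapped <- setdiff(unique(test_manifest$gait_type), label_map)
  if (length(unmapped))
    stop("test labels not reachable through the label map: ",
         paste(unmapped, collapse = ", "), call. = FALSE)
  clf <- build_classifier(config)
  clf <- train_classifier(clf, train_representations[train_manifest$sequence_uri],
                          train_manifest$gait_type,
                          validation_fraction = validation_fraction,
                          epochs = epochs)
  pred <- score_sequences(clf, test_representations[test_manifest$sequence_uri])
  pred_mapped <- unname(label_map[pred])
  new_evaluation_report(pred_mapped, test_manifest$gait_type,
                        unname(label_map[config$classes]))
}
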