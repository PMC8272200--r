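#' Compute the posture feature vector for one frame
#'
#' Applies the pipeline's standard preparation — the default enhancement
#' chain, optionally a sacrum crop — and extracts the HOG descriptor.
#'
#' @param frame a [pressure_frame()] or matrix.
#' @param feature_scope `"whole_body"` or `"sacrum"`.
#' @param config a [hog_config()].
#' @param enhance_first run [enhance_chain()] before HOG (the pipeline
#'   default).
#' @return numeric feature vector.
#' @export
posture_features <- function(frame, feature_scope = c("whole_body", "sacrum"),
                             config = hog_config(), enhance_first = TRUE) {
  feature_scope <- match.arg(feature_scope)
  f <- as_frame(frame)
  if (enhance_first) f <- enhance_chain(f)
  if (feature_scope == "sacrum") f <- crop_sacrum(f)
  extract_hog(f, config)
}

POSTURE_LEVELS <- c("supine", "left_lateral", "right_lateral")

# Standardize columns with training statistics; zero-variance columns pass
# through unscaled.
fit_scaler <- function(X) {
  mu <- colMeans(X)
  s <- apply(X, 2, sd)
  s[s < 1e-12] <- 1
  list(mu = mu, s = s)
}
apply_scaler <- function(X, sc) sweep(sweep(X, 2, sc$mu), 2, sc$s, `/`)

fit_one <- function(model_type, X, y, seed) {
  colnames(X) <- paste0("V", seq_len(ncol(X)))
  set.seed(seed)  # ksvm estimates its RBF width from a random subsample
  switch(model_type,
    svm = kernlab::ksvm(X, y, kernel = "rbfdot", scaled = FALSE),
    knn = list(train_x = X, train_y = y, k = 10L),
    random_forest = ranger::ranger(x = X, y = y, num.trees = 100,
                                   seed = seed, num.threads = 1)
  )
}

predict_one <- function(model_type, fit, X, seed) {
  colnames(X) <- paste0("V", seq_len(ncol(X)))
  set.seed(seed + 7919L)  # fixes KNN tie-breaking; harmless elsewhere
  switch(model_type,
    svm = as.character(kernlab::predict(fit, X)),
    knn = as.character(class::knn(fit$train_x, X, fit$train_y, k = fit$k)),
    random_forest = as.character(predict(fit, data = X)$predictions)
  )
}

#' Train a posture classifier on labelled pressure frames
#'
#' Implements the evaluation protocol used for in-bed posture models:
#' a subject-wise 80/20 split (roughly 20\% of subjects held out; no subject
#' appears in both partitions), subject-wise k-fold cross-validation on the
#' training portion (10 folds, reduced with a warning when fewer training
#' subjects are available), a final fit on all training data, and a held-out
#' per-class accuracy report. Supported models: RBF support-vector machine
#' (kernlab), k-nearest-neighbour with k = 10, and a 100-tree random forest
#' (ranger); features are standardized with training statistics.
#'
#' @param dataset list of samples `list(frame, label, subject_id)`, e.g. from
#'   [labelled_dataset()]. Labels must be among supine / left_lateral /
#'   right_lateral.
#' @param model_type `"svm"`, `"knn"` or `"random_forest"`.
#' @param feature_scope `"whole_body"` or `"sacrum"` (HOG of the sacrum crop
#'   only).
#' @param config a [hog_config()].
#' @param seed integer controlling the split, CV folds and any stochastic
#'   fitting; the whole procedure is reproducible from it.
#' @param cv_folds requested number of CV folds.
#' @param features optional precomputed feature matrix (rows = samples) to
#'   avoid recomputing HOG when training several models on one dataset.
#' @return a `posture_model` with the fitted classifier, the scaler, the
#'   configuration, and a `report` (CV accuracy, held-out accuracy, per-class
#'   held-out accuracy, the subject split and fold count).
#' @export
train_posture_model <- function(dataset,
                                model_type = c("svm", "knn", "random_forest"),
                                feature_scope = c("whole_body", "sacrum"),
                                config = hog_config(), seed = 1,
                                cv_folds = 10, features = NULL) {
  model_type <- match.arg(model_type)
  feature_scope <- match.arg(feature_scope)
  labels <- vapply(dataset, `[[`, character(1), "label")
  subjects <- vapply(dataset, `[[`, character(1), "subject_id")
  if (!all(labels %in% POSTURE_LEVELS)) stop("unknown posture label in dataset")
  if (length(unique(labels)) < 2) stop("dataset contains a single class")
  per_class_subj <- tapply(subjects, labels, function(s) length(unique(s)))
  if (any(per_class_subj < 2)) stop("need >= 2 subjects per class")
  tab <- table(labels)
  if (max(tab) > 2 * min(tab)) warning("classes are strongly unbalanced")

  y <- factor(labels, levels = POSTURE_LEVELS)
  if (is.null(features)) {
    features <- t(vapply(dataset,
      function(s) posture_features(s$frame, feature_scope, config),
      numeric(length(posture_features(dataset[[1]]$frame, feature_scope, config)))))
  }

  # Subject-wise 80/20 split.
  subj_all <- unique(subjects)
  set.seed(seed)
  n_test <- max(1, round(0.2 * length(subj_all)))
  test_subjects <- sample(subj_all, n_test)
  is_test <- subjects %in% test_subjects
  if (length(unique(y[!is_test])) < length(unique(y))) {
    stop("training partition lost a class; provide more subjects")
  }

  X_tr <- features[!is_test, , drop = FALSE]; y_tr <- y[!is_test]
  X_te <- features[is_test, , drop = FALSE]; y_te <- y[is_test]
  subj_tr <- subjects[!is_test]

  # Subject-wise k-fold CV on the training portion.
  tr_subj <- unique(subj_tr)
  folds <- cv_folds
  if (length(tr_subj) < folds) {
    folds <- length(tr_subj)
    warning("fewer training subjects than folds; reduced to ", folds)
  }
  fold_of <- setNames(sample(rep_len(seq_len(folds), length(tr_subj))), tr_subj)
  cv_pred <- character(length(y_tr))
  for (f in seq_len(folds)) {
    hold <- fold_of[subj_tr] == f
    if (!any(hold) || all(hold)) next
    sc <- fit_scaler(X_tr[!hold, , drop = FALSE])
    fit <- fit_one(model_type, apply_scaler(X_tr[!hold, , drop = FALSE], sc),
                   droplevels(y_tr[!hold]), seed + f)
    cv_pred[hold] <- predict_one(model_type, fit,
                                 apply_scaler(X_tr[hold, , drop = FALSE], sc),
                                 seed + f)
  }
  cv_acc <- mean(cv_pred == as.character(y_tr))

  # Final fit on all training data, then held-out evaluation.
  scaler <- fit_scaler(X_tr)
  fit <- fit_one(model_type, apply_scaler(X_tr, scaler), y_tr, seed)
  te_pred <- predict_one(model_type, fit, apply_scaler(X_te, scaler), seed)
  holdout_acc <- mean(te_pred == as.character(y_te))
  per_class <- vapply(POSTURE_LEVELS, function(l) {
    idx <- y_te == l
    if (!any(idx)) return(NA_real_)
    mean(te_pred[idx] == l)
  }, numeric(1))

  structure(list(
    model_type = model_type, feature_scope = feature_scope,
    hog_config = config, fit = fit, scaler = scaler, seed = seed,
    frame_shape = frame_shape(dataset[[1]]$frame),
    levels = POSTURE_LEVELS,
    report = list(cv_accuracy = cv_acc, cv_folds = folds,
                  holdout_accuracy = holdout_acc,
                  holdout_per_class = per_class,
                  test_subjects = sort(test_subjects),
                  train_subjects = sort(setdiff(subj_all, test_subjects)),
                  n_train = length(y_tr), n_test = length(y_te))
  ), class = "posture_model")
}

#' @export
print.posture_model <- function(x, ...) {
  cat(sprintf("<posture_model> %s on %s HOG: held-out accuracy %.3f (CV %.3f, %d folds)\n",
              x$model_type, x$feature_scope, x$report$holdout_accuracy,
              x$report$cv_accuracy, x$report$cv_folds))
  invisible(x)
}

#' Predict the posture of a single frame
#'
#' Deterministic for a fixed model (KNN tie-breaking is seeded from the
#' model). The frame must match the training grid shape. Content-free frames
#' (e.g. an empty bed) still return one of the three labels; interpretation
#' of such frames is undefined.
#'
#' @param model a `posture_model`.
#' @param frame a [pressure_frame()] or matrix.
#' @return one of `"supine"`, `"left_lateral"`, `"right_lateral"`.
#' @export
predict_posture <- function(model, frame) {
  frame <- as_frame(frame)
  if (!all(dim(frame$values) == model$frame_shape)) {
    stop("frame shape does not match the training grid")
  }
  x <- posture_features(frame, model$feature_scope, model$hog_config)
  X <- apply_scaler(matrix(x, nrow = 1), model$scaler)
  predict_one(model$model_type, model$fit, X, model$seed)
}
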