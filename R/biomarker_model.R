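#' @importFrom stats glm binomial predict plogis quantile
NULL

#' Percentile-cap feature normalisation
#'
#' Each feature (column) is divided by its 97.5th percentile
#' (linear-interpolation quantile) across subjects and capped at 1, so
#' all values lie in \[0, 1\] and a handful of extreme responders cannot
#' dominate the model fit.
#'
#' @param features numeric matrix, subjects x features.
#' @param probs capping percentile (0.975).
#' @return matrix of the same shape with values in \[0, 1\].
#' @export
cap_normalize_features <- function(features, probs = 0.975) {
  features <- as.matrix(features)
  stopifnot(nrow(features) >= 2L)
  q <- apply(features, 2L, quantile, probs = probs, type = 7, names = FALSE)
  zero <- q == 0
  if (any(zero))
    stop("all-zero (or zero-percentile) feature: ",
         paste(colnames(features)[zero], collapse = ", "))
  out <- sweep(features, 2L, q, "/")
  out[out > 1] <- 1
  out
}

#' Balanced accuracy
#'
#' Mean of the per-class recalls; for two classes this is
#' (sensitivity + specificity) / 2 and is invariant to class prevalence.
#'
#' @param predictions vector of predicted class labels.
#' @param labels vector of true class labels (two classes required).
#' @return balanced accuracy in \[0, 1\].
#' @export
balanced_accuracy <- function(predictions, labels) {
  labels <- as.character(labels); predictions <- as.character(predictions)
  cls <- unique(labels)
  if (length(cls) < 2L) stop("labels contain a single class")
  mean(vapply(cls, function(cl)
    mean(predictions[labels == cl] == cl), numeric(1)))
}

#' ROC threshold selection by Youden's J
#'
#' Sweeps every observed value as a candidate threshold for the rule
#' "value >= threshold calls positive" (or <= with `direction = "le"`),
#' picks the threshold maximising Youden's J = sens + spec - 1 (ties
#' resolved toward higher specificity), and reports the AUROC by
#' trapezoidal integration of the ROC curve.
#'
#' @param values numeric marker values.
#' @param labels logical (or two-level) vector; TRUE / the second level
#'   marks the positive class.
#' @param direction `"ge"` (high values call positive) or `"le"`.
#' @return list: `threshold`, `sensitivity`, `specificity`, `auroc`,
#'   `direction`, and `sweep` (all candidate threshold/sens/spec rows).
#' @export
roc_threshold <- function(values, labels, direction = c("ge", "le")) {
  direction <- match.arg(direction)
  if (is.logical(labels)) pos <- labels
  else {
    lv <- sort(unique(as.character(labels)))
    if (length(lv) != 2L) stop("labels must have exactly two levels")
    pos <- as.character(labels) == lv[2L]
  }
  if (all(pos) || !any(pos)) stop("both classes must be present")
  v <- if (direction == "ge") values else -values
  p <- v[pos]; n <- v[!pos]
  cand <- sort(unique(c(v, max(v) + 1)))
  sens <- vapply(cand, function(t) mean(p >= t), numeric(1))
  spec <- vapply(cand, function(t) mean(n < t), numeric(1))
  j <- sens + spec - 1
  best <- which(j == max(j))
  best <- best[order(-spec[best], -cand[best])][1L]
  # trapezoidal AUROC over the full curve
  fpr <- c(1, 1 - spec, 0); tpr <- c(1, sens, 0)
  ord <- order(fpr, tpr)
  auroc <- sum(diff(fpr[ord]) * (tpr[ord][-1] + tpr[ord][-length(tpr)]) / 2)
  thr <- if (direction == "ge") cand[best] else -cand[best]
  list(threshold = thr, sensitivity = sens[best], specificity = spec[best],
       auroc = auroc, direction = direction,
       sweep = data.frame(
         threshold = if (direction == "ge") cand else rev(-cand),
         sens = if (direction == "ge") sens else rev(sens),
         spec = if (direction == "ge") spec else rev(spec)))
}

#' Fit the step-1 periodontitis classifier
#'
#' Unpenalised logistic regression of periodontal status on epitope
#' features, fit to a stratified 80% training split. The decision
#' threshold on the predicted probability is chosen to maximise balanced
#' accuracy of out-of-fold predictions from 5-fold cross-validation
#' within the training part. Reports balanced accuracy on the training
#' part and the held-out 20%, plus the training AUROC with a seeded
#' bootstrap 95% CI.
#'
#' @param features numeric matrix, subjects x features (typically the
#'   cap-normalised abundances of epitopes A, B, C); rownames are
#'   subject ids.
#' @param labels two-level vector aligned with rows, e.g. "P"/"H"; the
#'   positive class is the alphabetically later level ("P" vs "H").
#' @param split training fraction (0.8).
#' @param folds cross-validation folds for threshold selection (5).
#' @param seed integer seed (split, folds and bootstrap).
#' @param n_boot bootstrap resamples for the AUROC CI (2000).
#' @return object of class `mva_step1`: coefficients, decision
#'   threshold, positive class, metrics (balanced accuracy train /
#'   validation, AUROC + CI), the ROC sweep, and the split membership.
#' @export
fit_step1_model <- function(features, labels, split = 0.8, folds = 5,
                            seed, n_boot = 2000) {
  if (missing(seed)) stop("seed is mandatory")
  features <- as.matrix(features)
  labels <- as.character(labels)
  lv <- sort(unique(labels))
  if (length(lv) != 2L) stop("labels must have exactly two levels")
  positive <- lv[2L]
  y <- as.integer(labels == positive)

  withr::with_seed(seed, {
    idx_train <- stratified_sample(y, split)
    if (length(unique(y[idx_train])) < 2L ||
        length(unique(y[-idx_train])) < 2L)
      stop("a class is absent from the train or validation part")

    df <- as.data.frame(features)
    fit <- suppressWarnings(
      glm(y ~ ., data = cbind(y = y[idx_train], df[idx_train, , drop = FALSE]),
          family = binomial()))
    # complete separation drives the deviance to ~0 without formally
    # converging; that is a legitimate (perfectly separable) fit
    if (!fit$converged && fit$deviance > 1e-4)
      stop("logistic model did not converge (deviance ", round(fit$deviance, 3),
           " after ", fit$iter, " iterations)")

    # out-of-fold probabilities on the training part
    fold_id <- stratified_folds(y[idx_train], folds)
    oof <- numeric(length(idx_train))
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      m <- suppressWarnings(
        glm(y ~ ., family = binomial(),
            data = cbind(y = y[idx_train][tr],
                         df[idx_train[tr], , drop = FALSE])))
      oof[!tr] <- suppressWarnings(
        predict(m, newdata = df[idx_train[!tr], , drop = FALSE],
                type = "response"))
    }
    cand <- sort(unique(c(oof, 1)))
    ba <- vapply(cand, function(t)
      balanced_accuracy(ifelse(oof >= t, positive, lv[1L]),
                        labels[idx_train]),
      numeric(1))
    threshold <- max(cand[ba == max(ba)])

    prob_train <- suppressWarnings(
      predict(fit, newdata = df[idx_train, , drop = FALSE], type = "response"))
    prob_val <- suppressWarnings(
      predict(fit, newdata = df[-idx_train, , drop = FALSE], type = "response"))
    call_of <- function(p) ifelse(p >= threshold, positive, lv[1L])
    ba_train <- balanced_accuracy(call_of(prob_train), labels[idx_train])
    ba_val <- balanced_accuracy(call_of(prob_val), labels[-idx_train])

    roc <- roc_threshold(prob_train, y[idx_train] == 1L, "ge")
    boot <- replicate(n_boot, {
      i <- sample.int(length(prob_train), replace = TRUE)
      if (length(unique(y[idx_train][i])) < 2L) NA_real_
      else roc_threshold(prob_train[i], y[idx_train][i] == 1L, "ge")$auroc
    })
    ci <- quantile(boot, c(0.025, 0.975), na.rm = TRUE, names = FALSE)

    structure(list(
      coefficients = coef(fit), threshold = threshold,
      positive_class = positive, negative_class = lv[1L],
      feature_names = colnames(features),
      metrics = list(balanced_accuracy_train = ba_train,
                     balanced_accuracy_validation = ba_val,
                     auroc_train = roc$auroc, auroc_ci = ci),
      roc = roc$sweep,
      train_idx = idx_train), class = "mva_step1")
  })
}

stratified_sample <- function(y, frac) {
  sort(unlist(lapply(unique(y), function(cl) {
    idx <- which(y == cl)
    sample(idx, round(frac * length(idx)))
  }), use.names = FALSE))
}

stratified_folds <- function(y, k) {
  id <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    id[idx] <- rep_len(seq_len(k), length(idx))
  }
  id
}

#' Predict periodontal status with a fitted step-1 model
#'
#' @param object `mva_step1` model.
#' @param features subjects x features matrix with the model's feature
#'   columns.
#' @param ... unused.
#' @return character vector of class calls.
#' @export
predict.mva_step1 <- function(object, features, ...) {
  x <- as.matrix(features)[, object$feature_names, drop = FALSE]
  eta <- object$coefficients[1L] +
    x %*% object$coefficients[object$feature_names]
  ifelse(plogis(as.numeric(eta)) >= object$threshold,
         object$positive_class, object$negative_class)
}

#' Fit step-2 per-stratum ROC rules for ACS vs no-CAD
#'
#' Within each periodontal stratum, the designated epitope marker(s) get
#' a Youden-optimal threshold for separating ACS from no-CAD subjects;
#' "value >= threshold" calls the CAD group with the higher marker mean
#' in that stratum.
#'
#' @param features subjects x epitopes matrix (rownames = subject ids).
#' @param subjects subject metadata data.frame.
#' @param markers named list, periodontal group -> character vector of
#'   epitope features; the default mirrors the biomarker scheme this
#'   package models (C in H, A in G, A and E in P).
#' @return named list per stratum of rules: `feature`, `ge_calls` (the
#'   CAD group called when the marker is at or above threshold),
#'   `threshold`, `sensitivity`, `specificity`, `auroc`.
#' @export
fit_step2_rules <- function(features, subjects,
                            markers = list(H = "C", G = "A",
                                           P = c("A", "E"))) {
  rules <- list()
  for (g in names(markers)) {
    ids <- subjects$subject_id[subjects$perio_group == g &
                                 subjects$cad_group %in% c("ACS", "noCAD")]
    cad <- subjects$cad_group[match(ids, subjects$subject_id)]
    if (length(unique(cad)) < 2L)
      stop("stratum ", g, " lacks both ACS and no-CAD subjects")
    rules[[g]] <- lapply(markers[[g]], function(feat) {
      v <- features[ids, feat]
      hi <- if (mean(v[cad == "ACS"]) >= mean(v[cad == "noCAD"]))
        "ACS" else "noCAD"
      rt <- roc_threshold(v, cad == hi, "ge")
      list(feature = feat, ge_calls = hi, threshold = rt$threshold,
           sensitivity = rt$sensitivity, specificity = rt$specificity,
           auroc = rt$auroc)
    })
  }
  rules
}

#' Fit the full two-step biomarker model
#'
#' Step 1: logistic classification of periodontitis (P) vs periodontally
#' healthy (H) from epitopes A, B, C. Step 2: per-periodontal-stratum
#' single-marker ROC thresholds separating ACS from no-CAD (C in H, A in
#' G, A and E in P).
#'
#' @param features subjects x epitopes abundance matrix (columns at
#'   least A, B, C, E), typically cap-normalised.
#' @param subjects subject metadata data.frame.
#' @param seed integer seed.
#' @param step1_features features for step 1 (A, B, C).
#' @param markers step-2 marker scheme (see [fit_step2_rules()]).
#' @param combine how multiple step-2 rules in one stratum combine:
#'   `"or"` (default; the no-CAD-indicating call wins if any marker
#'   exceeds its threshold) or `"and"`.
#' @param ... passed to [fit_step1_model()].
#' @return object of class `mva_two_step`.
#' @export
fit_two_step_model <- function(features, subjects, seed,
                               step1_features = c("A", "B", "C"),
                               markers = list(H = "C", G = "A",
                                              P = c("A", "E")),
                               combine = c("or", "and"), ...) {
  combine <- match.arg(combine)
  ph <- subjects$subject_id[subjects$perio_group %in% c("P", "H")]
  step1 <- fit_step1_model(
    features[ph, step1_features, drop = FALSE],
    subjects$perio_group[match(ph, subjects$subject_id)],
    seed = seed, ...)
  step2 <- fit_step2_rules(features, subjects, markers)
  structure(list(step1 = step1, step2 = step2, combine = combine),
            class = "mva_two_step")
}

#' Classify subjects with a fitted two-step model
#'
#' Step 1 assigns periodontal status (P vs H) from the logistic model;
#' step 2 applies the assigned stratum's marker rule(s) to call ACS vs
#' no-CAD. Where a stratum has several rules they are combined by the
#' model's `combine` logic over the per-rule calls.
#'
#' @param model `mva_two_step`.
#' @param features subjects x epitopes matrix (rownames = subject ids).
#' @return data.frame: `subject_id`, `perio_call`, `cad_call`.
#' @export
two_step_classify <- function(model, features) {
  stopifnot(inherits(model, "mva_two_step"))
  features <- as.matrix(features)
  perio <- predict(model$step1, features)
  cad <- character(nrow(features))
  for (i in seq_len(nrow(features))) {
    g <- perio[i]
    rules <- model$step2[[g]]
    if (is.null(rules)) stop("no step-2 rule for stratum '", g, "'")
    calls <- vapply(rules, function(r) {
      if (features[i, r$feature] >= r$threshold) r$ge_calls
      else setdiff(c("ACS", "noCAD"), r$ge_calls)
    }, character(1))
    cad[i] <- if (length(calls) == 1L) calls
    else {
      target <- rules[[1L]]$ge_calls  # shared by design within a stratum
      hitting <- calls == target
      if ((model$combine == "or" && any(hitting)) ||
          (model$combine == "and" && all(hitting))) target
      else setdiff(c("ACS", "noCAD"), target)
    }
  }
  data.frame(subject_id = rownames(features), perio_call = unname(perio),
             cad_call = cad, stringsAsFactors = FALSE)
}
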