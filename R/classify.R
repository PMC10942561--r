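#' Classifier configuration
#'
#' Configuration for the 4-layer MLP protocol: min-max normalised features,
#' fully connected stack `FC-BN-LeakyReLU` (x3) followed by `FC-sigmoid`,
#' binary cross-entropy, ADAM with the learning rate dropping permanently from
#' `lr_initial` to `lr_reduced` at the end of the first epoch whose training
#' accuracy reaches `lr_switch_train_acc`, trained for exactly `epochs`
#' epochs, evaluated with `n_folds`-fold cross-validation.
#'
#' @param feature_set ordered feature names fed to the network; the default is
#'   the nine parameters that discriminate the child groups (all magnitude and
#'   temporal parameters plus Type-2 movement units).
#' @param hidden_sizes three hidden-layer widths.
#' @param leaky_slope negative-side slope of the leaky ReLU.
#' @param epochs training epochs.
#' @param lr_initial,lr_reduced,lr_switch_train_acc learning-rate schedule.
#' @param n_folds cross-validation folds.
#' @param batch_size minibatch size (capped at the training-set size).
#' @param seed RNG seed for weight initialisation, shuffling and fold
#'   assignment.
#' @param normalization_scope `"whole_dataset"` min-max normalises over all
#'   rows before splitting (mirrors the protocol this package follows);
#'   `"per_fold_train"` computes the ranges on each fold's training rows only,
#'   avoiding validation leakage.
#' @param repeats shuffles averaged per feature in permutation importance.
#' @param adam_beta1,adam_beta2,adam_eps ADAM moments and epsilon.
#' @param bn_eps,bn_momentum batch-norm epsilon and running-stat momentum.
#' @return An object of class `classifier_config`.
#' @export
classifier_config <- function(feature_set = c("reaction_time", "total_distance",
                                              "avg_velocity", "max_velocity",
                                              "time_to_peak_velocity",
                                              "avg_acceleration",
                                              "max_acceleration",
                                              "time_to_peak_acceleration",
                                              "mu_type2_rms"),
                              hidden_sizes = c(64L, 32L, 16L),
                              leaky_slope = 0.01, epochs = 200L,
                              lr_initial = 1e-5, lr_reduced = 1e-6,
                              lr_switch_train_acc = 0.95, n_folds = 10L,
                              batch_size = 16L, seed = 1L,
                              normalization_scope = c("whole_dataset",
                                                      "per_fold_train"),
                              repeats = 10L,
                              adam_beta1 = 0.9, adam_beta2 = 0.999,
                              adam_eps = 1e-8, bn_eps = 1e-5,
                              bn_momentum = 0.1) {
  normalization_scope <- match.arg(normalization_scope)
  if (epochs < 1L) stop("epochs must be >= 1", call. = FALSE)
  if (lr_reduced <= 0 || lr_reduced > lr_initial)
    stop("require 0 < lr_reduced <= lr_initial", call. = FALSE)
  if (n_folds < 2L) stop("n_folds must be >= 2", call. = FALSE)
  if (length(hidden_sizes) != 3L) stop("need three hidden sizes", call. = FALSE)
  structure(list(feature_set = feature_set,
                 hidden_sizes = as.integer(hidden_sizes),
                 leaky_slope = leaky_slope, epochs = as.integer(epochs),
                 lr_initial = lr_initial, lr_reduced = lr_reduced,
                 lr_switch_train_acc = lr_switch_train_acc,
                 n_folds = as.integer(n_folds),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 normalization_scope = normalization_scope,
                 repeats = as.integer(repeats),
                 adam_beta1 = adam_beta1, adam_beta2 = adam_beta2,
                 adam_eps = adam_eps, bn_eps = bn_eps,
                 bn_momentum = bn_momentum),
            class = "classifier_config")
}

#' Min-max normalisation
#'
#' Affine rescaling of each feature to `[0, 1]` using its observed minimum and
#' maximum. Constant features map to 0.5 and are flagged.
#'
#' @param x numeric matrix or data.frame (rows: samples).
#' @param ranges optional data.frame with `feature`, `min`, `max` columns from
#'   a previous call; when given, those ranges are re-applied (values outside
#'   them map outside `[0, 1]`).
#' @return A list with the normalised matrix `x`, the `ranges` data.frame and
#'   a logical `constant` flag per feature.
#' @examples
#' minmax_normalize(matrix(c(-1, 0, 3), ncol = 1))$x  # 0, 0.25, 1
#' @export
minmax_normalize <- function(x, ranges = NULL) {
  x <- as.matrix(x)
  if (any(!is.finite(x))) stop("features must be finite", call. = FALSE)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  if (is.null(ranges)) {
    ranges <- data.frame(feature = colnames(x),
                         min = apply(x, 2L, min), max = apply(x, 2L, max))
    rownames(ranges) <- NULL
  } else {
    ranges <- ranges[match(colnames(x), ranges$feature), , drop = FALSE]
    if (any(is.na(ranges$feature)))
      stop("ranges do not cover all features", call. = FALSE)
  }
  span <- ranges$max - ranges$min
  constant <- span == 0
  out <- sweep(x, 2L, ranges$min)
  out <- sweep(out, 2L, ifelse(constant, 1, span), "/")
  if (any(constant)) {
    out[, constant] <- 0.5
    warning("constant feature(s) mapped to 0.5: ",
            paste(colnames(x)[constant], collapse = ", "), call. = FALSE)
  }
  list(x = out, ranges = ranges, constant = stats::setNames(constant, colnames(x)))
}

# He-style initial weights; the output layer starts near zero so the initial
# logits are uninformative and training determines the decision direction.
mlp_init <- function(n_in, hidden) {
  sizes <- c(n_in, hidden, 1L)
  params <- list()
  for (l in seq_len(4L)) {
    sd <- sqrt(2 / sizes[l])
    if (l == 4L) sd <- 1e-3
    params[[paste0("W", l)]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1L],
                                                    0, sd),
                                       sizes[l], sizes[l + 1L])
    params[[paste0("b", l)]] <- numeric(sizes[l + 1L])
  }
  for (l in seq_len(3L)) {
    params[[paste0("gamma", l)]] <- rep(1, sizes[l + 1L])
    params[[paste0("beta", l)]] <- numeric(sizes[l + 1L])
    params[[paste0("rmean", l)]] <- numeric(sizes[l + 1L])
    params[[paste0("rvar", l)]] <- rep(1, sizes[l + 1L])
  }
  params
}

as_feature_matrix <- function(table, feature_set) {
  missing <- setdiff(feature_set, colnames(table))
  if (length(missing) > 0L)
    stop("feature table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  m <- as.matrix(as.data.frame(table)[, feature_set, drop = FALSE])
  storage.mode(m) <- "double"
  m
}

check_binary <- function(labels) {
  if (!all(labels %in% c(0, 1)))
    stop("labels must be binary 0/1", call. = FALSE)
  as.numeric(labels)
}

#' Train the MLP
#'
#' Trains the four-layer batch-normalised MLP for exactly `cfg$epochs` epochs
#' and records the epoch with the lowest validation loss together with its
#' parameters.
#'
#' @param train_table samples x features (matrix or data.frame) holding the
#'   columns of `cfg$feature_set`; expected already normalised.
#' @param labels binary 0/1 vector for the training rows.
#' @param cfg a [classifier_config].
#' @param validation_table,validation_labels held-out rows scored each epoch.
#' @return An object of class `reachkin_mlp`: final and best parameter sets,
#'   `best_epoch`, `best_val_loss`, `lr_switched` and a per-epoch `history`
#'   data.frame (train accuracy, validation loss, learning rate).
#' @export
train_mlp <- function(train_table, labels, cfg = classifier_config(),
                      validation_table, validation_labels) {
  X <- as_feature_matrix(train_table, cfg$feature_set)
  Xv <- as_feature_matrix(validation_table, cfg$feature_set)
  y <- check_binary(labels)
  yv <- check_binary(validation_labels)
  if (nrow(X) != length(y) || nrow(Xv) != length(yv))
    stop("labels must align with table rows", call. = FALSE)
  set.seed(cfg$seed)
  params <- mlp_init(ncol(X), cfg$hidden_sizes)
  order <- t(vapply(seq_len(cfg$epochs), function(i) sample.int(nrow(X)),
                    integer(nrow(X))))
  fit <- mlp_train_cpp(params, X, y, Xv, yv, order, unclass(cfg))
  structure(list(final = fit$final, best = fit$best,
                 best_epoch = fit$best_epoch,
                 best_val_loss = fit$best_val_loss,
                 lr_switched = fit$lr_switched,
                 history = data.frame(epoch = seq_len(cfg$epochs),
                                      train_acc = fit$history$train_acc,
                                      val_loss = fit$history$val_loss,
                                      lr = fit$history$lr),
                 cfg = cfg),
            class = "reachkin_mlp")
}

#' Predict class probabilities from a trained MLP
#'
#' @param object a `reachkin_mlp` from [train_mlp()].
#' @param newdata samples x features with the model's feature set.
#' @param use_best use the parameters from the best validation-loss epoch
#'   (default) rather than the final epoch.
#' @param ... unused.
#' @return Numeric vector of sigmoid outputs in `(0, 1)`.
#' @export
predict.reachkin_mlp <- function(object, newdata, use_best = TRUE, ...) {
  X <- as_feature_matrix(newdata, object$cfg$feature_set)
  params <- if (use_best) object$best else object$final
  as.numeric(mlp_eval_cpp(params, X, object$cfg$leaky_slope,
                          object$cfg$bn_eps))
}

#' Binary cross-entropy of a trained MLP on a dataset
#'
#' @inheritParams predict.reachkin_mlp
#' @param labels binary 0/1 vector.
#' @return Mean binary cross-entropy.
#' @export
mlp_loss <- function(object, newdata, labels, use_best = TRUE) {
  p <- pmin(pmax(predict(object, newdata, use_best = use_best), 1e-12),
            1 - 1e-12)
  y <- check_binary(labels)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# Stratified fold assignment: within each class (or each subject stratum),
# indices are shuffled and dealt round-robin so every fold keeps the class
# balance as far as counts allow.
make_folds <- function(y, n_folds, groups = NULL) {
  fold <- integer(length(y))
  if (is.null(groups)) {
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  } else {
    for (cls in unique(y)) {
      subj <- unique(groups[y == cls])
      subj <- sample(subj)
      sf <- rep_len(seq_len(n_folds), length(subj))
      for (k in seq_along(subj)) fold[groups == subj[k]] <- sf[k]
    }
  }
  fold
}

#' k-fold cross-validated classification
#'
#' Splits the samples into `cfg$n_folds` stratified folds, trains one model on
#' the remainder for each fold (the held-out fold doubles as the validation
#' set for loss tracking), and scores held-out accuracy at the 0.5 sigmoid
#' threshold.
#'
#' @param table samples x features holding `cfg$feature_set` columns, raw
#'   scale (normalisation is applied according to
#'   `cfg$normalization_scope`).
#' @param labels binary 0/1 vector.
#' @param cfg a [classifier_config].
#' @param grouping optional subject identifiers; when given, folds never split
#'   a subject.
#' @return An object of class `reachkin_cv`: per-fold accuracies and best
#'   validation losses, their mean, pooled confusion counts, fold assignment,
#'   the per-fold models' best epochs and (under `per_fold_train`) the
#'   normalisation ranges each fold's training split produced.
#' @export
cross_validate <- function(table, labels, cfg = classifier_config(),
                           grouping = NULL) {
  y <- check_binary(labels)
  n <- length(y)
  if (n < cfg$n_folds)
    stop("need at least n_folds samples", call. = FALSE)
  if (min(sum(y == 0), sum(y == 1)) < 2L)
    stop("each class needs at least two samples", call. = FALSE)
  X <- as_feature_matrix(table, cfg$feature_set)
  set.seed(cfg$seed)
  fold <- make_folds(y, cfg$n_folds, grouping)
  if (cfg$normalization_scope == "whole_dataset")
    Xn <- minmax_normalize(X)$x
  acc <- numeric(cfg$n_folds)
  best_loss <- numeric(cfg$n_folds)
  best_epoch <- integer(cfg$n_folds)
  fold_ranges <- vector("list", cfg$n_folds)
  conf <- matrix(0L, 2L, 2L,
                 dimnames = list(truth = c("0", "1"), pred = c("0", "1")))
  for (k in seq_len(cfg$n_folds)) {
    tr <- fold != k
    te <- fold == k
    if (sum(te) == 0L) {
      acc[k] <- NA_real_
      best_loss[k] <- NA_real_
      next
    }
    if (length(unique(y[tr])) < 2L)
      stop("a training split lost a class; use more data or fewer folds",
           call. = FALSE)
    if (cfg$normalization_scope == "whole_dataset") {
      Xtr <- Xn[tr, , drop = FALSE]
      Xte <- Xn[te, , drop = FALSE]
    } else {
      nm <- minmax_normalize(X[tr, , drop = FALSE])
      Xtr <- nm$x
      Xte <- minmax_normalize(X[te, , drop = FALSE], ranges = nm$ranges)$x
      fold_ranges[[k]] <- nm$ranges
    }
    fold_cfg <- cfg
    fold_cfg$seed <- cfg$seed + k
    fit <- train_mlp(Xtr, y[tr], fold_cfg, Xte, y[te])
    p <- predict(fit, Xte, use_best = TRUE)
    pred <- as.integer(p > 0.5)
    acc[k] <- mean(pred == y[te])
    best_loss[k] <- fit$best_val_loss
    best_epoch[k] <- fit$best_epoch
    for (i in seq_along(pred))
      conf[as.character(y[te][i]), as.character(pred[i])] <-
        conf[as.character(y[te][i]), as.character(pred[i])] + 1L
  }
  used <- !is.na(acc)
  structure(list(fold_accuracy = acc, mean_accuracy = mean(acc[used]),
                 fold_best_val_loss = best_loss, best_epoch = best_epoch,
                 confusion = conf, fold = fold, fold_ranges = fold_ranges,
                 cfg = cfg),
            class = "reachkin_cv")
}

#' Permutation feature importance
#'
#' For each feature, shuffles only that column of the validation table,
#' re-evaluates the trained model (at its best validation-loss parameters)
#' and reports the loss increase `permuted loss - baseline loss`, averaged
#' over `repeats` seeded shuffles. Features are ranked by descending
#' importance.
#'
#' @param model a `reachkin_mlp` from [train_mlp()].
#' @param validation_table,labels the held-out data the baseline loss is
#'   measured on.
#' @param repeats shuffles averaged per feature.
#' @param seed RNG seed for the shuffles.
#' @return A data.frame with `feature`, `importance`, `rank` (1 = most
#'   important), plus the baseline loss as attribute `"baseline_loss"`.
#' @export
permutation_importance <- function(model, validation_table, labels,
                                   repeats = model$cfg$repeats, seed = 1L) {
  stopifnot(inherits(model, "reachkin_mlp"), repeats >= 1L)
  X <- as_feature_matrix(validation_table, model$cfg$feature_set)
  y <- check_binary(labels)
  base <- mlp_loss(model, X, y)
  set.seed(seed)
  imp <- vapply(seq_len(ncol(X)), function(j) {
    losses <- vapply(seq_len(repeats), function(r) {
      Xp <- X
      Xp[, j] <- Xp[sample.int(nrow(X)), j]
      mlp_loss(model, Xp, y)
    }, numeric(1L))
    mean(losses) - base
  }, numeric(1L))
  out <- data.frame(feature = model$cfg$feature_set, importance = imp)
  out$rank <- rank(-out$importance, ties.method = "first")
  attr(out, "baseline_loss") <- base
  out
}
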