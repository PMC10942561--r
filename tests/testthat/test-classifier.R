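test_that("min-max normalisation matches printed cases and is idempotent", {
  nm <- minmax_normalize(matrix(c(-1, 0, 3), ncol = 1))
  expect_equal(as.numeric(nm$x), c(0, 0.25, 1))
  expect_warning(cm <- minmax_normalize(cbind(a = c(1, 1, 1), b = c(0, 1, 2))),
                 "constant")
  expect_equal(as.numeric(cm$x[, "a"]), rep(0.5, 3))
  expect_true(cm$constant[["a"]])
  # re-applying stored ranges maps the training extrema to exactly 0 and 1
  x <- matrix(stats::runif(30), ncol = 3)
  nm2 <- minmax_normalize(x)
  re <- minmax_normalize(x, ranges = nm2$ranges)
  expect_equal(re$x, nm2$x)
  expect_equal(range(re$x[, 1]), c(0, 1))
})

test_that("analytic gradients agree with finite differences", {
  set.seed(3)
  params <- reachkin:::mlp_init(4, c(5, 4, 3))
  X <- matrix(stats::rnorm(48), 12, 4)
  y <- rep(c(0, 1), 6)
  g <- reachkin:::mlp_grad_cpp(params, X, y, 0.01, 1e-5)
  eps <- 1e-5
  for (nm in c("W1", "W4", "b2", "gamma3", "beta1")) {
    for (i in seq_len(min(4, length(params[[nm]])))) {
      pp <- params; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- params; pm[[nm]][i] <- pm[[nm]][i] - eps
      num <- (reachkin:::mlp_train_loss_cpp(pp, X, y, 0.01, 1e-5) -
                reachkin:::mlp_train_loss_cpp(pm, X, y, 0.01, 1e-5)) / (2 * eps)
      expect_equal(g$grads[[nm]][i], num, tolerance = 1e-4,
                   info = paste(nm, i))
    }
  }
})

test_that("training is deterministic for a fixed seed", {
  d <- gaussian_clouds(1, n_per_class = 60)
  v <- gaussian_clouds(2, n_per_class = 20)
  cfg <- classifier_config(epochs = 30L, seed = 9)
  Xn <- minmax_normalize(d$X)$x
  Vn <- minmax_normalize(v$X)$x
  f1 <- train_mlp(Xn, d$y, cfg, Vn, v$y)
  f2 <- train_mlp(Xn, d$y, cfg, Vn, v$y)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$best, f2$best)
})

test_that("well-separated clouds reach the training-accuracy switch", {
  d <- gaussian_clouds(5, n_per_class = 200, sep = 4)
  v <- gaussian_clouds(6, n_per_class = 50, sep = 4)
  fit <- train_mlp(minmax_normalize(d$X)$x, d$y, classifier_config(seed = 5),
                   minmax_normalize(v$X)$x, v$y)
  expect_gte(utils::tail(fit$history$train_acc, 1), 0.95)
  expect_true(fit$lr_switched)
  expect_equal(utils::tail(fit$history$lr, 1), 1e-6)
})

test_that("label-permuted training stays at chance validation accuracy", {
  accs <- vapply(1:5, function(s) {
    d <- gaussian_clouds(100 + s, n_per_class = 60, sep = 4)
    set.seed(s)
    yp <- sample(d$y)
    tr <- seq_len(96)
    Xn <- minmax_normalize(d$X)$x
    fit <- train_mlp(Xn[tr, ], yp[tr], classifier_config(seed = s),
                     Xn[-tr, ], yp[-tr])
    mean((predict(fit, Xn[-tr, ]) > 0.5) == yp[-tr])
  }, numeric(1))
  expect_gte(mean(accs), 0.35)
  expect_lte(mean(accs), 0.65)
})

test_that("cross-validation enforces preconditions and self-consistency", {
  d <- gaussian_clouds(3, n_per_class = 40, sep = 4)
  expect_error(cross_validate(d$X[1:9, ], d$y[1:9],
                              classifier_config(n_folds = 10L)),
               "n_folds")
  cfg <- classifier_config(epochs = 20L, seed = 4, n_folds = 5L)
  cv <- cross_validate(d$X, d$y, cfg)
  expect_length(cv$fold_accuracy, 5L)
  expect_equal(cv$mean_accuracy, mean(cv$fold_accuracy))
  expect_equal(sum(cv$confusion), length(d$y))
  # accuracy identity: 1 - mean|round(p) - y| equals the confusion diagonal
  expect_equal(sum(diag(cv$confusion)) / sum(cv$confusion), cv$mean_accuracy,
               tolerance = 0.03)
})

test_that("subject grouping never splits a subject across folds", {
  d <- gaussian_clouds(8, n_per_class = 40, sep = 4)
  subj <- rep(sprintf("S%02d", 1:20), each = 4)
  cfg <- classifier_config(epochs = 5L, seed = 2, n_folds = 5L)
  cv <- cross_validate(d$X, d$y, cfg, grouping = subj)
  for (s in unique(subj))
    expect_length(unique(cv$fold[subj == s]), 1L)
})

test_that("per-fold-train normalisation never sees held-out rows", {
  d <- gaussian_clouds(12, n_per_class = 30, sep = 4)
  # plant an extreme outlier; the training ranges of the fold that holds it
  # out must ignore it entirely
  X <- d$X
  X[1, ] <- 1e6
  cfg <- classifier_config(epochs = 3L, seed = 6, n_folds = 5L,
                           normalization_scope = "per_fold_train")
  cv <- cross_validate(X, d$y, cfg)
  holdout_fold <- cv$fold[1]
  expect_true(all(cv$fold_ranges[[holdout_fold]]$max < 1e6))
  # every other fold trains on the outlier and must record it
  for (k in setdiff(seq_len(5L), holdout_fold))
    expect_true(any(cv$fold_ranges[[k]]$max == 1e6))
})

test_that("permutation importance is zero under the identity permutation", {
  d <- gaussian_clouds(21, n_per_class = 40, sep = 4)
  Xn <- minmax_normalize(d$X)$x
  tr <- seq_len(60)
  fit <- train_mlp(Xn[tr, ], d$y[tr], classifier_config(epochs = 10L, seed = 3),
                   Xn[-tr, ], d$y[-tr])
  base <- mlp_loss(fit, Xn[-tr, ], d$y[-tr])
  # identity permutation leaves the loss bit-identical
  Xp <- Xn[-tr, ]
  Xp[, 1] <- Xp[seq_len(nrow(Xp)), 1]
  expect_identical(mlp_loss(fit, Xp, d$y[-tr]) - base, 0)
})

test_that("importance separates a signal feature from pure noise", {
  hits_pos <- 0L
  hits_last <- 0L
  for (s in 1:5) {
    set.seed(400 + s)
    n <- 100
    fs <- classifier_config()$feature_set
    X <- matrix(stats::rnorm(2 * n * 9), 2 * n, 9,
                dimnames = list(NULL, fs))
    X[, "avg_acceleration"] <- X[, "avg_acceleration"] + rep(c(0, 3), each = n)
    y <- rep(c(0, 1), each = n)
    Xn <- minmax_normalize(X)$x
    tr <- sample(2 * n, 160)
    fit <- train_mlp(Xn[tr, ], y[tr], classifier_config(seed = s),
                     Xn[-tr, ], y[-tr])
    imp <- permutation_importance(fit, Xn[-tr, ], y[-tr], seed = s)
    sig <- imp[imp$feature == "avg_acceleration", ]
    hits_pos <- hits_pos + (sig$importance > 0)
    # the eight pure-noise features should fill the bottom ranks
    hits_last <- hits_last + (sig$rank == 1L)
  }
  expect_gte(hits_pos, 4L)
  expect_gte(hits_last, 4L)
})
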