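#' Z-score standardization
#'
#' Column-wise `(X - mu) / sigma` with the population standard deviation
#' (divisor `n`, not `n - 1`). Columns with zero variance cannot be
#' scaled; they are returned as all-zeros and flagged.
#'
#' @param x numeric matrix or data frame, n >= 2 rows.
#' @return An object of class `standardized_matrix`: `values` (the
#'   standardized matrix), `mean` and `sd` (per-column statistics),
#'   `constant` (logical flag per column).
#' @export
#' @examples
#' zscore(cbind(a = c(1, 2, 3)))$values  # -1.2247, 0, 1.2247
zscore <- function(x) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  n <- nrow(x)
  if (n < 2) stop("zscore needs at least 2 rows", call. = FALSE)
  mu <- colMeans(x)
  sigma <- sqrt(colMeans(sweep(x, 2, mu)^2))  # population sd
  constant <- sigma == 0
  sigma_safe <- ifelse(constant, 1, sigma)
  vals <- sweep(sweep(x, 2, mu), 2, sigma_safe, `/`)
  vals[, constant] <- 0
  structure(list(values = vals, mean = mu, sd = sigma, constant = constant),
            class = "standardized_matrix")
}

#' Pearson correlation matrix
#'
#' Symmetric p x p matrix of pairwise Pearson coefficients with unit
#' diagonal. Entries involving a zero-variance column are undefined; they
#' are set to 0 and the columns flagged in the `"constant"` attribute.
#'
#' @param x numeric matrix or data frame, n >= 3 rows.
#' @return p x p correlation matrix.
#' @export
pearson_matrix <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 3) stop("pearson_matrix needs at least 3 rows", call. = FALSE)
  sds <- apply(x, 2, stats::sd)
  constant <- sds == 0
  r <- suppressWarnings(stats::cor(x))
  r[is.na(r)] <- 0
  diag(r) <- 1
  attr(r, "constant") <- constant
  r
}

#' Agreement metrics between manual and system measurements
#'
#' Mean absolute percentage error
#' `MAPE = 100/n * sum(|x_i - y_i| / x_i)`, root mean square error
#' `RMSE = sqrt(sum((x_i - y_i)^2) / n)` and the determination coefficient
#' `R^2 = 1 - sum((x_i - y_i)^2) / sum((x_i - ybar)^2)`, where `x` are the
#' manual reference values, `y` the system values and `ybar` the mean of
#' the system values (note the unusual centring: the reference is compared
#' against the system mean).
#'
#' @param x_manual reference measurements (all non-zero; MAPE is undefined
#'   otherwise).
#' @param y_system system measurements, same length.
#' @return A list with `mape_pct`, `rmse`, `r2` (NA with a flag when the
#'   denominator degenerates), `n`.
#' @export
#' @examples
#' error_metrics(c(10, 20), c(11, 19))  # MAPE 7.5, RMSE 1, R2 0.96
error_metrics <- function(x_manual, y_system) {
  x <- as.numeric(x_manual)
  y <- as.numeric(y_system)
  if (length(x) != length(y)) stop("inputs must have equal length", call. = FALSE)
  n <- length(x)
  if (n < 1) stop("need at least one measurement", call. = FALSE)
  if (any(x == 0)) stop("MAPE undefined: reference contains zero values", call. = FALSE)
  mape <- mean(abs(x - y) / abs(x)) * 100
  rmse <- sqrt(sum((x - y)^2) / n)
  denom <- sum((x - mean(y))^2)
  if (denom == 0) {
    r2 <- NA_real_
    degenerate <- TRUE
  } else {
    r2 <- 1 - sum((x - y)^2) / denom
    degenerate <- FALSE
  }
  list(mape_pct = mape, rmse = rmse, r2 = r2, r2_degenerate = degenerate, n = n)
}

#' Tenfold cross-validated classification
#'
#' The recognition protocol: the samples are shuffled with the given seed
#' and split into 10 folds (stratified by class unless `stratify = FALSE`),
#' each fold serving once as the test set for a model trained on the other
#' nine; the reported accuracy is the mean of the 10 fold accuracies.
#' Precision, recall and F1 are macro-averaged over classes from the
#' pooled out-of-fold predictions. Six back ends are available with the
#' protocol's fixed hyperparameters:
#' \describe{
#'   \item{cart}{decision tree (entropy impurity, depth 4).}
#'   \item{rf}{random forest (24 trees, depth 2, Gini).}
#'   \item{svm}{support vector machine (Gaussian kernel, cost 6).}
#'   \item{nb}{Gaussian Naive Bayes.}
#'   \item{bp}{back-propagation network (hidden layers 100 and 50, 2000
#'     iterations, learning rate 0.0003237).}
#'   \item{xgboost}{gradient boosting (20 rounds, depth 5, learning
#'     rate 0.3, logistic/softmax loss).}
#' }
#' For `cart`, `rf` and `xgboost` a model fitted on the full data set also
#' yields normalized feature-importance weights.
#'
#' @param traits a [zscore()] result, or a numeric matrix taken as already
#'   standardized.
#' @param labels class labels (factor or coercible), length n.
#' @param method one of `"cart"`, `"rf"`, `"svm"`, `"nb"`, `"bp"`,
#'   `"xgboost"`.
#' @param seed integer seed controlling the shuffle (and any back-end
#'   randomness).
#' @param stratify stratify folds by class (default TRUE).
#' @param folds number of folds (default 10).
#' @return An object of class `classification_report`: `method`,
#'   `fold_accuracies` (percent), `accuracy_pct` (their mean),
#'   `precision_pct`, `recall`, `f1`, `confusion`, `importance` (data
#'   frame or NULL), `folds`, `n`.
#' @export
crossval_classify <- function(traits, labels,
                              method = c("cart", "rf", "svm", "nb", "bp", "xgboost"),
                              seed = 1, stratify = TRUE, folds = 10) {
  method <- match.arg(method)
  x <- if (inherits(traits, "standardized_matrix")) traits$values else as.matrix(traits)
  if (is.null(colnames(x))) colnames(x) <- paste0("t", seq_len(ncol(x)))
  y <- factor(labels)
  n <- nrow(x)
  if (length(y) != n) stop("labels must match the trait rows", call. = FALSE)
  if (nlevels(y) < 2) stop("need at least 2 classes", call. = FALSE)
  if (n < 2 * folds) stop(sprintf("need at least %d samples for %d folds",
                                  2 * folds, folds), call. = FALSE)
  if (min(table(y)) < folds && stratify) {
    stop(sprintf("each class needs at least %d members for stratified folds",
                 folds), call. = FALSE)
  }
  with_local_seed(seed, {
    fold_id <- integer(n)
    if (stratify) {
      for (lv in levels(y)) {
        idx <- sample(which(y == lv))
        fold_id[idx] <- rep_len(seq_len(folds), length(idx))
      }
    } else {
      fold_id[sample.int(n)] <- rep_len(seq_len(folds), n)
    }
    pred <- factor(rep(levels(y)[1], n), levels = levels(y))
    fold_acc <- numeric(folds)
    for (fd in seq_len(folds)) {
      te <- which(fold_id == fd)
      tr <- which(fold_id != fd)
      fit <- fit_classifier(method, x[tr, , drop = FALSE], y[tr], seed + fd)
      ph <- predict_classifier(method, fit, x[te, , drop = FALSE], levels(y))
      pred[te] <- ph
      fold_acc[fd] <- mean(ph == y[te]) * 100
    }
    conf <- table(truth = y, predicted = pred)
    pr <- macro_prf(conf)
    importance <- if (method %in% c("cart", "rf", "xgboost")) {
      fit_all <- fit_classifier(method, x, y, seed)
      classifier_importance(method, fit_all, colnames(x))
    } else NULL
    structure(list(method = method, fold_accuracies = fold_acc,
                   accuracy_pct = mean(fold_acc),
                   precision_pct = pr$precision * 100,
                   recall = pr$recall, f1 = pr$f1,
                   confusion = conf, importance = importance,
                   folds = folds, n = n),
              class = "classification_report")
  })
}

macro_prf <- function(conf) {
  tp <- diag(conf)
  fp <- colSums(conf) - tp
  fn <- rowSums(conf) - tp
  prec <- ifelse(tp + fp == 0, 0, tp / (tp + fp))
  rec <- ifelse(tp + fn == 0, 0, tp / (tp + fn))
  f1 <- ifelse(prec + rec == 0, 0, 2 * prec * rec / (prec + rec))
  list(precision = mean(prec), recall = mean(rec), f1 = mean(f1))
}

fit_classifier <- function(method, x, y, seed) {
  df <- data.frame(.label = y, x, check.names = FALSE)
  switch(method,
    cart = rpart::rpart(.label ~ ., df, method = "class",
                        parms = list(split = "information"),
                        control = rpart::rpart.control(maxdepth = 4, cp = 0,
                                                       xval = 0)),
    rf = ranger::ranger(.label ~ ., df, num.trees = 24, max.depth = 2,
                        splitrule = "gini", seed = seed,
                        importance = "impurity", num.threads = 1),
    svm = e1071::svm(.label ~ ., df, kernel = "radial", cost = 6,
                     scale = FALSE),
    nb = e1071::naiveBayes(.label ~ ., df),
    bp = mlp_fit(x, y, hidden = c(100, 50), iters = 2000, lr = 0.0003237,
                 seed = seed),
    xgboost = {
      num_class <- nlevels(y)
      params <- if (num_class == 2) {
        list(objective = "binary:logistic", max_depth = 5, eta = 0.3,
             nthread = 1)
      } else {
        list(objective = "multi:softmax", num_class = num_class,
             max_depth = 5, eta = 0.3, nthread = 1)
      }
      xgboost::xgb.train(params = params,
                         data = xgboost::xgb.DMatrix(x, label = as.integer(y) - 1),
                         nrounds = 20, verbose = 0)
    })
}

predict_classifier <- function(method, fit, x, lev) {
  df <- data.frame(x, check.names = FALSE)
  out <- switch(method,
    cart = {
      pr <- predict(fit, df, type = "class")
      as.character(pr)
    },
    rf = as.character(predict(fit, df, num.threads = 1)$predictions),
    svm = as.character(predict(fit, df)),
    nb = as.character(predict(fit, df)),
    bp = mlp_predict(fit, x),
    xgboost = {
      ph <- predict(fit, xgboost::xgb.DMatrix(x))
      if (length(lev) == 2) lev[1 + (ph > 0.5)] else lev[ph + 1]
    })
  factor(out, levels = lev)
}

classifier_importance <- function(method, fit, feature_names) {
  w <- switch(method,
    cart = {
      vi <- fit$variable.importance
      full <- stats::setNames(numeric(length(feature_names)), feature_names)
      if (!is.null(vi)) full[names(vi)] <- vi
      full
    },
    rf = {
      vi <- ranger::importance(fit)
      vi[vi < 0] <- 0
      full <- stats::setNames(numeric(length(feature_names)), feature_names)
      full[names(vi)] <- vi
      full
    },
    xgboost = {
      imp <- xgboost::xgb.importance(model = fit)
      full <- stats::setNames(numeric(length(feature_names)), feature_names)
      full[imp$Feature] <- imp$Gain
      full
    })
  tot <- sum(w)
  if (tot > 0) w <- w / tot
  ord <- order(-w)
  data.frame(trait = names(w)[ord], weight = unname(w)[ord])
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("<classification_report> %s, %d-fold CV on %d samples\n",
              x$method, x$folds, x$n))
  cat(sprintf("  accuracy %.3f%%  precision %.3f%%  recall %.5f  F1 %.5f\n",
              x$accuracy_pct, x$precision_pct, x$recall, x$f1))
  invisible(x)
}

#' Ranked feature importances of a classification report
#'
#' Importance weights (non-negative, summing to one, sorted descending)
#' of the full-data model behind a report; only the tree-based back ends
#' (`cart`, `rf`, `xgboost`) expose importances.
#'
#' @param report a `classification_report`.
#' @param threshold weights strictly above this fraction are flagged in
#'   the `above_threshold` column (default 0.04).
#' @return Data frame with `trait`, `weight`, `above_threshold`, ordered
#'   by descending weight.
#' @export
feature_importance <- function(report, threshold = 0.04) {
  stopifnot(inherits(report, "classification_report"))
  if (is.null(report$importance)) {
    stop(sprintf("method '%s' does not expose feature importances",
                 report$method), call. = FALSE)
  }
  imp <- report$importance
  imp$above_threshold <- imp$weight > threshold
  imp
}

# ---- minimal two-hidden-layer back-propagation network --------------------
# Full-batch Adam on softmax cross-entropy with ReLU hidden units; sized
# for trait tables (tens of features, hundreds to thousands of samples).

mlp_fit <- function(x, y, hidden = c(100, 50), iters = 2000, lr = 0.0003237,
                    seed = 1) {
  lev <- levels(y)
  k <- length(lev)
  n <- nrow(x)
  p <- ncol(x)
  t_onehot <- matrix(0, n, k)
  t_onehot[cbind(seq_len(n), as.integer(y))] <- 1
  dims <- c(p, hidden, k)
  with_local_seed(seed, {
    w <- lapply(seq_len(length(dims) - 1), function(i) {
      matrix(stats::rnorm(dims[i] * dims[i + 1], 0, sqrt(2 / dims[i])),
             dims[i], dims[i + 1])
    })
    b <- lapply(dims[-1], function(d) numeric(d))
    mw <- lapply(w, function(m) m * 0); vw <- mw
    mb <- lapply(b, function(v) v * 0); vb <- mb
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    nl <- length(w)
    for (it in seq_len(iters)) {
      a <- list(x)
      for (j in seq_len(nl)) {
        z <- sweep(a[[j]] %*% w[[j]], 2, b[[j]], `+`)
        a[[j + 1]] <- if (j < nl) pmax(z, 0) else z
      }
      zl <- a[[nl + 1]]
      zl <- zl - apply(zl, 1, max)
      ez <- exp(zl)
      prob <- ez / rowSums(ez)
      delta <- (prob - t_onehot) / n
      for (j in rev(seq_len(nl))) {
        gw <- crossprod(a[[j]], delta)
        gb <- colSums(delta)
        if (j > 1) delta <- (delta %*% t(w[[j]])) * (a[[j]] > 0)
        mw[[j]] <- b1 * mw[[j]] + (1 - b1) * gw
        vw[[j]] <- b2 * vw[[j]] + (1 - b2) * gw^2
        mb[[j]] <- b1 * mb[[j]] + (1 - b1) * gb
        vb[[j]] <- b2 * vb[[j]] + (1 - b2) * gb^2
        corr1 <- 1 - b1^it; corr2 <- 1 - b2^it
        w[[j]] <- w[[j]] - lr * (mw[[j]] / corr1) / (sqrt(vw[[j]] / corr2) + eps)
        b[[j]] <- b[[j]] - lr * (mb[[j]] / corr1) / (sqrt(vb[[j]] / corr2) + eps)
      }
    }
    list(w = w, b = b, levels = lev)
  })
}

mlp_predict <- function(fit, x) {
  a <- x
  nl <- length(fit$w)
  for (j in seq_len(nl)) {
    a <- sweep(a %*% fit$w[[j]], 2, fit$b[[j]], `+`)
    if (j < nl) a <- pmax(a, 0)
  }
  fit$levels[max.col(a, ties.method = "first")]
}
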