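#' Classifier configuration
#'
#' Hyperparameter bundles for the three supported algorithms, defaulting to
#' the settings used for the complex-feature datasets: SVM with RBF kernel,
#' gamma = 0.059, C = 300; MLP with five hidden layers of 800, 400, 200,
#' 100 and 50 tanh neurons, SGD solver, L2 term alpha = 1e-4, batch size
#' 200, at most 200 epochs and an adaptive learning rate; k-NN with the
#' Euclidean metric and k = 3. For amplitude-only features the selected SVM
#' gamma was 0.11 and the MLP learning rate constant; for multi-model
#' training the MLP epoch cap was 1000 with a constant rate.
#'
#' @param algorithm `"svm"`, `"mlp"` or `"knn"`.
#' @param ... Overrides of the per-algorithm defaults (see Details).
#' @param scale Feature scaling fit on the training split: `"global"`
#'   (centre each feature, divide all by one pooled scale — the default,
#'   preserving relative channel magnitudes), `"standard"` (per-feature
#'   z-score) or `"none"`.
#' @param seed Seed threaded through stochastic trainers.
#' @return A `classifier_config` list.
#' @details SVM: `gamma`, `cost`. MLP: `hidden`, `alpha`, `batch_size`,
#'   `max_epochs`, `learning_rate` (`"adaptive"`/`"constant"`),
#'   `learning_rate_init`, `momentum`, `tol`. k-NN: `k`.
#' @export
classifier_config <- function(algorithm = c("svm", "mlp", "knn"), ...,
                              scale = c("global", "standard", "none"),
                              seed = 1L) {
  scale <- match.arg(scale)
  algorithm <- match.arg(algorithm)
  defaults <- switch(algorithm,
    svm = list(gamma = 0.059, cost = 300),
    mlp = list(hidden = c(800, 400, 200, 100, 50), alpha = 1e-4,
               batch_size = 200, max_epochs = 200,
               learning_rate = "adaptive", learning_rate_init = 0.01,
               momentum = 0.9, tol = 1e-4),
    knn = list(k = 3)
  )
  hp <- utils::modifyList(defaults, list(...))
  structure(list(algorithm = algorithm, hyperparameters = hp,
                 scale = scale, seed = seed),
            class = "classifier_config")
}

#' @export
print.classifier_config <- function(x, ...) {
  cat("<classifier_config>", x$algorithm, "\n")
  utils::str(x$hyperparameters, give.attr = FALSE)
  invisible(x)
}

dataset_xy <- function(data) {
  stopifnot("label" %in% names(data))
  x <- as.matrix(dplyr::select(as.data.frame(data), -"label"))
  y <- factor(data$label, levels = class_levels())
  y <- droplevels(y)
  list(x = x, y = y)
}

## "global": centre per feature, one pooled scale factor — preserves the
## relative magnitude of the physical channels (per-feature z-scoring
## inflates antenna pairs whose variance is pure noise to unit variance).
## "standard": classical per-feature z-score.
fit_scaler <- function(x, method = "global") {
  mu <- colMeans(x)
  s <- if (method == "global") {
    rep(sqrt(mean(sweep(x, 2, mu)^2)), ncol(x))
  } else {
    apply(x, 2, sd)
  }
  s[s == 0] <- 1
  list(mu = mu, s = s)
}

apply_scaler <- function(scaler, x) {
  if (is.null(scaler)) return(x)
  sweep(sweep(x, 2, scaler$mu), 2, scaler$s, "/")
}

#' Train a stroke classifier
#'
#' Fits the configured algorithm on a labelled dataset. Features are
#' standardized with statistics of the training data when
#' `config$scale` is TRUE (recommended for all three algorithms). Training
#' is deterministic given the config seed (exactly for k-NN; up to solver
#' determinism for SVM/MLP).
#'
#' @param data A `stroke_dataset` (or data frame with `label` + features).
#' @param config A [classifier_config()].
#' @return A `stroke_classifier` with a [predict()] method returning a
#'   factor over [class_levels()].
#' @export
fit_classifier <- function(data, config = classifier_config("svm")) {
  xy <- dataset_xy(data)
  if (nlevels(xy$y) < 2) abort("training set contains a single class")
  scaler <- if (config$scale == "none") NULL else fit_scaler(xy$x, config$scale)
  xs <- apply_scaler(scaler, xy$x)
  hp <- config$hyperparameters
  set.seed(config$seed)
  fit <- switch(config$algorithm,
    svm = e1071::svm(x = xs, y = xy$y, kernel = "radial",
                     gamma = hp$gamma, cost = hp$cost, scale = FALSE),
    knn = list(x = xs, y = xy$y, k = hp$k),
    mlp = mlp_train(xs, xy$y, hidden = hp$hidden, alpha = hp$alpha,
                    batch_size = hp$batch_size, max_epochs = hp$max_epochs,
                    learning_rate = hp$learning_rate,
                    lr_init = hp$learning_rate_init, momentum = hp$momentum,
                    tol = hp$tol)
  )
  structure(list(config = config, scaler = scaler, fit = fit,
                 levels = levels(xy$y), n_train = nrow(xs)),
            class = "stroke_classifier")
}

#' @export
print.stroke_classifier <- function(x, ...) {
  cat("<stroke_classifier>", x$config$algorithm, "trained on", x$n_train,
      "records,", length(x$levels), "classes\n")
  invisible(x)
}

## run expr under a fixed seed without disturbing the caller's RNG stream
with_preserved_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

#' @export
predict.stroke_classifier <- function(object, newdata, ...) {
  x <- if (is.matrix(newdata)) newdata else {
    df <- as.data.frame(newdata)
    as.matrix(df[, setdiff(names(df), "label"), drop = FALSE])
  }
  xs <- apply_scaler(object$scaler, x)
  out <- switch(object$config$algorithm,
    svm = as.character(predict(object$fit, xs)),
    # distance ties in k-NN are broken randomly; pin them to the model seed
    knn = with_preserved_seed(object$config$seed,
      as.character(class::knn(object$fit$x, xs, object$fit$y,
                              k = object$fit$k))),
    mlp = object$fit$classes[max.col(mlp_forward(object$fit, xs), "first")]
  )
  factor(out, levels = class_levels())
}

#' One-row model summary
#' @param x A `stroke_classifier`.
#' @param ... Unused.
#' @return Tibble with algorithm, training size and key hyperparameters.
#' @export
glance.stroke_classifier <- function(x, ...) {
  hp <- x$config$hyperparameters
  tibble::tibble(
    algorithm = x$config$algorithm, n_train = x$n_train,
    n_classes = length(x$levels),
    hyperparameters = paste(names(hp), vapply(hp, function(v)
      paste(format(v), collapse = "/"), character(1)), sep = "=",
      collapse = ", ")
  )
}

## ---- multilayer perceptron (tanh hidden layers, softmax output, SGD) ----

glorot_init <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(runif(n_in * n_out, -lim, lim), n_in, n_out)
}

softmax <- function(z) {
  z <- z - apply(z, 1, max)
  ez <- exp(z)
  ez / rowSums(ez)
}

mlp_forward <- function(net, x) {
  a <- x
  nl <- length(net$W)
  for (l in seq_len(nl - 1)) {
    a <- tanh(sweep(a %*% net$W[[l]], 2, net$b[[l]], "+"))
  }
  softmax(sweep(a %*% net$W[[nl]], 2, net$b[[nl]], "+"))
}

mlp_train <- function(x, y, hidden, alpha = 1e-4, batch_size = 200,
                      max_epochs = 200, learning_rate = "adaptive",
                      lr_init = 0.01, momentum = 0.9, tol = 1e-4) {
  classes <- levels(y)
  sizes <- c(ncol(x), hidden, length(classes))
  nl <- length(sizes) - 1
  W <- vW <- vb <- b <- vector("list", nl)
  for (l in seq_len(nl)) {
    W[[l]] <- glorot_init(sizes[l], sizes[l + 1])
    b[[l]] <- numeric(sizes[l + 1])
    vW[[l]] <- W[[l]] * 0
    vb[[l]] <- b[[l]] * 0
  }
  n <- nrow(x)
  Y <- matrix(0, n, length(classes))
  Y[cbind(seq_len(n), as.integer(y))] <- 1
  lr <- lr_init
  best_loss <- Inf; no_improve <- 0L
  for (epoch in seq_len(max_epochs)) {
    ord <- sample.int(n)
    epoch_loss <- 0
    for (start in seq(1, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1, n)]
      m <- length(idx)
      xb <- x[idx, , drop = FALSE]; yb <- Y[idx, , drop = FALSE]
      ## forward, keeping activations
      act <- vector("list", nl + 1)
      act[[1]] <- xb
      for (l in seq_len(nl - 1)) {
        act[[l + 1]] <- tanh(sweep(act[[l]] %*% W[[l]], 2, b[[l]], "+"))
      }
      prob <- softmax(sweep(act[[nl]] %*% W[[nl]], 2, b[[nl]], "+"))
      epoch_loss <- epoch_loss - sum(log(pmax(prob[yb == 1], 1e-12)))
      ## backward
      delta <- (prob - yb) / m
      for (l in nl:1) {
        gW <- crossprod(act[[l]], delta) + (alpha / m) * W[[l]]
        gb <- colSums(delta)
        if (l > 1) {
          delta <- (delta %*% t(W[[l]])) * (1 - act[[l]]^2)
        }
        vW[[l]] <- momentum * vW[[l]] - lr * gW
        vb[[l]] <- momentum * vb[[l]] - lr * gb
        W[[l]] <- W[[l]] + vW[[l]]
        b[[l]] <- b[[l]] + vb[[l]]
      }
    }
    epoch_loss <- epoch_loss / n
    if (epoch_loss < best_loss - tol) {
      best_loss <- epoch_loss; no_improve <- 0L
    } else {
      no_improve <- no_improve + 1L
      if (learning_rate == "adaptive" && no_improve >= 2L) {
        lr <- lr / 5
        no_improve <- 0L
        if (lr < 1e-6) break
      }
    }
  }
  list(W = W, b = b, classes = classes, loss = best_loss)
}

## ---- grid search ----

#' Exhaustive hyperparameter grid search
#'
#' Evaluates every configuration in `grid` by stratified k-fold
#' cross-validated accuracy (correct / total) on `data` and returns the
#' best; ties are broken by first-in-grid order.
#'
#' @param grid List of [classifier_config()] objects.
#' @param data Labelled dataset.
#' @param folds Number of cross-validation folds (default 5).
#' @param seed Seed for the fold assignment.
#' @return List with `best` (the winning config), `results` (tibble of
#'   config index, algorithm, mean CV accuracy).
#' @export
grid_search <- function(grid, data, folds = 5, seed = 1L) {
  stopifnot(length(grid) >= 1)
  xy <- dataset_xy(data)
  set.seed(seed)
  fold_id <- integer(length(xy$y))
  for (cl in levels(xy$y)) {
    idx <- which(xy$y == cl)
    fold_id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  acc <- vapply(grid, function(cfg) {
    correct <- 0L
    for (f in seq_len(folds)) {
      tr <- data[fold_id != f, , drop = FALSE]
      te <- data[fold_id == f, , drop = FALSE]
      model <- fit_classifier(tr, cfg)
      correct <- correct + sum(predict(model, te) == te$label)
    }
    correct / length(xy$y)
  }, numeric(1))
  best <- which.max(acc)   # first index on ties
  list(best = grid[[best]],
       results = tibble::tibble(config = seq_along(grid),
                                algorithm = vapply(grid, `[[`, "",
                                                   "algorithm"),
                                cv_accuracy = acc))
}
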