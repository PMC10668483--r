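#' @importFrom stats predict
NULL

# EC-level classifiers: a single-hidden-layer ReLU MLP trained with Adam,
# exponential learning-rate decay and validation-loss early stopping.
#
# The network is implemented in base R on purpose: the attribution engine
# needs direct access to the two weight matrices, and the training recipe
# (Adam lr 0.001, scheduler gamma 0.9, stop when the mean validation loss of
# the 5 most recent epochs improves by less than 0.001) must be followed
# exactly. ECX / ECXY / ECXYZ differ only in how the EC labels are truncated;
# they are independent models and their predictions are not forced to agree
# across levels (see hierarchy_consistency()).

#' Training configuration
#'
#' Defaults are the published recipe: hidden layer of 1664 ReLU units, Adam
#' with learning rate 0.001, exponential learning-rate decay with gamma 0.9
#' per epoch, early stopping once the mean validation loss of the 5 most
#' recent epochs improves by less than 0.001. Batch size (256) and the epoch
#' cap (100) are implementation choices; the hidden activation (ReLU) is an
#' assumption required by the Rescale attribution rule.
#'
#' @param hidden_size hidden-layer width.
#' @param learning_rate Adam learning rate.
#' @param scheduler_gamma per-epoch multiplicative learning-rate decay.
#' @param early_stop_window number of recent epochs whose mean validation
#'   loss is monitored.
#' @param early_stop_min_delta minimum improvement of the current validation
#'   loss over that mean.
#' @param max_epochs epoch cap.
#' @param batch_size minibatch size.
#' @param seed master seed (expanded into init and shuffle seeds).
#' @return a `train_config` list.
#' @export
train_config <- function(hidden_size = 1664L, learning_rate = 0.001,
                         scheduler_gamma = 0.9, early_stop_window = 5L,
                         early_stop_min_delta = 0.001, max_epochs = 100L,
                         batch_size = 256L, seed = 1L) {
  stopifnot(hidden_size >= 1, learning_rate > 0, scheduler_gamma > 0,
            early_stop_window >= 1, early_stop_min_delta >= 0,
            max_epochs >= 1, batch_size >= 1)
  structure(list(hidden_size = as.integer(hidden_size),
                 learning_rate = learning_rate,
                 scheduler_gamma = scheduler_gamma,
                 early_stop_window = as.integer(early_stop_window),
                 early_stop_min_delta = early_stop_min_delta,
                 max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "train_config")
}

.softmax_rows <- function(S) {
  m <- apply(S, 1, max)
  E <- exp(S - m)
  E / rowSums(E)
}

# mean cross-entropy of scores S against integer class ids y
.ce_loss <- function(S, y) {
  P <- .softmax_rows(S)
  -mean(log(pmax(P[cbind(seq_along(y), y)], 1e-300)))
}

.mlp_forward <- function(model, X) {
  Z1 <- sweep(X %*% model$W1, 2, model$b1, `+`)
  A1 <- pmax(Z1, 0)
  sweep(A1 %*% model$W2, 2, model$b2, `+`)
}

#' Pre-softmax class scores
#'
#' @param model an `ec_model`.
#' @param X matrix (rows are fingerprints) or a single fingerprint vector.
#' @return matrix of scores, one row per input, columns in vocabulary order.
#' @export
mlp_scores <- function(model, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  if (ncol(X) != model$layer_dims[1]) {
    stop_input(sprintf("input dim %d does not match model input layer %d",
                       ncol(X), model$layer_dims[1]))
  }
  .mlp_forward(model, X)
}

#' Train the MLP classifier
#'
#' @param X binary fingerprint matrix (reactions x dim).
#' @param y character labels (level-truncated EC strings), one per row.
#' @param X_val,y_val validation data for early stopping; when omitted the
#'   training data is monitored (documented fallback for tiny corpora).
#' @param config [train_config()].
#' @param fp_params fingerprint parameters to embed in the bundle.
#' @return an `ec_model` bundle: layer dims, weights, activation id, label
#'   vocabulary, fingerprint params, config and per-epoch loss `history`.
#' @export
train_mlp <- function(X, y, X_val = NULL, y_val = NULL,
                      config = train_config(), fp_params = NULL) {
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stop_input("X rows must match length(y)")
  vocab <- sort(unique(c(y, y_val)))
  if (length(vocab) < 2) stop_input("training requires at least 2 distinct labels")
  yi <- match(y, vocab)
  if (is.null(X_val)) { X_val <- X; y_val <- y }
  X_val <- as.matrix(X_val)
  yvi <- match(y_val, vocab)
  d <- ncol(X); h <- config$hidden_size; C <- length(vocab)

  seeds <- derive_seeds(config$seed, c("init", "shuffle"))
  params <- with_seed(seeds[["init"]], function() {
    l1 <- 1 / sqrt(d); l2 <- 1 / sqrt(h)
    list(W1 = matrix(stats::runif(d * h, -l1, l1), d, h),
         b1 = stats::runif(h, -l1, l1),
         W2 = matrix(stats::runif(h * C, -l2, l2), h, C),
         b2 = stats::runif(C, -l2, l2))
  })
  adam <- lapply(params, function(p) list(m = p * 0, v = p * 0))
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  t_step <- 0L
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_loss = numeric(0), lr = numeric(0))
  win <- config$early_stop_window

  with_seed(seeds[["shuffle"]], function() {
    for (epoch in seq_len(config$max_epochs)) {
      lr <- config$learning_rate * config$scheduler_gamma^(epoch - 1)
      ord <- sample.int(nrow(X))
      batch_losses <- numeric(0)
      for (start in seq(1, nrow(X), by = config$batch_size)) {
        bi <- ord[start:min(start + config$batch_size - 1L, nrow(X))]
        Xb <- X[bi, , drop = FALSE]
        yb <- yi[bi]
        m <- length(bi)
        Z1 <- sweep(Xb %*% params$W1, 2, params$b1, `+`)
        A1 <- pmax(Z1, 0)
        S <- sweep(A1 %*% params$W2, 2, params$b2, `+`)
        P <- .softmax_rows(S)
        loss <- -mean(log(pmax(P[cbind(seq_len(m), yb)], 1e-300)))
        if (!is.finite(loss)) stop("NaN/Inf training loss at epoch ", epoch,
                                   "; lower the learning rate", call. = FALSE)
        batch_losses <- c(batch_losses, loss)
        dS <- P
        dS[cbind(seq_len(m), yb)] <- dS[cbind(seq_len(m), yb)] - 1
        dS <- dS / m
        grads <- list(
          W1 = crossprod(Xb, (dS %*% t(params$W2)) * (Z1 > 0)),
          b1 = colSums((dS %*% t(params$W2)) * (Z1 > 0)),
          W2 = crossprod(A1, dS),
          b2 = colSums(dS))
        t_step <<- t_step + 1L
        for (nm in names(params)) {
          adam[[nm]]$m <<- beta1 * adam[[nm]]$m + (1 - beta1) * grads[[nm]]
          adam[[nm]]$v <<- beta2 * adam[[nm]]$v + (1 - beta2) * grads[[nm]]^2
          mhat <- adam[[nm]]$m / (1 - beta1^t_step)
          vhat <- adam[[nm]]$v / (1 - beta2^t_step)
          params[[nm]] <<- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
        }
      }
      Sv <- sweep(pmax(sweep(X_val %*% params$W1, 2, params$b1, `+`), 0) %*%
                    params$W2, 2, params$b2, `+`)
      vloss <- .ce_loss(Sv, yvi)
      if (!is.finite(vloss)) stop("NaN/Inf validation loss at epoch ", epoch, call. = FALSE)
      hist[nrow(hist) + 1L, ] <<- list(epoch, mean(batch_losses), vloss, lr)
      if (epoch > win) {
        recent_mean <- mean(hist$val_loss[(epoch - win):(epoch - 1)])
        if (recent_mean - vloss < config$early_stop_min_delta) break
      }
    }
  })

  structure(list(layer_dims = c(d, h, C),
                 W1 = params$W1, b1 = params$b1,
                 W2 = params$W2, b2 = params$b2,
                 activation = "relu", vocab = vocab,
                 fp_params = fp_params, config = config,
                 history = hist),
            class = "ec_model")
}

#' @export
print.ec_model <- function(x, ...) {
  cat(sprintf("<EC classifier: %d-%d-%d ReLU MLP, %d labels, %d epochs>\n",
              x$layer_dims[1], x$layer_dims[2], x$layer_dims[3],
              length(x$vocab), nrow(x$history)))
  invisible(x)
}

#' Predict EC labels for a fingerprint
#'
#' @param object an `ec_model`.
#' @param x fingerprint vector, matrix, or `ecx_fp`.
#' @param top_k how many ranked labels to return per input.
#' @param ... unused.
#' @return data frame `label`, `probability`, `rank` (and `input` when `x`
#'   has several rows); probabilities are the softmax over all labels.
#' @export
predict.ec_model <- function(object, x, top_k = 3L, ...) {
  if (inherits(x, "ecx_fp")) x <- x$bits
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  S <- mlp_scores(object, x)
  P <- .softmax_rows(S)
  out <- do.call(rbind, lapply(seq_len(nrow(P)), function(i) {
    ord <- order(-P[i, ], seq_len(ncol(P)))[seq_len(min(top_k, ncol(P)))]
    data.frame(input = i, label = object$vocab[ord], probability = P[i, ord],
               rank = seq_along(ord), stringsAsFactors = FALSE)
  }))
  if (nrow(x) == 1) out$input <- NULL
  rownames(out) <- NULL
  out
}

#' Save / load a model bundle
#'
#' RDS serialisation; the round trip is bit-exact.
#' @param model an `ec_model`.
#' @param path file path.
#' @return `load_model` returns the `ec_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "ec_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "ec_model")) stop_input("not an ec_model bundle: ", path)
  m
}

#' Classification metrics from predicted labels
#'
#' @param truth,pred character vectors of true and predicted labels.
#' @param vocab label universe for the confusion matrix (default: union).
#' @return an `ec_eval`: `accuracy`, `macro_f1` (unweighted mean of per-class
#'   F1 over classes with test support), `confusion` (rows = truth) and a
#'   `per_class` table (label, support, accuracy = recall).
#' @export
metrics_from_predictions <- function(truth, pred, vocab = NULL) {
  if (length(truth) == 0) stop_input("empty test set")
  stopifnot(length(truth) == length(pred))
  if (is.null(vocab)) vocab <- sort(unique(c(truth, pred)))
  cm <- table(factor(truth, levels = vocab), factor(pred, levels = vocab))
  total <- sum(cm)
  acc <- sum(diag(cm)) / total
  support <- rowSums(cm)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- support - tp
  prec <- ifelse(tp + fp == 0, 0, tp / (tp + fp))
  rec <- ifelse(support == 0, 0, tp / support)
  f1 <- ifelse(prec + rec == 0, 0, 2 * prec * rec / (prec + rec))
  has_support <- support > 0
  structure(list(
    accuracy = acc,
    macro_f1 = mean(f1[has_support]),
    confusion = unclass(cm),
    per_class = data.frame(label = vocab, support = as.integer(support),
                           accuracy = as.numeric(rec), f1 = as.numeric(f1),
                           stringsAsFactors = FALSE)
  ), class = "ec_eval")
}

#' Evaluate a model on a test set
#'
#' @param model an `ec_model`.
#' @param X_test fingerprint matrix.
#' @param y_test character labels.
#' @return an `ec_eval` (see [metrics_from_predictions()]).
#' @export
evaluate_model <- function(model, X_test, y_test) {
  if (length(y_test) == 0) stop_input("empty test set")
  S <- mlp_scores(model, as.matrix(X_test))
  pred <- model$vocab[max.col(S, ties.method = "first")]
  metrics_from_predictions(y_test, pred, vocab = sort(unique(c(model$vocab, y_test))))
}

#' @export
print.ec_eval <- function(x, ...) {
  cat(sprintf("<evaluation: accuracy %.4f, macro F1 %.4f, %d classes>\n",
              x$accuracy, x$macro_f1, nrow(x$per_class)))
  invisible(x)
}

.record_labels <- function(records, level) {
  vapply(records, function(r) truncate_ec(r$ec, level), "")
}

#' k-fold cross-validation of the EC classifier
#'
#' Encodes the records (unless a prebuilt corpus is passed), builds stratified
#' folds, trains one model per fold with a held-out validation split for
#' early stopping, and evaluates on the fold's test portion.
#'
#' @param records list of `reaction_record`s.
#' @param level EC truncation level (1 = ECX, 2 = ECXY, 3 = ECXYZ).
#' @param k number of folds.
#' @param params [fp_params()] (ignored when `corpus` is given).
#' @param config [train_config()].
#' @param corpus optional pre-encoded `ecx_corpus`.
#' @return an `ec_cv`: per-fold `reports` and `models`, the `folds`, and a
#'   `summary` data frame of mean and SD of accuracy and macro F1.
#' @export
run_cv <- function(records, level = 1L, k = 4L, params = fp_params(),
                   config = train_config(), corpus = NULL) {
  if (is.null(corpus)) corpus <- encode_corpus(records, params)
  records <- corpus$records
  labels <- .record_labels(records, level)
  seeds <- derive_seeds(config$seed, c("folds", paste0("fold", seq_len(k))))
  folds <- make_cv_folds(records, k = k, level = level, seed = seeds[["folds"]])
  reports <- vector("list", k)
  models <- vector("list", k)
  for (f in seq_len(k)) {
    fd <- folds[[f]]
    cfg <- config
    cfg$seed <- seeds[[paste0("fold", f)]]
    models[[f]] <- train_mlp(corpus$matrix[fd$train, , drop = FALSE], labels[fd$train],
                             corpus$matrix[fd$validation, , drop = FALSE],
                             labels[fd$validation],
                             config = cfg, fp_params = corpus$params)
    reports[[f]] <- evaluate_model(models[[f]],
                                   corpus$matrix[fd$test, , drop = FALSE],
                                   labels[fd$test])
  }
  accs <- vapply(reports, `[[`, 0, "accuracy")
  f1s <- vapply(reports, `[[`, 0, "macro_f1")
  structure(list(
    reports = reports, models = models, folds = folds, level = level,
    summary = data.frame(metric = c("accuracy", "macro_f1"),
                         mean = c(mean(accs), mean(f1s)),
                         sd = c(stats::sd(accs), stats::sd(f1s)))
  ), class = "ec_cv")
}

#' @export
print.ec_cv <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<%d-fold CV, EC level %d: accuracy %.3f +/- %.3f, macro F1 %.3f +/- %.3f>\n",
              length(x$reports), x$level, s$mean[1], s$sd[1], s$mean[2], s$sd[2]))
  invisible(x)
}

#' Label-shuffle ablation
#'
#' For each fraction `p`, `ceiling(p * n_train)` training labels per fold are
#' permuted uniformly among themselves (test labels untouched), the model is
#' retrained, and accuracy is re-measured. Robustness to sporadic
#' mislabelling shows as a flat curve at small `p`; at `p = 1` accuracy drops
#' to chance level.
#'
#' @param records list of `reaction_record`s.
#' @param fractions fractions in `[0, 1]`.
#' @inheritParams run_cv
#' @return data frame `fraction`, `mean_accuracy`, `sd_accuracy`.
#' @export
label_shuffle_ablation <- function(records, fractions, level = 1L, k = 4L,
                                   params = fp_params(), config = train_config(),
                                   corpus = NULL) {
  if (any(fractions < 0 | fractions > 1)) stop_input("fractions must be in [0, 1]")
  if (is.null(corpus)) corpus <- encode_corpus(records, params)
  records <- corpus$records
  labels <- .record_labels(records, level)
  seeds <- derive_seeds(config$seed,
                        c("folds", paste0("fold", seq_len(k)), "shuffle"))
  folds <- make_cv_folds(records, k = k, level = level, seed = seeds[["folds"]])
  out <- data.frame(fraction = numeric(0), mean_accuracy = numeric(0),
                    sd_accuracy = numeric(0))
  for (p in fractions) {
    accs <- numeric(k)
    for (f in seq_len(k)) {
      fd <- folds[[f]]
      y_tr <- labels[fd$train]
      m <- ceiling(p * length(y_tr))
      if (m > 0) {
        y_tr <- with_seed(seeds[["shuffle"]] + f, function() {
          pos <- sample(length(y_tr), m)
          y_tr[pos] <- y_tr[pos][sample(m)]
          y_tr
        })
      }
      cfg <- config
      cfg$seed <- seeds[[paste0("fold", f)]]
      mdl <- train_mlp(corpus$matrix[fd$train, , drop = FALSE], y_tr,
                       corpus$matrix[fd$validation, , drop = FALSE],
                       labels[fd$validation], config = cfg,
                       fp_params = corpus$params)
      accs[f] <- evaluate_model(mdl, corpus$matrix[fd$test, , drop = FALSE],
                                labels[fd$test])$accuracy
    }
    out[nrow(out) + 1L, ] <- list(p, mean(accs), stats::sd(accs))
  }
  out
}

#' Hierarchy-inconsistency rate between independent EC-level models
#'
#' The three models are trained independently, so the class predicted by the
#' sub-subclass model need not match the class model. This reports how often
#' the level-(l) truncation of a deeper model's prediction disagrees with the
#' shallower model's prediction.
#'
#' @param models named list with elements `ECX`, `ECXY` and/or `ECXYZ`.
#' @param X fingerprint matrix.
#' @return data frame of pairwise inconsistency rates.
#' @export
hierarchy_consistency <- function(models, X) {
  pred1 <- function(m) m$vocab[max.col(mlp_scores(m, X), ties.method = "first")]
  lv <- c(ECX = 1L, ECXY = 2L, ECXYZ = 3L)
  have <- intersect(names(lv), names(models))
  preds <- lapply(models[have], pred1)
  out <- data.frame(deeper = character(0), shallower = character(0),
                    inconsistency_rate = numeric(0))
  for (i in seq_along(have)) for (j in seq_along(have)) {
    if (lv[have[i]] <= lv[have[j]]) next
    trunc <- vapply(strsplit(preds[[have[i]]], ".", fixed = TRUE),
                    function(v) paste(v[seq_len(lv[have[j]])], collapse = "."), "")
    out[nrow(out) + 1L, ] <- list(have[i], have[j], mean(trunc != preds[[have[j]]]))
  }
  out
}
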