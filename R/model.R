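# The convolutional pair classifier: configuration, construction, training,
# prediction, evaluation metrics, and protein-level k-fold splitting.

#' Classifier configuration
#'
#' The architecture is fixed by design: five convolutional blocks of 512,
#' 1024, 512, 1024 and 1024 channels, kernel width 3, ReLU,
#' width-2/stride-2 max pooling (skipped once the spatial length reaches
#' 1), a 31-element input and a single-probability output. The training
#' hyperparameters are free parameters with frozen defaults: Adam,
#' learning rate 1e-3, 3 epochs, batch size 128, class weight
#' `N_neg/N_pos` capped at 50, decision threshold 0.5.
#'
#' @param channels Channel counts of the convolutional blocks.
#' @param kernel Convolution kernel width (odd; the implementation is
#'   specialized to 3).
#' @param input_length Length of the pair feature vector (31).
#' @param threshold Decision probability cut in (0, 1).
#' @param optimizer Optimizer name; only `"adam"` is implemented.
#' @param learning_rate,epochs,batch_size Training schedule.
#' @param class_weight_cap Upper bound on the positive-class loss weight.
#' @param seed Seed for weight initialization and batch shuffling.
#' @return Object of class `ihrc_model_config`.
#' @export
model_config <- function(channels = c(512L, 1024L, 512L, 1024L, 1024L),
                         kernel = 3L,
                         input_length = 31L,
                         threshold = 0.5,
                         optimizer = "adam",
                         learning_rate = 1e-3,
                         epochs = 3L,
                         batch_size = 128L,
                         class_weight_cap = 50,
                         seed = 42L) {
  channels <- vapply(channels, stopifnot_scalar_int, integer(1), "channels")
  if (any(channels <= 0L))
    abort("block channel counts must be positive", "ihrc_config_error")
  if (!identical(as.integer(kernel), 3L))
    abort("only kernel width 3 is implemented", "ihrc_config_error")
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1)
    abort("decision threshold must lie strictly in (0, 1)",
          "ihrc_config_error")
  if (!identical(tolower(optimizer), "adam"))
    abort(sprintf("unknown optimizer '%s'", optimizer), "ihrc_config_error")
  structure(list(channels = channels,
                 kernel = 3L,
                 input_length = stopifnot_scalar_int(input_length,
                                                     "input_length"),
                 threshold = threshold,
                 optimizer = "adam",
                 learning_rate = learning_rate,
                 epochs = stopifnot_scalar_int(epochs, "epochs"),
                 batch_size = stopifnot_scalar_int(batch_size, "batch_size"),
                 class_weight_cap = class_weight_cap,
                 seed = stopifnot_scalar_int(seed, "seed")),
            class = "ihrc_model_config")
}

#' Build an untrained classifier
#'
#' Weight initialization is fully determined by `config$seed`: two builds
#' from the same config are identical.
#'
#' @param config A [model_config()].
#' @return Object of class `ihrc_model` with fields `config`, `params`,
#'   `trained`, `log`.
#' @export
build_model <- function(config = model_config()) {
  if (!inherits(config, "ihrc_model_config"))
    abort("expected an ihrc_model_config", "ihrc_contract_error")
  structure(list(config = config, params = nn_init(config),
                 trained = FALSE,
                 log = data.frame(epoch = integer(), loss = numeric(),
                                  train_acc = numeric())),
            class = "ihrc_model")
}

#' @export
print.ihrc_model <- function(x, ...) {
  cat(sprintf("<ihrc_model> blocks [%s], %s, %d parameters\n",
              paste(x$config$channels, collapse = ", "),
              if (x$trained) "trained" else "untrained",
              count_params(x$params)))
  invisible(x)
}

count_params <- function(params) {
  sum(vapply(params$blocks, function(b) length(b$W) + length(b$b),
             numeric(1))) + length(params$fc$w) + length(params$fc$b)
}

check_feature_matrix <- function(x, input_length) {
  x <- as.matrix(x)
  if (ncol(x) != input_length)
    abort(sprintf("feature matrix has %d columns; the model expects %d",
                  ncol(x), input_length), "ihrc_shape_error")
  if (!all(is.finite(x)))
    abort("feature matrix contains non-finite values", "ihrc_shape_error")
  x
}

#' Train the classifier
#'
#' Minimizes class-weighted binary cross-entropy with Adam. The positive
#' class is weighted by `N_neg / N_pos` (capped) to counter the heavy
#' negative imbalance of contact data. With a fixed config seed and a fixed
#' input order, training is bit-reproducible.
#'
#' @param model An `ihrc_model`.
#' @param x Feature matrix, one 31-element row per pair.
#' @param y Binary labels (0/1), one per row; both classes must be present.
#' @param verbose Print per-epoch loss.
#' @return The trained `ihrc_model` with an appended training log.
#' @export
train_model <- function(model, x, y, verbose = FALSE) {
  cfg <- model$config
  x <- check_feature_matrix(x, cfg$input_length)
  y <- as.integer(y)
  if (nrow(x) != length(y))
    abort("x and y disagree in length", "ihrc_contract_error")
  if (length(unique(y)) < 2L)
    abort("training set must contain both classes", "ihrc_training_error")
  n_pos <- sum(y == 1L); n_neg <- sum(y == 0L)
  pos_weight <- min(cfg$class_weight_cap, n_neg / n_pos)
  params <- model$params
  adam <- nn_adam_init(params)
  n <- nrow(x)
  log <- model$log
  for (epoch in seq_len(cfg$epochs)) {
    ord <- with_seed(cfg$seed + epoch, sample.int(n))
    losses <- numeric(); correct <- 0L
    for (start in seq.int(1L, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
      Xb <- t(x[idx, , drop = FALSE])
      yb <- y[idx]
      fwd <- nn_forward(params, cfg, Xb, keep = TRUE)
      lo <- nn_bce(fwd$logits, yb, pos_weight)
      grads <- nn_backward(params, cfg, fwd, lo$dlogits)
      st <- nn_adam_step(params, grads, adam, cfg$learning_rate)
      params <- st$params; adam <- st$state
      losses <- c(losses, lo$loss)
      correct <- correct + sum((fwd$logits > 0) == (yb == 1L))
    }
    log <- rbind(log, data.frame(epoch = epoch, loss = mean(losses),
                                 train_acc = correct / n))
    if (verbose)
      message(sprintf("epoch %d: loss %.5f, train acc %.4f",
                      epoch, mean(losses), correct / n))
  }
  model$params <- params
  model$trained <- TRUE
  model$log <- log
  model
}

#' Predict contact probabilities for pair feature vectors
#'
#' @param object A trained `ihrc_model`.
#' @param x Feature matrix (rows of length 31); may be empty.
#' @param threshold Probability cut for the 0/1 label; defaults to the
#'   config threshold.
#' @param ... Unused.
#' @return Data frame with columns `probability` and `label`, row order
#'   preserved. Probabilities are independent of how the input is batched.
#' @export
predict.ihrc_model <- function(object, x, threshold = NULL, ...) {
  cfg <- object$config
  if (is.null(threshold)) threshold <- cfg$threshold
  if (is.null(dim(x)) && length(x) == cfg$input_length)
    x <- matrix(x, nrow = 1L)
  x <- check_feature_matrix(x, cfg$input_length)
  n <- nrow(x)
  if (n == 0L)
    return(data.frame(probability = numeric(), label = integer()))
  prob <- numeric(n)
  for (start in seq.int(1L, n, by = cfg$batch_size)) {
    idx <- start:min(start + cfg$batch_size - 1L, n)
    fwd <- nn_forward(object$params, cfg, t(x[idx, , drop = FALSE]))
    prob[idx] <- 1 / (1 + exp(-fwd$logits))
  }
  data.frame(probability = prob, label = as.integer(prob >= threshold))
}

#' Confusion-matrix evaluation metrics
#'
#' ACC, Precision, Recall and the Matthews correlation coefficient. Any
#' ratio with a zero denominator is reported as 0 and flagged in
#' `undefined`; in particular MCC is 0 whenever its denominator vanishes
#' (e.g., a predictor that never emits positives).
#'
#' @param predicted,truth Binary 0/1 label vectors of equal length.
#' @return Object of class `ihrc_metrics`: `ACC`, `Precision`, `Recall`,
#'   `MCC`, counts `TP`, `FP`, `TN`, `FN`, and `undefined` (character
#'   vector of flagged metrics).
#' @export
evaluate_predictions <- function(predicted, truth) {
  if (length(predicted) != length(truth))
    abort("predicted and true label vectors disagree in length",
          "ihrc_contract_error")
  if (!all(predicted %in% c(0L, 1L)) || !all(truth %in% c(0L, 1L)))
    abort("labels must be binary 0/1", "ihrc_contract_error")
  tp <- sum(predicted == 1L & truth == 1L)
  fp <- sum(predicted == 1L & truth == 0L)
  tn <- sum(predicted == 0L & truth == 0L)
  fn <- sum(predicted == 0L & truth == 1L)
  undefined <- character()
  ratio <- function(num, den, name) {
    if (den == 0) { undefined <<- c(undefined, name); 0 } else num / den
  }
  acc <- ratio(tp + tn, tp + fp + tn + fn, "ACC")
  prec <- ratio(tp, tp + fp, "Precision")
  rec <- ratio(tp, tp + fn, "Recall")
  den2 <- as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (den2 == 0) { undefined <- c(undefined, "MCC"); 0 } else
    (as.numeric(tp) * tn - as.numeric(fp) * fn) / sqrt(den2)
  structure(list(ACC = acc, Precision = prec, Recall = rec, MCC = mcc,
                 TP = tp, FP = fp, TN = tn, FN = fn, undefined = undefined),
            class = "ihrc_metrics")
}

#' @export
print.ihrc_metrics <- function(x, ...) {
  cat(sprintf(
    "<ihrc_metrics> ACC %.4f  Precision %.4f  Recall %.4f  MCC %.4f\n",
    x$ACC, x$Precision, x$Recall, x$MCC))
  cat(sprintf("  TP %d  FP %d  TN %d  FN %d%s\n", x$TP, x$FP, x$TN, x$FN,
              if (length(x$undefined))
                paste0("  (undefined: ",
                       paste(x$undefined, collapse = ", "), ")")
              else ""))
  invisible(x)
}

#' Protein-level k-fold partition
#'
#' Proteins (not pairs) are shuffled with the given seed and dealt into `k`
#' folds whose sizes differ by at most one, so no residue pair of one
#' protein can appear on both sides of a split.
#'
#' @param protein_ids Character vector of protein identifiers (duplicates
#'   collapsed).
#' @param k Number of folds (default 5).
#' @param seed Shuffle seed.
#' @return List of `k` elements, each `list(train = ids, test = ids)`.
#' @export
kfold_split <- function(protein_ids, k = 5L, seed = 1L) {
  ids <- unique(as.character(protein_ids))
  k <- stopifnot_scalar_int(k, "k")
  if (k < 2L || k > length(ids))
    abort(sprintf("k = %d folds impossible for %d proteins", k, length(ids)),
          "ihrc_config_error")
  shuffled <- with_seed(seed, sample(ids))
  fold_of <- rep(seq_len(k), length.out = length(shuffled))
  lapply(seq_len(k), function(f)
    list(train = sort(shuffled[fold_of != f]),
         test = sort(shuffled[fold_of == f])))
}

#' Save / load a trained model as plain text
#'
#' The checkpoint embeds the config and all weights in an RDS-free,
#' text-only dialect (dput), so models survive source-only distribution.
#'
#' @param model An `ihrc_model`.
#' @param path Checkpoint path.
#' @export
save_model <- function(model, path) {
  payload <- list(config = unclass(model$config),
                  params = model$params,
                  trained = model$trained,
                  log = model$log)
  dput(payload, file = path,
       control = c("keepNA", "keepInteger", "showAttributes", "hexNumeric"))
  invisible(path)
}

#' @rdname save_model
#' @return `load_model()` returns the restored `ihrc_model`.
#' @export
load_model <- function(path) {
  payload <- dget(path)
  cfg <- do.call(model_config, payload$config)
  structure(list(config = cfg, params = payload$params,
                 trained = payload$trained, log = payload$log),
            class = "ihrc_model")
}
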