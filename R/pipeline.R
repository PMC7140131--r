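# End-to-end orchestration: whole-protein prediction with the dual output
# files, protein-level cross-validation, and the controlled comparison of
# covariation methods.

#' Predict interhelical contacts for one protein
#'
#' Builds every feature once — covariation matrix from the alignment
#' (z-standardized), conservation from the PSSM, topology and relative
#' position tracks — scores all interhelical candidate pairs with the
#' trained model, and writes the two mutually consistent output files:
#' `<out_prefix>_pairs.tsv` (tab-separated pair list) and
#' `<out_prefix>_matrix.txt` (upper-triangular 0/1 matrix). With a fixed
#' checkpoint and fixed inputs the outputs are byte-identical across runs.
#'
#' @param sequence An `ihrc_sequence`.
#' @param aln An [msa()] whose first (query) row, gaps removed, equals the
#'   sequence.
#' @param topo An `ihrc_topology` of matching length.
#' @param pssm An [pssm_profile()] of matching length.
#' @param model A trained `ihrc_model`.
#' @param out_prefix Output path prefix.
#' @param method Covariation method (`"ELSC"` default, `"MI"`, `"OMES"`).
#' @param cov Optional precomputed `ihrc_covmat` (e.g., read from TSV via
#'   [read_covariation_tsv()]); overrides `method`. Standardized on the
#'   fly when raw.
#' @param all_pairs Score all pairs instead of interhelical ones only.
#' @param threshold Optional probability cut overriding the model config.
#' @return Invisibly, a list with `predictions` (data frame `i`, `j`,
#'   `probability`, `label`) and `files`.
#' @export
predict_protein <- function(sequence, aln, topo, pssm, model, out_prefix,
                            method = "ELSC", cov = NULL, all_pairs = FALSE,
                            threshold = NULL) {
  L <- nchar(sequence$residues)
  if (topo$length != L)
    abort(sprintf("topology length %d != sequence length %d (input: topology)",
                  topo$length, L), "ihrc_consistency_error")
  if (pssm$length != L)
    abort(sprintf("PSSM length %d != sequence length %d (input: PSSM)",
                  pssm$length, L), "ihrc_consistency_error")
  query <- gsub("-", "", aln$seqs[1], fixed = TRUE)
  if (query != sequence$residues)
    abort("alignment query row does not match the sequence (input: MSA)",
          "ihrc_consistency_error")
  if (is.null(cov)) {
    cov <- covariation_matrix(aln, method)
  } else if (cov$L != L) {
    abort(sprintf("covariation matrix dimension %d != sequence length %d",
                  cov$L, L), "ihrc_consistency_error")
  }
  if (!cov$standardized) cov <- zscore_standardize(cov)
  tracks <- feature_tracks(pssm, topo)
  pairs <- enumerate_candidate_pairs(topo, all_pairs = all_pairs)
  x <- build_pair_matrix(pairs, tracks, cov)
  pred <- predict(model, x, threshold = threshold)
  out <- data.frame(i = as.integer(pairs[, 1]), j = as.integer(pairs[, 2]),
                    probability = pred$probability, label = pred$label)
  files <- c(pairs = paste0(out_prefix, "_pairs.tsv"),
             matrix = paste0(out_prefix, "_matrix.txt"))
  write_pair_list(files[["pairs"]], out)
  write_contact_matrix(files[["matrix"]], L, out)
  check_output_consistency(files[["pairs"]], files[["matrix"]])
  invisible(list(predictions = out, files = files))
}

#' Verify that a pair-list file and a matrix file agree cell-for-cell
#'
#' Every label-1 row must correspond to a `"1"` cell and vice versa; run
#' automatically after every [predict_protein()] call.
#'
#' @param pair_path,matrix_path The two output files.
#' @return `TRUE` invisibly; inconsistency raises an error.
#' @export
check_output_consistency <- function(pair_path, matrix_path) {
  pl <- read_pair_list(pair_path)
  m <- read_contact_matrix(matrix_path)
  ones <- which(m == "1", arr.ind = TRUE)
  key_m <- sort(paste(ones[, 1], ones[, 2]))
  key_p <- sort(paste(pl$i[pl$label == 1L], pl$j[pl$label == 1L]))
  scored0 <- pl[pl$label == 0L, , drop = FALSE]
  bad0 <- nrow(scored0) && any(m[cbind(scored0$i, scored0$j)] != "0")
  if (!identical(key_m, key_p) || isTRUE(bad0))
    abort("pair-list and matrix outputs are inconsistent",
          "ihrc_consistency_error")
  invisible(TRUE)
}

train_on_ids <- function(dataset, ids, config) {
  sel <- dataset$protein %in% ids
  train_model(build_model(config),
              dataset$x[sel, , drop = FALSE], dataset$y[sel])
}

eval_on_ids <- function(model, dataset, ids) {
  sel <- dataset$protein %in% ids
  pred <- predict(model, dataset$x[sel, , drop = FALSE])
  evaluate_predictions(pred$label, dataset$y[sel])
}

#' Protein-level k-fold cross-validation
#'
#' Splits proteins (never pairs) into `k` seeded folds, trains one model
#' per fold on the remaining proteins, and evaluates on the held-out fold.
#'
#' @param dataset A training set as produced by [generate_training_set()]
#'   (fields `x`, `y`, `protein`).
#' @param k Number of folds (default 5).
#' @param seed Fold-assignment seed.
#' @param config A [model_config()].
#' @return List with `folds` (per-fold `ihrc_metrics`), `assignments`
#'   (the [kfold_split()] result) and `summary` (mean/sd data frame over
#'   ACC, Precision, Recall, MCC).
#' @export
run_cv <- function(dataset, k = 5L, seed = 1L, config = model_config()) {
  folds <- kfold_split(unique(dataset$protein), k = k, seed = seed)
  metrics <- vector("list", k)
  for (f in seq_len(k)) {
    res <- tryCatch(
      eval_on_ids(train_on_ids(dataset, folds[[f]]$train, config),
                  dataset, folds[[f]]$test),
      error = function(e)
        abort(sprintf("fold %d failed: %s", f, conditionMessage(e)),
              "ihrc_training_error"))
    metrics[[f]] <- res
  }
  vals <- sapply(metrics, function(m)
    unlist(m[c("ACC", "Precision", "Recall", "MCC")]))
  list(folds = metrics, assignments = folds,
       summary = data.frame(metric = rownames(vals),
                            mean = rowMeans(vals),
                            sd = apply(vals, 1, stats::sd),
                            row.names = NULL))
}

#' Single seeded holdout experiment (optionally label-permuted control)
#'
#' Randomly assigns `train_fraction` of the proteins to training and the
#' rest to testing, trains one model, and reports held-out metrics. With
#' `permute_labels = TRUE` the training labels are randomly permuted
#' (a signal-destroying control): held-out performance should then hover
#' around chance.
#'
#' @param dataset As for [run_cv()].
#' @param config A [model_config()].
#' @param train_fraction Fraction of proteins used for training.
#' @param seed Split (and permutation) seed.
#' @param permute_labels Destroy the training signal.
#' @return List with `metrics` (`ihrc_metrics`), `model`, `train_ids`,
#'   `test_ids`.
#' @export
holdout_experiment <- function(dataset, config = model_config(),
                               train_fraction = 0.8, seed = 1L,
                               permute_labels = FALSE) {
  ids <- unique(dataset$protein)
  n_train <- max(1L, round(train_fraction * length(ids)))
  train_ids <- with_seed(seed, sample(ids, n_train))
  test_ids <- setdiff(ids, train_ids)
  sel <- dataset$protein %in% train_ids
  y_train <- dataset$y[sel]
  if (permute_labels)
    y_train <- with_seed(seed + 1L, sample(y_train))
  model <- train_model(build_model(config),
                       dataset$x[sel, , drop = FALSE], y_train)
  list(metrics = eval_on_ids(model, dataset, test_ids), model = model,
       train_ids = sort(train_ids), test_ids = sort(test_ids))
}

#' Controlled comparison of covariation methods
#'
#' Rebuilds the feature set once per method from the same synthetic world
#' (identical per-protein seeds, hence identical bundles, alignments and
#' labels), trains with the identical model config on the identical
#' protein split, and reports one metrics row per method; only the
#' covariation feature differs between rows.
#'
#' @param spec An [synthetic_spec()].
#' @param methods Covariation methods to compare (at least 2).
#' @param config A [model_config()].
#' @param train_fraction,seed Shared holdout split.
#' @return Data frame with one row per method (ACC, Precision, Recall,
#'   MCC); the shared split is attached as attributes `train_ids` /
#'   `test_ids`.
#' @export
compare_covariation_methods <- function(spec,
                                        methods = c("ELSC", "MI", "OMES"),
                                        config = model_config(),
                                        train_fraction = 0.8, seed = 1L) {
  if (length(methods) < 2L)
    abort("need at least 2 methods to compare", "ihrc_config_error")
  rows <- list(); split <- NULL
  for (m in methods) {
    ds <- generate_training_set(spec, method = m)
    ex <- holdout_experiment(ds, config, train_fraction, seed)
    if (is.null(split)) split <- ex[c("train_ids", "test_ids")]
    stopifnot(identical(split$train_ids, ex$train_ids))
    mt <- ex$metrics
    rows[[m]] <- data.frame(method = m, ACC = mt$ACC,
                            Precision = mt$Precision, Recall = mt$Recall,
                            MCC = mt$MCC)
  }
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  attr(out, "train_ids") <- split$train_ids
  attr(out, "test_ids") <- split$test_ids
  out
}
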