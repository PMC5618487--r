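#' Default RBF-SVM hyperparameter grid
#'
#' Penalty C over 2^-5, 2^-3, ..., 2^15 (exponent step 2; 11 values) and
#' kernel width gamma over 2^5, 2^4, ..., 2^-15 (exponent step 1; 21
#' values): 231 pairs in total. The RBF kernel is
#' exp(-gamma * ||x - y||^2).
#'
#' @param c_exponents Integer exponents for C = 2^e.
#' @param gamma_exponents Integer exponents for gamma = 2^e.
#' @return Data frame with columns `C` and `gamma`, one row per pair.
#' @export
svm_grid <- function(c_exponents = seq(-5L, 15L, by = 2L),
                     gamma_exponents = seq(5L, -15L, by = -1L)) {
  expand.grid(C = 2^c_exponents, gamma = 2^gamma_exponents,
              KEEP.OUT.ATTRS = FALSE)
}

#' Exhaustive grid search over SVM hyperparameters
#'
#' Scores every (C, gamma) pair and returns the maximizer. Ties are broken
#' by smaller C, then smaller gamma, independently of grid enumeration
#' order.
#'
#' @param x Feature matrix (samples x features).
#' @param labels Class label per row.
#' @param grid Data frame of `C`, `gamma` pairs (default [svm_grid()]).
#' @param scorer Function `(x, labels, C, gamma) -> accuracy`; default is
#'   jackknife overall accuracy ([svm_jackknife_evaluator()]).
#' @return List with `C`, `gamma`, `score` and the full `scores` data
#'   frame.
#' @export
grid_search <- function(x, labels, grid = svm_grid(), scorer = NULL) {
  if (nrow(grid) == 0) stop("empty hyperparameter grid")
  if (is.null(scorer)) {
    scorer <- function(x, labels, C, gamma) {
      jackknife_evaluate(x, labels, svm_trainer(C, gamma))$OA
    }
  }
  scores <- vapply(seq_len(nrow(grid)), function(i) {
    res <- tryCatch(scorer(x, labels, grid$C[i], grid$gamma[i]),
                    error = identity)
    if (inherits(res, "error")) {
      stop(sprintf("scorer failed at (C = %g, gamma = %g): %s",
                   grid$C[i], grid$gamma[i], conditionMessage(res)))
    }
    as.numeric(res)
  }, numeric(1))
  best <- which(scores == max(scores))
  best <- best[order(grid$C[best], grid$gamma[best])][1]
  list(C = grid$C[best], gamma = grid$gamma[best], score = scores[best],
       scores = cbind(grid, score = scores))
}

#' Trainer factory for an RBF-kernel SVM with fixed hyperparameters
#'
#' Returns a function `(x, labels) -> fitted model` suitable for
#' [jackknife_evaluate()]. Multiclass problems use libsvm's one-vs-one
#' decomposition. Features are used as-is (no rescaling): the
#' pseudo-dipeptide encoding already normalizes each vector to unit sum.
#'
#' @param C Penalty parameter (positive).
#' @param gamma RBF kernel width (positive).
#' @param seed Seed pinning any stochastic element of the solver.
#' @return A training function.
#' @export
svm_trainer <- function(C, gamma, seed = 1L) {
  force(C); force(gamma); force(seed)
  function(x, labels) {
    set.seed(seed)
    e1071::svm(x = as.matrix(x), y = factor(labels), scale = FALSE,
               kernel = "radial", cost = C, gamma = gamma)
  }
}

#' Jackknife (leave-one-out) evaluation
#'
#' For each of the N samples, a model is trained on the other N - 1 and
#' used to predict the held-out sample; the N held-out predictions are
#' assembled into a confusion matrix from which per-class sensitivity,
#' overall accuracy and average accuracy are computed. Deterministic given
#' a deterministic trainer.
#'
#' @param x Feature matrix (samples x features).
#' @param labels Class label per row; every class needs at least 2 samples.
#' @param trainer Function `(x_train, labels_train) -> model`.
#' @param predictor Function `(model, x_new) -> predicted labels`
#'   (default `predict`).
#' @return An `eval_report`: list with `confusion` (true rows x predicted
#'   columns), `Sn` (per-class sensitivity), `OA`, `AA` and `predictions`.
#' @export
jackknife_evaluate <- function(x, labels, trainer, predictor = predict) {
  x <- as.matrix(x)
  labels <- .check_labels(x, labels)
  lev <- levels(factor(labels))
  N <- nrow(x)
  preds <- character(N)
  for (i in seq_len(N)) {
    fit <- trainer(x[-i, , drop = FALSE], labels[-i])
    preds[i] <- as.character(predictor(fit, x[i, , drop = FALSE]))
  }
  confusion <- table(true = factor(labels, levels = lev),
                     predicted = factor(preds, levels = union(lev, unique(preds))))
  metrics <- metrics_from_confusion(unclass(confusion))
  structure(c(list(confusion = confusion, predictions = preds), metrics),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Jackknife evaluation: OA = %.4f, AA = %.4f\n", x$OA, x$AA))
  cat("Per-class sensitivity:\n")
  print(round(x$Sn, 4))
  print(x$confusion)
  invisible(x)
}

#' Sensitivity, overall and average accuracy from a confusion matrix
#'
#' Rows are true classes, columns predicted. For class i,
#' Sn(i) = TP_i / (TP_i + FN_i) with TP_i the diagonal entry and FN_i the
#' rest of row i; OA = sum of the diagonal / N; AA = mean of the Sn(i).
#'
#' @param confusion Square-or-wider numeric matrix of non-negative counts;
#'   every true class (row) must have at least one sample.
#' @return List with `Sn` (named per-class), `OA` and `AA`.
#' @export
metrics_from_confusion <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (any(confusion < 0) || sum(confusion) < 1) {
    stop("confusion matrix must hold non-negative counts with at least one sample")
  }
  k <- nrow(confusion)
  diag_idx <- cbind(seq_len(k), seq_len(k))
  tp <- confusion[diag_idx]
  row_tot <- rowSums(confusion)
  if (any(row_tot == 0)) {
    stop("empty class row(s): sensitivity undefined for ",
         paste(rownames(confusion)[row_tot == 0], collapse = ", "))
  }
  sn <- tp / row_tot
  names(sn) <- rownames(confusion)
  list(Sn = sn, OA = sum(tp) / sum(confusion), AA = sum(sn) / length(sn))
}

#' Jackknife-OA evaluator with fixed SVM hyperparameters
#'
#' Convenience wrapper producing the `(x, labels) -> OA` evaluator used by
#' [ifs_search()].
#'
#' @inheritParams svm_trainer
#' @return Function mapping a feature matrix and labels to jackknife
#'   overall accuracy.
#' @export
svm_jackknife_evaluator <- function(C = 32, gamma = 8, seed = 1L) {
  trainer <- svm_trainer(C, gamma, seed)
  function(x, labels) jackknife_evaluate(x, labels, trainer)$OA
}

#' Train an RBF-SVM model bundle on selected features
#'
#' The bundle records everything needed to reproduce predictions on new
#' sequences: the fitted classifier, the selected feature names, the
#' encoder parameters, the hyperparameters, the class labels and the seed.
#'
#' @param x Full feature matrix (samples x features) whose columns include
#'   `selected_features`.
#' @param labels Class label per row.
#' @param encoder_params The [encoder_params()] used to build `x`.
#' @param selected_features Ordered character vector of feature names to
#'   train on (default: all columns).
#' @param C,gamma RBF-SVM hyperparameters.
#' @param seed Seed recorded in the bundle and used at fit time.
#' @return An object of class `model_bundle`.
#' @export
train_model <- function(x, labels, encoder_params,
                        selected_features = colnames(x),
                        C = 32, gamma = 8, seed = 1L) {
  x <- as.matrix(x)
  missing <- setdiff(selected_features, colnames(x))
  if (length(missing) > 0) {
    stop("feature name mismatch; absent from the matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  sub <- x[, selected_features, drop = FALSE]
  fit <- svm_trainer(C, gamma, seed)(sub, labels)
  structure(list(
    model = fit,
    selected_features = selected_features,
    encoder_params = encoder_params,
    C = C, gamma = gamma, seed = seed,
    classes = levels(factor(labels)),
    trained_on = Sys.time(),
    data_fingerprint = c(n = nrow(sub), p = ncol(sub))
  ), class = "model_bundle")
}

#' @export
print.model_bundle <- function(x, ...) {
  cat(sprintf(
    "RBF-SVM bundle: %d features, C = %g, gamma = %g, classes: %s\n",
    length(x$selected_features), x$C, x$gamma,
    paste(x$classes, collapse = ", ")))
  invisible(x)
}

#' Predict class labels with a model bundle
#'
#' @param object A [train_model()] bundle.
#' @param newdata Either a feature matrix with named columns covering the
#'   bundle's selected features, or a [protein_set()] of sequences (which
#'   are then encoded with the bundle's own encoder parameters).
#' @param ... Unused.
#' @return Character vector of predicted class labels.
#' @export
predict.model_bundle <- function(object, newdata, ...) {
  if (inherits(newdata, "protein_set")) {
    newdata <- encode_matrix(newdata, object$encoder_params)
  }
  newdata <- as.matrix(newdata)
  missing <- setdiff(object$selected_features, colnames(newdata))
  if (length(missing) > 0) {
    stop("input features incompatible with the bundle; absent: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  as.character(predict(object$model,
                       newdata[, object$selected_features, drop = FALSE]))
}

#' Hierarchical ion-channel-type prediction
#'
#' Three-stage decision flow. Stage 1 decides ion channel (IC) vs
#' non-ion-channel (NIC); for IC hits, stage 2 decides voltage-gated
#' (VGIC) vs ligand-gated (LGIC); for VGIC hits, stage 3 assigns one of
#' the four voltage-gated types (potassium, calcium, sodium, anion). Each
#' stage carries its own encoder parameters, so a sequence too short for a
#' stage's lag depth receives an explicit "unencodable" verdict rather
#' than an error.
#'
#' @param records A [protein_set()] of query sequences.
#' @param stage1 Bundle separating ion channels from non-channels.
#' @param stage2 Bundle separating voltage-gated from ligand-gated
#'   channels.
#' @param stage3 Bundle assigning the four voltage-gated types.
#' @param route1 Stage-1 label that advances a record to stage 2 (default
#'   `"IC"`).
#' @param route2 Stage-2 label that advances a record to stage 3 (default
#'   `"VGIC"`).
#' @return Data frame with columns `id`, `verdict` and the per-stage
#'   decision path (`stage1`, `stage2`, `stage3`; `NA` where a stage was
#'   not reached).
#' @export
predict_hierarchy <- function(records, stage1, stage2, stage3,
                              route1 = "IC", route2 = "VGIC") {
  for (b in list(stage1, stage2, stage3)) {
    if (!inherits(b, "model_bundle")) stop("all three stages need a model_bundle")
  }
  tabs <- lapply(list(stage1, stage2, stage3),
                 function(b) b$encoder_params$table$property_names)
  if (!all(vapply(tabs, identical, logical(1), tabs[[1]]))) {
    warning("stages use different property tables")
  }
  stage_predict <- function(bundle, sequence) {
    if (nchar(sequence) <= bundle$encoder_params$lambda) {
      return(NA_character_)
    }
    predict(bundle, encode_matrix(protein_set("q", sequence),
                                  bundle$encoder_params))
  }
  n <- nrow(records)
  s1 <- s2 <- s3 <- verdict <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    seq_i <- records$sequence[i]
    s1[i] <- stage_predict(stage1, seq_i)
    if (is.na(s1[i])) {
      verdict[i] <- sprintf("unencodable (L <= %d at stage 1)",
                            stage1$encoder_params$lambda)
      next
    }
    if (s1[i] != route1) { verdict[i] <- s1[i]; next }
    s2[i] <- stage_predict(stage2, seq_i)
    if (is.na(s2[i])) {
      verdict[i] <- sprintf("unencodable (L <= %d at stage 2)",
                            stage2$encoder_params$lambda)
      next
    }
    if (s2[i] != route2) { verdict[i] <- s2[i]; next }
    s3[i] <- stage_predict(stage3, seq_i)
    verdict[i] <- if (is.na(s3[i])) {
      sprintf("unencodable (L <= %d at stage 3)",
              stage3$encoder_params$lambda)
    } else {
      s3[i]
    }
  }
  data.frame(id = records$id, verdict = verdict,
             stage1 = s1, stage2 = s2, stage3 = s3,
             stringsAsFactors = FALSE)
}

#' Save / load a model bundle
#'
#' The bundle is stored as a directory: a JSON manifest (encoder
#' parameters, selected features, hyperparameters, classes, seed) plus the
#' serialized classifier state.
#'
#' @param bundle A [train_model()] bundle.
#' @param dir Directory to create.
#' @return `save_bundle` invisibly returns `dir`; `load_bundle` returns the
#'   bundle.
#' @export
save_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    selected_features = bundle$selected_features,
    lambda = bundle$encoder_params$lambda,
    omega = bundle$encoder_params$omega,
    C = bundle$C, gamma = bundle$gamma, seed = bundle$seed,
    classes = bundle$classes
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  write_property_table(bundle$encoder_params$table,
                       file.path(dir, "properties.tsv"))
  saveRDS(bundle$model, file.path(dir, "model.rds"))
  invisible(dir)
}

#' @rdname save_bundle
#' @export
load_bundle <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  table <- load_property_table(file.path(dir, "properties.tsv"))
  structure(list(
    model = readRDS(file.path(dir, "model.rds")),
    selected_features = manifest$selected_features,
    encoder_params = encoder_params(manifest$lambda, manifest$omega, table),
    C = manifest$C, gamma = manifest$gamma, seed = manifest$seed,
    classes = manifest$classes
  ), class = "model_bundle")
}
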