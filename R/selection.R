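.check_labels <- function(x, labels) {
  labels <- as.character(labels)
  if (length(labels) != nrow(x)) {
    stop("labels length (", length(labels), ") != number of rows (",
         nrow(x), ")")
  }
  counts <- table(labels)
  if (length(counts) < 2) stop("need at least 2 classes, got ", length(counts))
  if (any(counts < 2)) {
    stop("every class needs at least 2 samples; too small: ",
         paste(names(counts)[counts < 2], collapse = ", "))
  }
  labels
}

#' One-way ANOVA F-value of each feature
#'
#' For each feature (column) the F-value is MSB / MSW with
#' MSB = sum_i n_i (mean_i - grand mean)^2 / (K - 1) and
#' MSW = sum_i sum_j (x_ij - mean_i)^2 / (N - K), where K is the number of
#' classes and N the number of samples. Larger F means better class
#' discrimination. A feature with zero within-class variance but non-zero
#' between-class variance is a perfect separator and scores `Inf`; a
#' feature constant across all samples is uninformative and scores 0 (with
#' a warning).
#'
#' @param x Numeric feature matrix (samples x features).
#' @param labels Class label per row.
#' @return Numeric vector of F-values, one per column of `x`.
#' @export
anova_f <- function(x, labels) {
  x <- as.matrix(x)
  labels <- .check_labels(x, labels)
  g <- factor(labels)
  K <- nlevels(g)
  N <- nrow(x)
  n_i <- as.vector(table(g))
  grand <- colMeans(x)
  # class means: K x P
  means <- rowsum(x, g) / n_i
  ssb <- colSums(n_i * (means - rep(grand, each = K))^2)
  centered <- x - means[as.integer(g), , drop = FALSE]
  ssw <- colSums(centered^2)
  msb <- ssb / (K - 1)
  msw <- ssw / (N - K)
  eps <- 1e-300
  f <- ifelse(msw > eps, msb / msw, ifelse(msb > eps, Inf, 0))
  if (any(msw <= eps & msb <= eps)) {
    warning(sum(msw <= eps & msb <= eps),
            " feature(s) constant across all samples (F set to 0)")
  }
  names(f) <- colnames(x)
  f
}

#' Rank features by decreasing ANOVA F-value
#'
#' Perfect separators (infinite F) sort first; ties are broken by ascending
#' original column index, so the ranking is deterministic.
#'
#' @inheritParams anova_f
#' @return An object of class `feature_ranking`: list with `f_values`
#'   (per-feature F, input column order) and `order` (permutation of column
#'   indices, best first).
#' @export
rank_features <- function(x, labels) {
  f <- anova_f(x, labels)
  ord <- order(-f, seq_along(f))
  structure(list(f_values = f, order = ord,
                 feature_names = colnames(x)),
            class = "feature_ranking")
}

#' @export
print.feature_ranking <- function(x, ...) {
  cat("Feature ranking over", length(x$f_values), "features; top 5:\n")
  top <- x$order[seq_len(min(5, length(x$order)))]
  print(data.frame(feature = x$feature_names[top],
                   F = unname(x$f_values[top])))
  invisible(x)
}

#' Write a feature ranking as TSV
#'
#' Columns: feature name, F-value, rank (1 = best).
#'
#' @param ranking A [rank_features()] result.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_ranking <- function(ranking, path) {
  ord <- ranking$order
  df <- data.frame(feature = ranking$feature_names[ord],
                   f_value = unname(ranking$f_values[ord]),
                   rank = seq_along(ord), stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Incremental feature selection
#'
#' Evaluates classification accuracy on growing prefixes of the F-ranked
#' feature list and returns the accuracy-vs-k curve together with the
#' smallest k attaining the maximum. The evaluator is injected so that any
#' accuracy protocol (typically jackknife overall accuracy with fixed SVM
#' hyperparameters, see [svm_jackknife_evaluator()]) — or a cheap stand-in
#' in tests — can be used.
#'
#' @param x Numeric feature matrix (samples x features).
#' @param labels Class label per row.
#' @param ranking A [rank_features()] result covering all columns of `x`.
#' @param evaluator Function `(x_subset, labels) -> overall accuracy`.
#' @param k_grid Prefix sizes to evaluate; defaults to every k from 1 to
#'   the number of features (step 1). A coarser grid trades resolution for
#'   speed.
#' @return An object of class `ifs_result`: list with `curve` (data frame
#'   of `k`, `accuracy`), `best_k`, `best_accuracy` and
#'   `selected_features`.
#' @export
ifs_search <- function(x, labels, ranking, evaluator,
                       k_grid = seq_len(ncol(x))) {
  x <- as.matrix(x)
  if (length(ranking$order) != ncol(x)) {
    stop("ranking covers ", length(ranking$order),
         " features but the matrix has ", ncol(x))
  }
  k_grid <- sort(unique(as.integer(k_grid)))
  if (any(k_grid < 1) || any(k_grid > ncol(x))) {
    stop("k_grid values must be in 1..", ncol(x))
  }
  acc <- vapply(k_grid, function(k) {
    sub <- x[, ranking$order[seq_len(k)], drop = FALSE]
    res <- tryCatch(evaluator(sub, labels), error = identity)
    if (inherits(res, "error")) {
      stop("evaluator failed at k = ", k, ": ", conditionMessage(res))
    }
    as.numeric(res)
  }, numeric(1))
  best_i <- which.max(acc) # first max -> smallest k on ties
  best_k <- k_grid[best_i]
  structure(list(
    curve = data.frame(k = k_grid, accuracy = acc),
    best_k = best_k,
    best_accuracy = acc[best_i],
    selected_features = colnames(x)[ranking$order[seq_len(best_k)]]
  ), class = "ifs_result")
}

#' @export
print.ifs_result <- function(x, ...) {
  cat(sprintf("IFS: best accuracy %.4f at k = %d (of %d prefixes evaluated)\n",
              x$best_accuracy, x$best_k, nrow(x$curve)))
  invisible(x)
}

#' Write an IFS accuracy curve as TSV
#'
#' @param result An [ifs_search()] result.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_ifs_curve <- function(result, path) {
  utils::write.table(result$curve, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
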