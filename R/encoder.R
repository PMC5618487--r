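#' Names of the 400 dipeptides
#'
#' First-residue-major alphabetical enumeration: "AA", "AC", ..., "AY",
#' "CA", ..., "YY".
#'
#' @return Character vector of length 400.
#' @export
dipeptide_names <- function() {
  aa <- amino_acids()
  paste0(rep(aa, each = 20), rep(aa, times = 20))
}

#' Encoder parameters for pseudo-dipeptide composition
#'
#' @param lambda Lag depth: the maximum residue-pair separation used for
#'   sequence-order correlation factors. Positive integer.
#' @param omega Weight of the correlation block relative to the dipeptide
#'   block. Non-negative real.
#' @param table A [property_table()] supplying the n physicochemical scales.
#' @return An object of class `encoder_params`.
#' @export
encoder_params <- function(lambda, omega, table = load_property_table()) {
  lambda <- as.integer(lambda)
  if (length(lambda) != 1 || is.na(lambda) || lambda < 1) {
    stop("lambda must be a positive integer")
  }
  if (length(omega) != 1 || is.na(omega) || omega < 0) {
    stop("omega must be a non-negative real")
  }
  if (!inherits(table, "property_table")) {
    stop("table must be a property_table")
  }
  structure(list(lambda = lambda, omega = omega, table = table),
            class = "encoder_params")
}

#' @export
print.encoder_params <- function(x, ...) {
  cat(sprintf("Encoder: lambda = %d, omega = %.3f, n = %d properties (dim %d)\n",
              x$lambda, x$omega, n_properties(x$table),
              400L + n_properties(x$table) * x$lambda))
  invisible(x)
}

#' Feature names of the full encoding
#'
#' The 400 dipeptides followed by the correlation components, tier-major:
#' `tier1_<property 1..n>`, `tier2_...`, up to `tier<lambda>`.
#'
#' @param params An [encoder_params()] object.
#' @return Character vector of length `400 + n * lambda`.
#' @export
feature_names <- function(params) {
  c(dipeptide_names(),
    paste0("tier", rep(seq_len(params$lambda), each = n_properties(params$table)),
           "_", rep(params$table$property_names, times = params$lambda)))
}

.residue_index <- function(sequence) {
  chars <- strsplit(sequence, "")[[1]]
  idx <- match(chars, amino_acids())
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1]
    stop(sprintf("non-canonical residue %s at position %d", chars[bad], bad))
  }
  idx
}

#' Normalized dipeptide frequencies of a sequence
#'
#' Component for dipeptide d is (number of adjacent occurrences of d) /
#' (L - 1); components sum to 1.
#'
#' @param sequence A single amino acid sequence over the canonical alphabet.
#' @return Named numeric vector of length 400 (names from
#'   [dipeptide_names()]).
#' @export
#' @examples
#' f <- dipeptide_frequencies("ACAC")
#' f[f > 0]
dipeptide_frequencies <- function(sequence) {
  idx <- .residue_index(sequence)
  L <- length(idx)
  if (L < 2) stop("no dipeptides: sequence length ", L, " < 2")
  codes <- (idx[-L] - 1L) * 20L + idx[-1L]
  freq <- tabulate(codes, nbins = 400L) / (L - 1)
  names(freq) <- dipeptide_names()
  freq
}

#' Sequence-order correlation factor for one tier and one property
#'
#' The tier-j factor for property k is the average, over all residue pairs
#' separated by j positions, of the product of standardized property-k
#' values: (1/(L-j)) * sum_i h_k(R_i) h_k(R_(i+j)).
#'
#' @param sequence Amino acid sequence (length L > `tier`).
#' @param tier Lag (residue-pair separation), a positive integer.
#' @param property_index Index of the property row in `table`.
#' @param table A [property_table()].
#' @return A single numeric value.
#' @export
correlation_factor <- function(sequence, tier, property_index, table) {
  idx <- .residue_index(sequence)
  L <- length(idx)
  tier <- as.integer(tier)
  if (L <= tier) {
    stop("sequence shorter than lag: L = ", L, ", tier = ", tier)
  }
  h <- table$standardized[property_index, ]
  mean(h[idx[seq_len(L - tier)]] * h[idx[seq_len(L - tier) + tier]])
}

# All n*lambda correlation factors, tier-major. Returns a numeric vector
# tau with tau[(j-1)*n + k] for tier j, property k.
.correlation_factors <- function(idx, lambda, table) {
  L <- length(idx)
  H <- table$standardized[, idx, drop = FALSE] # n x L
  out <- vector("list", lambda)
  for (j in seq_len(lambda)) {
    left <- H[, seq_len(L - j), drop = FALSE]
    right <- H[, seq_len(L - j) + j, drop = FALSE]
    out[[j]] <- rowSums(left * right) / (L - j)
  }
  unlist(out, use.names = FALSE)
}

#' Encode a sequence as a pseudo-dipeptide composition vector
#'
#' The first 400 components are f_u / D and the remaining n*lambda
#' components are omega * tau_u / D, where f are the dipeptide frequencies,
#' tau the correlation factors and D = sum(f) + omega * sum(tau). The
#' components therefore sum to 1 whenever D is non-degenerate. With
#' omega = 0 the encoding reduces to the plain dipeptide composition padded
#' with zeros.
#'
#' @param sequence Amino acid sequence with L > lambda.
#' @param params An [encoder_params()] object.
#' @return Named numeric vector of length `400 + n * lambda`.
#' @export
encode <- function(sequence, params) {
  idx <- .residue_index(sequence)
  L <- length(idx)
  if (L <= params$lambda) {
    stop(sprintf("sequence of length %d cannot be encoded at lambda = %d (requires L > lambda)",
                 L, params$lambda))
  }
  codes <- (idx[-L] - 1L) * 20L + idx[-1L]
  f <- tabulate(codes, nbins = 400L) / (L - 1)
  tau <- .correlation_factors(idx, params$lambda, params$table)
  D <- sum(f) + params$omega * sum(tau)
  if (abs(D) <= 1e-9) {
    stop("degenerate normalization: sum(f) + omega * sum(tau) = ", D)
  }
  p <- c(f, params$omega * tau) / D
  names(p) <- feature_names(params)
  p
}

#' Encode a set of records into a feature matrix
#'
#' @param records A [protein_set()] data frame.
#' @param params An [encoder_params()] object.
#' @param fail_fast If `TRUE` (default) the first record that cannot be
#'   encoded raises an error naming it. If `FALSE`, failing records are
#'   dropped; their ids and reasons are attached as the `"failures"`
#'   attribute (a data frame) and reported in a warning.
#' @return Numeric matrix, one row per (successfully encoded) record, rows
#'   named by record id, columns by [feature_names()].
#' @export
encode_matrix <- function(records, params, fail_fast = TRUE) {
  nms <- feature_names(params)
  n_rec <- nrow(records)
  if (n_rec == 0) {
    return(matrix(numeric(0), nrow = 0, ncol = length(nms),
                  dimnames = list(NULL, nms)))
  }
  rows <- vector("list", n_rec)
  failed <- character(n_rec)
  for (i in seq_len(n_rec)) {
    res <- tryCatch(encode(records$sequence[i], params), error = identity)
    if (inherits(res, "error")) {
      msg <- conditionMessage(res)
      if (fail_fast) {
        stop("record '", records$id[i], "': ", msg)
      }
      failed[i] <- msg
    } else {
      rows[[i]] <- res
    }
  }
  ok <- vapply(rows, Negate(is.null), logical(1))
  if (any(!ok)) {
    warning(sum(!ok), " record(s) could not be encoded and were dropped")
  }
  m <- do.call(rbind, rows[ok])
  if (is.null(m)) {
    m <- matrix(numeric(0), nrow = 0, ncol = length(nms))
  }
  dimnames(m) <- list(records$id[ok], nms)
  if (any(!ok)) {
    attr(m, "failures") <- data.frame(id = records$id[!ok],
                                      reason = failed[!ok],
                                      stringsAsFactors = FALSE)
  }
  m
}

#' Enumerate the encoder parameter search grid
#'
#' The default grid is lambda = 1..30 (step 1) crossed with
#' omega = 0.05..0.70 (step 0.05): 30 x 14 = 420 combinations.
#'
#' @param lambda Integer vector of lag depths.
#' @param omega Numeric vector of correlation weights.
#' @return Data frame with columns `lambda` and `omega`, one row per
#'   combination.
#' @export
encoder_param_grid <- function(lambda = 1:30,
                               omega = seq(0.05, 0.70, by = 0.05)) {
  expand.grid(lambda = as.integer(lambda), omega = omega,
              KEEP.OUT.ATTRS = FALSE)
}

#' Write a feature matrix as TSV with a JSON parameter sidecar
#'
#' The TSV has the record id in the first column, then one named feature
#' column per component. The sidecar `<path>.json` records lambda, omega
#' and the property names for provenance.
#'
#' @param m Feature matrix from [encode_matrix()].
#' @param path Output TSV path.
#' @param params The [encoder_params()] used to build `m` (optional).
#' @return Invisibly, `path`.
#' @export
write_feature_matrix <- function(m, path, params = NULL) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(params)) {
    jsonlite::write_json(
      list(lambda = params$lambda, omega = params$omega,
           properties = params$table$property_names),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a feature matrix written by [write_feature_matrix()]
#'
#' @param path TSV path.
#' @return Numeric matrix with row names (record ids) and feature column
#'   names.
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
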