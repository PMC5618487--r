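# Shared fixture builders. All randomness is seeded at the call site.

random_sequence <- function(L, prob = rep(1 / 20, 20)) {
  paste(sample(amino_acids(), L, replace = TRUE, prob = prob), collapse = "")
}

random_protein_set <- function(n, L_range = c(30, 80)) {
  lens <- sample(L_range[1]:L_range[2], n, replace = TRUE)
  protein_set(sprintf("s%03d", seq_len(n)),
              vapply(lens, random_sequence, character(1)))
}

# Two-class planted-dipeptide dataset used across selection/classify tests.
planted_two_class <- function(n_per_class = 30, L = 150, enrichment = 8,
                              dipeptides = c("AC", "CA", "DE", "KL", "WY"),
                              seed = 42) {
  spec <- synthetic_spec(
    classes = c(pos = as.integer(n_per_class), neg = as.integer(n_per_class)),
    length_range = c(as.integer(L), as.integer(L)),
    signals = list(pos = list(dipeptides = dipeptides,
                              enrichment = enrichment)),
    seed = seed)
  generate_dataset(spec)
}

# Direct per-formula metrics, independent of metrics_from_confusion.
reference_metrics <- function(cm) {
  k <- nrow(cm)
  sn <- numeric(k)
  for (i in seq_len(k)) {
    tp <- cm[i, i]
    fn <- sum(cm[i, ]) - tp
    sn[i] <- tp / (tp + fn)
  }
  list(Sn = sn, OA = sum(diag(cm)) / sum(cm), AA = sum(sn) / k)
}
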