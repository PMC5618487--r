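test_that("the default hyperparameter grid enumerates 11 x 21 pairs", {
  grid <- svm_grid()
  expect_equal(nrow(grid), 231L)
  expect_setequal(unique(grid$C), 2^seq(-5, 15, by = 2))
  expect_setequal(unique(grid$gamma), 2^seq(5, -15, by = -1))
})

test_that("grid_search is exhaustive, tie-stable and order-invariant", {
  x <- matrix(rnorm(40), ncol = 2)
  g <- rep(c("a", "b"), each = 10)
  # single-pair grid returns that pair regardless of score
  one <- grid_search(x, g, data.frame(C = 4, gamma = 0.5),
                     scorer = function(x, l, C, gamma) 0.1)
  expect_equal(one$C, 4)
  expect_equal(one$gamma, 0.5)
  # constant scorer: ties resolved by smallest C then smallest gamma,
  # independent of enumeration order
  grid <- expand.grid(C = c(8, 2), gamma = c(1, 0.25))
  flat <- function(x, l, C, gamma) 0.7
  for (perm in list(1:4, 4:1, c(2, 4, 1, 3))) {
    res <- grid_search(x, g, grid[perm, ], scorer = flat)
    expect_equal(res$C, 2)
    expect_equal(res$gamma, 0.25)
  }
  # maximizer is found wherever it sits in the grid
  res <- grid_search(x, g, grid,
                     scorer = function(x, l, C, gamma) {
                       if (C == 8 && gamma == 0.25) 0.9 else 0.2
                     })
  expect_equal(res$C, 8)
  expect_equal(res$score, 0.9)
  expect_error(grid_search(x, g, grid[0, ]), "empty")
  expect_error(
    grid_search(x, g, grid, scorer = function(x, l, C, gamma) stop("no")),
    "scorer failed at")
})

test_that("metrics_from_confusion matches the defining formulas", {
  m <- metrics_from_confusion(matrix(c(3, 0, 1, 4), nrow = 2))
  expect_equal(unname(m$Sn), c(0.75, 1.0))
  expect_equal(m$OA, 7 / 8)
  expect_equal(m$AA, 0.875)
  # identity-like confusion: everything perfect
  id <- diag(c(5, 3, 8))
  mid <- metrics_from_confusion(id)
  expect_equal(mid$OA, 1)
  expect_equal(mid$AA, 1)
  expect_error(metrics_from_confusion(rbind(c(0, 0), c(1, 2))),
               "empty class row")
})

test_that("metrics agree exactly with an independent recomputation", {
  set.seed(55)
  for (rep in 1:100) {
    k <- sample(2:5, 1)
    cm <- matrix(rpois(k * k, 4), nrow = k)
    diag(cm) <- diag(cm) + 1 # no empty rows
    got <- metrics_from_confusion(cm)
    ref <- reference_metrics(cm)
    expect_identical(unname(got$Sn), ref$Sn)
    expect_identical(got$OA, ref$OA)
    expect_identical(got$AA, ref$AA)
    expect_true(got$OA >= 0 && got$OA <= 1)
    expect_true(got$AA >= 0 && got$AA <= 1)
  }
})

test_that("OA equals AA on balanced classes", {
  set.seed(65)
  for (rep in 1:20) {
    k <- sample(2:4, 1)
    cm <- matrix(rpois(k * k, 3), nrow = k)
    # force equal row sums by padding the diagonal
    target <- max(rowSums(cm)) + 1
    diag(cm) <- diag(cm) + (target - rowSums(cm))
    m <- metrics_from_confusion(cm)
    expect_equal(m$OA, m$AA, tolerance = 1e-12)
  }
})

test_that("jackknife runs N leave-one-out rounds and scores a dummy classifier", {
  set.seed(75)
  x <- matrix(rnorm(14), ncol = 1)
  g <- c(rep("big", 9), rep("small", 5))
  sizes <- integer(0)
  majority_trainer <- function(xt, lt) {
    sizes <<- c(sizes, nrow(xt))
    names(which.max(table(lt)))
  }
  rep <- jackknife_evaluate(x, g, majority_trainer,
                            predictor = function(fit, xn) fit)
  expect_length(sizes, 14L)
  expect_true(all(sizes == 13L))
  # majority class ("big", 9/14) is always predicted
  expect_equal(rep$OA, 9 / 14)
  expect_equal(unname(rep$Sn), c(1, 0))
  expect_equal(rep$AA, 0.5)
  expect_equal(sum(rep$confusion), 14)
})

test_that("an always-right classifier scores perfectly under jackknife", {
  x <- matrix(seq_len(8), ncol = 1)
  g <- rep(c("a", "b"), each = 4)
  oracle_trainer <- function(xt, lt) function(xn) {
    ifelse(xn[, 1] <= 4, "a", "b")
  }
  rep <- jackknife_evaluate(x, g, oracle_trainer,
                            predictor = function(fit, xn) fit(xn))
  expect_equal(rep$OA, 1)
  expect_equal(rep$AA, 1)
  expect_true(all(rep$Sn == 1))
})

test_that("the RBF-SVM separates separable data and supports 2 and 4 classes", {
  set.seed(85)
  # two well-separated Gaussian blobs
  x2 <- rbind(matrix(rnorm(40, 0, 0.2), ncol = 2),
              matrix(rnorm(40, 3, 0.2), ncol = 2))
  colnames(x2) <- c("u", "v")
  g2 <- rep(c("a", "b"), each = 20)
  fit <- svm_trainer(C = 32, gamma = 1)(x2, g2)
  expect_equal(as.character(predict(fit, x2)), g2)
  best <- grid_search(x2, g2, data.frame(C = c(1, 32), gamma = c(1, 1)))
  expect_equal(best$score, 1)
  # four classes via one-vs-one
  x4 <- rbind(x2, x2 + 10)
  colnames(x4) <- c("u", "v")
  g4 <- c(g2, rep(c("c", "d"), each = 20))
  rep4 <- jackknife_evaluate(x4, g4, svm_trainer(32, 1))
  expect_equal(rep4$OA, 1)
  expect_equal(dim(rep4$confusion), c(4L, 4L))
})

test_that("training, bundling and prediction are deterministic and name-safe", {
  set.seed(95)
  ds <- planted_two_class(n_per_class = 15, L = 100, seed = 7)
  params <- encoder_params(1, 0.1)
  m <- encode_matrix(ds$records, params)
  b1 <- train_model(m, ds$labels, params, C = 32, gamma = 8, seed = 3)
  b2 <- train_model(m, ds$labels, params, C = 32, gamma = 8, seed = 3)
  expect_identical(predict(b1, m), predict(b2, m))
  expect_error(train_model(m, ds$labels, params,
                           selected_features = c("AC", "nope")),
               "feature name mismatch")
  expect_error(predict(b1, m[, 1:10]), "incompatible")
  # predicting straight from sequences re-encodes with the bundle's params
  expect_identical(predict(b1, ds$records), predict(b1, m))
  # bundles survive a save/load round trip
  dir <- withr::local_tempdir()
  save_bundle(b1, dir)
  b3 <- load_bundle(dir)
  expect_identical(predict(b3, m), predict(b1, m))
  expect_equal(b3$encoder_params$lambda, 1L)
})

test_that("hierarchical prediction short-circuits, routes and surfaces encoding limits", {
  # Nested planted signals mirror the biology of the hierarchy: every ion
  # channel carries the IC mark, voltage-gated channels add the VGIC mark,
  # and each voltage-gated type adds its own mark. All three stages train
  # on splits of one composite dataset.
  ic_mark <- list(dipeptides = c("AC", "CA"), enrichment = 14)
  composite <- function(type_dipep) {
    list(dipeptides = c("AC", "CA", "DE", "ED", type_dipep), enrichment = 14)
  }
  make_spec <- function(counts, seed) synthetic_spec(
    classes = counts, length_range = c(150L, 150L),
    signals = list(
      LGIC = ic_mark,
      "VGIC-K" = composite("KK"), "VGIC-Ca" = composite("WW"),
      "VGIC-Na" = composite("MM"), "VGIC-Anion" = composite("HH")),
    seed = seed)
  ds <- generate_dataset(make_spec(
    c(NIC = 20L, LGIC = 14L, "VGIC-K" = 10L, "VGIC-Ca" = 10L,
      "VGIC-Na" = 10L, "VGIC-Anion" = 10L), seed = 11))
  params <- encoder_params(1, 0.1)
  m <- encode_matrix(ds$records, params)
  lab <- ds$labels
  s1 <- ifelse(lab == "NIC", "NIC", "IC")
  b1 <- train_model(m, s1, params, C = 8, gamma = 32)
  keep2 <- lab != "NIC"
  s2 <- ifelse(grepl("^VGIC", lab[keep2]), "VGIC", "LGIC")
  b2 <- train_model(m[keep2, ], s2, params, C = 8, gamma = 32)
  keep3 <- grepl("^VGIC", lab)
  b3 <- train_model(m[keep3, ], lab[keep3], params, C = 8, gamma = 32)

  # in-distribution records traverse to their planted leaf labels
  res <- predict_hierarchy(ds$records, b1, b2, b3)
  expect_equal(res$verdict, lab)
  k_rows <- res[lab == "VGIC-K", ]
  expect_true(all(k_rows$stage1 == "IC" & k_rows$stage2 == "VGIC"))
  nic_rows <- res[lab == "NIC", ]
  # short-circuit: stages 2-3 never invoked for NIC verdicts
  expect_true(all(is.na(nic_rows$stage2)) && all(is.na(nic_rows$stage3)))

  # held-out queries from a fresh seed mostly reach the right leaf
  # (planted counts are Poisson-noisy, so routing is not exact)
  q <- generate_dataset(make_spec(
    c(NIC = 4L, LGIC = 4L, "VGIC-K" = 4L, "VGIC-Ca" = 4L,
      "VGIC-Na" = 4L, "VGIC-Anion" = 4L), seed = 99))
  rq <- predict_hierarchy(q$records, b1, b2, b3)
  expect_gte(mean(rq$verdict == q$labels), 0.7)

  # a sequence shorter than a stage's lambda gets an explicit verdict
  b1_deep <- b1
  b1_deep$encoder_params <- encoder_params(21, 0.2)
  short <- protein_set("tiny", strrep("ACDEF", 3)) # L = 15 <= 21
  res_short <- predict_hierarchy(short, b1_deep, b2, b3)
  expect_match(res_short$verdict, "unencodable \\(L <= 21 at stage 1\\)")

  # mismatched property tables between stages are warned about
  one_prop <- property_table(matrix(rnorm(20), nrow = 1,
                                    dimnames = list("p", amino_acids())))
  b2_alt <- b2
  b2_alt$encoder_params <- encoder_params(1, 0.1, one_prop)
  # the short query stops at stage 1, so only the table check fires
  expect_warning(predict_hierarchy(short, b1_deep, b2_alt, b3),
                 "different property tables")
})
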