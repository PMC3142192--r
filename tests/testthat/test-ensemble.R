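make_candidates <- function(pair_id, starts, ends, ddg) {
  n <- length(starts)
  cand <- data.frame(pair_id = pair_id,
                     seed_id = sprintf("s%d", seq_len(n)),
                     target_start = starts, target_end = ends,
                     ddg_seed = ddg)
  for (f in feature_names()) cand[[f]] <- stats::runif(n)
  cand$f19 <- ddg
  cand
}

test_that("training-sample construction follows the smallest-ddg dedup rules", {
  set.seed(41)
  # two candidates consistent with the validated site: ddg -5 wins
  cand <- make_candidates("p1", c(10, 12, 60, 62, 64, 200),
                          c(20, 22, 70, 72, 74, 210),
                          c(-3, -5, -4, -2, -6, -4))
  val <- data.frame(pair_id = "p1", target_start = 15, target_end = 25)
  tab <- build_training_samples(cand, val)
  pos <- tab[tab$label == "positive", ]
  expect_equal(nrow(pos), 1)
  expect_equal(pos$ddg_seed, -5)
  # candidate overlapping the chosen positive is excluded from negatives;
  # three mutually overlapping negatives collapse to the smallest ddg
  neg <- tab[tab$label == "negative", ]
  expect_equal(sort(neg$ddg_seed), c(-6, -4))
  expect_false(any(neg$target_start <= 22 & neg$target_end >= 12))

  # pair with a validated site but no consistent candidate: no positive
  val2 <- data.frame(pair_id = "p1", target_start = 500, target_end = 510)
  expect_message(tab2 <- build_training_samples(cand, val2), "no candidate")
  expect_equal(sum(tab2$label == "positive"), 0)
})

test_that("LOOCV forward selection finds the separating feature first", {
  tab <- generate_training_table(n_pos = 15, n_neg = 30,
                                 effect = c(f19 = 1000, f22 = 0),
                                 rng_seed = 42)
  cands <- loocv_forward_selection(tab, max_features = 2)
  size1 <- Filter(function(c) c$size == 1, cands)
  expect_equal(size1[[1]]$subset, 19L)
  expect_equal(size1[[1]]$accuracy, 1.0)   # separable: perfect LOOCV
  # beam bookkeeping: top_k subsets per size, sorted by accuracy
  expect_lte(length(size1), 10)
  accs <- vapply(size1, `[[`, numeric(1), "accuracy")
  expect_true(all(diff(accs) <= 0))
})

test_that("the compiled base learner agrees with an R reimplementation", {
  set.seed(43)
  for (rep in 1:10) {
    n <- 40
    X <- matrix(rnorm(n * 3), n, 3)
    y <- as.integer(X[, 2] + 0.5 * rnorm(n) > 0)
    if (length(unique(y)) < 2) next
    clf <- starpick:::cpp_lda_fit(X, y, integer(0))
    got <- starpick:::cpp_lda_predict(clf, X)
    want <- r_lda_predict(X, y, X)
    expect_equal(got, want)
  }
})

test_that("LOOCV accuracy equals a fold-by-fold recomputation", {
  set.seed(44)
  n <- 30
  X <- matrix(rnorm(n * 2), n, 2)
  y <- as.integer(X[, 1] + 0.8 * rnorm(n) > 0)
  got <- starpick:::cpp_lda_loocv(X, y)
  naive <- mean(vapply(seq_len(n), function(i) {
    pred <- r_lda_predict(X[-i, , drop = FALSE], y[-i],
                          X[i, , drop = FALSE])
    pred == y[i]
  }, logical(1)))
  expect_equal(got, naive)
})

test_that("stability analysis behaves at the separable and null extremes", {
  sep <- generate_training_table(n_pos = 20, n_neg = 20,
                                 effect = c(f19 = 1000, f22 = 0),
                                 rng_seed = 45)
  st <- stability_analysis(19L, sep, n_rounds = 100, rng_seed = 7)
  expect_equal(st$stability_index, 1.0)
  expect_length(st$classifiers, 100)

  # permuted labels, balanced classes: index near 1/2. Each single
  # permutation leaves a table-level chance correlation the classifier
  # can exploit, so the null expectation is checked as an average over
  # several independent permutations.
  null <- generate_training_table(n_pos = 100, n_neg = 100,
                                  effect = c(f19 = 1000, f22 = 0),
                                  rng_seed = 45)
  idx <- vapply(1:5, function(perm) {
    set.seed(46 + perm)
    null$label <- sample(null$label)
    stability_analysis(19L, null, n_rounds = 100,
                       rng_seed = 7 + perm)$stability_index
  }, numeric(1))
  expect_lt(abs(mean(idx) - 0.5), 0.05)

  # determinism of the whole stability path
  st2 <- stability_analysis(19L, sep, n_rounds = 100, rng_seed = 7)
  expect_identical(st$stability_index, st2$stability_index)
  expect_identical(st$classifiers, st2$classifiers)
})

test_that("subset selection prefers stability, then smaller subsets", {
  tab <- generate_training_table(n_pos = 15, n_neg = 30, rng_seed = 47)
  # a constant feature cannot change the fitted trees: exact tie with the
  # singleton, and the smaller subset must win
  tab$f2 <- 0
  cands <- list(list(subset = c(2L, 19L), size = 2, accuracy = 0.9),
                list(subset = 19L, size = 1, accuracy = 0.9))
  sel <- select_final_subset_by_stability(cands, tab, rng_seed = 3,
                                          n_rounds = 50)
  expect_equal(sel$subset, 19L)
  # single candidate: that subset wins
  sel1 <- select_final_subset_by_stability(list(list(subset = 5L, size = 1,
                                                     accuracy = 0.5)),
                                           tab, rng_seed = 3, n_rounds = 20)
  expect_equal(sel1$subset, 5L)
  expect_s3_class(sel1$model, "ensemble_model")
})

test_that("voting probabilities are exact vote fractions", {
  v <- stats::setNames(stats::rnorm(22), feature_names())
  expect_identical(predict_probability(stub_model(500, 1000), v), 0.5)
  expect_identical(predict_probability(stub_model(0, 1000), v), 0)
  expect_identical(predict_probability(stub_model(1000, 1000), v), 1)
  probs <- vapply(c(1, 37, 999), function(k)
    predict_probability(stub_model(k, 1000), v), numeric(1))
  expect_equal(probs, c(0.001, 0.037, 0.999))
  expect_true(all(abs(probs * 1000 - round(probs * 1000)) < 1e-12))
  expect_error(predict_probability(stub_model(1, 10), v[1:10]), "missing")
})

test_that("the decision rule is strict at the threshold", {
  expect_equal(classify(0.501), "interacting")
  expect_equal(classify(0.5), "non-interacting")
  expect_equal(classify(c(0.999, 1), threshold = 1),
               c("non-interacting", "non-interacting"))
  expect_error(classify(1.2))
})

test_that("model serialization round-trips exactly", {
  tab <- generate_training_table(n_pos = 10, n_neg = 20, rng_seed = 48)
  st <- stability_analysis(c(19L, 22L), tab, n_rounds = 25, rng_seed = 5)
  model <- ensemble_model(c(19L, 22L), st$classifiers, rng_seed = 5,
                          stability_index = st$stability_index,
                          engine_id = "toy-nn-1")
  f <- withr::local_tempfile(fileext = ".json")
  write_model(model, f)
  back <- read_model(f)
  expect_equal(back$subset, model$subset)
  expect_equal(back$feature_names, model$feature_names)
  expect_equal(back$stability_index, model$stability_index)
  expect_equal(back$engine_id, model$engine_id)
  X <- as.matrix(as.data.frame(generate_training_table(
    n_pos = 10, n_neg = 10, rng_seed = 49))[, feature_names()])
  expect_identical(predict_probability(model, X),
                   predict_probability(back, X))
})
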