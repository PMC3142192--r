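#' Build a labeled training table from candidate binding sites
#'
#' Per sRNA-target pair: among candidates whose target interval overlaps a
#' validated binding site, only the one with the smallest seed `ddg_seed`
#' becomes the positive sample. Candidates overlapping the chosen positive
#' are excluded from the negatives; mutually overlapping negatives are
#' greedily deduplicated keeping the smallest `ddg_seed`. A pair with a
#' validated site but no consistent candidate contributes no positive (a
#' message is logged).
#'
#' @param candidates data.frame with columns `pair_id`, `seed_id`,
#'   `target_start`, `target_end`, `ddg_seed` and the feature columns
#'   `f1` ... `f22`.
#' @param validated data.frame of experimentally validated sites:
#'   `pair_id`, `target_start`, `target_end` (may be empty).
#' @return A `training_table` data.frame: feature columns, `label`
#'   (factor negative/positive), `pair_id`, `seed_id`.
#' @export
build_training_samples <- function(candidates, validated) {
  stopifnot(all(c("pair_id", "seed_id", "target_start", "target_end",
                  "ddg_seed") %in% names(candidates)))
  overlaps <- function(a1, a2, b1, b2) a1 <= b2 & b1 <= a2
  rows <- list()
  for (pid in unique(candidates$pair_id)) {
    cand <- candidates[candidates$pair_id == pid, , drop = FALSE]
    val <- validated[validated$pair_id == pid, , drop = FALSE]
    pos_idx <- integer(0)
    if (nrow(val) > 0L) {
      consistent <- which(vapply(seq_len(nrow(cand)), function(k)
        any(overlaps(cand$target_start[k], cand$target_end[k],
                     val$target_start, val$target_end)), logical(1)))
      if (length(consistent) == 0L) {
        message("pair ", pid, ": no candidate consistent with the validated site")
      } else {
        pos_idx <- consistent[which.min(cand$ddg_seed[consistent])]
      }
    }
    neg_pool <- setdiff(seq_len(nrow(cand)), pos_idx)
    if (length(pos_idx) == 1L) {
      neg_pool <- neg_pool[!overlaps(cand$target_start[neg_pool],
                                     cand$target_end[neg_pool],
                                     cand$target_start[pos_idx],
                                     cand$target_end[pos_idx])]
    }
    # greedy dedup of mutually overlapping negatives, best (smallest
    # ddg_seed) first
    neg_pool <- neg_pool[order(cand$ddg_seed[neg_pool])]
    neg_keep <- integer(0)
    for (k in neg_pool) {
      if (!any(overlaps(cand$target_start[k], cand$target_end[k],
                        cand$target_start[neg_keep], cand$target_end[neg_keep])))
        neg_keep <- c(neg_keep, k)
    }
    keep <- c(pos_idx, neg_keep)
    if (length(keep) == 0L) next
    sub <- cand[keep, , drop = FALSE]
    sub$label <- c(rep("positive", length(pos_idx)),
                   rep("negative", length(neg_keep)))
    rows[[length(rows) + 1L]] <- sub
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$label <- factor(out$label, levels = c("negative", "positive"))
  class(out) <- c("training_table", class(out))
  out
}

table_xy <- function(table, features = feature_names()) {
  X <- as.matrix(as.data.frame(table)[, features, drop = FALSE])
  y <- as.integer(table$label == "positive")
  list(X = X, y = y)
}

# Deterministic derivation of per-round seeds from a master seed.
derive_seed <- function(master, round, salt = 0L) {
  as.integer((as.numeric(master) * 48271 + round * 69621 + salt * 1e6 + 1) %%
               2147483647)
}

#' Forward feature selection scored by leave-one-out cross-validation
#'
#' Greedy forward (beam) selection with the package's base learner, a
#' ridge-regularized linear discriminant with empirical class priors (see
#' [stability_analysis()]). For each subset size `k = 1 ... max_features`,
#' the `top_k` subsets with the best LOOCV accuracy are recorded (ties
#' broken by lexicographic feature order) and seed the next size.
#'
#' @param table a `training_table` ([build_training_samples()] or
#'   [generate_training_table()]).
#' @param max_features largest subset size (selection stops early if
#'   fewer features exist).
#' @param top_k number of subsets recorded per size.
#' @return A list of candidate records, each `list(subset, size,
#'   accuracy)`, with `subset` a sorted integer vector of feature indices.
#' @export
loocv_forward_selection <- function(table, max_features = 10L, top_k = 10L) {
  d <- table_xy(table)
  p <- ncol(d$X)
  beam <- list(integer(0))
  out <- list()
  for (k in seq_len(min(max_features, p))) {
    seen <- new.env(parent = emptyenv())
    cands <- list()
    for (base in beam) {
      for (f in setdiff(seq_len(p), base)) {
        s <- sort(c(base, f))
        key <- paste(s, collapse = ",")
        if (!is.null(seen[[key]])) next
        seen[[key]] <- TRUE
        acc <- cpp_lda_loocv(d$X[, s, drop = FALSE], d$y)
        cands[[length(cands) + 1L]] <- list(subset = s, size = k, accuracy = acc)
      }
    }
    accs <- vapply(cands, `[[`, numeric(1), "accuracy")
    keys <- vapply(cands, function(c) paste(sprintf("%03d", c$subset),
                                            collapse = ","), character(1))
    ord <- order(-accs, keys)
    take <- ord[seq_len(min(top_k, length(ord)))]
    out <- c(out, cands[take])
    beam <- lapply(cands[take], `[[`, "subset")
  }
  out
}

#' Stability analysis of a feature subset
#'
#' Repeatedly partitions the training table at random into 75% training /
#' 25% test rows, fits the base classifier on the training part using
#' only the given features, and scores accuracy on the test part. The
#' base classifier is a linear discriminant with a small ridge on the
#' pooled covariance and empirical class priors, so a negatives-heavy
#' table produces conservative (high-specificity) base rules. The
#' stability index is the mean test accuracy over all rounds; the trained
#' classifiers are returned and become the voting ensemble for the winning
#' subset. A degenerate split leaving one class absent from the training
#' portion is resampled (deterministically, from the derived round seed).
#'
#' @inheritParams loocv_forward_selection
#' @param subset integer vector of feature indices.
#' @param n_rounds number of random partitions (1000 for the full model).
#' @param train_fraction fraction of rows used for training per round.
#' @param rng_seed master seed; per-round seeds are derived from it.
#' @return list with `stability_index`, `accuracies` (length `n_rounds`)
#'   and `classifiers` (list of coefficient vectors).
#' @export
stability_analysis <- function(subset, table, n_rounds = 1000L,
                               train_fraction = 0.75, rng_seed = 1L) {
  stopifnot(length(subset) >= 1L)
  d <- table_xy(table)
  X <- d$X[, subset, drop = FALSE]; y <- d$y
  n <- nrow(X)
  n_train <- round(train_fraction * n)
  stopifnot(n_train >= 1L, n_train < n)
  accs <- numeric(n_rounds)
  clfs <- vector("list", n_rounds)
  for (r in seq_len(n_rounds)) {
    attempt <- 0L
    repeat {
      set.seed(derive_seed(rng_seed, r, attempt))
      train <- sort(sample.int(n, n_train))
      if (length(unique(y[train])) == 2L) break
      attempt <- attempt + 1L
      if (attempt > 100L) stop("cannot draw a split containing both classes")
    }
    clf <- cpp_lda_fit(X, y, as.integer(train))
    test <- setdiff(seq_len(n), train)
    pred <- cpp_lda_predict(clf, X[test, , drop = FALSE])
    accs[r] <- mean(pred == y[test])
    clfs[[r]] <- clf
  }
  list(stability_index = mean(accs), accuracies = accs, classifiers = clfs)
}

#' Choose the final feature subset by stability and build the ensemble
#'
#' Evaluates [stability_analysis()] for every recorded candidate subset —
#' all candidates see the same sequence of random partitions, so subsets
#' are compared on common splits — and picks the one with the highest
#' stability index (ties: smaller subset, then lexicographic feature
#' order). The classifiers trained during the winning subset's stability
#' rounds become the voting ensemble.
#'
#' @param candidates list from [loocv_forward_selection()].
#' @inheritParams stability_analysis
#' @return list with `subset`, `stability_index`, `model` (an
#'   `ensemble_model`), and `stability_by_candidate`.
#' @export
select_final_subset_by_stability <- function(candidates, table,
                                             rng_seed = 1L, n_rounds = 1000L,
                                             train_fraction = 0.75) {
  stopifnot(length(candidates) >= 1L)
  stats <- vector("list", length(candidates))
  for (ci in seq_along(candidates)) {
    sub <- candidates[[ci]]$subset
    stats[[ci]] <- stability_analysis(sub, table, n_rounds = n_rounds,
                                      train_fraction = train_fraction,
                                      rng_seed = rng_seed)
  }
  idx <- vapply(stats, `[[`, numeric(1), "stability_index")
  sizes <- vapply(candidates, function(c) length(c$subset), integer(1))
  keys <- vapply(candidates, function(c) paste(sprintf("%03d", c$subset),
                                               collapse = ","), character(1))
  best <- order(-idx, sizes, keys)[1]
  subset <- candidates[[best]]$subset
  model <- ensemble_model(subset = subset,
                          classifiers = stats[[best]]$classifiers,
                          rng_seed = rng_seed,
                          stability_index = idx[best])
  list(subset = subset, stability_index = idx[best], model = model,
       stability_by_candidate = data.frame(
         subset = keys, size = sizes, stability_index = idx))
}

#' Voting ensemble model
#'
#' @param subset integer feature indices used by every base classifier.
#' @param classifiers list of base-classifier coefficient vectors
#'   `c(intercept, weights...)` over the subset features.
#' @param rng_seed master seed the training path was run with.
#' @param stability_index mean test accuracy of the winning subset.
#' @param engine_id folding-engine identifier recorded for provenance.
#' @return An object of class `ensemble_model`.
#' @export
ensemble_model <- function(subset, classifiers, rng_seed = NA_integer_,
                           stability_index = NA_real_, engine_id = NA_character_) {
  structure(list(subset = as.integer(subset),
                 feature_names = feature_names()[subset],
                 classifiers = classifiers,
                 n_classifiers = length(classifiers),
                 rng_seed = rng_seed,
                 stability_index = stability_index,
                 engine_id = engine_id,
                 format_version = 1L),
            class = "ensemble_model")
}

#' @export
print.ensemble_model <- function(x, ...) {
  cat(sprintf("<ensemble_model> %d voting classifiers on {%s}\n",
              x$n_classifiers, paste(x$feature_names, collapse = ", ")))
  invisible(x)
}

#' Full training path: selection, stability, ensemble
#'
#' Runs [loocv_forward_selection()] and
#' [select_final_subset_by_stability()] and returns the fitted
#' `ensemble_model` together with the selection diagnostics.
#'
#' @inheritParams select_final_subset_by_stability
#' @inheritParams loocv_forward_selection
#' @param engine optional [energy_engines] object whose `engine_id` is
#'   recorded in the model.
#' @return list with `model`, `candidates`, `selection`.
#' @export
train_ensemble <- function(table, rng_seed = 1L, n_rounds = 1000L,
                           max_features = 10L, top_k = 10L,
                           train_fraction = 0.75, engine = NULL) {
  candidates <- loocv_forward_selection(table, max_features = max_features,
                                        top_k = top_k)
  sel <- select_final_subset_by_stability(candidates, table,
                                          rng_seed = rng_seed,
                                          n_rounds = n_rounds,
                                          train_fraction = train_fraction)
  model <- sel$model
  if (!is.null(engine)) model$engine_id <- engine$engine_id
  list(model = model, candidates = candidates, selection = sel)
}

#' Interaction probability by unweighted voting
#'
#' The probability is the fraction of base classifiers voting
#' "interacting", quantized to multiples of 0.001 (exact for the standard
#' 1000-member ensemble).
#'
#' @param model an `ensemble_model`.
#' @param v named feature vector (`f1` ... `f22`), or a matrix/data.frame
#'   with those columns (one probability per row).
#' @return Numeric probability in `[0, 1]`.
#' @export
predict_probability <- function(model, v) {
  if (is.null(dim(v))) v <- matrix(v, nrow = 1, dimnames = list(NULL, names(v)))
  v <- as.matrix(v)
  missing <- setdiff(model$feature_names, colnames(v))
  if (length(missing) > 0L)
    stop("feature(s) missing from input: ", paste(missing, collapse = ", "))
  X <- v[, model$feature_names, drop = FALSE]
  storage.mode(X) <- "double"
  W <- do.call(cbind, model$classifiers)       # (p+1) x k coefficients
  scores <- cbind(1, X) %*% W
  votes <- rowSums(scores > 0)
  round(unname(votes) / model$n_classifiers, 3)
}

#' Decision rule on the voting probability
#'
#' A pair is called interacting iff its probability is strictly greater
#' than the threshold (so exactly 0.5 is non-interacting at the default).
#'
#' @param probability numeric in `[0, 1]`.
#' @param threshold decision threshold (default 0.5).
#' @return Character vector, `"interacting"` or `"non-interacting"`.
#' @export
classify <- function(probability, threshold = 0.5) {
  stopifnot(all(probability >= 0 & probability <= 1))
  ifelse(probability > threshold, "interacting", "non-interacting")
}

#' Write / read an ensemble model
#'
#' Models are stored in a versioned JSON container holding the feature
#' subset, every base classifier's coefficient vector, the master RNG
#' seed and the engine metadata, at full numeric precision so that a
#' round trip reproduces predictions exactly.
#'
#' @param model an `ensemble_model`.
#' @param path file path (conventionally `.json`).
#' @return `write_model()`: `path`, invisibly. `read_model()`: the
#'   restored `ensemble_model`.
#' @export
write_model <- function(model, path) {
  payload <- list(
    container = "starpick-ensemble-model",
    format_version = model$format_version,
    subset = model$subset,
    feature_names = model$feature_names,
    rng_seed = model$rng_seed,
    stability_index = model$stability_index,
    engine_id = model$engine_id,
    n_classifiers = model$n_classifiers,
    classifiers = lapply(model$classifiers, as.numeric))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  if (!identical(p$container, "starpick-ensemble-model"))
    stop("not a starpick model file: ", path)
  if (p$format_version != 1L) stop("unsupported model format version")
  clfs <- lapply(p$classifiers, as.numeric)
  m <- ensemble_model(subset = p$subset, classifiers = clfs,
                      rng_seed = p$rng_seed,
                      stability_index = p$stability_index,
                      engine_id = if (is.null(p$engine_id)) NA_character_
                                  else p$engine_id)
  m
}
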