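# Independent oracles used by the tests. These deliberately reimplement
# the quantities with different algorithms (enumeration / naive recursion
# in R) than the package's dynamic programs.

RT37 <- 0.0019872041 * 310.15

toy_ps <- function(a, b) {
  key <- paste0(a, b)
  if (key %in% c("GC", "CG")) return(3)
  if (key %in% c("AU", "UA")) return(2)
  if (key %in% c("GU", "UG")) return(1)
  0
}

rand_rna <- function(n, letters = c("A", "C", "G", "U")) {
  paste(sample(letters, n, replace = TRUE), collapse = "")
}

# Best inter-molecular antiparallel non-crossing matching score by naive
# recursion over "next sRNA position / highest target position still
# available" (memoised).
oracle_duplex_best <- function(a, b) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  memo <- matrix(NA_real_, n + 1, m + 1)
  f <- function(i, jhi) {
    if (i > n || jhi < 1) return(0)
    if (!is.na(memo[i, jhi])) return(memo[i, jhi])
    best <- f(i + 1, jhi)
    for (j in seq_len(jhi)) {
      s <- toy_ps(av[i], bv[j])
      if (s > 0) best <- max(best, s + f(i + 1, j - 1))
    }
    memo[i, jhi] <<- best
    best
  }
  f(1, m)
}

# Energies of every intra-molecular structure (min hairpin loop 3) as an
# explicit vector, by interval recursion; blocked positions cannot pair.
oracle_structure_energies <- function(seq, blocked = NULL) {
  sv <- strsplit(seq, "")[[1]]
  n <- length(sv)
  if (is.null(blocked)) blocked <- rep(FALSE, n)
  memo <- vector("list", (n + 2) * (n + 2))
  idx <- function(i, j) (i - 1) * (n + 2) + j
  f <- function(i, j) {
    if (i >= j) return(0)          # empty / single: open chain only
    key <- idx(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    out <- f(i + 1, j)             # i unpaired
    if (!blocked[i] && i + 4 <= j) {
      for (k in (i + 4):j) {
        if (blocked[k]) next
        s <- toy_ps(sv[i], sv[k])
        if (s > 0) {
          inner <- f(i + 1, k - 1)
          rest <- if (k < j) f(k + 1, j) else 0
          out <- c(out, as.vector(outer(inner, rest, `+`)) - s)
        }
      }
    }
    memo[[key]] <<- out
    out
  }
  if (n < 5) return(0)
  f(1, n)
}

oracle_ensemble_energy <- function(seq, blocked = NULL) {
  e <- oracle_structure_energies(seq, blocked)
  -RT37 * log(sum(exp(-e / RT37)))
}

# All joint structures of two concatenated molecules (pair lists), for
# small instances; the min-hairpin rule applies within a molecule only.
oracle_joint_structures <- function(concat, cut) {
  sv <- strsplit(concat, "")[[1]]
  n <- length(sv)
  same_mol <- function(i, k) (i <= cut) == (k <= cut)
  g <- function(i, j) {
    if (i > j) return(list(matrix(0L, 0, 2)))
    out <- list()
    for (st in g(i + 1, j)) out[[length(out) + 1L]] <- st
    for (k in if (i + 1 <= j) (i + 1):j else integer(0)) {
      if (same_mol(i, k) && k - i < 4) next
      if (toy_ps(sv[i], sv[k]) == 0) next
      for (inner in g(i + 1, k - 1)) for (rest in g(k + 1, j)) {
        out[[length(out) + 1L]] <- rbind(c(i, k), inner, rest)
      }
    }
    out
  }
  g(1, n)
}

oracle_cofold_best <- function(a, b, forced) {
  concat <- paste0(a, b)
  cut <- nchar(a)
  sv <- strsplit(concat, "")[[1]]
  forced_j <- cbind(forced[, 1], cut + forced[, 2])
  best <- -Inf; best_pairs <- NULL
  for (st in oracle_joint_structures(concat, cut)) {
    ok <- TRUE
    for (t in seq_len(nrow(forced_j))) {
      hit <- which(st[, 1] == forced_j[t, 1] | st[, 2] == forced_j[t, 1] |
                   st[, 1] == forced_j[t, 2] | st[, 2] == forced_j[t, 2])
      if (length(hit) != 1L ||
          !all(sort(st[hit, ]) == sort(forced_j[t, ]))) { ok <- FALSE; break }
    }
    if (!ok) next
    sc <- if (nrow(st) == 0L) 0 else
      sum(vapply(seq_len(nrow(st)), function(q)
        toy_ps(sv[st[q, 1]], sv[st[q, 2]]), numeric(1)))
    if (sc > best) { best <- sc; best_pairs <- st }
  }
  list(energy = -best, pairs = best_pairs)
}

# Brute-force seed scan: every start pair extended along its diagonal,
# then terminal wobble trimming and the length filter.
oracle_helices <- function(a, b, min_len = 5L) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  P <- outer(av, bv, Vectorize(function(x, y) toy_ps(x, y) > 0))
  starts <- which(P, arr.ind = TRUE)
  rows <- list()
  for (q in seq_len(nrow(starts))) {
    i <- starts[q, 1]; j <- starts[q, 2]
    if (i > 1 && j < m && P[i - 1, j + 1]) next   # not a run start
    len <- 0L
    while (i + len <= n && j - len >= 1 && P[i + len, j - len]) len <- len + 1L
    i0 <- i; j0 <- j
    is_gu <- function(x, y) paste0(x, y) %in% c("GU", "UG")
    repeat {
      if (len == 0L) break
      if (is_gu(av[i0], bv[j0])) { i0 <- i0 + 1L; j0 <- j0 - 1L; len <- len - 1L; next }
      if (is_gu(av[i0 + len - 1L], bv[j0 - len + 1L])) { len <- len - 1L; next }
      break
    }
    if (len < min_len) next
    rows[[length(rows) + 1L]] <- c(i0, i0 + len - 1L, j0 - len + 1L, j0)
  }
  out <- if (length(rows)) unique(do.call(rbind, rows)) else
    matrix(0L, 0, 4)
  colnames(out) <- c("srna_start", "srna_end", "target_start", "target_end")
  out[order(out[, 1], out[, 3]), , drop = FALSE]
}

# An R-native reimplementation of the base LDA learner (solve()-based,
# independent code path) for dual-route checks.
r_lda_predict <- function(X, y, Xq) {
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0)
    return(rep(if (n1 >= n0 && n1 > 0) 1L else 0L, nrow(Xq)))
  mu1 <- colMeans(X[y == 1, , drop = FALSE])
  mu0 <- colMeans(X[y == 0, , drop = FALSE])
  C1 <- sweep(X[y == 1, , drop = FALSE], 2, mu1)
  C0 <- sweep(X[y == 0, , drop = FALSE], 2, mu0)
  S <- (crossprod(C1) + crossprod(C0)) / max(1, n1 + n0 - 2)
  ridge <- 0.05 * max(mean(diag(S)), 1e-30)
  w <- solve(S + diag(ridge, ncol(X)), mu1 - mu0)
  b <- log(n1 / n0) - sum(w * (mu1 + mu0) / 2)
  as.integer(as.numeric(Xq %*% w) + b > 0)
}

# First run of k consecutive values in x, or NULL.
first_run <- function(x, k) {
  if (length(x) < k) return(NULL)
  for (s in seq_len(length(x) - k + 1)) {
    if (x[s + k - 1] - x[s] == k - 1) return(x[s:(s + k - 1)])
  }
  NULL
}

# Graft a 3-pair inter-molecular seed onto consecutive unpaired
# stretches of two random single-molecule structures; returns NULL when
# no consecutive stretch exists.
graft_joint <- function(s, t) {
  na <- nchar(s)
  st <- dotbracket_to_table(paste0(s, "&", t))
  ap <- first_run(which(st$partner[1:na] == 0), 3)
  bp <- first_run(which(st$partner[(na + 1):st$n] == 0) + na, 3)
  if (is.null(ap) || is.null(bp)) return(NULL)
  part <- st$partner
  part[ap] <- rev(bp); part[bp] <- rev(ap)
  list(joint = structure_table(part, cut = na), ap = ap, bp = bp)
}

# Random balanced dot-bracket strings (via random nested structures).
rand_dotbracket <- function(n) {
  chars <- rep(".", n)
  open <- integer(0)
  for (i in seq_len(n)) {
    roll <- runif(1)
    if (roll < 0.35) { chars[i] <- "("; open <- c(open, i) }
    else if (roll < 0.7 && length(open) > 0) {
      chars[i] <- ")"; open <- open[-length(open)]
    }
  }
  chars[open] <- "."  # drop unmatched opens
  paste(chars, collapse = "")
}

# A binding_site object built directly from chosen pairs (both endpoints
# of each strand paired, as the site-clipping rule guarantees).
make_site <- function(srna_seq, target_seq, pairs,
                      dg_binding = -10, ddg_binding = -8) {
  structure(list(seed_id = "seedX",
                 srna_site = c(1L, nchar(srna_seq)),
                 target_site = c(1L, nchar(target_seq)),
                 srna_seq = srna_seq, target_seq = target_seq,
                 pairs = pairs,
                 structure = starpick:::hybrid_dotbracket(nchar(srna_seq),
                                                          nchar(target_seq),
                                                          pairs),
                 dg_binding = dg_binding, ddg_binding = ddg_binding),
            class = "binding_site")
}

# Random hybrid with paired outermost positions on both strands.
rand_site <- function() {
  resample <- function(x, k) x[sample.int(length(x), k)]
  np <- sample(2:10, 1)
  na <- np + sample(0:6, 1); nb <- np + sample(0:6, 1)
  a_pos <- sort(c(1L, na,
                  if (np > 2) resample(2:(na - 1), np - 2)))
  b_pos <- sort(c(1L, nb,
                  if (np > 2) resample(2:(nb - 1), np - 2)),
                decreasing = TRUE)
  pairs <- cbind(srna = as.integer(a_pos), target = as.integer(b_pos))
  make_site(rand_rna(na), rand_rna(nb), pairs)
}

dummy_seed_row <- function(length = 6L, dg = -12, ddg = -9) {
  data.frame(seed_id = "seedX", srna_start = 1L, srna_end = length,
             target_start = 1L, target_end = length, length = length,
             n_gc = 3L, n_gu = 0L, n_au = length - 3L, max_consec_gc = 2L,
             dg_hybrid_seed = dg, ddg_seed = ddg)
}

# Voting stub: k_pos classifiers always vote positive, the rest negative.
stub_model <- function(k_pos, k_total) {
  const <- function(sign) c(sign, rep(0, 5))   # intercept-only rule
  clfs <- c(replicate(k_pos, const(1), simplify = FALSE),
            replicate(k_total - k_pos, const(-1), simplify = FALSE))
  ensemble_model(subset = c(1L, 4L, 18L, 19L, 22L), classifiers = clfs)
}
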