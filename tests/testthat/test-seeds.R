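toy <- toy_engine()

test_that("helix enumeration finds planted matches and trims wobbles", {
  h <- enumerate_helices("GGGGG", "CCCCC")
  expect_equal(nrow(h), 1)
  expect_equal(h$length, 5)
  expect_equal(h$n_gc, 5)
  expect_equal(h$n_gu, 0)

  # terminal U.G wobble trimmed from the run
  h2 <- enumerate_helices("UGGGGG", "CCCCCG")
  expect_equal(nrow(h2), 1)
  expect_equal(h2$length, 5)
  expect_equal(h2$n_gc, 5)
  expect_equal(h2$srna_start, 2)
  expect_equal(h2$target_end, 5)

  expect_equal(nrow(enumerate_helices(strrep("A", 30), strrep("C", 30))), 0)
})

test_that("enumeration agrees with the brute-force diagonal-scan oracle", {
  set.seed(11)
  for (rep in 1:40) {
    a <- rand_rna(40)
    b <- rand_rna(40)
    got <- enumerate_helices(a, b)
    want <- oracle_helices(a, b)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want) > 0) {
      m <- as.matrix(got[, c("srna_start", "srna_end",
                             "target_start", "target_end")])
      storage.mode(m) <- "integer"
      expect_equal(m, want, ignore_attr = TRUE)
    }
  }
})

test_that("no surviving seed has a terminal wobble; trimming is idempotent", {
  set.seed(12)
  for (rep in 1:30) {
    a <- rand_rna(50); b <- rand_rna(50)
    h <- enumerate_helices(a, b, min_len = 3L)
    if (nrow(h) == 0) next
    av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
    for (k in seq_len(nrow(h))) {
      first <- paste0(av[h$srna_start[k]], bv[h$target_end[k]])
      last <- paste0(av[h$srna_end[k]], bv[h$target_start[k]])
      expect_false(first %in% c("GU", "UG"))
      expect_false(last %in% c("GU", "UG"))
      expect_equal(h$length[k], h$n_gc[k] + h$n_gu[k] + h$n_au[k])
    }
  }
})

test_that("composition rules match the length-specific truth table", {
  case <- function(length, n_gc, n_gu, max_consec_gc = 0L) {
    data.frame(length = length, n_gc = n_gc, n_gu = n_gu,
               n_au = length - n_gc - n_gu, max_consec_gc = max_consec_gc)
  }
  truth <- list(
    # length 5: no wobble, >= 4 G-C or 3 consecutive G-C
    list(case(5, 4, 0, 2), TRUE),
    list(case(5, 4, 1, 2), FALSE),   # any wobble forbidden
    list(case(5, 3, 0, 3), TRUE),    # 3 consecutive G-C alternative
    list(case(5, 3, 0, 2), FALSE),
    list(case(5, 5, 0, 5), TRUE),
    # length 6-7: at most one wobble, at least 3 G-C
    list(case(6, 3, 0, 1), TRUE),
    list(case(6, 3, 1, 1), TRUE),
    list(case(6, 3, 2, 1), FALSE),
    list(case(6, 2, 0, 2), FALSE),
    list(case(7, 3, 1, 1), TRUE),
    list(case(7, 3, 2, 1), FALSE),
    # length 8-9: at most one wobble, at least 2 G-C
    list(case(8, 2, 1, 1), TRUE),
    list(case(8, 1, 0, 1), FALSE),
    list(case(8, 2, 2, 1), FALSE),
    list(case(9, 2, 1, 2), TRUE),
    list(case(9, 2, 2, 1), FALSE),
    # length >= 10: at most 4 wobbles, at least 2 G-C
    list(case(10, 2, 4, 1), TRUE),
    list(case(10, 2, 5, 1), FALSE),
    list(case(10, 1, 0, 1), FALSE),
    list(case(12, 2, 4, 1), TRUE),
    list(case(12, 2, 5, 1), FALSE))
  for (tc in truth) {
    expect_equal(passes_composition_rules(tc[[1]]), tc[[2]],
                 info = paste(unlist(tc[[1]]), collapse = "/"))
  }
  expect_error(passes_composition_rules(case(4, 2, 0)), "length")
})

test_that("seed scoring adds opening costs to the duplex energy", {
  # planted all-G-C 5-mer in structure-free context: opening terms vanish
  pr <- generate_pair(seed_len = 5L, n_gc = 5L, rng_seed = 2)
  seeds <- enumerate_helices(pr$srna, pr$target)
  expect_equal(nrow(seeds), 1)
  seeds <- score_seeds(seeds, pr$srna, pr$target, toy)
  expect_equal(seeds$dg_hybrid_seed, -15)
  expect_equal(seeds$ddg_seed, -15)

  # seed inside a designed hairpin stem: accessibility penalty is real
  occ <- generate_pair(seed_len = 5L, n_gc = 5L, context = "occluded",
                       rng_seed = 2)
  so <- score_seeds(enumerate_helices(occ$srna, occ$target)[1, ],
                    occ$srna, occ$target, toy)
  expect_gt(so$ddg_seed[1], so$dg_hybrid_seed[1])
  expect_gt(so$ddg_seed[1], seeds$ddg_seed)
})

test_that("seed selection applies the strict -2 kcal/mol rule", {
  base <- data.frame(length = 6L, n_gc = 3L, n_gu = 0L, n_au = 3L,
                     max_consec_gc = 2L)
  seeds <- rbind(base, base, base)
  seeds$seed_id <- c("a", "b", "c")
  seeds$ddg_seed <- c(-2.5, -2.0, -1.0)
  kept <- select_seeds(seeds)
  expect_equal(kept$seed_id, "a")      # exactly -2 is dropped
  expect_equal(nrow(select_seeds(seeds[0, ])), 0)
  # subset and order preservation
  seeds$ddg_seed <- c(-3, -4, -5)
  expect_equal(select_seeds(seeds)$seed_id, c("a", "b", "c"))
})
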