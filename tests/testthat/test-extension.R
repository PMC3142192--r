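toy <- toy_engine()

test_that("outward scan halts at the first intra-molecular pair", {
  # molecule a: 12 nt with a hairpin at 1..8 ( (((..))) ) directly left of
  # a 4-pair seed at 9..12; molecule b: 8 nt, pairs 9..12 with 8..5
  joint <- dotbracket_to_table("(((..)))((((&.))))...")
  expect_equal(joint$cut, 12)
  site <- scan_outward(joint, seed_a = c(9, 12), seed_b = c(14, 17))
  expect_equal(site$a_site, c(9, 12))        # halted by the hairpin
  expect_equal(site$b_site, c(14, 17))       # trailing unpaired clipped

  # no intra-molecular pairs anywhere: site spans outermost pairs
  joint2 <- dotbracket_to_table("..((((....&.))))...")
  site2 <- scan_outward(joint2, seed_a = c(3, 6), seed_b = c(12, 15))
  expect_equal(site2$a_site, c(3, 6))
  expect_equal(site2$b_site, c(12, 15))
})

test_that("scan matches a manual trace on a mixed structure", {
  # a: positions 1-14; intra pair (1,6); inter pairs 8..11 with b
  # b: inter partners plus an intra hairpin far right
  db <- paste0("(....)." , "((((", "..." , "&", "..", "))))", ".(((...))).")
  joint <- dotbracket_to_table(db)
  site <- scan_outward(joint, seed_a = c(8, 11), seed_b = c(17, 20))
  # left scan on a halts before position 6 (intra pair); clipping pulls
  # the boundary back to the outermost inter pair at 8
  expect_equal(site$a_site, c(8, 11))
  expect_equal(site$b_site, c(17, 20))
})

test_that("no returned site ever contains an intra-molecular pair", {
  set.seed(21)
  for (rep in 1:40) {
    g <- graft_joint(rand_dotbracket(sample(6:14, 1)),
                     rand_dotbracket(sample(6:14, 1)))
    if (is.null(g)) next
    joint <- g$joint; ap <- g$ap; bp <- g$bp
    site <- scan_outward(joint, seed_a = range(ap), seed_b = range(bp))
    intra <- which(joint$partner > 0 &
                   joint$molecule[pmax(joint$partner, 1)] == joint$molecule)
    expect_false(any(intra >= site$a_site[1] & intra <= site$a_site[2]))
    expect_false(any(intra >= site$b_site[1] & intra <= site$b_site[2]))
    # site contains the seed
    expect_lte(site$a_site[1], min(ap))
    expect_gte(site$a_site[2], max(ap))
  }
})

test_that("constrained co-folding matches exhaustive enumeration", {
  set.seed(22)
  for (rep in 1:12) {
    a <- paste0(rand_rna(3), "GGC", rand_rna(2))
    b <- paste0(rand_rna(2), "GCC", rand_rna(3))
    forced <- cbind(4:6, 5:3)   # GGC with GCC reversed
    st <- cofold_constrained(toy, a, b, forced)
    if (!cofold_satisfies(st, forced, nchar(a))) next
    want <- oracle_cofold_best(a, b, forced)
    expect_equal(attr(st, "energy"), want$energy, info = paste(a, b))
  }
})

test_that("co-fold honors every seed constraint or the extension aborts", {
  pr <- generate_pair(seed_len = 6L, n_gc = 4L, rng_seed = 31)
  seeds <- score_seeds(enumerate_helices(pr$srna, pr$target),
                       pr$srna, pr$target, toy)
  seed <- seeds[which.min(seeds$ddg_seed), ]
  cf <- cofold_with_seed(pr$srna, pr$target, seed, toy)
  expect_false(is.null(cf))
  for (t in 0:(seed$length - 1)) {
    p <- cf$joint$partner[seed$srna_start + t]
    expect_gt(p, cf$na)   # paired into the target molecule
  }
})

test_that("fully complementary pair in open context extends to a full duplex", {
  a <- "GCGGCAUCCGGAUGCGGCAU"
  b <- revcomp_rna(a)
  seeds <- enumerate_helices(a, b)
  seeds <- score_seeds(seeds, a, b, toy)
  seed <- seeds[which.max(seeds$length), ]
  expect_equal(seed$length, 20)
  site <- extend_seed(a, b, seed, toy)
  expect_equal(site$srna_site, c(1, 20))
  expect_equal(site$target_site, c(1, 20))
  expect_equal(nrow(site$pairs), 20)
})

test_that("site scoring reduces to seed scoring for a seed-sized site", {
  pr <- generate_pair(seed_len = 5L, n_gc = 5L, rng_seed = 5)
  seeds <- score_seeds(enumerate_helices(pr$srna, pr$target),
                       pr$srna, pr$target, toy)
  site <- extend_seed(pr$srna, pr$target, seeds[1, ], toy)
  expect_equal(unname(site$srna_site), c(seeds$srna_start, seeds$srna_end))
  expect_equal(site$dg_binding, seeds$dg_hybrid_seed)
  expect_equal(site$ddg_binding, seeds$ddg_seed)   # unstructured context
  # determinism
  site2 <- extend_seed(pr$srna, pr$target, seeds[1, ], toy)
  expect_identical(site[names(site) != "seed_id"],
                   site2[names(site2) != "seed_id"])
})
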