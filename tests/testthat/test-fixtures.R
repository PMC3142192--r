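toy <- toy_engine()

test_that("planted seeds are recovered uniquely and reproducibly", {
  pr <- generate_pair(seed_len = 6L, n_gc = 6L, rng_seed = 3)
  h <- enumerate_helices(pr$srna, pr$target)
  expect_equal(nrow(h), 1)
  expect_equal(h$srna_start, pr$truth$srna_start)
  expect_equal(h$srna_end, pr$truth$srna_end)
  expect_equal(h$target_start, pr$truth$target_start)
  expect_equal(h$target_end, pr$truth$target_end)
  expect_equal(h$n_gc, 6)

  pr2 <- generate_pair(seed_len = 6L, n_gc = 6L, rng_seed = 3)
  expect_identical(pr$srna$residues, pr2$srna$residues)
  expect_identical(pr$target$residues, pr2$target$residues)
})

test_that("planted seeds pass the composition rules they were built for", {
  set.seed(61)
  for (rep in 1:15) {
    len <- sample(5:9, 1)
    gc <- if (len == 5L) sample(4:5, 1) else sample((len - 2L):len, 1)
    pr <- generate_pair(seed_len = len, n_gc = gc, rng_seed = rep)
    h <- enumerate_helices(pr$srna, pr$target)
    planted <- h[h$srna_start <= pr$truth$srna_start &
                 h$srna_end >= pr$truth$srna_end, , drop = FALSE]
    expect_gte(nrow(planted), 1)
    expect_true(any(passes_composition_rules(planted)))
  }
})

test_that("occlusion by a designed hairpin raises the seed energy", {
  for (seed in c(2, 9, 17)) {
    open <- generate_pair(seed_len = 6L, n_gc = 4L, context = "open",
                          rng_seed = seed)
    occ <- generate_pair(seed_len = 6L, n_gc = 4L, context = "occluded",
                         rng_seed = seed)
    score1 <- score_seeds(enumerate_helices(open$srna, open$target)[1, ],
                          open$srna, open$target, toy)
    score2 <- score_seeds(enumerate_helices(occ$srna, occ$target)[1, ],
                          occ$srna, occ$target, toy)
    expect_gt(score2$ddg_seed, score1$ddg_seed)
  }
})

test_that("synthetic feature tables have the stated class structure", {
  tb <- generate_training_table(rng_seed = 4)
  expect_equal(sum(tb$label == "positive"), 31)
  expect_equal(sum(tb$label == "negative"), 102)
  expect_true(all(feature_names() %in% names(tb)))
  expect_equal(tb$f14, tb$f12 + tb$f13)
  expect_equal(tb$f8 + tb$f17, rep(100, nrow(tb)))
  # signal lives on f19 (lower in positives) and f22 (higher)
  expect_lt(mean(tb$f19[tb$label == "positive"]),
            mean(tb$f19[tb$label == "negative"]))
  expect_gt(mean(tb$f22[tb$label == "positive"]),
            mean(tb$f22[tb$label == "negative"]))
  expect_identical(generate_training_table(rng_seed = 4), tb)

  # no planted signal: stability near the majority-class prior
  tb0 <- generate_training_table(n_pos = 20, n_neg = 40,
                                 effect = c(f19 = 0, f22 = 0), rng_seed = 5)
  st <- stability_analysis(c(19L, 22L), tb0, n_rounds = 200, rng_seed = 6)
  expect_lt(abs(st$stability_index - 2 / 3), 0.09)
})

test_that("synthetic genomes plant recoverable targets on both strands", {
  sr <- generate_srna(seed_len = 9L, n_gc = 7L, id = "s", rng_seed = 3)
  srna <- sr$srna
  g <- generate_genome(srna, sr$seed_interval, n_genes = 8, n_planted = 2,
                       planted_genes = c(3, 4), rng_seed = 7)
  expect_equal(g$truth, c("g03", "g04"))
  expect_equal(nrow(g$genome$genes), 8)
  strands <- g$genome$genes$strand[g$genome$genes$gene_id %in% g$truth]
  expect_setequal(strands, c("+", "-"))
  for (gid in g$truth) {
    gene <- g$genome$genes[g$genome$genes$gene_id == gid, ]
    tw <- extract_target_window(g$genome$contigs[[1]], gene)
    seeds <- enumerate_helices(srna, tw)
    seeds <- seeds[passes_composition_rules(seeds), , drop = FALSE]
    expect_gte(nrow(seeds), 1)   # planted complement present in the window
  }
  # determinism of the whole genome build
  g2 <- generate_genome(srna, sr$seed_interval, n_genes = 8, n_planted = 2,
                        planted_genes = c(3, 4), rng_seed = 7)
  expect_identical(g$genome$contigs, g2$genome$contigs)
})

test_that("genome fixtures round-trip through FASTA + GFF3", {
  sr <- generate_srna(seed_len = 8L, n_gc = 6L, length = 40L,
                      seed_pos = 11L, id = "s", rng_seed = 4)
  g <- generate_genome(sr$srna, sr$seed_interval, n_genes = 4, n_planted = 1,
                       planted_genes = 2, rng_seed = 8)
  fa <- withr::local_tempfile(fileext = ".fa")
  gff <- withr::local_tempfile(fileext = ".gff3")
  write_genome_fixtures(g$genome, fa, gff)
  ann <- read_annotation(gff, "gff3+fasta", fasta = fa)
  expect_equal(nrow(ann$genes), 4)
  expect_equal(sort(ann$genes$gene_id), sort(g$genome$genes$gene_id))
  ord <- match(g$genome$genes$gene_id, ann$genes$gene_id)
  expect_equal(ann$genes$start_codon_pos[ord], g$genome$genes$start_codon_pos)
  expect_equal(ann$contigs[[1]], g$genome$contigs[[1]])
})

test_that("pipeline-derived training tables contain both classes", {
  tab <- generate_candidate_training(toy, n_pairs = 12, rng_seed = 5)
  expect_gte(sum(tab$label == "positive"), 2)
  expect_gte(sum(tab$label == "negative"), 2)
  expect_lt(mean(tab$f19[tab$label == "positive"]),
            mean(tab$f19[tab$label == "negative"]))
  expect_identical(generate_candidate_training(toy, n_pairs = 12,
                                               rng_seed = 5), tab)
})
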