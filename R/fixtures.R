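#' Synthetic sRNA-target pair with a planted seed helix
#'
#' Builds a label-known sRNA/target pair: random (or structure-free)
#' backgrounds with an exact antiparallel complementary stretch — with a
#' chosen number of G-C pairs and G-U wobbles — planted at stated
#' positions. In the `"occluded"` context the planted target stretch is
#' wrapped in a designed hairpin stem so that its opening energy is large;
#' in the `"open"` context backgrounds are poly-A, which admits no
#' intra-molecular structure under any engine, so opening energies vanish.
#'
#' @param seed_len planted helix length (nt).
#' @param n_gc number of G-C pairs in the helix.
#' @param n_gu number of G-U wobble pairs (the rest are A-U).
#' @param srna_len,target_len molecule lengths (nt).
#' @param srna_pos,target_pos 1-based start of the planted stretch on each
#'   molecule.
#' @param context `"open"` or `"occluded"`.
#' @param background `"structure_free"` (poly-A sRNA background; poly-A
#'   or poly-C target background, chosen so that neither molecule can
#'   fold on its own background), `"au_rich"` or `"uniform"`.
#' @param rng_seed integer seed; identical seeds give identical pairs.
#' @return list with `srna`, `target` ([rna_seq()]), and `truth`
#'   (data.frame with the planted seed's intervals and composition).
#' @section Unique recovery: with at most two A-U pairs (and G-C counts
#'   that fit two blocks of four, i.e. `n_gc + n_gu <= 8` for mixed
#'   plants) the planted helix is the only rule-passing candidate the
#'   pair contains. A-U-richer or near-saturated compositions can admit
#'   shifted duplicate helices; callers who care should rescan the
#'   output (as [generate_genome()]'s audit does).
#' @export
generate_pair <- function(seed_len = 6L, n_gc = 6L, n_gu = 0L,
                          srna_len = 60L, target_len = 250L,
                          srna_pos = 20L, target_pos = 120L,
                          context = c("open", "occluded"),
                          background = c("structure_free", "au_rich", "uniform"),
                          rng_seed = 1L) {
  context <- match.arg(context)
  background <- match.arg(background)
  stopifnot(n_gc + n_gu <= seed_len,
            srna_pos + seed_len - 1L <= srna_len,
            target_pos + seed_len - 1L <= target_len)
  set.seed(rng_seed)
  helix <- plant_letters(seed_len, n_gc, n_gu, shuffle = TRUE)
  plant_s <- helix$srna
  plant_t <- helix$target
  bg <- function(n, letter) switch(background,
    structure_free = strrep(letter, n),
    au_rich = paste(sample(c("A", "U", "C", "G"), n, replace = TRUE,
                           prob = c(0.4, 0.4, 0.1, 0.1)), collapse = ""),
    uniform = paste(sample(c("A", "C", "G", "U"), n, replace = TRUE),
                    collapse = ""))
  splice <- function(base, at, what) {
    paste0(substr(base, 1, at - 1L), what,
           substr(base, at + nchar(what), nchar(base)))
  }
  srna <- splice(bg(srna_len, "A"), srna_pos, plant_s)
  target <- splice(bg(target_len, helix$target_background), target_pos, plant_t)
  if (background == "structure_free" && helix$target_background == "C") {
    # guard letters flanking a mixed plant: a C beside the sRNA plant and
    # an A beside the target plant stop shifted alignments from running
    # across the plant boundary into the backgrounds
    guard <- function(s, at, letter) {
      if (at >= 1L && at <= nchar(s))
        substr(s, at, at) <- letter
      s
    }
    srna <- guard(guard(srna, srna_pos - 1L, "C"),
                  srna_pos + seed_len, "C")
    target <- guard(guard(target, target_pos - 1L, "A"),
                    target_pos + seed_len, "A")
  }
  if (context == "occluded") {
    # hairpin partner of the planted stretch 4 nt downstream
    partner_at <- target_pos + seed_len + 4L
    stopifnot(partner_at + seed_len - 1L <= target_len)
    target <- splice(target, partner_at, revcomp_rna(plant_t))
  }
  truth <- data.frame(srna_start = srna_pos, srna_end = srna_pos + seed_len - 1L,
                      target_start = target_pos,
                      target_end = target_pos + seed_len - 1L,
                      length = seed_len, n_gc = n_gc, n_gu = n_gu,
                      n_au = seed_len - n_gc - n_gu)
  list(srna = rna_seq(sprintf("srna_s%d", rng_seed), srna),
       target = rna_seq(sprintf("target_s%d", rng_seed), target),
       truth = truth)
}

# Letters of a planted helix over structure-free backgrounds. Two design
# constraints drive the letter choice. (i) Unique recovery: a repetitive
# plant admits shifted off-diagonal helices, so letters must vary along
# the plant. (ii) Controlled accessibility: neither molecule may contain
# a letter that pairs with its own background, or the planted region
# becomes combinatorially occluded by background pairing.
#
# Mixed helices put G (G-C pairs), A (A-U pairs) and G (wobbles) on the
# sRNA side — the sRNA is then {A, G}-only and exactly structure-free
# over its poly-A background — and C/U on the target side, which is
# {C, U}-only and exactly structure-free over a poly-C background.
# Watson-Crick-only all-G-C helices instead alternate G and C over
# poly-A backgrounds on both molecules (a poly-G plant would complement
# a poly-C background wholesale). G-C/G-U runs are broken up by the A-U
# pairs so that accidental sRNA-G-run vs C-background helices stay below
# the minimum seed length. Returns the sRNA-side stretch 5'->3' and the
# antiparallel target-side stretch 5'->3'.
plant_letters <- function(seed_len, n_gc, n_gu, shuffle = FALSE) {
  n_au <- seed_len - n_gc - n_gu
  strong <- c(rep("GC", n_gc), rep("GU", n_gu))
  if (shuffle && length(strong) > 1L) strong <- sample(strong)
  if (n_au == 0L) {
    kinds <- strong
  } else {
    # distribute the strong pairs into n_au + 1 blocks of at most 4,
    # filled from the back so that at most two blocks are non-empty for
    # typical compositions. Shifted self-alignments of block patterns
    # form spurious helices when three or more comparable blocks (or a
    # leading run of several A-U pairs next to a large block) occur;
    # with <= 2 A-U pairs the back-filled layout provably keeps every
    # shifted alignment below the minimum seed length. A-U-richer plants
    # can carry shifted duplicates — callers see them via the audit.
    ng <- n_au + 1L
    sizes <- integer(ng); rem <- length(strong)
    for (i in rev(seq_len(ng))) {
      sizes[i] <- min(4L, rem); rem <- rem - sizes[i]
    }
    sizes[1] <- sizes[1] + rem
    kinds <- character(0)
    taken <- 0L
    for (gi in seq_len(ng)) {
      if (sizes[gi] > 0L) kinds <- c(kinds, strong[taken + seq_len(sizes[gi])])
      taken <- taken + sizes[gi]
      if (gi <= n_au) kinds <- c(kinds, "AU")
    }
  }
  all_gc <- (n_au == 0L && n_gu == 0L)
  if (all_gc) {
    # pure G/C alternation is period-2 and self-similar from length 7 on
    # (a shift-2 alignment against its own complement reaches seed
    # length), so longer all-G-C plants double the C after position 4,
    # which leaves no 5-mer repeated at any lag
    alt <- function(k, first) {
      two <- if (first == "G") c("G", "C") else c("C", "G")
      rep_len(two, k)
    }
    srna_side <- if (seed_len <= 6L) alt(seed_len, "G")
                 else c(alt(4L, "G"), alt(seed_len - 4L, "C"))
  } else {
    srna_side <- vapply(kinds, function(k)
      switch(k, GC = "G", AU = "A", GU = "G"), character(1))
  }
  target_side <- c(A = "U", C = "G", G = "C")[srna_side]
  target_side[kinds == "GU"] <- "U"
  list(srna = paste(srna_side, collapse = ""),
       target = paste(rev(target_side), collapse = ""),
       kinds = kinds,
       target_background = if (any(target_side == "U")) "C" else "A")
}

#' Synthetic labeled feature table
#'
#' Draws feature vectors in the schema of [extract_features()] with class
#' signal planted only on f19 (positives shifted to lower
#' accessibility-corrected binding energies) and f22 (positives carry
#' longer seeds); all other features are drawn from the same distribution
#' in both classes. The default class sizes mirror the 31 positive / 102
#' negative imbalance of curated interaction collections. The default
#' effect sizes make the planted signal clearly separable (2.5 SD on f19,
#' 2 nt on f22) while leaving a few percent of class overlap: strong
#' enough that a wrapper selection recovers the informative pair against
#' twenty chance-correlated noise features, weak enough that boundary
#' errors remain and the class imbalance shows up as a
#' specificity/sensitivity asymmetry.
#'
#' @param n_pos,n_neg class sizes (each >= 2).
#' @param effect named numeric vector `c(f19 = ..., f22 = ...)`: the shift
#'   applied to positives (kcal/mol on f19, nt on f22).
#' @param rng_seed integer seed.
#' @return A `training_table` data.frame (`f1` ... `f22`, `label`,
#'   `pair_id`, `seed_id`).
#' @export
generate_training_table <- function(n_pos = 31L, n_neg = 102L,
                                    effect = c(f19 = 4, f22 = 3),
                                    rng_seed = 1L) {
  stopifnot(n_pos >= 2L, n_neg >= 2L)
  set.seed(rng_seed)
  n <- n_pos + n_neg
  y <- c(rep(1L, n_pos), rep(0L, n_neg))
  tb <- data.frame(matrix(0, n, 22, dimnames = list(NULL, feature_names())))
  # shared composition block respecting the percentage identities
  a <- pmax(0, pmin(100, rnorm(n, 30, 6))); c_ <- pmax(0, pmin(100, rnorm(n, 20, 5)))
  g <- pmax(0, pmin(100, rnorm(n, 22, 5)))
  tot <- a + c_ + g
  scale <- pmin(1, 100 / tot)
  a <- a * scale; c_ <- c_ * scale; g <- g * scale
  u <- 100 - a - c_ - g
  tb$f1 <- a; tb$f2 <- c_; tb$f3 <- g; tb$f4 <- u
  tb$f5 <- c_ + g; tb$f6 <- a + u; tb$f7 <- a + c_
  tb$f8 <- pmax(40, pmin(100, rnorm(n, 80, 10)))
  tb$f17 <- 100 - tb$f8
  tb$f9 <- tb$f8 * runif(n, 0.8, 1)
  tb$f10 <- runif(n, 0.7, 1)
  tb$f11 <- 5L + rbinom(n, 10, 0.4)
  tb$f12 <- rbinom(n, 3, 0.4); tb$f13 <- rbinom(n, 3, 0.4)
  tb$f14 <- tb$f12 + tb$f13
  il_share <- runif(n)
  tb$f15 <- tb$f17 * il_share; tb$f16 <- tb$f17 * (1 - il_share)
  tb$f18 <- rnorm(n, -14, 3)
  tb$f19 <- rnorm(n, -4, 2) - y * effect[["f19"]]
  tb$f20 <- rnorm(n, -8, 2)
  tb$f21 <- rnorm(n, -4, 1.5)
  tb$f22 <- 5L + rbinom(n, 8, 0.25) + y * round(effect[["f22"]])
  tb$label <- factor(ifelse(y == 1L, "positive", "negative"),
                     levels = c("negative", "positive"))
  tb$pair_id <- sprintf("pair%03d", seq_len(n))
  tb$seed_id <- sprintf("seed%03d", seq_len(n))
  class(tb) <- c("training_table", class(tb))
  tb
}

#' Synthetic sRNA with one designed seed stretch
#'
#' Builds a poly-A-background sRNA carrying a single planted seed stretch
#' (same letter scheme as [generate_pair()]: G for G-C pairs, A for A-U
#' pairs, G for wobbles), without the boundary guard letters that
#' [generate_pair()] adds around its plants. This is the form [generate_genome()] expects:
#' guard letters would pair with start-codon bases in the genomic
#' windows and manufacture spurious seeds on every gene.
#'
#' @inheritParams generate_pair
#' @param length sRNA length (nt).
#' @param seed_pos 1-based start of the seed stretch.
#' @param id sequence identifier.
#' @return list with `srna` ([rna_seq()]) and `seed_interval`
#'   (`c(start, end)` of the planted stretch).
#' @export
generate_srna <- function(seed_len = 9L, n_gc = 7L, n_gu = 0L,
                          length = 60L, seed_pos = 20L, id = "synthetic_srna",
                          rng_seed = 1L) {
  stopifnot(seed_pos + seed_len - 1L <= length)
  set.seed(rng_seed)
  helix <- plant_letters(seed_len, n_gc, n_gu, shuffle = TRUE)
  res <- paste0(strrep("A", seed_pos - 1L), helix$srna,
                strrep("A", length - seed_pos - seed_len + 1L))
  list(srna = rna_seq(id, res),
       seed_interval = c(seed_pos, seed_pos + seed_len - 1L))
}

#' Synthetic genome with planted sRNA targets
#'
#' Builds a contig carrying `n_genes` non-overlapping protein-coding genes
#' on alternating strands. `n_planted` of them carry, inside their
#' window around the start codon (at relative position `plant_rel`), an
#' open, rule-passing complement of the sRNA stretch given by
#' `srna_seed_interval`, so the pipeline should recover exactly these
#' genes. The contig background is C in mRNA sense for every gene window
#' (forward-strand C, with G patches spanning minus-strand gene windows):
#' a C background can pair neither with itself, with the planted C/U
#' letters, nor with the sRNA's poly-A background, so windows stay
#' structure-free on both strands and no spurious window-wide duplex with
#' the sRNA can form. The sRNA seed stretch should therefore contain at
#' least one A-U pair (see [generate_pair()]'s letter scheme); a G on the
#' planted target side would pair the C background and is warned about.
#' Generators audit their own output: the returned `audit` lists
#' unplanned rule-passing seed candidates between the sRNA and any
#' decoy-gene window.
#'
#' @param srna the sRNA ([rna_seq()] or character).
#' @param srna_seed_interval `c(start, end)` stretch of the sRNA whose
#'   complement is planted.
#' @param n_genes number of genes.
#' @param n_planted number of genes receiving a planted target site.
#' @param plant_rel relative position (start-codon scale, negative =
#'   upstream) of the first planted base.
#' @param planted_genes optional integer indices of the genes to plant
#'   (overrides the random choice; useful to cover both strands).
#' @param rng_seed integer seed.
#' @return list with `genome` (list of `contigs`, `genes` as in
#'   [read_annotation()]), `truth` (planted gene ids), `audit`
#'   (data.frame of accidental candidate seeds on decoy genes).
#' @export
generate_genome <- function(srna, srna_seed_interval, n_genes = 20L,
                            n_planted = 2L, plant_rel = -20L,
                            planted_genes = NULL, rng_seed = 1L) {
  stopifnot(n_planted <= n_genes)
  set.seed(rng_seed)
  sa <- res_of(srna)
  plant <- revcomp_rna(substr(sa, srna_seed_interval[1], srna_seed_interval[2]))
  if (grepl("G", plant))
    warning("planted target stretch contains G, which pairs the C window ",
            "background; expect occluded or ambiguous planted sites")
  gene_len <- 300L; spacing <- 700L; margin <- 400L
  L <- margin * 2L + n_genes * spacing
  contig <- strrep("C", L)
  planted_idx <- if (is.null(planted_genes))
    sort(sample.int(n_genes, n_planted)) else sort(as.integer(planted_genes))
  genes <- data.frame(gene_id = sprintf("g%02d", seq_len(n_genes)),
                      contig_id = "synthetic_contig",
                      strand = rep(c("+", "-"), length.out = n_genes),
                      start_codon_pos = 0L, stringsAsFactors = FALSE)
  splice <- function(base, at, what)
    paste0(substr(base, 1, at - 1L), what,
           substr(base, at + nchar(what), nchar(base)))
  for (k in seq_len(n_genes)) {
    anchor <- margin + (k - 1L) * spacing
    if (genes$strand[k] == "+") {
      S <- anchor
      contig <- splice(contig, S, "AUG")
      contig <- splice(contig, S + gene_len - 3L, "UAA")
    } else {
      S <- anchor + gene_len - 1L
      # G patch over the minus-strand window + flanks so the mRNA-sense
      # background of this gene's window is C like everywhere else
      patch1 <- max(1L, S - 199L); patch2 <- min(L, S + 250L)
      contig <- splice(contig, patch1, strrep("G", patch2 - patch1 + 1L))
      contig <- splice(contig, S - 2L, revcomp_rna("AUG"))
      contig <- splice(contig, anchor, revcomp_rna("UAA"))
    }
    genes$start_codon_pos[k] <- S
    if (k %in% planted_idx) {
      # sense-strand coordinate of the planted stretch: plant_rel is on
      # the no-zero start-codon scale
      off <- if (plant_rel > 0L) plant_rel - 1L else plant_rel
      if (genes$strand[k] == "+") {
        contig <- splice(contig, S + off, plant)
      } else {
        # sense position S+off..: forward-strand interval ending at S-off
        p2 <- S - off
        contig <- splice(contig, p2 - nchar(plant) + 1L, revcomp_rna(plant))
      }
    }
  }
  genome <- list(contigs = c(synthetic_contig = contig), genes = genes)
  audit <- audit_decoy_seeds(genome, sa, setdiff(seq_len(n_genes), planted_idx))
  list(genome = genome, truth = genes$gene_id[planted_idx], audit = audit)
}

# Scan decoy-gene windows for unplanned rule-passing seed candidates.
audit_decoy_seeds <- function(genome, srna_res, decoy_idx) {
  hits <- list()
  for (k in decoy_idx) {
    tw <- extract_target_window(genome$contigs[[1]],
                                genome$genes[k, , drop = FALSE])
    seeds <- enumerate_helices(srna_res, tw)
    if (nrow(seeds) == 0L) next
    seeds <- seeds[passes_composition_rules(seeds), , drop = FALSE]
    if (nrow(seeds) > 0L) {
      seeds$gene_id <- genome$genes$gene_id[k]
      hits[[length(hits) + 1L]] <- seeds
    }
  }
  if (length(hits)) do.call(rbind, hits) else
    data.frame(gene_id = character(0))
}

#' Write a synthetic genome as FASTA + GFF3 fixture files
#'
#' @param genome list with `contigs` and `genes` ([generate_genome()]).
#' @param fasta_path,gff_path output paths.
#' @return Invisibly, the two paths.
#' @export
write_genome_fixtures <- function(genome, fasta_path, gff_path) {
  seqs <- lapply(names(genome$contigs), function(id)
    rna_seq(id, genome$contigs[[id]], allow_n = TRUE))
  write_fasta(seqs, fasta_path)
  g <- genome$genes
  gene_len <- 300L
  lines <- c("##gff-version 3")
  for (k in seq_len(nrow(g))) {
    S <- g$start_codon_pos[k]
    if (g$strand[k] == "+") { s1 <- S; s2 <- S + gene_len - 1L }
    else { s1 <- S - gene_len + 1L; s2 <- S }
    lines <- c(lines, sprintf(
      "%s\tstarpick\tCDS\t%d\t%d\t.\t%s\t0\tID=%s;locus_tag=%s",
      g$contig_id[k], s1, s2, g$strand[k], g$gene_id[k], g$gene_id[k]))
  }
  writeLines(lines, gff_path)
  invisible(c(fasta_path, gff_path))
}

#' Pipeline-derived synthetic training table
#'
#' Emulates the construction of a real training set from candidate
#' binding sites. A fraction of the synthetic sRNA-target pairs carries a
#' strong open seed that is declared the experimentally "validated" site;
#' the remaining pairs carry only a weaker pseudo seed and no validated
#' site, so their candidates become negative samples. The
#' candidate-generation stages (enumeration, screening, extension,
#' feature extraction) are run on every pair and
#' [build_training_samples()] labels the candidates against the planted
#' validated intervals.
#'
#' @param engine an [energy_engines] object.
#' @param n_pairs number of synthetic pairs.
#' @param pos_fraction fraction of pairs with a validated strong seed.
#' @param rng_seed integer seed.
#' @return A `training_table` data.frame.
#' @export
generate_candidate_training <- function(engine, n_pairs = 30L,
                                        pos_fraction = 1 / 3, rng_seed = 1L) {
  cands <- list(); vals <- list()
  n_strong <- max(2L, round(pos_fraction * n_pairs))
  for (k in seq_len(n_pairs)) {
    pid <- sprintf("pair%03d", k)
    set.seed(derive_seed(rng_seed, k))
    if (k <= n_strong) {
      len <- sample(7:9, 1)
      gc <- len - sample(2:3, 1)
    } else {
      len <- sample(6:7, 1)
      gc <- 3L
    }
    s_pos <- sample(5:40, 1)
    t_pos <- sample(30:200, 1)
    pr <- generate_pair(seed_len = len, n_gc = gc, n_gu = 0L,
                        srna_len = 60L, target_len = 250L,
                        srna_pos = s_pos, target_pos = t_pos,
                        context = "open", rng_seed = derive_seed(rng_seed, k, 2L))
    cand <- pair_candidates(pr$srna, pr$target, engine)
    if (nrow(cand) == 0L) next
    cand$pair_id <- pid
    cands[[length(cands) + 1L]] <- cand
    if (k <= n_strong)
      vals[[length(vals) + 1L]] <- data.frame(
        pair_id = pid, target_start = t_pos, target_end = t_pos + len - 1L)
  }
  build_training_samples(do.call(rbind, cands),
                         if (length(vals)) do.call(rbind, vals) else
                           data.frame(pair_id = character(0),
                                      target_start = integer(0),
                                      target_end = integer(0)))
}

# Candidate sites + features of one pair, without a model (training path).
pair_candidates <- function(srna, target, engine, min_seed_len = 5L,
                            seed_ddg_threshold = -2) {
  tw <- as_target_window(target)
  seeds <- enumerate_helices(srna, tw, min_len = min_seed_len)
  if (nrow(seeds) == 0L) return(data.frame())
  seeds <- seeds[passes_composition_rules(seeds), , drop = FALSE]
  if (nrow(seeds) == 0L) return(data.frame())
  seeds <- score_seeds(seeds, srna, tw, engine)
  seeds <- select_seeds(seeds, ddg_threshold = seed_ddg_threshold)
  if (nrow(seeds) == 0L) return(data.frame())
  rows <- list()
  for (k in seq_len(nrow(seeds))) {
    seed <- seeds[k, , drop = FALSE]
    site <- extend_seed(srna, tw, seed, engine)
    if (is.null(site) || is.na(site$ddg_binding)) next
    f <- extract_features(site, seed)
    rows[[length(rows) + 1L]] <- cbind(
      data.frame(seed_id = seed$seed_id,
                 target_start = site$target_site[1],
                 target_end = site$target_site[2],
                 ddg_seed = seed$ddg_seed, stringsAsFactors = FALSE),
      as.data.frame(as.list(f)))
  }
  if (length(rows) == 0L) return(data.frame())
  do.call(rbind, rows)
}
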