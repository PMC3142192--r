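#' Target window around an annotated start codon
#'
#' The putative binding region of a target mRNA is the sub-sequence from
#' 150 nt upstream of the first base of the start codon to 100 nt
#' downstream of (and including) that base — 250 nt in total, in mRNA
#' sense. Up to 100 nt of additional genomic flank on each side is kept as
#' context for accessibility calculations. Windows are truncated silently
#' at contig ends; minus-strand genes are reverse-complemented to mRNA
#' sense. Relative coordinates have no position 0: the first base of the
#' start codon is +1 and the base just upstream is -1.
#'
#' @param contig forward-strand contig sequence (character, RNA alphabet).
#' @param gene one-row data.frame or list with `gene_id`, `strand`,
#'   `start_codon_pos` (forward-strand coordinate of the first base of the
#'   start codon).
#' @param upstream,downstream window extent in nt (window length is
#'   `upstream + downstream`).
#' @param flank accessibility context kept on each side (nt).
#' @return A `target_window`: list with `gene_id`, `strand`, `residues`
#'   (the window, mRNA sense), `context` (window plus flanks), `offset`
#'   (flank width actually present on the left), `rel_start` (relative
#'   coordinate of window position 1).
#' @export
extract_target_window <- function(contig, gene, upstream = 150L,
                                  downstream = 100L, flank = 100L) {
  contig <- res_of(contig)
  L <- nchar(contig)
  S <- as.integer(gene$start_codon_pos)
  if (S < 1L || S > L) stop("start codon position outside contig")
  if (gene$strand == "+") {
    w1 <- max(1L, S - upstream); w2 <- min(L, S + downstream - 1L)
    c1 <- max(1L, w1 - flank); c2 <- min(L, w2 + flank)
    residues <- substr(contig, w1, w2)
    context <- substr(contig, c1, c2)
    offset <- w1 - c1
    rel_start <- w1 - S          # negative upstream; +1 handled by window_rel
  } else {
    w1 <- max(1L, S - downstream + 1L); w2 <- min(L, S + upstream)
    c1 <- max(1L, w1 - flank); c2 <- min(L, w2 + flank)
    residues <- revcomp_rna(substr(contig, w1, w2))
    context <- revcomp_rna(substr(contig, c1, c2))
    offset <- c2 - w2
    rel_start <- S - w2          # distance of window start (sense) from S
  }
  structure(list(gene_id = as.character(gene$gene_id),
                 strand = gene$strand,
                 residues = residues, context = context,
                 offset = as.integer(offset),
                 rel_start = as.integer(rel_start),
                 absolute = FALSE),
            class = "target_window")
}

#' @rdname extract_target_window
#' @param x object to coerce: a `target_window` is returned unchanged; a
#'   plain sequence becomes a windowless target reported in its own
#'   1-based coordinates.
#' @export
as_target_window <- function(x) {
  if (inherits(x, "target_window")) return(x)
  s <- res_of(x)
  structure(list(gene_id = id_of(x, "target"), strand = "+",
                 residues = s, context = s, offset = 0L,
                 rel_start = 1L, absolute = TRUE),
            class = "target_window")
}

#' @export
print.target_window <- function(x, ...) {
  cat(sprintf("<target_window> %s (%s), %d nt window, %d nt context\n",
              x$gene_id, x$strand, nchar(x$residues), nchar(x$context)))
  invisible(x)
}

# Window position -> reported coordinate. For genomic windows the scale is
# relative to the start codon and skips 0; for plain targets it is 1-based.
window_rel <- function(window, w) {
  r <- window$rel_start + as.integer(w) - 1L
  if (!window$absolute) r <- ifelse(r >= 0L, r + 1L, r)
  r
}

#' Predict all candidate interactions of one sRNA-target pair
#'
#' Runs the full cascade: seed enumeration, composition screening,
#' seed-level energy scoring and selection, extension of each surviving
#' seed by constrained co-folding, binding-site scoring, feature
#' extraction, and ensemble voting. Every candidate interaction is
#' returned; a pair with no surviving seed yields an empty record set (it
#' is non-interacting by construction). Candidates with identical site
#' intervals arising from different seeds are deduplicated keeping the one
#' with the smallest `ddg_seed`.
#'
#' @param srna the sRNA ([rna_seq()] or character).
#' @param target a [target_window()] or plain sequence.
#' @param model an `ensemble_model`.
#' @param engine an [energy_engines] object.
#' @param min_seed_len minimum seed length (nt).
#' @param seed_ddg_threshold seed stability/accessibility threshold
#'   (kcal/mol).
#' @return data.frame of prediction records: `srna_id`, `gene_id`,
#'   `probability`, `ddg_binding`, `ddg_seed`, `srna_start`, `srna_end`,
#'   `target_start`, `target_end` (relative coordinates), `structure`,
#'   plus the 22 feature columns.
#' @export
predict_pair <- function(srna, target, model, engine,
                         min_seed_len = 5L, seed_ddg_threshold = -2) {
  if (!is.null(model$engine_id) && !is.na(model$engine_id) &&
      !identical(model$engine_id, engine$engine_id))
    warning(sprintf("model was trained with engine '%s' but '%s' is in use",
                    model$engine_id, engine$engine_id))
  tw <- as_target_window(target)
  empty <- prediction_schema()
  seeds <- enumerate_helices(srna, tw, min_len = min_seed_len)
  if (nrow(seeds) == 0L) return(empty)
  seeds <- seeds[passes_composition_rules(seeds), , drop = FALSE]
  if (nrow(seeds) == 0L) return(empty)
  seeds <- score_seeds(seeds, srna, tw, engine)
  seeds <- select_seeds(seeds, ddg_threshold = seed_ddg_threshold)
  if (nrow(seeds) == 0L) return(empty)
  recs <- list()
  for (k in seq_len(nrow(seeds))) {
    seed <- seeds[k, , drop = FALSE]
    site <- extend_seed(srna, tw, seed, engine)
    if (is.null(site) || is.na(site$ddg_binding)) next
    f <- extract_features(site, seed)
    prob <- predict_probability(model, f)
    rec <- data.frame(srna_id = id_of(srna, "srna"), gene_id = tw$gene_id,
                      probability = prob,
                      ddg_binding = site$ddg_binding,
                      ddg_seed = seed$ddg_seed,
                      srna_start = site$srna_site[1],
                      srna_end = site$srna_site[2],
                      target_start = window_rel(tw, site$target_site[1]),
                      target_end = window_rel(tw, site$target_site[2]),
                      structure = site$structure,
                      stringsAsFactors = FALSE)
    recs[[length(recs) + 1L]] <- cbind(rec, as.data.frame(as.list(f)))
  }
  if (length(recs) == 0L) return(empty)
  out <- do.call(rbind, recs)
  # identical sites reached from different seeds: keep smallest ddg_seed
  key <- sprintf("%d:%d:%d:%d", out$srna_start, out$srna_end,
                 out$target_start, out$target_end)
  out <- out[order(key, out$ddg_seed), , drop = FALSE]
  out <- out[!duplicated(sprintf("%d:%d:%d:%d", out$srna_start, out$srna_end,
                                 out$target_start, out$target_end)), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

prediction_schema <- function() {
  base <- data.frame(srna_id = character(0), gene_id = character(0),
                     probability = numeric(0), ddg_binding = numeric(0),
                     ddg_seed = numeric(0), srna_start = integer(0),
                     srna_end = integer(0), target_start = integer(0),
                     target_end = integer(0), structure = character(0),
                     stringsAsFactors = FALSE)
  for (f in feature_names()) base[[f]] <- numeric(0)
  base
}

#' Rank prediction records
#'
#' Three-key total order: probability descending, then binding-region
#' accessibility-corrected energy ascending, then seed energy ascending;
#' remaining ties are broken by `gene_id` (then `srna_id`) lexicographic
#' for determinism. With `per_pair = TRUE` only the best-ranked record of
#' every sRNA-gene pair is kept (the genome-wide ranking view).
#'
#' @param records data.frame of prediction records.
#' @param per_pair collapse to the best record per pair.
#' @return The ranked records with a `rank` column.
#' @export
rank_predictions <- function(records, per_pair = FALSE) {
  if (nrow(records) == 0L) { records$rank <- integer(0); return(records) }
  ord <- order(-records$probability, records$ddg_binding, records$ddg_seed,
               records$gene_id, records$srna_id)
  out <- records[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  if (per_pair) {
    out <- out[!duplicated(paste(out$srna_id, out$gene_id, sep = "\r")), ,
               drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Apply point mutations to a sequence
#'
#' @param seq an [rna_seq()] or character sequence.
#' @param spec data.frame with columns `pos` (1-based), `ref`, `alt`;
#'   every `ref` must match the sequence (error naming the position
#'   otherwise).
#' @return The mutated sequence, same type/length as the input.
#' @examples
#' apply_mutations("AAGAA", data.frame(pos = 3, ref = "G", alt = "C"))
#' @export
apply_mutations <- function(seq, spec) {
  s <- res_of(seq)
  if (is.null(spec) || nrow(spec) == 0L)
    return(if (inherits(seq, "rna_seq")) seq else s)
  chars <- strsplit(s, "")[[1]]
  for (k in seq_len(nrow(spec))) {
    pos <- as.integer(spec$pos[k])
    if (pos < 1L || pos > length(chars))
      stop("mutation position ", pos, " outside sequence")
    ref <- clean_rna(as.character(spec$ref[k]))
    alt <- clean_rna(as.character(spec$alt[k]))
    if (chars[pos] != ref)
      stop(sprintf("reference mismatch at position %d: expected %s, found %s",
                   pos, ref, chars[pos]))
    chars[pos] <- alt
  }
  out <- paste(chars, collapse = "")
  if (inherits(seq, "rna_seq"))
    rna_seq(seq$id, out, note = paste0(seq$note, "+mutated"))
  else out
}

#' Genome-wide target prediction for one sRNA
#'
#' Extracts the window around every annotated start codon, runs
#' [predict_pair()] per gene, and reports the ranked records whose voting
#' probability exceeds the threshold (strictly). Per-gene failures are
#' logged and skipped, never fatal.
#'
#' @param genome list with `contigs` (named character vector) and `genes`
#'   (data.frame as returned by [read_annotation()]).
#' @param srna the sRNA.
#' @param model an `ensemble_model`.
#' @param engine an [energy_engines] object.
#' @param threshold reporting threshold on the voting probability.
#' @param per_pair collapse the report to the best record per gene.
#' @inheritParams predict_pair
#' @return Ranked data.frame of reported records; the full candidate list
#'   (all probabilities) is attached as attribute `"all"`.
#' @export
predict_genome <- function(genome, srna, model, engine, threshold = 0.5,
                           per_pair = FALSE, min_seed_len = 5L,
                           seed_ddg_threshold = -2) {
  stopifnot(is.list(genome), !is.null(genome$genes), !is.null(genome$contigs))
  recs <- list()
  for (k in seq_len(nrow(genome$genes))) {
    gene <- genome$genes[k, , drop = FALSE]
    r <- tryCatch({
      tw <- extract_target_window(genome$contigs[[gene$contig_id]], gene)
      predict_pair(srna, tw, model, engine, min_seed_len = min_seed_len,
                   seed_ddg_threshold = seed_ddg_threshold)
    }, error = function(e) {
      message("gene ", gene$gene_id, " skipped: ", conditionMessage(e))
      NULL
    })
    if (!is.null(r) && nrow(r) > 0L) recs[[length(recs) + 1L]] <- r
  }
  all <- if (length(recs)) do.call(rbind, recs) else prediction_schema()
  all <- rank_predictions(all, per_pair = per_pair)
  report <- all[all$probability > threshold, , drop = FALSE]
  rownames(report) <- NULL
  attr(report, "all") <- all
  report
}
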