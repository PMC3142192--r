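#' Enumerate candidate seed helices between an sRNA and a target
#'
#' Finds all maximal antiparallel runs of consecutive complementary base
#' pairs (Watson-Crick plus G-U wobble) between the two molecules, trims
#' terminal G-U pairs from both ends, and keeps runs whose post-trim
#' length is at least `min_len`. Sub-runs of a maximal run are not emitted
#' separately.
#'
#' @param srna,target sequences ([rna_seq()], [target_window()] for the
#'   target, or character).
#' @param min_len minimum helix length after trimming (nt).
#' @return A data.frame of seed matches: `seed_id`, `srna_start`,
#'   `srna_end`, `target_start`, `target_end` (1-based inclusive, both
#'   intervals in 5'->3' coordinates of their molecule; the helix pairs
#'   `srna_start` with `target_end` and so on, antiparallel), `length`,
#'   `n_gc`, `n_gu`, `n_au`, `max_consec_gc`, and placeholder columns
#'   `dg_hybrid_seed`, `ddg_seed` filled by [score_seeds()].
#' @examples
#' enumerate_helices("GGGGG", "CCCCC")
#' @export
enumerate_helices <- function(srna, target, min_len = 5L) {
  sa <- res_of(srna)
  sb <- res_of(if (inherits(target, "target_window")) target$residues else target)
  a <- strsplit(sa, "")[[1]]; b <- strsplit(sb, "")[[1]]
  n <- length(a); m <- length(b)
  ptype <- outer(a, b, pair_type)      # n x m matrix of "", "GC", "AU", "GU"
  ok <- ptype != ""
  rows <- list()
  # antiparallel consecutive pairs (i, j), (i+1, j-1), ... live on
  # anti-diagonals i + j = const
  for (s in 2:(n + m)) {
    i_lo <- max(1L, s - m); i_hi <- min(n, s - 1L)
    if (i_lo > i_hi) next
    iv <- i_lo:i_hi
    v <- ok[cbind(iv, s - iv)]
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (q in which(r$values & r$lengths >= 1L)) {
      i0 <- iv[starts[q]]; len <- r$lengths[q]
      # trim terminal G-U pairs from both ends
      repeat {
        if (len == 0L) break
        if (ptype[i0, s - i0] == "GU") { i0 <- i0 + 1L; len <- len - 1L; next }
        if (ptype[i0 + len - 1L, s - (i0 + len - 1L)] == "GU") { len <- len - 1L; next }
        break
      }
      if (len < min_len) next
      ii <- i0:(i0 + len - 1L)
      tp <- ptype[cbind(ii, s - ii)]
      gc_runs <- rle(tp == "GC")
      rows[[length(rows) + 1L]] <- data.frame(
        srna_start = i0, srna_end = i0 + len - 1L,
        target_start = s - (i0 + len - 1L), target_end = s - i0,
        length = len,
        n_gc = sum(tp == "GC"), n_gu = sum(tp == "GU"), n_au = sum(tp == "AU"),
        max_consec_gc = if (any(gc_runs$values))
          max(gc_runs$lengths[gc_runs$values]) else 0L)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(srna_start = integer(0), srna_end = integer(0),
               target_start = integer(0), target_end = integer(0),
               length = integer(0), n_gc = integer(0), n_gu = integer(0),
               n_au = integer(0), max_consec_gc = integer(0))
  out <- out[order(out$srna_start, out$target_start), , drop = FALSE]
  rownames(out) <- NULL
  out$seed_id <- sprintf("seed%03d", seq_len(nrow(out)))
  out$dg_hybrid_seed <- rep(NA_real_, nrow(out))
  out$ddg_seed <- rep(NA_real_, nrow(out))
  out
}

#' Length-specific composition rules for seed helices
#'
#' A candidate helix passes iff its length-specific rule holds:
#' * length 5: no G-U pair, and at least 4 G-C pairs or 3 consecutive
#'   G-C pairs;
#' * length 6-7: at most one G-U pair and at least 3 G-C pairs;
#' * length 8-9: at most one G-U pair and at least 2 G-C pairs;
#' * length 10+: at most 4 G-U pairs and at least 2 G-C pairs.
#'
#' @param seeds data.frame from [enumerate_helices()] (lengths must be
#'   >= 5).
#' @return Logical vector, one element per seed.
#' @export
passes_composition_rules <- function(seeds) {
  if (nrow(seeds) == 0L) return(logical(0))
  if (any(seeds$length < 5L)) stop("composition rules are defined for length >= 5")
  len <- seeds$length; gc <- seeds$n_gc; gu <- seeds$n_gu
  cgc <- seeds$max_consec_gc
  ifelse(len == 5L, gu == 0L & (gc >= 4L | cgc >= 3L),
  ifelse(len <= 7L, gu <= 1L & gc >= 3L,
  ifelse(len <= 9L, gu <= 1L & gc >= 2L,
                    gu <= 4L & gc >= 2L)))
}

#' Thermodynamic scoring of seed helices
#'
#' Fills `dg_hybrid_seed` (duplex energy of the two seed subsequences) and
#' `ddg_seed` (`dg_hybrid_seed` plus the opening energies of the seed
#' region on the sRNA, folded full length, and on the target, folded with
#' up to 100 nt of flanking context).
#'
#' @param seeds data.frame from [enumerate_helices()].
#' @param srna the sRNA ([rna_seq()] or character).
#' @param target the target: a [target_window()] (its flanking context is
#'   used for accessibility) or a plain sequence.
#' @param engine an [energy_engines] object.
#' @return `seeds` with the two energy columns filled.
#' @export
score_seeds <- function(seeds, srna, target, engine) {
  if (nrow(seeds) == 0L) return(seeds)
  sa <- res_of(srna)
  tw <- as_target_window(target)
  for (k in seq_len(nrow(seeds))) {
    s1 <- seeds$srna_start[k]; s2 <- seeds$srna_end[k]
    t1 <- seeds$target_start[k]; t2 <- seeds$target_end[k]
    dup <- duplex_energy(engine, substr(sa, s1, s2),
                         substr(tw$residues, t1, t2))
    open_s <- open_energy(engine, sa, c(s1, s2), "full_length")
    open_t <- open_energy(engine, tw$context,
                          c(t1, t2) + tw$offset, "flank_100")
    seeds$dg_hybrid_seed[k] <- dup$energy
    seeds$ddg_seed[k] <- if (is.na(dup$energy)) NA_real_
                         else dup$energy + open_s + open_t
  }
  seeds
}

#' Select stable, accessible, well-composed seeds
#'
#' Keeps exactly the scored seeds that pass [passes_composition_rules()]
#' and whose `ddg_seed` is strictly below `ddg_threshold`. Order is
#' preserved.
#'
#' @param seeds scored seed data.frame ([score_seeds()]).
#' @param ddg_threshold stability/accessibility threshold in kcal/mol
#'   (default -2; a seed at exactly the threshold is dropped).
#' @return The surviving subset of `seeds`.
#' @export
select_seeds <- function(seeds, ddg_threshold = -2) {
  if (nrow(seeds) == 0L) return(seeds)
  keep <- passes_composition_rules(seeds) &
    !is.na(seeds$ddg_seed) & seeds$ddg_seed < ddg_threshold
  out <- seeds[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
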