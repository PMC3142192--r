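#' Co-fold an sRNA with the context around a target seed
#'
#' Computes the joint minimum-free-energy structure of the sRNA and the
#' target context (seed region plus up to `context_flank` nt on each
#' side), imposing every seed pair. If the engine cannot realise all seed
#' pairs in its optimum, `NULL` is returned with a warning and the seed
#' contributes no binding site.
#'
#' @param srna the sRNA ([rna_seq()] or character).
#' @param target a [target_window()] or plain sequence.
#' @param seed one-row data.frame from [score_seeds()]/[select_seeds()].
#' @param engine an [energy_engines] object.
#' @param context_flank nt of target context on each side of the seed.
#' @return list with `joint` (the [structure_table()]), `ctx_start` (first
#'   context position, in window coordinates), `na` (sRNA length), or
#'   `NULL` on constraint failure.
#' @export
cofold_with_seed <- function(srna, target, seed, engine, context_flank = 100L) {
  sa <- res_of(srna)
  tw <- as_target_window(target)
  na <- nchar(sa)
  t1c <- seed$target_start + tw$offset   # context coordinates
  t2c <- seed$target_end + tw$offset
  c1 <- max(1L, t1c - context_flank)
  c2 <- min(nchar(tw$context), t2c + context_flank)
  sb <- substr(tw$context, c1, c2)
  len <- seed$length
  forced <- cbind(seed$srna_start:(seed$srna_start + len - 1L),
                  (t2c - c1 + 1L) - 0:(len - 1L))
  joint <- cofold_constrained(engine, sa, sb, forced)
  if (!cofold_satisfies(joint, forced, na)) {
    warning(sprintf("engine could not impose seed %s; extension aborted",
                    seed$seed_id))
    return(NULL)
  }
  list(joint = joint, ctx_start = c1 - tw$offset, na = na)
}

#' Extend a seed to its maximal binding site
#'
#' Starting at each seed boundary, positions are scanned outward over
#' inter-molecularly paired or unpaired nucleotides; a side halts at the
#' first position engaged in an intra-molecular pair. The site is then
#' clipped to the outermost inter-molecular pair on each side, so a site
#' never contains an intra-molecular pair and never ends in unpaired
#' trailing bases.
#'
#' @param joint a [structure_table()] over the concatenated molecules.
#' @param seed_a,seed_b seed intervals `c(start, end)` in joint
#'   coordinates (first and second molecule respectively).
#' @return list with `a_site` and `b_site` intervals in joint coordinates.
#' @export
scan_outward <- function(joint, seed_a, seed_b) {
  n <- joint$n; cut <- joint$cut
  pos <- seq_len(n)
  paired <- joint$partner > 0L
  intra <- paired & (joint$molecule[pmax(joint$partner, 1L)] == joint$molecule)
  inter <- paired & !intra
  scan_side <- function(lo_bound, hi_bound, s1, s2) {
    lo <- s1
    while (lo - 1L >= lo_bound && !intra[lo - 1L]) lo <- lo - 1L
    hi <- s2
    while (hi + 1L <= hi_bound && !intra[hi + 1L]) hi <- hi + 1L
    keep <- which(inter & pos >= lo & pos <= hi)
    c(min(keep), max(keep))
  }
  list(a_site = scan_side(1L, cut, seed_a[1], seed_a[2]),
       b_site = scan_side(cut + 1L, n, seed_b[1], seed_b[2]))
}

#' Extend one selected seed into a scored binding site
#'
#' Convenience wrapper: co-folds with the seed imposed, scans outward from
#' the seed, collects the inter-molecular hybrid structure restricted to
#' the site, and scores the site with [score_binding_site()].
#'
#' @inheritParams cofold_with_seed
#' @return A `binding_site` object (list with `seed_id`, `srna_site`,
#'   `target_site` in window coordinates, `srna_seq`, `target_seq`,
#'   `pairs` (matrix of site-relative pair positions), `structure`
#'   (dot-bracket of the hybrid), `dg_binding`, `ddg_binding`), or `NULL`
#'   if the seed constraint could not be imposed.
#' @export
extend_seed <- function(srna, target, seed, engine, context_flank = 100L) {
  cf <- cofold_with_seed(srna, target, seed, engine, context_flank)
  if (is.null(cf)) return(NULL)
  tw <- as_target_window(target)
  joint <- cf$joint; na <- cf$na
  len <- seed$length
  # seed positions in joint coordinates (molecule b follows molecule a)
  b_ctx1 <- seed$target_start - cf$ctx_start + 1L
  site <- scan_outward(joint,
                       seed_a = c(seed$srna_start, seed$srna_end),
                       seed_b = na + c(b_ctx1, b_ctx1 + len - 1L))
  a_site <- site$a_site
  b_site_ctx <- site$b_site - na                   # context-relative
  b_site <- b_site_ctx + cf$ctx_start - 1L         # window coordinates
  # inter-molecular pairs restricted to the site, site-relative
  apos <- a_site[1]:a_site[2]
  partner <- joint$partner[apos]
  sel <- partner >= site$b_site[1] & partner <= site$b_site[2]
  pairs <- cbind(srna = apos[sel] - a_site[1] + 1L,
                 target = (partner[sel] - na + cf$ctx_start - 1L) - b_site[1] + 1L)
  a_seq <- substr(res_of(srna), a_site[1], a_site[2])
  b_seq <- substr(tw$context, b_site[1] + tw$offset, b_site[2] + tw$offset)
  bs <- structure(list(seed_id = seed$seed_id,
                       srna_site = a_site,
                       target_site = b_site,
                       srna_seq = a_seq, target_seq = b_seq,
                       pairs = pairs,
                       structure = hybrid_dotbracket(nchar(a_seq), nchar(b_seq), pairs),
                       dg_binding = NA_real_, ddg_binding = NA_real_),
                  class = "binding_site")
  score_binding_site(bs, srna, target, engine)
}

hybrid_dotbracket <- function(na, nb, pairs) {
  a <- rep(".", na); b <- rep(".", nb)
  a[pairs[, 1]] <- "("
  b[pairs[, 2]] <- ")"
  paste0(paste(a, collapse = ""), "&", paste(b, collapse = ""))
}

#' Score a binding site
#'
#' `dg_binding` is the duplex energy of the two site subsequences;
#' `ddg_binding` adds the opening energies of the site regions (sRNA
#' folded full length, target folded with up to 100 nt of flanking
#' context).
#'
#' @param site a `binding_site` from [extend_seed()].
#' @inheritParams cofold_with_seed
#' @return `site` with `dg_binding` and `ddg_binding` filled.
#' @export
score_binding_site <- function(site, srna, target, engine) {
  sa <- res_of(srna)
  tw <- as_target_window(target)
  dup <- duplex_energy(engine, site$srna_seq, site$target_seq)
  if (is.na(dup$energy)) {
    site$dg_binding <- NA_real_; site$ddg_binding <- NA_real_
    return(site)
  }
  open_s <- open_energy(engine, sa, site$srna_site, "full_length")
  open_t <- open_energy(engine, tw$context, site$target_site + tw$offset,
                        "flank_100")
  site$dg_binding <- dup$energy
  site$ddg_binding <- dup$energy + open_s + open_t
  site
}
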