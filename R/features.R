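#' Names of the 22 hybrid descriptors
#'
#' @return Character vector `f1` ... `f22`.
#' @export
feature_names <- function() paste0("f", 1:22)

#' Extract the 22 descriptors of a binding-site hybrid
#'
#' The hybrid is the concatenation of the sRNA-site and target-site
#' nucleotides together with the inter-molecular pairing found during
#' extension. Percentages use the total nucleotide count of both strands
#' as denominator, so the paired and unpaired percentages sum to 100.
#'
#' Features: f1-f7 percent A, C, G, U, G+C, A+U, A+C; f8 percent paired
#' nucleotides; f9 percent nucleotides paired in duplexes of >= 3 bp; f10
#' ratio of base pairs in duplexes >= 3 bp to all base pairs; f11 maximum
#' number of consecutive base pairs; f12 interior loops; f13 bulges; f14
#' their sum; f15 percent nucleotides in interior loops; f16 percent in
#' bulges; f17 percent unpaired; f18 binding-region duplex energy; f19
#' binding-region accessibility-corrected energy; f20 seed duplex energy;
#' f21 seed accessibility-corrected energy; f22 seed length.
#'
#' @param site a scored `binding_site` ([extend_seed()]).
#' @param seed the one-row scored seed data.frame the site grew from.
#' @return Named numeric vector `f1` ... `f22`.
#' @export
extract_features <- function(site, seed) {
  if (is.null(site) || nrow(site$pairs) == 0L) stop("empty binding site")
  nt <- strsplit(paste0(site$srna_seq, site$target_seq), "")[[1]]
  N <- length(nt)
  pct <- function(x) 100 * x / N
  f <- numeric(22); names(f) <- feature_names()
  f[1] <- pct(sum(nt == "A")); f[2] <- pct(sum(nt == "C"))
  f[3] <- pct(sum(nt == "G")); f[4] <- pct(sum(nt == "U"))
  f[5] <- f[2] + f[3]; f[6] <- f[1] + f[4]; f[7] <- f[1] + f[2]
  p <- site$pairs[order(site$pairs[, 1]), , drop = FALSE]
  np <- nrow(p)
  f[8] <- pct(2 * np)
  # stems: maximal runs of consecutive pairs (a ascending, b descending)
  consec <- if (np > 1L) (diff(p[, 1]) == 1L) & (diff(p[, 2]) == -1L) else logical(0)
  stem_len <- integer(0)
  t <- 1L
  while (t <= np) {
    len <- 1L
    while (t < np && consec[t]) { len <- len + 1L; t <- t + 1L }
    stem_len <- c(stem_len, len)
    t <- t + 1L
  }
  bp3 <- sum(stem_len[stem_len >= 3L])
  f[9] <- pct(2 * bp3)
  f[10] <- bp3 / np
  f[11] <- max(stem_len)
  # loops between consecutive pairs: unpaired on both strands = interior
  # loop, on exactly one strand = bulge
  il <- 0L; bulge <- 0L; il_nt <- 0L; bulge_nt <- 0L
  if (np > 1L) {
    ga <- diff(p[, 1]) - 1L
    gb <- -diff(p[, 2]) - 1L
    both <- ga > 0L & gb > 0L
    one <- xor(ga > 0L, gb > 0L)
    il <- sum(both); bulge <- sum(one)
    il_nt <- sum((ga + gb)[both]); bulge_nt <- sum((ga + gb)[one])
  }
  f[12] <- il; f[13] <- bulge; f[14] <- il + bulge
  f[15] <- pct(il_nt); f[16] <- pct(bulge_nt)
  f[17] <- 100 - f[8]
  f[18] <- site$dg_binding
  f[19] <- site$ddg_binding
  f[20] <- seed$dg_hybrid_seed
  f[21] <- seed$ddg_seed
  f[22] <- seed$length
  f
}

#' Project a feature vector onto the final classifier subset
#'
#' The final model uses features f1 (percent A), f4 (percent U), f18
#' (binding-region duplex energy), f19 (binding-region
#' accessibility-corrected energy) and f22 (seed length), untransformed.
#'
#' @param v named numeric vector with at least `f1`, `f4`, `f18`, `f19`,
#'   `f22`.
#' @return The ordered 5-vector.
#' @export
project_final_subset <- function(v) {
  v[c("f1", "f4", "f18", "f19", "f22")]
}
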