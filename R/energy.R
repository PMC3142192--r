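#' Folding-energy engines
#'
#' All thermodynamic quantities are computed through a small behavioral
#' contract (an "energy engine") so that the prediction pipeline is
#' independent of any particular folding implementation. Two engines ship
#' with the package:
#'
#' * `toy_engine()` — a self-contained deterministic nearest-neighbour toy
#'   model (pair energies G-C -3, A-U -2, G-U -1 kcal/mol, no loop terms,
#'   minimum hairpin loop 3 nt) with exact dynamic-programming duplex
#'   optimisation, partition functions, and constrained co-folding. It
#'   needs no external binaries and is the default for tests and synthetic
#'   studies.
#' * `vienna_engine()` — an adapter to the ViennaRNA command-line suite
#'   (`RNAduplex`, `RNAfold -p0`, `RNAcofold -C --noLP --noClosingGU`),
#'   the production path for real sequences. Dangling-end and terminal-AU
#'   options are left at the suite's defaults.
#'
#' Engines are deterministic: identical inputs give identical outputs.
#' Temperature is fixed at 37 degrees Celsius. Energies are in kcal/mol.
#'
#' @return An object of class `energy_engine`.
#' @name energy_engines
NULL

#' @rdname energy_engines
#' @export
toy_engine <- function() {
  structure(list(engine_id = "toy-nn-1", temperature = 37),
            class = c("toy_engine", "energy_engine"))
}

#' @rdname energy_engines
#' @export
vienna_engine <- function() {
  for (bin in c("RNAduplex", "RNAfold", "RNAcofold"))
    if (Sys.which(bin) == "")
      stop("ViennaRNA binary not found on PATH: ", bin)
  ver <- tryCatch(system2("RNAfold", "--version", stdout = TRUE)[1],
                  error = function(e) "RNAfold unknown")
  structure(list(engine_id = paste0("vienna/", sub("^RNAfold ", "", ver)),
                 temperature = 37),
            class = c("vienna_engine", "energy_engine"))
}

#' @export
print.energy_engine <- function(x, ...) {
  cat(sprintf("<energy_engine> %s (T = %g C)\n", x$engine_id, x$temperature))
  invisible(x)
}

#' Minimum free energy of the inter-molecular duplex of two RNAs
#'
#' Minimum free energy over all structures containing only inter-molecular
#' base pairs (Watson-Crick and G-U). When no pair can form, a
#' no-interaction sentinel is returned (`energy = NA`, empty pairing).
#'
#' @param engine an [energy_engines] object.
#' @param a,b sequences ([rna_seq()] or character).
#' @return list with `energy` (kcal/mol, `NA` if no interaction), `a_pos`,
#'   `b_pos` (1-based paired positions, `a_pos` ascending, `b_pos`
#'   descending).
#' @export
duplex_energy <- function(engine, a, b) UseMethod("duplex_energy")

#' @export
duplex_energy.toy_engine <- function(engine, a, b) {
  sa <- res_of(a); sb <- res_of(b)
  stopifnot(nchar(sa) > 0, nchar(sb) > 0)
  r <- cpp_toy_duplex(base_codes(sa), base_codes(sb))
  if (length(r$a_pos) == 0L)
    return(list(energy = NA_real_, a_pos = integer(0), b_pos = integer(0)))
  list(energy = r$energy, a_pos = r$a_pos, b_pos = r$b_pos)
}

#' @export
duplex_energy.vienna_engine <- function(engine, a, b) {
  sa <- res_of(a); sb <- res_of(b)
  stopifnot(nchar(sa) > 0, nchar(sb) > 0)
  out <- run_vienna("RNAduplex", character(0), c(sa, sb))
  line <- out[length(out)]
  m <- regmatches(line, regexec(
    "^(\\S+)\\s+(\\d+),(\\d+)\\s+:\\s+(\\d+),(\\d+)\\s+\\(\\s*(-?[0-9.]+)\\)", line))[[1]]
  if (length(m) != 7L) stop("unparseable RNAduplex output: ", line)
  e <- as.numeric(m[7])
  i1 <- as.integer(m[3]); j1 <- as.integer(m[5])
  if (e >= 99999 || (i1 == 0 && as.integer(m[4]) == 0))
    return(list(energy = NA_real_, a_pos = integer(0), b_pos = integer(0)))
  halves <- strsplit(m[2], "&", fixed = TRUE)[[1]]
  # k-th '(' of the left half pairs with the k-th-from-last ')' of the right
  lp <- which(strsplit(halves[1], "")[[1]] == "(")
  rp <- which(strsplit(halves[2], "")[[1]] == ")")
  a_pos <- as.integer(m[3]) + lp - 1L
  b_pos <- rev(as.integer(m[5]) + rp - 1L)
  list(energy = e, a_pos = a_pos, b_pos = b_pos)
}

#' Equilibrium ensemble free energy of one RNA
#'
#' The ensemble free energy -RT ln Z over all intra-molecular secondary
#' structures of `seq`. With `unpaired_region`, the sum runs only over
#' structures in which every base of the region is unpaired (the
#' constrained ensemble behind the opening energy).
#'
#' @inheritParams duplex_energy
#' @param seq sequence ([rna_seq()] or character).
#' @param unpaired_region `c(start, end)` (1-based, inclusive) forced
#'   single-stranded, or `NULL`.
#' @return Free energy in kcal/mol.
#' @export
ensemble_energy <- function(engine, seq, unpaired_region = NULL)
  UseMethod("ensemble_energy")

check_region <- function(region, n) {
  stopifnot(length(region) == 2L)
  if (region[1] < 1 || region[2] > n || region[1] > region[2])
    stop(sprintf("region [%d,%d] out of bounds for sequence of length %d",
                 region[1], region[2], n))
}

#' @export
ensemble_energy.toy_engine <- function(engine, seq, unpaired_region = NULL) {
  s <- res_of(seq)
  blocked <- rep(FALSE, nchar(s))
  if (!is.null(unpaired_region)) {
    check_region(unpaired_region, nchar(s))
    blocked[unpaired_region[1]:unpaired_region[2]] <- TRUE
  }
  cpp_toy_ensemble(base_codes(s), blocked)
}

#' @export
ensemble_energy.vienna_engine <- function(engine, seq, unpaired_region = NULL) {
  s <- res_of(seq)
  args <- c("-p0", "--noPS")
  input <- s
  if (!is.null(unpaired_region)) {
    check_region(unpaired_region, nchar(s))
    con <- rep(".", nchar(s))
    con[unpaired_region[1]:unpaired_region[2]] <- "x"
    args <- c(args, "-C")
    input <- c(s, paste(con, collapse = ""))
  }
  out <- run_vienna("RNAfold", args, input)
  line <- grep("free energy of ensemble", out, value = TRUE)
  if (length(line) == 0L) stop("unparseable RNAfold output")
  as.numeric(sub(".*=\\s*(-?[0-9.]+)\\s*kcal/mol.*", "\\1", line[1]))
}

#' Opening energy of a region
#'
#' Energy needed to make `region` single-stranded, computed as the
#' difference between the constrained (`dG_unpaired`) and unconstrained
#' (`dG_paired`) ensemble free energies. With `flank_policy =
#' "full_length"` the whole molecule is folded (the sRNA convention); with
#' `"flank_100"` only the region plus up to `flank` nt on each side is
#' folded (the mRNA-target convention), truncated at molecule ends. The
#' result is never negative: the constrained ensemble is a subset of the
#' unconstrained one (tiny negative differences from an engine's printed
#' rounding are clamped to 0).
#'
#' @inheritParams ensemble_energy
#' @param region `c(start, end)`, 1-based inclusive.
#' @param flank_policy `"full_length"` or `"flank_100"`.
#' @param flank flank width in nt for `"flank_100"`.
#' @return Opening energy in kcal/mol (>= 0).
#' @export
open_energy <- function(engine, seq, region,
                        flank_policy = c("full_length", "flank_100"),
                        flank = 100L) {
  flank_policy <- match.arg(flank_policy)
  s <- res_of(seq)
  check_region(region, nchar(s))
  if (flank_policy == "flank_100") {
    lo <- max(1L, region[1] - flank)
    hi <- min(nchar(s), region[2] + flank)
    s <- substr(s, lo, hi)
    region <- region - lo + 1L
  }
  dgp <- ensemble_energy(engine, s)
  dgu <- ensemble_energy(engine, s, unpaired_region = region)
  max(0, dgu - dgp)
}

#' Combine hybridization and opening energies
#'
#' The accessibility-corrected interaction energy is the sum of the duplex
#' hybridization energy and the opening energies of the participating
#' regions on both molecules.
#'
#' @param dg_hybrid duplex energy (kcal/mol), `NA` for the no-interaction
#'   sentinel.
#' @param open_srna,open_target opening energies (kcal/mol, >= 0).
#' @return An `energy_bundle`: list with `dg_hybrid`, `dg_open_srna`,
#'   `dg_open_target`, `ddg` and `interacting`.
#' @examples
#' energy_bundle(-10, 3, 2)$ddg # -5
#' @export
energy_bundle <- function(dg_hybrid, open_srna, open_target) {
  interacting <- !is.na(dg_hybrid)
  if (interacting) stopifnot(is.finite(dg_hybrid), is.finite(open_srna),
                             is.finite(open_target),
                             open_srna >= 0, open_target >= 0)
  structure(list(dg_hybrid = dg_hybrid,
                 dg_open_srna = open_srna,
                 dg_open_target = open_target,
                 ddg = if (interacting) dg_hybrid + open_srna + open_target
                       else NA_real_,
                 interacting = interacting),
            class = "energy_bundle")
}

#' Joint co-folded structure with forced inter-molecular pairs
#'
#' Minimum-free-energy joint structure of two concatenated molecules with
#' the given inter-molecular pairs imposed (the seed constraint of the
#' binding-site extension step). The ViennaRNA backend additionally
#' forbids lonely pairs and helix-closing G-U pairs. If the engine's
#' optimum does not realise every forced pair, callers must treat the
#' extension as failed (see [cofold_satisfies()]).
#'
#' @inheritParams duplex_energy
#' @param forced two-column matrix of forced pairs: position in `a`,
#'   position in `b` (both 1-based).
#' @return A [structure_table()] over the concatenation of `a` and `b`
#'   with the cut after `a`, with an `energy` attribute.
#' @export
cofold_constrained <- function(engine, a, b, forced)
  UseMethod("cofold_constrained")

check_forced <- function(forced, na, nb) {
  stopifnot(is.matrix(forced), ncol(forced) == 2L, nrow(forced) >= 1L)
  stopifnot(all(forced[, 1] >= 1), all(forced[, 1] <= na),
            all(forced[, 2] >= 1), all(forced[, 2] <= nb))
}

#' @export
cofold_constrained.toy_engine <- function(engine, a, b, forced) {
  sa <- res_of(a); sb <- res_of(b)
  na <- nchar(sa); nb <- nchar(sb)
  check_forced(forced, na, nb)
  r <- cpp_toy_cofold(c(base_codes(sa), base_codes(sb)), na,
                      as.integer(forced[, 1]),
                      as.integer(na + forced[, 2]))
  st <- structure_table(r$partner, cut = na)
  attr(st, "energy") <- r$energy
  st
}

#' @export
cofold_constrained.vienna_engine <- function(engine, a, b, forced) {
  sa <- res_of(a); sb <- res_of(b)
  na <- nchar(sa); nb <- nchar(sb)
  check_forced(forced, na, nb)
  con <- rep(".", na + nb)
  con[forced[, 1]] <- "("
  con[na + forced[, 2]] <- ")"
  input <- c(paste0(sa, "&", sb),
             paste0(paste(con[1:na], collapse = ""), "&",
                    paste(con[(na + 1):(na + nb)], collapse = "")))
  out <- run_vienna("RNAcofold",
                    c("-C", "--noLP", "--noClosingGU", "--noPS"), input)
  line <- out[length(out)]
  m <- regmatches(line, regexec("^(\\S+)\\s+\\(\\s*(-?[0-9.]+)\\)", line))[[1]]
  if (length(m) != 3L) stop("unparseable RNAcofold output: ", line)
  st <- dotbracket_to_table(m[2])
  attr(st, "energy") <- as.numeric(m[3])
  st
}

#' @rdname cofold_constrained
#' @param joint a [structure_table()] returned by [cofold_constrained()].
#' @param na length of molecule `a`.
#' @return `cofold_satisfies()`: `TRUE` iff every forced pair is present.
#' @export
cofold_satisfies <- function(joint, forced, na) {
  all(joint$partner[forced[, 1]] == na + forced[, 2])
}

run_vienna <- function(bin, args, input) {
  owd <- setwd(tempdir())
  on.exit(setwd(owd))
  out <- suppressWarnings(system2(bin, args, input = input, stdout = TRUE,
                                  stderr = FALSE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0)
    stop(bin, " exited with status ", status)
  out[nzchar(out)]
}
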