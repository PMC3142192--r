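#' RNA sequence record
#'
#' Lightweight container for a single RNA sequence. DNA input is accepted
#' and transliterated (`T` -> `U`); lowercase is uppercased. Any residue
#' outside `A`, `C`, `G`, `U` (plus `N` when `allow_n = TRUE`) is rejected.
#'
#' @param id sequence identifier.
#' @param residues character scalar of residues.
#' @param note free-text provenance note.
#' @param allow_n allow ambiguous `N` residues (used for genomic contigs).
#' @return An object of class `rna_seq` with fields `id`, `residues`,
#'   `note`.
#' @examples
#' rna_seq("s1", "acgt")$residues # "ACGU"
#' @export
rna_seq <- function(id, residues, note = "", allow_n = FALSE) {
  structure(list(id = as.character(id),
                 residues = clean_rna(residues, allow_n = allow_n),
                 note = note),
            class = "rna_seq")
}

#' @export
print.rna_seq <- function(x, ...) {
  cat(sprintf("<rna_seq> %s (%d nt)\n", x$id, nchar(x$residues)))
  invisible(x)
}

# Normalize to the RNA alphabet; error on anything else.
clean_rna <- function(x, allow_n = FALSE) {
  stopifnot(is.character(x), length(x) == 1L)
  s <- chartr("t", "u", toupper(x))
  s <- chartr("T", "U", s)
  alphabet <- if (allow_n) "ACGUN" else "ACGU"
  bad <- setdiff(unique(strsplit(s, "")[[1]]), strsplit(alphabet, "")[[1]])
  if (nchar(s) == 0L) stop("empty sequence")
  if (length(bad) > 0L)
    stop(sprintf("illegal residue(s) %s (alphabet %s)",
                 paste(bad, collapse = ","), alphabet))
  s
}

# Extract the residue string from rna_seq or character input.
res_of <- function(x) {
  if (inherits(x, "rna_seq")) x$residues
  else if (is.character(x) && length(x) == 1L) clean_rna(x, allow_n = TRUE)
  else stop("expected an rna_seq or a single character string")
}

id_of <- function(x, default = "seq") {
  if (inherits(x, "rna_seq")) x$id else default
}

# Integer base codes A=0 C=1 G=2 U=3 N=4 (matches the compiled engine).
base_codes <- function(s) {
  codes <- integer(128)
  codes[utf8ToInt("A")] <- 0L; codes[utf8ToInt("C")] <- 1L
  codes[utf8ToInt("G")] <- 2L; codes[utf8ToInt("U")] <- 3L
  codes[utf8ToInt("N")] <- 4L
  codes[utf8ToInt(s)]
}

#' Reverse complement of an RNA string
#'
#' @param s character scalar over `A`,`C`,`G`,`U`,`N`.
#' @return The reverse complement as a character scalar.
#' @export
revcomp_rna <- function(s) {
  chartr("ACGUN", "UGCAN", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# Pair lookup used by seed enumeration: Watson-Crick + G-U wobble.
PAIR_TYPE <- local({
  m <- matrix("", 5, 5, dimnames = list(c("A","C","G","U","N"),
                                        c("A","C","G","U","N")))
  m["G", "C"] <- m["C", "G"] <- "GC"
  m["A", "U"] <- m["U", "A"] <- "AU"
  m["G", "U"] <- m["U", "G"] <- "GU"
  m
})

pair_type <- function(a, b) PAIR_TYPE[cbind(a, b)]
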