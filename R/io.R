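#' Read RNA (or DNA) sequences from a FASTA file
#'
#' DNA is transliterated to RNA on ingest and lowercase is uppercased.
#' Identifiers are taken from the header up to the first whitespace.
#' Residues outside the `A`,`C`,`G`,`U`/`T` alphabet (plus `N` when
#' `allow_n = TRUE`) raise a parse error naming the offending line.
#'
#' @param path path to a FASTA file.
#' @param allow_n accept ambiguous `N` residues (genomic contigs).
#' @return A list of [rna_seq()] records.
#' @export
read_fasta <- function(path, allow_n = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in ", path)
  ids <- sub("\\s.*$", "", names(set))
  out <- vector("list", length(set))
  for (k in seq_along(set)) {
    res <- tryCatch(clean_rna(as.character(set[[k]]), allow_n = allow_n),
                    error = function(e) e)
    if (inherits(res, "error")) {
      stop(sprintf("%s: record '%s' (near line %d): %s",
                   path, ids[k], fasta_line_of(path, ids[k]),
                   conditionMessage(res)))
    }
    out[[k]] <- rna_seq(ids[k], res, note = paste0("fasta:", path),
                        allow_n = allow_n)
  }
  out
}

# Line number of the first sequence line of a record (error reporting only).
fasta_line_of <- function(path, id) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^>", lines)
  hit <- hdr[sub("\\s.*$", "", sub("^>", "", lines[hdr])) == id]
  if (length(hit) == 0L) return(NA_integer_)
  hit[1] + 1L
}

#' Write sequences to a FASTA file
#'
#' @param seqs a list of [rna_seq()] records.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.list(seqs))
  res <- vapply(seqs, function(s) s$residues, character(1))
  ids <- vapply(seqs, function(s) s$id, character(1))
  set <- Biostrings::BStringSet(stats::setNames(res, ids))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read protein-coding gene annotation and contig sequences
#'
#' Every CDS with an annotated start codon becomes one gene record. The
#' `start_codon_pos` is always the forward-strand coordinate of the base
#' that is the first base of the start codon: the CDS start for
#' plus-strand genes and the CDS end for minus-strand genes. CDS features
#' without usable strand/coordinates (joins, partial starts) are skipped
#' with a warning.
#'
#' @param path GenBank flat file, or a GFF3 file when
#'   `dialect = "gff3+fasta"`.
#' @param dialect `"genbank"` or `"gff3+fasta"`.
#' @param fasta companion FASTA of contigs (required for GFF3).
#' @return A list with `genes` (data.frame: `gene_id`, `contig_id`,
#'   `strand`, `start_codon_pos`) and `contigs` (named character vector of
#'   RNA-alphabet contig sequences).
#' @export
read_annotation <- function(path, dialect = c("genbank", "gff3+fasta"),
                            fasta = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "genbank") parse_genbank(path)
  else {
    if (is.null(fasta)) stop("the gff3+fasta dialect requires a companion FASTA")
    parse_gff3(path, fasta)
  }
}

parse_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  loci <- grep("^LOCUS", lines)
  if (length(loci) == 0L) stop("not a GenBank flat file: ", path)
  genes <- list(); contigs <- character(0)
  ends <- c(loci[-1] - 1L, length(lines))
  for (e in seq_along(loci)) {
    block <- lines[loci[e]:ends[e]]
    contig_id <- strsplit(trimws(sub("^LOCUS", "", block[1])), "\\s+")[[1]][1]
    ori <- grep("^ORIGIN", block)
    seqtxt <- ""
    if (length(ori) == 1L) {
      stop_at <- grep("^//", block)
      stop_at <- if (length(stop_at)) stop_at[1] - 1L else length(block)
      body <- block[(ori + 1L):stop_at]
      seqtxt <- toupper(gsub("[^A-Za-z]", "", paste(body, collapse = "")))
    }
    contigs[contig_id] <- clean_rna(seqtxt, allow_n = TRUE)
    cds_idx <- grep("^\\s{5}CDS\\s", block)
    for (ci in cds_idx) {
      loc <- trimws(sub("^\\s{5}CDS\\s+", "", block[ci]))
      rec <- parse_gb_location(loc)
      if (is.null(rec)) {
        warning(sprintf("%s: skipping CDS with unsupported location '%s'",
                        contig_id, loc))
        next
      }
      gid <- gb_qualifier(block, ci, c("locus_tag", "gene"))
      if (is.na(gid)) gid <- sprintf("%s_CDS_%d", contig_id, rec$start)
      genes[[length(genes) + 1L]] <- data.frame(
        gene_id = gid, contig_id = contig_id, strand = rec$strand,
        start_codon_pos = if (rec$strand == "+") rec$start else rec$end,
        stringsAsFactors = FALSE)
    }
  }
  genes <- if (length(genes)) do.call(rbind, genes) else
    data.frame(gene_id = character(0), contig_id = character(0),
               strand = character(0), start_codon_pos = integer(0))
  list(genes = genes, contigs = contigs)
}

parse_gb_location <- function(loc) {
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("join|order|<|>", loc)) return(NULL) # joins / partial starts
  m <- regmatches(loc, regexec("^(\\d+)\\.\\.(\\d+)$", loc))[[1]]
  if (length(m) != 3L) return(NULL)
  list(start = as.integer(m[2]), end = as.integer(m[3]), strand = strand)
}

gb_qualifier <- function(block, ci, keys) {
  j <- ci + 1L
  while (j <= length(block) && grepl("^\\s{6,}", block[j]) &&
         !grepl("^\\s{5}\\S", block[j])) {
    for (key in keys) {
      pat <- sprintf('/%s="([^"]*)"', key)
      m <- regmatches(block[j], regexec(pat, block[j]))[[1]]
      if (length(m) == 2L) return(m[2])
    }
    j <- j + 1L
  }
  NA_character_
}

parse_gff3 <- function(path, fasta) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("the gff3+fasta dialect requires the rtracklayer package")
  gr <- rtracklayer::import(path)
  contig_seqs <- read_fasta(fasta, allow_n = TRUE)
  contigs <- stats::setNames(vapply(contig_seqs, function(s) s$residues,
                                    character(1)),
                             vapply(contig_seqs, function(s) s$id, character(1)))
  meta <- as.data.frame(gr[gr$type == "CDS"])
  keep <- as.character(meta$strand) %in% c("+", "-")
  if (any(!keep))
    warning(sum(!keep), " CDS record(s) without strand skipped")
  meta <- meta[keep, , drop = FALSE]
  gid <- rep(NA_character_, nrow(meta))
  for (key in c("locus_tag", "ID", "gene", "Name", "Parent")) {
    if (key %in% names(meta)) {
      v <- vapply(meta[[key]], function(el)
        if (length(el) == 0L || is.na(el[1])) NA_character_ else as.character(el[1]),
        character(1))
      fill <- is.na(gid) & !is.na(v) & nzchar(v)
      gid[fill] <- v[fill]
    }
  }
  gid[is.na(gid)] <- sprintf("CDS_%d", which(is.na(gid)))
  strand <- as.character(meta$strand)
  genes <- data.frame(
    gene_id = gid,
    contig_id = as.character(meta$seqnames),
    strand = strand,
    start_codon_pos = as.integer(ifelse(strand == "+", meta$start, meta$end)),
    stringsAsFactors = FALSE)
  list(genes = genes, contigs = contigs)
}

#' Pairing table of a secondary structure
#'
#' Converts dot-bracket notation to a CT-style pairing table. A `&` in the
#' string (or an explicit `cut_point`) marks the junction of two
#' concatenated molecules in a co-folded structure.
#'
#' @param structure dot-bracket string, optionally containing one `&`.
#' @param cut_point last position belonging to the first molecule, or
#'   `NULL` for a single molecule.
#' @return An object of class `structure_table`: list with `partner`
#'   (integer vector, 0 = unpaired), `molecule` (1/2 per position), `cut`
#'   and `n`.
#' @examples
#' dotbracket_to_table("((..))")$partner # 6 5 0 0 2 1
#' @export
dotbracket_to_table <- function(structure, cut_point = NULL) {
  stopifnot(is.character(structure), length(structure) == 1L)
  if (grepl("&", structure)) {
    halves <- strsplit(structure, "&", fixed = TRUE)[[1]]
    if (length(halves) != 2L) stop("at most one '&' cut is supported")
    if (!is.null(cut_point) && cut_point != nchar(halves[1]))
      stop("cut_point disagrees with the '&' position")
    cut_point <- nchar(halves[1])
    structure <- paste0(halves[1], halves[2])
  }
  chars <- strsplit(structure, "")[[1]]
  if (!all(chars %in% c("(", ")", ".")))
    stop("illegal character in dot-bracket string")
  n <- length(chars)
  partner <- integer(n)
  stack <- integer(0)
  for (i in seq_len(n)) {
    if (chars[i] == "(") stack <- c(stack, i)
    else if (chars[i] == ")") {
      if (length(stack) == 0L) stop("unbalanced brackets: unmatched ')' at ", i)
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      partner[i] <- j; partner[j] <- i
    }
  }
  if (length(stack) > 0L)
    stop("unbalanced brackets: unmatched '(' at ", stack[length(stack)])
  structure_table(partner, cut = cut_point)
}

#' @rdname dotbracket_to_table
#' @param partner integer vector of pairing partners (0 = unpaired).
#' @export
structure_table <- function(partner, cut = NULL) {
  partner <- as.integer(partner)
  n <- length(partner)
  paired <- which(partner > 0L)
  if (any(partner[paired] == paired)) stop("a position cannot pair with itself")
  if (!all(partner[partner[paired]] == paired))
    stop("pairing table is not an involution")
  molecule <- rep(1L, n)
  if (!is.null(cut)) {
    stopifnot(cut >= 0, cut <= n)
    if (cut < n) molecule[(cut + 1L):n] <- 2L
  }
  structure(list(partner = partner, molecule = molecule,
                 cut = if (is.null(cut)) n else as.integer(cut), n = n),
            class = "structure_table")
}

# Dot-bracket rendering of a structure table (nested structures only).
table_to_dotbracket <- function(st, with_cut = FALSE) {
  chars <- rep(".", st$n)
  chars[st$partner > seq_len(st$n)] <- "("
  chars[st$partner > 0L & st$partner < seq_len(st$n)] <- ")"
  s <- paste(chars, collapse = "")
  if (with_cut && st$cut < st$n)
    s <- paste0(substr(s, 1, st$cut), "&", substr(s, st$cut + 1, st$n))
  s
}

#' Write ranked predictions to a tab-separated file
#'
#' One row per candidate interaction; all candidate interactions of a pair
#' are listed. Expects records already ordered by [rank_predictions()].
#'
#' @param records data.frame of prediction records.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(records, path) {
  cols <- c("srna_id", "gene_id", "probability", "ddg_binding", "ddg_seed",
            "srna_site_interval", "target_site_interval", "structure")
  if (nrow(records) == 0L) {
    out <- stats::setNames(
      as.data.frame(matrix(character(0), 0, length(cols))), cols)
  } else {
    records$srna_site_interval <-
      sprintf("%d-%d", records$srna_start, records$srna_end)
    records$target_site_interval <-
      sprintf("%d..%d", records$target_start, records$target_end)
    out <- records[, cols]
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
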