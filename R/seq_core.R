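#' Construct a coding sequence record
#'
#' A `cds` bundles a nucleotide sequence with its identity and provenance.
#' Sequences are stored uppercase; the alphabet (DNA or RNA) is detected from
#' the characters unless given explicitly. Mixed T/U content is rejected, as
#' are IUPAC ambiguity codes.
#'
#' @param seq Nucleotide string over `{A,C,G,T}` (DNA) or `{A,C,G,U}` (RNA),
#'   case-insensitive.
#' @param id Identifier (typically the FASTA header word or an accession).
#' @param source Free-text provenance, e.g. an accession or `"synthetic"`.
#' @param alphabet `"DNA"`, `"RNA"`, or `NULL` to detect from the sequence
#'   (a sequence with neither T nor U defaults to DNA).
#' @return An object of class `cds`: a list with fields `id`, `seq`,
#'   `alphabet`, `source`, and `length`.
#' @examples
#' x <- cds("ATGAAATAA", id = "toy")
#' x$length
#' @export
cds <- function(seq, id = "cds", source = "synthetic", alphabet = NULL) {
  if (length(seq) != 1L || !is.character(seq) || is.na(seq) || !nzchar(seq))
    stop("`seq` must be a single non-empty string", call. = FALSE)
  s <- toupper(seq)
  chars <- unique(strsplit(s, "", fixed = TRUE)[[1L]])
  has_t <- "T" %in% chars
  has_u <- "U" %in% chars
  if (has_t && has_u)
    stop("sequence mixes T and U; declare a single alphabet", call. = FALSE)
  if (is.null(alphabet)) alphabet <- if (has_u) "RNA" else "DNA"
  alphabet <- match.arg(alphabet, c("DNA", "RNA"))
  allowed <- if (alphabet == "DNA") c("A", "C", "G", "T") else c("A", "C", "G", "U")
  bad <- setdiff(chars, allowed)
  if (length(bad) > 0L)
    stop(sprintf("invalid %s character(s): %s", alphabet,
                 paste(bad, collapse = ", ")), call. = FALSE)
  structure(
    list(id = as.character(id), seq = s, alphabet = alphabet,
         source = as.character(source), length = nchar(s)),
    class = "cds"
  )
}

#' @export
print.cds <- function(x, ...) {
  head <- if (x$length > 60L) paste0(substr(x$seq, 1L, 57L), "...") else x$seq
  cat(sprintf("<cds> %s [%s, %d nt, source: %s]\n%s\n",
              x$id, x$alphabet, x$length, x$source, head))
  invisible(x)
}

is_cds <- function(x) inherits(x, "cds")

assert_cds <- function(x) {
  if (!is_cds(x)) stop("expected a `cds` object", call. = FALSE)
  invisible(x)
}

#' The bacterial genetic code
#'
#' Codon-to-amino-acid map used throughout the package. Amino-acid
#' assignments follow NCBI translation table 11 (the bacterial, archaeal and
#' plastid code), whose codon-to-residue map is identical to the standard
#' code; the tables differ only in permitted initiation codons, which are not
#' modelled here. Codons are keyed in DNA letters; U is mapped to T before
#' lookup.
#'
#' @return A list with `code` (named character vector, 64 codons to one-letter
#'   residues, `"*"` for stops), `stops` (the stop codons `TAA`, `TAG`,
#'   `TGA`), and `table_id` (`"11"`).
#' @export
codon_table <- function() {
  code <- Biostrings::GENETIC_CODE
  list(code = code,
       stops = names(code)[code == "*"],
       table_id = "11")
}

.CODON_CODE <- Biostrings::GENETIC_CODE
.STOP_CODONS <- names(.CODON_CODE)[.CODON_CODE == "*"]

# Split a DNA-letter string into consecutive codons starting at `start`;
# trailing partial codon dropped.
codons_from <- function(s, start = 1L) {
  L <- nchar(s)
  if (start + 2L > L) return(character(0))
  first <- seq.int(start, L - 2L, by = 3L)
  substring(s, first, first + 2L)
}

#' Translate a coding sequence
#'
#' Translates consecutive codons from a given position and frame offset until
#' the first stop codon or the end of the sequence. RNA input is handled by
#' mapping U to T for codon lookup; a trailing partial codon is ignored.
#'
#' @param x A [cds()].
#' @param frame Frame offset, 0, 1 or 2, added to `start_at`.
#' @param start_at 1-based nucleotide position of the first codon (before the
#'   frame offset is applied).
#' @return An object of class `protein_seq`: a list with `residues` (string of
#'   one-letter amino acids, no stop symbol) and `terminated` (`TRUE` iff a
#'   stop codon was reached).
#' @examples
#' translate_cds(cds("ATGAAATAA"))          # "MK", terminated
#' translate_cds(cds("ATGAAA"))             # "MK", runs off the end
#' translate_cds(cds("ATGAAATAA"), frame = 1)
#' @export
translate_cds <- function(x, frame = 0L, start_at = 1L) {
  assert_cds(x)
  if (!frame %in% 0:2) stop("`frame` must be 0, 1 or 2", call. = FALSE)
  if (start_at < 1L) stop("`start_at` must be >= 1", call. = FALSE)
  pos <- as.integer(start_at + frame)
  if (pos > x$length)
    stop("translation start lies beyond the sequence end", call. = FALSE)
  s <- chartr("U", "T", x$seq)
  cod <- codons_from(s, pos)
  if (length(cod) == 0L) return(protein_seq("", terminated = FALSE))
  aa <- unname(.CODON_CODE[cod])
  stop_i <- which(aa == "*")
  if (length(stop_i) > 0L) {
    i <- stop_i[1L]
    protein_seq(paste(aa[seq_len(i - 1L)], collapse = ""), terminated = TRUE)
  } else {
    protein_seq(paste(aa, collapse = ""), terminated = FALSE)
  }
}

#' @rdname translate_cds
#' @param residues One-letter amino-acid string (may be empty).
#' @param terminated Whether translation ended at a stop codon.
#' @export
protein_seq <- function(residues, terminated) {
  if (grepl("*", residues, fixed = TRUE))
    stop("stop symbol inside residues", call. = FALSE)
  structure(list(residues = residues, terminated = terminated,
                 length_aa = nchar(residues)),
            class = "protein_seq")
}

#' @export
print.protein_seq <- function(x, ...) {
  cat(sprintf("<protein_seq> %d aa%s\n", x$length_aa,
              if (x$terminated) " (stop-terminated)" else " (no stop reached)"))
  invisible(x)
}

#' Reverse complement of a nucleotide string
#'
#' Watson-Crick complement, reversed. DNA and RNA are both supported; the
#' alphabet of the output matches the input.
#'
#' @param seq Nucleotide string (or a [cds()], in which case the sequence
#'   field is used).
#' @return A character string.
#' @examples
#' reverse_complement("AAAA")  # "TTTT"
#' reverse_complement("ACGT")  # "ACGT" (self reverse-complementary)
#' @export
reverse_complement <- function(seq) {
  if (is_cds(seq)) seq <- seq$seq
  s <- toupper(seq)
  if (grepl("U", s, fixed = TRUE)) {
    if (grepl("[^ACGU]", s)) stop("invalid RNA character", call. = FALSE)
    as.character(Biostrings::reverseComplement(Biostrings::RNAString(s)))
  } else {
    if (grepl("[^ACGT]", s)) stop("invalid DNA character", call. = FALSE)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }
}

#' Read coding sequences from a FASTA file
#'
#' One [cds()] per record, in file order. Record ids are the first
#' whitespace-delimited word of each header; lowercase bodies are uppercased.
#'
#' @param path Path to a FASTA file.
#' @param source Provenance recorded on each record (defaults to the file
#'   name).
#' @return A list of [cds()] objects.
#' @export
read_fasta <- function(path, source = basename(path)) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("malformed FASTA: ",
                                           conditionMessage(e), call. = FALSE))
  if (length(set) == 0L) stop("FASTA file contains no records", call. = FALSE)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  lapply(seq_along(set), function(i)
    cds(as.character(set[[i]]), id = ids[i], source = source))
}

#' Write coding sequences to a FASTA file
#'
#' @param records A [cds()] or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  if (is_cds(records)) records <- list(records)
  seqs <- vapply(records, function(x) x$seq, character(1))
  names(seqs) <- vapply(records, function(x) x$id, character(1))
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}

#' Write / read a TSV report with provenance header
#'
#' Reports are tab-separated with a header row, preceded by `#`-prefixed
#' comment lines recording the generating parameters and seed, so outputs are
#' self-describing and byte-reproducible.
#'
#' @param x A data frame. List columns are flattened by joining elements with
#'   commas.
#' @param path Output path.
#' @param params Optional named list recorded in the `#` header.
#' @param seed Optional seed recorded in the `#` header.
#' @return `path` invisibly (write); a [tibble::tibble()] (read).
#' @export
write_tsv_report <- function(x, path, params = NULL, seed = NULL) {
  x <- as.data.frame(x)
  for (j in seq_along(x)) {
    if (is.list(x[[j]]))
      x[[j]] <- vapply(x[[j]], function(v) paste(v, collapse = ","), character(1))
  }
  con <- file(path, open = "wb")  # binary: fixed "\n", identical bytes on rerun
  on.exit(close(con))
  hdr <- c(sprintf("# slipscan %s", as.character(utils::packageVersion("slipscan"))))
  if (!is.null(seed)) hdr <- c(hdr, sprintf("# seed: %s", format(seed)))
  if (!is.null(params) && length(params) > 0L)
    hdr <- c(hdr, sprintf("# %s: %s", names(params),
                          vapply(params, function(p) paste(format(p), collapse = ","),
                                 character(1))))
  writeLines(hdr, con, sep = "\n")
  utils::write.table(x, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}

#' @rdname write_tsv_report
#' @export
read_tsv_report <- function(path) {
  tibble::as_tibble(utils::read.delim(path, comment.char = "#",
                                      stringsAsFactors = FALSE))
}
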