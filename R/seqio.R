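#' Read a FASTA file
#'
#' Reads a (possibly line-wrapped) multi-record FASTA file and returns the
#' sequences as an uppercased named character vector in file order. For DNA,
#' `U` is silently mapped to `T`; characters outside `A,C,G,T,N` raise an
#' error naming the offending record. Records with `N` are kept: k-mers
#' containing `N` are skipped later at sketching time.
#'
#' @param path Path to a FASTA file.
#' @param molecule `"dna"` or `"protein"`.
#' @return Named character vector of sequences (names are record ids, the
#'   first whitespace-delimited token of each header).
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">x", "acgt"), fa)
#' read_fasta(fa, "dna")
read_fasta <- function(path, molecule = c("dna", "protein")) {
  molecule <- match.arg(molecule)
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L) return(character(0))
  set <- tryCatch(
    if (molecule == "dna") {
      Biostrings::readBStringSet(path)
    } else {
      Biostrings::readAAStringSet(path)
    },
    error = function(e) stop("malformed FASTA in ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  seqs <- toupper(as.character(set))
  ids <- vapply(strsplit(names(set), "[ \t]"), `[`, "", 1)
  if (any(!nzchar(seqs))) {
    stop("malformed FASTA: record '", ids[which(!nzchar(seqs))[1]],
         "' has no sequence", call. = FALSE)
  }
  if (molecule == "dna") {
    seqs <- chartr("U", "T", seqs)
    bad <- grepl("[^ACGTN]", seqs)
    if (any(bad)) {
      stop("non-ACGTN characters in DNA record '", ids[which(bad)[1]], "'",
           call. = FALSE)
    }
  }
  names(seqs) <- ids
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line width (default 60 columns).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  stopifnot(!is.null(names(seqs)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

# Standard genetic code, DNA codons -> one-letter amino acids ('*' = stop).
genetic_code <- function() Biostrings::GENETIC_CODE

#' Split a coding sequence into codons
#'
#' @param s A nucleotide sequence (character scalar, length divisible by 3).
#' @return Character vector of non-overlapping triplets in order.
#' @export
#' @examples
#' codons("ATGAAA")
codons <- function(s) {
  n <- nchar(s)
  if (n == 0L || n %% 3L != 0L) {
    stop("coding sequence length must be a positive multiple of 3, got ", n)
  }
  starts <- seq(1L, n, by = 3L)
  substring(s, starts, starts + 2L)
}

#' Translate a coding sequence
#'
#' Translates in frame +1 with the standard genetic code. Stop codons map to
#' `*`; codons containing `N` (or any non-ACGT character) map to `X`.
#'
#' @param s A nucleotide sequence whose length is divisible by 3.
#' @return The protein sequence (character scalar), one letter per codon.
#' @export
#' @examples
#' translate_cds("ATGTTTTAA")  # "MF*"
translate_cds <- function(s) {
  cods <- codons(s)
  aa <- genetic_code()[cods]
  aa[is.na(aa)] <- "X"
  paste0(aa, collapse = "")
}

#' Reverse complement
#'
#' @param s A DNA sequence; non-ACGT characters complement to `N`.
#' @return The reverse complement string.
#' @export
revcomp <- function(s) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

#' Six-frame translation
#'
#' Translates frames +1, +2, +3 of `s` and +1, +2, +3 of its reverse
#' complement, dropping trailing partial codons.
#'
#' @param s A DNA sequence of length at least 3.
#' @return Character vector of 6 protein sequences, named
#'   `+1, +2, +3, -1, -2, -3`.
#' @export
six_frame_translate <- function(s) {
  if (nchar(s) < 3L) stop("sequence shorter than one codon")
  frame <- function(x, off) {
    n <- nchar(x) - off
    n <- n - n %% 3L
    if (n == 0L) return("")
    translate_cds(substr(x, off + 1L, off + n))
  }
  rc <- revcomp(s)
  out <- c(frame(s, 0L), frame(s, 1L), frame(s, 2L),
           frame(rc, 0L), frame(rc, 1L), frame(rc, 2L))
  names(out) <- c("+1", "+2", "+3", "-1", "-2", "-3")
  out
}
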