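#' @importFrom stats rbinom runif setNames
#' @importFrom utils head tail
NULL

# Coordinate conventions used throughout the package:
#   * all genomic coordinates are 0-based, half-open intervals [start, end);
#   * a nick position is a BOND coordinate b in {1, ..., L-1}: the backbone
#     bond between sense-strand positions b-1 and b.  Antisense nicks use the
#     same sense-frame bond coordinate.

DNA_BASES <- c("A", "C", "G", "T")

assert_dna <- function(x, what = "sequence") {
  if (!is.character(x) || length(x) != 1L || is.na(x) || nchar(x) < 1L)
    stop(what, " must be a single non-empty character string", call. = FALSE)
  if (grepl("[^ACGT]", x))
    stop(what, " contains characters outside {A,C,G,T}", call. = FALSE)
  invisible(x)
}

assert_interval <- function(start, end, what = "interval") {
  if (start < 0 || end <= start)
    stop(what, " must satisfy 0 <= start < end (0-based, half-open)",
         call. = FALSE)
  invisible(c(start, end))
}

#' Reverse complement of a DNA sequence
#'
#' @param s Character scalar over the alphabet {A,C,G,T} (a character vector
#'   is handled element-wise).
#' @return The reverse complement, same type and length as `s`.
#' @examples
#' revcomp("ACCG")  # "CGGT"
#' @export
revcomp <- function(s) {
  if (length(s) == 0L) return(character(0))
  for (x in s) assert_dna(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))
}

# Run code under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored on exit.  `seed = NULL` leaves the RNG alone.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Generate a synthetic genome fixture
#'
#' Draws an i.i.d. random dsDNA sequence with a prescribed GC fraction.  The
#' fixture stands in for a bacterial genome as the source of register
#' windows: because bases are independent, 16-mers are overwhelmingly unique,
#' so the guide-design constraints are satisfiable.  No repeat structure is
#' injected.
#'
#' @param length Sequence length in nt (>= 1000).
#' @param gc_fraction Target GC content, strictly between 0 and 1.
#' @param seed Integer seed; the same seed always yields the same sequence.
#' @return An object of class `genome_fixture` with elements `sequence`,
#'   `seed` and `gc_fraction`.
#' @examples
#' g <- make_genome(2000, 0.5, seed = 1)
#' nchar(g$sequence)
#' @export
make_genome <- function(length, gc_fraction, seed) {
  if (length < 1000)
    stop("fixture genome length must be >= 1000 nt", call. = FALSE)
  if (gc_fraction <= 0 || gc_fraction >= 1)
    stop("gc_fraction must lie strictly in (0, 1); degenerate GC makes the ",
         "guide composition constraints unsatisfiable", call. = FALSE)
  prob <- c((1 - gc_fraction) / 2, gc_fraction / 2,
            gc_fraction / 2, (1 - gc_fraction) / 2)
  bases <- with_seed(seed,
                     sample(DNA_BASES, size = length, replace = TRUE,
                            prob = prob))
  structure(list(sequence = paste(bases, collapse = ""),
                 seed = as.integer(seed),
                 gc_fraction = gc_fraction),
            class = "genome_fixture")
}

#' @export
print.genome_fixture <- function(x, ...) {
  cat(sprintf("<genome_fixture> %d nt, target GC %.2f, seed %d\n",
              nchar(x$sequence), x$gc_fraction, x$seed))
  invisible(x)
}

# Accept either a genome_fixture or a bare character sequence.
genome_sequence <- function(genome) {
  if (inherits(genome, "genome_fixture")) genome$sequence
  else { assert_dna(genome, "genome"); genome }
}

#' Read and write FASTA files
#'
#' Thin wrappers over Biostrings readers/writers that return plain R
#' structures: a named character vector of sequences.
#'
#' @param path File path.
#' @param seqs Named character vector of DNA sequences.
#' @return `read_fasta` returns a named character vector.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path, format = "fasta")
  setNames(as.character(set), names(set))
}

#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::DNAStringSet(seqs)
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, filepath = path, format = "fasta")
  invisible(path)
}

#' Read and write FASTQ files (Sanger Phred+33)
#'
#' @param path File path.
#' @param seqs Named character vector of read sequences.
#' @param quals Character vector of quality strings, same lengths as `seqs`.
#' @return `read_fastq` returns a data.frame with columns `id`, `seq`,
#'   `qual`; qualities round-trip byte-exactly.
#' @export
read_fastq <- function(path) {
  # the reader warns about dropped metadata columns it creates itself
  set <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  data.frame(id = names(set),
             seq = as.character(set),
             qual = as.character(Biostrings::quality(set)),
             stringsAsFactors = FALSE)
}

#' @rdname read_fastq
#' @export
write_fastq <- function(seqs, quals, path) {
  if (length(seqs) != length(quals))
    stop("seqs and quals must have equal length", call. = FALSE)
  bad <- nchar(seqs) != nchar(quals)
  if (any(bad))
    stop("sequence/quality length mismatch for record(s): ",
         paste(head(which(bad), 5), collapse = ", "), call. = FALSE)
  set <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(seqs),
    Biostrings::PhredQuality(quals))
  names(set) <- names(seqs)
  Biostrings::writeQualityScaledXStringSet(set, filepath = path)
  invisible(path)
}

phred_string <- function(len, q = 30L) {
  strrep(rawToChar(as.raw(q + 33L)), len)
}
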