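# Physical write/read channel simulation: nicking, denaturation, toehold
# release, reporter readout, pooling and paired-end read generation.

#' Apply a nick pattern to a register
#'
#' Symbol 1 places a nick on the sense strand at the site's cut bond,
#' symbol 2 on the antisense strand (same sense-frame bond), symbol 0
#' leaves the site intact.  All sites are nicked in parallel.
#'
#' @param reg A `punch_register`.
#' @param pattern A `punch_pattern` defined on `reg`'s sites.
#' @return A `punch_nicked` duplex: `register_id`, sorted `sense_cuts`
#'   and `antisense_cuts` bond vectors.
#' @export
apply_pattern <- function(reg, pattern) {
  check_pattern(reg, pattern)
  bonds <- cut_bonds(reg)
  structure(list(register_id = reg$id,
                 sense_cuts = bonds[pattern$symbols == 1L],
                 antisense_cuts = bonds[pattern$symbols == 2L]),
            class = "punch_nicked")
}

#' Denature a nicked duplex into single-stranded fragments
#'
#' Melting separates the strands; each strand falls apart at its nicks
#' into the maximal fragments between consecutive cuts (and the register
#' ends).  Fragments are reported as sense-frame intervals; per strand
#' they tile `[0, L)` exactly, so lengths sum to the register length.
#'
#' @param d A `punch_nicked` duplex.
#' @param L Register length in nt.
#' @return A fragment set: data.frame with columns `register_id`, `start`,
#'   `end`, `strand`, `multiplicity`.
#' @export
denature <- function(d, L) {
  one_strand <- function(cuts, strand) {
    bounds <- c(0L, sort(cuts), as.integer(L))
    data.frame(register_id = d$register_id,
               start = bounds[-length(bounds)],
               end = bounds[-1],
               strand = strand,
               multiplicity = 1L,
               stringsAsFactors = FALSE)
  }
  rbind(one_strand(d$sense_cuts, "sense"),
        one_strand(d$antisense_cuts, "antisense"))
}

#' Create a toehold from two nearby nicks
#'
#' Two nicks on the same strand release the intervening fragment when it
#' is short enough to dissociate at room temperature (default threshold
#' 20 nt; the designed inter-site spacing of >= 25 bp deliberately exceeds
#' it so data-bearing fragments stay annealed).  The exposed single-strand
#' gap serves as a hybridization handle for nondestructive random access.
#'
#' @param reg A `punch_register`.
#' @param bond_a,bond_b Bond coordinates of the two nicks (a designed
#'   site's bond plus an auxiliary nick nearby; see [cut_bonds()]).
#' @param strand Strand carrying both nicks.
#' @param dissociation_threshold Longest fragment that dissociates (nt).
#' @return A `punch_toehold`: `register_id`, `gap` interval, `strand`,
#'   `length`.
#' @export
make_toehold <- function(reg, bond_a, bond_b, strand = c("sense", "antisense"),
                         dissociation_threshold = 20L) {
  strand <- match.arg(strand)
  if (bond_a == bond_b)
    stop("toehold requires two distinct nicks", call. = FALSE)
  lo <- as.integer(min(bond_a, bond_b)); hi <- as.integer(max(bond_a, bond_b))
  if (lo < 1L || hi > reg$length - 1L)
    stop("nick bonds outside register", call. = FALSE)
  gap <- hi - lo
  if (gap > dissociation_threshold)
    stop(sprintf(paste0("no release: inter-nick fragment of %d nt exceeds ",
                        "the %d nt dissociation threshold and stays ",
                        "annealed"), gap, dissociation_threshold),
         call. = FALSE)
  structure(list(register_id = reg$id, gap = c(lo, hi), strand = strand,
                 length = gap),
            class = "punch_toehold")
}

#' Linear fluorescence readout of a toehold-bearing register fraction
#'
#' The reporter signal is modeled as a unit-slope, zero-intercept linear
#' function of the fraction of registers carrying the toehold.
#'
#' @param toehold_fraction Real in [0, 1].
#' @return Normalized fluorescence signal in [0, 1].
#' @export
reporter_readout <- function(toehold_fraction) {
  if (any(toehold_fraction < 0 | toehold_fraction > 1))
    stop("toehold fraction must lie in [0, 1]", call. = FALSE)
  toehold_fraction
}

#' Pool fragment sets
#'
#' Multiset union of fragment sets (e.g., all patterns in one well, or
#' several nicked copies of the same register for combinatorial mixing).
#'
#' @param ... Fragment sets as returned by [denature()].
#' @return A single combined fragment set.
#' @export
pool <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1]]) && !is.data.frame(sets[[1]]))
    sets <- sets[[1]]
  do.call(rbind, sets)
}

#' Simulate paired-end sequencing of a fragment pool
#'
#' Emulates a directional single-strand library read for `read_len` cycles
#' from each fragment end: mate 1 starts at the fragment's 5' end, mate 2
#' is the reverse complement of its 3' end; both are truncated to the
#' fragment length.  Strand of origin is preserved by pair orientation
#' (sense fragments yield mate-1-forward pairs).  Substitution errors are
#' i.i.d. at `err_rate`; no indels, PCR bias or quality decay are modeled.
#'
#' @param fs Fragment set (see [denature()]).
#' @param panel A `punch_panel` or `punch_register` providing reference
#'   sequences.
#' @param coverage Read pairs generated per fragment copy (>= 1).
#' @param read_len Sequencing cycles per mate (default 250).
#' @param err_rate Per-base substitution probability in [0, 0.1).
#' @param seed Optional integer seed (deterministic batches).
#' @param well Well label embedded in read ids (`"<well>:<k>"`), mirroring
#'   demultiplexed per-sample FASTQ.
#' @param phred Constant Phred quality for all bases (default 30).
#' @return A `punch_reads` batch: data.frame with read ids, mate sequences
#'   and qualities, and truth columns (`truth_*`) retained for testing.
#' @export
sim_reads <- function(fs, panel, coverage = 5L, read_len = 250L,
                      err_rate = 0, seed = NULL, well = "A1", phred = 30L) {
  if (coverage < 1L) stop("coverage must be >= 1", call. = FALSE)
  if (err_rate < 0 || err_rate >= 0.1)
    stop("err_rate must lie in [0, 0.1)", call. = FALSE)
  panel <- as_panel(panel)
  refs <- setNames(lapply(panel$registers, function(r) r$sequence),
                   vapply(panel$registers, function(r) r$id, character(1)))
  if (is.null(fs) || nrow(fs) == 0L) return(empty_batch())
  idx <- rep(seq_len(nrow(fs)), times = fs$multiplicity * coverage)
  f <- fs[idx, , drop = FALSE]
  regseq <- unlist(refs[f$register_id], use.names = FALSE)
  dup <- substr(regseq, f$start + 1L, f$end)       # sense-frame duplex slice
  frag <- ifelse(f$strand == "sense", dup, NA_character_)
  if (any(f$strand == "antisense"))
    frag[f$strand == "antisense"] <- revcomp(dup[f$strand == "antisense"])
  flen <- f$end - f$start
  rl <- pmin(read_len, flen)
  mate1 <- substr(frag, 1L, rl)
  mate2 <- revcomp(substr(frag, flen - rl + 1L, flen))
  with_seed(seed, {
    mate1 <- add_substitutions(mate1, err_rate)
    mate2 <- add_substitutions(mate2, err_rate)
  })
  n <- length(mate1)
  data.frame(id = sprintf("%s:%d", well, seq_len(n)),
             well = well,
             seq1 = mate1, qual1 = phred_string(nchar(mate1), phred),
             seq2 = mate2, qual2 = phred_string(nchar(mate2), phred),
             truth_register = f$register_id,
             truth_start = f$start, truth_end = f$end,
             truth_strand = f$strand,
             stringsAsFactors = FALSE)
}

empty_batch <- function() {
  data.frame(id = character(0), well = character(0),
             seq1 = character(0), qual1 = character(0),
             seq2 = character(0), qual2 = character(0),
             truth_register = character(0),
             truth_start = integer(0), truth_end = integer(0),
             truth_strand = character(0), stringsAsFactors = FALSE)
}

# i.i.d. substitutions on a character vector of reads; each erroneous base
# is replaced by one of the three other bases uniformly.
add_substitutions <- function(reads, err_rate) {
  if (err_rate <= 0 || length(reads) == 0L) return(reads)
  lens <- nchar(reads)
  nerr <- rbinom(length(reads), lens, err_rate)
  for (i in which(nerr > 0L)) {
    pos <- sample.int(lens[i], nerr[i])
    chars <- strsplit(reads[i], "")[[1]]
    chars[pos] <- vapply(chars[pos], function(b)
      sample(setdiff(DNA_BASES, b), 1L), character(1))
    reads[i] <- paste(chars, collapse = "")
  }
  reads
}

#' Write a read batch as paired FASTQ files
#'
#' @param batch A `punch_reads` batch from [sim_reads()].
#' @param prefix Output path prefix; writes `<prefix>_R1.fastq` and
#'   `<prefix>_R2.fastq`.
#' @return Character vector of the two paths, invisibly.
#' @export
write_fastq_pair <- function(batch, prefix) {
  r1 <- paste0(prefix, "_R1.fastq")
  r2 <- paste0(prefix, "_R2.fastq")
  write_fastq(setNames(batch$seq1, batch$id), batch$qual1, r1)
  write_fastq(setNames(batch$seq2, batch$id), batch$qual2, r2)
  invisible(c(r1, r2))
}

#' Read a paired FASTQ run back into a read batch
#'
#' Mates are matched by read id; the well label is recovered from the id
#' prefix (`"<well>:<k>"`).
#'
#' @param r1,r2 Paths to the mate-1 and mate-2 FASTQ files.
#' @return A `punch_reads` batch (truth columns absent).
#' @export
read_fastq_pair <- function(r1, r2) {
  a <- read_fastq(r1)
  b <- read_fastq(r2)
  if (!identical(a$id, b$id)) {
    b <- b[match(a$id, b$id), , drop = FALSE]
    if (anyNA(b$id))
      stop("mate files do not contain the same read ids", call. = FALSE)
  }
  data.frame(id = a$id,
             well = sub(":.*$", "", a$id),
             seq1 = a$seq, qual1 = a$qual,
             seq2 = b$seq, qual2 = b$qual,
             stringsAsFactors = FALSE)
}
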