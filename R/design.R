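# Register and guide design.
#
# A register is a fixed genomic window (default 450 bp) carrying 5-10
# designed nick sites.  Each site is addressed by a 16 nt single-stranded
# DNA guide; the enzyme cuts between guide positions 10 and 11.  Guides must
# satisfy composition constraints (GC 20-60%, no G run longer than 3),
# be pairwise distant (Hamming >= 8) and genome-unique, and consecutive cut
# bonds must be >= 25 bp apart so inter-nick strands stay annealed.

GUIDE_LEN <- 16L

#' Check a candidate guide sequence against the design constraints
#'
#' Returns every violated constraint, not just the first: guide length must
#' be exactly 16 nt, GC content within `gc_bounds`, and no run of G longer
#' than `max_g_run` (a nanopore-readout precaution).
#'
#' @param g Candidate 16-mer guide sequence.
#' @param strand Target strand of the guide (`"sense"` or `"antisense"`);
#'   recorded, not constrained.
#' @param gc_bounds Inclusive GC-fraction bounds, default `c(0.20, 0.60)`.
#' @param max_g_run Longest admissible G homopolymer, default 3.
#' @return Character vector of violation messages; `character(0)` means pass.
#' @examples
#' check_guide("ACGTACGTACGTACGT")   # passes, GC = 8/16
#' check_guide("ATATATATATATATAT")   # fails: GC 0%
#' @export
check_guide <- function(g, strand = c("sense", "antisense"),
                        gc_bounds = c(0.20, 0.60), max_g_run = 3L) {
  strand <- match.arg(strand)
  assert_dna(g, "guide")
  if (nchar(g) != GUIDE_LEN)
    stop("guide must be exactly ", GUIDE_LEN, " nt, got ", nchar(g),
         call. = FALSE)
  violations <- character(0)
  gc <- gc_fraction(g)
  if (gc < gc_bounds[1] || gc > gc_bounds[2])
    violations <- c(violations,
                    sprintf("GC %.0f%% outside [%.0f%%, %.0f%%]",
                            100 * gc, 100 * gc_bounds[1], 100 * gc_bounds[2]))
  if (grepl(strrep("G", max_g_run + 1L), g, fixed = TRUE))
    violations <- c(violations,
                    sprintf("G run longer than %d", max_g_run))
  violations
}

gc_fraction <- function(s) {
  n <- nchar(s)
  (n - nchar(gsub("[GC]", "", s))) / n
}

#' Hamming distance between equal-length sequences
#'
#' @param a,b Character scalars of equal length.
#' @return Integer count of mismatching positions.
#' @export
hamming <- function(a, b) {
  if (nchar(a) != nchar(b))
    stop("hamming distance requires equal-length sequences", call. = FALSE)
  sum(charToRaw(a) != charToRaw(b))
}

#' Map a guide footprint to its cut-bond coordinate
#'
#' The enzyme cuts between positions 10 and 11 of the guide (counted from
#' the guide's 5' end).  For a sense-strand guide with footprint
#' `[f, f+16)` that bond is `f + 10` in the sense frame.  An antisense guide
#' runs antiparallel, so its 5' end sits at the footprint's right edge and
#' the 10|11 bond maps to sense-frame bond `f + 6`.
#'
#' @param footprint Length-2 integer vector `c(start, end)` (0-based,
#'   half-open, length 16).
#' @param target_strand `"sense"` or `"antisense"`.
#' @return A bond coordinate (integer) in the sense frame.
#' @export
cut_bond_for <- function(footprint, target_strand = c("sense", "antisense")) {
  target_strand <- match.arg(target_strand)
  assert_interval(footprint[1], footprint[2], "guide footprint")
  if (footprint[2] - footprint[1] != GUIDE_LEN)
    stop("guide footprint must have length ", GUIDE_LEN, call. = FALSE)
  f <- as.integer(footprint[1])
  if (target_strand == "sense") f + 10L else f + 6L
}

new_guide <- function(sequence, target_strand, footprint) {
  structure(list(sequence = sequence, target_strand = target_strand,
                 footprint = as.integer(footprint)),
            class = "punch_guide")
}

new_register <- function(id, sequence, origin, sites) {
  structure(list(id = id, sequence = sequence,
                 origin = as.integer(origin), sites = sites,
                 length = nchar(sequence)),
            class = "punch_register")
}

#' @export
print.punch_register <- function(x, ...) {
  cat(sprintf("<punch_register> %s: %d nt, %d nick sites at bonds {%s}\n",
              x$id, x$length, length(x$sites),
              paste(cut_bonds(x), collapse = ", ")))
  invisible(x)
}

#' Cut-bond coordinates of a register's sites
#'
#' @param reg A `punch_register`.
#' @return Integer vector of bond coordinates, ascending with site ordinal.
#' @export
cut_bonds <- function(reg) {
  vapply(reg$sites, function(s) s$cut_bond, integer(1))
}

# Forward-strand k-mer occurrence counts in a genome, as a fast lookup table.
kmer_table <- function(genome, k) {
  g <- genome_sequence(genome)
  n <- nchar(g)
  if (k > n) stop("k exceeds genome length", call. = FALSE)
  kmers <- substring(g, 1:(n - k + 1L), k:n)
  table(kmers)
}

#' Count distinct k-mers in a genome
#'
#' Exact distinct count over a sliding window; used to audit how quickly
#' k-mer uniqueness (the basis of guide specificity) sets in.
#'
#' @param genome A `genome_fixture` or character sequence.
#' @param k Word size, `1 <= k <= nchar(genome)`.
#' @return Integer count of distinct k-mers.
#' @examples
#' kmer_census("ACGTACGT", 4)  # 4
#' @export
kmer_census <- function(genome, k) {
  length(kmer_table(genome, k))
}

#' Design a register with constrained nick sites
#'
#' Scans the genome for a window of length `L` that can host `n_sites` nick
#' sites satisfying every constraint, selecting sites greedily left to
#' right within the window (first feasible candidate wins, no
#' backtracking).  Constraints: guide composition (see [check_guide()]),
#' pairwise guide Hamming distance `>= min_hamming`, genome-unique guide
#' 16-mers, consecutive cut bonds `>= min_spacing` apart, and cut bonds at
#' least `edge_margin` from the register ends so every inter-nick fragment
#' is long enough to stay annealed and to seed an alignment.
#'
#' @param genome A `genome_fixture` or character sequence.
#' @param L Register length in nt (default 450).
#' @param n_sites Number of nick sites (default 10; 5-10 is typical).
#' @param min_spacing Minimum distance between consecutive cut bonds in bp
#'   (default 25).
#' @param min_hamming Minimum pairwise Hamming distance between guide
#'   sequences (default 8).
#' @param gc_bounds,max_g_run Passed to [check_guide()].
#' @param target_strand Strand the guides address (all sites on one strand;
#'   default `"sense"`).
#' @param edge_margin Minimum distance of a cut bond from either register
#'   end (default `min_spacing`).
#' @param seed Optional integer; randomizes which feasible window is found
#'   first while keeping the design fully reproducible.
#' @param id Register identifier.
#' @param scan_step Stride between candidate window starts (nt).
#' @return A `punch_register`.
#' @export
design_register <- function(genome, L = 450L, n_sites = 10L,
                            min_spacing = 25L, min_hamming = 8L,
                            gc_bounds = c(0.20, 0.60), max_g_run = 3L,
                            target_strand = c("sense", "antisense"),
                            edge_margin = min_spacing,
                            seed = NULL, id = "R1", scan_step = 50L) {
  target_strand <- match.arg(target_strand)
  g <- genome_sequence(genome)
  glen <- nchar(g)
  if (glen < L) stop("genome shorter than register length", call. = FALSE)
  if ((n_sites - 1L) * min_spacing + 2L * edge_margin > L)
    stop(sprintf(paste0("design infeasible: %d sites with spacing >= %d bp ",
                        "and edge margin %d bp cannot fit in a %d nt ",
                        "register (binding constraint: min_spacing)"),
                 n_sites, min_spacing, edge_margin, L), call. = FALSE)
  kt <- kmer_table(g, GUIDE_LEN)
  starts0 <- seq.int(0L, glen - L, by = scan_step)
  if (!is.null(seed)) {
    off <- with_seed(seed, sample.int(length(starts0), 1L))
    starts0 <- c(starts0[off:length(starts0)],
                 if (off > 1L) starts0[1:(off - 1L)])
  }
  for (w in starts0) {
    reg <- try_window(g, w, L, n_sites, min_spacing, min_hamming,
                      gc_bounds, max_g_run, target_strand, edge_margin,
                      kt, id)
    if (!is.null(reg)) return(reg)
  }
  stop("design infeasible: no ", L, " nt window hosts ", n_sites,
       " sites under the guide constraints (binding constraint: ",
       "guide composition/uniqueness)", call. = FALSE)
}

# Greedy left-to-right site selection inside one candidate window; NULL if
# the window cannot host n_sites.
try_window <- function(g, w, L, n_sites, min_spacing, min_hamming,
                       gc_bounds, max_g_run, target_strand, edge_margin,
                       kmer_tab, id) {
  regseq <- substr(g, w + 1L, w + L)
  # admissible footprint starts: cut bond within [edge_margin, L-edge_margin]
  off <- if (target_strand == "sense") 10L else 6L
  f_lo <- max(0L, edge_margin - off)
  f_hi <- min(L - GUIDE_LEN, L - edge_margin - off)
  if (f_hi < f_lo) return(NULL)
  sites <- list()
  guides <- character(0)
  last_bond <- -Inf
  for (f in f_lo:f_hi) {
    bond <- f + off
    if (bond - last_bond < min_spacing) next
    fp16 <- substr(regseq, f + 1L, f + GUIDE_LEN)
    if (grepl("[^ACGT]", fp16)) next
    gseq <- if (target_strand == "sense") fp16 else revcomp(fp16)
    if (length(check_guide(gseq, target_strand, gc_bounds, max_g_run)) > 0L)
      next
    cnt <- kmer_tab[fp16]
    if (is.na(cnt) || cnt != 1L) next          # genome-unique footprint only
    if (length(guides) > 0L &&
        any(vapply(guides, hamming, integer(1), b = gseq) < min_hamming))
      next
    sites[[length(sites) + 1L]] <- list(
      ordinal = length(sites) + 1L,
      guide = new_guide(gseq, target_strand, c(f, f + GUIDE_LEN)),
      cut_bond = bond)
    guides <- c(guides, gseq)
    last_bond <- bond
    if (length(sites) == n_sites)
      return(new_register(id, regseq, c(w, w + L), sites))
  }
  NULL
}

#' Re-validate a designed register from scratch
#'
#' Independent post-hoc check of every design invariant: guide length, GC,
#' G-run, pairwise Hamming distance, cut-bond spacing, cut bonds inside
#' guide footprints, and ascending site ordinals.
#'
#' @param reg A `punch_register`.
#' @param min_spacing,min_hamming,gc_bounds,max_g_run Constraint values to
#'   check against (defaults mirror [design_register()]).
#' @return Character vector of violations; `character(0)` if all pass.
#' @export
validate_register <- function(reg, min_spacing = 25L, min_hamming = 8L,
                              gc_bounds = c(0.20, 0.60), max_g_run = 3L) {
  bad <- character(0)
  gs <- vapply(reg$sites, function(s) s$guide$sequence, character(1))
  for (i in seq_along(gs)) {
    v <- check_guide(gs[i], reg$sites[[i]]$guide$target_strand,
                     gc_bounds, max_g_run)
    if (length(v)) bad <- c(bad, paste0("site ", i, ": ", v))
  }
  if (length(gs) > 1L) {
    for (i in 1:(length(gs) - 1L)) for (j in (i + 1L):length(gs))
      if (hamming(gs[i], gs[j]) < min_hamming)
        bad <- c(bad, sprintf("guides %d/%d Hamming %d < %d", i, j,
                              hamming(gs[i], gs[j]), min_hamming))
  }
  bonds <- cut_bonds(reg)
  if (is.unsorted(bonds, strictly = TRUE))
    bad <- c(bad, "cut bonds not strictly increasing with ordinal")
  if (length(bonds) > 1L && any(diff(bonds) < min_spacing))
    bad <- c(bad, sprintf("cut spacing %d < %d", min(diff(bonds)),
                          min_spacing))
  for (s in reg$sites) {
    fp <- s$guide$footprint
    if (s$cut_bond <= fp[1] || s$cut_bond >= fp[2])
      bad <- c(bad, sprintf("site %d cut bond outside guide footprint",
                            s$ordinal))
  }
  bad
}

#' Similarity between two registers
#'
#' Score of the best local alignment under unit scoring (match +1,
#' mismatch/gap -1), normalized by the shorter register length.  Identical
#' sequences score 1; unrelated 450 nt sequences score well below the 0.5
#' orthogonality threshold.
#'
#' @param a,b `punch_register`s or character sequences.
#' @return A real in [0, 1]; symmetric.
#' @export
similarity <- function(a, b) {
  sa <- if (inherits(a, "punch_register")) a$sequence else a
  sb <- if (inherits(b, "punch_register")) b$sequence else b
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  sc <- Biostrings::pairwiseAlignment(sa, sb, type = "local",
                                      substitutionMatrix = mat,
                                      gapOpening = 0, gapExtension = 1,
                                      scoreOnly = TRUE)
  max(0, min(1, sc / min(nchar(sa), nchar(sb))))
}

#' Design a panel of orthogonal registers
#'
#' Scans the genome left to right for disjoint windows that each host a
#' feasible register and whose sequences are mutually orthogonal: pairwise
#' similarity below `similarity_threshold` and no guide 16-mer shared
#' (guaranteed by genome-wide guide uniqueness).  Registers are returned in
#' genome order, which fixes the bit order of multi-register blocks.
#'
#' @param genome A `genome_fixture` or character sequence.
#' @param count Number of registers required.
#' @param L Register length (default 450).
#' @param per_register_sites Integer vector of site counts, recycled to
#'   `count` (default 10 each; the reference five-register layout is
#'   `c(10, 5, 6, 5, 6)` for 32 sites total).
#' @param similarity_threshold Strict upper bound on pairwise similarity
#'   (default 0.50).
#' @param seed Accepted for interface symmetry; panel construction is fully
#'   deterministic (windows pack left to right), so the genome seed alone
#'   determines the panel.
#' @param ... Further constraint arguments passed to [design_register()].
#' @return A `punch_panel`: list with `registers` (genome-ordered) and
#'   `pairwise_similarity` matrix.
#' @export
design_panel <- function(genome, count, L = 450L,
                         per_register_sites = 10L,
                         similarity_threshold = 0.50, seed = NULL, ...) {
  g <- genome_sequence(genome)
  glen <- nchar(g)
  sites <- rep_len(as.integer(per_register_sites), count)
  registers <- list()
  pos <- 0L
  k <- 0L
  while (length(registers) < count && pos + L <= glen) {
    k <- k + 1L
    # scan the remaining genome left to right (no per-register window
    # randomization: packing from the left keeps the panel feasible and
    # genome-ordered; panel-to-panel variation comes from the genome)
    reg <- tryCatch(
      design_register(substr(g, pos + 1L, glen), L = L,
                      n_sites = sites[length(registers) + 1L],
                      id = sprintf("O%d", length(registers) + 1L),
                      ...),
      error = function(e) NULL)
    if (is.null(reg)) break
    reg$origin <- reg$origin + pos                 # lift to genome frame
    ok <- all(vapply(registers, function(r)
      similarity(r, reg) < similarity_threshold, logical(1)))
    shared <- any(vapply(registers, function(r)
      any(vapply(r$sites, function(s) s$guide$sequence, character(1)) %in%
            vapply(reg$sites, function(s) s$guide$sequence, character(1))),
      logical(1)))
    if (ok && !shared) registers[[length(registers) + 1L]] <- reg
    pos <- reg$origin[2]                           # continue past the window
  }
  if (length(registers) < count)
    stop("partial panel: only ", length(registers), " of ", count,
         " orthogonal registers found in the genome", call. = FALSE)
  sim <- diag(1, count)
  rownames(sim) <- colnames(sim) <-
    vapply(registers, function(r) r$id, character(1))
  if (count > 1L)
    for (i in 1:(count - 1L)) for (j in (i + 1L):count)
      sim[i, j] <- sim[j, i] <- similarity(registers[[i]], registers[[j]])
  structure(list(registers = registers, pairwise_similarity = sim),
            class = "punch_panel")
}

#' @export
print.punch_panel <- function(x, ...) {
  cat(sprintf("<punch_panel> %d registers, %d sites total, max off-diagonal similarity %.3f\n",
              length(x$registers),
              sum(vapply(x$registers, function(r) length(r$sites), integer(1))),
              if (length(x$registers) > 1)
                max(x$pairwise_similarity[upper.tri(x$pairwise_similarity)])
              else 0))
  invisible(x)
}

#' Expected single-strand fragment lengths for a nick pattern
#'
#' After denaturation, a strand carrying cuts at bonds `b1 < ... < bk`
#' melts into fragments of lengths `b1, b2-b1, ..., L-bk`; an unnicked
#' strand stays full length.  Lengths on each strand always sum to `L`.
#'
#' @param reg A `punch_register`.
#' @param pattern A `punch_pattern` on `reg`'s sites.
#' @return List with sorted numeric vectors `sense` and `antisense`.
#' @export
expected_fragments <- function(reg, pattern) {
  check_pattern(reg, pattern)
  d <- apply_pattern(reg, pattern)
  list(sense = sort(strand_lengths(d$sense_cuts, reg$length)),
       antisense = sort(strand_lengths(d$antisense_cuts, reg$length)))
}

strand_lengths <- function(cuts, L) {
  diff(c(0L, sort(cuts), L))
}

# All achievable fragment lengths on a register: every distance between two
# breakpoints, where breakpoints are the register ends and the cut bonds.
achievable_lengths <- function(reg) {
  pts <- c(0L, cut_bonds(reg), reg$length)
  sort(unique(as.vector(outer(pts, pts, "-"))[as.vector(outer(pts, pts, "-")) > 0]))
}
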