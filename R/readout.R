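# Reference-based decoding: seed-and-extend alignment of reads against the
# known register panel, fragment inference from mate pairs, insert-size
# gating, boundary-evidence accumulation and per-site nick calling.
#
# The references are a handful of known 450 nt registers, so a bespoke
# exact-20-mer seed index with mismatch-counting extension is sufficient;
# a production short-read aligner would be interchangeable here.

#' Build a seed index over a register panel
#'
#' Indexes every exact 20-mer of each register and of its reverse
#' complement; a read is located by looking up one of its 20-mers and
#' extending with mismatch counting.
#'
#' @param panel A `punch_panel` or `punch_register`.
#' @param seed_len Exact-seed length (default 20).
#' @return A `punch_index` used by [align_read()].
#' @export
build_index <- function(panel, seed_len = 20L) {
  panel <- as_panel(panel)
  env <- new.env(hash = TRUE, parent = emptyenv())
  ids <- vapply(panel$registers, function(r) r$id, character(1))
  fwd <- vapply(panel$registers, function(r) r$sequence, character(1))
  rc <- revcomp(fwd)
  add <- function(s, reg_i, orient) {
    n <- nchar(s)
    if (n < seed_len) return()
    kmers <- substring(s, 1:(n - seed_len + 1L), seed_len:n)
    for (p in seq_along(kmers)) {
      key <- kmers[p]
      hit <- c(reg_i, orient, p)
      env[[key]] <- if (is.null(env[[key]])) matrix(hit, nrow = 1L)
                    else rbind(env[[key]], hit)
    }
  }
  for (i in seq_along(ids)) {
    add(fwd[i], i, 1L)   # orient 1: forward strand of the register
    add(rc[i], i, 2L)    # orient 2: reverse complement
  }
  structure(list(env = env, seed_len = as.integer(seed_len), ids = ids,
                 fwd = fwd, rc = rc,
                 lens = nchar(fwd)),
            class = "punch_index")
}

#' Align one read to the panel by seed-and-extend
#'
#' Exact `seed_len`-mers of the read are looked up in the index (seed
#' offsets stepped along the read so a substitution inside one seed does
#' not lose the read); each hit is extended over the full read length,
#' counting mismatches.  The fewest-mismatch placement wins; an exact tie
#' across different registers is ambiguous and reported unmapped.
#'
#' @param read Read sequence (character scalar).
#' @param index A `punch_index` from [build_index()].
#' @param max_mismatch Maximum mismatches tolerated (default 10).
#' @return A list `(register_id, start, end, orientation, mismatches)` in
#'   the sense frame (0-based, half-open), or `NULL` if unmapped.
#' @export
align_read <- function(read, index, max_mismatch = 10L) {
  len <- nchar(read)
  sl <- index$seed_len
  if (len < sl) return(NULL)
  offsets <- unique(c(seq.int(1L, len - sl + 1L, by = sl), len - sl + 1L))
  rraw <- charToRaw(read)
  best <- NULL
  for (off in offsets) {
    hits <- index$env[[substr(read, off, off + sl - 1L)]]
    if (is.null(hits)) next
    for (h in seq_len(nrow(hits))) {
      reg_i <- hits[h, 1L]; orient <- hits[h, 2L]; pos <- hits[h, 3L]
      start <- pos - off + 1L                        # 1-based in oriented ref
      L <- index$lens[reg_i]
      if (start < 1L || start + len - 1L > L) next
      refstr <- if (orient == 1L) index$fwd[reg_i] else index$rc[reg_i]
      mm <- sum(rraw != charToRaw(substr(refstr, start, start + len - 1L)))
      if (mm > max_mismatch) next
      cand <- list(reg_i = reg_i, orient = orient, start = start, mm = mm)
      if (is.null(best) || mm < best$mm) { best <- cand; best$tie <- FALSE }
      else if (mm == best$mm &&
               (cand$reg_i != best$reg_i || cand$orient != best$orient ||
                cand$start != best$start)) {
        if (cand$reg_i != best$reg_i) best$tie <- TRUE
      }
    }
    if (!is.null(best)) break   # seeds further right only re-find the locus
  }
  if (is.null(best) || isTRUE(best$tie)) return(NULL)
  L <- index$lens[best$reg_i]
  if (best$orient == 1L) {
    s0 <- best$start - 1L
    list(register_id = index$ids[best$reg_i], start = s0, end = s0 + len,
         orientation = "forward", mismatches = best$mm)
  } else {
    s0 <- L - (best$start - 1L) - len
    list(register_id = index$ids[best$reg_i], start = s0, end = s0 + len,
         orientation = "reverse", mismatches = best$mm)
  }
}

#' Infer the sequenced fragment from a mate pair
#'
#' Concordant mates (same register, opposite orientations) delimit the
#' fragment `[min start, max end)`; the strand of origin follows mate 1's
#' orientation (forward implies a sense-strand fragment).
#'
#' @param a1,a2 Alignment records for mate 1 and mate 2 (see
#'   [align_read()]).
#' @return A list `(register_id, start, end, strand, template_length)`, or
#'   `NULL` for a discordant pair.
#' @export
infer_fragment <- function(a1, a2) {
  if (is.null(a1) || is.null(a2)) return(NULL)
  if (a1$register_id != a2$register_id) return(NULL)
  if (a1$orientation == a2$orientation) return(NULL)
  start <- min(a1$start, a2$start)
  end <- max(a1$end, a2$end)
  list(register_id = a1$register_id, start = start, end = end,
       strand = if (a1$orientation == "forward") "sense" else "antisense",
       template_length = end - start)
}

#' Gate an inferred fragment on its insert size
#'
#' A fragment is kept only when its template length is within `tol` of a
#' length achievable on the register, i.e. a distance between two
#' breakpoints (register ends or designed cut bonds).  The default
#' tolerance of one base mirrors size-splitting at one base greater and
#' lesser than each expected size.
#'
#' @param template_length Inferred fragment length (nt).
#' @param expected Numeric vector of achievable lengths (see
#'   `achievable_lengths`).
#' @param tol Tolerance in nt (default 1).
#' @return Logical: keep (`TRUE`) or reject.
#' @export
size_gate <- function(template_length, expected, tol = 1L) {
  any(abs(template_length - expected) <= tol)
}

#' Accumulate boundary evidence over inferred fragments
#'
#' Each size-gated fragment contributes its two boundaries; a boundary
#' falling within `tol` of a site's cut bond adds one count for that site
#' on the fragment's strand.  Boundaries at the register ends are the
#' natural termini and carry no site evidence.  A nick whose own fragment
#' went unobserved is still evidenced by its neighbours' boundaries (hole
#' inference falls out of the tiling).
#'
#' @param frags List of inferred fragments (see [infer_fragment()]),
#'   already size-gated.
#' @param reg The `punch_register` the fragments belong to.
#' @param tol Boundary tolerance in nt (default 1).
#' @return Evidence table: data.frame with columns `ordinal`, `cut_bond`,
#'   `sense`, `antisense` (boundary counts).
#' @export
accumulate_evidence <- function(frags, reg, tol = 1L) {
  bonds <- cut_bonds(reg)
  ev <- data.frame(ordinal = seq_along(bonds), cut_bond = bonds,
                   sense = 0L, antisense = 0L)
  for (f in frags) {
    if (f$register_id != reg$id) next
    for (b in c(f$start, f$end)) {
      if (b == 0L || b == reg$length) next   # register ends, not nick sites
      hit <- which(abs(bonds - b) <= tol)
      if (length(hit))
        ev[hit, f$strand] <- ev[hit, f$strand] + 1L
    }
  }
  ev
}

#' Call the nick pattern from an evidence table
#'
#' Binary mode: a site is 1 when its total boundary count reaches the
#' evidence threshold `tau` (default one read pair), else 0 -- sites with
#' no covering evidence are declared 0.  Ternary mode: 1 when only sense
#' evidence reaches `tau`, 2 when only antisense does, 0 when neither;
#' evidence on both strands of one site is a conflict and is flagged, not
#' silently resolved (as is antisense evidence in binary mode).
#'
#' @param ev Evidence table from [accumulate_evidence()].
#' @param tau Minimum boundary count to call a nick (default 1).
#' @param mode `"binary"` or `"ternary"`.
#' @param register_id Register identifier for the returned pattern.
#' @return A `punch_pattern` with attribute `conflicts` (integer vector of
#'   conflicted site ordinals).
#' @export
call_pattern <- function(ev, tau = 1L, mode = c("binary", "ternary"),
                         register_id = "R1") {
  mode <- match.arg(mode)
  if (tau < 1L) stop("tau must be >= 1", call. = FALSE)
  sense <- ev$sense >= tau
  anti <- ev$antisense >= tau
  if (mode == "binary") {
    symbols <- as.integer((ev$sense + ev$antisense) >= tau)
    conflicts <- ev$ordinal[sense & anti]
  } else {
    symbols <- integer(nrow(ev))
    symbols[sense & !anti] <- 1L
    symbols[anti & !sense] <- 2L
    conflicts <- ev$ordinal[sense & anti]
  }
  p <- new_pattern(register_id, symbols, mode)
  attr(p, "conflicts") <- conflicts
  attr(p, "evidence") <- ev
  p
}

#' Decode one register's pattern from a read batch
#'
#' Full single-register pipeline: align both mates of every pair, pair
#' them into fragments, size-gate, accumulate boundary evidence and call
#' the pattern.
#'
#' @param batch A `punch_reads` batch (one well's reads).
#' @param reg The `punch_register` to decode.
#' @param index Optional prebuilt `punch_index` over the containing panel.
#' @param mode `"binary"` or `"ternary"`.
#' @param tau,tol,max_mismatch,min_read_len Decoder tunables: evidence
#'   threshold, boundary/size tolerance (nt), alignment mismatch cap, and
#'   minimum read length kept (default 20, mirroring a MINLEN:20 trim).
#' @return A `punch_pattern` with `conflicts`, `evidence` and `stats`
#'   attributes.
#' @export
decode_register <- function(batch, reg, index = NULL,
                            mode = c("binary", "ternary"),
                            tau = 1L, tol = 1L, max_mismatch = 10L,
                            min_read_len = 20L) {
  mode <- match.arg(mode)
  if (is.null(index)) index <- build_index(reg)
  expected <- achievable_lengths(reg)
  stats <- c(pairs = nrow(batch), unmapped = 0L, discordant = 0L,
             size_rejected = 0L, other_register = 0L)
  frags <- list()
  for (i in seq_len(nrow(batch))) {
    if (nchar(batch$seq1[i]) < min_read_len ||
        nchar(batch$seq2[i]) < min_read_len) {
      stats["unmapped"] <- stats["unmapped"] + 1L; next
    }
    a1 <- align_read(batch$seq1[i], index, max_mismatch)
    a2 <- align_read(batch$seq2[i], index, max_mismatch)
    if (is.null(a1) || is.null(a2)) {
      stats["unmapped"] <- stats["unmapped"] + 1L; next
    }
    f <- infer_fragment(a1, a2)
    if (is.null(f)) { stats["discordant"] <- stats["discordant"] + 1L; next }
    if (f$register_id != reg$id) {
      stats["other_register"] <- stats["other_register"] + 1L; next
    }
    if (!size_gate(f$template_length, expected, tol)) {
      stats["size_rejected"] <- stats["size_rejected"] + 1L; next
    }
    frags[[length(frags) + 1L]] <- f
  }
  ev <- accumulate_evidence(frags, reg, tol)
  p <- call_pattern(ev, tau, mode, reg$id)
  attr(p, "stats") <- stats
  attr(p, "fragments") <- frags
  p
}

#' Decode a full run back to the payload
#'
#' Inverse of encode -> layout -> simulate: reads are grouped by well,
#' each well's registers are decoded against the panel, per-register
#' symbol vectors are reassembled into blocks in panel order, and blocks
#' into the payload with padding removed.  Decoding fails loudly on an
#' empty well or an unresolved evidence conflict, naming the well and
#' site.
#'
#' @param batch A `punch_reads` batch covering all wells (from
#'   [sim_reads()] or [read_fastq_pair()]).
#' @param panel The `punch_panel` used at encode time.
#' @param layout The `punch_layout` used at encode time.
#' @param ... Decoder tunables passed to [decode_register()].
#' @return List with `payload` (raw vector), `patterns` (per well), and
#'   `report` (per-well stats and evidence).
#' @export
decode_run <- function(batch, panel, layout, ...) {
  panel <- as_panel(panel)
  index <- build_index(panel)
  regs <- setNames(panel$registers,
                   vapply(panel$registers, function(r) r$id, character(1)))
  blocks <- vector("list", length(layout$wells))
  patterns <- vector("list", length(layout$wells))
  report <- list()
  for (w in seq_along(layout$wells)) {
    well <- names(layout$wells)[w]
    wb <- batch[batch$well == well, , drop = FALSE]
    if (nrow(wb) == 0L)
      stop("decoding error: well ", well, " has no reads", call. = FALSE)
    pats <- lapply(layout$wells[[w]], function(tmpl) {
      p <- decode_register(wb, regs[[tmpl$register_id]], index = index,
                           mode = layout$mode, ...)
      st <- attr(p, "stats")
      if (st["pairs"] > 0L && st["unmapped"] == st["pairs"])
        stop("decoding error: well ", well, ": no read aligned to the ",
             "panel (reads do not match the supplied design)",
             call. = FALSE)
      if (length(attr(p, "conflicts")))
        stop("decoding error: well ", well, ", register ", tmpl$register_id,
             ", site(s) ", paste(attr(p, "conflicts"), collapse = ","),
             " have conflicting strand evidence", call. = FALSE)
      p
    })
    patterns[[w]] <- pats
    syms <- unlist(lapply(pats, function(p) p$symbols))
    blocks[[w]] <- if (layout$mode == "binary") as.integer(syms)
                   else decode_ternary(syms, layout$block_size)
    report[[well]] <- lapply(pats, function(p)
      list(stats = attr(p, "stats"), evidence = attr(p, "evidence")))
  }
  names(patterns) <- names(layout$wells)
  stream <- structure(list(blocks = blocks, block_size = layout$block_size,
                           payload_length = layout$payload_length,
                           padding = layout$padding),
                      class = "punch_blocks")
  list(payload = bytes_from_blocks(stream), patterns = patterns,
       report = report)
}
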