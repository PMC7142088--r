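# End-to-end pipeline: fixture -> design -> encode -> simulate -> decode.

#' Default run configuration
#'
#' All tunables of the storage system, with defaults reproducing the
#' reference operating point: 450 nt registers, sites >= 25 bp apart,
#' guides at pairwise Hamming >= 8 with GC in [20%, 60%] and no G run
#' longer than 3, panel orthogonality below 0.50 similarity, 250-cycle
#' paired-end reads, +/-1 nt size and boundary tolerance, evidence
#' threshold of one read pair, and a 20 nt toehold dissociation threshold.
#'
#' @param ... Named overrides of any default.
#' @return A named list of class `punch_config`.
#' @export
punch_config <- function(...) {
  cfg <- list(
    register_length = 450L,
    n_sites = 10L,
    min_spacing = 25L,
    min_hamming = 8L,
    gc_bounds = c(0.20, 0.60),
    max_g_run = 3L,
    similarity_threshold = 0.50,
    read_length = 250L,
    size_tol = 1L,
    boundary_tol = 1L,
    tau = 1L,
    dissociation_threshold = 20L,
    seed_len = 20L,
    max_mismatch = 10L,
    coverage = 5L,
    error_rate = 0.001,
    phred = 30L,
    genome_length = 4000L,
    genome_gc = 0.5)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad))
    stop("unknown config field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  cfg[names(over)] <- over
  structure(cfg, class = "punch_config")
}

#' Simulate sequencing of an entire plate layout
#'
#' For each well: apply its patterns to their registers, denature, pool
#' the well's fragments and generate paired-end reads tagged with the
#' well label (one demultiplexed sample per well).
#'
#' @param layout A `punch_layout`.
#' @param panel The `punch_panel` the layout refers to.
#' @param coverage,read_len,err_rate,phred See [sim_reads()].
#' @param seed Optional integer seed; each well derives its own stream.
#' @return A combined `punch_reads` batch.
#' @export
simulate_layout <- function(layout, panel, coverage = 5L, read_len = 250L,
                            err_rate = 0, seed = NULL, phred = 30L) {
  panel <- as_panel(panel)
  regs <- setNames(panel$registers,
                   vapply(panel$registers, function(r) r$id, character(1)))
  batches <- vector("list", length(layout$wells))
  for (w in seq_along(layout$wells)) {
    well <- names(layout$wells)[w]
    fsets <- lapply(layout$wells[[w]], function(p) {
      reg <- regs[[p$register_id]]
      denature(apply_pattern(reg, p), reg$length)
    })
    batches[[w]] <- sim_reads(pool(fsets), panel, coverage = coverage,
                              read_len = read_len, err_rate = err_rate,
                              seed = if (is.null(seed)) NULL else seed + w,
                              well = well, phred = phred)
  }
  do.call(rbind, batches)
}

#' One-shot write/read round trip
#'
#' Chains the full pipeline: synthetic genome, register (or panel)
#' design, payload blocking and encoding, plate layout, channel
#' simulation, and decoding; then compares the recovered payload with the
#' input bit for bit.
#'
#' @param payload Raw vector or character scalar.
#' @param config A `punch_config` (see [punch_config()]).
#' @param seed Integer master seed for genome, design and channel.
#' @param genome Optional pre-built genome (fixture or character);
#'   defaults to a fresh fixture from `config`.
#' @param mode `"binary"` or `"ternary"`.
#' @return List: `recovered` (raw), `ok` (logical), `bit_accuracy`
#'   (fraction in [0,1]), `report`, `panel`, `layout`.
#' @export
roundtrip <- function(payload, config = punch_config(), seed = 1L,
                      genome = NULL, mode = "binary") {
  if (is.character(payload)) payload <- charToRaw(payload)
  if (is.null(genome))
    genome <- make_genome(config$genome_length, config$genome_gc, seed)
  reg <- design_register(genome, L = config$register_length,
                         n_sites = config$n_sites,
                         min_spacing = config$min_spacing,
                         min_hamming = config$min_hamming,
                         gc_bounds = config$gc_bounds,
                         max_g_run = config$max_g_run,
                         seed = seed)
  panel <- as_panel(reg)
  m <- if (mode == "binary") config$n_sites
       else floor(config$n_sites * log2(3))
  stream <- blocks_from_bytes(payload, m)
  layout <- layout_blocks(stream, panel, mode = mode)
  batch <- simulate_layout(layout, panel, coverage = config$coverage,
                           read_len = config$read_length,
                           err_rate = config$error_rate, seed = seed,
                           phred = config$phred)
  res <- decode_run(batch, panel, layout, tau = config$tau,
                    tol = config$boundary_tol,
                    max_mismatch = config$max_mismatch)
  acc <- bit_accuracy(payload, res$payload)
  list(recovered = res$payload, ok = identical(res$payload, payload),
       bit_accuracy = acc, report = res$report, panel = panel,
       layout = layout)
}

#' Fraction of payload bits recovered correctly
#'
#' @param truth,recovered Raw vectors.
#' @return Real in [0, 1]; 1 for two empty payloads.
#' @export
bit_accuracy <- function(truth, recovered) {
  if (length(truth) == 0L && length(recovered) == 0L) return(1)
  n <- min(length(truth), length(recovered))
  agree <- if (n > 0L)
    sum(bytes_to_bits(truth[seq_len(n)]) ==
          bytes_to_bits(recovered[seq_len(n)]))
  else 0L
  agree / (8L * max(length(truth), length(recovered)))
}
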