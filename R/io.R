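# Design/layout serialization: JSON design files, BED nick-site tracks,
# TSV evidence reports and bedGraph coverage.  All coordinates on disk are
# 0-based half-open, matching the in-memory convention.

#' Write and read a panel design as JSON
#'
#' The design file carries registers, sites, guides and cut bonds, plus
#' the bit/digit order conventions, and is the authoritative record of a
#' design (BED is a derived view).
#'
#' @param panel A `punch_panel` or `punch_register`.
#' @param path Output path.
#' @export
write_design <- function(panel, path) {
  panel <- as_panel(panel)
  obj <- list(
    format = "punchcard-design",
    conventions = list(coordinates = "0-based half-open",
                       nick_position = "bond b between sense bases b-1 and b",
                       bit_order = "MSB-first within each byte",
                       trit_order = "most-significant digit first"),
    registers = lapply(panel$registers, function(r) list(
      id = r$id, sequence = r$sequence, origin = r$origin,
      sites = lapply(r$sites, function(s) list(
        ordinal = s$ordinal, cut_bond = s$cut_bond,
        guide = s$guide$sequence,
        target_strand = s$guide$target_strand,
        footprint = s$guide$footprint)))),
    pairwise_similarity = panel$pairwise_similarity)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_design
#' @return `read_design` returns the `punch_panel`.
#' @export
read_design <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  registers <- lapply(obj$registers, function(r) {
    sites <- lapply(r$sites, function(s) list(
      ordinal = as.integer(s$ordinal),
      guide = new_guide(s$guide, s$target_strand,
                        unlist(s$footprint)),
      cut_bond = as.integer(s$cut_bond)))
    new_register(r$id, r$sequence, unlist(r$origin), sites)
  })
  n <- length(registers)
  sim <- matrix(unlist(obj$pairwise_similarity), n, n)
  rownames(sim) <- colnames(sim) <-
    vapply(registers, function(r) r$id, character(1))
  structure(list(registers = registers, pairwise_similarity = sim),
            class = "punch_panel")
}

#' Export nick sites as a BED track
#'
#' One record per site: 0-based half-open guide footprint on the register,
#' name = site ordinal, score = cut bond, strand = guide target strand.
#'
#' @param panel A `punch_panel` or `punch_register`.
#' @param path Output path.
#' @export
write_sites_bed <- function(panel, path) {
  panel <- as_panel(panel)
  rows <- do.call(rbind, lapply(panel$registers, function(r)
    do.call(rbind, lapply(r$sites, function(s)
      data.frame(chrom = r$id, start = s$guide$footprint[1],
                 end = s$guide$footprint[2], name = s$ordinal,
                 score = s$cut_bond,
                 strand = if (s$guide$target_strand == "sense") "+" else "-",
                 stringsAsFactors = FALSE)))))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write and read a plate layout as JSON
#'
#' @param layout A `punch_layout`.
#' @param path Output path.
#' @export
write_layout <- function(layout, path) {
  obj <- list(
    format = "punchcard-layout",
    mode = layout$mode, block_size = layout$block_size,
    payload_length = layout$payload_length, padding = layout$padding,
    rows = layout$rows, cols = layout$cols,
    wells = lapply(layout$wells, function(pats)
      lapply(pats, function(p) list(register_id = p$register_id,
                                    symbols = p$symbols))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_layout
#' @return `read_layout` returns the `punch_layout`.
#' @export
read_layout <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  wells <- lapply(obj$wells, function(pats)
    lapply(pats, function(p)
      new_pattern(p$register_id, unlist(p$symbols), obj$mode)))
  structure(list(wells = wells, block_size = as.integer(obj$block_size),
                 mode = obj$mode,
                 payload_length = as.integer(obj$payload_length),
                 padding = as.integer(obj$padding),
                 rows = as.integer(obj$rows), cols = as.integer(obj$cols)),
            class = "punch_layout")
}

#' Write per-site evidence as a TSV report
#'
#' @param report Report component of [decode_run()]'s result.
#' @param path Output path.
#' @export
write_evidence_tsv <- function(report, path) {
  rows <- do.call(rbind, lapply(names(report), function(well)
    do.call(rbind, lapply(report[[well]], function(entry) {
      ev <- entry$evidence
      ev$well <- well
      ev
    }))))
  utils::write.table(rows[, c("well", "ordinal", "cut_bond",
                              "sense", "antisense")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
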