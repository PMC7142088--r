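# Payload <-> nick-pattern codecs.
#
# Bit order is MSB-first within each byte; base-3 digits are emitted
# most-significant-first.  The positional-code string ("238") is a
# presentation format only; the symbol vector is authoritative.

new_pattern <- function(register_id, symbols, mode = c("binary", "ternary")) {
  mode <- match.arg(mode)
  symbols <- as.integer(symbols)
  if (any(is.na(symbols)))
    stop("pattern symbols must be integers", call. = FALSE)
  if (mode == "binary" && !all(symbols %in% 0:1))
    stop("binary pattern symbols must be in {0,1}", call. = FALSE)
  if (mode == "ternary" && !all(symbols %in% 0:2))
    stop("ternary pattern symbols must be in {0,1,2}", call. = FALSE)
  structure(list(register_id = register_id, symbols = symbols, mode = mode),
            class = "punch_pattern")
}

#' @export
print.punch_pattern <- function(x, ...) {
  cat(sprintf("<punch_pattern> %s [%s]: %s\n", x$register_id, x$mode,
              paste(x$symbols, collapse = "")))
  invisible(x)
}

check_pattern <- function(reg, pattern) {
  if (!inherits(pattern, "punch_pattern"))
    stop("expected a punch_pattern", call. = FALSE)
  if (length(pattern$symbols) != length(reg$sites))
    stop(sprintf("pattern has %d symbols but register %s has %d sites",
                 length(pattern$symbols), reg$id, length(reg$sites)),
         call. = FALSE)
  invisible(pattern)
}

#' Parse a byte payload into fixed-width bit blocks
#'
#' Bytes are unpacked MSB-first and concatenated; the bit stream is split
#' into blocks of `m` bits (the number of nick sites a block occupies:
#' 10 for a single register, 32 for the five-register panel, 50 for
#' two-sided ternary recording).  The final block is zero-padded and the
#' padding count recorded, so the inverse is exact.
#'
#' @param payload A raw vector (or character scalar, encoded as ASCII
#'   bytes).
#' @param m Block width in bits.
#' @return A `punch_blocks` object: list of m-bit integer vectors plus
#'   `payload_length` (bytes) and `padding` (bits).
#' @export
blocks_from_bytes <- function(payload, m) {
  if (is.character(payload)) payload <- charToRaw(payload)
  if (!is.raw(payload)) stop("payload must be raw or character", call. = FALSE)
  m <- as.integer(m)
  if (m < 1L) stop("block width must be >= 1", call. = FALSE)
  bits <- bytes_to_bits(payload)
  padding <- (m - length(bits) %% m) %% m
  bits <- c(bits, integer(padding))
  blocks <- if (length(bits) == 0L) list()
            else split(bits, rep(seq_len(length(bits) / m), each = m))
  structure(list(blocks = unname(blocks), block_size = m,
                 payload_length = length(payload),
                 padding = as.integer(padding)),
            class = "punch_blocks")
}

#' @rdname blocks_from_bytes
#' @param stream A `punch_blocks` object.
#' @return `bytes_from_blocks` returns the original raw payload.
#' @export
bytes_from_blocks <- function(stream) {
  bits <- unlist(stream$blocks)
  if (stream$padding > 0L)
    bits <- bits[seq_len(length(bits) - stream$padding)]
  bits_to_bytes(bits)
}

bytes_to_bits <- function(payload) {
  if (length(payload) == 0L) return(integer(0))
  m <- matrix(as.integer(rawToBits(payload)), nrow = 8L)  # LSB-first rows
  as.vector(m[8:1, ])                                     # flip to MSB-first
}

bits_to_bytes <- function(bits) {
  if (length(bits) == 0L) return(raw(0))
  if (length(bits) %% 8L != 0L)
    stop("bit count not a multiple of 8 after removing padding",
         call. = FALSE)
  m <- matrix(as.integer(bits), nrow = 8L)
  packBits(as.raw(as.vector(m[8:1, ])), type = "raw")
}

#' Encode a bit block as a binary nick pattern
#'
#' Symbol-for-symbol: bit 1 means "nick the site", bit 0 means leave it in
#' the ground state (writing a 0 needs no reaction).
#'
#' @param bits Integer vector over {0,1}.
#' @param register_id Identifier of the register carrying the block.
#' @return A binary `punch_pattern`.
#' @examples
#' p <- encode_block(c(0,1,1,0,0,0,0,1,0,0))
#' positional_code(p)  # "238"
#' @export
encode_block <- function(bits, register_id = "R1") {
  new_pattern(register_id, bits, "binary")
}

#' Positional-code string of a binary pattern
#'
#' The ordinals of the nicked sites, concatenated as digits when every
#' nicked ordinal is a single digit (the compact form, e.g. `0110000100`
#' -> `"238"`), otherwise comma-separated (unambiguous for registers with
#' 10 or more sites); the all-zero pattern prints as `"-"`.
#'
#' @param p A binary `punch_pattern`.
#' @return Character scalar.
#' @export
positional_code <- function(p) {
  if (p$mode != "binary")
    stop("positional codes are defined for binary patterns", call. = FALSE)
  ord <- which(p$symbols == 1L)
  if (length(ord) == 0L) return("-")
  if (all(ord <= 9L)) paste(ord, collapse = "")
  else paste(ord, collapse = ",")
}

#' Binary/ternary block conversion for two-sided recording
#'
#' With both strands available each site carries one of three states, i.e.
#' log2(3) = 1.58 bits.  A block of `n_bits` bits is read as a big-endian
#' integer and re-expressed in base 3, most-significant digit first,
#' left-padded to `n_trits` digits.  The default 50-bit block fits in 32
#' trits because 3^32 > 2^50.  Exact for blocks up to 52 bits (double
#' precision integer range).
#'
#' @param bits Integer vector over {0,1}.
#' @param n_trits Number of trits to emit (default `ceiling(len / log2(3))`).
#' @return Integer vector over {0,1,2} of length `n_trits`.
#' @export
encode_ternary <- function(bits, n_trits = NULL) {
  nb <- length(bits)
  if (nb > 52L) stop("ternary blocks support at most 52 bits", call. = FALSE)
  if (is.null(n_trits)) n_trits <- ceiling(nb / log2(3))
  if (3^n_trits < 2^nb)
    stop("n_trits too small: 3^", n_trits, " < 2^", nb, call. = FALSE)
  value <- sum(as.numeric(bits) * 2^((nb - 1L):0))
  trits <- numeric(n_trits)
  for (i in n_trits:1) {
    trits[i] <- value %% 3
    value <- (value - trits[i]) / 3
  }
  as.integer(trits)
}

#' @rdname encode_ternary
#' @param trits Integer vector over {0,1,2}.
#' @param n_bits Width of the recovered bit block.
#' @export
decode_ternary <- function(trits, n_bits) {
  if (n_bits > 52L) stop("ternary blocks support at most 52 bits", call. = FALSE)
  value <- sum(as.numeric(trits) * 3^((length(trits) - 1L):0))
  if (value >= 2^n_bits)
    stop("trit value exceeds ", n_bits, "-bit capacity", call. = FALSE)
  bits <- numeric(n_bits)
  for (i in n_bits:1) {
    bits[i] <- value %% 2
    value <- (value - bits[i]) / 2
  }
  as.integer(bits)
}

#' Ternary nick pattern from a trit vector
#'
#' Per site: 1 nicks the sense strand, 2 the antisense strand, 0 leaves
#' the site unmodified.
#'
#' @param trits Integer vector over {0,1,2}.
#' @param register_id Register identifier.
#' @return A ternary `punch_pattern`.
#' @export
ternary_pattern <- function(trits, register_id = "R1") {
  new_pattern(register_id, trits, "ternary")
}

#' 7-bit ASCII bit vector of a text string
#'
#' Each character contributes 7 bits, MSB first; used for compact text
#' titles (e.g. an 18-character title occupies 126 bits).
#'
#' @param text Character scalar of ASCII characters (< 128).
#' @return Integer bit vector of length `7 * nchar(text)`.
#' @export
ascii7_bits <- function(text) {
  codes <- utf8ToInt(text)
  if (any(codes > 127L)) stop("text must be 7-bit ASCII", call. = FALSE)
  unlist(lapply(codes, function(v) as.integer(intToBits(v))[7:1]))
}

# ---- plate layout --------------------------------------------------------

well_names <- function(n, rows = 16L, cols = 24L) {
  if (n > rows * cols)
    stop("plate capacity exceeded: need ", n, " wells but plate has ",
         rows * cols, call. = FALSE)
  all <- as.vector(t(outer(LETTERS[seq_len(rows)], seq_len(cols), paste0)))
  all[seq_len(n)]
}

#' Lay out encoded blocks on a microplate
#'
#' Each block occupies one well, row-major (A1, A2, ..., B1, ...), so well
#' order reproduces block order, like tracks and sectors on a disk.  A
#' block as wide as a single register's site count occupies that register
#' alone; a block spanning the whole panel (e.g. 32 bits over five
#' registers) is split into per-register sub-vectors in panel (genome)
#' order.  In ternary mode the block's bits are first converted to trits
#' and the trits split across the panel.
#'
#' @param stream A `punch_blocks` object.
#' @param panel A `punch_panel` (or single `punch_register`).
#' @param mode `"binary"` or `"ternary"`.
#' @param rows,cols Plate dimensions (default 384-well: 16 x 24).
#' @return A `punch_layout`: named list of wells, each a list of
#'   `punch_pattern`s (one per register used), plus codec metadata.
#' @export
layout_blocks <- function(stream, panel, mode = c("binary", "ternary"),
                          rows = 16L, cols = 24L) {
  mode <- match.arg(mode)
  panel <- as_panel(panel)
  widths <- vapply(panel$registers, function(r) length(r$sites), integer(1))
  ids <- vapply(panel$registers, function(r) r$id, character(1))
  m <- stream$block_size
  n_sym <- if (mode == "binary") m else {
    nt <- sum(widths)
    if (3^nt < 2^m)
      stop("panel carries only ", floor(sum(widths) * log2(3)),
           " ternary bits per block; block width ", m, " too large",
           call. = FALSE)
    nt
  }
  use <- cumsum(widths) >= n_sym
  n_regs <- if (any(use)) which(use)[1] else
    stop(sprintf("block of %d symbols exceeds the panel's %d sites",
                 n_sym, sum(widths)), call. = FALSE)
  if (sum(widths[seq_len(n_regs)]) != n_sym)
    stop(sprintf("block width %d symbols does not tile the first %d register(s) (%s sites)",
                 n_sym, n_regs,
                 paste(widths[seq_len(n_regs)], collapse = "+")),
         call. = FALSE)
  wells <- well_names(length(stream$blocks), rows, cols)
  layout <- lapply(stream$blocks, function(bits) {
    syms <- if (mode == "binary") bits else encode_ternary(bits, n_sym)
    splits <- split(syms, rep(seq_len(n_regs), times = widths[seq_len(n_regs)]))
    lapply(seq_len(n_regs), function(i)
      new_pattern(ids[i], splits[[i]], mode))
  })
  names(layout) <- wells
  structure(list(wells = layout, block_size = m, mode = mode,
                 payload_length = stream$payload_length,
                 padding = stream$padding, rows = rows, cols = cols),
            class = "punch_layout")
}

#' @rdname layout_blocks
#' @param layout A `punch_layout`.
#' @return `collect_layout` returns the `punch_blocks` stream (inverse of
#'   `layout_blocks`).
#' @export
collect_layout <- function(layout) {
  blocks <- lapply(layout$wells, function(pats) {
    syms <- unlist(lapply(pats, function(p) p$symbols))
    if (layout$mode == "binary") as.integer(syms)
    else decode_ternary(syms, layout$block_size)
  })
  structure(list(blocks = unname(blocks), block_size = layout$block_size,
                 payload_length = layout$payload_length,
                 padding = layout$padding),
            class = "punch_blocks")
}

as_panel <- function(x) {
  if (inherits(x, "punch_panel")) return(x)
  if (inherits(x, "punch_register"))
    return(structure(list(registers = list(x),
                          pairwise_similarity = matrix(1, 1, 1,
                            dimnames = list(x$id, x$id))),
                     class = "punch_panel"))
  stop("expected a punch_panel or punch_register", call. = FALSE)
}
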