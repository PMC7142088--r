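test_that("seed-and-extend finds exact and near-exact placements", {
  reg <- fixture_register()
  idx <- build_index(reg)
  read <- substr(reg$sequence, 38, 137)        # register[37:137) 0-based
  a <- align_read(read, idx)
  expect_identical(a$start, 37L)
  expect_identical(a$end, 137L)
  expect_identical(a$orientation, "forward")
  expect_identical(a$mismatches, 0L)

  # one substitution at position 50: same locus, 1 mismatch
  mut <- read
  substr(mut, 50, 50) <- setdiff(c("A","C","G","T"),
                                 substr(read, 50, 50))[1]
  am <- align_read(mut, idx)
  expect_identical(am$start, 37L)
  expect_identical(am$mismatches, 1L)

  # reverse-complement reads align with reverse orientation, same interval
  ar <- align_read(revcomp(read), idx)
  expect_identical(ar$start, 37L)
  expect_identical(ar$orientation, "reverse")

  expect_null(align_read("ACGTACGT", idx))      # shorter than the seed
  expect_null(align_read(strrep("A", 100), idx))  # foreign sequence
})

test_that("reads demultiplex to the correct register of a panel", {
  pan <- fixture_panel()
  idx <- build_index(pan)
  set.seed(31)
  for (i in 1:20) {
    r <- sample(5, 1)
    reg <- pan$registers[[r]]
    start <- sample(reg$length - 100, 1)
    read <- substr(reg$sequence, start, start + 99)
    a <- align_read(read, idx)
    expect_identical(a$register_id, reg$id)
    expect_identical(a$start, start - 1L)
  }
})

test_that("fragment inference uses mate extremes and mate-1 strand", {
  a1 <- list(register_id = "R1", start = 0L, end = 100L,
             orientation = "forward", mismatches = 0L)
  a2 <- list(register_id = "R1", start = 50L, end = 150L,
             orientation = "reverse", mismatches = 0L)
  f <- infer_fragment(a1, a2)
  expect_identical(f$start, 0L)
  expect_identical(f$end, 150L)
  expect_identical(f$template_length, 150L)
  expect_identical(f$strand, "sense")
  # short fragment: both mates span it fully
  b1 <- list(register_id = "R1", start = 10L, end = 60L,
             orientation = "reverse", mismatches = 0L)
  b2 <- list(register_id = "R1", start = 10L, end = 60L,
             orientation = "forward", mismatches = 0L)
  fb <- infer_fragment(b1, b2)
  expect_identical(fb$template_length, 50L)
  expect_identical(fb$strand, "antisense")
  # discordant pairs are dropped
  expect_null(infer_fragment(a1, list(register_id = "R2", start = 0L,
                                      end = 100L, orientation = "reverse",
                                      mismatches = 0L)))
  expect_null(infer_fragment(a1, b2))  # same orientation
})

test_that("insert-size gate keeps expected lengths within one base", {
  expected <- c(100, 150, 200)
  expect_true(size_gate(150, expected))
  expect_true(size_gate(149, expected, tol = 1))
  expect_true(size_gate(151, expected, tol = 1))
  expect_false(size_gate(160, expected, tol = 1))
  expect_false(size_gate(148, expected, tol = 1))
})

test_that("boundary evidence counts fragment ends at matching sites", {
  reg <- fixture_register()
  bonds <- cut_bonds(reg)
  frag <- function(a, b, strand = "sense")
    list(register_id = reg$id, start = a, end = b, strand = strand,
         template_length = b - a)
  # full tiling of the all-ones pattern: every site hit by both neighbours
  cuts <- c(0L, bonds, reg$length)
  frags <- lapply(seq_len(length(cuts) - 1),
                  function(i) frag(cuts[i], cuts[i + 1]))
  ev <- accumulate_evidence(frags, reg)
  expect_true(all(ev$sense >= 2))
  expect_true(all(ev$antisense == 0))
  # full-length fragment only: no site evidence
  ev0 <- accumulate_evidence(list(frag(0L, reg$length)), reg)
  expect_true(all(ev0$sense == 0))
  # fragments [0, c3) and [c3, L): evidence only at site 3
  ev3 <- accumulate_evidence(list(frag(0L, bonds[3]),
                                  frag(bonds[3], reg$length)), reg)
  expect_identical(which(ev3$sense > 0), 3L)
})

test_that("pattern calling thresholds evidence and flags conflicts", {
  ev <- data.frame(ordinal = 1:10, cut_bond = 1:10 * 30,
                   sense = 0L, antisense = 0L)
  ev$sense[c(2, 3, 8)] <- 4L
  p <- call_pattern(ev, tau = 1, mode = "binary")
  expect_identical(positional_code(p), "238")
  expect_length(attr(p, "conflicts"), 0)
  # zero evidence -> all sites declared 0
  ev0 <- ev; ev0$sense <- 0L
  expect_identical(sum(call_pattern(ev0)$symbols), 0L)
  # ternary: strand-resolved symbols, both-strand evidence is a conflict
  evt <- ev0
  evt$sense[c(1, 3)] <- 2L
  evt$antisense[c(2, 3)] <- 2L
  pt <- call_pattern(evt, mode = "ternary")
  expect_identical(pt$symbols[1:3], c(1L, 2L, 0L))
  expect_identical(attr(pt, "conflicts"), 3L)
  expect_error(call_pattern(ev, tau = 0), "tau")
})

test_that("a dropped middle fragment is still called through its neighbours", {
  reg <- fixture_register()
  p <- encode_block(bits("0110000100"), reg$id)
  fs <- denature(apply_pattern(reg, p), reg$length)
  # drop the sense fragment between the cuts at sites 3 and 8; both its
  # breakpoints remain evidenced by the flanking fragments
  sense <- which(fs$strand == "sense")
  drop <- sense[3]
  b <- sim_reads(fs[-drop, ], reg, coverage = 2, err_rate = 0, seed = 6)
  dec <- decode_register(b, reg)
  expect_identical(dec$symbols, p$symbols)
})

test_that("decoding is exact across all 1024 patterns of a 10-site register", {
  reg <- fixture_register()
  idx <- build_index(reg)
  sel <- as.matrix(expand.grid(rep(list(0:1), 10)))
  mismatches <- 0L
  for (i in seq_len(nrow(sel))) {
    p <- encode_block(sel[i, ], reg$id)
    fs <- denature(apply_pattern(reg, p), reg$length)
    b <- sim_reads(fs, reg, coverage = 2, err_rate = 0, seed = i)
    dec <- decode_register(b, reg, index = idx)
    if (!identical(dec$symbols, p$symbols)) mismatches <- mismatches + 1L
  }
  expect_identical(mismatches, 0L)
})

test_that("single-read coverage decodes exactly across a panel", {
  pan <- fixture_panel()
  idx <- build_index(pan)
  set.seed(77)
  for (i in 1:100) {
    r <- sample(5, 1)
    reg <- pan$registers[[r]]
    p <- encode_block(sample(0:1, length(reg$sites), TRUE), reg$id)
    fs <- denature(apply_pattern(reg, p), reg$length)
    b <- sim_reads(fs, pan, coverage = 1, err_rate = 0, seed = i)
    dec <- decode_register(b, reg, index = idx)
    expect_identical(dec$symbols, p$symbols)
  }
})

test_that("decoder is invariant to read order", {
  reg <- fixture_register()
  p <- encode_block(bits("1001100110"), reg$id)
  fs <- denature(apply_pattern(reg, p), reg$length)
  b <- sim_reads(fs, reg, coverage = 3, err_rate = 0, seed = 12)
  set.seed(3)
  shuffled <- b[sample(nrow(b)), ]
  expect_identical(decode_register(b, reg)$symbols,
                   decode_register(shuffled, reg)$symbols)
})

test_that("raising coverage never corrupts a correct noiseless call", {
  reg <- fixture_register()
  p <- encode_block(bits("0101010101"), reg$id)
  fs <- denature(apply_pattern(reg, p), reg$length)
  for (cov in c(1, 2, 5, 10)) {
    b <- sim_reads(fs, reg, coverage = cov, err_rate = 0, seed = 20 + cov)
    expect_identical(decode_register(b, reg)$symbols, p$symbols)
  }
})

test_that("ternary sense/antisense recording decodes the worked pattern", {
  reg <- fixture_register()
  p <- ternary_pattern(bits("1212121211"), reg$id)
  fs <- denature(apply_pattern(reg, p), reg$length)
  b <- sim_reads(fs, reg, coverage = 3, err_rate = 0, seed = 14)
  dec <- decode_register(b, reg, mode = "ternary")
  expect_identical(paste(dec$symbols, collapse = ""), "1212121211")
})

test_that("decode_run errors on an empty well, naming it", {
  reg <- fixture_register()
  lay <- layout_blocks(blocks_from_bytes(as.raw(1:5), 10), reg)
  batch <- simulate_layout(lay, reg, coverage = 1, err_rate = 0, seed = 2)
  expect_error(decode_run(batch[batch$well != "A2", ], reg, lay),
               "well A2")
})
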