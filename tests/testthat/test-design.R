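test_that("check_guide reports every violated constraint", {
  expect_match(check_guide("ATATATATATATATAT"), "GC 0%", all = FALSE)
  expect_match(check_guide("ATATATATATAGGGGA"), "G run", all = FALSE)
  expect_length(check_guide("ACGTACGTACGTACGT"), 0)  # GC = 8/16
  # simultaneously bad GC and G run -> both reported
  v <- check_guide("GGGGGGGGGGGGGGGG")
  expect_length(v, 2)
  expect_error(check_guide("ACGT"), "exactly 16")
})

test_that("hamming agrees with an independent per-position oracle", {
  oracle <- function(a, b) {
    ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
    n <- 0L
    for (i in seq_along(ca)) if (ca[i] != cb[i]) n <- n + 1L
    n
  }
  expect_identical(hamming("ACGTACGTACGTACGT", "ACGTACGTACGTACGT"), 0L)
  expect_identical(hamming("ACGTACGTACGTACGT", "TGCATGCATGCATGCA"), 16L)
  set.seed(5)
  for (i in 1:20) {
    a <- paste(sample(c("A","C","G","T"), 16, TRUE), collapse = "")
    b <- paste(sample(c("A","C","G","T"), 16, TRUE), collapse = "")
    expect_identical(hamming(a, b), oracle(a, b))
    expect_identical(hamming(a, b), hamming(b, a))
  }
  expect_error(hamming("ACGT", "ACGTA"), "equal-length")
})

test_that("cut bond follows the guide 10|11 rule on both strands", {
  expect_identical(cut_bond_for(c(100, 116), "sense"), 110L)
  expect_identical(cut_bond_for(c(100, 116), "antisense"), 106L)
  expect_identical(cut_bond_for(c(0, 16), "sense"), 10L)
  expect_error(cut_bond_for(c(0, 20), "sense"), "length 16")
})

test_that("designed registers satisfy all constraints, rechecked from scratch", {
  reg <- fixture_register()
  expect_s3_class(reg, "punch_register")
  expect_length(reg$sites, 10)
  expect_identical(validate_register(reg), character(0))
  # exhaustive pairwise Hamming check on the output
  gs <- vapply(reg$sites, function(s) s$guide$sequence, character(1))
  for (i in 1:9) for (j in (i + 1):10)
    expect_gte(hamming(gs[i], gs[j]), 8)
  expect_gte(min(diff(cut_bonds(reg))), 25)
})

test_that("design is deterministic given a seed and infeasibility is caught", {
  g <- fixture_genome()
  r1 <- design_register(g, L = 450, n_sites = 6, seed = 3)
  r2 <- design_register(g, L = 450, n_sites = 6, seed = 3)
  expect_identical(r1, r2)
  # pigeonhole: 9 gaps x 50 bp cannot fit a 450 nt register
  expect_error(design_register(g, L = 450, n_sites = 10, min_spacing = 50),
               "infeasible")
})

test_that("constraints hold across 20 design seeds", {
  for (s in 1:20) {
    reg <- design_register(make_genome(4000, 0.5, seed = s),
                           L = 450, n_sites = 10, seed = s,
                           id = sprintf("S%d", s))
    expect_identical(validate_register(reg), character(0))
  }
})

test_that("similarity is a normalized symmetric score with expected extremes", {
  reg <- fixture_register()
  expect_equal(similarity(reg, reg), 1.0)
  s <- similarity("ACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGT",
                  "TTGCATCAGGACTTAACTGTTCCGACTGGCAGTCACTTCAATATCAAGGTACCAACTAGG")
  expect_lt(s, 0.5)
  # unrelated random 450-mers are far below the orthogonality threshold
  set.seed(8)
  for (i in 1:5) {
    a <- paste(sample(c("A","C","G","T"), 450, TRUE), collapse = "")
    b <- paste(sample(c("A","C","G","T"), 450, TRUE), collapse = "")
    expect_lt(similarity(a, b), 0.5)
    expect_equal(similarity(a, b), similarity(b, a))
  }
})

test_that("panels are genome-ordered, orthogonal and guide-disjoint", {
  pan <- fixture_panel()
  expect_length(pan$registers, 5)
  expect_identical(vapply(pan$registers, function(r) length(r$sites),
                          integer(1)), c(10L, 5L, 6L, 5L, 6L))
  # recompute the similarity matrix on the output
  for (i in 1:4) for (j in (i + 1):5) {
    s <- similarity(pan$registers[[i]], pan$registers[[j]])
    expect_lt(s, 0.5)
    expect_equal(s, pan$pairwise_similarity[i, j])
  }
  starts <- vapply(pan$registers, function(r) r$origin[1], integer(1))
  ends <- vapply(pan$registers, function(r) r$origin[2], integer(1))
  expect_true(all(diff(starts) > 0))
  expect_true(all(starts[-1] >= ends[-5]))  # disjoint windows
  all_guides <- unlist(lapply(pan$registers, function(r)
    vapply(r$sites, function(s) s$guide$sequence, character(1))))
  expect_identical(anyDuplicated(all_guides), 0L)
})

test_that("expected fragment lengths are conserved and match worked cases", {
  reg <- fixture_register()
  L <- reg$length
  # all-zero pattern: both strands full length
  ef0 <- expected_fragments(reg, encode_block(rep(0, 10), reg$id))
  expect_identical(ef0$sense, L)
  expect_identical(ef0$antisense, L)
  # 10 cuts on one strand -> 11 fragments
  ef1 <- expected_fragments(reg, encode_block(rep(1, 10), reg$id))
  expect_length(ef1$sense, 11)
  expect_identical(sum(ef1$sense), L)
  # conservation over random patterns
  set.seed(21)
  for (i in 1:50) {
    p <- encode_block(sample(0:1, 10, TRUE), reg$id)
    ef <- expected_fragments(reg, p)
    expect_identical(sum(ef$sense), L)
    expect_identical(sum(ef$antisense), L)
  }
})

test_that("kmer census counts distinct words exactly", {
  expect_identical(kmer_census("ACGTACGT", 4), 4L)
  expect_identical(kmer_census("ACGTACGT", 1), 4L)
  g <- fixture_genome()
  for (k in c(2, 8, 16)) {
    n <- kmer_census(g, k)
    expect_lte(n, min(4^k, nchar(g$sequence) - k + 1))
    expect_gte(n, 1)
  }
  # brute-force oracle on a toy string
  toy <- "AACGTTACGGA"
  k <- 3
  oracle <- length(unique(substring(toy, 1:(nchar(toy) - k + 1),
                                    k:nchar(toy))))
  expect_identical(kmer_census(toy, k), oracle)
})

test_that("design files round-trip through JSON and export BED", {
  pan <- fixture_panel()
  path <- withr::local_tempfile(fileext = ".json")
  write_design(pan, path)
  back <- read_design(path)
  expect_identical(length(back$registers), length(pan$registers))
  for (i in seq_along(pan$registers)) {
    expect_identical(back$registers[[i]]$sequence,
                     pan$registers[[i]]$sequence)
    expect_identical(cut_bonds(back$registers[[i]]),
                     cut_bonds(pan$registers[[i]]))
  }
  expect_equal(back$pairwise_similarity, pan$pairwise_similarity,
               tolerance = 1e-12)
  bed <- withr::local_tempfile(fileext = ".bed")
  write_sites_bed(pan, bed)
  tab <- read.table(bed, sep = "\t")
  expect_identical(nrow(tab), 32L)
  expect_true(all(tab$V3 - tab$V2 == 16))
})
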