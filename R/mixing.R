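# Combinatorial mixing codecs for pooled copies of the same register.
#
# Fragments from same-register mixtures cannot be demultiplexed by
# alignment, so information is carried by the per-site NICK COUNTS of the
# pool (an adder channel).  A detecting matrix D (N binary row vectors of
# length M with all 2^N subset sums distinct) lets the decoder recover
# exactly which of N allowed patterns are present; Lindstrom-type
# constructions achieve M approaching 2N/log2(N).  A k-of-N group-testing
# codec encodes a message as the choice of a k-subset of patterns.

#' Verify that a binary matrix is detecting
#'
#' Exhaustively checks that all 2^N subset sums of the rows are distinct
#' (the defining property that makes same-register mixtures uniquely
#' decodable).
#'
#' @param D Binary matrix, N rows (patterns) by M columns (sites).
#' @param max_n Enumeration budget; N above this errors out (default 20).
#' @return Logical.
#' @export
verify_detecting <- function(D, max_n = 20L) {
  D <- as.matrix(D)
  N <- nrow(D)
  if (N > max_n)
    stop("verification budget exceeded: 2^", N, " subset sums", call. = FALSE)
  sums <- selector_matrix(N) %*% D
  !anyDuplicated(apply(sums, 1L, paste, collapse = ","))
}

# All 2^N binary selectors as a (2^N) x N matrix.
selector_matrix <- function(N) {
  m <- matrix(0L, 2^N, N)
  for (j in seq_len(N))
    m[, j] <- rep(rep(0:1, each = 2^(j - 1L)), length.out = 2^N)
  m
}

#' Build a detecting matrix for N mixture members
#'
#' Searches for a verified detecting matrix shorter than the identity:
#' starting at the counting lower bound `M >= N / log2(N+1)`, candidate
#' row sets are drawn from a deterministic (N-seeded) stream and each is
#' verified exhaustively; the first verified matrix wins.  If no shorter
#' matrix is found within the attempt budget the N x N identity is
#' returned, which is always detecting.  Construction is cached per
#' session.
#'
#' @param N Number of mixture members (>= 1).
#' @param attempts Candidate draws per length M (default 80).
#' @return A verified `DetectingMatrix` (binary matrix, N x M) with
#'   attribute `construction` (`"search"` or `"identity"`).
#' @export
build_detecting_matrix <- function(N, attempts = 80L) {
  N <- as.integer(N)
  if (N < 1L) stop("N must be >= 1", call. = FALSE)
  key <- as.character(N)
  if (!is.null(.detecting_cache[[key]])) return(.detecting_cache[[key]])
  D <- if (N <= 3L || N > 16L) NULL else search_detecting(N, attempts)
  if (is.null(D)) {
    D <- diag(1L, N)
    attr(D, "construction") <- "identity"
  }
  stopifnot(verify_detecting(D))
  .detecting_cache[[key]] <- D
  D
}

.detecting_cache <- new.env(parent = emptyenv())

search_detecting <- function(N, attempts) {
  m_lo <- max(1L, ceiling(N / log2(N + 1)))
  for (M in m_lo:(N - 1L)) {
    found <- with_seed(1000L + N, {
      res <- NULL
      for (a in seq_len(attempts)) {
        D <- matrix(sample(0:1, N * M, replace = TRUE), N, M)
        if (anyDuplicated(apply(D, 1L, paste, collapse = "")) ||
            any(rowSums(D) == 0L)) next
        if (verify_detecting(D)) { res <- D; break }
      }
      res
    })
    if (!is.null(found)) {
      attr(found, "construction") <- "search"
      return(found)
    }
  }
  NULL
}

#' Encode a selector through the adder channel
#'
#' The pooled mixture contains pattern i iff `x[i] = 1`; sequencing the
#' pool measures the integer per-site nick counts, i.e. the subset sum of
#' the selected rows.
#'
#' @param x Binary selector of length `nrow(D)`.
#' @param D A detecting matrix.
#' @return Integer count vector of length `ncol(D)`.
#' @export
mix_encode <- function(x, D) {
  D <- as.matrix(D)
  if (length(x) != nrow(D))
    stop("selector length must equal nrow(D)", call. = FALSE)
  as.integer(as.vector(t(D) %*% as.integer(x)))
}

#' Decode per-site nick counts back to the selector
#'
#' Depth-first search over the rows with per-site residual pruning; the
#' detecting property guarantees a unique solution for every achievable
#' count vector.
#'
#' @param s Integer count vector (per-site nick counts of the pool).
#' @param D The detecting matrix used at encode time.
#' @return The unique binary selector `x` with `t(D) %*% x == s`.
#' @export
mix_decode <- function(s, D) {
  D <- as.matrix(D)
  N <- nrow(D)
  s <- as.integer(s)
  if (length(s) != ncol(D))
    stop("count vector length must equal ncol(D)", call. = FALSE)
  # suffix column maxima: prune when residual cannot be covered
  suffix <- apply(D, 2L, function(col) rev(cumsum(rev(col))))
  if (N == 1L) suffix <- matrix(suffix, nrow = 1L)
  dfs <- function(i, residual) {
    if (any(residual < 0L)) return(NULL)
    if (i > N) return(if (all(residual == 0L)) integer(0) else NULL)
    if (any(residual > suffix[i, ])) return(NULL)
    take <- dfs(i + 1L, residual - D[i, ])
    if (!is.null(take)) return(c(1L, take))
    skip <- dfs(i + 1L, residual)
    if (!is.null(skip)) return(c(0L, skip))
    NULL
  }
  x <- dfs(1L, s)
  if (is.null(x))
    stop("inconsistent count vector: no selector reproduces the observed ",
         "per-site nick counts (count estimation may have failed)",
         call. = FALSE)
  x
}

#' Group-testing (k-of-N) codec
#'
#' Encodes an integer message as a k-subset of N allowed patterns via the
#' combinatorial number system (colex ranking); capacity is
#' `floor(log2(choose(N, k)))` bits, scaling as k*log2(N).
#'
#' @param message Non-negative integer `< choose(N, k)`.
#' @param k,N Subset size and pattern universe size.
#' @return `gt_encode`: sorted integer vector of k pattern indices in
#'   `1..N`; `gt_decode`: the message.
#' @export
gt_encode <- function(message, k, N) {
  if (message < 0 || message >= choose(N, k))
    stop("message out of range: need 0 <= message < choose(N, k) = ",
         choose(N, k), call. = FALSE)
  res <- integer(k)
  r <- message
  for (i in k:1) {
    v <- i - 1L
    while (choose(v + 1L, i) <= r) v <- v + 1L
    res[i] <- v
    r <- r - choose(v, i)
  }
  sort(res) + 1L
}

#' @rdname gt_encode
#' @param subset Integer vector of k distinct pattern indices in `1..N`.
#' @export
gt_decode <- function(subset, k, N) {
  subset <- sort(subset) - 1L
  if (length(subset) != k || any(subset < 0L) || any(subset >= N) ||
      anyDuplicated(subset))
    stop("subset must be k distinct indices in 1..N", call. = FALSE)
  sum(choose(subset, seq_len(k)))
}

#' Estimate per-site nick counts from decoder evidence
#'
#' In an equimolar pool of `N` nicked register copies sequenced at a known
#' per-fragment coverage, each member nicked at a site contributes
#' boundary counts from its two flanking fragments, so the member count at
#' a site is `boundary_count / (2 * coverage)`, rounded and clamped to
#' `[0, N]`.
#'
#' @param ev Evidence table from [accumulate_evidence()].
#' @param N Mixture size.
#' @param coverage_per_member Read pairs per fragment per member.
#' @return Integer count vector (one entry per site).
#' @export
estimate_counts <- function(ev, N, coverage_per_member) {
  raw <- (ev$sense + ev$antisense) / (2 * coverage_per_member)
  pmin(pmax(as.integer(round(raw)), 0L), as.integer(N))
}
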