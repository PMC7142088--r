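---
title: "Storing data in DNA backbone nicks: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Storing data in DNA backbone nicks: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(punchcard)
```

## The storage model

`punchcard` implements a topological DNA storage scheme: instead of
synthesizing sequence content, data is written onto *native* double-stranded
DNA by nicking (cutting one strand of) the sugar-phosphate backbone at
predesignated sites. The medium is a **register** — a fixed, known genomic
fragment, 450 bp by default — carrying $n$ designed nick sites (5–10 per
register). A binary block $b_1 \dots b_n$ maps positionally onto the sites:
$b_i = 1$ means "nick site $i$", $b_i = 0$ means leave it in the ground
state, so writing zeros costs nothing. With both strands available the
alphabet becomes ternary (1 = sense nick, 2 = antisense nick, 0 = none),
carrying $\log_2 3 \approx 1.58$ bits per site.

Reading inverts the physics: the nicked duplex is denatured, each strand
falls apart at its nicks into single-stranded fragments whose lengths are
fully determined by the nick positions, the fragment pool is sequenced
paired-end, and reads are aligned to the known reference register. Because
the reference is known a priori, the decoder only has to locate fragment
*breakpoints*, which is why even one read per fragment suffices in a clean
channel.

### Coordinates

Everything is 0-based, half-open. A nick is a **bond coordinate**
$b \in \{1, \dots, L-1\}$: the backbone bond between sense positions $b-1$
and $b$. Antisense nicks reuse the same sense-frame coordinate, which keeps
both strands in a single frame and avoids strand-specific off-by-one
errors. The enzyme cuts between positions 10 and 11 of its 16 nt guide; for
a sense-strand guide with footprint $[f, f+16)$ that is bond $f + 10$. An
antisense guide is antiparallel — its 5′ end sits at the footprint's right
edge — so the same rule lands on bond $f + 6$. The genome-frame mapping for
antisense guides is a declared convention of this package (derived from the
antiparallel geometry), not an empirical calibration.

## Design constraints and their defaults

| Parameter | Default | Units | Why |
|---|---|---|---|
| register length | 450 | nt | enough sites, still convenient for paired-end reading |
| sites per register | 10 (5–10) | — | one bit (or trit) per site |
| guide length | 16 | nt | the enzyme's guide span |
| guide GC | [20%, 60%] | — | binding efficiency window |
| max G run | 3 | nt | nanopore-readout precaution |
| pairwise guide Hamming | ≥ 8 | mismatches | suppress cross-site nicking |
| cut spacing | ≥ 25 | bp | inter-nick fragments must not dissociate |
| edge margin | 25 | bp | end fragments stay alignable |
| similarity threshold | < 0.50 | — | register orthogonality for pooling |
| toehold dissociation threshold | 20 | nt | 14 nt fragments release, ≥ 25 nt stay annealed |
| read length | 250 | cycles | paired-end, from each fragment end |
| size / boundary tolerance | ±1 | nt | insert-size splitting one base either way |
| evidence threshold τ | 1 | read pair | a single concordant pair calls a nick |

`design_register()` selects sites greedily left to right inside a scanned
window: the first candidate footprint passing composition, uniqueness,
Hamming and spacing checks is accepted, with no backtracking. Greedy
selection is reproducible and adequate because the constraints are loose on
a random-ish genome; a window that cannot host the requested site count is
simply skipped. `validate_register()` re-checks every invariant from
scratch and is run on every designed register in the test suite.

The dissociation threshold (20 nt) is a declared model constant sitting
strictly between the released 14 nt toehold fragment and the ≥ 25 bp
spacing at which fragments are required to stay annealed; it is
configurable.

The similarity score between two registers is the best local-alignment
score under unit scoring (match +1, mismatch/gap −1) divided by the shorter
length. This is a declared metric choice: identical sequences score 1,
unrelated 450-mers score ≈ 0.1, and the orthogonality threshold is strict
(< 0.50).

## The synthetic genome fixture

`make_genome()` draws i.i.d. bases at a target GC fraction (default 0.5).
It emulates the one property of a bacterial genome the designer depends on
— abundant unique 16-mers — and deliberately omits everything else: no
repeats, no skew, no coding structure. Passing tests therefore demonstrate
correctness of design, codec and decoding logic on a clean reference; they
do not demonstrate robustness to genomic repeats, which real deployments
would handle through the genome-wide uniqueness scan (the mechanism exists;
the adversarial input does not arise in the fixture). Guide uniqueness is
enforced against the full fixture genome's forward strand.

## The simulated channel

`sim_reads()` models a directional single-strand library: each fragment
yields `coverage` read pairs, mate 1 from the fragment's 5′ end, mate 2 the
reverse complement of its 3′ end, truncated to the fragment length.
Directionality preserves strand of origin in pair orientation, which is
what makes ternary (sense/antisense) decoding possible. Errors are i.i.d.
substitutions only; no indels, PCR bias or quality decay — the decoder's
acceptance surface is breakpoint positions, which substitutions stress
sufficiently. Qualities are a constant Phred 30 because the decoder never
reads them; trimming is reduced to a minimum-length filter (20 nt).
Coverage is per fragment, not per base, matching the decoder's evidence
model. Per-site nicking failure probabilities are not modeled (the channel
writes what the pattern says); the decoder's τ threshold is the knob that
would absorb partial nicking in noisy runs.

## Decoding

The aligner is a bespoke seed-and-extend: exact 20-mers of the read are
looked up in an index of the ≤ 5 × 450 nt panel (both orientations) and
extended by mismatch counting; the fewest-mismatch placement wins and ties
across registers are discarded as ambiguous (correctness over yield — panel
orthogonality makes them rare). With references this small a general-purpose
aligner would be interchangeable but adds nothing testable.

Concordant mates delimit an inferred fragment; its template length must
match an achievable breakpoint distance to ±1 nt (the size gate), and its
two boundaries then add evidence to any site whose cut bond lies within
±1 nt. Register ends carry no evidence. A site is called nicked when its
boundary count reaches τ = 1; uncovered sites are declared 0. Hole
inference is implicit: a fragment that was never sequenced still has both
its breakpoints evidenced by the neighbouring fragments, so the call
survives dropouts. Evidence on both strands of a binary site (or of one
ternary site) is flagged as a conflict and decoding fails loudly rather
than guessing.

## Combinatorial mixing

Copies of the *same* register cannot be demultiplexed by alignment, so
mixed pools store data in per-site nick **counts** (an adder channel). A
detecting matrix $D$ — $N$ binary rows whose $2^N$ subset sums are all
distinct — makes the pool uniquely decodable; Lindström-type constructions
approach length $M = 2N/\log_2 N$. Because the classical construction's
details are a matter of literature fidelity rather than checkable
correctness, this package treats "any verified detecting matrix" as the
contract: `build_detecting_matrix()` draws candidate row sets from a
deterministic N-seeded stream, starting at the counting lower bound
$M \ge N/\log_2(N+1)$, verifies each candidate exhaustively, and falls back
to the (always detecting) identity if the search fails. Achieved lengths:

| N | 4 | 5 | 6 | 7 | 8 | 9 | 10 | 11 | 12 |
|---|---|---|---|---|---|---|----|----|----|
| M achieved | 3 | 4 | 5 | 5 | 6 | 6 | 7 | 8 | 9 |
| $2N/\log_2 N$ | 4.0 | 4.3 | 4.6 | 5.0 | 5.3 | 5.7 | 6.0 | 6.4 | 6.7 |

(For $N \le 3$ no binary detecting matrix shorter than the identity
exists.) Decoding is depth-first search with per-site residual pruning —
exponential in the worst case, instant at the supported $N \le 20$
verification budget — and count estimation assumes an equimolar pool at
known per-member coverage: each member nicked at a site contributes
boundaries from its two flanking fragments, so the member count is
`boundary_count / (2 × coverage)`. The k-of-N group-testing codec is the
combinatorial number system (colex ranking), carrying
$\lfloor \log_2 \binom{N}{k} \rfloor \approx k \log_2 N$ bits.

## Numerical and representation choices

* Bit order is MSB-first within each byte; base-3 digits are emitted
  most-significant-first. Both are arbitrary but must be fixed; they are
  recorded in every design file header.
* Ternary blocks are capped at 52 bits so the big-endian integer stays
  exact in double precision; the reference 50-bit block fits in 32 trits
  since $3^{32} > 2^{50}$ (both values are themselves exact doubles).
* The positional-code string ("238") is presentation only and switches to a
  comma-separated canonical form whenever an ordinal ≥ 10 is present,
  because the compact form is ambiguous there. The symbol vector in the
  layout JSON is authoritative.
* Payload length and padding live in the layout JSON, not in DNA; the
  scheme stores files of known size and in-DNA headers are out of scope.
* The empty pattern decodes from full-length fragments; the empty payload
  produces an empty, valid layout.

## Problem sizes in the test suite

The suite runs the exhaustive enumerations the design admits at desk
scale: all 1024 patterns of a 10-site register for fragment-length
conservation and for end-to-end encode→sequence→decode identity
(coverage 2, error-free), 20 design seeds for constraint satisfaction,
100 random patterns across a 5-register panel at single-read coverage,
detecting-matrix verification to $N = 12$ ($2^{12}$ subset sums), full
selector enumeration for mixture recovery at $N = 6$, and an 80-bit
payload at coverage 5 with substitution rate $10^{-3}$. Genomes are 4 kb
(single register) and 20 kb (5-register panel).

## Known limitations

* The fixture genome is repeat-free; repeat-induced ambiguity is handled
  by design-time uniqueness checks but never exercised end to end.
* The channel has no indels, so the ±1 nt tolerances are stressed only by
  substitutions near breakpoints.
* Adder-channel decoding is integer-exact; noise-robust (non-integer)
  count deconvolution and unequal-concentration pools are out of scope.
* The reporter model is a unit-slope line — sufficient for ordering
  fractions, silent on kinetics.
* Registers designed here place all guides on one strand per register;
  two-sided guide placement would change only `cut_bond_for`'s offset
  bookkeeping.
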