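# punchcard

Tools for storing digital data in the backbone topology of native
double-stranded DNA. Instead of synthesizing information-bearing sequence,
data is written as **nicks** — single-strand cuts of the sugar-phosphate
backbone — placed by a DNA-guided nicking enzyme at designed sites on a
known genomic fragment (a *register*, 450 bp by default). Reading denatures
the nicked duplex into single-stranded fragments whose lengths are dictated
by the nick positions, sequences the pool paired-end, and recovers the nick
pattern by reference alignment and breakpoint analysis. Because the
reference is known, a single concordant read pair per fragment suffices for
exact recovery.

The package is aimed at people studying molecular data storage: it covers
the whole desk-scale loop — register/guide design under the scheme's
sequence constraints, payload encoding, a simulator of the physical channel,
and the exact decoder — plus the combinatorial codecs that make pooled
recording work.

## The scheme in brief

* **Positional encoding.** A register with $n$ sites stores an $n$-bit
  block: bit $i$ = 1 ⇔ site $i$ is nicked; the block `0110000100` becomes
  the positional code 238 (nick sites 2, 3 and 8). Two-sided (sense /
  antisense) nicking makes the alphabet ternary at
  $\log_2 3 \approx 1.58$ bits/site.
* **Guide design.** Each site is addressed by a 16 nt guide that cuts
  between its positions 10 and 11. Guides need GC in [20%, 60%], no G run
  longer than 3, pairwise Hamming distance ≥ 8, genome-unique footprints,
  and cut sites ≥ 25 bp apart so inter-nick fragments stay annealed.
  Orthogonal registers (pairwise similarity < 0.5) let blocks span a panel.
* **Decoding.** Reads are aligned by seed-and-extend against the known
  panel, mate pairs delimit fragments, fragments are kept when their length
  matches an achievable inter-breakpoint distance (±1 nt), and each
  fragment boundary within ±1 nt of a site's cut bond is evidence that the
  site is nicked; uncovered sites are 0.
* **Mixing codecs.** Pools of the *same* register store data in per-site
  nick counts (an adder channel); a verified *detecting matrix* (all
  $2^N$ subset sums distinct, Lindström-style length approaching
  $2N/\log_2 N$) makes the pool uniquely decodable. A k-of-N group-testing
  codec (combinatorial number system) carries
  $\lfloor\log_2\binom{N}{k}\rfloor$ bits.

## Worked example

```r
library(punchcard)

genome <- make_genome(4000, 0.5, seed = 7)        # synthetic source genome
reg <- design_register(genome, L = 450, n_sites = 10, seed = 7)
reg
#> <punch_register> R1: 450 nt, 10 nick sites at bonds {28, 53, 94, 126,
#>   151, 176, 201, 226, 251, 276}

p <- encode_block(c(0,1,1,0,0,0,0,1,0,0), reg$id) # one 10-bit block
positional_code(p)
#> [1] "238"

expected_fragments(reg, p)                        # what sequencing will see
#> $sense
#> [1]  41  53 132 224
#> $antisense
#> [1] 450

fs <- denature(apply_pattern(reg, p), reg$length) # write + melt
batch <- sim_reads(fs, reg, coverage = 1, err_rate = 0, seed = 1)
nrow(batch)                                       # one pair per fragment
#> [1] 5

decode_register(batch, reg)                       # read back
#> <punch_pattern> R1 [binary]: 0110000100

rt <- roundtrip(charToRaw("DNA punch cards"), punch_config(), seed = 1)
rawToChar(rt$recovered); rt$bit_accuracy
#> [1] "DNA punch cards"
#> [1] 1
```

The three nicks cut the sense strand into four fragments (41 + 53 + 132 +
224 = 450 nt) while the unnicked antisense strand stays full length; the
decoder recovers the pattern from five read pairs, and the one-shot
`roundtrip()` drives the same pipeline from payload bytes to recovered
bytes.

A command-line wrapper with `fixture`, `design`, `encode`, `simulate`,
`decode` and `roundtrip` subcommands lives at `inst/cli/punchcard.R`
(after installation: `system.file("cli", "punchcard.R", package =
"punchcard")`).

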