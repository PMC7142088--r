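# Shared fixtures: one small genome and one fully designed register reused
# across test files (design is deterministic, so building once is safe).

fixture_genome <- function(len = 4000, gc = 0.5, seed = 7) {
  make_genome(len, gc, seed)
}

fixture_register <- local({
  cache <- new.env(parent = emptyenv())
  function(n_sites = 10L, seed = 7) {
    key <- paste(n_sites, seed)
    if (is.null(cache[[key]]))
      cache[[key]] <- design_register(fixture_genome(seed = seed),
                                      L = 450, n_sites = n_sites,
                                      seed = seed)
    cache[[key]]
  }
})

fixture_panel <- local({
  cache <- new.env(parent = emptyenv())
  function() {
    if (is.null(cache$panel))
      cache$panel <- design_panel(make_genome(20000, 0.5, seed = 11),
                                  count = 5,
                                  per_register_sites = c(10, 5, 6, 5, 6),
                                  seed = 11)
    cache$panel
  }
})

# integer bit vector from a "0101" style string
bits <- function(s) as.integer(strsplit(s, "")[[1]])
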