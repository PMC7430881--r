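# Shared fixtures, all built in code.

# four-term hand-worked vocabulary: a chain C01 -> C01.100 -> C01.100.500
# plus a sibling C01.200
toy_v0 <- function() {
  mesh_vocab(list(R = "C01", X = "C01.100", A = "C01.100.500",
                  B = "C01.200"))
}

# small random binary association matrix over given diseases
rand_assoc <- function(diseases, n_lnc, density = 0.4, seed = 1) {
  idssim:::with_seed(seed, {
    m <- matrix(as.numeric(runif(n_lnc * length(diseases)) < density),
                n_lnc, length(diseases),
                dimnames = list(sprintf("u%02d", seq_len(n_lnc)), diseases))
    m
  })
}

# the default planted-block study fixture
planted_fixture <- function(seed = 11) {
  vocab <- synth_vocab(n_terms = 200, seed = seed)
  assoc <- synth_assoc(vocab, n_lncrnas = 40, n_diseases = 30, n_blocks = 4,
                       within_block_density = 0.6, background_density = 0.02,
                       seed = seed)
  list(vocab = vocab, assoc = assoc)
}
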