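# shared helpers: random sequences and event sets for property-style tests

random_protein <- function(n = 50, id = "rnd") {
  protein_seq(id, sample(names(paleomb::RESIDUE_MASS), n, replace = TRUE))
}

# random set of substitution events applicable (forward) to seq
random_events <- function(seq, k = 5) {
  pos <- sample(seq_along(seq$residues), k)
  lapply(pos, function(p) {
    from <- seq$residues[p]
    to <- sample(setdiff(names(paleomb::RESIDUE_MASS), from), 1)
    parse_substitution(paste0(from, p, to))
  })
}
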