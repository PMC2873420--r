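# Shared fixtures built in code.

# reduced-alphabet scheme for oracle sweeps: 4 usable residues (A,C,D,E),
# match +3 / mismatch -2, small gap penalties so gapped paths matter
mini_scheme <- function() {
  m <- matrix(-2, 20, 20, dimnames = list(rfxcilia:::AA20, rfxcilia:::AA20))
  diag(m) <- 3
  substitution_scheme(matrix = m, gap_open = 2, gap_extend = 1)
}

mini_alphabet <- c("A", "C", "D", "E")

random_mini_peptide <- function(len) {
  paste(sample(mini_alphabet, len, replace = TRUE), collapse = "")
}

# the default scheme, built once per test file
blosum <- function() substitution_scheme()

# packaged synthetic seed queries
seed_queries <- function() load_dbd_seeds()

# a quick single-implant proteome: one evolved seed domain plus decoys
quick_proteome <- function(species, divergence, n_decoys = 10,
                           preserve_anchors = TRUE, rng_seed = 1L,
                           label = "RFX", seed_q = seed_queries()[[1]]) {
  simulate_proteome(
    species, n_decoys = n_decoys,
    implants = list(implant_spec(seed_q, divergence,
                                 preserve_anchors = preserve_anchors,
                                 flank_lengths = c(80L, 80L), label = label)),
    decoy_length_range = c(200L, 300L), rng_seed = rng_seed)
}

# fast config for tests: fewer shuffles (still >= the 99 floor)
test_config <- function(...) run_config(n_shuffles = 99, ...)

# deterministically substitute the given 0-based positions to a different
# residue (first alphabet residue that differs)
substitute_positions <- function(sequence, positions) {
  ch <- strsplit(sequence, "")[[1]]
  for (p in positions) {
    ch[p + 1] <- setdiff(rfxcilia:::AA20, ch[p + 1])[1]
  }
  paste(ch, collapse = "")
}

# two-step homolog chain with disjoint substitution sets: each step replaces
# 23 non-anchor sites, so step neighbours share 53/76 (~70%) while the
# end-point shares only 30/76 (39.5%, below the 40% rule) with the seed
chain_fixture <- function(seed_q = seed_queries()[[1]]) {
  nonanchor <- setdiff(0:75, seed_q$anchors)
  ord <- rfxcilia:::with_seed(777, sample(nonanchor))
  ev1 <- substitute_positions(seed_q$sequence, ord[1:23])
  ev2 <- substitute_positions(ev1, ord[24:46])
  list(ev1 = ev1, ev2 = ev2, seed_q = seed_q)
}

# embed a fixed domain (divergence 0 implant) in a one-protein proteome
embed_domain <- function(species, domain, anchors, rng_seed,
                         flanks = c(80L, 80L)) {
  q <- query_domain(paste0(species, "_dom"), domain, anchors)
  simulate_proteome(species, n_decoys = 0,
                    implants = list(implant_spec(q, 0, flank_lengths = flanks)),
                    rng_seed = rng_seed)$records
}
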