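# Shared fixtures; everything built in code, no files.

# Small promoter-style region: upstream tract, ATG near the 3' end.
toy_region <- function(upstream = "AACCGTACGT", downstream = "ATGGCA",
                       name = "toy") {
  suppressWarnings(
    reference_region(name, paste0(upstream, downstream),
                     atg_index = nchar(upstream) + 1L))
}

# Deterministic mid-size promoter used across synthetic tests.
std_promoter <- function(seed = 7, length = 1300, gc = 0.38) {
  gen_reference(length, gc_fraction = gc, atg_index = length - 149L,
                seed = seed)
}

# Binomial standard error on the percent scale.
binom_se_pct <- function(p, n) 100 * sqrt(p * (1 - p) / n)

# Build a MoleculePool by hand (bypassing the profile draw) for exact
# digestion arithmetic.
manual_pool <- function(states, halfsite_local, region, fragment) {
  structure(
    list(n_molecules = nrow(states), states = states,
         halfsite_local = halfsite_local,
         halfsite_atg = atg_positions(fragment[1], fragment[2])[halfsite_local],
         fragment = as_fragment(fragment), region = region),
    class = "MoleculePool")
}
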