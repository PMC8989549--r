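# Shared fixtures: tiny designs and constructed populations, built in code.

tiny_design <- function(lengths = c(1, 2)) {
  library_design("ACGT", lengths, "GGTTAACCGG", name = "tiny")
}

# A noiseless two-level droplet population: n_empty empties plus occupied
# droplets at two GFP levels, with deterministic optics.
two_level_population <- function(n_empty = 8950, n_low = 800, n_high = 250,
                                 low = 2, high = 20) {
  optics <- optics_model(noise_cv = 0, gfp_cap = 1e6)
  bead_count <- c(rep(0L, n_empty), rep(1L, n_low + n_high))
  expr <- c(rep(0, n_empty), rep(low, n_low), rep(high, n_high))
  droplet_signals(bead_count, expr, optics)
}

# Hill responses with multiplicative noise, replicated per concentration.
hill_dataset <- function(concs, baseline, max_response, ec50, hill,
                         noise_cv = 0, reps = 1) {
  cc <- rep(concs, each = reps)
  y <- baseline + (max_response - baseline) *
    ifelse(cc == 0, 0, cc^hill / (ec50^hill + cc^hill))
  if (noise_cv > 0) {
    y <- y * stats::rlnorm(length(y), 0, sqrt(log(1 + noise_cv^2)))
  }
  tibble::tibble(ligand_conc = cc, response = y)
}

# Error-free reads constructed directly from a design (one cycle).
make_reads <- function(design, variant_ids, barcode, qual_char = "I") {
  seqs <- paste0(barcode, design$upstream_constant, variant_ids,
                 design$downstream_constant)
  tibble::tibble(
    id = sprintf("r%d", seq_along(seqs)),
    sequence = seqs,
    quality = strrep(qual_char, nchar(seqs))
  )
}
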