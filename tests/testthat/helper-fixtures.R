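# Shared fixtures, built once per test run and cached.  The small panel keeps
# unit tests fast; the study panel (20 taxa, 200 loci) backs the
# property-level checks and is only built when first requested.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

small_panel <- function() fixture("small_panel", function() {
  generate_panel(panel_params(n_taxa = 8L, n_loci = 30L), seed = 101L)
})

small_design <- function() fixture("small_design", function() {
  p <- small_panel()
  run_design(p$assemblies[[1]], p$assemblies[-1],
             discovery_params(),
             design_params(min_species_for_final = 6L))
})

study_panel <- function() fixture("study_panel", function() {
  generate_panel(panel_params(), seed = 20260920L %% 2^30)
})

study_design <- function() fixture("study_design", function() {
  p <- study_panel()
  run_design(p$assemblies[[1]], p$assemblies[-1])
})

# Planted-locus bookkeeping: which truth cores are recovered by called loci
# (>= half the core covered by one called locus), and which called loci are
# background (not half-contained in any core).
recovery_stats <- function(loci, truth_one_taxon) {
  tr <- truth_one_taxon
  recovered <- vapply(seq_len(nrow(tr)), function(i) {
    ov <- pmin(loci$end, tr$end[i]) - pmax(loci$start, tr$start[i])
    any(loci$contig == tr$contig[i] & ov > 0.5 * (tr$end[i] - tr$start[i]))
  }, logical(1))
  false_loci <- vapply(seq_len(nrow(loci)), function(i) {
    ov <- pmin(loci$end[i], tr$end) - pmax(loci$start[i], tr$start)
    !any(tr$contig == loci$contig[i] & ov >= 0.5 * (loci$end[i] - loci$start[i]))
  }, logical(1))
  list(recovery = mean(recovered), n_false = sum(false_loci))
}

# A tiny hand-buildable assembly from explicit sequences.
toy_assembly <- function(seqs, taxon = "toy", mask = NULL,
                         datatype = "genome") {
  assembly(seqs, taxon = taxon, datatype = datatype, mask = mask)
}
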