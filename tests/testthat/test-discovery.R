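test_that("read tiling arithmetic matches the stride contract", {
  a <- toy_assembly(c(c1 = rnd_dna(250)))
  r <- simulate_reads(a, 100, 50)
  expect_equal(r$offset, c(0, 50, 100, 150))
  expect_equal(unique(nchar(r$sequence)), 100)
  expect_equal(nrow(simulate_reads(toy_assembly(c(c1 = rnd_dna(99))), 100, 50)), 0)
  # non-overlapping tiling reconstructs the contig prefix
  r2 <- simulate_reads(a, 100, 100)
  expect_equal(paste(r2$sequence, collapse = ""), substr(a$contigs[["c1"]], 1, 200))
})

test_that("self-mapping covers exactly the tiling-reachable prefix", {
  set.seed(8)
  ref <- toy_assembly(c(c1 = rnd_dna(1030)))
  reads <- simulate_reads(ref, 100, 50)
  cov <- map_taxon_to_reference(reads, ref, 0.05)
  expect_equal(nrow(cov$c1), 1)
  expect_equal(cov$c1$start, 0)
  expect_equal(cov$c1$end, 1000)
})

test_that("the divergence ceiling separates mappable from unmappable taxa", {
  set.seed(9)
  anc <- rnd_dna(3000)
  ref <- toy_assembly(c(c1 = anc))
  far <- toy_assembly(c(c1 = evolve_sequence(anc, 0.10, seed = 2)), taxon = "far")
  near <- toy_assembly(c(c1 = evolve_sequence(anc, 0.02, seed = 3)), taxon = "near")
  cov_far <- map_taxon_to_reference(simulate_reads(far), ref, 0.05)
  cov_near <- map_taxon_to_reference(simulate_reads(near), ref, 0.05)
  covered_bp <- function(cov) sum(cov$c1$end - cov$c1$start)
  expect_lt(covered_bp(cov_far), 0.2 * 3000)
  expect_gt(covered_bp(cov_near), 0.9 * 3000)
})

test_that("occupancy threshold arithmetic and error handling", {
  ref <- toy_assembly(c(c1 = rnd_dna(500)))
  # fabricate coverages: 19 taxa, all covering [100, 400)
  covs <- rep(list(list(c1 = data.frame(start = 100, end = 400))), 19)
  p <- discovery_params(min_locus_length = 100)
  loci <- call_conserved_loci(covs, ref, p, n_taxa_total = 20)
  expect_equal(attr(loci, "occupancy_threshold"), 18)  # ceil(0.9 * 20)
  expect_equal(loci$start, 100)
  expect_equal(loci$end, 400)
  expect_equal(loci$occupancy_count, 20)
  expect_error(call_conserved_loci(covs, ref, discovery_params(occupancy_count = 25),
                                   n_taxa_total = 20), "exceeds")
  # explicit integer override
  loci2 <- call_conserved_loci(covs[1:10], ref,
                               discovery_params(occupancy_count = 11,
                                                min_locus_length = 100),
                               n_taxa_total = 11)
  expect_equal(attr(loci2, "occupancy_threshold"), 11)
})

test_that("length, repeat and merge filters shape the called loci", {
  set.seed(13)
  s <- rnd_dna(2000)
  mask <- rep(FALSE, 2000)
  mask[1001:1300] <- TRUE  # a masked tract inside the second region
  ref <- assembly(c(c1 = s), taxon = "r", mask = list(c1 = mask))
  covs <- rep(list(list(c1 = data.frame(start = c(100, 950, 1700),
                                        end = c(300, 1450, 1790)))), 3)
  loci <- call_conserved_loci(covs, ref, discovery_params(occupancy_fraction = 1),
                              n_taxa_total = 4)
  # region 2 is 60% repeat-masked -> dropped; region 3 is 90 bp -> dropped
  expect_equal(nrow(loci), 1)
  expect_equal(loci$start, 100)
  expect_equal(loci$end, 300)
  # nearby candidates merge across a sub-threshold gap
  covs2 <- rep(list(list(c1 = data.frame(start = c(100, 320),
                                         end = c(250, 500)))), 3)
  loci2 <- call_conserved_loci(covs2, ref,
                               discovery_params(occupancy_fraction = 1),
                               n_taxa_total = 4)
  expect_equal(loci2$start, 100)
  expect_equal(loci2$end, 500)
})

test_that("raising the occupancy fraction never adds loci", {
  p <- small_panel()
  ref <- p$assemblies[[1]]
  covs <- lapply(p$assemblies[-1], function(a)
    map_taxon_to_reference(simulate_reads(a), ref, 0.05))
  n_prev <- Inf
  for (f in c(0.6, 0.75, 0.9, 1.0)) {
    loci <- call_conserved_loci(covs, ref,
                                discovery_params(occupancy_fraction = f),
                                n_taxa_total = 8)
    expect_lte(nrow(loci), n_prev)
    n_prev <- nrow(loci)
    # every emitted locus satisfies every filter
    expect_true(all(loci$end - loci$start >= 160))
    rf <- vapply(seq_len(nrow(loci)), function(i)
      repeat_fraction(ref$mask[[loci$contig[i]]][(loci$start[i] + 1):loci$end[i]]),
      numeric(1))
    expect_true(all(rf <= 0.25))
  }
})

test_that("discovery recovers planted loci on the small panel", {
  p <- small_panel()
  loci <- discover_loci(p$assemblies[[1]], p$assemblies[-1])
  st <- recovery_stats(loci, p$truth[p$truth$taxon == "t01", ])
  expect_gte(st$recovery, 0.95)
  expect_equal(st$n_false, 0)
})
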