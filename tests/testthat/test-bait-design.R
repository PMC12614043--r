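test_that("bait tiling geometry centres both baits on the locus midpoint", {
  set.seed(31)
  locus <- rnd_dna(400)
  pr <- design_probes_for_locus(locus, rep(FALSE, 400), "L1", "ref")
  # stride = 120 / 3 = 40; starts = 200 - 120 + 20, + 40
  expect_equal(pr$offset, c(100, 140))
  expect_true(all(pr$offset < 200 & pr$offset + 120 > 200))
  expect_equal(unique(nchar(pr$sequence)), 120)
  expect_equal(pr$sequence[1], substr(locus, 101, 220))
})

test_that("bait starts clamp at locus bounds and collapse when equal", {
  set.seed(32)
  locus <- rnd_dna(120)
  pr <- design_probes_for_locus(locus, rep(FALSE, 120), "L1", "ref")
  expect_equal(pr$offset, 0)
  expect_equal(nrow(pr), 1)
  expect_warning(
    short <- design_probes_for_locus(rnd_dna(100), rep(FALSE, 100), "L2", "ref"),
    "shorter than the probe length")
  expect_equal(nrow(short), 0)
})

test_that("repeat filter applies a strict > 25% rule and GC bounds are inclusive", {
  set.seed(33)
  locus <- rnd_dna(120)
  m30 <- c(rep(TRUE, 30), rep(FALSE, 90))    # exactly 25%
  m31 <- c(rep(TRUE, 31), rep(FALSE, 89))    # 25.8%
  expect_equal(nrow(design_probes_for_locus(locus, m30, "L", "r",
                                            design_params(probes_per_locus = 1))), 1)
  expect_equal(nrow(design_probes_for_locus(locus, m31, "L", "r",
                                            design_params(probes_per_locus = 1))), 0)
  gc_seq <- function(ngc) paste0(strrep("G", ngc), strrep("A", 120 - ngc))
  one <- design_params(probes_per_locus = 1)
  expect_equal(nrow(design_probes_for_locus(gc_seq(36), rep(FALSE, 120),
                                            "L", "r", one)), 1)  # GC = 0.30
  expect_equal(nrow(design_probes_for_locus(gc_seq(35), rep(FALSE, 120),
                                            "L", "r", one)), 0)  # GC = 0.29
  expect_equal(nrow(design_probes_for_locus(gc_seq(84), rep(FALSE, 120),
                                            "L", "r", one)), 1)  # GC = 0.70
  expect_equal(nrow(design_probes_for_locus(gc_seq(85), rep(FALSE, 120),
                                            "L", "r", one)), 0)  # GC = 0.71
})

test_that("temporary set designs two baits per locus then deduplicates", {
  set.seed(34)
  spacer <- function() rnd_dna(300)
  cores <- vapply(rep(400, 10), rnd_dna, character(1))
  genome <- paste0(spacer(), paste(vapply(cores, function(x)
    paste0(x, spacer()), character(1)), collapse = ""))
  ref <- toy_assembly(c(chr = genome), taxon = "ref")
  starts <- 300 + (0:9) * 700
  loci <- data.frame(locus_id = sprintf("uce-%d", 1:10), contig = "chr",
                     start = starts, end = starts + 400,
                     occupancy_count = 10L)
  tset <- build_temporary_set(loci, ref)
  expect_equal(unname(attr(tset, "counts")["probes_designed"]), 20)
  expect_true(all(tset$gc >= 0.3 & tset$gc <= 0.7))
  expect_true(all(tset$repeat_frac <= 0.25))
  # the two same-locus baits overlap by 2/3 and are similar: one survives
  expect_setequal(unique(tset$locus_id), loci$locus_id)
  # duplicated locus sequence: its probes collapse across loci
  genome2 <- paste0(spacer(), cores[1], spacer(), cores[1], spacer())
  ref2 <- toy_assembly(c(chr = genome2), taxon = "ref")
  loci2 <- data.frame(locus_id = c("uce-1", "uce-2"), contig = "chr",
                      start = c(300, 1000), end = c(700, 1400),
                      occupancy_count = 2L)
  tset2 <- build_temporary_set(loci2, ref2)
  expect_equal(nrow(tset2), 1)
})

test_that("final-locus selection applies the species threshold monotonically", {
  d <- small_design()
  p <- small_panel()
  pres <- attr(d$final_loci, "presence")
  nsp <- rowSums(pres)
  expect_true(all(nsp[d$final_loci] >= 6))
  n_prev <- -Inf
  for (thr in c(8, 6, 4, 2)) {
    keep <- select_final_loci(d$temporary, p$assemblies,
                              design_params(min_species_for_final = thr))
    expect_gte(length(keep), n_prev)
    n_prev <- length(keep)
  }
  # loci planted everywhere are present everywhere at the match thresholds
  expect_true(all(rowSums(pres) == ncol(pres)))
})

test_that("single-assembly master design degenerates to the temporary set", {
  p <- small_panel()
  ref <- p$assemblies[[1]]
  d <- small_design()
  m1 <- build_master_set(d$final_loci, d$loci, ref, list(ref))
  expect_setequal(m1$sequence, d$temporary$sequence[
    d$temporary$locus_id %in% d$final_loci])
})

test_that("unalignably divergent sources keep per-locus representatives", {
  set.seed(36)
  # same locus id, but sequences unrelated (divergence far beyond recognition)
  recs <- do.call(rbind, lapply(1:3, function(t)
    design_probes_for_locus(rnd_dna(400), rep(FALSE, 400), "uce-1",
                            sprintf("t%02d", t))))
  recs$probe_id <- make.unique(recs$probe_id)
  kept <- dedupe_by_similarity(recs)
  expect_equal(nrow(kept), 3)  # one per source; within-source pairs collapse
})

test_that("taxon subsetting keeps exactly the requested provenance", {
  d <- small_design()
  m <- d$master
  all_taxa <- unique(m$source_taxon)
  expect_equal(as.data.frame(subset_by_taxa(m, all_taxa)), as.data.frame(m))
  one <- subset_by_taxa(m, all_taxa[1])
  expect_true(all(one$source_taxon == all_taxa[1]))
  expect_true(all(attr(one, "target_loci") %in% attr(m, "target_loci")))
  expect_error(subset_by_taxa(m, "nosuch"), "unknown taxa")
})

test_that("probe-set merging screens cross-set redundancy", {
  d <- small_design()
  m <- d$master
  # self-merge is the identity (sequence content unchanged)
  mm <- merge_probe_sets(m, m)
  expect_setequal(mm$sequence, m$sequence)
  # disjoint, dissimilar sets concatenate
  set.seed(37)
  other <- probe_set(data.frame(
    probe_id = sprintf("x%d", 1:5), locus_id = sprintf("xl%d", 1:5),
    source_taxon = "ext", offset = 0L,
    sequence = vapply(rep(120, 5), rnd_dna, character(1)),
    gc = 0.5, repeat_frac = 0))
  mo <- merge_probe_sets(m, other)
  expect_equal(nrow(mo), nrow(m) + 5)
  # planted cross-set duplicates shrink the union
  dup <- probe_set(data.frame(
    probe_id = sprintf("d%d", 1:3), locus_id = sprintf("dl%d", 1:3),
    source_taxon = "ext", offset = 0L,
    sequence = m$sequence[1:3], gc = m$gc[1:3], repeat_frac = 0))
  md <- merge_probe_sets(m, dup)
  expect_equal(nrow(md), nrow(m))
  expect_lt(nrow(md), nrow(m) + nrow(dup))
})

test_that("every emitted probe in every set passes the filter audit", {
  d <- small_design()
  for (s in list(d$temporary, d$master)) {
    expect_true(all(nchar(s$sequence) == 120))
    expect_true(all(s$gc >= 0.30 & s$gc <= 0.70))
    expect_true(all(s$repeat_frac <= 0.25))
    expect_false(any(duplicated(s$probe_id)))
  }
})

test_that("probe FASTA round trip preserves records", {
  d <- small_design()
  f <- withr::local_tempfile(fileext = ".fasta")
  write_probe_fasta(d$master, f)
  back <- read_probe_fasta(f)
  expect_equal(back$probe_id, d$master$probe_id)
  expect_equal(back$sequence, d$master$sequence)
  expect_equal(back$gc, d$master$gc)
})
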