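test_that("self-capture at flank 0 recovers every designable locus exactly", {
  d <- small_design()
  p <- small_panel()
  cap <- capture_taxon(d$master, p$assemblies[[1]],
                       capture_params(match_identity = 0.75, flank = 0))
  expect_setequal(cap$captured$locus_id, attr(d$master, "target_loci"))
  expect_equal(nrow(cap$conflicts), 0)
  # extracted sequences contain their probes verbatim for the source taxon
  ref_probes <- d$master[d$master$source_taxon == "t01", ]
  for (i in seq_len(min(5, nrow(ref_probes)))) {
    lid <- ref_probes$locus_id[i]
    sl <- cap$captured$sequence[cap$captured$locus_id == lid]
    expect_true(grepl(ref_probes$sequence[i], sl, fixed = TRUE))
  }
})

test_that("flank extraction adds exactly 2 x flank for interior loci and clips at ends", {
  set.seed(41)
  probe <- rnd_dna(120)
  # interior locus and one 30 bp from the contig start
  contig1 <- paste0(rnd_dna(500), probe, rnd_dna(500))
  contig2 <- paste0(rnd_dna(30), probe, rnd_dna(500))
  a <- toy_assembly(c(c1 = contig1, c2 = contig2))
  ps <- probe_set(data.frame(probe_id = "p1", locus_id = "L1",
                             source_taxon = "t", offset = 0L,
                             sequence = probe, gc = gc_fraction(probe),
                             repeat_frac = 0))
  cap0 <- capture_taxon(ps, a, capture_params(flank = 0))
  cap100 <- capture_taxon(ps, a, capture_params(flank = 100))
  len0 <- nchar(cap0$captured$sequence[cap0$captured$contig == "c1"])
  len100 <- nchar(cap100$captured$sequence[cap100$captured$contig == "c1"])
  expect_equal(len100, len0 + 200)
  # clipped contig: left flank truncated to the 30 bp available
  lenc <- nchar(cap100$captured$sequence[cap100$captured$contig == "c2"])
  expect_equal(lenc, len0 + 130)
})

test_that("conflict resolution removes multi-locus slices and multi-slice loci", {
  # one slice <-> one locus: kept
  t1 <- data.frame(slice_id = "s1", slice_locus = "A", probe_locus = "A")
  r1 <- resolve_conflicts(t1)
  expect_equal(r1$kept_loci, "A")
  # a slice matching probes of two loci is removed
  t2 <- data.frame(slice_id = c("s1", "s1"), slice_locus = "A",
                   probe_locus = c("A", "B"))
  r2 <- resolve_conflicts(t2)
  expect_equal(length(r2$kept_slices), 0)
  expect_true("multi-probe-sequence" %in% r2$conflicts$reason)
  # two slices matching one locus's probes remove the locus
  t3 <- data.frame(slice_id = c("s1", "s2"), slice_locus = c("A", "A"),
                   probe_locus = c("A", "A"))
  r3 <- resolve_conflicts(t3)
  expect_equal(length(r3$kept_loci), 0)
  expect_true("multi-sequence-probe" %in% r3$conflicts$reason)
  # matches within one locus's own probe cohort are not conflicts
  t4 <- data.frame(slice_id = c("s1", "s1"), slice_locus = c("A", "A"),
                   probe_locus = c("A", "A"))
  expect_equal(resolve_conflicts(t4)$kept_loci, "A")
})

test_that("a tandem-duplicated locus is removed for that taxon", {
  set.seed(42)
  locus <- rnd_dna(400)
  probe <- substr(locus, 141, 260)
  genome <- paste0(rnd_dna(400), locus, rnd_dna(400), locus, rnd_dna(400))
  a <- toy_assembly(c(c1 = genome))
  ps <- probe_set(data.frame(probe_id = "p1", locus_id = "L1",
                             source_taxon = "t", offset = 140L,
                             sequence = probe, gc = gc_fraction(probe),
                             repeat_frac = 0))
  cap <- capture_taxon(ps, a, capture_params(flank = 0))
  expect_equal(nrow(cap$captured), 0)
  expect_true("multi-sequence-probe" %in% cap$conflicts$reason)
})

test_that("efficiency follows the captured / targeted convention", {
  counts <- c(sp1 = 2515, sp2 = 3271, bad = 438)
  fake <- structure(list(), target_loci = sprintf("u%d", 1:3271),
                    class = c("probe_set", "data.frame"))
  eff <- efficiency(counts, fake, exclude = "bad")
  expect_equal(round(eff$per_taxon[["sp1"]], 3), 0.769)
  expect_equal(eff$per_taxon[["sp2"]], 1)
  expect_equal(eff$mean, mean(c(2515 / 3271, 1)))
  expect_equal(eff$excluded, "bad")
  expect_error(efficiency(counts, probe_set(data.frame(
    probe_id = character(), locus_id = character(), source_taxon = character(),
    offset = integer(), sequence = character(), gc = numeric(),
    repeat_frac = numeric()))), "zero target loci")
})

test_that("occupancy filtering and the shared-locus matrix match a naive recount", {
  set.seed(43)
  occ <- matrix(runif(300) < 0.6, 50, 6,
                dimnames = list(sprintf("L%02d", 1:50), sprintf("t%d", 1:6)))
  res <- occupancy_and_shared(occ, min_taxa_per_locus = 3,
                              occupancy_fractions = c(0.5, 0.75))
  kept <- occ[rowSums(occ) >= 3, ]
  expect_equal(rownames(res$occupancy), rownames(kept))
  # brute-force double loop
  S <- matrix(0L, 6, 6, dimnames = list(colnames(occ), colnames(occ)))
  for (i in 1:6) for (j in 1:6)
    S[i, j] <- sum(kept[, i] & kept[, j])
  expect_equal(unname(res$shared), unname(S))
  expect_true(isSymmetric(res$shared))
  expect_equal(diag(res$shared), colSums(kept))
  expect_setequal(res$sublists$occ_gt_50, rownames(kept)[rowSums(kept) > 3])
  # loci below the taxon floor are gone
  expect_true(all(rowSums(res$occupancy) >= 3))
})

test_that("capture is monotone in match identity and flank changes lengths only", {
  d <- small_design()
  p <- small_panel()
  a <- p$assemblies[[4]]
  # pre-conflict captured-locus counts as identity loosens
  n_prev <- -Inf
  for (ident in c(0.95, 0.85, 0.75, 0.6, 0.5)) {
    hits <- local_match(d$master$sequence, a, ident, 0.83, small_cutoff = 0)
    n <- length(unique(d$master$locus_id[hits$query]))
    expect_gte(n, n_prev)
    n_prev <- n
  }
  # flank sweep: membership fixed, interior lengths shift by 2 x delta
  caps <- lapply(c(0, 100, 200), function(f)
    capture_taxon(d$master, a, capture_params(match_identity = 0.75, flank = f)))
  ids <- lapply(caps, function(cp) sort(cp$captured$locus_id))
  expect_equal(ids[[1]], ids[[2]])
  expect_equal(ids[[2]], ids[[3]])
  for (k in 2:3) {
    m <- merge(caps[[1]]$captured[, c("locus_id", "sequence")],
               caps[[k]]$captured[, c("locus_id", "sequence")], by = "locus_id")
    delta <- nchar(m$sequence.y) - nchar(m$sequence.x)
    expect_true(all(delta == 2 * c(0, 100, 200)[k]))
  }
})

test_that("transcriptome-view captures are contained in genome captures", {
  d <- small_design()
  p <- small_panel()
  for (tx in c("t02", "t05")) {
    tv <- make_transcriptome_view(p, tx, seed = 17)
    gi <- match(tx, vapply(p$assemblies, `[[`, character(1), "taxon"))
    cg <- capture_taxon(d$master, p$assemblies[[gi]],
                        capture_params(match_identity = 0.75, flank = 0))
    ct <- capture_taxon(d$master, tv$assembly,
                        capture_params(match_identity = 0.75, flank = 0))
    expect_true(all(ct$captured$locus_id %in% cg$captured$locus_id))
  }
})
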