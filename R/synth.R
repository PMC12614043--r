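#' Evolve a sequence by independent per-site substitution
#'
#' Each position is substituted with the given probability to a uniformly
#' chosen different base.  N positions are left untouched.  Deterministic for
#' a given seed.
#'
#' @param x sequence (uppercase A/C/G/T/N).
#' @param p substitution probability per site, in `[0, 1)`.
#' @param seed integer seed.
#' @return the derived sequence (same length).
#' @export
evolve_sequence <- function(x, p, seed) {
  stopifnot(p >= 0, p < 1)
  if (p == 0) return(x)
  withr::with_seed(seed, {
    ch <- strsplit(x, "", fixed = TRUE)[[1]]
    hit <- runif(length(ch)) < p & ch != "N"
    idx <- which(hit)
    if (length(idx)) {
      alts <- matrix(c("C", "G", "T",  # A ->
                       "A", "G", "T",  # C ->
                       "A", "C", "T",  # G ->
                       "A", "C", "G"), # T ->
                     nrow = 4, byrow = TRUE,
                     dimnames = list(c("A", "C", "G", "T"), NULL))
      pick <- sample.int(3L, length(idx), replace = TRUE)
      ch[idx] <- alts[cbind(match(ch[idx], rownames(alts)), pick)]
    }
    paste(ch, collapse = "")
  })
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

#' Parameters for the synthetic multi-taxon panel
#'
#' The defaults emulate the study conditions used throughout the test suite:
#' 20 taxa (taxon 1 is the undiverged reference), 200 planted conserved
#' cores of 300-600 bp evolved at 1-3% per-taxon divergence, background
#' spacers at 15% divergence, and soft-masked tandem-repeat tracts seeded
#' into a fraction of the spacers.
#'
#' @param n_taxa number of taxa (taxon 1 is the reference, divergence 0).
#' @param n_loci number of planted conserved cores.
#' @param core_length length range (bp) of the cores, drawn uniformly.
#' @param core_divergence per-taxon substitution probability range for cores.
#' @param background_divergence substitution probability for spacers.
#' @param spacer_length spacer length range between cores, bp.
#' @param repeat_density fraction of spacers receiving a soft-masked tandem
#'   repeat tract.
#' @param repeat_length length range of a repeat tract, bp.
#' @param dropout fraction of (taxon, locus) pairs where the core is replaced
#'   by random sequence (locus absent from that taxon).
#' @param expressed_fraction fraction of loci exported by
#'   [make_transcriptome_view()].
#' @param transcript_flank native flank retained around an exported core, bp.
#' @return a `panel_params` list.
#' @export
panel_params <- function(n_taxa = 20L, n_loci = 200L,
                         core_length = c(300L, 600L),
                         core_divergence = c(0.01, 0.03),
                         background_divergence = 0.15,
                         spacer_length = c(400L, 800L),
                         repeat_density = 0.2,
                         repeat_length = c(60L, 200L),
                         dropout = 0,
                         expressed_fraction = 0.7,
                         transcript_flank = 80L) {
  stopifnot(n_taxa >= 2, n_loci >= 1,
            core_divergence[2] < 1, background_divergence < 1,
            dropout >= 0, dropout < 1,
            expressed_fraction > 0, expressed_fraction <= 1)
  structure(list(n_taxa = as.integer(n_taxa), n_loci = as.integer(n_loci),
                 core_length = as.integer(core_length),
                 core_divergence = core_divergence,
                 background_divergence = background_divergence,
                 spacer_length = as.integer(spacer_length),
                 repeat_density = repeat_density,
                 repeat_length = as.integer(repeat_length),
                 dropout = dropout,
                 expressed_fraction = expressed_fraction,
                 transcript_flank = as.integer(transcript_flank)),
            class = "panel_params")
}

#' Generate a synthetic multi-taxon panel with planted conserved cores
#'
#' Builds one ancestral chromosome of alternating spacers and conserved
#' cores, then derives each taxon by substitution-only evolution: cores at a
#' low per-taxon divergence, background (spacers, including repeat tracts) at
#' a high divergence.  Taxon 1 is emitted unevolved as the reference.
#' Because evolution is substitution-only, planted-core coordinates are
#' identical across taxa and the truth table is exact.
#'
#' @param params a [panel_params()].
#' @param seed integer master seed; the run is byte-identical per
#'   (seed, params).
#' @return list with `assemblies` (list of [assembly], first = reference),
#'   `truth` (data.frame: `taxon`, `locus_id`, `contig`, `start`, `end`,
#'   `present`, `core_divergence`), and `params`/`seed` echoed.
#' @export
generate_panel <- function(params = panel_params(), seed = 1L) {
  stopifnot(inherits(params, "panel_params"))
  if (params$core_length[1] < 1) stop("core length must be positive")
  built <- withr::with_seed(seed, {
    n <- params$n_loci
    core_len <- sample(params$core_length[1]:params$core_length[2], n,
                       replace = TRUE)
    spacer_len <- sample(params$spacer_length[1]:params$spacer_length[2],
                         n + 1L, replace = TRUE)
    pieces <- character(0); mask <- logical(0)
    starts <- ends <- integer(n)
    pos <- 0L
    add_spacer <- function(len) {
      sp <- random_dna(len); m <- rep(FALSE, len)
      if (runif(1) < params$repeat_density && len > params$repeat_length[2] + 2) {
        rl <- sample(params$repeat_length[1]:params$repeat_length[2], 1)
        unit <- random_dna(sample(4:10, 1))
        tract <- substr(strrep(unit, ceiling(rl / nchar(unit))), 1, rl)
        at <- sample.int(len - rl, 1)
        substr(sp, at + 1, at + rl) <- tract
        m[(at + 1):(at + rl)] <- TRUE
      }
      list(seq = sp, mask = m)
    }
    for (i in seq_len(n)) {
      sp <- add_spacer(spacer_len[i])
      pieces <- c(pieces, sp$seq); mask <- c(mask, sp$mask)
      pos <- pos + spacer_len[i]
      starts[i] <- pos
      pieces <- c(pieces, random_dna(core_len[i]))
      mask <- c(mask, rep(FALSE, core_len[i]))
      pos <- pos + core_len[i]
      ends[i] <- pos
    }
    sp <- add_spacer(spacer_len[n + 1L])
    pieces <- c(pieces, sp$seq); mask <- c(mask, sp$mask)
    ancestor <- paste(pieces, collapse = "")

    taxa <- sprintf("t%02d", seq_len(params$n_taxa))
    core_div <- c(0, runif(params$n_taxa - 1L, params$core_divergence[1],
                           params$core_divergence[2]))
    dropped <- matrix(FALSE, n, params$n_taxa)
    if (params$dropout > 0)
      dropped[, -1] <- matrix(runif(n * (params$n_taxa - 1L)) < params$dropout,
                              n, params$n_taxa - 1L)
    taxon_seeds <- sample.int(2^30, params$n_taxa * 2L)
    drop_seq <- vapply(core_len, random_dna, character(1))
    list(ancestor = ancestor, mask = mask, starts = starts, ends = ends,
         taxa = taxa, core_div = core_div, dropped = dropped,
         taxon_seeds = taxon_seeds, drop_seq = drop_seq)
  })

  n <- params$n_loci
  locus_ids <- sprintf("locus%03d", seq_len(n))
  in_core <- logical(nchar(built$ancestor))
  for (i in seq_len(n)) in_core[(built$starts[i] + 1L):built$ends[i]] <- TRUE

  assemblies <- vector("list", params$n_taxa)
  truth <- NULL
  for (t in seq_len(params$n_taxa)) {
    tx <- built$taxa[t]
    if (t == 1L) {
      g <- built$ancestor
    } else {
      # evolve background and cores at their own rates, then splice
      bg <- evolve_sequence(built$ancestor, params$background_divergence,
                            built$taxon_seeds[2 * t - 1L])
      cr <- evolve_sequence(built$ancestor, built$core_div[t],
                            built$taxon_seeds[2 * t])
      ch <- strsplit(bg, "", fixed = TRUE)[[1]]
      chc <- strsplit(cr, "", fixed = TRUE)[[1]]
      ch[in_core] <- chc[in_core]
      g <- paste(ch, collapse = "")
    }
    for (i in seq_len(n)) {
      if (built$dropped[i, t]) {
        substr(g, built$starts[i] + 1L, built$ends[i]) <- built$drop_seq[i]
      }
    }
    assemblies[[t]] <- assembly(setNames(g, "chr1"), taxon = tx,
                                datatype = "genome",
                                mask = list(chr1 = built$mask))
    truth <- rbind(truth,
                   data.frame(taxon = tx, locus_id = locus_ids,
                              contig = "chr1", start = built$starts,
                              end = built$ends,
                              present = !built$dropped[, t],
                              core_divergence = built$core_div[t]))
  }
  list(assemblies = assemblies, truth = truth, params = params, seed = seed)
}

#' Export a transcriptome-like view of one taxon
#'
#' A random fraction of that taxon's planted loci are exported as contigs:
#' the core plus a short native flank, cut from the taxon's own genome.  By
#' construction every transcript contig is an exact substring of the genome.
#'
#' @param panel result of [generate_panel()].
#' @param taxon taxon name.
#' @param expressed_fraction fraction of present loci exported (defaults to
#'   the panel's parameter).
#' @param flank native flank retained around the core, bp.
#' @param seed integer seed for the expression draw.
#' @return list with `assembly` (datatype `"transcriptome"`) and `expressed`
#'   (data.frame: `locus_id`, `expressed`).
#' @export
make_transcriptome_view <- function(panel, taxon,
                                    expressed_fraction = NULL,
                                    flank = NULL, seed = 1L) {
  p <- panel$params
  if (is.null(expressed_fraction)) expressed_fraction <- p$expressed_fraction
  if (is.null(flank)) flank <- p$transcript_flank
  tx <- vapply(panel$assemblies, `[[`, character(1), "taxon")
  g <- panel$assemblies[[match(taxon, tx)]]
  tr <- panel$truth[panel$truth$taxon == taxon & panel$truth$present, ,
                    drop = FALSE]
  expressed <- withr::with_seed(seed, runif(nrow(tr)) < expressed_fraction)
  tr <- tr[expressed, , drop = FALSE]
  if (nrow(tr) == 0) stop("no loci expressed; raise expressed_fraction")
  contigs <- character(nrow(tr)); masks <- vector("list", nrow(tr))
  for (i in seq_len(nrow(tr))) {
    len <- nchar(g$contigs[[tr$contig[i]]])
    s <- max(0L, tr$start[i] - flank); e <- min(len, tr$end[i] + flank)
    contigs[i] <- slice_seq(g$contigs[[tr$contig[i]]], s, e)
    masks[[i]] <- g$mask[[tr$contig[i]]][(s + 1L):e]
  }
  names(contigs) <- tr$locus_id
  names(masks) <- tr$locus_id
  list(assembly = assembly(contigs, taxon = paste0(taxon, "_tr"),
                           datatype = "transcriptome", mask = masks),
       expressed = data.frame(locus_id = panel$truth$locus_id[
                                panel$truth$taxon == taxon & panel$truth$present],
                              expressed = expressed))
}
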