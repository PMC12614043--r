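#' Parameters for in-silico capture
#'
#' Defaults follow the evaluation protocol: probes matched to assemblies at
#' 50% identity (75% is the convention for genome-derived probes against
#' genomes), matched spans sliced out with a chosen flank, slices re-matched
#' to probes at coverage 67% / identity 80%, multi-locus and multi-slice
#' conflicts removed, and loci present in fewer than 3 taxa dropped from
#' matrices.
#'
#' @param match_identity probe-to-assembly identity threshold.
#' @param match_coverage probe-to-assembly coverage threshold (the design
#'   validation default, 0.83).
#' @param flank flank length in bp added on both sides of a matched span
#'   (clipped at contig ends).
#' @param rematch_min_coverage,rematch_min_identity slice-to-probe re-match
#'   thresholds.
#' @param min_taxa_per_locus loci in fewer taxa are removed from matrices.
#' @return a `capture_params` list.
#' @export
capture_params <- function(match_identity = 0.50, match_coverage = 0.83,
                           flank = 0L, rematch_min_coverage = 0.67,
                           rematch_min_identity = 0.80,
                           min_taxa_per_locus = 3L) {
  stopifnot(match_identity >= 0, match_identity <= 1, flank >= 0)
  structure(list(match_identity = match_identity,
                 match_coverage = match_coverage,
                 flank = as.integer(flank),
                 rematch_min_coverage = rematch_min_coverage,
                 rematch_min_identity = rematch_min_identity,
                 min_taxa_per_locus = as.integer(min_taxa_per_locus)),
            class = "capture_params")
}

#' Capture loci from one assembly with a probe set
#'
#' Probes are matched to the assembly; hits are grouped per locus and
#' overlapping target spans collapsed to maximal intervals; each interval is
#' sliced out with the flank (clipped at contig ends) and reverse-complemented
#' for minus-strand hits so slices are probe-oriented; slices are re-matched
#' against the full probe set and conflicts resolved (see
#' [resolve_conflicts()]).
#'
#' @param probes a `probe_set`.
#' @param x an [assembly].
#' @param params a [capture_params()].
#' @return list with `captured` (data.frame: `locus_id`, `contig`, `start`,
#'   `end`, `strand`, `sequence` -- coordinates are the matched span without
#'   flanks), and `conflicts` (data.frame of removals with reason codes
#'   `multi-probe-sequence` / `multi-sequence-probe` / `no-rematch`).
#' @export
capture_taxon <- function(probes, x, params = capture_params()) {
  stopifnot(inherits(x, "assembly"))
  if (!nrow(probes)) stop("empty probe set")
  hits <- local_match(probes$sequence, x,
                      min_identity = params$match_identity,
                      min_query_coverage = params$match_coverage,
                      small_cutoff = 0L)
  no_capture <- list(
    captured = data.frame(locus_id = character(), contig = character(),
                          start = integer(), end = integer(),
                          strand = character(), sequence = character()),
    conflicts = data.frame(locus_id = character(), reason = character()))
  if (nrow(hits) == 0) return(no_capture)
  hits$locus_id <- probes$locus_id[hits$query]

  # Collapse per-locus overlapping spans to maximal intervals.
  spans <- NULL
  for (lid in unique(hits$locus_id)) {
    h <- hits[hits$locus_id == lid, , drop = FALSE]
    for (cid in unique(h$contig)) {
      hc <- h[h$contig == cid, , drop = FALSE]
      iv <- merge_adjacent(merge_intervals(
        data.frame(start = hc$tstart, end = hc$tend), max_gap = 0L))
      # orient each merged span by its best-scoring constituent hit
      iv$strand <- vapply(seq_len(nrow(iv)), function(i) {
        inside <- hc$tstart < iv$end[i] & hc$tend > iv$start[i]
        hc$strand[inside][which.max(hc$score[inside])]
      }, character(1))
      iv$locus_id <- lid; iv$contig <- cid
      spans <- rbind(spans, iv)
    }
  }

  # Slice with flanks, clipped at contig bounds; probe-oriented output.
  spans$slice_id <- sprintf("slice%d", seq_len(nrow(spans)))
  slices <- vapply(seq_len(nrow(spans)), function(i) {
    len <- nchar(x$contigs[[spans$contig[i]]])
    s <- max(0L, spans$start[i] - params$flank)
    e <- min(len, spans$end[i] + params$flank)
    sq <- slice_seq(x$contigs[[spans$contig[i]]], s, e)
    if (spans$strand[i] == "-") sq <- revcomp(sq)
    sq
  }, character(1))
  names(slices) <- spans$slice_id

  # Re-match every probe against the slices.
  rematch <- local_match(probes$sequence, slices,
                         min_identity = params$rematch_min_identity,
                         min_query_coverage = params$rematch_min_coverage,
                         small_cutoff = 0L)
  tab <- data.frame(slice_id = rematch$contig,
                    slice_locus = spans$locus_id[match(rematch$contig,
                                                       spans$slice_id)],
                    probe_locus = probes$locus_id[rematch$query])
  res <- resolve_conflicts(tab)
  keep <- spans$slice_id %in% res$kept_slices &
    spans$locus_id %in% res$kept_loci
  conflicts <- res$conflicts
  # slices that re-matched no probe at all fail validation
  unvalidated <- unique(spans$locus_id[!spans$slice_id %in% tab$slice_id])
  unvalidated <- setdiff(unvalidated, c(conflicts$locus_id, spans$locus_id[keep]))
  if (length(unvalidated))
    conflicts <- rbind(conflicts,
                       data.frame(locus_id = unvalidated, reason = "no-rematch"))
  out <- spans[keep, , drop = FALSE]
  out$sequence <- unname(slices[out$slice_id])
  rownames(out) <- NULL
  list(captured = out[, c("locus_id", "contig", "start", "end", "strand",
                          "sequence")],
       conflicts = conflicts)
}

#' Resolve slice/probe capture conflicts
#'
#' Removes (a) any slice whose re-matches span probes of more than one
#' distinct locus (`multi-probe-sequence`), and (b) any locus whose probes
#' are re-matched by more than one distinct slice in the same assembly
#' (`multi-sequence-probe`).  Matches within one locus's own probe cohort do
#' not count as conflicts.
#'
#' @param tab data.frame with columns `slice_id`, `slice_locus`,
#'   `probe_locus`: one row per (slice, probe) re-match.
#' @return list with `kept_slices`, `kept_loci`, `conflicts` (data.frame of
#'   removed locus ids and reasons).
#' @export
resolve_conflicts <- function(tab) {
  if (nrow(tab) == 0)
    return(list(kept_slices = character(), kept_loci = character(),
                conflicts = data.frame(locus_id = character(),
                                       reason = character())))
  loci_per_slice <- tapply(tab$probe_locus, tab$slice_id,
                           function(z) length(unique(z)))
  bad_slices <- names(loci_per_slice)[loci_per_slice > 1]
  tab2 <- tab[!tab$slice_id %in% bad_slices, , drop = FALSE]
  slices_per_locus <- tapply(tab2$slice_id, tab2$probe_locus,
                             function(z) length(unique(z)))
  bad_loci <- names(slices_per_locus)[slices_per_locus > 1]
  kept_slices <- setdiff(unique(tab2$slice_id), bad_slices)
  kept_loci <- setdiff(unique(tab2$probe_locus), bad_loci)
  conflicts <- rbind(
    if (length(bad_slices))
      data.frame(locus_id = unique(tab$slice_locus[tab$slice_id %in% bad_slices]),
                 reason = "multi-probe-sequence") else NULL,
    if (length(bad_loci))
      data.frame(locus_id = bad_loci, reason = "multi-sequence-probe")
    else NULL)
  if (is.null(conflicts))
    conflicts <- data.frame(locus_id = character(), reason = character())
  list(kept_slices = kept_slices, kept_loci = kept_loci,
       conflicts = conflicts)
}

#' Capture a whole panel and build the occupancy structure
#'
#' @param probes a `probe_set`.
#' @param assemblies list of [assembly] objects.
#' @param params a [capture_params()].
#' @return a `capture_table`: list with `by_taxon` (per-taxon capture
#'   results), `occupancy` (logical loci x taxa matrix over all captured
#'   loci) and `counts` (per-taxon captured-locus counts).
#' @export
capture_panel <- function(probes, assemblies, params = capture_params()) {
  by_taxon <- lapply(assemblies, function(a) capture_taxon(probes, a, params))
  names(by_taxon) <- vapply(assemblies, `[[`, character(1), "taxon")
  loci <- sort(unique(unlist(lapply(by_taxon, function(r) r$captured$locus_id))))
  occ <- matrix(FALSE, length(loci), length(by_taxon),
                dimnames = list(loci, names(by_taxon)))
  for (tx in names(by_taxon))
    occ[by_taxon[[tx]]$captured$locus_id, tx] <- TRUE
  structure(list(by_taxon = by_taxon, occupancy = occ,
                 counts = colSums(occ)),
            class = "capture_table")
}

#' @export
print.capture_table <- function(x, ...) {
  cat(sprintf("<capture_table> %d loci x %d taxa; per-taxon counts %s\n",
              nrow(x$occupancy), ncol(x$occupancy),
              paste(range(x$counts), collapse = "-")))
  invisible(x)
}

#' Per-taxon and mean capture efficiency
#'
#' Efficiency is captured loci divided by the probe set's distinct target
#' locus count; the mean is taken over taxa not listed in `exclude`.
#'
#' @param capture a `capture_table` (or named numeric vector of per-taxon
#'   captured-locus counts).
#' @param probes the `probe_set` evaluated (declares its target locus count).
#' @param exclude taxa excluded from the mean (logged in the result).
#' @return list with `per_taxon` (named fractions), `mean`, `excluded`.
#' @export
efficiency <- function(capture, probes, exclude = character()) {
  n_target <- n_target_loci(probes)
  if (n_target == 0) stop("probe set declares zero target loci")
  counts <- if (inherits(capture, "capture_table")) capture$counts else capture
  per_taxon <- counts / n_target
  used <- setdiff(names(per_taxon), exclude)
  list(per_taxon = per_taxon, mean = mean(per_taxon[used]),
       excluded = intersect(exclude, names(per_taxon)))
}

#' Occupancy filtering and the shared-locus matrix
#'
#' Loci present in fewer than `min_taxa_per_locus` taxa are removed.  The
#' shared-locus matrix `S[i, j]` counts loci present in both taxa i and j
#' (diagonal = per-taxon counts).  For each fraction in
#' `occupancy_fractions`, the loci present in strictly more than that
#' fraction of taxa are listed for matrix export.
#'
#' @param capture a `capture_table` or logical loci x taxa matrix.
#' @param min_taxa_per_locus minimum taxa per locus.
#' @param occupancy_fractions fractions for sublist export (e.g. 0.5, 0.75).
#' @return list with `occupancy` (filtered matrix), `shared` (taxa x taxa
#'   integer matrix), `sublists` (named list of locus-id vectors).
#' @export
occupancy_and_shared <- function(capture, min_taxa_per_locus = 3L,
                                 occupancy_fractions = c(0.5, 0.75)) {
  occ <- if (inherits(capture, "capture_table")) capture$occupancy else capture
  if (ncol(occ) < 2) stop("need at least 2 taxa")
  occ <- occ[rowSums(occ) >= min_taxa_per_locus, , drop = FALSE]
  shared <- crossprod(occ * 1L)
  sublists <- lapply(occupancy_fractions, function(f) {
    rownames(occ)[rowSums(occ) > f * ncol(occ)]
  })
  names(sublists) <- sprintf("occ_gt_%d", round(100 * occupancy_fractions))
  list(occupancy = occ, shared = shared, sublists = sublists)
}

#' Write per-taxon captured loci as FASTA files
#'
#' One file per taxon; headers are `locus_id|taxon|contig:start-end:strand`.
#'
#' @param capture a `capture_table`.
#' @param dir output directory (created if needed).
#' @return the file paths, invisibly.
#' @export
write_capture_fastas <- function(capture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (tx in names(capture$by_taxon)) {
    cap <- capture$by_taxon[[tx]]$captured
    if (nrow(cap) == 0) next
    hdr <- sprintf("%s|%s|%s:%d-%d:%s", cap$locus_id, tx, cap$contig,
                   cap$start, cap$end, cap$strand)
    p <- file.path(dir, paste0(tx, ".fasta"))
    Biostrings::writeXStringSet(
      Biostrings::BStringSet(setNames(cap$sequence, hdr)), p, width = 80L)
    paths <- c(paths, p)
  }
  invisible(paths)
}
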