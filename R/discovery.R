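#' Parameters for conserved-locus discovery
#'
#' Defaults follow the genome-based design protocol: 100 bp error-free reads
#' tiled at a 50 bp stride (2x coverage), a 5% divergence ceiling for
#' mapping, 90% species occupancy (75% is the transcriptome convention),
#' candidate loci merged across gaps under 100 bp, and loci dropped when
#' shorter than 160 bp or more than 25% repeat-masked.
#'
#' @param read_length simulated read length, bp.
#' @param read_stride distance between successive read starts, bp.
#' @param max_divergence mapping divergence ceiling (identity floor is
#'   `1 - max_divergence`).
#' @param occupancy_fraction fraction of taxa that must support a position.
#' @param merge_gap merge candidate loci separated by gaps strictly below
#'   this, bp.
#' @param min_locus_length minimum locus length, bp.
#' @param max_repeat_fraction maximum repeat-masked fraction of a locus.
#' @param occupancy_count optional explicit integer occupancy threshold
#'   overriding `ceiling(occupancy_fraction * n_taxa)`.
#' @return a `discovery_params` list.
#' @export
discovery_params <- function(read_length = 100L, read_stride = 50L,
                             max_divergence = 0.05,
                             occupancy_fraction = 0.90,
                             merge_gap = 100L, min_locus_length = 160L,
                             max_repeat_fraction = 0.25,
                             occupancy_count = NULL) {
  stopifnot(max_divergence > 0, max_divergence < 1,
            occupancy_fraction > 0, occupancy_fraction <= 1,
            min_locus_length > 0, read_stride >= 1, merge_gap >= 0)
  structure(list(read_length = as.integer(read_length),
                 read_stride = as.integer(read_stride),
                 max_divergence = max_divergence,
                 occupancy_fraction = occupancy_fraction,
                 merge_gap = as.integer(merge_gap),
                 min_locus_length = as.integer(min_locus_length),
                 max_repeat_fraction = max_repeat_fraction,
                 occupancy_count = occupancy_count),
            class = "discovery_params")
}

#' Tile error-free reads from an assembly
#'
#' Reads of fixed length are taken from each contig starting at offset 0 and
#' stepping by `read_stride`; a final window shorter than `read_length` is
#' not emitted.  Read ids encode taxon, contig and offset.
#'
#' @param x an [assembly].
#' @param read_length read length, bp.
#' @param read_stride stride between read starts, bp.
#' @return data.frame with `read_id`, `taxon`, `contig`, `offset`, `sequence`.
#' @export
simulate_reads <- function(x, read_length = 100L, read_stride = 50L) {
  stopifnot(inherits(x, "assembly"), read_stride >= 1)
  out <- lapply(names(x$contigs), function(cid) {
    len <- nchar(x$contigs[[cid]])
    if (len < read_length)
      return(data.frame(read_id = character(), taxon = character(),
                        contig = character(), offset = integer(),
                        sequence = character()))
    offs <- seq.int(0L, len - read_length, by = read_stride)
    data.frame(read_id = sprintf("%s|%s|%d", x$taxon, cid, offs),
               taxon = x$taxon, contig = cid, offset = offs,
               sequence = substring(x$contigs[[cid]], offs + 1L,
                                    offs + read_length))
  })
  do.call(rbind, out)
}

#' Map one taxon's reads to the reference and return covered intervals
#'
#' A reference position counts as covered by the taxon when some read aligns
#' across it full-length (fitting alignment) at identity
#' `>= 1 - max_divergence`.  Reads with more than one qualifying reference
#' location are discarded as non-unique.
#'
#' @param reads data.frame from [simulate_reads()].
#' @param reference the reference [assembly].
#' @param max_divergence divergence ceiling.
#' @param seed_k seed length for mapping.
#' @return named list (per reference contig) of data.frames with `start`,
#'   `end` covered intervals (0-based half-open, merged).
#' @export
map_taxon_to_reference <- function(reads, reference, max_divergence = 0.05,
                                   seed_k = 12L) {
  empty <- setNames(
    rep(list(data.frame(start = integer(), end = integer())),
        length(reference$contigs)),
    names(reference$contigs))
  if (nrow(reads) == 0) return(empty)
  hits <- local_match(reads$sequence, reference,
                      min_identity = 1 - max_divergence,
                      min_query_coverage = 1, seed_k = seed_k,
                      mode = "glocal", small_cutoff = 0L)
  if (nrow(hits) == 0) return(empty)
  nhit <- tabulate(hits$query, nbins = nrow(reads))
  hits <- hits[nhit[hits$query] == 1L, , drop = FALSE]
  cov <- empty
  for (cid in unique(hits$contig)) {
    h <- hits[hits$contig == cid, c("tstart", "tend")]
    iv <- data.frame(start = h$tstart, end = h$tend)
    cov[[cid]] <- merge_adjacent(merge_intervals(iv, max_gap = 0L))
  }
  cov
}

# Union adjacent/overlapping covered intervals (gap <= 0) into runs.
merge_adjacent <- function(iv) {
  if (nrow(iv) < 2) return(iv)
  keep_s <- iv$start[1]; res <- NULL
  cur_e <- iv$end[1]
  for (i in 2:nrow(iv)) {
    if (iv$start[i] <= cur_e) cur_e <- max(cur_e, iv$end[i])
    else { res <- rbind(res, c(keep_s, cur_e)); keep_s <- iv$start[i]; cur_e <- iv$end[i] }
  }
  res <- rbind(res, c(keep_s, cur_e))
  data.frame(start = res[, 1], end = res[, 2])
}

#' Call conserved loci from per-taxon coverage
#'
#' Positions of the reference supported by at least
#' `ceiling(occupancy_fraction * n_taxa_total)` taxa (the reference itself
#' always supports every position) form candidate intervals; candidates are
#' merged across gaps under `merge_gap`, then loci failing the repeat or
#' length filter are dropped.  Locus ids `uce-<N>` are assigned in
#' (contig, start) order.
#'
#' @param coverages list (one element per non-reference taxon) of per-contig
#'   covered-interval lists as returned by [map_taxon_to_reference()].
#' @param reference the reference [assembly] (supplies contig lengths and the
#'   repeat mask for filtering).
#' @param params a [discovery_params()].
#' @param n_taxa_total total number of taxa the occupancy fraction refers to
#'   (defaults to `length(coverages) + 1` for the reference).
#' @return data.frame of loci: `locus_id`, `contig`, `start`, `end`,
#'   `occupancy_count`, plus a `counts` attribute logging the filter funnel.
#' @export
call_conserved_loci <- function(coverages, reference, params,
                                n_taxa_total = length(coverages) + 1L) {
  stopifnot(inherits(params, "discovery_params"))
  if (n_taxa_total < 2) stop("need at least 2 taxa")
  thr <- if (!is.null(params$occupancy_count)) as.integer(params$occupancy_count)
         else as.integer(ceiling(params$occupancy_fraction * n_taxa_total))
  if (thr > n_taxa_total)
    stop("occupancy threshold (", thr, ") exceeds the taxon count (",
         n_taxa_total, ")")
  loci <- NULL
  for (cid in names(reference$contigs)) {
    len <- nchar(reference$contigs[[cid]])
    support <- rep(1L, len)  # the reference supports every position
    for (covs in coverages) {
      iv <- covs[[cid]]
      if (is.null(iv) || nrow(iv) == 0) next
      for (r in seq_len(nrow(iv)))
        support[(iv$start[r] + 1L):iv$end[r]] <-
          support[(iv$start[r] + 1L):iv$end[r]] + 1L
    }
    runs <- rle(support >= thr)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths
    cand <- data.frame(start = starts[runs$values], end = ends[runs$values])
    if (nrow(cand) == 0) next
    # occupancy recorded per candidate: the maximum support inside it
    merged <- merge_intervals(cand, max_gap = params$merge_gap)
    merged$contig <- cid
    merged$occupancy_count <- vapply(seq_len(nrow(merged)), function(i) {
      max(support[(merged$start[i] + 1L):merged$end[i]])
    }, integer(1))
    loci <- rbind(loci, merged)
  }
  n_cand <- if (is.null(loci)) 0L else nrow(loci)
  if (!is.null(loci)) {
    loci$length <- loci$end - loci$start
    loci$repeat_frac <- vapply(seq_len(nrow(loci)), function(i) {
      m <- reference$mask[[loci$contig[i]]]
      repeat_fraction(m[(loci$start[i] + 1L):loci$end[i]])
    }, numeric(1))
    n_repeat_fail <- sum(loci$repeat_frac > params$max_repeat_fraction)
    loci <- loci[loci$repeat_frac <= params$max_repeat_fraction &
                 loci$length >= params$min_locus_length, , drop = FALSE]
  } else {
    n_repeat_fail <- 0L
    loci <- data.frame(contig = character(), start = integer(),
                       end = integer(), occupancy_count = integer(),
                       length = integer(), repeat_frac = numeric())
  }
  loci <- loci[order(loci$contig, loci$start), , drop = FALSE]
  rownames(loci) <- NULL
  loci <- data.frame(locus_id = sprintf("uce-%d", seq_len(nrow(loci))),
                     loci[, c("contig", "start", "end", "occupancy_count")],
                     stringsAsFactors = FALSE)
  attr(loci, "counts") <- c(candidates = n_cand,
                            repeat_failed = n_repeat_fail,
                            final = nrow(loci))
  attr(loci, "occupancy_threshold") <- thr
  loci
}

#' Run discovery end to end on a panel of assemblies
#'
#' Simulates reads from every non-reference taxon, maps them to the
#' reference, and calls conserved loci.
#'
#' @param reference the reference [assembly].
#' @param others list of non-reference [assembly] objects.
#' @param params a [discovery_params()].
#' @return the locus data.frame from [call_conserved_loci()].
#' @export
discover_loci <- function(reference, others, params = discovery_params()) {
  coverages <- lapply(others, function(a) {
    reads <- simulate_reads(a, params$read_length, params$read_stride)
    map_taxon_to_reference(reads, reference, params$max_divergence)
  })
  call_conserved_loci(coverages, reference, params,
                      n_taxa_total = length(others) + 1L)
}

#' Extract locus sequences (and masks) from the reference
#' @param reference an [assembly].
#' @param loci locus data.frame.
#' @return named list with `sequence` and `mask` character/logical lists,
#'   one element per locus.
#' @export
extract_loci <- function(reference, loci) {
  seqs <- vapply(seq_len(nrow(loci)), function(i) {
    slice_seq(reference$contigs[[loci$contig[i]]], loci$start[i], loci$end[i])
  }, character(1))
  masks <- lapply(seq_len(nrow(loci)), function(i) {
    reference$mask[[loci$contig[i]]][(loci$start[i] + 1L):loci$end[i]]
  })
  names(seqs) <- names(masks) <- loci$locus_id
  list(sequence = seqs, mask = masks)
}
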