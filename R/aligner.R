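#' Seed-and-extend local matching against an assembly
#'
#' Finds local alignments of each query on both strands of every contig,
#' reporting hits whose identity (matches / alignment columns, gaps counted)
#' and query coverage (aligned query span / query length) meet the thresholds.
#' Scoring is fixed package-wide: match +1, mismatch -1, gap open -2,
#' gap extend -1.  Overlapping hits of one query on one target region are
#' collapsed to the best-scoring hit.  With `mode = "glocal"` the entire query
#' must align (fitting alignment; used for error-free read mapping) and
#' coverage is 1 by construction.
#'
#' @param queries character vector of query sequences (named or not).
#' @param target an [assembly], or a named character vector of target contigs.
#' @param min_identity minimum identity in `[0, 1]`.
#' @param min_query_coverage minimum query coverage in `[0, 1]`.
#' @param seed_k exact-seed length (queries shorter than this error out).
#' @param mode `"local"` or `"glocal"`.
#' @param band diagonal band half-width for the gapped extension.
#' @param small_cutoff contigs at or below this length skip seeding and are
#'   verified by exhaustive dynamic programming.
#' @return data.frame of hits: `query` (name or index), `contig`, `tstart`,
#'   `tend` (0-based half-open), `strand`, `score`, `identity`, `qcov`,
#'   sorted per query by descending score then (contig, tstart).
#' @export
local_match <- function(queries, target, min_identity, min_query_coverage,
                        seed_k = 12L, mode = c("local", "glocal"),
                        band = 16L, small_cutoff = 1000L) {
  mode <- match.arg(mode)
  stopifnot(min_identity >= 0, min_identity <= 1,
            min_query_coverage >= 0, min_query_coverage <= 1)
  if (inherits(target, "assembly")) target <- target$contigs
  if (is.null(names(target))) names(target) <- paste0("contig", seq_along(target))
  if (length(queries) == 0)
    return(data.frame(query = character(), contig = character(),
                      tstart = integer(), tend = integer(),
                      strand = character(), score = integer(),
                      identity = numeric(), qcov = numeric()))
  short <- nchar(queries) < seed_k
  if (any(short))
    stop("query shorter than the seed size (minimum ", seed_k, " bp): ",
         paste(utils::head(which(short), 3), collapse = ","))
  res <- cpp_match(unname(queries), unname(target), names(target),
                   min_identity, min_query_coverage, as.integer(seed_k),
                   mode == "glocal", as.integer(band),
                   as.integer(small_cutoff))$hits
  if (!is.null(names(queries))) res$query <- names(queries)[res$query]
  res
}

#' Best pairwise local alignment (exhaustive dynamic program)
#'
#' Full Smith-Waterman (or query-global fitting) alignment of one pair under
#' the package scoring scheme.  Intended for small sequences.
#'
#' @param query,target sequences.
#' @param mode `"local"` or `"glocal"`.
#' @return list with `score`, `identity`, `qcov`, `tstart`, `tend`,
#'   `qstart`, `qend`, `matches`, `columns`.
#' @export
align_pair <- function(query, target, mode = c("local", "glocal")) {
  mode <- match.arg(mode)
  cpp_align_pair(query, target, mode == "glocal")
}

#' Deduplicate probes by pairwise similarity
#'
#' Builds an undirected similarity graph over probe sequences: an edge joins
#' two probes when, in either orientation, their best local alignment scores
#' at least `min_score`, reaches `min_identity`, and covers at least
#' `min_coverage` of one of them.  The score floor plays the role of the HSP
#' significance threshold of seed-and-extend aligners: without it, the best
#' local alignment of two unrelated baits can drift past a 50%/50% screen
#' through long low-scoring gapped paths.  Exactly one probe per connected
#' component is retained: the probe whose source taxon appears earliest in
#' `priority`, ties broken by lexicographically smallest probe id.
#'
#' @param probes a `probe_set` or data.frame with columns `probe_id`,
#'   `source_taxon`, `sequence`.
#' @param min_identity,min_coverage similarity thresholds (defaults 0.5/0.5).
#' @param priority ordered character vector of taxa for representative
#'   choice; taxa absent from it rank after it, alphabetically.
#' @param seed_k seed length for the candidate-pair scan.
#' @param min_score minimum alignment score for a similarity edge
#'   (default 40, about a third of the default bait length; genuine
#'   duplicates at capture-relevant divergences score well above it).
#' @return the retained probes, same class as the input, with a
#'   `dedupe_removed` attribute giving the number dropped.
#' @export
dedupe_by_similarity <- function(probes, min_identity = 0.5,
                                 min_coverage = 0.5,
                                 priority = character(), seed_k = 10L,
                                 min_score = 40L) {
  df <- as.data.frame(probes)
  if (nrow(df) == 0) return(probes)
  pairs <- cpp_similar_pairs(df$sequence, min_identity, min_coverage,
                             as.integer(seed_k), as.integer(min_score))
  comp <- union_find(nrow(df), pairs$i, pairs$j)
  taxon_rank <- match(df$source_taxon, priority)
  taxon_rank[is.na(taxon_rank)] <- length(priority) + 1L
  o <- order(comp, taxon_rank, df$source_taxon, df$probe_id)
  keep_idx <- o[!duplicated(comp[o])]
  keep <- sort(keep_idx)
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  out <- restore_probe_set(out, probes)
  attr(out, "dedupe_removed") <- nrow(df) - length(keep)
  out
}

# Minimal union-find over 1..n given edge lists.
union_find <- function(n, i, j) {
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (k in seq_along(i)) {
    a <- find(i[k]); b <- find(j[k])
    if (a != b) parent[b] <- a
  }
  vapply(seq_len(n), find, integer(1))
}

#' Write alignment hits as TSV
#' @param hits data.frame from [local_match()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_hits_tsv <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
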