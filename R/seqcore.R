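#' Assembly objects: soft-masked contigs for one taxon
#'
#' An `assembly` bundles the contigs of one taxon with a per-position repeat
#' mask (TRUE = repeat-masked, the lowercase convention of soft-masked FASTA)
#' and a data-type tag (`"genome"` or `"transcriptome"`).
#'
#' @param contigs named character vector of contig sequences over A/C/G/T/N
#'   (case is ignored; use `mask` or lowercase letters to mark repeats).
#' @param taxon taxon name.
#' @param datatype `"genome"` or `"transcriptome"`.
#' @param mask optional named list of logical vectors, one per contig, TRUE at
#'   repeat-masked positions.  If omitted, lowercase letters in `contigs`
#'   define the mask.
#' @return an object of class `assembly` with elements `taxon`, `datatype`,
#'   `contigs` (uppercase sequences) and `mask`.
#' @export
assembly <- function(contigs, taxon, datatype = c("genome", "transcriptome"),
                     mask = NULL) {
  datatype <- match.arg(datatype)
  if (length(contigs) == 0) stop("assembly must contain at least one contig")
  ids <- names(contigs)
  if (is.null(ids) || anyNA(ids) || any(ids == ""))
    stop("every contig must be named")
  if (anyDuplicated(ids)) stop("contig ids must be unique within an assembly")
  if (any(nchar(contigs) == 0)) stop("empty contig sequence: ",
                                     ids[nchar(contigs) == 0][1])
  if (is.null(mask)) {
    mask <- lapply(contigs, function(s) {
      ch <- strsplit(s, "", fixed = TRUE)[[1]]
      ch %in% c("a", "c", "g", "t", "n")
    })
  } else {
    if (!setequal(names(mask), ids)) stop("mask names must match contig ids")
    mask <- mask[ids]
    bad <- which(lengths(mask) != nchar(contigs))
    if (length(bad)) stop("mask length differs from sequence length for ",
                          ids[bad[1]])
  }
  contigs <- toupper(contigs)
  chars <- unique(unlist(strsplit(unname(contigs), "", fixed = TRUE)))
  if (!all(chars %in% c("A", "C", "G", "T", "N")))
    stop("contigs may only contain A, C, G, T, N (got: ",
         paste(setdiff(chars, c("A", "C", "G", "T", "N")), collapse = ","), ")")
  structure(list(taxon = taxon, datatype = datatype,
                 contigs = contigs, mask = mask),
            class = "assembly")
}

#' @export
print.assembly <- function(x, ...) {
  cat(sprintf("<assembly> %s (%s): %d contig(s), %s bp, %.1f%% masked\n",
              x$taxon, x$datatype, length(x$contigs),
              format(sum(nchar(x$contigs)), big.mark = ","),
              100 * sum(unlist(x$mask)) / sum(nchar(x$contigs))))
  invisible(x)
}

#' Read a soft-masked FASTA file into an assembly
#'
#' Lowercase letters mark repeat-masked positions (the output convention of
#' standard repeat maskers); the stored sequence is uppercased and the mask
#' kept separately, so a write/read round trip is case-exact.
#'
#' @param path FASTA file.
#' @inheritParams assembly
#' @return an [assembly].
#' @export
read_assembly <- function(path, taxon = sub("\\.(fa|fasta|fna)$", "", basename(path)),
                          datatype = "genome") {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("FASTA parse error in ", path, ": ",
                                           conditionMessage(e)))
  if (length(set) == 0) stop("empty FASTA file: ", path)
  seqs <- as.character(set)
  names(seqs) <- sub("\\s.*$", "", names(set))
  if (any(nchar(seqs) == 0))
    stop("empty sequence for header '", names(seqs)[nchar(seqs) == 0][1],
         "' in ", path)
  assembly(seqs, taxon = taxon, datatype = datatype)
}

#' Write an assembly as soft-masked FASTA
#'
#' Masked positions are emitted in lowercase so the file can be consumed by
#' any tool understanding soft-masking.
#'
#' @param x an [assembly].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_assembly <- function(x, path) {
  stopifnot(inherits(x, "assembly"))
  seqs <- vapply(names(x$contigs), function(id) {
    ch <- strsplit(x$contigs[[id]], "", fixed = TRUE)[[1]]
    m <- x$mask[[id]]
    ch[m] <- tolower(ch[m])
    paste(ch, collapse = "")
  }, character(1))
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path, width = 80L)
  invisible(path)
}

#' GC fraction of a sequence
#'
#' `(G + C) / (A + C + G + T)`; N positions are excluded from both numerator
#' and denominator.
#'
#' @param x character vector of sequences.
#' @return numeric vector of fractions in `[0, 1]`.
#' @export
gc_fraction <- function(x) {
  if (any(nchar(x) == 0)) stop("empty sequence")
  x <- toupper(x)
  f <- Biostrings::letterFrequency(Biostrings::BStringSet(x),
                                   c("A", "C", "G", "T"))
  denom <- rowSums(f)
  if (any(denom == 0)) stop("all-N sequence has undefined composition")
  unname((f[, "G"] + f[, "C"]) / denom)
}

#' Repeat fraction of a masked sequence
#'
#' The fraction of positions flagged as repeat-masked.  N bases count as
#' unmasked unless the mask marks them.
#'
#' @param mask logical vector (TRUE = masked), or a list of such vectors.
#' @return numeric fraction(s) in `[0, 1]`.
#' @export
repeat_fraction <- function(mask) {
  if (!is.list(mask)) mask <- list(mask)
  if (any(lengths(mask) == 0)) stop("zero-length mask")
  vapply(mask, function(m) sum(m) / length(m), numeric(1))
}

#' Merge nearby intervals
#'
#' Intervals on one contig (0-based, half-open) are merged when the gap
#' between consecutive intervals, `next_start - prev_end`, is strictly less
#' than `max_gap`.  Overlapping intervals (negative gap) always merge.
#'
#' @param intervals data.frame with integer columns `start`, `end`.
#' @param max_gap non-negative gap threshold in bp.
#' @return data.frame of sorted, pairwise-disjoint merged intervals.
#' @export
merge_intervals <- function(intervals, max_gap = 0L) {
  stopifnot(is.data.frame(intervals), max_gap >= 0)
  if (nrow(intervals) == 0) return(data.frame(start = integer(), end = integer()))
  if (any(intervals$start < 0)) stop("negative coordinates")
  if (any(intervals$end <= intervals$start)) stop("empty or inverted interval")
  o <- order(intervals$start, intervals$end)
  s <- as.integer(intervals$start[o]); e <- as.integer(intervals$end[o])
  out_s <- s[1]; out_e <- e[1]
  res_s <- integer(); res_e <- integer()
  if (length(s) > 1) {
    for (i in 2:length(s)) {
      if (s[i] - out_e < max_gap) {
        out_e <- max(out_e, e[i])
      } else {
        res_s <- c(res_s, out_s); res_e <- c(res_e, out_e)
        out_s <- s[i]; out_e <- e[i]
      }
    }
  }
  data.frame(start = c(res_s, out_s), end = c(res_e, out_e))
}

#' Reverse complement
#'
#' @param x character vector of A/C/G/T/N sequences.
#' @return reverse-complemented character vector.
#' @export
revcomp <- function(x) cpp_revcomp(x)

# Extract [start, end) (0-based half-open) from a contig string.
slice_seq <- function(seq, start, end) substr(seq, start + 1L, end)

# Interval dump in the package's BED-like 0-based half-open TSV.
#' Write loci as a BED-like TSV (locus_id, contig, start, end, occupancy)
#' @param loci data.frame of loci.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_locus_tsv <- function(loci, path) {
  utils::write.table(loci, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
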