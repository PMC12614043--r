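#' Parameters for bait (probe) design
#'
#' Defaults implement the standard design recipe: 120 bp baits, two per
#' locus at 3x tiling density (stride = probe_length / 3) placed so both
#' overlap the locus midpoint; baits with GC outside 30-70% or more than 25%
#' repeat content are dropped; self-dedupe at identity/coverage 50/50; the
#' temporary-to-master validation match runs at identity 50% / coverage 83%;
#' final loci must be present in at least 15 species.
#'
#' @param probe_length bait length, bp.
#' @param probes_per_locus baits designed per locus.
#' @param tiling_density tiling density (stride = probe_length / density).
#' @param gc_min,gc_max allowed GC range (inclusive).
#' @param max_repeat_fraction maximum repeat-masked fraction of a bait.
#' @param dedupe_identity,dedupe_coverage self-dedupe thresholds.
#' @param master_identity,master_coverage probe-to-assembly validation
#'   thresholds used for final-locus selection and master design.
#' @param min_species_for_final minimum species a locus must be present in.
#' @return a `design_params` list.
#' @export
design_params <- function(probe_length = 120L, probes_per_locus = 2L,
                          tiling_density = 3L, gc_min = 0.30, gc_max = 0.70,
                          max_repeat_fraction = 0.25,
                          dedupe_identity = 0.5, dedupe_coverage = 0.5,
                          master_identity = 0.5, master_coverage = 0.83,
                          min_species_for_final = 15L) {
  stopifnot(probe_length >= 1, probes_per_locus >= 1, tiling_density >= 1)
  structure(list(probe_length = as.integer(probe_length),
                 probes_per_locus = as.integer(probes_per_locus),
                 tiling_density = as.integer(tiling_density),
                 gc_min = gc_min, gc_max = gc_max,
                 max_repeat_fraction = max_repeat_fraction,
                 dedupe_identity = dedupe_identity,
                 dedupe_coverage = dedupe_coverage,
                 master_identity = master_identity,
                 master_coverage = master_coverage,
                 min_species_for_final = as.integer(min_species_for_final)),
            class = "design_params")
}

#' Probe-set container
#'
#' A data.frame of probe records (`probe_id`, `locus_id`, `source_taxon`,
#' `offset`, `sequence`, `gc`, `repeat_frac`) carrying the set's distinct
#' target loci as an attribute.
#'
#' @param df probe record data.frame.
#' @param target_loci character vector of distinct target locus ids
#'   (defaults to the loci present in `df`).
#' @return a `probe_set`.
#' @export
probe_set <- function(df, target_loci = unique(df$locus_id)) {
  need <- c("probe_id", "locus_id", "source_taxon", "offset", "sequence",
            "gc", "repeat_frac")
  stopifnot(all(need %in% names(df)))
  if (anyDuplicated(df$probe_id)) stop("probe ids must be unique within a set")
  rownames(df) <- NULL
  structure(df, target_loci = target_loci, class = c("probe_set", "data.frame"))
}

restore_probe_set <- function(df, template) {
  if (inherits(template, "probe_set"))
    probe_set(df, target_loci = attr(template, "target_loci"))
  else df
}

#' @export
print.probe_set <- function(x, ...) {
  cat(sprintf("<probe_set> %d probes, %d target loci, %d source taxa\n",
              nrow(x), length(attr(x, "target_loci")),
              length(unique(x$source_taxon))))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 4))
  invisible(x)
}

#' Number of distinct target loci of a probe set
#' @param x a `probe_set`.
#' @return integer count.
#' @export
n_target_loci <- function(x) length(attr(x, "target_loci"))

#' Design baits for one locus
#'
#' Two baits (by default) are tiled so both overlap the locus midpoint:
#' with stride `probe_length %/% tiling_density`, candidate starts are
#' `mid - probe_length + floor(stride / 2)` and that plus one stride,
#' clamped into `[0, locus_length - probe_length]`.  Duplicate starts after
#' clamping collapse; baits failing the GC or repeat filter are dropped
#' individually.
#'
#' @param locus_sequence locus sequence (uppercase A/C/G/T/N).
#' @param locus_mask logical repeat mask of the locus.
#' @param locus_id locus id for bookkeeping.
#' @param source_taxon taxon the sequence came from.
#' @param params a [design_params()].
#' @return probe record data.frame (possibly zero rows; a locus shorter than
#'   the probe length yields zero rows with a warning).
#' @export
design_probes_for_locus <- function(locus_sequence, locus_mask, locus_id,
                                    source_taxon, params = design_params()) {
  L <- nchar(locus_sequence)
  P <- params$probe_length
  empty <- data.frame(probe_id = character(), locus_id = character(),
                      source_taxon = character(), offset = integer(),
                      sequence = character(), gc = numeric(),
                      repeat_frac = numeric())
  if (L < P) {
    warning("locus ", locus_id, " shorter than the probe length (", L, " < ",
            P, "): no baits designed")
    return(empty)
  }
  stride <- P %/% params$tiling_density
  mid <- L %/% 2L
  starts <- mid - P + stride %/% 2L + stride * (seq_len(params$probes_per_locus) - 1L)
  starts <- unique(pmin(pmax(starts, 0L), L - P))
  seqs <- substring(locus_sequence, starts + 1L, starts + P)
  masks <- lapply(starts, function(s) locus_mask[(s + 1L):(s + P)])
  gc <- vapply(seqs, function(s) {
    if (grepl("[ACGT]", s)) gc_fraction(s) else NA_real_
  }, numeric(1), USE.NAMES = FALSE)
  rf <- repeat_fraction(masks)
  ok <- !is.na(gc) & gc >= params$gc_min & gc <= params$gc_max &
        rf <= params$max_repeat_fraction
  out <- data.frame(probe_id = sprintf("%s_%s_p%d", locus_id, source_taxon,
                                       seq_along(starts)),
                    locus_id = locus_id, source_taxon = source_taxon,
                    offset = starts, sequence = seqs, gc = gc,
                    repeat_frac = rf, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[ok, , drop = FALSE]
}

#' Build the temporary probe set from the reference
#'
#' Designs baits for every discovered locus from the reference sequence, then
#' deduplicates the pool at the self-dedupe thresholds (50/50 by default).
#'
#' @param loci locus data.frame from [discover_loci()].
#' @param reference the reference [assembly].
#' @param params a [design_params()].
#' @return a `probe_set` whose target loci are the designable loci.
#' @export
build_temporary_set <- function(loci, reference, params = design_params()) {
  ext <- extract_loci(reference, loci)
  recs <- lapply(loci$locus_id, function(lid) {
    design_probes_for_locus(ext$sequence[[lid]], ext$mask[[lid]], lid,
                            reference$taxon, params)
  })
  pool <- do.call(rbind, recs)
  n_designed <- nrow(pool)
  out <- dedupe_by_similarity(probe_set(pool), params$dedupe_identity,
                              params$dedupe_coverage,
                              priority = reference$taxon)
  out <- probe_set(as.data.frame(out), target_loci = unique(out$locus_id))
  attr(out, "counts") <- c(loci_in = nrow(loci), probes_designed = n_designed,
                           probes_after_dedupe = nrow(out))
  out
}

#' Per-assembly presence of each locus under validation matching
#'
#' A locus is present in an assembly when at least one of its probes hits the
#' assembly at `master_identity` / `master_coverage`.
#'
#' @param probes a `probe_set`.
#' @param assemblies list of [assembly] objects.
#' @param params a [design_params()].
#' @return logical matrix, loci x assemblies.
#' @export
locus_presence <- function(probes, assemblies, params = design_params()) {
  loci <- sort(unique(probes$locus_id))
  taxa <- vapply(assemblies, `[[`, character(1), "taxon")
  pres <- matrix(FALSE, length(loci), length(taxa),
                 dimnames = list(loci, taxa))
  for (a in assemblies) {
    hits <- local_match(probes$sequence, a,
                        min_identity = params$master_identity,
                        min_query_coverage = params$master_coverage,
                        small_cutoff = 0L)
    if (nrow(hits)) {
      hit_loci <- unique(probes$locus_id[hits$query])
      pres[hit_loci, a$taxon] <- TRUE
    }
  }
  pres
}

#' Select final loci present in enough species
#'
#' Retains the loci whose temporary probes hit at least
#' `min_species_for_final` of the supplied assemblies at the validation
#' thresholds.
#'
#' @param temporary_probes the temporary `probe_set`.
#' @param assemblies list of all [assembly] objects (reference included).
#' @param params a [design_params()].
#' @param loci optional locus data.frame to subset (defaults to the probe
#'   set's target loci as a bare id vector).
#' @return character vector of retained locus ids with a `presence`
#'   attribute (the full presence matrix).
#' @export
select_final_loci <- function(temporary_probes, assemblies,
                              params = design_params()) {
  pres <- locus_presence(temporary_probes, assemblies, params)
  n_sp <- rowSums(pres)
  keep <- names(n_sp)[n_sp >= params$min_species_for_final]
  structure(keep, presence = pres, n_species = n_sp)
}

#' Build the master probe set from all assemblies
#'
#' For every assembly, each final locus is located by its best qualifying
#' hit of the reference locus sequence (validation thresholds); baits are
#' then designed from that assembly's own sequence at the located interval,
#' pooled across assemblies, and deduplicated at 50/50 with source-taxon
#' provenance preserved.
#'
#' @param final_loci character vector of locus ids to design for.
#' @param reference_loci locus data.frame (reference coordinates).
#' @param reference the reference [assembly].
#' @param assemblies list of all [assembly] objects (may include the
#'   reference).
#' @param params a [design_params()].
#' @param priority taxon priority order for dedupe representatives
#'   (defaults to the order of `assemblies`).
#' @return a `probe_set`.
#' @export
build_master_set <- function(final_loci, reference_loci, reference,
                             assemblies, params = design_params(),
                             priority = NULL) {
  if (length(final_loci) == 0) stop("no final loci to design for")
  taxa <- vapply(assemblies, `[[`, character(1), "taxon")
  if (is.null(priority)) priority <- taxa
  loci <- reference_loci[reference_loci$locus_id %in% final_loci, , drop = FALSE]
  ext <- extract_loci(reference, loci)
  parts <- list()
  for (a in assemblies) {
    if (identical(a$taxon, reference$taxon)) {
      recs <- lapply(loci$locus_id, function(lid) {
        design_probes_for_locus(ext$sequence[[lid]], ext$mask[[lid]], lid,
                                a$taxon, params)
      })
      parts[[length(parts) + 1L]] <- do.call(rbind, recs)
      next
    }
    hits <- local_match(ext$sequence, a,
                        min_identity = params$master_identity,
                        min_query_coverage = params$master_coverage,
                        small_cutoff = 0L)
    if (nrow(hits) == 0) next
    best <- hits[!duplicated(hits$query), , drop = FALSE]  # sorted by score
    recs <- lapply(seq_len(nrow(best)), function(r) {
      lid <- best$query[r]
      seq <- slice_seq(a$contigs[[best$contig[r]]], best$tstart[r], best$tend[r])
      msk <- a$mask[[best$contig[r]]][(best$tstart[r] + 1L):best$tend[r]]
      if (best$strand[r] == "-") { seq <- revcomp(seq); msk <- rev(msk) }
      design_probes_for_locus(seq, msk, lid, a$taxon, params)
    })
    parts[[length(parts) + 1L]] <- do.call(rbind, recs)
  }
  pool <- do.call(rbind, parts)
  if (is.null(pool) || nrow(pool) == 0) stop("no master probes could be designed")
  pool$probe_id <- make.unique(pool$probe_id, sep = "_d")
  n_designed <- nrow(pool)
  out <- dedupe_by_similarity(probe_set(pool), params$dedupe_identity,
                              params$dedupe_coverage, priority = priority)
  out <- probe_set(as.data.frame(out), target_loci = sort(unique(out$locus_id)))
  attr(out, "counts") <- c(loci_in = length(final_loci),
                           probes_designed = n_designed,
                           probes_after_dedupe = nrow(out))
  out
}

#' Subset a probe set by source taxa
#'
#' @param master a `probe_set`.
#' @param taxa taxa whose probes to retain.
#' @return a `probe_set` with the target-locus list recomputed.
#' @export
subset_by_taxa <- function(master, taxa) {
  stopifnot(inherits(master, "probe_set"), length(taxa) > 0)
  known <- unique(master$source_taxon)
  bad <- setdiff(taxa, known)
  if (length(bad))
    stop("unknown taxa: ", paste(bad, collapse = ", "),
         " (valid: ", paste(sort(known), collapse = ", "), ")")
  df <- as.data.frame(master)[master$source_taxon %in% taxa, , drop = FALSE]
  probe_set(df, target_loci = sort(unique(df$locus_id)))
}

#' Merge two probe sets with cross-redundancy screening
#'
#' The union of both sets is screened for similar pairs at the given
#' identity (coverage 0.5), retaining one probe per similarity component.
#' Representatives favour set A (its taxa head the priority order).  Locus
#' ids are kept in distinct namespaces by prefixing when the two sets share
#' locus ids.
#'
#' @param set_a,set_b `probe_set` objects.
#' @param identity,coverage screening thresholds.
#' @param prefix_a,prefix_b locus/probe namespace prefixes applied when ids
#'   collide between sets.
#' @return the merged `probe_set`.
#' @export
merge_probe_sets <- function(set_a, set_b, identity = 0.5, coverage = 0.5,
                             prefix_a = "A", prefix_b = "B") {
  a <- as.data.frame(set_a); b <- as.data.frame(set_b)
  if (length(intersect(a$locus_id, b$locus_id)) > 0 ||
      length(intersect(a$probe_id, b$probe_id)) > 0) {
    a$locus_id <- paste0(prefix_a, ".", a$locus_id)
    a$probe_id <- paste0(prefix_a, ".", a$probe_id)
    b$locus_id <- paste0(prefix_b, ".", b$locus_id)
    b$probe_id <- paste0(prefix_b, ".", b$probe_id)
  }
  pool <- rbind(a, b)
  priority <- unique(c(a$source_taxon, b$source_taxon))
  out <- dedupe_by_similarity(probe_set(pool), identity, coverage,
                              priority = priority)
  probe_set(as.data.frame(out), target_loci = sort(unique(out$locus_id)))
}

#' Write a probe set as FASTA with structured headers
#'
#' Headers have the form `probe_id|locus_id|source_taxon|offset`.
#'
#' @param x a `probe_set`.
#' @param path output FASTA.
#' @return `path`, invisibly.
#' @export
write_probe_fasta <- function(x, path) {
  hdr <- sprintf("%s|%s|%s|%d", x$probe_id, x$locus_id, x$source_taxon,
                 x$offset)
  seqs <- setNames(x$sequence, hdr)
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path, width = 80L)
  invisible(path)
}

#' Read a probe set written by [write_probe_fasta()]
#' @param path FASTA file.
#' @return a `probe_set` (GC and repeat fractions recomputed; repeat from
#'   lowercase letters).
#' @export
read_probe_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  parts <- strsplit(names(set), "|", fixed = TRUE)
  seqs <- as.character(set)
  mask <- lapply(seqs, function(s)
    strsplit(s, "", fixed = TRUE)[[1]] %in% c("a", "c", "g", "t", "n"))
  df <- data.frame(probe_id = vapply(parts, `[`, "", 1),
                   locus_id = vapply(parts, `[`, "", 2),
                   source_taxon = vapply(parts, `[`, "", 3),
                   offset = as.integer(vapply(parts, `[`, "", 4)),
                   sequence = toupper(seqs),
                   gc = gc_fraction(seqs),
                   repeat_frac = repeat_fraction(mask),
                   stringsAsFactors = FALSE)
  probe_set(df)
}
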