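# Independent oracles: Smith-Waterman via Biostrings::pairwiseAlignment under
# the package scoring scheme (match +1, mismatch -1; a gap of length L costs
# 1 + L*1 = the package's open-2/extend-1 convention), plus brute-force
# interval merging and connected components.

rnd_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                             collapse = "")

.sub_mat <- local({
  m <- NULL
  function() {
    if (is.null(m))
      m <<- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                     baseOnly = TRUE)
    m
  }
})

# Best local alignment of a pair by exhaustive DP (independent of the
# package's aligner).
oracle_local <- function(q, t) {
  aln <- Biostrings::pairwiseAlignment(q, t, type = "local",
                                       substitutionMatrix = .sub_mat(),
                                       gapOpening = 1, gapExtension = 1)
  pat <- as.character(Biostrings::alignedPattern(aln))
  columns <- nchar(pat)
  matches <- Biostrings::nmatch(aln)
  p <- Biostrings::pattern(aln)
  s <- Biostrings::subject(aln)
  qspan <- Biostrings::end(p) - Biostrings::start(p) + 1L
  tspan <- Biostrings::end(s) - Biostrings::start(s) + 1L
  list(score = Biostrings::score(aln),
       identity = if (columns > 0) matches / columns else 0,
       cov_q = qspan / nchar(q), cov_t = tspan / nchar(t))
}

# The package's similarity-edge rule evaluated with the oracle aligner.
oracle_similar <- function(a, b, min_identity = 0.5, min_cov = 0.5,
                           min_score = 40) {
  for (q in c(a, as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(a))))) {
    r <- oracle_local(q, b)
    if (r$score >= min_score && r$identity >= min_identity - 1e-12 &&
        max(r$cov_q, r$cov_t) >= min_cov - 1e-12)
      return(TRUE)
  }
  FALSE
}

# Pairwise gap-check merging iterated to a fixpoint.
oracle_merge <- function(iv, max_gap) {
  iv <- iv[order(iv$start, iv$end), , drop = FALSE]
  repeat {
    changed <- FALSE
    i <- 1
    while (i < nrow(iv)) {
      if (iv$start[i + 1] - iv$end[i] < max_gap) {
        iv$end[i] <- max(iv$end[i], iv$end[i + 1])
        iv <- iv[-(i + 1), , drop = FALSE]
        changed <- TRUE
      } else i <- i + 1
    }
    if (!changed) break
  }
  rownames(iv) <- NULL
  iv
}

# Vectorised all-pairs audit: returns TRUE if any pair of sequences is
# similar under the package edge rule, judged by the oracle aligner.
oracle_any_similar_pair <- function(seqs, min_identity = 0.5, min_cov = 0.5,
                                    min_score = 40) {
  n <- length(seqs)
  if (n < 2) return(FALSE)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(seqs)))
  check <- function(pats, subj, lens_p, len_s) {
    aln <- Biostrings::pairwiseAlignment(pats, subj, type = "local",
                                         substitutionMatrix = .sub_mat(),
                                         gapOpening = 1, gapExtension = 1)
    sc <- Biostrings::score(aln)
    cand <- which(sc >= min_score)
    if (!length(cand)) return(FALSE)
    columns <- nchar(as.character(Biostrings::alignedPattern(aln)))[cand]
    matches <- Biostrings::nmatch(aln)[cand]
    p <- Biostrings::pattern(aln)
    s <- Biostrings::subject(aln)
    qspan <- (Biostrings::end(p) - Biostrings::start(p) + 1L)[cand]
    tspan <- (Biostrings::end(s) - Biostrings::start(s) + 1L)[cand]
    ident <- ifelse(columns > 0, matches / columns, 0)
    cov <- pmax(qspan / lens_p[cand], tspan / len_s)
    any(ident >= min_identity - 1e-12 & cov >= min_cov - 1e-12)
  }
  for (j in 2:n) {
    idx <- seq_len(j - 1L)
    if (check(seqs[idx], seqs[j], nchar(seqs)[idx], nchar(seqs[j])))
      return(TRUE)
    if (check(rc[idx], seqs[j], nchar(rc)[idx], nchar(seqs[j])))
      return(TRUE)
  }
  FALSE
}
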