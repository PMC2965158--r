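# Closest-reference retrieval: k-mer seeded candidate ranking followed by
# exact Smith-Waterman re-ranking (the homology-search role that external
# BLASTN plays in classic T-RFLP workflows, done natively so the package
# has no external binary dependency).

.sub_matrix <- function(match, mismatch) {
  Biostrings::nucleotideSubstitutionMatrix(match = match, mismatch = mismatch,
                                           baseOnly = FALSE, type = "DNA")
}

# Convert one pairwiseAlignment (pattern = a, subject = b) into the
# result contract used throughout the package.
.sw_result <- function(pwa, i = 1L) {
  sc <- Biostrings::score(pwa)[i]
  pa <- Biostrings::alignedPattern(pwa)[i]
  sa <- Biostrings::alignedSubject(pwa)[i]
  astr <- as.character(pa)
  bstr <- as.character(sa)
  w <- nchar(astr)
  if (w == 0L || sc <= 0) {
    return(structure(list(sample_start = NA_integer_, sample_end = NA_integer_,
                          ref_start = NA_integer_, ref_end = NA_integer_,
                          score = max(sc, 0), percent_identity = NA_real_,
                          aligned_sample = "", aligned_ref = ""),
                     class = "sw_alignment"))
  }
  ac <- strsplit(astr, "", fixed = TRUE)[[1]]
  bc <- strsplit(bstr, "", fixed = TRUE)[[1]]
  pid <- 100 * sum(ac == bc & ac != "-") / w
  structure(list(
    sample_start = Biostrings::start(Biostrings::pattern(pwa))[i],
    sample_end = Biostrings::end(Biostrings::pattern(pwa))[i],
    ref_start = Biostrings::start(Biostrings::subject(pwa))[i],
    ref_end = Biostrings::end(Biostrings::subject(pwa))[i],
    score = sc, percent_identity = pid,
    aligned_sample = astr, aligned_ref = bstr),
    class = "sw_alignment")
}

#' Optimal local alignment of two sequences
#'
#' Smith-Waterman with affine gaps: a gap of length L costs
#' `gap_open + L * gap_extend`. Scoring defaults mirror BLASTN's +5/-4
#' match/mismatch and EMBOSS water's 10/0.5 gap penalties. Percent
#' identity counts identical columns over all alignment columns, gap
#' columns included in the denominator (EMBOSS convention). When no
#' positive-scoring local alignment exists the result has score 0, empty
#' aligned strings and `NA` coordinates.
#'
#' @param a Sample-side sequence (coordinates reported as `sample_*`).
#' @param b Reference-side sequence (coordinates reported as `ref_*`).
#' @param match,mismatch Substitution scores.
#' @param gap_open,gap_extend Affine gap penalties (positive numbers).
#' @return Object of class `sw_alignment`: `sample_start`, `sample_end`,
#'   `ref_start`, `ref_end` (1-based inclusive), `score`,
#'   `percent_identity`, `aligned_sample`, `aligned_ref`.
#' @export
smith_waterman <- function(a, b, match = 5, mismatch = -4,
                           gap_open = 10, gap_extend = 0.5) {
  stopifnot(nchar(a) > 0L, nchar(b) > 0L)
  pwa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "local",
    substitutionMatrix = .sub_matrix(match, mismatch),
    gapOpening = gap_open, gapExtension = gap_extend)
  .sw_result(pwa)
}

#' @export
print.sw_alignment <- function(x, ...) {
  cat(sprintf("<sw_alignment> score %.1f, identity %s, sample %s-%s, ref %s-%s\n",
              x$score,
              if (is.na(x$percent_identity)) "NA"
              else sprintf("%.1f%%", x$percent_identity),
              x$sample_start, x$sample_end, x$ref_start, x$ref_end))
  invisible(x)
}

# Distinct k-mers of a sequence.
.kmer_set <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  unique(substring(seq, 1:(n - k + 1L), k:n))
}

# Per-subset cache of reference k-mer sets, keyed by k.
.ref_kmer_sets <- function(subset, k) {
  key <- paste0("k", k)
  cache <- subset$.cache
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  sets <- lapply(subset$records$ungapped_seq, .kmer_set, k = k)
  names(sets) <- subset$records$id
  if (!is.null(cache)) cache[[key]] <- sets
  sets
}

#' Rank reference candidates by shared distinct k-mers
#'
#' Seeding stage of the closest-reference search: candidates are ordered
#' by the number of distinct k-mers shared with the sample (descending),
#' ties broken by reference id (ascending).
#'
#' @param sample Concrete nucleotide string.
#' @param subset A [build_subset()] result.
#' @param k k-mer size (default 11).
#' @param top_m Maximum number of candidates returned (default 25).
#' @return Data frame with columns `ref_id`, `seed_score`, `rank`.
#' @export
seed_rank <- function(sample, subset, k = 11L, top_m = 25L) {
  stopifnot(inherits(subset, "trf_subset"), k >= 4L)
  if (nrow(subset$records) == 0L)
    stop("reference subset is empty", call. = FALSE)
  skmers <- .kmer_set(toupper(sample), k)
  if (length(skmers) == 0L) {
    warning("sample shorter than k; no candidates")
    return(data.frame(ref_id = character(0), seed_score = integer(0),
                      rank = integer(0)))
  }
  sets <- .ref_kmer_sets(subset, k)
  shared <- vapply(sets, function(s) sum(s %in% skmers), integer(1))
  ord <- order(-shared, names(shared))
  ids <- names(shared)[ord]
  out <- data.frame(ref_id = ids, seed_score = as.integer(shared[ord]),
                    stringsAsFactors = FALSE)
  out <- utils::head(out, top_m)
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Best reference hits for a sample
#'
#' Runs [seed_rank()] to pick `top_m` candidates, aligns each with
#' [smith_waterman()], and returns the first `n` after ordering by
#' alignment score (descending), seed score (descending), then reference
#' id (ascending). Candidates whose best local alignment has score 0 are
#' dropped; an empty result means the sample is unassignable.
#'
#' @inheritParams seed_rank
#' @param n Number of hits to report.
#' @param match,mismatch,gap_open,gap_extend Passed to [smith_waterman()].
#' @return Object of class `trf_hits`: list of entries, each a list with
#'   `ref_id`, `seed_score`, `sw_score`, `rank` and `alignment`
#'   (an `sw_alignment`).
#' @export
best_hits <- function(sample, subset, n = 1L, k = 11L, top_m = 25L,
                      match = 5, mismatch = -4, gap_open = 10,
                      gap_extend = 0.5) {
  cand <- seed_rank(sample, subset, k = k, top_m = top_m)
  if (nrow(cand) == 0L) return(structure(list(), class = "trf_hits"))
  idx <- match(cand$ref_id, subset$records$id)
  refs <- Biostrings::DNAStringSet(subset$records$ungapped_seq[idx])
  # One vectorized call: pattern = references, subject = sample; swap the
  # coordinate roles afterwards so results read as sample-vs-reference.
  pwa <- Biostrings::pairwiseAlignment(
    refs, Biostrings::DNAString(toupper(sample)), type = "local",
    substitutionMatrix = .sub_matrix(match, mismatch),
    gapOpening = gap_open, gapExtension = gap_extend)
  # Rank by score first; aligned strings are materialized only for the n
  # reported hits (extraction is far more expensive than the alignment).
  sw_scores <- Biostrings::score(pwa)
  keep <- which(sw_scores > 0)
  if (length(keep) == 0L) return(structure(list(), class = "trf_hits"))
  ord <- keep[order(-sw_scores[keep], -cand$seed_score[keep], cand$ref_id[keep])]
  ord <- utils::head(ord, n)
  out <- lapply(seq_along(ord), function(j) {
    i <- ord[j]
    r <- .sw_result(pwa[i], 1L)
    aln <- structure(list(sample_start = r$ref_start, sample_end = r$ref_end,
                          ref_start = r$sample_start, ref_end = r$sample_end,
                          score = r$score, percent_identity = r$percent_identity,
                          aligned_sample = r$aligned_ref,
                          aligned_ref = r$aligned_sample),
                     class = "sw_alignment")
    list(ref_id = cand$ref_id[i], seed_score = cand$seed_score[i],
         sw_score = sw_scores[i], rank = j, alignment = aln)
  })
  structure(out, class = "trf_hits")
}

#' Write an alignment as plain text for manual inspection
#'
#' EMBOSS-pair-like block layout so users can eyeball the local alignment
#' behind any prediction.
#'
#' @param alignment An `sw_alignment`.
#' @param con File path or connection.
#' @param sample_id,ref_id Labels for the two sequences.
#' @param block Characters per line.
#' @return `con`, invisibly.
#' @export
write_alignment_text <- function(alignment, con, sample_id = "sample",
                                 ref_id = "reference", block = 60L) {
  lines <- c(
    "########################################",
    sprintf("# 1: %s", sample_id),
    sprintf("# 2: %s", ref_id),
    sprintf("# Score: %.1f", alignment$score),
    sprintf("# Identity: %s",
            if (is.na(alignment$percent_identity)) "NA"
            else sprintf("%.2f%%", alignment$percent_identity)),
    sprintf("# Sample: %s-%s  Reference: %s-%s",
            alignment$sample_start, alignment$sample_end,
            alignment$ref_start, alignment$ref_end),
    "########################################")
  a <- alignment$aligned_sample
  b <- alignment$aligned_ref
  w <- nchar(a)
  if (w > 0L) {
    ac <- strsplit(a, "", fixed = TRUE)[[1]]
    bc <- strsplit(b, "", fixed = TRUE)[[1]]
    mid <- ifelse(ac == bc & ac != "-", "|", " ")
    for (s in seq(1L, w, by = block)) {
      e <- min(s + block - 1L, w)
      lines <- c(lines,
                 sprintf("%-10s %s", substr(sample_id, 1, 10),
                         substr(a, s, e)),
                 sprintf("%-10s %s", "", paste(mid[s:e], collapse = "")),
                 sprintf("%-10s %s", substr(ref_id, 1, 10), substr(b, s, e)),
                 "")
    }
  }
  writeLines(lines, con)
  invisible(con)
}
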