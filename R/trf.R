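# Core T-RF size estimation for possibly 5'-truncated sequences.
#
# Geometry: the labeled primer sits near the 5' end of the gene on a
# full-length reference; a partial clone read typically starts 10-30 nt
# downstream of the primer (the unsequenced "gap"). The closest
# full-length reference bridges that gap: gap length is measured on the
# reference between the primer anchor and the start of the local
# alignment, and the estimated T-RF is gap + distance to the first cut
# site observed on the sample itself. When the sample carries no usable
# cut site (or its true cut lies inside the gap), the reference's own
# terminal fragment is reported instead.

#' Terminal fragment length of a reference record
#'
#' Distance, on the reference's ungapped sequence, from the primer's 5'
#' base through the last base before the first downstream cut.
#'
#' @param record One row of a `trf_refdb` data frame.
#' @param primer_start 1-based start of the primer hit on the ungapped
#'   reference (see [build_subset()]).
#' @param enzyme An [enzyme_spec()].
#' @return Integer length, or `NA_integer_` when the reference has no cut
#'   at or after the primer.
#' @export
reference_trf <- function(record, primer_start, enzyme) {
  stopifnot(!is.na(primer_start))
  terminal_fragment(record$ungapped_seq, primer_start, enzyme)
}

#' Gap length between primer and alignment start
#'
#' Number of truly missing nucleotides between the labeled primer's 5'
#' base and the sample's first base, measured on the best-hit reference:
#' `ref_start - primer_start`, reduced by `sample_start - 1` when the
#' local alignment does not begin at the sample's first base (those
#' unaligned sample bases are present sequence, not gap), and clamped at
#' 0 when the alignment begins at or upstream of the primer.
#'
#' @param alignment An `sw_alignment` (sample vs reference ungapped
#'   coordinates).
#' @param primer_start 1-based primer start on the same reference
#'   coordinate system.
#' @return List with `gap` (integer >= 0) and `upstream` (logical: the
#'   raw alignment start lay at or upstream of the primer start and the
#'   gap was clamped).
#' @export
compute_gap <- function(alignment, primer_start) {
  stopifnot(!is.na(alignment$ref_start))
  raw <- alignment$ref_start - primer_start
  upstream <- raw < 0L
  gap <- raw - (alignment$sample_start - 1L)
  if (gap < 0L) gap <- 0L
  list(gap = as.integer(gap), upstream = upstream)
}

#' Truncate a lineage string to a taxonomy depth
#'
#' @param lineage Semicolon-separated lineage, domain first.
#' @param rank Number of ranks to keep; the full lineage when `rank`
#'   exceeds the available depth.
#' @return Truncated lineage string.
#' @examples
#' assign_taxonomy("Bacteria;Proteobacteria;Alphaproteobacteria", 2)
#' @export
assign_taxonomy <- function(lineage, rank = Inf) {
  stopifnot(is.character(lineage), nchar(lineage) > 0L)
  ranks <- strsplit(lineage, ";", fixed = TRUE)[[1]]
  paste(ranks[seq_len(min(rank, length(ranks)))], collapse = ";")
}

.EMPTY_PREDICTION <- function(sample_id, enzyme_name, flags) {
  data.frame(sample_id = sample_id, enzyme = enzyme_name,
             best_hit_id = NA_character_, ref_fragment_length = NA_integer_,
             est_fragment_length = NA_integer_, gap_length = NA_integer_,
             percent_identity = NA_real_, lineage = NA_character_,
             method = NA_character_, flags = flags,
             stringsAsFactors = FALSE)
}

#' Predict the T-RF size of a sample sequence
#'
#' For each of the `n_hits` closest references: locate the primer anchor
#' on the reference, compute the reference's own terminal fragment, align
#' sample and reference, derive the gap, and decide the estimation
#' method. If the sample carries a cut site (searched from its first
#' base, or from the base aligned to the primer when the alignment
#' extends upstream of the primer), the estimate is
#' `gap + terminal_fragment(sample)` (`method = "sample-site"`). If the
#' reference's own first cut -- or any part of the recognition site that
#' produces it -- lies upstream of the aligned region, the sample cannot
#' detect its true cut: the row is flagged `cut-in-gap` and the reference
#' estimate is used. Otherwise (`no cut on the sample`) the
#' reference's terminal fragment is reported
#' (`method = "reference-estimated"`).
#'
#' @param sample Concrete nucleotide string (a possibly 5'-truncated
#'   read).
#' @param sample_id Identifier used in the output rows.
#' @param enzyme An [enzyme_spec()].
#' @param subset A [build_subset()] result built with the same primer
#'   used to generate the amplicons.
#' @param n_hits Number of closest references to report (one output row
#'   per hit, in rank order).
#' @param hits Optional precomputed [best_hits()] result for this sample
#'   (avoids re-aligning when predicting for several enzymes).
#' @param min_identity Percent-identity threshold below which rows carry
#'   a `low-confidence` flag (default 80).
#' @param ... Passed to [best_hits()] when `hits` is not supplied.
#' @return Data frame with columns `sample_id`, `enzyme`, `best_hit_id`,
#'   `ref_fragment_length`, `est_fragment_length`, `gap_length`,
#'   `percent_identity`, `lineage`, `method`, `flags` (comma-separated,
#'   empty when none).
#' @export
predict_trf <- function(sample, sample_id, enzyme, subset, n_hits = 1L,
                        hits = NULL, min_identity = 80, ...) {
  stopifnot(inherits(enzyme, "enzyme_spec"), inherits(subset, "trf_subset"))
  sample <- toupper(sample)
  if (is.null(hits)) hits <- best_hits(sample, subset, n = n_hits, ...)
  if (length(hits) == 0L)
    return(.EMPTY_PREDICTION(sample_id, enzyme$name, "unassignable"))

  sample_cuts <- find_cut_positions(sample, enzyme)

  rows <- lapply(hits, function(h) {
    flags <- character(0)
    rec <- subset$records[match(h$ref_id, subset$records$id), , drop = FALSE]
    aln <- h$alignment
    pid <- aln$percent_identity
    if (!is.na(pid) && pid < min_identity) flags <- c(flags, "low-confidence")

    pstart <- .subset_primer_start(subset, h$ref_id)
    if (is.na(pstart)) {
      # No stored primer anchor (hit supplied outside build_subset): no
      # coordinate to measure from, so lengths stay NA.
      flags <- c(flags, "no-primer-on-ref")
      out <- .EMPTY_PREDICTION(sample_id, enzyme$name,
                               paste(flags, collapse = ","))
      out$best_hit_id <- h$ref_id
      out$percent_identity <- pid
      out$lineage <- rec$lineage
      return(out)
    }

    ref_cuts <- find_cut_positions(rec$ungapped_seq, enzyme)
    first <- which(ref_cuts$positions >= pstart)[1]
    ref_frag <- if (is.na(first)) NA_integer_
                else as.integer(ref_cuts$positions[first] - pstart + 1L)
    g <- compute_gap(aln, pstart)
    if (g$upstream) flags <- c(flags, "upstream-clamped")

    # Sample-side cut search starts at the sample's first base; under an
    # upstream-extending alignment, at the base aligned to the primer.
    label_pos <- 1L
    if (g$upstream) {
      label_pos <- aln$sample_start + (pstart - aln$ref_start)
      if (label_pos < 1L) label_pos <- 1L
    }
    samp_frag <- if (label_pos <= nchar(sample)) {
      cuts <- sample_cuts$positions
      cuts <- cuts[cuts >= label_pos]
      if (length(cuts) > 0L) as.integer(cuts[1L] - label_pos + 1L)
      else NA_integer_
    } else NA_integer_

    # The sample can only detect the reference's first cut if the whole
    # recognition site lies inside the aligned region: a cut whose site
    # straddles the truncation point is as invisible to the sample as one
    # entirely inside the gap.
    cut_in_gap <- !is.na(ref_frag) &&
      (ref_cuts$positions[first] < aln$ref_start ||
         ref_cuts$site_starts[first] < aln$ref_start)
    if (cut_in_gap) flags <- c(flags, "cut-in-gap")

    if (!cut_in_gap && !is.na(samp_frag)) {
      method <- "sample-site"
      est <- g$gap + samp_frag
    } else {
      method <- "reference-estimated"
      est <- ref_frag
      if (is.na(ref_frag)) flags <- c(flags, "no-cut-site")
    }

    data.frame(sample_id = sample_id, enzyme = enzyme$name,
               best_hit_id = h$ref_id,
               ref_fragment_length = ref_frag,
               est_fragment_length = as.integer(est),
               gap_length = g$gap,
               percent_identity = pid,
               lineage = rec$lineage,
               method = method,
               flags = paste(flags, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
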