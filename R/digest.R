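# In silico restriction digestion on the labeled strand.
#
# A "cut at p" means cleavage of the labeled (top) strand between bases p
# and p+1 (1-based). Capillary electrophoresis sizes only the labeled
# strand, so fragment arithmetic uses top-strand cut coordinates alone.

#' Locate labeled-strand cut positions of an enzyme on a sequence
#'
#' Top-strand matches of the recognition site at 1-based start `s` cut at
#' `s - 1 + cut_offset_top`; matches of the reverse complement of the site
#' (the site sitting on the bottom strand) cut the labeled strand at
#' `s - 1 + (site_length - cut_offset_bottom)`. For palindromic sites both
#' match sets coincide and so do the derived cuts; duplicates are merged.
#' Overlapping site occurrences all count. Cuts falling outside
#' `[0, nchar(seq)]` (outside cutters near sequence ends) are discarded
#' with a warning.
#'
#' @param seq Concrete nucleotide string.
#' @param enzyme An [enzyme_spec()].
#' @return An object of class `cut_list`: list with `enzyme`, `positions`
#'   (strictly increasing integer vector) and `site_starts` (parallel to
#'   `positions`: leftmost start of a recognition-site occurrence giving
#'   rise to each cut, used to decide whether a cut is detectable on a
#'   truncated sequence).
#' @examples
#' hha <- enzyme_spec("HhaI", "GCG^C")
#' find_cut_positions("AATTGCGCAATT", hha)$positions  # 7
#' @export
find_cut_positions <- function(seq, enzyme) {
  stopifnot(inherits(enzyme, "enzyme_spec"))
  seq <- toupper(seq)
  len <- nchar(seq)
  L <- nchar(enzyme$site)
  top <- .fuzzy_scan(seq, enzyme$site, 0L)$start
  rcsite <- reverse_complement(enzyme$site)
  bot <- .fuzzy_scan(seq, rcsite, 0L)$start
  cuts <- c(top - 1L + enzyme$cut_offset_top,
            bot - 1L + (L - enzyme$cut_offset_bottom))
  starts <- c(top, bot)
  keep <- cuts >= 0L & cuts <= len
  if (any(!keep))
    warning(sprintf("%s: %d cut(s) fell outside [0, %d] and were discarded",
                    enzyme$name, sum(!keep), len))
  cuts <- cuts[keep]
  starts <- starts[keep]
  if (length(cuts) > 0L) {
    sstart <- vapply(split(starts, cuts), min, integer(1))
    cuts <- sort(unique(cuts))
    starts <- unname(sstart[as.character(cuts)])
  }
  structure(list(enzyme = enzyme, positions = as.integer(cuts),
                 site_starts = as.integer(starts)),
            class = "cut_list")
}

#' @export
print.cut_list <- function(x, ...) {
  cat(sprintf("<cut_list> %s: %d cut(s)%s\n", x$enzyme$name,
              length(x$positions),
              if (length(x$positions) > 0)
                paste0(" at ", paste(utils::head(x$positions, 10), collapse = ", "),
                       if (length(x$positions) > 10) ", ..." else "")
              else ""))
  invisible(x)
}

#' Terminal restriction fragment length on the labeled strand
#'
#' Length, in nucleotides, from the labeled 5' base through the last base
#' before the first cut at or after it: `(first p >= label_pos) -
#' label_pos + 1`. `NA` when no cut lies at or after `label_pos`.
#'
#' @param seq Concrete nucleotide string.
#' @param label_pos 1-based position of the fluorescently labeled 5' base
#'   (the primer's first base).
#' @param enzyme An [enzyme_spec()], or a precomputed [find_cut_positions()]
#'   result for `seq`.
#' @return Integer length, or `NA_integer_`.
#' @export
terminal_fragment <- function(seq, label_pos, enzyme) {
  len <- nchar(seq)
  stopifnot(label_pos >= 1L, label_pos <= len)
  cuts <- if (inherits(enzyme, "cut_list")) enzyme$positions
          else find_cut_positions(seq, enzyme)$positions
  cuts <- cuts[cuts >= label_pos]
  if (length(cuts) == 0L) return(NA_integer_)
  as.integer(cuts[1L] - label_pos + 1L)
}

#' Full digestion fragment lengths
#'
#' Partitions the sequence at every internal cut position; fragment
#' lengths sum to the sequence length. Cuts at position 0 or at the full
#' sequence length do not create additional fragments.
#'
#' @inheritParams terminal_fragment
#' @return Integer vector of fragment lengths, 5' to 3'.
#' @export
full_digest <- function(seq, enzyme) {
  len <- nchar(seq)
  cuts <- if (inherits(enzyme, "cut_list")) enzyme$positions
          else find_cut_positions(seq, enzyme)$positions
  cuts <- cuts[cuts > 0L & cuts < len]
  as.integer(diff(c(0L, cuts, len)))
}
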