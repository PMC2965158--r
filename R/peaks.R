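# Observed chromatogram peaks: loading, matching to predictions,
# multi-enzyme consensus and taxon tallies.

#' Load an observed peak table
#'
#' CSV with header; a `size` column is required, `height` and `area` are
#' optional. Rows with missing or negative sizes are rejected with a
#' diagnostic. Peaks are sorted by size.
#'
#' @param path CSV file path.
#' @param enzyme Enzyme name the chromatogram was generated with.
#' @return Object of class `peak_table`: list with `enzyme` and `peaks`
#'   (data frame `size`, `height`, `area`).
#' @export
load_peak_table <- function(path, enzyme) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"size" %in% names(df))
    stop(sprintf("%s: peak CSV must have a 'size' column", path), call. = FALSE)
  if (!"height" %in% names(df)) df$height <- NA_real_
  if (!"area" %in% names(df)) {
    df$area <- NA_real_
    warning(sprintf("%s: no 'area' column; relative-abundance operations disabled",
                    path))
  }
  size <- suppressWarnings(as.numeric(df$size))
  bad <- which(is.na(size) | size < 0)
  if (length(bad) > 0L)
    warning(sprintf("%s: %d row(s) rejected (missing or negative size): rows %s",
                    path, length(bad), paste(bad, collapse = ", ")))
  keep <- setdiff(seq_len(nrow(df)), bad)
  if (length(keep) == 0L)
    stop(sprintf("%s: no parsable peak rows", path), call. = FALSE)
  peaks <- data.frame(size = size[keep],
                      height = suppressWarnings(as.numeric(df$height[keep])),
                      area = suppressWarnings(as.numeric(df$area[keep])))
  peaks <- peaks[order(peaks$size), , drop = FALSE]
  rownames(peaks) <- NULL
  structure(list(enzyme = enzyme, peaks = peaks), class = "peak_table")
}

#' @export
print.peak_table <- function(x, ...) {
  cat(sprintf("<peak_table> %s: %d peak(s), sizes %.1f-%.1f nt\n", x$enzyme,
              nrow(x$peaks), min(x$peaks$size), max(x$peaks$size)))
  invisible(x)
}

#' Match T-RF predictions to observed peaks
#'
#' Each prediction with a finite estimated length is matched to the
#' nearest peak within `tolerance` nt; when two peaks are equally near,
#' the smaller size wins. Several predictions may share one peak
#' (distinct taxa can share a T-RF). Predictions without a peak in range
#' are left unmatched (dropped from the result).
#'
#' @param predictions Data frame from [predict_trf()], same enzyme as the
#'   table (rows for other enzymes are dropped with a warning).
#' @param table A [load_peak_table()] result.
#' @param tolerance Maximum |observed - predicted| in nt (default 2).
#' @return Data frame of class `peak_match` with columns `sample_id`,
#'   `enzyme`, `peak_size`, `predicted`, `delta`, `lineage`.
#' @export
match_to_peaks <- function(predictions, table, tolerance = 2) {
  stopifnot(inherits(table, "peak_table"))
  if (any(predictions$enzyme != table$enzyme)) {
    warning("dropping prediction rows for other enzymes than the peak table's")
    predictions <- predictions[predictions$enzyme == table$enzyme, , drop = FALSE]
  }
  predictions <- predictions[!is.na(predictions$est_fragment_length), ,
                             drop = FALSE]
  sizes <- table$peaks$size
  rows <- lapply(seq_len(nrow(predictions)), function(i) {
    pred <- predictions$est_fragment_length[i]
    d <- abs(sizes - pred)
    j <- which(d == min(d))
    j <- j[which.min(sizes[j])]   # tie -> smaller peak size
    if (d[j] > tolerance) return(NULL)
    data.frame(sample_id = predictions$sample_id[i], enzyme = table$enzyme,
               peak_size = sizes[j], predicted = pred,
               delta = sizes[j] - pred, lineage = predictions$lineage[i],
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows) > 0L) do.call(rbind, rows)
         else data.frame(sample_id = character(0), enzyme = character(0),
                         peak_size = numeric(0), predicted = numeric(0),
                         delta = numeric(0), lineage = character(0))
  rownames(out) <- NULL
  class(out) <- c("peak_match", "data.frame")
  out
}

#' Multi-enzyme consensus of peak-matched samples
#'
#' A sample is accepted when its predicted T-RF matched an observed peak
#' under at least `required` distinct enzymes. Fingerprints digested with
#' a single enzyme often cannot separate broad phylogenetic groups that
#' happen to share a fragment size; requiring agreement across two or
#' more enzymes sharpens the taxon lists attached to each peak.
#'
#' @param matches_by_enzyme Named list of [match_to_peaks()] results, one
#'   per enzyme.
#' @param required Minimum number of distinct enzymes (default: all).
#' @return Sorted character vector of accepted sample ids.
#' @export
multi_enzyme_consensus <- function(matches_by_enzyme,
                                   required = length(matches_by_enzyme)) {
  n_enz <- length(matches_by_enzyme)
  if (required < 1L) stop("required must be >= 1", call. = FALSE)
  if (required > n_enz)
    stop(sprintf("required (%d) exceeds number of enzyme tables (%d)",
                 required, n_enz), call. = FALSE)
  ids <- unlist(lapply(matches_by_enzyme,
                       function(m) unique(m$sample_id)), use.names = FALSE)
  tab <- table(ids)
  sort(names(tab)[tab >= required])
}

#' Tally taxa among consensus-accepted samples
#'
#' Counts accepted samples per lineage (truncated to `rank`), descending,
#' with a `Total` row equal to the consensus set size. Each sample
#' contributes the lineage of its top-ranked prediction.
#'
#' @param consensus_ids Character vector from [multi_enzyme_consensus()].
#' @param predictions Data frame from [predict_trf()] covering the ids.
#' @param rank Taxonomy depth for grouping (default: full lineage).
#' @return Data frame with columns `taxon`, `n_sequences`; last row is
#'   `Total`.
#' @export
tally_taxa <- function(consensus_ids, predictions, rank = Inf) {
  if (length(consensus_ids) == 0L)
    return(data.frame(taxon = "Total", n_sequences = 0L,
                      stringsAsFactors = FALSE))
  first_idx <- match(consensus_ids, predictions$sample_id)
  if (anyNA(first_idx))
    stop("every consensus id must have a prediction row", call. = FALSE)
  lin <- vapply(predictions$lineage[first_idx], assign_taxonomy, "",
                rank = rank, USE.NAMES = FALSE)
  tab <- sort(table(lin), decreasing = TRUE)
  out <- data.frame(taxon = names(tab), n_sequences = as.integer(tab),
                    stringsAsFactors = FALSE)
  rbind(out, data.frame(taxon = "Total",
                        n_sequences = length(consensus_ids),
                        stringsAsFactors = FALSE))
}

#' Per-peak relative abundance from peak areas
#'
#' Peak area is proportional to the T-RF's abundance in the amplicon
#' pool; fractions of total area serve as a relative-abundance proxy.
#'
#' @param table A [load_peak_table()] result with areas present.
#' @return The peak data frame with an added `fraction` column summing
#'   to 1.
#' @export
relative_abundance <- function(table) {
  stopifnot(inherits(table, "peak_table"))
  areas <- table$peaks$area
  if (all(is.na(areas)))
    stop("peak table has no areas; cannot compute relative abundance",
         call. = FALSE)
  total <- sum(areas, na.rm = TRUE)
  if (total <= 0) stop("total peak area is zero", call. = FALSE)
  out <- table$peaks
  out$fraction <- ifelse(is.na(areas), NA_real_, areas / total)
  out
}

#' Fit and apply a linear drift correction to observed peak sizes
#'
#' Observed fragment sizes drift linearly against true sizes on some
#' instruments (`observed = a + b * predicted`). Given user-supplied
#' anchor pairs, fits the drift by least squares and returns a corrected
#' copy of the peak table (`size` mapped through the inverse line). Off
#' by default in the pipeline; apply explicitly before matching when
#' anchors are available.
#'
#' @param table A [load_peak_table()] result.
#' @param anchors Data frame with columns `observed` and `predicted`
#'   (at least two rows).
#' @return A corrected `peak_table`; the fitted coefficients are attached
#'   as attribute `"drift"`.
#' @export
drift_correct <- function(table, anchors) {
  stopifnot(inherits(table, "peak_table"),
            all(c("observed", "predicted") %in% names(anchors)),
            nrow(anchors) >= 2L)
  fit <- stats::lm(observed ~ predicted, data = anchors)
  a <- stats::coef(fit)[1]
  b <- stats::coef(fit)[2]
  if (abs(b) < 1e-12) stop("degenerate drift fit (zero slope)", call. = FALSE)
  out <- table
  out$peaks$size <- (table$peaks$size - a) / b
  attr(out, "drift") <- c(intercept = unname(a), slope = unname(b))
  out
}
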