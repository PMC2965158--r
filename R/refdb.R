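# Augmented reference 16S database: parse, index, subset.
#
# The reference flat file is FASTA whose headers carry the taxonomy
# lineage and the first/last non-gap alignment columns of each sequence
# in its source multiple alignment:
#
#   >ACC0001|Bacteria;Proteobacteria;...;Roseobacter|25|1480
#   --ACGT-ACGT...
#
# This dialect is this package's own (the delimiters are configurable);
# upstream databases do not publish one. Bodies may contain '-' and '.'
# gap characters; sequences are upper-cased and U mapped to T on ingest.

.GAP_CHARS_RE <- "[-.]"

#' Parse an augmented reference FASTA file
#'
#' One record per entry. Malformed headers (wrong field count, empty
#' lineage, non-numeric or inconsistent alignment positions, domain other
#' than Bacteria/Archaea) are skipped; diagnostics carrying the offending
#' header and its line number are attached as the `"diagnostics"`
#' attribute and summarized in a warning.
#'
#' @param path FASTA file path.
#' @param field_sep Header field delimiter (default `"|"`).
#' @param lineage_sep Separator between lineage ranks (default `";"`).
#' @return A data frame of class `trf_refdb` with columns `id`, `lineage`,
#'   `aligned_seq`, `ungapped_seq`, `first_nongap_fwd`, `first_nongap_rev`.
#' @export
parse_reference_fasta <- function(path, field_sep = "|", lineage_sep = ";") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  seqs <- Biostrings::readBStringSet(path)
  empty <- data.frame(id = character(0), lineage = character(0),
                      aligned_seq = character(0), ungapped_seq = character(0),
                      first_nongap_fwd = integer(0), first_nongap_rev = integer(0),
                      stringsAsFactors = FALSE)
  class(empty) <- c("trf_refdb", "data.frame")
  if (length(seqs) == 0L) {
    warning(sprintf("no FASTA entries in %s", path))
    return(empty)
  }
  header_lines <- grep("^>", readLines(path))

  recs <- vector("list", length(seqs))
  diags <- character(0)
  for (i in seq_along(seqs)) {
    header <- names(seqs)[i]
    line <- header_lines[i]
    fields <- strsplit(header, field_sep, fixed = TRUE)[[1]]
    bad <- function(msg) sprintf("line %d: >%s -- %s", line, header, msg)
    if (length(fields) != 4L) {
      diags <- c(diags, bad("expected 4 '|'-separated fields")); next
    }
    lineage <- trimws(fields[2])
    if (nchar(lineage) == 0L) {
      diags <- c(diags, bad("missing taxonomy field")); next
    }
    domain <- strsplit(lineage, lineage_sep, fixed = TRUE)[[1]][1]
    if (!domain %in% c("Bacteria", "Archaea")) {
      diags <- c(diags, bad(sprintf("domain rank '%s' not Bacteria/Archaea", domain)))
      next
    }
    fwd <- suppressWarnings(as.integer(fields[3]))
    rev <- suppressWarnings(as.integer(fields[4]))
    if (is.na(fwd) || is.na(rev)) {
      diags <- c(diags, bad("non-numeric alignment position fields")); next
    }
    aligned <- chartr("uU", "tT", as.character(seqs[[i]]))
    aligned <- toupper(aligned)
    if (!(fwd >= 1L && fwd <= rev && rev <= nchar(aligned))) {
      diags <- c(diags, bad(sprintf(
        "alignment positions %d/%d inconsistent with length %d",
        fwd, rev, nchar(aligned)))); next
    }
    ungapped <- gsub(.GAP_CHARS_RE, "", aligned)
    ok <- tryCatch({ .check_iupac(ungapped, sprintf("record '%s'", fields[1])); TRUE },
                   error = function(e) { diags <<- c(diags, bad(conditionMessage(e))); FALSE })
    if (!ok) next
    recs[[i]] <- data.frame(id = fields[1], lineage = lineage,
                            aligned_seq = aligned, ungapped_seq = ungapped,
                            first_nongap_fwd = fwd, first_nongap_rev = rev,
                            stringsAsFactors = FALSE)
  }
  recs <- recs[!vapply(recs, is.null, logical(1))]
  out <- if (length(recs) > 0L) do.call(rbind, recs) else empty
  rownames(out) <- NULL
  class(out) <- c("trf_refdb", "data.frame")
  if (length(diags) > 0L) {
    warning(sprintf("%d malformed record(s) skipped; see attr(x, 'diagnostics')",
                    length(diags)))
    attr(out, "diagnostics") <- diags
  }
  out
}

#' Write a reference database back to the augmented FASTA dialect
#'
#' Inverse of [parse_reference_fasta()]: re-parsing the written file
#' reproduces the records.
#'
#' @param db A `trf_refdb` data frame.
#' @param path Output file path.
#' @param field_sep,lineage_sep As in [parse_reference_fasta()].
#' @param width Line-wrap width for sequence bodies.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(db, path, field_sep = "|",
                                  lineage_sep = ";", width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(db))) {
    writeLines(paste0(">", paste(db$id[i], db$lineage[i],
                                 db$first_nongap_fwd[i], db$first_nongap_rev[i],
                                 sep = field_sep)), con)
    s <- db$aligned_seq[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Map an alignment column to an ungapped sequence position
#'
#' Returns the 1-based position in the ungapped sequence of the character
#' at alignment column `aligned_pos`, or `NA` when that column holds a gap
#' character.
#'
#' @param record One row of a `trf_refdb` data frame (or any list with an
#'   `aligned_seq` element).
#' @param aligned_pos 1-based alignment column.
#' @return Integer position or `NA_integer_`.
#' @export
aligned_to_ungapped <- function(record, aligned_pos) {
  aligned <- record$aligned_seq
  stopifnot(is.character(aligned), length(aligned) == 1L)
  n <- nchar(aligned)
  if (aligned_pos < 1L || aligned_pos > n)
    stop(sprintf("aligned_pos %d out of range for alignment of length %d",
                 aligned_pos, n), call. = FALSE)
  chars <- strsplit(aligned, "", fixed = TRUE)[[1]]
  isgap <- chars %in% c("-", ".")
  if (isgap[aligned_pos]) return(NA_integer_)
  as.integer(sum(!isgap[seq_len(aligned_pos)]))
}

#' Subset a reference database for one labeled primer
#'
#' Retains records whose domain (first lineage rank) matches, whose
#' ungapped length strictly exceeds the domain threshold (Bacteria 1200,
#' Archaea 900 by default), and in which [find_primer()] locates the
#' primer with at most `max_mismatch` mismatches. The best hit per record
#' (fewest mismatches, then leftmost) is stored as the anchor for later
#' gap arithmetic.
#'
#' @param records A `trf_refdb` data frame.
#' @param primer A [primer_spec()].
#' @param domain `"Bacteria"` or `"Archaea"`.
#' @param max_mismatch Maximum primer mismatches (default 1).
#' @param min_length Length threshold (strict `>`). Defaults to 1200 for
#'   Bacteria, 900 for Archaea.
#' @return An object of class `trf_subset`: list with `records` (filtered
#'   `trf_refdb`), `hits` (data frame `id`, `start`, `mismatches`),
#'   `primer`, `domain`, `min_length`, `max_mismatch`.
#' @export
build_subset <- function(records, primer, domain = c("Bacteria", "Archaea"),
                         max_mismatch = 1L, min_length = NULL) {
  domain <- match.arg(domain)
  stopifnot(inherits(primer, "primer_spec"))
  if (is.null(min_length))
    min_length <- if (domain == "Bacteria") 1200L else 900L

  dom <- vapply(strsplit(records$lineage, ";", fixed = TRUE), `[`, "", 1L)
  cand <- which(dom == domain & nchar(records$ungapped_seq) > min_length)

  keep <- integer(0)
  hits <- vector("list", 0L)
  for (i in cand) {
    h <- find_primer(records$ungapped_seq[i], primer, max_mismatch)
    if (nrow(h) == 0L) next
    h <- h[order(h$mismatches, h$start), , drop = FALSE][1L, , drop = FALSE]
    keep <- c(keep, i)
    hits[[length(hits) + 1L]] <- data.frame(id = records$id[i],
                                            start = h$start,
                                            mismatches = h$mismatches,
                                            stringsAsFactors = FALSE)
  }
  recs <- records[keep, , drop = FALSE]
  rownames(recs) <- NULL
  class(recs) <- c("trf_refdb", "data.frame")
  if (length(keep) == 0L)
    warning("no reference records satisfy the subset criteria")
  structure(list(records = recs,
                 hits = if (length(hits) > 0L) do.call(rbind, hits)
                        else data.frame(id = character(0), start = integer(0),
                                        mismatches = integer(0)),
                 primer = primer, domain = domain,
                 min_length = as.integer(min_length),
                 max_mismatch = as.integer(max_mismatch),
                 .cache = new.env(parent = emptyenv())),
            class = "trf_subset")
}

#' @export
print.trf_subset <- function(x, ...) {
  cat(sprintf("<trf_subset> %d %s record(s), primer %s (max %d mismatch), length > %d\n",
              nrow(x$records), x$domain, x$primer$name, x$max_mismatch,
              x$min_length))
  invisible(x)
}

# Primer anchor (1-based start on the ungapped reference) for record `id`.
.subset_primer_start <- function(subset, id) {
  j <- match(id, subset$hits$id)
  if (is.na(j)) NA_integer_ else subset$hits$start[j]
}
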