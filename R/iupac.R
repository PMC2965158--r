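# IUPAC nucleotide semantics, reverse complement, and fuzzy primer search.

#' @keywords internal
.IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

.IUPAC_ALPHABET <- names(.IUPAC_SETS)

.check_iupac <- function(seq, what = "sequence") {
  chars <- unique(strsplit(seq, "", fixed = TRUE)[[1]])
  bad <- setdiff(chars, .IUPAC_ALPHABET)
  if (length(bad) > 0L) {
    stop(sprintf("invalid IUPAC character(s) in %s: %s", what,
                 paste(sQuote(bad), collapse = ", ")), call. = FALSE)
  }
  invisible(seq)
}

#' Normalize a nucleotide string for analysis
#'
#' Upper-cases, maps RNA `U` to `T`, and validates against the 15-letter
#' IUPAC alphabet. Gap characters (`-`, `.`) are rejected here; strip them
#' first where they are expected (see [parse_reference_fasta()]).
#'
#' @param seq Character scalar, nucleotide sequence.
#' @param what Label used in error messages.
#' @return The normalized sequence.
#' @export
normalize_seq <- function(seq, what = "sequence") {
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- chartr("u", "t", toupper(seq))
  seq <- chartr("U", "T", seq)
  .check_iupac(seq, what)
  seq
}

#' Is a concrete base compatible with an IUPAC code?
#'
#' Asymmetric semantics: `code` is interpreted as a set of bases
#' (N = \{A,C,G,T\}, R = \{A,G\}, ...), `base` must be a concrete A/C/G/T.
#'
#' @param code IUPAC character (vectorized).
#' @param base Concrete base A, C, G or T (vectorized, recycled).
#' @return Logical vector.
#' @examples
#' iupac_compatible("N", "T")  # TRUE
#' iupac_compatible("R", "C")  # FALSE
#' @export
iupac_compatible <- function(code, base) {
  code <- toupper(code)
  base <- toupper(base)
  bad <- setdiff(unique(code), .IUPAC_ALPHABET)
  if (length(bad) > 0L)
    stop(sprintf("unknown IUPAC code(s): %s", paste(sQuote(bad), collapse = ", ")),
         call. = FALSE)
  bad <- setdiff(unique(base), c("A", "C", "G", "T"))
  if (length(bad) > 0L)
    stop(sprintf("base must be concrete A/C/G/T, got: %s",
                 paste(sQuote(bad), collapse = ", ")), call. = FALSE)
  mapply(function(co, ba) ba %in% .IUPAC_SETS[[co]], code, base,
         USE.NAMES = FALSE)
}

#' Reverse complement of an IUPAC nucleotide string
#'
#' Ambiguity codes are complemented under IUPAC rules (R <-> Y, W and S
#' self-complementary, N <-> N).
#'
#' @param seq IUPAC nucleotide string.
#' @return The reverse complement, same alphabet.
#' @examples
#' reverse_complement("ACGT")  # "ACGT"
#' reverse_complement("AAN")   # "NTT"
#' @export
reverse_complement <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  .check_iupac(seq, "sequence")
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Construct a primer specification
#'
#' @param name Primer name, e.g. `"27F"`.
#' @param sequence IUPAC nucleotide string, written 5' to 3'.
#' @param orientation `"forward"` or `"reverse"` relative to the sense
#'   strand of the gene.
#' @return An object of class `primer_spec`.
#' @export
primer_spec <- function(name, sequence, orientation = c("forward", "reverse")) {
  orientation <- match.arg(orientation)
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0L) stop("primer sequence must be non-empty", call. = FALSE)
  .check_iupac(sequence, sprintf("primer '%s'", name))
  structure(list(name = name, sequence = sequence, orientation = orientation),
            class = "primer_spec")
}

#' @export
print.primer_spec <- function(x, ...) {
  cat(sprintf("<primer_spec> %s: 5'-%s-3' (%s)\n", x$name, x$sequence,
              x$orientation))
  invisible(x)
}

#' Read a primer list from a TSV file
#'
#' Expected columns: `name`, `sequence`, `orientation` (tab-separated,
#' with header). The package ships a starter list of common 16S primers
#' in `system.file("extdata", "primers.tsv", package = "trftax")`;
#' these are convenience data, users should supply their own where needed.
#'
#' @param path File path.
#' @return Named list of [primer_spec()] objects.
#' @export
read_primers <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "sequence", "orientation")
  if (!all(need %in% names(df)))
    stop("primer file must have columns name, sequence, orientation", call. = FALSE)
  out <- lapply(seq_len(nrow(df)), function(i)
    primer_spec(df$name[i], df$sequence[i], df$orientation[i]))
  names(out) <- df$name
  out
}

# Core fuzzy scan: all windows of `pattern` length in `seq` with at most
# `max_mismatch` positions whose (concrete) subject base is NOT in the
# pattern code's set. Subject ambiguity letters never satisfy a pattern
# code, i.e. they are normalized to mismatches.
.fuzzy_scan <- function(seq, pattern, max_mismatch) {
  L <- nchar(seq)
  m <- nchar(pattern)
  if (m == 0L) stop("empty pattern", call. = FALSE)
  if (m > L) {
    warning("pattern longer than sequence; no windows to search")
    return(data.frame(start = integer(0), mismatches = integer(0)))
  }
  x <- strsplit(seq, "", fixed = TRUE)[[1]]
  p <- strsplit(pattern, "", fixed = TRUE)[[1]]
  W <- L - m + 1L
  mism <- integer(W)
  for (j in seq_len(m)) {
    mism <- mism + !(x[j:(j + W - 1L)] %in% .IUPAC_SETS[[p[j]]])
  }
  keep <- which(mism <= max_mismatch)
  data.frame(start = keep, mismatches = mism[keep])
}

#' Fuzzy primer search on a concrete nucleotide sequence
#'
#' Reports every window of primer length whose substitution-only distance
#' to the primer is at most `max_mismatch`. Primer IUPAC codes act as base
#' sets; subject bases must be concrete (any ambiguity letter in the
#' subject counts as a mismatch at that position). Reverse-orientation
#' primers are searched as their reverse complement on the sense strand,
#' so reported starts are always sense-strand coordinates of the window's
#' leftmost base.
#'
#' @param seq Concrete nucleotide string (A/C/G/T after ingest
#'   normalization; stray ambiguity letters are tolerated and treated as
#'   mismatches).
#' @param primer A [primer_spec()].
#' @param max_mismatch Maximum number of mismatching positions (default 1).
#' @return Data frame with columns `start` (1-based), `mismatches`,
#'   `strand` (always `"sense"`), sorted by position.
#' @export
find_primer <- function(seq, primer, max_mismatch = 1L) {
  stopifnot(inherits(primer, "primer_spec"), max_mismatch >= 0L)
  seq <- toupper(seq)
  .check_iupac(seq, "sequence")
  pat <- if (primer$orientation == "reverse")
    reverse_complement(primer$sequence) else primer$sequence
  hits <- .fuzzy_scan(seq, pat, as.integer(max_mismatch))
  hits$strand <- rep("sense", nrow(hits))
  hits
}
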