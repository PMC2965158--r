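# Restriction enzyme model: recognition site + cut offsets.
#
# Offset convention (REBASE-style, both offsets in top-strand coordinates
# of the canonical site): the top strand is cleaved after `cut_offset_top`
# bases from the site's 5' start; the bottom strand after
# `cut_offset_bottom` bases, still counted on the top strand. For HhaI
# (GCG^C) this is 3/1: top cut between site positions 3|4, bottom cut
# between 1|2 (2-nt 3' overhang). Palindromic enzymes therefore satisfy
# cut_offset_bottom == site_length - cut_offset_top, which makes the
# labeled-strand cut derived from a reverse-complement site match coincide
# with the top-strand cut of the same duplex site.

#' Construct a restriction enzyme specification
#'
#' The recognition site may contain IUPAC ambiguity codes and may carry a
#' caret marking the top-strand cut (`"GCG^C"`); the caret is stripped and
#' converted to `cut_offset_top` on ingest. Offsets may be negative or
#' exceed the site length for outside cutters.
#'
#' @param name Enzyme name, e.g. `"HhaI"`.
#' @param site IUPAC recognition pattern, optionally with `^` cut mark.
#' @param cut_offset_top Bases from the site's 5' start after which the
#'   top strand is cleaved. Ignored when `site` carries a caret.
#' @param cut_offset_bottom Same convention for the bottom-strand cut,
#'   measured on the top strand. Defaults to
#'   `nchar(site) - cut_offset_top`, exact for palindromic sites.
#' @return An object of class `enzyme_spec`.
#' @examples
#' enzyme_spec("HhaI", "GCG^C")
#' enzyme_spec("MspI", "CCGG", cut_offset_top = 1)
#' @export
enzyme_spec <- function(name, site, cut_offset_top = NULL,
                        cut_offset_bottom = NULL) {
  site <- toupper(site)
  if (grepl("^", site, fixed = TRUE)) {
    caret <- regexpr("^", site, fixed = TRUE)
    if (lengths(regmatches(site, gregexpr("\\^", site))) > 1L)
      stop("at most one '^' cut mark allowed in a site", call. = FALSE)
    cut_offset_top <- as.integer(caret) - 1L
    site <- sub("^", "", site, fixed = TRUE)
  }
  if (nchar(site) == 0L) stop("enzyme site must be non-empty", call. = FALSE)
  .check_iupac(site, sprintf("enzyme '%s' site", name))
  if (is.null(cut_offset_top))
    stop(sprintf("enzyme '%s': cut_offset_top missing and no '^' in site", name),
         call. = FALSE)
  cut_offset_top <- as.integer(cut_offset_top)
  if (is.null(cut_offset_bottom) || is.na(cut_offset_bottom))
    cut_offset_bottom <- nchar(site) - cut_offset_top
  structure(list(name = name, site = site,
                 cut_offset_top = cut_offset_top,
                 cut_offset_bottom = as.integer(cut_offset_bottom)),
            class = "enzyme_spec")
}

#' @export
print.enzyme_spec <- function(x, ...) {
  cat(sprintf("<enzyme_spec> %s: %s (top %d / bottom %d)\n",
              x$name, x$site, x$cut_offset_top, x$cut_offset_bottom))
  invisible(x)
}

#' Read restriction enzyme definitions from a flat file
#'
#' Tab-separated with header: `name`, `site`, `cut_offset_top`,
#' `cut_offset_bottom`. Sites may use `^` notation, in which case the
#' offset columns may be `NA`. A small curated set sufficient for common
#' 16S work ships with the package (see [default_enzymes()]); importing a
#' full REBASE dump into this format is a user-side extension point.
#'
#' @param path File path.
#' @return Named list of [enzyme_spec()] objects.
#' @export
read_enzymes <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("name", "site") %in% names(df)))
    stop("enzyme file must have at least columns name, site", call. = FALSE)
  if (!"cut_offset_top" %in% names(df)) df$cut_offset_top <- NA_integer_
  if (!"cut_offset_bottom" %in% names(df)) df$cut_offset_bottom <- NA_integer_
  out <- lapply(seq_len(nrow(df)), function(i) {
    top <- df$cut_offset_top[i]
    enzyme_spec(df$name[i], df$site[i],
                cut_offset_top = if (is.na(top)) NULL else top,
                cut_offset_bottom = df$cut_offset_bottom[i])
  })
  names(out) <- df$name
  out
}

#' Curated enzyme set shipped with the package
#'
#' CfoI/HhaI, HaeIII, AluI, MspI and RsaI: the 4-cutters most frequently
#' used in 16S rRNA T-RFLP fingerprinting.
#'
#' @return Named list of [enzyme_spec()] objects.
#' @export
default_enzymes <- function() {
  read_enzymes(system.file("extdata", "enzymes.tsv", package = "trftax",
                           mustWork = TRUE))
}
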