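# Independent brute-force oracles. These re-derive the IUPAC table and
# every algorithm from first principles, by plain loops, so that the
# package implementation is checked against a second, unrelated route.

ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

ORACLE_COMP <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
                 S = "S", W = "W", K = "M", M = "K", B = "V", V = "B",
                 D = "H", H = "D", N = "N")

oracle_revcomp <- function(seq) {
  chars <- rev(strsplit(seq, "", fixed = TRUE)[[1]])
  paste(ORACLE_COMP[chars], collapse = "")
}

# All windows of `seq` within `max_mm` substitution mismatches of the
# IUPAC `pattern`; subject letters outside A/C/G/T never match.
oracle_window_hits <- function(seq, pattern, max_mm) {
  x <- strsplit(seq, "", fixed = TRUE)[[1]]
  p <- strsplit(pattern, "", fixed = TRUE)[[1]]
  m <- length(p)
  out <- data.frame(start = integer(0), mismatches = integer(0))
  if (m > length(x)) return(out)
  for (s in 1:(length(x) - m + 1L)) {
    mm <- 0L
    for (j in seq_len(m)) {
      if (!(x[s + j - 1L] %in% ORACLE_IUPAC[[p[j]]])) mm <- mm + 1L
    }
    if (mm <= max_mm) out <- rbind(out, data.frame(start = s, mismatches = mm))
  }
  out
}

# Labeled-strand cuts by scanning every window on both site orientations.
oracle_cuts <- function(seq, site, top, bottom) {
  L <- nchar(site)
  len <- nchar(seq)
  cuts <- integer(0)
  fw <- oracle_window_hits(seq, site, 0L)$start
  cuts <- c(cuts, fw - 1L + top)
  rc <- oracle_window_hits(seq, oracle_revcomp(site), 0L)$start
  cuts <- c(cuts, rc - 1L + (L - bottom))
  cuts <- sort(unique(cuts))
  cuts[cuts >= 0L & cuts <= len]
}

# Textbook Gotoh affine-gap local alignment, score only. A gap of length
# L costs open + L * ext.
oracle_sw_score <- function(a, b, match = 5, mismatch = -4,
                            gap_open = 10, gap_extend = 0.5) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(av); m <- length(bv)
  H <- matrix(0, n + 1L, m + 1L)
  E <- matrix(-Inf, n + 1L, m + 1L)
  F_ <- matrix(-Inf, n + 1L, m + 1L)
  best <- 0
  for (i in 2:(n + 1L)) {
    for (j in 2:(m + 1L)) {
      s <- if (av[i - 1L] == bv[j - 1L]) match else mismatch
      E[i, j] <- max(H[i, j - 1L] - (gap_open + gap_extend),
                     E[i, j - 1L] - gap_extend)
      F_[i, j] <- max(H[i - 1L, j] - (gap_open + gap_extend),
                      F_[i - 1L, j] - gap_extend)
      H[i, j] <- max(0, H[i - 1L, j - 1L] + s, E[i, j], F_[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

# Minimal reference db construction without going through a file.
make_refdb <- function(ids, lineages, seqs) {
  df <- data.frame(id = ids, lineage = lineages, aligned_seq = seqs,
                   ungapped_seq = seqs,
                   first_nongap_fwd = 1L, first_nongap_rev = nchar(seqs),
                   stringsAsFactors = FALSE)
  class(df) <- c("trf_refdb", "data.frame")
  df
}

# A concrete 27F realization used by hand-built fixtures (M -> C).
PRIMER27F <- primer_spec("27F", "AGAGTTTGATCMTGGCTCAG")
PRIMER27F_SEQ <- "AGAGTTTGATCCTGGCTCAG"

# Background alphabet {A,T} cannot contain GCGC/GGCC/AGCT sites, giving
# full control over planted cut positions.
rand_at <- function(n) paste(sample(c("A", "T"), n, TRUE), collapse = "")

# Reference with sequence fully under control: A/T background, planted
# primer, and recognition sites planted at fixed offsets after the
# primer's first base. `sites` is a list of list(off=, site=) entries.
plant_ref <- function(id, sites, total = 1300, pad = 30,
                      lineage = "Bacteria;Proteobacteria;Alphaproteobacteria;Rhodobacterales;Roseobacter") {
  body <- paste0(rand_at(pad), PRIMER27F_SEQ,
                 rand_at(total - pad - nchar(PRIMER27F_SEQ)))
  for (s in sites) {
    at <- pad + s$off   # site starts `off` bases after the primer's first base
    substr(body, at + 1, at + nchar(s$site)) <- s$site
  }
  make_refdb(id, lineage, body)
}

# Shorthand for GCGC (CfoI) planting only.
make_ref <- function(id, cut_offsets, total = 1300, pad = 30,
                     lineage = "Bacteria;Proteobacteria;Alphaproteobacteria;Rhodobacterales;Roseobacter") {
  plant_ref(id, lapply(cut_offsets, function(o) list(off = o, site = "GCGC")),
            total = total, pad = pad, lineage = lineage)
}
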