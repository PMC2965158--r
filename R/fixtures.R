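# Synthetic community fixture generator.
#
# Emulates the study design the package targets: a reference database of
# full-length 16S sequences with known lineages, and partial clone reads
# amplified with a labeled primer whose first 10-30 nt are missing (the
# usual quality trim of directional Sanger reads). Every quantity is
# reproducible from a single seed.
#
# Mutation model: per-sample substitutions emulate evolutionary
# divergence between the sampled organism and its closest database
# relative. The truth table is therefore computed by digesting the
# sample's own (mutated, untruncated) amplicon while the reference stays
# clean. Substitutions are applied only downstream of a conserved block
# covering the primer and its flank (16S primers such as 27F sit in
# conserved regions; divergence concentrates in the variable regions).

.DEFAULT_TAXA <- c(
  "Bacteria;Proteobacteria;Alphaproteobacteria;Rhodobacterales;Roseobacter" = 0.3,
  "Bacteria;Proteobacteria;Alphaproteobacteria;Pelagibacterales;SAR11" = 0.3,
  "Bacteria;Cyanobacteria;Cyanophyceae;Synechococcales;Synechococcus" = 0.1,
  "Bacteria;Proteobacteria;Gammaproteobacteria;Oceanospirillales;SAR86" = 0.1,
  "Bacteria;Proteobacteria;Alphaproteobacteria;Puniceispirillales;SAR116" = 0.1,
  "Bacteria;Proteobacteria;Deltaproteobacteria;SAR324" = 0.1)

.random_bases <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Concrete realization of an IUPAC string (each code drawn uniformly
# from its base set).
.realize_iupac <- function(seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  paste(vapply(chars, function(ch) {
    s <- .IUPAC_SETS[[ch]]
    if (length(s) == 1L) s else sample(s, 1L)
  }, ""), collapse = "")
}

.substitute_base <- function(base) sample(setdiff(c("A", "C", "G", "T"), base), 1L)

#' Generate a reproducible synthetic community fixture
#'
#' Builds a reference database whose sequences carry a planted primer
#' site and at least one planted recognition site per enzyme (on top of
#' whatever sites occur by chance in the random background), draws
#' 5'-truncated sample reads from those references, and emits per-enzyme
#' peak tables containing the true T-RF sizes (with sub-nucleotide
#' jitter) plus decoy peaks.
#'
#' @param seed Integer seed; fixes every random draw.
#' @param n_refs Number of reference sequences (>= 2).
#' @param n_samples Number of sample reads.
#' @param taxa_profile Named numeric vector: lineage strings ->
#'   sampling weights. Defaults to a small marine bacterioplankton
#'   profile.
#' @param primer A [primer_spec()]; default 27F.
#' @param enzymes Named list of [enzyme_spec()]; default CfoI, HaeIII,
#'   AluI.
#' @param ref_length_range Ungapped reference length range (default
#'   1250-1450 nt, comfortably above the bacterial subset threshold).
#' @param pad_range Length range of reference sequence upstream of the
#'   primer site.
#' @param plant_range Offsets (relative to the primer's first base) at
#'   which one site per enzyme is planted.
#' @param trunc_range Range of 5'-truncation depths for sample reads
#'   (default 10-30 nt).
#' @param read_length Sample read length after truncation (nt).
#' @param mutation_rate Per-base substitution probability applied to each
#'   sample's amplicon (default 0 = clean copies).
#' @param mut_protect Conserved block length (nt, from the primer's first
#'   base) never mutated.
#' @param n_decoys Decoy peaks per enzyme table.
#' @param jitter Maximum absolute size jitter of true peaks (nt).
#' @return Object of class `trf_fixture`: list with `refs` (a
#'   `trf_refdb`), `samples` (named character vector), `truth` (data
#'   frame `sample_id`, `source_ref`, `trunc_depth`, `enzyme`,
#'   `true_trf`), `peaks` (named list of `peak_table`), `primer`,
#'   `enzymes`, `params`.
#' @export
generate_fixture <- function(seed, n_refs = 50L, n_samples = 200L,
                             taxa_profile = .DEFAULT_TAXA,
                             primer = primer_spec("27F", "AGAGTTTGATCMTGGCTCAG"),
                             enzymes = default_enzymes()[c("CfoI", "HaeIII", "AluI")],
                             ref_length_range = c(1250L, 1450L),
                             pad_range = c(20L, 60L),
                             plant_range = c(100L, 380L),
                             trunc_range = c(10L, 30L),
                             read_length = 450L,
                             mutation_rate = 0,
                             mut_protect = 40L,
                             n_decoys = 5L,
                             jitter = 0.5) {
  if (n_refs < 2L) stop("n_refs must be >= 2", call. = FALSE)
  if (is.null(names(taxa_profile)) || length(taxa_profile) < 1L)
    stop("taxa_profile must be a named weight vector", call. = FALSE)
  plen <- nchar(primer$sequence)
  min_amplicon <- ref_length_range[1] - pad_range[2]
  site_max <- max(vapply(enzymes, function(e) nchar(e$site), integer(1)))
  if (plant_range[2] + site_max > min_amplicon)
    stop("plant_range exceeds the amplicon; a planted T-RF would be longer than the amplicon",
         call. = FALSE)
  if (plant_range[1] <= plen + 8L)
    stop("plant_range must start downstream of the primer site", call. = FALSE)
  if (trunc_range[2] + 50L > read_length)
    stop("read_length too short for the requested truncation depths", call. = FALSE)

  has_seed <- exists(".Random.seed", envir = globalenv())
  if (has_seed) old_seed <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_seed) assign(".Random.seed", old_seed, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)

  # --- references -----------------------------------------------------
  lineages <- sample(names(taxa_profile), n_refs, replace = TRUE,
                     prob = taxa_profile)
  refs <- vector("list", n_refs)
  for (i in seq_len(n_refs)) {
    pad <- sample(pad_range[1]:pad_range[2], 1L)
    total <- sample(ref_length_range[1]:ref_length_range[2], 1L)
    body <- paste0(.random_bases(pad), .realize_iupac(primer$sequence),
                   .random_bases(total - pad - plen))
    # plant one site per enzyme at non-overlapping random offsets
    offsets <- integer(0)
    for (e in enzymes) {
      repeat {
        off <- sample(plant_range[1]:plant_range[2], 1L)
        if (all(abs(off - offsets) > site_max + 2L)) break
      }
      offsets <- c(offsets, off)
      site <- .realize_iupac(e$site)
      at <- pad + off   # site starts `off` bases after the primer's first base
      substr(body, at + 1L, at + nchar(site)) <- site
    }
    # fake model-alignment coordinates: leading '.' gaps + a few internal runs
    lead <- sample(0:40, 1L)
    aligned <- body
    for (g in seq_len(sample(0:2, 1L))) {
      at <- sample(seq(10L, nchar(aligned) - 10L), 1L)
      aligned <- paste0(substr(aligned, 1L, at), strrep("-", sample(1:5, 1L)),
                        substr(aligned, at + 1L, nchar(aligned)))
    }
    aligned <- paste0(strrep(".", lead), aligned)
    refs[[i]] <- data.frame(
      id = sprintf("REF%04d", i), lineage = lineages[i],
      aligned_seq = aligned, ungapped_seq = body,
      first_nongap_fwd = lead + 1L,
      first_nongap_rev = nchar(aligned),
      stringsAsFactors = FALSE)
  }
  refdb <- do.call(rbind, refs)
  class(refdb) <- c("trf_refdb", "data.frame")

  # primer anchor per reference (planted, so an exact hit exists)
  anchors <- vapply(seq_len(n_refs), function(i)
    find_primer(refdb$ungapped_seq[i], primer, 0L)$start[1L], integer(1))

  # --- samples and truth ----------------------------------------------
  sample_ids <- sprintf("S%04d", seq_len(n_samples))
  src <- sample(n_refs, n_samples, replace = TRUE)
  truncs <- sample(trunc_range[1]:trunc_range[2], n_samples, replace = TRUE)
  samples <- character(n_samples)
  truth <- vector("list", n_samples)
  for (j in seq_len(n_samples)) {
    i <- src[j]
    amp <- substr(refdb$ungapped_seq[i], anchors[i],
                  nchar(refdb$ungapped_seq[i]))
    if (mutation_rate > 0) {
      eligible <- seq(mut_protect + 1L, nchar(amp))
      hit <- eligible[stats::runif(length(eligible)) < mutation_rate]
      for (p in hit) substr(amp, p, p) <- .substitute_base(substr(amp, p, p))
    }
    samples[j] <- substr(amp, truncs[j] + 1L,
                         min(truncs[j] + read_length, nchar(amp)))
    truth[[j]] <- data.frame(
      sample_id = sample_ids[j], source_ref = refdb$id[i],
      trunc_depth = truncs[j],
      enzyme = vapply(enzymes, function(e) e$name, ""),
      true_trf = vapply(enzymes, function(e)
        terminal_fragment(amp, 1L, e), integer(1)),
      stringsAsFactors = FALSE)
  }
  names(samples) <- sample_ids
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL

  # --- peak tables ----------------------------------------------------
  peaks <- lapply(enzymes, function(e) {
    true_sizes <- sort(unique(truth$true_trf[truth$enzyme == e$name &
                                               !is.na(truth$true_trf)]))
    obs <- true_sizes + stats::runif(length(true_sizes), -jitter, jitter)
    decoys <- numeric(0)
    while (length(decoys) < n_decoys) {
      d <- stats::runif(1, 40, 700)
      if (all(abs(d - c(true_sizes, decoys)) > 3)) decoys <- c(decoys, d)
    }
    sizes <- c(obs, decoys)
    areas <- stats::rlnorm(length(sizes), meanlog = 8, sdlog = 1)
    tab <- data.frame(size = sizes, height = round(areas / 10), area = areas)
    tab <- tab[order(tab$size), , drop = FALSE]
    rownames(tab) <- NULL
    structure(list(enzyme = e$name, peaks = tab), class = "peak_table")
  })
  names(peaks) <- vapply(enzymes, function(e) e$name, "")

  structure(list(refs = refdb, samples = samples, truth = truth,
                 peaks = peaks, primer = primer, enzymes = enzymes,
                 params = list(seed = seed, n_refs = n_refs,
                               n_samples = n_samples,
                               mutation_rate = mutation_rate,
                               mut_protect = mut_protect,
                               trunc_range = trunc_range,
                               read_length = read_length,
                               plant_range = plant_range,
                               jitter = jitter)),
            class = "trf_fixture")
}

#' @export
print.trf_fixture <- function(x, ...) {
  cat(sprintf("<trf_fixture> %d refs, %d samples, enzymes: %s (seed %s)\n",
              nrow(x$refs), length(x$samples),
              paste(names(x$peaks), collapse = ", "), x$params$seed))
  invisible(x)
}

#' Write a fixture bundle to disk
#'
#' Emits `refs.fasta` (augmented-header dialect), `samples.fasta`,
#' `truth.tsv` and one `peaks_<enzyme>.csv` per enzyme.
#'
#' @param fixture A [generate_fixture()] result.
#' @param dir Output directory (created if needed).
#' @return Named list of written paths, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  stopifnot(inherits(fixture, "trf_fixture"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(refs = file.path(dir, "refs.fasta"),
                samples = file.path(dir, "samples.fasta"),
                truth = file.path(dir, "truth.tsv"))
  write_reference_fasta(fixture$refs, paths$refs)
  sset <- Biostrings::DNAStringSet(fixture$samples)
  Biostrings::writeXStringSet(sset, paths$samples)
  utils::write.table(fixture$truth, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  for (en in names(fixture$peaks)) {
    p <- file.path(dir, sprintf("peaks_%s.csv", en))
    utils::write.csv(fixture$peaks[[en]]$peaks, p, row.names = FALSE)
    paths[[paste0("peaks_", en)]] <- p
  }
  invisible(paths)
}
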