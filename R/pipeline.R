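# Non-interactive pipeline orchestration and TSV output.

#' Write predictions to a tab-delimited file
#'
#' Columns, in order: `sample_id`, `enzyme`, `best_hit_id`,
#' `ref_fragment_length`, `est_fragment_length`, `gap_length`,
#' `percent_identity`, `lineage`, `method`, `flags`. Absent values are
#' rendered `NA`; the file is UTF-8 with a header row.
#'
#' @param predictions Data frame from [predict_trf()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_predictions_tsv <- function(predictions, path) {
  cols <- c("sample_id", "enzyme", "best_hit_id", "ref_fragment_length",
            "est_fragment_length", "gap_length", "percent_identity",
            "lineage", "method", "flags")
  stopifnot(all(cols %in% names(predictions)))
  con <- tryCatch(file(path, "w", encoding = "UTF-8"),
                  error = function(e) stop(sprintf("cannot write %s: %s", path,
                                                   conditionMessage(e)),
                                           call. = FALSE))
  on.exit(close(con))
  utils::write.table(predictions[, cols], con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a predictions TSV written by [write_predictions_tsv()]
#'
#' @param path File path.
#' @return Data frame with the prediction columns and their types
#'   restored.
#' @export
read_predictions_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "NA",
                          colClasses = c(sample_id = "character",
                                         enzyme = "character",
                                         best_hit_id = "character",
                                         ref_fragment_length = "integer",
                                         est_fragment_length = "integer",
                                         gap_length = "integer",
                                         percent_identity = "numeric",
                                         lineage = "character",
                                         method = "character",
                                         flags = "character"))
  df$flags[is.na(df$flags)] <- ""
  df
}

.resolve_enzymes <- function(config) {
  bank <- if (!is.null(config$enzyme_file)) read_enzymes(config$enzyme_file)
          else default_enzymes()
  wanted <- config$enzymes
  if (is.null(wanted)) stop("config must name at least one enzyme", call. = FALSE)
  missing <- setdiff(wanted, names(bank))
  if (length(missing) > 0L)
    stop(sprintf("unknown enzyme(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  bank[wanted]
}

.resolve_primer <- function(config) {
  p <- config$primer
  if (inherits(p, "primer_spec")) return(p)
  if (is.list(p) && !is.null(p$sequence))
    return(primer_spec(p$name %||% "primer", p$sequence,
                       p$orientation %||% "forward"))
  if (is.character(p) && length(p) == 1L) {
    file <- config$primer_file %||%
      system.file("extdata", "primers.tsv", package = "trftax", mustWork = TRUE)
    bank <- read_primers(file)
    if (!p %in% names(bank))
      stop(sprintf("unknown primer '%s' in %s", p, file), call. = FALSE)
    return(bank[[p]])
  }
  stop("config$primer must be a primer_spec, a list with $sequence, or a primer name",
       call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full prediction pipeline
#'
#' Reads references and samples, builds the primer-specific reference
#' subset, finds the closest references per sample, predicts T-RF sizes
#' per enzyme, and (when peak tables are supplied) matches predictions to
#' observed peaks, applies the multi-enzyme consensus and tallies taxa.
#' Outputs are written under `config$out_dir`: `predictions.tsv`,
#' optional per-hit alignment dumps, `matches_<enzyme>.tsv`, `tally.tsv`
#' and `run.log`.
#'
#' Reverse-primer runs are handled by a single code path: the references
#' are reverse-complemented so the labeled primer reads forward, and the
#' sample reads -- assumed to be written 5' to 3' from the labeling
#' primer's end, as directional clone reads are -- are used as given.
#'
#' A per-sample failure is logged and the run continues; the call errors
#' only if every sample fails.
#'
#' @param config A named list or a YAML file path. Recognized keys:
#'   `ref_fasta`, `sample_fasta`, `out_dir`, `primer` (name, list or
#'   [primer_spec()]), `primer_file`, `enzymes` (character names),
#'   `enzyme_file`, `domain`, `max_mismatch`, `min_length`, `n_hits`,
#'   `k`, `top_m`, `min_identity`, `tolerance`, `peak_tables` (named
#'   list enzyme -> CSV path), `consensus_required`, `tally_rank`,
#'   `write_alignments`.
#' @param overrides Named list merged over `config` (CLI flags).
#' @return Invisibly, a list with `predictions`, `matches`, `consensus`,
#'   `tally`, `subset` and `paths`.
#' @export
run_pipeline <- function(config, overrides = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config[names(overrides)] <- overrides

  for (key in c("ref_fasta", "sample_fasta", "out_dir"))
    if (is.null(config[[key]]))
      stop(sprintf("config key '%s' is required", key), call. = FALSE)

  enzymes <- .resolve_enzymes(config)
  primer <- .resolve_primer(config)
  domain <- config$domain %||% "Bacteria"
  max_mismatch <- config$max_mismatch %||% 1L
  n_hits <- config$n_hits %||% 1L
  k <- config$k %||% 11L
  top_m <- config$top_m %||% 25L
  min_identity <- config$min_identity %||% 80
  tolerance <- config$tolerance %||% 2
  tally_rank <- config$tally_rank %||% Inf

  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  logf <- file(log_path, "w")
  on.exit(close(logf))
  logmsg <- function(fmt, ...) {
    writeLines(sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                       sprintf(fmt, ...)), logf)
  }
  logmsg("parameters: primer=%s(%s,%s) enzymes=%s domain=%s max_mismatch=%d n_hits=%d k=%d top_m=%d min_identity=%s tolerance=%s",
         primer$name, primer$sequence, primer$orientation,
         paste(names(enzymes), collapse = ","), domain, max_mismatch,
         n_hits, k, top_m, min_identity, tolerance)

  refs <- parse_reference_fasta(config$ref_fasta)
  sset <- Biostrings::readBStringSet(config$sample_fasta)
  samples <- toupper(chartr("uU", "tT", as.character(sset)))
  names(samples) <- vapply(strsplit(names(sset), "\\s+"), `[`, "", 1L)
  logmsg("loaded %d reference(s), %d sample(s)", nrow(refs), length(samples))

  if (primer$orientation == "reverse") {
    refs$ungapped_seq <- vapply(refs$ungapped_seq, reverse_complement, "",
                                USE.NAMES = FALSE)
    primer <- primer_spec(primer$name, primer$sequence, "forward")
    logmsg("reverse primer: references reverse-complemented, one forward code path")
  }

  subset <- build_subset(refs, primer, domain = domain,
                         max_mismatch = max_mismatch,
                         min_length = config$min_length)
  logmsg("subset: %d record(s) retained", nrow(subset$records))
  if (nrow(subset$records) == 0L)
    stop("reference subset is empty; nothing to predict against", call. = FALSE)

  aln_dir <- file.path(out_dir, "alignments")
  if (isTRUE(config$write_alignments))
    dir.create(aln_dir, showWarnings = FALSE)

  preds <- list()
  n_failed <- 0L
  for (sid in names(samples)) {
    res <- tryCatch({
      hits <- best_hits(samples[[sid]], subset, n = n_hits, k = k,
                        top_m = top_m)
      if (isTRUE(config$write_alignments) && length(hits) > 0L) {
        for (h in hits)
          write_alignment_text(h$alignment,
                               file.path(aln_dir, sprintf("%s_hit%d.txt", sid, h$rank)),
                               sample_id = sid, ref_id = h$ref_id)
      }
      do.call(rbind, lapply(enzymes, function(e)
        predict_trf(samples[[sid]], sid, e, subset, n_hits = n_hits,
                    hits = hits, min_identity = min_identity)))
    }, error = function(e) {
      logmsg("ERROR sample %s: %s", sid, conditionMessage(e))
      NULL
    })
    if (is.null(res)) n_failed <- n_failed + 1L else preds[[sid]] <- res
  }
  if (length(preds) == 0L)
    stop("all samples failed; see run.log", call. = FALSE)
  predictions <- do.call(rbind, preds)
  rownames(predictions) <- NULL
  logmsg("predicted %d row(s); %d sample(s) failed", nrow(predictions), n_failed)

  paths <- list(predictions = file.path(out_dir, "predictions.tsv"),
                log = log_path)
  write_predictions_tsv(predictions, paths$predictions)

  matches <- NULL
  consensus <- NULL
  tally <- NULL
  if (!is.null(config$peak_tables)) {
    matches <- list()
    for (en in names(config$peak_tables)) {
      if (!en %in% names(enzymes))
        stop(sprintf("peak table given for unknown enzyme '%s'", en), call. = FALSE)
      tab <- load_peak_table(config$peak_tables[[en]], en)
      m <- match_to_peaks(predictions[predictions$enzyme == en, , drop = FALSE],
                          tab, tolerance = tolerance)
      matches[[en]] <- m
      p <- file.path(out_dir, sprintf("matches_%s.tsv", en))
      utils::write.table(m, p, sep = "\t", quote = FALSE, row.names = FALSE)
      paths[[paste0("matches_", en)]] <- p
      logmsg("enzyme %s: %d match(es) within +/-%s nt (tolerance noted in header)",
             en, nrow(m), tolerance)
    }
    required <- config$consensus_required %||% length(matches)
    consensus <- multi_enzyme_consensus(matches, required = required)
    tally <- tally_taxa(consensus, predictions, rank = tally_rank)
    paths$tally <- file.path(out_dir, "tally.tsv")
    con <- file(paths$tally, "w")
    writeLines(sprintf("# consensus over >=%d of %d enzyme(s); tolerance +/-%s nt",
                       required, length(matches), tolerance), con)
    utils::write.table(tally, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
    logmsg("consensus: %d sample(s) over >=%d enzyme(s)", length(consensus),
           required)
  }

  invisible(list(predictions = predictions, matches = matches,
                 consensus = consensus, tally = tally, subset = subset,
                 paths = paths))
}
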