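write_peaks_csv <- function(df) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  utils::write.csv(df, path, row.names = FALSE)
  path
}

pred_row <- function(id, enzyme, est, lineage = "Bacteria;X") {
  data.frame(sample_id = id, enzyme = enzyme, best_hit_id = "R",
             ref_fragment_length = est, est_fragment_length = est,
             gap_length = 0L, percent_identity = 100, lineage = lineage,
             method = "sample-site", flags = "", stringsAsFactors = FALSE)
}

test_that("peak tables load, sort and reject bad rows", {
  p <- write_peaks_csv(data.frame(size = c(150.2, 63.0),
                                  height = c(900, 400), area = c(12000, 5100)))
  tab <- load_peak_table(p, "CfoI")
  expect_equal(tab$peaks$size, c(63.0, 150.2))

  p <- write_peaks_csv(data.frame(size = c(100, -5, 200)))
  expect_warning(expect_warning(tab <- load_peak_table(p, "CfoI"), "rejected"),
                 "relative-abundance")
  expect_equal(tab$peaks$size, c(100, 200))

  p <- write_peaks_csv(data.frame(size = c(-1, -2), area = c(1, 1)))
  expect_warning(expect_error(load_peak_table(p, "CfoI"), "no parsable"))
})

test_that("predictions match the nearest peak within tolerance, ties to the smaller", {
  tab <- structure(list(enzyme = "CfoI",
                        peaks = data.frame(size = c(98.5, 101.5, 150),
                                           height = NA_real_, area = NA_real_)),
                   class = "peak_table")
  m <- match_to_peaks(pred_row("a", "CfoI", 148.7), tab, tolerance = 2)
  expect_equal(m$peak_size, 150)
  expect_equal(m$delta, 1.3)

  m <- match_to_peaks(pred_row("a", "CfoI", 148.7), tab, tolerance = 1)
  expect_equal(nrow(m), 0L)

  m <- match_to_peaks(pred_row("a", "CfoI", 100), tab, tolerance = 2)
  expect_equal(m$peak_size, 98.5)   # |delta| 1.5 both sides -> smaller size

  expect_warning(match_to_peaks(pred_row("a", "HaeIII", 100), tab), "dropping")
})

test_that("matching is stable under permutation of prediction order", {
  tab <- structure(list(enzyme = "CfoI",
                        peaks = data.frame(size = c(60, 100, 140),
                                           height = NA_real_, area = NA_real_)),
                   class = "peak_table")
  preds <- do.call(rbind, lapply(1:8, function(i)
    pred_row(sprintf("s%d", i), "CfoI", sample(c(59, 61, 99, 139, 141), 1))))
  m1 <- match_to_peaks(preds, tab)
  m2 <- match_to_peaks(preds[sample(nrow(preds)), ], tab)
  m2 <- m2[order(match(m2$sample_id, m1$sample_id)), ]
  rownames(m2) <- NULL
  expect_equal(m1, m2)
  expect_true(all(abs(m1$delta) <= 2))
})

test_that("multi-enzyme consensus is the required-count filter", {
  mk <- function(ids) data.frame(sample_id = ids, stringsAsFactors = FALSE)
  ml <- list(CfoI = mk(c("a", "b", "c")), HaeIII = mk(c("a", "b")),
             AluI = mk("b"))
  expect_equal(multi_enzyme_consensus(ml, 3), "b")
  expect_equal(multi_enzyme_consensus(ml, 2), c("a", "b"))
  expect_equal(multi_enzyme_consensus(ml, 1), c("a", "b", "c"))
  expect_error(multi_enzyme_consensus(ml, 4), "exceeds")
  # sample matched under two of three enzymes is excluded at required = 3
  expect_false("a" %in% multi_enzyme_consensus(ml, 3))
})

test_that("consensus shrinks (weakly) as required grows, on random fixtures", {
  set.seed(71)
  for (trial in 1:30) {
    n_enz <- sample(2:4, 1)
    ids <- sprintf("s%02d", 1:12)
    ml <- lapply(seq_len(n_enz), function(i)
      data.frame(sample_id = sample(ids, sample(0:12, 1)),
                 stringsAsFactors = FALSE))
    names(ml) <- sprintf("E%d", seq_len(n_enz))
    # brute-force expected sets
    counts <- table(unlist(lapply(ml, function(m) unique(m$sample_id))))
    prev <- NULL
    for (req in seq_len(n_enz)) {
      got <- multi_enzyme_consensus(ml, req)
      expect_setequal(got, names(counts)[counts >= req])
      if (!is.null(prev)) expect_true(all(got %in% prev))
      prev <- got
    }
  }
})

test_that("taxon tallies are conserved and ordered", {
  preds <- rbind(pred_row("a", "CfoI", 100, "Bacteria;P;A;R;Roseobacter"),
                 pred_row("b", "CfoI", 100, "Bacteria;P;A;R;Roseobacter"),
                 pred_row("c", "CfoI", 100, "Bacteria;P;A;P2;SAR11"))
  t <- tally_taxa(c("a", "b", "c"), preds, rank = 5)
  expect_equal(t$taxon[1], "Bacteria;P;A;R;Roseobacter")
  expect_equal(t$n_sequences[t$taxon == "Total"], 3L)
  expect_equal(sum(t$n_sequences[t$taxon != "Total"]),
               t$n_sequences[t$taxon == "Total"])

  t0 <- tally_taxa(character(0), preds)
  expect_equal(t0$n_sequences, 0L)

  set.seed(72)
  for (trial in 1:20) {
    n <- sample(1:20, 1)
    preds <- do.call(rbind, lapply(seq_len(n), function(i)
      pred_row(sprintf("s%d", i), "CfoI", 100,
               sample(c("Bacteria;A", "Bacteria;B", "Bacteria;C"), 1))))
    ids <- sprintf("s%d", sample(n, sample(n, 1)))
    t <- tally_taxa(ids, preds)
    expect_equal(sum(t$n_sequences[t$taxon != "Total"]), length(ids))
  }
})

test_that("relative abundance normalizes peak areas", {
  tab <- structure(list(enzyme = "CfoI",
                        peaks = data.frame(size = c(1, 2), height = NA,
                                           area = c(3, 1))),
                   class = "peak_table")
  ra <- relative_abundance(tab)
  expect_equal(ra$fraction, c(0.75, 0.25))
  tab$peaks <- tab$peaks[1, ]
  expect_equal(relative_abundance(tab)$fraction, 1)
  set.seed(73)
  for (trial in 1:20) {
    tab$peaks <- data.frame(size = 1:5, height = NA,
                            area = stats::runif(5, 1, 100))
    expect_equal(sum(relative_abundance(tab)$fraction), 1, tolerance = 1e-9)
  }
  tab$peaks$area <- NA_real_
  expect_error(relative_abundance(tab), "no areas")
})

test_that("linear drift correction inverts a known size drift", {
  tab <- structure(list(enzyme = "CfoI",
                        peaks = data.frame(size = 2 + 1.01 * c(100, 200, 300),
                                           height = NA, area = NA)),
                   class = "peak_table")
  anchors <- data.frame(predicted = c(100, 300), observed = 2 + 1.01 * c(100, 300))
  fixed <- drift_correct(tab, anchors)
  expect_equal(fixed$peaks$size, c(100, 200, 300), tolerance = 1e-8)
  expect_equal(unname(attr(fixed, "drift")["slope"]), 1.01, tolerance = 1e-8)
})
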