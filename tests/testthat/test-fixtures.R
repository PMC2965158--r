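test_that("fixtures are byte-identical under a fixed seed", {
  f1 <- generate_fixture(seed = 1, n_refs = 6, n_samples = 8)
  f2 <- generate_fixture(seed = 1, n_refs = 6, n_samples = 8)
  expect_identical(f1, f2)
  f3 <- generate_fixture(seed = 2, n_refs = 6, n_samples = 8)
  expect_false(identical(f1$refs$ungapped_seq, f3$refs$ungapped_seq))
})

test_that("fixture generation does not disturb the caller's RNG stream", {
  set.seed(99)
  a <- runif(1)
  set.seed(99)
  invisible(generate_fixture(seed = 1, n_refs = 3, n_samples = 2))
  expect_identical(runif(1), a)
})

test_that("truth table agrees with digestion of the generated amplicons", {
  fx <- generate_fixture(seed = 3, n_refs = 8, n_samples = 20)
  anchors <- vapply(seq_len(nrow(fx$refs)), function(i)
    find_primer(fx$refs$ungapped_seq[i], fx$primer, 0)$start[1], integer(1))
  names(anchors) <- fx$refs$id
  for (i in seq_len(nrow(fx$truth))) {
    row <- fx$truth[i, ]
    ref <- fx$refs$ungapped_seq[match(row$source_ref, fx$refs$id)]
    amp <- substr(ref, anchors[row$source_ref], nchar(ref))
    expect_equal(row$true_trf,
                 terminal_fragment(amp, 1, fx$enzymes[[row$enzyme]]),
                 info = paste(row$sample_id, row$enzyme))
  }
  # clean samples are exact substrings of their source amplicon
  row1 <- fx$truth[fx$truth$sample_id == "S0001", ][1, ]
  ref <- fx$refs$ungapped_seq[match(row1$source_ref, fx$refs$id)]
  amp <- substr(ref, anchors[row1$source_ref], nchar(ref))
  expect_identical(fx$samples[["S0001"]],
                   substr(amp, row1$trunc_depth + 1,
                          row1$trunc_depth + fx$params$read_length))
})

test_that("references carry planted primer, per-enzyme sites and requested taxa", {
  taxa <- c("Bacteria;A;LineageOne" = 0.5, "Bacteria;B;LineageTwo" = 0.5)
  fx <- generate_fixture(seed = 4, n_refs = 12, n_samples = 4,
                         taxa_profile = taxa)
  expect_setequal(unique(fx$refs$lineage), names(taxa))
  for (i in seq_len(nrow(fx$refs))) {
    expect_gt(nrow(find_primer(fx$refs$ungapped_seq[i], fx$primer, 0)), 0L)
    for (e in fx$enzymes)
      expect_gt(length(find_cut_positions(fx$refs$ungapped_seq[i], e)$positions),
                0L)
  }
  expect_true(all(fx$truth$trunc_depth >= 10 & fx$truth$trunc_depth <= 30))
})

test_that("mutated fixtures keep the primer-side conserved block intact", {
  fx <- generate_fixture(seed = 5, n_refs = 5, n_samples = 30,
                         mutation_rate = 0.02)
  anchors <- vapply(seq_len(nrow(fx$refs)), function(i)
    find_primer(fx$refs$ungapped_seq[i], fx$primer, 0)$start[1], integer(1))
  names(anchors) <- fx$refs$id
  n_diff <- 0L
  for (sid in names(fx$samples)) {
    row <- fx$truth[fx$truth$sample_id == sid, ][1, ]
    ref <- fx$refs$ungapped_seq[match(row$source_ref, fx$refs$id)]
    amp <- substr(ref, anchors[row$source_ref], nchar(ref))
    clean <- substr(amp, row$trunc_depth + 1,
                    row$trunc_depth + fx$params$read_length)
    got <- fx$samples[[sid]]
    # conserved block: positions up to mut_protect of the amplicon
    keep <- fx$params$mut_protect - row$trunc_depth
    expect_identical(substr(got, 1, keep), substr(clean, 1, keep), info = sid)
    if (!identical(got, clean)) n_diff <- n_diff + 1L
  }
  expect_gt(n_diff, 20L)  # 2% over ~420 mutable bases hits nearly every read
})

test_that("peak tables hold jittered true sizes plus decoys", {
  fx <- generate_fixture(seed = 6, n_refs = 8, n_samples = 20, n_decoys = 4)
  for (en in names(fx$peaks)) {
    truth <- unique(fx$truth$true_trf[fx$truth$enzyme == en &
                                        !is.na(fx$truth$true_trf)])
    sizes <- fx$peaks[[en]]$peaks$size
    for (t in truth)
      expect_true(any(abs(sizes - t) <= fx$params$jitter + 1e-9), info = en)
    expect_equal(length(sizes), length(truth) + 4L)
  }
})

test_that("impossible fixture constraints error early", {
  expect_error(generate_fixture(seed = 1, n_refs = 1), "n_refs")
  expect_error(generate_fixture(seed = 1, n_refs = 4,
                                plant_range = c(200, 5000)),
               "longer than the amplicon")
  expect_error(generate_fixture(seed = 1, n_refs = 4, read_length = 60),
               "read_length")
})

test_that("written bundles round-trip through the standard parsers", {
  fx <- generate_fixture(seed = 7, n_refs = 5, n_samples = 6)
  dir <- withr::local_tempdir()
  paths <- write_fixture(fx, dir)
  db <- parse_reference_fasta(paths$refs)
  expect_identical(db$ungapped_seq, fx$refs$ungapped_seq)
  expect_identical(db$lineage, fx$refs$lineage)
  samp <- Biostrings::readBStringSet(paths$samples)
  expect_identical(unname(as.character(samp)), unname(fx$samples))
  tab <- load_peak_table(paths$peaks_CfoI, "CfoI")
  expect_equal(tab$peaks$size, fx$peaks$CfoI$peaks$size)
})
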