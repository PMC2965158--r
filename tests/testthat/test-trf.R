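# Hand-built references on an A/T background (see helper-oracles.R) give
# full control over cut sites: GCGC cannot occur in {A,T} sequence, nor
# across junctions with the 27F primer realization.

cfo <- enzyme_spec("CfoI", "GCG^C")

test_that("reference terminal fragment from the primer anchor", {
  set.seed(61)
  db <- make_ref("R1", cut_offsets = 149)  # site start offset 149
  sub <- build_subset(db, PRIMER27F)
  pstart <- sub$hits$start[1]
  # cut at pstart + 149 - 1 + 3 => fragment length 152
  expect_equal(reference_trf(db[1, ], pstart, cfo), 152L)
  # no cut anywhere
  db0 <- make_refdb("R0", "Bacteria;X", paste0(rand_at(30), PRIMER27F_SEQ,
                                               rand_at(1300)))
  expect_true(is.na(reference_trf(db0[1, ], 31L, cfo)))
})

test_that("gap arithmetic follows the reference bridge geometry", {
  aln <- structure(list(sample_start = 1L, ref_start = 30L), class = "sw_alignment")
  expect_equal(compute_gap(aln, 10L)$gap, 20L)
  aln$ref_start <- 10L
  expect_equal(compute_gap(aln, 10L)$gap, 0L)
  aln <- structure(list(sample_start = 3L, ref_start = 30L), class = "sw_alignment")
  expect_equal(compute_gap(aln, 10L)$gap, 18L)
  # alignment beginning upstream of the primer clamps to zero
  aln <- structure(list(sample_start = 1L, ref_start = 5L), class = "sw_alignment")
  g <- compute_gap(aln, 10L)
  expect_equal(g$gap, 0L)
  expect_true(g$upstream)
})

test_that("full-length and truncated amplicons recover the true T-RF exactly", {
  set.seed(62)
  db <- make_ref("R1", cut_offsets = c(147, 300))
  sub <- build_subset(db, PRIMER27F)
  pstart <- sub$hits$start[1]
  amp <- substr(db$ungapped_seq[1], pstart, nchar(db$ungapped_seq[1]))
  true_trf <- terminal_fragment(amp, 1, cfo)
  expect_equal(true_trf, 150L)

  # full amplicon: gap 0, sample-site, est == reference fragment
  p <- predict_trf(amp, "full", cfo, sub)
  expect_equal(p$method, "sample-site")
  expect_equal(p$gap_length, 0L)
  expect_equal(p$est_fragment_length, p$ref_fragment_length)

  # every truncation depth 0-30 recovers the true size exactly
  for (d in 0:30) {
    p <- predict_trf(substr(amp, d + 1, nchar(amp)), "t", cfo, sub)
    expect_equal(p$method, "sample-site", info = d)
    expect_equal(p$gap_length, as.integer(d), info = d)
    expect_equal(p$est_fragment_length, true_trf, info = d)
  }
})

test_that("gap length never decreases with deeper truncation", {
  set.seed(63)
  db <- make_ref("R1", cut_offsets = 200)
  sub <- build_subset(db, PRIMER27F)
  amp <- substr(db$ungapped_seq[1], sub$hits$start[1],
                nchar(db$ungapped_seq[1]))
  gaps <- vapply(0:30, function(d)
    predict_trf(substr(amp, d + 1, nchar(amp)), "t", cfo, sub)$gap_length,
    integer(1))
  expect_true(all(diff(gaps) >= 0))
})

test_that("a cut inside the unsequenced gap falls back to the reference estimate", {
  set.seed(64)
  # first cut 25 bases after the primer start (just past the primer, still
  # inside a deep truncation gap), second cut downstream that the sample
  # *can* see
  db <- make_ref("R1", cut_offsets = c(22, 200))
  sub <- build_subset(db, PRIMER27F)
  amp <- substr(db$ungapped_seq[1], sub$hits$start[1],
                nchar(db$ungapped_seq[1]))
  ref_frag <- terminal_fragment(amp, 1, cfo)
  expect_equal(ref_frag, 25L)
  for (d in 26:30) {
    p <- predict_trf(substr(amp, d + 1, nchar(amp)), "t", cfo, sub)
    expect_equal(p$method, "reference-estimated", info = d)
    expect_match(p$flags, "cut-in-gap", info = d)
    expect_equal(p$est_fragment_length, ref_frag, info = d)
  }
})

test_that("samples and references without cut sites are flagged, not fabricated", {
  set.seed(65)
  # reference has no GCGC at all -> no reference fragment either
  db <- make_refdb("R1", "Bacteria;X",
                   paste0(rand_at(30), PRIMER27F_SEQ, rand_at(1300)))
  sub <- build_subset(db, PRIMER27F)
  amp <- substr(db$ungapped_seq[1], sub$hits$start[1], nchar(db$ungapped_seq[1]))
  p <- predict_trf(substr(amp, 21, nchar(amp)), "t", cfo, sub)
  expect_equal(p$method, "reference-estimated")
  expect_true(is.na(p$est_fragment_length))
  expect_match(p$flags, "no-cut-site")
})

test_that("unassignable samples yield a single flagged row", {
  set.seed(66)
  db <- make_ref("R1", cut_offsets = 100)
  sub <- build_subset(db, PRIMER27F)
  expect_warning(p <- predict_trf("ACGT", "tiny", cfo, sub), "shorter than k")
  expect_equal(nrow(p), 1L)
  expect_equal(p$flags, "unassignable")
  expect_true(is.na(p$est_fragment_length))
})

test_that("lineage truncation respects available depth", {
  lin <- "Bacteria;Proteobacteria;Alphaproteobacteria;Rhodobacterales"
  expect_equal(assign_taxonomy(lin, 2), "Bacteria;Proteobacteria")
  expect_equal(assign_taxonomy(lin, 10), lin)
  expect_equal(assign_taxonomy(lin, 1), "Bacteria")
})

test_that("sample-site estimates are recomputable from gap + sample cut distance", {
  set.seed(67)
  db <- make_ref("R1", cut_offsets = 180)
  sub <- build_subset(db, PRIMER27F)
  amp <- substr(db$ungapped_seq[1], sub$hits$start[1], nchar(db$ungapped_seq[1]))
  for (d in c(0, 10, 25)) {
    samp <- substr(amp, d + 1, nchar(amp))
    p <- predict_trf(samp, "t", cfo, sub)
    expect_equal(p$method, "sample-site")
    expect_equal(p$est_fragment_length,
                 p$gap_length + terminal_fragment(samp, 1, cfo))
  }
})
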