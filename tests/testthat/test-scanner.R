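test_that("window tiling follows floor((n - w)/step) + 1 and coordinates are half-open", {
  cfg <- scan_config(window = 10, step = 3)
  set.seed(11)
  for (n in c(10, 11, 25, 40, 63)) {
    p <- scan_sequence(random_seq(n), cfg)
    expect_equal(nrow(p), (n - 10) %/% 3 + 1)
    expect_true(all(p$end - p$start == 10))
    expect_true(all(p$end <= n))
    expect_equal(p$start[1], 0)
  }
  # shorter than the window: one whole-sequence window
  p <- scan_sequence("GTGT", scan_config(window = 25))
  expect_equal(nrow(p), 1L)
  expect_equal(p$end, 4)
  expect_equal(p$qs, qs_score("GTGT", psi = 30))
  # empty sequence: empty profile
  expect_equal(nrow(scan_sequence("", scan_config())), 0L)
})

test_that("windowed scores equal direct rescoring of each window", {
  set.seed(3)
  s <- random_seq(200)
  cfg <- scan_config(psi = 30, window = 25, step = 7)
  p <- scan_sequence(s, cfg)
  direct <- vapply(seq_len(nrow(p)), function(i) {
    qs_score(substr(s, p$start[i] + 1, p$end[i]), psi = 30)
  }, numeric(1))
  expect_equal(p$qs, direct, tolerance = 1e-12)
})

test_that("whole-oligo windows reproduce printed scores and homopolymer closed form", {
  p <- scan_sequence(strrep("GT", 27), scan_config(psi = 15, window = 54))
  expect_equal(nrow(p), 1L)
  expect_equal(round(p$qs, 2), 1.85)
  # all-A 30-mer at window 25: every window -A0 sin(psi) (w-1)/w
  p <- scan_sequence(strrep("A", 30), scan_config(psi = 30, window = 25))
  expect_equal(nrow(p), 6L)
  expect_true(all(abs(p$qs - (-1.5 * 24 / 25)) < 1e-12))
})

test_that("interval calling thresholds, mirrors and merges correctly", {
  cfg <- scan_config(threshold = 1.2)
  # below threshold: no calls
  prof <- scan_sequence(strrep("GA", 6), scan_config(window = 12))
  expect_equal(nrow(call_intervals(prof, cfg)), 0L)
  # a strongly negative window is a minus-strand (i-motif) call
  prof <- scan_sequence(strrep("CA", 10), scan_config(window = 20))
  calls <- call_intervals(prof, cfg)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$strand, "-")
  expect_equal(calls$label, "imotif_candidate")
  # overlapping windows merge to a maximal interval keeping the extremal score
  prof <- structure(
    data.frame(start = c(0L, 5L, 10L), end = c(25L, 30L, 35L),
               qs = c(1.3, 1.5, 1.3)),
    record_id = "x", psi = 30, window = 25L, step = 5L,
    class = c("score_profile", "data.frame"))
  m <- call_intervals(prof, scan_config(threshold = 1.2, merge_adjacent = TRUE))
  expect_equal(nrow(m), 1L)
  expect_equal(m$start, 0L)
  expect_equal(m$end, 35L)
  expect_equal(m$qs, 1.5)
  unmerged <- call_intervals(prof, scan_config(threshold = 1.2, merge_adjacent = FALSE))
  expect_equal(nrow(unmerged), 3L)
})

test_that("merged calls are disjoint per strand", {
  g <- make_spiked_genome(5, 5000,
                          list(list(make_repeat_oligo("GT", 14), 1000),
                               list(make_repeat_oligo("GT", 14), 1100),
                               list(normalize_sequence(revcomp(strrep("GT", 14)), "rc"), 3000)))
  calls <- call_intervals(scan_sequence(g$record, scan_config()), scan_config())
  for (st in c("+", "-")) {
    cs <- calls[calls$strand == st, ]
    if (nrow(cs) > 1) expect_true(all(cs$start[-1] >= cs$end[-nrow(cs)]))
  }
})

test_that("scanning the reverse complement swaps strands and remaps coordinates", {
  set.seed(9)
  g <- make_spiked_genome(2, 4000,
                          list(list(make_repeat_oligo("GT", 16), 800),
                               list(normalize_sequence(revcomp(strrep("GT", 16)), "rc"), 2500)))
  cfg <- scan_config()
  n <- g$record$n
  fwd <- call_intervals(scan_sequence(g$record, cfg), cfg)
  rc <- normalize_sequence(revcomp(g$record$seq), id = g$record$id)
  rev <- call_intervals(scan_sequence(rc, cfg), cfg)
  # remap reverse-strand calls back onto forward coordinates
  remapped <- data.frame(start = n - rev$end, end = n - rev$start,
                         strand = ifelse(rev$strand == "+", "-", "+"),
                         qs = -rev$qs)
  remapped <- remapped[order(remapped$start), ]
  expect_equal(nrow(remapped), nrow(fwd))
  expect_equal(remapped$start, fwd$start)
  expect_equal(remapped$end, fwd$end)
  expect_equal(remapped$strand, fwd$strand)
  expect_equal(remapped$qs, fwd$qs, tolerance = 1e-12)
})

test_that("FASTA round trip, BED6 and TSV outputs are consistent", {
  tmp <- withr::local_tempdir()
  fa <- file.path(tmp, "oligos.fa.gz")
  recs <- list(make_repeat_oligo("GT", 18), make_repeat_oligo("GA", 18))
  write_fasta(recs, fa)
  res <- scan_fasta(fa, scan_config(window = 36))
  expect_named(res$profiles, c("(GT)_18", "(GA)_18"))
  expect_equal(res$profiles[["(GT)_18"]]$qs[1], 2.1875, tolerance = 1e-6)
  # the GT repeat exceeds the call threshold, the GA repeat (0.73) does not
  expect_true(all(res$calls$record_id == "(GT)_18"))

  bed <- file.path(tmp, "calls.bed")
  write_bed(res$calls, bed)
  tab <- read.table(bed, sep = "\t")
  expect_equal(ncol(tab), 6L)
  expect_equal(tab$V2, res$calls$start)          # BED keeps 0-based starts
  expect_equal(tab$V5, round(1000 * pmin(abs(res$calls$qs) / 3, 1)))
  expect_true(all(tab$V6 %in% c("+", "-")))

  tsv <- file.path(tmp, "calls.tsv")
  write_calls_tsv(res$calls, tsv)
  lines <- readLines(tsv)
  expect_match(lines[1], "1-based inclusive")
  tab2 <- read.table(tsv, sep = "\t", header = TRUE, comment.char = "#")
  expect_equal(tab2$start, res$calls$start + 1L) # human-readable is 1-based
})
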