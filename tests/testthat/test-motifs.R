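test_that("count matrices are normalized and malformed models rejected", {
  m <- toy_motif()
  expect_equal(colSums(m$prob), rep(1, m$width), tolerance = 1e-12)
  counts <- matrix(c(10, 70, 10, 10), 4, 5,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  mc <- motif_model(counts)
  expect_equal(colSums(mc$prob), rep(1, 5), tolerance = 1e-12)
  expect_equal(unname(mc$prob["C", 1]), 70.25 / 101)  # pseudocount 0.25 per cell
  expect_error(motif_model(matrix(0.25, 3, 6)), "4 rows")
  expect_error(motif_model(matrix(0.25, 4, 3)), "width")
  expect_error(motif_model(matrix(0.25, 4, 6), background = c(0.5, 0.5, 0.1, 0.1)),
               "background")
})

test_that("the consensus scores the global maximum on both strands", {
  m <- toy_motif(threshold = 0)
  cons <- consensus_sequence(m)
  hits <- scan_pwm(cons, m)
  fwd <- hits[hits$strand == "+", ]
  expect_equal(fwd$score, m$max_score, tolerance = 1e-12)
  # no window on any random sequence can beat it
  set.seed(5)
  s <- paste(sample(c("A", "C", "G", "T"), 500, TRUE), collapse = "")
  all_hits <- scan_pwm(s, m, threshold = -Inf)
  expect_true(all(all_hits$score <= m$max_score + 1e-12))

  rc <- reverse_complement_chr(cons)
  hrc <- scan_pwm(rc, m)
  rev <- hrc[hrc$strand == "-", ]
  expect_equal(rev$score, m$max_score, tolerance = 1e-12)
  expect_equal(rev$position, 0L)
})

test_that("scanning a reverse complement mirrors hits with strands swapped", {
  m <- toy_motif(threshold = 2)
  set.seed(8)
  for (rep in 1:5) {
    s <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
    h <- scan_pwm(s, m)
    hrc <- scan_pwm(reverse_complement_chr(s), m)
    n <- nchar(s)
    mirrored <- data.frame(position = n - m$width - hrc$position,
                           strand = as.character(ifelse(hrc$strand == "+", "-", "+")),
                           score = hrc$score)
    mirrored <- mirrored[order(mirrored$position, mirrored$strand), ]
    rownames(mirrored) <- NULL
    expect_equal(h, mirrored, tolerance = 1e-12)
  }
})

test_that("the vectorized scanner agrees with a brute-force scorer", {
  m <- toy_motif()
  set.seed(11)
  for (rep in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
    got <- scan_pwm(s, m, threshold = -Inf)
    want <- naive_scan(s, m)
    fwd <- got[got$strand == "+", ]
    rev <- got[got$strand == "-", ]
    expect_equal(fwd$score, want$fwd[match(fwd$position, want$position)],
                 tolerance = 1e-12)
    expect_equal(rev$score, want$rev[match(rev$position, want$position)],
                 tolerance = 1e-12)
    expect_equal(nrow(fwd), nchar(s) - m$width + 1L)
  }
})

test_that("N windows are skipped and short sequences warn", {
  m <- toy_motif(threshold = -100)
  h <- scan_pwm("CANGTGACGTGA", m)
  # windows 0..2 contain the N at position 2 (0-based); only 3..6 scored
  expect_true(all(h$position >= 3))
  expect_warning(h0 <- scan_pwm("ACG", m), "shorter")
  expect_equal(nrow(h0), 0L)
  expect_error(scan_pwm("ACGTXXGTACGT", m), "A, C, G, T, N")
})

test_that("raising the threshold never adds hits", {
  m <- toy_motif()
  set.seed(13)
  s <- paste(sample(c("A", "C", "G", "T"), 1000, TRUE), collapse = "")
  prev <- Inf
  for (thr in c(-5, 0, 3, 6)) {
    n_hits <- nrow(scan_pwm(s, m, threshold = thr))
    expect_lte(n_hits, prev)
    prev <- n_hits
  }
})

test_that("anchor orientation follows the strand/window predicate", {
  seg <- dupHiC:::new_tad_segmentation(
    10L, 20L, contact_matrix(integer(0), integer(0), numeric(0), 20, 25000),
    NULL)
  # "+" at the left edge, "-" at the right edge of TAD 1: convergent
  hits <- data.frame(position = c(1000, 248000), strand = c("+", "-"),
                     score = c(10, 10))
  lab <- classify_anchor_orientation(hits, seg, anchor_window = 50000)
  expect_equal(lab$label[1], "convergent")
  # hits only in the TAD interior: unanchored
  mid <- data.frame(position = 125000, strand = "+", score = 10)
  expect_equal(classify_anchor_orientation(mid, seg, 50000)$label[1],
               "unanchored")
  # mirror image: divergent; same-strand pair: tandem
  div <- data.frame(position = c(1000, 248000), strand = c("-", "+"),
                    score = c(10, 10))
  expect_equal(classify_anchor_orientation(div, seg, 50000)$label[1],
               "divergent")
  tdm <- data.frame(position = c(1000, 248000), strand = c("+", "+"),
                    score = c(10, 10))
  expect_equal(classify_anchor_orientation(tdm, seg, 50000)$label[1],
               "tandem")
  empty <- data.frame(position = numeric(0), strand = character(0),
                      score = numeric(0))
  expect_true(all(classify_anchor_orientation(empty, seg, 50000)$label ==
                  "unanchored"))
})

test_that("duplication copies plant one reverse motif hit per copy", {
  model <- read_motif(system.file("extdata", "ctcf_motif_synthetic.tsv",
                                  package = "dupHiC"))
  lay <- build_layout()
  seqc <- synth_region_sequence(lay, model, seed = 3)
  expect_equal(nchar(seqc), lay$region_length)
  # high threshold isolates the planted consensus sites from background
  hits <- scan_pwm(seqc, model, threshold = 20)
  planted_rev <- lay$ctcf_sites[lay$ctcf_sites$strand == "-", "position"]
  copies <- dupHiC:::dup_copy_intervals(lay)
  for (k in seq_len(nrow(copies))) {
    in_copy <- hits$strand == "-" & hits$position >= copies$start[k] &
      hits$position < copies$end[k]
    expect_equal(sum(in_copy), 1L)
    expect_true(hits$position[in_copy] %in% planted_rev)
  }
  # and the classifier reports them at TAD 1's right anchor
  sim <- simulate_contacts(lay, 100000, seed = 7)
  res <- rescue_reads(sim$reads, lay$n_bins, lay$bin_size)
  seg <- call_tads(coarsen(res$matrix, 5))
  anc <- classify_anchor_orientation(scan_pwm(seqc, model, threshold = 20),
                                     seg)
  expect_equal(anc$n_minus_right[1], lay$dup_copies)
  expect_equal(anc$label, c("convergent", "convergent"))
})

test_that("FASTA and hit tables round-trip through their writers", {
  m <- toy_motif(threshold = 0)
  set.seed(15)
  s <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  fa <- withr::local_tempfile(fileext = ".fa")
  write_region_fasta(s, fa)
  expect_equal(read_region_fasta(fa), s)
  hits <- scan_pwm(s, m)
  expect_gt(nrow(hits), 0)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_motif_hits(hits, m, tsv)
  tab <- read.table(tsv, sep = "\t")
  expect_equal(nrow(tab), nrow(hits))
  expect_equal(tab$V7, hits$score, tolerance = 1e-12)
  expect_true(all(tab$V5 >= 0 & tab$V5 <= 1000))
  expect_equal(tab$V3 - tab$V2, rep(m$width, nrow(tab)))
})
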