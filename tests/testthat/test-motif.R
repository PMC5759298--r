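# Upstream extraction, shared-motif discovery, PWM scoring, overlap test.

test_that("upstream extraction follows strand and truncates at edges", {
  withr::local_seed(51)
  sc <- random_dna(8000)
  genome <- c(chr = sc)
  ann <- gene_annotation(scaffold = rep("chr", 3),
                         start = c(5001L, 100L, 1001L),
                         end = c(6000L, 200L, 1500L),
                         strand = c("+", "-", "+"),
                         gene_id = c("plus", "minus", "edge"))
  expect_identical(extract_upstream(genome, ann, "plus", 3000L),
                   substr(sc, 2001, 5000))
  expect_identical(extract_upstream(genome, ann, "minus", 3000L),
                   revcomp(substr(sc, 201, 3200)))
  expect_identical(extract_upstream(genome, ann, "edge", 3000L),
                   substr(sc, 1, 1000))
  ann0 <- gene_annotation("chr", 1L, 10L, "+", "none")
  expect_warning(out <- extract_upstream(genome, ann0, "none"), "upstream")
  expect_equal(out, "")
})

test_that("shared-motif discovery recovers planted conserved words", {
  fx <- make_promoter_fixture(planted_fraction = 1, seed = 52)
  found <- find_shared_motifs(fx, width = 15L, max_mismatch = 2L, min_seqs = 7L)
  top <- found$motifs$motif[1]
  expect_true(top %in% c(sdor_sdr_motif(), revcomp(sdor_sdr_motif())))
  expect_equal(found$motifs$n_seqs[1], 7L)

  fx5 <- make_promoter_fixture(planted_fraction = 5 / 7, seed = 53)
  found5 <- find_shared_motifs(fx5, width = 15L, max_mismatch = 2L, min_seqs = 5L)
  expect_equal(found5$motifs$n_seqs[1], 5L)
  hits <- found5$hits[found5$hits$motif == found5$motifs$motif[1], ]
  planted <- attr(fx5, "planted")
  expect_setequal(hits$seq_id, planted$seq_id)
})

test_that("shared-motif discovery equals brute-force enumeration on short inputs", {
  seqs <- c(a = "ACGTACGG", b = "TTACGTAA", c = "ACGTTTTT")
  w <- 4L
  found <- find_shared_motifs(seqs, width = w, max_mismatch = 0L, min_seqs = 3L,
                              max_report = 100L)
  # brute force: every word of seq a, exact matches on either strand
  rc_chr <- function(s) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  }
  words <- unique(vapply(1:(nchar(seqs[1]) - w + 1),
                         function(i) substr(seqs[1], i, i + w - 1), character(1)))
  in_all <- vapply(words, function(word) {
    all(vapply(seqs, function(s) {
      grepl(word, s, fixed = TRUE) || grepl(rc_chr(word), s, fixed = TRUE)
    }, logical(1)))
  }, logical(1))
  # the motifs reported must be exactly a subset of the brute-force common
  # words, and every brute-force word must overlap a reported representative
  expect_true(all(found$motifs$motif %in% words[in_all]))
  expect_true(all(vapply(words[in_all], function(word) {
    any(vapply(found$motifs$motif, function(m) {
      p1 <- regexpr(word, seqs[1], fixed = TRUE)
      p2 <- regexpr(m, seqs[1], fixed = TRUE)
      abs(p1 - p2) < w
    }, logical(1)))
  }, logical(1))))
  # with mismatches disabled and min_seqs = n this is common-substring detection
  cs <- find_shared_motifs(c(x = "AAAACCCC", y = "GGGGTTTT"), width = 4L,
                           max_mismatch = 0L, min_seqs = 2L)
  # every 4-mer of x matches y on the minus strand; merging leaves the two
  # non-overlapping representatives AAAA (pos 1) and CCCC (pos 5)
  expect_setequal(cs$motifs$motif, c("AAAA", "CCCC"))
})

test_that("relative PWM scores span [0, 1] and match exhaustive enumeration", {
  counts <- rbind(A = c(8, 0), C = c(1, 1), G = c(1, 9), T = c(0, 0))
  p <- pwm(counts, name = "toy")
  expect_equal(relative_score(p, "AG"), 1)   # per-position argmax
  expect_equal(relative_score(p, "TT"), 0)   # per-position argmin
  # brute-force check of all 16 dinucleotides against direct arithmetic
  bg <- 0.25; pc <- 0.8
  freq <- sweep(counts + pc * bg, 2, colSums(counts) + pc, "/")
  lo <- log2(freq / bg)
  smin <- sum(apply(lo, 2, min)); smax <- sum(apply(lo, 2, max))
  bases <- c("A", "C", "G", "T")
  for (b1 in bases) for (b2 in bases) {
    s <- unname(lo[b1, 1] + lo[b2, 2])
    expect_equal(relative_score(p, paste0(b1, b2)), (s - smin) / (smax - smin))
  }
  expect_error(relative_score(p, "ACG"), "width")
})

test_that("PWM scanning finds planted consensus sites on both strands", {
  withr::local_seed(54)
  counts <- rbind(A = c(9, 0, 0, 9, 0), C = c(0, 9, 0, 0, 0),
                  G = c(0, 0, 9, 0, 0), T = c(0, 0, 0, 0, 9))
  p <- pwm(counts)
  cons <- pwm_consensus(p)
  expect_equal(cons, "ACGAT")
  seq <- paste0(random_dna(20), cons, random_dna(20))
  hits <- scan_pwm(p, seq, threshold = 1)
  expect_true(any(hits$pos == 21L & hits$strand == "+"))
  rc_hits <- scan_pwm(p, revcomp(seq), threshold = 1)
  expect_true(any(rc_hits$strand == "-"))
  expect_equal(nrow(scan_pwm(p, seq, threshold = 1.01)), 0L)

  # brute-force per-offset oracle on a 50-base sequence
  s50 <- random_dna(50)
  hits50 <- scan_pwm(p, s50, threshold = 0)
  for (i in sample(seq_len(50 - 5 + 1), 10)) {
    expect_equal(hits50$score[hits50$pos == i & hits50$strand == "+"],
                 relative_score(p, substr(s50, i, i + 4)))
    expect_equal(hits50$score[hits50$pos == i & hits50$strand == "-"],
                 relative_score(p, revcomp(substr(s50, i, i + 4))))
  }
})

test_that("relative score is invariant under joint reverse complement", {
  withr::local_seed(55)
  counts <- matrix(rpois(4 * 6, 5), 4, dimnames = list(c("A", "C", "G", "T"), NULL))
  p <- pwm(counts)
  rc_counts <- counts[c("T", "G", "C", "A"), ncol(counts):1]
  rownames(rc_counts) <- c("A", "C", "G", "T")
  p_rc <- pwm(rc_counts)
  for (i in 1:5) {
    w <- random_dna(6)
    expect_equal(relative_score(p, w), relative_score(p_rc, revcomp(w)))
  }
})

test_that("the conserved motif overlaps the deletion by at least 12 bases on the minus strand", {
  ov <- deletion_overlap(sdor_sdr_motif(), "-", sdor_deletion_seq())
  expect_gte(ov, 12L)
  # a motif identical to a deletion substring overlaps by its full length
  sub <- substr(sdor_deletion_seq(), 10, 24)
  expect_equal(deletion_overlap(sub, "+", sdor_deletion_seq()), nchar(sub))
  # disjoint alphabets can only share chance-level overlap
  expect_equal(deletion_overlap("GGGGGGGG", "+", "AAAAAAAA"), 0L)
  expect_error(deletion_overlap("", "+", "ACGT"), "empty")
})

test_that("JASPAR PFM files parse into scoring-ready matrices", {
  path <- system.file("extdata", "synthetic_sox_like.pfm", package = "zwseeker")
  expect_true(nzchar(path))
  mats <- read_jaspar_pfm(path)
  expect_equal(length(mats), 1L)
  m <- mats[[1]]
  expect_s3_class(m, "PWM")
  expect_equal(ncol(m$counts), nchar(pwm_consensus(m)))
  expect_equal(relative_score(m, pwm_consensus(m)), 1)
})
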