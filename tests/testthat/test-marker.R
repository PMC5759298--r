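# Indel marker scan, melting temperatures, in-silico PCR and sex calls.

test_that("the simulated cohort yields exactly one candidate: the 61-bp deletion", {
  sim <- simulate_cohort(small_config(seed = 41))
  cand <- scan_indels(sim$variants, sim$panel, sim$truth$sdr)
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$length, 61L)
  expect_equal(cand$type, "del")
  expect_identical(cand$sequence, sdor_deletion_seq())
  expect_equal(cand$pos, sim$truth$deletion$pos)
})

test_that("length and sex-pattern filters exclude short and unpatterned indels", {
  # noise-free cohort so the genotype-mode rule is exact
  sim <- simulate_cohort(small_config(seed = 42, coverage = Inf))
  cand <- scan_indels(sim$variants, sim$panel, sim$truth$sdr, mode = "genotype")
  expect_equal(nrow(cand), 1L)  # the 45-bp decoy fails the sex pattern
  expect_equal(cand$length, 61L)
  # a 40-base indel is excluded by the strict > 40 rule even if W-patterned
  vt <- sim$variants
  i <- which(nchar(vt$sites$ref) - nchar(sub(",.*", "", vt$sites$alt)) == 61L)
  vt$sites$ref[i] <- substr(vt$sites$ref[i], 1, 41)  # now a 40-bp deletion
  expect_equal(nrow(scan_indels(vt, sim$panel, sim$truth$sdr, mode = "genotype")), 0L)
})

test_that("a deletion carried by too many males is rejected by the sex pattern", {
  n <- 20
  sex <- rep(c("F", "M"), each = n / 2)
  panel <- cohort_panel(paste0("s", 1:n), sex, "P1")
  gt <- matrix(ifelse(sex == "F", "0/1", "0/0"), 1, n)
  gt[1, n] <- "1/1"  # one homozygous male (10% of males > 5% cap)
  sites <- data.frame(scaffold = "sc", pos = 100L,
                      ref = paste0("A", paste(rep("T", 61), collapse = "")),
                      alt = "A", stringsAsFactors = FALSE)
  ad <- matrix(5L, 1, n)
  vt <- variant_table(sites, gt, ad, ad, samples = paste0("s", 1:n))
  region <- list(scaffold = "sc", start = 1L, end = 1000L)
  expect_equal(nrow(scan_indels(vt, panel, region, mode = "genotype")), 0L)
  gt[1, n] <- "0/0"
  vt2 <- variant_table(sites, gt, ad, ad, samples = paste0("s", 1:n))
  expect_equal(nrow(scan_indels(vt2, panel, region, mode = "genotype")), 1L)
})

test_that("melting temperatures match a hand-summed nearest-neighbour oracle", {
  # 8-mer AAAAAAAA, Breslauer parameters: 7 AA stacks
  dH <- 7 * -9.1
  dS <- 7 * -24.0 + -20.1           # all-A/T duplex initiation entropy
  tm_hand <- 1000 * dH / (dS + 1.987 * log(250e-9)) - 273.15 + 16.6 * log10(0.05)
  expect_equal(primer_tm("AAAAAAAA"), tm_hand, tolerance = 0.1 / abs(tm_hand))

  # same oligo under the SantaLucia 1998 set
  dH2 <- 7 * -7.9 + 2 * 2.3
  dS2 <- 7 * -22.2 + 2 * 4.1 + 0.368 * 7 * log(0.05)
  tm_hand2 <- 1000 * dH2 / (dS2 + 1.987 * log(250e-9 / 4)) - 273.15
  expect_equal(primer_tm("AAAAAAAA", method = "santalucia"), tm_hand2,
               tolerance = 0.1 / abs(tm_hand2))
})

test_that("Tm is duplex-symmetric and validates its input", {
  withr::local_seed(43)
  for (i in 1:5) {
    s <- random_dna(20)
    expect_equal(primer_tm(s), primer_tm(revcomp(s)), tolerance = 1e-12)
    expect_equal(primer_tm(s, method = "santalucia"),
                 primer_tm(revcomp(s), method = "santalucia"), tolerance = 1e-12)
  }
  expect_error(primer_tm("ACGTNACGTT"), "A/C/G/T")
  expect_error(primer_tm("ACGT"), "length")
})

test_that("published primers score close to their published melting temperatures", {
  a <- sdor_del_assays()
  expect_equal(primer_tm(a$fwd[1]), a$tm_fwd[1], tolerance = 1.0 / a$tm_fwd[1])
  expect_equal(primer_tm(a$rev[1]), a$tm_rev[1], tolerance = 1.0 / a$tm_rev[1])
  expect_equal(primer_tm(a$fwd[2]), a$tm_fwd[2], tolerance = 1.0 / a$tm_fwd[2])
  expect_equal(primer_tm(a$rev[2]), a$tm_rev[2], tolerance = 1.0 / a$tm_rev[2])
})

test_that("in-silico PCR finds the published product sizes on the fixture", {
  fx <- make_marker_fixture()
  a <- sdor_del_assays()
  for (i in seq_len(nrow(a))) {
    amp_z <- in_silico_pcr(fx[["Z"]], a$fwd[i], a$rev[i])
    amp_w <- in_silico_pcr(fx[["W"]], a$fwd[i], a$rev[i])
    expect_equal(amp_z$length, a$size_z[i])
    expect_equal(amp_w$length, a$size_w[i])
    expect_equal(amp_z$length - amp_w$length, 61L)
  }
})

test_that("in-silico PCR degenerate cases and strand symmetry hold", {
  fwd <- "ACGTACGTACGTACGTACGT"
  rev <- "TTGGCCAATTGGCCAATTGG"
  minimal <- paste0(fwd, revcomp(rev))
  amp <- in_silico_pcr(minimal, fwd, rev)
  expect_equal(amp$length, nchar(fwd) + nchar(rev))

  withr::local_seed(44)
  tmpl <- paste0(random_dna(30), fwd, random_dna(100), revcomp(rev), random_dna(30))
  expect_equal(in_silico_pcr(tmpl, fwd, rev)$length, 140L)
  # reverse-complementing the template and swapping primers keeps lengths
  flipped <- in_silico_pcr(revcomp(tmpl), fwd, rev)
  expect_equal(sort(flipped$length), sort(in_silico_pcr(tmpl, fwd, rev)$length))
  expect_equal(nrow(in_silico_pcr(random_dna(200), fwd, rev)), 0L)
  # max_product excludes over-long pairings
  expect_equal(nrow(in_silico_pcr(tmpl, fwd, rev, max_product = 100L)), 0L)
})

test_that("band patterns map to sex calls as on the assay gel", {
  expect_equal(call_sex(c(452, 391), 452, 391), "F")
  expect_equal(call_sex(452, 452, 391), "M")
  expect_equal(call_sex(391, 452, 391), "anomalous")
  expect_equal(call_sex(integer(0), 452, 391), "anomalous")
})

test_that("sex calls at true haplotypes recover every sample of a cohort", {
  sim <- simulate_cohort(small_config(seed = 45))
  a <- sdor_del_assays()
  tmpl <- sim$truth$templates
  bands_zw <- c(in_silico_pcr(tmpl[["Z"]], a$fwd[1], a$rev[1])$length,
                in_silico_pcr(tmpl[["W"]], a$fwd[1], a$rev[1])$length)
  bands_zz <- in_silico_pcr(tmpl[["Z"]], a$fwd[1], a$rev[1])$length
  calls <- vapply(sim$truth$sample_sex, function(chr) {
    call_sex(if (chr == "ZW") bands_zw else bands_zz, a$size_z[1], a$size_w[1])
  }, character(1))
  truth <- ifelse(sim$truth$sample_sex == "ZW", "F", "M")
  expect_identical(unname(calls), unname(truth))
})

test_that("primer design recovers a discriminating pair from the fixture flanks", {
  fx <- make_marker_fixture()
  di <- attr(fx, "del_interval")
  z <- fx[["Z"]]
  flank_left <- substr(z, di[["start"]] - 150L, di[["start"]] - 1L)
  flank_right <- substr(z, di[["end"]] + 1L, di[["end"]] + 150L)
  des <- design_primers(flank_left, flank_right,
                        templates = c(Z = fx[["Z"]], W = fx[["W"]]))
  expect_gt(nrow(des), 0L)
  ok <- !is.na(des$size_Z) & !is.na(des$size_W)
  expect_true(any(ok))
  expect_true(all(des$size_Z[ok] - des$size_W[ok] == 61L))

  all_a <- paste(rep("A", 150), collapse = "")
  empty <- design_primers(all_a, all_a)
  expect_equal(nrow(empty), 0L)
  expect_match(attr(empty, "diagnostics"), "constraint")
})

test_that("the published primers rank among the top candidates in their own flanks", {
  fx <- make_marker_fixture()
  a <- sdor_del_assays()
  z <- fx[["Z"]]
  # flanks centred on the SdorDel02 primer footprints
  f_start <- as.integer(regexpr(a$fwd[2], z, fixed = TRUE))
  r_site <- as.integer(regexpr(revcomp(a$rev[2]), z, fixed = TRUE))
  flank_left <- substr(z, f_start - 40L, f_start + 60L)
  flank_right <- substr(z, r_site - 40L, r_site + 60L)
  des <- design_primers(flank_left, flank_right, n_top = 10L)
  expect_true(a$fwd[2] %in% des$fwd || a$rev[2] %in% des$rev)
})
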