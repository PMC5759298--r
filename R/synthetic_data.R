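# Seeded generator for ZW resequencing cohorts and promoter fixtures.
#
# The generator emulates the data a sexed, ~2x whole-genome resequencing
# study produces after joint variant calling: a multi-scaffold reference,
# gene annotations, a GT:AD VCF over 90 samples (45 F / 45 M in three
# populations of 15+15), a fully sex-linked SDR carrying W-linked SNPs and
# one W-specific 61-bp deletion 954 bp upstream of a target gene, and
# orthologous promoter sequences sharing a conserved motif.

DEPTH_CAP_INF <- 30L  # deterministic per-site depth used when coverage = Inf

#' Simulation configuration
#'
#' Default values define the reference cohort this package is tested
#' against: three populations of 15 females + 15 males each, ~2x mean
#' coverage, a fully W-linked SDR at 231-320 kb of a 400 kb scaffold, the
#' 61-bp W deletion at position 246,495 with its downstream target gene 954
#' bp away, and a desk-scale six-scaffold (~1 Mb) genome. Background SNP
#' density inside the SDR is reduced (`sdr_density_factor`) to reflect the
#' suppressed diversity of a differentiated sex-linked region.
#'
#' @param seed Integer seed; drives every random draw (mandatory).
#' @param scaffold_lengths Named integer vector of scaffold lengths.
#' @param populations Data frame with columns `label`, `n_female`, `n_male`.
#' @param sdr List `(scaffold, start, end)` of the fully sex-linked segment.
#' @param snp_density Background SNP probability per base.
#' @param sdr_density_factor Multiplier on `snp_density` inside the SDR.
#' @param maf_range Range of the uniform alt-allele-frequency distribution
#'   for background SNPs.
#' @param n_w_snps Number of W-linked SNPs planted inside the SDR.
#' @param deletion_seq The W-specific deleted sequence (length > 40).
#' @param deletion_start 1-based start of the deletion on the SDR scaffold.
#' @param upstream_offset Bases between the deletion end and the target gene
#'   start (exclusive gap; the deletion sits this far upstream).
#' @param target_gene Gene id given to the downstream target gene.
#' @param coverage Mean per-sample read depth (Poisson); `Inf` gives a
#'   deterministic depth of 30 with exact allele splits (noise-free limit).
#' @param n_multiallelic Number of background SNPs given a second ALT allele.
#' @param decoy_indels Data frame of sex-independent indels
#'   (`scaffold`, `start`, `length`, `freq`) used as negative controls for
#'   the marker scan; `NULL` for none.
#' @param system `"ZW"` (default) or `"XY"`; `"XY"` swaps the sex labels of
#'   the panel, turning the simulated cohort into a male-heterogametic
#'   negative control for the classifier.
#' @return A list of class `SimulationConfig`.
#' @export
sim_config <- function(seed,
                       scaffold_lengths = c(scaffold_22 = 400000L,
                                            scaffold_01 = 120000L,
                                            scaffold_02 = 120000L,
                                            scaffold_03 = 120000L,
                                            scaffold_04 = 120000L,
                                            scaffold_05 = 120000L),
                       populations = data.frame(label = c("CI", "SD", "LP"),
                                                n_female = 15L, n_male = 15L),
                       sdr = list(scaffold = "scaffold_22",
                                  start = 231000L, end = 320000L),
                       snp_density = 0.01,
                       sdr_density_factor = 0.12,
                       maf_range = c(0.05, 0.5),
                       n_w_snps = 120L,
                       deletion_seq = sdor_deletion_seq(),
                       deletion_start = 246495L,
                       upstream_offset = 954L,
                       target_gene = "hsd17b1",
                       coverage = 2.0,
                       n_multiallelic = 20L,
                       decoy_indels = data.frame(
                         scaffold = c("scaffold_22", "scaffold_02"),
                         start = c(300000L, 60000L),
                         length = c(45L, 50L),
                         freq = c(0.3, 0.3)),
                       system = c("ZW", "XY")) {
  if (missing(seed)) stop("seed is mandatory")
  system <- match.arg(system)
  if (!(sdr$scaffold %in% names(scaffold_lengths))) {
    stop("SDR scaffold not in scaffold_lengths")
  }
  if (sdr$start < 1 || sdr$end > scaffold_lengths[[sdr$scaffold]]) {
    stop("SDR interval overlaps a scaffold end")
  }
  if (nchar(deletion_seq) <= 40) stop("deletion sequence must be longer than 40 bases")
  if (!(coverage > 0)) stop("coverage must be positive")
  del_end <- deletion_start + nchar(deletion_seq) - 1L
  if (deletion_start < sdr$start || del_end > sdr$end) {
    stop("deletion must lie inside the SDR")
  }
  structure(list(seed = as.integer(seed), scaffold_lengths = scaffold_lengths,
                 populations = populations, sdr = sdr,
                 snp_density = snp_density,
                 sdr_density_factor = sdr_density_factor,
                 maf_range = maf_range, n_w_snps = as.integer(n_w_snps),
                 deletion_seq = toupper(deletion_seq),
                 deletion_start = as.integer(deletion_start),
                 upstream_offset = as.integer(upstream_offset),
                 target_gene = target_gene, coverage = coverage,
                 n_multiallelic = as.integer(n_multiallelic),
                 decoy_indels = decoy_indels, system = system),
            class = "SimulationConfig")
}

# The primer cassette surrounding the deletion. Spacer lengths are fixed so
# that the assay product sizes on the intact (Z) allele are 452 bp
# (SdorDel01) and 282 bp (SdorDel02); excising the 61-mer yields 391/221.
# The three bases following the deletion complete the conserved promoter
# motif on the minus strand, so the motif straddles the deletion boundary.
marker_cassette <- function(deletion_seq = sdor_deletion_seq()) {
  assays <- sdor_del_assays()
  gaps <- c(a = 65L, b = 90L, c = 91L, d = 65L)
  gap_a <- random_dna(gaps["a"])
  gap_b <- random_dna(gaps["b"])
  gap_c <- paste0("GAC", random_dna(gaps["c"] - 3L))
  gap_d <- random_dna(gaps["d"])
  z <- paste0(assays$fwd[1], gap_a, assays$fwd[2], gap_b, deletion_seq,
              gap_c, revcomp(assays$rev[2]), gap_d, revcomp(assays$rev[1]))
  del_start <- 20L + gaps["a"] + 20L + gaps["b"] + 1L
  del_end <- del_start + nchar(deletion_seq) - 1L
  w <- paste0(substr(z, 1L, del_start - 1L), substring(z, del_end + 1L))
  list(z = z, w = w, del_start = unname(del_start), del_end = unname(del_end))
}

#' Deterministic two-allele PCR template fixture
#'
#' Builds a Z (intact) and a W (deletion-carrying) template around the
#' published sexing-assay primer sites: the SdorDel01 primer pair spans the
#' nested SdorDel02 pair, with spacer lengths fixed so the intact-allele
#' products are 452 bp and 282 bp; the W template is the Z template with the
#' 61-bp deletion excised (391 bp / 221 bp products). Random flanks are
#' generated under a fixed seed and the construction asserts that each
#' primer site occurs exactly once per template.
#'
#' @param pad Length of random flanking sequence on each side.
#' @param seed Seed for the flank/spacer sequence (fixed default).
#' @return Named character vector `c(Z = ..., W = ...)` with attributes
#'   `deletion` (the excised sequence) and `del_interval` (1-based interval
#'   of the deletion within the Z template).
#' @export
make_marker_fixture <- function(pad = 100L, seed = 61L) {
  with_seed(seed, {
    cass <- marker_cassette()
    left <- random_dna(pad)
    right <- random_dna(pad)
    z <- paste0(left, cass$z, right)
    w <- paste0(left, cass$w, right)
    assays <- sdor_del_assays()
    for (tmpl in c(z, w)) {
      for (p in c(assays$fwd, revcomp(assays$rev))) {
        hits <- Biostrings::countPattern(p, Biostrings::DNAString(tmpl))
        if (hits != 1L) stop("primer site not unique in constructed template")
      }
    }
    out <- c(Z = z, W = w)
    attr(out, "deletion") <- sdor_deletion_seq()
    attr(out, "del_interval") <- c(start = pad + cass$del_start,
                                   end = pad + cass$del_end)
    out
  })
}

# Genotype caller used on sampled read counts: heterozygous when two alleles
# are seen, homozygous for the single seen allele otherwise, missing at zero
# depth (joint calling on low-coverage data is emulated, not modelled).
call_gt_from_counts <- function(ref, a1, a2) {
  n <- length(ref)
  gt <- rep("./.", n)
  r <- ref > 0L; x <- a1 > 0L; y <- a2 > 0L
  gt[r & !x & !y] <- "0/0"
  gt[!r & x & !y] <- "1/1"
  gt[!r & !x & y] <- "2/2"
  gt[r & x & !y] <- "0/1"
  gt[r & !x & y] <- "0/2"
  gt[!r & x & y] <- "1/2"
  three <- which(r & x & y)  # rare: keep the two best-supported alleles
  if (length(three)) {
    counts <- cbind(ref[three], a1[three], a2[three])
    alleles <- c("0", "1", "2")
    gt[three] <- vapply(seq_along(three), function(i) {
      top <- sort(order(-counts[i, ], 1:3)[1:2])
      paste0(alleles[top[1]], "/", alleles[top[2]])
    }, character(1))
  }
  gt
}

#' Simulate a sexed resequencing cohort
#'
#' Generates the reference genome, gene annotation, GT:AD variant table,
#' cohort panel and a truth set for parameter-recovery testing. Background
#' SNPs follow Hardy-Weinberg at a uniformly drawn alt frequency,
#' independent of sex. W-linked SNPs and the W deletion are heterozygous in
#' every true female and absent from every true male at the haplotype level;
#' observed genotypes are called from Poisson-sampled read depths with
#' binomial allele draws, so low-coverage dropout and miscalls are present.
#' The same seed reproduces byte-identical output.
#'
#' @param config A [sim_config()].
#' @return List with elements `genome`, `annotation`, `variants` (a
#'   `VariantTable`), `panel` (a `CohortPanel`), `truth` and `config`.
#'   `truth` records the SDR, W-linked sites, the deletion locus, each
#'   sample's true sex chromosomes (`"ZW"`/`"ZZ"`), the Z/W PCR templates
#'   around the deletion and the multi-allelic bookkeeping count.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  with_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(config) {
  lens <- config$scaffold_lengths
  sdr <- config$sdr

  ## genome
  genome <- vapply(names(lens), function(s) random_dna(lens[[s]]), character(1))

  ## embed the primer cassette so the deletion interval carries the printed
  ## 61-mer and the published assays amplify from the simulated reference
  cass <- marker_cassette(config$deletion_seq)
  del_start <- config$deletion_start
  del_end <- del_start + nchar(config$deletion_seq) - 1L
  cass_start <- del_start - (cass$del_start - 1L)
  cass_end <- cass_start + nchar(cass$z) - 1L
  if (cass_start < sdr$start || cass_end > sdr$end) {
    stop("deletion too close to the SDR edge to host the primer cassette")
  }
  sc <- sdr$scaffold
  substr(genome[[sc]], cass_start, cass_end) <- cass$z

  ## annotation: target gene downstream of the deletion plus filler genes
  gene_start <- del_end + config$upstream_offset + 1L
  gene_end <- min(gene_start + 1999L, lens[[sc]])
  others <- setdiff(names(lens), sc)
  sdr_filler_starts <- sdr$start + 500L + (0:5) * 2200L
  ann <- gene_annotation(
    scaffold = c(sc, rep(sc, 6), others),
    start = c(gene_start, sdr_filler_starts,
              pmin(lens[others] - 3000L, 50000L)),
    end = c(gene_end, sdr_filler_starts + 1500L,
            pmin(lens[others] - 3000L, 50000L) + 1500L),
    strand = c("+", rep("+", 3), rep("-", 3), rep("+", length(others))),
    gene_id = c(config$target_gene, sprintf("sdr_gene_%02d", 1:6),
                sprintf("gene_%s", others)))

  ## panel
  pops <- config$populations
  sample_id <- character(0); sexes <- character(0); poplab <- character(0)
  for (i in seq_len(nrow(pops))) {
    nf <- pops$n_female[i]; nm <- pops$n_male[i]
    ids <- sprintf("%s_%02d", pops$label[i], seq_len(nf + nm))
    sample_id <- c(sample_id, ids)
    sexes <- c(sexes, rep(c("F", "M"), c(nf, nm)))
    poplab <- c(poplab, rep(pops$label[i], nf + nm))
  }
  true_chromosomes <- ifelse(sexes == "F", "ZW", "ZZ")
  panel_sex <- if (config$system == "XY") ifelse(sexes == "F", "M", "F") else sexes
  panel <- cohort_panel(sample_id, panel_sex, poplab)
  n <- length(sample_id)
  is_zw <- true_chromosomes == "ZW"

  ## site catalogue -----------------------------------------------------
  blocked <- c(del_start:(del_end + 1L))  # keep the deletion span SNP-free
  site_list <- list()
  for (s in names(lens)) {
    L <- lens[[s]]
    if (s == sc) {
      pos_out <- which(stats::runif(L) < config$snp_density)
      in_sdr <- pos_out >= sdr$start & pos_out <= sdr$end
      # thin background inside the SDR to its reduced density
      keep_sdr <- stats::runif(sum(in_sdr)) < config$sdr_density_factor
      pos <- c(pos_out[!in_sdr], pos_out[in_sdr][keep_sdr])
      pos <- setdiff(pos, blocked - 1L)  # also clear of the anchor base
      pos <- setdiff(pos, blocked)
      w_pool <- setdiff(sdr$start:sdr$end, c(pos, blocked, blocked - 1L))
      w_pos <- sort(sample(w_pool, config$n_w_snps))
      site_list[[s]] <- data.frame(pos = c(pos, w_pos),
                                   w_linked = rep(c(FALSE, TRUE),
                                                  c(length(pos), length(w_pos))))
    } else {
      pos <- which(stats::runif(L) < config$snp_density)
      site_list[[s]] <- data.frame(pos = pos, w_linked = FALSE)
    }
  }
  sites <- do.call(rbind, lapply(names(site_list), function(s) {
    d <- site_list[[s]]; d$scaffold <- s; d
  }))
  sites <- sites[order(match(sites$scaffold, names(lens)), sites$pos), ]

  ## alleles
  m <- nrow(sites)
  ref_base <- unname(substring(genome[sites$scaffold], sites$pos, sites$pos))
  alt_base <- vapply(ref_base, function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1), USE.NAMES = FALSE)

  ## true dosages (samples in columns)
  p_alt <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  dos1 <- matrix(0L, m, n)
  bg <- !sites$w_linked
  dos1[bg, ] <- stats::rbinom(sum(bg) * n, 2L, rep(p_alt[bg], times = n))
  dos1[sites$w_linked, is_zw] <- 1L
  dos1[sites$w_linked, !is_zw] <- 0L

  ## second ALT allele for a known number of multi-allelic background sites
  multi_idx <- sort(sample(which(bg), min(config$n_multiallelic, sum(bg))))
  dos2 <- matrix(0L, m, n)
  if (length(multi_idx)) {
    d2 <- stats::rbinom(length(multi_idx) * n, 2L, 0.05)
    d2 <- matrix(d2, length(multi_idx), n)
    room <- 2L - dos1[multi_idx, , drop = FALSE]
    dos2[multi_idx, ] <- pmin(d2, room)
  }
  alt2_base <- rep(NA_character_, m)
  alt2_base[multi_idx] <- vapply(multi_idx, function(i)
    sample(setdiff(c("A", "C", "G", "T"), c(ref_base[i], alt_base[i])), 1L),
    character(1))

  site_df <- data.frame(scaffold = sites$scaffold, pos = sites$pos,
                        ref = ref_base,
                        alt = ifelse(is.na(alt2_base), alt_base,
                                     paste0(alt_base, ",", alt2_base)),
                        stringsAsFactors = FALSE)

  ## indel records: the W deletion plus sex-independent decoys
  anchor <- substr(genome[[sc]], del_start - 1L, del_start - 1L)
  indel_sites <- data.frame(scaffold = sc, pos = del_start - 1L,
                            ref = paste0(anchor, config$deletion_seq),
                            alt = anchor, stringsAsFactors = FALSE)
  indel_dos <- matrix(ifelse(is_zw, 1L, 0L), 1L, n)
  if (!is.null(config$decoy_indels) && nrow(config$decoy_indels)) {
    for (i in seq_len(nrow(config$decoy_indels))) {
      di <- config$decoy_indels[i, ]
      a <- substr(genome[[di$scaffold]], di$start - 1L, di$start - 1L)
      refseq <- substr(genome[[di$scaffold]], di$start - 1L, di$start + di$length - 1L)
      indel_sites <- rbind(indel_sites,
                           data.frame(scaffold = di$scaffold, pos = di$start - 1L,
                                      ref = refseq, alt = a,
                                      stringsAsFactors = FALSE))
      indel_dos <- rbind(indel_dos, stats::rbinom(n, 2L, di$freq))
    }
  }

  site_df <- rbind(site_df, indel_sites)
  dos1 <- rbind(dos1, indel_dos)
  dos2 <- rbind(dos2, matrix(0L, nrow(indel_sites), n))
  ord <- order(match(site_df$scaffold, names(lens)), site_df$pos)
  site_df <- site_df[ord, ]
  dos1 <- dos1[ord, , drop = FALSE]
  dos2 <- dos2[ord, , drop = FALSE]
  m <- nrow(site_df)

  ## read sampling and genotype calling ---------------------------------
  if (is.infinite(config$coverage)) {
    depth <- matrix(DEPTH_CAP_INF, m, n)
    a1 <- matrix(as.integer(round(DEPTH_CAP_INF * dos1 / 2)), m, n)
    a2 <- matrix(as.integer(round(DEPTH_CAP_INF * dos2 / 2)), m, n)
  } else {
    depth <- matrix(stats::rpois(m * n, config$coverage), m, n)
    a1 <- matrix(stats::rbinom(m * n, as.vector(depth), as.vector(dos1) / 2), m, n)
    p2 <- ifelse(dos1 == 2L, 0, dos2 / 2 / (1 - dos1 / 2))
    a2 <- matrix(stats::rbinom(m * n, as.vector(depth - a1), as.vector(p2)), m, n)
  }
  adr <- depth - a1 - a2
  gt <- matrix(call_gt_from_counts(as.vector(adr), as.vector(a1), as.vector(a2)), m, n)
  colnames(gt) <- sample_id

  variants <- variant_table(site_df, gt, adr, a1, a2, samples = sample_id)

  ## truth set
  pad_ctx <- 100L
  z_tmpl <- substr(genome[[sc]], cass_start - pad_ctx, cass_end + pad_ctx)
  w_tmpl <- paste0(substr(genome[[sc]], cass_start - pad_ctx, del_start - 1L),
                   substr(genome[[sc]], del_end + 1L, cass_end + pad_ctx))
  truth <- list(
    sdr = sdr,
    w_snps = data.frame(scaffold = sc,
                        pos = sites$pos[sites$w_linked]),
    deletion = list(scaffold = sc, pos = del_start - 1L,
                    start = del_start, end = del_end,
                    seq = config$deletion_seq),
    sample_sex = stats::setNames(true_chromosomes, sample_id),
    templates = c(Z = z_tmpl, W = w_tmpl),
    target_gene = config$target_gene,
    n_multiallelic = length(multi_idx),
    decoys = config$decoy_indels)

  list(genome = genome, annotation = ann, variants = variants,
       panel = panel, truth = truth, config = config)
}

#' Orthologous promoter fixture with a planted conserved motif
#'
#' Generates `n_species` upstream sequences of i.i.d. uniform nucleotides
#' and plants the motif (forward or reverse-complement) at similar offsets
#' in a configured subset, emulating a conserved transcription-factor site
#' in orthologous promoters.
#'
#' @param n_species Number of sequences.
#' @param motif Motif to plant (A/C/G/T).
#' @param planted_fraction Fraction of sequences receiving the motif.
#' @param span Sequence length (bases).
#' @param center Approximate plant offset; jittered by up to `jitter`.
#' @param jitter Maximum absolute offset jitter.
#' @param seed Seed for reproducibility.
#' @return Named character vector of sequences with attribute `planted`, a
#'   data frame of (`seq_id`, `pos`, `strand`) for each planted copy.
#' @export
make_promoter_fixture <- function(n_species = 7L, motif = sdor_sdr_motif(),
                                  planted_fraction = 1, span = 3000L,
                                  center = 1500L, jitter = 100L, seed = 7L) {
  assert_acgt(motif, "motif")
  if (nchar(motif) >= span) stop("motif length must be below span")
  with_seed(seed, {
    seqs <- stats::setNames(vapply(seq_len(n_species), function(i) random_dna(span),
                                   character(1)),
                            sprintf("sp%d", seq_len(n_species)))
    n_plant <- min(n_species, ceiling(planted_fraction * n_species))
    planted <- data.frame(seq_id = character(0), pos = integer(0),
                          strand = character(0), stringsAsFactors = FALSE)
    for (i in seq_len(n_plant)) {
      pos <- center + sample(-jitter:jitter, 1L)
      strand <- sample(c("+", "-"), 1L)
      word <- if (strand == "+") motif else revcomp(motif)
      substr(seqs[[i]], pos, pos + nchar(motif) - 1L) <- word
      planted <- rbind(planted, data.frame(seq_id = names(seqs)[i], pos = pos,
                                           strand = strand,
                                           stringsAsFactors = FALSE))
    }
    attr(seqs, "planted") <- planted
    seqs
  })
}
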