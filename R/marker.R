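# W-linked deletion marker discovery and the in-silico PCR sexing assay:
# indel scan with a sex-pattern filter, nearest-neighbor primer melting
# temperatures, amplicon prediction and gel-pattern sex calls.

#' Scan the SDR for sex-patterned long indels
#'
#' Finds indels inside the SDR whose length (|ref| - |alt| magnitude) is at
#' least `min_len` and whose carrier pattern matches a W-linked variant:
#' heterozygous in females, absent in males.
#'
#' With the default `mode = "pooled"`, the pattern is assessed on allelic
#' depths pooled per sex (robust at low per-sample coverage, where most
#' individual het genotypes are miscalled or missing): females must show a
#' pooled alt fraction inside `female_band` at pooled depth >=
#' `min_pooled`, males a pooled alt fraction of at most `male_max`.
#' `mode = "genotype"` applies the per-genotype reading: at least
#' `female_frac` of females with non-missing calls are heterozygous and at
#' most `male_frac` of males with non-missing calls carry the alt allele
#' (appropriate when genotypes are reliable, e.g. deep coverage).
#'
#' @param table A `VariantTable`.
#' @param panel A `CohortPanel`.
#' @param sdr_interval List/vector with `scaffold`, `start`, `end`.
#' @param min_len Minimum indel length (default 41: strictly longer than 40).
#' @param mode Evidence mode, `"pooled"` (default) or `"genotype"`.
#' @param female_band Pooled-mode alt-fraction band for females.
#' @param min_pooled Pooled-mode minimum female pooled depth.
#' @param male_max Pooled-mode maximum male pooled alt fraction.
#' @param female_frac Genotype-mode minimum het fraction among females.
#' @param male_frac Genotype-mode maximum carrier fraction among males.
#' @return Data frame of candidates: `scaffold`, `pos` (anchor), `type`
#'   (`"del"`/`"ins"`), `length`, `sequence` (deleted/inserted bases),
#'   `female_support`, `male_support`, `het_in_females`, `absent_in_males`.
#' @export
scan_indels <- function(table, panel, sdr_interval, min_len = 41L,
                        mode = c("pooled", "genotype"),
                        female_band = c(0.3, 0.7), min_pooled = 10L,
                        male_max = 0.05, female_frac = 0.9, male_frac = 0.05) {
  mode <- match.arg(mode)
  panel <- match_panel(table, panel)
  vt <- vt_region(table, sdr_interval$scaffold, sdr_interval$start, sdr_interval$end)
  alt1 <- sub(",.*$", "", vt$sites$alt)
  len <- abs(nchar(vt$sites$ref) - nchar(alt1))
  idx <- which(len >= min_len)
  females <- panel$sex == "F"
  males <- panel$sex == "M"
  out <- list()
  for (i in idx) {
    if (mode == "pooled") {
      if (!table$ad_available) stop("pooled mode needs allelic depths")
      fr <- sum(vt$ad_ref[i, females]); fa <- sum(vt$ad_alt[i, females])
      mr <- sum(vt$ad_ref[i, males]); ma <- sum(vt$ad_alt[i, males])
      f_frac <- if (fr + fa > 0) fa / (fr + fa) else NA_real_
      m_frac <- if (mr + ma > 0) ma / (mr + ma) else 0
      het_f <- !is.na(f_frac) && (fr + fa) >= min_pooled &&
        f_frac >= female_band[1] && f_frac <= female_band[2]
      abs_m <- m_frac <= male_max
      f_support <- f_frac; m_support <- m_frac
    } else {
      g_f <- vt$gt[i, females]; g_m <- vt$gt[i, males]
      g_f <- g_f[g_f != "./."]; g_m <- g_m[g_m != "./."]
      f_support <- if (length(g_f)) mean(g_f %in% c("0/1", "1/0")) else 0
      m_support <- if (length(g_m)) mean(grepl("1", g_m, fixed = TRUE)) else 0
      het_f <- length(g_f) > 0 && f_support >= female_frac
      abs_m <- m_support <= male_frac
    }
    if (het_f && abs_m) {
      ref <- vt$sites$ref[i]; alt <- alt1[i]
      # strip the left-anchored shared prefix to recover the event sequence
      k <- 0L
      while (k < min(nchar(ref), nchar(alt)) &&
             substr(ref, k + 1L, k + 1L) == substr(alt, k + 1L, k + 1L)) k <- k + 1L
      seqs <- if (nchar(ref) > nchar(alt)) substring(ref, k + 1L) else substring(alt, k + 1L)
      out[[length(out) + 1L]] <- data.frame(
        scaffold = vt$sites$scaffold[i], pos = vt$sites$pos[i],
        type = if (nchar(ref) > nchar(alt)) "del" else "ins",
        length = len[i], sequence = seqs,
        female_support = f_support, male_support = m_support,
        het_in_females = het_f, absent_in_males = abs_m,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(scaffold = character(0), pos = integer(0),
                      type = character(0), length = integer(0),
                      sequence = character(0), female_support = numeric(0),
                      male_support = numeric(0), het_in_females = logical(0),
                      absent_in_males = logical(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

## ---- melting temperature --------------------------------------------------

# Nearest-neighbor parameter sets: dH in kcal/mol, dS in cal/(mol K).
# Keys cover one orientation; the complementary stack shares the values.
NN_BRESLAUER <- list(
  pairs = c(AA = 1, AT = 2, TA = 3, CA = 4, GT = 5, CT = 6, GA = 7,
            CG = 8, GC = 9, GG = 10,
            TT = 1, AT = 2, TA = 3, TG = 4, AC = 5, AG = 6, TC = 7,
            CG = 8, GC = 9, CC = 10),
  dH = c(-9.1, -8.6, -6.0, -5.8, -6.5, -7.8, -5.6, -11.9, -11.1, -11.0),
  dS = c(-24.0, -23.9, -16.9, -12.9, -17.3, -20.8, -13.5, -27.8, -26.7, -26.6)
)
NN_SANTALUCIA <- list(
  pairs = c(AA = 1, AT = 2, TA = 3, CA = 4, GT = 5, CT = 6, GA = 7,
            CG = 8, GC = 9, GG = 10,
            TT = 1, AT = 2, TA = 3, TG = 4, AC = 5, AG = 6, TC = 7,
            CG = 8, GC = 9, CC = 10),
  dH = c(-7.9, -7.2, -7.2, -8.5, -8.4, -7.8, -8.2, -10.6, -9.8, -8.0),
  dS = c(-22.2, -20.4, -21.3, -22.7, -22.4, -21.0, -22.2, -27.2, -24.4, -19.9)
)

#' Primer melting temperature by nearest-neighbor thermodynamics
#'
#' Computes the duplex melting temperature of a PCR primer from
#' nearest-neighbor stacking enthalpies and entropies.
#'
#' `method = "breslauer"` (default) uses the Breslauer 1986 parameter set
#' with the Schildkraut-Lifson salt term `16.6 log10[Na+]` and an
#' excess-primer duplex concentration term `R ln(conc)` — the classic
#' primer-design parameterization, which reproduces the published Tm values
#' of the *S. dorsalis* sexing assays to within 0.1 degree at the defaults
#' (50 mM monovalent cation, 250 nM primer, matching the assay's
#' 0.15-0.3 uM primer concentrations).
#'
#' `method = "santalucia"` uses the SantaLucia 1998 unified parameters with
#' terminal initiation penalties, the entropic salt correction
#' `0.368 (N-1) ln[Na+]` and the symmetric-duplex term `R ln(conc/4)`.
#'
#' @param sequence Primer sequence, 8-36 bases of A/C/G/T.
#' @param method Parameter set, `"breslauer"` or `"santalucia"`.
#' @param Na Monovalent cation concentration (mol/L).
#' @param conc Primer concentration (mol/L).
#' @return Melting temperature in degrees Celsius.
#' @export
#' @examples
#' primer_tm("AATTCATCCAAACCCAGCAG")  # ~59.9
primer_tm <- function(sequence, method = c("breslauer", "santalucia"),
                      Na = 0.05, conc = 250e-9) {
  method <- match.arg(method)
  sequence <- toupper(sequence)
  assert_acgt(sequence, "primer")
  n <- nchar(sequence)
  if (n < 8L || n > 36L) stop("primer length must be between 8 and 36 bases")
  tab <- if (method == "breslauer") NN_BRESLAUER else NN_SANTALUCIA
  dinucs <- substring(sequence, 1:(n - 1L), 2:n)
  idx <- tab$pairs[dinucs]
  dH <- sum(tab$dH[idx])
  dS <- sum(tab$dS[idx])
  R <- 1.987  # cal / (mol K)
  if (method == "breslauer") {
    # duplex initiation entropy depends on whether any G:C pair is present
    dS <- dS + if (grepl("[GC]", sequence)) -16.8 else -20.1
    tm_k <- 1000 * dH / (dS + R * log(conc))
    tm_k - 273.15 + 16.6 * log10(Na)
  } else {
    ends <- c(substr(sequence, 1L, 1L), substr(sequence, n, n))
    n_at <- sum(ends %in% c("A", "T"))
    n_gc <- 2L - n_at
    dH <- dH + 2.3 * n_at + 0.1 * n_gc
    dS <- dS + 4.1 * n_at - 2.8 * n_gc
    dS <- dS + 0.368 * (n - 1L) * log(Na)
    tm_k <- 1000 * dH / (dS + R * log(conc / 4))
    tm_k - 273.15
  }
}

## ---- in-silico PCR --------------------------------------------------------

# All match positions of a primer on a template (+ strand), honouring the
# mismatch budget but never allowing a mismatch in the 3'-terminal 3 bases.
primer_sites <- function(primer, template_dna, max_mismatch) {
  m <- Biostrings::matchPattern(primer, template_dna, max.mismatch = max_mismatch)
  if (!length(m) || max_mismatch == 0L) return(m)
  keep <- vapply(seq_along(m), function(i) {
    hit <- as.character(m[[i]])
    tail_len <- 3L
    substring(hit, nchar(hit) - tail_len + 1L) ==
      substring(primer, nchar(primer) - tail_len + 1L)
  }, logical(1))
  m[keep]
}

#' Predict PCR amplicons on a template
#'
#' Locates forward-primer matches and reverse-primer matches (as the
#' reverse complement) on both orientations of the template and emits an
#' amplicon for every properly oriented pair within `max_product` bases.
#' Lengths include both primer footprints. Mismatches up to `max_mismatch`
#' are tolerated anywhere except the 3'-terminal 3 bases of either primer.
#'
#' @param template Template sequence (single character string).
#' @param fwd,rev Primer sequences (A/C/G/T).
#' @param max_product Maximum product length in bases.
#' @param max_mismatch Mismatch budget per primer site (default exact).
#' @return Data frame: `start`, `end` (1-based inclusive on the template),
#'   `length`, `strand` (strand carrying the forward primer).
#' @export
in_silico_pcr <- function(template, fwd, rev, max_product = 3000L,
                          max_mismatch = 0L) {
  assert_acgt(fwd, "forward primer"); assert_acgt(rev, "reverse primer")
  template <- toupper(template)
  dna <- Biostrings::DNAString(template)
  n <- nchar(template)
  pairs <- list(list(f = fwd, r = rev, strand = "+"),
                list(f = rev, r = fwd, strand = "-"))
  out <- list()
  for (orient in pairs) {
    f_hits <- primer_sites(orient$f, dna, max_mismatch)
    r_hits <- primer_sites(revcomp(orient$r), dna, max_mismatch)
    if (!length(f_hits) || !length(r_hits)) next
    for (fi in seq_along(f_hits)) {
      fs <- Biostrings::start(f_hits)[fi]; fe <- Biostrings::end(f_hits)[fi]
      for (ri in seq_along(r_hits)) {
        rs <- Biostrings::start(r_hits)[ri]; re <- Biostrings::end(r_hits)[ri]
        if (rs > fe && re - fs + 1L <= max_product) {
          out[[length(out) + 1L]] <- data.frame(
            start = fs, end = re, length = re - fs + 1L,
            strand = orient$strand, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(0), end = integer(0),
                      length = integer(0), strand = character(0),
                      stringsAsFactors = FALSE))
  }
  unique(do.call(rbind, out))
}

#' Call sex from the band pattern of a deletion assay
#'
#' Under ZW heterogamety with a W-linked deletion, a female shows both the
#' intact-allele and the deletion-allele products, a male only the intact
#' (larger) product. Any other pattern is anomalous.
#'
#' @param amplicon_lengths Integer vector of observed product lengths for
#'   one sample (both alleles pooled, as on a gel).
#' @param size_z Expected product length on the intact (Z) allele.
#' @param size_w Expected product length on the deletion (W) allele.
#' @return `"F"`, `"M"`, or `"anomalous"`.
#' @export
#' @examples
#' call_sex(c(452, 391), 452, 391)  # "F"
#' call_sex(452, 452, 391)          # "M"
call_sex <- function(amplicon_lengths, size_z, size_w) {
  bands <- unique(amplicon_lengths)
  has_z <- size_z %in% bands
  has_w <- size_w %in% bands
  if (has_z && has_w) "F" else if (has_z) "M" else "anomalous"
}

#' Enumerate candidate primer pairs flanking a target
#'
#' Simple exhaustive primer design: every 18-22-mer of the left flank (as a
#' forward primer) and of the right flank (reverse-complemented, as a
#' reverse primer) is scored by `|Tm - target_tm|`, plus 1 when the 3' base
#' is not G/C; candidates containing a homopolymer run of 5 or more, or any
#' non-ACGT character, are excluded. The best-scoring pairs are returned;
#' when allele templates are supplied, predicted product sizes on each are
#' attached.
#'
#' @param flank_left,flank_right Flanking sequences (>= 100 bases each).
#' @param target_len Preferred primer length (ties broken toward it).
#' @param target_tm Target melting temperature (degrees C).
#' @param n_top Number of pairs to return.
#' @param templates Optional named character vector of allele templates on
#'   which to predict product sizes.
#' @param tm_method Passed to [primer_tm()].
#' @return Data frame of candidate assays sorted by combined score: `fwd`,
#'   `rev`, `tm_fwd`, `tm_rev`, `score`, and `size_<allele>` columns when
#'   `templates` were given. Empty (with attribute `diagnostics`) when no
#'   candidate passes the constraints.
#' @export
design_primers <- function(flank_left, flank_right, target_len = 20L,
                           target_tm = 60.0, n_top = 10L, templates = NULL,
                           tm_method = "breslauer") {
  if (nchar(flank_left) < 100L || nchar(flank_right) < 100L) {
    stop("flanks must be at least 100 bases")
  }
  enumerate <- function(flank, reverse) {
    cand <- character(0)
    for (len in 18:22) {
      n <- nchar(flank)
      if (n < len) next
      cand <- c(cand, substring(flank, 1:(n - len + 1L), len:n))
    }
    cand <- unique(cand)
    if (reverse) cand <- revcomp(cand)
    ok <- !grepl("[^ACGT]", cand) & !grepl("A{5,}|C{5,}|G{5,}|T{5,}", cand)
    cand <- cand[ok]
    if (!length(cand)) return(NULL)
    tm <- vapply(cand, primer_tm, numeric(1), method = tm_method)
    gc3 <- substring(cand, nchar(cand)) %in% c("G", "C")
    score <- abs(tm - target_tm) + ifelse(gc3, 0, 1) +
      0.01 * abs(nchar(cand) - target_len)
    d <- data.frame(seq = cand, tm = tm, score = score,
                    stringsAsFactors = FALSE, row.names = NULL)
    d[order(d$score, d$seq), ]
  }
  fw <- enumerate(toupper(flank_left), reverse = FALSE)
  rv <- enumerate(toupper(flank_right), reverse = TRUE)
  if (is.null(fw) || is.null(rv)) {
    out <- data.frame(fwd = character(0), rev = character(0),
                      tm_fwd = numeric(0), tm_rev = numeric(0),
                      score = numeric(0), stringsAsFactors = FALSE)
    attr(out, "diagnostics") <- "no candidate passed the composition constraints"
    return(out)
  }
  top_f <- utils::head(fw, n_top)
  top_r <- utils::head(rv, n_top)
  grid <- expand.grid(fi = seq_len(nrow(top_f)), ri = seq_len(nrow(top_r)))
  out <- data.frame(fwd = top_f$seq[grid$fi], rev = top_r$seq[grid$ri],
                    tm_fwd = top_f$tm[grid$fi], tm_rev = top_r$tm[grid$ri],
                    score = top_f$score[grid$fi] + top_r$score[grid$ri],
                    stringsAsFactors = FALSE)
  out <- out[order(out$score), ]
  out <- utils::head(out, n_top)
  rownames(out) <- NULL
  if (!is.null(templates)) {
    for (al in names(templates)) {
      sizes <- vapply(seq_len(nrow(out)), function(i) {
        amp <- in_silico_pcr(templates[[al]], out$fwd[i], out$rev[i])
        if (nrow(amp)) min(amp$length) else NA_integer_
      }, integer(1))
      out[[paste0("size_", al)]] <- sizes
    }
  }
  out
}
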