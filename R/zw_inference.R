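# Heterogamety classification from heterozygosity ratios: compare
# female/male heterozygous-SNP counts in the SDR against size-matched
# random control regions. At ~2x per-sample coverage, individual genotype
# calls are unreliable, so heterozygosity is assessed on allelic depths
# pooled across each population-by-sex group.

#' Count pooled-heterozygous SNPs for a group in a region
#'
#' For each SNP in the region, allelic depths are pooled across all
#' individuals of the group (one population, one sex); the SNP counts as
#' heterozygous when the pooled alt fraction lies in `[lo, hi]` (inclusive)
#' and the pooled depth is at least `min_depth`. A per-individual variant of
#' the rule (`per_individual = TRUE`) counts a SNP when every individual
#' with nonzero depth has an allelic ratio inside the band.
#'
#' @param table A `VariantTable` with allelic depths.
#' @param panel A `CohortPanel`.
#' @param region List or vector with `scaffold`, `start`, `end`.
#' @param population Population label selecting the group.
#' @param sex `"F"` or `"M"`.
#' @param lo,hi Inclusive bounds of the heterozygous allelic-ratio band.
#' @param min_depth Minimum pooled depth for a SNP to be assessable.
#' @param per_individual Use the per-individual reading of the rule instead
#'   of pooling (not the default; see Details in the vignette).
#' @return Integer count of heterozygous SNPs.
#' @export
group_het_sites <- function(table, panel, region, population, sex,
                            lo = 0.4, hi = 0.6, min_depth = 10L,
                            per_individual = FALSE) {
  if (!table$ad_available) stop("variant table has no allelic depths")
  panel <- match_panel(table, panel)
  grp <- which(panel$population == population & panel$sex == sex)
  if (!length(grp)) stop("empty group: ", population, "/", sex)
  vt <- vt_region(table, region$scaffold, region$start, region$end)
  is_snp <- nchar(vt$sites$ref) == 1L & nchar(vt$sites$alt) == 1L
  vt <- vt_subset(vt, is_snp)
  if (!n_sites(vt)) return(0L)
  ref <- vt$ad_ref[, grp, drop = FALSE]
  alt <- vt$ad_alt[, grp, drop = FALSE]
  if (per_individual) {
    d <- ref + alt
    frac <- alt / d
    ok_ind <- frac >= lo & frac <= hi
    ok_ind[d == 0L] <- NA
    n_inf <- rowSums(!is.na(ok_ind))
    counted <- n_inf > 0L & rowSums(ok_ind, na.rm = TRUE) == n_inf &
      rowSums(d) >= min_depth
    return(sum(counted))
  }
  pr <- rowSums(ref); pa <- rowSums(alt)
  depth <- pr + pa
  if (all(depth == 0L)) {
    warning("zero pooled depth at every site in region")
    return(0L)
  }
  frac <- ifelse(depth > 0L, pa / depth, NA_real_)
  sum(depth >= min_depth & frac >= lo & frac <= hi, na.rm = TRUE)
}

#' Female/male heterozygosity ratio
#'
#' Ratio of female to male heterozygous-SNP counts, rounded half away from
#' zero to `decimals` places (the convention of the published ratio table).
#'
#' @param female_count,male_count Non-negative counts.
#' @param decimals Decimal places of the reported ratio.
#' @return The rounded ratio, or `NA` when `male_count` is zero.
#' @export
#' @examples
#' het_ratio(90, 20)   # 4.5
#' het_ratio(123, 20)  # 6.2
het_ratio <- function(female_count, male_count, decimals = 1L) {
  out <- rep(NA_real_, length(female_count))
  ok <- male_count > 0
  scale <- 10^decimals
  # scale before dividing so exact halves (e.g. 1230/20) survive binary math
  out[ok] <- floor(female_count[ok] * scale / male_count[ok] + 0.5 + 1e-9) / scale
  out
}

#' Random control regions matched to the SDR
#'
#' Places `n` intervals of exactly the SDR's length, uniformly at random, on
#' `n` distinct scaffolds other than the SDR scaffold.
#'
#' @param genome Named character vector of scaffolds.
#' @param sdr_interval List/vector with `scaffold`, `start`, `end`.
#' @param n Number of control regions.
#' @param seed Seed for placement.
#' @return Data frame with columns `scaffold`, `start`, `end`.
#' @export
random_control_regions <- function(genome, sdr_interval, n = 5L, seed = NULL) {
  len <- sdr_interval$end - sdr_interval$start + 1L
  eligible <- setdiff(names(genome)[nchar(genome) >= len], sdr_interval$scaffold)
  if (length(eligible) < n) {
    stop("need at least ", n, " non-SDR scaffolds of length >= ", len)
  }
  with_seed(seed, {
    chosen <- sample(eligible, n)
    start <- vapply(chosen, function(s)
      sample.int(nchar(genome[[s]]) - len + 1L, 1L), integer(1))
    data.frame(scaffold = chosen, start = unname(start),
               end = unname(start) + len - 1L, stringsAsFactors = FALSE,
               row.names = NULL)
  })
}

#' Heterozygosity-ratio table for the SDR and control regions
#'
#' Builds the per-population table of female and male heterozygous-SNP
#' counts with their ratio, for the SDR and for `n_controls` size-matched
#' random regions.
#'
#' @param table A `VariantTable` with allelic depths.
#' @param panel A `CohortPanel`.
#' @param genome Named character vector of scaffolds (control placement).
#' @param sdr List with `scaffold`, `start`, `end`.
#' @param n_controls Number of random control regions.
#' @param seed Seed for control placement.
#' @param ... Passed to [group_het_sites()].
#' @return Data frame of class `HetRatioReport` with columns `population`,
#'   `region` (`"SDR"`/`"Random"`), `scaffold`, `start`, `end`, `female`,
#'   `male`, `ratio`.
#' @export
het_ratio_report <- function(table, panel, genome, sdr, n_controls = 5L,
                             seed = NULL, ...) {
  regions <- rbind(data.frame(scaffold = sdr$scaffold, start = sdr$start,
                              end = sdr$end, region = "SDR",
                              stringsAsFactors = FALSE),
                   cbind(random_control_regions(genome, sdr, n_controls, seed),
                         region = "Random"))
  pops <- unique(panel$population)
  rows <- list()
  for (p in pops) {
    for (r in seq_len(nrow(regions))) {
      reg <- list(scaffold = regions$scaffold[r], start = regions$start[r],
                  end = regions$end[r])
      f <- group_het_sites(table, panel, reg, p, "F", ...)
      m <- group_het_sites(table, panel, reg, p, "M", ...)
      rows[[length(rows) + 1L]] <-
        data.frame(population = p, region = regions$region[r],
                   scaffold = reg$scaffold, start = reg$start, end = reg$end,
                   female = f, male = m, ratio = het_ratio(f, m),
                   stringsAsFactors = FALSE)
    }
  }
  structure(do.call(rbind, rows), class = c("HetRatioReport", "data.frame"))
}

#' Classify the heterogametic system from a heterozygosity-ratio table
#'
#' ZW when every population's SDR ratio is at least `ratio_hi` while all
#' control ratios stay strictly inside `(ratio_lo, ratio_hi)`; XY when every
#' SDR ratio is at most `ratio_lo` under the same control condition;
#' undetermined otherwise.
#'
#' @param report A `HetRatioReport` (or data frame with `population`,
#'   `region`, `ratio`).
#' @param ratio_hi,ratio_lo Decision thresholds.
#' @return `"ZW"`, `"XY"`, or `"undetermined"`.
#' @export
classify_system <- function(report, ratio_hi = 2.0, ratio_lo = 0.5) {
  sdr <- report$ratio[report$region == "SDR"]
  ctrl <- report$ratio[report$region == "Random"]
  if (!length(sdr) || !length(ctrl) || anyNA(ctrl)) return("undetermined")
  controls_flat <- all(ctrl > ratio_lo & ctrl < ratio_hi)
  if (!controls_flat) return("undetermined")
  if (!anyNA(sdr) && all(sdr >= ratio_hi)) return("ZW")
  # NA SDR ratio means a zero male count: infinitely female-skewed
  if (all(is.na(sdr) | sdr >= ratio_hi)) return("ZW")
  if (!anyNA(sdr) && all(sdr <= ratio_lo)) return("XY")
  "undetermined"
}
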