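# Published inputs from the original California yellowtail (Seriola dorsalis)
# sexing study that this package's assays are built around. These are inputs
# to the analysis (primer sequences, the W-linked deletion allele, observed
# heterozygosity counts), not fitted quantities.

#' The W-linked 61-bp deletion allele of *Seriola dorsalis*
#'
#' The female-specific deletion found on scaffold 22 of the *S. dorsalis*
#' assembly, 954 bp upstream of the estradiol 17-beta-dehydrogenase gene
#' (*hsd17b1*). Females (ZW) are heterozygous for the deletion; males (ZZ)
#' lack it.
#'
#' @return A single character string (61 bases, the deleted sequence).
#' @export
#' @examples
#' nchar(sdor_deletion_seq())
sdor_deletion_seq <- function() {
  "CGTTCATGATTACTACTTTTACACAAATTTACACAAAAGACATCTGTACCAAAGAACAAAA"
}

#' PCR sexing assays for *Seriola dorsalis*
#'
#' The two primer pairs (SdorDel01, SdorDel02) spanning the W-linked 61-bp
#' deletion, with their published melting temperatures and expected product
#' sizes on the Z (no deletion) and W (deletion) alleles.
#'
#' @return Data frame with one row per assay: `assay`, `fwd`, `rev`,
#'   `tm_fwd`, `tm_rev` (degrees C), `size_z`, `size_w` (bp).
#' @export
sdor_del_assays <- function() {
  data.frame(
    assay = c("SdorDel01", "SdorDel02"),
    fwd = c("AATTCATCCAAACCCAGCAG", "TGACAACAAGGCAACAGGAG"),
    rev = c("GGTCTTGTCAACTGCGATCA", "TTGGCCTTTCTTTTGACCAC"),
    tm_fwd = c(59.9, 59.9),
    tm_rev = c(59.8, 60.1),
    size_z = c(452L, 282L),
    size_w = c(391L, 221L),
    stringsAsFactors = FALSE
  )
}

#' Conserved promoter motif overlapping the W-linked deletion
#'
#' The 15-mer found by cross-species promoter footprinting upstream of
#' *hsd17b1*; it overlaps the 61-bp deletion on the negative strand.
#'
#' @return A single character string.
#' @export
sdor_sdr_motif <- function() "GTCTTTTGTTCTTTG"

#' Observed heterozygous-SNP counts by population and region
#'
#' Female and male heterozygous-SNP counts for the *S. dorsalis* SDR and for
#' five size-matched random control regions, in each of the three sampling
#' populations (CI = Cedros Island, SD = San Diego, LP = La Paz), as reported
#' in the original study. Used with [het_ratio()] to reproduce the
#' female/male ratio table.
#'
#' @return Data frame with columns `population`, `region` (`"SDR"` or
#'   `"Random"`), `female`, `male`.
#' @export
sdor_het_counts <- function() {
  data.frame(
    population = c("CI", "SD", "LP",
                   "LP", "LP", "LP", "LP",
                   "SD", "SD", "SD", "SD", "SD",
                   "CI", "CI", "CI", "CI", "CI"),
    region = c(rep("SDR", 3), rep("Random", 14)),
    female = c(90L, 106L, 123L,
               140L, 129L, 82L, 261L,
               161L, 123L, 101L, 58L, 238L,
               146L, 113L, 84L, 55L, 262L),
    male = c(20L, 27L, 20L,
             141L, 107L, 91L, 226L,
             142L, 97L, 82L, 66L, 263L,
             170L, 131L, 91L, 65L, 238L),
    stringsAsFactors = FALSE
  )
}
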