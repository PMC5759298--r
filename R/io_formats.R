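# Standard-format I/O and the core containers shared by every stage.
#
# Conventions (package-wide): all coordinates are 1-based and inclusive;
# sequences are stored as uppercase character strings; genotypes are
# unphased "a/b" strings with "./." for missing.

#' Construct a variant table
#'
#' The central per-site container: site metadata plus per-sample genotype
#' calls and allelic depths, as produced by joint variant calling on a
#' resequencing cohort (GT and AD FORMAT fields of a VCF).
#'
#' @param sites Data frame with columns `scaffold`, `pos` (1-based), `ref`,
#'   `alt` (comma-separated for multi-allelic sites).
#' @param gt Character matrix (sites x samples) of genotype strings such as
#'   `"0/1"`; `"./."` denotes missing.
#' @param ad_ref,ad_alt Integer matrices (sites x samples) of reference and
#'   first-alternate read depths; `NA` throughout when the source had no AD.
#' @param ad_other Integer matrix of read depth summed over any further
#'   alternate alleles (0 for biallelic sites).
#' @param samples Character vector of sample ids (column names).
#' @return An object of class `VariantTable`.
#' @export
variant_table <- function(sites, gt, ad_ref, ad_alt, ad_other = NULL, samples = colnames(gt)) {
  stopifnot(is.data.frame(sites),
            all(c("scaffold", "pos", "ref", "alt") %in% names(sites)),
            nrow(sites) == nrow(gt))
  if (is.null(ad_other)) {
    ad_other <- matrix(0L, nrow = nrow(gt), ncol = ncol(gt))
  }
  sites$scaffold <- as.character(sites$scaffold)
  sites$pos <- as.integer(sites$pos)
  sites$ref <- as.character(sites$ref)
  sites$alt <- as.character(sites$alt)
  rownames(sites) <- NULL
  for (sc in unique(sites$scaffold)) {
    p <- sites$pos[sites$scaffold == sc]
    if (is.unsorted(p)) stop("positions must be sorted within scaffold ", sc)
  }
  if (any(ad_ref < 0, na.rm = TRUE) || any(ad_alt < 0, na.rm = TRUE)) {
    stop("allelic depths must be non-negative")
  }
  structure(list(sites = sites, gt = gt, ad_ref = ad_ref, ad_alt = ad_alt,
                 ad_other = ad_other, samples = as.character(samples),
                 ad_available = !all(is.na(ad_ref))),
            class = "VariantTable")
}

#' @export
print.VariantTable <- function(x, ...) {
  cat("VariantTable:", nrow(x$sites), "sites x", length(x$samples), "samples\n")
  cat("  scaffolds:", paste(utils::head(unique(x$sites$scaffold), 5), collapse = ", "))
  if (length(unique(x$sites$scaffold)) > 5) cat(", ...")
  cat("\n  allelic depths:", if (x$ad_available) "present" else "absent", "\n")
  invisible(x)
}

#' Number of sites / samples in a variant table
#' @param x A `VariantTable`.
#' @return Integer count.
#' @export
n_sites <- function(x) nrow(x$sites)

#' @rdname n_sites
#' @export
n_samples <- function(x) length(x$samples)

#' Subset a variant table by site index
#'
#' @param x A `VariantTable`.
#' @param idx Integer or logical index over sites.
#' @return A `VariantTable` with the selected sites, order preserved.
#' @export
vt_subset <- function(x, idx) {
  variant_table(x$sites[idx, , drop = FALSE],
                x$gt[idx, , drop = FALSE],
                x$ad_ref[idx, , drop = FALSE],
                x$ad_alt[idx, , drop = FALSE],
                x$ad_other[idx, , drop = FALSE],
                x$samples)
}

#' Subset a variant table to a genomic interval
#'
#' @param x A `VariantTable`.
#' @param scaffold Scaffold id.
#' @param start,end 1-based inclusive bounds.
#' @return A `VariantTable` restricted to the interval.
#' @export
vt_region <- function(x, scaffold, start, end) {
  vt_subset(x, x$sites$scaffold == scaffold & x$sites$pos >= start & x$sites$pos <= end)
}

#' Construct a cohort panel
#'
#' Sample sheet for a sexed cohort: id, phenotypic sex and sampling
#' population. This is the phenotype side of the association scan.
#'
#' @param sample Character vector of sample ids.
#' @param sex Character vector, `"F"` or `"M"`.
#' @param population Character vector of population labels.
#' @return A data frame of class `CohortPanel`.
#' @export
cohort_panel <- function(sample, sex, population) {
  sex <- as.character(sex)
  if (!all(sex %in% c("F", "M"))) stop("sex must be 'F' or 'M'")
  if (anyDuplicated(sample)) stop("sample ids must be unique")
  structure(data.frame(sample = as.character(sample), sex = sex,
                       population = as.character(population),
                       stringsAsFactors = FALSE),
            class = c("CohortPanel", "data.frame"))
}

# Panels must cover the table's samples exactly, in order.
match_panel <- function(table, panel) {
  if (!setequal(panel$sample, table$samples)) {
    stop("panel sample ids do not match variant table columns")
  }
  panel[match(table$samples, panel$sample), , drop = FALSE]
}

## ---- FASTA ----------------------------------------------------------------

#' Read a FASTA file into a reference genome
#'
#' The genome container is a named character vector (scaffold id -> uppercase
#' sequence). Lowercase input is uppercased; characters outside the IUPAC
#' nucleotide alphabet are an error.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of scaffold sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                  error = function(e) stop("FASTA parse error in ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  if (length(set) == 0) stop("FASTA file has no records: ", path)
  if (any(Biostrings::width(set) == 0)) {
    stop("empty FASTA record: ", names(set)[Biostrings::width(set) == 0][1])
  }
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) stop("duplicate scaffold ids in ", path)
  out <- toupper(as.character(set))
  bad <- grepl("[^ACGTRYSWKMBDHVN-]", out)
  if (any(bad)) {
    stop("non-IUPAC nucleotide characters in record ", ids[bad][1], " of ", path)
  }
  names(out) <- ids
  out
}

#' Write a reference genome to FASTA
#'
#' @param genome Named character vector of sequences.
#' @param path Output path.
#' @param width Line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path, width = 70) {
  set <- Biostrings::DNAStringSet(toupper(genome))
  names(set) <- names(genome)
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

## ---- GFF3 -----------------------------------------------------------------

#' Read gene annotations from a GFF3 file
#'
#' Keeps `gene` features only; the gene id is taken from the `ID=` attribute.
#'
#' @param path Path to a GFF3 file.
#' @return Data frame with columns `scaffold`, `start`, `end`, `strand`,
#'   `gene_id` (1-based inclusive coordinates).
#' @export
read_gff <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  g <- ape::read.gff(path)
  g <- g[g$type == "gene", , drop = FALSE]
  ids <- sub(".*ID=([^;]+).*", "\\1", g$attributes)
  ann <- gene_annotation(scaffold = as.character(g$seqid), start = g$start,
                         end = g$end, strand = as.character(g$strand),
                         gene_id = ids)
  ann
}

#' Construct a gene annotation table
#'
#' @param scaffold,start,end,strand,gene_id Per-gene fields; coordinates are
#'   1-based inclusive, strand is `"+"` or `"-"`.
#' @return Data frame of class `GeneAnnotation`.
#' @export
gene_annotation <- function(scaffold, start, end, strand, gene_id) {
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (any(start < 1) || any(end < start)) stop("need 1 <= start <= end")
  if (anyDuplicated(gene_id)) stop("gene ids must be unique")
  structure(data.frame(scaffold = as.character(scaffold),
                       start = as.integer(start), end = as.integer(end),
                       strand = as.character(strand),
                       gene_id = as.character(gene_id),
                       stringsAsFactors = FALSE),
            class = c("GeneAnnotation", "data.frame"))
}

#' Write gene annotations to GFF3
#'
#' @param annotation A `GeneAnnotation` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff <- function(annotation, path) {
  lines <- c("##gff-version 3",
             sprintf("%s\tzwseeker\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     annotation$scaffold, annotation$start, annotation$end,
                     annotation$strand, annotation$gene_id))
  writeLines(lines, path)
  invisible(path)
}

## ---- VCF ------------------------------------------------------------------

#' Read a VCF into a variant table
#'
#' Requires a per-sample GT field; AD is used when present and flagged absent
#' otherwise. Multi-allelic records are retained (see [keep_biallelic()]).
#'
#' @param path Path to a VCF 4.x file (plain or gzipped).
#' @return A [variant_table()].
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fmt_parts <- strsplit(v@gt[, "FORMAT"], ":", fixed = TRUE)
  if (!all(vapply(fmt_parts, function(p) "GT" %in% p, logical(1)))) {
    stop("VCF has no GT FORMAT field: ", path)
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  gt[is.na(gt)] <- "./."
  gt <- gsub("|", "/", gt, fixed = TRUE)
  samples <- colnames(v@gt)[-1]
  nsite <- nrow(v@fix)
  ad_ref <- matrix(NA_integer_, nsite, length(samples))
  ad_alt <- matrix(NA_integer_, nsite, length(samples))
  ad_other <- matrix(0L, nsite, length(samples))
  has_ad <- all(vapply(fmt_parts, function(p) "AD" %in% p, logical(1)))
  if (has_ad) {
    ad <- vcfR::extract.gt(v, element = "AD")
    parts <- strsplit(as.vector(ad), ",", fixed = TRUE)
    r <- vapply(parts, function(p) if (length(p) >= 1) suppressWarnings(as.integer(p[1])) else NA_integer_, integer(1))
    a <- vapply(parts, function(p) if (length(p) >= 2) suppressWarnings(as.integer(p[2])) else NA_integer_, integer(1))
    o <- vapply(parts, function(p) if (length(p) >= 3) sum(suppressWarnings(as.integer(p[-(1:2)]))) else 0L, integer(1))
    ad_ref <- matrix(r, nsite, length(samples))
    ad_alt <- matrix(a, nsite, length(samples))
    ad_other <- matrix(o, nsite, length(samples))
  } else {
    warning("VCF has no AD FORMAT field; allelic depths recorded as unknown")
  }
  colnames(gt) <- samples
  sites <- data.frame(scaffold = as.character(v@fix[, "CHROM"]),
                      pos = as.integer(v@fix[, "POS"]),
                      ref = as.character(v@fix[, "REF"]),
                      alt = as.character(v@fix[, "ALT"]),
                      stringsAsFactors = FALSE)
  variant_table(sites, gt, ad_ref, ad_alt, ad_other, samples)
}

#' Write a variant table as VCF 4.2
#'
#' Emits GT:AD per sample. Sites with one or two ALT alleles round-trip
#' exactly; depth beyond the second ALT is collapsed (with a warning).
#'
#' @param table A `VariantTable`.
#' @param panel Optional `CohortPanel`; when given, sample order is checked.
#' @param path Output path (plain text).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(table, panel = NULL, path) {
  if (!is.null(panel)) match_panel(table, panel)
  n_alt <- lengths(strsplit(table$sites$alt, ",", fixed = TRUE))
  if (any(n_alt > 2)) warning("sites with >2 ALT alleles: extra allele depths are collapsed")
  gt <- table$gt
  if (table$ad_available) {
    ad <- matrix(paste0(table$ad_ref, ",", table$ad_alt), nrow(gt), ncol(gt))
    multi <- which(n_alt >= 2)
    if (length(multi)) {
      ad[multi, ] <- paste0(table$ad_ref[multi, ], ",", table$ad_alt[multi, ],
                            ",", table$ad_other[multi, ])
    }
    body <- matrix(paste0(gt, ":", ad), nrow(gt), ncol(gt))
    fmt <- "GT:AD"
  } else {
    body <- gt
    fmt <- "GT"
  }
  fix <- sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t.\t%s",
                 table$sites$scaffold, table$sites$pos,
                 table$sites$ref, table$sites$alt, fmt)
  rows <- paste(fix, apply(body, 1, paste, collapse = "\t"), sep = "\t")
  if (nrow(gt) == 0) rows <- character(0)
  header <- c("##fileformat=VCFv4.2",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", table$samples), collapse = "\t"))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Keep only biallelic sites
#'
#' Multi-allelic records are retained at parse time so that this filter is an
#' observable, testable step (mirroring the reduction of a raw call set to
#' its biallelic subset before association).
#'
#' @param table A `VariantTable`.
#' @return A `VariantTable` containing only sites with exactly one ALT
#'   allele, original order preserved.
#' @export
keep_biallelic <- function(table) {
  keep <- !grepl(",", table$sites$alt, fixed = TRUE)
  vt_subset(table, keep)
}

## ---- phenotype panel ------------------------------------------------------

#' Read a cohort panel from a tab-separated phenotype file
#'
#' Expected header: `sample<TAB>sex<TAB>population`.
#'
#' @param path Path to the TSV file.
#' @return A [cohort_panel()].
#' @export
read_panel <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample", "sex", "population") %in% names(d))) {
    stop("phenotype file must have header: sample\tsex\tpopulation")
  }
  cohort_panel(d$sample, d$sex, d$population)
}

#' Write a cohort panel to a tab-separated phenotype file
#'
#' @param panel A `CohortPanel`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  utils::write.table(panel, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
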