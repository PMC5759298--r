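# Assembly curation: drop short scaffolds, scaffolds largely contained in a
# larger scaffold, and gene-less small scaffolds.

# Canonical k-mer set of a sequence (lexicographic min of k-mer and its
# reverse complement), via Biostrings for speed.
canonical_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  kmers <- substring(seq, 1:(n - k + 1), k:n)
  keep <- !grepl("[^ACGT]", kmers)
  kmers <- kmers[keep]
  if (!length(kmers)) return(character(0))
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(kmers)))
  pmin(kmers, rc)
}

#' Fraction of a scaffold's k-mers contained in a larger scaffold
#'
#' Alignment-free containment proxy: the fraction of the query's canonical
#' k-mers (lexicographic minimum of each k-mer and its reverse complement)
#' that occur among the subject's canonical k-mers.
#'
#' @param query,subject Scaffold sequences; `subject` must be the longer.
#' @param k K-mer size (>= 11).
#' @return Containment fraction in `[0, 1]`; `NaN` when the query yields no
#'   valid k-mer.
#' @export
containment_fraction <- function(query, subject, k = 21L) {
  if (k < 11L) stop("k must be at least 11")
  if (nchar(query) >= nchar(subject)) {
    stop("query must be strictly shorter than subject")
  }
  qk <- canonical_kmers(query, k)
  if (!length(qk)) return(NaN)
  sk <- unique(canonical_kmers(subject, k))
  sum(qk %in% sk) / length(qk)
}

#' Curate an assembly by length, containment and gene content
#'
#' A scaffold is retained iff its length is at least `min_len`, its k-mer
#' containment fraction against every strictly larger scaffold is below
#' `containment`, and it either carries an annotated gene or is longer than
#' `gene_or_len` bases. Boundary semantics: length exactly `min_len` is
#' kept; a gene-less scaffold of exactly `gene_or_len` is removed.
#'
#' @param genome Named character vector of scaffold sequences.
#' @param annotation A `GeneAnnotation` (used for the has-gene flag).
#' @param min_len Minimum scaffold length (kept when `length >= min_len`).
#' @param containment Containment threshold (removed when `>= containment`).
#' @param gene_or_len Gene-less scaffolds must exceed this length.
#' @param k K-mer size for [containment_fraction()].
#' @return List with `retained` (character vector of ids) and `log`, a
#'   per-scaffold data frame recording length, gene flag, the maximum
#'   containment fraction, the decision and the rule that removed it
#'   (`"min_len"`, `"containment"`, `"gene_or_len"`, or `""`).
#' @export
filter_scaffolds <- function(genome, annotation, min_len = 800L,
                             containment = 0.90, gene_or_len = 10000L,
                             k = 21L) {
  ids <- names(genome)
  lens <- nchar(genome)
  has_gene <- ids %in% annotation$scaffold
  ord <- order(lens, decreasing = TRUE)

  kmer_sets <- vector("list", length(ids))
  names(kmer_sets) <- ids
  max_cont <- stats::setNames(rep(0, length(ids)), ids)
  for (i in ids) {
    larger <- ids[lens > lens[[i]]]
    if (!length(larger)) next
    qk <- canonical_kmers(genome[[i]], k)
    if (!length(qk)) { max_cont[[i]] <- NaN; next }
    for (j in larger) {
      if (is.null(kmer_sets[[j]])) kmer_sets[[j]] <- unique(canonical_kmers(genome[[j]], k))
      frac <- sum(qk %in% kmer_sets[[j]]) / length(qk)
      if (frac > max_cont[[i]]) max_cont[[i]] <- frac
    }
  }

  reason <- character(length(ids))
  retained <- logical(length(ids))
  for (i in seq_along(ids)) {
    if (lens[i] < min_len) {
      reason[i] <- "min_len"
    } else if (!is.nan(max_cont[i]) && max_cont[i] >= containment) {
      reason[i] <- "containment"
    } else if (!has_gene[i] && lens[i] <= gene_or_len) {
      reason[i] <- "gene_or_len"
    } else {
      retained[i] <- TRUE
    }
  }
  log <- data.frame(id = ids, length = as.integer(lens), has_gene = has_gene,
                    max_containment = unname(max_cont), retained = retained,
                    reason = reason, stringsAsFactors = FALSE, row.names = NULL)
  list(retained = ids[retained], log = log)
}
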