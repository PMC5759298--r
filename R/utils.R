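# Internal helpers shared across modules.

#' Reverse complement of a DNA string
#'
#' Thin wrapper around [Biostrings::reverseComplement()] operating on plain
#' character vectors.
#'
#' @param x Character vector of DNA sequences (IUPAC letters).
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' revcomp("GTCTTTTGTTCTTTG")
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Round half away from zero
#'
#' Base `round()` rounds half to even; ratio tables in this package follow the
#' convention of rounding halves away from zero (so 61.5 tenths -> 6.2, not 6.1).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal digits.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  # small epsilon guards against 61.499999999 artefacts from binary division
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

#' Generate a random DNA sequence
#'
#' Uniform i.i.d. nucleotides; uses the current RNG state (callers seed).
#'
#' @param n Length in bases.
#' @return A single character string of length `n`.
#' @export
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG
# stream. All seeded operations in the package go through this.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(expr)
}

# Check a sequence uses only A/C/G/T (primers, motifs: N is disallowed).
assert_acgt <- function(x, what = "sequence") {
  bad <- grepl("[^ACGT]", x)
  if (any(bad)) {
    stop(what, " contains characters other than A/C/G/T: ",
         paste(unique(unlist(strsplit(gsub("[ACGT]", "", x[bad]), ""))), collapse = ", "),
         call. = FALSE)
  }
  invisible(x)
}

# 1-based inclusive substring of a scaffold, truncated to its bounds.
seq_window <- function(seq, start, end) {
  start <- max(1L, start)
  end <- min(nchar(seq), end)
  if (end < start) return("")
  substr(seq, start, end)
}
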