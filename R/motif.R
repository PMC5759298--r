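# Phylogenetic footprinting of the deletion: upstream extraction, shared
# consensus-word discovery across orthologous promoters, PWM relative
# scoring/scanning and the deletion-overlap test.

#' Extract the upstream (promoter) region of a gene
#'
#' For a plus-strand gene, the `span` bases ending immediately before the
#' gene start (5' to 3'); for a minus-strand gene, the reverse complement of
#' the `span` bases starting immediately after the gene end. Truncated at
#' scaffold edges.
#'
#' @param genome Named character vector of scaffolds.
#' @param annotation A `GeneAnnotation`.
#' @param gene_id Gene id.
#' @param span Upstream span in bases.
#' @return The upstream sequence (possibly shorter than `span` at a
#'   scaffold edge; empty with a warning when there is no upstream base).
#' @export
extract_upstream <- function(genome, annotation, gene_id, span = 3000L) {
  g <- annotation[annotation$gene_id == gene_id, , drop = FALSE]
  if (!nrow(g)) stop("no such gene: ", gene_id)
  seq <- genome[[g$scaffold]]
  if (g$strand == "+") {
    out <- seq_window(seq, g$start - span, g$start - 1L)
  } else {
    out <- seq_window(seq, g$end + 1L, g$end + span)
    if (nchar(out)) out <- revcomp(out)
  }
  if (!nchar(out)) warning("gene ", gene_id, " has no upstream sequence")
  out
}

#' Find motifs shared across orthologous sequences
#'
#' Seeded consensus-word enumeration: every `width`-mer of the first
#' sequence is tested against all sequences for matches within
#' `max_mismatch` mismatches on either strand; words present in at least
#' `min_seqs` sequences are reported, ranked by the number of sequences
#' containing a match and then by total match count. Overlapping reported
#' words (by their first occurrence in the seed sequence) are merged to the
#' best-ranked representative. This is a deliberately simple stand-in for
#' EM-based motif discovery; planted conserved words are recovered exactly.
#'
#' @param sequences Named character vector (>= 2 sequences).
#' @param width Motif width.
#' @param max_mismatch Mismatch tolerance per site.
#' @param min_seqs Minimum number of sequences containing the word.
#' @param max_report Cap on the number of reported motifs.
#' @return List with `motifs` (data frame: `motif`, `n_seqs`,
#'   `total_matches`) and `hits` (data frame: `motif`, `seq_id`, `pos`,
#'   `strand`), both ranked.
#' @export
find_shared_motifs <- function(sequences, width = 15L, max_mismatch = 2L,
                               min_seqs = length(sequences) %/% 2L + 1L,
                               max_report = 10L) {
  if (length(sequences) < 2L) stop("need at least 2 sequences")
  if (width > min(nchar(sequences))) stop("width exceeds the shortest sequence")
  if (is.null(names(sequences))) names(sequences) <- sprintf("seq%d", seq_along(sequences))
  seed <- sequences[[1]]
  words <- unique(substring(seed, 1:(nchar(seed) - width + 1L), width:nchar(seed)))
  words <- words[!grepl("[^ACGT]", words)]
  set <- Biostrings::DNAStringSet(sequences)
  rcset <- Biostrings::reverseComplement(set)
  n_fwd <- vapply(words, function(w)
    Biostrings::vcountPattern(w, set, max.mismatch = max_mismatch), integer(length(set)))
  n_rev <- vapply(words, function(w)
    Biostrings::vcountPattern(w, rcset, max.mismatch = max_mismatch), integer(length(set)))
  if (length(sequences) == 1L) dim(n_fwd) <- dim(n_rev) <- c(1L, length(words))
  counts <- n_fwd + n_rev
  n_seqs <- colSums(counts > 0L)
  total <- colSums(counts)
  # exact-match support breaks ties between a conserved word and its
  # one-off shifted variants (which also clear the mismatch budget)
  e_fwd <- vapply(words, function(w)
    Biostrings::vcountPattern(w, set, max.mismatch = 0L), integer(length(set)))
  e_rev <- vapply(words, function(w)
    Biostrings::vcountPattern(w, rcset, max.mismatch = 0L), integer(length(set)))
  n_exact <- colSums(e_fwd + e_rev)
  cand <- which(n_seqs >= min_seqs)
  if (!length(cand)) {
    return(list(motifs = data.frame(motif = character(0), n_seqs = integer(0),
                                    total_matches = integer(0)),
                hits = data.frame(motif = character(0), seq_id = character(0),
                                  pos = integer(0), strand = character(0))))
  }
  ord <- cand[order(-n_seqs[cand], -n_exact[cand], -total[cand], words[cand])]
  # merge words overlapping in the seed sequence into the best-ranked one
  first_pos <- vapply(words[ord], function(w) regexpr(w, seed, fixed = TRUE)[[1]],
                      integer(1))
  accepted <- integer(0)
  for (i in seq_along(ord)) {
    s <- first_pos[i]; e <- s + width - 1L
    overlaps <- any(vapply(accepted, function(j) {
      s2 <- first_pos[j]; e2 <- s2 + width - 1L
      s <= e2 && s2 <= e
    }, logical(1)))
    if (!overlaps) accepted <- c(accepted, i)
    if (length(accepted) >= max_report) break
  }
  sel <- ord[accepted]
  motifs <- data.frame(motif = words[sel], n_seqs = unname(n_seqs[sel]),
                       total_matches = unname(total[sel]),
                       stringsAsFactors = FALSE, row.names = NULL)
  hits <- list()
  widths <- nchar(sequences)
  for (w in motifs$motif) {
    mf <- Biostrings::vmatchPattern(w, set, max.mismatch = max_mismatch)
    mr <- Biostrings::vmatchPattern(w, rcset, max.mismatch = max_mismatch)
    for (si in seq_along(sequences)) {
      fs <- Biostrings::start(mf[[si]])
      for (p in fs) {
        hits[[length(hits) + 1L]] <- data.frame(
          motif = w, seq_id = names(sequences)[si], pos = p, strand = "+",
          stringsAsFactors = FALSE)
      }
      rs <- Biostrings::start(mr[[si]])
      for (p in rs) {
        # convert a reverse-complement coordinate back to the input sequence
        orig <- widths[si] - (p + width - 1L) + 1L
        hits[[length(hits) + 1L]] <- data.frame(
          motif = w, seq_id = names(sequences)[si], pos = orig, strand = "-",
          stringsAsFactors = FALSE)
      }
    }
  }
  hits <- if (length(hits)) do.call(rbind, hits) else
    data.frame(motif = character(0), seq_id = character(0), pos = integer(0),
               strand = character(0), stringsAsFactors = FALSE)
  list(motifs = motifs, hits = hits)
}

## ---- position weight matrices --------------------------------------------

#' Construct a position frequency/weight matrix object
#'
#' @param counts 4 x width numeric matrix of per-position base counts (or
#'   frequencies), rows named A, C, G, T.
#' @param name Matrix name.
#' @param background Background base frequencies (A, C, G, T).
#' @param pseudocount Total pseudocount, split by background frequency
#'   before normalization (JASPAR convention).
#' @return Object of class `PWM`.
#' @export
pwm <- function(counts, name = "pwm", background = rep(0.25, 4),
                pseudocount = 0.8) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L) stop("counts must have 4 rows (A, C, G, T)")
  if (is.null(rownames(counts))) rownames(counts) <- c("A", "C", "G", "T")
  counts <- counts[c("A", "C", "G", "T"), , drop = FALSE]
  if (any(counts < 0)) stop("counts must be non-negative")
  background <- background / sum(background)
  structure(list(counts = counts, name = name, background = background,
                 pseudocount = pseudocount),
            class = "PWM")
}

#' @export
print.PWM <- function(x, ...) {
  cat("PWM", x$name, "- width", ncol(x$counts), "\n")
  cat("consensus:", pwm_consensus(x), "\n")
  invisible(x)
}

#' Consensus sequence of a PWM
#' @param x A `PWM`.
#' @return Character string of per-position argmax bases.
#' @export
pwm_consensus <- function(x) {
  paste(rownames(x$counts)[apply(x$counts, 2L, which.max)], collapse = "")
}

# Per-position log2-odds matrix with background-split pseudocount.
pwm_log_odds <- function(x) {
  cs <- colSums(x$counts)
  freq <- sweep(x$counts + x$pseudocount * x$background, 2L,
                cs + x$pseudocount, "/")
  log2(freq / x$background)
}

#' Relative PWM score of a window
#'
#' Log-odds sum of the window under the PWM, rescaled linearly between the
#' minimum and maximum attainable per-position log-odds sums, so that the
#' best possible window scores 1 and the worst 0.
#'
#' @param x A `PWM`.
#' @param window Sequence of exactly the PWM width (A/C/G/T).
#' @return Score in `[0, 1]`.
#' @export
relative_score <- function(x, window) {
  window <- toupper(window)
  assert_acgt(window, "window")
  L <- pwm_log_odds(x)
  w <- ncol(L)
  if (nchar(window) != w) stop("window length must equal PWM width")
  b <- match(strsplit(window, "")[[1]], c("A", "C", "G", "T"))
  s <- sum(L[cbind(b, seq_len(w))])
  smin <- sum(apply(L, 2L, min))
  smax <- sum(apply(L, 2L, max))
  if (smax == smin) return(1)
  (s - smin) / (smax - smin)
}

#' Scan a sequence with a PWM
#'
#' Scores every window on both strands and reports hits with relative score
#' at or above `threshold`, sorted by score. Windows containing non-ACGT
#' characters are skipped.
#'
#' @param x A `PWM`.
#' @param sequence Sequence to scan.
#' @param threshold Minimum relative score.
#' @return Data frame: `pos` (1-based on the input strand), `strand`,
#'   `score`.
#' @export
scan_pwm <- function(x, sequence, threshold = 0.8) {
  sequence <- toupper(sequence)
  L <- pwm_log_odds(x)
  w <- ncol(L)
  if (nchar(sequence) < w) stop("sequence shorter than PWM width")
  smin <- sum(apply(L, 2L, min))
  smax <- sum(apply(L, 2L, max))
  rng <- if (smax == smin) 1 else smax - smin
  scan_one <- function(s) {
    b <- match(strsplit(s, "")[[1]], c("A", "C", "G", "T"))
    n <- length(b) - w + 1L
    sc <- numeric(n)
    for (j in seq_len(w)) sc <- sc + L[cbind(b[seq_len(n) + j - 1L], j)]
    (sc - smin) / rng
  }
  fwd <- scan_one(sequence)
  rev <- scan_one(revcomp(sequence))
  n <- nchar(sequence)
  d <- rbind(data.frame(pos = seq_along(fwd), strand = "+", score = fwd,
                        stringsAsFactors = FALSE),
             data.frame(pos = n - (seq_along(rev) + w - 1L) + 1L, strand = "-",
                        score = rev, stringsAsFactors = FALSE))
  d <- d[!is.na(d$score) & d$score >= threshold, , drop = FALSE]
  d <- d[order(-d$score, d$pos), , drop = FALSE]
  rownames(d) <- NULL
  d
}

#' Longest contiguous overlap between a motif and a deletion
#'
#' Orients the motif to the plus strand (reverse-complementing when
#' `strand == "-"`) and returns the length of its longest contiguous match
#' to any substring of the deletion sequence; the match may abut either end
#' of the deletion, so partial boundary overlaps count.
#'
#' @param motif Motif sequence.
#' @param strand Strand of the motif hit (`"+"` or `"-"`).
#' @param deletion_sequence The deleted bases.
#' @return Overlap length in bases (0 when nothing matches).
#' @export
deletion_overlap <- function(motif, strand, deletion_sequence) {
  if (!nchar(motif) || !nchar(deletion_sequence)) stop("empty input")
  a <- if (strand == "+") toupper(motif) else revcomp(toupper(motif))
  b <- toupper(deletion_sequence)
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  # longest common substring by dynamic programming (inputs are short)
  best <- 0L
  prev <- integer(length(bv))
  for (i in seq_along(av)) {
    cur <- integer(length(bv))
    match_j <- which(bv == av[i])
    for (j in match_j) {
      cur[j] <- if (j > 1L) prev[j - 1L] + 1L else 1L
      if (cur[j] > best) best <- cur[j]
    }
    prev <- cur
  }
  best
}

#' Read a JASPAR-format position frequency matrix file
#'
#' Parses the JASPAR text format: a `>ID name` header followed by four
#' lines `A [ 1 2 3 ]` (brackets optional). Multiple records are returned
#' as a list.
#'
#' @param path Path to the PFM file.
#' @return List of [pwm()] objects (named by matrix id).
#' @export
read_jaspar_pfm <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  if (!length(starts)) stop("no JASPAR records in ", path)
  out <- list()
  for (s in starts) {
    header <- sub("^>\\s*", "", lines[s])
    id <- strsplit(header, "\\s+")[[1]][1]
    block <- lines[(s + 1):(s + 4)]
    rows <- lapply(block, function(l) {
      l <- gsub("[][]", " ", l)
      parts <- strsplit(trimws(l), "\\s+")[[1]]
      if (parts[1] %in% c("A", "C", "G", "T")) parts <- parts[-1]
      as.numeric(parts)
    })
    if (length(unique(lengths(rows))) != 1L) {
      stop("ragged PFM rows in record ", id)
    }
    counts <- do.call(rbind, rows)
    rownames(counts) <- c("A", "C", "G", "T")
    out[[id]] <- pwm(counts, name = header)
  }
  out
}
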