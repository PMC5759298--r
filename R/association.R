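# Single-marker association scan against sex: dosage extraction, KNN
# imputation, interval thinning, least-squares GLM with F-tests,
# permutation thresholds, centered-IBS kinship and SDR bounding.

#' Alt-allele dosage matrix from genotype calls
#'
#' Dosage is the count of first-ALT alleles in the genotype call (0/1/2),
#' `NA` when missing. Sites whose genotypes involve a second ALT allele
#' should be removed beforehand with [keep_biallelic()].
#'
#' @param table A `VariantTable`.
#' @return List of class `DosageMatrix` with `dosage` (samples x sites
#'   integer matrix) and `sites` (scaffold/pos data frame).
#' @export
dosage_matrix <- function(table) {
  codes <- sort(unique(as.vector(table$gt)))
  dose <- vapply(strsplit(codes, "/", fixed = TRUE), function(a) {
    if (any(a == ".")) return(NA_integer_)
    sum(a == "1")
  }, integer(1))
  d <- matrix(dose[match(table$gt, codes)], nrow(table$gt), ncol(table$gt))
  structure(list(dosage = t(d),
                 sites = table$sites[, c("scaffold", "pos")],
                 samples = table$samples),
            class = "DosageMatrix")
}

#' K-nearest-neighbour genotype imputation
#'
#' Each missing dosage is replaced by the mean dosage of the `k` nearest
#' samples that are observed at that site, where sample-to-sample distance
#' is the Euclidean distance over sites observed in both, and the mean is
#' rounded to the nearest integer dosage. Observed entries are untouched.
#' Sites missing in every sample are left missing with a warning.
#'
#' @param dm A [dosage_matrix()].
#' @param k Number of neighbours (must be below the sample count).
#' @return A `DosageMatrix` without missing values (barring all-missing
#'   sites).
#' @export
knn_impute <- function(dm, k = 5L) {
  X <- dm$dosage
  n <- nrow(X)
  if (k >= n) stop("k must be smaller than the number of samples")
  obs <- !is.na(X)
  if (any(rowSums(obs) == 0)) stop("every sample needs at least one observed site")
  if (!anyNA(X)) return(dm)
  Xz <- X; Xz[!obs] <- 0
  O <- obs * 1
  A <- Xz * Xz
  # sum over shared sites of (xi - xj)^2
  D2 <- A %*% t(O) + O %*% t(A) - 2 * Xz %*% t(Xz)
  diag(D2) <- Inf
  nb_order <- apply(D2, 1L, order)  # columns: neighbour ranking per sample
  all_missing <- integer(0)
  for (s in which(colSums(obs) < n)) {
    obs_s <- obs[, s]
    if (!any(obs_s)) { all_missing <- c(all_missing, s); next }
    for (i in which(!obs_s)) {
      nb <- nb_order[, i]
      nb <- nb[obs_s[nb]]
      nb <- nb[seq_len(min(k, length(nb)))]
      m <- mean(X[nb, s])
      X[i, s] <- max(0L, min(2L, as.integer(floor(m + 0.5))))
    }
  }
  if (length(all_missing)) {
    warning(length(all_missing), " site(s) missing in all samples were left unimputed")
  }
  dm$dosage <- X
  dm
}

#' Thin variants to one random site per fixed-width interval
#'
#' Retains exactly one uniformly chosen site from every non-empty window
#' `[i*interval + 1, (i+1)*interval]` of each scaffold (the genome-wide
#' pass of the two-stage scan works on this subset).
#'
#' @param table A `VariantTable`.
#' @param interval Window width in bases.
#' @param seed Seed; fixed seed gives an identical subset.
#' @return A `VariantTable` with the thinned sites, sorted order preserved.
#' @export
thin_by_interval <- function(table, interval = 5000L, seed = NULL) {
  win <- paste(table$sites$scaffold, (table$sites$pos - 1L) %/% interval)
  groups <- split(seq_len(nrow(table$sites)), win)
  keep <- with_seed(seed, {
    vapply(groups, function(idx) idx[sample.int(length(idx), 1L)], integer(1))
  })
  vt_subset(table, sort(unname(keep)))
}

#' Per-site association of dosage with sex
#'
#' Least-squares regression of the binary sex phenotype (F = 1, M = 0) on
#' alt-allele dosage, site by site; the p-value comes from the F statistic
#' on (1, n - 2) degrees of freedom. Kinship is not part of the model (the
#' single-marker GLM is fixed-effects only); monomorphic sites are returned
#' untested (`NA` statistic and p).
#'
#' @param dm An imputed [dosage_matrix()].
#' @param panel A `CohortPanel` covering the samples.
#' @return Data frame of class `AssocResult`: `scaffold`, `pos`, `stat`
#'   (F), `p`, `neg_log10_p`, `tested`.
#' @export
glm_assoc <- function(dm, panel) {
  X <- dm$dosage
  n <- nrow(X)
  if (n < 3L) stop("need at least 3 samples")
  panel <- panel[match(dm$samples, panel$sample), , drop = FALSE]
  y <- ifelse(panel$sex == "F", 1, 0)
  if (anyNA(X)) {
    tested_site <- colSums(is.na(X)) == 0
  } else {
    tested_site <- rep(TRUE, ncol(X))
  }
  xm <- colMeans(X)
  xc <- sweep(X, 2L, xm)
  yc <- y - mean(y)
  ssx <- colSums(xc^2)
  mono <- ssx <= 0 | is.na(ssx)
  tested <- tested_site & !mono
  r2 <- rep(NA_real_, ncol(X))
  idx <- which(tested)
  num <- as.vector(crossprod(yc, xc[, idx, drop = FALSE]))^2
  r2[idx] <- num / (sum(yc^2) * ssx[idx])
  Fstat <- (n - 2) * r2 / pmax(1 - r2, 0)
  p <- stats::pf(Fstat, 1, n - 2, lower.tail = FALSE)
  p <- pmax(p, 1e-300)  # keep p in (0, 1] under perfect separation
  p[!tested] <- NA_real_
  Fstat[!tested] <- NA_real_
  structure(data.frame(scaffold = dm$sites$scaffold, pos = dm$sites$pos,
                       stat = Fstat, p = p, neg_log10_p = -log10(p),
                       tested = tested, stringsAsFactors = FALSE),
            class = c("AssocResult", "data.frame"))
}

#' Experiment-wise permutation threshold
#'
#' Permutes the sex labels `n_perm` times, records the minimum p-value of
#' each permuted scan, and returns the empirical `alpha`-quantile of those
#' minima as the experiment-wise significance threshold.
#'
#' @param dm An imputed [dosage_matrix()].
#' @param panel A `CohortPanel`.
#' @param n_perm Number of permutations (>= 100 recommended).
#' @param alpha Experiment-wise error rate.
#' @param seed Seed for the permutations.
#' @return Threshold p-value, with the per-permutation minima attached as
#'   attribute `min_p`.
#' @export
permutation_threshold <- function(dm, panel, n_perm = 1000L, alpha = 0.05,
                                  seed = NULL) {
  X <- dm$dosage
  n <- nrow(X)
  panel <- panel[match(dm$samples, panel$sample), , drop = FALSE]
  y <- ifelse(panel$sex == "F", 1, 0)
  xm <- colMeans(X)
  xc <- sweep(X, 2L, xm)
  ssx <- colSums(xc^2)
  use <- ssx > 0 & !is.na(ssx)
  xc <- xc[, use, drop = FALSE]
  ssx <- ssx[use]
  Y <- with_seed(seed, {
    t(vapply(seq_len(n_perm), function(i) sample(y), numeric(n)))
  })
  Yc <- Y - rowMeans(Y)
  ssy <- rowSums(Yc^2)
  num <- (Yc %*% xc)^2
  r2 <- sweep(sweep(num, 2L, ssx, "/"), 1L, ssy, "/")
  Fstat <- (n - 2) * r2 / pmax(1 - r2, .Machine$double.eps)
  minF <- apply(Fstat, 1L, max)
  min_p <- stats::pf(minF, 1, n - 2, lower.tail = FALSE)
  min_p <- pmax(min_p, 1e-300)
  thr <- unname(stats::quantile(min_p, alpha, type = 1))
  attr(thr, "min_p") <- min_p
  thr
}

#' Centered identity-by-state kinship matrix
#'
#' VanRaden-style centered IBS: dosages are column-centered by twice the
#' allele frequency and the cross-product matrix is scaled by the sum of
#' 2p(1-p) over sites. Reported alongside the scan for diagnostics; the
#' single-marker GLM itself does not use it.
#'
#' @param dm An imputed [dosage_matrix()].
#' @return Symmetric samples x samples matrix.
#' @export
centered_ibs <- function(dm) {
  X <- dm$dosage
  keep <- colSums(is.na(X)) == 0
  X <- X[, keep, drop = FALSE]
  p <- colMeans(X) / 2
  M <- sweep(X, 2L, 2 * p)
  denom <- 2 * sum(p * (1 - p))
  K <- tcrossprod(M) / denom
  dimnames(K) <- list(dm$samples, dm$samples)
  K
}

#' Bound the sex-determining region on a scaffold
#'
#' The SDR interval is the span from the first to the last site with
#' `p <= p_cut` on the given scaffold (a p-value exactly at the cutoff
#' counts as significant).
#'
#' @param assoc An `AssocResult`.
#' @param scaffold Scaffold id.
#' @param p_cut Significance cutoff.
#' @return Named numeric `c(start, end)`, or `NULL` when no site passes.
#' @export
sdr_bounds <- function(assoc, scaffold, p_cut = 1e-7) {
  d <- assoc[assoc$scaffold == scaffold & assoc$tested & assoc$p <= p_cut, ]
  if (!nrow(d)) return(NULL)
  c(start = min(d$pos), end = max(d$pos))
}

#' Two-stage genome scan for the sex-determining region
#'
#' Stage one runs the association on a thinned subset (one SNP per
#' `thin_interval`); scaffolds showing at least `colinear_n` significant
#' sites (`p <= thin_p`) within `colinear_span` bases are then rescanned at
#' full density, and the SDR is bounded at `p_cut` on the scaffold carrying
#' the global minimum p. SNP sites only (single-base ref and alt) enter the
#' scan; both passes are KNN-imputed first.
#'
#' @param table A biallelic `VariantTable`.
#' @param panel A `CohortPanel`.
#' @param thin_interval Thinning window (bases).
#' @param thin_p Stage-one significance cutoff.
#' @param p_cut SDR bounding cutoff for the full-density pass.
#' @param k Imputation neighbours.
#' @param n_perm Permutations for the experiment-wise threshold (stage one).
#' @param colinear_n,colinear_span Operational definition of "multiple
#'   co-linear significant SNPs" promoting a scaffold to stage two.
#' @param seed Seed (thinning and permutations).
#' @return List of class `SdrScan`: `assoc_thinned`, `assoc_full`,
#'   `scaffolds_followed`, `sdr` (scaffold/start/end or `NULL`),
#'   `perm_threshold`, `kinship`.
#' @export
sdr_scan <- function(table, panel, thin_interval = 5000L, thin_p = 1e-3,
                     p_cut = 1e-7, k = 5L, n_perm = 1000L,
                     colinear_n = 3L, colinear_span = 1e5, seed = 1L) {
  is_snp <- nchar(table$sites$ref) == 1L & nchar(table$sites$alt) == 1L
  snps <- vt_subset(table, is_snp)
  thinned <- thin_by_interval(snps, thin_interval, seed = seed)
  dm1 <- knn_impute(dosage_matrix(thinned), k = k)
  a1 <- glm_assoc(dm1, panel)
  thr <- permutation_threshold(dm1, panel, n_perm = n_perm, seed = seed + 1L)
  kin <- centered_ibs(dm1)

  sig <- a1[a1$tested & a1$p <= thin_p, ]
  followed <- character(0)
  for (s in unique(sig$scaffold)) {
    pos <- sort(sig$pos[sig$scaffold == s])
    if (length(pos) >= colinear_n) {
      # any run of colinear_n consecutive significant sites within the span
      span_ok <- pos[seq_len(length(pos) - colinear_n + 1L) + colinear_n - 1L] -
        pos[seq_len(length(pos) - colinear_n + 1L)] <= colinear_span
      if (any(span_ok)) followed <- c(followed, s)
    }
  }

  a2 <- NULL
  sdr <- NULL
  if (length(followed)) {
    full <- vt_subset(snps, snps$sites$scaffold %in% followed)
    dm2 <- knn_impute(dosage_matrix(full), k = k)
    a2 <- glm_assoc(dm2, panel)
    best <- a2[a2$tested, ]
    best_sc <- best$scaffold[which.min(best$p)]
    b <- sdr_bounds(a2, best_sc, p_cut = p_cut)
    if (!is.null(b)) sdr <- list(scaffold = best_sc, start = b[["start"]], end = b[["end"]])
  }
  structure(list(assoc_thinned = a1, assoc_full = a2,
                 scaffolds_followed = followed, sdr = sdr,
                 perm_threshold = as.numeric(thr), kinship = kin),
            class = "SdrScan")
}

#' @export
print.SdrScan <- function(x, ...) {
  cat("Two-stage sex association scan\n")
  cat("  stage 1 sites:", nrow(x$assoc_thinned),
      "| permutation threshold:", signif(x$perm_threshold, 3), "\n")
  cat("  scaffolds followed:", if (length(x$scaffolds_followed))
    paste(x$scaffolds_followed, collapse = ", ") else "none", "\n")
  if (is.null(x$sdr)) {
    cat("  SDR: not localized\n")
  } else {
    cat(sprintf("  SDR: %s:%d-%d\n", x$sdr$scaffold, x$sdr$start, x$sdr$end))
  }
  invisible(x)
}
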