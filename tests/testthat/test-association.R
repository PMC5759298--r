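# Imputation, thinning, the sex GLM, permutation thresholds and kinship.

make_dm <- function(X, samples = paste0("s", seq_len(nrow(X))),
                    scaffold = "sc", pos = seq_len(ncol(X)) * 100L) {
  structure(list(dosage = X,
                 sites = data.frame(scaffold = scaffold, pos = pos,
                                    stringsAsFactors = FALSE),
                 samples = samples),
            class = "DosageMatrix")
}

make_panel <- function(sex, samples = paste0("s", seq_along(sex))) {
  cohort_panel(samples, sex, rep("P1", length(sex)))
}

test_that("knn imputation leaves complete data alone and uses nearest neighbours", {
  X <- matrix(rep(0:2, each = 4), 4, 3)
  dm <- make_dm(X)
  expect_identical(knn_impute(dm, k = 2)$dosage, X)

  # a missing entry whose 5 nearest neighbours all carry dosage 2
  X2 <- rbind(matrix(2L, 5, 4), c(2L, 2L, 2L, NA))
  X2[6, 1:3] <- 2L
  dm2 <- make_dm(X2)
  out <- knn_impute(dm2, k = 5)
  expect_equal(out$dosage[6, 4], 2L)
  expect_error(knn_impute(dm2, k = 6), "smaller")
})

test_that("knn neighbour sets equal exhaustive pairwise distances on a toy", {
  withr::local_seed(21)
  X <- matrix(sample(c(0:2, NA), 6 * 8, replace = TRUE,
                     prob = c(0.3, 0.3, 0.3, 0.1)), 6, 8)
  X[, 1] <- c(0L, 1L, 2L, 0L, 1L, 2L)  # every sample observed somewhere
  dm <- make_dm(X)
  k <- 3L
  out <- knn_impute(dm, k = k)$dosage
  # brute-force oracle: loop over all pairs and all missing entries
  for (s in seq_len(ncol(X))) {
    for (i in seq_len(nrow(X))) {
      if (!is.na(X[i, s])) {
        expect_identical(out[i, s], X[i, s])
        next
      }
      d <- vapply(seq_len(nrow(X)), function(j) {
        if (j == i) return(Inf)
        shared <- !is.na(X[i, ]) & !is.na(X[j, ])
        if (!any(shared)) return(Inf)
        sum((X[i, shared] - X[j, shared])^2)
      }, numeric(1))
      cand <- order(d)
      cand <- cand[!is.na(X[cand, s])]
      nb <- cand[seq_len(min(k, length(cand)))]
      if (!length(nb)) next
      expected <- max(0L, min(2L, as.integer(floor(mean(X[nb, s]) + 0.5))))
      expect_identical(out[i, s], expected)
    }
  }
})

test_that("interval thinning keeps one site per window, reproducibly", {
  sites <- data.frame(scaffold = "sc", pos = c(100L, 2000L, 4999L, 5001L, 12000L),
                      ref = "A", alt = "T", stringsAsFactors = FALSE)
  gt <- matrix("0/0", 5, 1); ad <- matrix(1L, 5, 1)
  vt <- variant_table(sites, gt, ad, ad, samples = "x")
  thin <- thin_by_interval(vt, 5000L, seed = 1)
  expect_equal(n_sites(thin), 3L)                    # windows 1, 2, 3 occupied
  expect_true(5001L %in% thin$sites$pos)             # singleton windows all kept
  expect_true(12000L %in% thin$sites$pos)
  expect_equal(thin_by_interval(vt, 5000L, seed = 1)$sites$pos, thin$sites$pos)

  spread <- vt_subset(vt, c(1L, 4L, 5L))             # all in distinct windows
  expect_equal(n_sites(thin_by_interval(spread, 5000L, seed = 2)), 3L)
})

test_that("sex GLM matches lm's F-test and flags monomorphic sites", {
  withr::local_seed(22)
  n <- 30
  X <- cbind(matrix(rbinom(n * 5, 2, 0.4), n, 5), 1L)  # last site constant
  sex <- sample(rep(c("F", "M"), each = n / 2))
  dm <- make_dm(X)
  panel <- make_panel(sex)
  res <- glm_assoc(dm, panel)
  expect_false(res$tested[6])
  expect_true(is.na(res$p[6]))
  y <- ifelse(sex == "F", 1, 0)
  for (j in 1:5) {
    fit <- summary(stats::lm(y ~ X[, j]))
    expect_equal(res$p[j], unname(fit$coefficients[2, 4]), tolerance = 1e-10)
  }
  expect_error(glm_assoc(make_dm(X[1:2, ]), make_panel(c("F", "M"))), "3 samples")
})

test_that("a perfectly sex-linked site is extreme for both the GLM and Fisher enumeration", {
  sex <- rep(c("F", "M"), each = 10)
  X <- cbind(ifelse(sex == "F", 1L, 0L), rbinom(20, 2, 0.5))
  res <- glm_assoc(make_dm(X), make_panel(sex))
  expect_lt(res$p[1], 1e-12)
  # brute-force Fisher oracle: the observed allele-count table is the most
  # extreme attainable under its margins
  alt_f <- sum(X[sex == "F", 1]); alt_m <- sum(X[sex == "M", 1])
  n_al <- 20L  # alleles per group
  total_alt <- alt_f + alt_m
  p_obs <- stats::dhyper(alt_f, n_al, n_al, total_alt)
  p_all <- stats::dhyper(0:total_alt, n_al, n_al, total_alt)
  expect_equal(p_obs, min(p_all[p_all > 0]))
  p_fisher <- sum(p_all[p_all <= p_obs])
  expect_lt(p_fisher, 0.001)
})

test_that("GLM and Fisher p-values are co-monotone across an association ladder", {
  nf <- 20
  sex <- rep(c("F", "M"), each = nf)
  carriers <- seq(2, nf, by = 2)
  X <- vapply(carriers, function(kf) c(rep(1L, kf), rep(0L, 2 * nf - kf)), integer(2 * nf))
  res <- glm_assoc(make_dm(X), make_panel(sex))
  p_fisher <- vapply(carriers, function(kf) {
    stats::fisher.test(matrix(c(kf, 2 * nf - kf, 0L, 2 * nf), 2, byrow = TRUE))$p.value
  }, numeric(1))
  expect_equal(stats::cor(-log10(res$p), -log10(p_fisher), method = "spearman"), 1)
})

test_that("null p-values are uniform (KS test not rejecting at alpha = 0.01)", {
  withr::local_seed(23)
  n <- 120  # large enough for the F-test's null to be close to uniform
  sex <- rep(c("F", "M"), each = n / 2)
  X <- matrix(rbinom(n * 500, 2, runif(500, 0.2, 0.5)[rep(1:500, each = n)]), n, 500)
  res <- glm_assoc(make_dm(X), make_panel(sex))
  p <- res$p[res$tested]
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("permutation threshold is seeded and degenerates correctly", {
  withr::local_seed(24)
  n <- 40
  sex <- rep(c("F", "M"), each = n / 2)
  X <- matrix(rbinom(n * 50, 2, 0.3), n, 50)
  dm <- make_dm(X); panel <- make_panel(sex)
  t1 <- permutation_threshold(dm, panel, n_perm = 200, seed = 7)
  t2 <- permutation_threshold(dm, panel, n_perm = 200, seed = 7)
  expect_equal(as.numeric(t1), as.numeric(t2))
  expect_length(attr(t1, "min_p"), 200L)
  # n_perm = 1: the threshold is that permutation's minimum p
  t3 <- permutation_threshold(dm, panel, n_perm = 1, seed = 8)
  expect_equal(as.numeric(t3), unname(attr(t3, "min_p")[1]))
})

test_that("centered IBS kinship matches hand arithmetic and is symmetric", {
  # 3 samples x 2 sites: X = [[0,2],[1,1],[2,0]]; p = (.5,.5); M = X - 1
  # K = M M' / (2 * (0.25 + 0.25)) = [[2,0,-2],[0,0,0],[-2,0,2]]
  X <- rbind(c(0L, 2L), c(1L, 1L), c(2L, 0L))
  K <- centered_ibs(make_dm(X))
  expect_equal(unname(K), rbind(c(2, 0, -2), c(0, 0, 0), c(-2, 0, 2)))

  withr::local_seed(25)
  X2 <- matrix(rbinom(8 * 20, 2, 0.4), 8, 20)
  X2[2, ] <- X2[1, ]  # identical pair
  K2 <- centered_ibs(make_dm(X2))
  expect_equal(K2, t(K2))
  expect_equal(K2[1, ], K2[2, ])
  off <- K2; diag(off) <- -Inf
  expect_equal(which(off == max(off), arr.ind = TRUE)[1, ] %in% 1:2, c(TRUE, TRUE))
})

test_that("SDR bounds span the significant sites or return NULL", {
  assoc <- data.frame(scaffold = "sc22",
                      pos = c(231000L, 280000L, 320000L, 350000L),
                      p = c(1e-9, 1e-8, 1e-7, 1e-3),
                      tested = TRUE, stringsAsFactors = FALSE)
  b <- sdr_bounds(assoc, "sc22", p_cut = 1e-7)
  expect_equal(b, c(start = 231000, end = 320000))  # p at the cutoff counts
  expect_null(sdr_bounds(assoc, "sc22", p_cut = 1e-12))
  expect_null(sdr_bounds(assoc, "other"))
})
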