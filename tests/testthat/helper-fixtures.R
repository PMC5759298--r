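# Shared fixtures, built in code at test time.

# A reduced cohort configuration for fast unit tests: two scaffolds, a small
# SDR, the same cohort structure (three populations of 15 + 15) and 2x
# coverage as the default conditions.
small_config <- function(seed, coverage = 2.0, system = "ZW", ...) {
  sim_config(
    seed = seed,
    scaffold_lengths = c(scaffold_22 = 80000L, scaffold_01 = 30000L,
                         scaffold_02 = 30000L),
    sdr = list(scaffold = "scaffold_22", start = 20000L, end = 40000L),
    n_w_snps = 40L,
    deletion_start = 25000L,
    coverage = coverage,
    system = system,
    n_multiallelic = 5L,
    decoy_indels = data.frame(scaffold = "scaffold_22", start = 35000L,
                              length = 45L, freq = 0.3),
    ...
  )
}

# Hand-rolled variant table: explicit GT/AD matrices for boundary tests.
toy_table <- function(sites, gt, ad_ref, ad_alt, samples) {
  variant_table(sites, gt, ad_ref, ad_alt, samples = samples)
}

# Independent brute-force canonical k-mer containment (string reversal done
# by hand so the oracle shares no code with the implementation under test).
brute_containment <- function(query, subject, k) {
  rc_chr <- function(s) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  }
  kmers <- function(s) {
    n <- nchar(s)
    vapply(1:(n - k + 1), function(i) substr(s, i, i + k - 1), character(1))
  }
  canon <- function(ks) {
    vapply(ks, function(x) {
      r <- rc_chr(x)
      if (x <= r) x else r
    }, character(1))
  }
  qk <- canon(kmers(query))
  sk <- unique(canon(kmers(subject)))
  sum(qk %in% sk) / length(qk)
}
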