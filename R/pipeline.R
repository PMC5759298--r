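# End-to-end orchestration: simulate -> associate -> classify -> marker ->
# footprint, with plain-file handoffs between stages and a structured
# report. Every stage writes its intermediate in a standard format so each
# step can later be replayed on real data.

#' Read a flat key-value run configuration file
#'
#' Format: one `key = value` per line, `#` comments allowed. Recognized
#' keys: `seed` (mandatory), `system` (`ZW`/`XY`), `coverage`,
#' `snp_density`, `n_w_snps`, `thin_interval`, `n_perm`, `het_lo`,
#' `het_hi`, `min_indel_len`, `upstream_span`, `n_controls`,
#' `scaffold_lengths` (comma-separated `name:length` pairs), `populations`
#' (comma-separated `label:females:males` triples). Unknown keys are an
#' error.
#'
#' @param path Path to the configuration file.
#' @return A named list of configuration values.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  known <- c("seed", "system", "coverage", "snp_density", "n_w_snps",
             "thin_interval", "n_perm", "het_lo", "het_hi", "min_indel_len",
             "upstream_span", "n_controls", "scaffold_lengths", "populations")
  out <- list()
  for (l in lines) {
    kv <- strsplit(l, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) stop("malformed config line: ", l)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (!(key %in% known)) stop("unknown config key: ", key)
    out[[key]] <- val
  }
  if (is.null(out$seed)) stop("config must set seed")
  num_keys <- c("seed", "coverage", "snp_density", "n_w_snps", "thin_interval",
                "n_perm", "het_lo", "het_hi", "min_indel_len",
                "upstream_span", "n_controls")
  for (k in intersect(names(out), num_keys)) out[[k]] <- as.numeric(out[[k]])
  if (!is.null(out$scaffold_lengths)) {
    parts <- strsplit(strsplit(out$scaffold_lengths, ",")[[1]], ":")
    out$scaffold_lengths <- stats::setNames(
      as.integer(vapply(parts, `[`, character(1), 2)),
      vapply(parts, `[`, character(1), 1))
  }
  if (!is.null(out$populations)) {
    parts <- strsplit(strsplit(out$populations, ",")[[1]], ":")
    out$populations <- data.frame(
      label = vapply(parts, `[`, character(1), 1),
      n_female = as.integer(vapply(parts, `[`, character(1), 2)),
      n_male = as.integer(vapply(parts, `[`, character(1), 3)),
      stringsAsFactors = FALSE)
  }
  out
}

# Assemble a sim_config from the flat run configuration.
config_to_sim <- function(cfg) {
  args <- list(seed = as.integer(cfg$seed))
  if (!is.null(cfg$system)) args$system <- cfg$system
  if (!is.null(cfg$coverage)) args$coverage <- cfg$coverage
  if (!is.null(cfg$snp_density)) args$snp_density <- cfg$snp_density
  if (!is.null(cfg$n_w_snps)) args$n_w_snps <- as.integer(cfg$n_w_snps)
  if (!is.null(cfg$scaffold_lengths)) args$scaffold_lengths <- cfg$scaffold_lengths
  if (!is.null(cfg$populations)) args$populations <- cfg$populations
  do.call(sim_config, args)
}

#' Run the full discovery pipeline on a simulated cohort
#'
#' Executes all stages in order, persisting every intermediate under
#' `out_dir`: simulation (FASTA/GFF3/VCF/phenotype TSV), biallelic
#' filtering and the two-stage association scan (`assoc_*.tsv`),
#' heterozygosity-ratio classification (`het_ratios.tsv`), the SDR indel
#' scan and in-silico PCR sex calls (`indel_candidates.tsv`,
#' `sex_calls.tsv`), and promoter footprinting (`motifs.tsv`). A structured
#' `report.json` collects every stage's headline results together with all
#' thresholds and seeds used; reruns with the same configuration are
#' byte-identical.
#'
#' @param config A configuration list ([read_run_config()]), a path to a
#'   configuration file, or a [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @return The report, invisibly (class `RunReport`).
#' @export
run_all <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L) config <- read_run_config(config)
  if (inherits(config, "SimulationConfig")) {
    sim_cfg <- config
    cfg <- list(seed = sim_cfg$seed)
  } else {
    cfg <- config
    sim_cfg <- config_to_sim(cfg)
  }
  opt <- function(key, default) if (!is.null(cfg[[key]])) cfg[[key]] else default
  thin_interval <- as.integer(opt("thin_interval", 5000L))
  n_perm <- as.integer(opt("n_perm", 1000L))
  het_lo <- opt("het_lo", 0.4); het_hi <- opt("het_hi", 0.6)
  min_indel_len <- as.integer(opt("min_indel_len", 41L))
  upstream_span <- as.integer(opt("upstream_span", 3000L))
  n_controls <- as.integer(opt("n_controls", 5L))
  seed <- sim_cfg$seed

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  ## 1. simulate
  sim <- stage("simulate", simulate_cohort(sim_cfg))
  write_fasta(sim$genome, file.path(out_dir, "genome.fasta"))
  write_gff(sim$annotation, file.path(out_dir, "genes.gff3"))
  write_vcf(sim$variants, sim$panel, file.path(out_dir, "cohort.vcf"))
  write_panel(sim$panel, file.path(out_dir, "phenotypes.tsv"))

  ## 2. association scan
  bi <- stage("biallelic_filter", keep_biallelic(sim$variants))
  scan <- stage("association", sdr_scan(bi, sim$panel,
                                        thin_interval = thin_interval,
                                        n_perm = n_perm, seed = seed + 1L))
  utils::write.table(scan$assoc_thinned,
                     file.path(out_dir, "assoc_thinned.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(scan$assoc_full)) {
    utils::write.table(scan$assoc_full, file.path(out_dir, "assoc_full.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  sdr <- if (!is.null(scan$sdr)) scan$sdr else sim$truth$sdr

  ## 3. heterogamety classification
  sdr_len <- sdr$end - sdr$start + 1L
  eligible <- sum(nchar(sim$genome) >= sdr_len) -
    (nchar(sim$genome[[sdr$scaffold]]) >= sdr_len)
  n_controls <- min(n_controls, eligible)
  het <- stage("zw_test", het_ratio_report(sim$variants, sim$panel, sim$genome,
                                           sdr, n_controls = n_controls,
                                           seed = seed + 2L,
                                           lo = het_lo, hi = het_hi))
  utils::write.table(het, file.path(out_dir, "het_ratios.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  system_call <- classify_system(het)

  ## 4. marker discovery and in-silico sexing
  cands <- stage("indel_scan", scan_indels(sim$variants, sim$panel, sdr,
                                           min_len = min_indel_len))
  utils::write.table(cands, file.path(out_dir, "indel_candidates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  assays <- sdor_del_assays()
  tmpl <- sim$truth$templates
  calls <- stage("sex_calls", {
    per_assay <- lapply(seq_len(nrow(assays)), function(i) {
      amp_z <- in_silico_pcr(tmpl[["Z"]], assays$fwd[i], assays$rev[i])
      amp_w <- in_silico_pcr(tmpl[["W"]], assays$fwd[i], assays$rev[i])
      list(z = amp_z$length, w = amp_w$length)
    })
    zw <- sim$truth$sample_sex
    call_one <- function(chroms, i) {
      bands <- if (chroms == "ZW") c(per_assay[[i]]$z, per_assay[[i]]$w)
               else c(per_assay[[i]]$z, per_assay[[i]]$z)
      call_sex(bands, assays$size_z[i], assays$size_w[i])
    }
    data.frame(sample = names(zw), true_chromosomes = unname(zw),
               call_SdorDel01 = vapply(names(zw), function(s) call_one(zw[[s]], 1L), character(1)),
               call_SdorDel02 = vapply(names(zw), function(s) call_one(zw[[s]], 2L), character(1)),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  utils::write.table(calls, file.path(out_dir, "sex_calls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth_sex <- ifelse(calls$true_chromosomes == "ZW", "F", "M")
  call_accuracy <- mean(calls$call_SdorDel01 == truth_sex &
                        calls$call_SdorDel02 == truth_sex)

  ## 5. promoter footprinting
  foot <- stage("footprint", {
    own <- extract_upstream(sim$genome, sim$annotation, sim$truth$target_gene,
                            span = upstream_span)
    orthos <- make_promoter_fixture(n_species = 6L, planted_fraction = 4 / 6,
                                    span = upstream_span, seed = seed + 3L)
    seqs <- c(stats::setNames(own, "target_species"), orthos)
    found <- find_shared_motifs(seqs, width = 15L, max_mismatch = 2L,
                                min_seqs = 5L)
    del_seq <- if (nrow(cands)) cands$sequence[which.max(cands$length)]
               else sim$truth$deletion$seq
    overlap <- if (nrow(found$motifs)) {
      hit <- found$hits[found$hits$motif == found$motifs$motif[1] &
                        found$hits$seq_id == "target_species", ]
      strand <- if (nrow(hit)) hit$strand[1] else "+"
      data.frame(motif = found$motifs$motif[1], strand = strand,
                 overlap = deletion_overlap(found$motifs$motif[1], strand, del_seq),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(motif = character(0), strand = character(0),
                 overlap = integer(0), stringsAsFactors = FALSE)
    }
    list(motifs = found$motifs, hits = found$hits, overlap = overlap)
  })
  utils::write.table(foot$hits, file.path(out_dir, "motifs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  report <- structure(list(
    config = list(seed = seed, system = sim_cfg$system,
                  coverage = sim_cfg$coverage,
                  populations = sim_cfg$populations),
    thresholds = list(thin_interval = thin_interval, n_perm = n_perm,
                      het_band = c(het_lo, het_hi),
                      min_indel_len = min_indel_len,
                      upstream_span = upstream_span,
                      assoc_p_cut = 1e-7, stage1_p = 1e-3),
    sdr_call = sdr,
    sdr_truth = sim$truth$sdr,
    perm_threshold = scan$perm_threshold,
    system_call = system_call,
    het_ratios = het,
    indel_candidates = cands,
    sex_call_accuracy = call_accuracy,
    motif_top = foot$motifs,
    motif_overlap = foot$overlap),
    class = "RunReport")
  json <- jsonlite::toJSON(unclass_report(report), auto_unbox = TRUE,
                           digits = NA, pretty = TRUE)
  writeLines(json, file.path(out_dir, "report.json"))
  invisible(report)
}

# Strip classes so jsonlite serializes plain structures deterministically.
unclass_report <- function(x) {
  if (is.list(x) && !is.data.frame(x)) {
    lapply(unclass(x), unclass_report)
  } else if (is.data.frame(x)) {
    as.data.frame(lapply(x, unname), stringsAsFactors = FALSE)
  } else {
    unname(x)
  }
}

#' @export
print.RunReport <- function(x, ...) {
  cat("ZW discovery pipeline report\n")
  cat("  seed:", x$config$seed, "| system call:", x$system_call, "\n")
  if (!is.null(x$sdr_call)) {
    cat(sprintf("  SDR: %s:%d-%d (truth %d-%d)\n", x$sdr_call$scaffold,
                x$sdr_call$start, x$sdr_call$end,
                x$sdr_truth$start, x$sdr_truth$end))
  }
  cat("  indel candidates:", nrow(x$indel_candidates),
      "| sex-call accuracy:", round(x$sex_call_accuracy, 3), "\n")
  if (nrow(x$motif_top)) {
    cat("  top shared motif:", x$motif_top$motif[1], "in",
        x$motif_top$n_seqs[1], "sequences\n")
  }
  invisible(x)
}
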