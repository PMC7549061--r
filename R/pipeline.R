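## End-to-end pipeline: simulation -> calling -> diagnostic SNPs ->
## dosage painting -> ploidy -> reconciliation report.

#' Pipeline configuration
#'
#' Collects every stage's parameters plus the accession panel. In
#' simulation mode each accession row needs a `true_composition` (the
#' composition actually simulated, which may deliberately disagree with
#' `expected_composition` to emulate mis-identified material).
#'
#' @param accessions data.frame with columns sample_id, name,
#'   expected_ploidy, expected_composition, true_composition.
#' @param seed master seed; all stage seeds derive from it.
#' @param n_chrom,chrom_length,divergence_rate,indel_rate passed to
#'   [generate_subgenomes()].
#' @param mean_depth,error_rate passed to [simulate_pileup()] and
#'   [call_variants()].
#' @param filter a [filter_config()].
#' @param hom_fraction passed to [identify_informative_snps()].
#' @param depth_min,depth_max dosage depth window.
#' @param span,degree,bounds passed to [dosage_track()].
#' @param pure_threshold passed to [reconcile()].
#' @param min_het_sites minimum heterozygous sites for a ploidy call.
#' @param hx_segments optional named list (by sample_id) of
#'   homeologous-exchange data.frames, see [genotype_spec()].
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(accessions, seed = 1L, n_chrom = 2L,
                            chrom_length = 300000L, divergence_rate = 0.005,
                            indel_rate = 2e-4, mean_depth = 30,
                            error_rate = 0.005, filter = filter_config(),
                            hom_fraction = 0.9, depth_min = 10,
                            depth_max = 50, span = 0.5, degree = 2L,
                            bounds = c(33, 66), pure_threshold = 5,
                            min_het_sites = 50L, hx_segments = NULL) {
  cfg <- as.list(environment())
  need <- c("sample_id", "name", "expected_ploidy", "expected_composition",
            "true_composition")
  if (!all(need %in% names(accessions))) {
    .stop_invalid("accessions needs columns ", paste(need, collapse = ", "))
  }
  structure(cfg, class = "pipeline_config")
}

#' Run the whole pipeline on a simulated panel
#'
#' Generates the A/B subgenome pair, simulates a pure-B accession and
#' derives the diagnostic SNP set from it (calling + filter chain), then
#' for every accession in the panel simulates a pileup, paints its dosage
#' track, infers its ploidy and reconciles observation against
#' expectation. All outputs are written under `out_dir`; the report is
#' returned invisibly.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if missing).
#' @param quiet suppress progress messages.
#' @return (invisibly) the report data.frame; files written: `report.tsv`
#'   (Table-5-style, seeds recorded in header comments),
#'   `diagnostic_snps.tsv`, per-accession `<id>_dosage.tsv`,
#'   `<id>_circos.txt` / `<id>_highlight.txt`, `<id>_ploidy.tsv`, and
#'   `pipeline.log` with every filter's kept/dropped counts.
#' @export
run_pipeline <- function(config, out_dir = tempfile("musapaint_"),
                         quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  log_add <- function(...) {
    line <- paste0(...)
    log_lines <<- c(log_lines, line)
    if (!quiet) message(line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage [", name, "] failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  cfg <- config

  log_add("stage simulate: seed=", cfg$seed, " n_chrom=", cfg$n_chrom,
          " chrom_length=", cfg$chrom_length)
  pair <- stage("simulate", generate_subgenomes(
    cfg$seed, cfg$n_chrom, cfg$chrom_length, cfg$divergence_rate,
    cfg$indel_rate))
  log_add("  truth sites: ", nrow(pair$truth_sites),
          "; private indels: ", nrow(pair$indels))

  ## diagnostic SNPs from a simulated pure-B accession
  b_seed <- cfg$seed + 10000L
  b_acc <- stage("call", compose_genotype(pair, genotype_spec("BB")))
  b_pile <- stage("call", simulate_pileup(b_acc, cfg$mean_depth,
                                          cfg$error_rate, seed = b_seed))
  b_calls <- stage("call", call_variants(b_pile, cfg$error_rate))
  log_add("stage call: B accession seed=", b_seed, "; calls=", nrow(b_calls))
  b_filtered <- stage("diagnose", filter_variants(b_calls, cfg$filter))
  log_add("stage diagnose: filter kept ", nrow(b_filtered), "/",
          nrow(b_calls), " calls")
  snps <- stage("diagnose", identify_informative_snps(
    b_filtered, b_pile, cfg$hom_fraction))
  log_add("  diagnostic SNPs: ", nrow(snps))
  write_diagnostic_snps(snps, file.path(out_dir, "diagnostic_snps.tsv"))

  reports <- vector("list", nrow(cfg$accessions))
  for (i in seq_len(nrow(cfg$accessions))) {
    row <- cfg$accessions[i, ]
    acc_seed <- cfg$seed + i
    hx <- if (!is.null(cfg$hx_segments)) cfg$hx_segments[[row$sample_id]]
    acc <- stage("paint", compose_genotype(
      pair, genotype_spec(row$true_composition, hx)))
    pile <- stage("paint", simulate_pileup(acc, cfg$mean_depth,
                                           cfg$error_rate, seed = acc_seed))

    pts <- stage("paint", suppressMessages(quantify_b_fraction(
      pile, snps, cfg$depth_min, cfg$depth_max)))
    track <- stage("paint", dosage_track(pts, cfg$span, cfg$degree,
                                         cfg$bounds))
    pct_b <- median(track$smoothed)
    write_dosage_points(track, file.path(out_dir,
                                         paste0(row$sample_id, "_dosage.tsv")))
    write_circos_track(track,
                       file.path(out_dir, paste0(row$sample_id, "_circos.txt")),
                       file.path(out_dir, paste0(row$sample_id, "_highlight.txt")))

    freqs <- stage("ploidy", extract_site_frequencies(pile, cfg$depth_min))
    n_raw <- nrow(freqs)
    if (n_raw >= 50L) {
      freqs <- stage("ploidy", suppressWarnings(denoise(freqs)))
    }
    pcall <- stage("ploidy", infer_ploidy(freqs,
                                          min_sites = cfg$min_het_sites,
                                          seed = acc_seed))
    write_ploidy_table(pcall, file.path(out_dir,
                                        paste0(row$sample_id, "_ploidy.tsv")))
    log_add("accession ", row$sample_id, " (true ", row$true_composition,
            ", seed=", acc_seed, "): dosage sites=", nrow(pts),
            " median %B=", sprintf("%.2f", pct_b),
            " het sites=", n_raw, "->", nrow(freqs),
            " ploidy=", if (is.na(pcall$observed_ploidy)) "undetermined"
                        else pcall$observed_ploidy)

    reports[[i]] <- stage("report", reconcile(
      row, pcall$observed_ploidy, pct_b, cfg$pure_threshold))
  }

  report <- do.call(rbind, reports)
  rownames(report) <- NULL
  report_path <- file.path(out_dir, "report.tsv")
  con <- file(report_path, "w")
  writeLines(c(paste0("# musapaint reconciliation report"),
               paste0("# master_seed=", cfg$seed, " b_accession_seed=", b_seed),
               paste0("# pure_threshold=", cfg$pure_threshold,
                      " span=", cfg$span, " bounds=",
                      paste(cfg$bounds, collapse = ","))), con)
  suppressWarnings(write.table(report, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  close(con)
  writeLines(log_lines, file.path(out_dir, "pipeline.log"))

  attr(report, "out_dir") <- out_dir
  attr(report, "diagnostic_snps") <- snps
  invisible(report)
}

#' Read a key=value pipeline configuration file
#'
#' Plain text, one `key=value` per line, `#` comments; the `accessions`
#' key names a TSV with the panel columns. Unknown keys are rejected.
#'
#' @param path config file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- trimws(vapply(kv, function(x) paste(x[-1L], collapse = "="), ""))
  names(vals) <- keys

  if (!"accessions" %in% keys) .stop_invalid("config must name an accessions TSV")
  acc_path <- vals[["accessions"]]
  if (!file.exists(acc_path)) {
    acc_path <- file.path(dirname(path), vals[["accessions"]])
  }
  accessions <- read.delim(acc_path, stringsAsFactors = FALSE)

  numeric_keys <- c("seed", "n_chrom", "chrom_length", "divergence_rate",
                    "indel_rate", "mean_depth", "error_rate", "hom_fraction",
                    "depth_min", "depth_max", "span", "degree",
                    "pure_threshold", "min_het_sites")
  args <- list(accessions = accessions)
  for (k in setdiff(keys, "accessions")) {
    if (!k %in% numeric_keys) .stop_invalid("unknown config key: ", k)
    args[[k]] <- as.numeric(vals[[k]])
  }
  for (k in c("seed", "n_chrom", "chrom_length", "degree", "min_het_sites")) {
    if (!is.null(args[[k]])) args[[k]] <- as.integer(args[[k]])
  }
  do.call(pipeline_config, args)
}
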