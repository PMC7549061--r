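## Pileup -> annotated variant calls, the stand-in for SAMtools mpileup +
## BCFtools multiallelic calling (-m -v). QUAL is defined here as the
## phred-scaled binomial-tail probability of seeing the observed number of
## non-reference reads if all of them were sequencing errors:
##   qual = -10 log10 P(X >= n_alt),  X ~ Binomial(depth, error_rate),
## capped at qual_cap. This is not BCFtools' genotype-likelihood QUAL, but
## it is monotone in the same quantities (more alt reads -> higher QUAL,
## higher assumed error rate -> lower QUAL) and is fully specified, so it
## can be checked against a brute-force binomial-tail oracle.

#' Call variants from a pileup
#'
#' Emits a substitution call wherever at least `min_alt_reads`
#' non-reference bases are observed (variant sites only), listing all
#' supported alternate alleles in decreasing read-support order, and an
#' indel call wherever any read supports an indel. The per-call
#' annotations QUAL, DP (column depth), IDV (indel-supporting reads) and
#' the indel flag feed the downstream filter chain. A diploid
#' maximum-likelihood genotype (GT) is attached for completeness but
#' dosage, not genotype, drives the downstream analysis.
#'
#' @param pileup a `pileup` data.frame (see [simulate_pileup()]); positions
#'   must be strictly increasing within each chromosome.
#' @param error_rate assumed per-base miscall rate (in `(0, 0.25)`).
#' @param min_alt_reads minimum non-reference reads to emit a substitution
#'   call (default 2).
#' @param qual_cap upper bound on QUAL (default 999), so that error-free
#'   simulations yield finite scores.
#' @return A `variant_calls` data.frame: chrom, pos, ref, alt
#'   (comma-joined, support-ordered), qual, dp, idv, is_indel, gt.
#' @export
call_variants <- function(pileup, error_rate = 0.005, min_alt_reads = 2L,
                          qual_cap = 999) {
  if (!is.numeric(error_rate) || length(error_rate) != 1L ||
      error_rate <= 0 || error_rate >= 0.25) {
    .stop_invalid("error_rate must be in (0, 0.25)")
  }
  min_alt_reads <- .check_count(min_alt_reads, "min_alt_reads")
  .check_sorted(pileup$chrom, pileup$pos, "pileup")

  counts <- as.matrix(pileup[, DNA_BASES])
  ref_idx <- match(pileup$ref, DNA_BASES)
  alt_counts <- counts
  alt_counts[cbind(seq_len(nrow(counts)), ref_idx)] <- 0L
  alt_total <- rowSums(alt_counts)

  snp_rows <- which(alt_total >= min_alt_reads)
  indel_rows <- which(pileup$indel_support >= 1L)

  phred_tail <- function(k, size) {
    q <- -10 / log(10) *
      pbinom(k - 1, size, error_rate, lower.tail = FALSE, log.p = TRUE)
    pmin(q, qual_cap)
  }

  snp_calls <- NULL
  if (length(snp_rows)) {
    alt_str <- vapply(snp_rows, function(r) {
      ac <- alt_counts[r, ]
      ord <- order(-ac, seq_len(4L))
      ord <- ord[ac[ord] > 0L]
      paste(DNA_BASES[ord], collapse = ",")
    }, character(1))
    dp <- pileup$depth[snp_rows]
    at <- alt_total[snp_rows]
    ## diploid ML genotype from total alt reads: RR, RA or AA
    ll_rr <- dbinom(at, dp, error_rate, log = TRUE)
    ll_ra <- dbinom(at, dp, 0.5, log = TRUE)
    ll_aa <- dbinom(at, dp, 1 - error_rate, log = TRUE)
    gt <- c("0/0", "0/1", "1/1")[max.col(cbind(ll_rr, ll_ra, ll_aa),
                                         ties.method = "last")]
    snp_calls <- data.frame(
      chrom = pileup$chrom[snp_rows], pos = pileup$pos[snp_rows],
      ref = pileup$ref[snp_rows], alt = alt_str,
      qual = phred_tail(at, dp), dp = dp, idv = 0L,
      is_indel = FALSE, gt = gt, stringsAsFactors = FALSE
    )
  }

  indel_calls <- NULL
  if (length(indel_rows)) {
    idv <- pileup$indel_support[indel_rows]
    dp <- pileup$depth[indel_rows]
    indel_calls <- data.frame(
      chrom = pileup$chrom[indel_rows], pos = pileup$pos[indel_rows],
      ref = pileup$ref[indel_rows],
      alt = paste0(pileup$ref[indel_rows], "N"),  # placeholder indel allele
      qual = phred_tail(idv, dp), dp = dp, idv = idv,
      is_indel = TRUE, gt = "0/1", stringsAsFactors = FALSE
    )
  }

  calls <- rbind(snp_calls, indel_calls)
  if (is.null(calls)) {
    calls <- data.frame(chrom = character(0), pos = integer(0),
                        ref = character(0), alt = character(0),
                        qual = numeric(0), dp = integer(0), idv = integer(0),
                        is_indel = logical(0), gt = character(0),
                        stringsAsFactors = FALSE)
  } else {
    calls <- calls[order(match(calls$chrom, unique(pileup$chrom)),
                         calls$pos, calls$is_indel), ]
  }
  rownames(calls) <- NULL
  class(calls) <- c("variant_calls", "data.frame")
  calls
}

#' Write variant calls as uncompressed VCF 4.2
#'
#' QUAL goes in the VCF QUAL column; DP, IDV and the INDEL flag are INFO
#' keys; GT is the single sample's FORMAT field. Alternate alleles are
#' comma-joined in support order.
#'
#' @param calls a `variant_calls` data.frame.
#' @param path output path.
#' @param sample_name sample column header.
#' @export
write_vcf <- function(calls, path, sample_name = "SAMPLE") {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=musapaint",
    '##INFO=<ID=DP,Number=1,Type=Integer,Description="Raw read depth">',
    '##INFO=<ID=IDV,Number=1,Type=Integer,Description="Number of reads supporting an indel">',
    '##INFO=<ID=INDEL,Number=0,Type=Flag,Description="Indicates that the variant is an indel">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_name, sep = "\t")
  )
  lines <- header
  if (nrow(calls)) {
    info <- paste0("DP=", calls$dp, ";IDV=", calls$idv,
                   ifelse(calls$is_indel, ";INDEL", ""))
    lines <- c(header, paste(calls$chrom, calls$pos, ".", calls$ref,
                             calls$alt, sprintf("%.10g", calls$qual), ".",
                             info, "GT", calls$gt, sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a musapaint-style VCF back into variant calls
#'
#' @param path VCF path (uncompressed).
#' @return A `variant_calls` data.frame.
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  body_at <- which(!startsWith(lines, "#"))
  if (!any(startsWith(lines, "##fileformat=VCF"))) {
    .stop_malformed("not a VCF file: ", path)
  }
  parse_info <- function(info, key) {
    m <- regmatches(info, regexpr(paste0("(?:^|;)", key, "=[^;]+"), info))
    if (!length(m)) return(NA_integer_)
    as.integer(sub(paste0(".*", key, "="), "", m))
  }
  rows <- lapply(body_at, function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 8L) {
      .stop_malformed("malformed VCF line ", i, " in ", path)
    }
    pos <- suppressWarnings(as.integer(f[2]))
    qual <- suppressWarnings(as.numeric(f[6]))
    if (is.na(pos) || is.na(qual)) {
      .stop_malformed("malformed VCF line ", i, " in ", path)
    }
    data.frame(
      chrom = f[1], pos = pos, ref = f[4], alt = f[5], qual = qual,
      dp = parse_info(f[8], "DP"), idv = parse_info(f[8], "IDV"),
      is_indel = grepl("(^|;)INDEL(;|$)", f[8]),
      gt = if (length(f) >= 10L) f[10] else NA_character_,
      stringsAsFactors = FALSE
    )
  })
  calls <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(0), pos = integer(0), ref = character(0),
               alt = character(0), qual = numeric(0), dp = integer(0),
               idv = integer(0), is_indel = logical(0), gt = character(0),
               stringsAsFactors = FALSE)
  calls$idv[is.na(calls$idv)] <- 0L
  rownames(calls) <- NULL
  class(calls) <- c("variant_calls", "data.frame")
  calls
}
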