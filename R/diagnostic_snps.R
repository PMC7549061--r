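## The BCFtools-style filter chain and informative-SNP derivation.
##
## Filter semantics: a SNP call is kept iff
##   qual >= qual_min  AND  dp >= dp_min  AND  is_indel is FALSE
##   AND its distance to the nearest *credible* indel (one whose
##   indel-supporting read count idv >= idv_min) is strictly greater than
##   snp_gap ("within snp_gap bp" excludes, so the boundary distance ==
##   snp_gap is excluded too, matching bcftools --SnpGap).
## Distance is measured to the indel's anchor position; indel length is
## ignored (a deliberate simplification, documented in the vignette).

#' Filter-chain configuration
#'
#' Defaults follow the standard Musa A/B pipeline settings: QUAL >= 35,
#' DP >= 5, indels credible at IDV >= 2, SNPs within 100 bp of a credible
#' indel dropped, indel records excluded from the output.
#'
#' @param qual_min minimum phred QUAL for a SNP to pass.
#' @param dp_min minimum read depth.
#' @param idv_min minimum indel-supporting reads for an indel to count
#'   (both as an emitted indel and for the gap rule).
#' @param snp_gap exclusion distance around credible indels, in bp.
#' @param exclude_indels drop indel records from the filtered output.
#' @return A `filter_config` list.
#' @export
filter_config <- function(qual_min = 35, dp_min = 5, idv_min = 2,
                          snp_gap = 100, exclude_indels = TRUE) {
  for (v in c("qual_min", "dp_min", "idv_min", "snp_gap")) {
    .check_number(get(v), v, lower = 0)
  }
  structure(list(qual_min = qual_min, dp_min = dp_min, idv_min = idv_min,
                 snp_gap = snp_gap, exclude_indels = isTRUE(exclude_indels)),
            class = "filter_config")
}

#' Apply the variant filter chain
#'
#' @param calls coordinate-sorted `variant_calls`.
#' @param cfg a [filter_config()].
#' @return The passing subset of `calls`, same class and column layout.
#' @export
filter_variants <- function(calls, cfg = filter_config()) {
  stopifnot(inherits(cfg, "filter_config"))
  if (!nrow(calls)) return(calls)
  ## sorted check: non-decreasing per chromosome (SNP and indel records may
  ## legitimately share a position)
  for (ch in unique(calls$chrom)) {
    p <- calls$pos[calls$chrom == ch]
    if (length(p) > 1L && any(diff(p) < 0)) {
      .stop_malformed("variant calls not coordinate-sorted on ", ch)
    }
  }

  near_indel <- logical(nrow(calls))
  for (ch in unique(calls$chrom)) {
    in_ch <- calls$chrom == ch
    anchors <- calls$pos[in_ch & calls$is_indel & calls$idv >= cfg$idv_min]
    if (!length(anchors)) next
    anchors <- sort(unique(anchors))
    pos <- calls$pos[in_ch]
    ## distance to nearest anchor via findInterval on the sorted anchors
    i <- findInterval(pos, anchors)
    d_lo <- ifelse(i >= 1L, pos - anchors[pmax(i, 1L)], Inf)
    d_hi <- ifelse(i < length(anchors), anchors[pmin(i + 1L, length(anchors))] - pos, Inf)
    near_indel[in_ch] <- pmin(d_lo, d_hi) <= cfg$snp_gap
  }

  keep_snp <- !calls$is_indel &
    calls$qual >= cfg$qual_min &
    calls$dp >= cfg$dp_min &
    !near_indel
  keep <- keep_snp
  if (!cfg$exclude_indels) {
    keep <- keep | (calls$is_indel & calls$idv >= cfg$idv_min &
                      calls$qual >= cfg$qual_min & calls$dp >= cfg$dp_min)
  }
  out <- calls[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Identify informative (A-vs-B diagnostic) SNPs from a B-genome accession
#'
#' Given filtered variant calls from a pure B accession aligned against the
#' A reference, returns the sites where the accession looks homozygous for
#' a non-reference allele (alternate-base fraction at least `hom_fraction`
#' in its pileup): at such sites the B genome carries a fixed allele
#' different from A, so reads in any target accession can be attributed to
#' a subgenome. The reference base becomes `a_allele` and the major
#' alternate becomes `b_allele`; minor alternates at multiallelic sites
#' are ignored.
#'
#' @param b_calls_filtered filtered `variant_calls` from the B accession.
#' @param b_pileup the same accession's `pileup` (for base counts).
#' @param hom_fraction minimum alternate-base fraction (default 0.9).
#' @return A `diagnostic_snps` data.frame: chrom, pos, a_allele, b_allele.
#' @export
identify_informative_snps <- function(b_calls_filtered, b_pileup,
                                      hom_fraction = 0.9) {
  .check_number(hom_fraction, "hom_fraction", 0, 1)
  calls <- b_calls_filtered[!b_calls_filtered$is_indel, , drop = FALSE]
  empty <- data.frame(chrom = character(0), pos = integer(0),
                      a_allele = character(0), b_allele = character(0),
                      stringsAsFactors = FALSE)
  if (!nrow(calls)) {
    class(empty) <- c("diagnostic_snps", "data.frame")
    return(empty)
  }
  idx <- match(.site_key(calls$chrom, calls$pos),
               .site_key(b_pileup$chrom, b_pileup$pos))
  if (anyNA(idx)) {
    .stop_malformed(sum(is.na(idx)),
                    " variant call(s) have no matching pileup column")
  }
  counts <- as.matrix(b_pileup[idx, DNA_BASES])
  ref_i <- match(calls$ref, DNA_BASES)
  n <- nrow(counts)
  total <- rowSums(counts)
  ref_count <- counts[cbind(seq_len(n), ref_i)]
  alt_counts <- counts
  alt_counts[cbind(seq_len(n), ref_i)] <- -1L  # ref never the major alt
  frac <- ifelse(total > 0, (total - ref_count) / total, 0)
  major_alt <- DNA_BASES[max.col(alt_counts, ties.method = "first")]

  keep <- frac >= hom_fraction
  out <- data.frame(chrom = calls$chrom[keep], pos = calls$pos[keep],
                    a_allele = calls$ref[keep], b_allele = major_alt[keep],
                    stringsAsFactors = FALSE)
  out <- out[!duplicated(.site_key(out$chrom, out$pos)), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("diagnostic_snps", "data.frame")
  out
}

#' Intersect diagnostic-SNP sets from two B accessions
#'
#' Sites are kept when present in both sets with identical alleles.
#' @param x,y `diagnostic_snps` data.frames.
#' @export
intersect_diagnostic_snps <- function(x, y) {
  kx <- paste(x$chrom, x$pos, x$a_allele, x$b_allele)
  ky <- paste(y$chrom, y$pos, y$a_allele, y$b_allele)
  out <- x[kx %in% ky, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write/read a diagnostic-SNP set
#'
#' TSV columns chrom, pos, a_allele, b_allele; or a sites-only VCF (REF =
#' a_allele, ALT = b_allele). [read_diagnostic_snps()] auto-detects the
#' format from the first line.
#'
#' @param snps a `diagnostic_snps` data.frame.
#' @param path file path.
#' @param format `"tsv"` or `"vcf"`.
#' @export
write_diagnostic_snps <- function(snps, path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "tsv") {
    write.table(snps, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    lines <- c("##fileformat=VCFv4.2", "##source=musapaint-diagnostic-snps",
               paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", sep = "\t"))
    if (nrow(snps)) {
      lines <- c(lines, paste(snps$chrom, snps$pos, ".", snps$a_allele,
                              snps$b_allele, ".", ".", ".", sep = "\t"))
    }
    writeLines(lines, path)
  }
  invisible(path)
}

#' @rdname write_diagnostic_snps
#' @export
read_diagnostic_snps <- function(path) {
  first <- readLines(path, n = 1L)
  if (startsWith(first, "##fileformat=VCF")) {
    lines <- readLines(path)
    body <- lines[!startsWith(lines, "#")]
    f <- strsplit(body, "\t", fixed = TRUE)
    out <- data.frame(
      chrom = vapply(f, `[`, "", 1L),
      pos = as.integer(vapply(f, `[`, "", 2L)),
      a_allele = vapply(f, `[`, "", 4L),
      b_allele = vapply(f, `[`, "", 5L),
      stringsAsFactors = FALSE
    )
  } else {
    out <- read.delim(path, stringsAsFactors = FALSE)
  }
  class(out) <- c("diagnostic_snps", "data.frame")
  out
}
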