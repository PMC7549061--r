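## Synthetic allopolyploid data generator.
##
## Coordinates are 1-based throughout the package; intervals are half-open
## [start, end). Subgenome divergence is modelled as substitutions recorded
## in truth_sites (A and B sequences keep identical lengths), plus small
## (1-3 bp) indel events private to one subgenome, recorded as annotations
## rather than applied to the sequences: pileups are simulated against the
## A-reference coordinate system, which is what the downstream filter chain
## consumes, so applying indels to the strings would only complicate the
## coordinate bookkeeping without adding testable behaviour.

#' Generate a pair of diverged A/B subgenome references
#'
#' Simulates an A reference genome and a B genome diverged from it at a
#' controllable per-base substitution rate, recording every divergent site
#' (the "truth sites" that an ideal diagnostic-SNP scan should recover) and
#' a set of small subgenome-private indel events used to exercise the
#' indel-aware variant filters.
#'
#' @param seed integer seed; identical seeds and parameters reproduce the
#'   pair byte-for-byte.
#' @param n_chrom number of chromosomes.
#' @param chrom_length length of every chromosome in bp.
#' @param divergence_rate per-base probability that the B genome carries a
#'   substitution relative to A (in `[0, 0.1]`).
#' @param indel_rate per-base probability of a 1-3 bp indel private to one
#'   subgenome (in `[0, 0.1]`).
#' @return A `subgenome_pair`: list with `chrom_names`, `a_seqs` and
#'   `b_seqs` (named character vectors of equal-length sequences),
#'   `truth_sites` (data.frame chrom, pos, a_allele, b_allele) and
#'   `indels` (data.frame chrom, pos, subgenome, type, len).
#' @examples
#' pair <- generate_subgenomes(1, n_chrom = 1, chrom_length = 2000)
#' nrow(pair$truth_sites)
#' @export
generate_subgenomes <- function(seed, n_chrom = 2L, chrom_length = 100000L,
                                divergence_rate = 0.005, indel_rate = 2e-4) {
  .check_count(seed, "seed", lower = 0L)
  n_chrom <- .check_count(n_chrom, "n_chrom")
  chrom_length <- .check_count(chrom_length, "chrom_length")
  .check_number(divergence_rate, "divergence_rate", 0, 0.1)
  .check_number(indel_rate, "indel_rate", 0, 0.1)

  set.seed(seed)
  chrom_names <- sprintf("chr%02d", seq_len(n_chrom))
  a_seqs <- character(n_chrom)
  b_seqs <- character(n_chrom)
  ts_list <- vector("list", n_chrom)
  indel_list <- vector("list", n_chrom)

  for (i in seq_len(n_chrom)) {
    a <- sample(DNA_BASES, chrom_length, replace = TRUE)
    b <- a
    sub_pos <- which(runif(chrom_length) < divergence_rate)
    if (length(sub_pos)) {
      ai <- match(a[sub_pos], DNA_BASES)
      shift <- sample.int(3L, length(sub_pos), replace = TRUE)
      b[sub_pos] <- DNA_BASES[OTHER_BASES[cbind(ai, shift)]]
    }
    ts_list[[i]] <- data.frame(
      chrom = rep(chrom_names[i], length(sub_pos)),
      pos = sub_pos,
      a_allele = a[sub_pos],
      b_allele = b[sub_pos],
      stringsAsFactors = FALSE
    )
    ind_pos <- which(runif(chrom_length) < indel_rate)
    ind_pos <- setdiff(ind_pos, sub_pos)  # keep events distinct
    n_ind <- length(ind_pos)
    indel_list[[i]] <- data.frame(
      chrom = rep(chrom_names[i], n_ind),
      pos = ind_pos,
      subgenome = if (n_ind) sample(c("A", "B"), n_ind, replace = TRUE) else character(0),
      type = if (n_ind) sample(c("ins", "del"), n_ind, replace = TRUE) else character(0),
      len = if (n_ind) sample.int(3L, n_ind, replace = TRUE) else integer(0),
      stringsAsFactors = FALSE
    )
    a_seqs[i] <- paste(a, collapse = "")
    b_seqs[i] <- paste(b, collapse = "")
  }
  names(a_seqs) <- names(b_seqs) <- chrom_names

  structure(
    list(
      chrom_names = chrom_names,
      chrom_lengths = stats::setNames(rep(chrom_length, n_chrom), chrom_names),
      a_seqs = a_seqs,
      b_seqs = b_seqs,
      truth_sites = do.call(rbind, ts_list),
      indels = do.call(rbind, indel_list)
    ),
    class = "subgenome_pair"
  )
}

#' @export
print.subgenome_pair <- function(x, ...) {
  cat("A/B subgenome pair:", length(x$chrom_names), "chromosome(s),",
      sum(x$chrom_lengths), "bp total\n")
  cat("  divergent sites:", nrow(x$truth_sites),
      " subgenome-private indels:", nrow(x$indels), "\n")
  invisible(x)
}

#' Describe a polyploid genotype to simulate
#'
#' @param composition string over `{A, B}` giving the subgenome of each
#'   chromosome copy, e.g. `"AAB"`; its length is the ploidy (2-4).
#' @param hx_segments optional data.frame of homeologous-exchange segments
#'   with columns `chrom`, `start`, `end` (half-open, 1-based), `donor`
#'   (`"A"` or `"B"`) and `copy` (1-based index into the composition);
#'   within the segment the copy's sequence is replaced by the donor
#'   subgenome's.
#' @return A `genotype_spec` list.
#' @export
genotype_spec <- function(composition, hx_segments = NULL) {
  if (!is.character(composition) || length(composition) != 1L ||
      grepl("[^AB]", composition)) {
    .stop_invalid("composition must be a string over {A,B}, got ", composition)
  }
  ploidy <- nchar(composition)
  if (ploidy < 2L || ploidy > 4L) {
    .stop_invalid("ploidy (nchar(composition)) must be 2, 3 or 4")
  }
  if (!is.null(hx_segments)) {
    need <- c("chrom", "start", "end", "donor", "copy")
    if (!all(need %in% names(hx_segments))) {
      .stop_invalid("hx_segments needs columns ", paste(need, collapse = ", "))
    }
    if (any(hx_segments$start >= hx_segments$end)) {
      .stop_invalid("hx_segments must satisfy start < end (half-open intervals)")
    }
    if (any(!hx_segments$donor %in% c("A", "B"))) {
      .stop_invalid("hx donor must be 'A' or 'B'")
    }
    if (any(hx_segments$copy < 1L | hx_segments$copy > ploidy)) {
      .stop_invalid("hx copy index out of range for ploidy ", ploidy)
    }
    ## no overlap on the same copy of the same chromosome
    sp <- split(hx_segments, paste(hx_segments$chrom, hx_segments$copy))
    for (seg in sp) {
      seg <- seg[order(seg$start), ]
      if (nrow(seg) > 1L && any(seg$start[-1L] < seg$end[-nrow(seg)])) {
        .stop_invalid("hx_segments overlap on the same chromosome copy")
      }
    }
  }
  structure(
    list(composition = composition, ploidy = as.integer(ploidy),
         hx_segments = hx_segments),
    class = "genotype_spec"
  )
}

#' Compose a simulated accession from a subgenome pair and a genotype
#'
#' Builds the accession's per-copy haplotypes: copy i is the A sequence if
#' `composition[i] == "A"` and the B sequence otherwise, with any
#' homeologous-exchange segments substituted from the donor subgenome.
#' Indel carriage follows the same rule. The per-site true B dosage (the
#' fraction of copies carrying the B allele at each divergent site) is
#' computed from the final haplotypes, so exchanges are reflected in it.
#'
#' @param pair a [generate_subgenomes()] result.
#' @param spec a [genotype_spec()].
#' @param seed kept for interface symmetry; composition is deterministic.
#' @return A `sim_accession`: list with `spec`, `chrom_lengths`, `a_ref`
#'   (the A reference sequences), `haplotypes` (list per chromosome of
#'   per-copy sequences), `hap_indels` (data.frame chrom, pos, copy) and
#'   `truth_b_dosage` (data.frame chrom, pos, a_allele, b_allele, dosage).
#' @export
compose_genotype <- function(pair, spec, seed = 1L) {
  stopifnot(inherits(pair, "subgenome_pair"))
  if (!inherits(spec, "genotype_spec")) spec <- genotype_spec(spec)
  p <- spec$ploidy
  copies <- strsplit(spec$composition, "")[[1]]
  hx <- spec$hx_segments
  if (!is.null(hx) && !all(hx$chrom %in% pair$chrom_names)) {
    .stop_invalid("hx_segments reference unknown chromosomes")
  }
  if (!is.null(hx)) {
    L <- pair$chrom_lengths[hx$chrom]
    if (any(hx$start < 1L) || any(hx$end > L + 1L)) {
      .stop_invalid("hx_segments out of chromosome bounds")
    }
  }

  haplotypes <- vector("list", length(pair$chrom_names))
  names(haplotypes) <- pair$chrom_names
  dos_list <- vector("list", length(pair$chrom_names))
  hap_indel_list <- list()

  for (ch in pair$chrom_names) {
    a <- strsplit(pair$a_seqs[[ch]], "")[[1]]
    b <- strsplit(pair$b_seqs[[ch]], "")[[1]]
    src <- list(A = a, B = b)
    hmat <- vapply(seq_len(p), function(i) src[[copies[i]]], character(length(a)))
    ## per-copy source subgenome along the chromosome (for indel carriage)
    src_geno <- matrix(rep(copies, each = length(a)), ncol = p)
    if (!is.null(hx)) {
      for (k in which(hx$chrom == ch)) {
        idx <- hx$start[k]:(hx$end[k] - 1L)
        hmat[idx, hx$copy[k]] <- src[[hx$donor[k]]][idx]
        src_geno[idx, hx$copy[k]] <- hx$donor[k]
      }
    }
    haplotypes[[ch]] <- apply(hmat, 2, paste, collapse = "")

    ts <- pair$truth_sites[pair$truth_sites$chrom == ch, , drop = FALSE]
    if (nrow(ts)) {
      dosage <- rowMeans(hmat[ts$pos, , drop = FALSE] ==
                           matrix(ts$b_allele, nrow(ts), p))
      dos_list[[ch]] <- cbind(ts, dosage = dosage)
    }

    ind <- pair$indels[pair$indels$chrom == ch, , drop = FALSE]
    if (nrow(ind)) {
      carried <- do.call(rbind, lapply(seq_len(nrow(ind)), function(k) {
        cc <- which(src_geno[ind$pos[k], ] == ind$subgenome[k])
        if (length(cc)) data.frame(chrom = ch, pos = ind$pos[k], copy = cc) else NULL
      }))
      hap_indel_list[[ch]] <- carried
    }
  }

  hap_indels <- do.call(rbind, hap_indel_list)
  if (is.null(hap_indels)) {
    hap_indels <- data.frame(chrom = character(0), pos = integer(0), copy = integer(0))
  }
  truth_b_dosage <- do.call(rbind, dos_list)
  if (is.null(truth_b_dosage)) {
    truth_b_dosage <- data.frame(chrom = character(0), pos = integer(0),
                                 a_allele = character(0), b_allele = character(0),
                                 dosage = numeric(0))
  }
  rownames(truth_b_dosage) <- NULL

  structure(
    list(spec = spec, chrom_lengths = pair$chrom_lengths,
         a_ref = pair$a_seqs, haplotypes = haplotypes,
         hap_indels = hap_indels, truth_b_dosage = truth_b_dosage),
    class = "sim_accession"
  )
}

#' @export
print.sim_accession <- function(x, ...) {
  cat("Simulated accession:", x$spec$composition,
      sprintf("(ploidy %d)", x$spec$ploidy), "\n")
  cat("  chromosomes:", length(x$haplotypes),
      " divergent sites:", nrow(x$truth_b_dosage), "\n")
  if (!is.null(x$spec$hx_segments)) {
    cat("  homeologous-exchange segments:", nrow(x$spec$hx_segments), "\n")
  }
  invisible(x)
}

#' Simulate a read pileup for an accession against the A reference
#'
#' Column-wise read simulation: at each position the depth is Poisson with
#' the given mean, each read draws a haplotype copy uniformly, reports that
#' copy's base and is miscalled to one of the three other bases with
#' probability `error_rate`. Reads drawn from copies carrying a
#' subgenome-private indel at the position count towards `indel_support`.
#' No read-pair or fragment structure is modelled: the downstream pipeline
#' consumes pileups, so per-column simulation covers everything it sees.
#'
#' @param acc a [compose_genotype()] result.
#' @param mean_depth mean Poisson read depth (> 0).
#' @param error_rate per-base miscall probability (in `[0, 0.25)`).
#' @param seed integer seed (same seed, same pileup).
#' @param positions optional named list (by chromosome) of sorted positions
#'   to emit; default all positions. Restricting positions reproduces
#'   exactly the columns a full simulation would not, since fewer random
#'   draws occur, but each column's distribution is identical.
#' @return A `pileup` data.frame: chrom, pos, ref, depth, A, C, G, T,
#'   indel_support; rows in coordinate order.
#' @export
simulate_pileup <- function(acc, mean_depth = 30, error_rate = 0.005,
                            seed = 1L, positions = NULL) {
  stopifnot(inherits(acc, "sim_accession"))
  .check_number(mean_depth, "mean_depth", lower = 1e-9)
  if (!is.numeric(error_rate) || length(error_rate) != 1L ||
      error_rate < 0 || error_rate >= 0.25) {
    .stop_invalid("error_rate must be in [0, 0.25)")
  }
  .check_count(seed, "seed", lower = 0L)

  set.seed(seed)
  p <- acc$spec$ploidy
  out <- vector("list", length(acc$haplotypes))

  for (ci in seq_along(acc$haplotypes)) {
    ch <- names(acc$haplotypes)[ci]
    hmat <- vapply(acc$haplotypes[[ch]], function(s) strsplit(s, "")[[1]],
                   character(acc$chrom_lengths[[ch]]))
    ref <- strsplit(acc$a_ref[[ch]], "")[[1]]
    P <- if (is.null(positions)) seq_along(ref) else as.integer(positions[[ch]])
    n <- length(P)
    if (!n) next
    d <- rpois(n, mean_depth)

    ## positions where the copies disagree need per-read copy assignment;
    ## everywhere else a binomial error model on the shared base suffices
    hP <- hmat[P, , drop = FALSE]
    is_var <- rowSums(hP != hP[, 1L]) > 0L

    true_idx <- match(hP[, 1L], DNA_BASES)
    n_err <- rbinom(n, d, error_rate)
    errs <- .split_errors_3(n_err)
    counts <- matrix(0L, n, 4L)
    counts[cbind(seq_len(n), true_idx)] <- d - n_err
    for (j in 1:3) {
      tgt <- OTHER_BASES[cbind(true_idx, j)]
      counts[cbind(seq_len(n), tgt)] <- counts[cbind(seq_len(n), tgt)] + errs[, j]
    }

    vp <- which(is_var & d > 0L)
    if (length(vp)) {
      rows <- rep(vp, d[vp])
      copy <- sample.int(p, length(rows), replace = TRUE)
      base_i <- match(hP[cbind(rows, copy)], DNA_BASES)
      mis <- runif(length(rows)) < error_rate
      if (any(mis)) {
        shift <- sample.int(3L, sum(mis), replace = TRUE)
        base_i[mis] <- OTHER_BASES[cbind(base_i[mis], shift)]
      }
      tab <- tabulate((base_i - 1L) * n + rows, nbins = 4L * n)
      counts[vp, ] <- matrix(tab, n, 4L)[vp, ]
    }
    counts[is_var & d == 0L, ] <- 0L

    indel_support <- integer(n)
    hi <- acc$hap_indels[acc$hap_indels$chrom == ch, , drop = FALSE]
    if (nrow(hi)) {
      carriers <- table(hi$pos)
      ip <- match(as.integer(names(carriers)), P)
      keep <- !is.na(ip)
      if (any(keep)) {
        ipk <- ip[keep]
        indel_support[ipk] <- rbinom(length(ipk), d[ipk],
                                     as.integer(carriers)[keep] / p)
      }
    }

    out[[ci]] <- data.frame(
      chrom = rep(ch, n), pos = P, ref = ref[P], depth = d,
      A = counts[, 1L], C = counts[, 2L], G = counts[, 3L], T = counts[, 4L],
      indel_support = indel_support, stringsAsFactors = FALSE
    )
  }

  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("pileup", "data.frame")
  res
}

#' Write subgenome references as multi-FASTA
#'
#' @param pair a [generate_subgenomes()] result.
#' @param a_path,b_path output FASTA paths for the A and B references.
#' @export
write_subgenome_fasta <- function(pair, a_path, b_path) {
  stopifnot(inherits(pair, "subgenome_pair"))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(pair$a_seqs), a_path)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(pair$b_seqs), b_path)
  invisible(c(a_path, b_path))
}

#' Write/read the divergent-site truth table as TSV
#' @param pair a `subgenome_pair`.
#' @param path output path.
#' @export
write_truth_sites <- function(pair, path) {
  write.table(pair$truth_sites, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth_sites
#' @export
read_truth_sites <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Write/read a pileup as samtools-like TSV
#'
#' Columns: chrom, pos, ref, depth, A, C, G, T, indel_support.
#' @param pileup a `pileup` data.frame.
#' @param path file path.
#' @export
write_pileup <- function(pileup, path) {
  write.table(pileup, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pileup
#' @export
read_pileup <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE,
                  colClasses = c(chrom = "character", ref = "character"))
  need <- c("chrom", "pos", "ref", "depth", "A", "C", "G", "T", "indel_support")
  if (!all(need %in% names(x))) {
    .stop_malformed("pileup file ", path, " lacks columns ",
                    paste(setdiff(need, names(x)), collapse = ", "))
  }
  class(x) <- c("pileup", "data.frame")
  x
}
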