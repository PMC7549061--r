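## B-allele dosage quantification and chromosome painting.
##
## At each diagnostic SNP the target accession's pileup yields the counts
## of reads supporting the A and the B allele; reads carrying any third
## allele are excluded from both numerator and denominator. Only sites
## whose column depth lies in the inclusive window [depth_min, depth_max]
## are used. The per-site percent-B values are LOESS-smoothed along each
## chromosome and painted into three bands: A-like [0,33), mixed [33,66),
## B-like [66,100].

#' Quantify per-site B-allele dosage in a target accession
#'
#' @param target_pileup the target accession's `pileup`, coordinate-sorted.
#' @param snps a `diagnostic_snps` data.frame, coordinate-sorted.
#' @param depth_min,depth_max inclusive depth window; sites outside it are
#'   dropped (defaults 10 and 50).
#' @return A `dosage_points` data.frame: chrom, pos, depth, a_count,
#'   b_count, pct_b (100 * b / (a + b)). Diagnostic sites missing from the
#'   pileup, outside the depth window, or with no A/B-supporting reads are
#'   skipped; a message reports how many.
#' @export
quantify_b_fraction <- function(target_pileup, snps, depth_min = 10,
                                depth_max = 50) {
  .check_number(depth_min, "depth_min", lower = 0)
  .check_number(depth_max, "depth_max", lower = depth_min)
  idx <- match(.site_key(snps$chrom, snps$pos),
               .site_key(target_pileup$chrom, target_pileup$pos))
  n_missing <- sum(is.na(idx))
  present <- !is.na(idx)
  snps_p <- snps[present, , drop = FALSE]
  cols <- target_pileup[idx[present], , drop = FALSE]

  counts <- as.matrix(cols[, DNA_BASES])
  nn <- nrow(counts)
  a_count <- counts[cbind(seq_len(nn), match(snps_p$a_allele, DNA_BASES))]
  b_count <- counts[cbind(seq_len(nn), match(snps_p$b_allele, DNA_BASES))]
  in_window <- cols$depth >= depth_min & cols$depth <= depth_max
  informative <- (a_count + b_count) > 0
  keep <- in_window & informative

  if (n_missing || any(!keep)) {
    message(sprintf(
      "quantify_b_fraction: skipped %d missing, %d outside depth [%g,%g], %d with no A/B reads",
      n_missing, sum(!in_window), depth_min, depth_max,
      sum(in_window & !informative)))
  }

  out <- data.frame(
    chrom = snps_p$chrom[keep], pos = snps_p$pos[keep],
    depth = cols$depth[keep], a_count = a_count[keep],
    b_count = b_count[keep],
    pct_b = 100 * b_count[keep] / (a_count[keep] + b_count[keep]),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("dosage_points", "data.frame")
  out
}

#' LOESS-smooth percent-B values along each chromosome
#'
#' Locally weighted polynomial regression (tricube weights, via
#' [stats::loess()]) of `pct_b` against position, fitted per chromosome and
#' evaluated at every point; fitted values are clamped to `[0, 100]`.
#'
#' @param points a `dosage_points` data.frame.
#' @param span LOESS span as a fraction of points (default 0.5).
#' @param degree local polynomial degree, 1 or 2 (default 2, the
#'   [stats::loess()] default).
#' @param weight_by_depth weight each site by its read depth (off by
#'   default: the standard pipeline smooths the raw percentages).
#' @return Numeric vector of smoothed percent-B, aligned with `points`.
#'   Chromosomes with a single point are returned unchanged with a warning.
#' @export
loess_smooth <- function(points, span = 0.5, degree = 2L,
                         weight_by_depth = FALSE) {
  .check_number(span, "span", lower = 1e-9, upper = 1)
  degree <- .check_count(degree, "degree", lower = 0L)
  out <- numeric(nrow(points))
  for (ch in unique(points$chrom)) {
    sel <- which(points$chrom == ch)
    x <- points$pos[sel]
    y <- points$pct_b[sel]
    if (length(sel) == 1L) {
      warning("loess_smooth: single point on ", ch, ", returned unsmoothed")
      out[sel] <- y
      next
    }
    w <- if (weight_by_depth) points$depth[sel] else rep(1, length(sel))
    fit <- tryCatch(
      stats::loess(y ~ x, span = span, degree = degree, weights = w,
                   family = "gaussian",
                   control = stats::loess.control(surface = "direct")),
      error = function(e) NULL)
    if (is.null(fit)) {
      warning("loess_smooth: fit failed on ", ch,
              " (too few points?), returned unsmoothed")
      out[sel] <- y
    } else {
      out[sel] <- pmin(pmax(stats::predict(fit, data.frame(x = x)), 0), 100)
    }
  }
  out
}

#' Build a painted dosage track
#'
#' Combines [loess_smooth()] and [classify_track()] into the per-accession
#' track object used for Circos export and reporting.
#'
#' @inheritParams loess_smooth
#' @param bounds two class boundaries in percent (default `c(33, 66)`).
#' @return A `dosage_track` data.frame: the columns of `points` plus
#'   `smoothed` and `class`.
#' @export
dosage_track <- function(points, span = 0.5, degree = 2L,
                         bounds = c(33, 66), weight_by_depth = FALSE) {
  out <- as.data.frame(points)
  out$smoothed <- loess_smooth(points, span = span, degree = degree,
                               weight_by_depth = weight_by_depth)
  out$class <- classify_track(out$smoothed, bounds)
  attr(out, "span") <- span
  attr(out, "degree") <- degree
  attr(out, "bounds") <- bounds
  class(out) <- c("dosage_track", "data.frame")
  out
}

#' Classify smoothed percent-B values into painting bands
#'
#' Bands follow the half-open convention of the green/grey/red painting:
#' `A_like` for values below `bounds[1]`, `mixed` for values in
#' `[bounds[1], bounds[2])`, `B_like` for values at or above `bounds[2]`.
#'
#' @param smoothed numeric vector of smoothed percent-B values, or a
#'   `dosage_track` (its `smoothed` column is used).
#' @param bounds two boundaries in percent, `0 < low < high < 100`.
#' @return Character vector of labels in `{A_like, mixed, B_like}`.
#' @export
classify_track <- function(smoothed, bounds = c(33, 66)) {
  if (is.data.frame(smoothed)) smoothed <- smoothed$smoothed
  if (length(bounds) != 2L || bounds[1] <= 0 || bounds[2] >= 100 ||
      bounds[1] >= bounds[2]) {
    .stop_invalid("bounds must satisfy 0 < low < high < 100")
  }
  ifelse(smoothed < bounds[1], "A_like",
         ifelse(smoothed < bounds[2], "mixed", "B_like"))
}

#' Write a dosage track in Circos 2D data format
#'
#' Writes one line `chrom start end value` per point (start = end = pos)
#' for the smoothed values, and optionally a highlight file with one line
#' per run of same-class points (`chrom start end fill_color=...`, green
#' for A_like, grey for mixed, red for B_like).
#'
#' @param track a `dosage_track`.
#' @param path output path for the data track.
#' @param highlight_path optional output path for the class highlights.
#' @export
write_circos_track <- function(track, path, highlight_path = NULL) {
  lines <- if (nrow(track)) {
    sprintf("%s %d %d %.4f", track$chrom, track$pos, track$pos, track$smoothed)
  } else character(0)
  writeLines(lines, path)
  if (!is.null(highlight_path)) {
    hl <- character(0)
    col <- c(A_like = "green", mixed = "grey", B_like = "red")
    for (ch in unique(track$chrom)) {
      t_ch <- track[track$chrom == ch, , drop = FALSE]
      r <- rle(t_ch$class)
      ends <- cumsum(r$lengths)
      starts <- c(1L, head(ends, -1L) + 1L)
      hl <- c(hl, sprintf("%s %d %d fill_color=%s", ch, t_ch$pos[starts],
                          t_ch$pos[ends], col[r$values]))
    }
    writeLines(hl, highlight_path)
  }
  invisible(path)
}

#' Write/read per-accession dosage points as TSV
#'
#' Columns: chrom, pos, depth, a_count, b_count, pct_b (plus smoothed and
#' class when given a full track).
#' @param points a `dosage_points` or `dosage_track` data.frame.
#' @param path file path.
#' @export
write_dosage_points <- function(points, path) {
  write.table(as.data.frame(points), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_dosage_points
#' @export
read_dosage_points <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  class(x) <- c("dosage_points", "data.frame")
  x
}

#' Read a Circos 2D data track back
#'
#' @param path a file written by [write_circos_track()].
#' @return data.frame: chrom, start, end, value.
#' @export
read_circos_track <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), value = numeric(0)))
  }
  f <- strsplit(lines, " ", fixed = TRUE)
  data.frame(
    chrom = vapply(f, `[`, "", 1L),
    start = as.integer(vapply(f, `[`, "", 2L)),
    end = as.integer(vapply(f, `[`, "", 3L)),
    value = as.numeric(vapply(f, `[`, "", 4L)),
    stringsAsFactors = FALSE
  )
}

#' @export
print.dosage_track <- function(x, ...) {
  cat("Dosage track:", nrow(x), "diagnostic sites on",
      length(unique(x$chrom)), "chromosome(s)\n")
  cat(sprintf("  median smoothed %%B: %.2f  (span %.2f, degree %d)\n",
              median(x$smoothed), attr(x, "span"), attr(x, "degree")))
  print(table(factor(x$class, levels = c("A_like", "mixed", "B_like"))))
  invisible(x)
}

#' Plot a dosage track
#'
#' One panel per chromosome: per-site percent-B points, the LOESS curve,
#' and the painting-band boundaries.
#'
#' @param x a `dosage_track`.
#' @param ... passed to [plot()].
#' @export
plot.dosage_track <- function(x, ...) {
  chroms <- unique(x$chrom)
  op <- graphics::par(mfrow = c(length(chroms), 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  bounds <- attr(x, "bounds")
  for (ch in chroms) {
    t_ch <- x[x$chrom == ch, , drop = FALSE]
    plot(t_ch$pos, t_ch$pct_b, pch = 16, cex = 0.3, col = "grey60",
         xlab = sprintf("%s position (bp)", ch), ylab = "% B allele",
         ylim = c(0, 100), main = ch, ...)
    graphics::lines(t_ch$pos, t_ch$smoothed, col = "firebrick", lwd = 2)
    graphics::abline(h = bounds, lty = 3)
  }
  invisible(x)
}
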