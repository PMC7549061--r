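## Independent oracles and small fixture builders. Everything here is
## deliberately brute-force and separate from the package's code paths.

## Brute-force filter oracle: apply every predicate per call, no sorting
## tricks. Mirrors the documented semantics only, not the implementation.
brute_filter <- function(calls, cfg) {
  keep <- logical(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    cl <- calls[i, ]
    if (cl$is_indel) next
    if (cl$qual < cfg$qual_min) next
    if (cl$dp < cfg$dp_min) next
    anchors <- calls$pos[calls$chrom == cl$chrom & calls$is_indel &
                           calls$idv >= cfg$idv_min]
    if (length(anchors) && min(abs(anchors - cl$pos)) <= cfg$snp_gap) next
    keep[i] <- TRUE
  }
  out <- calls[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

## Exhaustive binomial upper-tail: P(X >= k), X ~ Bin(n, p), by summation.
binom_tail_exact <- function(k, n, p) {
  sum(vapply(k:n, function(j) choose(n, j) * p^j * (1 - p)^(n - j), 0))
}

## Hand-rolled tricube local-linear smoother (loess-style q nearest
## neighbours), evaluated at each x.
tricube_local_linear <- function(x, y, span) {
  n <- length(x)
  q <- max(2L, floor(span * n))
  vapply(seq_len(n), function(i) {
    d <- abs(x - x[i])
    h <- sort(d)[q]
    w <- pmax(1 - (d / h)^3, 0)^3
    fit <- stats::lm.wfit(cbind(1, x - x[i]), y, w)
    fit$coefficients[1]
  }, numeric(1))
}

## Dense two-stage grid search for the fixed-mean mixture with shared sd:
## independent of the EM path. Returns the maximum log-likelihood found.
grid_search_fixed <- function(x, means, w_steps = 81, sd_range = c(0.005, 0.2)) {
  loglik <- function(w, sdv) {
    dens <- 0
    for (j in seq_along(means)) dens <- dens + w[j] * dnorm(x, means[j], sdv)
    sum(log(dens))
  }
  k <- length(means)
  stopifnot(k <= 2L)  # oracle used for the two-component triploid case
  best <- -Inf
  best_w <- NULL
  best_sd <- NULL
  for (w1 in seq(0.01, 0.99, length.out = w_steps)) {
    for (sdv in seq(sd_range[1], sd_range[2], length.out = 80)) {
      ll <- loglik(c(w1, 1 - w1), sdv)
      if (ll > best) {
        best <- ll
        best_w <- w1
        best_sd <- sdv
      }
    }
  }
  ## refine twice around the running optimum
  w_half <- 0.02
  sd_half <- (sd_range[2] - sd_range[1]) / 40
  for (stage in 1:2) {
    for (w1 in seq(max(0.001, best_w - w_half), min(0.999, best_w + w_half),
                   length.out = 81)) {
      for (sdv in seq(best_sd - sd_half, best_sd + sd_half, length.out = 81)) {
        ll <- loglik(c(w1, 1 - w1), sdv)
        if (ll > best) {
          best <- ll
          best_w <- w1
          best_sd <- sdv
        }
      }
    }
    w_half <- w_half / 20
    sd_half <- sd_half / 20
  }
  best
}

## Small pileup column builder for direct unit tests.
make_column <- function(chrom = "chr01", pos = 1L, ref = "A",
                        counts = c(A = 0L, C = 0L, G = 0L, T = 0L),
                        depth = sum(counts), indel_support = 0L) {
  structure(
    data.frame(chrom = chrom, pos = pos, ref = ref, depth = depth,
               A = counts[["A"]], C = counts[["C"]], G = counts[["G"]],
               T = counts[["T"]], indel_support = indel_support,
               stringsAsFactors = FALSE),
    class = c("pileup", "data.frame")
  )
}

## Random variant-call table spanning SNPs and indels near/far from each
## other, for the filter oracle comparison.
random_calls <- function(n, seed) {
  set.seed(seed)
  pos <- sort(sample.int(5000L, n))
  is_indel <- runif(n) < 0.2
  calls <- data.frame(
    chrom = sample(c("chr01", "chr02"), n, replace = TRUE),
    pos = pos,
    ref = sample(c("A", "C", "G", "T"), n, replace = TRUE),
    alt = sample(c("A", "C", "G", "T"), n, replace = TRUE),
    qual = round(runif(n, 0, 120), 1),
    dp = sample(1:60, n, replace = TRUE),
    idv = ifelse(is_indel, sample(1:6, n, replace = TRUE), 0L),
    is_indel = is_indel,
    gt = "0/1",
    stringsAsFactors = FALSE
  )
  calls <- calls[order(calls$chrom, calls$pos), ]
  rownames(calls) <- NULL
  class(calls) <- c("variant_calls", "data.frame")
  calls
}

## site_frequencies builder from a plain numeric vector.
freqs_from <- function(x, depth = 30L) {
  structure(
    data.frame(chrom = "sim", pos = seq_along(x), depth = depth,
               alt_fraction = x, stringsAsFactors = FALSE),
    class = c("site_frequencies", "data.frame")
  )
}
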