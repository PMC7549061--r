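## internal input-validation helpers; all raise classed conditions so tests
## can distinguish invalid parameters from malformed data

.stop_invalid <- function(...) {
  stop(errorCondition(paste0(...), class = c("musapaint_invalid_parameter", "error")))
}

.stop_malformed <- function(...) {
  stop(errorCondition(paste0(...), class = c("musapaint_malformed_input", "error")))
}

.check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    .stop_invalid(name, " must be a single number in [", lower, ", ", upper, "]")
  }
  invisible(x)
}

.check_count <- function(x, name, lower = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x != floor(x)) {
    .stop_invalid(name, " must be a single integer >= ", lower)
  }
  invisible(as.integer(x))
}

## strictly increasing positions within each chromosome
.check_sorted <- function(chrom, pos, what) {
  for (ch in unique(chrom)) {
    p <- pos[chrom == ch]
    if (length(p) > 1L && any(diff(p) <= 0)) {
      .stop_malformed(what, ": positions not strictly increasing on ", ch)
    }
  }
  invisible(TRUE)
}

.site_key <- function(chrom, pos) paste(chrom, pos, sep = ":")

## split n error reads uniformly over the three non-true bases, vectorised
.split_errors_3 <- function(n_err) {
  e1 <- rbinom(length(n_err), n_err, 1 / 3)
  e2 <- rbinom(length(n_err), n_err - e1, 1 / 2)
  cbind(e1, e2, n_err - e1 - e2)
}

## log-sum-exp over matrix rows
.row_logsumexp <- function(m) {
  mx <- do.call(pmax, c(as.data.frame(m), list(na.rm = FALSE)))
  mx + log(rowSums(exp(m - mx)))
}
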