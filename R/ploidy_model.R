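## Gaussian-mixture ploidy inference from heterozygous-site allele
## frequencies.
##
## At a heterozygous site in a sample of ploidy p, the non-reference
## allele is carried by k of the p chromosome copies, so its read
## fraction concentrates near k/p: near 1/2 for diploids, 1/3 or 2/3 for
## triploids, 1/4, 1/2 or 3/4 for tetraploids. Each candidate ploidy is
## scored by a Gaussian mixture with means FIXED at those fractions, free
## mixture weights and one shared standard deviation; a free model (three
## Gaussians with free means, free weights, shared sd) provides the
## reference fit. The fixed model with the smallest delta log-likelihood
## (logL_free - logL_fixed) indicates the most likely ploidy.
##
## Numerical notes: Gaussian densities are used unnormalised over (0,1)
## (truncation ignored), a good approximation for sd <= 0.15; the shared
## sd is floored at 1e-4; EM stops when the log-likelihood improves by
## less than 1e-8 nats (or after max_iter iterations).

PLOIDY_MEANS <- list(`2` = 1 / 2, `3` = c(1 / 3, 2 / 3),
                     `4` = c(1 / 4, 1 / 2, 3 / 4))
MODEL_NAMES <- c(`2` = "diploid", `3` = "triploid", `4` = "tetraploid")

#' Extract heterozygous-site allele frequencies from a pileup
#'
#' Keeps biallelic columns (two alleles each supported by at least
#' `min_minor_reads` reads) with depth at least `min_depth`. The fraction
#' is oriented against the reference: `alt_fraction` is the count of the
#' non-reference member of the top two alleles over the top-two total (if
#' the reference is not among the top two, the second-most-supported
#' allele is used).
#'
#' @param pileup a `pileup`, coordinate-sorted.
#' @param min_depth minimum column depth (default 10, mirroring the lower
#'   bound of the dosage depth window).
#' @param min_minor_reads minimum reads on each of the two alleles
#'   (default 2).
#' @param min_fraction minimum frequency of the minor of the two alleles
#'   (default 0.1): screens out apparent
#'   heterozygosity created by recurrent sequencing errors, whose
#'   fractions sit near `error_rate`, far below any real allelic ratio
#'   for ploidy 2-4.
#' @return A `site_frequencies` data.frame: chrom, pos, depth,
#'   alt_fraction (strictly inside (0, 1)).
#' @export
extract_site_frequencies <- function(pileup, min_depth = 10,
                                     min_minor_reads = 2L,
                                     min_fraction = 0.1) {
  .check_number(min_depth, "min_depth", lower = 0)
  min_minor_reads <- .check_count(min_minor_reads, "min_minor_reads")
  .check_number(min_fraction, "min_fraction", 0, 0.5)
  counts <- as.matrix(pileup[, DNA_BASES])
  n <- nrow(counts)
  i1 <- max.col(counts, ties.method = "first")
  c1 <- counts[cbind(seq_len(n), i1)]
  tmp <- counts
  tmp[cbind(seq_len(n), i1)] <- -1L
  i2 <- max.col(tmp, ties.method = "first")
  c2 <- counts[cbind(seq_len(n), i2)]

  ref_i <- match(pileup$ref, DNA_BASES)
  ## reference-oriented: alt is the top-two member that is not the reference
  alt_count <- ifelse(ref_i == i1, c2, ifelse(ref_i == i2, c1, c2))
  frac <- alt_count / (c1 + c2)
  keep <- pileup$depth >= min_depth & c2 >= min_minor_reads &
    c2 / (c1 + c2) >= min_fraction

  out <- data.frame(chrom = pileup$chrom[keep], pos = pileup$pos[keep],
                    depth = pileup$depth[keep], alt_fraction = frac[keep],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("site_frequencies", "data.frame")
  out
}

#' Simulate heterozygous-site allele frequencies for a known ploidy
#'
#' Frequency-level simulator for calibrating the ploidy model: each site
#' draws its allelic copy number k uniformly from 1..(ploidy-1), a Poisson
#' depth, and a binomial read count at the error-adjusted allele fraction
#' k/ploidy. This emulates natural heterozygosity (all k values occur),
#' which composed A/B accessions do not show: an AAB accession is
#' heterozygous only at B dosage 1/3.
#'
#' @param ploidy 2, 3 or 4.
#' @param n_sites number of heterozygous sites.
#' @param mean_depth mean Poisson depth.
#' @param error_rate per-base miscall rate.
#' @param seed integer seed.
#' @param min_depth drop sites shallower than this (default 10).
#' @param min_fraction minimum minor-allele frequency, as in
#'   [extract_site_frequencies()].
#' @return A `site_frequencies` data.frame.
#' @export
simulate_allele_frequencies <- function(ploidy, n_sites = 5000L,
                                        mean_depth = 30, error_rate = 0.005,
                                        seed = 1L, min_depth = 10,
                                        min_fraction = 0.1) {
  if (!ploidy %in% 2:4) .stop_invalid("ploidy must be 2, 3 or 4")
  n_sites <- .check_count(n_sites, "n_sites")
  set.seed(seed)
  k <- sample.int(ploidy - 1L, n_sites, replace = TRUE)
  p_true <- k / ploidy
  q <- p_true * (1 - error_rate) + (1 - p_true) * error_rate / 3
  d <- rpois(n_sites, mean_depth)
  alt <- rbinom(n_sites, d, q)
  keep <- d >= min_depth & alt > 0L & alt < d &
    pmin(alt, d - alt) / d >= min_fraction
  out <- data.frame(chrom = "sim", pos = seq_len(n_sites)[keep],
                    depth = d[keep], alt_fraction = (alt / d)[keep],
                    stringsAsFactors = FALSE)
  class(out) <- c("site_frequencies", "data.frame")
  out
}

## Core EM for a Gaussian mixture with optional fixed means and an
## optional uniform(0,1) noise component (used by denoise()). Returns the
## fit with the per-iteration log-likelihood trace.
.gmm_em <- function(x, means, weights = NULL, sd0 = NULL,
                    fix_means = TRUE, uniform_weight = 0,
                    tol = 1e-8, max_iter = 500L, sd_floor = 1e-4) {
  n <- length(x)
  k <- length(means)
  if (is.null(weights)) weights <- rep((1 - uniform_weight) / k, k)
  if (is.null(sd0)) sd0 <- max(min(stats::sd(x), 0.15), 0.01)
  sdv <- sd0
  w_u <- uniform_weight
  has_u <- uniform_weight > 0
  trace <- numeric(0)
  ll_prev <- -Inf
  converged <- FALSE
  floored <- FALSE

  for (it in seq_len(max_iter)) {
    logd <- vapply(seq_len(k),
                   function(j) dnorm(x, means[j], sdv, log = TRUE) +
                     log(weights[j]),
                   numeric(n))
    if (has_u) logd <- cbind(logd, rep(log(w_u), n))  # uniform(0,1): density 1
    ll_row <- .row_logsumexp(logd)
    ll <- sum(ll_row)
    trace <- c(trace, ll)
    resp <- exp(logd - ll_row)  # posteriors under the current parameters
    if (is.finite(ll) && ll - ll_prev < tol && it > 1L) {
      converged <- TRUE
      break
    }
    ll_prev <- ll

    nk <- colSums(resp)
    if (has_u) {
      w_u <- nk[k + 1L] / n
      weights <- nk[seq_len(k)] / n
    } else {
      weights <- nk[seq_len(k)] / n
    }
    weights <- pmax(weights, 1e-12)
    if (has_u) w_u <- max(w_u, 1e-12)
    if (!fix_means) {
      means <- colSums(resp[, seq_len(k), drop = FALSE] * x) /
        pmax(nk[seq_len(k)], 1e-12)
    }
    var_hat <- sum(resp[, seq_len(k), drop = FALSE] *
                     (outer(x, means, "-"))^2) / sum(nk[seq_len(k)])
    sdv <- sqrt(var_hat)
    if (sdv < sd_floor) {
      sdv <- sd_floor
      floored <- TRUE
    }
  }
  if (floored) warning("EM: shared sd floored at ", sd_floor)

  list(log_likelihood = trace[length(trace)], means = means,
       weights = weights / sum(weights, w_u), uniform_weight = w_u,
       sd = sdv, responsibilities = if (has_u) resp else NULL,
       trace = trace, converged = converged, n_iter = length(trace))
}

.new_ploidy_fit <- function(model, ploidy, em, n_sites) {
  structure(
    list(model = model, ploidy = ploidy,
         log_likelihood = em$log_likelihood, delta_loglik = NA_real_,
         params = list(means = em$means, weights = em$weights, sd = em$sd),
         trace = em$trace, converged = em$converged, n_sites = n_sites),
    class = "ploidy_fit"
  )
}

#' Fit the fixed-mean Gaussian mixture for one candidate ploidy
#'
#' Mixture means are fixed at the heterozygous allele fractions implied by
#' the ploidy (1/2; 1/3, 2/3; 1/4, 1/2, 3/4); the mixture weights and one
#' shared standard deviation are optimised by EM.
#'
#' @param freqs a `site_frequencies` data.frame (>= 50 sites).
#' @param ploidy 2, 3 or 4.
#' @param tol EM convergence tolerance in nats (default 1e-8).
#' @param max_iter maximum EM iterations.
#' @return A `ploidy_fit` object.
#' @export
fit_fixed_model <- function(freqs, ploidy, tol = 1e-8, max_iter = 500L) {
  if (!ploidy %in% 2:4) .stop_invalid("ploidy must be 2, 3 or 4")
  x <- freqs$alt_fraction
  if (length(x) < 50L) {
    .stop_invalid("at least 50 sites required, got ", length(x))
  }
  em <- .gmm_em(x, means = PLOIDY_MEANS[[as.character(ploidy)]],
                fix_means = TRUE, tol = tol, max_iter = max_iter)
  .new_ploidy_fit(MODEL_NAMES[[as.character(ploidy)]], as.integer(ploidy),
                  em, length(x))
}

#' Fit the free three-component Gaussian mixture
#'
#' Reference model for the delta-log-likelihood comparison: three
#' Gaussians with free means, free weights and a shared standard
#' deviation. EM is restarted from several deterministic initialisations
#' -- quantile-based means, a jittered variant, and one start per fixed
#' ploidy model constructed to reproduce that model's converged density
#' exactly (duplicated means split one component's weight without changing
#' the density), which guarantees the free fit is never worse than any
#' fixed fit beyond EM's own tolerance.
#'
#' @param freqs a `site_frequencies` data.frame (>= 50 sites).
#' @param seed seed for the jittered restart (default 1, so fits are
#'   reproducible).
#' @param tol,max_iter EM controls, as in [fit_fixed_model()].
#' @param fixed_fits optional list of pre-computed fixed-model
#'   `ploidy_fit`s to seed restarts from (avoids refitting inside
#'   [infer_ploidy()]).
#' @return A `ploidy_fit` with `model = "free"`.
#' @export
fit_free_model <- function(freqs, seed = 1L, tol = 1e-8, max_iter = 500L,
                           fixed_fits = NULL) {
  x <- freqs$alt_fraction
  if (length(x) < 50L) {
    .stop_invalid("at least 50 sites required, got ", length(x))
  }
  if (is.null(fixed_fits)) {
    fixed_fits <- lapply(2:4, function(p) fit_fixed_model(freqs, p,
                                                          tol = tol,
                                                          max_iter = max_iter))
  }
  set.seed(seed)
  starts <- list(
    list(means = as.numeric(quantile(x, c(0.2, 0.5, 0.8))),
         weights = rep(1 / 3, 3), sd0 = NULL),
    list(means = sort(as.numeric(quantile(x, runif(3)))),
         weights = rep(1 / 3, 3), sd0 = NULL)
  )
  for (ff in fixed_fits) {
    m <- ff$params$means
    w <- ff$params$weights
    ## pad to three components by duplicating the last mean: identical
    ## means carry identical density no matter how the weight is split
    while (length(m) < 3L) {
      m <- c(m, m[length(m)])
      w <- c(w[-length(w)], w[length(w)] / 2, w[length(w)] / 2)
    }
    starts <- c(starts, list(list(means = m, weights = w, sd0 = ff$params$sd)))
  }

  best <- NULL
  for (s in starts) {
    em <- .gmm_em(x, means = s$means, weights = s$weights, sd0 = s$sd0,
                  fix_means = FALSE, tol = tol, max_iter = max_iter)
    if (is.null(best) || em$log_likelihood > best$log_likelihood) best <- em
  }
  fit <- .new_ploidy_fit("free", NA_integer_, best, length(x))
  fit$delta_loglik <- 0
  fit
}

#' De-noise heterozygous-site frequencies
#'
#' Mis-mapping in repetitive regions scatters allele fractions across
#' (0, 1). A free three-Gaussian + uniform(0, 1) mixture is fitted by EM
#' and sites whose posterior mass on the uniform component exceeds
#' `max_noise_posterior` are dropped.
#'
#' @param freqs a `site_frequencies` data.frame (>= 50 sites).
#' @param max_noise_posterior drop threshold on the uniform-component
#'   posterior (default 0.5).
#' @param tol,max_iter EM controls. The default tolerance is looser than
#'   the model fits' (1e-5 vs 1e-8): free-mean components covering one
#'   cluster drift for hundreds of iterations at likelihood changes that
#'   leave the uniform-component posteriors, the only thing de-noising
#'   consumes, unchanged to far beyond the 0.5 cut.
#' @return The retained subset of `freqs`; attributes `n_dropped` and
#'   `noise_weight` record what was removed. If EM does not converge
#'   within `max_iter`, a warning is raised and the input is returned
#'   unchanged.
#' @export
denoise <- function(freqs, max_noise_posterior = 0.5, tol = 1e-5,
                    max_iter = 2000L) {
  .check_number(max_noise_posterior, "max_noise_posterior", 0, 1)
  x <- freqs$alt_fraction
  if (length(x) < 50L) {
    .stop_invalid("at least 50 sites required for de-noising, got ", length(x))
  }
  em <- .gmm_em(x, means = as.numeric(quantile(x, c(0.25, 0.5, 0.75))),
                fix_means = FALSE, uniform_weight = 0.1,
                tol = tol, max_iter = max_iter)
  if (!em$converged) {
    warning("denoise: EM did not converge in ", max_iter,
            " iterations; input returned unchanged")
    return(freqs)
  }
  post_u <- em$responsibilities[, 4L]
  keep <- post_u <= max_noise_posterior
  out <- freqs[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(!keep)
  attr(out, "noise_weight") <- em$uniform_weight
  class(out) <- c("site_frequencies", "data.frame")
  out
}

#' Infer ploidy by delta log-likelihood
#'
#' Fits the free model and the three fixed-mean models and selects the
#' ploidy whose fixed model has the smallest delta log-likelihood
#' (logL_free - logL_fixed). Delta differences smaller than `tie_nats`
#' are treated as ties and broken toward the lower ploidy with a
#' warning: the tetraploid mean set contains the diploid's, so on truly
#' diploid data the tetraploid fit can never be worse and typically edges
#' ahead by a fraction of a nat of pure overfitting; the default margin
#' of 2 nats is the difference in free-parameter count between the most
#' and least complex fixed models (the AIC yardstick), far below the
#' hundreds of nats separating genuinely different ploidies at realistic
#' site counts. With fewer than `min_sites` sites the result is an
#' explicit "undetermined" call, never a silent default.
#'
#' @param freqs a `site_frequencies` data.frame (post de-noising).
#' @param min_sites minimum usable sites (default 50).
#' @param seed seed passed to [fit_free_model()].
#' @param tie_nats delta differences below this count as ties (default 2).
#' @param tol,max_iter EM controls.
#' @return A `ploidy_call`: list with `observed_ploidy` (2, 3, 4 or NA),
#'   `status` ("ok" or "undetermined"), `fits` (named `ploidy_fit` list
#'   including "free") and `delta` (named delta log-likelihoods).
#' @export
infer_ploidy <- function(freqs, min_sites = 50L, seed = 1L, tie_nats = 2,
                         tol = 1e-8, max_iter = 500L) {
  n <- nrow(freqs)
  if (n < min_sites) {
    return(structure(
      list(observed_ploidy = NA_integer_, status = "undetermined",
           n_sites = n, fits = NULL, delta = NULL),
      class = "ploidy_call"
    ))
  }
  fixed <- lapply(2:4, function(p) fit_fixed_model(freqs, p, tol = tol,
                                                   max_iter = max_iter))
  names(fixed) <- MODEL_NAMES
  free <- fit_free_model(freqs, seed = seed, tol = tol, max_iter = max_iter,
                         fixed_fits = fixed)
  delta <- vapply(fixed, function(f) free$log_likelihood - f$log_likelihood,
                  numeric(1))
  for (nm in names(fixed)) fixed[[nm]]$delta_loglik <- delta[[nm]]
  best_raw <- which.min(delta)  # first minimum = lowest ploidy on exact ties
  best <- min(which(delta <= delta[best_raw] + tie_nats))
  if (best != best_raw || sum(delta == delta[best_raw]) > 1L) {
    warning("infer_ploidy: delta log-likelihoods tie within ", tie_nats,
            " nats; choosing lower ploidy")
  }
  structure(
    list(observed_ploidy = c(2L, 3L, 4L)[best], status = "ok", n_sites = n,
         fits = c(fixed, list(free = free)), delta = delta),
    class = "ploidy_call"
  )
}

#' @export
print.ploidy_fit <- function(x, ...) {
  cat(sprintf("%s mixture fit: logL = %.3f on %d sites (%s, %d EM iterations)\n",
              x$model, x$log_likelihood, x$n_sites,
              if (x$converged) "converged" else "not converged",
              length(x$trace)))
  cat("  means:", sprintf("%.4f", x$params$means), "\n")
  cat("  weights:", sprintf("%.4f", x$params$weights), "\n")
  cat(sprintf("  shared sd: %.4f\n", x$params$sd))
  invisible(x)
}

#' @export
logLik.ploidy_fit <- function(object, ...) {
  val <- object$log_likelihood
  ## free parameters: weights (k-1) + shared sd + free means if any
  k <- length(object$params$means)
  df <- (k - 1L) + 1L + if (object$model == "free") k else 0L
  structure(val, df = df, nobs = object$n_sites, class = "logLik")
}

#' @export
print.ploidy_call <- function(x, ...) {
  if (x$status == "undetermined") {
    cat("Ploidy: undetermined (", x$n_sites, " usable sites)\n", sep = "")
    return(invisible(x))
  }
  cat("Ploidy inference on", x$n_sites, "heterozygous sites\n")
  tab <- data.frame(
    model = names(x$delta),
    logL = vapply(x$fits[names(x$delta)], `[[`, 0, "log_likelihood"),
    delta_logL = as.numeric(x$delta)
  )
  tab$logL <- sprintf("%.3f", tab$logL)
  tab$delta_logL <- sprintf("%.3f", tab$delta_logL)
  print(tab, row.names = FALSE)
  cat("Lowest delta log-likelihood: ploidy", x$observed_ploidy, "\n")
  invisible(x)
}

#' @export
summary.ploidy_call <- function(object, ...) {
  object
}

#' Write the per-model fit table (lrdmodel-style)
#'
#' @param call a `ploidy_call`.
#' @param path output TSV path.
#' @export
write_ploidy_table <- function(call, path) {
  if (call$status == "undetermined") {
    tab <- data.frame(model = "undetermined", logL = NA_real_,
                      delta_logL = NA_real_)
  } else {
    tab <- data.frame(
      model = c(names(call$delta), "free"),
      logL = c(vapply(call$fits[names(call$delta)], `[[`, 0, "log_likelihood"),
               call$fits$free$log_likelihood),
      delta_logL = c(as.numeric(call$delta), 0)
    )
  }
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
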