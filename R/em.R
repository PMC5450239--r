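# Maximum-likelihood haplotype frequency estimation by EM under
# Hardy-Weinberg equilibrium.
#
# The observed data of record i is its set of candidate diplotypes
# {(h1, h2)} with expansion weights w_d (fractions summing to 1 over the
# record's resolved genotypes). The likelihood contribution of record i is
#   L_i(f) = sum_d w_d * P(d | f),  P(d | f) = (2 - delta_{h1 h2}) f_h1 f_h2,
# and records enter with integer multiplicity `count`.

# Index the diplotype table once for fast iteration.
em_index <- function(diplotypes) {
  if (nrow(diplotypes) == 0) {
    abort("no haplotypes after preprocessing", class = "hlafreq_input_error")
  }
  haps <- sort(unique(c(diplotypes$h1, diplotypes$h2)), method = "radix")
  i1 <- match(diplotypes$h1, haps)
  i2 <- match(diplotypes$h2, haps)
  rec_f <- factor(diplotypes$id, levels = unique(diplotypes$id))
  rec <- as.integer(rec_f)
  n_rec <- nlevels(rec_f)
  count <- numeric(n_rec)
  count[rec] <- diplotypes$count
  mult <- ifelse(i1 == i2, 1, 2)
  # haplotype occurrence weights (chromosome counting over candidates)
  occ_raw <- diplotypes$weight * count[rec]
  occ <- numeric(length(haps))
  acc <- rowsum(c(occ_raw, occ_raw), c(i1, i2))
  occ[as.integer(rownames(acc))] <- acc[, 1]
  list(
    haplotypes = haps, i1 = i1, i2 = i2, mult = mult,
    w = diplotypes$weight, rec = rec, n_rec = n_rec,
    count = count, W = sum(count), occurrence = occ / sum(occ)
  )
}

#' Initialize haplotype frequencies
#'
#' Three initialization routines are supported: `"uniform"` sets every
#' candidate haplotype to 1/N_H; `"count"` sets frequencies proportional to
#' the haplotypes' occurrence numbers among the candidate diplotypes;
#' `"perturbed"` multiplies each count-based frequency by
#' `1 + perturbation_scale * u`, u ~ Uniform(-1, 1), and renormalizes;
#' `"random"` draws frequencies uniformly at random and normalizes. Random
#' draws use R's Mersenne-Twister generator under the given seed.
#'
#' @param haplotypes Character vector of candidate haplotypes.
#' @param occurrence Occurrence weights (same length), required for
#'   `"count"` and `"perturbed"`.
#' @param init One of `"count"`, `"uniform"`, `"perturbed"`, `"random"`.
#' @param perturbation_scale Relative perturbation amplitude.
#' @param seed Integer seed for the random modes.
#' @return A tibble with columns `haplotype`, `frequency` (summing to 1).
#' @export
initialize_frequencies <- function(haplotypes, occurrence = NULL,
                                   init = c("count", "uniform", "perturbed",
                                     "random"),
                                   perturbation_scale = 0.1, seed = 1L) {
  init <- match.arg(init)
  n <- length(haplotypes)
  if (n == 0) {
    abort("no haplotypes after preprocessing", class = "hlafreq_input_error")
  }
  if (init %in% c("count", "perturbed") && is.null(occurrence)) {
    abort("occurrence weights required for count-based initialization",
      class = "hlafreq_config_error")
  }
  f <- switch(init,
    uniform = rep(1 / n, n),
    count = occurrence / sum(occurrence),
    perturbed = withr::with_seed(seed, {
      base <- occurrence / sum(occurrence)
      p <- base * (1 + perturbation_scale * stats::runif(n, -1, 1))
      p / sum(p)
    }),
    random = withr::with_seed(seed, {
      p <- stats::runif(n)
      p / sum(p)
    })
  )
  tibble(haplotype = haplotypes, frequency = f)
}

# One E-step: expected diplotype mass given frequencies. Returns the mass
# vector (aligned with the diplotype rows), the per-record totals, and the
# number of records with zero total prior mass (skipped).
em_estep <- function(f, ix) {
  pri <- f[ix$i1] * f[ix$i2] * ix$mult
  m <- ix$w * pri
  tot <- numeric(ix$n_rec)
  acc <- rowsum(m, ix$rec)
  tot[as.integer(rownames(acc))] <- acc[, 1]
  denom <- tot[ix$rec]
  mass <- ifelse(denom > 0, m * ix$count[ix$rec] / denom, 0)
  list(mass = mass, tot = tot, n_zero = sum(tot == 0 & ix$count > 0))
}

# One M-step: chromosome-count the expected masses back into frequencies.
em_mstep <- function(mass, ix) {
  f <- numeric(length(ix$haplotypes))
  acc <- rowsum(c(mass, mass), c(ix$i1, ix$i2))
  f[as.integer(rownames(acc))] <- acc[, 1]
  f / sum(f)
}

#' Expectation step on a diplotype table
#'
#' Computes each candidate diplotype's expected mass under Hardy-Weinberg
#' priors: mass(d) is proportional to `w_d * (2 - delta) * f_h1 * f_h2`,
#' normalized within each record to that record's total weight
#' (its multiplicity). Records whose every diplotype has zero prior mass
#' contribute nothing and are counted.
#'
#' @param freqs Tibble with `haplotype`, `frequency`.
#' @param diplotypes Diplotype tibble from [build_diplotypes()].
#' @return The diplotype tibble with an added `mass` column; attribute
#'   `n_zero` counts skipped records.
#' @export
expectation_step <- function(freqs, diplotypes) {
  ix <- em_index(diplotypes)
  f <- numeric(length(ix$haplotypes))
  f[match(freqs$haplotype, ix$haplotypes)] <- freqs$frequency
  es <- em_estep(f, ix)
  out <- diplotypes
  out$mass <- es$mass
  structure(out, n_zero = es$n_zero)
}

#' Maximization step from expected diplotype masses
#'
#' Re-estimates each haplotype's frequency as its expected chromosome count
#' over twice the total individual weight; the result sums to 1.
#'
#' @param masses Output of [expectation_step()] (columns `h1`, `h2`, `mass`).
#' @return A tibble with columns `haplotype`, `frequency`.
#' @export
maximization_step <- function(masses) {
  haps <- sort(unique(c(masses$h1, masses$h2)), method = "radix")
  i1 <- match(masses$h1, haps)
  i2 <- match(masses$h2, haps)
  f <- numeric(length(haps))
  acc <- rowsum(c(masses$mass, masses$mass), c(i1, i2))
  f[as.integer(rownames(acc))] <- acc[, 1]
  tibble(haplotype = haps, frequency = f / sum(f))
}

# Run one EM pass from a given start vector. Returns frequencies, trace,
# iteration count, convergence flag and final max change.
em_single_run <- function(f0, ix, epsilon, max_iterations) {
  f <- f0
  trace <- numeric(0)
  delta <- Inf
  it <- 0L
  n_zero <- 0L
  repeat {
    es <- em_estep(f, ix)
    ll <- sum(ix$count[es$tot > 0] * log(es$tot[es$tot > 0]))
    trace <- c(trace, ll)
    f_new <- em_mstep(es$mass, ix)
    delta <- max(abs(f_new - f))
    n_zero <- es$n_zero
    f <- f_new
    it <- it + 1L
    if (delta < epsilon || it >= max_iterations) break
  }
  # likelihood at the final frequencies
  es <- em_estep(f, ix)
  ll <- sum(ix$count[es$tot > 0] * log(es$tot[es$tot > 0]))
  trace <- c(trace, ll)
  list(
    f = f, trace = trace, iterations = it, final_change = delta,
    converged = delta < epsilon, logLik = ll, n_zero = n_zero
  )
}

#' Estimate haplotype frequencies by EM
#'
#' Iterates expectation and maximization steps until the maximal change in
#' haplotype frequency between consecutive estimates falls below `epsilon`
#' (L-infinity criterion on the full, pre-cutoff table) or `max_iterations`
#' is reached. Multiple restarts from different random starts are supported;
#' the run with the best observed-data log-likelihood is kept. After
#' convergence, frequencies below `cutoff` are removed and, if requested,
#' the remainder renormalized.
#'
#' @param diplotypes Diplotype tibble from [build_diplotypes()].
#' @param epsilon Stop criterion on the maximal frequency change.
#' @param cutoff Minimum reported frequency.
#' @param init Initialization routine (see [initialize_frequencies()]).
#' @param perturbation_scale Perturbation amplitude for `init = "perturbed"`.
#' @param seed Integer seed for random initializations.
#' @param normalize Renormalize frequencies after the cutoff.
#' @param max_iterations Safety bound on EM iterations.
#' @param restarts Number of EM runs; restarts beyond the first use random
#'   initialization with seeds `seed + 1, seed + 2, ...`.
#' @return An object of class `hla_em_fit`.
#' @export
run_em <- function(diplotypes, epsilon = 1e-6, cutoff = 1e-6,
                   init = c("count", "uniform", "perturbed", "random"),
                   perturbation_scale = 0.1, seed = 1L, normalize = TRUE,
                   max_iterations = 10000L, restarts = 1L) {
  init <- match.arg(init)
  stopifnot(epsilon > 0, cutoff >= 0, cutoff < 1, restarts >= 1)
  ix <- em_index(diplotypes)

  best <- NULL
  restart_ll <- numeric(restarts)
  for (r in seq_len(restarts)) {
    f0 <- if (r == 1) {
      initialize_frequencies(ix$haplotypes, ix$occurrence, init,
        perturbation_scale, seed)$frequency
    } else {
      initialize_frequencies(ix$haplotypes, ix$occurrence, "random",
        seed = seed + r - 1L)$frequency
    }
    run <- em_single_run(f0, ix, epsilon, max_iterations)
    restart_ll[r] <- run$logLik
    if (is.null(best) || run$logLik > best$logLik) best <- run
  }
  if (!best$converged) {
    warn(
      sprintf("EM did not converge in %d iterations (last change %.3g)",
        max_iterations, best$final_change),
      class = "hlafreq_convergence_warning"
    )
  }

  raw <- tibble(haplotype = ix$haplotypes, frequency = best$f)
  final <- finalize_frequencies(raw, cutoff = cutoff, normalize = normalize)

  structure(
    list(
      frequencies = final,
      raw_frequencies = raw,
      logLik = best$logLik,
      trace = best$trace,
      iterations = best$iterations,
      converged = best$converged,
      final_change = best$final_change,
      epsilon = epsilon,
      cutoff = cutoff,
      normalize = normalize,
      init = init,
      seed = seed,
      restarts = restarts,
      restart_logLik = restart_ll,
      n_haplotypes_initial = length(ix$haplotypes),
      n_records = ix$n_rec,
      total_weight = ix$W,
      n_zero_support = best$n_zero
    ),
    class = "hla_em_fit"
  )
}

#' Remove sub-threshold frequencies and optionally renormalize
#'
#' @param freqs Tibble with `haplotype`, `frequency`.
#' @param cutoff Entries strictly below this frequency are dropped.
#' @param normalize Renormalize the remaining frequencies to sum to 1.
#' @return A tibble sorted by descending frequency, ties broken
#'   lexicographically.
#' @export
finalize_frequencies <- function(freqs, cutoff = 0, normalize = TRUE) {
  out <- freqs[freqs$frequency >= cutoff & freqs$frequency > 0, , drop = FALSE]
  if (nrow(out) == 0) {
    abort("all haplotype frequencies fall below the cutoff",
      class = "hlafreq_config_error")
  }
  if (normalize) out$frequency <- out$frequency / sum(out$frequency)
  out[order(-out$frequency, out$haplotype, method = "radix"), , drop = FALSE]
}

#' @export
print.hla_em_fit <- function(x, ...) {
  cat("<hla_em_fit>\n")
  cat(sprintf("  records: %d (total weight %.0f)\n", x$n_records,
    x$total_weight))
  cat(sprintf("  haplotypes: %d candidates, %d reported (cutoff %g)\n",
    x$n_haplotypes_initial, nrow(x$frequencies), x$cutoff))
  cat(sprintf("  EM: %d iterations, final max change %.3g (epsilon %g)%s\n",
    x$iterations, x$final_change, x$epsilon,
    if (x$converged) "" else " [NOT CONVERGED]"))
  cat(sprintf("  log-likelihood: %.6f\n", x$logLik))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted haplotype frequency table
#'
#' @param x An `hla_em_fit`.
#' @param ... Unused.
#' @return A tibble with columns `haplotype`, `frequency`, `rank`.
#' @method tidy hla_em_fit
#' @export
tidy.hla_em_fit <- function(x, ...) {
  out <- x$frequencies
  out$rank <- seq_len(nrow(out))
  out
}

#' One-row summary of an EM fit
#'
#' @param x An `hla_em_fit`.
#' @param ... Unused.
#' @return A one-row tibble with fit diagnostics.
#' @method glance hla_em_fit
#' @export
glance.hla_em_fit <- function(x, ...) {
  tibble(
    n_records = x$n_records,
    total_weight = x$total_weight,
    n_haplotypes_initial = x$n_haplotypes_initial,
    n_haplotypes = nrow(x$frequencies),
    iterations = x$iterations,
    converged = x$converged,
    final_change = x$final_change,
    logLik = x$logLik,
    n_zero_support = x$n_zero_support
  )
}

#' @importFrom stats logLik
#' @export
logLik.hla_em_fit <- function(object, ...) {
  structure(object$logLik, class = "logLik",
    df = object$n_haplotypes_initial - 1L)
}
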