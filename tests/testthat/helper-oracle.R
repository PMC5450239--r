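# Independent oracle for the EM: direct evaluation of the observed-data
# log-likelihood from a diplotype table, and its maximization by
# multi-start Nelder-Mead simplex search in softmax coordinates. Shares no
# code with the package's E/M steps.

oracle_prep <- function(dips) {
  haps <- sort(unique(c(dips$h1, dips$h2)), method = "radix")
  list(
    haplotypes = haps, k = length(haps),
    i1 = match(dips$h1, haps), i2 = match(dips$h2, haps),
    hom = dips$h1 == dips$h2, w = dips$weight,
    rec = match(dips$id, unique(dips$id)),
    cnt = dips$count[!duplicated(dips$id)]
  )
}

oracle_loglik <- function(prep, f) {
  term <- prep$w * ifelse(prep$hom, f[prep$i1]^2, 2 * f[prep$i1] * f[prep$i2])
  li <- tapply(term, prep$rec, sum)
  sum(prep$cnt * log(as.numeric(li)))
}

oracle_max_loglik <- function(prep, n_starts = 8, seed = 1) {
  obj <- function(theta) {
    f <- exp(theta - max(theta))
    f <- f / sum(f)
    -oracle_loglik(prep, f)
  }
  best <- Inf
  withr::with_seed(seed, {
    for (s in seq_len(n_starts)) {
      th0 <- if (s == 1) rep(0, prep$k) else stats::rnorm(prep$k, 0, 2)
      o <- stats::optim(th0, obj, method = "Nelder-Mead",
        control = list(maxit = 3000, reltol = 1e-13))
      if (o$value < best) best <- o$value
    }
  })
  -best
}

# Brute-force diplotype enumeration: all 2^L orderings of a genotype's
# allele pairs, deduplicated as unordered haplotype pairs.
brute_force_diplotypes <- function(pairs) {
  L <- length(pairs)
  picks <- expand.grid(rep(list(1:2), L))
  seen <- character(0)
  for (r in seq_len(nrow(picks))) {
    h1 <- vapply(seq_len(L), function(l) pairs[[l]][picks[r, l]], character(1))
    h2 <- vapply(seq_len(L), function(l) pairs[[l]][3 - picks[r, l]],
      character(1))
    k1 <- paste(h1, collapse = "~")
    k2 <- paste(h2, collapse = "~")
    key <- paste(min(k1, k2), max(k1, k2), sep = "|")
    seen <- union(seen, key)
  }
  seen
}
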