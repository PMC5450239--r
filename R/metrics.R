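# Comparison observables between two haplotype frequency sets, and the
# Hardy-Weinberg effect-size statistic of a population sample.

as_freq_tbl <- function(x, what) {
  if (inherits(x, "hla_em_fit")) x <- x$frequencies
  if (is.numeric(x) && !is.null(names(x))) {
    x <- tibble(haplotype = names(x), frequency = unname(x))
  }
  if (!is.data.frame(x) || !all(c("haplotype", "frequency") %in% names(x))) {
    abort(sprintf("%s must have columns 'haplotype' and 'frequency'", what),
      class = "hlafreq_config_error")
  }
  if (anyDuplicated(x$haplotype)) {
    abort(sprintf("duplicate haplotypes in %s", what),
      class = "hlafreq_config_error")
  }
  tibble(haplotype = x$haplotype, frequency = x$frequency)
}

#' Compare two haplotype frequency sets
#'
#' Computes the distance `d` (the L1 distance over the union support, with
#' absent haplotypes at frequency 0), the maximal absolute frequency
#' difference `delta`, the first reference rank (1-based, by descending
#' reference frequency) whose relative deviation `|est - ref| / ref`
#' exceeds `rel_threshold` (`rho`, `NA` when no rank exceeds it), and the
#' counts of additional haplotypes (present only in the estimate) and
#' missing haplotypes (present only in the reference). With
#' `intersection_only = TRUE` all statistics are computed on the shared
#' support only, excluding additional and missing haplotypes.
#'
#' @param estimate,reference Frequency tibbles (`haplotype`, `frequency`),
#'   named numeric vectors, or `hla_em_fit` objects.
#' @param rel_threshold Relative deviation threshold for `rho`.
#' @param intersection_only Restrict to the shared support.
#' @return A one-row tibble: `d`, `delta`, `rho`, `n_additional`,
#'   `n_missing`, `n_estimate`, `n_reference`.
#' @export
compare_frequency_sets <- function(estimate, reference, rel_threshold = 0.05,
                                   intersection_only = FALSE) {
  est <- as_freq_tbl(estimate, "estimate")
  ref <- as_freq_tbl(reference, "reference")
  if (nrow(ref) == 0) {
    abort("empty reference frequency set", class = "hlafreq_config_error")
  }
  n_additional <- length(setdiff(est$haplotype, ref$haplotype))
  n_missing <- length(setdiff(ref$haplotype, est$haplotype))

  if (intersection_only) {
    shared <- intersect(est$haplotype, ref$haplotype)
    if (length(shared) == 0) {
      abort("estimate and reference share no haplotypes",
        class = "hlafreq_config_error")
    }
    est <- est[est$haplotype %in% shared, , drop = FALSE]
    ref <- ref[ref$haplotype %in% shared, , drop = FALSE]
  }

  union_h <- union(ref$haplotype, est$haplotype)
  fe <- stats::setNames(rep(0, length(union_h)), union_h)
  fr <- fe
  fe[est$haplotype] <- est$frequency
  fr[ref$haplotype] <- ref$frequency
  diffs <- abs(fe - fr)
  d <- sum(diffs)
  delta <- max(diffs)

  # rho over the reference ranks (descending frequency, ties lexicographic)
  ord <- order(-ref$frequency, ref$haplotype, method = "radix")
  ref_sorted <- ref[ord, , drop = FALSE]
  est_at_ref <- fe[ref_sorted$haplotype]
  rel <- abs(est_at_ref - ref_sorted$frequency) / ref_sorted$frequency
  over <- which(rel > rel_threshold)
  rho <- if (length(over) == 0) NA_integer_ else as.integer(over[1])

  tibble(
    d = d, delta = delta, rho = rho,
    n_additional = n_additional, n_missing = n_missing,
    n_estimate = nrow(est), n_reference = nrow(ref)
  )
}

#' Compare on the shared support only
#'
#' Convenience wrapper for [compare_frequency_sets()] with
#' `intersection_only = TRUE`: additional and missing haplotypes are
#' excluded from the distance computation.
#'
#' @inheritParams compare_frequency_sets
#' @return A one-row tibble as in [compare_frequency_sets()].
#' @export
compare_excluding <- function(estimate, reference, rel_threshold = 0.05) {
  compare_frequency_sets(estimate, reference, rel_threshold,
    intersection_only = TRUE)
}

#' Hardy-Weinberg effect size per locus
#'
#' For each locus, allele frequencies are chromosome-counted from the
#' unambiguous single-locus genotypes, expected genotype proportions are
#' formed under HWE (`p_i^2`, `2 p_i p_j`), and Cohen's effect size
#' `W_n = sqrt( sum_g (obs_g - exp_g)^2 / exp_g )` is computed over genotype
#' categories with positive expectation, all on proportions. Individuals
#' whose typing at a locus is ambiguous (a multiple allele code) are
#' excluded from that locus and counted.
#'
#' @param pop A wide population tibble (`id`, optional `count`,
#'   `<locus>.1/.2`).
#' @param loci Loci to assess; defaults to those present.
#' @return A tibble with columns `locus`, `w_n`, `n_used`, `n_excluded`.
#' @export
hwe_effect_size <- function(pop, loci = NULL) {
  loci <- loci %||% attr(pop, "loci") %||% population_loci(pop)
  count <- if ("count" %in% names(pop)) pop$count else rep(1L, nrow(pop))
  purrr::map_dfr(loci, function(l) {
    cols <- locus_cols(pop, l)
    a1 <- as.character(pop[[cols[1]]])
    a2 <- as.character(pop[[cols[2]]])
    ambiguous <- is_mac_token(a1) | is_mac_token(a2) | is.na(a1) | is.na(a2)
    u1 <- a1[!ambiguous]
    u2 <- a2[!ambiguous]
    cnt <- count[!ambiguous]
    n <- sum(cnt)
    if (n == 0) {
      return(tibble(locus = l, w_n = NA_real_, n_used = 0L,
        n_excluded = sum(count[ambiguous])))
    }
    alleles <- sort(unique(c(u1, u2)), method = "radix")
    p <- numeric(length(alleles))
    acc <- rowsum(c(cnt, cnt), c(match(u1, alleles), match(u2, alleles)))
    p[as.integer(rownames(acc))] <- acc[, 1]
    p <- p / (2 * n)
    # observed genotype proportions over unordered categories
    key <- pair_key(u1, u2)
    obs_tab <- rowsum(cnt, key)
    obs <- stats::setNames(obs_tab[, 1] / n, rownames(obs_tab))
    # expected proportions over all unordered pairs of observed alleles
    ii <- rep(seq_along(alleles), times = seq_along(alleles))
    jj <- unlist(lapply(seq_along(alleles), seq_len))
    cat_key <- pair_key(alleles[jj], alleles[ii])
    expd <- p[ii] * p[jj] * ifelse(ii == jj, 1, 2)
    obs_full <- stats::setNames(rep(0, length(cat_key)), cat_key)
    obs_full[names(obs)] <- obs
    keep <- expd > 0
    w_n <- sqrt(sum((obs_full[keep] - expd[keep])^2 / expd[keep]))
    tibble(locus = l, w_n = w_n, n_used = as.integer(n),
      n_excluded = as.integer(sum(count[ambiguous])))
  })
}
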