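# End-to-end estimation: split -> (filter) -> translate -> recombine ->
# diplotypes -> EM -> finalize.

#' Estimate haplotype frequencies from a population genotype table
#'
#' Runs the full workflow on raw records: splitting multi-locus genotypes
#' into per-locus genotypes (expanding multiple allele codes or genotype
#' list strings), optionally applying the implicit-ambiguity filter,
#' translating to the uniform per-locus target resolution, recombining the
#' loci into weighted resolved genotypes, enumerating candidate diplotypes,
#' and estimating frequencies by EM.
#'
#' @param data A population tibble ([read_population()]) or a file path.
#' @param tables An `hla_nomenclature` object.
#' @param resolution Target resolution, single value or named per locus.
#' @param format `"mac"` or `"gls"`.
#' @param loci Loci in canonical order; defaults to those present.
#' @param filter_ambiguities Apply the Sanger implicit-ambiguity filter.
#' @param max_expansion Discard records splitting into more resolved
#'   genotypes than this.
#' @param strict Abort on bad records instead of dropping them.
#' @inheritParams run_em
#' @return An `hla_em_fit` whose `report` element summarizes preprocessing:
#'   records read/rejected/discarded and the loci/resolution used.
#' @examples
#' \dontrun{
#' tbls <- fixture_nomenclature()
#' fit <- estimate_haplotype_frequencies(pop, tbls, resolution = "g")
#' tidy(fit)
#' }
#' @export
estimate_haplotype_frequencies <- function(data, tables, resolution = "g",
                                           format = c("mac", "gls"),
                                           loci = NULL,
                                           filter_ambiguities = FALSE,
                                           max_expansion = 64L,
                                           strict = FALSE,
                                           epsilon = 1e-6, cutoff = 1e-6,
                                           init = "count",
                                           perturbation_scale = 0.1,
                                           seed = 1L, normalize = TRUE,
                                           max_iterations = 10000L,
                                           restarts = 1L) {
  format <- match.arg(format)
  if (is.character(data) && length(data) == 1) {
    data <- read_population(data, format = format)
  }
  n_read <- nrow(data)
  slg <- split_mlg(data, tables, format = format, loci = loci,
    strict = strict)
  slg <- apply_ambiguity_filter(slg, tables, enabled = filter_ambiguities)
  slg <- translate_slg(slg, tables, resolution)
  resolved <- recombine(slg, max_expansion = max_expansion)
  dips <- build_diplotypes(resolved)
  fit <- run_em(dips, epsilon = epsilon, cutoff = cutoff, init = init,
    perturbation_scale = perturbation_scale, seed = seed,
    normalize = normalize, max_iterations = max_iterations,
    restarts = restarts)
  fit$report <- list(
    n_read = n_read,
    n_rejected = nrow(attr(slg, "rejected")),
    rejected = attr(slg, "rejected"),
    n_discarded = length(attr(resolved, "discarded")),
    discarded = attr(resolved, "discarded"),
    loci = attr(slg, "loci"),
    resolution = resolution,
    filter_ambiguities = filter_ambiguities,
    max_expansion = max_expansion
  )
  fit
}
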