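# Validation-study machinery: artificial populations with known haplotype
# frequencies, resolution heterogenization, allele-code masking, and a
# self-consistent miniature nomenclature generator for tests and demos.

#' Construct a haplotype frequency distribution
#'
#' @param haplotypes Character vector of `~`-joined haplotypes.
#' @param frequency Numeric frequencies (non-negative, summing to 1 within
#'   1e-9).
#' @return A tibble with columns `haplotype`, `frequency`, sorted by
#'   descending frequency.
#' @export
haplotype_distribution <- function(haplotypes, frequency) {
  stopifnot(length(haplotypes) == length(frequency))
  if (any(frequency < 0)) {
    abort("haplotype frequencies must be non-negative",
      class = "hlafreq_config_error")
  }
  if (abs(sum(frequency) - 1) > 1e-9) {
    abort("haplotype frequencies must sum to 1",
      class = "hlafreq_config_error")
  }
  if (anyDuplicated(haplotypes)) {
    abort("duplicate haplotypes in distribution",
      class = "hlafreq_config_error")
  }
  out <- tibble(haplotype = haplotypes, frequency = frequency)
  out[order(-out$frequency, out$haplotype, method = "radix"), , drop = FALSE]
}

#' All alleles of a locus at a target resolution
#'
#' Translates every full-length allele of the locus and returns the
#' deduplicated result — the allele universe the simulators draw from.
#'
#' @param tables An `hla_nomenclature` object.
#' @param locus Locus symbol.
#' @param resolution Target resolution (default `"g"`).
#' @return Character vector.
#' @export
allele_universe <- function(tables, locus, resolution = "g") {
  full <- tables$valid_parsed$allele[tables$valid_parsed$locus == locus]
  sort(unique(unlist(translate_allele(full, resolution, tables),
    use.names = FALSE)), method = "radix")
}

#' Draw a random haplotype distribution over a nomenclature
#'
#' Samples `n_haplotypes` distinct haplotypes uniformly from the per-locus
#' allele universes and assigns Zipf-like frequencies — rank^-`decay`,
#' jittered by a log-normal factor — mixed with a uniform floor of weight
#' `uniform_mix`. The floor keeps the rarest haplotype within a factor
#' `~n_haplotypes/uniform_mix` of the commonest, mirroring the frequency
#' truncation of published registry haplotype lists and guaranteeing that
#' every haplotype pair is representable by integer genotype counts in
#' populations of the sizes used here.
#'
#' @param tables An `hla_nomenclature` object.
#' @param loci Loci in canonical order.
#' @param n_haplotypes Number of haplotypes.
#' @param seed Integer seed.
#' @param resolution Resolution of the haplotype alleles (default `"g"`).
#' @param decay Zipf decay exponent.
#' @param uniform_mix Weight of the uniform floor component, in `[0, 1)`.
#' @return A tibble with columns `haplotype`, `frequency`.
#' @export
random_haplotype_distribution <- function(tables, loci, n_haplotypes,
                                          seed = 1L, resolution = "g",
                                          decay = 1, uniform_mix = 0.3) {
  universes <- lapply(loci, function(l) allele_universe(tables, l, resolution))
  n_comb <- prod(lengths(universes))
  if (n_haplotypes > n_comb) {
    abort(sprintf("only %d distinct haplotypes possible, %d requested",
      n_comb, n_haplotypes), class = "hlafreq_config_error")
  }
  stopifnot(uniform_mix >= 0, uniform_mix < 1)
  withr::with_seed(seed, {
    haps <- character(0)
    while (length(haps) < n_haplotypes) {
      draw <- vapply(universes, function(u) u[sample.int(length(u), 1)],
        character(1))
      haps <- union(haps, paste(draw, collapse = "~"))
    }
    f <- seq_len(n_haplotypes)^(-decay) * exp(stats::rnorm(n_haplotypes, 0, 0.3))
    f <- uniform_mix / n_haplotypes + (1 - uniform_mix) * f / sum(f)
    haplotype_distribution(haps, f / sum(f))
  })
}

# Unordered haplotype-pair grid with HWE probabilities (2 - delta) f_i f_j.
hwe_pair_grid <- function(dist) {
  n <- nrow(dist)
  i <- rep(seq_len(n), times = n)
  j <- rep(seq_len(n), each = n)
  keep <- i <= j
  i <- i[keep]
  j <- j[keep]
  p <- dist$frequency[i] * dist$frequency[j] * ifelse(i == j, 1, 2)
  list(i = i, j = j, p = p)
}

# Turn haplotype index pairs into a wide MAC-format population tibble with
# one row per genotype class (phase stripped per locus).
pairs_to_population <- function(dist, i, j, count, loci) {
  parts <- stringr::str_split(dist$haplotype, stringr::fixed("~"))
  if (any(lengths(parts) != length(loci))) {
    abort("haplotypes do not span the configured loci",
      class = "hlafreq_config_error")
  }
  H <- matrix(unlist(parts), ncol = length(loci), byrow = TRUE)
  out <- tibble(id = paste0("g", seq_along(i)), count = as.integer(count))
  for (l in seq_along(loci)) {
    pc <- pair_canonical(H[i, l], H[j, l])
    out[[paste0(loci[l], ".1")]] <- pc$a
    out[[paste0(loci[l], ".2")]] <- pc$b
  }
  # phase stripping can merge classes; re-aggregate
  gcols <- setdiff(names(out), c("id", "count"))
  out <- dplyr::summarise(
    dplyr::group_by(out, dplyr::across(dplyr::all_of(gcols))),
    count = as.integer(sum(.data$count)), .groups = "drop"
  )
  out <- dplyr::bind_cols(tibble(id = paste0("g", seq_len(nrow(out)))), out)
  dplyr::select(out, "id", "count", dplyr::all_of(gcols))
}

#' Combinatorial population under exact Hardy-Weinberg proportions
#'
#' Builds genotypes from all unordered haplotype pairs with replacement;
#' pair (i, j) receives the integer count `round(total_n * (2 - delta_ij) *
#' f_i * f_j)` (round-half-even), zero-count pairs are omitted and phase is
#' stripped. The result deviates from perfect HWE only through integer
#' rounding.
#'
#' @param dist A haplotype distribution tibble.
#' @param total_n Target population size.
#' @param loci Loci spanned by the haplotypes, in order.
#' @return A wide population tibble (`id`, `count`, `<locus>.1/.2`) with a
#'   `provenance` attribute.
#' @export
build_combinatorial_population <- function(dist, total_n, loci) {
  stopifnot(total_n >= 1)
  g <- hwe_pair_grid(dist)
  cnt <- round(total_n * g$p)
  keep <- cnt > 0
  if (!any(keep)) {
    abort("total_n too small: every genotype count rounds to 0",
      class = "hlafreq_config_error")
  }
  out <- pairs_to_population(dist, g$i[keep], g$j[keep], cnt[keep], loci)
  structure(out, loci = loci,
    realized_frequencies = realized_frequencies(dist, g$i[keep], g$j[keep],
      cnt[keep]),
    provenance = list(model = 1, total_n = total_n, n_haplotypes = nrow(dist)))
}

# Haplotype frequencies actually present in a constructed population:
# chromosome counts over haplotype pairs (phase is known per construction).
realized_frequencies <- function(dist, i, j, cnt) {
  chrom <- numeric(nrow(dist))
  acc <- rowsum(c(cnt, cnt), c(i, j))
  chrom[as.integer(rownames(acc))] <- acc[, 1]
  keep <- chrom > 0
  haplotype_distribution(dist$haplotype[keep], chrom[keep] / sum(chrom))
}

#' Haplotype frequencies realized in a constructed population
#'
#' Returns the phase-known chromosome-count frequencies of a population
#' built by [build_combinatorial_population()] or [sample_population()] —
#' the reference against which an estimate should be compared, since the
#' constructed population embodies these frequencies exactly (integer
#' approximation included).
#'
#' @param pop A population tibble carrying the builder's attributes.
#' @return A tibble with columns `haplotype`, `frequency`.
#' @export
population_frequencies <- function(pop) {
  rf <- attr(pop, "realized_frequencies")
  if (is.null(rf)) {
    abort("population carries no realized frequencies (not built here?)",
      class = "hlafreq_config_error")
  }
  rf
}

#' Sample a population by random haplotype pairing
#'
#' Each of `n` individuals receives two independent haplotype draws from the
#' distribution; phase is stripped and identical genotypes are aggregated
#' into counts.
#'
#' @param dist A haplotype distribution tibble.
#' @param n Number of individuals.
#' @param seed Integer seed.
#' @param loci Loci spanned by the haplotypes, in order.
#' @return A wide population tibble with a `provenance` attribute.
#' @export
sample_population <- function(dist, n, seed = 1L, loci) {
  stopifnot(n >= 1)
  withr::with_seed(seed, {
    i <- sample.int(nrow(dist), n, replace = TRUE, prob = dist$frequency)
    j <- sample.int(nrow(dist), n, replace = TRUE, prob = dist$frequency)
  })
  lo <- pmin(i, j)
  hi <- pmax(i, j)
  key <- paste(lo, hi)
  agg <- table(key)
  first <- !duplicated(key)
  km <- match(names(agg), key[first])
  out <- pairs_to_population(dist, lo[first][km], hi[first][km],
    as.integer(agg), loci)
  structure(out, loci = loci,
    realized_frequencies = realized_frequencies(dist, lo[first][km],
      hi[first][km], as.integer(agg)),
    provenance = list(model = 2, n = n, seed = seed,
      n_haplotypes = nrow(dist)))
}

# Expand a counted population into one row per individual (for per-typing
# randomization) and re-aggregate afterwards.
expand_counts <- function(pop) {
  idx <- rep(seq_len(nrow(pop)), pop$count)
  out <- pop[idx, , drop = FALSE]
  out$count <- 1L
  out$id <- paste0("i", seq_len(nrow(out)))
  out
}

reaggregate_population <- function(pop, loci) {
  gcols <- as.vector(rbind(paste0(loci, ".1"), paste0(loci, ".2")))
  out <- dplyr::summarise(
    dplyr::group_by(pop, dplyr::across(dplyr::all_of(gcols))),
    count = as.integer(sum(.data$count)), .groups = "drop"
  )
  dplyr::bind_cols(
    tibble(id = paste0("g", seq_len(nrow(out)))),
    dplyr::select(out, dplyr::all_of(gcols), "count")
  )[, c("id", "count", gcols)]
}

#' Heterogenize typing resolutions of a population
#'
#' Independently replaces each typing by a uniform choice from its
#' replacement menu (the original is always among the choices), emulating
#' registry records typed at mixed resolutions. Every menu entry must
#' translate back to the original designation at the original's resolution,
#' so the heterogenized sample carries exactly the original information.
#'
#' @param pop A wide population tibble.
#' @param menu Named list: original designation -> character vector of
#'   equivalent designations (higher resolution or group codes).
#' @param tables An `hla_nomenclature` object (used to verify the menu).
#' @param seed Integer seed.
#' @param loci Loci; defaults to the `loci` attribute.
#' @return The heterogenized population (one row per genotype class).
#' @export
heterogenize_resolution <- function(pop, menu, tables, seed = 1L,
                                    loci = NULL) {
  loci <- loci %||% attr(pop, "loci") %||% population_loci(pop)
  if (length(menu) == 0) return(pop)
  for (orig in names(menu)) {
    p <- parse_allele(orig)
    res <- if (p$marker == "g") "g" else if (p$marker == "G") "G" else
      if (p$marker == "P") "P" else paste0(p$n_fields, "f")
    for (repl in menu[[orig]]) {
      back <- translate_allele(repl, res, tables)[[1]]
      if (!identical(back, p$allele)) {
        abort(
          sprintf("menu entry '%s' does not translate back to '%s' (got %s)",
            repl, orig, paste(back, collapse = ", ")),
          class = "hlafreq_config_error"
        )
      }
    }
  }
  ind <- expand_counts(pop)
  withr::with_seed(seed, {
    for (l in loci) {
      for (col in paste0(l, ".", 1:2)) {
        cells <- ind[[col]]
        for (orig in names(menu)) {
          choices <- unique(c(orig, menu[[orig]]))
          hit <- which(cells == orig)
          if (length(hit) > 0) {
            cells[hit] <- choices[sample.int(length(choices), length(hit),
              replace = TRUE)]
          }
        }
        ind[[col]] <- cells
      }
    }
  })
  out <- reaggregate_population(ind, loci)
  structure(out, loci = loci, provenance = attr(pop, "provenance"),
    realized_frequencies = attr(pop, "realized_frequencies"))
}

#' Mask typings with multiple allele codes
#'
#' Replaces a Bernoulli-`fraction` share of typings with an NMDP-style
#' multiple allele code drawn uniformly from the codes eligible for that
#' allele. An eligible code's expansion must contain the allele it replaces
#' (checked up front). Typings with no eligible code are left unchanged and
#' counted.
#'
#' @param pop A wide population tibble.
#' @param fraction Share of typings to mask, in `[0, 1]`.
#' @param tables An `hla_nomenclature` object.
#' @param eligible_codes Tibble with columns `allele` (the typing as it
#'   appears in `pop`) and `mac` (the replacement token, e.g.
#'   `"A*31:VSCB"`), such as produced by [masking_codes()].
#' @param seed Integer seed.
#' @param loci Loci; defaults to the `loci` attribute.
#' @return The masked population; attribute `n_unmaskable` counts typings
#'   selected for masking that had no eligible code.
#' @export
mask_with_macs <- function(pop, fraction, tables, eligible_codes, seed = 1L,
                           loci = NULL) {
  if (fraction < 0 || fraction > 1) {
    abort("masking fraction must be in [0, 1]", class = "hlafreq_config_error")
  }
  loci <- loci %||% attr(pop, "loci") %||% population_loci(pop)
  if (fraction == 0) return(pop)

  # verify eligibility: the code expansion, brought to the allele's
  # resolution, must contain the allele
  codes <- dplyr::distinct(eligible_codes[, c("allele", "mac")])
  for (r in seq_len(nrow(codes))) {
    p <- parse_allele(codes$allele[r])
    res <- if (p$marker == "g") "g" else if (p$marker == "G") "G" else
      if (p$marker == "P") "P" else paste0(p$n_fields, "f")
    exp2 <- expand_mac(codes$mac[r], tables = tables)
    back <- unique(unlist(translate_allele(exp2, res, tables),
      use.names = FALSE))
    if (!(p$allele %in% back)) {
      abort(
        sprintf("code '%s' is not eligible for '%s': expansion covers %s",
          codes$mac[r], codes$allele[r], paste(back, collapse = ", ")),
        class = "hlafreq_config_error"
      )
    }
  }
  code_of <- split(codes$mac, codes$allele)

  ind <- expand_counts(pop)
  n_unmaskable <- 0L
  withr::with_seed(seed, {
    for (l in loci) {
      for (col in paste0(l, ".", 1:2)) {
        cells <- ind[[col]]
        pick <- stats::runif(length(cells)) < fraction
        for (i in which(pick)) {
          opts <- code_of[[cells[i]]]
          if (is.null(opts)) {
            n_unmaskable <- n_unmaskable + 1L
          } else {
            cells[i] <- opts[sample.int(length(opts), 1)]
          }
        }
        ind[[col]] <- cells
      }
    }
  })
  out <- reaggregate_population(ind, loci)
  structure(out, loci = loci, provenance = attr(pop, "provenance"),
    realized_frequencies = attr(pop, "realized_frequencies"),
    n_unmaskable = n_unmaskable)
}

#' Eligible masking codes implied by a nomenclature
#'
#' For every MAC in the tables and every locus/first-field combination
#' occurring among the valid alleles, lists the code against each
#' `resolution`-level allele its expansion covers. The result feeds
#' [mask_with_macs()].
#'
#' @param tables An `hla_nomenclature` object.
#' @param resolution Resolution of the typings to be masked (default `"g"`).
#' @param min_expansion Keep only codes whose valid expansion has at least
#'   this many alleles (2 = the code masks real information).
#' @return A tibble with columns `allele`, `mac`.
#' @export
masking_codes <- function(tables, resolution = "g", min_expansion = 1L) {
  vp <- tables$valid_parsed
  stems <- dplyr::distinct(tibble(
    locus = vp$locus,
    first = truncate_fields(vp$fields, 1)
  ))
  out <- list()
  for (ci in seq_len(nrow(tables$mac_table))) {
    code <- tables$mac_table$code[ci]
    for (si in seq_len(nrow(stems))) {
      token <- paste0(stems$locus[si], "*", stems$first[si], ":", code)
      exp2 <- tryCatch(expand_mac(token, tables = tables),
        error = function(e) character(0))
      if (length(exp2) < min_expansion) next
      covered <- unique(unlist(translate_allele(exp2, resolution, tables),
        use.names = FALSE))
      out[[length(out) + 1]] <- tibble(allele = covered, mac = token)
    }
  }
  if (length(out) == 0) return(tibble(allele = character(), mac = character()))
  dplyr::distinct(dplyr::bind_rows(out))
}

#' Heterogenization menu implied by a nomenclature
#'
#' For every small-g group, lists its full-length member alleles and, where
#' one exists, the corresponding P-group code — all designations that
#' translate back to the g group, mirroring mixed-resolution registry
#' records.
#'
#' @param tables An `hla_nomenclature` object.
#' @return Named list: g-group code -> character vector of replacements.
#' @export
heterogenization_menu <- function(tables) {
  menu <- list()
  for (gname in names(tables$small_g_members)) {
    members <- tables$small_g_members[[gname]]
    pg <- unique(stats::na.omit(unname(tables$member_to_p[members])))
    entries <- c(members, pg)
    ok <- vapply(entries, function(e) {
      identical(translate_allele(e, "g", tables)[[1]], gname)
    }, logical(1))
    entries <- entries[ok]
    if (length(entries) > 0) menu[[gname]] <- unname(entries)
  }
  menu
}

#' Write a self-consistent miniature nomenclature
#'
#' Generates an allele list, G- and P-group files, a MAC table and an
#' ambiguity-pair table in the dialects read by [read_nomenclature()]. Each
#' locus carries `n_families` generic allele families: family `ff` has
#' full-length alleles `ff:01:01` and `ff:01:02` (G group `ff:01:01G`,
#' P group `ff:01P`), a standalone full-length two-field allele `ff:02`,
#' and, when `nulls_per_group > 0`, a null allele `ff:03N` inside the G
#' group. A fixed demo block (locus A family 31 with the two-field alleles
#' 31:41 and 31:68 and the code VSCB, locus B family 07, locus C family
#' 16:04) exercises group-spanning and worked-example lookups. Output is
#' deterministic, hence byte-identical for identical arguments.
#'
#' @param dir Output directory (created if needed).
#' @param loci Locus symbols.
#' @param n_families Generic families per locus.
#' @param nulls_per_group Null alleles per G group (0 or 1).
#' @param seed Accepted for interface symmetry; generation is deterministic.
#' @return The directory path, invisibly; files `alleles.txt`,
#'   `g_groups.txt`, `p_groups.txt`, `mac_table.txt`,
#'   `ambiguity_pairs.txt`.
#' @export
make_fixture_nomenclature <- function(dir, loci = c("A", "B", "C"),
                                      n_families = 6L, nulls_per_group = 1L,
                                      seed = 1L) {
  stopifnot(n_families >= 1, nulls_per_group >= 0)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  alleles <- character(0)
  g_lines <- character(0)
  p_lines <- character(0)
  ambig_lines <- character(0)

  add_family <- function(locus, ff, extra_two_field = character(0)) {
    mem <- c(paste0(ff, ":01:01"), paste0(ff, ":01:02"))
    fam_alleles <- c(mem, paste0(ff, ":02"), extra_two_field)
    g_mem <- mem
    if (nulls_per_group >= 1) {
      null <- paste0(ff, ":03N")
      fam_alleles <- c(fam_alleles, null)
      g_mem <- c(g_mem, null)
    }
    alleles <<- c(alleles, paste0(locus, "*", fam_alleles))
    g_lines <<- c(g_lines, paste0(locus, "*;", paste(g_mem, collapse = "/"),
      ";", ff, ":01:01G"))
    p_lines <<- c(p_lines, paste0(locus, "*;", paste(mem, collapse = "/"),
      ";", ff, ":01P"))
    ambig_lines <<- c(ambig_lines, paste0(locus, "*", mem[1], "\t",
      locus, "*", mem[2]))
  }

  for (locus in loci) {
    for (j in seq_len(n_families)) {
      add_family(locus, sprintf("%02d", j))
    }
  }
  # demo block: worked-example families
  if ("A" %in% loci) add_family("A", "31", extra_two_field = c("31:41", "31:68"))
  if ("B" %in% loci) add_family("B", "07")
  if ("C" %in% loci) {
    alleles <- c(alleles, paste0("C*", c("16:04:01", "16:04:03")))
    g_lines <- c(g_lines, "C*;16:04:01/16:04:03;16:04:01G")
    p_lines <- c(p_lines, "C*;16:04:01/16:04:03;16:04P")
  }

  mac_lines <- c(
    "AB\t01/02",
    "XX\t01",
    "VSCB\t01/41/68",
    "GRP\t*\t02:01/03:01"
  )

  writeLines(sort(unique(alleles), method = "radix"),
    file.path(dir, "alleles.txt"))
  writeLines(g_lines, file.path(dir, "g_groups.txt"))
  writeLines(p_lines, file.path(dir, "p_groups.txt"))
  writeLines(mac_lines, file.path(dir, "mac_table.txt"))
  writeLines(ambig_lines, file.path(dir, "ambiguity_pairs.txt"))
  invisible(dir)
}

#' Generate and load a miniature nomenclature in one step
#'
#' @inheritParams make_fixture_nomenclature
#' @return An `hla_nomenclature` object.
#' @export
fixture_nomenclature <- function(loci = c("A", "B", "C"), n_families = 6L,
                                 nulls_per_group = 1L, seed = 1L) {
  dir <- tempfile("nomenclature")
  make_fixture_nomenclature(dir, loci = loci, n_families = n_families,
    nulls_per_group = nulls_per_group, seed = seed)
  on.exit(unlink(dir, recursive = TRUE))
  read_nomenclature(dir)
}
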