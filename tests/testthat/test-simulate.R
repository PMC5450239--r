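test_that("combinatorial construction reproduces HWE arithmetic", {
  dist <- haplotype_distribution(c("H1~x", "H2~x"), c(0.8, 0.2))
  pop <- build_combinatorial_population(dist, 100, loci = c("L", "M"))
  # counts 64 / 32 / 4 for H1H1 / H1H2 / H2H2
  expect_equal(sort(pop$count), c(4, 32, 64))
  expect_equal(sum(pop$count), 100)
  # degenerate single-haplotype distribution: one homozygous class
  d1 <- haplotype_distribution("H1~x", 1)
  p1 <- build_combinatorial_population(d1, 50, loci = c("L", "M"))
  expect_equal(nrow(p1), 1)
  expect_equal(p1$count, 50)
  # too-small populations are refused
  d2 <- haplotype_distribution(paste0("H", 1:10, "~x"), rep(0.1, 10))
  expect_error(build_combinatorial_population(d2, 1, loci = c("L", "M")),
    class = "hlafreq_config_error")
})

test_that("combinatorial populations sit in near-perfect HWE", {
  tbls <- fixture_tables()
  dist <- random_haplotype_distribution(tbls, test_loci, 50, seed = 2)
  pop <- build_combinatorial_population(dist, 1e5, test_loci)
  wn <- hwe_effect_size(pop)
  expect_true(all(wn$w_n <= 1e-2))
  # the residual is rounding noise: it shrinks as total_n grows
  wn_small <- mean(hwe_effect_size(
    build_combinatorial_population(dist, 1e3, test_loci))$w_n)
  expect_lt(mean(wn$w_n), wn_small)
})

test_that("random pairing samples honor frequencies and seeds", {
  # degenerate distribution: all individuals identical homozygotes
  d1 <- haplotype_distribution("H1~x", 1)
  s1 <- sample_population(d1, 5, seed = 9, loci = c("L", "M"))
  expect_equal(sum(s1$count), 5)
  expect_equal(nrow(s1), 1)
  # heterozygote share near 0.5 for a 50/50 distribution (5 sigma)
  d2 <- haplotype_distribution(c("H1~x", "H2~x"), c(0.5, 0.5))
  s2 <- sample_population(d2, 10000, seed = 11, loci = c("L", "M"))
  het <- s2$count[s2$L.1 != s2$L.2] / 10000
  expect_lt(abs(sum(het) - 0.5), 5 * sqrt(0.25 / 10000))
  # determinism
  s3 <- sample_population(d2, 1000, seed = 13, loci = c("L", "M"))
  s4 <- sample_population(d2, 1000, seed = 13, loci = c("L", "M"))
  expect_identical(as.data.frame(s3), as.data.frame(s4))
})

test_that("heterogenization preserves the information content exactly", {
  tbls <- fixture_tables()
  dist <- random_haplotype_distribution(tbls, test_loci, 30, seed = 4)
  pop <- build_combinatorial_population(dist, 5000, test_loci)
  # empty menu is the identity
  expect_identical(
    as.data.frame(heterogenize_resolution(pop, list(), tbls, seed = 1)),
    as.data.frame(pop))
  # the paper-style menu for one g group, plus the generated full menu
  menu <- heterogenization_menu(tbls)
  expect_setequal(menu[["C*16:04g"]],
    c("C*16:04:01", "C*16:04:03", "C*16:04P"))
  het <- heterogenize_resolution(pop, menu, tbls, seed = 5)
  # translating back to g reproduces the original sample exactly
  slg <- translate_slg(split_mlg(het, tbls, format = "mac"), tbls, "g")
  expect_true(all(slg$weight == 1))
  back <- recombine(slg, max_expansion = 1)
  expect_equal(length(attr(back, "discarded")), 0)
  # compare multisets of genotype rows (chromosome content per locus)
  key_of <- function(df) {
    k <- rep("", nrow(df))
    for (l in test_loci) {
      c1 <- if (paste0(l, ".1") %in% names(df)) df[[paste0(l, ".1")]] else
        df[[paste0("a.", l)]]
      c2 <- if (paste0(l, ".2") %in% names(df)) df[[paste0(l, ".2")]] else
        df[[paste0("b.", l)]]
      k <- paste(k, pmin(c1, c2), pmax(c1, c2))
    }
    k
  }
  orig <- sort(rep(key_of(pop), pop$count))
  rec <- sort(rep(key_of(back), back$count))
  expect_identical(rec, orig)
  # a menu entry that does not translate back to the original is refused
  expect_error(
    heterogenize_resolution(pop,
      list("A*01:01g" = "A*02:01:01"), tbls, seed = 1),
    class = "hlafreq_config_error")
})

test_that("masking replaces typings with eligible codes only", {
  tbls <- fixture_tables()
  dist <- random_haplotype_distribution(tbls, test_loci, 20, seed = 6)
  pop <- build_combinatorial_population(dist, 2000, test_loci)
  codes <- masking_codes(tbls, min_expansion = 2)
  # fraction 0 is the identity
  expect_identical(
    as.data.frame(mask_with_macs(pop, 0, tbls, codes, seed = 1)),
    as.data.frame(pop))
  expect_error(mask_with_macs(pop, 1.5, tbls, codes, seed = 1),
    class = "hlafreq_config_error")
  # the worked example: A*31:01g may be masked by the VSCB code
  expect_true(any(codes$allele == "A*31:01g" & codes$mac == "A*31:VSCB"))
  # an ineligible pairing is rejected up front
  expect_error(
    mask_with_macs(pop, 0.1, tbls,
      tibble::tibble(allele = "A*01:01g", mac = "B*07:XX"), seed = 1),
    class = "hlafreq_config_error")
  # masking at fraction 1 with information-preserving singleton codes
  # leaves the EM recovery unchanged
  single <- masking_codes(tbls, min_expansion = 1)
  single <- single[vapply(single$mac, function(m) {
    length(expand_mac(m, tables = tbls)) == 1
  }, logical(1)), ]
  covered <- unique(unlist(lapply(test_loci, function(l) {
    c(pop[[paste0(l, ".1")]], pop[[paste0(l, ".2")]])
  })))
  if (all(covered %in% single$allele)) {
    m <- mask_with_macs(pop, 1, tbls, single, seed = 3)
    fit_m <- estimate_haplotype_frequencies(m, tbls, resolution = "g",
      epsilon = 1e-8, cutoff = 1e-7)
    fit_0 <- estimate_haplotype_frequencies(pop, tbls, resolution = "g",
      epsilon = 1e-8, cutoff = 1e-7)
    cmp <- compare_frequency_sets(fit_m, fit_0)
    expect_lt(cmp$d, 1e-9)
  }
})

test_that("fixture generation is deterministic and self-consistent", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  make_fixture_nomenclature(d1, loci = c("A", "B"), n_families = 3,
    nulls_per_group = 1)
  make_fixture_nomenclature(d2, loci = c("A", "B"), n_families = 3,
    nulls_per_group = 1)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  tbls <- read_nomenclature(d1)
  expect_s3_class(tbls, "hla_nomenclature")
  # minimal spec loads too
  d3 <- withr::local_tempdir()
  make_fixture_nomenclature(d3, loci = "A", n_families = 1,
    nulls_per_group = 0)
  expect_s3_class(read_nomenclature(d3), "hla_nomenclature")
})

test_that("model-2 recovery improves with sample size", {
  tbls <- fixture_tables()
  dist <- random_haplotype_distribution(tbls, test_loci, 25, seed = 8)
  mean_d <- vapply(c(500, 5000, 50000), function(n) {
    ds <- vapply(1:3, function(s) {
      pop <- sample_population(dist, n, seed = 100 + s, loci = test_loci)
      fit <- estimate_haplotype_frequencies(pop, tbls, resolution = "g",
        epsilon = 1e-7, cutoff = 1e-7, max_iterations = 5000)
      compare_frequency_sets(fit, dist)$d
    }, numeric(1))
    mean(ds)
  }, numeric(1))
  expect_true(all(diff(mean_d) < 0))
})
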