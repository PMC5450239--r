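test_that("MLG splitting expands MACs over a Cartesian product per locus", {
  tbls <- fixture_tables()
  pop <- tibble::tibble(id = "r1", A.1 = "31:VSCB", A.2 = "31:01")
  slg <- split_mlg(pop, tbls, format = "mac")
  # the code side expands to three alleles, the plain side stays single
  expect_equal(nrow(slg), 3)
  expect_equal(sum(slg$weight), 1)
  expect_true(all(abs(slg$weight - 1 / 3) < 1e-12))
  expect_setequal(
    paste(slg$a1, slg$a2),
    c("A*31:01 A*31:01", "A*31:01 A*31:41", "A*31:01 A*31:68")
  )
  # unambiguous rows give a single pair of weight 1
  slg2 <- split_mlg(tibble::tibble(id = "r", A.1 = "01:01", A.2 = "02:01"),
    tbls, format = "mac")
  expect_equal(nrow(slg2), 1)
  expect_equal(slg2$weight, 1)
  # 2 x 3 candidates give 6 pairs of weight 1/6 before dedup
  slg3 <- split_mlg(
    tibble::tibble(id = "r", A.1 = "01:AB", A.2 = "31:VSCB"),
    tbls, format = "mac"
  )
  expect_equal(nrow(slg3), 6)
  expect_true(all(abs(slg3$weight - 1 / 6) < 1e-12))
})

test_that("bad records are dropped with reasons, or abort in strict mode", {
  tbls <- fixture_tables()
  pop <- tibble::tibble(
    id = c("ok", "bad", "gap"),
    A.1 = c("01:01", "99:99", "01:01"), A.2 = c("01:01", "01:01", "01:01"),
    B.1 = c("07:01", "07:01", NA), B.2 = c("07:01", "07:01", "07:01")
  )
  slg <- split_mlg(pop, tbls, format = "mac")
  expect_setequal(unique(slg$id), "ok")
  rej <- attr(slg, "rejected")
  expect_setequal(rej$id, c("bad", "gap"))
  expect_match(rej$reason[rej$id == "bad"], "99:99")
  expect_error(split_mlg(pop, tbls, format = "mac", strict = TRUE),
    class = "hlafreq_input_error")
})

test_that("GLS records split per locus through the GL grammar", {
  tbls <- fixture_tables()
  pop <- tibble::tibble(
    id = c("x", "y"),
    gl = c("A*01:01/A*01:02+A*02:01^B*07:01+B*07:01",
      "A*01:01+A*01:01^B*07:01+B*07:02")
  )
  slg <- split_mlg(pop, tbls, format = "gls")
  expect_setequal(unique(slg$locus), c("A", "B"))
  sums <- tapply(slg$weight, paste(slg$id, slg$locus), sum)
  expect_true(all(abs(sums - 1) < 1e-12))
})

test_that("the ambiguity filter keeps listed pairs and falls back when none match", {
  tbls <- fixture_tables()
  # fixture lists (A*ff:01:01, A*ff:01:02) pairs; build an SLG with two
  # listed pairs and two unlisted ones
  slg <- structure(
    tibble::tibble(
      id = "r", count = 1L, locus = "A",
      a1 = c("A*01:01:01", "A*02:01:01", "A*01:01:01", "A*03:01:01"),
      a2 = c("A*01:01:02", "A*02:01:02", "A*01:01:02", "A*04:02"),
      weight = rep(0.25, 4)
    )[c(1, 2, 4), ],
    loci = "A", rejected = tibble::tibble(id = character(),
      reason = character())
  )
  filtered <- apply_ambiguity_filter(slg, tbls, enabled = TRUE)
  expect_equal(nrow(filtered), 2)
  expect_true(all(abs(filtered$weight - 0.5) < 1e-12))
  # disabled filter is the identity
  expect_identical(
    apply_ambiguity_filter(slg, tbls, enabled = FALSE)$a1, slg$a1)
  # nothing listed: unchanged with a warning
  slg_none <- slg
  slg_none$a1 <- c("A*05:02", "A*05:02", "A*05:02")
  slg_none$a2 <- c("A*06:02", "A*06:02", "A*06:02")
  expect_warning(
    out <- apply_ambiguity_filter(slg_none, tbls, enabled = TRUE),
    class = "hlafreq_filter_warning"
  )
  expect_equal(nrow(out), nrow(slg_none))
})

test_that("SLG translation recombines expansions and merges duplicates", {
  tbls <- fixture_tables()
  mk_slg <- function(a1, a2, w = 1) {
    structure(
      tibble::tibble(id = "r", count = 1L, locus = parse_allele(a1)$locus,
        a1 = a1, a2 = a2, weight = w),
      loci = parse_allele(a1)$locus,
      rejected = tibble::tibble(id = character(), reason = character())
    )
  }
  # two synonymous full-length alleles collapse to one homozygous g pair
  tr <- translate_slg(mk_slg("C*16:04:01", "C*16:04:03"), tbls, "g")
  expect_equal(nrow(tr), 1)
  expect_equal(tr$a1, "C*16:04g")
  expect_equal(tr$a2, "C*16:04g")
  expect_equal(tr$weight, 1)
  # a pair already at target is unchanged
  tr2 <- translate_slg(mk_slg("A*01:01g", "A*02:01g"), tbls, "g")
  expect_equal(nrow(tr2), 1)
  expect_equal(tr2$weight, 1)
  # one position expanding to two full-length alleles splits the weight
  tr3 <- translate_slg(mk_slg("A*01:01", "A*02:02"), tbls, "3f")
  expect_equal(nrow(tr3), 2)
  expect_true(all(abs(tr3$weight - 0.5) < 1e-12))
})

test_that("recombination multiplies weights and applies the discard threshold", {
  tbls <- fixture_tables()
  # 2 x 3 pairs across two loci -> 6 resolved genotypes of weight 1/6
  slg <- structure(
    tibble::tibble(
      id = "r", count = 1L,
      locus = c("A", "A", "B", "B", "B"),
      a1 = c("A*01:01g", "A*01:02g", "B*01:01g", "B*02:01g", "B*03:01g"),
      a2 = c("A*01:01g", "A*01:02g", "B*01:01g", "B*02:01g", "B*03:01g"),
      weight = c(0.5, 0.5, 1 / 3, 1 / 3, 1 / 3)
    ),
    loci = c("A", "B"),
    rejected = tibble::tibble(id = character(), reason = character())
  )
  res <- recombine(slg, max_expansion = 8)
  expect_equal(nrow(res), 6)
  expect_true(all(abs(res$weight - 1 / 6) < 1e-12))
  expect_equal(sum(res$weight), 1)
  # threshold below the count discards the whole individual
  res2 <- recombine(slg, max_expansion = 5)
  expect_equal(nrow(res2), 0)
  expect_equal(attr(res2, "discarded"), "r")
})

test_that("weight conservation holds across the preprocessing chain", {
  tbls <- fixture_tables()
  withr::with_seed(42, {
    cells <- c("01:01", "01:AB", "02:01g", "31:VSCB", "02:01:01")
    pop <- tibble::tibble(
      id = paste0("i", 1:20),
      A.1 = sample(cells, 20, TRUE), A.2 = sample(cells, 20, TRUE),
      B.1 = sample(c("01:01", "01:AB", "02:02"), 20, TRUE),
      B.2 = sample(c("01:01", "02:01", "03:02g"), 20, TRUE)
    )
  })
  slg <- split_mlg(pop, tbls, format = "mac")
  for (s in list(slg, translate_slg(slg, tbls, "g"))) {
    sums <- tapply(s$weight, paste(s$id, s$locus), sum)
    expect_true(all(abs(sums - 1) < 1e-12))
    # unordered pairs are deduplicated
    expect_false(any(duplicated(paste(s$id, s$locus, s$a1, s$a2))))
    expect_true(all(s$a1 <= s$a2))
  }
  res <- recombine(translate_slg(slg, tbls, "g"), max_expansion = 1e6)
  sums <- tapply(res$weight, res$id, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
})

test_that("discard threshold is monotone in max_expansion", {
  tbls <- fixture_tables()
  withr::with_seed(7, {
    cells <- c("01:AB", "31:VSCB", "01:01", "02:01")
    pop <- tibble::tibble(
      id = paste0("i", 1:30),
      A.1 = sample(cells, 30, TRUE), A.2 = sample(cells, 30, TRUE),
      B.1 = sample(cells[3:4], 30, TRUE), B.2 = sample(cells, 30, TRUE)
    )
  })
  slg <- translate_slg(split_mlg(pop, tbls, format = "mac"), tbls, "g")
  retained <- vapply(c(1, 2, 4, 8, 16, 64), function(m) {
    length(unique(recombine(slg, max_expansion = m)$id))
  }, numeric(1))
  expect_true(all(diff(retained) >= 0))
})

test_that("diplotype counts follow 2^(k-1) and match brute-force enumeration", {
  # direct law on constructed genotypes with 0..5 heterozygous loci
  for (L in c(2, 4, 6)) {
    for (k in 0:min(L, 5)) {
      pairs <- lapply(seq_len(L), function(l) {
        if (l <= k) c(paste0("L", l, "x"), paste0("L", l, "y"))
        else rep(paste0("L", l, "x"), 2)
      })
      res <- tibble::tibble(id = "r", count = 1L, weight = 1)
      loci <- paste0("loc", seq_len(L))
      for (l in seq_len(L)) {
        res[[paste0("a.", loci[l])]] <- pairs[[l]][1]
        res[[paste0("b.", loci[l])]] <- pairs[[l]][2]
      }
      attr(res, "loci") <- loci
      dips <- build_diplotypes(res)
      expect_equal(nrow(dips), max(1, 2^(max(0, k - 1))),
        label = sprintf("L=%d k=%d", L, k))
      # brute force over all 2^L orderings agrees
      expect_setequal(paste(dips$h1, dips$h2, sep = "|"),
        brute_force_diplotypes(pairs))
    }
  }
})

test_that("random genotypes agree with brute-force phase enumeration", {
  for (s in 1:20) {
    res <- random_resolved_genotypes(s)
    dips <- build_diplotypes(res)
    for (i in seq_len(nrow(res))) {
      pairs <- list(c(res$a.A[i], res$b.A[i]), c(res$a.B[i], res$b.B[i]))
      got <- dips[dips$id == res$id[i], ]
      expect_setequal(paste(got$h1, got$h2, sep = "|"),
        brute_force_diplotypes(pairs))
    }
  }
})
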