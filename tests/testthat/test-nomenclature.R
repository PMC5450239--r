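test_that("fixture nomenclature satisfies the table invariants", {
  tbls <- fixture_tables()
  # every group member is a valid allele
  expect_true(all(tbls$g_group_map$member %in% tbls$valid_alleles))
  expect_true(all(tbls$p_group_map$member %in% tbls$valid_alleles))
  # one G and one P group per allele at most
  expect_false(anyDuplicated(tbls$g_group_map$member) > 0)
  expect_false(anyDuplicated(tbls$p_group_map$member) > 0)
  # g groups contain the P groups member-wise
  for (pg in unique(tbls$p_group_map$group)) {
    members_p <- tbls$p_group_map$member[tbls$p_group_map$group == pg]
    gname <- unique(tbls$small_g_map$group[tbls$small_g_map$member %in%
      members_p])
    expect_length(gname, 1)
    expect_true(all(members_p %in%
      tbls$small_g_map$member[tbls$small_g_map$group == gname]))
  }
})

test_that("validation accepts completable designations and rejects others", {
  tbls <- fixture_tables()
  expect_true(validate_allele("A*01:01:01", tbls))
  expect_true(validate_allele("A*01:01", tbls))    # prefix completion
  expect_true(validate_allele("A*01", tbls))       # one-field completion
  expect_true(validate_allele("A*01:01:01G", tbls))
  expect_true(validate_allele("A*01:01P", tbls))
  expect_true(validate_allele("A*01:01g", tbls))
  expect_false(validate_allele("A*99:99", tbls))
  expect_false(validate_allele("Z*01:01", tbls))
  expect_false(validate_allele("not an allele", tbls))
})

test_that("MAC expansion covers the worked example and table semantics", {
  tbls <- fixture_tables()
  # the worked example: the original allele plus exactly two more
  got <- expand_mac("A*31:VSCB", tables = tbls)
  expect_setequal(got, c("A*31:01", "A*31:41", "A*31:68"))
  # singleton code
  expect_equal(expand_mac("B*07:XX", tables = tbls), "B*07:01")
  # group-spanning entries override the queried first field
  expect_setequal(expand_mac("A*02:GRP", tables = tbls),
    c("A*02:01", "A*03:01"))
  # separate locus/code calling convention agrees
  expect_equal(expand_mac("A", "31:VSCB", tables = tbls),
    expand_mac("A*31:VSCB", tables = tbls))
  expect_error(expand_mac("A*31:ZZZZ", tables = tbls),
    class = "hlafreq_input_error")
  # every expansion validates
  for (tok in c("A*31:VSCB", "B*07:XX", "A*02:GRP", "C*01:AB")) {
    expect_true(all(validate_allele(expand_mac(tok, tables = tbls), tbls)))
  }
})

test_that("translation routes through expand-then-project", {
  tbls <- fixture_tables()
  expect_equal(translate_allele("A*31:01", "g", tbls)[[1]], "A*31:01g")
  expect_setequal(translate_allele("C*16:04", "3f", tbls)[[1]],
    c("C*16:04:01", "C*16:04:03"))
  expect_equal(translate_allele("C*16:04:01", "P", tbls)[[1]], "C*16:04P")
  expect_equal(translate_allele("C*16:04", "g", tbls)[[1]], "C*16:04g")
  # a full-length allele translated to its own resolution is itself
  expect_equal(translate_allele("A*01:01:01", "3f", tbls)[[1]], "A*01:01:01")
  # a full-length 2-field designation is its own 3f/4f equivalent
  expect_equal(translate_allele("A*31:41", "4f", tbls)[[1]], "A*31:41")
  # group codes translate down to fields
  expect_setequal(translate_allele("A*01:01P", "3f", tbls)[[1]],
    c("A*01:01:01", "A*01:01:02"))
  expect_error(translate_allele("A*99:99", "g", tbls),
    class = "hlafreq_translation_error")
})

test_that("translation round trip and projection consistency hold for all alleles", {
  tbls <- fixture_tables()
  full <- tbls$valid_alleles
  for (target in c("1f", "2f", "3f", "4f", "G", "P", "g")) {
    # null alleles have no P group; their documented 2-field fallback warns
    tr <- suppressWarnings(translate_allele(full, target, tbls))
    for (i in seq_along(full)) {
      back <- unique(unlist(lapply(tr[[i]], function(x) {
        hlafreq:::expand_to_full(x, tbls)
      })))
      expect_true(full[i] %in% back,
        label = sprintf("%s -> %s -> back", full[i], target))
    }
  }
  # translate(a, 2f) equals the first two fields of a
  p <- parse_allele(full)
  two <- paste0(p$locus, "*",
    vapply(strsplit(p$fields, ":"), function(x) {
      paste(x[seq_len(min(2, length(x)))], collapse = ":")
    }, character(1)), p$suffix)
  tr2 <- translate_allele(full, "2f", tbls)
  expect_equal(unname(vapply(tr2, identity, character(1))), two)
})

test_that("the small-g map adds null alleles to their P group's g group", {
  # fixture of the defining rule: G group joins a null to the P members
  valid <- c("A*31:01:01", "A*31:01:02", "A*31:14N", "A*98:01N")
  g_map <- tibble::tibble(
    group = "A*31:01:01G",
    member = c("A*31:01:01", "A*31:01:02", "A*31:14N")
  )
  p_map <- tibble::tibble(
    group = "A*31:01P",
    member = c("A*31:01:01", "A*31:01:02")
  )
  sg <- build_small_g_map(g_map, p_map, valid)
  expect_setequal(sg$member[sg$group == "A*31:01g"],
    c("A*31:01:01", "A*31:01:02", "A*31:14N"))
  # a null in no G group forms a singleton g group of its own 2-field stem
  expect_equal(sg$member[sg$group == "A*98:01g"], "A*98:01N")
  # without nulls, g mirrors P member-wise
  sg2 <- build_small_g_map(
    g_map[g_map$member != "A*31:14N", ], p_map,
    c("A*31:01:01", "A*31:01:02")
  )
  expect_setequal(sg2$member[sg2$group == "A*31:01g"], p_map$member)
  # empty maps give an empty result
  empty <- build_small_g_map(
    tibble::tibble(group = character(), member = character()),
    tibble::tibble(group = character(), member = character()),
    character(0)
  )
  expect_equal(nrow(empty), 0)
  # a null whose G group straddles two P groups is a hard error
  g_bad <- tibble::tibble(
    group = "A*31:01:01G",
    member = c("A*31:01:01", "A*32:01:01", "A*31:14N")
  )
  p_bad <- tibble::tibble(
    group = c("A*31:01P", "A*32:01P"),
    member = c("A*31:01:01", "A*32:01:01")
  )
  expect_error(
    build_small_g_map(g_bad, p_bad,
      c("A*31:01:01", "A*32:01:01", "A*31:14N")),
    class = "hlafreq_input_error"
  )
})

test_that("GL strings expand ambiguities with conserved weights", {
  # allele ambiguity: '/' lists cross within one alternative
  g <- parse_gl_string("A*01:01/A*01:02+A*02:01")
  expect_equal(nrow(g), 2)
  expect_equal(g$weight, c(0.5, 0.5))
  expect_setequal(g$a1, c("A*01:01", "A*01:02"))
  # genotype ambiguity: '|' alternatives are equally weighted
  g2 <- parse_gl_string("A*01:01+A*02:01|A*01:03+A*02:02")
  expect_equal(nrow(g2), 2)
  expect_equal(g2$weight, c(0.5, 0.5))
  # homozygous single pair
  g3 <- parse_gl_string("A*01:01+A*01:01")
  expect_equal(nrow(g3), 1)
  expect_equal(g3$weight, 1)
  # multi-locus strings split per locus, weights sum to 1 per locus
  g4 <- parse_gl_string("A*01:01+A*02:01^B*07:02+B*08:01/B*08:02")
  sums <- as.numeric(tapply(g4$weight, g4$locus, sum))
  expect_equal(sums, rep(1, 2))
  # pair count = sum over alternatives of the product of '/' lengths
  g5 <- parse_gl_string(
    "A*01:01/A*01:02+A*02:01/A*02:02|A*03:01+A*03:01")
  expect_equal(nrow(g5), 5)
  expect_equal(sum(g5$weight), 1)
  # phase operator is rejected loudly
  expect_error(parse_gl_string("A*01:01~B*07:02+A*02:01~B*08:01"),
    "unsupported operator", class = "hlafreq_input_error")
  expect_error(parse_gl_string("A*01:01+B*07:02"),
    class = "hlafreq_input_error")
})

test_that("nomenclature files round-trip through their readers", {
  dir <- withr::local_tempdir()
  make_fixture_nomenclature(dir)
  tbls <- read_nomenclature(dir)
  expect_s3_class(tbls, "hla_nomenclature")
  expect_gt(length(tbls$valid_alleles), 0)
  # regeneration is byte-identical
  dir2 <- withr::local_tempdir()
  make_fixture_nomenclature(dir2)
  for (f in list.files(dir)) {
    expect_identical(readLines(file.path(dir, f)),
      readLines(file.path(dir2, f)), label = f)
  }
  # truncated group file errors with the offending line
  writeLines("A*E", file.path(dir, "g_groups.txt"))
  expect_error(read_nomenclature(dir), class = "hlafreq_input_error")
})
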