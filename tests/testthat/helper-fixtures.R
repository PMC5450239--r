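# Shared miniature nomenclature, built once per test session.
.fixture_env <- new.env(parent = emptyenv())

fixture_tables <- function() {
  if (is.null(.fixture_env$tables)) {
    .fixture_env$tables <- fixture_nomenclature()
  }
  .fixture_env$tables
}

test_loci <- c("A", "B", "C")

# Two-record worked example: one double heterozygote plus one double
# homozygote; the maximum-likelihood explanation puts 0.75 on A1~B1 and
# 0.25 on A2~B2.
worked_example_population <- function() {
  tibble::tibble(
    id = c("het", "hom"),
    A.1 = c("A*01:01:01", "A*01:01:01"), A.2 = c("A*02:01:01", "A*01:01:01"),
    B.1 = c("B*01:01:01", "B*01:01:01"), B.2 = c("B*02:01:01", "B*01:01:01")
  )
}

worked_example_diplotypes <- function(tbls = fixture_tables()) {
  slg <- split_mlg(worked_example_population(), tbls, format = "mac")
  slg <- translate_slg(slg, tbls, "4f")
  build_diplotypes(recombine(slg))
}

# A tiny two-locus genotype table in recombine() output shape, with
# abstract allele labels (bypasses the nomenclature; phase enumeration and
# EM do not need it).
random_resolved_genotypes <- function(seed, n_a = 3, n_b = 2, n_min = 3,
                                      n_max = 8) {
  withr::with_seed(seed, {
    A <- paste0("A", seq_len(n_a))
    B <- paste0("B", seq_len(n_b))
    n <- sample(n_min:n_max, 1)
    g <- tibble::tibble(
      id = paste0("i", seq_len(n)), count = 1L, weight = 1,
      a.A = sample(A, n, TRUE), b.A = sample(A, n, TRUE),
      a.B = sample(B, n, TRUE), b.B = sample(B, n, TRUE)
    )
    for (L in c("A", "B")) {
      lo <- pmin(g[[paste0("a.", L)]], g[[paste0("b.", L)]])
      hi <- pmax(g[[paste0("a.", L)]], g[[paste0("b.", L)]])
      g[[paste0("a.", L)]] <- lo
      g[[paste0("b.", L)]] <- hi
    }
    attr(g, "loci") <- c("A", "B")
    g
  })
}
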