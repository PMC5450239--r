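# File dialects: haplotype frequency lists (the shared interchange format),
# wide MAC-format population tables, and GL-string tables.

#' Read a haplotype frequency file
#'
#' Plain text, one `haplotype<TAB>frequency` line per haplotype; haplotypes
#' are `~`-joined alleles in canonical locus order.
#'
#' @param path File path.
#' @return A tibble with columns `haplotype`, `frequency`.
#' @export
read_haplotype_frequencies <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: '%s'", path),
      class = "hlafreq_input_error")
  }
  out <- readr::read_tsv(path, col_names = c("haplotype", "frequency"),
    col_types = readr::cols(haplotype = readr::col_character(),
      frequency = readr::col_double()),
    progress = FALSE)
  if (any(is.na(out$frequency))) {
    abort(sprintf("non-numeric frequency in '%s'", path),
      class = "hlafreq_input_error")
  }
  out
}

#' Write a haplotype frequency file
#'
#' Entries are written sorted by descending frequency, ties broken
#' lexicographically, with full double precision, so identical tables
#' produce byte-identical files.
#'
#' @param x A frequency tibble, named numeric vector or `hla_em_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_haplotype_frequencies <- function(x, path) {
  x <- as_freq_tbl(x, "frequency table")
  x <- x[order(-x$frequency, x$haplotype, method = "radix"), , drop = FALSE]
  writeLines(paste0(x$haplotype, "\t", sprintf("%.17g", x$frequency)), path)
  invisible(path)
}

#' Read a population genotype table
#'
#' `"mac"` dialect: a header with `id`, optionally `count`, and two columns
#' per locus (`A.1`, `A.2`, ...); tab- or comma-separated (sniffed). Cell
#' entries may omit the locus prefix. `"gls"` dialect: columns `id` and
#' `gl` holding one genotype list string per individual.
#'
#' @param path File path.
#' @param format `"mac"` or `"gls"`.
#' @return A tibble; for `"mac"` with attribute `loci`.
#' @export
read_population <- function(path, format = c("mac", "gls")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(sprintf("file not found: '%s'", path),
      class = "hlafreq_input_error")
  }
  first <- readr::read_lines(path, n_max = 1)
  delim <- if (stringr::str_detect(first, "\t")) "\t" else ","
  out <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE)
  if (!"id" %in% names(out)) {
    abort(sprintf("'%s' lacks an 'id' column", path),
      class = "hlafreq_input_error")
  }
  if ("count" %in% names(out)) out$count <- as.integer(out$count)
  if (format == "mac") {
    loci <- population_loci(out)
    if (length(loci) == 0) {
      abort(sprintf("'%s' has no locus column pairs (e.g. A.1/A.2)", path),
        class = "hlafreq_input_error")
    }
    structure(out, loci = loci)
  } else {
    if (!"gl" %in% names(out)) {
      abort(sprintf("'%s' lacks a 'gl' column", path),
        class = "hlafreq_input_error")
    }
    out
  }
}

#' Write a population genotype table in the MAC dialect
#'
#' @param pop A wide population tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_population_mac <- function(pop, path) {
  readr::write_tsv(pop, path, progress = FALSE)
  invisible(path)
}
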