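#' @importFrom rlang abort warn .data %||%
#' @importFrom tibble tibble as_tibble
NULL

# Expression suffixes defined by the WHO nomenclature (null, low, secreted,
# cytoplasm, aberrant, questionable).
.suffix_letters <- c("N", "L", "S", "C", "A", "Q")

# Internal, quiet parser: returns one row per input with a `problem` column
# instead of failing, so callers can choose between hard errors and
# predicate-style validation.
parse_allele_quietly <- function(x) {
  raw <- as.character(x)
  s <- stringr::str_trim(raw)
  n <- length(s)
  problem <- rep(NA_character_, n)
  problem[is.na(s) | s == ""] <- "empty designation"

  # the small-g group marker is the only case-sensitive token; detect it
  # before upper-casing everything else ("A*31:01 g" and "A*31:01g" are
  # both accepted)
  has_g <- !is.na(s) & stringr::str_detect(s, " ?g$")
  core <- ifelse(has_g, stringr::str_remove(s, " ?g$"), s)
  core <- toupper(core)

  m <- stringr::str_match(core, "^([A-Z][A-Z0-9]{0,9})\\*(.+)$")
  locus <- m[, 2]
  rest <- m[, 3]
  problem[is.na(problem) & is.na(locus)] <- "missing locus or '*' separator"

  marker <- ifelse(has_g, "g", "")
  endG <- !is.na(rest) & stringr::str_detect(rest, "[0-9]G$")
  endP <- !is.na(rest) & stringr::str_detect(rest, "[0-9]P$")
  problem[is.na(problem) & (endG | endP) & marker == "g"] <-
    "conflicting group markers"
  marker[endG & marker == ""] <- "G"
  marker[endP & marker == ""] <- "P"
  rest <- ifelse((endG | endP), stringr::str_sub(rest, 1, -2L), rest)

  suffix <- rep("", n)
  suf_re <- paste0("[0-9][", paste(.suffix_letters, collapse = ""), "]$")
  has_suf <- !is.na(rest) & stringr::str_detect(rest, suf_re)
  suffix[has_suf] <- stringr::str_sub(rest[has_suf], -1L)
  rest <- ifelse(has_suf, stringr::str_sub(rest, 1, -2L), rest)

  ok_fields <- !is.na(rest) &
    stringr::str_detect(rest, "^[0-9]{1,4}(:[0-9]{1,4}){0,3}$")
  problem[is.na(problem) & !ok_fields] <-
    "fields must be 1-4 colon-separated digit groups (no empty fields)"

  n_fields <- ifelse(ok_fields, stringr::str_count(rest, ":") + 1L, NA_integer_)

  problem[is.na(problem) & marker == "G" & n_fields != 3L] <-
    "G group codes carry exactly 3 fields"
  problem[is.na(problem) & marker == "P" & n_fields != 2L] <-
    "P group codes carry exactly 2 fields"
  problem[is.na(problem) & marker == "g" & n_fields != 2L] <-
    "g group codes carry exactly 2 fields"
  problem[is.na(problem) & marker != "" & suffix != ""] <-
    "group codes cannot carry an expression suffix"

  bad <- !is.na(problem)
  allele <- ifelse(bad, NA_character_,
    paste0(locus, "*", rest, suffix, marker))
  tibble(
    input = raw,
    allele = allele,
    locus = ifelse(bad, NA_character_, locus),
    fields = ifelse(bad, NA_character_, rest),
    n_fields = ifelse(bad, NA_integer_, n_fields),
    suffix = ifelse(bad, NA_character_, suffix),
    marker = ifelse(bad, NA_character_, marker),
    problem = problem
  )
}

#' Parse HLA allele designations
#'
#' Splits designations of the form `locus*f1:f2[:f3[:f4]][suffix][marker]`
#' into their components: locus, up to four numeric fields (leading zeros
#' preserved), an optional expression suffix (N, L, S, C, A, Q) and an
#' optional allele-group marker (`G`, `P`, or lower-case `g`; the g marker is
#' accepted with or without a preceding space and rendered without one).
#'
#' @param x Character vector of allele designations.
#' @return A tibble with one row per input and columns `input`, `allele`
#'   (canonical rendering), `locus`, `fields` (colon-joined), `n_fields`,
#'   `suffix` and `marker`. Re-parsing the `allele` column is the identity.
#' @examples
#' parse_allele(c("C*16:04:01", "A*31:01 g", "B*07:02P"))
#' @export
parse_allele <- function(x) {
  out <- parse_allele_quietly(x)
  bad <- !is.na(out$problem)
  if (any(bad)) {
    i <- which(bad)[1]
    abort(
      sprintf(
        "malformed allele designation '%s': %s%s",
        out$input[i], out$problem[i],
        if (sum(bad) > 1) sprintf(" (and %d more)", sum(bad) - 1L) else ""
      ),
      class = "hlafreq_parse_error"
    )
  }
  out$problem <- NULL
  out
}

#' Render parsed allele components back to designation strings
#'
#' @param parsed A tibble as returned by [parse_allele()] (columns `locus`,
#'   `fields`, `suffix`, `marker`).
#' @return Character vector of canonical designations.
#' @export
format_allele <- function(parsed) {
  paste0(parsed$locus, "*", parsed$fields, parsed$suffix, parsed$marker)
}

# Truncate colon-joined field strings to at most `k` fields.
truncate_fields <- function(fields, k) {
  parts <- stringr::str_split(fields, stringr::fixed(":"))
  vapply(parts, function(p) paste(p[seq_len(min(length(p), k))], collapse = ":"),
    character(1))
}

# Canonical unordered allele pair: returns list(a, b) with a <= b.
pair_canonical <- function(a, b) {
  list(a = pmin(a, b), b = pmax(a, b))
}

# Canonical pair key "a|b" with a <= b.
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}
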