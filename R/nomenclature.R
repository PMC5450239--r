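# Nomenclature tables: allele validity list, G/P group maps, the derived
# small-g map, the locus-independent multiple-allele-code (MAC) table and an
# optional table of indistinguishable allele pairs.

#' Read an allele validity list
#'
#' One full-length designation per line (with locus prefix); blank lines and
#' lines starting with `#` are ignored.
#'
#' @param path Path to the allele list file.
#' @return Character vector of canonical designations.
#' @export
read_allele_list <- function(path) {
  lines <- readr::read_lines(path)
  lines <- stringr::str_trim(lines)
  lines <- lines[lines != "" & !stringr::str_starts(lines, "#")]
  parse_allele(lines)$allele
}

#' Read a G- or P-group file
#'
#' Semicolon-separated lines `locus*;member/member/...;GROUPCODE`. Members are
#' written without the locus prefix; lines with an empty group code describe
#' alleles outside any group and are skipped.
#'
#' @param path Path to the group file.
#' @return A tibble with columns `group` and `member` (canonical designations).
#' @export
read_group_file <- function(path) {
  lines <- readr::read_lines(path)
  lines <- stringr::str_trim(lines)
  lines <- lines[lines != "" & !stringr::str_starts(lines, "#")]
  if (length(lines) == 0) {
    return(tibble(group = character(), member = character()))
  }
  parts <- stringr::str_split(lines, stringr::fixed(";"))
  bad <- which(lengths(parts) < 2)
  if (length(bad) > 0) {
    abort(
      sprintf("malformed group file line %d in '%s': '%s'",
        bad[1], path, lines[bad[1]]),
      class = "hlafreq_input_error"
    )
  }
  purrr::map_dfr(seq_along(parts), function(i) {
    p <- parts[[i]]
    code <- if (length(p) >= 3) stringr::str_trim(p[3]) else ""
    if (code == "") {
      return(tibble(group = character(), member = character()))
    }
    locus <- stringr::str_remove(stringr::str_trim(p[1]), "\\*$")
    members <- stringr::str_split(stringr::str_trim(p[2]), stringr::fixed("/"))[[1]]
    members <- members[members != ""]
    if (length(members) == 0) {
      abort(
        sprintf("group file line %d in '%s' has no members", i, path),
        class = "hlafreq_input_error"
      )
    }
    tibble(
      group = parse_allele(paste0(locus, "*", code))$allele,
      member = parse_allele(paste0(locus, "*", members))$allele
    )
  })
}

#' Read a multiple-allele-code (MAC) table
#'
#' Tab-separated lines `CODE<TAB>members` with an optional `*` flag column
#' (`CODE<TAB>*<TAB>members`) marking group-spanning codes. Members are
#' slash-separated; plain members are second fields completing the queried
#' first field, members containing `:` carry their own first field and
#' override the query's (group-spanning entries).
#'
#' @param path Path to the MAC table file.
#' @return A tibble with columns `code`, `members` (list of character) and
#'   `spanning` (logical).
#' @export
read_mac_table <- function(path) {
  lines <- readr::read_lines(path)
  lines <- stringr::str_trim(lines)
  lines <- lines[lines != "" & !stringr::str_starts(lines, "#")]
  if (length(lines) == 0) {
    return(tibble(code = character(), members = list(), spanning = logical()))
  }
  parts <- stringr::str_split(lines, "\t")
  purrr::map_dfr(seq_along(parts), function(i) {
    p <- stringr::str_trim(parts[[i]])
    p <- p[p != ""]
    if (length(p) < 2 || length(p) > 3 || (length(p) == 3 && p[2] != "*")) {
      abort(
        sprintf("malformed MAC table line %d in '%s': '%s'",
          i, path, lines[i]),
        class = "hlafreq_input_error"
      )
    }
    code <- toupper(p[1])
    members <- stringr::str_split(p[length(p)], stringr::fixed("/"))[[1]]
    members <- members[members != ""]
    if (!stringr::str_detect(code, "^[A-Z]{2,5}$")) {
      abort(
        sprintf("invalid MAC code '%s' on line %d of '%s'", p[1], i, path),
        class = "hlafreq_input_error"
      )
    }
    spanning <- length(p) == 3 || any(stringr::str_detect(members, ":"))
    tibble(code = code, members = list(members), spanning = spanning)
  })
}

#' Read an ambiguity-pair table
#'
#' Tab-separated lines holding two allele designations per line; each line
#' names one unordered allele pair that a typing chemistry cannot
#' distinguish.
#'
#' @param path Path to the pair table.
#' @return A tibble with columns `a1`, `a2` (canonical, `a1 <= a2`).
#' @export
read_ambiguity_pairs <- function(path) {
  lines <- readr::read_lines(path)
  lines <- stringr::str_trim(lines)
  lines <- lines[lines != "" & !stringr::str_starts(lines, "#")]
  if (length(lines) == 0) {
    return(tibble(a1 = character(), a2 = character()))
  }
  parts <- stringr::str_split(lines, "\t")
  bad <- which(lengths(parts) != 2)
  if (length(bad) > 0) {
    abort(
      sprintf("malformed ambiguity-pair line %d in '%s'", bad[1], path),
      class = "hlafreq_input_error"
    )
  }
  a <- parse_allele(vapply(parts, `[`, character(1), 1))$allele
  b <- parse_allele(vapply(parts, `[`, character(1), 2))$allele
  pc <- pair_canonical(a, b)
  dplyr::distinct(tibble(a1 = pc$a, a2 = pc$b))
}

#' Derive the small-g group map from G and P groups
#'
#' g groups mirror P groups but additionally contain null alleles: one g
#' group is formed per P group, named by the P group's two-field stem plus a
#' lower-case `g`; its members are the P-group members plus every null allele
#' that shares a G group with any member. Null alleles in no such G group
#' form singleton g groups named by their own two-field stem.
#'
#' @param g_group_map,p_group_map Tibbles with columns `group`, `member`.
#' @param valid_alleles Character vector of all full-length designations.
#' @return A tibble with columns `group`, `member`.
#' @export
build_small_g_map <- function(g_group_map, p_group_map, valid_alleles) {
  if (nrow(p_group_map) == 0 && length(valid_alleles) == 0) {
    return(tibble(group = character(), member = character()))
  }
  p_parsed <- parse_allele(unique(p_group_map$group))
  g_name_of_p <- stats::setNames(
    paste0(p_parsed$locus, "*", p_parsed$fields, "g"),
    p_parsed$allele
  )
  out <- tibble(
    group = unname(g_name_of_p[p_group_map$group]),
    member = p_group_map$member
  )

  nulls <- valid_alleles[stringr::str_detect(valid_alleles, "N$")]
  member2p <- stats::setNames(p_group_map$group, p_group_map$member)
  g_of <- split(g_group_map$group, g_group_map$member)
  assigned <- character(0)
  extra <- list()
  for (nu in nulls) {
    ggs <- g_of[[nu]]
    target <- character(0)
    if (!is.null(ggs)) {
      for (gg in unique(ggs)) {
        mem <- g_group_map$member[g_group_map$group == gg]
        pg <- unique(stats::na.omit(unname(member2p[mem])))
        if (length(pg) > 0) target <- union(target, unname(g_name_of_p[pg]))
      }
    }
    if (length(target) > 1) {
      abort(
        sprintf(
          "null allele '%s' would join several g groups (%s)",
          nu, paste(target, collapse = ", ")
        ),
        class = "hlafreq_input_error"
      )
    }
    if (length(target) == 1) {
      extra[[length(extra) + 1]] <- tibble(group = target, member = nu)
    } else {
      p <- parse_allele(nu)
      stem <- paste0(p$locus, "*", truncate_fields(p$fields, 2), "g")
      extra[[length(extra) + 1]] <- tibble(group = stem, member = nu)
    }
  }
  out <- dplyr::distinct(dplyr::bind_rows(out, extra))
  dup <- out$member[duplicated(out$member)]
  if (length(dup) > 0) {
    abort(
      sprintf("allele(s) assigned to more than one g group: %s",
        paste(unique(dup), collapse = ", ")),
      class = "hlafreq_input_error"
    )
  }
  out
}

#' Assemble nomenclature tables
#'
#' Builds the translation oracle used by all preprocessing steps from its
#' component tables (typically read with [read_allele_list()],
#' [read_group_file()], [read_mac_table()] and [read_ambiguity_pairs()], or
#' produced by [make_fixture_nomenclature()]).
#'
#' @param valid_alleles Character vector of full-length designations.
#' @param g_group_map,p_group_map Tibbles with columns `group`, `member`.
#' @param mac_table Tibble with columns `code`, `members`, `spanning`.
#' @param ambiguity_pairs Optional tibble with columns `a1`, `a2`.
#' @return An object of class `hla_nomenclature`.
#' @export
nomenclature_tables <- function(valid_alleles, g_group_map, p_group_map,
                                mac_table = NULL, ambiguity_pairs = NULL) {
  valid_alleles <- unique(parse_allele(valid_alleles)$allele)
  g_group_map <- dplyr::distinct(g_group_map)
  p_group_map <- dplyr::distinct(p_group_map)
  mac_table <- mac_table %||%
    tibble(code = character(), members = list(), spanning = logical())
  ambiguity_pairs <- ambiguity_pairs %||% tibble(a1 = character(), a2 = character())

  missing_members <- setdiff(
    c(g_group_map$member, p_group_map$member), valid_alleles
  )
  if (length(missing_members) > 0) {
    abort(
      sprintf("group member(s) absent from the allele list: %s",
        paste(utils::head(missing_members, 5), collapse = ", ")),
      class = "hlafreq_input_error"
    )
  }
  for (nm in c("g_group_map", "p_group_map")) {
    map <- get(nm)
    dup <- map$member[duplicated(map$member)]
    if (length(dup) > 0) {
      abort(
        sprintf("allele(s) in more than one %s: %s",
          if (nm == "g_group_map") "G group" else "P group",
          paste(unique(dup), collapse = ", ")),
        class = "hlafreq_input_error"
      )
    }
  }

  small_g_map <- build_small_g_map(g_group_map, p_group_map, valid_alleles)

  parsed <- parse_allele(valid_alleles)
  for (k in 1:4) {
    parsed[[paste0("t", k)]] <- truncate_fields(parsed$fields, k)
  }

  obj <- list(
    valid_alleles = valid_alleles,
    valid_parsed = parsed,
    g_group_map = g_group_map,
    p_group_map = p_group_map,
    small_g_map = small_g_map,
    mac_table = mac_table,
    ambiguity_pairs = ambiguity_pairs,
    member_to_g = stats::setNames(g_group_map$group, g_group_map$member),
    member_to_p = stats::setNames(p_group_map$group, p_group_map$member),
    member_to_small_g = stats::setNames(small_g_map$group, small_g_map$member),
    small_g_members = split(small_g_map$member, small_g_map$group),
    g_members = split(g_group_map$member, g_group_map$group),
    p_members = split(p_group_map$member, p_group_map$group),
    mac_members = stats::setNames(mac_table$members, mac_table$code),
    ambiguity_keys = pair_key(ambiguity_pairs$a1, ambiguity_pairs$a2),
    cache = new.env(parent = emptyenv())
  )
  class(obj) <- "hla_nomenclature"
  obj
}

#' @export
print.hla_nomenclature <- function(x, ...) {
  cat("<hla_nomenclature>\n")
  cat("  loci:          ", paste(sort(unique(x$valid_parsed$locus)),
    collapse = ", "), "\n")
  cat("  valid alleles: ", length(x$valid_alleles), "\n")
  cat("  G groups:      ", length(x$g_members), "\n")
  cat("  P groups:      ", length(x$p_members), "\n")
  cat("  g groups:      ", length(x$small_g_members), "\n")
  cat("  MAC codes:     ", nrow(x$mac_table), "\n")
  cat("  ambiguity pairs:", nrow(x$ambiguity_pairs), "\n")
  invisible(x)
}

#' Read nomenclature tables from a directory of raw files
#'
#' Expects `alleles.txt`, `g_groups.txt`, `p_groups.txt`, `mac_table.txt`
#' and (optionally) `ambiguity_pairs.txt` in the dialects documented on the
#' individual readers; [make_fixture_nomenclature()] writes this layout.
#'
#' @param dir Directory holding the raw files.
#' @return An `hla_nomenclature` object.
#' @export
read_nomenclature <- function(dir) {
  pth <- function(f) file.path(dir, f)
  for (f in c("alleles.txt", "g_groups.txt", "p_groups.txt", "mac_table.txt")) {
    if (!file.exists(pth(f))) {
      abort(sprintf("nomenclature file '%s' not found in '%s'", f, dir),
        class = "hlafreq_input_error")
    }
  }
  ambig <- if (file.exists(pth("ambiguity_pairs.txt"))) {
    read_ambiguity_pairs(pth("ambiguity_pairs.txt"))
  } else {
    NULL
  }
  nomenclature_tables(
    valid_alleles = read_allele_list(pth("alleles.txt")),
    g_group_map = read_group_file(pth("g_groups.txt")),
    p_group_map = read_group_file(pth("p_groups.txt")),
    mac_table = read_mac_table(pth("mac_table.txt")),
    ambiguity_pairs = ambig
  )
}

# Full-length completions of a parsed partial designation at its locus:
# all valid alleles whose truncation to the query's field count equals the
# query (suffix must agree when the query carries one).
completions_of <- function(locus, fields, n_fields, suffix, tables) {
  vp <- tables$valid_parsed
  hit <- vp$locus == locus & vp[[paste0("t", n_fields)]] == fields
  if (suffix != "") hit <- hit & vp$suffix == suffix
  vp$allele[hit]
}

# Expand any designation (full, partial, or G/P/g code) to the full-length
# alleles compatible with it. Returns character(0) when nothing matches.
expand_to_full <- function(allele, tables) {
  key <- paste0("F|", allele)
  hit <- tables$cache[[key]]
  if (!is.null(hit)) return(hit)
  p <- parse_allele_quietly(allele)
  res <- if (!is.na(p$problem[1])) {
    character(0)
  } else if (p$marker[1] == "G") {
    tables$g_members[[p$allele[1]]] %||% character(0)
  } else if (p$marker[1] == "P") {
    tables$p_members[[p$allele[1]]] %||% character(0)
  } else if (p$marker[1] == "g") {
    members <- tables$small_g_members[[p$allele[1]]]
    if (is.null(members)) {
      # g designations formed from a 2-field stem (alleles outside any P
      # group translate to stem + "g"): expand the stem and keep the full
      # alleles whose g translation is this designation
      comp <- completions_of(p$locus[1], p$fields[1], p$n_fields[1], "",
        tables)
      members <- comp[project_full(comp, "g", tables) == p$allele[1]]
    }
    members
  } else {
    completions_of(p$locus[1], p$fields[1], p$n_fields[1], p$suffix[1], tables)
  }
  assign(key, res, envir = tables$cache)
  res
}

#' Check allele designations against the nomenclature
#'
#' A designation is valid if it is a known group code (G/P/g) or if at least
#' one full-length allele in the validity list completes it (a full-length
#' designation completes itself). Malformed strings are reported as invalid
#' rather than raising a parse error.
#'
#' @param x Character vector of designations.
#' @param tables An `hla_nomenclature` object.
#' @return Logical vector.
#' @export
validate_allele <- function(x, tables) {
  vapply(as.character(x), function(a) length(expand_to_full(a, tables)) > 0,
    logical(1), USE.NAMES = FALSE)
}

#' Expand a multiple allele code (MAC)
#'
#' Expands a designation of the form `locus*firstfield:CODE` to the set of
#' two-field designations the code stands for at that locus. Plain table
#' members complete the queried first field; members carrying their own
#' first field (group-spanning codes) override it. Members that do not
#' validate at the queried locus are dropped; if none validates, an error is
#' raised.
#'
#' @param x A MAC designation such as `"A*31:VSCB"`, or a locus when `code`
#'   is given separately.
#' @param code Optional `firstfield:CODE` part when `x` is just the locus.
#' @param tables An `hla_nomenclature` object.
#' @return Character vector of two-field designations.
#' @examples
#' \dontrun{expand_mac("A*31:VSCB", tables = tbls)}
#' @export
expand_mac <- function(x, code = NULL, tables) {
  token <- if (is.null(code)) x else paste0(x, "*", code)
  m <- stringr::str_match(
    toupper(stringr::str_trim(token)),
    "^([A-Z][A-Z0-9]{0,9})\\*([0-9]{1,4}):([A-Z]{2,5})$"
  )
  if (is.na(m[1, 1])) {
    abort(sprintf("not a multiple-allele-code designation: '%s'", token),
      class = "hlafreq_parse_error")
  }
  locus <- m[1, 2]
  first <- m[1, 3]
  letters <- m[1, 4]
  members <- tables$mac_members[[letters]]
  if (is.null(members)) {
    abort(sprintf("unknown multiple allele code '%s'", letters),
      class = "hlafreq_input_error")
  }
  two_field <- ifelse(
    stringr::str_detect(members, ":"),
    paste0(locus, "*", members),
    paste0(locus, "*", first, ":", members)
  )
  two_field <- parse_allele(two_field)$allele
  ok <- validate_allele(two_field, tables)
  if (!any(ok)) {
    abort(
      sprintf("MAC '%s' expands to no valid allele at locus %s (tried: %s)",
        token, locus, paste(two_field, collapse = ", ")),
      class = "hlafreq_input_error"
    )
  }
  unique(two_field[ok])
}

# Is this token a MAC designation (letters code after the first field)?
is_mac_token <- function(x) {
  stringr::str_detect(
    toupper(stringr::str_trim(x)),
    "^([A-Z][A-Z0-9]{0,9}\\*)?[0-9]{1,4}:[A-Z]{2,5}$"
  )
}

# Project full-length alleles onto a target resolution. Vectorized over
# `full`. Fallbacks when an allele is in no group: G -> the allele itself;
# P -> its two-field name (nulls have no P group by definition); g -> its
# two-field stem + "g".
project_full <- function(full, target, tables) {
  if (target %in% c("1f", "2f", "3f", "4f")) {
    k <- as.integer(substr(target, 1, 1))
    p <- parse_allele(full)
    return(paste0(p$locus, "*", truncate_fields(p$fields, k), p$suffix))
  }
  if (target == "G") {
    grp <- unname(tables$member_to_g[full])
    return(ifelse(is.na(grp), full, grp))
  }
  if (target == "P") {
    grp <- unname(tables$member_to_p[full])
    miss <- is.na(grp)
    if (any(miss)) {
      p <- parse_allele(full[miss])
      stem <- paste0(p$locus, "*", truncate_fields(p$fields, 2), p$suffix)
      if (any(p$suffix == "N")) {
        warn(
          sprintf(
            "null allele(s) without P group mapped to their 2-field name: %s",
            paste(unique(p$allele[p$suffix == "N"]), collapse = ", ")
          ),
          class = "hlafreq_translation_warning"
        )
      }
      grp[miss] <- stem
    }
    return(grp)
  }
  if (target == "g") {
    grp <- unname(tables$member_to_small_g[full])
    miss <- is.na(grp)
    if (any(miss)) {
      p <- parse_allele(full[miss])
      grp[miss] <- paste0(p$locus, "*", truncate_fields(p$fields, 2), "g")
    }
    return(grp)
  }
  abort(sprintf("unknown target resolution '%s'", target),
    class = "hlafreq_config_error")
}

.resolutions <- c("1f", "2f", "3f", "4f", "G", "P", "g")

#' Translate allele designations between resolutions and allele groups
#'
#' The canonical route is expand-then-project: each designation is expanded
#' to all compatible full-length alleles, each of which is mapped to the
#' target (field truncation for `1f`/`2f`/`3f`/`4f`, group lookup for
#' `G`/`P`/`g`), and the results are deduplicated. A two-field designation
#' that is already full length is its own three- and four-field equivalent.
#' Expansion never weights its results; equal weighting across a
#' translation's outcomes is applied by the preprocessing caller.
#'
#' @param x Character vector of designations.
#' @param target One of `"1f"`, `"2f"`, `"3f"`, `"4f"`, `"G"`, `"P"`, `"g"`.
#' @param tables An `hla_nomenclature` object.
#' @return A named list (one element per input) of character vectors.
#' @examples
#' \dontrun{translate_allele("A*31:01", "g", tbls)}
#' @export
translate_allele <- function(x, target, tables) {
  target <- match.arg(target, .resolutions)
  out <- lapply(as.character(x), function(a) {
    key <- paste0("T", target, "|", a)
    hit <- tables$cache[[key]]
    if (!is.null(hit)) return(hit)
    full <- expand_to_full(a, tables)
    if (length(full) == 0) {
      abort(sprintf("cannot translate unknown allele designation '%s'", a),
        class = "hlafreq_translation_error")
    }
    res <- sort(unique(project_full(full, target, tables)), method = "radix")
    assign(key, res, envir = tables$cache)
    res
  })
  stats::setNames(out, as.character(x))
}

#' Parse a genotype list (GL) string into per-locus genotypes
#'
#' Supports the locus separator `^`, genotype-ambiguity separator `|`, the
#' chromosome separator `+` and allele-ambiguity lists with `/`. Within one
#' `|` alternative the `/` lists on the two chromosomes are combined by
#' Cartesian product; alternatives are equally weighted and the pairs inside
#' one alternative split its weight equally. The multi-locus phase operator
#' `~` is rejected: the pipeline is locus-independent after splitting, so
#' cross-locus phase assertions cannot be honored.
#'
#' @param text A single GL string.
#' @param tables Optional `hla_nomenclature` object; when supplied, alleles
#'   are checked for validity.
#' @return A tibble with columns `locus`, `a1`, `a2`, `weight`; weights sum
#'   to 1 within each locus.
#' @examples
#' parse_gl_string("A*01:01/A*01:02+A*02:01")
#' @export
parse_gl_string <- function(text, tables = NULL) {
  stopifnot(length(text) == 1)
  text <- stringr::str_trim(text)
  if (stringr::str_detect(text, stringr::fixed("~"))) {
    abort(
      "unsupported operator '~' (multi-locus phase) in GL string",
      class = "hlafreq_input_error"
    )
  }
  blocks <- stringr::str_split(text, stringr::fixed("^"))[[1]]
  out <- purrr::map_dfr(blocks, function(block) {
    alts <- stringr::str_split(block, stringr::fixed("|"))[[1]]
    n_alt <- length(alts)
    rows <- purrr::map_dfr(alts, function(alt) {
      sides <- stringr::str_split(alt, stringr::fixed("+"))[[1]]
      if (length(sides) != 2) {
        abort(
          sprintf("GL alternative '%s' must contain exactly one '+'", alt),
          class = "hlafreq_input_error"
        )
      }
      l1 <- parse_allele(stringr::str_split(sides[1], stringr::fixed("/"))[[1]])
      l2 <- parse_allele(stringr::str_split(sides[2], stringr::fixed("/"))[[1]])
      grid <- tidyr::expand_grid(a1 = l1$allele, a2 = l2$allele)
      pc <- pair_canonical(grid$a1, grid$a2)
      tibble(a1 = pc$a, a2 = pc$b, weight = 1 / (n_alt * nrow(grid)))
    })
    loci <- unique(parse_allele(c(rows$a1, rows$a2))$locus)
    if (length(loci) != 1) {
      abort(
        sprintf("GL block '%s' mixes loci: %s", block,
          paste(loci, collapse = ", ")),
        class = "hlafreq_input_error"
      )
    }
    rows <- dplyr::summarise(
      dplyr::group_by(rows, .data$a1, .data$a2),
      weight = sum(.data$weight), .groups = "drop"
    )
    dplyr::bind_cols(tibble(locus = loci), rows)
  })
  if (!is.null(tables)) {
    alleles <- unique(c(out$a1, out$a2))
    ok <- validate_allele(alleles, tables)
    if (!all(ok)) {
      abort(
        sprintf("GL string contains unknown allele(s): %s",
          paste(alleles[!ok], collapse = ", ")),
        class = "hlafreq_input_error"
      )
    }
  }
  out
}
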