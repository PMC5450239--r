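# Preprocessing: raw individual records -> weighted single-locus genotypes
# (SLGs) -> uniformly resolved multi-locus genotypes -> candidate diplotypes.
#
# All stages work on long tibbles with columns
#   id, count, locus, a1, a2, weight
# where (a1, a2) is an unordered pair (a1 <= a2), weights sum to 1 within
# (id, locus), and `count` is the record's integer multiplicity.

# Locus columns of a wide genotype table: pairs like A.1/A.2 (or A_1/A_2).
population_loci <- function(data) {
  nm <- names(data)
  cand <- stringr::str_match(nm, "^(.+)[._]([12])$")
  loci <- unique(stats::na.omit(cand[, 2]))
  loci[vapply(loci, function(l) {
    all(paste0(l, ".", 1:2) %in% nm) || all(paste0(l, "_", 1:2) %in% nm)
  }, logical(1))]
}

locus_cols <- function(data, locus) {
  nm <- names(data)
  dot <- paste0(locus, ".", 1:2)
  if (all(dot %in% nm)) dot else paste0(locus, "_", 1:2)
}

# Candidate alleles for one raw cell entry: a plain designation gives a
# singleton, a MAC designation is expanded. The locus prefix is prepended
# when absent. Returns character(0) with attribute "reason" on failure.
cell_candidates <- function(cell, locus, tables) {
  cell <- stringr::str_trim(cell)
  if (is.na(cell) || cell == "") {
    return(structure(character(0), reason = "missing typing"))
  }
  if (!stringr::str_detect(cell, stringr::fixed("*"))) {
    cell <- paste0(locus, "*", cell)
  }
  if (is_mac_token(cell)) {
    res <- tryCatch(expand_mac(cell, tables = tables), error = function(e) e)
    if (inherits(res, "error")) {
      return(structure(character(0), reason = conditionMessage(res)))
    }
    return(res)
  }
  p <- parse_allele_quietly(cell)
  if (!is.na(p$problem[1])) {
    return(structure(character(0),
      reason = sprintf("'%s': %s", cell, p$problem[1])))
  }
  if (!validate_allele(p$allele[1], tables)) {
    return(structure(character(0),
      reason = sprintf("unknown allele '%s'", p$allele[1])))
  }
  p$allele[1]
}

#' Split raw records into weighted single-locus genotypes
#'
#' Each multi-locus genotype record is split into one genotype per locus.
#' In `"mac"` format, cell entries may be plain designations (any
#' resolution, G/P/g codes included) or NMDP multiple allele codes, which
#' are expanded; allele lists at the two positions are combined by Cartesian
#' product with equal weights. In `"gls"` format the `gl` column is parsed
#' as a genotype list string. Records containing an invalid allele, or
#' missing a configured locus, are dropped and reported.
#'
#' @param data A tibble: for `"mac"` an `id` column plus two columns per
#'   locus (`A.1`, `A.2`, ...) and an optional integer `count`; for `"gls"`
#'   columns `id` and `gl` (optional `count`).
#' @param tables An `hla_nomenclature` object.
#' @param format `"mac"` or `"gls"`.
#' @param loci Loci to keep, in canonical order; defaults to those present.
#' @param strict Abort on the first bad record instead of dropping it.
#' @return A long SLG tibble (`id`, `count`, `locus`, `a1`, `a2`, `weight`)
#'   with attributes `loci` and `rejected` (tibble of `id`, `reason`).
#' @export
split_mlg <- function(data, tables, format = c("mac", "gls"), loci = NULL,
                      strict = FALSE) {
  format <- match.arg(format)
  if (!"id" %in% names(data)) {
    abort("input must contain an 'id' column", class = "hlafreq_input_error")
  }
  if (anyDuplicated(data$id)) {
    abort("duplicate record ids in input", class = "hlafreq_input_error")
  }
  count <- if ("count" %in% names(data)) as.integer(data$count) else
    rep(1L, nrow(data))
  if (any(is.na(count) | count < 1)) {
    abort("record multiplicities must be positive integers",
      class = "hlafreq_input_error")
  }

  if (format == "mac") {
    found <- population_loci(data)
    loci <- loci %||% found
    if (length(loci) == 0) {
      abort("no locus columns (e.g. A.1/A.2) found",
        class = "hlafreq_input_error")
    }
    missing_cols <- setdiff(loci, found)
    if (length(missing_cols) > 0) {
      abort(sprintf("locus column pair missing for: %s",
        paste(missing_cols, collapse = ", ")), class = "hlafreq_input_error")
    }
    rows <- vector("list", length(loci))
    reject <- new.env(parent = emptyenv())
    for (li in seq_along(loci)) {
      locus <- loci[li]
      cols <- locus_cols(data, locus)
      c1 <- as.character(data[[cols[1]]])
      c2 <- as.character(data[[cols[2]]])
      c1[is.na(c1)] <- ""
      c2[is.na(c2)] <- ""
      # expand each distinct cell once (cells repeat heavily in registry and
      # simulated data)
      ucells <- unique(c(c1, c2))
      cand <- lapply(ucells, cell_candidates, locus = locus, tables = tables)
      l1 <- cand[match(c1, ucells)]
      l2 <- cand[match(c2, ucells)]
      n1 <- lengths(l1)
      n2 <- lengths(l2)
      bad <- which(n1 == 0 | n2 == 0)
      for (i in bad) {
        reason <- attr(if (n1[i] == 0) l1[[i]] else l2[[i]], "reason")
        msg <- sprintf("locus %s: %s", locus, reason)
        if (strict) {
          abort(sprintf("record '%s': %s", data$id[i], msg),
            class = "hlafreq_input_error")
        }
        assign(as.character(data$id[i]), msg, envir = reject)
      }
      ok <- which(n1 > 0 & n2 > 0)
      reps <- n1[ok] * n2[ok]
      a1 <- unlist(purrr::map2(l1[ok], n2[ok], function(x, m) rep(x, each = m)),
        use.names = FALSE)
      a2 <- unlist(purrr::map2(l2[ok], n1[ok], function(y, k) rep(y, times = k)),
        use.names = FALSE)
      pc <- pair_canonical(a1, a2)
      part <- tibble(
        id = rep(data$id[ok], reps),
        count = rep(count[ok], reps),
        locus = locus,
        a1 = pc$a, a2 = pc$b,
        weight = rep(1 / reps, reps)
      )
      rows[[li]] <- dplyr::summarise(
        dplyr::group_by(part, .data$id, .data$count, .data$locus,
          .data$a1, .data$a2),
        weight = sum(.data$weight), .groups = "drop"
      )
    }
    slg <- dplyr::bind_rows(rows)
    slg <- dplyr::select(slg, "id", "count", "locus", "a1", "a2", "weight")
  } else {
    if (!"gl" %in% names(data)) {
      abort("GLS input must contain a 'gl' column",
        class = "hlafreq_input_error")
    }
    reject <- new.env(parent = emptyenv())
    per_rec <- purrr::map(seq_len(nrow(data)), function(i) {
      res <- tryCatch(parse_gl_string(data$gl[i], tables),
        error = function(e) e)
      if (inherits(res, "error")) {
        if (strict) {
          abort(sprintf("record '%s': %s", data$id[i], conditionMessage(res)),
            class = "hlafreq_input_error")
        }
        assign(as.character(data$id[i]), conditionMessage(res), envir = reject)
        return(NULL)
      }
      dplyr::bind_cols(tibble(id = data$id[i], count = count[i]), res)
    })
    slg <- dplyr::bind_rows(per_rec)
    loci <- loci %||% unique(slg$locus)
    slg <- dplyr::filter(slg, .data$locus %in% loci)
    slg <- dplyr::select(slg, "id", "count", "locus", "a1", "a2", "weight")
  }

  rejected_ids <- ls(reject)
  # a record rejected at any locus is dropped entirely, as are records not
  # covering every configured locus (default missing-locus policy: drop)
  if (length(rejected_ids) > 0) {
    slg <- dplyr::filter(slg, !(as.character(.data$id) %in% rejected_ids))
  }
  cover <- dplyr::summarise(dplyr::group_by(slg, .data$id),
    n_loci = dplyr::n_distinct(.data$locus), .groups = "drop")
  incomplete <- cover$id[cover$n_loci < length(loci)]
  if (length(incomplete) > 0) {
    if (strict) {
      abort(sprintf("record '%s' does not cover all configured loci",
        incomplete[1]), class = "hlafreq_input_error")
    }
    slg <- dplyr::filter(slg, !(.data$id %in% incomplete))
    for (i in incomplete) {
      assign(as.character(i), "does not cover all configured loci",
        envir = reject)
    }
  }
  rejected <- tibble(
    id = ls(reject),
    reason = vapply(ls(reject), get, character(1), envir = reject)
  )
  structure(slg, loci = loci, rejected = rejected)
}

#' Apply the Sanger implicit-ambiguity filter to SLG pairs
#'
#' Keeps only allele pairs listed as indistinguishable in the nomenclature's
#' ambiguity-pair table, plus homozygous pairs of listed alleles. If no pair
#' of an SLG survives, that SLG falls back to its unfiltered pair set with a
#' warning. Weights are renormalized per SLG. The filter is advisory: with
#' `enabled = FALSE` the input is returned unchanged.
#'
#' @param slg A long SLG tibble as produced by [split_mlg()].
#' @param tables An `hla_nomenclature` object.
#' @param enabled Logical flag.
#' @return A filtered SLG tibble with the input's attributes.
#' @export
apply_ambiguity_filter <- function(slg, tables, enabled = TRUE) {
  if (!enabled || nrow(slg) == 0 || nrow(tables$ambiguity_pairs) == 0) {
    if (enabled && nrow(slg) > 0 && nrow(tables$ambiguity_pairs) == 0) {
      warn("ambiguity filter enabled but no pair table loaded; skipping",
        class = "hlafreq_filter_warning")
    }
    return(slg)
  }
  listed_alleles <- unique(c(tables$ambiguity_pairs$a1, tables$ambiguity_pairs$a2))
  keys <- pair_key(slg$a1, slg$a2)
  keep <- keys %in% tables$ambiguity_keys |
    (slg$a1 == slg$a2 & slg$a1 %in% listed_alleles)

  grp <- paste(slg$id, slg$locus, sep = "\r")
  kept_any <- tapply(keep, grp, any)
  fallback <- names(kept_any)[!kept_any]
  if (length(fallback) > 0) {
    warn(
      sprintf("%d SLG(s) had no pair in the ambiguity table; left unfiltered",
        length(fallback)),
      class = "hlafreq_filter_warning"
    )
    keep[grp %in% fallback] <- TRUE
  }
  out <- slg[keep, , drop = FALSE]
  out <- dplyr::mutate(dplyr::group_by(out, .data$id, .data$locus),
    weight = .data$weight / sum(.data$weight))
  out <- dplyr::ungroup(out)
  structure(out, loci = attr(slg, "loci"), rejected = attr(slg, "rejected"))
}

#' Translate SLGs to a uniform per-locus target resolution
#'
#' Each allele is translated with [translate_allele()]; when a translation
#' yields several alleles, the two positions are recombined by Cartesian
#' product with the pair's weight split equally over the outcomes, and
#' duplicate unordered pairs are merged by summing weights.
#'
#' @param slg A long SLG tibble.
#' @param tables An `hla_nomenclature` object.
#' @param resolution A single target resolution, or a named character vector
#'   keyed by locus (e.g. `c(A = "g", B = "4f")`).
#' @return A translated SLG tibble with the input's attributes.
#' @export
translate_slg <- function(slg, tables, resolution) {
  if (nrow(slg) == 0) return(slg)
  loci <- attr(slg, "loci") %||% unique(slg$locus)
  res_of <- if (length(resolution) == 1 && is.null(names(resolution))) {
    stats::setNames(rep(resolution, length(loci)), loci)
  } else {
    missing_res <- setdiff(loci, names(resolution))
    if (length(missing_res) > 0) {
      abort(sprintf("no target resolution configured for locus: %s",
        paste(missing_res, collapse = ", ")), class = "hlafreq_config_error")
    }
    resolution
  }

  parts <- lapply(split(slg, slg$locus), function(d) {
    target <- res_of[[d$locus[1]]]
    uniq <- unique(c(d$a1, d$a2))
    tr <- translate_allele(uniq, target, tables)
    t1 <- tr[d$a1]
    t2 <- tr[d$a2]
    n1 <- lengths(t1)
    n2 <- lengths(t2)
    simple <- n1 == 1L & n2 == 1L
    out_simple <- if (any(simple)) {
      pc <- pair_canonical(
        unlist(t1[simple], use.names = FALSE),
        unlist(t2[simple], use.names = FALSE)
      )
      tibble(
        id = d$id[simple], count = d$count[simple], locus = d$locus[simple],
        a1 = pc$a, a2 = pc$b, weight = d$weight[simple]
      )
    } else {
      NULL
    }
    out_multi <- if (any(!simple)) {
      idx <- which(!simple)
      m1 <- n1[idx]
      m2 <- n2[idx]
      reps <- m1 * m2
      a1 <- unlist(purrr::map2(t1[idx], m2, function(x, m) rep(x, each = m)),
        use.names = FALSE)
      a2 <- unlist(purrr::map2(t2[idx], m1, function(y, k) rep(y, times = k)),
        use.names = FALSE)
      pc <- pair_canonical(a1, a2)
      tibble(
        id = rep(d$id[idx], reps), count = rep(d$count[idx], reps),
        locus = d$locus[1], a1 = pc$a, a2 = pc$b,
        weight = rep(d$weight[idx] / reps, reps)
      )
    } else {
      NULL
    }
    dplyr::bind_rows(out_simple, out_multi)
  })
  out <- dplyr::bind_rows(parts)
  out <- dplyr::summarise(
    dplyr::group_by(out, .data$id, .data$count, .data$locus, .data$a1, .data$a2),
    weight = sum(.data$weight), .groups = "drop"
  )
  structure(out, loci = loci, rejected = attr(slg, "rejected"))
}

#' Recombine SLGs into resolved multi-locus genotypes
#'
#' Takes the Cartesian product of each record's per-locus pair sets. Each
#' resolved genotype's weight is the product of its constituent pair
#' weights, so weights sum to 1 per record. Records splitting into more
#' distinct target-resolution genotypes than `max_expansion` are discarded
#' entirely and reported (the threshold applies after deduplication).
#'
#' @param slg A translated SLG tibble.
#' @param max_expansion Positive integer discard threshold.
#' @return A wide tibble with columns `id`, `count`, `weight` and, per locus
#'   `L`, `a.L`/`b.L`; attributes `loci` and `discarded` (ids).
#' @export
recombine <- function(slg, max_expansion = 64L) {
  stopifnot(max_expansion >= 1)
  loci <- attr(slg, "loci") %||% unique(slg$locus)
  if (nrow(slg) == 0) {
    return(structure(tibble(id = character(), count = integer(),
      weight = double()), loci = loci, discarded = character()))
  }
  res <- NULL
  for (locus in loci) {
    dd <- slg[slg$locus == locus, , drop = FALSE]
    d <- tibble(id = dd$id, count = dd$count, weight = dd$weight)
    d[[paste0("a.", locus)]] <- dd$a1
    d[[paste0("b.", locus)]] <- dd$a2
    if (is.null(res)) {
      res <- d
    } else {
      d$count <- NULL
      res <- dplyr::inner_join(res, d, by = "id",
        relationship = "many-to-many", suffix = c("", ".y"))
      res$weight <- res$weight * res$weight.y
      res$weight.y <- NULL
    }
  }
  n_per <- table(res$id)
  discarded <- names(n_per)[n_per > max_expansion]
  if (length(discarded) > 0) {
    res <- dplyr::filter(res, !(as.character(.data$id) %in% discarded))
  }
  structure(res, loci = loci, discarded = discarded)
}

#' Enumerate candidate diplotypes of resolved genotypes
#'
#' For a genotype with k heterozygous loci there are max(1, 2^(k-1))
#' unordered haplotype pairs consistent with it. Each diplotype inherits its
#' genotype's weight unchanged; apportioning weight across a record's
#' diplotypes is the E-step's job. Haplotypes are rendered as `~`-joined
#' alleles in the canonical locus order.
#'
#' @param resolved Output of [recombine()].
#' @param loci Canonical locus order; defaults to the `loci` attribute.
#' @return A tibble with columns `id`, `count`, `weight`, `h1`, `h2`
#'   (`h1 <= h2`).
#' @export
build_diplotypes <- function(resolved, loci = NULL) {
  loci <- loci %||% attr(resolved, "loci")
  if (nrow(resolved) == 0) {
    return(tibble(id = character(), count = integer(), weight = double(),
      h1 = character(), h2 = character()))
  }
  A <- as.matrix(as.data.frame(resolved[paste0("a.", loci)],
    stringsAsFactors = FALSE))
  B <- as.matrix(as.data.frame(resolved[paste0("b.", loci)],
    stringsAsFactors = FALSE))
  het <- A != B
  k <- rowSums(het)

  paste_rows <- function(M) {
    do.call(paste, c(as.data.frame(M, stringsAsFactors = FALSE), sep = "~"))
  }

  out <- vector("list", 0)
  for (kk in sort(unique(k))) {
    idx <- which(k == kk)
    n_dip <- max(1L, 2L^(max(0L, kk - 1L)))
    if (kk <= 1) {
      # single phase assignment (up to pair order)
      pc <- pair_canonical(
        paste_rows(A[idx, , drop = FALSE]),
        paste_rows(B[idx, , drop = FALSE])
      )
      out[[length(out) + 1]] <- tibble(
        id = resolved$id[idx], count = resolved$count[idx],
        weight = resolved$weight[idx], h1 = pc$a, h2 = pc$b
      )
      next
    }
    # per-row column positions of the kk heterozygous loci
    het_sub <- het[idx, , drop = FALSE]
    hp <- matrix(which(t(het_sub)) - (rep(seq_along(idx), each = kk) - 1L) *
      ncol(het_sub), ncol = kk, byrow = TRUE)
    # the first heterozygous locus is pinned to haplotype 1; the remaining
    # kk-1 heterozygous loci take both phase assignments
    assign_mat <- as.matrix(expand.grid(
      rep(list(c(FALSE, TRUE)), kk - 1), KEEP.OUT.ATTRS = FALSE
    ))
    for (j in seq_len(n_dip)) {
      flip <- c(FALSE, as.logical(assign_mat[j, ]))
      H1 <- A[idx, , drop = FALSE]
      H2 <- B[idx, , drop = FALSE]
      for (m in which(flip)) {
        cells <- cbind(seq_along(idx), hp[, m])
        tmp <- H1[cells]
        H1[cells] <- H2[cells]
        H2[cells] <- tmp
      }
      pc <- pair_canonical(paste_rows(H1), paste_rows(H2))
      out[[length(out) + 1]] <- tibble(
        id = resolved$id[idx], count = resolved$count[idx],
        weight = resolved$weight[idx], h1 = pc$a, h2 = pc$b
      )
    }
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$id)
}
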