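# Ecological linking: each woman is assigned the average readiness and
# provision/experience-of-care scores of the stratum (geographic domain x
# facility category) matching each source of ANC she reported, falling back
# to the national category mean where the stratum holds no surveyed units.
# Unqualified sources score zero; care-seeking from unqualified sources is
# ignored when at least one qualified source was reported.

# per-index lookup vectors from a stratum table
stratum_lookup <- function(stratum_table, index) {
  tab <- as.data.frame(stratum_table)
  st <- tab[tab$index == index & !tab$is_national, , drop = FALSE]
  nat <- tab[tab$index == index & tab$is_national, , drop = FALSE]
  list(
    stratum = stats::setNames(st$mean_score, st_key(st$geo_domain, st$facility_category)),
    national = stats::setNames(nat$mean_score, nat$facility_category)
  )
}

lookup_category <- function(lk, geo_domain, category) {
  v <- unname(lk$stratum[st_key(geo_domain, category)])
  tag <- rep("stratum", length(v))
  miss <- is.na(v)
  if (any(miss)) {
    v[miss] <- unname(lk$national[category[miss]])
    tag[miss] <- "national"
  }
  list(value = v, tag = tag)
}

#' Resolve one reported source of care to stratum scores
#'
#' @param source_code A provider-category code as reported in the household
#'   survey.
#' @param geo_domain The woman's geographic domain (region or district).
#' @param mapping The provider mapping from the country configuration: each
#'   code maps to a facility category, to `"UNQUALIFIED"`, or to a fixed
#'   score in \[0, 1\] for qualified non-facility providers with no usable
#'   facility proxy.
#' @param stratum_table A `cc_stratum_table` from [build_stratum_table()].
#' @param indices Character vector of index names to resolve; defaults to all
#'   indices present in `stratum_table`.
#' @return List with `scores` (named numeric per index) and `provenance`
#'   (named character per index: `"stratum"`, `"national"`, `"unqualified"`
#'   or `"literal"`).
#' @export
resolve_source <- function(source_code, geo_domain, mapping, stratum_table,
                           indices = NULL) {
  if (!source_code %in% names(mapping)) {
    stop_cc("unmapped-provider", "source code '%s' is not in the provider mapping", source_code)
  }
  indices <- indices %||% unique(as.data.frame(stratum_table)$index)
  target <- mapping[[source_code]]
  if (is.numeric(target)) {
    return(list(scores = stats::setNames(rep(target, length(indices)), indices),
                provenance = stats::setNames(rep("literal", length(indices)), indices)))
  }
  if (identical(target, "UNQUALIFIED")) {
    return(list(scores = stats::setNames(rep(0, length(indices)), indices),
                provenance = stats::setNames(rep("unqualified", length(indices)), indices)))
  }
  scores <- numeric(length(indices))
  prov <- character(length(indices))
  for (i in seq_along(indices)) {
    lk <- stratum_lookup(stratum_table, indices[i])
    r <- lookup_category(lk, geo_domain, target)
    if (is.na(r$value)) {
      stop_cc("unlinkable-category",
              "category '%s' has no stratum or national row for index '%s'",
              target, indices[i])
    }
    scores[i] <- r$value
    prov[i] <- r$tag
  }
  list(scores = stats::setNames(scores, indices),
       provenance = stats::setNames(prov, indices))
}

#' Assign stratum-average scores to every woman
#'
#' For each woman, every distinct reported source is resolved via
#' [resolve_source()]; her score per index is the unweighted mean over her
#' qualified sources (unqualified sources are ignored when a qualified source
#' exists, and score zero when she reported only unqualified sources or no
#' ANC at all).
#'
#' @param women Validated women table.
#' @param mapping Provider mapping (see [resolve_source()]).
#' @param stratum_table A `cc_stratum_table`.
#' @param indices Character vector of index names; defaults to all indices in
#'   `stratum_table`.
#' @return Data frame with `woman_id`, one score column per index,
#'   `n_sources` (distinct qualified sources) and `n_national_fallbacks`
#'   (source-by-index resolutions that used a national fallback row). A long
#'   provenance table (`woman_id`, `source`, `index`, `resolution`) is
#'   attached as attribute `"provenance"`.
#' @export
assign_woman_scores <- function(women, mapping, stratum_table, indices = NULL) {
  indices <- indices %||% unique(as.data.frame(stratum_table)$index)
  src <- qualified_sources_long(women, mapping)
  n <- nrow(women)
  scores <- matrix(0, n, length(indices), dimnames = list(NULL, indices))
  n_nat <- integer(n)
  prov <- NULL
  if (nrow(src$long)) {
    L <- src$long
    prov_list <- list()
    row_scores <- matrix(NA_real_, nrow(L), length(indices))
    row_tag <- matrix("literal", nrow(L), length(indices))
    for (i in seq_along(indices)) {
      lk <- stratum_lookup(stratum_table, indices[i])
      is_cat <- L$kind == "category"
      if (any(is_cat)) {
        r <- lookup_category(lk, L$geo_domain[is_cat], L$category[is_cat])
        if (anyNA(r$value)) {
          bad <- unique(L$category[is_cat][is.na(r$value)])
          stop_cc("unlinkable-category",
                  "category '%s' has no stratum or national row for index '%s'",
                  bad[1], indices[i])
        }
        row_scores[is_cat, i] <- r$value
        row_tag[is_cat, i] <- r$tag
      }
      row_scores[!is_cat, i] <- L$literal[!is_cat]
    }
    agg <- rowsum(row_scores, L$widx)
    widx <- as.integer(rownames(agg))
    scores[widx, ] <- agg / src$n_src[widx]
    nat_counts <- rowsum(rowSums(row_tag == "national"), L$widx)
    n_nat[widx] <- as.integer(nat_counts)
    prov <- data.frame(
      woman_id = rep(women$woman_id[L$widx], length(indices)),
      source = rep(L$source, length(indices)),
      index = rep(indices, each = nrow(L)),
      resolution = as.vector(row_tag),
      stringsAsFactors = FALSE
    )
  }
  out <- data.frame(woman_id = women$woman_id, stringsAsFactors = FALSE)
  for (i in seq_along(indices)) out[[indices[i]]] <- scores[, i]
  out$n_sources <- src$n_src
  out$n_national_fallbacks <- n_nat
  attr(out, "provenance") <- prov
  out
}

# Long table of distinct qualified sources per woman.
# Returns list(long = data.frame(widx, source, kind, geo_domain, category,
# literal), n_src = integer per woman (0 when no qualified source)).
qualified_sources_long <- function(women, mapping) {
  src <- split_sources(women$sources)
  src <- lapply(src, unique)
  widx <- rep(seq_along(src), lengths(src))
  code <- unlist(src)
  if (length(code) == 0L) {
    return(list(long = data.frame(widx = integer(), source = character(),
                                  kind = character(), geo_domain = character(),
                                  category = character(), literal = numeric(),
                                  stringsAsFactors = FALSE),
                n_src = integer(nrow(women))))
  }
  unknown <- setdiff(unique(code), names(mapping))
  if (length(unknown)) {
    stop_cc("unmapped-provider", "source code(s) not in the provider mapping: %s",
            paste(unknown, collapse = ", "))
  }
  target <- mapping[code]
  is_num <- vapply(target, is.numeric, logical(1))
  tchr <- rep(NA_character_, length(target))
  tchr[!is_num] <- vapply(target[!is_num], as.character, character(1))
  lit <- rep(NA_real_, length(target))
  lit[is_num] <- vapply(target[is_num], as.numeric, numeric(1))
  kind <- ifelse(is_num, "literal",
                 ifelse(tchr == "UNQUALIFIED", "unqualified", "category"))
  keep <- kind != "unqualified"
  long <- data.frame(
    widx = widx[keep],
    source = code[keep],
    kind = kind[keep],
    geo_domain = women$geo_domain[widx][keep],
    category = ifelse(kind == "category", tchr, NA_character_)[keep],
    literal = lit[keep],
    stringsAsFactors = FALSE
  )
  n_src <- integer(nrow(women))
  tab <- table(long$widx)
  n_src[as.integer(names(tab))] <- as.integer(tab)
  list(long = long, n_src = n_src)
}
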