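# Facility readiness scoring: simple additive indices on a 0-1 scale.
# Binary items (equipment, medicines, diagnostics, guidelines) contribute 0/1;
# provider-training items contribute the proportion of ANC providers trained,
# in [0,1]. Items not collected for a facility drop out of that facility's
# denominator; items not collected in a country are excluded via the index's
# country mask.

# value matrix for an index over units: rows units, cols masked item codes
index_value_matrix <- function(df, index_def) {
  items <- index_def$items[index_def$items$code %in% index_def$country_mask, , drop = FALSE]
  if (nrow(items) == 0L) stop_cc("empty-mask", "index '%s' has an empty country mask", index_def$name)
  cols <- ifelse(items$kind == "proportion", paste0("train_", items$code),
                 paste0("item_", items$code))
  m <- matrix(NA_real_, nrow(df), nrow(items), dimnames = list(NULL, items$code))
  for (j in seq_along(cols)) {
    if (cols[j] %in% names(df)) m[, j] <- as.numeric(df[[cols[j]]])
  }
  attr(m, "domains") <- items$domain
  m
}

#' Score one facility on a readiness index
#'
#' The readiness score is the unweighted mean of the index's masked items that
#' were collected for the facility. Per-domain scores are means within each
#' item domain (basic amenities, equipment, medicines, diagnostics, human
#' resources, ...), so the overall score equals the item-count-weighted mean
#' of the domain scores.
#'
#' @param facility A single-row data frame (or coercible list) following the
#'   facility schema.
#' @param index_def An index definition from a `cc_config` (e.g.
#'   `config$indices$anc_readiness`).
#' @return A `cc_unit_score`: list with `facility_id`, `index`, `score`,
#'   `n_items_used`, `domain_scores`.
#' @export
facility_readiness_score <- function(facility, index_def) {
  facility <- as.data.frame(facility, stringsAsFactors = FALSE)
  stopifnot(nrow(facility) == 1L)
  unit_score(facility, index_def, id = facility$facility_id, id_field = "facility_id")
}

unit_score <- function(df, index_def, id, id_field) {
  m <- index_value_matrix(df, index_def)
  v <- m[1L, ]
  used <- !is.na(v)
  if (!any(used)) {
    stop_cc("no-scoreable-items", "unit '%s' has no collected items for index '%s'",
            id, index_def$name)
  }
  domains <- attr(m, "domains")[used]
  vals <- v[used]
  ds <- vapply(split(vals, domains), mean, numeric(1))
  out <- list(score = mean(vals), index = index_def$name,
              n_items_used = sum(used), domain_scores = ds)
  out[[id_field]] <- id
  class(out) <- "cc_unit_score"
  out
}

#' @export
print.cc_unit_score <- function(x, ...) {
  cat(sprintf("<%s> score %.4f over %d item(s)\n", x$index, x$score, x$n_items_used))
  invisible(x)
}

#' Score all facilities on an index
#'
#' Vectorised version of [facility_readiness_score()].
#'
#' @param facilities Facility table (ANC-offering scoring view).
#' @param index_def A facility-target index definition.
#' @return Data frame: `facility_id`, `index`, `score`, `n_items_used`.
#' @export
score_facilities <- function(facilities, index_def) {
  m <- index_value_matrix(facilities, index_def)
  n_used <- rowSums(!is.na(m))
  if (any(n_used == 0L)) {
    stop_cc("no-scoreable-items", "facility(ies) with no collected items for '%s': %s",
            index_def$name,
            paste(utils::head(facilities$facility_id[n_used == 0L], 5), collapse = ", "))
  }
  data.frame(
    facility_id = facilities$facility_id,
    index = index_def$name,
    score = rowMeans(m, na.rm = TRUE),
    n_items_used = n_used,
    stringsAsFactors = FALSE
  )
}

#' Facility-weighted mean readiness for one stratum
#'
#' A stratum is a geographic domain crossed with a facility category. The mean
#' is weighted by the facility-assessment sampling weights.
#'
#' @param facility_scores Output of [score_facilities()].
#' @param facilities The matching facility table.
#' @param stratum_key Length-2 character vector `c(geo_domain, facility_category)`.
#' @return The weighted mean score in \[0, 1\], or `NA` when the stratum holds
#'   no facilities (callers fall back to the national mean).
#' @export
stratum_mean_readiness <- function(facility_scores, facilities, stratum_key) {
  i <- match(facility_scores$facility_id, facilities$facility_id)
  sel <- facilities$geo_domain[i] == stratum_key[1L] &
    facilities$facility_category[i] == stratum_key[2L]
  if (!any(sel)) return(NA_real_)
  wmean(facility_scores$score[sel], facilities$weight[i][sel])
}

#' Build the stratum score table
#'
#' Computes, for every index, the weighted mean score per stratum
#' (geographic domain x facility category) plus a national fallback row per
#' category. Readiness rows are facility-weight-weighted means of facility
#' scores. Quality rows pool all client observations within the stratum with
#' client weights (never a mean of per-facility means), so high-caseload
#' facilities carry more weight.
#'
#' @param facilities ANC-offering facility table.
#' @param config A `cc_config`.
#' @param observations Optional client-observation table (required for
#'   quality rows when the country has quality data).
#' @return A `cc_stratum_table` data frame: `geo_domain`, `facility_category`,
#'   `index`, `mean_score`, `n_units`, `is_national`. National rows carry
#'   `geo_domain = "NATIONAL"`.
#' @export
build_stratum_table <- function(facilities, config, observations = NULL) {
  config <- as_country_config(config)
  out <- list()
  for (nm in readiness_indices(config)) {
    fs <- score_facilities(facilities, config$indices[[nm]])
    out[[nm]] <- aggregate_stratum(fs$score, facilities$weight,
                                   facilities$geo_domain, facilities$facility_category, nm)
  }
  if (config$has_quality_data && !is.null(observations) && nrow(observations)) {
    fi <- match(observations$facility_id, facilities$facility_id)
    for (nm in quality_indices(config)) {
      cs <- score_clients(observations, config$indices[[nm]])
      out[[nm]] <- aggregate_stratum(cs$score, observations$weight,
                                     facilities$geo_domain[fi],
                                     facilities$facility_category[fi], nm)
    }
  }
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  class(tab) <- c("cc_stratum_table", "data.frame")
  tab
}

aggregate_stratum <- function(score, weight, geo_domain, category, index_name) {
  key <- st_key(geo_domain, category)
  agg <- function(keys, doms, cats, is_nat) {
    num <- rowsum(weight * score, keys)
    den <- rowsum(weight, keys)
    n <- rowsum(rep(1L, length(keys)), keys)
    ord <- rownames(num)
    data.frame(
      geo_domain = doms[match(ord, keys)],
      facility_category = cats[match(ord, keys)],
      index = index_name,
      mean_score = as.numeric(num / den),
      n_units = as.integer(n),
      is_national = is_nat,
      stringsAsFactors = FALSE
    )
  }
  strat <- agg(key, geo_domain, category, FALSE)
  nat <- agg(category, rep("NATIONAL", length(category)), category, TRUE)
  rbind(strat, nat)
}

#' Write a stratum score table to CSV
#' @param stratum_table A `cc_stratum_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stratum_table <- function(stratum_table, path) {
  utils::write.csv(as.data.frame(stratum_table), path, row.names = FALSE, na = "")
  invisible(path)
}
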