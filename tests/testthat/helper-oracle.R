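# Independent brute-force oracle: every estimator re-implemented with plain
# loops straight from the definitions, kept deliberately separate from the
# package's vectorised code paths.

o_masked_items <- function(index_def) {
  index_def$items[index_def$items$code %in% index_def$country_mask, , drop = FALSE]
}

o_unit_score <- function(row, index_def) {
  it <- o_masked_items(index_def)
  vals <- numeric(0)
  for (i in seq_len(nrow(it))) {
    col <- if (it$kind[i] == "proportion") paste0("train_", it$code[i]) else paste0("item_", it$code[i])
    v <- if (col %in% names(row)) row[[col]] else NA
    if (!is.na(v)) vals <- c(vals, v)
  }
  if (!length(vals)) return(NA_real_)
  mean(vals)
}

# stratum (or national, domain = NULL) mean for a facility-target index
o_readiness_mean <- function(facilities, config, index, category, domain = NULL) {
  num <- 0; den <- 0
  for (i in seq_len(nrow(facilities))) {
    f <- facilities[i, ]
    if (f$facility_category != category) next
    if (!is.null(domain) && f$geo_domain != domain) next
    s <- o_unit_score(f, config$indices[[index]])
    num <- num + f$weight * s
    den <- den + f$weight
  }
  if (den == 0) NA_real_ else num / den
}

# pooled client-weighted mean for a client-target index
o_quality_mean <- function(observations, facilities, config, index, category, domain = NULL) {
  num <- 0; den <- 0
  for (i in seq_len(nrow(observations))) {
    o <- observations[i, ]
    f <- facilities[facilities$facility_id == o$facility_id, ]
    if (f$facility_category != category) next
    if (!is.null(domain) && f$geo_domain != domain) next
    s <- o_unit_score(o, config$indices[[index]])
    num <- num + o$weight * s
    den <- den + o$weight
  }
  if (den == 0) NA_real_ else num / den
}

# stratum value with national fallback
o_lookup <- function(bundle, index, category, domain) {
  cfg <- bundle$config
  if (cfg$indices[[index]]$target == "facility") {
    v <- o_readiness_mean(bundle$facilities, cfg, index, category, domain)
    if (is.na(v)) v <- o_readiness_mean(bundle$facilities, cfg, index, category)
  } else {
    v <- o_quality_mean(bundle$observations, bundle$facilities, cfg, index, category, domain)
    if (is.na(v)) v <- o_quality_mean(bundle$observations, bundle$facilities, cfg, index, category)
  }
  v
}

o_sources <- function(woman) {
  s <- strsplit(woman$sources, ";", fixed = TRUE)[[1]]
  unique(s[nzchar(s)])
}

o_is_qualified <- function(code, mapping) {
  tgt <- mapping[[code]]
  is.numeric(tgt) || !identical(tgt, "UNQUALIFIED")
}

o_woman_score <- function(woman, bundle, index) {
  mapping <- bundle$config$provider_mapping
  vals <- numeric(0)
  for (code in o_sources(woman)) {
    tgt <- mapping[[code]]
    if (is.numeric(tgt)) {
      vals <- c(vals, tgt)
    } else if (!identical(tgt, "UNQUALIFIED")) {
      v <- o_lookup(bundle, index, tgt, woman$geo_domain)
      stopifnot(!is.na(v))
      vals <- c(vals, v)
    }
  }
  if (length(vals)) mean(vals) else 0
}

o_contact <- function(woman, k, mapping) {
  if (!woman$any_anc) return(0)
  qual <- FALSE
  for (code in o_sources(woman)) if (o_is_qualified(code, mapping)) qual <- TRUE
  visits <- if (is.na(woman$n_visits)) 1 else woman$n_visits
  as.numeric(qual && visits >= k)
}

o_service_contact <- function(bundle, k) {
  num <- 0; den <- 0
  for (i in seq_len(nrow(bundle$women))) {
    w <- bundle$women[i, ]
    num <- num + w$weight * o_contact(w, k, bundle$config$provider_mapping)
    den <- den + w$weight
  }
  num / den
}

o_intervention_score <- function(woman, set) {
  vals <- numeric(0)
  for (code in set$country_mask) {
    col <- paste0("recv_", code)
    v <- if (col %in% names(woman)) woman[[col]] else NA
    if (!is.na(v)) vals <- c(vals, v)
  }
  if (!length(vals)) return(NA_real_)
  mean(vals)
}

o_intervention_coverage <- function(bundle, service) {
  set <- bundle$config$intervention_sets[[service]]
  num <- 0; den <- 0
  for (i in seq_len(nrow(bundle$women))) {
    w <- bundle$women[i, ]
    s <- o_intervention_score(w, set)
    if (is.na(s)) next
    num <- num + w$weight * s
    den <- den + w$weight
  }
  num / den
}

o_adjusted_coverage <- function(bundle, service, k, type) {
  index <- paste(service, type, sep = "_")
  mapping <- bundle$config$provider_mapping
  num <- 0; den <- 0
  for (i in seq_len(nrow(bundle$women))) {
    w <- bundle$women[i, ]
    num <- num + w$weight * o_contact(w, k, mapping) * o_woman_score(w, bundle, index)
    den <- den + w$weight
  }
  num / den
}

# Taylor linearisation of the weighted ratio mean, coded directly from the
# textbook formula (no lonely-PSU handling: designs used with it have >= 2
# clusters per stratum)
o_taylor_var <- function(y, w, cluster, stratum) {
  incl <- !is.na(y)
  W <- sum(w[incl])
  theta <- sum(w[incl] * y[incl]) / W
  z <- ifelse(incl, w * (y - theta), 0) / W
  v <- 0
  for (h in unique(stratum)) {
    cl <- unique(cluster[stratum == h])
    zc <- numeric(length(cl))
    for (j in seq_along(cl)) zc[j] <- sum(z[stratum == h & cluster == cl[j]])
    nh <- length(cl)
    v <- v + nh / (nh - 1) * sum((zc - mean(zc))^2)
  }
  v
}

# two-survey delete-one-group jackknife, recomputing everything from scratch
o_jackknife2_var <- function(bundle, service, k, type) {
  est <- function(b) o_adjusted_coverage(b, service, k, type)
  clusters <- unique(bundle$women$cluster_id)
  thA <- numeric(length(clusters))
  for (g in seq_along(clusters)) {
    b2 <- bundle
    b2$women <- bundle$women[bundle$women$cluster_id != clusters[g], , drop = FALSE]
    thA[g] <- est(b2)
  }
  G <- length(clusters)
  varA <- (G - 1) / G * sum((thA - mean(thA))^2)
  fids <- bundle$facilities$facility_id
  thB <- numeric(length(fids))
  for (f in seq_along(fids)) {
    b2 <- bundle
    b2$facilities <- bundle$facilities[bundle$facilities$facility_id != fids[f], , drop = FALSE]
    if (!is.null(bundle$observations)) {
      b2$observations <- bundle$observations[bundle$observations$facility_id != fids[f], , drop = FALSE]
    }
    thB[f] <- est(b2)
  }
  Fn <- length(fids)
  varB <- (Fn - 1) / Fn * sum((thB - mean(thB))^2)
  list(var_cluster = varA, var_facility = varB, total = varA + varB)
}
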