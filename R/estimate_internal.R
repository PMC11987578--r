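# Internal estimation context: precomputed structures shared by the cascade
# estimators and the two-survey jackknife, so that stratum score tables can be
# rebuilt and women re-linked cheaply for every delete-one replicate.

link_context <- function(bundle) {
  cfg <- bundle$config
  women <- bundle$women
  fac <- bundle$facilities
  obs <- bundle$observations
  n <- nrow(women)
  if (n == 0L) stop_cc("empty-table", "women table is empty")
  if (nrow(fac) == 0L) stop_cc("empty-table", "no ANC-offering facilities")

  src <- qualified_sources_long(women, cfg$provider_mapping)
  ks <- sort(unique(cfg$contact_thresholds))
  C <- vmat(as.character(ks), n,
            function(k) contact_indicator(women, as.integer(k), cfg$provider_mapping))

  ridx <- readiness_indices(cfg)
  qidx <- if (cfg$has_quality_data && !is.null(obs) && nrow(obs)) quality_indices(cfg) else character()

  fac_key <- st_key(fac$geo_domain, fac$facility_category)
  ukeys <- sort(unique(fac_key))
  ucats <- sort(unique(fac$facility_category))
  fac_sid <- match(fac_key, ukeys)
  fac_cid <- match(fac$facility_category, ucats)
  S_f <- vmat(ridx, nrow(fac),
              function(nm) score_facilities(fac, cfg$indices[[nm]])$score)

  obs_fidx <- NULL; S_o <- NULL; obs_sid <- NULL; obs_cid <- NULL
  if (length(qidx)) {
    obs_fidx <- match(obs$facility_id, fac$facility_id)
    obs_sid <- fac_sid[obs_fidx]
    obs_cid <- fac_cid[obs_fidx]
    S_o <- vmat(qidx, nrow(obs),
                function(nm) score_clients(obs, cfg$indices[[nm]])$score)
  }

  L <- src$long
  is_cat <- L$kind == "category"
  src_sid <- ifelse(is_cat, match(st_key(L$geo_domain, L$category), ukeys), NA_integer_)
  src_cid <- ifelse(is_cat, match(L$category, ucats), NA_integer_)
  if (any(is_cat & is.na(src_cid))) {
    bad <- unique(L$category[is_cat & is.na(src_cid)])
    stop_cc("unlinkable-category",
            "category '%s' has no surveyed facility anywhere", bad[1])
  }

  list(
    config = cfg, women = women, n = n,
    w = women$weight, cluster = women$cluster_id, stratum = women$design_stratum,
    ks = ks, C = C,
    src = L, src_is_cat = is_cat, src_sid = src_sid, src_cid = src_cid,
    n_src = src$n_src,
    ukeys = ukeys, ucats = ucats,
    fac = fac, w_f = fac$weight, fac_sid = fac_sid, fac_cid = fac_cid, S_f = S_f,
    ridx = ridx, qidx = qidx,
    obs = obs, w_o = if (length(qidx)) obs$weight else NULL,
    obs_fidx = obs_fidx, obs_sid = obs_sid, obs_cid = obs_cid, S_o = S_o
  )
}

# weighted group means per stratum id and per category id, for one score
# matrix; recomputed from scratch for each jackknife replicate
group_means <- function(sid, cid, w, S, keep, n_keys, n_cats) {
  if (!is.null(keep)) {
    sid <- sid[keep]; cid <- cid[keep]; w <- w[keep]
    S <- S[keep, , drop = FALSE]
  }
  nidx <- ncol(S)
  m_st <- matrix(NA_real_, n_keys, nidx)
  m_nat <- matrix(NA_real_, n_cats, nidx)
  if (length(w)) {
    num <- rowsum(S * w, sid)
    den <- rowsum(w, sid)
    ids <- as.integer(rownames(num))
    m_st[ids, ] <- num / as.vector(den)
    numc <- rowsum(S * w, cid)
    denc <- rowsum(w, cid)
    idsc <- as.integer(rownames(numc))
    m_nat[idsc, ] <- numc / as.vector(denc)
  }
  list(stratum = m_st, national = m_nat)
}

# Per-woman score matrix over all indices (readiness then quality).
# keep_fac / keep_obs are logical masks for jackknife replicates.
# Returns list(S = n x nidx matrix, valid = flag); valid = FALSE when a
# needed category lost its national row (replicate must be excluded).
woman_score_matrix <- function(ctx, keep_fac = NULL, keep_obs = NULL) {
  indices <- c(ctx$ridx, ctx$qidx)
  nidx <- length(indices)
  S <- matrix(0, ctx$n, nidx, dimnames = list(NULL, indices))
  L <- ctx$src
  if (!nrow(L)) return(list(S = S, valid = TRUE))

  gm_f <- group_means(ctx$fac_sid, ctx$fac_cid, ctx$w_f, ctx$S_f, keep_fac,
                      length(ctx$ukeys), length(ctx$ucats))
  gm <- list(stratum = gm_f$stratum, national = gm_f$national)
  if (length(ctx$qidx)) {
    gm_o <- group_means(ctx$obs_sid, ctx$obs_cid, ctx$w_o, ctx$S_o, keep_obs,
                        length(ctx$ukeys), length(ctx$ucats))
    gm$stratum <- cbind(gm$stratum, gm_o$stratum)
    gm$national <- cbind(gm$national, gm_o$national)
  }

  row_scores <- matrix(NA_real_, nrow(L), nidx)
  ic <- ctx$src_is_cat
  if (any(ic)) {
    v <- gm$stratum[ctx$src_sid[ic], , drop = FALSE]
    nat <- gm$national[ctx$src_cid[ic], , drop = FALSE]
    miss <- is.na(v)
    v[miss] <- nat[miss]
    if (anyNA(v)) return(list(S = S, valid = FALSE))
    row_scores[ic, ] <- v
  }
  if (any(!ic)) row_scores[!ic, ] <- L$literal[!ic]

  agg <- rowsum(row_scores, L$widx)
  widx <- as.integer(rownames(agg))
  S[widx, ] <- agg / ctx$n_src[widx]
  list(S = S, valid = TRUE)
}

# adjusted-coverage point estimates for all (index, k) combinations:
# theta[idx, k] = sum(w * c_k * s_idx) / sum(w)
adjusted_theta <- function(ctx, S, w = ctx$w, C = ctx$C) {
  crossprod(S, C * w) / sum(w)
}
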