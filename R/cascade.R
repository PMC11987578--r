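# Cascade step estimators. All national estimates are women's-weight-weighted
# means (ratio means) over the target population: women 15-49 with a live
# birth in the last two years -- every row of the women table.

#' Service-contact indicator
#'
#' A woman counts as having had service contact at threshold `k` if she
#' reported any ANC, at least one of her reported sources is qualified under
#' the provider mapping, and her visit count is at least `k`. Women who
#' reported ANC but were unsure of the visit count are imputed one contact,
#' so they count for `k = 1` only.
#'
#' @param women Validated women table.
#' @param k Visit threshold (1, 4 or 8 in the standard cascades).
#' @param mapping Provider mapping from the country configuration.
#' @return Numeric 0/1 vector, one element per woman.
#' @export
contact_indicator <- function(women, k, mapping) {
  src <- qualified_sources_long(women, mapping)
  qualified <- src$n_src > 0L
  visits <- ifelse(is.na(women$n_visits), 1L, women$n_visits)
  as.numeric(women$any_anc & qualified & visits >= k)
}

#' Service contact coverage
#'
#' Weighted proportion of the target population with at least `k` qualified
#' ANC contacts.
#'
#' @inheritParams contact_indicator
#' @return Point estimate in \[0, 1\].
#' @export
service_contact <- function(women, k, mapping) {
  wmean(contact_indicator(women, k, mapping), women$weight)
}

# per-woman intervention score: mean receipt over masked, non-missing items;
# NA when every masked receipt is missing (woman excluded from the estimate)
intervention_score <- function(women, intervention_set) {
  mask <- intervention_set$country_mask
  if (length(mask) == 0L) stop_cc("empty-mask", "intervention set has an empty country mask")
  m <- matrix(NA_real_, nrow(women), length(mask), dimnames = list(NULL, mask))
  for (code in mask) {
    col <- paste0("recv_", code)
    if (col %in% names(women)) m[, code] <- as.numeric(women[[col]])
  }
  s <- rowMeans(m, na.rm = TRUE)
  s[rowSums(!is.na(m)) == 0L] <- NA_real_
  s
}

#' Intervention coverage
#'
#' Each woman's score is the mean of the masked key interventions she reported
#' receiving, over the interventions with a non-missing response (missing
#' responses are not imputed); the national estimate is the women's-weight-
#' weighted mean of these scores. Women with all masked responses missing are
#' excluded from numerator and denominator. The estimate does not depend on
#' the visit threshold, so the same value appears in the 1/4+/8+ cascades.
#'
#' @param women Validated women table.
#' @param intervention_set An intervention set from the configuration (e.g.
#'   `config$intervention_sets$anc`).
#' @return Point estimate in \[0, 1\], with attribute `n_included`.
#' @export
intervention_coverage <- function(women, intervention_set) {
  s <- intervention_score(women, intervention_set)
  incl <- !is.na(s)
  if (!any(incl)) stop_cc("all-missing", "every woman has all masked receipts missing")
  out <- wmean(s[incl], women$weight[incl])
  attr(out, "n_included") <- sum(incl)
  out
}

#' Readiness- or quality-adjusted coverage
#'
#' The binary service-contact indicator is multiplied by each woman's linked
#' stratum-average score and the products are averaged with the women's
#' weights: `sum(w * c_k * s) / sum(w)`.
#'
#' @param women Validated women table.
#' @param woman_scores Output of [assign_woman_scores()].
#' @param k Visit threshold.
#' @param index Index name (column of `woman_scores`), e.g. `"anc_readiness"`.
#' @param mapping Provider mapping.
#' @return Point estimate in \[0, 1\].
#' @export
adjusted_coverage <- function(women, woman_scores, k, index, mapping) {
  i <- match(women$woman_id, woman_scores$woman_id)
  s <- woman_scores[[index]][i]
  cvec <- contact_indicator(women, k, mapping)
  if (anyNA(s[cvec == 1])) {
    stop_cc("missing-score", "woman with service contact lacks a '%s' score", index)
  }
  s[is.na(s)] <- 0
  wmean(cvec * s, women$weight)
}

#' Net decline between two cascade steps, in percentage points
#' @param step_a,step_b Step estimates in \[0, 1\] (a the earlier step).
#' @return `100 * (a - b)`.
#' @export
net_decline_pp <- function(step_a, step_b) 100 * (step_a - step_b)

#' Relative change between two cascade steps
#' @param step_a,step_b Step estimates in \[0, 1\] (a the earlier step).
#' @return `(a - b) / a` as a proportion; `NA` where `a` is 0.
#' @export
relative_change <- function(step_a, step_b) {
  ifelse(step_a > 0, (step_a - step_b) / step_a, NA_real_)
}

cascade_index <- function(service, type) {
  paste(match.arg(service, c("anc", "mn")), type, sep = "_")
}

#' Build one effective-coverage cascade
#'
#' Assembles the ordered cascade for a service and visit threshold: target
#' population (1 by definition), service contact, readiness-adjusted coverage,
#' intervention coverage, and -- when the country's facility assessment
#' observed care -- quality-adjusted coverage. User-adherence- and
#' outcome-adjusted steps are not estimable from these data and are never
#' emitted.
#'
#' Variance follows the design-based analysis: Taylor linearisation for the
#' household-survey-only steps (contact, intervention), and the two-survey
#' delete-one-group jackknife for the linked steps (readiness- and
#' quality-adjusted). 95% confidence intervals are truncated to \[0, 1\].
#'
#' @param bundle A validated `cc_bundle`.
#' @param service `"anc"` or `"mn"` (maternal nutrition).
#' @param k Visit threshold: 1, 4 or 8.
#' @param variance `"full"` (Taylor + jackknife, the default), `"taylor"`
#'   (household-survey steps only), `"jackknife2"` (linked steps only) or
#'   `"none"`.
#' @return A `cc_cascade` data frame: `country`, `service`, `k`, `step`,
#'   `estimate`, `se`, `ci_low`, `ci_high`, `n`, `variance_method`.
#' @export
build_cascade <- function(bundle, service = c("anc", "mn"), k = 1,
                          variance = c("full", "taylor", "jackknife2", "none")) {
  service <- match.arg(service)
  variance <- match.arg(variance)
  ctx <- link_context(bundle)
  build_cascade_ctx(ctx, service, k, variance)
}

build_cascade_ctx <- function(ctx, service, k, variance, jk = NULL) {
  cfg <- ctx$config
  if (!k %in% ctx$ks) stop_cc("bad-threshold", "k = %s is not a configured contact threshold", k)
  kc <- as.character(k)
  women <- ctx$women
  wsm <- woman_score_matrix(ctx)
  if (!wsm$valid) stop_cc("unlinkable-category", "a category has no national score row")
  theta <- adjusted_theta(ctx, wsm$S)

  cvec <- ctx$C[, kc]
  contact <- wmean(cvec, ctx$w)
  iset <- cfg$intervention_sets[[service]]
  iscore <- intervention_score(women, iset)
  interv <- wmean(iscore[!is.na(iscore)], ctx$w[!is.na(iscore)])

  has_quality <- length(ctx$qidx) > 0
  steps <- c("target", "contact", "readiness_adjusted", "intervention",
             if (has_quality) "quality_adjusted")
  est <- c(1, contact, theta[cascade_index(service, "readiness"), kc], interv,
           if (has_quality) theta[cascade_index(service, "quality"), kc])
  se <- rep(NA_real_, length(steps))
  method <- rep("none", length(steps))
  se[1] <- 0; method[1] <- "exact"

  if (variance %in% c("full", "taylor")) {
    se[2] <- taylor_variance(cvec, ctx$w, ctx$cluster, ctx$stratum)$se
    se[4] <- taylor_variance(iscore, ctx$w, ctx$cluster, ctx$stratum)$se
    method[c(2, 4)] <- "taylor"
  }
  if (variance %in% c("full", "jackknife2")) {
    if (is.null(jk)) jk <- jackknife2_all(ctx)
    cm <- paste(cascade_index(service, "readiness"), kc, sep = "|")
    se[3] <- sqrt(jk$variance[cm])
    method[3] <- "jackknife2"
    if (has_quality) {
      cm <- paste(cascade_index(service, "quality"), kc, sep = "|")
      se[5] <- sqrt(jk$variance[cm])
      method[5] <- "jackknife2"
    }
  }
  ci_low <- pmax(0, est - 1.96 * se)
  ci_high <- pmin(1, est + 1.96 * se)
  out <- data.frame(
    country = cfg$country, service = toupper(service), k = k,
    step = factor(steps, levels = c("target", "contact", "readiness_adjusted",
                                    "intervention", "quality_adjusted")),
    estimate = est, se = se, ci_low = ci_low, ci_high = ci_high,
    n = c(ctx$n, ctx$n, ctx$n, sum(!is.na(iscore)), if (has_quality) ctx$n),
    variance_method = method,
    stringsAsFactors = FALSE
  )
  class(out) <- c("cc_cascade", "data.frame")
  out
}

#' Run all cascades for a bundle
#'
#' Builds cascades for every requested service and visit threshold, sharing
#' the linking and jackknife computations across them.
#'
#' @param bundle A validated `cc_bundle`.
#' @param services Character vector among `"anc"`, `"mn"`.
#' @param ks Integer vector of visit thresholds (defaults to the
#'   configuration's thresholds).
#' @param variance See [build_cascade()].
#' @return A `cc_cascade` data frame stacking all cascades.
#' @export
run_cascades <- function(bundle, services = c("anc", "mn"), ks = NULL,
                         variance = c("full", "taylor", "jackknife2", "none")) {
  variance <- match.arg(variance)
  ctx <- link_context(bundle)
  ks <- ks %||% ctx$ks
  jk <- if (variance %in% c("full", "jackknife2")) jackknife2_all(ctx) else NULL
  out <- list()
  for (sv in services) {
    for (k in ks) {
      out[[paste(sv, k)]] <- build_cascade_ctx(ctx, sv, k, variance, jk = jk)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("cc_cascade", "data.frame")
  res
}
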