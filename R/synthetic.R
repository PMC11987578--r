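# Synthetic country bundles with known closed-form expected cascade values.
#
# The generator emulates the structure of the real inputs: a stratified
# cluster sample of women with a recent live birth (care-seeking over provider
# categories including unqualified ones, zero-truncated visit counts with an
# "unsure" sentinel, intervention receipt), a facility census with per-type
# item-availability probabilities and Beta-distributed provider-training
# proportions, and per-facility client observations. Item indicators are
# independent given the facility/client category, which keeps every cascade
# step's expectation available in closed form.

default_readiness_items <- function() {
  # per-category availability probabilities; hospitals lead health centres,
  # as facility assessments consistently find
  items <- read.table(header = TRUE, stringsAsFactors = FALSE, text = "
code                        domain           kind        in_anc in_mn  public_hospital public_health_centre private_clinic
water_source                basic_amenities  binary      TRUE   FALSE  0.95 0.75 0.85
exam_bed                    basic_amenities  binary      TRUE   TRUE   0.90 0.70 0.85
weighing_scale              equipment        binary      TRUE   TRUE   0.95 0.90 0.90
bp_apparatus                equipment        binary      TRUE   FALSE  0.90 0.75 0.85
ifa_stock                   medicines        binary      TRUE   TRUE   0.90 0.80 0.75
tt_vaccine_stock            medicines        binary      TRUE   FALSE  0.80 0.70 0.50
sp_stock                    medicines        binary      FALSE  TRUE   0.60 0.50 0.35
deworming_stock             medicines        binary      FALSE  TRUE   0.55 0.45 0.35
urine_protein_test          diagnostics      binary      TRUE   FALSE  0.75 0.40 0.65
haemoglobin_test            diagnostics      binary      TRUE   TRUE   0.70 0.30 0.55
anc_guidelines              human_resources  binary      TRUE   TRUE   0.70 0.60 0.45
anc_training                human_resources  proportion  TRUE   TRUE   0.55 0.50 0.40
nutrition_training          human_resources  proportion  FALSE  TRUE   0.35 0.30 0.25
")
  items
}

default_quality_items <- function() {
  # provision/experience of care during an observed first ANC visit; clinical
  # measurement near-universal, counselling weakest, like observed care data
  read.table(header = TRUE, stringsAsFactors = FALSE, text = "
code                        domain                 in_anc in_mn  public_hospital public_health_centre private_clinic
weight_measured             examination            TRUE   TRUE   0.95 0.90 0.90
bp_measured                 examination            TRUE   FALSE  0.90 0.85 0.85
urine_test_requested        investigation          TRUE   FALSE  0.60 0.45 0.55
blood_test_requested        investigation          TRUE   TRUE   0.65 0.50 0.55
ifa_provided                treatment              TRUE   TRUE   0.85 0.80 0.75
danger_signs_explained      counselling            TRUE   FALSE  0.40 0.35 0.35
diet_counselling            counselling            TRUE   TRUE   0.35 0.30 0.30
breastfeeding_counselling   counselling            FALSE  TRUE   0.30 0.25 0.25
client_questions_welcomed   experience             TRUE   TRUE   0.80 0.75 0.80
")
}

default_interventions <- function() {
  # receipt probabilities given at least one qualified contact / given none
  # (TT and IFA reachable outside ANC, hence nonzero without contact)
  read.table(header = TRUE, stringsAsFactors = FALSE, text = "
code       in_anc in_mn  p_contact p_nocontact
tt         TRUE   FALSE  0.80 0.10
sp         TRUE   TRUE   0.45 0.02
ifa        TRUE   TRUE   0.85 0.10
bp         TRUE   FALSE  0.90 0.02
urine      TRUE   FALSE  0.65 0.02
blood      TRUE   TRUE   0.70 0.02
deworming  TRUE   TRUE   0.35 0.02
")
}

default_source_patterns <- function() {
  # care-seeking over the course of the pregnancy: sets of reported sources
  # with probabilities; public primary care dominates, unqualified-only care
  # is rare, a minority of women combine sources
  list(
    list(sources = character(0), prob = 0.08),
    list(sources = "public_health_centre", prob = 0.40),
    list(sources = "public_hospital", prob = 0.18),
    list(sources = "private_clinic", prob = 0.08),
    list(sources = c("public_hospital", "public_health_centre"), prob = 0.10),
    list(sources = c("public_health_centre", "chw"), prob = 0.06),
    list(sources = "chw", prob = 0.04),
    list(sources = "unqualified", prob = 0.03),
    list(sources = c("public_health_centre", "unqualified"), prob = 0.03)
  )
}

default_provider_mapping <- function() {
  list(
    public_hospital = "public_hospital",
    public_health_centre = "public_health_centre",
    private_clinic = "private_clinic",
    chw = "public_health_centre",   # community health workers proxy primary care
    unqualified = "UNQUALIFIED"
  )
}

#' Generator parameters for a synthetic country
#'
#' All probabilities and distributions of the synthetic survey generator, with
#' defaults emulating a plausible low-/middle-income country: high ANC1
#' contact, a steep ANC1 >> ANC4 >> ANC8 gradient from a zero-truncated
#' negative-binomial visit-count model, readiness declining from hospitals to
#' primary facilities, and counselling the weakest area of observed care.
#'
#' @param n_domains Number of geographic domains (regions).
#' @param n_clusters Household-survey clusters (PSUs), assigned to domains
#'   round-robin; the design stratum equals the domain.
#' @param women_per_cluster Women sampled per cluster.
#' @param categories Named list of facility categories; each element has
#'   `n_per_domain` (scalar or length-`n_domains` vector) and
#'   `lambda_clients` (mean observed clients per facility; at least one
#'   client is always observed).
#' @param readiness_items,quality_items,interventions Data frames as produced
#'   by the defaults; per-category probability columns must cover every
#'   category.
#' @param source_patterns List of `list(sources =, prob =)` defining the
#'   care-seeking distribution over source sets (empty set = no ANC).
#' @param provider_mapping Provider mapping used in the generated
#'   configuration.
#' @param visit_mu,visit_size Mean and dispersion of the (untruncated)
#'   negative-binomial visit model; counts are zero-truncated.
#' @param p_unknown_visits Probability a woman with ANC is unsure of her visit
#'   count (imputed as one contact downstream).
#' @param p_missing_receipt Probability each receipt response is missing,
#'   equal across interventions.
#' @param training_concentration Beta concentration for training proportions.
#' @param woman_weight_sdlog,facility_weight_sdlog,client_weight_sdlog
#'   Log-normal sdlog of the survey weights (mean weight 1).
#' @param has_quality_data Whether client observations are generated.
#' @param country Label for the generated configuration.
#' @return A `cc_params` object.
#' @export
cc_params <- function(n_domains = 2,
                      n_clusters = 12,
                      women_per_cluster = 8,
                      categories = list(
                        public_hospital = list(n_per_domain = 1, lambda_clients = 6),
                        public_health_centre = list(n_per_domain = 3, lambda_clients = 4),
                        private_clinic = list(n_per_domain = 1, lambda_clients = 3)
                      ),
                      readiness_items = default_readiness_items(),
                      quality_items = default_quality_items(),
                      interventions = default_interventions(),
                      source_patterns = default_source_patterns(),
                      provider_mapping = default_provider_mapping(),
                      visit_mu = 3.8, visit_size = 3,
                      p_unknown_visits = 0.02,
                      p_missing_receipt = 0.01,
                      training_concentration = 10,
                      woman_weight_sdlog = 0.2,
                      facility_weight_sdlog = 0.3,
                      client_weight_sdlog = 0.3,
                      has_quality_data = TRUE,
                      country = "synthland") {
  p <- list(n_domains = n_domains, n_clusters = n_clusters,
            women_per_cluster = women_per_cluster, categories = categories,
            readiness_items = readiness_items, quality_items = quality_items,
            interventions = interventions, source_patterns = source_patterns,
            provider_mapping = provider_mapping,
            visit_mu = visit_mu, visit_size = visit_size,
            p_unknown_visits = p_unknown_visits,
            p_missing_receipt = p_missing_receipt,
            training_concentration = training_concentration,
            woman_weight_sdlog = woman_weight_sdlog,
            facility_weight_sdlog = facility_weight_sdlog,
            client_weight_sdlog = client_weight_sdlog,
            has_quality_data = isTRUE(has_quality_data), country = country)
  class(p) <- "cc_params"
  validate_params(p)
  p
}

validate_params <- function(p) {
  probs <- vapply(p$source_patterns, `[[`, numeric(1), "prob")
  if (any(probs < 0) || abs(sum(probs) - 1) > 1e-8) {
    stop_cc("bad-params", "source pattern probabilities must be non-negative and sum to 1")
  }
  cats <- names(p$categories)
  for (tab in list(p$readiness_items, p$quality_items)) {
    missing <- setdiff(cats, names(tab))
    if (length(missing)) stop_cc("bad-params", "item table lacks probability column(s): %s",
                                 paste(missing, collapse = ", "))
    pm <- as.matrix(tab[, cats, drop = FALSE])
    if (any(pm < 0 | pm > 1)) stop_cc("bad-params", "item probabilities must lie in [0,1]")
  }
  if (any(p$interventions$p_contact < 0 | p$interventions$p_contact > 1) ||
      any(p$interventions$p_nocontact < 0 | p$interventions$p_nocontact > 1)) {
    stop_cc("bad-params", "receipt probabilities must lie in [0,1]")
  }
  # every category reachable through the mapping from a positive-probability
  # pattern must have at least one facility somewhere
  used_codes <- unique(unlist(lapply(
    p$source_patterns[probs > 0], `[[`, "sources")))
  for (code in used_codes) {
    tgt <- p$provider_mapping[[code]]
    if (is.null(tgt)) stop_cc("bad-params", "pattern source '%s' is unmapped", code)
    if (is.character(tgt) && tgt != "UNQUALIFIED") {
      nf <- sum(rep_len(p$categories[[tgt]]$n_per_domain %||% 0, p$n_domains))
      if (nf < 1) stop_cc("infeasible-params",
                          "category '%s' receives care-seeking but has no facilities", tgt)
    }
  }
  invisible(p)
}

#' Small generator preset (runs in well under a second)
#' @param ... Overrides passed to [cc_params()].
#' @return A `cc_params`.
#' @export
params_small <- function(...) cc_params(...)

#' Recovery-scale generator preset
#'
#' The scale used for parameter-recovery validation: 200 clusters of 25 women
#' (5000 women) across 8 domains and 200 facilities.
#'
#' @param ... Overrides passed to [cc_params()].
#' @return A `cc_params`.
#' @export
params_recovery <- function(...) {
  cc_params(n_domains = 8, n_clusters = 200, women_per_cluster = 25,
            categories = list(
              public_hospital = list(n_per_domain = 5, lambda_clients = 6),
              public_health_centre = list(n_per_domain = 15, lambda_clients = 4),
              private_clinic = list(n_per_domain = 5, lambda_clients = 3)
            ), ...)
}

with_preserved_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# zero-truncated negative binomial sampler (exact, via inverse CDF)
rztnbinom <- function(n, mu, size) {
  p0 <- stats::pnbinom(0, mu = mu, size = size)
  u <- stats::runif(n, p0, 1)
  stats::qnbinom(u, mu = mu, size = size)
}

#' Generate a complete synthetic country bundle
#'
#' Draws women, facilities and (optionally) client observations from the
#' generator model and assembles them, together with the matching country
#' configuration, into a validated bundle. Identical parameters and seed give
#' identical tables.
#'
#' @param params A `cc_params` object.
#' @param seed Integer seed (mandatory; the global RNG state is restored
#'   afterwards).
#' @return A validated `cc_bundle`.
#' @export
generate_bundle <- function(params, seed) {
  stopifnot(inherits(params, "cc_params"), is.numeric(seed))
  validate_params(params)
  with_preserved_seed(seed, generate_bundle_impl(params))
}

generate_bundle_impl <- function(p) {
  domains <- sprintf("d%02d", seq_len(p$n_domains))
  cats <- names(p$categories)

  # --- facilities ---
  fac_rows <- list()
  for (cat in cats) {
    npd <- rep_len(p$categories[[cat]]$n_per_domain, p$n_domains)
    for (d in seq_len(p$n_domains)) {
      if (npd[d] > 0) {
        fac_rows[[paste(cat, d)]] <- data.frame(
          geo_domain = domains[d], facility_category = cat,
          stringsAsFactors = FALSE)[rep(1, npd[d]), , drop = FALSE]
      }
    }
  }
  fac <- do.call(rbind, fac_rows)
  rownames(fac) <- NULL
  nf <- nrow(fac)
  fac <- data.frame(facility_id = sprintf("f%04d", seq_len(nf)),
                    weight = exp(stats::rnorm(nf, 0, p$facility_weight_sdlog)),
                    fac, offers_anc = TRUE, stringsAsFactors = FALSE)
  ri <- p$readiness_items
  for (j in seq_len(nrow(ri))) {
    pr <- unlist(ri[j, fac$facility_category], use.names = FALSE)
    if (ri$kind[j] == "binary") {
      fac[[paste0("item_", ri$code[j])]] <- stats::rbinom(nf, 1, pr)
    } else {
      cc <- p$training_concentration
      fac[[paste0("train_", ri$code[j])]] <- stats::rbeta(nf, pr * cc, (1 - pr) * cc)
    }
  }

  # --- women ---
  G <- p$n_clusters
  m <- p$women_per_cluster
  n <- G * m
  cl_domain <- rep_len(domains, G)
  cluster <- sprintf("c%04d", seq_len(G))
  widx_cl <- rep(seq_len(G), each = m)
  pat_probs <- vapply(p$source_patterns, `[[`, numeric(1), "prob")
  pat <- sample.int(length(p$source_patterns), n, replace = TRUE, prob = pat_probs)
  src_list <- lapply(p$source_patterns, `[[`, "sources")
  sources <- vapply(src_list, paste, character(1), collapse = ";")[pat]
  any_anc <- nchar(sources) > 0
  n_visits <- rep(NA_integer_, n)
  iv <- which(any_anc)
  unk <- stats::runif(length(iv)) < p$p_unknown_visits
  n_visits[iv[!unk]] <- as.integer(rztnbinom(sum(!unk), p$visit_mu, p$visit_size))
  women <- data.frame(
    woman_id = sprintf("w%05d", seq_len(n)),
    weight = exp(stats::rnorm(n, 0, p$woman_weight_sdlog)),
    cluster_id = cluster[widx_cl],
    design_stratum = paste0("s_", cl_domain[widx_cl]),
    geo_domain = cl_domain[widx_cl],
    any_anc = any_anc, n_visits = n_visits, sources = sources,
    stringsAsFactors = FALSE
  )
  qual_src <- vapply(src_list, function(s) {
    any(vapply(s, function(code) {
      tgt <- p$provider_mapping[[code]]
      is.numeric(tgt) || !identical(tgt, "UNQUALIFIED")
    }, logical(1)))
  }, logical(1))
  qualified <- qual_src[pat]
  for (j in seq_len(nrow(p$interventions))) {
    pr <- ifelse(qualified, p$interventions$p_contact[j], p$interventions$p_nocontact[j])
    r <- stats::rbinom(n, 1, pr)
    r[stats::runif(n) < p$p_missing_receipt] <- NA
    women[[paste0("recv_", p$interventions$code[j])]] <- r
  }

  # --- client observations ---
  obs <- NULL
  if (p$has_quality_data) {
    lam <- vapply(cats, function(cat) p$categories[[cat]]$lambda_clients, numeric(1))
    n_cl <- 1L + stats::rpois(nf, pmax(lam[fac$facility_category] - 1, 0))
    fidx <- rep(seq_len(nf), n_cl)
    no <- length(fidx)
    obs <- data.frame(
      obs_id = sprintf("o%05d", seq_len(no)),
      facility_id = fac$facility_id[fidx],
      weight = exp(stats::rnorm(no, 0, p$client_weight_sdlog)),
      stringsAsFactors = FALSE
    )
    qi <- p$quality_items
    for (j in seq_len(nrow(qi))) {
      pr <- unlist(qi[j, fac$facility_category[fidx]], use.names = FALSE)
      obs[[paste0("item_", qi$code[j])]] <- stats::rbinom(no, 1, pr)
    }
  }

  new_bundle(women, fac, obs, params_config(p))
}

# country configuration implied by generator parameters
params_config <- function(p) {
  ri <- p$readiness_items
  qi <- p$quality_items
  idx <- function(tab, sel, name, target) {
    list(name = name, target = target,
         items = data.frame(code = tab$code[sel],
                            domain = tab$domain[sel],
                            kind = if ("kind" %in% names(tab)) tab$kind[sel] else "binary",
                            stringsAsFactors = FALSE),
         country_mask = tab$code[sel])
  }
  iv <- p$interventions
  as_country_config(list(
    country = p$country,
    geo_domain_level = "region",
    has_quality_data = p$has_quality_data,
    contact_thresholds = c(1L, 4L, 8L),
    indices = list(
      anc_readiness = idx(ri, ri$in_anc, "anc_readiness", "facility"),
      mn_readiness = idx(ri, ri$in_mn, "mn_readiness", "facility"),
      anc_quality = idx(qi, qi$in_anc, "anc_quality", "client"),
      mn_quality = idx(qi, qi$in_mn, "mn_quality", "client")
    ),
    intervention_sets = list(
      anc = list(service = "ANC", interventions = iv$code, country_mask = iv$code[iv$in_anc]),
      mn = list(service = "MN", interventions = iv$code, country_mask = iv$code[iv$in_mn])
    ),
    provider_mapping = p$provider_mapping
  ))
}

#' Closed-form expected cascade values for generator parameters
#'
#' Derives the expectation of every cascade step analytically from the
#' generator model: contact from the pattern and visit-count distributions
#' (unknown counts imputed as one visit), adjusted steps by enumerating the
#' configured source sets and averaging the per-category expected scores
#' (mean item probability over the index mask), intervention coverage from
#' the receipt probabilities. All pipeline estimators are unbiased for these
#' values, because scores and weights are independent of care-seeking.
#'
#' @param params A `cc_params`.
#' @return A data frame `service`, `k`, `step`, `truth`.
#' @export
closed_form_truth <- function(params) {
  p <- params
  validate_params(p)
  cats <- names(p$categories)

  expected_cat_score <- function(tab, sel) {
    m <- as.matrix(tab[sel, cats, drop = FALSE])
    colMeans(m)
  }
  r_cat <- list(
    anc_readiness = expected_cat_score(p$readiness_items, p$readiness_items$in_anc),
    mn_readiness = expected_cat_score(p$readiness_items, p$readiness_items$in_mn),
    anc_quality = expected_cat_score(p$quality_items, p$quality_items$in_anc),
    mn_quality = expected_cat_score(p$quality_items, p$quality_items$in_mn)
  )

  pattern_score <- function(sources, index) {
    vals <- numeric(0)
    for (code in unique(sources)) {
      tgt <- p$provider_mapping[[code]]
      if (is.numeric(tgt)) vals <- c(vals, tgt)
      else if (!identical(tgt, "UNQUALIFIED")) vals <- c(vals, r_cat[[index]][[tgt]])
    }
    if (length(vals)) mean(vals) else NA_real_   # NA = no qualified source
  }

  probs <- vapply(p$source_patterns, `[[`, numeric(1), "prob")
  srcs <- lapply(p$source_patterns, `[[`, "sources")
  p_visits_ge <- function(k) {
    if (k <= 1) return(1)
    p_ge1 <- stats::pnbinom(0, mu = p$visit_mu, size = p$visit_size, lower.tail = FALSE)
    p_gek <- stats::pnbinom(k - 1, mu = p$visit_mu, size = p$visit_size, lower.tail = FALSE)
    (1 - p$p_unknown_visits) * p_gek / p_ge1
  }

  iv <- p$interventions
  p_qual <- sum(probs[vapply(srcs, function(s) !is.na(pattern_score(s, "anc_readiness")), logical(1))])
  interv_truth <- function(sel) {
    p_qual * mean(iv$p_contact[sel]) + (1 - p_qual) * mean(iv$p_nocontact[sel])
  }

  out <- list()
  for (svc in c("anc", "mn")) {
    ridx <- paste0(svc, "_readiness")
    qidx <- paste0(svc, "_quality")
    iv_sel <- iv[[paste0("in_", svc)]]
    for (k in c(1L, 4L, 8L)) {
      pv <- p_visits_ge(k)
      contact <- 0; r_adj <- 0; q_adj <- 0
      for (i in seq_along(probs)) {
        s_r <- pattern_score(srcs[[i]], ridx)
        if (is.na(s_r)) next
        contact <- contact + probs[i] * pv
        r_adj <- r_adj + probs[i] * pv * s_r
        if (p$has_quality_data) {
          q_adj <- q_adj + probs[i] * pv * pattern_score(srcs[[i]], qidx)
        }
      }
      steps <- c(target = 1, contact = contact, readiness_adjusted = r_adj,
                 intervention = interv_truth(iv_sel),
                 quality_adjusted = if (p$has_quality_data) q_adj else NA_real_)
      out[[paste(svc, k)]] <- data.frame(
        service = toupper(svc), k = k, step = names(steps), truth = unname(steps),
        stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
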