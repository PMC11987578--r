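# Fixtures built in code: a hand-sized toy country and small random bundles.

toy_config <- function(has_quality_data = TRUE, mapping = NULL) {
  as_country_config(list(
    country = "toyland",
    geo_domain_level = "region",
    has_quality_data = has_quality_data,
    indices = list(
      anc_readiness = list(items = data.frame(
        code = c("a", "b", "c", "t"),
        domain = c("equipment", "equipment", "medicines", "human_resources"),
        kind = c("binary", "binary", "binary", "proportion"),
        stringsAsFactors = FALSE
      )),
      mn_readiness = list(items = data.frame(
        code = c("a", "c"), domain = c("equipment", "medicines"),
        kind = "binary", stringsAsFactors = FALSE
      )),
      anc_quality = list(items = data.frame(
        code = c("q1", "q2", "q3"),
        domain = c("examination", "counselling", "experience"),
        kind = "binary", stringsAsFactors = FALSE
      )),
      mn_quality = list(items = data.frame(
        code = c("q1", "q3"), domain = c("examination", "experience"),
        kind = "binary", stringsAsFactors = FALSE
      ))
    ),
    intervention_sets = list(
      anc = list(interventions = c("tt", "sp", "ifa", "bp", "urine", "blood", "deworming"),
                 country_mask = c("tt", "ifa", "bp", "urine")),
      mn = list(interventions = c("sp", "ifa", "blood", "deworming"),
                country_mask = c("ifa", "blood"))
    ),
    provider_mapping = mapping %||% list(
      hosp = "hospital", hc = "health_centre", chw = "health_centre",
      th = "UNQUALIFIED"
    )
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

toy_facilities <- function() {
  data.frame(
    facility_id = c("f1", "f2", "f3", "f4"),
    weight = c(2, 1, 1, 3),
    geo_domain = c("r1", "r1", "r2", "r2"),
    facility_category = c("hospital", "health_centre", "health_centre", "health_centre"),
    offers_anc = TRUE,
    item_a = c(1, 1, 0, 1),
    item_b = c(1, NA, 1, 0),
    item_c = c(0, 0, 1, 1),
    train_t = c(0.5, 0.25, 1, 0.75),
    stringsAsFactors = FALSE
  )
}

toy_women <- function() {
  data.frame(
    woman_id = paste0("w", 1:6),
    weight = c(1, 1, 2, 1, 1, 1),
    cluster_id = c("c1", "c1", "c2", "c2", "c3", "c3"),
    design_stratum = c("s1", "s1", "s1", "s1", "s2", "s2"),
    geo_domain = c("r1", "r1", "r1", "r2", "r2", "r2"),
    any_anc = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE),
    n_visits = c(4L, NA, 8L, NA, 1L, 2L),
    sources = c("hc", "hosp;th", "hosp;hc", "", "th", "hc"),
    recv_tt = c(1, 1, 0, 0, NA, 1),
    recv_ifa = c(0, NA, 1, 0, NA, 1),
    recv_bp = c(1, 0, 1, NA, NA, 0),
    recv_urine = c(NA, NA, 1, 0, NA, 1),
    stringsAsFactors = FALSE
  )
}

toy_observations <- function() {
  data.frame(
    obs_id = paste0("o", 1:5),
    facility_id = c("f1", "f1", "f2", "f3", "f4"),
    weight = c(1, 1, 2, 1, 2),
    item_q1 = c(1, 0, 1, 1, 0),
    item_q2 = c(0, 0, 1, 0, 1),
    item_q3 = c(1, 1, NA, 1, 0),
    stringsAsFactors = FALSE
  )
}

toy_bundle <- function(has_quality_data = TRUE) {
  new_bundle(toy_women(), toy_facilities(),
             if (has_quality_data) toy_observations(),
             toy_config(has_quality_data))
}

# small random bundle: <= 50 women, 10 facilities, every category has >= 2
# facilities so no jackknife replicate can empty a national category
rand_params <- function(...) {
  cc_params(n_domains = 2, n_clusters = 6, women_per_cluster = 8,
            categories = list(
              public_hospital = list(n_per_domain = 1, lambda_clients = 4),
              public_health_centre = list(n_per_domain = 3, lambda_clients = 3),
              private_clinic = list(n_per_domain = 1, lambda_clients = 2)
            ), ...)
}

rand_bundle <- function(seed, ...) generate_bundle(rand_params(...), seed)
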