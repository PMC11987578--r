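test_that("Taylor variance matches the two-cluster closed form", {
  # one stratum, two equal-weight clusters with means p1 and p2
  y <- c(1, 0, 1, 1)             # cluster means 0.5 and 1
  w <- rep(1, 4)
  cl <- c("a", "a", "b", "b")
  st <- rep("s1", 4)
  v <- taylor_variance(y, w, cl, st)
  expect_equal(v$se, abs(0.5 - 1) / 2)
  expect_identical(v$df, 1L)

  # identical cluster means give zero variance
  v0 <- taylor_variance(c(1, 0, 1, 0), w, cl, st)
  expect_equal(v0$variance, 0)
})

test_that("Taylor variance equals an independent linearisation oracle", {
  for (seed in c(41, 42)) {
    b <- rand_bundle(seed)
    mapping <- b$config$provider_mapping
    y <- contact_indicator(b$women, 4, mapping)
    v <- taylor_variance(y, b$women$weight, b$women$cluster_id, b$women$design_stratum)
    expect_equal(v$variance,
                 o_taylor_var(y, b$women$weight, b$women$cluster_id, b$women$design_stratum),
                 tolerance = 1e-10)
    # domain estimator: some women excluded (all receipts missing)
    s <- effcascade:::intervention_score(b$women, b$config$intervention_sets$anc)
    vi <- taylor_variance(s, b$women$weight, b$women$cluster_id, b$women$design_stratum)
    expect_equal(vi$variance,
                 o_taylor_var(s, b$women$weight, b$women$cluster_id, b$women$design_stratum),
                 tolerance = 1e-10)
  }
})

test_that("single-cluster strata are collapsed, all-lonely designs refused", {
  y <- c(1, 0, 1, 1, 0, 1)
  w <- rep(1, 6)
  cl <- c("a", "a", "b", "b", "c", "c")
  st <- c("s1", "s1", "s1", "s1", "s2", "s2")   # s2 has one cluster
  v <- taylor_variance(y, w, cl, st)
  expect_true(is.finite(v$variance) && v$variance >= 0)
  expect_identical(v$df, 2L)    # 3 clusters - 1 collapsed stratum
  expect_error(taylor_variance(y, w, cl, c("s1", "s1", "s2", "s2", "s3", "s3")),
               "all-lonely")
})

test_that("degenerate designs yield zero jackknife variance", {
  # identical clusters and identical facilities: nothing varies
  cfg <- toy_config(has_quality_data = FALSE)
  women <- data.frame(
    woman_id = paste0("w", 1:6), weight = 1,
    cluster_id = rep(c("c1", "c2", "c3"), each = 2),
    design_stratum = "s1", geo_domain = "r1",
    any_anc = TRUE, n_visits = 4L, sources = "hc",
    stringsAsFactors = FALSE
  )
  fac <- data.frame(
    facility_id = c("f1", "f2", "f3"), weight = 1, geo_domain = "r1",
    facility_category = "health_centre", offers_anc = TRUE,
    item_a = 1, item_b = 0, item_c = 1, train_t = 0.5,
    stringsAsFactors = FALSE
  )
  b <- new_bundle(women, fac, NULL, cfg)
  v <- jackknife2_variance(b, "anc", 1, "readiness")
  expect_equal(v$variance, 0)

  # constant facility scores: the facility component vanishes exactly
  b2 <- b
  b2$women$n_visits <- c(4L, 1L, 8L, 2L, 1L, 6L)
  v2 <- jackknife2_variance(b2, "anc", 4, "readiness")
  expect_equal(v2$var_facility, 0)
  expect_equal(v2$variance, v2$var_cluster)
  expect_gte(v2$var_cluster, 0)
})

test_that("jackknife components are non-negative and additive", {
  b <- rand_bundle(51)
  v <- jackknife2_variance(b, "anc", 1, "quality")
  expect_gte(v$var_cluster, 0)
  expect_gte(v$var_facility, 0)
  expect_equal(v$variance, v$var_cluster + v$var_facility)
  expect_equal(v$se, sqrt(v$variance))
  expect_true(v$ci_low >= 0 && v$ci_high <= 1)
})

test_that("two-survey jackknife equals the brute-force oracle", {
  b <- rand_bundle(52)
  for (case in list(c("anc", 1, "readiness"), c("mn", 4, "quality"))) {
    v <- jackknife2_variance(b, case[1], as.integer(case[2]), case[3])
    o <- o_jackknife2_var(b, case[1], as.integer(case[2]), case[3])
    expect_equal(v$var_cluster, o$var_cluster, tolerance = 1e-10)
    expect_equal(v$var_facility, o$var_facility, tolerance = 1e-10)
  }
})

test_that("duplicating clusters with halved weights cannot inflate variance", {
  b <- rand_bundle(53)
  w2 <- b$women
  dup <- transform(w2, woman_id = paste0(woman_id, "_d"),
                   cluster_id = paste0(cluster_id, "_d"))
  both <- rbind(transform(w2, weight = weight / 2),
                transform(dup, weight = weight / 2))
  b2 <- new_bundle(both, b$facilities, b$observations, b$config)
  r1 <- run_cascades(b, services = "anc", ks = 1, variance = "full")
  r2 <- run_cascades(b2, services = "anc", ks = 1, variance = "full")
  expect_equal(r2$estimate, r1$estimate, tolerance = 1e-12)
  sel <- r1$step %in% c("contact", "readiness_adjusted", "quality_adjusted", "intervention")
  expect_true(all(r2$se[sel] <= r1$se[sel] + 1e-12))
})

test_that("with constant unit scores the jackknife approaches scaled Taylor", {
  # every readiness item present everywhere: all facility scores are exactly 1,
  # so adjusted coverage = contact and its only variability is the household
  # survey's
  ri <- default_readiness_items()
  ri[, c("public_hospital", "public_health_centre", "private_clinic")] <- 1
  p <- cc_params(n_domains = 2, n_clusters = 100, women_per_cluster = 8,
                 readiness_items = ri, has_quality_data = FALSE)
  b <- generate_bundle(p, 99)
  v <- jackknife2_variance(b, "anc", 1, "readiness")
  expect_equal(v$var_facility, 0, tolerance = 1e-20)
  tv <- taylor_variance(contact_indicator(b$women, 1, b$config$provider_mapping),
                        b$women$weight, b$women$cluster_id, b$women$design_stratum)
  expect_lt(abs(v$se / tv$se - 1), 0.1)
})
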