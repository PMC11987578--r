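test_that("generation is deterministic given parameters and seed", {
  p <- rand_params()
  b1 <- generate_bundle(p, 123)
  b2 <- generate_bundle(p, 123)
  expect_identical(b1$women, b2$women)
  expect_identical(b1$facilities, b2$facilities)
  expect_identical(b1$observations, b2$observations)
  b3 <- generate_bundle(p, 124)
  expect_false(identical(b1$women, b3$women))
})

test_that("generated bundles are schema-valid with a consistent configuration", {
  b <- rand_bundle(61)
  expect_identical(nrow(b$diagnostics), 0L)
  expect_identical(nrow(validate_config(b$config, women = b$women,
                                        facilities = b$facilities)), 0L)
  expect_true(all(b$women$weight > 0))
  expect_true(all(is.na(b$women$n_visits) | b$women$n_visits >= 1))
  # unsure-visit sentinel only among women with ANC
  expect_true(all(b$women$any_anc | is.na(b$women$n_visits)))
})

test_that("a population that never seeks ANC produces an all-zero cascade", {
  iv <- default_interventions()
  iv$p_nocontact <- 0
  p <- cc_params(source_patterns = list(list(sources = character(0), prob = 1)),
                 interventions = iv, has_quality_data = FALSE)
  b <- generate_bundle(p, 7)
  res <- run_cascades(b, variance = "none")
  after <- res$estimate[res$step != "target"]
  expect_true(all(after == 0))
  tt <- closed_form_truth(p)
  expect_true(all(tt$truth[tt$step %in% c("contact", "readiness_adjusted",
                                          "intervention")] == 0))
})

test_that("perfect item availability collapses the readiness gap exactly", {
  ri <- default_readiness_items()
  ri[, c("public_hospital", "public_health_centre", "private_clinic")] <- 1
  p <- cc_params(readiness_items = ri, has_quality_data = FALSE)
  b <- generate_bundle(p, 8)
  res <- run_cascades(b, services = "anc", variance = "none")
  for (k in c(1, 4, 8)) {
    sub <- res[res$k == k, ]
    expect_equal(sub$estimate[sub$step == "readiness_adjusted"],
                 sub$estimate[sub$step == "contact"], tolerance = 1e-12)
  }
  tt <- closed_form_truth(p)
  expect_equal(tt$truth[tt$service == "ANC" & tt$k == 1 & tt$step == "readiness_adjusted"],
               tt$truth[tt$service == "ANC" & tt$k == 1 & tt$step == "contact"])
})

test_that("closed-form truth obeys the cascade ordering for random parameters", {
  set.seed(71)
  for (rep in 1:100) {
    ri <- default_readiness_items()
    qi <- default_quality_items()
    cats <- c("public_hospital", "public_health_centre", "private_clinic")
    ri[, cats] <- matrix(runif(nrow(ri) * 3), nrow(ri))
    qi[, cats] <- matrix(runif(nrow(qi) * 3), nrow(qi))
    pr <- runif(5); pr <- pr / sum(pr)
    pats <- list(
      list(sources = character(0), prob = pr[1]),
      list(sources = "unqualified", prob = pr[2]),
      list(sources = "public_health_centre", prob = pr[3]),
      list(sources = c("public_hospital", "chw"), prob = pr[4]),
      list(sources = "private_clinic", prob = pr[5])
    )
    p <- cc_params(readiness_items = ri, quality_items = qi,
                   source_patterns = pats,
                   visit_mu = runif(1, 1, 6), visit_size = runif(1, 0.5, 5),
                   p_unknown_visits = runif(1, 0, 0.1))
    tt <- closed_form_truth(p)
    expect_true(all(tt$truth >= 0 & tt$truth <= 1))
    for (sv in c("ANC", "MN")) {
      ct <- sapply(c(1, 4, 8), function(k)
        tt$truth[tt$service == sv & tt$k == k & tt$step == "contact"])
      expect_true(ct[3] <= ct[2] + 1e-12 && ct[2] <= ct[1] + 1e-12)
      for (k in c(1, 4, 8)) {
        sub <- tt[tt$service == sv & tt$k == k, ]
        expect_lte(sub$truth[sub$step == "readiness_adjusted"],
                   sub$truth[sub$step == "contact"] + 1e-12)
        expect_lte(sub$truth[sub$step == "quality_adjusted"],
                   sub$truth[sub$step == "contact"] + 1e-12)
      }
    }
  }
})

test_that("two equally likely sole-source categories average their scores", {
  # categories with expected readiness 0.4 and 0.8, certain contact
  ri <- default_readiness_items()[1:2, ]
  ri$in_anc <- TRUE; ri$in_mn <- TRUE; ri$kind <- "binary"
  ri$public_hospital <- 0.8
  ri$public_health_centre <- 0.4
  ri$private_clinic <- 0.5
  p <- cc_params(
    readiness_items = ri,
    source_patterns = list(
      list(sources = "public_hospital", prob = 0.5),
      list(sources = "public_health_centre", prob = 0.5)
    ),
    p_unknown_visits = 0, has_quality_data = FALSE
  )
  tt <- closed_form_truth(p)
  expect_equal(tt$truth[tt$service == "ANC" & tt$k == 1 & tt$step == "contact"], 1)
  expect_equal(tt$truth[tt$service == "ANC" & tt$k == 1 & tt$step == "readiness_adjusted"],
               0.6)
})

test_that("infeasible parameters are rejected", {
  cats <- list(public_hospital = list(n_per_domain = 0, lambda_clients = 4),
               public_health_centre = list(n_per_domain = 3, lambda_clients = 4),
               private_clinic = list(n_per_domain = 1, lambda_clients = 3))
  expect_error(cc_params(categories = cats), "infeasible-params")
  expect_error(cc_params(source_patterns = list(list(sources = "hc", prob = 0.5))),
               "bad-params")
})
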