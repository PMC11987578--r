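test_that("unsure visit counts are imputed as one contact", {
  mapping <- list(hc = "health_centre", th = "UNQUALIFIED")
  woman <- data.frame(woman_id = "w1", weight = 1, cluster_id = "c1",
                      design_stratum = "s1", geo_domain = "r1",
                      any_anc = TRUE, n_visits = NA_integer_, sources = "hc",
                      stringsAsFactors = FALSE)
  expect_equal(contact_indicator(woman, 1, mapping), 1)
  expect_equal(contact_indicator(woman, 4, mapping), 0)
  expect_equal(contact_indicator(woman, 8, mapping), 0)

  # eight visits counts at every threshold
  w8 <- transform(woman, n_visits = 8L)
  for (k in c(1, 4, 8)) expect_equal(contact_indicator(w8, k, mapping), 1)

  # care only from unqualified providers is not service contact
  wu <- transform(woman, sources = "th", n_visits = 5L)
  for (k in c(1, 4, 8)) expect_equal(contact_indicator(wu, k, mapping), 0)
})

test_that("service contact is the weighted proportion over the target population", {
  mapping <- list(hc = "health_centre")
  women <- data.frame(
    woman_id = paste0("w", 1:5),
    weight = c(1, 1, 2, 1, 1),
    cluster_id = "c1", design_stratum = "s1", geo_domain = "r1",
    any_anc = c(FALSE, TRUE, TRUE, TRUE, TRUE),
    n_visits = c(NA, 1L, 4L, NA, 8L),
    sources = c("", "hc", "hc", "hc", "hc"),
    stringsAsFactors = FALSE
  )
  expect_equal(service_contact(women, 1, mapping), 5 / 6)
  expect_equal(service_contact(women, 4, mapping), 3 / 6)
  expect_equal(service_contact(women, 8, mapping), 1 / 6)

  all0 <- transform(women, any_anc = FALSE, n_visits = NA_integer_, sources = "")
  expect_equal(service_contact(all0, 1, mapping), 0)
  all8 <- transform(women, any_anc = TRUE, n_visits = 9L, sources = "hc")
  for (k in c(1, 4, 8)) expect_equal(service_contact(all8, k, mapping), 1)
})

test_that("intervention coverage averages per-woman receipt scores", {
  set <- list(service = "ANC", interventions = c("a", "b", "c", "d"),
              country_mask = c("a", "b", "c", "d"))
  women <- data.frame(woman_id = c("w1", "w2"), weight = 1,
                      cluster_id = "c1", design_stratum = "s1", geo_domain = "r1",
                      any_anc = TRUE, n_visits = 1L, sources = "hc",
                      recv_a = c(1, 0), recv_b = c(1, 0),
                      recv_c = c(0, 1), recv_d = c(1, 1),
                      stringsAsFactors = FALSE)
  expect_equal(as.numeric(intervention_coverage(women, set)), 0.625)

  # missing receipts shrink the woman's denominator, not her score
  w3 <- women[1, ]
  w3$recv_b <- NA; w3$recv_d <- NULL
  set3 <- list(interventions = c("a", "b", "c"), country_mask = c("a", "b", "c"))
  expect_equal(as.numeric(intervention_coverage(w3, set3)), 0.5)

  # women with everything missing are excluded entirely
  w4 <- rbind(women[1, ], transform(women[2, ], recv_a = NA, recv_b = NA,
                                    recv_c = NA, recv_d = NA))
  out <- intervention_coverage(w4, set)
  expect_equal(as.numeric(out), 0.75)
  expect_identical(attr(out, "n_included"), 1L)

  all1 <- transform(women, recv_a = 1, recv_b = 1, recv_c = 1, recv_d = 1)
  expect_equal(as.numeric(intervention_coverage(all1, set)), 1)
})

test_that("adjusted coverage multiplies contact by the linked score", {
  mapping <- list(hc = "health_centre")
  women <- data.frame(
    woman_id = paste0("w", 1:3), weight = 1,
    cluster_id = "c1", design_stratum = "s1", geo_domain = "r1",
    any_anc = c(TRUE, TRUE, FALSE), n_visits = c(2L, 3L, NA),
    sources = c("hc", "hc", ""), stringsAsFactors = FALSE
  )
  ws <- data.frame(woman_id = paste0("w", 1:3),
                   anc_readiness = c(0.5, 1.0, 0.9))
  expect_equal(adjusted_coverage(women, ws, 1, "anc_readiness", mapping), 0.5)

  # perfect scores make adjustment the identity; zero scores annihilate
  ws1 <- transform(ws, anc_readiness = 1)
  expect_equal(adjusted_coverage(women, ws1, 1, "anc_readiness", mapping),
               service_contact(women, 1, mapping))
  ws0 <- transform(ws, anc_readiness = 0)
  expect_equal(adjusted_coverage(women, ws0, 1, "anc_readiness", mapping), 0)
})

test_that("cascades carry the expected ordered steps", {
  b <- rand_bundle(21)
  cas <- build_cascade(b, "anc", k = 1, variance = "none")
  expect_identical(as.character(cas$step),
                   c("target", "contact", "readiness_adjusted", "intervention",
                     "quality_adjusted"))
  expect_identical(cas$estimate[1], 1)

  # no direct observation of care: cascade ends at intervention coverage
  bq <- generate_bundle(rand_params(has_quality_data = FALSE), 21)
  cas4 <- build_cascade(bq, "anc", k = 1, variance = "none")
  expect_identical(nrow(cas4), 4L)
  expect_false("quality_adjusted" %in% cas4$step)

  # maternal nutrition routes through its own indices and intervention set
  casm <- build_cascade(b, "mn", k = 1, variance = "none")
  expect_false(isTRUE(all.equal(casm$estimate[3], cas$estimate[3])))
  expect_false(isTRUE(all.equal(casm$estimate[4], cas$estimate[4])))
})

test_that("cascade invariants hold on random bundles", {
  for (seed in c(31, 32)) {
    b <- rand_bundle(seed)
    res <- run_cascades(b, variance = "none")
    expect_true(all(res$estimate >= 0 & res$estimate <= 1))
    for (sv in c("ANC", "MN")) {
      sub <- res[res$service == sv, ]
      contact <- sapply(c(1, 4, 8), function(k) sub$estimate[sub$k == k & sub$step == "contact"])
      expect_true(contact[3] <= contact[2] && contact[2] <= contact[1])
      for (k in c(1, 4, 8)) {
        ck <- sub$estimate[sub$k == k & sub$step == "contact"]
        expect_lte(sub$estimate[sub$k == k & sub$step == "readiness_adjusted"], ck + 1e-12)
        expect_lte(sub$estimate[sub$k == k & sub$step == "quality_adjusted"], ck + 1e-12)
      }
      # intervention coverage is not restricted by the visit threshold
      iv <- sub$estimate[sub$step == "intervention"]
      expect_true(all(abs(iv - iv[1]) < 1e-15))
    }
  }
})

test_that("net declines and relative changes match the reporting arithmetic", {
  expect_equal(net_decline_pp(0.95, 0.43), 52)
  expect_equal(relative_change(0.95, 0.43), (0.95 - 0.43) / 0.95)
  expect_equal(net_decline_pp(0.4, 0.4), 0)
  expect_equal(relative_change(0.4, 0.4), 0)
  expect_true(is.na(relative_change(0, 0.1)))
  # cross-country average is the unweighted mean of per-country declines
  expect_equal(mean(net_decline_pp(c(0.9, 0.8, 0.7), c(0.5, 0.6, 0.3))),
               mean(c(40, 20, 40)))
})
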