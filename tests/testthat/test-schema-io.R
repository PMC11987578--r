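fixture <- function(f) system.file("extdata", f, package = "effcascade")

test_that("shipped toy tables load, validate and round-trip through CSV", {
  cfg <- read_country_config(fixture("config.yaml"))
  expect_s3_class(cfg, "cc_config")
  expect_identical(nrow(validate_config(cfg)), 0L)

  b <- load_tables(list(women = fixture("women.csv"),
                        facilities = fixture("facilities.csv"),
                        observations = fixture("observations.csv")), cfg)
  expect_identical(nrow(b$women), 3L)
  expect_identical(nrow(b$facilities), 3L)
  expect_identical(nrow(b$observations), 3L)
  expect_identical(nrow(b$diagnostics), 0L)
  # the unsure-visits sentinel survives, distinct from no-ANC
  expect_true(b$women$any_anc[2] && is.na(b$women$n_visits[2]))
  # NOT_COLLECTED stays distinct from zero
  expect_true(is.na(b$facilities$item_b[2]))

  dir <- withr::local_tempdir()
  write_bundle(b, dir)
  b2 <- load_tables(list(women = file.path(dir, "women.csv"),
                         facilities = file.path(dir, "facilities.csv"),
                         observations = file.path(dir, "observations.csv")),
                    file.path(dir, "config.yaml"))
  for (tab in c("women", "facilities", "observations")) {
    expect_identical(dim(b[[tab]]), dim(b2[[tab]]))
    for (cl in names(b[[tab]])) {
      x <- b[[tab]][[cl]]; y <- b2[[tab]][[cl]]
      if (is.numeric(x)) expect_equal(y, x, tolerance = 1e-12)
      else expect_identical(y, x)
    }
  }
})

test_that("parquet is accepted as an equivalent storage format", {
  b <- toy_bundle()
  dir <- withr::local_tempdir()
  write_bundle(b, dir, format = "parquet")
  w2 <- read_women(file.path(dir, "women.parquet"))
  expect_equal(w2$weight, b$women$weight, tolerance = 1e-12)
  expect_identical(w2$sources, b$women$sources)
})

test_that("row validation is total: each row accepted or exactly one diagnostic", {
  w <- toy_women()
  w$any_anc[1] <- FALSE; w$n_visits[1] <- NA # sources without ANC
  w$weight[2] <- -1                          # and a bad weight on another row
  w$sources[5] <- "martian"                  # unmapped source code
  v <- validate_women(w, toy_config())
  expect_identical(nrow(v$records) + nrow(v$diagnostics), nrow(w))
  expect_identical(sort(v$diagnostics$id), c("w1", "w2", "w5"))
  # one diagnostic per rejected row even when several invariants fail
  expect_identical(anyDuplicated(v$diagnostics$id), 0L)
  expect_setequal(
    v$diagnostics$code[match(c("w1", "w2"), v$diagnostics$id)],
    c("sources-without-anc", "bad-weight")
  )
})

test_that("facilities not offering ANC are excluded from the scoring view", {
  f <- toy_facilities()[rep(1:4, length.out = 10), ]
  f$facility_id <- paste0("f", 1:10)
  f$offers_anc <- rep(c(TRUE, TRUE, TRUE, TRUE, FALSE), 2)
  b <- new_bundle(toy_women(), f, NULL, toy_config(has_quality_data = FALSE))
  expect_identical(nrow(b$facilities), 8L)
  expect_identical(b$n_facilities_total, 10L)
})

test_that("structural problems are fatal with a clear report", {
  w <- toy_women(); w$weight <- NULL
  expect_error(load_tables(list(women = {
    p <- withr::local_tempfile(fileext = ".csv"); utils::write.csv(w, p, row.names = FALSE); p
  }, facilities = ""), toy_config()), "weight")

  o <- toy_observations(); o$facility_id[2] <- "f99"
  expect_error(new_bundle(toy_women(), toy_facilities(), o, toy_config()),
               "dangling-facility")

  w2 <- toy_women(); w2$recv_unicorn <- 1
  expect_error(validate_women(w2, toy_config()), "schema-mismatch")
})

test_that("config validation flags real defects and passes country-style masks", {
  # a maternal-nutrition mask without SP (not collected in some countries)
  # is a valid configuration, not a finding
  cfg <- toy_config()
  expect_identical(nrow(validate_config(cfg)), 0L)

  # unmapped provider used in the women table
  w <- toy_women(); w$sources[1] <- "pharmacy"
  f1 <- validate_config(cfg, women = w)
  expect_true("unmapped-provider" %in% f1$code)

  # duplicate item code in an index
  cfg2 <- toy_config()
  cfg2$indices$anc_readiness$items <- rbind(cfg2$indices$anc_readiness$items,
                                            cfg2$indices$anc_readiness$items[1, ])
  expect_true("dup-item" %in% validate_config(cfg2)$code)

  # missing required intervention from the universe
  cfg3 <- toy_config()
  cfg3$intervention_sets$anc$interventions <- c("tt", "ifa")
  cfg3$intervention_sets$anc$country_mask <- c("tt", "ifa")
  expect_true("missing-universe-item" %in% validate_config(cfg3)$code)

  # mapping to a category with no facilities
  f2 <- validate_config(cfg, facilities = toy_facilities()[2:4, ])
  expect_true("unknown-category" %in% f2$code)
})
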