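# Canonical flat tables
#
# women.csv:        woman_id, weight, cluster_id, design_stratum, geo_domain,
#                   any_anc, n_visits, sources (semicolon-delimited), recv_<code>...
# facilities.csv:   facility_id, weight, geo_domain, facility_category,
#                   offers_anc, item_<code>..., train_<code>...
# observations.csv: obs_id, facility_id, weight, item_<code>...
#
# Empty cells are NA. On women, NA n_visits with any_anc = TRUE is the
# "unsure how many visits" sentinel; NA in a recv_ column means the receipt
# question was missing; NA in item_/train_ columns means the item was not
# collected for that unit (distinct from an observed 0).

WOMEN_BASE_COLS <- c("woman_id", "weight", "cluster_id", "design_stratum",
                     "geo_domain", "any_anc", "n_visits", "sources")
FACILITY_BASE_COLS <- c("facility_id", "weight", "geo_domain",
                        "facility_category", "offers_anc")
OBS_BASE_COLS <- c("obs_id", "facility_id", "weight")

read_flat <- function(path) {
  if (grepl("\\.parquet$", path)) {
    if (!requireNamespace("arrow", quietly = TRUE)) {
      stop_cc("no-parquet-support", "reading %s requires the 'arrow' package", path)
    }
    as.data.frame(arrow::read_parquet(path))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
}

write_flat <- function(df, path) {
  if (grepl("\\.parquet$", path)) {
    if (!requireNamespace("arrow", quietly = TRUE)) {
      stop_cc("no-parquet-support", "writing %s requires the 'arrow' package", path)
    }
    arrow::write_parquet(df, path)
  } else {
    utils::write.csv(df, path, row.names = FALSE, na = "")
  }
  invisible(path)
}

check_columns <- function(df, required, what, path) {
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop_cc("schema-mismatch", "%s table (%s) is missing column(s): %s",
            what, path, paste(missing, collapse = ", "))
  }
}

coerce_logical <- function(x) {
  if (is.logical(x)) return(x)
  if (is.numeric(x)) return(x != 0)
  tolower(as.character(x)) %in% c("true", "t", "1", "yes")
}

#' Read a women table
#'
#' @param path CSV (or Parquet) file following the canonical women schema.
#' @return A data frame; types coerced (`any_anc` logical, `n_visits`
#'   integer, `recv_` columns numeric).
#' @export
read_women <- function(path) {
  df <- read_flat(path)
  check_columns(df, WOMEN_BASE_COLS, "women", path)
  df$woman_id <- as.character(df$woman_id)
  df$cluster_id <- as.character(df$cluster_id)
  df$design_stratum <- as.character(df$design_stratum)
  df$geo_domain <- as.character(df$geo_domain)
  df$any_anc <- coerce_logical(df$any_anc)
  df$n_visits <- suppressWarnings(as.integer(df$n_visits))
  df$sources <- ifelse(is.na(df$sources), "", as.character(df$sources))
  for (cl in grep("^recv_", names(df), value = TRUE)) df[[cl]] <- as.numeric(df[[cl]])
  df
}

#' Read a facility table
#' @param path CSV (or Parquet) file following the canonical facility schema.
#' @return A data frame.
#' @export
read_facilities <- function(path) {
  df <- read_flat(path)
  check_columns(df, FACILITY_BASE_COLS, "facility", path)
  df$facility_id <- as.character(df$facility_id)
  df$geo_domain <- as.character(df$geo_domain)
  df$facility_category <- as.character(df$facility_category)
  df$offers_anc <- coerce_logical(df$offers_anc)
  for (cl in grep("^(item|train)_", names(df), value = TRUE)) df[[cl]] <- as.numeric(df[[cl]])
  df
}

#' Read a client-observation table
#' @param path CSV (or Parquet) file following the canonical observation schema.
#' @return A data frame.
#' @export
read_observations <- function(path) {
  df <- read_flat(path)
  check_columns(df, OBS_BASE_COLS, "observation", path)
  df$obs_id <- as.character(df$obs_id)
  df$facility_id <- as.character(df$facility_id)
  for (cl in grep("^item_", names(df), value = TRUE)) df[[cl]] <- as.numeric(df[[cl]])
  df
}

diag_row <- function(table, id, code, message) {
  data.frame(table = table, id = id, code = code, message = message,
             stringsAsFactors = FALSE)
}

no_diags <- function() {
  data.frame(table = character(), id = character(), code = character(),
             message = character(), stringsAsFactors = FALSE)
}

# Row-level validation. Each row is either accepted or rejected with exactly
# one diagnostic (the first violated invariant).
validate_women <- function(women, config) {
  config <- as_country_config(config)
  known_recv <- unique(unlist(lapply(config$intervention_sets, `[[`, "interventions")))
  recv_cols <- grep("^recv_", names(women), value = TRUE)
  unknown <- setdiff(sub("^recv_", "", recv_cols), known_recv)
  if (length(unknown)) {
    stop_cc("schema-mismatch", "unknown intervention column(s): %s",
            paste0("recv_", unknown, collapse = ", "))
  }
  src <- split_sources(women$sources)
  mapped <- names(config$provider_mapping)
  codes <- character(nrow(women))
  codes[!is.finite(women$weight) | women$weight <= 0] <- "bad-weight"
  i <- codes == "" & !women$any_anc & !is.na(women$n_visits)
  codes[i] <- "visits-without-anc"
  i <- codes == "" & !women$any_anc & lengths(src) > 0
  codes[i] <- "sources-without-anc"
  i <- codes == "" & women$any_anc & lengths(src) == 0
  codes[i] <- "anc-without-sources"
  i <- codes == "" & !is.na(women$n_visits) & women$n_visits < 0
  codes[i] <- "bad-visits"
  i <- codes == "" & !vapply(src, function(s) all(s %in% mapped), logical(1))
  codes[i] <- "unknown-source"
  bad <- codes != ""
  list(
    records = women[!bad, , drop = FALSE],
    diagnostics = if (any(bad)) {
      diag_row("women", women$woman_id[bad], codes[bad],
               paste0("invariant violated: ", codes[bad]))
    } else no_diags()
  )
}

validate_facilities <- function(facilities, config) {
  config <- as_country_config(config)
  ridx <- readiness_indices(config)
  universe_bin <- unique(unlist(lapply(config$indices[ridx], function(i) i$items$code[i$items$kind == "binary"])))
  universe_prop <- unique(unlist(lapply(config$indices[ridx], function(i) i$items$code[i$items$kind == "proportion"])))
  item_cols <- grep("^item_", names(facilities), value = TRUE)
  train_cols <- grep("^train_", names(facilities), value = TRUE)
  unknown <- c(setdiff(sub("^item_", "", item_cols), universe_bin),
               setdiff(sub("^train_", "", train_cols), universe_prop))
  if (length(unknown)) {
    stop_cc("schema-mismatch", "facility item column(s) outside the index universe: %s",
            paste(unknown, collapse = ", "))
  }
  im <- item_matrix(facilities, "item_")
  tm <- item_matrix(facilities, "train_")
  codes <- character(nrow(facilities))
  codes[!is.finite(facilities$weight) | facilities$weight <= 0] <- "bad-weight"
  if (ncol(im)) {
    bad_item <- rowSums(!(is.na(im) | im == 0 | im == 1)) > 0
    codes[codes == "" & bad_item] <- "bad-item-value"
  }
  if (ncol(tm)) {
    bad_train <- rowSums(!is.na(tm) & (tm < 0 | tm > 1)) > 0
    codes[codes == "" & bad_train] <- "bad-training-value"
  }
  bad <- codes != ""
  list(
    records = facilities[!bad, , drop = FALSE],
    diagnostics = if (any(bad)) {
      diag_row("facilities", facilities$facility_id[bad], codes[bad],
               paste0("invariant violated: ", codes[bad]))
    } else no_diags()
  )
}

validate_observations <- function(observations, facilities, config) {
  config <- as_country_config(config)
  qidx <- quality_indices(config)
  universe <- unique(unlist(lapply(config$indices[qidx], function(i) i$items$code)))
  item_cols <- grep("^item_", names(observations), value = TRUE)
  unknown <- setdiff(sub("^item_", "", item_cols), universe)
  if (length(unknown)) {
    stop_cc("schema-mismatch", "observation item column(s) outside the index universe: %s",
            paste(unknown, collapse = ", "))
  }
  anc_fac <- facilities$facility_id[facilities$offers_anc]
  dangling <- setdiff(unique(observations$facility_id), anc_fac)
  if (length(dangling)) {
    stop_cc("dangling-facility", "observation(s) reference unknown or non-ANC facilities: %s",
            paste(utils::head(dangling, 5), collapse = ", "))
  }
  im <- item_matrix(observations, "item_")
  codes <- character(nrow(observations))
  codes[!is.finite(observations$weight) | observations$weight <= 0] <- "bad-weight"
  if (ncol(im)) {
    bad_item <- rowSums(!(is.na(im) | im == 0 | im == 1)) > 0
    codes[codes == "" & bad_item] <- "bad-item-value"
  }
  bad <- codes != ""
  list(
    records = observations[!bad, , drop = FALSE],
    diagnostics = if (any(bad)) {
      diag_row("observations", observations$obs_id[bad], codes[bad],
               paste0("invariant violated: ", codes[bad]))
    } else no_diags()
  )
}

#' Assemble a validated country bundle from in-memory tables
#'
#' Applies row-level invariant validation to each table, filters facilities to
#' those offering ANC (the scoring view), and attaches the configuration. Rows
#' violating an invariant are dropped and reported in the `diagnostics`
#' element; structural problems (schema mismatch, observations referencing a
#' missing facility) are fatal.
#'
#' @param women,facilities,observations Data frames following the canonical
#'   schemas; `observations` may be `NULL` for countries without direct
#'   observation of care.
#' @param config A `cc_config`.
#' @return A `cc_bundle`: list with elements `women`, `facilities` (ANC-offering
#'   only), `observations`, `config`, `diagnostics`, `n_facilities_total`.
#' @export
new_bundle <- function(women, facilities, observations = NULL, config) {
  config <- as_country_config(config)
  vw <- validate_women(women, config)
  vf <- validate_facilities(facilities, config)
  fac_anc <- vf$records[vf$records$offers_anc, , drop = FALSE]
  vo <- NULL
  if (!is.null(observations) && config$has_quality_data) {
    vo <- validate_observations(observations, vf$records, config)
  }
  bundle <- list(
    women = vw$records,
    facilities = fac_anc,
    observations = if (is.null(vo)) NULL else vo$records,
    config = config,
    diagnostics = rbind(vw$diagnostics, vf$diagnostics,
                        if (is.null(vo)) no_diags() else vo$diagnostics),
    n_facilities_total = nrow(vf$records)
  )
  class(bundle) <- "cc_bundle"
  bundle
}

#' Load and validate all pipeline tables
#'
#' @param paths Named list/vector with elements `women`, `facilities` and
#'   optionally `observations`, pointing to CSV or Parquet files.
#' @param config A `cc_config` object or the path to a YAML configuration.
#' @return A validated `cc_bundle`; see [new_bundle()].
#' @export
load_tables <- function(paths, config) {
  if (is.character(config)) config <- read_country_config(config)
  women <- read_women(paths[["women"]])
  facilities <- read_facilities(paths[["facilities"]])
  observations <- NULL
  if (!is.null(paths[["observations"]]) && !is.na(paths[["observations"]])) {
    observations <- read_observations(paths[["observations"]])
  }
  new_bundle(women, facilities, observations, config)
}

#' Write a bundle's tables to a directory
#'
#' Writes `women.csv`, `facilities.csv`, `observations.csv` (when present) and
#' `config.yaml`. Note the facility table written is the validated ANC-offering
#' scoring view.
#'
#' @param bundle A `cc_bundle`.
#' @param dir Output directory, created if needed.
#' @param format `"csv"` or `"parquet"`.
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir, format = c("csv", "parquet")) {
  format <- match.arg(format)
  ext <- if (format == "csv") ".csv" else ".parquet"
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_flat(bundle$women, file.path(dir, paste0("women", ext)))
  write_flat(bundle$facilities, file.path(dir, paste0("facilities", ext)))
  if (!is.null(bundle$observations)) {
    write_flat(bundle$observations, file.path(dir, paste0("observations", ext)))
  }
  write_country_config(bundle$config, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' @export
print.cc_bundle <- function(x, ...) {
  cat("<cc_bundle>", x$config$country, "\n")
  cat(sprintf("  %d women, %d ANC-offering facilities (%d total), %s observations\n",
              nrow(x$women), nrow(x$facilities), x$n_facilities_total,
              if (is.null(x$observations)) "no" else nrow(x$observations)))
  if (nrow(x$diagnostics)) cat(sprintf("  %d row(s) rejected during validation\n", nrow(x$diagnostics)))
  invisible(x)
}
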