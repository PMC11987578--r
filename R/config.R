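#' Read a country configuration from YAML
#'
#' A country configuration bundles everything that is country-specific about a
#' cascade analysis: the four additive index definitions (ANC and maternal
#' nutrition readiness, measured on facilities; ANC and maternal nutrition
#' provision/experience of care, measured on observed clients), the two key
#' intervention sets, the mapping from household-survey provider categories to
#' facility categories, the geographic domain level used for stratification
#' (region or district) and whether the country's facility assessment collected
#' direct observations of care.
#'
#' @param path Path to a YAML file.
#' @return A `cc_config` object (a named list).
#' @seealso [validate_config()]
#' @export
read_country_config <- function(path) {
  if (!file.exists(path)) stop_cc("no-such-file", "config file not found: %s", path)
  as_country_config(yaml::read_yaml(path))
}

#' Coerce a list to a country configuration
#'
#' Normalises a plain list (e.g. parsed YAML) into the canonical `cc_config`
#' layout: index item tables as data frames, default country masks equal to
#' the full item universe, and default contact thresholds of 1, 4 and 8
#' visits.
#'
#' @param x A named list with elements `indices`, `intervention_sets`,
#'   `provider_mapping`, and optionally `country`, `geo_domain_level`,
#'   `has_quality_data`, `contact_thresholds`.
#' @return A `cc_config` object.
#' @export
as_country_config <- function(x) {
  if (inherits(x, "cc_config")) return(x)
  stopifnot(is.list(x))
  cfg <- list(
    country = x$country %||% "unnamed",
    geo_domain_level = x$geo_domain_level %||% "region",
    has_quality_data = isTRUE(x$has_quality_data %||% TRUE),
    contact_thresholds = as.integer(x$contact_thresholds %||% c(1L, 4L, 8L)),
    indices = lapply(x$indices, normalise_index),
    intervention_sets = lapply(x$intervention_sets, normalise_intervention_set),
    provider_mapping = x$provider_mapping %||% list()
  )
  for (nm in names(cfg$indices)) {
    cfg$indices[[nm]]$name <- cfg$indices[[nm]]$name %||% nm
    cfg$indices[[nm]]$target <- cfg$indices[[nm]]$target %||%
      if (grepl("quality", nm)) "client" else "facility"
  }
  for (nm in names(cfg$intervention_sets)) {
    cfg$intervention_sets[[nm]]$service <- cfg$intervention_sets[[nm]]$service %||% toupper(nm)
  }
  class(cfg) <- "cc_config"
  cfg
}

normalise_index <- function(idx) {
  items <- idx$items
  if (is.data.frame(items)) {
    it <- items
  } else {
    it <- data.frame(
      code = vapply(items, function(i) i$code, character(1)),
      domain = vapply(items, function(i) i$domain %||% "general", character(1)),
      kind = vapply(items, function(i) i$kind %||% "binary", character(1)),
      stringsAsFactors = FALSE
    )
  }
  list(
    name = idx$name,
    target = idx$target,
    items = it,
    country_mask = as.character(idx$country_mask %||% it$code)
  )
}

normalise_intervention_set <- function(set) {
  list(
    service = set$service,
    interventions = as.character(set$interventions),
    country_mask = as.character(set$country_mask %||% set$interventions)
  )
}

#' @export
print.cc_config <- function(x, ...) {
  cat("<cc_config>", x$country, "\n")
  cat("  geo domain level:", x$geo_domain_level, "\n")
  cat("  quality data:", x$has_quality_data, "\n")
  cat("  indices:", paste(names(x$indices), collapse = ", "), "\n")
  cat("  providers mapped:", length(x$provider_mapping), "\n")
  invisible(x)
}

#' Write a country configuration to YAML
#'
#' @param config A `cc_config` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_country_config <- function(config, path) {
  config <- as_country_config(config)
  out <- unclass(config)
  out$indices <- lapply(out$indices, function(idx) {
    idx$items <- lapply(seq_len(nrow(idx$items)), function(i) as.list(idx$items[i, ]))
    idx
  })
  yaml::write_yaml(out, path)
  invisible(path)
}

# intervention codes every configuration must define (the country mask may
# still exclude some of them, e.g. no SP where malaria is not endemic)
ANC_INTERVENTION_UNIVERSE <- c("tt", "sp", "ifa", "bp", "urine", "blood", "deworming")
MN_INTERVENTION_UNIVERSE <- c("sp", "ifa", "blood", "deworming")

#' Validate a country configuration
#'
#' Checks the internal consistency of a configuration and, optionally, its
#' consistency with loaded survey tables. Findings are returned, not raised:
#' an empty result means the configuration is valid.
#'
#' Checked invariants include: unique item codes per index, country masks
#' that are subsets of the item universe and non-empty, intervention sets
#' containing the canonical ANC and maternal-nutrition universes, provider
#' mappings whose values are facility categories, the literal `UNQUALIFIED`,
#' or a fixed score in \[0, 1\], and (when tables are supplied) no provider
#' code in the women's table left unmapped and no mapped category without
#' facilities.
#'
#' @param config A `cc_config` object or a list coercible to one.
#' @param women Optional validated women table; enables the unmapped-provider
#'   check.
#' @param facilities Optional validated facility table; enables the
#'   unknown-category check for mapping targets.
#' @return A data frame with columns `code`, `location`, `message`; zero rows
#'   when all invariants hold.
#' @export
validate_config <- function(config, women = NULL, facilities = NULL) {
  config <- as_country_config(config)
  out <- list(no_findings())

  need_idx <- c("anc_readiness", "mn_readiness")
  if (config$has_quality_data) need_idx <- c(need_idx, "anc_quality", "mn_quality")
  for (nm in setdiff(need_idx, names(config$indices))) {
    out <- c(out, list(finding("missing-index", nm, sprintf("index '%s' is not defined", nm))))
  }

  for (nm in names(config$indices)) {
    idx <- config$indices[[nm]]
    loc <- paste0("indices/", nm)
    dup <- unique(idx$items$code[duplicated(idx$items$code)])
    for (d in dup) out <- c(out, list(finding("dup-item", loc, sprintf("duplicate item code '%s'", d))))
    unknown <- setdiff(idx$country_mask, idx$items$code)
    for (u in unknown) out <- c(out, list(finding("mask-unknown-item", loc, sprintf("mask code '%s' not among items", u))))
    if (length(setdiff(idx$country_mask, unknown)) == 0L) {
      out <- c(out, list(finding("empty-mask", loc, "country mask selects no items")))
    }
    bad_kind <- setdiff(unique(idx$items$kind), c("binary", "proportion"))
    for (b in bad_kind) out <- c(out, list(finding("bad-item-kind", loc, sprintf("unknown item kind '%s'", b))))
  }

  universes <- list(anc = ANC_INTERVENTION_UNIVERSE, mn = MN_INTERVENTION_UNIVERSE)
  for (nm in c("anc", "mn")) {
    set <- config$intervention_sets[[nm]]
    loc <- paste0("intervention_sets/", nm)
    if (is.null(set)) {
      out <- c(out, list(finding("missing-intervention-set", loc, "intervention set not defined")))
      next
    }
    missing <- setdiff(universes[[nm]], set$interventions)
    for (m in missing) out <- c(out, list(finding("missing-universe-item", loc, sprintf("required intervention '%s' absent from universe", m))))
    unknown <- setdiff(set$country_mask, set$interventions)
    for (u in unknown) out <- c(out, list(finding("mask-unknown-item", loc, sprintf("mask code '%s' not among interventions", u))))
    if (length(setdiff(set$country_mask, unknown)) == 0L) {
      out <- c(out, list(finding("empty-mask", loc, "country mask selects no interventions")))
    }
  }

  mapping <- config$provider_mapping
  for (nm in names(mapping)) {
    v <- mapping[[nm]]
    loc <- paste0("provider_mapping/", nm)
    if (is.numeric(v)) {
      if (length(v) != 1L || is.na(v) || v < 0 || v > 1) {
        out <- c(out, list(finding("bad-literal", loc, "literal score must be a single value in [0,1]")))
      }
    } else if (!is.character(v) || length(v) != 1L || !nzchar(v)) {
      out <- c(out, list(finding("bad-mapping-value", loc, "mapping value must be a category, 'UNQUALIFIED', or a score")))
    } else if (!is.null(facilities) && v != "UNQUALIFIED" &&
               !v %in% facilities$facility_category) {
      out <- c(out, list(finding("unknown-category", loc, sprintf("mapped category '%s' has no facilities", v))))
    }
  }

  if (!is.null(women)) {
    used <- unique(unlist(split_sources(women$sources)))
    for (u in setdiff(used, names(mapping))) {
      out <- c(out, list(finding("unmapped-provider", paste0("women/sources/", u),
                                 sprintf("provider code '%s' is not in the provider mapping", u))))
    }
  }

  if (any(is.na(config$contact_thresholds)) || any(config$contact_thresholds < 1L)) {
    out <- c(out, list(finding("bad-threshold", "contact_thresholds", "thresholds must be positive integers")))
  }
  if (!config$geo_domain_level %in% c("region", "district")) {
    out <- c(out, list(finding("bad-domain-level", "geo_domain_level", "must be 'region' or 'district'")))
  }

  do.call(rbind, out)
}

# readiness indices measured on facilities / quality indices on clients
readiness_indices <- function(config) {
  names(config$indices)[vapply(config$indices, function(i) i$target == "facility", logical(1))]
}

quality_indices <- function(config) {
  names(config$indices)[vapply(config$indices, function(i) i$target == "client", logical(1))]
}
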