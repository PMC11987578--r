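# Cross-country summaries, figures and pipeline orchestration.

round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Summarise cascades across countries
#'
#' For every service, visit threshold and ordered pair of cascade steps,
#' computes the per-country net decline in percentage points and relative
#' change, then the unweighted cross-country means over the countries
#' possessing both steps. The headline label renders the means with half-up
#' integer rounding (e.g. `"52 pp (55%)"`); full precision is kept in the
#' numeric columns.
#'
#' @param results A `cc_cascade` data frame (one or more countries).
#' @param by_country Return the per-country gaps instead of cross-country
#'   means.
#' @return A data frame: `service`, `k`, `step_from`, `step_to`,
#'   `mean_gap_pp`, `mean_relative`, `n_countries`, `label` (or per-country
#'   rows when `by_country = TRUE`).
#' @export
summarise_cascades <- function(results, by_country = FALSE) {
  df <- as.data.frame(results)
  step_order <- c("target", "contact", "readiness_adjusted", "intervention",
                  "quality_adjusted")
  df$step <- as.character(df$step)
  rows <- list()
  for (sv in unique(df$service)) {
    for (k in unique(df$k[df$service == sv])) {
      sub <- df[df$service == sv & df$k == k, ]
      steps <- intersect(step_order, unique(sub$step))
      for (i in seq_along(steps)) {
        for (j in seq_along(steps)) {
          if (j <= i) next
          a <- sub[sub$step == steps[i], c("country", "estimate")]
          b <- sub[sub$step == steps[j], c("country", "estimate")]
          both <- merge(a, b, by = "country", suffixes = c("_a", "_b"))
          if (!nrow(both)) next
          rows[[length(rows) + 1L]] <- data.frame(
            service = sv, k = k, step_from = steps[i], step_to = steps[j],
            country = both$country,
            gap_pp = net_decline_pp(both$estimate_a, both$estimate_b),
            relative = relative_change(both$estimate_a, both$estimate_b),
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  per_country <- do.call(rbind, rows)
  if (by_country) return(per_country)
  agg <- stats::aggregate(
    cbind(gap_pp, relative) ~ service + k + step_from + step_to,
    data = per_country, FUN = mean, na.action = stats::na.omit
  )
  n <- stats::aggregate(country ~ service + k + step_from + step_to,
                        data = per_country, FUN = length)
  out <- merge(agg, n, by = c("service", "k", "step_from", "step_to"))
  names(out)[names(out) == "gap_pp"] <- "mean_gap_pp"
  names(out)[names(out) == "relative"] <- "mean_relative"
  names(out)[names(out) == "country"] <- "n_countries"
  out$label <- sprintf("%d pp (%d%%)",
                       as.integer(round_half_up(out$mean_gap_pp)),
                       as.integer(round_half_up(100 * out$mean_relative)))
  out[order(out$service, out$k, match(out$step_from, step_order),
            match(out$step_to, step_order)), ]
}

#' Plot effective-coverage cascades
#'
#' One panel per country; bars ordered from the target population to
#' quality-adjusted coverage (truncated cascades show four bars), with 95%
#' confidence-interval whiskers where variance was computed.
#'
#' @param results A `cc_cascade` data frame.
#' @param service,k Which cascade to draw (defaults: first present).
#' @param file Optional output path (any extension `ggplot2::ggsave`
#'   understands, e.g. `.svg`, `.pdf`, `.png`).
#' @return The ggplot object, invisibly when written to file.
#' @export
render_cascade_figure <- function(results, service = NULL, k = NULL, file = NULL) {
  df <- as.data.frame(results)
  service <- service %||% df$service[1]
  k <- k %||% df$k[df$service == service][1]
  df <- df[df$service == service & df$k == k, ]
  df$step <- factor(as.character(df$step),
                    levels = c("target", "contact", "readiness_adjusted",
                               "intervention", "quality_adjusted"))
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$step, y = .data$estimate)) +
    ggplot2::geom_col(fill = "#4477aa") +
    ggplot2::facet_wrap(~country) +
    ggplot2::scale_y_continuous(limits = c(0, 1), labels = function(v) sprintf("%d%%", as.integer(100 * v))) +
    ggplot2::labs(
      title = sprintf("%s effective coverage cascade (%s+ visit%s)", service, k, if (k > 1) "s" else ""),
      x = NULL, y = "coverage"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
  if (any(!is.na(df$se) & df$se > 0)) {
    gg <- gg + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
      width = 0.25, na.rm = TRUE
    )
  }
  if (!is.null(file)) {
    ggplot2::ggsave(file, gg, width = 8, height = 5)
    return(invisible(gg))
  }
  gg
}

#' Run the full estimation pipeline and write its outputs
#'
#' Orchestrates scoring, linking, cascade estimation and variance for one
#' country bundle, writing `stratum_scores.csv`, `woman_scores.csv`,
#' `cascade_results.csv`, `summary.csv` and a `manifest.json` recording
#' inputs, seed, package version and diagnostic counts (national fallbacks
#' used, zero-score women, rejected rows).
#'
#' @param bundle A validated `cc_bundle`.
#' @param out_dir Output directory (created if needed).
#' @param services,ks,variance Passed to [run_cascades()].
#' @param seed Optional integer recorded in the manifest (estimation itself is
#'   deterministic; a seed only matters when the bundle was generated).
#' @param input_paths Optional named character vector of input files, hashed
#'   into the manifest.
#' @return The `cc_cascade` results, invisibly.
#' @export
run_pipeline <- function(bundle, out_dir, services = c("anc", "mn"), ks = NULL,
                         variance = "full", seed = NULL, input_paths = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- bundle$config
  stratum <- build_stratum_table(bundle$facilities, cfg, bundle$observations)
  write_stratum_table(stratum, file.path(out_dir, "stratum_scores.csv"))
  ws <- assign_woman_scores(bundle$women, cfg$provider_mapping, stratum)
  utils::write.csv(ws, file.path(out_dir, "woman_scores.csv"), row.names = FALSE, na = "")
  results <- run_cascades(bundle, services = services, ks = ks, variance = variance)
  utils::write.csv(as.data.frame(results), file.path(out_dir, "cascade_results.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(summarise_cascades(results), file.path(out_dir, "summary.csv"),
                   row.names = FALSE, na = "")
  manifest <- list(
    created = format(Sys.time(), tz = "UTC", usetz = TRUE),
    package_version = as.character(utils::packageVersion("effcascade")),
    country = cfg$country,
    seed = seed,
    inputs = if (!is.null(input_paths)) as.list(tools::md5sum(input_paths)),
    warnings = list(
      n_rejected_rows = nrow(bundle$diagnostics),
      n_national_fallbacks = sum(ws$n_national_fallbacks),
      n_zero_score_women = sum(ws$n_sources == 0L)
    )
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(results)
}
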