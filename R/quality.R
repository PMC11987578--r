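# Provision/experience-of-care scoring from direct observation of ANC first
# visits. Same additive construction as readiness, but the unit is an observed
# client, and stratum means pool clients (client-weighted) across facilities.

#' Score one observed ANC client on a quality index
#'
#' The provision/experience-of-care score is the unweighted mean of the
#' index's masked items that were collected for this observation (history
#' taking, examination, counselling, client experience, ...).
#'
#' @param observation A single-row data frame following the observation schema.
#' @param index_def A client-target index definition (e.g.
#'   `config$indices$anc_quality`).
#' @return A `cc_unit_score` with `obs_id`, `index`, `score`, `n_items_used`,
#'   `domain_scores`.
#' @export
client_quality_score <- function(observation, index_def) {
  observation <- as.data.frame(observation, stringsAsFactors = FALSE)
  stopifnot(nrow(observation) == 1L)
  unit_score(observation, index_def, id = observation$obs_id, id_field = "obs_id")
}

#' Score all client observations on an index
#'
#' Vectorised version of [client_quality_score()].
#'
#' @param observations Observation table.
#' @param index_def A client-target index definition.
#' @return Data frame: `obs_id`, `index`, `score`, `n_items_used`.
#' @export
score_clients <- function(observations, index_def) {
  m <- index_value_matrix(observations, index_def)
  n_used <- rowSums(!is.na(m))
  if (any(n_used == 0L)) {
    stop_cc("no-scoreable-items", "observation(s) with no collected items for '%s': %s",
            index_def$name,
            paste(utils::head(observations$obs_id[n_used == 0L], 5), collapse = ", "))
  }
  data.frame(
    obs_id = observations$obs_id,
    index = index_def$name,
    score = rowMeans(m, na.rm = TRUE),
    n_items_used = n_used,
    stringsAsFactors = FALSE
  )
}

#' Pooled client-weighted mean quality for one stratum
#'
#' All observations within the stratum are pooled with their client weights --
#' deliberately not a mean of per-facility means -- so that higher-caseload
#' facilities contribute proportionally more and the mean represents the
#' average client's experience rather than the average facility.
#'
#' @param client_scores Output of [score_clients()].
#' @param observations The matching observation table.
#' @param facilities Facility table used to place each observation in a
#'   stratum via its facility.
#' @param stratum_key Length-2 character vector `c(geo_domain, facility_category)`.
#' @return Pooled weighted mean in \[0, 1\], or `NA` for an empty stratum
#'   (callers fall back to the national pooled mean).
#' @export
stratum_mean_quality <- function(client_scores, observations, facilities, stratum_key) {
  oi <- match(client_scores$obs_id, observations$obs_id)
  fi <- match(observations$facility_id[oi], facilities$facility_id)
  sel <- facilities$geo_domain[fi] == stratum_key[1L] &
    facilities$facility_category[fi] == stratum_key[2L]
  if (!any(sel)) return(NA_real_)
  wmean(client_scores$score[sel], observations$weight[oi][sel])
}
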