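# Design-based variance estimation.
#
# Household-survey-only estimators (service contact, intervention coverage)
# use Taylor linearisation of the weighted ratio mean under stratified cluster
# sampling with the with-replacement PSU approximation. Linked estimators
# (readiness- and quality-adjusted coverage) draw uncertainty from two
# independent surveys, so their variance is the sum of a delete-one-cluster
# jackknife component (household survey) and a delete-one-facility jackknife
# component (facility assessment, stratum score tables rebuilt per replicate).

# merge single-cluster strata into the neighbouring stratum (sorted label
# order); returns a group label per input element
collapse_lonely_strata <- function(stratum_of_cluster) {
  counts <- table(stratum_of_cluster)
  labs <- names(counts)
  if (all(counts < 2)) {
    if (sum(counts) < 2) stop_cc("single-cluster-design", "fewer than two clusters")
    stop_cc("all-lonely-strata", "every design stratum holds a single cluster")
  }
  g <- seq_along(labs)
  for (i in seq_along(labs)) {
    if (counts[i] < 2) g[i] <- if (i > 1L) g[i - 1L] else 2L
  }
  g[match(stratum_of_cluster, labs)]
}

#' Taylor-linearised variance of a weighted ratio mean
#'
#' Linearises `sum(w*y)/sum(w)` under a stratified cluster design with the
#' with-replacement approximation for PSUs within strata. Elements with `NA`
#' in `y` lie outside the estimation domain (e.g. women with every masked
#' receipt missing): they contribute nothing to the estimate but their
#' clusters remain in the design. Strata containing a single cluster are
#' collapsed into the neighbouring stratum.
#'
#' @param y Numeric response per element; `NA` marks elements outside the
#'   estimation domain.
#' @param weights Positive survey weights.
#' @param cluster Primary-sampling-unit (cluster) identifiers.
#' @param stratum Design stratum identifiers; `NULL` for an unstratified
#'   design.
#' @return A `cc_variance`: list with `estimate`, `variance`, `se`, `df`
#'   (clusters minus strata after collapse), `method = "taylor"`,
#'   `n_clusters`.
#' @export
taylor_variance <- function(y, weights, cluster, stratum = NULL) {
  n <- length(y)
  stratum <- as.character(stratum %||% rep("_all", n))
  cluster <- as.character(cluster)
  incl <- !is.na(y)
  if (!any(incl)) stop_cc("all-missing", "no element lies in the estimation domain")
  W <- sum(weights[incl])
  theta <- sum(weights[incl] * y[incl]) / W
  z <- numeric(n)
  z[incl] <- weights[incl] * (y[incl] - theta) / W

  key <- paste(stratum, cluster, sep = "\x1f")
  zc <- rowsum(z, key)
  st_cl <- vapply(strsplit(rownames(zc), "\x1f", fixed = TRUE), `[[`, "", 1L)
  grp <- collapse_lonely_strata(st_cl)
  v <- 0
  for (g in unique(grp)) {
    zz <- zc[grp == g, 1L]
    nh <- length(zz)
    v <- v + nh / (nh - 1) * sum((zz - mean(zz))^2)
  }
  out <- list(estimate = theta, variance = v, se = sqrt(v),
              df = length(st_cl) - length(unique(grp)),
              method = "taylor", n_clusters = length(st_cl))
  class(out) <- "cc_variance"
  out
}

# jackknife over all (index, k) adjusted estimators at once; shared by
# build_cascade and jackknife2_variance so facility replicates are computed
# a single time per bundle
jackknife2_all <- function(ctx) {
  base <- woman_score_matrix(ctx)
  if (!base$valid) stop_cc("unlinkable-category", "a category has no national score row")
  S <- base$S
  nidx <- ncol(S)
  K <- ncol(ctx$C)
  combos <- as.vector(outer(colnames(S), colnames(ctx$C), paste, sep = "|"))
  nE <- nidx * K
  wC <- ctx$C * ctx$w
  D <- sum(ctx$w)
  theta_full <- as.vector(crossprod(S, wC)) / D

  # element-level numerator contributions, one column per estimator
  X <- matrix(0, ctx$n, nE)
  for (j in seq_len(K)) {
    X[, (j - 1L) * nidx + seq_len(nidx)] <- S * wC[, j]
  }

  # component A: withhold each household cluster, weights unchanged
  Xg <- rowsum(X, ctx$cluster)
  wg <- as.vector(rowsum(ctx$w, ctx$cluster))
  G <- nrow(Xg)
  if (G < 2L) stop_cc("too-few-clusters", "the cluster jackknife needs at least 2 clusters")
  thetaA <- (matrix(colSums(X), G, nE, byrow = TRUE) - Xg) / (D - wg)
  varA <- (G - 1) / G * colSums(sweep(thetaA, 2, colMeans(thetaA))^2)

  # component B: withhold each facility (and its client observations),
  # rebuild the stratum score table, re-link, re-estimate
  Fn <- nrow(ctx$fac)
  if (Fn < 2L) stop_cc("too-few-facilities", "the facility jackknife needs at least 2 facilities")
  thetaB <- matrix(NA_real_, Fn, nE)
  keep_fac <- rep(TRUE, Fn)
  for (f in seq_len(Fn)) {
    keep_fac[f] <- FALSE
    keep_obs <- if (length(ctx$qidx)) ctx$obs_fidx != f else NULL
    r <- woman_score_matrix(ctx, keep_fac, keep_obs)
    keep_fac[f] <- TRUE
    if (!r$valid) next
    thetaB[f, ] <- as.vector(crossprod(r$S, wC)) / D
  }
  valid <- !is.na(thetaB[, 1L])
  n_excluded <- sum(!valid)
  if (n_excluded > 0L) {
    warning(sprintf("%d facility jackknife replicate(s) excluded: deletion emptied a national category", n_excluded))
  }
  tB <- thetaB[valid, , drop = FALSE]
  Fv <- nrow(tB)
  varB <- (Fv - 1) / Fv * colSums(sweep(tB, 2, colMeans(tB))^2)

  list(
    estimate = stats::setNames(theta_full, combos),
    variance = stats::setNames(varA + varB, combos),
    var_cluster = stats::setNames(varA, combos),
    var_facility = stats::setNames(varB, combos),
    n_clusters = G, n_facilities = Fn, n_excluded = n_excluded
  )
}

#' Two-survey delete-one-group jackknife variance for an adjusted estimator
#'
#' Re-estimates the readiness- or quality-adjusted coverage withholding each
#' household cluster (component A) and each health facility together with its
#' client observations (component B, stratum score tables rebuilt per
#' replicate). Each component is scaled as `(G-1)/G * sum((theta_rep -
#' mean)^2)`; the total variance is their sum, justified by the independence
#' of the household and facility surveys. A facility replicate that empties a
#' national fallback category is excluded with a warning.
#'
#' @param bundle A validated `cc_bundle`.
#' @param service `"anc"` or `"mn"`.
#' @param k Visit threshold.
#' @param adjust `"readiness"` or `"quality"`.
#' @return A `cc_variance` with `estimate`, `variance`, `se`, `var_cluster`,
#'   `var_facility`, `ci_low`/`ci_high` (95%, truncated to \[0, 1\]),
#'   `n_clusters`, `n_facilities`, `n_excluded`.
#' @export
jackknife2_variance <- function(bundle, service = c("anc", "mn"), k = 1,
                                adjust = c("readiness", "quality")) {
  service <- match.arg(service)
  adjust <- match.arg(adjust)
  ctx <- link_context(bundle)
  if (adjust == "quality" && length(ctx$qidx) == 0L) {
    stop_cc("no-quality-data", "bundle has no client observations")
  }
  jk <- jackknife2_all(ctx)
  combo <- paste(cascade_index(service, adjust), k, sep = "|")
  if (!combo %in% names(jk$estimate)) {
    stop_cc("bad-threshold", "k = %s is not a configured contact threshold", k)
  }
  est <- unname(jk$estimate[combo])
  v <- unname(jk$variance[combo])
  out <- list(
    estimate = est, variance = v, se = sqrt(v),
    var_cluster = unname(jk$var_cluster[combo]),
    var_facility = unname(jk$var_facility[combo]),
    ci_low = max(0, est - 1.96 * sqrt(v)),
    ci_high = min(1, est + 1.96 * sqrt(v)),
    method = "jackknife2",
    n_clusters = jk$n_clusters, n_facilities = jk$n_facilities,
    n_excluded = jk$n_excluded
  )
  class(out) <- "cc_variance"
  out
}

#' @export
print.cc_variance <- function(x, ...) {
  cat(sprintf("<cc_variance:%s> estimate %.4f, SE %.5f\n", x$method,
              x$estimate, x$se))
  if (x$method == "jackknife2") {
    cat(sprintf("  cluster component %.3e + facility component %.3e\n",
                x$var_cluster, x$var_facility))
  }
  invisible(x)
}
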