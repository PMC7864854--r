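#' Per-region educational CFR differences
#'
#' Builds the regression input: one point per region holding the CFR
#' difference between the pair's two education groups (same estimation
#' method for both, never mixed) and the region's natural-log GDP per
#' capita.  Regions missing either estimate are skipped with a message.
#'
#' @param estimates CFR estimates from [raw_cfr()] or [smooth_table()].
#' @param regions region metadata with `gdp_pc`.
#' @param pair one of `"high_medium"`, `"medium_low"`, `"high_low"`.
#' @return data.frame: `country_id`, `region_id`, `pair`, `delta`, `log_gdp`.
#' @export
gradient_table <- function(estimates, regions, pair) {
  m <- pair_members(pair)
  stopifnot(length(unique(estimates$method)) == 1L)
  e1 <- estimates[estimates$education == m[1L], ]
  e2 <- estimates[estimates$education == m[2L], ]
  i1 <- match(regions$region_id, e1$region_id)
  i2 <- match(regions$region_id, e2$region_id)
  out <- data.frame(
    country_id = regions$country_id,
    region_id = regions$region_id,
    pair = pair,
    delta = e1$cfr[i1] - e2$cfr[i2],
    log_gdp = log(regions$gdp_pc),
    stringsAsFactors = FALSE
  )
  dropped <- is.na(out$delta) | is.na(out$log_gdp)
  if (any(dropped)) {
    message(sprintf("gradient_table: %d region(s) without both %s estimates skipped",
                    sum(dropped), pair))
    out <- out[!dropped, ]
  }
  rownames(out) <- NULL
  out
}

fit_result <- function(pair, model, slope, slope_se, intercept, n,
                       country_intercepts = NULL) {
  structure(list(pair = pair, model = model, slope = slope,
                 slope_se = slope_se, intercept = intercept,
                 n_regions = n, country_intercepts = country_intercepts),
            class = "gradient_fit")
}

#' @export
print.gradient_fit <- function(x, ...) {
  cat(sprintf("Educational gradient regression (%s, %s)\n", x$pair, x$model))
  cat(sprintf("  slope  %8.4f  (SE %.4f) children/woman per log-GDP unit\n",
              x$slope, x$slope_se))
  if (!is.null(x$intercept) && !is.na(x$intercept)) {
    cat(sprintf("  intercept %8.4f\n", x$intercept))
  }
  cat(sprintf("  regions used: %d\n", x$n_regions))
  invisible(x)
}

#' Pooled regression of the gradient on log GDP
#'
#' Ordinary least squares of the per-region CFR difference on log GDP per
#' capita, pooling all countries and regions, unweighted, with intercept.
#' Describes how the educational gradient varies with regional development
#' across the whole dataset.
#'
#' @param points output of [gradient_table()].
#' @return a `gradient_fit` with `slope`, `slope_se`, `intercept`,
#'   `n_regions`.
#' @export
fit_pooled <- function(points) {
  if (nrow(points) < 3L) stop("need at least 3 regions")
  if (length(unique(points$log_gdp)) < 2L) {
    stop("design is rank-deficient: all regions share one log GDP value")
  }
  fit <- stats::lm(delta ~ log_gdp, data = points)
  sm <- summary(fit)$coefficients
  fit_result(points$pair[1L], "pooled",
             slope = sm["log_gdp", "Estimate"],
             slope_se = sm["log_gdp", "Std. Error"],
             intercept = sm["(Intercept)", "Estimate"],
             n = nrow(points))
}

#' Country fixed-effects regression of the gradient on log GDP
#'
#' The within estimator: CFR difference and log GDP are demeaned within each
#' country and the slope fitted through the origin on the demeaned values —
#' algebraically identical to least squares with country dummy variables.
#' The slope is a variance-weighted average of the within-country
#' associations, immune to country-level shifts in either variable.
#'
#' @param points output of [gradient_table()]; needs at least 2 countries
#'   with 2+ regions each.
#' @return a `gradient_fit` with the within slope, its SE (residual df
#'   `n - n_countries - 1`), and per-country intercepts.
#' @export
fit_fixed_effects <- function(points) {
  n_per <- table(points$country_id)
  if (sum(n_per >= 2L) < 1L) {
    stop("no country with at least 2 regions; within estimator undefined")
  }
  x <- points$log_gdp - stats::ave(points$log_gdp, points$country_id)
  y <- points$delta - stats::ave(points$delta, points$country_id)
  sxx <- sum(x^2)
  if (sxx <= 0) stop("design is rank-deficient: no within-country GDP variation")
  slope <- sum(x * y) / sxx
  n <- nrow(points)
  k <- length(n_per)
  df <- n - k - 1L
  rss <- sum((y - slope * x)^2)
  se <- if (df > 0) sqrt(rss / df / sxx) else NA_real_
  mean_d <- tapply(points$delta, points$country_id, mean)
  mean_g <- tapply(points$log_gdp, points$country_id, mean)
  fit_result(points$pair[1L], "fixed_effects",
             slope = slope, slope_se = se, intercept = NA_real_,
             n = n, country_intercepts = mean_d - slope * mean_g)
}

#' Per-country gradient regressions
#'
#' [fit_pooled()] applied separately to each country's regions (the
#' per-country trend lines of the gradient-vs-GDP picture).  Countries with
#' fewer than 3 regions or no GDP variation are skipped.
#'
#' @param points output of [gradient_table()].
#' @return data.frame with one row per fitted country.
#' @export
fit_by_country <- function(points) {
  out <- lapply(split(points, points$country_id), function(p) {
    if (nrow(p) < 3L || length(unique(p$log_gdp)) < 2L) return(NULL)
    f <- fit_pooled(p)
    data.frame(country_id = p$country_id[1L], pair = f$pair,
               slope = f$slope, slope_se = f$slope_se,
               intercept = f$intercept, n_regions = f$n_regions,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Highest-GDP region versus the rest of each country
#'
#' For each country, contrasts the educational CFR difference in the region
#' with the highest GDP per capita (HGDP region) against the pooled
#' difference over all its other regions (cells summed before rates are
#' formed).  Point estimates are posterior means; 95% credible intervals
#' come from Monte-Carlo draws of the Gamma posteriors of the two education
#' groups' rates, differenced, at the empirical percentiles.
#'
#' @param estimates EB estimates from [smooth_table()] (must carry
#'   `shape_a`/`rate_b`).
#' @param cells the cell counts the estimates were computed from.
#' @param regions region metadata.
#' @param pair education pair.
#' @param params an [eb_params()]; `n_draws` and `seed` drive the intervals.
#' @return data.frame: `country_id`, `pair`, `delta_hgdp`, `hgdp_low`,
#'   `hgdp_high`, `delta_rest`, `rest_low`, `rest_high`, `hgdp_region`.
#' @export
hgdp_compare <- function(estimates, cells, regions, pair,
                         params = eb_params()) {
  stopifnot(all(c("shape_a", "rate_b") %in% names(estimates)))
  m <- pair_members(pair)
  nu_by_country <- attr(estimates, "nu")
  set.seed(substream_seed(params$seed, 97L))
  countries <- sort(unique(regions$country_id))
  rows <- vector("list", length(countries))
  for (ci in seq_along(countries)) {
    co <- countries[ci]
    reg <- regions[regions$country_id == co, ]
    reg <- reg[order(reg$region_id), ]
    top <- reg$region_id[which.max(reg$gdp_pc)]
    if (sum(reg$gdp_pc == max(reg$gdp_pc)) > 1L) {
      warning(sprintf("country %s: HGDP tie broken by region code order (%s)",
                      co, top))
    }
    post_of <- function(region_set, edu) {
      if (length(region_set) == 1L) {
        e <- estimates[estimates$region_id == region_set &
                       estimates$education == edu, ]
        if (nrow(e) == 0L || is.na(e$shape_a)) return(NULL)
        c(a = e$shape_a, b = e$rate_b)
      } else {
        cc <- cells[cells$region_id %in% region_set &
                    cells$education == edu, ]
        nu <- if (!is.null(nu_by_country)) nu_by_country[[co]] else 1
        # prior centred at the country-level pooled rate of this education
        ced <- cells$country_id == co & cells$education == edu
        if (sum(cells$n_women[ced]) == 0) return(NULL)
        m0 <- sum(cells$total_children[ced]) / sum(cells$n_women[ced])
        c(a = sum(cc$total_children) + nu * m0, b = sum(cc$n_women) + nu)
      }
    }
    draw_delta <- function(p1, p2) {
      d <- stats::rgamma(params$n_draws, p1[["a"]], rate = p1[["b"]]) -
           stats::rgamma(params$n_draws, p2[["a"]], rate = p2[["b"]])
      alpha <- (1 - params$ci_level) / 2
      c(mean = p1[["a"]] / p1[["b"]] - p2[["a"]] / p2[["b"]],
        lo = unname(stats::quantile(d, alpha)),
        hi = unname(stats::quantile(d, 1 - alpha)))
    }
    h1 <- post_of(top, m[1L]); h2 <- post_of(top, m[2L])
    hg <- if (!is.null(h1) && !is.null(h2)) draw_delta(h1, h2) else
      c(mean = NA_real_, lo = NA_real_, hi = NA_real_)
    rest_ids <- setdiff(reg$region_id, top)
    rs <- c(mean = NA_real_, lo = NA_real_, hi = NA_real_)
    if (length(rest_ids) >= 1L) {
      r1 <- post_of(rest_ids, m[1L]); r2 <- post_of(rest_ids, m[2L])
      if (!is.null(r1) && !is.null(r2)) rs <- draw_delta(r1, r2)
    }
    rows[[ci]] <- data.frame(
      country_id = co, pair = pair, hgdp_region = top,
      delta_hgdp = hg[["mean"]], hgdp_low = hg[["lo"]], hgdp_high = hg[["hi"]],
      delta_rest = rs[["mean"]], rest_low = rs[["lo"]], rest_high = rs[["hi"]],
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Slope-recovery simulation study
#'
#' Runs the full pipeline (generate regions and microdata, aggregate,
#' redistribute, estimate raw or EB rates, build gradient points, fit both
#' regressions) over independent replications of a synthetic configuration,
#' and reports how well the fixed-effects and pooled slopes recover the
#' generator's ground-truth gradient slope.
#'
#' @param config a [synthetic_config()] holding the ground truth.
#' @param n_replications number of independent replications.
#' @param seed master seed; each replication gets a derived sub-seed.
#' @param pair education pair to analyse.
#' @param outcome `"eb"` (default) or `"raw"`: which estimates feed the
#'   regression.
#' @param eb an [eb_params()] used when `outcome = "eb"`.
#' @return a list: `true_slope`, per-model mean slope, bias, empirical SD,
#'   mean reported SE, and coverage of nominal 95% (±1.96 SE) intervals;
#'   plus the per-replication slope table.
#' @export
recover_slope <- function(config, n_replications = 100L, seed = 1L,
                          pair = "high_medium", outcome = c("eb", "raw"),
                          eb = eb_params()) {
  outcome <- match.arg(outcome)
  beta <- true_slope(config, pair)
  res <- vector("list", n_replications)
  for (r in seq_len(n_replications)) {
    cfg <- config
    cfg$seed <- substream_seed(seed, r * 131L)
    regions <- generate_regions(cfg)
    md <- generate_microdata(regions, cfg)
    cells <- redistribute_unknown(aggregate_microdata(md))
    est <- if (outcome == "eb") smooth_table(cells, regions, eb)
           else raw_cfr(cells)
    pts <- gradient_table(est, regions, pair)
    fe <- fit_fixed_effects(pts)
    po <- fit_pooled(pts)
    res[[r]] <- data.frame(replication = r,
                           slope_fe = fe$slope, se_fe = fe$slope_se,
                           slope_pooled = po$slope, se_pooled = po$slope_se)
  }
  tab <- do.call(rbind, res)
  cover <- function(sl, se) mean(abs(sl - beta) <= 1.96 * se)
  list(
    true_slope = beta,
    n_replications = n_replications,
    fe = list(mean_slope = mean(tab$slope_fe),
              bias = mean(tab$slope_fe) - beta,
              sd = stats::sd(tab$slope_fe),
              mean_se = mean(tab$se_fe),
              coverage = cover(tab$slope_fe, tab$se_fe)),
    pooled = list(mean_slope = mean(tab$slope_pooled),
                  bias = mean(tab$slope_pooled) - beta,
                  sd = stats::sd(tab$slope_pooled),
                  mean_se = mean(tab$se_pooled),
                  coverage = cover(tab$slope_pooled, tab$se_pooled)),
    replications = tab
  )
}
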