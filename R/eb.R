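#' Empirical Bayes smoothing parameters
#'
#' Parameters of the Poisson-Gamma shrinkage estimator.  Each cell's prior is
#' `Gamma(nu * m, nu)`, where the reference rate `m` mixes two borrowing
#' sources: the same education group in GDP-similar regions of the same
#' country, and the other education groups of the same region rescaled by the
#' country's education-specific rate regularities.  Borrowing never crosses
#' country borders.
#'
#' @param bandwidth_h kernel scale on log GDP per capita; `NULL` (default)
#'   uses the pooled within-country SD of log GDP of the data at hand.
#' @param prior_strength_nu prior pseudo-women count; `"auto"` (default)
#'   estimates it per country by the method of moments.
#' @param mix_weights two non-negative weights summing to 1, named `region`
#'   and `education`: the mix of cross-region vs cross-education borrowing.
#' @param ci_level credible-interval level, default 0.95.
#' @param n_draws posterior Monte-Carlo draws for intervals of derived
#'   quantities (differences of rates).
#' @param seed integer seed for the posterior draws.
#' @return a list of class `eb_params`.
#' @export
eb_params <- function(bandwidth_h = NULL,
                      prior_strength_nu = "auto",
                      mix_weights = c(region = 0.7, education = 0.3),
                      ci_level = 0.95,
                      n_draws = 4000L,
                      seed = 1L) {
  mix_weights <- stats::setNames(as.numeric(mix_weights),
                                 c("region", "education"))
  stopifnot(all(mix_weights >= 0), abs(sum(mix_weights) - 1) < 1e-12,
            ci_level > 0, ci_level < 1, n_draws >= 1)
  if (!is.null(bandwidth_h) && bandwidth_h <= 0) {
    stop("bandwidth_h must be positive")
  }
  structure(list(bandwidth_h = bandwidth_h,
                 prior_strength_nu = prior_strength_nu,
                 mix_weights = mix_weights,
                 ci_level = ci_level,
                 n_draws = as.integer(n_draws),
                 seed = as.integer(seed)),
            class = "eb_params")
}

#' GDP-similarity kernel weights between regions
#'
#' Gaussian kernel on log GDP per capita:
#' `w(r, r') = exp(-(log g_r - log g_r')^2 / (2 h^2))` for distinct regions
#' `r`, `r'` of the same country, zero on the diagonal (a cell never informs
#' its own prior) and zero across country borders.  Rows are renormalised to
#' sum to 1 where any within-country neighbour exists; a country with a
#' single region keeps a zero row, so borrowing for it falls back to the
#' cross-education source.
#'
#' @param regions data.frame with `region_id`, `country_id`, `gdp_pc`.
#' @param h positive kernel bandwidth on the log-GDP scale.
#' @return square matrix with dimnames `region_id` x `region_id`.
#' @export
gdp_kernel_weights <- function(regions, h) {
  stopifnot(h > 0, all(regions$gdp_pc > 0))
  lg <- log(regions$gdp_pc)
  d <- outer(lg, lg, "-")
  w <- exp(-d^2 / (2 * h^2))
  same_country <- outer(regions$country_id, regions$country_id, "==")
  w[!same_country] <- 0
  diag(w) <- 0
  rs <- rowSums(w)
  w[rs > 0, ] <- w[rs > 0, , drop = FALSE] / rs[rs > 0]
  dimnames(w) <- list(regions$region_id, regions$region_id)
  w
}

# Pooled within-country SD of log GDP; the default kernel bandwidth.
default_bandwidth <- function(regions) {
  lg <- log(regions$gdp_pc)
  dev <- lg - stats::ave(lg, regions$country_id)
  h <- sqrt(sum(dev^2) / max(1L, length(dev) - length(unique(regions$country_id))))
  if (!is.finite(h) || h <= 0) 1 else h
}

# Expand cells to the full region x education grid of one dataset, inserting
# empty (N = 0) cells so that every region gets an estimate.
complete_cells <- function(cells, regions) {
  grid <- expand.grid(education = EDU_LEVELS,
                      region_id = regions$region_id,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$country_id <- regions$country_id[match(grid$region_id,
                                              regions$region_id)]
  key <- function(d) paste(d$region_id, d$education, sep = "\r")
  idx <- match(key(grid), key(cells))
  out <- data.frame(
    country_id = grid$country_id,
    region_id = grid$region_id,
    education = grid$education,
    n_women = ifelse(is.na(idx), 0L, cells$n_women[idx]),
    total_children = ifelse(is.na(idx), 0L, cells$total_children[idx]),
    n_unknown = 0L,
    stringsAsFactors = FALSE
  )
  out[order(out$country_id, out$region_id,
            match(out$education, EDU_LEVELS)), ]
}

#' Reference (prior mean) rates for every cell
#'
#' Computes the rate toward which each cell is shrunk, as a convex mix of
#' two sources:
#' \describe{
#'   \item{cross-region}{the size- and GDP-similarity-weighted mean raw CFR
#'     of the same education group in the country's other regions,
#'     `sum(w * N * cfr) / sum(w * N)` over donor regions;}
#'   \item{cross-education}{the pooled raw CFR of the region's other
#'     education groups, rescaled by the country-level ratio of the cell's
#'     education-specific rate to the other groups' pooled rate.}
#' }
#' A source without data hands its mix weight to the remaining source.  A
#' cell with no usable source anywhere in its country gets `NA` and a
#' warning.
#'
#' @param cells completed cell counts (one row per region x education).
#' @param regions region metadata.
#' @param weights kernel weight matrix from [gdp_kernel_weights()].
#' @param params an [eb_params()].
#' @return numeric vector of reference rates aligned with `cells` rows.
#' @export
reference_rate <- function(cells, regions, weights, params = eb_params()) {
  n <- nrow(cells)
  cfr <- ifelse(cells$n_women > 0,
                cells$total_children / cells$n_women, NA_real_)
  lam <- params$mix_weights
  m <- numeric(n)
  for (i in seq_len(n)) {
    co <- cells$country_id[i]
    re <- cells$region_id[i]
    ed <- cells$education[i]

    # (2) same education, other regions, weighted by kernel * cell size
    don <- which(cells$country_id == co & cells$education == ed &
                 cells$region_id != re & cells$n_women > 0)
    m_reg <- NA_real_
    if (length(don) > 0) {
      w <- weights[re, cells$region_id[don]] * cells$n_women[don]
      if (sum(w) > 0) m_reg <- sum(w * cfr[don]) / sum(w)
    }

    # (1)+(3) other educations in this region, scaled by the country-level
    # education-specific rate ratio
    oth <- which(cells$region_id == re & cells$education != ed)
    m_edu <- NA_real_
    if (sum(cells$n_women[oth]) > 0) {
      cfr_other <- sum(cells$total_children[oth]) / sum(cells$n_women[oth])
      ced <- cells$country_id == co & cells$education == ed
      cot <- cells$country_id == co & cells$education != ed
      if (sum(cells$n_women[ced]) > 0 && sum(cells$n_women[cot]) > 0) {
        rho <- (sum(cells$total_children[ced]) / sum(cells$n_women[ced])) /
               (sum(cells$total_children[cot]) / sum(cells$n_women[cot]))
        m_edu <- cfr_other * rho
      } else {
        m_edu <- cfr_other
      }
    }

    m[i] <- if (is.na(m_reg) && is.na(m_edu)) NA_real_
            else if (is.na(m_reg)) m_edu
            else if (is.na(m_edu)) m_reg
            else lam[["region"]] * m_reg + lam[["education"]] * m_edu
  }
  if (anyNA(m)) {
    warning(sprintf("%d cells have no borrowing source and cannot be smoothed",
                    sum(is.na(m))))
  }
  m
}

#' Method-of-moments prior strength
#'
#' Estimates the prior pseudo-women count `nu` from a set of cells (normally
#' one country): the between-cell variance of raw CFRs in excess of the
#' average Poisson sampling variance (`mean(cfr / N)`) is attributed to the
#' prior, and `nu = mean(cfr) / excess`, capped to `[1, 1e6]`.  Homogeneous
#' cells thus get maximal shrinkage, strongly heterogeneous ones almost
#' none.
#'
#' @param cells cell counts; cells with `n_women = 0` are ignored.
#' @return a positive scalar in `[1, 1e6]`.
#' @export
estimate_nu <- function(cells) {
  keep <- cells$n_women > 0
  if (sum(keep) < 2L) {
    warning("fewer than 2 populated cells; prior strength set to upper cap")
    return(1e6)
  }
  cfr <- cells$total_children[keep] / cells$n_women[keep]
  m_bar <- mean(cfr)
  excess <- stats::var(cfr) - mean(cfr / cells$n_women[keep])
  if (!is.finite(excess)) {
    warning("degenerate variance; prior strength set to upper cap")
    return(1e6)
  }
  nu <- m_bar / max(1e-12, excess)
  min(max(nu, 1), 1e6)
}

#' Conjugate Poisson-Gamma posterior of a cell rate
#'
#' With prior `Gamma(nu * m, nu)` and `B` children observed among `N` women,
#' the posterior of the cell's CFR is `Gamma(B + nu * m, N + nu)`; its mean
#' `(B + nu * m) / (N + nu)` is a convex combination of the raw CFR and the
#' reference rate `m`, with prior weight `nu / (N + nu)` vanishing as `N`
#' grows.  Works for `N = 0` (posterior mean `m`).
#'
#' @param B total children, `N` women counts (vectors allowed).
#' @param N number of women with known parity.
#' @param m reference rate(s), positive.
#' @param nu prior strength(s), positive.
#' @param ci_level credible-interval level.
#' @return data.frame with `shape_a`, `rate_b`, `mean`, `ci_low`, `ci_high`.
#' @export
eb_posterior <- function(B, N, m, nu, ci_level = 0.95) {
  stopifnot(all(m > 0 | is.na(m)), all(nu > 0))
  a <- B + nu * m
  b <- N + nu
  alpha <- (1 - ci_level) / 2
  data.frame(shape_a = a, rate_b = b, mean = a / b,
             ci_low = stats::qgamma(alpha, a, rate = b),
             ci_high = stats::qgamma(1 - alpha, a, rate = b))
}

#' Empirical Bayes smoothing of all cell rates
#'
#' Runs the full shrinkage procedure: completes the region x education grid
#' (so empty cells receive estimates), computes GDP-kernel weights and
#' reference rates, estimates the prior strength per country (unless fixed in
#' `params`), and forms each cell's Gamma posterior.  Small cells move
#' toward their reference rate; register-sized cells are left essentially at
#' their raw CFR.
#'
#' @param cells cell counts with `n_unknown = 0`.
#' @param regions region metadata covering all cells.
#' @param params an [eb_params()].
#' @return data.frame of estimates: `country_id`, `region_id`, `education`,
#'   `cfr` (posterior mean), `method = "eb"`, `ci_low`, `ci_high`, plus the
#'   posterior `shape_a`, `rate_b` columns used by downstream
#'   posterior-sampling code.  Attribute `nu` holds the per-country prior
#'   strengths; attribute `bandwidth_h` the kernel scale used.
#' @export
smooth_table <- function(cells, regions, params = eb_params()) {
  if (any(cells$n_unknown > 0)) {
    stop("cells still contain unknown-parity women; ",
         "run redistribute_unknown() first")
  }
  stopifnot(all(cells$region_id %in% regions$region_id))
  full <- complete_cells(cells, regions)
  h <- if (is.null(params$bandwidth_h)) default_bandwidth(regions)
       else params$bandwidth_h
  w <- gdp_kernel_weights(regions, h)
  m <- reference_rate(full, regions, w, params)

  countries <- unique(full$country_id)
  nu_by_country <- stats::setNames(numeric(length(countries)), countries)
  for (co in countries) {
    nu_by_country[[co]] <- if (identical(params$prior_strength_nu, "auto")) {
      estimate_nu(full[full$country_id == co, ])
    } else {
      as.numeric(params$prior_strength_nu)
    }
  }
  nu <- nu_by_country[full$country_id]

  ok <- !is.na(m)
  post <- eb_posterior(full$total_children[ok], full$n_women[ok],
                       m[ok], nu[ok], params$ci_level)
  out <- data.frame(
    country_id = full$country_id,
    region_id = full$region_id,
    education = full$education,
    cfr = NA_real_, method = "eb",
    ci_low = NA_real_, ci_high = NA_real_,
    shape_a = NA_real_, rate_b = NA_real_,
    stringsAsFactors = FALSE
  )
  out$cfr[ok] <- post$mean
  out$ci_low[ok] <- post$ci_low
  out$ci_high[ok] <- post$ci_high
  out$shape_a[ok] <- post$shape_a
  out$rate_b[ok] <- post$rate_b
  rownames(out) <- NULL
  attr(out, "nu") <- nu_by_country
  attr(out, "bandwidth_h") <- h
  attr(out, "reference_rate") <- m
  out
}
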