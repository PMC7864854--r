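# Independent, deliberately naive reference implementations used as oracles.
# These recompute the same quantities as the package with plain loops and
# nothing shared with the implementation code paths.

# Naive Poisson-Gamma smoother: explicit loops over cells and donors.
brute_force_eb <- function(cells, regions, params = eb_params()) {
  edu_levels <- c("low", "medium", "high")
  # full grid
  rows <- list()
  for (ri in seq_len(nrow(regions))) {
    for (ed in edu_levels) {
      hit <- which(cells$region_id == regions$region_id[ri] &
                   cells$education == ed)
      rows[[length(rows) + 1L]] <- data.frame(
        country_id = regions$country_id[ri],
        region_id = regions$region_id[ri],
        education = ed,
        n_women = if (length(hit)) cells$n_women[hit] else 0L,
        total_children = if (length(hit)) cells$total_children[hit] else 0L,
        stringsAsFactors = FALSE)
    }
  }
  full <- do.call(rbind, rows)
  full <- full[order(full$country_id, full$region_id,
                     match(full$education, edu_levels)), ]

  # bandwidth: pooled within-country SD of log GDP
  h <- params$bandwidth_h
  if (is.null(h)) {
    ss <- 0; nn <- 0
    for (co in unique(regions$country_id)) {
      lg <- log(regions$gdp_pc[regions$country_id == co])
      ss <- ss + sum((lg - mean(lg))^2)
      nn <- nn + length(lg)
    }
    h <- sqrt(ss / (nn - length(unique(regions$country_id))))
    if (!is.finite(h) || h <= 0) h <- 1
  }

  kern <- function(r1, r2) {
    g1 <- regions$gdp_pc[regions$region_id == r1]
    g2 <- regions$gdp_pc[regions$region_id == r2]
    exp(-(log(g1) - log(g2))^2 / (2 * h^2))
  }

  # nu per country via method of moments (or fixed by params)
  nu_of <- list()
  for (co in unique(full$country_id)) {
    if (identical(params$prior_strength_nu, "auto")) {
      sub <- full[full$country_id == co & full$n_women > 0, ]
      cfr <- sub$total_children / sub$n_women
      excess <- stats::var(cfr) - mean(cfr / sub$n_women)
      nu <- mean(cfr) / max(1e-12, excess)
      nu_of[[co]] <- min(max(nu, 1), 1e6)
    } else {
      nu_of[[co]] <- as.numeric(params$prior_strength_nu)
    }
  }

  lam_r <- params$mix_weights[["region"]]
  lam_e <- params$mix_weights[["education"]]
  out <- full
  out$cfr <- NA_real_; out$ci_low <- NA_real_; out$ci_high <- NA_real_
  for (i in seq_len(nrow(full))) {
    co <- full$country_id[i]; re <- full$region_id[i]; ed <- full$education[i]
    # cross-region source
    num <- 0; den <- 0
    for (j in seq_len(nrow(full))) {
      if (full$country_id[j] == co && full$education[j] == ed &&
          full$region_id[j] != re && full$n_women[j] > 0) {
        wj <- kern(re, full$region_id[j]) * full$n_women[j]
        num <- num + wj * full$total_children[j] / full$n_women[j]
        den <- den + wj
      }
    }
    m_reg <- if (den > 0) num / den else NA_real_
    # cross-education source
    Bo <- 0; No <- 0
    for (j in seq_len(nrow(full))) {
      if (full$region_id[j] == re && full$education[j] != ed) {
        Bo <- Bo + full$total_children[j]; No <- No + full$n_women[j]
      }
    }
    m_edu <- NA_real_
    if (No > 0) {
      Bce <- 0; Nce <- 0; Bco <- 0; Nco <- 0
      for (j in seq_len(nrow(full))) {
        if (full$country_id[j] == co) {
          if (full$education[j] == ed) {
            Bce <- Bce + full$total_children[j]; Nce <- Nce + full$n_women[j]
          } else {
            Bco <- Bco + full$total_children[j]; Nco <- Nco + full$n_women[j]
          }
        }
      }
      rho <- if (Nce > 0 && Nco > 0) (Bce / Nce) / (Bco / Nco) else 1
      m_edu <- (Bo / No) * rho
    }
    m <- if (is.na(m_reg) && is.na(m_edu)) NA_real_
         else if (is.na(m_reg)) m_edu
         else if (is.na(m_edu)) m_reg
         else lam_r * m_reg + lam_e * m_edu
    if (!is.na(m)) {
      nu <- nu_of[[co]]
      a <- full$total_children[i] + nu * m
      b <- full$n_women[i] + nu
      out$cfr[i] <- a / b
      out$ci_low[i] <- stats::qgamma((1 - params$ci_level) / 2, a, rate = b)
      out$ci_high[i] <- stats::qgamma(1 - (1 - params$ci_level) / 2, a, rate = b)
    }
  }
  rownames(out) <- NULL
  out
}

# Gamma quantile by quadrature: invert the numerically integrated density.
quadrature_gamma_quantile <- function(p, shape, rate) {
  cdf <- function(q) stats::integrate(function(x) stats::dgamma(x, shape, rate = rate),
                                      0, q, rel.tol = 1e-12)$value - p
  stats::uniroot(cdf, c(1e-12, shape / rate * 50), tol = 1e-10)$root
}

# Closed-form simple OLS of y on x.
closed_form_ols <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  rss <- sum((y - intercept - slope * x)^2)
  list(slope = slope, intercept = intercept,
       slope_se = sqrt(rss / (n - 2) / sxx))
}

# A small but fully populated toy dataset: 3 countries x 4 regions x 3
# educations, sizes and counts varied deterministically.
toy_dataset <- function(seed = 42) {
  set.seed(seed)
  regions <- data.frame(
    region_id = sprintf("C%02dR%02d", rep(1:3, each = 4), rep(1:4, 3)),
    country_id = sprintf("C%02d", rep(1:3, each = 4)),
    gdp_pc = exp(rnorm(12, 10, 0.3)),
    stringsAsFactors = FALSE)
  grid <- expand.grid(education = c("low", "medium", "high"),
                      region_id = regions$region_id,
                      stringsAsFactors = FALSE)
  grid$country_id <- regions$country_id[match(grid$region_id,
                                              regions$region_id)]
  n <- sample(20:400, nrow(grid), replace = TRUE)
  rate <- runif(nrow(grid), 1.2, 2.4)
  cells <- data.frame(
    country_id = grid$country_id,
    region_id = grid$region_id,
    education = grid$education,
    n_women = n,
    total_children = rpois(nrow(grid), n * rate),
    n_unknown = 0L,
    stringsAsFactors = FALSE)
  list(regions = regions, cells = cells)
}

# Small generator configuration reused across simulation tests.
small_config <- function(women_per_region = 2000, ...) {
  synthetic_config(n_countries = 3, regions_per_country = 4,
                   women_per_region = women_per_region, seed = 11, ...)
}
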