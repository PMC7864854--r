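EDU_LEVELS <- c("low", "medium", "high")

PAIRS <- c("high_medium", "medium_low", "high_low")

pair_members <- function(pair) {
  switch(pair,
    high_medium = c("high", "medium"),
    medium_low  = c("medium", "low"),
    high_low    = c("high", "low"),
    stop("unknown education pair: ", pair)
  )
}

# Deterministic sub-stream seeds: one master seed, one derived seed per
# consumer index.  Kept strictly below 2^31 - 1 so set.seed() accepts them.
substream_seed <- function(seed, i) {
  as.integer((abs(as.numeric(seed)) %% 1000003 * 2017 + (i + 1) * 7919) %%
    2147483629)
}

#' Configuration of the synthetic microdata generator
#'
#' Builds and validates the parameter set from which multi-country,
#' multi-region fertility microdata are simulated.  The generator emulates the
#' structure assumed by the estimation pipeline: completed parity is Poisson
#' with an education-specific mean that varies linearly with a region's log
#' GDP per capita, the share of high-educated women increases with regional
#' development, and countries carry additive rate shifts.
#'
#' @param n_countries number of countries.
#' @param regions_per_country regions simulated per country.
#' @param women_per_region cohort size per region before sampling.
#' @param gdp_log_mean,gdp_log_sd mean and SD of log GDP per capita; regional
#'   GDP is drawn log-normally.
#' @param education_base_shares length-3 non-negative vector (low, medium,
#'   high) summing to 1: education composition at the reference GDP.
#' @param education_gdp_tilt multinomial-logit tilt of the high-education
#'   share per unit of log-GDP deviation from `gdp_log_mean`.
#' @param base_rate_by_education length-3 positive vector (low, medium, high):
#'   mean completed parity at the reference GDP.
#' @param slope_by_education length-3 vector: change of each education
#'   group's mean parity per unit log GDP.  Differences of these are the
#'   ground-truth gradient slopes.
#' @param gradient_slope convenience scalar: if supplied (and
#'   `slope_by_education` is not), it is placed on the high-education group,
#'   so the high-medium and high-low pair gradients both carry this slope.
#' @param country_effect_sd SD of the additive normal country-level rate
#'   shift (children per woman).
#' @param sampling_fraction probability in (0, 1] that a simulated woman is
#'   retained, emulating survey/census sampling fractions.
#' @param unknown_fraction fraction of retained records whose parity is
#'   masked as unknown (NA), exercising the redistribution rule.
#' @param seed integer master seed; all randomness derives from it.
#'
#' @return a list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_countries = 5,
                             regions_per_country = 8,
                             women_per_region = 5000,
                             gdp_log_mean = 10,
                             gdp_log_sd = 0.3,
                             education_base_shares = c(low = 0.16,
                                                       medium = 0.53,
                                                       high = 0.31),
                             education_gdp_tilt = 0.5,
                             base_rate_by_education = c(low = 2.03,
                                                        medium = 1.78,
                                                        high = 1.62),
                             slope_by_education = NULL,
                             gradient_slope = 0.3,
                             country_effect_sd = 0.10,
                             sampling_fraction = 1,
                             unknown_fraction = 0,
                             seed = 1L) {
  if (is.null(slope_by_education)) {
    slope_by_education <- c(low = 0, medium = 0, high = gradient_slope)
  }
  cfg <- list(
    n_countries = as.integer(n_countries),
    regions_per_country = as.integer(regions_per_country),
    women_per_region = as.integer(women_per_region),
    gdp_log_mean = gdp_log_mean,
    gdp_log_sd = gdp_log_sd,
    education_base_shares = stats::setNames(as.numeric(education_base_shares),
                                            EDU_LEVELS),
    education_gdp_tilt = education_gdp_tilt,
    base_rate_by_education = stats::setNames(as.numeric(base_rate_by_education),
                                             EDU_LEVELS),
    slope_by_education = stats::setNames(as.numeric(slope_by_education),
                                         EDU_LEVELS),
    country_effect_sd = country_effect_sd,
    sampling_fraction = sampling_fraction,
    unknown_fraction = unknown_fraction,
    seed = as.integer(seed)
  )
  class(cfg) <- "synthetic_config"
  validate_synthetic_config(cfg)
  cfg
}

validate_synthetic_config <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (cfg$n_countries < 1L || cfg$regions_per_country < 1L ||
      cfg$women_per_region < 1L) {
    stop("n_countries, regions_per_country and women_per_region must be ",
         "positive integers")
  }
  sh <- cfg$education_base_shares
  if (any(sh < 0) || abs(sum(sh) - 1) > 1e-12) {
    stop("education_base_shares must be non-negative and sum to 1")
  }
  if (any(cfg$base_rate_by_education <= 0)) {
    stop("base_rate_by_education must be positive")
  }
  if (cfg$gdp_log_sd < 0) stop("gdp_log_sd must be non-negative")
  if (cfg$country_effect_sd < 0) stop("country_effect_sd must be non-negative")
  if (cfg$sampling_fraction <= 0 || cfg$sampling_fraction > 1) {
    stop("sampling_fraction must be in (0, 1]")
  }
  if (cfg$unknown_fraction < 0 || cfg$unknown_fraction >= 1) {
    stop("unknown_fraction must be in [0, 1)")
  }
  invisible(cfg)
}

#' Simulate region metadata
#'
#' Draws one GDP per capita value per region from a log-normal distribution
#' and assigns regions to countries.  Region codes are `C01R03`-style,
#' unique across the dataset.
#'
#' @param config a [synthetic_config()].
#' @return data.frame with columns `region_id`, `country_id`, `gdp_pc`.
#' @export
generate_regions <- function(config) {
  validate_synthetic_config(config)
  nc <- config$n_countries
  rpc <- config$regions_per_country
  country_id <- rep(sprintf("C%02d", seq_len(nc)), each = rpc)
  region_id <- sprintf("%sR%02d", country_id, rep(seq_len(rpc), times = nc))
  set.seed(substream_seed(config$seed, 0L))
  log_gdp <- stats::rnorm(nc * rpc, config$gdp_log_mean, config$gdp_log_sd)
  data.frame(region_id = region_id, country_id = country_id,
             gdp_pc = exp(log_gdp), stringsAsFactors = FALSE)
}

#' Education composition of a region
#'
#' Multinomial-logit tilt of the high-education share: the high category's
#' weight is multiplied by `exp(tilt * (log gdp_pc - gdp_log_mean))` and the
#' three weights renormalised, so richer regions hold more high-educated
#' women when the tilt is positive.
#'
#' @param regions data.frame as returned by [generate_regions()] (or any
#'   frame with a `gdp_pc` column).
#' @param config a [synthetic_config()].
#' @return numeric matrix, one row per region, columns `low`, `medium`,
#'   `high`; rows sum to 1.
#' @export
education_shares <- function(regions, config) {
  validate_synthetic_config(config)
  stopifnot(all(regions$gdp_pc > 0))
  dev <- log(regions$gdp_pc) - config$gdp_log_mean
  base <- config$education_base_shares
  w <- cbind(low = rep(base[["low"]], length(dev)),
             medium = rep(base[["medium"]], length(dev)),
             high = base[["high"]] * exp(config$education_gdp_tilt * dev))
  sh <- w / rowSums(w)
  rownames(sh) <- regions$region_id
  sh
}

# Expected mean parity for every region x education under the generator's
# mean structure, before country effects and Poisson noise.
mean_parity_matrix <- function(regions, config) {
  dev <- log(regions$gdp_pc) - config$gdp_log_mean
  mu <- outer(dev, config$slope_by_education) +
    rep(config$base_rate_by_education, each = length(dev))
  colnames(mu) <- EDU_LEVELS
  rownames(mu) <- regions$region_id
  mu
}

#' Simulate woman-level microdata
#'
#' For every region, `women_per_region` women are assigned an education level
#' according to [education_shares()] and a completed parity drawn from a
#' Poisson distribution with mean
#' `max(1e-6, mu_e + slope_e * (log gdp - gdp_log_mean) + u_c)`, where `u_c`
#' is a normal country effect.  Records are then thinned by an independent
#' Bernoulli(`sampling_fraction`) draw, and a configured fraction of parities
#' is masked as unknown (`NA`).
#'
#' @param regions data.frame from [generate_regions()].
#' @param config a [synthetic_config()].
#' @return data.frame with columns `country_id`, `region_id`, `education`,
#'   `parity` (non-negative integer, `NA` = unknown).
#' @export
generate_microdata <- function(regions, config) {
  validate_synthetic_config(config)
  stopifnot(nrow(regions) > 0)
  countries <- sort(unique(regions$country_id))
  set.seed(substream_seed(config$seed, 1L))
  u_c <- stats::setNames(stats::rnorm(length(countries), 0,
                                      config$country_effect_sd), countries)
  shares <- education_shares(regions, config)
  mu_base <- mean_parity_matrix(regions, config)
  n <- config$women_per_region
  clipped <- 0L
  out <- vector("list", nrow(regions))
  for (i in seq_len(nrow(regions))) {
    set.seed(substream_seed(config$seed, 1L + i))
    edu <- sample(EDU_LEVELS, n, replace = TRUE, prob = shares[i, ])
    mu <- mu_base[i, edu] + u_c[[regions$country_id[i]]]
    low <- mu <= 0
    if (any(low)) {
      clipped <- clipped + sum(low)
      mu[low] <- 1e-6
    }
    parity <- stats::rpois(n, mu)
    if (config$unknown_fraction > 0) {
      parity[stats::runif(n) < config$unknown_fraction] <- NA_integer_
    }
    keep <- if (config$sampling_fraction < 1) {
      stats::runif(n) < config$sampling_fraction
    } else rep(TRUE, n)
    out[[i]] <- data.frame(country_id = regions$country_id[i],
                           region_id = regions$region_id[i],
                           education = edu[keep],
                           parity = as.integer(parity[keep]),
                           stringsAsFactors = FALSE)
  }
  if (clipped > 0L) {
    warning(sprintf("%d non-positive Poisson means clipped to 1e-6", clipped))
  }
  do.call(rbind, out)
}

#' Ground-truth educational gradient of the generator
#'
#' Expected CFR difference for an education pair at given regions' GDP under
#' the generator's mean structure, with no sampling noise.  Country effects
#' are common to all education groups and cancel from the difference.
#'
#' @param config a [synthetic_config()].
#' @param pair one of `"high_medium"`, `"medium_low"`, `"high_low"`.
#' @param regions data.frame with a `gdp_pc` column.
#' @return numeric vector of expected differences, one per region.
#' @export
true_gradient <- function(config, pair, regions) {
  validate_synthetic_config(config)
  m <- pair_members(pair)
  dev <- log(regions$gdp_pc) - config$gdp_log_mean
  mu <- config$base_rate_by_education
  b <- config$slope_by_education
  (mu[[m[1]]] - mu[[m[2]]]) + (b[[m[1]]] - b[[m[2]]]) * dev
}

#' Ground-truth gradient slope for an education pair
#'
#' @param config a [synthetic_config()].
#' @param pair education pair.
#' @return the change of the pair's expected CFR difference per unit log GDP.
#' @export
true_slope <- function(config, pair) {
  m <- pair_members(pair)
  b <- config$slope_by_education
  b[[m[1]]] - b[[m[2]]]
}
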