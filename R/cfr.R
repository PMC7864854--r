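#' Aggregate microdata to cell counts
#'
#' Collapses woman-level records to one row per observed
#' (country, region, education) cell, the sufficient statistic for all rate
#' estimation: `n_women` women with known parity, their `total_children`, and
#' the count of women with unknown parity.
#'
#' @param microdata data.frame with columns `country_id`, `region_id`,
#'   `education`, `parity` (`NA` = unknown).
#' @return data.frame of cells: `country_id`, `region_id`, `education`,
#'   `n_women`, `total_children`, `n_unknown`.  Cells with no records are
#'   absent.
#' @export
aggregate_microdata <- function(microdata) {
  cols <- c("country_id", "region_id", "education", "parity")
  stopifnot(all(cols %in% names(microdata)))
  if (nrow(microdata) == 0L) {
    return(data.frame(country_id = character(), region_id = character(),
                      education = character(), n_women = integer(),
                      total_children = integer(), n_unknown = integer(),
                      stringsAsFactors = FALSE))
  }
  p <- microdata$parity
  if (any(p < 0, na.rm = TRUE)) stop("negative parity in microdata")
  key <- paste(microdata$country_id, microdata$region_id,
               microdata$education, sep = "\r")
  known <- !is.na(p)
  n_women <- rowsum(as.integer(known), key)
  total <- rowsum(ifelse(known, as.integer(p), 0L), key)
  n_unknown <- rowsum(as.integer(!known), key)
  parts <- strsplit(rownames(n_women), "\r", fixed = TRUE)
  cells <- data.frame(
    country_id = vapply(parts, `[[`, "", 1L),
    region_id = vapply(parts, `[[`, "", 2L),
    education = vapply(parts, `[[`, "", 3L),
    n_women = as.integer(n_women[, 1L]),
    total_children = as.integer(total[, 1L]),
    n_unknown = as.integer(n_unknown[, 1L]),
    stringsAsFactors = FALSE
  )
  cells <- cells[order(cells$country_id, cells$region_id, cells$education), ]
  rownames(cells) <- NULL
  cells
}

#' Redistribute women with unknown parity
#'
#' Assigns each unknown-parity woman the mean parity of her reference group
#' and folds her into the known counts, conserving the total number of women.
#' The default reference group is the same country and education pooled over
#' regions; `level = "cell"` uses each cell's own mean instead.
#'
#' @param cells cell counts from [aggregate_microdata()].
#' @param level reference group: `"country_education"` (default) or `"cell"`.
#' @return cells with `n_women`/`total_children` updated and `n_unknown = 0`.
#' @export
redistribute_unknown <- function(cells,
                                 level = c("country_education", "cell")) {
  level <- match.arg(level)
  if (!any(cells$n_unknown > 0)) {
    cells$n_unknown <- as.integer(cells$n_unknown)
    return(cells)
  }
  if (level == "country_education") {
    key <- paste(cells$country_id, cells$education, sep = "\r")
    N_ref <- rowsum(cells$n_women, key)
    B_ref <- rowsum(cells$total_children, key)
    ref_mean <- B_ref[, 1L] / N_ref[, 1L]
    ref_mean <- ref_mean[key]
  } else {
    ref_mean <- cells$total_children / cells$n_women
  }
  bad <- cells$n_unknown > 0 & !is.finite(ref_mean)
  if (any(bad)) {
    warning(sprintf(
      "%d cells have unknown-parity women but an empty reference group; ",
      sum(bad)), "those women are assigned parity 0")
    ref_mean[!is.finite(ref_mean)] <- 0
  }
  ref_mean[!is.finite(ref_mean)] <- 0
  add <- as.integer(round(cells$n_unknown * ref_mean))
  cells$total_children <- cells$total_children + add
  cells$n_women <- cells$n_women + cells$n_unknown
  cells$n_unknown <- 0L
  cells
}

#' Raw cohort fertility rates per cell
#'
#' The raw CFR of a cell is the mean number of children per woman,
#' `total_children / n_women`.  Cells with no women yield `NA`, signalling
#' that only the empirical Bayes estimator can speak for them.
#'
#' @param cells cell counts with `n_unknown = 0` (run
#'   [redistribute_unknown()] first).
#' @return data.frame of estimates: `country_id`, `region_id`, `education`,
#'   `cfr`, `method = "raw"`, `ci_low`, `ci_high` (always `NA` for raw).
#' @export
raw_cfr <- function(cells) {
  if (any(cells$n_unknown > 0)) {
    stop("cells still contain unknown-parity women; ",
         "run redistribute_unknown() first")
  }
  data.frame(
    country_id = cells$country_id,
    region_id = cells$region_id,
    education = cells$education,
    cfr = ifelse(cells$n_women > 0,
                 cells$total_children / cells$n_women, NA_real_),
    method = "raw",
    ci_low = NA_real_,
    ci_high = NA_real_,
    stringsAsFactors = FALSE
  )
}

pooled_rate <- function(B, N) {
  N <- sum(N)
  if (N == 0) NA_real_ else sum(B) / N
}

#' Country-level summary of CFR by education
#'
#' Pools each country's cells over regions to national CFRs by education
#' level and in total (women-weighted, i.e. the CFR of the national
#' population), derives the educational gradients from the unrounded rates,
#' and appends a `Mean` row of unweighted arithmetic column means across
#' countries.  Values are kept at full precision; round only for display.
#'
#' @param cells cell counts with `n_unknown = 0`.
#' @return data.frame with one row per country plus a `Mean` row; columns
#'   `country`, `cfr_high`, `cfr_medium`, `cfr_low`, `cfr_total`,
#'   `delta_high_medium`, `delta_medium_low`, `delta_high_low`.
#' @export
country_summary <- function(cells) {
  if (any(cells$n_unknown > 0)) {
    stop("cells still contain unknown-parity women; ",
         "run redistribute_unknown() first")
  }
  countries <- sort(unique(cells$country_id))
  stopifnot(length(countries) >= 1L)
  rows <- lapply(countries, function(co) {
    cc <- cells[cells$country_id == co, ]
    rate_of <- function(edu) {
      sub <- cc[cc$education == edu, ]
      if (nrow(sub) == 0L) NA_real_
      else pooled_rate(sub$total_children, sub$n_women)
    }
    hi <- rate_of("high"); me <- rate_of("medium"); lo <- rate_of("low")
    data.frame(country = co, cfr_high = hi, cfr_medium = me, cfr_low = lo,
               cfr_total = pooled_rate(cc$total_children, cc$n_women),
               delta_high_medium = hi - me,
               delta_medium_low = me - lo,
               delta_high_low = hi - lo,
               stringsAsFactors = FALSE)
  })
  tbl <- do.call(rbind, rows)
  rbind(tbl, summary_mean_row(tbl))
}

#' Unweighted column means of a country summary table
#'
#' @param tbl a country-level table with the [country_summary()] columns
#'   (country rows only).
#' @return a one-row data.frame labelled `Mean` holding the unweighted
#'   arithmetic mean of every numeric column across countries.
#' @export
summary_mean_row <- function(tbl) {
  num <- vapply(tbl, is.numeric, logical(1L))
  out <- tbl[1L, , drop = FALSE]
  out$country <- "Mean"
  out[num] <- lapply(tbl[num], mean, na.rm = TRUE)
  rownames(out) <- NULL
  out
}

#' Round a country summary for display
#'
#' @param tbl output of [country_summary()].
#' @param digits decimal places (default 2, the conventional display
#'   precision for CFRs).
#' @return the table with numeric columns rounded.
#' @export
format_country_summary <- function(tbl, digits = 2) {
  num <- vapply(tbl, is.numeric, logical(1L))
  tbl[num] <- lapply(tbl[num], round, digits = digits)
  tbl
}

#' Published 15-country CFR-by-education reference table
#'
#' Loads the packaged reference table of national cohort fertility rates by
#' education for 15 European countries (women born in the mid-1960s, observed
#' at the end of the reproductive lifespan), including the published
#' educational gradients and the published `Mean` row.  Gradients in the
#' source were computed from unrounded rates before rounding, so a printed
#' delta may differ from the difference of the printed rates by a rounding
#' residual.
#'
#' @param mean_row keep the published `Mean` row (default `TRUE`).
#' @return data.frame with the [country_summary()] columns.
#' @export
load_country_table <- function(mean_row = TRUE) {
  path <- system.file("extdata", "table2.csv", package = "regfert",
                      mustWork = TRUE)
  tbl <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!mean_row) tbl <- tbl[tbl$country != "Mean", ]
  tbl
}
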