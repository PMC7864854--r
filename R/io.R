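#' Default pipeline configuration
#'
#' Nested configuration driving the `simulate -> estimate -> report`
#' pipeline: a synthetic-data block, an EB block, a regression block
#' (outcome method and education pairs), and output paths.  Every field has
#' a default so the whole pipeline runs with no arguments.
#'
#' @param dir output directory for all files.
#' @return nested list of class `pipeline_config`.
#' @export
default_config <- function(dir = ".") {
  structure(list(
    synthetic = unclass(synthetic_config()),
    eb = unclass(eb_params()),
    regression = list(outcome_method = "eb", pairs = PAIRS),
    io = list(
      dir = dir,
      microdata = "microdata.csv",
      regions = "regions.csv",
      cells = "cells.csv",
      estimates_raw = "estimates_raw.csv",
      estimates_eb = "estimates_eb.csv",
      country_summary = "country_summary.csv",
      gradient_fits = "gradient_fits.json",
      hgdp = "hgdp_comparison.csv"
    )
  ), class = "pipeline_config")
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Read a pipeline configuration from YAML
#'
#' Fields absent from the file keep their [default_config()] values.
#'
#' @param path YAML file; `NULL` returns the defaults.
#' @param dir output directory override.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path = NULL, dir = ".") {
  cfg <- default_config(dir)
  if (!is.null(path)) {
    cfg <- merge_config(cfg, yaml::read_yaml(path))
    class(cfg) <- "pipeline_config"
  }
  if (!cfg$regression$outcome_method %in% c("raw", "eb")) {
    stop("regression outcome_method must be 'raw' or 'eb'")
  }
  cfg
}

config_synthetic <- function(cfg) do.call(synthetic_config, cfg$synthetic)

config_eb <- function(cfg) do.call(eb_params, cfg$eb)

io_path <- function(cfg, what) file.path(cfg$io$dir, cfg$io[[what]])

#' Write / read woman-level microdata CSV
#'
#' Schema: `country_id,region_id,education,parity`; parity is blank for
#' women with unknown parity.
#'
#' @param microdata,path data and file path.
#' @return `read_microdata` returns the data.frame; writers return the path
#'   invisibly.
#' @export
write_microdata <- function(microdata, path) {
  utils::write.csv(microdata, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_microdata
#' @export
read_microdata <- function(path) {
  md <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(country_id = "character",
                                       region_id = "character",
                                       education = "character",
                                       parity = "integer"))
  md
}

#' Write / read region metadata CSV (`region_id,country_id,gdp_pc`)
#' @param regions,path data and file path.
#' @export
write_regions <- function(regions, path) {
  utils::write.csv(regions[c("region_id", "country_id", "gdp_pc")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_regions
#' @export
read_regions <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(region_id = "character",
                                 country_id = "character",
                                 gdp_pc = "numeric"))
}

#' Write / read cell-count CSV
#' (`country_id,region_id,education,n_women,total_children,n_unknown`)
#' @param cells,path data and file path.
#' @export
write_cells <- function(cells, path) {
  utils::write.csv(cells, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cells
#' @export
read_cells <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(country_id = "character",
                                 region_id = "character",
                                 education = "character"))
}

#' Write / read CFR-estimate CSV
#' (`country_id,region_id,education,cfr,method,ci_low,ci_high`, plus
#' posterior shape/rate columns for EB estimates)
#' @param estimates,path data and file path.
#' @export
write_estimates <- function(estimates, path) {
  utils::write.csv(estimates, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_estimates
#' @export
read_estimates <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(country_id = "character",
                                 region_id = "character",
                                 education = "character",
                                 method = "character",
                                 cfr = "numeric",
                                 ci_low = "numeric",
                                 ci_high = "numeric"))
}

#' Pipeline step: simulate synthetic microdata
#'
#' Generates regions and microdata from the config's synthetic block and
#' writes both CSVs.  Record counts are reported via `message()`.
#'
#' @param cfg a `pipeline_config`.
#' @return invisibly, a list with the two paths.
#' @export
cmd_simulate <- function(cfg = default_config()) {
  scfg <- config_synthetic(cfg)
  regions <- generate_regions(scfg)
  md <- generate_microdata(regions, scfg)
  dir.create(cfg$io$dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- write_regions(regions, io_path(cfg, "regions"))
  p2 <- write_microdata(md, io_path(cfg, "microdata"))
  message(sprintf("simulate: %d regions, %d woman records written",
                  nrow(regions), nrow(md)))
  invisible(list(regions = p1, microdata = p2))
}

#' Pipeline step: estimate raw and EB rates
#'
#' Reads microdata and regions, aggregates to cells, redistributes unknown
#' parities, and writes the cell counts, the raw and EB estimate tables and
#' the country-level summary.
#'
#' @param cfg a `pipeline_config`.
#' @return invisibly, a list with the output paths.
#' @export
cmd_estimate <- function(cfg = default_config()) {
  md <- read_microdata(io_path(cfg, "microdata"))
  regions <- read_regions(io_path(cfg, "regions"))
  cells <- redistribute_unknown(aggregate_microdata(md))
  write_cells(cells, io_path(cfg, "cells"))
  write_estimates(raw_cfr(cells), io_path(cfg, "estimates_raw"))
  eb <- smooth_table(cells, regions, config_eb(cfg))
  write_estimates(eb, io_path(cfg, "estimates_eb"))
  utils::write.csv(format_country_summary(country_summary(cells)),
                   io_path(cfg, "country_summary"), row.names = FALSE)
  message(sprintf("estimate: %d cells, %d EB estimates written",
                  nrow(cells), nrow(eb)))
  invisible(lapply(c("cells", "estimates_raw", "estimates_eb",
                     "country_summary"), io_path, cfg = cfg))
}

#' Pipeline step: gradient regressions and HGDP comparison
#'
#' Reads the estimate tables, fits the pooled and country fixed-effects
#' regressions for every configured education pair, writes a JSON summary of
#' the fits and the HGDP-versus-rest comparison CSV.
#'
#' @param cfg a `pipeline_config`.
#' @return invisibly, the list written to JSON.
#' @export
cmd_report <- function(cfg = default_config()) {
  pairs <- cfg$regression$pairs
  if (length(pairs) == 0L) stop("regression pairs list is empty")
  regions <- read_regions(io_path(cfg, "regions"))
  cells <- read_cells(io_path(cfg, "cells"))
  ebp <- config_eb(cfg)
  est <- if (cfg$regression$outcome_method == "eb") {
    smooth_table(cells, regions, ebp)
  } else {
    read_estimates(io_path(cfg, "estimates_raw"))
  }
  fits <- list()
  hgdp_all <- list()
  for (pair in pairs) {
    pts <- gradient_table(est, regions, pair)
    po <- fit_pooled(pts)
    fe <- fit_fixed_effects(pts)
    fits[[pair]] <- list(
      pooled = list(slope = po$slope, se = po$slope_se,
                    intercept = po$intercept, n_regions = po$n_regions),
      fixed_effects = list(slope = fe$slope, se = fe$slope_se,
                           n_regions = fe$n_regions)
    )
    if (cfg$regression$outcome_method == "eb") {
      hgdp_all[[pair]] <- hgdp_compare(est, cells, regions, pair, ebp)
    }
  }
  jsonlite::write_json(fits, io_path(cfg, "gradient_fits"),
                       auto_unbox = TRUE, digits = NA)
  if (length(hgdp_all) > 0) {
    utils::write.csv(do.call(rbind, hgdp_all), io_path(cfg, "hgdp"),
                     row.names = FALSE, na = "")
  }
  message(sprintf("report: %d pair(s) analysed", length(pairs)))
  invisible(fits)
}
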