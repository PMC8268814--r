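#' Path to a packaged reference dataset
#'
#' @param file File name under the package's \code{extdata} directory;
#'   empty lists the available files.
#' @return A file path (or a vector of file names).
#' @export
demicell_extdata <- function(file = "") {
  if (!nzchar(file))
    return(dir(system.file("extdata", package = "demicell")))
  path <- system.file("extdata", file, package = "demicell")
  if (!nzchar(path)) stop("no packaged dataset named ", file, call. = FALSE)
  path
}

#' Packaged reference tables for the cholate derivatives
#'
#' \code{read_thermo_table()} returns the published per-temperature
#' demicellization parameters (cmc, mole-fraction cmc scaled by 1e6,
#' aggregation number, \eqn{\Delta G}, \eqn{\Delta H}, \eqn{\Delta S}) for
#' the three hydrophobically substituted sodium cholate derivatives NaAdC,
#' NaAdCH2C and NatButPhC in carbonate buffer.
#' \code{read_logp_table()} returns the published log P benchmark for six
#' natural unconjugated bile salts: five SwissADME predictors plus the
#' molecular-lipophilicity-potential (\code{virtual}) method against
#' experimental values.
#'
#' @param file CSV path; defaults to the packaged fixture.
#' @return A data frame.
#' @export
read_thermo_table <- function(file = demicell_extdata("bile_salt_demicellization_thermo.csv")) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("surfactant", "cmc_mM", "T_K", "n", "dG_kJ_mol", "dH_kJ_mol")
  if (!all(need %in% names(df)))
    stop("thermo table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  df
}

#' @rdname read_thermo_table
#' @export
read_logp_table <- function(file = demicell_extdata("bile_salt_logp_predictions.csv")) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  if (!"experimental" %in% names(df))
    stop("log P table must have an `experimental` column", call. = FALSE)
  df
}

#' Read / write an ITC titration as CSV plus a metadata sidecar
#'
#' The per-injection table is a CSV with columns \code{injection_id},
#' \code{volume_uL} and \code{heat_kJ_per_mol}; the experiment-level
#' metadata (\code{syringe_conc_mM}, \code{cell_volume_uL},
#' \code{temperature_K}, \code{buffer_total_mM}, \code{pH}, \code{label})
#' live in a JSON or YAML sidecar, chosen by file extension.
#'
#' @param heats_file Path to the per-injection CSV.
#' @param config_file Path to the sidecar (\code{.json}, \code{.yml} or
#'   \code{.yaml}).
#' @param series An [itc_series()] (for the writer).
#' @return \code{read_itc_series()} returns an [itc_series()];
#'   \code{write_itc_series()} returns the paths invisibly.
#' @export
read_itc_series <- function(heats_file, config_file) {
  df <- utils::read.csv(heats_file, stringsAsFactors = FALSE)
  need <- c("injection_id", "volume_uL", "heat_kJ_per_mol")
  if (!all(need %in% names(df)))
    stop("injection table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  df <- df[order(df$injection_id), , drop = FALSE]
  cfg <- read_config(config_file)
  need_cfg <- c("syringe_conc_mM", "cell_volume_uL", "temperature_K")
  if (!all(need_cfg %in% names(cfg)))
    stop("ITC sidecar must define ", paste(need_cfg, collapse = ", "),
         call. = FALSE)
  itc_series(
    syringe_conc = cfg$syringe_conc_mM,
    cell_volume = cfg$cell_volume_uL,
    injection_volumes = df$volume_uL,
    heats = df$heat_kJ_per_mol,
    temperature = cfg$temperature_K,
    buffer_total_conc = cfg$buffer_total_mM %||% NA_real_,
    pH = cfg$pH %||% NA_real_,
    label = cfg$label %||% ""
  )
}

#' @rdname read_itc_series
#' @export
write_itc_series <- function(series, heats_file, config_file) {
  stopifnot(inherits(series, "itc_series"))
  utils::write.csv(data.frame(
    injection_id = seq_along(series$heats),
    volume_uL = series$injection_volumes,
    heat_kJ_per_mol = series$heats
  ), heats_file, row.names = FALSE)
  cfg <- list(syringe_conc_mM = series$syringe_conc,
              cell_volume_uL = series$cell_volume,
              temperature_K = series$temperature,
              buffer_total_mM = series$buffer_total_conc,
              pH = series$pH,
              label = series$label)
  write_config(cfg, config_file)
  invisible(c(heats_file, config_file))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yml", "yaml")) yaml::read_yaml(path)
  else if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
  else stop("config must be .json, .yml or .yaml, got: ", path, call. = FALSE)
}

write_config <- function(x, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yml", "yaml")) yaml::write_yaml(x, path)
  else if (ext == "json")
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  else stop("config must be .json, .yml or .yaml, got: ", path, call. = FALSE)
}

#' Read a surface-tension CSV
#'
#' Expects columns \code{conc_mM} and \code{gamma_mN_per_m}.
#'
#' @param file CSV path.
#' @param temperature,label Passed to [surface_tension_curve()].
#' @return A [surface_tension_curve()].
#' @export
read_surface_tension_curve <- function(file, temperature = 298.15, label = "") {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("conc_mM", "gamma_mN_per_m")
  if (!all(need %in% names(df)))
    stop("surface-tension table must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  df <- df[order(df$conc_mM), , drop = FALSE]
  surface_tension_curve(df$conc_mM, df$gamma_mN_per_m,
                        temperature = temperature, label = label)
}

#' Write a demicellization fit result to disk
#'
#' Flat single-row CSV or JSON export of a [fit_demicellization()] result.
#'
#' @param fit A \code{"demic_fit"} object.
#' @param file Output path; format chosen by extension (\code{.csv} or
#'   \code{.json}).
#' @return The path, invisibly.
#' @export
write_demic_fit <- function(fit, file) {
  stopifnot(inherits(fit, "demic_fit"))
  flat <- fit[c("label", "temperature", "n", "dH_demic", "dH_dil", "K", "cmc",
                "line_intercept", "line_slope", "r_squared",
                "n_intercept", "n_slope", "n_dropped")]
  ext <- tolower(tools::file_ext(file))
  if (ext == "csv")
    utils::write.csv(as.data.frame(flat), file, row.names = FALSE)
  else if (ext == "json")
    jsonlite::write_json(flat, file, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  else stop("unsupported output format: ", file, call. = FALSE)
  invisible(file)
}

#' Configuration of the end-to-end analysis
#'
#' Collects every tunable the pipeline uses, with defaults matching the
#' packaged reference tables; the whole object serializes cleanly to
#' JSON/YAML via [write_config()] semantics.
#'
#' @param thermo_table Path to the per-temperature thermodynamics CSV.
#' @param logp_table Path to the log P benchmark CSV.
#' @param itc_heats,itc_configs Optional equal-length vectors of ITC
#'   CSV/sidecar paths to fit.
#' @param water_molarity Molarity of water (M) for mole-fraction cmc.
#' @param pKa2 Second carbonic-acid dissociation constant.
#' @param drop_first_injection Passed to [fit_demicellization()].
#' @param seed Seed recorded in the report (the reference-table pipeline is
#'   deterministic; the seed governs any simulated inputs).
#' @return A list of class \code{"analysis_config"}.
#' @export
analysis_config <- function(thermo_table = demicell_extdata("bile_salt_demicellization_thermo.csv"),
                            logp_table = demicell_extdata("bile_salt_logp_predictions.csv"),
                            itc_heats = character(0),
                            itc_configs = character(0),
                            water_molarity = 55.5,
                            pKa2 = 10.33,
                            drop_first_injection = FALSE,
                            seed = 1L) {
  stopifnot(length(itc_heats) == length(itc_configs))
  structure(list(thermo_table = thermo_table, logp_table = logp_table,
                 itc_heats = itc_heats, itc_configs = itc_configs,
                 water_molarity = water_molarity, pKa2 = pKa2,
                 drop_first_injection = drop_first_injection,
                 seed = as.integer(seed)),
            class = "analysis_config")
}

#' Run the full demicellization / lipophilicity analysis
#'
#' End-to-end pipeline over the configured inputs: (i) any ITC titrations
#' are fitted with [fit_demicellization()]; (ii) the per-temperature
#' thermodynamics table is re-derived -- the entropy column from
#' \eqn{\Delta G}, \eqn{\Delta H} and \eqn{T}, the mole-fraction cmc from
#' the molar cmc -- and summarized per surfactant (mean aggregation number,
#' \eqn{\Delta C_{P,demic}}); (iii) the log P benchmark is scored with
#' [score_logp_predictors()] and each surfactant's 298.15 K cmc is pushed
#' through the reference calibration [predict_logp_from_cmc()]. The result
#' is deterministic for a given config.
#'
#' @param config An [analysis_config()].
#' @return A list of class \code{"demicell_report"} with elements
#'   \code{thermo} (records with regenerated \code{dS_regen} and
#'   \code{x_cmc_regen_e6} columns), \code{summaries} (per-surfactant
#'   [summarize_thermo()] results), \code{logp_scores},
#'   \code{logp_from_cmc} and \code{itc_fits}.
#' @export
run_full_analysis <- function(config = analysis_config()) {
  stopifnot(inherits(config, "analysis_config"))

  itc_fits <- list()
  if (length(config$itc_heats)) {
    itc_fits <- Map(function(h, c) {
      fit_demicellization(read_itc_series(h, c),
                          drop_first = config$drop_first_injection)
    }, config$itc_heats, config$itc_configs)
    names(itc_fits) <- basename(config$itc_heats)
  }

  thermo <- read_thermo_table(config$thermo_table)
  thermo$dS_regen <- delta_s_demic(thermo$dG_kJ_mol, thermo$dH_kJ_mol,
                                   thermo$T_K)
  thermo$x_cmc_regen_e6 <- 1e6 *
    mole_fraction_from_cmc(thermo$cmc_mM, config$water_molarity)

  summaries <- lapply(split(thermo, thermo$surfactant), function(d)
    summarize_thermo(data.frame(temperature = d$T_K, n = d$n,
                                dH_demic = d$dH_kJ_mol)))

  logp <- read_logp_table(config$logp_table)
  logp_scores <- score_logp_predictors(logp)

  ref_fit <- reference_logp_cmc_fit()
  at25 <- thermo[thermo$T_K == 298.15, , drop = FALSE]
  logp_from_cmc <- data.frame(
    surfactant = at25$surfactant,
    cmc_mM = at25$cmc_mM,
    logp_predicted = predict_logp_from_cmc(at25$cmc_mM, ref_fit)
  )

  structure(list(thermo = thermo, summaries = summaries,
                 logp_scores = logp_scores, logp_from_cmc = logp_from_cmc,
                 itc_fits = itc_fits, config = config),
            class = "demicell_report")
}

#' @export
print.demicell_report <- function(x, digits = 3, ...) {
  cat("== Demicellization thermodynamics ==\n")
  print(x$thermo, digits = digits)
  cat("\n== Per-surfactant summaries ==\n")
  for (s in names(x$summaries)) {
    cat(sprintf("%s: ", s))
    print(x$summaries[[s]])
  }
  cat("\n== log P predictor benchmark ==\n")
  print(x$logp_scores, digits = digits)
  cat("\n== log P from cmc (reference calibration, 298.15 K) ==\n")
  print(x$logp_from_cmc, digits = digits)
  if (length(x$itc_fits)) {
    cat("\n== ITC fits ==\n")
    for (f in x$itc_fits) print(f)
  }
  invisible(x)
}
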