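# Orchestration: packaged reference dose table, config-driven end-to-end
# runs (simulate -> compute -> report), and fixture comparison.

#' Packaged reference dose table (per-beam-width block)
#'
#' The published per-beam-width dose table for the modeled CBCT system:
#' DPI, weighted CTDI, DLP and central ray dose f(0) for ten actual beam
#' widths in each of the head (full-fan, l = 600 mm) and body (half-fan,
#' l = 900 mm) scans. Used as the regression fixture for the report
#' arithmetic.
#'
#' @param scan `"head"`, `"body"` or `"both"`.
#' @return Data frame with columns `scan, beam_width_mm, dpi_cGycm,
#'   ctdi_w_cGy, dlp_cGycm, f0_cGy`.
#' @export
reference_dose_table <- function(scan = c("both", "head", "body")) {
  scan <- match.arg(scan)
  df <- utils::read.csv(system.file("extdata", "table1_mc.csv",
                                    package = "cbctdi"))
  if (scan != "both") df <- df[df$scan == scan, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Packaged reference point-dose block
#'
#' Published point-dose results at the clinical 20.6 cm beam width, from
#' ion-chamber measurement and simulation in standard-length phantoms:
#' weighted CTDI, mean peripheral dose, and central ray dose f(0).
#'
#' @param scan `"head"`, `"body"` or `"both"`.
#' @return Data frame with columns `scan, method, beam_width_mm,
#'   ctdi_w_cGy, mean_peripheral_cGy, f0_cGy`.
#' @export
reference_pointdose_table <- function(scan = c("both", "head", "body")) {
  scan <- match.arg(scan)
  df <- utils::read.csv(system.file("extdata", "table1_pointdose.csv",
                                    package = "cbctdi"))
  if (scan != "both") df <- df[df$scan == scan, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' End-to-end run configuration
#'
#' Exactly one profile source must be given: either the synthetic generator
#' (the default parameter sets, or explicit ones) or a list of profile CSV
#' files previously written with [write_profile_set()].
#'
#' @param fan_mode `"full_fan"` or `"half_fan"`.
#' @param nominal_widths_cm Console settings to run, default 1-10 cm.
#' @param seed Integer base seed; beam width `i` uses `seed + i - 1`.
#' @param noise_cv Generator noise CV (0 for noiseless runs).
#' @param center_params,periphery_params Optional [scatter_params()]
#'   overrides; defaults come from [default_scatter_params()] for the scan
#'   type.
#' @param integration_range_l_mm Integration range; defaults to the
#'   protocol's (600/900 mm).
#' @param weights CTDI weighting, default `c(0.5, 0.5)`.
#' @param profile_files Character vector of profile CSVs to analyze instead
#'   of generating.
#' @param out_dir Output directory for profiles, report and manifest;
#'   `NULL` to skip writing.
#' @param decimals Report precision.
#' @return An object of class `run_config`.
#' @export
run_config <- function(fan_mode = c("full_fan", "half_fan"),
                       nominal_widths_cm = nominal_beam_widths(),
                       seed = 1L, noise_cv = 0.01,
                       center_params = NULL, periphery_params = NULL,
                       integration_range_l_mm = NULL,
                       weights = c(0.5, 0.5),
                       profile_files = NULL, out_dir = NULL,
                       decimals = 2) {
  fan_mode <- match.arg(fan_mode)
  generator_requested <- !is.null(center_params) || !is.null(periphery_params)
  if (!is.null(profile_files) && generator_requested) {
    stop("configure exactly one profile source: generator parameters or profile files",
         call. = FALSE)
  }
  scan <- if (fan_mode == "full_fan") "head" else "body"
  if (is.null(profile_files)) {
    if (is.null(center_params)) {
      center_params <- default_scatter_params(scan, "center", noise_cv)
    }
    if (is.null(periphery_params)) {
      periphery_params <- default_scatter_params(scan, "periphery", noise_cv)
    }
  }
  structure(
    list(
      fan_mode = fan_mode,
      scan = scan,
      nominal_widths_cm = nominal_widths_cm,
      seed = as.integer(seed),
      noise_cv = noise_cv,
      center_params = center_params,
      periphery_params = periphery_params,
      integration_range_l_mm = integration_range_l_mm,
      weights = weights,
      profile_files = profile_files,
      out_dir = out_dir,
      decimals = decimals
    ),
    class = "run_config"
  )
}

#' Load a run configuration from YAML
#'
#' Keys mirror [run_config()] arguments; `center_params` and
#' `periphery_params` are given as mappings with keys `equilibrium_dose_h`,
#' `scatter_fraction_eta`, `scatter_range_d`, `penumbra_sigma`, `noise_cv`.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
load_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  for (k in c("center_params", "periphery_params")) {
    if (!is.null(y[[k]])) y[[k]] <- do.call(scatter_params, y[[k]])
  }
  do.call(run_config, y)
}

#' Run the full pipeline: simulate (or load), compute, report
#'
#' Generates (or reads) one five-position profile set per configured beam
#' width, builds the per-beam-width CTDI report, and -- when `out_dir` is
#' set -- writes the profile CSVs, the report as CSV and JSON, and a run
#' manifest (configuration, seed, package version) sufficient to reproduce
#' the run byte for byte.
#'
#' @param config A [run_config()].
#' @param quiet Suppress per-stage progress messages?
#' @return The [build_report()] `ctdi_report`, invisibly when writing.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  protocol <- scan_protocol(config$fan_mode)
  if (!is.null(config$integration_range_l_mm)) {
    protocol <- scan_protocol(config$fan_mode,
                              integration_range_l_mm = config$integration_range_l_mm)
  }

  if (is.null(config$profile_files)) {
    sets <- lapply(seq_along(config$nominal_widths_cm), function(i) {
      nw <- config$nominal_widths_cm[i]
      T_mm <- actual_beam_width(protocol, nw)
      say("simulate | nominal %d cm -> T = %g mm | seed %d",
          nw, T_mm, config$seed + i - 1L)
      tryCatch(
        generate_profile_set(protocol, beam_collimation(nw, T_mm),
                             config$center_params, config$periphery_params,
                             seed = config$seed + i - 1L,
                             noise_cv = config$noise_cv),
        error = function(e) {
          stop(sprintf("beam width %g mm failed: %s", T_mm, conditionMessage(e)),
               call. = FALSE)
        }
      )
    })
  } else {
    sets <- lapply(config$profile_files, function(f) {
      say("load | %s", f)
      s <- read_profile_set(f)
      if (is.null(s$protocol)) s$protocol <- protocol
      s
    })
  }

  cfg <- ctdi_config(protocol$integration_range_l_mm,
                     weights = config$weights, decimals = config$decimals)
  say("compute | l = %g mm, weights (%g, %g)", cfg$integration_range_l_mm,
      cfg$weights[1], cfg$weights[2])
  report <- build_report(sets, cfg)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    if (is.null(config$profile_files)) {
      for (s in sets) {
        write_profile_set(s, file.path(config$out_dir, sprintf(
          "profiles_%s_T%03d.csv", config$scan, round(s$collimation$actual_width_mm))))
      }
    }
    utils::write.csv(as.data.frame(report, rounded = TRUE),
                     file.path(config$out_dir, "report.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(rows = as.data.frame(report, rounded = TRUE),
           mean_ctdi_w = round_half_up(report$mean_ctdi_w, config$decimals),
           mean_ctdi_w_sd = report$mean_ctdi_w_sd),
      file.path(config$out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
    manifest <- unclass(config)
    manifest$center_params <- if (!is.null(config$center_params)) unclass(config$center_params)
    manifest$periphery_params <- if (!is.null(config$periphery_params)) unclass(config$periphery_params)
    manifest$package_version <- as.character(utils::packageVersion("cbctdi"))
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    say("write | %s", config$out_dir)
    return(invisible(report))
  }
  report
}

#' Compare a report to the packaged reference table
#'
#' Cell-by-cell absolute and percent differences between a report's
#' `ctdi_w_cGy` and `dlp_cGycm` columns (rounded to report precision) and a
#' fixture table, matched on beam width.
#'
#' @param report A `ctdi_report`.
#' @param fixture Data frame with columns `beam_width_mm, ctdi_w_cGy,
#'   dlp_cGycm` (e.g. one scan of [reference_dose_table()]).
#' @param tolerance Absolute tolerance for the `pass` flag.
#' @return Data frame with one row per (beam width, column): `beam_width_mm,
#'   quantity, report, fixture, abs_diff, pct_diff, pass`.
#' @export
compare_to_fixture <- function(report, fixture, tolerance = 0.01) {
  stopifnot(inherits(report, "ctdi_report"),
            all(c("beam_width_mm", "ctdi_w_cGy", "dlp_cGycm") %in% names(fixture)))
  rows <- as.data.frame(report, rounded = TRUE)
  if (!setequal(rows$beam_width_mm, fixture$beam_width_mm)) {
    stop("beam widths in report and fixture do not match", call. = FALSE)
  }
  fixture <- fixture[match(rows$beam_width_mm, fixture$beam_width_mm), ]
  out <- do.call(rbind, lapply(c("ctdi_w_cGy", "dlp_cGycm"), function(col) {
    data.frame(
      beam_width_mm = rows$beam_width_mm,
      quantity = col,
      report = rows[[col]],
      fixture = fixture[[col]],
      abs_diff = abs(rows[[col]] - fixture[[col]]),
      pct_diff = abs(rows[[col]] - fixture[[col]]) / fixture[[col]] * 100
    )
  }))
  out$pass <- out$abs_diff <= tolerance + 1e-12
  rownames(out) <- NULL
  out
}
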