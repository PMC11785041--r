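#' Resolution analysis of one elemental map
#'
#' Runs the full chain for a single map: exit wave, even-dimension padding,
#' 2D PSD, radial profile(s), power-law/noise-floor fit, and Rose-criterion
#' resolution. With `sector = "both"` an isotropic profile plus x- and
#' y-sector profiles are analyzed, giving directional resolution estimates.
#'
#' @param map An [elemental_map()].
#' @param sector `"isotropic"`, `"x_sector"`, `"y_sector"`, or `"both"`
#'   (isotropic plus both directional sectors).
#' @param half_angle Sector half-angle, degrees; default 30.
#' @param n_bins Radial bins; default `floor(min(nx, ny)/2)` after padding.
#' @param ranges A [fit_ranges()], or `NULL` to use [suggest_fit_ranges()]
#'   per profile (explicit ranges are recorded in reports either way).
#' @param snr_res Resolution signal-to-noise ratio; default 5.
#' @return A list of `PowerLawFit` objects, one per analyzed profile, named
#'   by sector mode.
#' @examples
#' r <- synth_map(synthetic_spec(nx = 128, ny = 128, mean_counts = 500, seed = 3))
#' fits <- resolve_map(r$map)
#' fits$isotropic$delta_res
#' @export
resolve_map <- function(map, sector = "isotropic", half_angle = 30,
                        n_bins = NULL, ranges = NULL, snr_res = 5) {
  stopifnot(inherits(map, "ElementalMap"))
  modes <- switch(sector,
    both = c("isotropic", "x_sector", "y_sector"),
    isotropic = "isotropic",
    x_sector = "x_sector",
    y_sector = "y_sector",
    stop(sprintf("unknown sector mode '%s'", sector), call. = FALSE)
  )
  spec2d <- compute_psd(pad_to_even(to_exit_wave(map)))
  fits <- lapply(modes, function(m) {
    prof <- radial_profile(spec2d, n_bins = n_bins,
                           sector = sector_spec(m, half_angle))
    rg <- if (is.null(ranges)) suggest_fit_ranges(prof) else ranges
    fit_resolution(prof, rg, snr_res = snr_res)
  })
  names(fits) <- modes
  fits
}

# ---- command-line entry point ------------------------------------------

cli_log <- function(fmt, ...) message(sprintf(paste0("[xrfres] ", fmt), ...))

# Very small flag parser: --key value pairs after the subcommand.
parse_flags <- function(args) {
  out <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[[i]]
    if (!startsWith(a, "--")) stop(sprintf("unexpected argument '%s'", a),
                                   call. = FALSE)
    key <- gsub("-", "_", substring(a, 3L))
    if (i == length(args) || startsWith(args[[i + 1L]], "--")) {
      out[[key]] <- TRUE
      i <- i + 1L
    } else {
      out[[key]] <- args[[i + 1L]]
      i <- i + 2L
    }
  }
  out
}

num_or <- function(x, default = NULL) {
  if (is.null(x)) return(default)
  v <- suppressWarnings(as.numeric(x))
  if (is.na(v)) stop(sprintf("expected a number, got '%s'", x), call. = FALSE)
  v
}

# Merge config file (YAML key/value, nestable) with flags; flags win.
load_config <- function(flags) {
  cfg <- list()
  if (!is.null(flags$config)) {
    if (!file.exists(flags$config)) {
      stop(sprintf("config file not found: %s", flags$config), call. = FALSE)
    }
    cfg <- yaml::read_yaml(flags$config)
    cfg$config_hash <- unname(tools::md5sum(flags$config))
  }
  for (k in names(flags)) cfg[[k]] <- flags[[k]]
  cfg
}

ranges_from_config <- function(cfg) {
  keys <- c("signal_lo", "signal_hi", "noise_lo", "noise_hi")
  have <- vapply(keys, function(k) !is.null(cfg[[k]]), logical(1))
  if (!any(have)) return(NULL)
  if (!all(have)) {
    stop("fit ranges require all of --signal-lo --signal-hi --noise-lo --noise-hi",
         call. = FALSE)
  }
  fit_ranges(num_or(cfg$signal_lo), num_or(cfg$signal_hi),
             num_or(cfg$noise_lo), num_or(cfg$noise_hi))
}

#' Run the resolve pipeline from a configuration list
#'
#' Batch-analyzes one or more elements of an input file and writes a JSON
#' report. A failure on one element is logged and the batch continues; the
#' returned status is 0 when every element succeeded, 1 when some failed.
#'
#' @param cfg Named list (from a YAML config and/or CLI flags): `input`,
#'   `format`, `elements` (comma-separated or vector), `dx`, `dy`, `sector`,
#'   `half_angle`, `n_bins`, fit-range bounds, `snr`, `dataset`,
#'   `channel_names_dataset`, `out`.
#' @return Integer exit status, invisibly.
#' @export
cmd_resolve <- function(cfg) {
  if (is.null(cfg$input)) stop("missing --input", call. = FALSE)
  if (is.null(cfg$out)) stop("missing --out (report path)", call. = FALSE)
  elements <- cfg$elements %||% "unknown"
  if (is.character(elements) && length(elements) == 1L) {
    elements <- strsplit(elements, ",", fixed = TRUE)[[1]]
  }
  ranges <- ranges_from_config(cfg)
  sector <- cfg$sector %||% "isotropic"
  snr <- num_or(cfg$snr, 5)
  dx <- num_or(cfg$dx, 1); dy <- num_or(cfg$dy, 1)
  cli_log("xrfres %s | resolve | seed n/a | config %s",
          utils::packageVersion("xrfres"), cfg$config_hash %||% "(flags only)")
  fits <- list()
  n_fail <- 0L
  for (el in elements) {
    res <- tryCatch({
      map <- read_map(cfg$input, format = cfg$format %||% "auto",
                      element = el, dx = dx, dy = dy,
                      dataset = cfg$dataset,
                      channel_names_dataset = cfg$channel_names_dataset)
      resolve_map(map, sector = sector,
                  half_angle = num_or(cfg$half_angle, 30),
                  n_bins = if (!is.null(cfg$n_bins)) num_or(cfg$n_bins),
                  ranges = ranges, snr_res = snr)
    }, error = function(e) {
      cli_log("element %s FAILED: %s", el, conditionMessage(e))
      NULL
    })
    if (is.null(res)) { n_fail <- n_fail + 1L; next }
    for (m in names(res)) {
      cli_log("element %s [%s]: delta_res = %.4g um (a = %.3f)",
              el, m, res[[m]]$delta_res, res[[m]]$a)
    }
    fits <- c(fits, unname(res))
  }
  if (length(fits) == 0L) stop("no element could be analyzed", call. = FALSE)
  write_report(fits, cfg$out,
               extra = list(input = cfg$input, sector = sector,
                            snr_res = snr, elements = elements,
                            config_hash = cfg$config_hash %||% NA,
                            n_failed = n_fail))
  cli_log("report written to %s", cfg$out)
  invisible(if (n_fail > 0L) 1L else 0L)
}

#' Generate a synthetic map from a configuration list
#'
#' Writes the Poisson-sampled map (TIFF or CSV by extension of `out`) and a
#' noiseless-truth sidecar (`<out>.truth.csv`).
#'
#' @param cfg Named list: `kind`, `nx`, `ny`, `dx`, `dy`, `a_true`,
#'   `mean_counts`, `seed`, `spot_separation`, `out`.
#' @return Integer exit status, invisibly.
#' @export
cmd_synth <- function(cfg) {
  if (is.null(cfg$out)) stop("missing --out", call. = FALSE)
  spec <- synthetic_spec(
    nx = num_or(cfg$nx, 512), ny = num_or(cfg$ny, 512),
    dx = num_or(cfg$dx, 1), dy = num_or(cfg$dy, 1),
    a_true = num_or(cfg$a_true, -3.5),
    mean_counts = num_or(cfg$mean_counts, 200),
    seed = num_or(cfg$seed, 1),
    kind = cfg$kind %||% "power_law_field",
    spot_separation = num_or(cfg$spot_separation)
  )
  cli_log("xrfres %s | synth %s | seed %d", utils::packageVersion("xrfres"),
          spec$kind, spec$seed)
  res <- synth_map(spec)
  write_map(res$map, cfg$out)
  truth_path <- paste0(cfg$out, ".truth.csv")
  write_map(elemental_map(res$truth, spec$dx, spec$dy,
                          element = res$map$element, source = "synthetic"),
            truth_path, format = "csv")
  cli_log("map written to %s (truth sidecar %s)", cfg$out, truth_path)
  invisible(0L)
}

#' Evaluate photometry from a configuration list
#'
#' @param cfg Named list of [photometry_summary()] settings plus optional
#'   `out` (JSON path; printed to stdout when omitted).
#' @return Integer exit status, invisibly.
#' @export
cmd_photometry <- function(cfg) {
  keys <- c("K_E", "g_s", "V_out", "Phi", "W_beam", "theta", "A_active",
            "d_sd", "delta_x", "delta_y")
  settings <- list()
  for (k in keys) settings[[k]] <- num_or(cfg[[k]])
  out <- photometry_summary(settings)
  txt <- jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(cfg$out)) writeLines(txt, cfg$out) else cat(txt, "\n")
  invisible(0L)
}

#' Wiener-filter a map from a configuration list
#'
#' Reads a map, fits (or accepts) the power-law/noise-floor model, applies
#' the Wiener filter, and writes the filtered map as delimited text.
#'
#' @param cfg Named list: as [cmd_resolve()] plus `out` for the filtered map.
#' @return Integer exit status, invisibly.
#' @export
cmd_wiener <- function(cfg) {
  if (is.null(cfg$input) || is.null(cfg$out)) {
    stop("wiener requires --input and --out", call. = FALSE)
  }
  map <- read_map(cfg$input, format = cfg$format %||% "auto",
                  element = (cfg$elements %||% "unknown")[1],
                  dx = num_or(cfg$dx, 1), dy = num_or(cfg$dy, 1),
                  dataset = cfg$dataset,
                  channel_names_dataset = cfg$channel_names_dataset)
  fits <- resolve_map(map, ranges = ranges_from_config(cfg),
                      snr_res = num_or(cfg$snr, 5))
  filtered <- apply_wiener(map, fits$isotropic)
  write_map(filtered, cfg$out, format = "csv")
  cli_log("filtered map written to %s", cfg$out)
  invisible(0L)
}

#' Command-line interface
#'
#' Entry point used by the installed `xrfres` script
#' (`system.file("scripts", "xrfres", package = "xrfres")`). Subcommands:
#' `resolve`, `synth`, `photometry`, `wiener`. Options come from an optional
#' YAML config (`--config file`) overridden by `--key value` flags.
#'
#' @param args Character vector of command-line arguments.
#' @return Integer exit status (0 success, 1 partial failure, 2 fatal).
#' @export
xrf_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) < 1L) {
    message("usage: xrfres <resolve|synth|photometry|wiener> [--config file] [--key value ...]")
    return(2L)
  }
  sub <- args[[1]]
  status <- tryCatch({
    cfg <- load_config(parse_flags(args[-1]))
    switch(sub,
      resolve = cmd_resolve(cfg),
      synth = cmd_synth(cfg),
      photometry = cmd_photometry(cfg),
      wiener = cmd_wiener(cfg),
      stop(sprintf("unknown subcommand '%s'", sub), call. = FALSE)
    )
  }, error = function(e) {
    cli_log("error: %s", conditionMessage(e))
    2L
  })
  invisible(as.integer(status))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
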