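#' Read a 1D spectrum from two-column text
#'
#' Whitespace/tab-separated two-column format (chemical shift in ppm,
#' intensity); lines starting with `#` are comments. Metadata (field,
#' contact time, temperature, ...) lives in an optional JSON sidecar
#' `<path>.json`, returned in the `metadata` attribute.
#'
#' @param path file path.
#' @return A [spectrum1d()]; malformed rows raise an error naming the line.
#' @export
load_spectrum <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  if (!any(keep)) stop("no data rows in ", path)
  idx <- which(keep)
  parsed <- lapply(idx, function(i) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    v <- suppressWarnings(as.numeric(f))
    if (length(v) < 2L || anyNA(v[1:2]))
      stop("malformed row at line ", i, " of ", path, ": '", lines[i], "'")
    v[1:2]
  })
  m <- do.call(rbind, parsed)
  sp <- spectrum1d(m[, 1], m[, 2])
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar))
    attr(sp, "metadata") <- jsonlite::read_json(sidecar)
  sp
}

#' Write a 1D spectrum as two-column text
#'
#' @param spectrum a [spectrum1d()].
#' @param path output path; values printed with `%.8g` so a load/save round
#'   trip is lossless at that precision.
#' @param metadata optional named list written to a `<path>.json` sidecar.
#' @return `path`, invisibly.
#' @export
save_spectrum <- function(spectrum, path, metadata = NULL) {
  stopifnot(inherits(spectrum, "spectrum1d"))
  writeLines(c("# ppm\tintensity",
               sprintf("%.8g\t%.8g", spectrum$axis, spectrum$intensity)),
             path)
  if (!is.null(metadata))
    jsonlite::write_json(metadata, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  invisible(path)
}

#' Read a dephasing curve from CSV
#'
#' Columns `t1_over_taur`, `amplitude` and optionally `sigma`; `#` comment
#' lines allowed.
#'
#' @param path file path.
#' @param mas_rate rotor frequency (Hz) converting the fractional times to
#'   seconds.
#' @return A [dephasing_curve()] (with a `sigma` attribute when present).
#' @export
load_dephasing <- function(path, mas_rate = 5000) {
  df <- utils::read.csv(path, comment.char = "#")
  if (!all(c("t1_over_taur", "amplitude") %in% names(df)))
    stop("dephasing CSV needs columns t1_over_taur, amplitude")
  cv <- dephasing_curve(df$t1_over_taur / mas_rate, df$amplitude, mas_rate)
  if ("sigma" %in% names(df)) attr(cv, "sigma") <- df$sigma
  cv
}

#' Write a dephasing curve as CSV
#'
#' @param curve a [dephasing_curve()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_dephasing <- function(curve, path) {
  stopifnot(inherits(curve, "dephasing_curve"))
  utils::write.csv(data.frame(t1_over_taur = curve$t1 * curve$mas_rate,
                              amplitude = curve$amplitude),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a binding assay table from CSV
#'
#' Columns `conc_nM` plus one or more replicate columns `rep1..repN`
#' (percent fluorescence).
#'
#' @param path file path.
#' @return A [dose_response()].
#' @export
load_binding <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  if (!"conc_nM" %in% names(df)) stop("binding CSV needs a conc_nM column")
  reps <- grep("^rep[0-9]+$", names(df), value = TRUE)
  if (length(reps) == 0L) stop("binding CSV needs replicate columns rep1..repN")
  dose_response(df$conc_nM, as.matrix(df[reps]))
}

#' Write a binding assay table as CSV
#'
#' @param data a [dose_response()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_binding <- function(data, path) {
  stopifnot(inherits(data, "dose_response"))
  df <- data.frame(conc_nM = data$x, data$y)
  names(df)[-1] <- paste0("rep", seq_len(ncol(data$y)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Save / load a fixture config as JSON
#'
#' Serialization is canonical (fixed field order, full precision), so the
#' same config always produces byte-identical files.
#'
#' @param config a [fixture_config()].
#' @param path file path.
#' @return `path` (save) or the reconstructed [fixture_config()] (load).
#' @export
save_fixture_config <- function(config, path) {
  stopifnot(inherits(config, "fixture_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_fixture_config
#' @export
load_fixture_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  fixture_config(x$scenario, as.list(x$params), as.list(x$noise),
                 x$replicates, x$seed)
}

#' Run the synthetic end-to-end pipeline
#'
#' Executes the requested stages in order (`synth` -> `fit` -> `tabulate`)
#' over the packaged DipShift scenarios: generates seeded dephasing-curve
#' replicates for every lipid/ligand condition, fits each for an order
#' parameter, and aggregates the fits into the condition-indexed summary
#' table. Writes `results.json` and `summary.csv` plus a `manifest.json`
#' recording the package version, config hash, seeds and per-stage status;
#' re-running with an identical config reproduces identical results files.
#'
#' @param config list with elements `seed` (integer) and `stages`
#'   (character subset of `c("synth", "fit", "tabulate")`; empty for a
#'   no-op run).
#' @param out_dir output directory (created if missing).
#' @return The manifest, invisibly (list of class `run_manifest`).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(is.list(config), !is.null(config$seed))
  stages <- config$stages %||% character()
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(config, cfg_path, auto_unbox = TRUE, digits = NA)
  manifest <- list(
    tool = "memdyn",
    version = as.character(utils::packageVersion("memdyn")),
    config_hash = unname(tools::md5sum(cfg_path)),
    seed = config$seed,
    timestamp = format(Sys.time(), tz = "UTC"),
    stages = list())
  scen <- fixture_scenarios(config$seed)
  dip_names <- grep("^dipshift_", names(scen), value = TRUE)
  generated <- NULL; fits <- NULL
  if ("synth" %in% stages) {
    generated <- lapply(scen[dip_names], gen_dipshift_curve)
    manifest$stages$synth <- list(status = "ok",
                                  n_conditions = length(generated))
  }
  if ("fit" %in% stages) {
    if (is.null(generated)) stop("fit stage requires synth stage")
    fits <- list()
    for (nm in dip_names) {
      g <- generated[[nm]]
      lip <- toupper(sub("dipshift_([a-z]+)_.*", "\\1", nm))
      lig <- sub("dipshift_[a-z]+_", "", nm)
      lig <- if (lig == "inverse") "inverse_agonist" else lig
      for (r in seq_along(g$curves)) {
        cl <- condition_label(excitation = "direct", lipid = lip,
                              ligand = lig, site = "Calpha")
        fits[[paste0(nm, "_rep", r)]] <-
          fit_dipshift(g$curves[[r]], g$params, condition = cl)
      }
    }
    res <- lapply(fits, function(f)
      list(S = f$order_parameter, d_eff_Hz = f$d_eff, residual = f$residual,
           units = list(d_eff = "Hz", S = "dimensionless")))
    jsonlite::write_json(res, file.path(out_dir, "results.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    manifest$stages$fit <- list(status = "ok", n_fits = length(fits),
                                results = "results.json")
  }
  if ("tabulate" %in% stages) {
    if (is.null(fits)) stop("tabulate stage requires fit stage")
    tab <- tabulate_conditions(unname(fits))
    utils::write.csv(tab, file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
    manifest$stages$tabulate <- list(status = "ok", summary = "summary.csv")
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(structure(manifest, class = "run_manifest"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
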