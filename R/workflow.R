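# Pipeline orchestration: validated config, staged execution, manifest,
# report generation.

pipeline_schema <- list(
  common = c("analysis", "output_dir", "seed", "log"),
  calibration = c("raw", "prescribed_flip_deg", "discard_first"),
  ventilation = c("image", "mask", "methods", "reference", "bias",
                  "ddi_radius"),
  diffusion = c("stack", "bvalues", "mask", "age_years", "methods",
                "morphometry", "diffusion_time_ms"),
  gasexchange = c("raw", "gas", "dissolved", "mask", "calibration",
                  "reference", "matrix_size"))

#' Validate a pipeline configuration
#'
#' Checks the config (a named list or a YAML file path) against the known
#' keys for its analysis type before any computation; unknown keys are
#' rejected.
#'
#' @param config named list or path to a YAML file.
#' @return the validated config list.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a named list or YAML path")
  analysis <- config$analysis %||% stop("config needs an `analysis` field")
  analysis <- match.arg(analysis, names(pipeline_schema)[-1])
  allowed <- c(pipeline_schema$common, pipeline_schema[[analysis]])
  unknown <- setdiff(names(config), allowed)
  if (length(unknown))
    stop("unknown config keys for ", analysis, " analysis: ",
         paste(unknown, collapse = ", "))
  config$analysis <- analysis
  config
}

stage_log <- function(log, stage, t0) {
  msg <- sprintf("[%s] %s: %.2fs", format(Sys.time(), "%H:%M:%S"), stage,
                 as.numeric(Sys.time()) - t0)
  message(msg)
  c(log, msg)
}

#' Run a configured analysis pipeline
#'
#' Executes the stages in order (load, segment, post-process, export) for the
#' configured analysis, with per-stage logging. Deterministic given the
#' config and seed. A stage failure halts with a stage-named error; outputs
#' written before the failure are preserved.
#'
#' @param config named list or YAML path; see [validate_config()].
#' @return list with `result` (the stage bundle), `manifest` (exported files
#'   with checksums) and `log`.
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  seed <- config$seed %||% 1
  out_dir <- config$output_dir %||% stop("config needs `output_dir`")
  log <- character(0); t0 <- as.numeric(Sys.time())
  run_stage <- function(stage, expr) {
    r <- tryCatch(expr, error = function(e)
      stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE))
    log <<- stage_log(log, stage, t0)
    r
  }
  load_mask <- function() {
    m <- read_image_volume(config$mask)
    lung_mask(array(as.integer(round(m$data)), dim(m$data)), m$spacing)
  }
  result <- switch(config$analysis,
    calibration = {
      raw <- run_stage("load", read_raw(config$raw))
      run_stage("calibrate",
                run_calibration(raw, config$prescribed_flip_deg %||%
                                  raw$prescribed_flip_deg,
                                discard_first = config$discard_first %||% 100))
    },
    ventilation = {
      vol <- run_stage("load", read_image_volume(config$image))
      mask <- run_stage("segment", if (!is.null(config$mask)) load_mask()
                        else otsu_lung_mask(vol))
      ref <- if (!is.null(config$reference))
        healthy_reference(config$reference[1], config$reference[2])
      else healthy_reference(0.68, 0.14)
      run_stage("postprocess",
                run_ventilation(vol, mask, ref,
                                methods = config$methods %||%
                                  c("threshold", "linbin", "kmeans"),
                                bias = config$bias %||% "none",
                                ddi_radius = config$ddi_radius %||% 3,
                                seed = seed))
    },
    diffusion = {
      vol <- run_stage("load", read_image_volume(config$stack))
      stack <- diffusion_stack(vol$data, config$bvalues,
                               config$diffusion_time_ms %||% NA_real_,
                               vol$spacing)
      mask <- run_stage("segment", if (!is.null(config$mask)) load_mask()
                        else otsu_lung_mask(image_volume(
                          stack$data[, , , 1, drop = TRUE], vol$spacing)))
      run_stage("postprocess",
                run_diffusion(stack, mask,
                              age_years = config$age_years %||% 30,
                              methods = config$methods %||% "loglinear",
                              morphometry = config$morphometry %||% character(0)))
    },
    gasexchange = {
      input <- run_stage("load", if (!is.null(config$raw)) read_raw(config$raw)
                         else list(gas = read_image_volume(config$gas),
                                   dissolved = read_image_volume(config$dissolved)))
      mask <- run_stage("segment", load_mask())
      cal <- if (is.list(config$calibration)) do.call(dixon_config,
                                                     config$calibration)
      else stop("gasexchange config needs a `calibration` block")
      ref <- if (!is.null(config$reference) && is.character(config$reference))
        do.call(gasexchange_reference, jsonlite::read_json(config$reference,
                                                           simplifyVector = TRUE))
      else gasexchange_reference()
      run_stage("postprocess",
                run_gasexchange(input, cal, mask, ref,
                                matrix_size = config$matrix_size))
    })
  manifest <- export_metrics(result, out_dir)
  log <- stage_log(log, "export", t0)
  list(result = result, manifest = manifest, log = log)
}

#' Generate a summary report
#'
#' Writes a single-page HTML summary (key metrics table, per-bin percentages)
#' plus the metrics JSON for any result bundle. Regeneration from the same
#' bundle is deterministic. Missing sections are omitted with a note.
#'
#' @param bundle a result object from any analysis stage.
#' @param out_dir output directory.
#' @param subject optional named list of subject/scan info fields.
#' @return path of the HTML file, invisibly.
#' @export
generate_report <- function(bundle, out_dir, subject = list()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- export_metrics(bundle, out_dir)
  json <- jsonlite::read_json(manifest$file[1])
  esc <- function(x) gsub("<", "&lt;", gsub("&", "&amp;", as.character(x)))
  fmt <- function(v) {
    v <- unlist(v)
    if (is.numeric(v)) v <- signif(v, 6)
    paste(v, collapse = ", ")
  }
  rows <- function(lst) paste(vapply(names(lst), function(k)
    sprintf("<tr><td>%s</td><td>%s</td></tr>", esc(k), esc(fmt(lst[[k]]))), ""),
    collapse = "\n")
  scalars <- Filter(function(v) is.numeric(unlist(v)) || is.character(unlist(v)),
                    json)
  body <- c("<html><head><title>xepipe report</title></head><body>",
            "<h1>xepipe analysis report</h1>",
            if (length(subject)) c("<h2>Subject</h2><table>", rows(subject),
                                   "</table>"),
            if (length(scalars)) c("<h2>Metrics</h2><table>", rows(scalars),
                                   "</table>")
            else "<p>no results</p>",
            "</body></html>")
  path <- file.path(out_dir, "report.html")
  writeLines(body, path)
  invisible(path)
}
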