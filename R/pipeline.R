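#' Default pipeline configuration
#'
#' A nested list mirroring the YAML configuration consumed by
#' [run_pipeline()] and the command-line wrapper. Any subset may be
#' overridden; unknown keys are rejected.
#'
#' @param ... Named overrides, e.g. `moco = list(strategy = "naive")`.
#' @return Configuration list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    io = list(
      series = NULL,       # NIfTI path (or NULL to simulate a phantom)
      meta = NULL,         # sidecar CSV
      bval = NULL,
      bvec = NULL,
      contours = NULL,     # JSON contours
      out = "cdti_out"
    ),
    registration = unclass(registration_params()),
    moco = list(strategy = "avg"),
    dti = list(target_spacing_mm = c(1.4, 1.4)),
    geometry = list(n_sectors = 6L),
    metric = list(line = NULL, window_center = NULL, window_half_width = 5L),
    phantom = NULL,        # list of phantom_params overrides, or NULL
    seed = 1L
  )
  overrides <- list(...)
  merge_into <- function(base, upd, path = "") {
    for (nm in names(upd)) {
      if (!nm %in% names(base)) stop("unknown configuration key: ", path, nm)
      if (is.list(base[[nm]]) && is.list(upd[[nm]])) {
        base[[nm]] <- merge_into(base[[nm]], upd[[nm]], paste0(path, nm, "."))
      } else {
        base[[nm]] <- upd[[nm]]
      }
    }
    base
  }
  structure(merge_into(cfg, overrides), class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#' @param path YAML file.
#' @return For `read_config`, a `pipeline_config`.
#' @export
read_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' @rdname read_config
#' @param config A `pipeline_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full processing pipeline
#'
#' Orchestrates one slice end to end: load (or simulate) the series, motion
#' correct, interpolate, fit the tensor, build LV geometry, produce MD / FA /
#' helix-angle maps and transmurality, run the epicardium tracking metric,
#' and write every artifact plus a `resolved_config.yaml` that reproduces the
#' run and a log of per-stage wall time. Deterministic given the
#' configuration and seed.
#'
#' @param config A [pipeline_config()] (or path to its YAML).
#' @return Invisibly, a list with the main in-memory results and the output
#'   directory.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_config(config)
  out_dir <- config$io$out
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "pipeline.log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con), add = TRUE)
  t_start <- proc.time()[["elapsed"]]
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      msg <- sprintf("stage '%s' failed: %s", name, conditionMessage(e))
      writeLines(msg, log_con)
      stop_cdti(msg, "cdtimoco_pipeline_error")
    })
    msg <- sprintf("[%8.2fs] stage %-12s done in %.2fs", proc.time()[["elapsed"]] - t_start,
                   name, proc.time()[["elapsed"]] - t0)
    writeLines(msg, log_con)
    message(msg)
    res
  }

  inputs <- stage("load", {
    if (!is.null(config$io$series)) {
      series <- read_series(config$io$series, config$io$meta)
      scheme_raw <- read_scheme(config$io$bval, config$io$bvec)
      contours <- if (!is.null(config$io$contours)) read_contours(config$io$contours) else NULL
      list(series = series, scheme_raw = scheme_raw, contours = contours,
           truth = NULL)
    } else {
      pp <- do.call(phantom_params, c(config$phantom %||% list(), list(seed = config$seed)))
      ph <- make_phantom(pp)
      list(series = ph$series, scheme_raw = ph$truth$scheme,
           contours = ph$truth$contours, truth = ph$truth)
    }
  })
  series <- inputs$series
  truth <- inputs$truth

  rp <- do.call(registration_params, config$registration)
  mres <- stage("moco", moco(series, config$moco$strategy, rp))
  stage("write_moco", {
    write_series(mres$corrected_series, file.path(out_dir, "corrected.nii"))
    write_series(mres$averaged_series, file.path(out_dir, "averaged.nii"))
    utils::write.csv(mres$diagnostics, file.path(out_dir, "moco_diagnostics.csv"),
                     row.names = FALSE)
  })

  target <- config$dti$target_spacing_mm
  interp <- stage("interpolate", interpolate_series(mres$averaged_series, target))

  # per-frame scheme for the averaged series, from the raw per-frame scheme
  scheme <- stage("scheme", {
    raw <- inputs$scheme_raw
    key_raw <- paste(series$meta$b_value, series$meta$direction_index)
    first <- !duplicated(key_raw)
    lut <- raw[first, c("gx", "gy", "gz")]
    key_avg <- paste(interp$meta$b_value, interp$meta$direction_index)
    g <- lut[match(key_avg, key_raw[first]), ]
    tibble(b_value = interp$meta$b_value, gx = g$gx, gy = g$gy, gz = g$gz,
           zero_direction = FALSE)
  })

  result <- list(config = config, out_dir = out_dir, moco = mres)
  if (!is.null(inputs$contours)) {
    geom_maps <- stage("fit_and_map", {
      contours_i <- rescale_contours(inputs$contours, series$pixel_spacing_mm, target)
      geom <- build_geometry(contours_i, dim(interp$frames)[1:2], target)
      tf <- fit_tensor(interp, scheme, geom$mask)
      maps <- tensor_maps(tf)
      ha_map <- helix_angle(maps$e1, geom)
      hat_res <- hat(ha_map, geom, n_sectors = config$geometry$n_sectors)
      list(geom = geom, tf = tf, maps = maps, ha = ha_map, hat = hat_res)
    })
    stage("write_maps", {
      write_maps(
        list(md = geom_maps$maps$md, fa = geom_maps$maps$fa, ha = geom_maps$ha,
             depth = geom_maps$geom$depth, lv_mask = geom_maps$geom$mask + 0),
        file.path(out_dir, "maps"), pixel_spacing_mm = target
      )
      summ <- roi_summary(list(list(
        maps = list(md = geom_maps$maps$md, fa = geom_maps$maps$fa,
                    hat = geom_maps$hat$global),
        geom = geom_maps$geom
      )))
      utils::write.csv(summ, file.path(out_dir, "summary.csv"), row.names = FALSE)
    })
    result <- c(result, geom_maps)
  }

  if (!is.null(config$metric$line) || !is.null(truth)) {
    track <- stage("track", {
      if (!is.null(config$metric$line)) {
        ln <- config$metric$line
        track_line(mres$corrected_series, c(ln[1], ln[2]), c(ln[3], ln[4]),
                   config$metric$window_center,
                   window_half_width = config$metric$window_half_width,
                   target_spacing_mm = target)
      } else {
        track_line(mres$corrected_series, truth$line$start, truth$line$end,
                   truth$line$window_center, n_samples = truth$line$n_samples,
                   target_spacing_mm = target)
      }
    })
    utils::write.csv(tidy(track), file.path(out_dir, "track.csv"), row.names = FALSE)
    result$track <- track
  }

  stage("resolve", write_config(config, file.path(out_dir, "resolved_config.yaml")))
  invisible(result)
}
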