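#' Read force curves from plain-text containers
#'
#' Two layouts are supported:
#' * `"tsv"`: one curve per file, tab-separated with header
#'   `time_s extension_nm force_pN`; optional `# key=value` comment lines
#'   carry `pulling_speed_nm_s`, `configuration` and `curve_id`.
#' * `"dataset"`: a directory holding `curves.tsv` (long format with a
#'   leading `curve_id` column) and `curve_metadata.tsv`
#'   (`curve_id`, `pulling_speed_nm_s`, `configuration`), as written by
#'   [write_curve_dataset()].
#'
#' Malformed curves (non-monotonic time, length < 2) are skipped with a
#' warning; an error is raised when no valid curve remains.
#'
#' @param path file (tsv) or directory (dataset).
#' @param format `"tsv"` or `"dataset"`.
#' @return list of [force_curve()].
#' @export
read_curves <- function(path, format = c("dataset", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("read_curves(): path not found: ", path, call. = FALSE)
  }
  curves <- list()
  if (format == "tsv") {
    hdr <- readLines(path, n = 20)
    meta <- parse_hash_meta(hdr[startsWith(hdr, "#")])
    df <- utils::read.delim(path, comment.char = "#",
                            stringsAsFactors = FALSE)
    cv <- try_force_curve(df$time_s, df$extension_nm, df$force_pN,
                          speed = as.numeric(meta[["pulling_speed_nm_s"]]),
                          id = meta[["curve_id"]] %||% basename(path),
                          config = meta[["configuration"]] %||% "unknown")
    if (!is.null(cv)) curves[[1]] <- cv
  } else {
    cf <- file.path(path, "curves.tsv")
    mf <- file.path(path, "curve_metadata.tsv")
    if (!file.exists(cf)) {
      stop("read_curves(): no curves.tsv in ", path, call. = FALSE)
    }
    df <- utils::read.delim(cf, stringsAsFactors = FALSE)
    meta <- if (file.exists(mf)) {
      utils::read.delim(mf, stringsAsFactors = FALSE)
    } else NULL
    for (id in unique(df$curve_id)) {
      d <- df[df$curve_id == id, ]
      sp <- NA_real_; cfg <- "unknown"
      if (!is.null(meta) && id %in% meta$curve_id) {
        m <- meta[meta$curve_id == id, ]
        sp <- m$pulling_speed_nm_s[1]
        cfg <- as.character(m$configuration[1])
      }
      cv <- try_force_curve(d$time_s, d$extension_nm, d$force_pN,
                            speed = sp, id = id, config = cfg)
      if (!is.null(cv)) curves[[length(curves) + 1]] <- cv
    }
  }
  if (!length(curves)) {
    stop("read_curves(): no valid curves in ", path, call. = FALSE)
  }
  curves
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

parse_hash_meta <- function(lines) {
  out <- list()
  for (l in lines) {
    l <- sub("^#\\s*", "", l)
    for (kv in strsplit(l, "[,;]\\s*")[[1]]) {
      p <- strsplit(kv, "=", fixed = TRUE)[[1]]
      if (length(p) == 2) out[[trimws(p[1])]] <- trimws(p[2])
    }
  }
  out
}

try_force_curve <- function(time, extension, force, speed, id, config) {
  if (!length(speed) || is.na(speed)) speed <- NA_real_
  if (!length(config) || !config %in% c("I", "II", "unknown")) {
    config <- "unknown"
  }
  tryCatch(
    force_curve(time, extension, force, pulling_speed = speed,
                curve_id = id, configuration = config),
    error = function(e) {
      warning(sprintf("curve '%s' skipped: %s", id, conditionMessage(e)),
              call. = FALSE)
      NULL
    })
}

#' Write a single curve as TSV
#'
#' @param curve a [force_curve()].
#' @param path output file.
#' @export
write_curve_tsv <- function(curve, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# curve_id=%s, pulling_speed_nm_s=%g, configuration=%s",
                     curve$curve_id, curve$pulling_speed,
                     curve$configuration), con)
  utils::write.table(
    data.frame(time_s = curve$time, extension_nm = curve$extension,
               force_pN = curve$force),
    con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a simulated dataset as a plain-text container
#'
#' Writes `curves.tsv` (long format), `curve_metadata.tsv` and, when
#' present, `ground_truth.csv` into `dir`.
#'
#' @param dataset output of [simulate_dataset()], or a list with `curves`.
#' @param dir output directory (created if needed).
#' @export
write_curve_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(dataset$curves, function(cv) {
    data.frame(curve_id = cv$curve_id, time_s = cv$time,
               extension_nm = cv$extension, force_pN = cv$force)
  })
  utils::write.table(do.call(rbind, rows), file.path(dir, "curves.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  meta <- do.call(rbind, lapply(dataset$curves, function(cv) {
    data.frame(curve_id = cv$curve_id,
               pulling_speed_nm_s = cv$pulling_speed,
               configuration = cv$configuration)
  }))
  utils::write.table(meta, file.path(dir, "curve_metadata.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(dataset$ground_truth)) {
    utils::write.csv(dataset$ground_truth,
                     file.path(dir, "ground_truth.csv"), row.names = FALSE)
  }
  invisible(dir)
}

#' Pipeline run configuration
#'
#' Collects every tunable of the analysis pipeline with its default.
#' Configurations serialize to YAML ([write_run_config()] /
#' [read_run_config()]), and every pipeline report embeds the
#' configuration hash and master seed so that runs are reproducible.
#'
#' @param ... overrides of the defaults (see the default list in the
#'   function body; unknown names are an error).
#' @return object of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    # polymer model
    frc_b = 0.11, frc_gamma = 41, kBT = 4.114,
    qm_correction = c(6.4e-6, 4.9e-9),
    # event detection
    min_drop = 30, min_force = 50, min_separation = 5,
    # contour-length transform
    force_threshold = 90, force_max = 160, bin_width = 1, max_shift = 10,
    # fingerprint classification
    tolerance = 8, required = c("Xyn", "CBM"), xmod_name = "XMod",
    # modal estimation and Bell-Evans fit
    window_fraction = 0.2, log_rates = TRUE, min_events = 10,
    weight_by_n = FALSE,
    # reproducibility
    seed = 1L
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) {
    stop("run_config(): unknown option(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param path YAML file.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

config_polymer <- function(cfg) {
  polymer_params(b = cfg$frc_b, gamma = cfg$frc_gamma,
                 qm_correction = cfg$qm_correction, kBT = cfg$kBT)
}

config_hash <- function(cfg) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(unclass(cfg), tf, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tf))
}

#' Run the full analysis pipeline
#'
#' Chains the data-reduction stages on a set of force curves: event
#' detection, per-curve contour-length transformation and increment
#' measurement, fingerprint classification with bond-history tagging,
#' loading-rate extraction at the final rupture, cross-correlation master
#' histogram assembly over the specific curves, per-speed Gaussian modal
#' estimation, and Bell-Evans dynamic force spectrum fits per history
#' class. Any stage failure aborts with a stage-tagged error.
#'
#' @param curves list of [force_curve()], or a path accepted by
#'   [read_curves()].
#' @param config a [run_config()].
#' @param templates an [increment_table()].
#' @param out_dir if non-`NULL`, write `events.csv`,
#'   `master_histogram.csv` and `report.json` there.
#' @return list of class `pipeline_report`: `counts` (per filter stage),
#'   `events` (per-event table), `master` (the [contour_hist()]),
#'   `domain_increments`, `fits` (named list of [fit_bell_evans()] results
#'   per history class), `provenance`.
#' @export
run_pipeline <- function(curves, config = run_config(),
                         templates = increment_table(), out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[stage:%s] %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  if (is.character(curves)) {
    curves <- stage("read", read_curves(curves))
  }
  stage("read", if (!length(curves)) stop("no curves supplied"))
  set.seed(config$seed)
  pol <- config_polymer(config)

  per_curve <- stage("detect", lapply(curves, function(cv) {
    ev <- detect_unfolding_events(cv, min_drop = config$min_drop,
                                  min_force = config$min_force,
                                  min_separation = config$min_separation)
    list(curve = cv, events = ev)
  }))
  with_events <- Filter(function(x) nrow(x$events) > 0, per_curve)

  classified <- stage("classify", lapply(with_events, function(x) {
    inc <- measure_curve_increments(x$curve, x$events, pol,
                                    config$force_threshold,
                                    config$force_max)
    cls <- classify_fingerprint(inc, templates, config$tolerance,
                                config$required, config$xmod_name)
    x$increments <- inc
    x$label <- cls$label
    x$history <- cls$history
    x
  }))
  specific <- Filter(function(x) x$label == "specific", classified)

  event_rows <- stage("loading_rate", do.call(rbind, lapply(
    classified, function(x) {
      ev <- x$events
      n <- nrow(ev)
      prev <- c(1, ev$index[-n] + 1)
      for (i in seq_len(n)) {
        ev$loading_rate[i] <- tryCatch(
          extract_loading_rate(x$curve, ev$index[i],
                               config$window_fraction, prev[i]),
          error = function(e) NA_real_)
      }
      data.frame(curve_id = x$curve$curve_id, index = ev$index,
                 force_pN = ev$force,
                 loading_rate_pN_s = ev$loading_rate,
                 is_final = ev$is_final, history = x$history,
                 label = x$label,
                 pulling_speed = x$curve$pulling_speed)
    })))

  master <- NULL; dom_inc <- NULL
  if (length(specific)) {
    master <- stage("transform", {
      hs <- lapply(specific, function(x) {
        transform_to_contour_length(x$curve, pol, config$force_threshold,
                                    config$force_max, config$bin_width)
      })
      assemble_master_histogram(hs, config$max_shift)
    })
    dom_inc <- stage("increments",
                     domain_increments(master, templates, config$tolerance))
  }

  fits <- list()
  finals <- event_rows[event_rows$is_final & event_rows$label == "specific" &
                         is.finite(event_rows$loading_rate_pN_s) &
                         event_rows$loading_rate_pN_s > 0, ]
  for (hc in c("intact", "shielded")) {
    sel <- finals[finals$history == hc, ]
    if (!nrow(sel)) next
    fit <- tryCatch({
      mp <- estimate_modal_points(sel$force_pN, sel$loading_rate_pN_s,
                                  sel$pulling_speed,
                                  log_rates = config$log_rates,
                                  min_events = config$min_events)
      fit_bell_evans(mp, kBT = config$kBT,
                     weight_by_n = config$weight_by_n,
                     history_class = hc)
    }, error = function(e) {
      message(sprintf("history '%s': no Bell-Evans fit (%s)", hc,
                      conditionMessage(e)))
      NULL
    })
    if (!is.null(fit)) fits[[hc]] <- fit
  }

  counts <- list(
    total = length(curves),
    with_events = length(with_events),
    specific = length(specific),
    intact = sum(vapply(classified, function(x) x$history == "intact",
                        logical(1))),
    shielded = sum(vapply(classified, function(x) x$history == "shielded",
                          logical(1))),
    fitted_classes = length(fits)
  )
  report <- structure(list(
    counts = counts,
    events = event_rows,
    master = master,
    domain_increments = dom_inc,
    fits = fits,
    provenance = list(config_hash = config_hash(config),
                      seed = config$seed,
                      package_version =
                        as.character(utils::packageVersion("forcespec")))
  ), class = "pipeline_report")
  if (!is.null(out_dir)) write_pipeline_report(report, out_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Pipeline report\n")
  cat(sprintf(
    "  curves: %d total, %d with events, %d specific (%d intact / %d shielded)\n",
    x$counts$total, x$counts$with_events, x$counts$specific,
    x$counts$intact, x$counts$shielded))
  if (!is.null(x$domain_increments)) {
    cat("  domain increments (nm):\n")
    print(x$domain_increments, row.names = FALSE)
  }
  for (f in x$fits) print(f)
  invisible(x)
}

#' Serialize a pipeline report
#'
#' Writes `events.csv`, `master_histogram.csv` (bin centers and counts)
#' and `report.json` (counts, increments, fits, provenance). The JSON
#' contains no timestamps, so reruns with identical configuration and
#' seed are byte-identical.
#'
#' @param report a `pipeline_report`.
#' @param dir output directory.
#' @export
write_pipeline_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$events, file.path(dir, "events.csv"),
                   row.names = FALSE)
  if (!is.null(report$master)) {
    m <- report$master
    mids <- (m$bin_edges[-1] + m$bin_edges[-length(m$bin_edges)]) / 2
    utils::write.csv(data.frame(contour_length_nm = mids,
                                counts = m$counts),
                     file.path(dir, "master_histogram.csv"),
                     row.names = FALSE)
  }
  fits <- lapply(report$fits, function(f) {
    list(history_class = f$history_class,
         delta_x_nm = f$params$delta_x,
         k_off_per_s = f$params$k_off,
         delta_x_stderr_nm = f$delta_x_stderr,
         k_off_factor_stderr = f$k_off_factor_stderr,
         points = f$points)
  })
  inc <- if (!is.null(report$domain_increments)) {
    di <- report$domain_increments
    attr(di, "peaks") <- NULL
    di
  }
  jsonlite::write_json(
    list(counts = report$counts, domain_increments = inc, fits = fits,
         provenance = report$provenance),
    file.path(dir, "report.json"),
    auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}

#' Serialize a Bell-Evans fit to JSON
#'
#' @param fit a [fit_bell_evans()] result.
#' @param path output file.
#' @export
write_fit_json <- function(fit, path) {
  jsonlite::write_json(
    list(history_class = fit$history_class,
         delta_x_nm = fit$params$delta_x,
         k_off_per_s = fit$params$k_off,
         delta_x_stderr_nm = fit$delta_x_stderr,
         k_off_factor_stderr = fit$k_off_factor_stderr,
         points = fit$points),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
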