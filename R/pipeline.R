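#' Configure an end-to-end pipeline run
#'
#' A run consumes either real inputs (a raw volume table, an anthropometrics
#' table, and a directory of per-trial trace files named
#' `<athlete_id>_trial<j>.csv`) or a synthetic [cohort_spec()] — exactly one
#' of the two.
#'
#' @param input Named list of paths: `volumes`, `anthropometrics`,
#'   `trace_dir`. Mutually exclusive with `synthetic`.
#' @param synthetic A [cohort_spec()] describing a synthetic cohort.
#'   Mutually exclusive with `input`.
#' @param cutoff_hz,filter_order Low-pass settings for speed extraction.
#' @param subset_size Muscles per combination (default 3).
#' @param top_k Lead muscles in the filtered display tables (default 10).
#' @param modes Which scans to run, a subset of
#'   `c("individual", "simple_sum", "optimized")`.
#' @param out_dir Output directory, or `NULL` to skip writing files.
#' @param trace_noise_sd Positional noise SD (m) for synthetic traces.
#' @param seed Integer seed governing every random draw of the run.
#' @return A list of class `sv_run_config`.
#' @export
run_config <- function(input = NULL, synthetic = NULL,
                       cutoff_hz = 1, filter_order = 4,
                       subset_size = 3, top_k = 10,
                       modes = c("individual", "simple_sum", "optimized"),
                       out_dir = NULL, trace_noise_sd = 0.02, seed = 1L) {
  if (is.null(input) == is.null(synthetic)) {
    abort("exactly one of `input` (real paths) or `synthetic` (a cohort_spec) must be supplied")
  }
  if (!is.null(input)) {
    missing <- setdiff(c("volumes", "anthropometrics", "trace_dir"),
                       names(input))
    if (length(missing) > 0) {
      abort(paste0("`input` is missing path(s): ",
                   paste(missing, collapse = ", ")))
    }
  }
  if (!is.null(synthetic) && !inherits(synthetic, "sv_cohort_spec")) {
    abort("`synthetic` must be a cohort_spec()")
  }
  assert_number(cutoff_hz, "cutoff_hz", 0, strict_lower = TRUE)
  if (!is_count(filter_order) || filter_order %% 2 != 0) {
    abort("`filter_order` must be a positive even integer")
  }
  if (!is_count(subset_size)) abort("`subset_size` must be a positive integer")
  if (!is_count(top_k) || top_k > 35) {
    abort("`top_k` must be a positive integer no larger than 35")
  }
  modes <- match.arg(modes, c("individual", "simple_sum", "optimized"),
                     several.ok = TRUE)
  structure(
    list(input = input, synthetic = synthetic, cutoff_hz = cutoff_hz,
         filter_order = as.integer(filter_order),
         subset_size = as.integer(subset_size), top_k = as.integer(top_k),
         modes = modes, out_dir = out_dir, trace_noise_sd = trace_noise_sd,
         seed = as.integer(seed)),
    class = "sv_run_config"
  )
}

#' Generate a full set of synthetic input artifacts
#'
#' Expands a [cohort_spec()] into the same artifacts a field collection
#' would produce: raw bilateral volume records, anthropometrics, and two
#' sprint position traces per athlete whose true peak speed is the athlete's
#' cohort speed and whose sprint distance follows the athlete's position
#' group (36.6 m linemen, 45.7 m others).
#'
#' @param spec A [cohort_spec()].
#' @param trace_noise_sd Positional noise SD, m.
#' @return A list: `cohort` (the generating truth), `volumes`,
#'   `anthropometrics`, and `traces` (named list of two-trace lists).
#' @export
simulate_inputs <- function(spec, trace_noise_sd = 0.02) {
  cohort <- generate_cohort(spec)
  records <- generate_athlete_records(cohort, seed = spec$seed + 1L)
  dist_by_group <- stats::setNames(anthro_params()$sprint_distance_m,
                                   anthro_params()$group)
  traces <- purrr::map(seq_len(nrow(cohort)), function(i) {
    generate_sprint_trace(
      trace_spec(peak_speed = cohort$speed_mps[i],
                 sprint_distance = dist_by_group[[cohort$group[i]]],
                 noise_sd = trace_noise_sd),
      seed = spec$seed + 1000L + i
    )
  })
  names(traces) <- cohort$athlete_id
  list(cohort = cohort, volumes = records$volumes,
       anthropometrics = records$anthropometrics, traces = traces)
}

#' Validate real input files
#'
#' Schema, unit, and completeness checks for a real-input path set. Returns
#' (rather than throws) an itemized diagnostics table so a caller can report
#' every problem at once; an empty table means the inputs are well formed.
#'
#' @param paths Named list with `volumes`, `anthropometrics`, `trace_dir`.
#' @return A tibble with columns `file` and `problem` (zero rows if clean).
#' @export
validate_inputs <- function(paths) {
  diags <- list()
  note <- function(file, problem) {
    diags[[length(diags) + 1]] <<- tibble::tibble(file = file,
                                                  problem = problem)
  }
  try_table <- function(path, reader) {
    tryCatch(reader(path), error = function(e) {
      note(path, conditionMessage(e)); NULL
    })
  }
  vols <- try_table(paths$volumes, read_volume_table)
  anth <- try_table(paths$anthropometrics, read_anthropometrics)
  if (!is.null(vols)) {
    tryCatch(group_muscles(vols),
             error = function(e) note(paths$volumes, conditionMessage(e)))
  }
  if (!is.null(anth)) {
    if (any(anth$height_m <= 0 | anth$height_m > 2.5)) {
      note(paths$anthropometrics,
           "height_m outside plausible range (0, 2.5] m; check units")
    }
    if (any(anth$mass_kg <= 0 | anth$mass_kg > 250)) {
      note(paths$anthropometrics,
           "mass_kg outside plausible range (0, 250] kg; check units")
    }
    bad_group <- setdiff(unique(anth$group), c("lineman", "other"))
    if (length(bad_group) > 0) {
      note(paths$anthropometrics,
           paste0("unknown group label(s): ", paste(bad_group, collapse = ", ")))
    }
  }
  if (!dir.exists(paths$trace_dir)) {
    note(paths$trace_dir, "trace directory does not exist")
  } else {
    files <- list.files(paths$trace_dir, pattern = "\\.csv$",
                        full.names = TRUE)
    if (length(files) == 0) note(paths$trace_dir, "no .csv trace files found")
    for (f in files) {
      tryCatch(read_trace(f), error = function(e) {
        note(f, conditionMessage(e))
      })
    }
  }
  if (length(diags) == 0) {
    tibble::tibble(file = character(), problem = character())
  } else {
    dplyr::bind_rows(diags)
  }
}

read_trace_dir <- function(trace_dir) {
  files <- list.files(trace_dir, pattern = "_trial[0-9]+\\.csv$",
                      full.names = TRUE)
  if (length(files) == 0) {
    abort(paste0("no '<athlete_id>_trial<j>.csv' trace files in ", trace_dir))
  }
  ids <- sub("_trial[0-9]+\\.csv$", "", basename(files))
  traces <- split(files, ids)
  purrr::map(traces, function(fs) purrr::map(sort(fs), read_trace))
}

#' Run the full analysis pipeline
#'
#' Sequences the whole chain: (synthetic generation or input reading) ->
#' per-athlete peak-speed extraction -> cohort assembly -> individual,
#' simple-sum, and optimized combination scans -> lead-muscle display
#' filters, improvement and negative-coefficient summaries -> a
#' reproducibility manifest. With `out_dir` set, every table is written as
#' delimited text. The run is a pure function of (inputs, config, seed).
#'
#' @param config A [run_config()].
#' @param quiet Suppress stage-level progress messages.
#' @return A named list (`report bundle`): `cohort`, `speeds`, `individual`,
#'   `simple_sum`, `optimized`, `filtered_simple_sum`, `filtered_optimized`,
#'   `improvement_simple_sum`, `improvement_optimized`,
#'   `negative_coefficients`, `manifest`. Entries for scans not requested
#'   are `NULL`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "sv_run_config"))
  say <- function(...) if (!quiet) rlang::inform(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }

  if (!is.null(config$synthetic)) {
    say("stage simulate: generating synthetic cohort (n = %d, seed = %d)",
        config$synthetic$n_athletes, config$seed)
    spec <- config$synthetic
    spec$seed <- config$seed
    inputs <- stage("simulate",
                    simulate_inputs(spec, config$trace_noise_sd))
    volumes <- inputs$volumes
    anthropometrics <- inputs$anthropometrics
    traces <- inputs$traces
  } else {
    say("stage read: loading input tables")
    stage("validate", {
      diags <- validate_inputs(config$input)
      if (nrow(diags) > 0) {
        abort(paste0("invalid inputs:\n", paste0(
          "  ", diags$file, ": ", diags$problem, collapse = "\n")))
      }
    })
    volumes <- read_volume_table(config$input$volumes)
    anthropometrics <- read_anthropometrics(config$input$anthropometrics)
    traces <- stage("read_traces", read_trace_dir(config$input$trace_dir))
  }

  say("stage speed: extracting peak speeds for %d athletes", length(traces))
  speeds <- stage("speed", speed_table(traces, cutoff_hz = config$cutoff_hz,
                                       order = config$filter_order))
  say("stage cohort: assembling cohort table (%d volume records)",
      nrow(volumes))
  cohort <- stage("cohort",
                  build_cohort(volumes, anthropometrics, speeds,
                               quiet = quiet))

  individual <- NULL
  if ("individual" %in% config$modes ||
      length(intersect(config$modes, c("simple_sum", "optimized"))) > 0) {
    say("stage scan: individual muscles")
    individual <- stage("individual_scan", individual_scan(cohort))
  }
  simple <- optimized <- NULL
  filtered_simple <- filtered_opt <- NULL
  improve_simple <- improve_opt <- NULL
  negatives <- NULL
  if ("simple_sum" %in% config$modes) {
    say("stage scan: simple sums of %d muscles", config$subset_size)
    simple <- stage("simple_sum_scan",
                    simple_sum_scan(cohort, subset_size = config$subset_size))
    filtered_simple <- top_per_muscle_filter(simple, individual,
                                             config$top_k)
    improve_simple <- improvement_summary(simple, individual)
  }
  if ("optimized" %in% config$modes) {
    say("stage scan: optimized combinations of %d muscles (%d subsets)",
        config$subset_size, choose(35, config$subset_size))
    optimized <- stage("optimized_scan",
                       optimized_scan(cohort,
                                      subset_size = config$subset_size))
    filtered_opt <- top_per_muscle_filter(optimized, individual,
                                          config$top_k)
    improve_opt <- improvement_summary(optimized, individual)
    negatives <- negative_coefficient_summary(optimized)
  }

  manifest <- list(
    package = "sprintvol",
    version = as.character(utils::packageVersion("sprintvol")),
    seed = config$seed,
    config_hash = rlang::hash(config),
    input_mode = if (is.null(config$synthetic)) "real" else "synthetic",
    n_athletes = nrow(cohort),
    modes = config$modes,
    subset_size = config$subset_size,
    cutoff_hz = config$cutoff_hz,
    filter_order = config$filter_order
  )

  bundle <- list(cohort = cohort, speeds = speeds, individual = individual,
                 simple_sum = simple, optimized = optimized,
                 filtered_simple_sum = filtered_simple,
                 filtered_optimized = filtered_opt,
                 improvement_simple_sum = improve_simple,
                 improvement_optimized = improve_opt,
                 negative_coefficients = negatives,
                 manifest = manifest)
  if (!is.null(config$out_dir)) {
    say("stage write: %s", config$out_dir)
    write_bundle(bundle, config$out_dir)
  }
  bundle
}

flatten_speeds <- function(speeds) {
  n_max <- max(speeds$n_trials)
  out <- speeds[c("athlete_id", "speed_mps", "n_trials")]
  for (j in seq_len(n_max)) {
    out[[paste0("trial", j, "_peak_mps")]] <-
      vapply(speeds$trial_peaks, function(p) p[j] %||% NA_real_, numeric(1))
    out[[paste0("trial", j, "_peak_distance_m")]] <-
      vapply(speeds$trial_distances, function(p) p[j] %||% NA_real_,
             numeric(1))
  }
  out
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a)) b else a

#' Write a report bundle as delimited text
#'
#' @param bundle A list from [run_pipeline()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(f) file.path(out_dir, f)
  write_cohort(bundle$cohort, path("cohort.csv"))
  write_table(flatten_speeds(bundle$speeds), path("speed_table.csv"))
  tables <- list(
    individual_scan = bundle$individual,
    simple_sum_scan = bundle$simple_sum,
    optimized_scan = bundle$optimized,
    filtered_simple_sum = bundle$filtered_simple_sum,
    filtered_optimized = bundle$filtered_optimized,
    improvement_simple_sum = bundle$improvement_simple_sum,
    improvement_optimized = bundle$improvement_optimized,
    negative_coefficients_per_muscle = bundle$negative_coefficients$per_muscle
  )
  for (nm in names(tables)) {
    if (!is.null(tables[[nm]])) {
      write_table(tibble::as_tibble(tables[[nm]]), path(paste0(nm, ".csv")))
    }
  }
  manifest <- bundle$manifest
  if (!is.null(bundle$negative_coefficients)) {
    manifest$negative_coefficient_fraction <-
      bundle$negative_coefficients$overall
  }
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Read a pipeline configuration from JSON
#'
#' A structured key-value file whose entries mirror the [run_config()]
#' arguments; `synthetic` is given as a nested object of [cohort_spec()]
#' arguments.
#'
#' @param path Path to a JSON config file.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(raw$synthetic)) {
    raw$synthetic <- do.call(cohort_spec, raw$synthetic)
  }
  if (!is.null(raw$input)) raw$input <- as.list(raw$input)
  do.call(run_config, raw)
}
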