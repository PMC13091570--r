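#' Read and write the pipeline's delimited-text tables
#'
#' All interchange formats are headered CSV: sprint traces (`t_s`, `x_m`,
#' `y_m`; one file per trial), raw volume tables (`athlete_id`, `side`,
#' `raw_muscle`, `volume_cm3`), anthropometrics (`athlete_id`, `group`,
#' `height_m`, `mass_kg`), speed tables (`athlete_id`, `speed_mps`, ...),
#' and cohort tables (`athlete_id`, `group`, `height_m`, `mass_kg`,
#' `speed_mps`, one column per muscle). Readers validate structure on load;
#' writers emit full double precision so tables round-trip without loss.
#'
#' @param path File path.
#' @param trace,cohort,table Object to write.
#' @param catalog A [muscle_catalog()]-shaped tibble (cohort reader only).
#' @name sprintvol-io
NULL

# base-R CSV I/O: unlike faster parsers, strtod() is correctly rounded, so
# 17-significant-digit output round-trips bit-identically
read_csv_strict <- function(path, required) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  out <- tibble::as_tibble(
    utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE))
  missing <- setdiff(required, names(out))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required column(s): %s",
                  path, paste(missing, collapse = ", ")))
  }
  out
}

write_csv_full <- function(x, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  num <- vapply(x, is.double, logical(1))
  x[num] <- lapply(x[num], function(col) sprintf("%.17g", col))
  utils::write.csv(x, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname sprintvol-io
#' @export
read_trace <- function(path) {
  out <- read_csv_strict(path, c("t_s", "x_m", "y_m"))
  validate_trace(out)
  out
}

#' @rdname sprintvol-io
#' @export
write_trace <- function(trace, path) {
  validate_trace(trace)
  write_csv_full(trace[c("t_s", "x_m", "y_m")], path)
}

#' @rdname sprintvol-io
#' @export
read_cohort <- function(path, catalog = muscle_catalog()) {
  out <- read_csv_strict(
    path, c("athlete_id", "group", "height_m", "mass_kg", "speed_mps",
            catalog$muscle))
  validate_cohort(out, catalog$muscle)
  out
}

#' @rdname sprintvol-io
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort)
  write_csv_full(cohort, path)
}

#' @rdname sprintvol-io
#' @export
read_volume_table <- function(path) {
  read_csv_strict(path, c("athlete_id", "side", "raw_muscle", "volume_cm3"))
}

#' @rdname sprintvol-io
#' @export
read_anthropometrics <- function(path) {
  read_csv_strict(path, c("athlete_id", "group", "height_m", "mass_kg"))
}

#' @rdname sprintvol-io
#' @export
read_speed_table <- function(path) {
  read_csv_strict(path, c("athlete_id", "speed_mps"))
}

#' @rdname sprintvol-io
#' @export
write_table <- function(table, path) {
  write_csv_full(tibble::as_tibble(table), path)
}
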