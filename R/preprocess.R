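#' Combine raw per-side muscles into the 35 analysis muscles
#'
#' Sums composite muscles' constituents (peroneus brevis + longus; gemelli
#' superior + inferior; the three phalangeal extensors) per athlete and per
#' side, before bilateral averaging; all other muscles pass through. Summing
#' before or after averaging sides is algebraically equivalent; summing first
#' allows a single completeness check.
#'
#' @param raw_volumes Long tibble with columns `athlete_id`, `side`
#'   ("left"/"right"), `raw_muscle`, `volume_cm3`. Every constituent of every
#'   catalogued muscle must be present for every athlete and side.
#' @return Long tibble with columns `athlete_id`, `side`, `muscle`,
#'   `volume_cm3` (35 muscles per athlete-side).
#' @export
group_muscles <- function(raw_volumes) {
  required <- c("athlete_id", "side", "raw_muscle", "volume_cm3")
  missing <- setdiff(required, names(raw_volumes))
  if (length(missing) > 0) {
    abort(paste0("raw volume table is missing columns: ",
                 paste(missing, collapse = ", ")))
  }
  grouping <- muscle_grouping()
  unknown <- setdiff(unique(raw_volumes$raw_muscle), grouping$raw_muscle)
  if (length(unknown) > 0) {
    abort(paste0("unknown raw muscle labels: ", paste(unknown, collapse = ", ")))
  }
  if (any(raw_volumes$volume_cm3 < 0)) {
    abort("raw volumes must be non-negative")
  }
  # completeness: every athlete-side must carry every raw muscle exactly once
  counts <- raw_volumes |>
    dplyr::count(.data$athlete_id, .data$side, .data$raw_muscle)
  if (any(counts$n > 1)) {
    bad <- counts[counts$n > 1, ][1, ]
    abort(sprintf("duplicate raw volume entry: %s %s %s",
                  bad$athlete_id, bad$side, bad$raw_muscle))
  }
  expected <- tidyr::expand_grid(
    dplyr::distinct(raw_volumes, .data$athlete_id, .data$side),
    raw_muscle = grouping$raw_muscle
  )
  absent <- dplyr::anti_join(
    expected, counts, by = c("athlete_id", "side", "raw_muscle"))
  if (nrow(absent) > 0) {
    abort(sprintf(
      "missing raw muscle volume(s), first: %s (%s, %s side); %d missing in total",
      absent$raw_muscle[1], absent$athlete_id[1], absent$side[1], nrow(absent)))
  }
  raw_volumes |>
    dplyr::inner_join(grouping, by = "raw_muscle") |>
    dplyr::summarise(volume_cm3 = sum(.data$volume_cm3),
                     .by = c("athlete_id", "side", "muscle"))
}

#' Average left and right muscle volumes
#'
#' Arithmetic mean of the two sides per athlete and muscle. Both sides must
#' be present for every athlete-muscle pair.
#'
#' @param volumes Long tibble with columns `athlete_id`, `side`
#'   ("left"/"right"), `muscle`, `volume_cm3` (output of [group_muscles()]).
#' @return Tibble with columns `athlete_id`, `muscle`, `volume_cm3`.
#' @export
bilateral_average <- function(volumes) {
  required <- c("athlete_id", "side", "muscle", "volume_cm3")
  missing <- setdiff(required, names(volumes))
  if (length(missing) > 0) {
    abort(paste0("volume table is missing columns: ",
                 paste(missing, collapse = ", ")))
  }
  bad_side <- setdiff(unique(volumes$side), c("left", "right"))
  if (length(bad_side) > 0) {
    abort(paste0("`side` must be 'left' or 'right', got: ",
                 paste(bad_side, collapse = ", ")))
  }
  counts <- volumes |>
    dplyr::count(.data$athlete_id, .data$muscle)
  if (any(counts$n != 2)) {
    bad <- counts[counts$n != 2, ][1, ]
    abort(sprintf("athlete %s, muscle %s: expected both sides, found %d entr%s",
                  bad$athlete_id, bad$muscle, bad$n,
                  if (bad$n == 1) "y" else "ies"))
  }
  volumes |>
    dplyr::summarise(volume_cm3 = mean(.data$volume_cm3),
                     .by = c("athlete_id", "muscle"))
}

#' Normalize a muscle volume to the height-body mass product
#'
#' Divides volume (cm^3) by height (m) times body mass (kg), removing the
#' gross scaling of muscle size with body size; units are cm^3 kg^-1 m^-1.
#'
#' @param volume Muscle volume(s), cm^3 (non-negative).
#' @param height Standing height, m (strictly positive).
#' @param mass Body mass, kg (strictly positive).
#' @return Normalized volume(s), cm^3 kg^-1 m^-1.
#' @examples
#' normalize_volume(4000, 2.0, 100) # 20
#' @export
normalize_volume <- function(volume, height, mass) {
  if (any(!is.finite(height)) || any(height <= 0)) {
    abort("`height` must be strictly positive")
  }
  if (any(!is.finite(mass)) || any(mass <= 0)) {
    abort("`mass` must be strictly positive")
  }
  if (any(volume < 0)) abort("`volume` must be non-negative")
  volume / (height * mass)
}

#' Assemble the cohort table
#'
#' Runs the preprocessing chain (constituent grouping, bilateral averaging,
#' height-mass normalization) on raw per-side volumes and joins the result
#' with anthropometrics and per-athlete peak speeds into the analysis's
#' central matrix: one row per athlete, one column per catalogued muscle, in
#' catalog order.
#'
#' @param raw_volumes Long tibble (`athlete_id`, `side`, `raw_muscle`,
#'   `volume_cm3`), as read by [read_volume_table()].
#' @param anthropometrics Tibble (`athlete_id`, `group`, `height_m`,
#'   `mass_kg`).
#' @param speeds Tibble (`athlete_id`, `speed_mps`), e.g. from
#'   [speed_table()].
#' @param catalog A [muscle_catalog()]-shaped tibble.
#' @param quiet Suppress the cohort summary message.
#' @return A cohort tibble (columns `athlete_id`, `group`, `height_m`,
#'   `mass_kg`, `speed_mps`, then 35 normalized volumes).
#' @export
build_cohort <- function(raw_volumes, anthropometrics, speeds,
                         catalog = muscle_catalog(), quiet = FALSE) {
  validate_catalog(catalog)
  for (nm in c("athlete_id", "group", "height_m", "mass_kg")) {
    if (!nm %in% names(anthropometrics)) {
      abort(paste0("anthropometrics table is missing column ", nm))
    }
  }
  for (nm in c("athlete_id", "speed_mps")) {
    if (!nm %in% names(speeds)) {
      abort(paste0("speed table is missing column ", nm))
    }
  }
  if (anyDuplicated(anthropometrics$athlete_id)) {
    abort("duplicate athlete_id in anthropometrics table")
  }
  if (anyDuplicated(speeds$athlete_id)) {
    abort("duplicate athlete_id in speed table")
  }
  ids <- unique(raw_volumes$athlete_id)
  check_ids <- function(have, label) {
    lost <- setdiff(ids, have)
    extra <- setdiff(have, ids)
    if (length(lost) > 0 || length(extra) > 0) {
      abort(sprintf("athlete ids do not match the %s table (missing: %s; extra: %s)",
                    label,
                    if (length(lost)) paste(lost, collapse = ", ") else "none",
                    if (length(extra)) paste(extra, collapse = ", ") else "none"))
    }
  }
  check_ids(anthropometrics$athlete_id, "anthropometrics")
  check_ids(speeds$athlete_id, "speed")

  normalized <- raw_volumes |>
    group_muscles() |>
    bilateral_average() |>
    dplyr::inner_join(anthropometrics, by = "athlete_id") |>
    dplyr::mutate(norm_vol = normalize_volume(.data$volume_cm3,
                                              .data$height_m,
                                              .data$mass_kg)) |>
    dplyr::select("athlete_id", "muscle", "norm_vol") |>
    tidyr::pivot_wider(names_from = "muscle", values_from = "norm_vol")

  cohort <- anthropometrics |>
    dplyr::inner_join(speeds[c("athlete_id", "speed_mps")], by = "athlete_id") |>
    dplyr::inner_join(normalized, by = "athlete_id") |>
    dplyr::select("athlete_id", "group", "height_m", "mass_kg", "speed_mps",
                  dplyr::all_of(catalog$muscle))
  validate_cohort(cohort, catalog$muscle)
  if (!quiet) {
    rlang::inform(sprintf(
      "cohort: %d athletes (%s); speed %.2f +/- %.2f m/s",
      nrow(cohort),
      paste(sprintf("%d %s", table(cohort$group), names(table(cohort$group))),
            collapse = ", "),
      mean(cohort$speed_mps), stats::sd(cohort$speed_mps)))
  }
  cohort
}
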