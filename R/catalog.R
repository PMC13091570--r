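#' Catalogue of the 35 lower-body muscles
#'
#' The analysis operates on 35 bilaterally-averaged lower-body muscles, three
#' of which are composites of smaller muscles (peroneus = peroneus brevis +
#' longus; gemelli = gemelli superior + inferior; phalangeal extensors =
#' extensor digitorum longus + extensor hallucis longus + peroneus tertius).
#' Each muscle carries the published cohort mean and SD of its normalized
#' volume (volume divided by the height-body mass product), which the
#' synthetic-cohort generator reproduces.
#'
#' @return A tibble with one row per muscle and columns:
#'   \describe{
#'     \item{muscle}{snake_case identifier, used as the column name in cohort
#'       tables.}
#'     \item{label}{human-readable muscle name.}
#'     \item{mean_norm_vol}{mean normalized volume, cm^3 kg^-1 m^-1.}
#'     \item{sd_norm_vol}{SD of normalized volume, cm^3 kg^-1 m^-1.}
#'   }
#' @examples
#' muscle_catalog()
#' @export
muscle_catalog <- function() {
  out <- tibble::tribble(
    ~muscle, ~label, ~mean_norm_vol, ~sd_norm_vol,
    "psoas_major",              "Psoas Major",              2.30, 0.43,
    "gluteus_medius",           "Gluteus Medius",           2.43, 0.34,
    "gluteus_maximus",          "Gluteus Maximus",          8.44, 1.36,
    "pectineus",                "Pectineus",                0.57, 0.09,
    "rectus_femoris",           "Rectus Femoris",           2.28, 0.43,
    "piriformis",               "Piriformis",               0.30, 0.09,
    "adductor_magnus",          "Adductor Magnus",          5.73, 0.88,
    "gluteus_minimus",          "Gluteus Minimus",          0.68, 0.10,
    "obturator_internus",       "Obturator Internus",       0.15, 0.05,
    "semitendinosus",           "Semitendinosus",           1.94, 0.38,
    "semimembranosus",          "Semimembranosus",          2.02, 0.33,
    "iliacus",                  "Iliacus",                  1.37, 0.23,
    "vastus_lateralis",         "Vastus Lateralis",         7.95, 1.05,
    "adductor_brevis",          "Adductor Brevis",          0.86, 0.13,
    "flexor_hallucis_longus",   "Flexor Hallucis Longus",   0.50, 0.09,
    "phalangeal_extensors",     "Phalangeal Extensors",     0.60, 0.10,
    "adductor_longus",          "Adductor Longus",          1.45, 0.22,
    "tibialis_anterior",        "Tibialis Anterior",        0.85, 0.15,
    "gemelli",                  "Gemelli",                  0.12, 0.03,
    "popliteus",                "Popliteus",                0.13, 0.03,
    "vastus_medialis",          "Vastus Medialis",          4.27, 0.58,
    "biceps_femoris_long_head", "Biceps Femoris Long Head", 1.66, 0.33,
    "sartorius",                "Sartorius",                1.41, 0.30,
    "tensor_fasciae_latae",     "Tensor Fasciae Latae",     0.62, 0.15,
    "soleus",                   "Soleus",                   3.05, 0.43,
    "tibialis_posterior",       "Tibialis Posterior",       0.66, 0.15,
    "flexor_digitorum_longus",  "Flexor Digitorum Longus",  0.17, 0.04,
    "biceps_femoris_short_head","Biceps Femoris Short Head",0.87, 0.17,
    "gracilis",                 "Gracilis",                 1.02, 0.19,
    "obturator_externus",       "Obturator Externus",       0.39, 0.07,
    "vastus_intermedius",       "Vastus Intermedius",       2.40, 0.36,
    "medial_gastrocnemius",     "Medial Gastrocnemius",     1.85, 0.31,
    "lateral_gastrocnemius",    "Lateral Gastrocnemius",    1.08, 0.17,
    "peroneus",                 "Peroneus",                 0.91, 0.15,
    "quadratus_femoris",        "Quadratus Femoris",        0.22, 0.06
  )
  validate_catalog(out)
  out
}

validate_catalog <- function(catalog) {
  stopifnot(is.data.frame(catalog))
  required <- c("muscle", "mean_norm_vol", "sd_norm_vol")
  missing <- setdiff(required, names(catalog))
  if (length(missing) > 0) {
    stop("muscle catalog is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(catalog) != 35) {
    stop("muscle catalog must have exactly 35 muscles, got ", nrow(catalog),
         call. = FALSE)
  }
  if (anyDuplicated(catalog$muscle)) {
    stop("muscle catalog labels must be unique", call. = FALSE)
  }
  if (any(catalog$mean_norm_vol <= 0) || any(catalog$sd_norm_vol <= 0)) {
    stop("muscle catalog means and SDs must be strictly positive",
         call. = FALSE)
  }
  invisible(catalog)
}

#' Map raw per-side muscles to the 35 analysis muscles
#'
#' Three analysis muscles are sums of smaller raw muscles, applied per side
#' before bilateral averaging. All other muscles map to themselves.
#'
#' @return A tibble with columns `raw_muscle` (the 39 per-side segmentation
#'   labels) and `muscle` (the 35 analysis labels).
#' @examples
#' dplyr::filter(muscle_grouping(), raw_muscle != muscle)
#' @export
muscle_grouping <- function() {
  composite <- tibble::tribble(
    ~raw_muscle, ~muscle,
    "peroneus_brevis",           "peroneus",
    "peroneus_longus",           "peroneus",
    "gemellus_superior",         "gemelli",
    "gemellus_inferior",         "gemelli",
    "extensor_digitorum_longus", "phalangeal_extensors",
    "extensor_hallucis_longus",  "phalangeal_extensors",
    "peroneus_tertius",          "phalangeal_extensors"
  )
  simple <- setdiff(muscle_catalog()$muscle, unique(composite$muscle))
  dplyr::bind_rows(
    tibble::tibble(raw_muscle = simple, muscle = simple),
    composite
  )
}

#' Published per-muscle variance explained
#'
#' Reference values of the coefficient of determination (R^2) between each
#' normalized individual muscle volume and peak sprint speed in the original
#' 66-athlete cohort. These are fixture values: the athlete data are not
#' public, so they cannot be recomputed, but they parameterize the synthetic
#' generator's default speed weights and anchor the printed-table arithmetic.
#'
#' @return A tibble with columns `rank`, `muscle`, `r2`.
#' @examples
#' head(reference_individual_r2(), 3)
#' @export
reference_individual_r2 <- function() {
  r2 <- c(0.499, 0.451, 0.365, 0.323, 0.321, 0.303, 0.287, 0.280, 0.276,
          0.269, 0.266, 0.239, 0.232, 0.230, 0.225, 0.219, 0.214, 0.205,
          0.202, 0.195, 0.190, 0.190, 0.188, 0.162, 0.162, 0.158, 0.156,
          0.152, 0.152, 0.133, 0.126, 0.090, 0.077, 0.063, 0.042)
  tibble::tibble(rank = seq_along(r2), muscle = muscle_catalog()$muscle, r2 = r2)
}

#' Published top three-muscle combinations
#'
#' Reference rows for the best-performing three-muscle combinations in the
#' original cohort: the top simple sum and the top optimized linear
#' combination, both psoas major + gluteus medius + piriformis. Stored as
#' fixtures for printed-table arithmetic (e.g., improvement over the best
#' individual muscle); they are not recomputable without the athlete data.
#'
#' @return A tibble with columns `mode` ("simple_sum" or "optimized"),
#'   `rank`, `muscle_1..3`, `coef_1..3` (unit coefficients for simple sums),
#'   and `r2`.
#' @examples
#' reference_top_combinations()
#' @export
reference_top_combinations <- function() {
  tibble::tribble(
    ~mode, ~rank, ~muscle_1, ~coef_1, ~muscle_2, ~coef_2, ~muscle_3, ~coef_3, ~r2,
    "simple_sum", 1L, "psoas_major", 1.00, "gluteus_medius", 1.00, "piriformis", 1.00, 0.568,
    "optimized",  1L, "psoas_major", 0.35, "gluteus_medius", 0.26, "piriformis", 1.00, 0.587
  )
}
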