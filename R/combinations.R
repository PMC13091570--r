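#' Coefficient of determination between two variables
#'
#' Squared Pearson correlation: the fraction of variance in one variable
#' linearly explainable by the other,
#' `[sum((v - vbar) (s - sbar))]^2 / [sum((v - vbar)^2) sum((s - sbar)^2)]`.
#' Invariant to affine transforms (with positive or negative scale) of either
#' argument. Constant inputs leave the correlation undefined and are
#' rejected rather than mapped to 0.
#'
#' @param v,s Numeric vectors of equal length (>= 3).
#' @return R^2 in `[0, 1]`.
#' @examples
#' r_squared(c(1, 2, 3), c(2, 4, 5)) # 27/28
#' @export
r_squared <- function(v, s) {
  if (length(v) != length(s)) abort("`v` and `s` must have equal length")
  if (length(v) < 3) abort("`v` and `s` must have at least 3 observations")
  if (anyNA(v) || anyNA(s)) abort("`v` and `s` must not contain NA")
  vc <- v - mean(v)
  sc <- s - mean(s)
  vss <- sum(vc^2)
  sss <- sum(sc^2)
  if (vss == 0) abort("`v` is constant: correlation undefined")
  if (sss == 0) abort("`s` is constant: correlation undefined")
  sum(vc * sc)^2 / (vss * sss)
}

#' Enumerate muscle subsets
#'
#' All unordered subsets of `subset_size` indices out of `n_muscles`, each
#' row with strictly increasing indices. `enumerate_triples()` is the
#' three-muscle case used throughout the analysis: 35 muscles give
#' `choose(35, 3) = 6545` triples.
#'
#' @param n_muscles Number of muscles (>= `subset_size`).
#' @param subset_size Subset size `k` (default 3). Above 4 the enumeration
#'   grows quickly (`choose(35, 4) = 52360`) and a warning is issued.
#' @return A tibble with columns `idx_1 .. idx_k`, one row per subset.
#' @examples
#' nrow(enumerate_triples(35)) # 6545
#' @export
enumerate_subsets <- function(n_muscles, subset_size = 3) {
  if (!is_count(n_muscles)) abort("`n_muscles` must be a positive integer")
  if (!is_count(subset_size)) abort("`subset_size` must be a positive integer")
  if (n_muscles < subset_size) {
    abort(sprintf("`n_muscles` = %d is smaller than the subset size %d",
                  n_muscles, subset_size))
  }
  if (subset_size > 4) {
    warn(sprintf("subset size %d enumerates %s combinations; sizes above 4 get expensive",
                 subset_size,
                 format(choose(n_muscles, subset_size), big.mark = " ")))
  }
  m <- t(utils::combn(n_muscles, subset_size))
  colnames(m) <- paste0("idx_", seq_len(subset_size))
  tibble::as_tibble(m)
}

#' @rdname enumerate_subsets
#' @export
enumerate_triples <- function(n_muscles) {
  if (!is_count(n_muscles) || n_muscles < 3) {
    abort("`n_muscles` must be an integer >= 3")
  }
  enumerate_subsets(n_muscles, 3)
}

# centered cross-products of the cohort's volume matrix and speed; every
# scan-level R^2 reduces to a quadratic form in these
cohort_crossprods <- function(cohort, catalog = muscle_catalog()) {
  validate_cohort(cohort, catalog$muscle)
  v <- as.matrix(cohort[catalog$muscle])
  s <- cohort$speed_mps
  if (nrow(v) < 3) abort("cohort must have at least 3 athletes")
  vc <- scale(v, center = TRUE, scale = FALSE)
  sc <- s - mean(s)
  sss <- sum(sc^2)
  if (sss == 0) abort("speed is constant across the cohort")
  vss <- colSums(vc^2)
  if (any(vss == 0)) {
    abort(paste0("constant volume column(s): ",
                 paste(catalog$muscle[vss == 0], collapse = ", ")))
  }
  list(muscles = catalog$muscle, n = nrow(v),
       C = crossprod(vc), cvs = drop(crossprod(vc, sc)), sss = sss)
}

# R^2 of the weighted sum x'V against speed, from cross-products
combo_r2 <- function(x, C, cvs, sss) {
  denom <- drop(x %*% C %*% x) * sss
  if (denom <= 0) return(0)
  sum(x * cvs)^2 / denom
}

new_rank_report <- function(df, mode, n_athletes, filter_meta = NULL) {
  df <- dplyr::mutate(df, rank = dplyr::row_number(), .before = 1)
  structure(df,
            class = c("sv_rank_report", class(tibble::tibble())),
            mode = mode, n_athletes = n_athletes, filter = filter_meta)
}

# descending r2; ties broken lexicographically by muscle indices
rank_rows <- function(df) {
  idx_cols <- grep("^idx_", names(df), value = TRUE)
  dplyr::arrange(df, dplyr::desc(.data$r2),
                 !!!rlang::syms(idx_cols))
}

#' Variance explained by each individual muscle
#'
#' R^2 between each normalized muscle volume and peak speed, ranked in
#' descending order (ties broken by catalog index).
#'
#' @param cohort A cohort table (see [build_cohort()] / [generate_cohort()]).
#' @param catalog A [muscle_catalog()]-shaped tibble fixing column order.
#' @return A `sv_rank_report` tibble: `rank`, `idx_1`, `muscle`, `r2`,
#'   `mode = "individual"`.
#' @export
individual_scan <- function(cohort, catalog = muscle_catalog()) {
  cp <- cohort_crossprods(cohort, catalog)
  df <- tibble::tibble(
    idx_1 = seq_along(cp$muscles),
    muscle = cp$muscles,
    r2 = unname(cp$cvs^2 / (diag(cp$C) * cp$sss)),
    mode = "individual"
  )
  new_rank_report(rank_rows(df), "individual", cp$n)
}

#' Variance explained by simple sums of muscle volumes
#'
#' R^2 between peak speed and the unweighted sum of every subset of
#' `subset_size` normalized muscle volumes (all `choose(35, 3) = 6545`
#' triples by default), ranked descending.
#'
#' @inheritParams individual_scan
#' @param subset_size Number of muscles per combination (default 3).
#' @return A `sv_rank_report` tibble: `rank`, `idx_*`, `muscle_*`, `r2`,
#'   `mode = "simple_sum"`.
#' @export
simple_sum_scan <- function(cohort, catalog = muscle_catalog(),
                            subset_size = 3) {
  cp <- cohort_crossprods(cohort, catalog)
  subsets <- as.matrix(enumerate_subsets(length(cp$muscles), subset_size))
  r2 <- vapply(seq_len(nrow(subsets)), function(i) {
    idx <- subsets[i, ]
    sum(cp$cvs[idx])^2 / (sum(cp$C[idx, idx]) * cp$sss)
  }, numeric(1))
  df <- tibble::as_tibble(subsets)
  for (j in seq_len(subset_size)) {
    df[[paste0("muscle_", j)]] <- cp$muscles[subsets[, j]]
  }
  df$r2 <- r2
  df$mode <- "simple_sum"
  new_rank_report(rank_rows(df), "simple_sum", cp$n)
}

# bounded Nelder-Mead on sine-transformed coordinates (the fminsearchbnd
# device: x = lo + (hi - lo) (sin t + 1) / 2 maps R^k onto the box), with one
# polishing restart from the converged simplex
optimize_triple_core <- function(C, cvs, sss, bounds, init, reltol = 1e-10,
                                 maxit = 10000) {
  k <- length(cvs)
  lo <- bounds[1]; hi <- bounds[2]
  to_x <- function(t) lo + (hi - lo) * (sin(t) + 1) / 2
  t0 <- rep(asin(2 * (init - lo) / (hi - lo) - 1), k)
  obj <- function(t) -combo_r2(to_x(t), C, cvs, sss)
  fit <- stats::optim(t0, obj, method = "Nelder-Mead",
                      control = list(reltol = reltol, maxit = maxit))
  for (r in 1:2) { # restart until the objective stops improving
    refit <- stats::optim(fit$par, obj, method = "Nelder-Mead",
                          control = list(reltol = reltol, maxit = maxit))
    if (fit$value - refit$value < 1e-12) { fit <- refit; break }
    fit <- refit
  }
  list(x = to_x(fit$par), r2 = -fit$value, evals = fit$counts[["function"]])
}

# closed-form optimum: maximizing squared correlation over linear
# combinations equals the R^2 of OLS of speed on the columns with intercept
ols_r2_core <- function(C, cvs, sss, tol = 1e-10) {
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  degenerate <- min(ev) < tol * max(ev)
  beta <- if (degenerate) drop(pinv(C) %*% cvs) else solve(C, cvs)
  list(r2 = min(1, sum(beta * cvs) / sss), beta = beta,
       degenerate = degenerate)
}

rescale_coefficients <- function(x) {
  m <- max(abs(x))
  if (m == 0) return(x)
  x / m
}

#' Optimal bounded linear combination of a muscle subset
#'
#' Finds coefficients `x` in `[-1, 1]^k` maximizing the R^2 between the
#' weighted volume sum `V(x) = x_1 V_1 + ... + x_k V_k` and peak speed, by a
#' bounded derivative-free Nelder-Mead search (sine variable transform,
#' initial guesses 0.5). Because R^2 depends only on the direction of `x`,
#' the bounds are non-binding; the achieved value equals the R^2 of an
#' ordinary least-squares fit of speed on the subset's columns, which is
#' used as a closed-form cross-check and as a fallback when the columns are
#' collinear. Coefficients are reported after dividing by the magnitude of
#' the largest, so the largest has magnitude exactly 1 with signs preserved.
#'
#' @inheritParams individual_scan
#' @param subset Integer vector of distinct catalog indices (typically 3) or
#'   a character vector of muscle names.
#' @param bounds Length-2 numeric search box (default `c(-1, 1)`).
#' @param init Initial coefficient guess (default 0.5).
#' @return An object of class `sv_combo`: muscles, rescaled `coefficients`,
#'   achieved `r2`, the closed-form `r2_ols`, and a `degenerate` flag. Has
#'   [tidy()] and [glance()] methods.
#' @export
optimize_combination <- function(cohort, subset, catalog = muscle_catalog(),
                                 bounds = c(-1, 1), init = 0.5) {
  cp <- cohort_crossprods(cohort, catalog)
  if (is.character(subset)) subset <- match(subset, cp$muscles)
  if (anyNA(subset) || anyDuplicated(subset) ||
      any(subset < 1 | subset > length(cp$muscles))) {
    abort("`subset` must be distinct catalog indices or muscle names")
  }
  subset <- sort(as.integer(subset))
  if (length(bounds) != 2 || bounds[1] >= bounds[2]) {
    abort("`bounds` must be c(lower, upper) with lower < upper")
  }
  if (init <= bounds[1] || init >= bounds[2]) {
    abort("`init` must lie strictly inside `bounds`")
  }
  fit <- fit_subset(cp, subset, bounds, init)
  structure(
    list(muscles = cp$muscles[subset], idx = subset,
         coefficients = fit$coefficients, r2 = fit$r2, r2_ols = fit$r2_ols,
         degenerate = fit$degenerate, n = cp$n, evals = fit$evals,
         mode = "optimized"),
    class = "sv_combo"
  )
}

fit_subset <- function(cp, idx, bounds, init) {
  C <- cp$C[idx, idx, drop = FALSE]
  cvs <- cp$cvs[idx]
  ols <- ols_r2_core(C, cvs, cp$sss)
  if (ols$degenerate) {
    # collinear columns: the simplex ridge is degenerate, use the
    # pseudo-inverse solution directly
    rlang::inform(paste0("collinear volume columns in subset {",
                         paste(cp$muscles[idx], collapse = ", "),
                         "}; using the pseudo-inverse closed form"))
    x <- rescale_coefficients(unname(ols$beta))
    return(list(coefficients = x, r2 = combo_r2(x, C, cvs, cp$sss),
                r2_ols = ols$r2, degenerate = TRUE, evals = 0L))
  }
  fit <- optimize_triple_core(C, cvs, cp$sss, bounds, init)
  list(coefficients = rescale_coefficients(fit$x), r2 = fit$r2,
       r2_ols = ols$r2, degenerate = FALSE, evals = fit$evals)
}

#' @export
print.sv_combo <- function(x, ...) {
  cat("Optimized muscle combination (n =", x$n, "athletes)\n")
  print(tidy(x))
  cat(sprintf("R^2 = %.4f (closed-form check %.4f)\n", x$r2, x$r2_ols))
  invisible(x)
}

#' @export
tidy.sv_combo <- function(x, ...) {
  tibble::tibble(muscle = x$muscles, index = x$idx,
                 coefficient = x$coefficients)
}

#' @export
glance.sv_combo <- function(x, ...) {
  tibble::tibble(r2 = x$r2, r2_ols = x$r2_ols, degenerate = x$degenerate,
                 n = x$n, mode = x$mode)
}

#' Variance explained by optimized combinations of every muscle subset
#'
#' Applies [optimize_combination()] to every subset of `subset_size` muscles
#' (all 6545 triples by default) and ranks the results.
#'
#' @inheritParams simple_sum_scan
#' @param bounds,init Passed to [optimize_combination()].
#' @param progress Print a progress message every 1000 subsets.
#' @return A `sv_rank_report` tibble: `rank`, `idx_*`, `muscle_*`, `coef_*`,
#'   `r2`, `r2_ols`, `mode = "optimized"`.
#' @export
optimized_scan <- function(cohort, catalog = muscle_catalog(),
                           subset_size = 3, bounds = c(-1, 1), init = 0.5,
                           progress = FALSE) {
  cp <- cohort_crossprods(cohort, catalog)
  subsets <- as.matrix(enumerate_subsets(length(cp$muscles), subset_size))
  fits <- vector("list", nrow(subsets))
  for (i in seq_len(nrow(subsets))) {
    fits[[i]] <- fit_subset(cp, subsets[i, ], bounds, init)
    if (progress && i %% 1000 == 0) {
      rlang::inform(sprintf("optimized %d / %d subsets", i, nrow(subsets)))
    }
  }
  df <- tibble::as_tibble(subsets)
  for (j in seq_len(subset_size)) {
    df[[paste0("muscle_", j)]] <- cp$muscles[subsets[, j]]
    df[[paste0("coef_", j)]] <-
      vapply(fits, function(f) f$coefficients[j], numeric(1))
  }
  df$r2 <- vapply(fits, `[[`, numeric(1), "r2")
  df$r2_ols <- vapply(fits, `[[`, numeric(1), "r2_ols")
  df$mode <- "optimized"
  new_rank_report(rank_rows(df), "optimized", cp$n)
}

#' Best combination per lead muscle, excluding higher-ranked muscles
#'
#' The display rule of the result tables: for each of the top `k` individual
#' muscles `m` (in individual rank order), report the best-scoring
#' combination that contains `m` and contains no muscle individually ranked
#' above `m`. The second row therefore cannot contain the top muscle, and so
#' on. Each emitted row keeps its global rank within the unfiltered scan.
#'
#' @param report A combination `sv_rank_report` ([simple_sum_scan()] or
#'   [optimized_scan()]).
#' @param individual_report An [individual_scan()] report for the same
#'   cohort.
#' @param k Number of lead muscles to report (default 10, at most 35).
#' @return A `sv_rank_report` tibble with columns `lead_muscle`,
#'   `lead_rank`, `global_rank`, then the combination columns.
#' @export
top_per_muscle_filter <- function(report, individual_report, k = 10) {
  stopifnot(inherits(report, "sv_rank_report"),
            inherits(individual_report, "sv_rank_report"))
  if (attr(individual_report, "mode") != "individual") {
    abort("`individual_report` must come from individual_scan()")
  }
  if (!is_count(k) || k > nrow(individual_report)) {
    abort("`k` must be a positive integer no larger than the number of muscles")
  }
  idx_cols <- grep("^idx_", names(report), value = TRUE)
  member_idx <- as.matrix(report[idx_cols])
  # individual rank of every catalog index
  ind_rank <- integer(max(individual_report$idx_1))
  ind_rank[individual_report$idx_1] <- individual_report$rank
  # the best (lowest) individual rank among each combination's members
  best_member_rank <- matrix(ind_rank[member_idx], nrow = nrow(member_idx))
  lead_rank_per_row <- apply(best_member_rank, 1, min)

  rows <- purrr::map(seq_len(k), function(r) {
    lead_idx <- individual_report$idx_1[individual_report$rank == r]
    contains_lead <- rowSums(member_idx == lead_idx) > 0
    eligible <- contains_lead & lead_rank_per_row == r
    if (!any(eligible)) return(NULL)
    best <- report[which(eligible)[1], ] # report is rank-ordered
    dplyr::bind_cols(
      tibble::tibble(lead_muscle = individual_report$muscle[
                       individual_report$rank == r],
                     lead_rank = r, global_rank = best$rank),
      dplyr::select(best, -"rank")
    )
  })
  out <- dplyr::bind_rows(rows)
  structure(out,
            class = c("sv_rank_report", class(tibble::tibble())),
            mode = attr(report, "mode"),
            n_athletes = attr(report, "n_athletes"),
            filter = list(k = k, rule = "no muscle ranked higher than the lead"))
}

#' Improvement of combinations over individual muscles
#'
#' For each lead muscle, the gain in variance explained by its best
#' constrained combination ([top_per_muscle_filter()]) over the muscle alone,
#' with the mean and SD of the gains across lead muscles. By default all 35
#' muscles serve as leads.
#'
#' @param report A combination `sv_rank_report`.
#' @param individual_report An [individual_scan()] report for the same
#'   cohort.
#' @param k Number of lead muscles (default: all).
#' @return A tibble of class `sv_improvement` with columns `lead_muscle`,
#'   `lead_rank`, `individual_r2`, `combination_r2`, `delta`; the mean and SD
#'   of `delta` are available via [glance()].
#' @export
improvement_summary <- function(report, individual_report,
                                k = nrow(individual_report)) {
  filtered <- top_per_muscle_filter(report, individual_report, k)
  out <- filtered |>
    tibble::as_tibble() |>
    dplyr::select("lead_muscle", "lead_rank",
                  combination_r2 = "r2") |>
    dplyr::inner_join(
      dplyr::select(tibble::as_tibble(individual_report),
                    lead_muscle = "muscle", individual_r2 = "r2"),
      by = "lead_muscle") |>
    dplyr::mutate(delta = .data$combination_r2 - .data$individual_r2) |>
    dplyr::select("lead_muscle", "lead_rank", "individual_r2",
                  "combination_r2", "delta")
  structure(out,
            class = c("sv_improvement", class(tibble::tibble())),
            mode = attr(report, "mode"))
}

#' @export
glance.sv_improvement <- function(x, ...) {
  tibble::tibble(
    mode = attr(x, "mode"),
    n_lead_muscles = nrow(x),
    mean_delta = mean(x$delta),
    sd_delta = stats::sd(x$delta)
  )
}

#' Frequency of negative coefficients in an optimized scan
#'
#' Across all optimized combinations, the fraction of coefficient slots that
#' came out negative, overall and per muscle (each of 35 muscles appears in
#' `choose(34, 2) = 561` triples).
#'
#' @param report An [optimized_scan()] report.
#' @return A list with `overall` (fraction of negative slots) and
#'   `per_muscle` (tibble: `muscle`, `appearances`, `negative`, `fraction`,
#'   sorted by descending fraction).
#' @export
negative_coefficient_summary <- function(report) {
  stopifnot(inherits(report, "sv_rank_report"))
  if (attr(report, "mode") != "optimized") {
    abort("negative-coefficient summary requires an optimized scan")
  }
  idx_cols <- grep("^idx_", names(report), value = TRUE)
  coef_cols <- sub("idx", "coef", idx_cols)
  idx <- as.vector(as.matrix(report[idx_cols]))
  neg <- as.vector(as.matrix(report[coef_cols])) < 0
  muscles <- sort(unique(idx))
  per <- tibble::tibble(
    muscle_idx = muscles,
    appearances = tabulate(idx, nbins = max(muscles))[muscles],
    negative = vapply(muscles, function(m) sum(neg[idx == m]), integer(1))
  ) |>
    dplyr::mutate(fraction = .data$negative / .data$appearances)
  # recover names from the report columns
  name_map <- stats::setNames(
    as.vector(as.matrix(report[sub("idx", "muscle", idx_cols)])), idx)
  per$muscle <- name_map[as.character(per$muscle_idx)]
  per <- dplyr::select(per, "muscle", "appearances", "negative", "fraction") |>
    dplyr::arrange(dplyr::desc(.data$fraction), .data$muscle)
  list(overall = sum(neg) / length(neg), per_muscle = per)
}

#' @export
tidy.sv_rank_report <- function(x, ...) {
  out <- x
  class(out) <- class(tibble::tibble())
  attr(out, "mode") <- NULL
  attr(out, "n_athletes") <- NULL
  attr(out, "filter") <- NULL
  out
}

#' @export
glance.sv_rank_report <- function(x, ...) {
  tibble::tibble(
    mode = attr(x, "mode"),
    n_results = nrow(x),
    best_r2 = max(x$r2),
    n_athletes = attr(x, "n_athletes")
  )
}
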