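#' @importFrom rlang .data abort warn .env
NULL

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

# truncated normal via rejection; bounds in SD units around the mean
rtruncnorm3 <- function(n, mean, sd, n_sd = 3) {
  out <- stats::rnorm(n, mean, sd)
  bad <- abs(out - mean) > n_sd * sd
  while (any(bad)) {
    out[bad] <- stats::rnorm(sum(bad), mean, sd)
    bad <- abs(out - mean) > n_sd * sd
  }
  out
}

# Moore-Penrose pseudo-inverse for small symmetric matrices (collinear
# fallback in the combination optimizer)
pinv <- function(m, tol = 1e-10) {
  sv <- svd(m)
  keep <- sv$d > tol * max(sv$d)
  if (!any(keep)) return(matrix(0, ncol(m), nrow(m)))
  sv$v[, keep, drop = FALSE] %*%
    ((1 / sv$d[keep]) * t(sv$u[, keep, drop = FALSE]))
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x == round(x) && x >= 1
}

is_number <- function(x) {
  is.numeric(x) && length(x) == 1 && is.finite(x)
}

assert_number <- function(x, name, lower = -Inf, upper = Inf,
                          strict_lower = FALSE) {
  if (!is_number(x)) {
    abort(sprintf("`%s` must be a single finite number", name))
  }
  if (x < lower || (strict_lower && x <= lower) || x > upper) {
    abort(sprintf("`%s` = %g is outside its allowed range [%g, %g]%s",
                  name, x, lower, upper,
                  if (strict_lower) " (lower bound exclusive)" else ""))
  }
  invisible(x)
}
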