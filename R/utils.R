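#' @keywords internal
#' @useDynLib swimmaze, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards. `seed = NULL` uses the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Stable per-subject sub-seeds derived from one master seed, so per-subject
# output does not depend on simulation order.
subject_seeds <- function(seed, n) {
  with_seed(seed, sample.int(2147483646L, n))
}

#' Min-max scale a numeric vector across a population
#'
#' Scales `x` to `[0, 1]` by the population minimum and maximum. A constant
#' vector (range below `eps`) maps to 0 for every element, so downstream
#' averages of scaled variables stay defined.
#'
#' @param x Numeric vector; `NA`s are propagated.
#' @param eps Range below which the column is treated as constant.
#' @return Numeric vector in `[0, 1]`.
#' @export
scale_minmax <- function(x, eps = .Machine$double.eps * 100) {
  stopifnot(is.numeric(x))
  rng <- range(x, na.rm = TRUE)
  if (!all(is.finite(rng)) || diff(rng) < eps) {
    return(ifelse(is.na(x), NA_real_, 0))
  }
  (x - rng[1L]) / (rng[2L] - rng[1L])
}

# log(sum(exp(v))) rowwise on a matrix, numerically stable
row_logsumexp <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

fmt_num <- function(x) {
  # 17 significant digits: round-trips doubles through text
  ifelse(is.na(x), "", sprintf("%.17g", x))
}
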