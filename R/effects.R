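#' Standardized effect size between two groups
#'
#' Absolute difference of group means divided by the total (pooled-sample)
#' standard deviation: `d = |mean(a) - mean(b)| / sd(c(a, b))`, with the
#' usual `n - 1` denominator on the pooled observations. This "total SD"
#' standardisation is the default; `method = "pooled_within"` gives the
#' classical Cohen's d denominator (the pooled within-group SD) instead.
#'
#' @param a,b Numeric vectors of the endpoint in the two groups
#'   (`length >= 2` each).
#' @param method `"total_sd"` (default) or `"pooled_within"`.
#' @param endpoint,group_a,group_b Optional labels carried into the result.
#' @return Object of class `effect_size`: `endpoint`, `group_a`, `group_b`,
#'   `d` (absolute, dimensionless; `NA` with a warning when the denominator
#'   SD is 0), `n_a`, `n_b`, `method`.
#' @export
standardized_effect <- function(a, b, method = c("total_sd", "pooled_within"),
                                endpoint = NA_character_,
                                group_a = NA_character_,
                                group_b = NA_character_) {
  method <- match.arg(method)
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2L || length(b) < 2L) {
    stop("each group needs at least 2 finite observations", call. = FALSE)
  }
  s <- if (method == "total_sd") {
    stats::sd(c(a, b))
  } else {
    sqrt(((length(a) - 1L) * stats::var(a) + (length(b) - 1L) * stats::var(b)) /
           (length(a) + length(b) - 2L))
  }
  d <- if (s > 0) abs(mean(a) - mean(b)) / s else {
    warning("zero pooled standard deviation; effect size undefined",
            call. = FALSE)
    NA_real_
  }
  structure(list(endpoint = endpoint, group_a = group_a, group_b = group_b,
                 d = d, n_a = length(a), n_b = length(b), method = method),
            class = "effect_size")
}

#' @export
print.effect_size <- function(x, ...) {
  cat(sprintf("<effect_size> d = %.4f (%s; n = %d vs %d)%s\n",
              x$d, x$method, x$n_a, x$n_b,
              if (!is.na(x$endpoint)) paste0("  [", x$endpoint, "]") else ""))
  invisible(x)
}

#' Composite effect size
#'
#' Unweighted mean of several standardized effect sizes, used to summarise a
#' multi-endpoint contrast (e.g. averaging the effects on shallow-arm
#' frequency and latency in the plus-maze together with the frequency and
#' latency effects in the show-jump test into one "isolation effect" cell).
#'
#' @param effects List of [standardized_effect()] results, or a numeric
#'   vector of d values.
#' @return Mean d (numeric scalar).
#' @export
composite_effect <- function(effects) {
  if (length(effects) == 0L) stop("empty effect list", call. = FALSE)
  d <- if (is.numeric(effects)) effects else
    vapply(effects, function(e) e$d, numeric(1L))
  mean(d)
}

#' Tidy table of effect sizes
#'
#' @param effects List of [standardized_effect()] results.
#' @return data.frame `endpoint, group_a, group_b, d, n_a, n_b`.
#' @export
effects_table <- function(effects) {
  do.call(rbind, lapply(effects, function(e) {
    data.frame(endpoint = e$endpoint, group_a = e$group_a, group_b = e$group_b,
               d = e$d, n_a = e$n_a, n_b = e$n_b, stringsAsFactors = FALSE)
  }))
}
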