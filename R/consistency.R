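#' One-way random-effects variance components
#'
#' Method-of-moments (ANOVA) decomposition of a repeated endpoint into
#' between-subject and within-subject variance. For subjects
#' `i = 1..n` with `n_i` sessions each (`N = sum(n_i)`):
#' `MS_within` is the pooled within-subject mean square,
#' `MS_between = sum(n_i (m_i - m)^2) / (n - 1)`, and the between-subject
#' variance is `(MS_between - MS_within) / k0`, truncated at 0, with the
#' (un)balanced design coefficient `k0 = (N - sum(n_i^2)/N) / (n - 1)`
#' (equal to the session count `k` for balanced designs).
#'
#' Subjects with fewer than two non-missing sessions carry no within-subject
#' information and are dropped before estimation.
#'
#' @param values Numeric matrix, subjects x sessions (rownames = subject
#'   ids); `NA` cells mark missing sessions.
#' @return List: `var_between`, `var_within`, `grand_mean`, `n_subjects`,
#'   `n_obs`, `k0`, `n_i` (per-subject session counts).
#' @export
variance_components <- function(values) {
  values <- as.matrix(values)
  n_i_all <- rowSums(!is.na(values))
  keep <- n_i_all >= 2L
  if (sum(keep) < 2L) {
    stop("need at least 2 subjects with >= 2 sessions each", call. = FALSE)
  }
  values <- values[keep, , drop = FALSE]
  n_i <- rowSums(!is.na(values))
  n <- nrow(values)
  N <- sum(n_i)
  m_i <- rowMeans(values, na.rm = TRUE)
  m <- sum(values, na.rm = TRUE) / N
  ss_within <- sum((values - m_i)^2, na.rm = TRUE)
  ms_within <- ss_within / (N - n)
  ms_between <- sum(n_i * (m_i - m)^2) / (n - 1L)
  k0 <- (N - sum(n_i^2) / N) / (n - 1L)
  var_between <- max(0, (ms_between - ms_within) / k0)
  list(var_between = var_between, var_within = ms_within,
       grand_mean = m, n_subjects = n, n_obs = N, k0 = k0, n_i = n_i)
}

#' Repeatability (intraclass correlation) with parametric-bootstrap CI
#'
#' Agreement repeatability of a repeated behavioral endpoint:
#' `R = var_between_subject / (var_between_subject + var_within_subject)`,
#' with variances from [variance_components()]. The 95% confidence interval
#' comes from a parametric bootstrap: `n_boot` datasets are simulated from
#' the fitted normal random-intercept model (grand mean, estimated variance
#' components, identical subject-session design), `R` is re-estimated on
#' each, and the 2.5/97.5 percentiles are taken. An estimate whose interval
#' excludes 0 is flagged significant.
#'
#' @param values Numeric subjects x sessions matrix (see
#'   [variance_components()]).
#' @param n_boot Number of bootstrap replicates (default 1000; below 100 a
#'   warning is issued).
#' @param seed Seed for the bootstrap stream (required for reproducibility).
#' @param conf Confidence level (default 0.95).
#' @return Object of class `repeatability_estimate`: `R`, `var_between`,
#'   `var_within`, `ci_low`, `ci_high`, `significant`, `n_boot`, `seed`,
#'   `n_subjects`, `boot_R` (the replicate estimates).
#' @examples
#' m <- rbind(s1 = c(0, 2), s2 = c(4, 6))
#' repeatability(m, n_boot = 200, seed = 1)$R  # 7/9
#' @export
repeatability <- function(values, n_boot = 1000L, seed = NULL, conf = 0.95) {
  if (n_boot < 100L) {
    warning("n_boot < 100 gives unstable percentile intervals", call. = FALSE)
  }
  vc <- variance_components(values)
  if (vc$var_between == 0 && vc$var_within == 0) {
    warning("degenerate data: both variance components are 0; R defined as 0",
            call. = FALSE)
    return(structure(list(R = 0, var_between = 0, var_within = 0,
                          ci_low = 0, ci_high = 0, significant = FALSE,
                          n_boot = n_boot, seed = seed,
                          n_subjects = vc$n_subjects, boot_R = rep(0, n_boot)),
                     class = "repeatability_estimate"))
  }
  R <- vc$var_between / (vc$var_between + vc$var_within)
  n_i <- vc$n_i
  boot_R <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
    y <- lapply(n_i, function(k) {
      vc$grand_mean + stats::rnorm(1L, 0, sqrt(vc$var_between)) +
        stats::rnorm(k, 0, sqrt(vc$var_within))
    })
    mat <- matrix(NA_real_, length(n_i), max(n_i))
    for (i in seq_along(y)) mat[i, seq_len(n_i[i])] <- y[[i]]
    v <- variance_components(mat)
    tot <- v$var_between + v$var_within
    if (tot == 0) 0 else v$var_between / tot
  }, numeric(1L)))
  alpha <- (1 - conf) / 2
  ci <- unname(stats::quantile(boot_R, c(alpha, 1 - alpha)))
  structure(list(R = R, var_between = vc$var_between,
                 var_within = vc$var_within,
                 ci_low = ci[1L], ci_high = ci[2L],
                 significant = ci[1L] > 0,
                 n_boot = n_boot, seed = seed, n_subjects = vc$n_subjects,
                 boot_R = boot_R),
            class = "repeatability_estimate")
}

#' @export
print.repeatability_estimate <- function(x, ...) {
  cat(sprintf("<repeatability_estimate> R = %.3f  95%% CI [%.3f, %.3f]%s\n",
              x$R, x$ci_low, x$ci_high,
              if (x$significant) "  (significant)" else ""))
  cat(sprintf("  var between-subject = %.4g, within-subject = %.4g, n = %d, n_boot = %d\n",
              x$var_between, x$var_within, x$n_subjects, x$n_boot))
  invisible(x)
}

#' Single and summary measures of a repeated endpoint
#'
#' Collapses a subjects x sessions matrix to one scalar per subject:
#' the single measure (`"SiM"`) takes session 1; the summary measure
#' (`"SuM"`) averages all available sessions. Subjects with no usable value
#' are dropped with a warning.
#'
#' @param values Numeric subjects x sessions matrix.
#' @param mode `"SuM"` (default) or `"SiM"`.
#' @return Named numeric vector, one element per retained subject.
#' @export
summarise_measures <- function(values, mode = c("SuM", "SiM")) {
  mode <- match.arg(mode)
  values <- as.matrix(values)
  out <- if (mode == "SiM") values[, 1L] else rowMeans(values, na.rm = TRUE)
  names(out) <- rownames(values)
  bad <- !is.finite(out)
  if (any(bad)) {
    warning(sum(bad), " subject(s) without a usable ", mode,
            " value excluded", call. = FALSE)
    out <- out[!bad]
  }
  out
}

#' Inter-test correlation of per-subject endpoints
#'
#' Pearson or Spearman correlation between two per-subject scalars (e.g.
#' the same endpoint summarised from two different assays), paired by
#' subject id when both vectors are named; otherwise by position.
#'
#' @param x,y Numeric vectors (optionally named by subject id).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return List `r`, `p`, `n`, `method`. `r` is `NA` (with a warning) when
#'   either vector has zero variance among complete pairs.
#' @export
intertest_correlation <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (!is.null(names(x)) && !is.null(names(y))) {
    common <- intersect(names(x), names(y))
    x <- x[common]; y <- y[common]
  }
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance; correlation undefined", call. = FALSE)
    return(list(r = NA_real_, p = NA_real_, n = n, method = method))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = method, exact = FALSE))
  list(r = unname(ct$estimate), p = ct$p.value, n = n, method = method)
}

#' Long-format repeated measures to a subjects x sessions matrix
#'
#' @param df data.frame with columns `subject_id`, `session`, `value`.
#' @return Numeric matrix with subject rownames and one column per session.
#' @export
repeated_measures_matrix <- function(df) {
  stopifnot(all(c("subject_id", "session", "value") %in% names(df)))
  subjects <- unique(as.character(df$subject_id))
  sessions <- sort(unique(df$session))
  m <- matrix(NA_real_, length(subjects), length(sessions),
              dimnames = list(subjects, as.character(sessions)))
  m[cbind(match(as.character(df$subject_id), subjects),
          match(df$session, sessions))] <- df$value
  m
}
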