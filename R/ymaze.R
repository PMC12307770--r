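#' Classify Y-maze exploratory actions
#'
#' Scores an ordered sequence of arm visits with the sliding-window scheme:
#' every overlapping window of three consecutive visits `(x, y, z)` receives
#' exactly one label —
#' a *direct revisit* when two consecutive visits repeat an arm
#' (`x == y` or `y == z`), otherwise an *alternation* when the three visits
#' hit three different arms, otherwise an *indirect revisit*
#' (`x == z != y`, a return to the arm before last). Precedence is
#' direct > alternation > indirect, so the three labels partition all
#' windows. Pairwise same-arm repeats are additionally counted over
#' consecutive visit pairs and reported separately.
#'
#' @param arms Character vector of arm visits over the alphabet
#'   `c("A", "B", "C")` (or a `data.frame` with an `arm` column).
#' @param alphabet Permitted arm symbols; visits outside it are an error.
#' @return An object of class `action_counts`: `alternations`,
#'   `direct_revisits`, `indirect_revisits`, `n_windows`
#'   (`= max(length - 2, 0)`), and `pairwise_direct` (same-arm consecutive
#'   pairs, counted over pairs rather than triads).
#' @examples
#' classify_actions(c("A", "B", "C", "A", "B", "C"))  # 4 alternations
#' @export
classify_actions <- function(arms, alphabet = c("A", "B", "C")) {
  if (is.data.frame(arms)) arms <- arms$arm
  arms <- as.character(arms)
  if (!all(arms %in% alphabet)) {
    stop("arm symbol(s) outside alphabet {",
         paste(alphabet, collapse = ", "), "}: ",
         paste(unique(setdiff(arms, alphabet)), collapse = ", "),
         call. = FALSE)
  }
  n <- length(arms)
  nw <- max(n - 2L, 0L)
  alt <- dir <- ind <- 0L
  if (nw > 0L) {
    x <- arms[seq_len(nw)]
    y <- arms[seq_len(nw) + 1L]
    z <- arms[seq_len(nw) + 2L]
    is_dir <- x == y | y == z
    is_alt <- !is_dir & x != z            # with no repeat, x!=y, y!=z: distinct iff x!=z
    dir <- sum(is_dir)
    alt <- sum(is_alt)
    ind <- nw - dir - alt
  }
  structure(list(alternations = as.integer(alt),
                 direct_revisits = as.integer(dir),
                 indirect_revisits = as.integer(ind),
                 n_windows = nw,
                 pairwise_direct = if (n >= 2L) sum(arms[-1L] == arms[-n]) else 0L),
            class = "action_counts")
}

#' @export
print.action_counts <- function(x, ...) {
  cat("<action_counts> windows:", x$n_windows,
      "| alternations:", x$alternations,
      "| direct:", x$direct_revisits,
      "| indirect:", x$indirect_revisits, "\n")
  invisible(x)
}

#' Alternation percentage
#'
#' `100 * alternations / n_windows`; 50% corresponds to random choice under
#' the uniform no-stay policy, 100% to a perfect alternator.
#'
#' @param counts An [classify_actions()] result.
#' @return Percent, or `NA` with a warning when there are no windows.
#' @export
alternation_percent <- function(counts) {
  stopifnot(inherits(counts, "action_counts"))
  if (counts$n_windows == 0L) {
    warning("no length-3 windows; alternation percentage undefined", call. = FALSE)
    return(NA_real_)
  }
  100 * counts$alternations / counts$n_windows
}

#' Distribution of exploratory actions
#'
#' Per-subject rates of the three action types, each count divided by the
#' number of windows; rates sum to 1.
#'
#' @param counts An [classify_actions()] result.
#' @return Named numeric vector `c(alternation, direct_revisit,
#'   indirect_revisit)`, or all-`NA` with a warning when there are no windows.
#' @export
action_distribution <- function(counts) {
  stopifnot(inherits(counts, "action_counts"))
  if (counts$n_windows == 0L) {
    warning("no length-3 windows; action distribution undefined", call. = FALSE)
    return(c(alternation = NA_real_, direct_revisit = NA_real_,
             indirect_revisit = NA_real_))
  }
  c(alternation = counts$alternations,
    direct_revisit = counts$direct_revisits,
    indirect_revisit = counts$indirect_revisits) / counts$n_windows
}

#' Arm-visit sequence from a Y-maze visit sequence
#'
#' Collapses a zone visit sequence to the ordered arm labels the action
#' classifier consumes. Center-zone visits are absorbed: passing through the
#' center does not end an arm visit, only arrival at a *different* arm does,
#' so consecutive duplicates created by arm-center-arm returns are collapsed.
#'
#' @param visits A `visit_sequence` over a Y-maze arena.
#' @param center Zone id of the central zone (default `"center"`).
#' @param collapse_center_returns Collapse arm-center-same-arm into one arm
#'   visit (default `TRUE`).
#' @return Character vector of arm labels (zone ids with the `arm_` prefix
#'   stripped when present).
#' @export
arm_sequence <- function(visits, center = "center",
                         collapse_center_returns = TRUE) {
  arms <- visits$zone_id[visits$zone_id != center]
  if (collapse_center_returns && length(arms) > 1L) {
    arms <- arms[c(TRUE, arms[-1L] != arms[-length(arms)])]
  }
  sub("^arm_", "", arms)
}
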