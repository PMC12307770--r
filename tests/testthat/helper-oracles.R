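# Independent brute-force oracle for Y-maze action scoring: classifies one
# window at a time by literal case analysis (set cardinality rather than the
# vectorised comparisons the implementation uses).
oracle_classify_triple <- function(tri) {
  if (tri[1L] == tri[2L] || tri[2L] == tri[3L]) return("direct")
  if (length(unique(tri)) == 3L) return("alternation")
  "indirect"
}

oracle_counts <- function(arms) {
  labels <- character(0L)
  if (length(arms) >= 3L) {
    for (i in seq_len(length(arms) - 2L)) {
      labels <- c(labels, oracle_classify_triple(arms[i:(i + 2L)]))
    }
  }
  c(alternations = sum(labels == "alternation"),
    direct_revisits = sum(labels == "direct"),
    indirect_revisits = sum(labels == "indirect"))
}

random_arm_sequence <- function(max_len = 50L) {
  sample(c("A", "B", "C"), sample(0:max_len, 1L), replace = TRUE)
}

# Build a zone-labelled "track" directly from a run-length description:
# runs = data.frame(zone, dur) sampled at `hz`.
labelled_track <- function(runs, hz = 10, subject = "s1", session = "1") {
  zone <- unlist(mapply(function(z, d) rep(z, round(d * hz)), runs$zone,
                        runs$dur, SIMPLIFY = FALSE))
  n <- length(zone)
  out <- data.frame(subject_id = subject, session_id = session,
                    t = (seq_len(n) - 1L) / hz,
                    x = 0, y = 0, zone = unname(zone),
                    stringsAsFactors = FALSE)
  attr(out, "frame_rate") <- hz
  out
}

# Closed-form one-component Gaussian ML log-likelihood.
gauss_ml_loglik <- function(x) {
  v <- mean((x - mean(x))^2)
  sum(stats::dnorm(x, mean(x), sqrt(v), log = TRUE))
}
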