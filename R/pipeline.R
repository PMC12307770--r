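#' Run the full synthetic-to-summary analysis pipeline
#'
#' Drives every analysis stage in dependency order on simulated behavior:
#' (1) simulate plus-maze visit sequences for two groups differing in
#' avoidance and compute occupancy endpoints and anxiety scores;
#' (2) simulate Y-maze choices and classify exploratory actions;
#' (3) simulate repeated measures and estimate repeatability with bootstrap
#' CIs plus SiM/SuM inter-test correlations; (4) run the mixture modality
#' decision on a simulated endpoint population; (5) summarise the group
#' contrast as standardized effect sizes. All outputs are written as
#' CSV/JSON under `out_dir` together with a JSON run manifest (package
#' version, configuration hash, seed), and re-running with the same
#' configuration reproduces them byte-identically.
#'
#' @param config Named list; recognised fields (all with defaults):
#'   `seed` (required), `n_subjects`, `session_length` (s),
#'   `avoidance` (two group values, default `c(0, 2)`), `ymaze_n_visits`,
#'   `p_alt`, `p_direct`, `n_boot`, `k_sessions`, `sd_between`, `sd_within`,
#'   `mixture` (for modality), `stages` (subset of
#'   `c("endpoints", "ymaze", "consistency", "modality", "effects")`).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with all stage results and the manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.null(config$seed)) stop("config$seed is required", call. = FALSE)
  defaults <- list(n_subjects = 24L, session_length = 600,
                   avoidance = c(control = 0, treated = 2),
                   ymaze_n_visits = 60L, p_alt = 0.5, p_direct = 0,
                   n_boot = 1000L, k_sessions = 3L,
                   sd_between = 1, sd_within = 1,
                   mixture = list(weights = c(0.5, 0.5), means = c(0, 4),
                                  sds = c(1, 1), n = 200L),
                   stages = c("endpoints", "ymaze", "consistency",
                              "modality", "effects"))
  cfg <- utils::modifyList(defaults, config)
  if ("effects" %in% cfg$stages && !"endpoints" %in% cfg$stages) {
    stop("stage 'effects' requires stage 'endpoints'", call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list()

  if ("endpoints" %in% cfg$stages) {
    arena <- arena_preset("spm")
    groups <- names(cfg$avoidance)
    if (is.null(groups)) groups <- paste0("g", seq_along(cfg$avoidance))
    ep <- list()
    for (gi in seq_along(cfg$avoidance)) {
      sim <- simulate_visits(arena, cfg$n_subjects, cfg$session_length,
                             avoidance = cfg$avoidance[[gi]],
                             aversive_roles = "shallow_arm",
                             subject_sd = 0.3,
                             start_zone = "center",
                             seed = cfg$seed + gi)
      sm <- lapply(sim$visits, session_metrics, track = NULL, arena = arena)
      sh_ids <- zones_with_role(arena, "shallow_arm")
      sh_time <- vapply(sm, function(m)
        sum(m$zones$time_s[m$zones$zone_id %in% sh_ids]), numeric(1L))
      sh_lat <- vapply(sm, function(m)
        min(m$zones$latency_s[m$zones$zone_id %in% sh_ids]), numeric(1L))
      cens <- vapply(sm, function(m)
        all(m$zones$censored[m$zones$zone_id %in% sh_ids]), logical(1L))
      score <- anxiety_score(sh_time, sh_lat)
      ep[[gi]] <- rbind(
        endpoint_table(names(sim$visits), "1", groups[gi],
                       "shallow_time_s", sh_time),
        endpoint_table(names(sim$visits), "1", groups[gi],
                       "shallow_latency_s", sh_lat, cens),
        endpoint_table(names(sim$visits), "1", groups[gi],
                       "anxiety_score", score))
    }
    res$endpoints <- do.call(rbind, ep)
    write_endpoints_csv(res$endpoints, file.path(out_dir, "endpoints.csv"))
  }

  if ("ymaze" %in% cfg$stages) {
    seqs <- simulate_ymaze(cfg$n_subjects, cfg$ymaze_n_visits,
                           p_alt = cfg$p_alt, p_direct = cfg$p_direct,
                           seed = cfg$seed + 101L)
    counts <- lapply(seqs, classify_actions)
    res$actions <- data.frame(
      subject_id = names(counts),
      alternations = vapply(counts, `[[`, integer(1L), "alternations"),
      direct_revisits = vapply(counts, `[[`, integer(1L), "direct_revisits"),
      indirect_revisits = vapply(counts, `[[`, integer(1L), "indirect_revisits"),
      n_windows = vapply(counts, `[[`, integer(1L), "n_windows"),
      alternation_pct = vapply(counts, function(cc)
        alternation_percent(cc), numeric(1L)),
      row.names = NULL, stringsAsFactors = FALSE)
    utils::write.csv(res$actions, file.path(out_dir, "actions.csv"),
                     row.names = FALSE, quote = FALSE)
  }

  if ("consistency" %in% cfg$stages) {
    rm1 <- simulate_repeated(10, cfg$sd_between, cfg$sd_within,
                             cfg$n_subjects, cfg$k_sessions,
                             seed = cfg$seed + 202L)
    rpt <- repeatability(rm1, n_boot = cfg$n_boot, seed = cfg$seed + 203L)
    rm2 <- simulate_repeated(10, cfg$sd_between, cfg$sd_within,
                             cfg$n_subjects, cfg$k_sessions,
                             seed = cfg$seed + 204L)
    cor_sim <- intertest_correlation(summarise_measures(rm1, "SiM"),
                                     summarise_measures(rm2, "SiM"))
    cor_sum <- intertest_correlation(summarise_measures(rm1, "SuM"),
                                     summarise_measures(rm2, "SuM"))
    res$repeatability <- rpt
    res$correlations <- list(SiM = cor_sim, SuM = cor_sum)
    jsonlite::write_json(
      list(R = rpt$R, var_between = rpt$var_between,
           var_within = rpt$var_within, ci_low = rpt$ci_low,
           ci_high = rpt$ci_high, significant = rpt$significant,
           n_boot = rpt$n_boot, seed = rpt$seed,
           intertest = list(SiM = cor_sim, SuM = cor_sum)),
      file.path(out_dir, "repeatability.json"),
      auto_unbox = TRUE, digits = NA)
  }

  if ("modality" %in% cfg$stages) {
    mx <- cfg$mixture
    xs <- simulate_population_values(mx$weights, mx$means, mx$sds,
                                     n = mx$n, seed = cfg$seed + 303L)
    dec <- select_modality(xs, seed = cfg$seed + 304L)
    res$modality <- dec
    jsonlite::write_json(
      list(best_K = dec$best_K, bic_by_K = as.list(dec$bic_by_K),
           scaled_bic_by_K = as.list(dec$scaled_bic_by_K)),
      file.path(out_dir, "modality.json"), auto_unbox = TRUE, digits = NA)
  }

  if ("effects" %in% cfg$stages) {
    eptab <- res$endpoints
    groups <- unique(eptab$group)
    if (length(groups) >= 2L) {
      effs <- lapply(unique(eptab$endpoint), function(e) {
        a <- eptab$value[eptab$endpoint == e & eptab$group == groups[1L]]
        b <- eptab$value[eptab$endpoint == e & eptab$group == groups[2L]]
        standardized_effect(a, b, endpoint = e,
                            group_a = groups[1L], group_b = groups[2L])
      })
      res$effects <- effects_table(effs)
      res$composite_effect <- composite_effect(effs)
      df <- res$effects
      df$d <- fmt_num(df$d)
      utils::write.csv(df, file.path(out_dir, "effects.csv"),
                       row.names = FALSE, quote = FALSE)
    }
  }

  manifest <- list(
    package = "swimmaze",
    version = as.character(utils::packageVersion("swimmaze")),
    seed = cfg$seed,
    config_hash = config_hash(cfg),
    stages = cfg$stages)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  res$manifest <- manifest
  invisible(res)
}

# md5 of the canonical JSON serialisation of the configuration
config_hash <- function(cfg) {
  cfg <- cfg[order(names(cfg))]
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp), add = TRUE)
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}
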