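#' Run the full analysis pipeline
#'
#' Executes the standard stage order on simulated or supplied data:
#' simulate (optional) -> baseline correction -> common-average re-reference
#' -> correct-trial filter -> automated epoch screen -> condition averaging
#' -> cluster-based permutation test -> SPN quantification (cluster-derived
#' and canonical ROI) -> behavioral signal-detection statistics ->
#' lateralization -> fixed-cohort subsampling reliability. Every numeric in
#' the summary comes from a module function; the report computes nothing of
#' its own.
#'
#' @param config List (or path to a YAML file) with optional entries:
#'   `sim` (list passed to [sim_config()]), `montage_path`, `epochs_path`,
#'   `behavior_path`, `neighbor_mm` (35), `n_perm` (1000), `alpha` (0.05),
#'   `alpha_forming` (0.05), `reliability_m` (5,10,15,20,25),
#'   `reliability_n_perm` (1000), `seed` (1), `out_dir` (optional: write
#'   JSON summary, cluster JSON, and TSV tables there).
#' @return List of class `spn_pipeline`: inputs, stage outputs, and `summary`
#'   (the machine-readable result list).
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- config$seed %||% 1
  neighbor_mm <- config$neighbor_mm %||% 35
  n_perm <- config$n_perm %||% 1000
  alpha <- config$alpha %||% 0.05
  alpha_forming <- config$alpha_forming %||% 0.05
  rel_m <- config$reliability_m %||% c(5, 10, 15, 20, 25)
  rel_n_perm <- config$reliability_n_perm %||% 1000

  montage <- if (!is.null(config$montage_path)) {
    load_montage(config$montage_path)
  } else acticap64()

  if (!is.null(config$epochs_path)) {
    epochs <- read_epochs(config$epochs_path)
    behavior <- if (!is.null(config$behavior_path)) {
      readr::read_tsv(config$behavior_path, show_col_types = FALSE)
    } else {
      dplyr::mutate(epochs$epoch_table,
                    response = ifelse(.data$correct, .data$condition,
                                      ifelse(.data$condition == "symmetric",
                                             "asymmetric", "symmetric")))
    }
    cfg <- NULL
  } else {
    cfg <- do.call(sim_config, c(config$sim %||% list(), list(seed = seed)))
    behavior <- simulate_behavior(cfg)
    epochs <- simulate_epochs(cfg, montage, behavior)
  }

  # preprocessing
  epochs <- baseline_correct(epochs)
  epochs <- rereference_average(epochs)
  epochs <- filter_correct(epochs, behavior)
  screened <- screen_epochs(epochs)
  epochs <- screened$epochs
  erps <- average_conditions(epochs)

  # inference
  graph <- build_neighbor_graph(montage, neighbor_mm)
  ct <- permutation_test(erps, graph, n_perm = n_perm, alpha = alpha,
                         alpha_forming = alpha_forming,
                         seed = substream_seed(seed, 101L))
  roi_can <- canonical_roi()
  roi_cl <- cluster_roi(ct)
  spn_can <- spn_amplitude(erps, roi_can)
  spn_cl <- if (!is.null(roi_cl)) spn_amplitude(erps, roi_cl) else NULL
  t_can <- one_sample_t(spn_can$amplitude_uv, alternative = "less")
  t_cl <- if (!is.null(spn_cl)) one_sample_t(spn_cl$amplitude_uv,
                                             alternative = "less") else NULL
  peak <- peak_latency(erps, if (!is.null(roi_cl)) roi_cl else roi_can)

  # behavior
  sdt <- sdt_from_behavior(behavior)
  gate <- chance_criterion(max(table(behavior$participant)))
  t_dprime <- one_sample_t(sdt$dprime)
  t_crit <- one_sample_t(sdt$criterion)
  corr_d <- correlate_spn_behavior(spn_can, sdt[, c("participant", "dprime")])
  corr_c <- correlate_spn_behavior(spn_can, sdt[, c("participant", "criterion")])

  # lateralization on the primary ROI
  roi_li <- if (!is.null(roi_cl)) roi_cl else roi_can
  li_spn <- lateralization(erps, roi_li, type = "spn")
  li_cond <- lateralization(erps, roi_li, type = "condition")
  t_li_spn <- one_sample_t(li_spn$li[!is.na(li_spn$li)])
  t_li_cond <- one_sample_t(li_cond$li[!is.na(li_cond$li)])

  # reliability (largest balanced m only if the cohort supports max(rel_m))
  tmeans <- trial_roi_means(epochs, roi_can)
  cc <- dplyr::count(tmeans, .data$participant, .data$condition)
  m_cap <- min(cc$n)
  rel_m_use <- rel_m[rel_m <= m_cap]
  rel <- if (length(rel_m_use) > 0) {
    subsample_reliability(tmeans, rel_m_use, n_perm = rel_n_perm,
                          seed = substream_seed(seed, 102L))
  } else NULL

  summary <- list(
    seed = seed,
    n_participants = length(erps$participants),
    montage = list(n_channels = nrow(montage),
                   neighbor_mm = neighbor_mm,
                   mean_neighbors = graph$mean_degree,
                   isolated = graph$isolated),
    screening = list(n_in = sum(screened$report$counts$n_in),
                     n_removed = sum(screened$report$counts$n_removed)),
    behavior = list(chance_min_correct = gate$min_correct,
                    chance_accuracy = gate$accuracy_fraction,
                    dprime_mean = mean(sdt$dprime),
                    dprime_sd = sd(sdt$dprime),
                    dprime_t = t_dprime$t, dprime_p = t_dprime$p,
                    criterion_mean = mean(sdt$criterion),
                    criterion_sd = sd(sdt$criterion),
                    criterion_t = t_crit$t, criterion_p = t_crit$p),
    cluster = list(n_significant = sum(ct$clusters$significant),
                   clusters = ct$clusters[, setdiff(names(ct$clusters),
                                                    "electrodes")]),
    spn = list(
      canonical = list(mean_uv = mean(spn_can$amplitude_uv),
                       t = t_can$t, p = t_can$p,
                       dz = dz_from_t(t_can$t, nrow(spn_can))),
      cluster = if (!is.null(spn_cl)) list(
        mean_uv = mean(spn_cl$amplitude_uv),
        t = t_cl$t, p = t_cl$p,
        dz = dz_from_t(t_cl$t, nrow(spn_cl)),
        window_ms = roi_cl$window_ms,
        n_electrodes = length(roi_cl$electrodes)) else NULL,
      peak = peak),
    lateralization = list(spn_based = list(mean = mean(li_spn$li, na.rm = TRUE),
                                           t = t_li_spn$t, p = t_li_spn$p),
                          condition_based = list(mean = mean(li_cond$li, na.rm = TRUE),
                                                 t = t_li_cond$t, p = t_li_cond$p)),
    correlation = list(dprime = as.list(corr_d), criterion = as.list(corr_c)),
    reliability = if (!is.null(rel)) rel$curve else NULL
  )

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_cluster_results(ct, file.path(config$out_dir, "clusters.json"))
    readr::write_tsv(spn_can, file.path(config$out_dir, "spn_canonical.tsv"))
    readr::write_tsv(sdt, file.path(config$out_dir, "sdt.tsv"))
    if (!is.null(rel)) {
      readr::write_tsv(rel$curve, file.path(config$out_dir, "reliability.tsv"))
    }
  }

  structure(list(config = config, montage = montage, graph = graph,
                 behavior = behavior, epochs = epochs,
                 screen_report = screened$report, erps = erps,
                 cluster_test = ct, spn_canonical = spn_can,
                 spn_cluster = spn_cl, sdt = sdt, reliability = rel,
                 summary = summary),
            class = "spn_pipeline")
}

#' @export
print.spn_pipeline <- function(x, ...) {
  s <- x$summary
  cat("<spn_pipeline>\n")
  cat(sprintf("  participants: %d; significant clusters: %d\n",
              s$n_participants, s$cluster$n_significant))
  cat(sprintf("  canonical SPN: %.3f uV (t = %.2f, p = %.4f, dz = %.2f)\n",
              s$spn$canonical$mean_uv, s$spn$canonical$t, s$spn$canonical$p,
              s$spn$canonical$dz))
  if (!is.null(s$spn$cluster)) {
    cat(sprintf("  cluster SPN: %.3f uV in %g-%g ms (%d electrodes)\n",
                s$spn$cluster$mean_uv, s$spn$cluster$window_ms[1],
                s$spn$cluster$window_ms[2], s$spn$cluster$n_electrodes))
  }
  cat(sprintf("  behavior: d' = %.2f, c = %.2f\n",
              s$behavior$dprime_mean, s$behavior$criterion_mean))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
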