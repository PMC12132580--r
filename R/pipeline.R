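# Configuration-driven orchestration of all analysis stages.

#' Pipeline configuration
#'
#' Collects every stage's tunables with their standard defaults (WaveMAP
#' 20/0.2/1.0, 0.4 ms ISI bins, 13 ms PSTH kernel, 67 ms screen delay, 25 ms
#' jitter, 7/5 SD CCG thresholds, 500 shuffles/resamples, 120 um CSD sigma,
#' 2.3 amplitude scale) plus either a Kilosort-style input directory or a
#' synthetic cohort specification.
#'
#' @param input_dir optional Kilosort-style directory (see [read_kilosort()]).
#' @param synthetic optional list for the synthetic route: `archetypes`,
#'   `n_per_class`, `edges`, `schedule` (defaults used when omitted).
#' @param stages character vector of stages to run, in dependency order, among
#'   `"curate"`, `"cluster"`, `"laminar"`, `"tuning"`, `"isi"`,
#'   `"propagation"`, `"ccg"`.
#' @param seed global seed; all stage randomness derives from it.
#' @param ... overrides for individual tunables (see the listed defaults in
#'   the function definition).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir = NULL, synthetic = NULL,
                            stages = c("curate", "cluster", "laminar",
                                       "tuning", "isi", "propagation", "ccg"),
                            seed = 1L, ...) {
  defaults <- list(
    snr_lo = 0, snr_hi = 3.7, theta_tri = 0.3, scale_to_uV = 2.3,
    n_neighbors = 20L, min_dist = 0.2, resolution = 1.0,
    csd_sigma_um = 120,
    psth_kernel_ms = 13, screen_delay_ms = 67,
    isi_bin_ms = 0.4, isi_max_ms = 100,
    n_shuffles = 500L, n_resamples = 500L,
    ccg_window_s = c(0.4, 1.0), ccg_bin_ms = 1, ccg_max_lag_ms = 100,
    jitter_ms = 25, z_excitatory = 7, z_inhibitory = 5, ca_window_ms = 10)
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown)) stop("unknown tunables: ", paste(unknown, collapse = ", "))
  defaults[names(over)] <- over
  if (is.null(input_dir) && is.null(synthetic)) {
    stop("config needs an input_dir or a synthetic cohort specification")
  }
  stages <- match.arg(stages, several.ok = TRUE)
  structure(c(list(input_dir = input_dir, synthetic = synthetic,
                   stages = stages, seed = as.integer(seed)), defaults),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Loads (or synthesizes) a session, then runs the requested stages in
#' dependency order: curation -> waveform clustering -> laminar mapping ->
#' tuning -> ISI/bursting -> multichannel propagation -> CCG connectivity.
#' Deterministic for a fixed config and seed.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, every result table is
#'   written as CSV/JSON.
#' @return Object of class `analysis_report`: named list of stage results plus
#'   a `provenance` block (seed, config, package version) and `summary`
#'   statistics.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  seeds <- child_seeds(config$seed, 8L)
  report <- list(provenance = list(
    seed = config$seed,
    package_version = as.character(utils::packageVersion("lamwave")),
    config = unclass(config)))

  # ---- load or synthesize -------------------------------------------------
  if (!is.null(config$input_dir)) {
    ses <- read_kilosort(config$input_dir)
    units <- ses$units
    trials <- ses$trials
    boundaries <- if (!is.null(ses$boundaries)) {
      layer_boundaries(ses$boundaries)
    } else default_layer_boundaries()
  } else {
    sy <- config$synthetic
    cohort <- make_cohort(
      archetypes = sy$archetypes %||% default_archetypes()[1:9],
      n_per_class = sy$n_per_class %||% 10L,
      schedule = sy$schedule %||% stimulus_schedule(),
      edges = sy$edges, seed = seeds[1])
    tbl <- synth_spikes(cohort, seed = seeds[2])
    units <- lapply(names(cohort$units), function(id) {
      u <- cohort$units[[id]]
      u$spike_times_s <- tbl$spikes[[id]]
      u
    })
    names(units) <- names(cohort$units)
    trials <- tbl$trials
    boundaries <- cohort$boundaries
    report$ground_truth <- list(cohort = cohort, counts = tbl$counts)
  }
  if ("ccg" %in% config$stages &&
      all(lengths(lapply(units, function(u) u$spike_times_s %||% numeric())) == 0)) {
    stop("ccg stage requires spike input; none found")
  }

  # ---- curate -------------------------------------------------------------
  cur <- curate_units(units, config$snr_lo, config$snr_hi, config$theta_tri)
  units <- cur$units
  report$curation <- cur$features
  if (length(units) == 0) stop("curation removed all units")
  meta <- data.frame(unit_id = vapply(units, `[[`, "", "unit_id"),
                     depth_um = vapply(units, `[[`, 0, "depth_um"),
                     snr = vapply(units, `[[`, 0, "snr"),
                     polarity = vapply(units, `[[`, "", "polarity"),
                     row.names = NULL)

  # ---- cluster ------------------------------------------------------------
  if ("cluster" %in% config$stages) {
    neg <- vapply(units, function(u) u$polarity == "negative", TRUE)
    wf <- t(vapply(units[neg], `[[`, numeric(length(units[[1]]$normalized)),
                   "normalized"))
    wm <- build_wavemap(wf, config$n_neighbors, config$min_dist,
                        config$resolution, seed = seeds[3])
    labels <- rep(NA_integer_, length(units))
    labels[neg] <- canonicalize_clusters(
      wm$labels, report$curation$ttp_width_ms[neg])
    meta$cluster <- labels
    report$clustering <- list(wavemap = wm,
                              table = data.frame(unit_id = meta$unit_id[neg],
                                                 label = labels[neg],
                                                 u1 = wm$embedding[, 1],
                                                 u2 = wm$embedding[, 2]))
  } else meta$cluster <- rep(1L, nrow(meta))

  # ---- laminar ------------------------------------------------------------
  scaled <- scale_depths(meta$depth_um, boundaries, boundaries)
  meta$layer <- scaled$layer
  meta$scaled_depth_um <- scaled$scaled_depth_um
  if ("laminar" %in% config$stages) {
    ns_units <- !is.na(meta$cluster) &
      report$curation$ttp_width_ms < 0.4 & !report$curation$triphasic
    grp <- c("2/3" = "2/3", "4A/B" = "4", "4C" = "4", "5/6" = "5/6")
    counts <- table(factor(grp[meta$layer[ns_units]], c("2/3", "4", "5/6")))
    report$laminar <- list(
      depth_table = cbind(meta["unit_id"], scaled),
      ns_layer_test = if (sum(counts) > 0) layer_chi_square(as.integer(counts))
      else NULL)
  }

  # ---- tuning -------------------------------------------------------------
  if ("tuning" %in% config$stages) {
    tun <- lapply(units, function(u) {
      tuning_analysis(u$spike_times_s, trials,
                      screen_delay_ms = config$screen_delay_ms)
    })
    report$tuning <- data.frame(
      unit_id = meta$unit_id,
      DI = vapply(tun, `[[`, 0, "DI"),
      OI = vapply(tun, `[[`, 0, "OI"),
      F1F0 = vapply(tun, `[[`, 0, "modulation_ratio"),
      cell_form = vapply(tun, function(x) x$cell_form %||% NA_character_, ""),
      latency_ms = vapply(tun, `[[`, 0, "latency_ms"),
      responsive = vapply(tun, `[[`, TRUE, "responsive"),
      preferred_direction = vapply(tun, function(x) x$preferred$direction_deg, 0),
      row.names = NULL)
  }

  # ---- isi ----------------------------------------------------------------
  if ("isi" %in% config$stages) {
    profs <- lapply(units, function(u) {
      isi_histogram(u$spike_times_s, config$isi_bin_ms, config$isi_max_ms)
    })
    hm <- t(vapply(profs, `[[`, numeric(length(profs[[1]]$hist)), "hist"))
    pca <- isi_pca(hm, bin_ms = config$isi_bin_ms)
    bi <- bursting_index(pca)
    report$isi <- list(hist_matrix = hm, pca = pca,
                       table = data.frame(unit_id = meta$unit_id,
                                          l1 = pca$loadings[, 1],
                                          l2 = pca$loadings[, 2],
                                          l3 = pca$loadings[, 3],
                                          bursting_index = bi,
                                          row.names = NULL))
    ok <- !is.na(meta$cluster)
    if (length(unique(meta$cluster[ok])) >= 2) {
      report$isi$shuffle <- shuffle_test(bi[ok], meta$cluster[ok],
                                         config$n_shuffles, seed = seeds[4])
    }
  }

  # ---- propagation --------------------------------------------------------
  if ("propagation" %in% config$stages) {
    prop <- lapply(units, function(u) propagation_profile(u$template))
    ptab <- data.frame(
      unit_id = meta$unit_id,
      v_inv_above = vapply(prop, `[[`, 0, "v_inv_above"),
      v_inv_below = vapply(prop, `[[`, 0, "v_inv_below"),
      si_signed = vapply(prop, `[[`, 0, "si_signed"),
      si_unsigned = vapply(prop, `[[`, 0, "si_unsigned"),
      row.names = NULL)
    report$propagation <- list(table = ptab)
    ok <- !is.na(meta$cluster) & !is.na(ptab$v_inv_below)
    if (length(unique(meta$cluster[ok])) >= 2 &&
        all(table(meta$cluster[ok]) >= 3)) {
      report$propagation$bootstrap <- bootstrap_compare(
        ptab$v_inv_below[ok], meta$cluster[ok], config$n_resamples,
        seed = seeds[5])
    }
  }

  # ---- ccg ----------------------------------------------------------------
  if ("ccg" %in% config$stages) {
    spikes <- lapply(units, `[[`, "spike_times_s")
    names(spikes) <- meta$unit_id
    pairs <- analyze_ccg_pairs(spikes, trials, meta,
                               window_s = config$ccg_window_s,
                               bin_ms = config$ccg_bin_ms,
                               max_lag_ms = config$ccg_max_lag_ms,
                               jitter_ms = config$jitter_ms)
    report$ccg <- list(pairs = pairs, graph = cluster_pair_graph(pairs))
  }

  report$summary <- list(
    n_units = nrow(meta),
    n_clusters = length(unique(stats::na.omit(meta$cluster))),
    fraction_narrow = mean(report$curation$ttp_width_ms < 0.4 &
                             !report$curation$triphasic, na.rm = TRUE),
    layer_counts = table(meta$layer),
    n_significant_ccg = if (!is.null(report$ccg)) {
      sum(report$ccg$pairs$kind != "ns")
    } else NA_integer_)
  report$meta <- meta
  class(report) <- "analysis_report"
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Write an analysis report's tables to disk
#'
#' @param report an `analysis_report`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(x, f) utils::write.csv(x, file.path(dir, f), row.names = FALSE)
  wcsv(report$curation, "features.csv")
  wcsv(report$meta, "units.csv")
  if (!is.null(report$clustering)) wcsv(report$clustering$table, "clusters.csv")
  if (!is.null(report$laminar)) wcsv(report$laminar$depth_table, "depths.csv")
  if (!is.null(report$tuning)) wcsv(report$tuning, "tuning.csv")
  if (!is.null(report$isi)) wcsv(report$isi$table, "isi.csv")
  if (!is.null(report$propagation)) wcsv(report$propagation$table, "propagation.csv")
  if (!is.null(report$ccg)) {
    wcsv(report$ccg$pairs, "ccg_pairs.csv")
    if (!is.null(report$ccg$graph$edges)) wcsv(report$ccg$graph$edges, "ccg_edges.csv")
  }
  jsonlite::write_json(
    list(provenance = list(seed = report$provenance$seed,
                           package_version = report$provenance$package_version),
         summary = report$summary["n_units" != "" | TRUE]),
    file.path(dir, "report.json"), auto_unbox = TRUE, force = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.analysis_report <- function(x, ...) {
  s <- x$summary
  cat("<analysis_report> ", s$n_units, " units, ", s$n_clusters, " clusters, ",
      round(100 * s$fraction_narrow, 1), "% narrow-spiking",
      if (!is.na(s$n_significant_ccg)) {
        paste0(", ", s$n_significant_ccg, " significant CCG pairs")
      } else "", "\n", sep = "")
  invisible(x)
}
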