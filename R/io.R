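# Plain-text reader/writer for a Kilosort-style output convention.
#
# Kilosort proper stores .npy arrays; this package emits the same logical
# arrays (spike_times, spike_clusters, templates, channel_positions) as CSV
# files so that synthetic sessions round-trip as text, plus the trial table and
# a ground-truth JSON sidecar.

#' Write a synthetic session as a Kilosort-style directory
#'
#' @param cohort a [make_cohort()] result.
#' @param spike_table the matching [synth_spikes()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_kilosort <- function(cohort, spike_table, dir) {
  stopifnot(inherits(cohort, "gt_cohort"),
            inherits(spike_table, "trial_spike_table"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- names(cohort$units)
  n_sp <- lengths(spike_table$spikes)
  all_t <- unlist(spike_table$spikes, use.names = FALSE)
  all_c <- rep(seq_along(ids) - 1L, n_sp) # 0-based cluster ids as in Kilosort
  ord <- order(all_t)
  fs <- cohort$units[[1]]$template$sampling_rate_hz
  utils::write.csv(data.frame(sample = round(all_t[ord] * fs),
                              time_s = all_t[ord]),
                   file.path(dir, "spike_times.csv"), row.names = FALSE)
  utils::write.csv(data.frame(cluster = all_c[ord]),
                   file.path(dir, "spike_clusters.csv"), row.names = FALSE)
  tmpl <- do.call(rbind, lapply(seq_along(ids), function(i) {
    v <- cohort$units[[i]]$template$voltages
    data.frame(cluster = i - 1L,
               sample = rep(seq_len(nrow(v)), ncol(v)),
               channel = rep(seq_len(ncol(v)), each = nrow(v)),
               voltage = as.vector(v))
  }))
  utils::write.csv(tmpl, file.path(dir, "templates.csv"), row.names = FALSE)
  pos <- do.call(rbind, lapply(seq_along(ids), function(i) {
    p <- cohort$units[[i]]$template$channel_positions_um
    data.frame(cluster = i - 1L, channel = seq_len(nrow(p)),
               x_um = p$x, y_um = p$y)
  }))
  utils::write.csv(pos, file.path(dir, "channel_positions.csv"),
                   row.names = FALSE)
  utils::write.csv(spike_table$trials, file.path(dir, "trials.csv"),
                   row.names = FALSE)
  gt <- list(
    seed = cohort$seed,
    units = data.frame(
      cluster = seq_along(ids) - 1L, unit_id = ids,
      archetype = vapply(cohort$units, `[[`, "", "archetype"),
      depth_um = vapply(cohort$units, `[[`, 0, "depth_um"),
      layer = vapply(cohort$units, `[[`, "", "layer"),
      snr = vapply(cohort$units, `[[`, 0, "snr"),
      row.names = NULL),
    edges = cohort$edges,
    boundaries = cohort$boundaries$edges,
    sampling_rate_hz = fs)
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a Kilosort-style directory written by [write_kilosort()]
#'
#' @param dir directory path.
#' @return List with `units` (named list: `unit_id`, `spike_times_s`,
#'   `template` as a `waveform_template`, plus ground-truth `archetype`,
#'   `depth_um`, `layer`, `snr`), `trials` data frame, `edges`, `boundaries`
#'   and `seed`.
#' @export
read_kilosort <- function(dir) {
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                            simplifyVector = TRUE)
  st <- utils::read.csv(file.path(dir, "spike_times.csv"))
  sc <- utils::read.csv(file.path(dir, "spike_clusters.csv"))
  tmpl <- utils::read.csv(file.path(dir, "templates.csv"))
  pos <- utils::read.csv(file.path(dir, "channel_positions.csv"))
  trials <- utils::read.csv(file.path(dir, "trials.csv"))
  units <- lapply(seq_len(nrow(gt$units)), function(i) {
    cl <- gt$units$cluster[i]
    tv <- tmpl[tmpl$cluster == cl, ]
    v <- matrix(tv$voltage, nrow = max(tv$sample), ncol = max(tv$channel))
    p <- pos[pos$cluster == cl, ]
    tpl <- structure(
      list(voltages = v, sampling_rate_hz = gt$sampling_rate_hz,
           channel_positions_um = data.frame(x = p$x_um, y = p$y_um),
           soma_channel = (ncol(v) + 1L) %/% 2L, scale_to_uV = 2.3),
      class = "waveform_template")
    list(unit_id = gt$units$unit_id[i],
         spike_times_s = st$time_s[sc$cluster == cl],
         template = tpl,
         archetype = gt$units$archetype[i],
         depth_um = gt$units$depth_um[i],
         layer = gt$units$layer[i],
         snr = gt$units$snr[i])
  })
  names(units) <- gt$units$unit_id
  list(units = units, trials = trials, edges = gt$edges,
       boundaries = gt$boundaries, seed = gt$seed)
}
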