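# Laminar structure: current source density, depth scaling to a common
# reference, and layer-distribution tests.

#' Current source density by the five-point formula
#'
#' Estimates the CSD as minus the second spatial derivative of the LFP along
#' the probe, using the five-point stencil (-1, 16, -30, 16, -1)/(12 h^2)
#' (edges truncated: no CSD on the outermost two channels), smoothed across
#' space with a Gaussian (sigma = 120 um by default, renormalized over valid
#' channels). Sinks are negative. The sink-source reversal depth is the lower
#' (deeper) zero crossing of the dominant sink, where "dominant" means the
#' connected negative region of the time-averaged CSD profile with the largest
#' integrated magnitude over the analysis window.
#'
#' @param lfp channels x time matrix (channel order = increasing depth), or a
#'   [synth_lfp()] result.
#' @param channel_depths_um channel depths (um; required when `lfp` is a bare
#'   matrix and spacing is not uniform).
#' @param times_s optional time axis (s) matching the columns.
#' @param sigma_um spatial smoothing sd (um).
#' @param window_s analysis window for the sink search (s, relative to the
#'   time axis; default 0 to 0.1).
#' @return Object of class `csd_result`: `csd` (channels x time, NA on the
#'   truncated edge channels), `profile` (time-averaged CSD over the window),
#'   `channel_depths_um`, `sigma_um`, `reversal_depth_um`.
#' @export
compute_csd <- function(lfp, channel_depths_um = NULL, times_s = NULL,
                        sigma_um = 120, window_s = c(0, 0.1)) {
  if (is.list(lfp) && !is.null(lfp$lfp)) {
    channel_depths_um <- channel_depths_um %||% lfp$channel_depths_um
    times_s <- times_s %||% lfp$times_s
    lfp <- lfp$lfp
  }
  stopifnot(is.matrix(lfp))
  nc <- nrow(lfp)
  if (nc < 5) stop("five-point formula undefined for fewer than 5 channels")
  if (is.null(channel_depths_um)) channel_depths_um <- seq_len(nc)
  stopifnot(length(channel_depths_um) == nc, !is.unsorted(channel_depths_um))
  h <- diff(channel_depths_um)
  if (max(h) - min(h) > 1e-6 * mean(h)) {
    stop("five-point formula requires uniform channel spacing")
  }
  h_um <- mean(h)
  h_mm <- h_um / 1000
  valid <- 3:(nc - 2)
  d2 <- (-lfp[valid - 2, , drop = FALSE] + 16 * lfp[valid - 1, , drop = FALSE] -
           30 * lfp[valid, , drop = FALSE] + 16 * lfp[valid + 1, , drop = FALSE] -
           lfp[valid + 2, , drop = FALSE]) / (12 * h_mm^2)
  csd_valid <- -d2 # sinks negative
  # Gaussian smoothing across space with edge renormalization
  if (sigma_um > 0) {
    z <- channel_depths_um[valid]
    wts <- outer(z, z, function(a, b) stats::dnorm(a - b, sd = sigma_um))
    wts <- wts / rowSums(wts)
    csd_valid <- wts %*% csd_valid
  }
  csd <- matrix(NA_real_, nc, ncol(lfp))
  csd[valid, ] <- csd_valid
  # time-averaged profile over the analysis window
  cols <- if (!is.null(times_s)) {
    which(times_s >= window_s[1] & times_s <= window_s[2])
  } else seq_len(ncol(lfp))
  if (length(cols) == 0) cols <- seq_len(ncol(lfp))
  profile <- rowMeans(csd[, cols, drop = FALSE])
  reversal <- find_sink_reversal(profile[valid], channel_depths_um[valid])
  structure(list(csd = csd, profile = profile,
                 channel_depths_um = channel_depths_um,
                 sigma_um = sigma_um, reversal_depth_um = reversal),
            class = "csd_result")
}

# Lower edge of the dominant sink: largest-|integral| connected negative run,
# zero crossing below (deeper than) its extremum, linearly interpolated.
find_sink_reversal <- function(profile, depths) {
  neg <- profile < 0
  if (!any(neg)) return(NA_real_)
  runs <- rle(neg)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  neg_runs <- which(runs$values)
  mass <- vapply(neg_runs, function(i) {
    sum(abs(profile[starts[i]:ends[i]]))
  }, 0)
  i <- neg_runs[which.max(mass)]
  seg <- starts[i]:ends[i]
  i_ext <- seg[which.min(profile[seg])]
  # first sign change at or below the sink's deep end
  j <- ends[i]
  if (j >= length(profile)) return(depths[j])
  # interpolate zero between j (negative) and j+1 (non-negative)
  frac <- profile[j] / (profile[j] - profile[j + 1])
  depths[j] + frac * (depths[j + 1] - depths[j])
}

#' Scale unit depths onto reference laminar boundaries
#'
#' Piecewise-linear map sending each session layer interval onto the matching
#' reference interval; inverted (calcarine) sessions are flipped about the
#' session span first. Each scaled depth gets the layer label of the reference
#' interval containing it. The map is the identity when session and reference
#' boundaries coincide, and fixes every shared boundary exactly.
#'
#' @param depths_um unit depths within the session span (um from pia).
#' @param session a [layer_boundaries()] for the session (set
#'   `inverted = TRUE` for calcarine sessions).
#' @param reference a [layer_boundaries()] for the common reference (e.g.
#'   [reference_boundaries()] over sessions).
#' @return Data frame: `depth_um` (input), `scaled_depth_um`, `layer`,
#'   `rel_depth_um` (scaled depth relative to the reference 4C|5/6 anchor,
#'   positive above the anchor).
#' @export
scale_depths <- function(depths_um, session, reference) {
  stopifnot(inherits(session, "layer_boundaries"),
            inherits(reference, "layer_boundaries"))
  d <- depths_um
  edges <- session$edges
  if (session$inverted) {
    span <- range(edges)
    d <- span[2] + span[1] - d
  }
  if (any(d < edges[1] - 1e-9 | d > edges[6] + 1e-9)) {
    stop("depth outside the session span")
  }
  scaled <- stats::approx(edges, reference$edges, xout = d, rule = 2)$y
  data.frame(depth_um = depths_um,
             scaled_depth_um = scaled,
             layer = layer_of(scaled, reference),
             rel_depth_um = reference$anchor - scaled)
}

#' Average session boundaries into a common reference
#'
#' @param sessions list of [layer_boundaries()]; inverted sessions are flipped
#'   before averaging.
#' @return A [layer_boundaries()] whose edges are the arithmetic mean.
#' @export
reference_boundaries <- function(sessions) {
  mats <- vapply(sessions, function(b) {
    e <- b$edges
    if (b$inverted) rev(max(e) + min(e) - e) else e
  }, numeric(6))
  layer_boundaries(rowMeans(mats))
}

#' Chi-square test of layer counts against a uniform distribution
#'
#' Pearson goodness-of-fit statistic sum((O-E)^2/E) with uniform expected
#' counts and `df = groups - 1`.
#'
#' @param observed_counts integer counts per layer group (length >= 2).
#' @return Object of class `layer_test`: `observed`, `expected`, `chi2`,
#'   `df`, `p`.
#' @export
layer_chi_square <- function(observed_counts) {
  k <- length(observed_counts)
  stopifnot(k >= 2, sum(observed_counts) > 0)
  expected <- rep(sum(observed_counts) / k, k)
  if (any(expected == 0)) stop("zero expected count")
  chi2 <- sum((observed_counts - expected)^2 / expected)
  df <- k - 1L
  structure(list(observed = observed_counts, expected = expected,
                 chi2 = chi2, df = df,
                 p = stats::pchisq(chi2, df, lower.tail = FALSE)),
            class = "layer_test")
}

#' @export
print.layer_test <- function(x, ...) {
  cat(sprintf("chi^2 (%d, %d) = %.4f, p = %.3g\n",
              x$df, sum(x$observed), x$chi2, x$p))
  invisible(x)
}
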