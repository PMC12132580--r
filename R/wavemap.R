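# WaveMAP: UMAP fuzzy-graph construction + Louvain community detection on the
# graph (never on the 2-D projection), plus clustering validation tools.

# Fuzzy simplicial-set graph and 2-D embedding from uwot, deterministic for a
# fixed seed. Degenerate inputs (all waveforms identical) short-circuit.
umap_graph <- function(x, n_neighbors, min_dist, seed) {
  # init = "spca" rather than the spectral default: deterministic and robust
  # when the fuzzy graph is disconnected (well-separated families); cluster
  # labels never depend on the layout.
  res <- uwot::umap(x, n_neighbors = n_neighbors, min_dist = min_dist,
                    n_threads = 1, seed = seed, batch = TRUE, init = "spca",
                    ret_extra = c("fgraph"))
  list(embedding = res$embedding, fgraph = res$fgraph)
}

#' WaveMAP clustering of normalized waveforms
#'
#' Applies UMAP to the normalized soma waveforms to obtain the fuzzy
#' simplicial-set neighbor graph, then partitions that graph with Louvain
#' community detection at the given resolution. The 2-D embedding is retained
#' for visualization only; labels are a function of the graph alone.
#'
#' @param waveforms numeric matrix, units x samples, each row aligned and
#'   normalized so its extremum is -1 or +1 (see [align_normalize()]).
#' @param n_neighbors UMAP neighborhood size (default 20).
#' @param min_dist UMAP minimum embedding distance (default 0.2).
#' @param resolution Louvain resolution parameter (default 1.0).
#' @param seed integer seed (UMAP graph + Louvain vertex order).
#' @return Object of class `wavemap_clustering`: `labels` (integer per unit),
#'   `embedding` (units x 2), `modularity`, `graph` (sparse symmetric weight
#'   matrix), `params`.
#' @export
build_wavemap <- function(waveforms, n_neighbors = 20L, min_dist = 0.2,
                          resolution = 1.0, seed = 42L) {
  stopifnot(is.matrix(waveforms))
  n <- nrow(waveforms)
  if (n < n_neighbors) stop("fewer waveforms than n_neighbors")
  if (all(abs(sweep(waveforms, 2, waveforms[1, ])) < 1e-12)) {
    # zero-variance input: a single community by definition
    return(structure(list(labels = rep(1L, n),
                          embedding = matrix(0, n, 2),
                          modularity = 0, graph = NULL,
                          params = list(n_neighbors = n_neighbors,
                                        min_dist = min_dist,
                                        resolution = resolution, seed = seed)),
                     class = "wavemap_clustering"))
  }
  ug <- umap_graph(waveforms, n_neighbors, min_dist, seed)
  part <- louvain_partition(ug$fgraph, resolution, seed)
  structure(list(labels = part$labels, embedding = ug$embedding,
                 modularity = part$modularity, graph = ug$fgraph,
                 params = list(n_neighbors = n_neighbors, min_dist = min_dist,
                               resolution = resolution, seed = seed)),
            class = "wavemap_clustering")
}

louvain_partition <- function(fgraph, resolution, seed) {
  g <- igraph::graph_from_adjacency_matrix(fgraph, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  cl <- with_seed(seed, igraph::cluster_louvain(g, resolution = resolution))
  # standard (resolution-1) modularity of the found partition, so values are
  # comparable across the resolution grid when sweeping
  q <- igraph::modularity(g, igraph::membership(cl),
                          weights = igraph::E(g)$weight)
  list(labels = as.integer(igraph::membership(cl)), modularity = q)
}

#' @export
print.wavemap_clustering <- function(x, ...) {
  cat("<wavemap_clustering> ", length(x$labels), " units, ",
      length(unique(x$labels)), " clusters, modularity ",
      round(x$modularity, 3), " (resolution ", x$params$resolution, ")\n",
      sep = "")
  invisible(x)
}

#' Louvain resolution sweep
#'
#' For each resolution on the grid, re-clusters `n_runs` random 80% subsamples
#' of the waveforms (each with its own seed) and records the mean and standard
#' deviation of the modularity and of the cluster count. The chosen resolution
#' maximizes mean modularity; ties go to the smallest resolution.
#'
#' @param waveforms normalized waveform matrix (units x samples).
#' @param resolutions resolution grid (default 0 to 10 in 0.5 steps).
#' @param n_runs subsample runs per resolution (default 25).
#' @param subsample_frac fraction of units per run (default 0.8).
#' @param n_neighbors,min_dist UMAP graph parameters.
#' @param seed integer seed for the run seeds.
#' @return Object of class `resolution_sweep`: data frame `sweep`
#'   (resolution, modularity_mean, modularity_sd, n_clusters_mean,
#'   n_clusters_sd) and `chosen_resolution`.
#' @export
resolution_sweep <- function(waveforms, resolutions = seq(0, 10, by = 0.5),
                             n_runs = 25L, subsample_frac = 0.8,
                             n_neighbors = 20L, min_dist = 0.2, seed = 42L) {
  stopifnot(length(resolutions) > 0)
  n <- nrow(waveforms)
  m <- max(2L, round(subsample_frac * n))
  if (m < n_neighbors) stop("subsample too small for n_neighbors")
  run_seeds <- child_seeds(seed, n_runs)
  mod <- matrix(NA_real_, n_runs, length(resolutions))
  ncl <- matrix(NA_real_, n_runs, length(resolutions))
  for (r in seq_len(n_runs)) {
    idx <- with_seed(run_seeds[r], sample.int(n, m))
    ug <- umap_graph(waveforms[idx, , drop = FALSE], n_neighbors, min_dist,
                     run_seeds[r])
    for (j in seq_along(resolutions)) {
      part <- louvain_partition(ug$fgraph, resolutions[j], run_seeds[r])
      mod[r, j] <- part$modularity
      ncl[r, j] <- length(unique(part$labels))
    }
  }
  sweep_df <- data.frame(
    resolution = resolutions,
    modularity_mean = colMeans(mod),
    modularity_sd = apply(mod, 2, stats::sd),
    n_clusters_mean = colMeans(ncl),
    n_clusters_sd = apply(ncl, 2, stats::sd))
  chosen <- resolutions[which.max(sweep_df$modularity_mean)]
  structure(list(sweep = sweep_df, chosen_resolution = chosen),
            class = "resolution_sweep")
}

# ---- gradient-boosted decision stumps (one-vs-rest logistic loss) ----------
# No boosted-tree library is assumed; this is a compact gradient-boosting
# machine with depth-1 trees: each round fits the best single-feature split to
# the logistic pseudo-residuals, with shrinkage.

fit_stump <- function(x_ord, ord, r) {
  # x_ord: presorted feature values; ord: their original indices; r: residuals
  n <- length(r)
  rs <- r[ord]
  cs <- cumsum(rs)
  tot <- cs[n]
  nl <- seq_len(n - 1)
  gain <- cs[nl]^2 / nl + (tot - cs[nl])^2 / (n - nl)
  # forbid splits between equal values
  valid <- x_ord[nl] < x_ord[nl + 1]
  if (!any(valid)) return(NULL)
  gain[!valid] <- -Inf
  i <- which.max(gain)
  list(threshold = (x_ord[i] + x_ord[i + 1]) / 2,
       left = cs[i] / i, right = (tot - cs[i]) / (n - i),
       gain = gain[i] - tot^2 / n)
}

boost_train <- function(x, y, n_rounds = 50L, shrinkage = 0.1) {
  classes <- sort(unique(y))
  n <- nrow(x)
  p <- ncol(x)
  orders <- lapply(seq_len(p), function(j) order(x[, j]))
  xs <- lapply(seq_len(p), function(j) x[orders[[j]], j])
  models <- lapply(classes, function(k) {
    yk <- as.numeric(y == k)
    f <- rep(0, n)
    stumps <- vector("list", n_rounds)
    for (m in seq_len(n_rounds)) {
      prob <- 1 / (1 + exp(-f))
      r <- yk - prob
      best <- NULL
      for (j in seq_len(p)) {
        s <- fit_stump(xs[[j]], orders[[j]], r)
        if (!is.null(s) && (is.null(best) || s$gain > best$gain)) {
          best <- s
          best$feature <- j
        }
      }
      if (is.null(best)) break
      contrib <- ifelse(x[, best$feature] <= best$threshold,
                        best$left, best$right)
      f <- f + shrinkage * contrib
      stumps[[m]] <- best
    }
    stumps[!vapply(stumps, is.null, TRUE)]
  })
  list(classes = classes, models = models, shrinkage = shrinkage)
}

boost_predict <- function(fit, x) {
  scores <- vapply(fit$models, function(stumps) {
    f <- rep(0, nrow(x))
    for (s in stumps) {
      f <- f + fit$shrinkage *
        ifelse(x[, s$feature] <= s$threshold, s$left, s$right)
    }
    f
  }, numeric(nrow(x)))
  fit$classes[max.col(matrix(scores, nrow = nrow(x)), ties.method = "first")]
}

#' Cluster separability by cross-validated classification
#'
#' Trains a gradient-boosted decision-tree classifier (one-vs-rest logistic
#' boosting on decision stumps) with stratified k-fold cross-validation and
#' reports the out-of-fold confusion matrix (rows = true cluster, normalized
#' to percent) and the mean diagonal accuracy.
#'
#' @param waveforms normalized waveform matrix (units x samples).
#' @param labels cluster labels (one per unit; every class needs >= `folds`
#'   members).
#' @param folds number of CV folds (default 5).
#' @param n_rounds boosting rounds per class (default 50).
#' @param seed integer seed for the fold assignment.
#' @return Object of class `separability_report`: `confusion` (K x K percent
#'   matrix), `mean_accuracy` (percent).
#' @export
separability_cv <- function(waveforms, labels, folds = 5L, n_rounds = 50L,
                            seed = 42L) {
  stopifnot(nrow(waveforms) == length(labels))
  labels <- as.vector(labels)
  tab <- table(labels)
  if (any(tab < folds)) {
    stop("every class needs at least `folds` members; too small: ",
         paste(names(tab)[tab < folds], collapse = ", "))
  }
  classes <- sort(unique(labels))
  fold_of <- integer(length(labels))
  with_seed(seed, {
    for (k in classes) {
      idx <- which(labels == k)
      fold_of[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
  })
  pred <- vector(mode = mode(classes), length(labels))
  for (fd in seq_len(folds)) {
    tr <- fold_of != fd
    fit <- boost_train(waveforms[tr, , drop = FALSE], labels[tr],
                       n_rounds = n_rounds)
    pred[!tr] <- boost_predict(fit, waveforms[!tr, , drop = FALSE])
  }
  conf <- table(factor(labels, classes), factor(pred, classes))
  conf <- sweep(conf, 1, rowSums(conf), "/") * 100
  structure(list(confusion = unclass(conf),
                 mean_accuracy = mean(diag(conf))),
            class = "separability_report")
}

#' Map a low-resolution partition onto a high-resolution one
#'
#' Reports, for each low-resolution cluster, which high-resolution clusters it
#' absorbs (by majority membership of the high-resolution cluster) and whether
#' the low-resolution partition is a coarsening of the high-resolution one
#' (every high-resolution cluster has at least `coarsening_frac` of its units
#' inside a single low-resolution cluster).
#'
#' @param labels_low,labels_high label vectors over the same units.
#' @param coarsening_frac majority threshold (default 0.9).
#' @return List with `mapping` (named list low -> high cluster ids),
#'   `absorbed_fraction` (per high-resolution cluster), `coarsening` flag.
#' @export
merge_map <- function(labels_low, labels_high, coarsening_frac = 0.9) {
  if (length(labels_low) != length(labels_high)) {
    stop("partitions cover different unit sets")
  }
  tab <- table(labels_high, labels_low)
  frac_in_major <- apply(tab, 1, max) / rowSums(tab)
  major_low <- colnames(tab)[apply(tab, 1, which.max)]
  mapping <- split(rownames(tab), major_low)
  list(mapping = mapping,
       absorbed_fraction = stats::setNames(as.numeric(frac_in_major),
                                           rownames(tab)),
       coarsening = all(frac_in_major >= coarsening_frac))
}

#' Canonicalize cluster labels by waveform width
#'
#' Renames integer clusters within each polarity group by descending median
#' trough-to-peak width, giving stable broad-to-narrow ordering (1 = broadest)
#' regardless of the arbitrary Louvain label order.
#'
#' @param labels integer cluster labels.
#' @param ttp_width_ms per-unit trough-to-peak widths.
#' @param polarity optional per-unit polarity; clusters are renumbered within
#'   each polarity group separately.
#' @return Integer labels renumbered 1..K (per polarity group).
#' @export
canonicalize_clusters <- function(labels, ttp_width_ms, polarity = NULL) {
  if (is.null(polarity)) polarity <- rep("negative", length(labels))
  out <- integer(length(labels))
  for (pg in unique(polarity)) {
    sel <- polarity == pg
    med <- tapply(ttp_width_ms[sel], labels[sel], stats::median)
    rank_map <- stats::setNames(rank(-med, ties.method = "first"), names(med))
    out[sel] <- as.integer(rank_map[as.character(labels[sel])])
  }
  out
}
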