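#' Global field power
#'
#' GFP at a time sample is the spatial standard deviation of the scalp map:
#' the root mean square over channels of the average-referenced potentials.
#' Peaks of the GFP time course mark moments of maximal topographic
#' signal-to-noise and are the maps submitted to clustering.
#'
#' @param ep An [eeg_epochs] object (average-referenced; if not, it is
#'   re-referenced with a message).
#' @return Object of class `ms_gfp`: list with `values` (epochs x samples
#'   matrix of GFP) and `fs`.
#' @export
gfp <- function(ep) {
  stopifnot(inherits(ep, "eeg_epochs"))
  d <- dim(ep$epochs)
  chk <- max(abs(apply(ep$epochs, c(1, 3), mean)))
  if (chk > 1e-8) {
    message("input not average-referenced; re-referencing")
    ep <- average_reference(ep)
  }
  vals <- matrix(0, d[1], d[3])
  for (e in seq_len(d[1]))
    vals[e, ] <- sqrt(colMeans(matrix(ep$epochs[e, , ], d[2])^2))
  structure(list(values = vals, fs = ep$fs), class = "ms_gfp")
}

# greedy minimum-distance pruning: keep the larger of any pair of peaks
# closer than min_dist samples
.prune_peaks <- function(idx, vals, min_dist) {
  if (min_dist <= 1 || length(idx) < 2) return(idx)
  ord <- order(vals[idx], decreasing = TRUE)
  kept <- integer(0)
  for (i in idx[ord])
    if (!length(kept) || min(abs(kept - i)) >= min_dist)
      kept <- c(kept, i)
  sort(kept)
}

#' Locate GFP peaks
#'
#' Strict local maxima of the GFP series (greater than both neighbours);
#' peaks closer than `min_distance_ms` keep only the larger. Epoch
#' boundaries are never peaks.
#'
#' @param g An `ms_gfp` object, or a plain numeric vector (one epoch).
#' @param min_distance_ms Minimum distance between retained peaks, in ms.
#' @param fs Sampling rate; only needed when `g` is a plain vector.
#' @return Data frame with columns `epoch`, `sample` (1-based indices).
#' @export
gfp_peaks <- function(g, min_distance_ms = 8, fs = NULL) {
  if (is.numeric(g) && is.null(dim(g))) {
    if (is.null(fs)) fs <- 250
    g <- structure(list(values = matrix(g, 1), fs = fs), class = "ms_gfp")
  }
  stopifnot(inherits(g, "ms_gfp"))
  n <- ncol(g$values)
  if (n < 3) stop("GFP series must have at least 3 samples")
  min_dist <- round(min_distance_ms / 1000 * g$fs)
  out <- NULL
  for (e in seq_len(nrow(g$values))) {
    v <- g$values[e, ]
    i <- 2:(n - 1)
    pk <- i[v[i] > v[i - 1] & v[i] > v[i + 1]]
    pk <- .prune_peaks(pk, v, min_dist)
    if (length(pk))
      out <- rbind(out, data.frame(epoch = e, sample = pk))
  }
  if (is.null(out)) stop("no GFP peaks found")
  out
}

#' Extract the scalp maps at GFP peaks
#'
#' @param ep An [eeg_epochs] object.
#' @param peaks Peak table from [gfp_peaks()].
#' @return Matrix, peaks x channels.
#' @export
peak_maps <- function(ep, peaks) {
  stopifnot(inherits(ep, "eeg_epochs"))
  m <- matrix(0, nrow(peaks), dim(ep$epochs)[2])
  for (i in seq_len(nrow(peaks)))
    m[i, ] <- ep$epochs[peaks$epoch[i], , peaks$sample[i]]
  m
}

#' Spatial correlation between two scalp maps
#'
#' Pearson correlation across channels of the zero-mean maps; with
#' `polarity_invariant = TRUE` (the microstate convention) the absolute
#' value is returned.
#'
#' @param u,w Numeric vectors (same channel count).
#' @param polarity_invariant Ignore map polarity (default `TRUE`).
#' @return Correlation in `[0, 1]` (invariant) or `[-1, 1]`.
#' @export
spatial_correlation <- function(u, w, polarity_invariant = TRUE) {
  stopifnot(length(u) == length(w))
  u <- u - mean(u); w <- w - mean(w)
  du <- sqrt(sum(u^2)); dw <- sqrt(sum(w^2))
  if (du == 0 || dw == 0) stop("zero-variance map in spatial correlation")
  r <- sum(u * w) / (du * dw)
  if (polarity_invariant) abs(r) else r
}

# one run of polarity-invariant k-means from given template seed rows
.kmeans_once <- function(X, k, init_idx, max_iter, tol, total_ss) {
  Tm <- X[init_idx, , drop = FALSE]
  Tm <- Tm / sqrt(rowSums(Tm^2))
  gev_prev <- -Inf
  assign <- rep(1L, nrow(X))
  for (it in seq_len(max_iter)) {
    P <- X %*% t(Tm)                     # n x k projections
    A2 <- P^2
    assign <- max.col(A2, ties.method = "first")
    expl <- A2[cbind(seq_len(nrow(X)), assign)]
    gev <- sum(expl) / total_ss
    # update: dominant eigenvector of each cluster's channel covariance
    for (j in seq_len(k)) {
      sel <- assign == j
      if (!any(sel)) {
        # re-seed an empty cluster from the worst-explained map
        worst <- which.min(expl / rowSums(X^2))
        v <- X[worst, ]
      } else {
        M <- crossprod(X[sel, , drop = FALSE])
        v <- eigen(M, symmetric = TRUE)$vectors[, 1]
      }
      v <- v / sqrt(sum(v^2))
      if (v[which.max(abs(v))] < 0) v <- -v   # deterministic sign
      Tm[j, ] <- v
    }
    if (is.finite(gev_prev) &&
        abs(gev - gev_prev) < tol * max(abs(gev_prev), 1e-12)) break
    gev_prev <- gev
  }
  P <- X %*% t(Tm)
  A2 <- P^2
  assign <- max.col(A2, ties.method = "first")
  gev <- sum(A2[cbind(seq_len(nrow(X)), assign)]) / total_ss
  list(templates = Tm, assignments = assign, gev = gev)
}

#' Polarity-invariant modified k-means clustering of topographies
#'
#' The microstate variant of k-means: maps are assigned to the template with
#' the largest squared spatial projection (so a map and its polarity
#' reversal are equivalent), and each template is updated as the dominant
#' eigenvector of the channel covariance of its assigned maps. The quality
#' criterion is the global explained variance (GEV): the fraction of total
#' map variance captured by the assigned templates. The best of `restarts`
#' random initializations (template seeds drawn from the input maps) is
#' returned.
#'
#' @param maps Numeric matrix, n x channels (n >= k). Rows are
#'   average-referenced internally.
#' @param k Number of clusters (default 4).
#' @param restarts Number of random restarts (default 50).
#' @param max_iter Iteration cap per restart.
#' @param tol Convergence tolerance on the relative GEV change.
#' @param seed Optional integer seed for the restarts.
#' @return List with `templates` (an [ms_templates]), `assignments`
#'   (cluster index per map), and `gev_total`.
#' @export
modified_kmeans <- function(maps, k = 4, restarts = 50, max_iter = 1000,
                            tol = 1e-6, seed = NULL) {
  X <- as.matrix(maps)
  if (nrow(X) < k) stop("need at least k maps (n = ", nrow(X), ", k = ", k, ")")
  X <- X - rowMeans(X)
  total_ss <- sum(X^2)
  if (total_ss == 0) stop("all maps have zero variance")
  run <- function() {
    best <- NULL
    for (r in seq_len(restarts)) {
      res <- .kmeans_once(X, k, sample.int(nrow(X), k), max_iter, tol,
                          total_ss)
      if (is.null(best) || res$gev > best$gev) best <- res
    }
    best
  }
  best <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  list(templates = ms_templates(best$templates, level = "individual"),
       assignments = best$assignments,
       gev_total = best$gev)
}

#' Two-level (individual then group) microstate clustering
#'
#' First level: each subject's GFP-peak topographies are clustered into `k`
#' individual template maps. Second level: the individual templates of all
#' subjects in a group are pooled and clustered with the same algorithm into
#' `k` group-mean microstate classes.
#'
#' @param epoch_sets Named list of [eeg_epochs], one per subject.
#' @param group Factor or character vector of group membership, aligned with
#'   `epoch_sets`; `NULL` treats everyone as one group `"all"`.
#' @param k Number of microstate classes (default 4).
#' @param restarts,seed Passed to [modified_kmeans()]; the same seed is used
#'   for every subject so results do not depend on subject order.
#' @param min_distance_ms Minimum GFP peak distance (ms).
#' @return List with `individual` (named list of [ms_templates]) and
#'   `group` (named list of [ms_templates], one per group, level "group").
#' @export
two_level_clustering <- function(epoch_sets, group = NULL, k = 4,
                                 restarts = 50, seed = 1,
                                 min_distance_ms = 8) {
  ids <- names(epoch_sets)
  if (is.null(ids)) ids <- sprintf("S%03d", seq_along(epoch_sets))
  if (is.null(group)) group <- rep("all", length(epoch_sets))
  group <- as.character(group)
  individual <- vector("list", length(epoch_sets))
  names(individual) <- ids
  for (s in seq_along(epoch_sets)) {
    individual[[s]] <- tryCatch({
      ep <- average_reference(epoch_sets[[s]])
      pk <- gfp_peaks(gfp(ep), min_distance_ms)
      km <- modified_kmeans(peak_maps(ep, pk), k = k, restarts = restarts,
                            seed = seed)
      km$templates
    }, error = function(e)
      stop("individual clustering failed for subject ", ids[s], ": ",
           conditionMessage(e), call. = FALSE))
  }
  group_templates <- list()
  for (gname in unique(group)) {
    pooled <- do.call(rbind, lapply(individual[group == gname],
                                    function(t) t$maps))
    km <- modified_kmeans(pooled, k = k, restarts = restarts, seed = seed)
    gt <- km$templates
    gt$level <- "group"
    group_templates[[gname]] <- gt
  }
  list(individual = individual, group = group_templates)
}

# all permutations of 1..n (n small: used for k! template matchings)
.perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .perms(n - 1L)
  out <- NULL
  for (i in seq_len(n)) {
    rest <- seq_len(n)[-i]
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  out
}

#' Order template maps against canonical classes
#'
#' Finds the one-to-one assignment of templates to canonical classes that
#' maximizes the total polarity-invariant spatial correlation (exhaustive
#' over all k! permutations), relabels accordingly, and aligns each map's
#' sign to correlate positively with its canonical class.
#'
#' @param ts An [ms_templates] to be ordered.
#' @param canonical An [ms_templates] carrying the reference class maps and
#'   labels (same k and channel count).
#' @return An [ms_templates] with maps reordered, sign-aligned, and labelled
#'   by the canonical class labels.
#' @export
order_classes <- function(ts, canonical) {
  stopifnot(inherits(ts, "ms_templates"), inherits(canonical, "ms_templates"))
  k <- nrow(ts$maps)
  if (k != nrow(canonical$maps) || ncol(ts$maps) != ncol(canonical$maps))
    stop("template sets must have matching k and channel count")
  C <- matrix(0, k, k)  # C[i, j] = corr(template i, canonical j)
  for (i in seq_len(k)) for (j in seq_len(k))
    C[i, j] <- spatial_correlation(ts$maps[i, ], canonical$maps[j, ],
                                   polarity_invariant = FALSE)
  perms <- .perms(k)
  tot <- apply(perms, 1, function(p)
    sum(abs(C[cbind(p, seq_len(k))])))
  best <- perms[which.max(tot), ]  # which.max: lowest index wins ties
  matched <- abs(C[cbind(best, seq_len(k))])
  if (min(matched) < 0.3)
    warning("weak match to canonical classes (min |r| = ",
            signif(min(matched), 2), ")")
  maps <- ts$maps[best, , drop = FALSE]
  for (j in seq_len(k))
    if (C[best[j], j] < 0) maps[j, ] <- -maps[j, ]
  ms_templates(maps, class_labels = canonical$class_labels, level = ts$level)
}

#' Backfit microstate templates to every sample
#'
#' Labels every time sample with the template of maximal polarity-invariant
#' spatial correlation. No temporal smoothing is applied by default;
#' segments never span epoch boundaries. Zero-variance samples inherit the
#' previous sample's label (or the next label at an epoch start).
#'
#' @param ep An [eeg_epochs] object (average-referenced; re-referenced if
#'   not).
#' @param ts An [ms_templates], typically ordered A--D.
#' @return Object of class `ms_labels`: list with `labels` (epochs x samples
#'   integer matrix), `fs`, and `class_labels`.
#' @export
backfit <- function(ep, ts) {
  stopifnot(inherits(ep, "eeg_epochs"), inherits(ts, "ms_templates"))
  ep <- average_reference(ep)
  d <- dim(ep$epochs)
  Tm <- ts$maps
  lab <- matrix(0L, d[1], d[3])
  n_zero <- 0L
  for (e in seq_len(d[1])) {
    X <- matrix(ep$epochs[e, , ], d[2])      # channels x samples
    P2 <- (Tm %*% X)^2                      # k x samples
    l <- max.col(t(P2), ties.method = "first")
    zero <- colSums(X^2) == 0
    if (any(zero)) {
      n_zero <- n_zero + sum(zero)
      ok <- which(!zero)
      if (!length(ok)) stop("epoch ", e, " is entirely zero")
      # inherit previous valid label; leading zeros take the next label
      l[zero] <- l[vapply(which(zero), function(i) {
        prev <- ok[ok < i]
        if (length(prev)) max(prev) else min(ok[ok > i])
      }, integer(1))]
    }
    lab[e, ] <- l
  }
  if (n_zero > 0)
    message(n_zero, " zero-variance samples inherited neighbouring labels")
  structure(list(labels = lab, fs = ep$fs, class_labels = ts$class_labels),
            class = "ms_labels")
}

#' Microstate parameters from a label sequence
#'
#' Computes, per class: mean microstate duration (MMD, ms), ratio of total
#' time covered (RTT), global explained variance (GEV), and occurrence
#' (segments per second). Runs are computed within epochs; runs touching an
#' epoch edge are excluded from MMD and occurrence (truncation-bias
#' control, toggleable) but their samples still count for RTT and GEV.
#' GEV of class k is the GFP-weighted squared spatial correlation between
#' each sample labelled k and the class template, as a fraction of the
#' total squared GFP over all samples.
#'
#' @param ls An `ms_labels` object from [backfit()].
#' @param ep The matching [eeg_epochs].
#' @param ts The [ms_templates] used for backfitting.
#' @param exclude_edge_runs Exclude epoch-edge-touching runs from
#'   MMD/occurrence (default `TRUE`).
#' @return Data frame with one row per class: `class`, `mmd_ms`, `rtt`,
#'   `gev`, `occurrence`. Classes absent from the labels get `NA` MMD and
#'   occurrence 0.
#' @export
microstate_parameters <- function(ls, ep, ts, exclude_edge_runs = TRUE) {
  stopifnot(inherits(ls, "ms_labels"), inherits(ep, "eeg_epochs"),
            inherits(ts, "ms_templates"))
  ep <- average_reference(ep)
  k <- nrow(ts$maps)
  d <- dim(ep$epochs)
  n_total <- d[1] * d[3]
  total_s <- n_total / ls$fs
  run_len <- vector("list", k)
  run_cnt <- numeric(k)
  gev_num <- numeric(k)
  gev_den <- 0
  rtt_cnt <- numeric(k)
  for (e in seq_len(d[1])) {
    l <- ls$labels[e, ]
    r <- rle(l)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    interior <- if (exclude_edge_runs)
      starts > 1L & ends < d[3] else rep(TRUE, length(starts))
    for (j in seq_len(k)) {
      sel <- r$values == j & interior
      run_len[[j]] <- c(run_len[[j]], r$lengths[sel])
      run_cnt[j] <- run_cnt[j] + sum(sel)
      rtt_cnt[j] <- rtt_cnt[j] + sum(l == j)
    }
    X <- matrix(ep$epochs[e, , ], d[2])
    P2 <- (ts$maps %*% X)^2 / d[2]  # (GFP * corr)^2, k x samples
    gev_den <- gev_den + sum(X^2) / d[2]
    for (j in seq_len(k))
      gev_num[j] <- gev_num[j] + sum(P2[j, l == j])
  }
  mmd <- vapply(run_len, function(v)
    if (length(v)) mean(v) * 1000 / ls$fs else NA_real_, numeric(1))
  data.frame(class = ts$class_labels,
             mmd_ms = mmd,
             rtt = rtt_cnt / n_total,
             gev = gev_num / gev_den,
             occurrence = run_cnt / total_s)
}
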