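#' Build a standardized minimum-norm (sLORETA-style) inverse operator
#'
#' Minimum-norm transform `T = K' (K K' + alpha * H)^+` where `K` is the
#' lead field, `H` the average-reference centering matrix, and `^+` the
#' Moore--Penrose pseudoinverse. The per-voxel standardization factors are
#' the diagonal entries of the resolution matrix `T K`; dividing estimated
#' power by them yields the standardized estimate with the zero
#' localization error property for noise-free single sources.
#'
#' @param lf An `ms_leadfield` from [make_leadfield()] or [read_leadfield()].
#' @param reg_alpha Tikhonov regularization (>= 0). The default scales with
#'   the mean eigenvalue of `K K'` (5 percent), a common heuristic; use 0
#'   for the exact noise-free operator.
#' @return Object of class `ms_inverse`: list with `transform`
#'   (voxels x channels), `standardization` (per-voxel positive scalars),
#'   `reg_alpha`, `voxel_ids`.
#' @export
build_inverse <- function(lf, reg_alpha = NULL) {
  stopifnot(inherits(lf, "ms_leadfield"))
  K <- lf$matrix
  C <- nrow(K)
  KKt <- K %*% t(K)
  if (is.null(reg_alpha))
    reg_alpha <- 0.05 * mean(diag(KKt))
  if (reg_alpha < 0) stop("'reg_alpha' must be >= 0")
  H <- diag(C) - matrix(1 / C, C, C)
  G <- KKt + reg_alpha * H
  Tm <- t(K) %*% MASS::ginv(G)
  std <- rowSums(Tm * t(K))        # diag(T %*% K)
  if (any(std <= 0))
    stop("non-positive standardization entries; with alpha = 0 and a ",
         "rank-deficient lead field, use reg_alpha > 0")
  structure(list(transform = Tm, standardization = std,
                 reg_alpha = reg_alpha, voxel_ids = lf$voxel_ids),
            class = "ms_inverse")
}

#' @export
print.ms_inverse <- function(x, ...) {
  cat(sprintf("<ms_inverse> %d voxels x %d channels, alpha = %g\n",
              nrow(x$transform), ncol(x$transform), x$reg_alpha))
  invisible(x)
}

#' Standardized current-density power of a scalp map
#'
#' Applies the inverse transform to a (zero-mean) scalp map and returns the
#' per-voxel standardized power `(T m)_v^2 / s_v`.
#'
#' @param map Numeric vector, one potential per channel.
#' @param inv An `ms_inverse` from [build_inverse()].
#' @return Numeric vector of nonnegative standardized power per voxel,
#'   named by voxel id.
#' @export
localize <- function(map, inv) {
  stopifnot(inherits(inv, "ms_inverse"),
            length(map) == ncol(inv$transform))
  map <- map - mean(map)
  j <- drop(inv$transform %*% map)
  p <- j^2 / inv$standardization
  names(p) <- inv$voxel_ids
  p
}

#' Voxelwise log-F statistic between two groups of source power maps
#'
#' For each voxel, the base-10 logarithm of the ratio of group geometric
#' mean power: the difference of group means of log10 power. Positive
#' values mean stronger sources in group A.
#'
#' @param powersA,powersB Numeric matrices, subjects x voxels, strictly
#'   positive.
#' @return Numeric vector, one statistic per voxel.
#' @export
logf_statistic <- function(powersA, powersB) {
  powersA <- as.matrix(powersA); powersB <- as.matrix(powersB)
  if (nrow(powersA) < 2 || nrow(powersB) < 2)
    stop("need at least 2 subjects per group")
  if (ncol(powersA) != ncol(powersB))
    stop("voxel counts differ between groups")
  if (any(powersA <= 0) || any(powersB <= 0))
    stop("power values must be strictly positive")
  colMeans(log10(powersA)) - colMeans(log10(powersB))
}

#' Permutation max-statistic correction (statistical non-parametric mapping)
#'
#' Recomputes the voxelwise log-F statistic under `n_perm` random
#' relabelings of the group assignment; the null distribution is the
#' maximum over voxels of the absolute statistic, and the corrected
#' threshold is its upper `alpha` quantile (order statistic
#' `floor(alpha * (n_perm + 1))` from the top, so the family-wise error is
#' controlled at `alpha`). If `n_perm` meets or exceeds the number of
#' distinct group relabelings, all of them are enumerated exactly instead.
#'
#' @param powers Numeric matrix, subjects x voxels, strictly positive.
#' @param labels Group labels (two levels), length = subjects.
#' @param n_perm Number of permutations (default 5000).
#' @param alpha Family-wise error level (default 0.05).
#' @param seed Optional integer seed.
#' @return Object of class `ms_snpm`: list with `statistic` (observed
#'   per-voxel log-F), `corrected_threshold`, `suprathreshold` (voxel
#'   indices with `|statistic|` above threshold), `max_null` (the
#'   permutation max-statistic distribution), `n_permutations`, `alpha`,
#'   `exact` (whether relabelings were enumerated).
#' @export
snpm_correct <- function(powers, labels, n_perm = 5000, alpha = 0.05,
                         seed = NULL) {
  powers <- as.matrix(powers)
  labels <- as.factor(labels)
  if (nlevels(labels) != 2) stop("'labels' must have exactly two levels")
  nA <- sum(labels == levels(labels)[1])
  nB <- sum(labels == levels(labels)[2])
  if (nA < 1 || nB < 1) stop("both groups must be non-empty")
  if (any(powers <= 0)) stop("power values must be strictly positive")
  n <- nA + nB
  L <- log10(powers)
  stat_for <- function(idxA) {
    colMeans(L[idxA, , drop = FALSE]) - colMeans(L[-idxA, , drop = FALSE])
  }
  obs_idx <- which(labels == levels(labels)[1])
  observed <- stat_for(obs_idx)
  n_distinct <- choose(n, nA)
  exact <- n_perm >= n_distinct
  run <- function() {
    if (exact) {
      combs <- utils::combn(n, nA)
      apply(combs, 2, function(ix) max(abs(stat_for(ix))))
    } else {
      vapply(seq_len(n_perm),
             function(i) max(abs(stat_for(sample.int(n, nA)))),
             numeric(1))
    }
  }
  max_null <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  if (exact) {
    message("enumerating all ", n_distinct, " group relabelings exactly")
    n_used <- n_distinct
    srt <- sort(max_null, decreasing = TRUE)
    ix <- floor(alpha * n_used)
    thr <- if (ix < 1) Inf else if (ix >= n_used) -Inf else srt[ix]
  } else {
    n_used <- n_perm
    srt <- sort(max_null, decreasing = TRUE)
    ix <- floor(alpha * (n_used + 1))
    thr <- if (ix < 1) Inf else if (ix > n_used) -Inf else srt[ix]
  }
  structure(list(statistic = observed, corrected_threshold = thr,
                 suprathreshold = which(abs(observed) > thr),
                 max_null = max_null, n_permutations = n_used,
                 alpha = alpha, exact = exact),
            class = "ms_snpm")
}

#' @export
print.ms_snpm <- function(x, ...) {
  cat(sprintf(paste0("<ms_snpm> %d voxels, %d permutations%s, alpha = %g\n",
                     "  corrected |log-F| threshold = %.4f; ",
                     "%d suprathreshold voxels\n"),
              length(x$statistic), x$n_permutations,
              if (x$exact) " (exact)" else "", x$alpha,
              x$corrected_threshold, length(x$suprathreshold)))
  invisible(x)
}

#' Source contrast of per-subject microstate templates between groups
#'
#' Localizes each subject's individual template map of one class, then
#' contrasts the two groups voxel-by-voxel with the log-F statistic and
#' permutation max-statistic correction.
#'
#' @param templates Named list of per-subject [ms_templates] (individual
#'   level, class-ordered).
#' @param group Group labels aligned with `templates` (two levels; the
#'   first level plays group A).
#' @param class_label Which microstate class to contrast (e.g. `"A"`).
#' @param inv An `ms_inverse`.
#' @inheritParams snpm_correct
#' @return An `ms_snpm` result (see [snpm_correct()]), plus a `powers`
#'   attribute holding the subjects x voxels standardized power matrix.
#' @export
source_contrast <- function(templates, group, class_label, inv,
                            n_perm = 5000, alpha = 0.05, seed = NULL) {
  group <- as.factor(group)
  powers <- t(vapply(templates, function(ts) {
    j <- match(class_label, ts$class_labels)
    if (is.na(j)) stop("class ", class_label, " not present in templates")
    localize(ts$maps[j, ], inv)
  }, numeric(nrow(inv$transform))))
  res <- snpm_correct(powers, group, n_perm = n_perm, alpha = alpha,
                      seed = seed)
  attr(res, "powers") <- powers
  res
}
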