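#' Approximate 2-D montage layout for a given channel count
#'
#' Places electrodes quasi-uniformly on the unit disk using a sunflower
#' (Fermat spiral) arrangement. The y axis points anterior (towards the
#' nose), x points right. Purely geometric and deterministic; used to
#' construct smooth synthetic topographies and lead fields.
#'
#' @param n_channels Number of electrodes (>= 2).
#' @return Data frame with columns `x`, `y` in `[-1, 1]`.
#' @export
montage_layout <- function(n_channels) {
  stopifnot(n_channels >= 2)
  i <- seq_len(n_channels)
  r <- sqrt((i - 0.5) / n_channels)
  theta <- i * pi * (3 - sqrt(5))
  data.frame(x = r * cos(theta), y = r * sin(theta))
}

# gaussian bump over the layout, centred at (cx, cy)
.bump <- function(lay, cx, cy, width) {
  exp(-((lay$x - cx)^2 + (lay$y - cy)^2) / (2 * width^2))
}

#' Generate canonical-style microstate template maps
#'
#' Builds `k` smooth, dipolar-looking scalp topographies over a 2-D montage
#' layout, mimicking the orientations of the canonical resting-state
#' microstate classes: A (right-anterior / left-posterior gradient),
#' B (left-anterior / right-posterior), C (anterior--posterior), and
#' D (fronto-central focus). Each map is zero-mean across channels and has
#' unit L2 norm; a small seeded smooth perturbation makes distinct seeds
#' produce distinct (but still canonical-looking) sets. For `k > 4`,
#' additional smooth random maps are appended.
#'
#' @param n_channels Number of channels (>= 8).
#' @param k Number of template maps (>= 2, at most `n_channels - 1`, the
#'   rank limit under the average reference).
#' @param seed Integer seed for reproducibility.
#' @return An [ms_templates] object with `k` maps.
#' @examples
#' ts <- make_templates(64, 4, seed = 1)
#' rowSums(ts$maps)   # ~0: average-referenced maps
#' @export
make_templates <- function(n_channels, k = 4, seed = 1) {
  stopifnot(n_channels >= 8, k >= 2)
  if (k > n_channels - 1)
    stop("k must be at most n_channels - 1 (rank limit under average reference)")
  lay <- montage_layout(n_channels)
  # compact dipolar pole pairs in the canonical orientations; the poles are
  # placed so the four maps are close to mutually orthogonal (mixtures of
  # two classes then never resemble a third)
  base <- list(
    A = .bump(lay, 0.78, 0.44, 0.21) - .bump(lay, -0.78, -0.44, 0.21),
    B = .bump(lay, -0.78, 0.44, 0.21) - .bump(lay, 0.78, -0.44, 0.21),
    C = .bump(lay, 0, -0.83, 0.26) - .bump(lay, 0, 0.83, 0.26),
    D = .bump(lay, 0, 0.16, 0.29) - 0.67 * .bump(lay, 0, 0.16, 0.64)
  )
  withr::with_seed(seed, {
    maps <- matrix(0, k, n_channels)
    for (j in seq_len(k)) {
      if (j <= 4) {
        v <- base[[j]]
      } else {
        # extra classes: smooth random field from a few gaussian bumps
        v <- 0
        for (b in 1:3)
          v <- v + stats::rnorm(1) *
            .bump(lay, stats::runif(1, -0.7, 0.7), stats::runif(1, -0.7, 0.7),
                  stats::runif(1, 0.3, 0.6))
      }
      # small smooth seeded perturbation so seeds differ
      pert <- stats::rnorm(1, sd = 0.05) * lay$x +
        stats::rnorm(1, sd = 0.05) * lay$y +
        stats::rnorm(1, sd = 0.05) * (lay$x * lay$y) +
        stats::rnorm(1, sd = 0.05) * (lay$x^2 - lay$y^2)
      v <- v / stats::sd(v) + pert
      maps[j, ] <- v - mean(v)
    }
    maps <- maps / sqrt(rowSums(maps^2))
    # reject-resample extra maps until pairwise correlation is acceptable
    if (k > 2) {
      cors <- abs(stats::cor(t(maps)))
      diag(cors) <- 0
      tries <- 0
      while (max(cors) >= 0.9 && tries < 100) {
        worst <- which(cors == max(cors), arr.ind = TRUE)[1, 1]
        v <- 0
        for (b in 1:3)
          v <- v + stats::rnorm(1) *
            .bump(lay, stats::runif(1, -0.7, 0.7), stats::runif(1, -0.7, 0.7),
                  stats::runif(1, 0.3, 0.6))
        v <- v - mean(v)
        maps[worst, ] <- v / sqrt(sum(v^2))
        cors <- abs(stats::cor(t(maps)))
        diag(cors) <- 0
        tries <- tries + 1
      }
    }
    ms_templates(maps,
                 class_labels = if (k <= 4) LETTERS[1:k] else NULL,
                 level = "group")
  })
}

# draw a semi-Markov run sequence: gamma(shape 2) run lengths, no immediate
# self-transition. mean_samples is per-class mean run length in samples.
.run_sequence <- function(n_samples, mean_samples) {
  k <- length(mean_samples)
  cls <- integer(0); len <- integer(0)
  total <- 0L
  cur <- sample.int(k, 1)
  while (total < n_samples) {
    m <- mean_samples[cur]
    d <- max(1L, as.integer(round(stats::rgamma(1, shape = 2, scale = m / 2))))
    d <- min(d, n_samples - total)
    cls <- c(cls, cur); len <- c(len, d)
    total <- total + d
    if (k > 1L) {
      nxt <- sample.int(k - 1L, 1)
      cur <- if (nxt >= cur) nxt + 1L else nxt
    }
  }
  data.frame(class = cls, length = len,
             start = cumsum(c(1L, len[-length(len)])))
}

#' Simulate a resting EEG recording from microstate templates
#'
#' Generates a piecewise-stable multichannel signal: a semi-Markov label
#' sequence (gamma-distributed run lengths, shape 2, mean per class as
#' requested, no immediate self-transitions), where each run contributes its
#' class template multiplied by an oscillatory amplitude envelope with a
#' random polarity sign and phase per run, plus spatially white Gaussian
#' noise scaled to the requested signal-to-noise power ratio.
#'
#' @param templates An [ms_templates] object (k maps).
#' @param duration_s Recording duration in seconds.
#' @param fs Sampling rate in Hz.
#' @param mean_durations_ms Per-class mean run duration in ms (recycled to k).
#' @param snr Signal-power / noise-power ratio; `Inf` disables noise.
#' @param seed Integer seed.
#' @param amplitudes Per-class amplitude weights (recycled to k).
#' @param envelope Within-run amplitude envelope. `"plateau"` (default): a
#'   quasi-stable amplitude with a mild half-sine lobe on top (depth
#'   `1 - plateau`), so the global field power peaks once near each run's
#'   centre while the topography stays strong right up to the transition;
#'   `"halfsine"`: amplitude rises from zero at the run onset, peaks at the
#'   centre and returns to zero; `"sine"`: continuous oscillation at
#'   `osc_freq_hz` with a random phase per run.
#' @param plateau Baseline amplitude fraction for `envelope = "plateau"`
#'   (default 0.95).
#' @param osc_freq_hz Envelope oscillation frequency for
#'   `envelope = "sine"` (default 10 Hz, the alpha rhythm that dominates
#'   eyes-closed resting EEG).
#' @param amplitude_uv Overall signal scale in microvolts.
#' @return List with `recording` (an [eeg_recording]) and `truth`, a ground
#'   truth list with `labels` (per-sample class index), `runs` (data frame
#'   of class/start/length), `templates`, and `mean_durations_ms`.
#' @export
simulate_recording <- function(templates, duration_s, fs,
                               mean_durations_ms = 40, snr = 5, seed = 1,
                               amplitudes = 1,
                               envelope = c("plateau", "halfsine", "sine"),
                               plateau = 0.95,
                               osc_freq_hz = 10, amplitude_uv = 10) {
  envelope <- match.arg(envelope)
  stopifnot(inherits(templates, "ms_templates"), fs > 0, duration_s > 0)
  if (!is.infinite(snr) && snr <= 0) stop("'snr' must be positive")
  k <- nrow(templates$maps)
  mean_durations_ms <- rep_len(mean_durations_ms, k)
  amplitudes <- rep_len(amplitudes, k)
  mean_smp <- mean_durations_ms * fs / 1000
  if (any(mean_smp < 2))
    stop("mean durations must be at least 2 samples at fs = ", fs, " Hz")
  n <- as.integer(round(duration_s * fs))
  withr::with_seed(seed, {
    runs <- .run_sequence(n, mean_smp)
    labels <- rep.int(runs$class, runs$length)
    x <- matrix(0, ncol(templates$maps), n)
    t_idx <- seq_len(n)
    for (r in seq_len(nrow(runs))) {
      idx <- runs$start[r]:(runs$start[r] + runs$length[r] - 1L)
      sgn <- sample(c(-1, 1), 1)
      a <- sgn * amplitudes[runs$class[r]] * amplitude_uv
      env <- if (envelope == "plateau") {
        a * (plateau + (1 - plateau) *
               sin(pi * (seq_along(idx) - 0.5) / runs$length[r]))
      } else if (envelope == "halfsine") {
        # one smooth lobe per run; half-sample offset avoids exact zeros
        a * sin(pi * (seq_along(idx) - 0.5) / runs$length[r])
      } else {
        phase <- stats::runif(1, 0, 2 * pi)
        a * sin(2 * pi * osc_freq_hz * t_idx[idx] / fs + phase)
      }
      x[, idx] <- tcrossprod(templates$maps[runs$class[r], ], env)
    }
    if (is.finite(snr)) {
      sig_pow <- mean(x^2)
      x <- x + matrix(stats::rnorm(length(x), sd = sqrt(sig_pow / snr)),
                      nrow(x))
    }
    list(recording = eeg_recording(x, fs),
         truth = list(labels = labels, runs = runs, templates = templates,
                      mean_durations_ms = mean_durations_ms))
  })
}

# ground-truth microstate parameters from a label run table:
# runs touching the sequence edges are excluded from duration/occurrence.
.truth_parameters <- function(runs, n_samples, fs, k) {
  interior <- runs$start > 1L & (runs$start + runs$length - 1L) < n_samples
  out <- data.frame(class = LETTERS[seq_len(k)], mmd_ms = NA_real_,
                    rtt = 0, occurrence = NA_real_)
  secs <- n_samples / fs
  for (j in seq_len(k)) {
    sel <- runs$class == j & interior
    if (any(sel)) {
      out$mmd_ms[j] <- mean(runs$length[sel]) * 1000 / fs
      out$occurrence[j] <- sum(sel) / secs
    }
    out$rtt[j] <- sum(runs$length[runs$class == j]) / n_samples
  }
  out
}

#' Default between-group effect specification
#'
#' Patients get shorter class A and B durations (-2 ms each) and a stronger
#' class C amplitude, mirroring the direction of reported group differences
#' (shorter A/B microstates and larger class C explained variance in the
#' patient group).
#'
#' @param duration_shift_ms Per-class additive shift (ms) applied to the
#'   patient group's mean durations.
#' @param amplitude_scale Per-class multiplicative amplitude factor for the
#'   patient group.
#' @return List with the two components, class `ms_effect_spec`.
#' @export
effect_spec <- function(duration_shift_ms = c(A = -2, B = -2, C = 0, D = 0),
                        amplitude_scale = c(A = 1, B = 1, C = 1.15, D = 1)) {
  structure(list(duration_shift_ms = duration_shift_ms,
                 amplitude_scale = amplitude_scale),
            class = "ms_effect_spec")
}

#' Simulate a two-group microstate study with covariates
#'
#' Generates a full synthetic study: shared generating templates, per-subject
#' recordings (control group at baseline mean durations, patient group with
#' the effect specification applied), per-subject ground truth, and a
#' covariate table (MA use frequency, two-back working-memory score, and
#' drug-word Stroop error rate) linearly linked to per-subject ground-truth
#' parameters with standardized slopes of 0.4 plus Gaussian noise.
#'
#' @param n_patients,n_controls Group sizes (default 55 and 27).
#' @param effects An [effect_spec()] describing the patient-group shifts.
#' @param snr Signal-to-noise power ratio of the recordings.
#' @param seed Integer seed.
#' @param duration_s,fs,n_channels,k Recording geometry.
#' @param baseline_durations_ms Control-group per-class mean durations (ms).
#' @param between_sd_ms Between-subject SD of per-class mean durations (ms).
#' @param signals If `FALSE`, only label sequences, ground-truth parameters
#'   and covariates are generated (no multichannel waveforms); much faster
#'   for replicate-level checks of the generator itself.
#' @param link_slope Standardized slope of the covariate links.
#' @return An object of class `ms_study`: list with `recordings` (list of
#'   [eeg_recording] or `NULL`s), `group` (factor patient/control),
#'   `covariates` (data frame), `ground_truth` (per subject), `templates`,
#'   `fs`, and the generating configuration.
#' @export
simulate_group_study <- function(n_patients = 55, n_controls = 27,
                                 effects = effect_spec(), snr = 5, seed = 1,
                                 duration_s = 60, fs = 250, n_channels = 64,
                                 k = 4,
                                 baseline_durations_ms = c(A = 39.5, B = 40.3,
                                                           C = 45.0, D = 46.1),
                                 between_sd_ms = 2.5, signals = TRUE,
                                 link_slope = 0.4) {
  stopifnot(n_patients >= 2, n_controls >= 2)
  baseline_durations_ms <- rep_len(baseline_durations_ms, k)
  pat_dur <- baseline_durations_ms + rep_len(effects$duration_shift_ms, k)
  if (any(pat_dur < 2000 / fs) || any(rep_len(effects$amplitude_scale, k) <= 0))
    stop("degenerate effect_spec: patient durations or amplitudes non-positive")
  templates <- make_templates(n_channels, k, seed = seed)
  n_sub <- n_patients + n_controls
  group <- factor(rep(c("patient", "control"), c(n_patients, n_controls)),
                  levels = c("control", "patient"))
  n_samples <- as.integer(round(duration_s * fs))
  withr::with_seed(seed + 1L, {
    sub_seeds <- sample.int(2^31 - 2, n_sub)
    recordings <- vector("list", n_sub)
    ground_truth <- vector("list", n_sub)
    for (s in seq_len(n_sub)) {
      is_pat <- group[s] == "patient"
      mu <- if (is_pat) pat_dur else baseline_durations_ms
      amp <- if (is_pat) rep_len(effects$amplitude_scale, k) else rep(1, k)
      dur_s <- pmax(mu + stats::rnorm(k, sd = between_sd_ms), 2500 / fs)
      if (signals) {
        sim <- simulate_recording(templates, duration_s, fs,
                                  mean_durations_ms = dur_s, snr = snr,
                                  seed = sub_seeds[s], amplitudes = amp)
        recordings[[s]] <- sim$recording
        runs <- sim$truth$runs
      } else {
        runs <- withr::with_seed(sub_seeds[s],
                                 .run_sequence(n_samples, dur_s * fs / 1000))
      }
      ground_truth[[s]] <- list(
        runs = runs,
        labels = rep.int(runs$class, runs$length),
        target_durations_ms = dur_s,
        amplitude = amp,
        parameters = .truth_parameters(runs, n_samples, fs, k))
    }
    # covariates linked to ground-truth per-subject parameters
    z <- function(v) (v - mean(v)) / stats::sd(v)
    mmd <- t(vapply(ground_truth, function(g) g$parameters$mmd_ms,
                    numeric(k)))
    tgt <- t(vapply(ground_truth, function(g) g$target_durations_ms,
                    numeric(k)))
    mmd[is.na(mmd)] <- tgt[is.na(mmd)]  # classes with no interior run
    noise_sd <- sqrt(1 - link_slope^2)
    covariates <- data.frame(
      subject = sprintf("S%03d", seq_len(n_sub)),
      group = group,
      ma_use_frequency = -link_slope * z(mmd[, 1]) +
        stats::rnorm(n_sub, sd = noise_sd),
      twob = link_slope * z(mmd[, 2]) + stats::rnorm(n_sub, sd = noise_sd),
      ma_word_error = -link_slope * z(mmd[, 2]) +
        stats::rnorm(n_sub, sd = noise_sd))
    structure(list(recordings = recordings, group = group,
                   covariates = covariates, ground_truth = ground_truth,
                   templates = templates, fs = fs,
                   config = list(n_patients = n_patients,
                                 n_controls = n_controls,
                                 effects = effects, snr = snr, seed = seed,
                                 duration_s = duration_s, k = k,
                                 baseline_durations_ms = baseline_durations_ms,
                                 between_sd_ms = between_sd_ms,
                                 link_slope = link_slope)),
              class = "ms_study")
  })
}

#' @export
print.ms_study <- function(x, ...) {
  cat(sprintf("<ms_study> %d patients + %d controls @ %g Hz%s\n",
              x$config$n_patients, x$config$n_controls, x$fs,
              if (is.null(x$recordings[[1]])) " (ground truth only)" else ""))
  invisible(x)
}

#' Generate a smooth synthetic lead field
#'
#' Builds a channels x voxels forward matrix with fixed-orientation sources:
#' voxels are scattered below a 2-D scalp layout and each column is a smooth
#' dipolar potential pattern, then average-referenced (column mean zero).
#' The matrix has full column rank whenever `n_voxels < n_channels`.
#' A geometric stand-in for a real head-model lead field, at desk scale.
#'
#' @param n_channels Number of electrodes.
#' @param n_voxels Number of source voxels (>= 2).
#' @param seed Integer seed.
#' @return Object of class `ms_leadfield`: list with `matrix`
#'   (channels x voxels), `voxel_ids`, `channel_names`.
#' @export
make_leadfield <- function(n_channels, n_voxels, seed = 1) {
  stopifnot(n_channels >= 8, n_voxels >= 2)
  lay <- montage_layout(n_channels)
  withr::with_seed(seed, {
    K <- matrix(0, n_channels, n_voxels)
    for (j in seq_len(n_voxels)) {
      repeat {
        rr <- sqrt(stats::runif(1)) * 0.75
        th <- stats::runif(1, 0, 2 * pi)
        vx <- rr * cos(th); vy <- rr * sin(th)
        depth <- stats::runif(1, 0.25, 0.6)
        ori <- stats::rnorm(2); ori <- ori / sqrt(sum(ori^2))
        dx <- lay$x - vx; dy <- lay$y - vy
        col <- (dx * ori[1] + dy * ori[2]) / (dx^2 + dy^2 + depth^2)^1.5
        col <- col - mean(col)
        if (sum(col^2) > 0) break
      }
      K[, j] <- col
    }
    structure(list(matrix = K,
                   voxel_ids = sprintf("v%04d", seq_len(n_voxels)),
                   channel_names = paste0("Ch", seq_len(n_channels))),
              class = "ms_leadfield")
  })
}

#' @export
print.ms_leadfield <- function(x, ...) {
  cat(sprintf("<ms_leadfield> %d channels x %d voxels\n",
              nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}
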