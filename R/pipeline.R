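#' Pipeline configuration
#'
#' Validated bundle of every tunable the end-to-end pipeline needs. The
#' defaults reproduce the study conditions the package emulates: 55
#' patients vs 27 controls, 64-channel eyes-closed EEG, 2--20 Hz band,
#' 250 Hz, twenty 2-s epochs, 4 microstate classes, Bonferroni m = 4.
#'
#' @param seed Master seed; every stochastic stage derives its seed from it.
#' @param fs Analysis sampling rate (Hz).
#' @param band Band-pass edges in Hz, `c(low, high)`.
#' @param epoch_s,n_epochs Epoch length (s) and number of epochs kept.
#' @param k Number of microstate classes.
#' @param restarts Modified k-means restarts.
#' @param template_scope `"per-group"` (each subject backfitted with their
#'   own group's mean templates) or `"shared"` (one template set clustered
#'   across both groups).
#' @param n_perm,alpha Permutation count and FWE level for source contrasts.
#' @param bonferroni_m Bonferroni multiplier for the parameter t-tests.
#' @param n_patients,n_controls,duration_s,snr,n_channels Simulation shape.
#' @param n_voxels Synthetic lead-field size (source stage).
#' @param source Run the source-localization stage.
#' @return A validated list of class `ms_config`.
#' @export
pipeline_config <- function(seed = 1, fs = 250, band = c(2, 20),
                            epoch_s = 2, n_epochs = 20, k = 4,
                            restarts = 50,
                            template_scope = c("per-group", "shared"),
                            n_perm = 5000, alpha = 0.05, bonferroni_m = 4,
                            n_patients = 55, n_controls = 27,
                            duration_s = 60, snr = 5, n_channels = 64,
                            n_voxels = 200, source = TRUE) {
  template_scope <- match.arg(template_scope)
  stopifnot(fs > 0, length(band) == 2, band[1] > 0, band[1] < band[2],
            band[2] < fs / 2, epoch_s > 0, n_epochs >= 1, k >= 2,
            restarts >= 1, n_perm >= 1, alpha > 0, alpha <= 1,
            bonferroni_m >= 1, n_patients >= 2, n_controls >= 2,
            duration_s >= epoch_s * n_epochs, snr > 0, n_channels >= 8,
            n_voxels >= 2)
  structure(list(seed = seed, fs = fs, band = band, epoch_s = epoch_s,
                 n_epochs = n_epochs, k = k, restarts = restarts,
                 template_scope = template_scope, n_perm = n_perm,
                 alpha = alpha, bonferroni_m = bonferroni_m,
                 n_patients = n_patients, n_controls = n_controls,
                 duration_s = duration_s, snr = snr,
                 n_channels = n_channels, n_voxels = n_voxels,
                 source = source),
            class = "ms_config")
}

#' Run the full microstate pipeline
#'
#' Simulate (or load) a two-group study, condition the signals, run
#' two-level clustering, order classes canonically, backfit, compute the
#' per-subject parameter table, the group statistics (parameter t-table,
#' mixed ANOVA per parameter, GLMs against the covariates), and -- when a
#' lead field is available -- the per-class source contrasts with
#' permutation correction. All artifacts are written under `out_dir`
#' together with a manifest (`manifest.json`) holding the configuration and
#' seed, so a rerun with the same inputs is reproducible.
#'
#' @param config An `ms_config` from [pipeline_config()].
#' @param out_dir Output directory (created if missing).
#' @param study An existing `ms_study` to analyse; `NULL` simulates one
#'   from `config`.
#' @param leadfield An `ms_leadfield`, a path to one, or `NULL` to simulate
#'   a synthetic lead field (when `config$source` is `TRUE`).
#' @return Invisibly, a list with `parameters` (tidy per-subject table),
#'   `templates` (group-level, class-ordered), `stats` (t-table, ANOVA,
#'   GLMs), `source` (per-class `ms_snpm` or `NULL`), `study`, `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         study = NULL, leadfield = NULL) {
  stopifnot(inherits(config, "ms_config"))
  # resolve inputs up front so failures happen before any computation
  if (config$source) {
    if (is.character(leadfield)) leadfield <- read_leadfield(leadfield)
    if (is.null(leadfield))
      leadfield <- make_leadfield(config$n_channels, config$n_voxels,
                                  seed = config$seed + 3L)
    if (!inherits(leadfield, "ms_leadfield"))
      stop("source stage enabled but no usable lead field given")
    if (nrow(leadfield$matrix) != config$n_channels)
      stop("lead field channel count (", nrow(leadfield$matrix),
           ") does not match the configuration (", config$n_channels, ")")
  }
  if (is.null(study))
    study <- simulate_group_study(
      n_patients = config$n_patients, n_controls = config$n_controls,
      snr = config$snr, seed = config$seed, duration_s = config$duration_s,
      fs = config$fs, n_channels = config$n_channels, k = config$k)
  ids <- study$covariates$subject
  # --- preprocessing -------------------------------------------------------
  epoch_sets <- vector("list", length(study$recordings))
  names(epoch_sets) <- ids
  for (s in seq_along(study$recordings)) {
    epoch_sets[[s]] <- tryCatch(
      preprocess(study$recordings[[s]], low = config$band[1],
                 high = config$band[2], target_fs = config$fs,
                 epoch_s = config$epoch_s, n_epochs = config$n_epochs,
                 subject = ids[s]),
      error = function(e) stop("preprocessing failed for subject ", ids[s],
                               ": ", conditionMessage(e), call. = FALSE))
  }
  # --- two-level clustering and class ordering -----------------------------
  scope_group <- if (config$template_scope == "per-group")
    study$group else rep("all", length(epoch_sets))
  clust <- two_level_clustering(epoch_sets, scope_group, k = config$k,
                                restarts = config$restarts,
                                seed = config$seed + 1L)
  canonical <- if (!is.null(study$templates)) study$templates
               else make_templates(config$n_channels, config$k,
                                   seed = config$seed)
  group_templates <- lapply(clust$group, order_classes, canonical = canonical)
  individual <- lapply(clust$individual, order_classes, canonical = canonical)
  # --- backfitting and parameters ------------------------------------------
  params <- NULL
  for (s in seq_along(epoch_sets)) {
    ts <- group_templates[[as.character(scope_group[s])]]
    ls <- backfit(epoch_sets[[s]], ts)
    p <- microstate_parameters(ls, epoch_sets[[s]], ts)
    params <- rbind(params, cbind(subject = ids[s],
                                  group = as.character(study$group[s]), p))
  }
  # --- group statistics ----------------------------------------------------
  ttable <- parameter_table(params, bonferroni_m = config$bonferroni_m)
  anovas <- list()
  for (pm in c("mmd_ms", "rtt", "gev", "occurrence")) {
    wide <- matrix(params[[pm]], nrow = length(ids), byrow = TRUE,
                   dimnames = list(ids, unique(params$class)))
    ok <- stats::complete.cases(wide)
    anovas[[pm]] <- mixed_anova(wide[ok, , drop = FALSE],
                                study$group[ok])
  }
  glms <- NULL
  covs <- study$covariates[, setdiff(names(study$covariates),
                                     c("subject", "group")), drop = FALSE]
  if (ncol(covs) > 0) {
    glms <- list()
    for (cl in unique(params$class)) for (pm in c("mmd_ms", "gev")) {
      y <- params[params$class == cl, pm][match(ids,
             params$subject[params$class == cl])]
      if (anyNA(y)) next
      glms[[paste0(pm, "_", cl)]] <- glm_fit(y, covs)
    }
  }
  # --- source localization -------------------------------------------------
  source_res <- NULL
  if (config$source) {
    inv <- build_inverse(leadfield)
    source_res <- list()
    for (cl in group_templates[[1]]$class_labels)
      source_res[[cl]] <- source_contrast(
        individual, study$group, cl, inv, n_perm = config$n_perm,
        alpha = config$alpha, seed = config$seed + 7L)
  }
  # --- outputs -------------------------------------------------------------
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_parameters(params, file.path(out_dir, "parameters.csv"))
    for (g in names(group_templates))
      write_templates(group_templates[[g]],
                      file.path(out_dir, paste0("templates_", g, ".csv")))
    utils::write.csv(study$covariates, file.path(out_dir, "covariates.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(ttable, file.path(out_dir, "parameter_tests.csv"),
                     row.names = FALSE, quote = FALSE)
    if (!is.null(source_res)) {
      src_tab <- NULL
      for (cl in names(source_res)) {
        r <- source_res[[cl]]
        src_tab <- rbind(src_tab, data.frame(
          class = cl, voxel = seq_along(r$statistic),
          statistic = r$statistic,
          suprathreshold = seq_along(r$statistic) %in% r$suprathreshold))
      }
      utils::write.csv(src_tab, file.path(out_dir, "source_contrasts.csv"),
                       row.names = FALSE, quote = FALSE)
    }
    jsonlite::write_json(
      list(package = "eegmicrostates",
           version = as.character(utils::packageVersion("eegmicrostates")),
           config = unclass(config)),
      file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(list(parameters = params, templates = group_templates,
                 individual_templates = individual,
                 stats = list(t_table = ttable, anova = anovas, glm = glms),
                 source = source_res, study = study, config = config))
}
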