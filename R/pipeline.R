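FEATURE_DVS <- c("motor_time", "peak_shoulder_flex", "peak_shoulder_abd",
                 "peak_elbow_flex", "peak_vel_shoulder_flex",
                 "peak_vel_shoulder_abd", "peak_vel_elbow_flex")
PIPELINE_COVARIATES <- c("sex", "age", "bmi", "months_post_onset",
                         "disp_manubrium", "disp_occiput")
CLUSTER_VARS <- c("motor_time", "peak_shoulder_flex", "peak_shoulder_abd",
                  "peak_elbow_flex")

#' Pipeline configuration
#'
#' Serializable configuration that, together with the inputs, fully
#' determines a pipeline run.
#'
#' @param cohort a [cohort_spec()] used when no input files are given.
#' @param input_paths optional marker files (TRC / long CSV) to analyse
#'   instead of a simulated cohort.
#' @param covariates_path optional covariate CSV companion for input files.
#' @param features a [feature_config()].
#' @param forest a [forest_config()] for the clustering stage.
#' @param k_max largest candidate cluster count for the elbow method.
#' @param row_unit clustering row construction: `"trial"` (one row per
#'   trial, default) or `"frame"` (per-frame angle samples joined to the
#'   trial motor time, subsampled by `frame_stride`).
#' @param frame_stride keep every `frame_stride`-th frame in frame mode.
#' @param alpha significance level gating which features enter the logistic
#'   / ROC stage.
#' @param output_dir optional directory for CSV/JSON artifacts.
#' @param seed integer master seed; overrides `cohort$seed` and seeds the
#'   clustering stage.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_spec(), input_paths = NULL,
                            covariates_path = NULL,
                            features = feature_config(),
                            forest = forest_config(n_trees = 500),
                            k_max = 8, row_unit = c("trial", "frame"),
                            frame_stride = 10, alpha = 0.05,
                            output_dir = NULL, seed = 1L) {
  row_unit <- match.arg(row_unit)
  structure(list(cohort = cohort, input_paths = input_paths,
                 covariates_path = covariates_path, features = features,
                 forest = forest, k_max = k_max, row_unit = row_unit,
                 frame_stride = frame_stride, alpha = alpha,
                 output_dir = output_dir, seed = seed),
            class = "pipeline_config")
}

# Keep only covariates that vary and that extend the column space of the
# design (participant-level covariates collapse to few distinct patterns in
# small cohorts and become collinear).
usable_covariates <- function(sub, covs) {
  kept <- character()
  X <- matrix(1, nrow(sub), 1)
  for (cv in covs) {
    v <- sub[[cv]]
    if (length(unique(v)) < 2) next
    col <- if (is.numeric(v)) matrix(as.numeric(v), ncol = 1) else
      stats::model.matrix(~v)[, -1, drop = FALSE]
    cand <- cbind(X, col)
    if (qr(cand)$rank == ncol(cand)) {
      X <- cand
      kept <- c(kept, cv)
    }
  }
  kept
}

descriptive_table <- function(features) {
  out <- list()
  for (ph in unique(features$phase)) for (sd_ in unique(features$side)) {
    sub <- features[features$phase == ph & features$side == sd_, ]
    for (v in c(FEATURE_DVS, "disp_manubrium", "disp_occiput")) {
      out[[length(out) + 1]] <- data.frame(
        phase = ph, side = sd_, feature = v, n = nrow(sub),
        mean = mean(sub[[v]]), sd = sd(sub[[v]]),
        min = min(sub[[v]]), max = max(sub[[v]]))
    }
  }
  do.call(rbind, out)
}

normality_table <- function(features, alpha) {
  out <- list()
  for (ph in unique(features$phase)) {
    sub <- features[features$phase == ph, ]
    for (v in FEATURE_DVS) {
      sw_p <- vapply(split(sub[[v]], sub$side),
                     function(x) shapiro_wilk(x)$p, numeric(1))
      normal <- all(sw_p >= alpha)
      kw <- if (!normal) kruskal_wallis(sub[[v]], sub$side) else
        list(H = NA_real_, p = NA_real_)
      out[[length(out) + 1]] <- data.frame(
        phase = ph, feature = v, sw_p_min = min(sw_p), normal = normal,
        kruskal_H = kw$H, kruskal_p = kw$p)
    }
  }
  do.call(rbind, out)
}

cluster_rows <- function(trials, features, side_, phase_, row_unit,
                         frame_stride, fconfig) {
  if (row_unit == "trial") {
    sub <- features[features$side == side_ & features$phase == phase_, ]
    return(as.matrix(sub[, CLUSTER_VARS]))
  }
  rows <- list()
  for (tr in trials) {
    if (tr$side != side_) next
    mk <- canonical_markers(tr)
    if (!is.null(fconfig$filter_cutoff))
      mk <- lapply(mk, lowpass_filter, fs = tr$sampling_rate,
                   cutoff_hz = fconfig$filter_cutoff,
                   order = fconfig$filter_order)
    bounds <- detect_motion_bounds(mk$FIN, tr$sampling_rate,
                                   speed_eps = fconfig$speed_eps,
                                   window_s = fconfig$window_s)
    b <- if (phase_ == "outward") bounds$outward else bounds$ret
    bases <- build_segment_bases(mk)
    sh <- shoulder_angles(bases)
    el <- elbow_flexion(bases)
    idx <- seq(b$onset_frame, b$end_frame, by = frame_stride)
    mt <- (b$end_frame - b$onset_frame) / tr$sampling_rate
    rows[[length(rows) + 1]] <- cbind(motor_time = mt,
                                      peak_shoulder_flex = sh$flex[idx],
                                      peak_shoulder_abd = sh$abd[idx],
                                      peak_elbow_flex = el[idx])
  }
  do.call(rbind, rows)
}

#' Run the full analysis pipeline
#'
#' Orchestrates the end-to-end chain on a simulated cohort or supplied
#' marker files: feature extraction, descriptive statistics per side and
#' phase, covariate-adjusted multivariate side comparison with a
#' normality-gated rank-test fallback, binomial logistic fits and ROC
#' cutoffs for the features that separate the sides, DeLong comparison of
#' each feature's AUC against the motor-time AUC, and unsupervised
#' random-forest clustering per side x phase condition with elbow-method
#' cluster-count selection and z-value cluster profiles. The run is
#' deterministic under `config$seed`.
#'
#' @param config a [pipeline_config()].
#' @return An object of class `run_report` (see print method) with elements
#'   `features`, `descriptives`, `manova`, `normality`, `logistic`, `roc`,
#'   `delong`, `clusters`, `config`, `parameters`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  trials <- if (!is.null(config$input_paths)) {
    covs <- if (!is.null(config$covariates_path))
      read.csv(config$covariates_path) else NULL
    read_trial_files(config$input_paths, covariates = covs)
  } else {
    spec <- config$cohort
    if (!is.null(config$seed)) spec$seed <- config$seed
    generate_cohort(spec)
  }
  n_part <- length(unique(vapply(trials, function(tr)
    as.character(tr$participant_id), character(1))))
  small_sample <- n_part < 8
  if (small_sample)
    warning(sprintf(
      "small sample: %d participants (below the n = 8 exact-binomial minimum); estimates will be unstable",
      n_part), call. = FALSE)

  features <- extract_cohort_features(trials, config$features)
  desc <- descriptive_table(features)
  norm_tab <- normality_table(features, config$alpha)

  manova_res <- list(); logistic_res <- list(); roc_res <- list()
  delong_res <- list()
  covariates_used <- list()
  for (ph in c("outward", "return")) {
    sub <- features[features$phase == ph, ]
    covs <- usable_covariates(sub, PIPELINE_COVARIATES)
    covariates_used[[ph]] <- covs
    if (length(covs) < length(PIPELINE_COVARIATES))
      warning(sprintf(
        "%s phase: dropped constant/collinear covariates: %s", ph,
        paste(setdiff(PIPELINE_COVARIATES, covs), collapse = ", ")),
        call. = FALSE)
    mv <- tryCatch(
      manova_rm(sub, dvs = FEATURE_DVS, factor = "side", covariates = covs),
      headreach_error = function(e) {
        warning(sprintf("%s phase: multivariate comparison infeasible (%s)",
                        ph, conditionMessage(e)), call. = FALSE)
        NULL
      })
    manova_res[[ph]] <- mv
    sig <- if (is.null(mv)) character() else
      mv$univariate$dv[mv$univariate$p < config$alpha]
    fits <- list(); rocs <- list(); dls <- list()
    for (v in sig) {
      fits[[v]] <- logistic_fit(sub, response = "side", predictor = v,
                                covariates = covs)
      rocs[[v]] <- roc_analysis(sub[[v]], sub$side)
      if (v != "motor_time" && "motor_time" %in% sig)
        dls[[v]] <- delong_auc_test(sub$motor_time, sub[[v]], sub$side)
    }
    logistic_res[[ph]] <- fits
    roc_res[[ph]] <- rocs
    delong_res[[ph]] <- dls
  }

  clusters <- list()
  cond_i <- 0
  for (sd_ in c("paralyzed", "non_paralyzed")) for (ph in c("outward", "return")) {
    cond_i <- cond_i + 1
    x <- cluster_rows(trials, features, sd_, ph, config$row_unit,
                      config$frame_stride, config$features)
    fc <- config$forest
    fc$seed <- if (is.null(config$seed)) NULL else config$seed + 100 * cond_i
    fit <- fit_unsupervised_forest(x, fc)
    kmax <- min(config$k_max, nrow(x) - 1)
    eb <- elbow_select_k(x, fit$proximity, k_max = kmax,
                         seed = fc$seed)
    prof <- cluster_profiles(x, eb$assignments)
    clusters[[paste(sd_, ph, sep = "_")]] <-
      list(side = sd_, phase = ph, n = nrow(x), k = eb$k,
           low_confidence = eb$low_confidence, wss_by_k = eb$wss_by_k,
           aic_by_k = eb$aic_by_k, bic_by_k = eb$bic_by_k,
           assignments = eb$assignments, r_squared = prof$r_squared,
           profiles = prof$profiles)
  }

  params <- list(speed_eps = config$features$speed_eps,
                 window_s = config$features$window_s,
                 filter_cutoff = config$features$filter_cutoff,
                 filter_order = config$features$filter_order,
                 velocity_mode = config$features$velocity_mode,
                 euler_order = "flexion-abduction-axial (YXZ, branch |flex| < 90)",
                 roc_direction = "score >= threshold predicts paralyzed",
                 row_unit = config$row_unit, k_max = config$k_max,
                 n_trees = config$forest$n_trees, seed = config$seed,
                 covariates_used = covariates_used)

  report <- structure(list(features = features, descriptives = desc,
                           normality = norm_tab, manova = manova_res,
                           logistic = logistic_res, roc = roc_res,
                           delong = delong_res, clusters = clusters,
                           small_sample = small_sample,
                           n_participants = n_part,
                           parameters = params, config = config),
                      class = "run_report")
  if (!is.null(config$output_dir)) write_report_artifacts(report)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %d trials x 2 phases, %d participants%s\n",
              nrow(x$features) / 2, x$n_participants,
              if (x$small_sample) " [small-sample warning]" else ""))
  for (ph in names(x$manova)) {
    mv <- x$manova[[ph]]
    if (is.null(mv)) {
      cat(sprintf("  %s: multivariate comparison not available\n", ph))
      next
    }
    cat(sprintf("  %s: Wilks lambda %.3f, F[%d,%d] = %.1f, p %s\n", ph,
                mv$wilks_lambda, mv$df1, mv$df2, mv$F,
                format.pval(mv$p, digits = 3)))
    for (v in names(x$roc[[ph]])) {
      r <- x$roc[[ph]][[v]]
      cat(sprintf("    %-24s cutoff %8.3g  sens %.2f  spec %.2f  J %.2f  AUC %.2f\n",
                  v, r$cutoff, r$sensitivity_at_cutoff,
                  r$specificity_at_cutoff, r$j_at_cutoff, r$auc))
    }
  }
  for (nm in names(x$clusters)) {
    cl <- x$clusters[[nm]]
    cat(sprintf("  clusters %-24s k = %d (n = %d, R2 = %.2f)%s\n", nm, cl$k,
                cl$n, cl$r_squared,
                if (cl$low_confidence) " [low confidence]" else ""))
  }
  invisible(x)
}

write_report_artifacts <- function(report) {
  dir.create(report$config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(report$config$output_dir, f)
  write.csv(report$features, out("features.csv"), row.names = FALSE)
  write.csv(report$descriptives, out("descriptives.csv"), row.names = FALSE)
  write.csv(report$normality, out("normality.csv"), row.names = FALSE)
  roc_rows <- list()
  for (ph in names(report$roc)) for (v in names(report$roc[[ph]])) {
    r <- report$roc[[ph]][[v]]
    roc_rows[[paste(ph, v)]] <- data.frame(
      phase = ph, feature = v, threshold = r$thresholds,
      sensitivity = r$sensitivity, specificity = r$specificity,
      youden_j = r$youden_j)
  }
  if (length(roc_rows))
    write.csv(do.call(rbind, roc_rows), out("roc_coordinates.csv"),
              row.names = FALSE)
  curves <- do.call(rbind, lapply(report$clusters, function(cl)
    data.frame(side = cl$side, phase = cl$phase,
               k = seq_along(cl$wss_by_k), wss = cl$wss_by_k,
               aic = cl$aic_by_k, bic = cl$bic_by_k)))
  write.csv(curves, out("cluster_curves.csv"), row.names = FALSE)
  jsonlite::write_json(report_summary(report), out("report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(NULL)
}

# compact JSON-serializable summary mirroring the report tables
report_summary <- function(report) {
  roc_sum <- list()
  for (ph in names(report$roc)) {
    roc_sum[[ph]] <- lapply(report$roc[[ph]], function(r)
      list(cutoff = r$cutoff, sensitivity = r$sensitivity_at_cutoff,
           specificity = r$specificity_at_cutoff, youden_j = r$j_at_cutoff,
           auc = r$auc))
  }
  list(
    parameters = report$parameters,
    n_participants = report$n_participants,
    manova = lapply(report$manova, function(m)
      if (is.null(m)) NULL else
        list(wilks_lambda = m$wilks_lambda, F = m$F, df1 = m$df1,
             df2 = m$df2, p = m$p)),
    logistic = lapply(report$logistic, function(fits)
      lapply(fits, function(f)
        list(deviance = f$deviance, aic = f$aic,
             mcfadden_r2 = f$mcfadden_r2, chisq = f$chisq, df = f$df,
             p = f$p))),
    roc = roc_sum,
    clusters = lapply(report$clusters, function(cl)
      list(n = cl$n, k = cl$k, r_squared = cl$r_squared,
           low_confidence = cl$low_confidence)))
}
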