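#' Run the full prediction pipeline from a configuration
#'
#' End-to-end orchestration: read montage and subjects table, preprocess
#' every baseline recording, build the seed-coherence feature matrix and
#' the outcome, fit the LOOCV lasso (and the comparison models: relative
#' power, CST injury, baseline UEFM, plus the residualized coherence
#' models), and write the feature matrix CSV, model JSON and a text
#' report.  Output is a pure function of the configuration, input files
#' and seed.  Per-stage progress and timing are logged to stderr.
#'
#' @param config a list, or path to a JSON file, with members `subjects`
#'   (CSV path), `montage` (JSON path), `out_dir`, and optional `options`
#'   (members `alpha`, `select`, `lowpass_hz`, `reject_uv`, `window`,
#'   `aggregate`, `power_model`, `residual_models`, `serial`, `seed`).
#' @return A `pipeline_report` list (invisibly): models, feature matrix
#'   paths and summary numbers.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::fromJSON(config)
  for (f in c("subjects", "montage", "out_dir"))
    if (is.null(config[[f]]))
      stop("configuration is missing required field '", f, "'")
  opt <- config$options
  getopt <- function(name, default)
    if (name %in% names(opt)) opt[[name]] else default
  alpha <- getopt("alpha", 1)
  select <- getopt("select", "min")
  lowpass_hz <- getopt("lowpass_hz", 50)
  reject_uv <- getopt("reject_uv", 100)
  window <- getopt("window", "rectangular")
  aggregate <- getopt("aggregate", "mean")
  seed <- getopt("seed", 1L)
  set.seed(seed)

  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    r <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    message(sprintf("[%s] %.1fs", name, proc.time()[["elapsed"]] - t0))
    r
  }

  montage <- stage("read_montage", read_montage(config$montage))
  subjects <- stage("read_subjects", read_subjects(config$subjects))
  scheme <- band_scheme()
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  fm <- stage("features",
              build_feature_matrix(subjects, montage, scheme,
                                   lowpass_hz = lowpass_hz,
                                   reject_uv = reject_uv, window = window,
                                   aggregate = aggregate))
  y <- outcome_vector(subjects)
  fpath <- file.path(config$out_dir, "features.csv")
  write_features(fm, fpath)

  model <- stage("fit", coh_enet(fm, y, alpha = alpha, select = select))
  write_model_json(model, file.path(config$out_dir, "model.json"))

  comparisons <- list()
  if (isTRUE(getopt("power_model", TRUE))) {
    pm <- stage("power_features",
                build_power_matrix(subjects, montage, scheme,
                                   lowpass_hz = lowpass_hz,
                                   reject_uv = reject_uv, window = window))
    comparisons$power <- stage("power_fit",
                               coh_enet(pm, y, alpha = alpha,
                                        select = select))
  }
  comparisons$cst <- stage("cst_model",
                           simple_linear_model(subjects$cst_injury, y))
  comparisons$uefm <- stage("uefm_model",
                            simple_linear_model(subjects$uefm, y))
  serial <- NULL
  if (isTRUE(getopt("serial", FALSE)) &&
      any(!is.na(subjects$rec_visit2) & nzchar(subjects$rec_visit2)))
    serial <- stage("serial", {
      base_maps <- visit_coherence_maps(subjects, montage, scheme,
                                        "baseline",
                                        lowpass_hz = lowpass_hz,
                                        reject_uv = reject_uv)
      v2_maps <- visit_coherence_maps(subjects, montage, scheme,
                                      "visit2",
                                      lowpass_hz = lowpass_hz,
                                      reject_uv = reject_uv)
      serial_coherence_change(base_maps, v2_maps, montage, outcome = y)
    })

  residuals <- NULL
  if (isTRUE(getopt("residual_models", TRUE)))
    residuals <- stage("residual_models", list(
      cst = residual_coherence_model(fm, y, subjects$cst_injury,
                                     alpha = alpha, select = select),
      uefm = residual_coherence_model(fm, y, subjects$uefm,
                                      alpha = alpha, select = select)))

  report <- structure(list(
    n = nrow(subjects),
    outcome_mean = attr(y, "mean"), outcome_sd = attr(y, "sd"),
    model = model, comparisons = comparisons, residual_models = residuals,
    serial = serial, features_path = fpath, config = config),
    class = "pipeline_report")
  stage("report", .write_report(report,
                                file.path(config$out_dir, "report.txt")))
  invisible(report)
}

.write_report <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  m <- report$model
  w("Seed-coherence motor-recovery prediction report")
  w("===============================================")
  w("Subjects: %d", report$n)
  w("FIM-motor change: %.1f +- %.1f points", report$outcome_mean,
    report$outcome_sd)
  w("")
  w("Coherence model (%s, lambda rule '%s'):",
    if (m$alpha == 1) "lasso" else sprintf("elastic net alpha=%.2f",
                                           m$alpha), m$select)
  w("  cross-validated R2: %.1f%% (raw %.3f)", 100 * max(0, m$r2_cv),
    m$r2_cv)
  w("  in-sample R2:       %.1f%%", 100 * m$r2_insample)
  w("  selected features (%d):", length(m$selected))
  s <- summary(m)$selected
  if (nrow(s)) for (i in seq_len(nrow(s)))
    w("    %-18s beta = %8.3f  %s", s$feature[i], s$coefficient[i],
      if (!is.null(s$region)) paste0("[", s$region[i], "]") else "")
  if (!is.null(report$comparisons$power))
    w("Relative-power model: cross-validated R2 = %.1f%%",
      100 * max(0, report$comparisons$power$r2_cv))
  w("CST injury model:  R2 = %.1f%%, p = %.3g",
    100 * report$comparisons$cst$r2, report$comparisons$cst$p_value)
  w("Baseline UEFM model: R2 = %.1f%%, p = %.3g",
    100 * report$comparisons$uefm$r2, report$comparisons$uefm$p_value)
  if (!is.null(report$residual_models)) {
    w("Residualized coherence models (cross-validated R2):")
    w("  vs CST residuals:  %.1f%%",
      100 * max(0, report$residual_models$cst$model$r2_cv))
    w("  vs UEFM residuals: %.1f%%",
      100 * max(0, report$residual_models$uefm$model$r2_cv))
  }
  if (!is.null(report$serial)) {
    w("Serial coherence change (visit2 - baseline):")
    s2 <- report$serial$stats
    for (i in seq_len(nrow(s2)))
      w("  iM1-%-5s %-9s n=%2d median=%+.3f t=%.2f p=%.3g r=%.2f",
        s2$region[i], s2$band[i], s2$n[i], s2$median[i], s2$t[i],
        s2$p[i], s2$r[i])
  }
  invisible(path)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report> n =", x$n, "\n")
  print(x$model)
  invisible(x)
}
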