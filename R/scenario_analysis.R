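#' Maximum safe soybean intake at a target cancer-risk percentile
#'
#' CR is exactly proportional to the intake rate IR, so the intake that
#' brings the chosen CR percentile down to `target_cr` is
#' `IR* = IR * target_cr / P(CR)` with `P(CR)` the percentile at the
#' current IR. The shortcut is verified by re-running the Monte-Carlo
#' simulation at `IR*` with the same seed and asserting the percentile
#' lands within 2% of the target.
#'
#' @param dist a [fit_concentration_distribution()] handle for the
#'   current contamination level.
#' @param params an [exposure_params()].
#' @param target_cr target carcinogenic risk (default 1e-4).
#' @param percentile CR percentile to control, one of 1, 25, 50, 75, 95,
#'   99 (default 95).
#' @param cfg an [mc_config()].
#' @return object of class `scenario_result` with `safe_intake` (g/day),
#'   the verification risk summary at `IR*`, and a verdict.
#' @export
safe_intake <- function(dist, params = exposure_params(),
                        target_cr = 1e-4, percentile = 95,
                        cfg = mc_config()) {
  stopifnot(target_cr > 0, percentile %in% .risk_probs)
  key <- paste0("P", percentile)
  base <- monte_carlo_risk(dist, params, cfg)
  p_cr <- base$cr[[key]]
  if (p_cr <= 0) stop("degenerate zero-risk distribution")
  ir_star <- params$IR * target_cr / p_cr
  params_star <- params
  params_star$IR <- ir_star
  check <- monte_carlo_risk(dist, params_star, cfg)
  if (abs(check$cr[[key]] / target_cr - 1) > 0.02) {
    stop("safe-intake verification failed: re-run percentile off target")
  }
  structure(list(
    kind = "safe_intake",
    inputs = list(target_cr = target_cr, percentile = percentile,
                  baseline_ir = params$IR, seed = cfg$seed),
    safe_intake = ir_star,
    baseline_summary = base,
    risk_summary = check,
    verdict = if (check$cr[[key]] <= target_cr * 1.02) "acceptable"
              else "unacceptable"
  ), class = "scenario_result")
}

#' Re-assess risk at a different soybean intake
#'
#' Re-runs the Monte-Carlo risk with all parameters unchanged except the
#' intake rate. With the same seed the draws are common, so CR percentiles
#' scale exactly by `new_ir / IR`.
#'
#' @param dist concentration distribution handle.
#' @param params an [exposure_params()].
#' @param new_ir intake rate to assess, g/day.
#' @param cfg an [mc_config()].
#' @return `scenario_result` with the risk summary at `new_ir`; verdict is
#'   unacceptable iff P95(CR) > 1e-4.
#' @export
intake_scenario <- function(dist, params = exposure_params(), new_ir,
                            cfg = mc_config()) {
  stopifnot(new_ir > 0)
  params2 <- params
  params2$IR <- new_ir
  rs <- monte_carlo_risk(dist, params2, cfg)
  structure(list(
    kind = "intake",
    inputs = list(new_ir = new_ir, baseline_ir = params$IR,
                  seed = cfg$seed),
    safe_intake = NULL,
    risk_summary = rs,
    verdict = if (rs$cr[["P95"]] > 1e-4) "unacceptable" else "acceptable"
  ), class = "scenario_result")
}

#' Risk re-assessment after a uniform soil-pH increase
#'
#' For each sample the trained network predicts grain Cd at
#' `(soil_cd, soil_ph + delta_ph)`; negative predictions are clipped to 0
#' and predictions beyond the training pH range are flagged as
#' extrapolation (a +1 shift pushes some soils past the observed maximum).
#' The Monte-Carlo concentration distribution is then fitted to the
#' predicted concentrations and pushed through the probabilistic risk
#' pipeline. The verdict is unacceptable iff P95(CR) > 1e-4. A baseline
#' for comparison should use the same pipeline at `delta_ph = 0` so that
#' model bias cancels.
#'
#' @param samples validated sample data frame.
#' @param model a trained [train_nn()] model.
#' @param delta_ph uniform pH shift (default +1).
#' @param params an [exposure_params()].
#' @param cfg an [mc_config()].
#' @return `scenario_result`; also carries the predicted concentrations
#'   (`predicted`), the number clipped at 0 and the extrapolation count.
#' @export
ph_shift_scenario <- function(samples, model, delta_ph = 1.0,
                              params = exposure_params(),
                              cfg = mc_config()) {
  if (!inherits(model, "nn_model")) stop("model must be a trained nn_model")
  validate_samples(samples)
  pred <- predict_nn(model, samples$soil_cd, samples$soil_ph + delta_ph)
  extrapolated <- attr(pred, "extrapolated")
  pred <- as.numeric(pred)
  clipped <- pred < 0
  pred[clipped] <- 0
  dist <- fit_concentration_distribution(pred, cfg$family)
  rs <- monte_carlo_risk(dist, params, cfg)
  structure(list(
    kind = "ph_shift",
    inputs = list(delta_ph = delta_ph, seed = cfg$seed,
                  family = cfg$family),
    predicted = pred,
    n_clipped = sum(clipped),
    n_extrapolated = sum(extrapolated),
    risk_summary = rs,
    verdict = if (rs$cr[["P95"]] > 1e-4) "unacceptable" else "acceptable"
  ), class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("Scenario: %s\n", x$kind))
  if (!is.null(x$safe_intake)) {
    cat(sprintf("  safe intake: %.4g g/day\n", x$safe_intake))
  }
  cat(sprintf("  P95(CR) = %.3g; verdict: %s\n",
              x$risk_summary$cr[["P95"]], x$verdict))
  invisible(x)
}
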