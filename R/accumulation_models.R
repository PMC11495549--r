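#' Bioconcentration factor of soybean grain for Cd
#'
#' BCF = grain Cd / soil Cd for each paired sample; dimensionless.
#'
#' @param soybean_cd either a validated sample data frame, or a numeric
#'   vector of grain Cd concentrations (mg/kg).
#' @param soil_cd numeric vector of soil Cd concentrations (mg/kg); ignored
#'   when `soybean_cd` is a data frame.
#' @return numeric vector of BCF values.
#' @export
compute_bcf <- function(soybean_cd, soil_cd = NULL) {
  if (is.data.frame(soybean_cd)) {
    soil_cd <- soybean_cd$soil_cd
    soybean_cd <- soybean_cd$soybean_cd
  }
  stopifnot(length(soybean_cd) == length(soil_cd))
  if (any(soil_cd <= 0)) stop("soil_cd must be > 0 to form a BCF ratio")
  soybean_cd / soil_cd
}

#' Pearson product-moment correlation with constant-series flagging
#'
#' Thin wrapper around the usual product-moment coefficient that returns a
#' flagged `NA` (attribute `reason = "constant"`) instead of dividing by a
#' zero standard deviation.
#'
#' @param x,y equal-length numeric vectors, length >= 3.
#' @return correlation coefficient in `[-1, 1]`, or flagged `NA` when
#'   either series is constant.
#' @export
pearson_corr <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (sd(x) == 0 || sd(y) == 0) {
    return(structure(NA_real_, reason = "constant"))
  }
  cor(x, y)
}

#' Two-area comparison by the least-significant-difference test
#'
#' With two groups the one-way ANOVA + LSD procedure reduces to a
#' pooled-variance two-sample t test; differences are reported as
#' low-area mean minus high-area mean.
#'
#' @param samples validated sample data frame containing both areas.
#' @param variable one of `"soil_cd"`, `"soil_ph"`, `"soybean_cd"`,
#'   `"bcf"`.
#' @return list with `variable`, `difference`, `t`, `df` and two-sided
#'   `p_value`.
#' @export
compare_areas <- function(samples,
                          variable = c("soil_cd", "soil_ph", "soybean_cd",
                                       "bcf")) {
  variable <- match.arg(variable)
  validate_samples(samples)
  v <- if (variable == "bcf") compute_bcf(samples) else samples[[variable]]
  g <- factor(samples$area, levels = .areas)
  if (any(table(g) < 2)) {
    stop("both areas must be present with at least 2 samples")
  }
  tt <- stats::t.test(v[g == "low"], v[g == "high"], var.equal = TRUE)
  list(variable = variable,
       difference = unname(tt$estimate[1] - tt$estimate[2]),
       t = unname(tt$statistic),
       df = unname(tt$parameter),
       p_value = tt$p.value)
}

#' Fit a multiple linear regression of grain Cd (or BCF) on soil Cd and pH
#'
#' Ordinary least squares on the model `response ~ soil_cd + soil_ph`
#' (raw scale, intercept included), the accumulation model used for both
#' the per-area and pooled fits.
#'
#' @param samples validated sample data frame.
#' @param response `"soybean_cd"` or `"bcf"`.
#' @param area `"pooled"` (default), `"low"` or `"high"`.
#' @return object of class `mlr_model`: coefficients, `r_squared`, overall
#'   F-test `p_value`, `n`, and the underlying `lm` fit.
#' @export
fit_mlr <- function(samples, response = c("soybean_cd", "bcf"),
                    area = c("pooled", "low", "high")) {
  response <- match.arg(response)
  area <- match.arg(area)
  validate_samples(samples)
  if (area != "pooled") samples <- samples[samples$area == area, ]
  if (nrow(samples) < 5) stop("need at least 5 samples after filtering")
  y <- if (response == "bcf") compute_bcf(samples) else samples$soybean_cd
  dat <- data.frame(y = y, soil_cd = samples$soil_cd,
                    soil_ph = samples$soil_ph)
  fit <- lm(y ~ soil_cd + soil_ph, data = dat)
  cf <- coef(fit)
  if (anyNA(cf)) {
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(names(cf)[is.na(cf)], collapse = ", "))
  }
  sm <- summary(fit)
  fstat <- sm$fstatistic
  structure(list(
    response = response,
    area = area,
    coef_soil_cd = unname(cf["soil_cd"]),
    coef_soil_ph = unname(cf["soil_ph"]),
    intercept = unname(cf["(Intercept)"]),
    r_squared = sm$r.squared,
    p_value = unname(pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)),
    n = nrow(samples),
    fit = fit
  ), class = "mlr_model")
}

#' Predict from a fitted or reference linear accumulation model
#'
#' Evaluates `intercept + coef_soil_cd * soil_cd + coef_soil_ph * soil_ph`.
#' Negative predictions (possible because the fits are unconstrained) are
#' clipped to 0; clipping is flagged through the `clipped` attribute and a
#' warning.
#'
#' @param model an `mlr_model`, e.g. from [fit_mlr()] or
#'   [reference_equations()].
#' @param soil_cd,soil_ph numeric vectors (mg/kg and pH units).
#' @return predicted grain Cd (mg/kg) or BCF, with attribute `clipped`.
#' @export
predict_mlr <- function(model, soil_cd, soil_ph) {
  stopifnot(inherits(model, "mlr_model"))
  pred <- model$intercept + model$coef_soil_cd * soil_cd +
    model$coef_soil_ph * soil_ph
  clipped <- pred < 0
  if (any(clipped)) {
    warning(sum(clipped), " negative prediction(s) clipped to 0")
    pred[clipped] <- 0
  }
  structure(pred, clipped = clipped)
}

#' Published reference regression equations
#'
#' The six published fits, frozen as constants for evaluation and
#' comparison (the raw survey data are not released, so they are never
#' refit): grain Cd on (soil Cd, soil pH) per area and pooled, BCF on
#' (soil Cd, soil pH) per area, and a worldwide pH-only meta-regression of
#' mean grain Cd (its soil-Cd coefficient is 0 by construction).
#'
#' @return named list of `mlr_model` objects (`soybean_low`,
#'   `soybean_high`, `soybean_pooled`, `bcf_low`, `bcf_high`,
#'   `worldwide_ph_only`), each carrying coefficients, `r_squared`,
#'   `p_value` (where published) and `n`.
#' @export
reference_equations <- function() {
  mk <- function(response, area, cd, ph, b0, r2, p, n) {
    structure(list(response = response, area = area,
                   coef_soil_cd = cd, coef_soil_ph = ph, intercept = b0,
                   r_squared = r2, p_value = p, n = n, fit = NULL),
              class = "mlr_model")
  }
  list(
    soybean_low    = mk("soybean_cd", "low",     0.057, -0.091, 0.612,
                        0.778, NA, 18),
    soybean_high   = mk("soybean_cd", "high",   -0.065, -0.106, 1.143,
                        0.133, 0.134, 18),
    soybean_pooled = mk("soybean_cd", "pooled",  0.133, -0.091, 0.646,
                        0.208, 0.008, 36),
    bcf_low        = mk("bcf", "low",           -0.443, -0.159, 1.391,
                        0.791, NA, 18),
    bcf_high       = mk("bcf", "high",          -0.205, -0.099, 1.222,
                        0.480, 0.003, 18),
    worldwide_ph_only = mk("soybean_cd", "worldwide", 0, -0.313, 0.972,
                           0.650, NA, 10)
  )
}
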