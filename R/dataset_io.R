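#' Validate a paired soil-soybean sample table
#'
#' Checks the structural and physical invariants of a paired sample table:
#' positive soil Cd, non-negative grain Cd, soil pH in the open interval
#' (3, 10), and an area label of `"low"` or `"high"`.
#'
#' @param samples data frame with columns `sample_id`, `area`, `soil_cd`,
#'   `soil_ph`, `soybean_cd`.
#' @param strict logical; if `TRUE` stop at the first offending row,
#'   otherwise collect all violations and report them together.
#' @return The validated data frame, invisibly unchanged.
#' @export
validate_samples <- function(samples, strict = TRUE) {
  need <- c("sample_id", "area", .vars)
  miss <- setdiff(need, names(samples))
  if (length(miss) > 0) {
    stop("sample table is missing column(s): ", paste(miss, collapse = ", "))
  }
  bad <- list()
  flag <- function(rows, msg) {
    if (any(rows)) bad[[length(bad) + 1]] <<- sprintf("row %d: %s",
                                                      which(rows), msg)
  }
  for (v in .vars) {
    x <- samples[[v]]
    flag(rep(!is.numeric(x), nrow(samples)) | is.na(x),
         sprintf("non-numeric or missing %s", v))
  }
  num <- function(v) {
    x <- samples[[v]]
    if (is.numeric(x)) ifelse(is.na(x), NA_real_, x) else NA_real_
  }
  flag(!samples$area %in% .areas, "area not one of low|high")
  flag(!is.na(num("soil_cd")) & num("soil_cd") <= 0, "soil_cd must be > 0")
  flag(!is.na(num("soybean_cd")) & num("soybean_cd") < 0,
       "soybean_cd must be >= 0")
  flag(!is.na(num("soil_ph")) &
         (num("soil_ph") <= 3 | num("soil_ph") >= 10),
       "soil_ph outside (3, 10)")
  problems <- unlist(bad)
  if (length(problems) > 0) {
    if (strict) stop(problems[1], call. = FALSE)
    stop("invalid sample table:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }
  invisible(samples)
}

#' Read a paired soil-soybean sample table from CSV
#'
#' The interchange format is a UTF-8 CSV with header
#' `sample_id,area,soil_cd_mg_kg,soil_ph,soybean_cd_mg_kg`, `.` as decimal
#' separator and area labels `low`/`high`. Concentrations are mg/kg dry
#' weight (soil and grain respectively).
#'
#' @param path path to the CSV file.
#' @param strict passed to [validate_samples()].
#' @return data frame with columns `sample_id`, `area`, `soil_cd`,
#'   `soil_ph`, `soybean_cd`, one row per sample, input order preserved.
#' @export
read_samples <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  miss <- setdiff(.csv_cols, names(raw))
  if (length(miss) > 0) {
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "))
  }
  out <- data.frame(
    sample_id  = raw$sample_id,
    area       = raw$area,
    soil_cd    = suppressWarnings(as.numeric(raw$soil_cd_mg_kg)),
    soil_ph    = suppressWarnings(as.numeric(raw$soil_ph)),
    soybean_cd = suppressWarnings(as.numeric(raw$soybean_cd_mg_kg)),
    stringsAsFactors = FALSE
  )
  validate_samples(out, strict = strict)
  out
}

#' Write a paired sample table to the standard CSV format
#'
#' Values are written at full double precision so that a write/read
#' round trip is lossless.
#'
#' @param samples validated sample data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_samples <- function(samples, path) {
  validate_samples(samples)
  out <- data.frame(
    sample_id        = samples$sample_id,
    area             = samples$area,
    soil_cd_mg_kg    = format(samples$soil_cd, digits = 15, trim = TRUE),
    soil_ph          = format(samples$soil_ph, digits = 15, trim = TRUE),
    soybean_cd_mg_kg = format(samples$soybean_cd, digits = 15, trim = TRUE),
    stringsAsFactors = FALSE
  )
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Regulatory limits for Cd in agricultural soil and soybean grain
#'
#' Defaults follow the Chinese food-contaminant limit of 0.2 mg/kg Cd in
#' beans (GB 2762-2017) and the agricultural-soil risk screening values of
#' GB 15618-2018, which depend on soil pH. Only the screening values for
#' pH <= 5.5 (0.3 mg/kg) and pH > 7.5 (0.6 mg/kg) are fixed here; the
#' middle band defaults to 0.3 mg/kg and the whole table is configurable.
#'
#' @param soybean_limit grain Cd limit, mg/kg.
#' @param soil_limit_table data frame with columns `ph_upper` (strictly
#'   increasing upper pH bound of each band, last may be `Inf`) and `limit`
#'   (soil Cd screening value, mg/kg, all positive).
#' @return object of class `regulatory_limits`.
#' @export
regulatory_limits <- function(soybean_limit = 0.2,
                              soil_limit_table = data.frame(
                                ph_upper = c(5.5, 7.5, Inf),
                                limit    = c(0.3, 0.3, 0.6))) {
  stopifnot(is.numeric(soybean_limit), soybean_limit > 0,
            all(c("ph_upper", "limit") %in% names(soil_limit_table)),
            all(diff(soil_limit_table$ph_upper) > 0),
            all(soil_limit_table$limit > 0))
  structure(list(soybean_limit = soybean_limit,
                 soil_limit_table = soil_limit_table),
            class = "regulatory_limits")
}

# Soil screening value applicable to each sample, selected by its own pH.
soil_limit_for_ph <- function(ph, limits) {
  tab <- limits$soil_limit_table
  idx <- vapply(ph, function(p) which(p <= tab$ph_upper)[1], integer(1))
  if (anyNA(idx)) stop("soil pH above the last limit band")
  tab$limit[idx]
}

#' Per-area summary statistics and exceedance fractions
#'
#' Computes mean, standard deviation (n-1 denominator), minimum and maximum
#' of soil Cd, soil pH and soybean Cd for one area, together with the
#' fraction of samples exceeding the regulatory limits. Soybean exceedance
#' counts samples with grain Cd strictly above the food limit; soil
#' exceedance compares each sample with the screening value selected by
#' that sample's own pH.
#'
#' @param samples validated sample data frame.
#' @param area `"low"` or `"high"`.
#' @param limits a [regulatory_limits()] object.
#' @return object of class `area_summary`: list with `area`, `n`, a `stats`
#'   data frame (rows = variables, columns mean/sd/min/max) and the two
#'   exceedance fractions.
#' @export
summarize_area <- function(samples, area, limits = regulatory_limits()) {
  validate_samples(samples)
  stopifnot(area %in% .areas)
  sub <- samples[samples$area == area, , drop = FALSE]
  if (nrow(sub) < 2) {
    stop(sprintf("need at least 2 samples with area '%s', found %d",
                 area, nrow(sub)))
  }
  stats <- do.call(rbind, lapply(.vars, function(v) {
    x <- sub[[v]]
    data.frame(variable = v, mean = mean(x), sd = sd(x),
               min = min(x), max = max(x))
  }))
  rownames(stats) <- stats$variable
  structure(list(
    area = area,
    n = nrow(sub),
    stats = stats,
    exceedance_soil = mean(sub$soil_cd >
                             soil_limit_for_ph(sub$soil_ph, limits)),
    exceedance_soybean = mean(sub$soybean_cd > limits$soybean_limit)
  ), class = "area_summary")
}

#' @export
print.area_summary <- function(x, ...) {
  cat(sprintf("Paired-sample summary: %s-Cd area (n = %d)\n", x$area, x$n))
  st <- x$stats
  for (v in rownames(st)) {
    cat(sprintf("  %-10s mean %.3f  sd %.3f  min %.3f  max %.3f\n",
                v, st[v, "mean"], st[v, "sd"], st[v, "min"], st[v, "max"]))
  }
  cat(sprintf("  exceedance: soil %.1f%%, soybean %.1f%%\n",
              100 * x$exceedance_soil, 100 * x$exceedance_soybean))
  invisible(x)
}
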