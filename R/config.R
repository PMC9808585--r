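#' Default pathway configuration
#'
#' All clinical thresholds used by the engine live in configuration, not in
#' code. The defaults follow the control targets and alert conventions of the
#' Chinese type 2 diabetes prevention and control guidelines that underpin
#' the pathway model:
#'
#' \describe{
#'   \item{targets}{Glycemic/pressure control targets. A patient is "stable"
#'     (routine level 1) when all available blood-glucose readings are within
#'     target (FBG <= 7.0 mmol/L, PBG <= 10.0 mmol/L); "unsatisfactory"
#'     (routine level 2) above target; and in intensive level 3 management
#'     when fasting glucose exceeds \code{intensive_fbg} = 11.1 mmol/L
#'     (strict inequality).}
#'   \item{thresholds}{Abnormal-attention warning bounds: any blood glucose
#'     < 3.9 (hypoglycemia) or >= 16.7 mmol/L, or fasting glucose >= 13.9
#'     mmol/L (severe hyperglycemia); SBP >= 160, DBP >= 100 or SBP < 90
#'     mmHg (urgent blood pressure); heart rate < 50 or > 120 bpm; coded
#'     symptom severity >= 2.}
#'   \item{compliance}{Task-completion window (7 days) and the low-compliance
#'     cutoff (completion rate < 0.5).}
#'   \item{followup_interval_days}{Regular follow-up interval per management
#'     level: 90 days for level 1, 30 days (monthly) for levels 2 and 3 —
#'     substandard patients are followed up at least monthly, i.e. 3 times
#'     within a 90-day management cycle.}
#'   \item{reeval_interval_days}{Periodic re-evaluation cadence (30 days);
#'     re-evaluation uses trailing 30-day mean readings.}
#'   \item{monitoring}{Self-monitoring frequencies per level (blood-glucose
#'     profile days per week: 1 / 3 / 7) and daily home blood pressure for
#'     comorbid hypertension.}
#'   \item{risk}{Cardiovascular risk-factor cutoffs used by the risk
#'     assessment rules (age >= 60 years, BMI >= 28 kg/m2).}
#' }
#'
#' @return A nested named list.
#' @export
default_config <- function() {
  list(
    targets = list(
      fbg = 7.0,            # mmol/L, fasting target
      pbg = 10.0,           # mmol/L, 2-h postprandial target
      intensive_fbg = 11.1, # mmol/L, strict > for intensive level 3
      sbp = 140,            # mmHg
      dbp = 90              # mmHg
    ),
    thresholds = list(
      bg_low = 3.9,          # any BG below: hypoglycemia warning
      bg_high = 16.7,        # any BG at/above: severe hyperglycemia warning
      fbg_high = 13.9,       # FBG at/above: hyperglycemia warning
      sbp_high = 160,
      sbp_low = 90,
      dbp_high = 100,
      hr_low = 50,
      hr_high = 120,
      symptom_severity = 2   # coded severity grade at/above: disorder warning
    ),
    compliance = list(window_days = 7L, low_rate = 0.5),
    followup_interval_days = c(`1` = 90L, `2` = 30L, `3` = 30L),
    reeval_interval_days = 30L,
    monitoring = list(
      bg_days_per_week = c(`1` = 1L, `2` = 3L, `3` = 7L),
      bp_daily_if_hypertension = TRUE
    ),
    risk = list(age_cutoff = 60, bmi_cutoff = 28)
  )
}

#' Load a configuration file, merged over the defaults
#'
#' Reads a JSON configuration and deep-merges it onto
#' \code{\link{default_config}}, so a file needs to carry only the keys it
#' overrides.
#'
#' @param path Path to a JSON configuration file.
#' @return A configuration list.
#' @export
load_config <- function(path) {
  stopifnot(file.exists(path))
  user <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- modify_list_deep(default_config(), user)
  # named level vectors may arrive as lists from JSON
  if (is.list(cfg$followup_interval_days)) {
    cfg$followup_interval_days <- unlist(cfg$followup_interval_days)
  }
  if (is.list(cfg$monitoring$bg_days_per_week)) {
    cfg$monitoring$bg_days_per_week <- unlist(cfg$monitoring$bg_days_per_week)
  }
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(
    is.numeric(cfg$targets$intensive_fbg),
    cfg$targets$fbg > 0, cfg$targets$pbg > 0,
    cfg$targets$intensive_fbg > cfg$targets$fbg,
    cfg$thresholds$bg_low < cfg$thresholds$bg_high,
    cfg$compliance$window_days >= 1,
    cfg$compliance$low_rate > 0, cfg$compliance$low_rate <= 1,
    length(cfg$followup_interval_days) == 3,
    all(cfg$followup_interval_days > 0),
    cfg$reeval_interval_days > 0
  )
  invisible(cfg)
}

modify_list_deep <- function(base, override) {
  if (!is.list(override)) return(override)
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- modify_list_deep(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Look up a dotted key path in a configuration list
#'
#' Used to resolve \code{\{"ref": "targets.intensive_fbg"\}} operands in rule
#' files, so clinical thresholds stay in configuration rather than rule text.
#'
#' @param cfg Configuration list.
#' @param key Dotted path, e.g. \code{"thresholds.bg_low"}.
#' @return The value at that path.
#' @export
config_ref <- function(cfg, key) {
  parts <- strsplit(key, ".", fixed = TRUE)[[1]]
  val <- cfg
  for (p in parts) {
    val <- if (is.null(names(val))) val[[as.integer(p)]] else val[[p]]
    if (is.null(val)) stop("unknown config reference: ", key, call. = FALSE)
  }
  val
}

# round half away from zero, matching the printed-style rounding used in
# reports (base round() is round-half-even)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
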