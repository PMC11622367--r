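# Extent-of-modification arithmetic.
#
# Peptide level: EOM = sum of FPOP-modified form areas over the total area
# of the peptide with and without modification. Residue level: the numerator
# is the area of forms carrying a modification at that residue; two
# denominator readings are offered (see residue_eom). APO weights each form
# by its number of FPOP events, so a triply oxidized form counts three times
# in the numerator.

#' Build a per-peptide area summary
#'
#' Container for one (file, protein, peptide): the unmodified-form area plus
#' one row per modified form, charge states already summed.
#'
#' @param unmod_area Unmodified-form area (numeric, `NA` when unobserved).
#' @param forms `data.frame` with columns `form_key`, `area`, `n_fpop`
#'   (FPOP events on that form), `positions` (comma-separated 1-based
#'   residue positions of the FPOP events, `""` when none). May have 0 rows.
#' @param file,condition,replicate,treatment,protein,sequence Identity
#'   metadata (optional for bare arithmetic use).
#' @return An object of class `"area_summary"`.
#' @export
#' @examples
#' s <- area_summary(75, data.frame(form_key = "PEPMIDE|5:Oxidation",
#'                                  area = 25, n_fpop = 1, positions = "5"))
#' peptide_eom(s)
area_summary <- function(unmod_area, forms = NULL, file = NA_character_,
                         condition = NA_character_, replicate = NA_integer_,
                         treatment = NA_character_, protein = NA_character_,
                         sequence = NA_character_) {
  if (is.null(forms) || nrow(forms) == 0L)
    forms <- data.frame(form_key = character(0), area = numeric(0),
                        n_fpop = integer(0), positions = character(0),
                        stringsAsFactors = FALSE)
  stopifnot(all(c("form_key", "area", "n_fpop", "positions") %in% names(forms)))
  if (any(forms$area < 0, na.rm = TRUE)) stop("form areas must be nonnegative")
  if (!is.na(unmod_area) && unmod_area < 0) stop("unmod_area must be nonnegative")
  structure(list(file = file, condition = condition, replicate = replicate,
                 treatment = treatment, protein = protein, sequence = sequence,
                 unmod_area = unmod_area, forms = forms),
            class = "area_summary")
}

parse_positions <- function(x) {
  if (is.na(x) || !nzchar(x)) return(integer(0))
  as.integer(strsplit(x, ",", fixed = TRUE)[[1]])
}

#' Peptide-level extent of modification
#'
#' EOM = (sum of FPOP-modified form areas) / (unmodified area + sum of all
#' form areas). Forms carrying only non-FPOP variable modifications
#' contribute to the denominator (they are real molecular species of the
#' peptide) but never to the numerator.
#'
#' @param summary An [area_summary()] whose `unmod_area` is present and
#'   positive (the missing-unmodified filter guarantees this upstream).
#' @return Fraction in \[0, 1\].
#' @export
peptide_eom <- function(summary) {
  check_quantifiable(summary)
  num <- sum(summary$forms$area[summary$forms$n_fpop > 0L])
  num / total_area(summary)
}

#' Residue-level extent of modification
#'
#' The numerator is the summed area of all forms modified at
#' `residue_position`. Two denominator readings are supported:
#' `"literal"` — numerator + unmodified area (the area of the modified
#' residue and the unmodified peptide); `"all_forms"` — unmodified area +
#' all form areas (the full peptide denominator, under which residue EOMs
#' sum exactly to the APO).
#'
#' @inheritParams peptide_eom
#' @param residue_position 1-based position within the peptide.
#' @param denominator_mode `"literal"` (default) or `"all_forms"`.
#' @return Fraction in \[0, 1\]; 0 when no form is modified at the residue.
#' @export
residue_eom <- function(summary, residue_position,
                        denominator_mode = c("literal", "all_forms")) {
  denominator_mode <- match.arg(denominator_mode)
  check_quantifiable(summary)
  hits <- vapply(summary$forms$positions, function(p)
    residue_position %in% parse_positions(p), logical(1), USE.NAMES = FALSE)
  num <- sum(summary$forms$area[hits])
  den <- if (denominator_mode == "literal") num + summary$unmod_area
         else total_area(summary)
  if (den == 0) return(0)
  num / den
}

#' Average peptide oxidation events (APO)
#'
#' Weights each modified form by its number of FPOP events:
#' APO = sum(n_fpop * area) / (unmodified area + sum of all form areas).
#' With a single triply modified form the numerator is three times the
#' form's area, so APO is three times the peptide EOM; APO equals the
#' peptide EOM exactly when every FPOP-modified form carries one event.
#'
#' @inheritParams peptide_eom
#' @return Nonnegative real.
#' @export
apo <- function(summary) {
  check_quantifiable(summary)
  sum(summary$forms$n_fpop * summary$forms$area) / total_area(summary)
}

total_area <- function(summary) summary$unmod_area + sum(summary$forms$area)

check_quantifiable <- function(summary) {
  if (is.na(summary$unmod_area) || summary$unmod_area <= 0)
    stop("contract violation: unmodified area absent or zero; ",
         "filter_missing_unmodified() must run before quantitation")
  invisible(TRUE)
}

#' Aggregate per-replicate EOM values
#'
#' @param values Numeric vector of per-replicate EOM values (length >= 1).
#' @param mean_mode `"arithmetic"` (default; sum/n with sample standard
#'   deviation) or `"geometric"` (`exp(mean(log(v)))`, the legacy
#'   spreadsheet convention; any zero value makes the geometric mean 0,
#'   flagged `geomean_zero`).
#' @return List with `mean`, `sd` (n-1 denominator; 0 with flag `low_n`
#'   when n = 1), `n`, `flags` (character vector).
#' @export
aggregate_replicates <- function(values, mean_mode = c("arithmetic", "geometric")) {
  mean_mode <- match.arg(mean_mode)
  if (length(values) == 0L) stop("contract violation: empty replicate list")
  if (anyNA(values)) stop("replicate EOM values must not be NA")
  flags <- character(0)
  n <- length(values)
  if (mean_mode == "arithmetic") {
    m <- mean(values)
  } else {
    if (any(values < 0)) stop("geometric mean requires nonnegative values")
    if (any(values == 0)) { m <- 0; flags <- c(flags, "geomean_zero") }
    else m <- exp(mean(log(values)))
  }
  if (n == 1L) { s <- 0; flags <- c(flags, "low_n") } else s <- stats::sd(values)
  list(mean = m, sd = s, n = n, flags = flags)
}

#' Subtract the control (background oxidation) EOM
#'
#' Control replicates are pooled into one background mean per condition;
#' the net EOM is `sample_mean - control_mean`. A negative net EOM is
#' reported as-is by default (flagged `negative_net`); with
#' `clip_negative = TRUE` it is clipped to 0 and the original value is
#' recorded in the flags.
#'
#' @param sample_mean Mean EOM of the laser-irradiated replicates.
#' @param control_mean Mean EOM of the no-laser controls; `NA` when the
#'   target was unquantifiable in controls (treated as 0, flagged
#'   `no_control`).
#' @param clip_negative Clip negative net EOM to zero?
#' @return List with `net`, `control_mean` (as used), `flags`.
#' @export
subtract_control <- function(sample_mean, control_mean, clip_negative = FALSE) {
  flags <- character(0)
  if (is.na(control_mean)) { control_mean <- 0; flags <- c(flags, "no_control") }
  net <- sample_mean - control_mean
  if (net < 0) {
    if (clip_negative) {
      flags <- c(flags, sprintf("clipped_negative:%.6g", net))
      net <- 0
    } else flags <- c(flags, "negative_net")
  }
  list(net = net, control_mean = control_mean, flags = flags)
}

#' Compare one target between two conditions
#'
#' Welch's two-sample t-test on per-replicate control-subtracted EOM
#' values, with a 1e-12 variance floor so zero-variance replicate lists do
#' not produce an undefined statistic.
#'
#' @param a,b Numeric vectors of per-replicate net EOM values.
#' @param var_floor Minimum per-group variance used in the statistic.
#' @return List with `delta` (mean(a) - mean(b)), `t`, `df`, `p`
#'   (two-sided), `flags`. When either side has fewer than 2 replicates the
#'   comparison is skipped (`t`, `df`, `p` are `NA`, flag `skipped_low_n`).
#' @export
compare_conditions <- function(a, b, var_floor = 1e-12) {
  if (length(a) < 2L || length(b) < 2L)
    return(list(delta = mean(a) - mean(b), t = NA_real_, df = NA_real_,
                p = NA_real_, flags = "skipped_low_n"))
  va <- max(stats::var(a), var_floor)
  vb <- max(stats::var(b), var_floor)
  na <- length(a); nb <- length(b)
  se2 <- va / na + vb / nb
  tstat <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  list(delta = mean(a) - mean(b), t = tstat, df = df, p = p,
       flags = character(0))
}
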