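# Radioactivity bookkeeping shared by all modules: decay correction of
# scintillation counts back to the soil-labeling date, and specific
# activity (SA) computation.
#
# Unit conventions, package-wide:
#   activity      Bq (per pot, per mL, or per kg soil basis as context dictates)
#   P mass        mg P
#   soil basis    kg dry soil
#   SA            Bq per mg P

#' Half-life of phosphorus-33
#'
#' The 33P half-life in days used as the package default for decay
#' correction. Overridable everywhere via the `half_life_days` argument or
#' config key.
#'
#' @return Half-life in days (25.383).
#' @export
p33_half_life <- function() 25.383

#' Back-correction factor for radioactive decay
#'
#' Factor by which a measured activity is multiplied to correct it back to
#' a reference date, i.e. `2^(elapsed_days / half_life_days)`.
#'
#' @param elapsed_days Days elapsed between the reference (labeling) date
#'   and the count date. Must be >= 0: counts are corrected backwards in
#'   time only.
#' @param half_life_days Isotope half-life in days; default 33P.
#' @return Positive multiplier (vectorized over `elapsed_days`).
#' @examples
#' decay_factor(25.383)  # one half-life -> 2
#' @export
decay_factor <- function(elapsed_days, half_life_days = p33_half_life()) {
  if (!is.numeric(half_life_days) || length(half_life_days) != 1L ||
      !is.finite(half_life_days) || half_life_days <= 0) {
    stop("`half_life_days` must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(elapsed_days) || any(!is.finite(elapsed_days))) {
    stop("`elapsed_days` must be finite numeric", call. = FALSE)
  }
  if (any(elapsed_days < 0)) {
    stop("`elapsed_days` must be >= 0 (count date precedes reference date)",
         call. = FALSE)
  }
  2^(elapsed_days / half_life_days)
}

#' Decay-correct a measured activity to the reference date
#'
#' Multiplies a raw scintillation reading by [decay_factor()]. Elapsed time
#' may be given directly in days, or as a pair of dates
#' (`count_date`, `reference_date`), both coercible by [as.Date()].
#'
#' @param raw_activity Measured activity in Bq, >= 0 (vectorized).
#' @param elapsed_days Days since the reference date; ignored when both
#'   dates are supplied.
#' @param count_date,reference_date Alternative to `elapsed_days`.
#' @param half_life_days Isotope half-life in days.
#' @return Activity in Bq at the reference date.
#' @export
decay_correct <- function(raw_activity, elapsed_days = NULL,
                          count_date = NULL, reference_date = NULL,
                          half_life_days = p33_half_life()) {
  if (!is.numeric(raw_activity) || any(!is.finite(raw_activity))) {
    stop("`raw_activity` must be finite numeric", call. = FALSE)
  }
  if (any(raw_activity < 0)) {
    stop("`raw_activity` must be >= 0", call. = FALSE)
  }
  if (!is.null(count_date) && !is.null(reference_date)) {
    elapsed_days <- as.numeric(as.Date(count_date) - as.Date(reference_date))
  }
  if (is.null(elapsed_days)) {
    stop("supply `elapsed_days` or both `count_date` and `reference_date`",
         call. = FALSE)
  }
  if (any(elapsed_days < 0)) {
    stop("count date precedes reference date: cannot correct forwards",
         call. = FALSE)
  }
  raw_activity * decay_factor(elapsed_days, half_life_days)
}

#' Specific activity
#'
#' SA = decay-corrected activity divided by the P mass it is carried on,
#' in Bq per mg P. The dilution of SA traces the mixing of labeled and
#' unlabeled P sources.
#'
#' @param activity Decay-corrected activity, Bq, >= 0 (vectorized).
#' @param p_mass P mass in mg, > 0 (vectorized).
#' @return SA in Bq per mg P.
#' @examples
#' specific_activity(1.2e6, 30)  # 40 kBq / mg P
#' @export
specific_activity <- function(activity, p_mass) {
  if (any(!is.finite(activity)) || any(activity < 0)) {
    stop("`activity` must be finite and >= 0", call. = FALSE)
  }
  if (any(!is.finite(p_mass)) || any(p_mass <= 0)) {
    stop("`p_mass` must be finite and > 0", call. = FALSE)
  }
  activity / p_mass
}
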