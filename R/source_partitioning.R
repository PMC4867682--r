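# Partitioning of plant P uptake into fertilizer-, soil-, and seed-derived
# sources from specific-activity dilution, for direct labeling (the
# fertilizer carries the tracer) and indirect labeling (the plant-available
# soil pool carries the tracer), plus fertilizer recovery and relative
# agronomic efficiency (RAE).
#
# Direct:    Pdf_fert = (SA_plant / SA_fert) * uptake
# Indirect:  Pdf_soil = (SA_plant / SA_NoP) * (uptake - Pdf_seed)
#            Pdf_fert = uptake - Pdf_soil - Pdf_seed
# where SA values entering the indirect route are computed on the
# seed-corrected P mass (activity / (uptake - Pdf_seed)); the sown seed is
# the only unlabeled P source shared by all pots and is removed from both
# the reference and the fertilized plant the same way.

#' Ordinary least-squares fit of a straight line
#'
#' Minimal simple-regression helper used for the seed-P calibration and the
#' uptake-vs-predictor reports. Returns the slope, intercept, coefficient of
#' determination and the two-sided p-value of the slope t-test.
#'
#' @param x,y Numeric vectors of equal length, >= 3 points, `var(x) > 0`.
#' @return A list with `slope`, `intercept`, `r_squared`, `p_value`, `n`.
#' @export
ols_fit <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("ols_fit needs at least 3 complete points", call. = FALSE)
  if (stats::var(x) == 0) {
    stop("ols_fit: zero variance in x (degenerate fit)", call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  rss <- sum(stats::residuals(fit)^2)
  ssy <- sum((y - mean(y))^2)
  r2 <- if (ssy == 0) 0 else 1 - rss / ssy
  # slope t-test computed directly so an exact fit gives p = 0, not a
  # "perfect fit" warning
  se <- sqrt(rss / (n - 2) / sum((x - mean(x))^2))
  pv <- if (ssy == 0) 1 else if (se == 0) 0 else
    2 * stats::pt(abs(unname(co[["x"]]) / se), df = n - 2,
                  lower.tail = FALSE)
  list(slope = unname(co[["x"]]), intercept = unname(co[["(Intercept)"]]),
       r_squared = r2, p_value = pv, n = n)
}

#' Fit the seed-P calibration line
#'
#' From a direct-labeled sand-culture experiment in which the sown seed is
#' the only unlabeled P source, fits the linear relationship
#' `pdf_seed = a * uptake + b` used to predict the seed contribution in soil
#' pot experiments.
#'
#' @param seed_records Data frame with numeric columns `uptake` (mg P per kg)
#'   and `pdf_seed` (mg P per kg), >= 3 rows.
#' @return An object of class `seed_p_model` with elements `a` (slope), `b`
#'   (intercept, mg P per kg), `r_squared`, `n_points`.
#' @export
fit_seed_model <- function(seed_records) {
  stopifnot(is.data.frame(seed_records),
            all(c("uptake", "pdf_seed") %in% names(seed_records)))
  f <- ols_fit(seed_records$uptake, seed_records$pdf_seed)
  structure(list(a = f$slope, b = f$intercept,
                 r_squared = f$r_squared, n_points = f$n),
            class = "seed_p_model")
}

#' @export
print.seed_p_model <- function(x, ...) {
  cat(sprintf(
    "Seed-P calibration: pdf_seed = %.4f * uptake + %.4f  (r2 = %.3f, n = %d)\n",
    x$a, x$b, x$r_squared, x$n_points))
  invisible(x)
}

#' Construct a seed-P model from known coefficients
#'
#' @param a Slope (mg P seed-derived per mg P uptake).
#' @param b Intercept (mg P per kg soil).
#' @return A `seed_p_model`.
#' @export
seed_p_model <- function(a, b) {
  structure(list(a = a, b = b, r_squared = NA_real_, n_points = 0L),
            class = "seed_p_model")
}

#' Predict seed-derived P from uptake
#'
#' Evaluates the calibration line, clamping negative predictions at zero
#' (a negative seed contribution is physically meaningless). Clamped entries
#' are marked in the `"clamped"` attribute.
#'
#' @param uptake P uptake, mg P per kg soil, >= 0 (vectorized).
#' @param model A `seed_p_model`.
#' @return Numeric vector of seed-derived P (mg P per kg soil) with a logical
#'   attribute `clamped`.
#' @export
predict_seed_p <- function(uptake, model) {
  stopifnot(inherits(model, "seed_p_model"))
  if (any(uptake < 0)) stop("`uptake` must be >= 0", call. = FALSE)
  raw <- model$a * uptake + model$b
  clamped <- raw < 0
  out <- pmax(raw, 0)
  attr(out, "clamped") <- clamped
  out
}

#' Fertilizer-derived P under direct labeling
#'
#' `(sa_plant / sa_fert) * uptake`: since the fertilizer is the only labeled
#' source, the SA ratio is the fertilizer-derived fraction of uptake. A plant
#' SA above the fertilizer SA is physically impossible and is flagged
#' `IMPOSSIBLE_RATIO` rather than erased.
#'
#' @param sa_plant Plant SA, Bq per mg P, >= 0.
#' @param sa_fert Fertilizer SA, Bq per mg P, > 0.
#' @param uptake P uptake, mg P per kg soil, > 0.
#' @return Fertilizer-derived P (mg P per kg soil) with logical attribute
#'   `impossible_ratio`.
#' @export
pdf_fertilizer_direct <- function(sa_plant, sa_fert, uptake) {
  if (any(sa_fert <= 0)) stop("`sa_fert` must be > 0", call. = FALSE)
  if (any(uptake <= 0)) stop("`uptake` must be > 0", call. = FALSE)
  if (any(sa_plant < 0)) stop("`sa_plant` must be >= 0", call. = FALSE)
  out <- (sa_plant / sa_fert) * uptake
  attr(out, "impossible_ratio") <- sa_plant > sa_fert
  out
}

#' Reference specific activity from unfertilized pots
#'
#' Recomputes, per unfertilized (NoP) pot, the SA of soil-derived plant P as
#' activity / (uptake - predicted seed P), and returns the mean across
#' replicates. This is the denominator of the indirect partition.
#'
#' @param noP_records Data frame with columns `activity` (Bq per kg soil,
#'   decay-corrected) and `uptake` (mg P per kg soil).
#' @param seed_model A `seed_p_model`.
#' @return Mean reference SA, Bq per mg P.
#' @export
sa_noP_reference <- function(noP_records, seed_model) {
  stopifnot(is.data.frame(noP_records), nrow(noP_records) >= 1L,
            all(c("activity", "uptake") %in% names(noP_records)))
  seed <- predict_seed_p(noP_records$uptake, seed_model)
  corrected <- noP_records$uptake - seed
  if (any(corrected <= 0)) {
    stop("degenerate NoP reference: uptake - seed P <= 0 for some pot",
         call. = FALSE)
  }
  mean(noP_records$activity / corrected)
}

#' Soil-derived P under indirect labeling
#'
#' `(sa_plant / sa_noP) * (uptake - pdf_seed)`: the SA of the fertilized
#' plant relative to the unfertilized reference is the soil-derived share of
#' the non-seed P. `sa_plant` must be on the seed-corrected mass basis
#' (activity / (uptake - pdf_seed)), symmetric with [sa_noP_reference()].
#'
#' @param sa_plant Fertilized-plant SA on seed-corrected basis, Bq per mg P.
#' @param sa_noP Reference SA from [sa_noP_reference()], > 0.
#' @param uptake P uptake, mg P per kg soil.
#' @param pdf_seed Seed-derived P, mg P per kg soil, in `[0, uptake)`.
#' @return Soil-derived P, mg P per kg soil.
#' @export
pdf_soil_indirect <- function(sa_plant, sa_noP, uptake, pdf_seed) {
  if (any(sa_noP <= 0)) stop("invalid reference: `sa_noP` must be > 0",
                             call. = FALSE)
  if (any(pdf_seed < 0) || any(pdf_seed >= uptake)) {
    stop("`pdf_seed` must satisfy 0 <= pdf_seed < uptake", call. = FALSE)
  }
  (sa_plant / sa_noP) * (uptake - pdf_seed)
}

#' Fertilizer-derived P under indirect labeling
#'
#' Mass-balance remainder `uptake - pdf_soil - pdf_seed`. Negative values
#' (possible under sampling noise) are retained and flagged
#' `NEGATIVE_PDF_FERTILIZER`; downstream summaries may exclude flagged pots.
#'
#' @param uptake,pdf_soil,pdf_seed mg P per kg soil, nonnegative.
#' @return Fertilizer-derived P with logical attribute `negative`.
#' @export
pdf_fertilizer_indirect <- function(uptake, pdf_soil, pdf_seed) {
  if (any(pdf_soil < 0) || any(pdf_seed < 0)) {
    stop("components must be nonnegative", call. = FALSE)
  }
  out <- uptake - pdf_soil - pdf_seed
  attr(out, "negative") <- out < 0
  out
}

#' Fertilizer recovery
#'
#' Fertilizer-derived plant P as a percentage of the applied P dose.
#'
#' @param pdf_fertilizer mg P per kg soil.
#' @param dose Applied dose, mg P per kg soil, > 0.
#' @return Recovery in percent.
#' @export
fertilizer_recovery <- function(pdf_fertilizer, dose) {
  if (any(dose <= 0)) stop("`dose` must be > 0", call. = FALSE)
  pdf_fertilizer / dose * 100
}

#' Relative agronomic efficiency
#'
#' A product's recovery as a percentage of the recovery of water-soluble
#' mineral P applied at the same dose.
#'
#' @param recovery_treatment Recovery of the treatment, percent.
#' @param recovery_minp Reference (mineral-P) recovery, percent, > 0.
#' @return RAE in percent.
#' @export
relative_agronomic_efficiency <- function(recovery_treatment, recovery_minp) {
  if (any(recovery_minp <= 0)) {
    stop("invalid reference: `recovery_minp` must be > 0", call. = FALSE)
  }
  recovery_treatment / recovery_minp * 100
}

#' Partition a pot experiment into P sources
#'
#' Runs the full per-pot partition: ingests plant observations (decay-
#' correcting activities when a count date or elapsed time is given), builds
#' the per-soil unfertilized reference SA, routes direct-labeled records
#' through the SA-ratio formula and indirect records through the dilution
#' mass balance, then computes recovery and RAE per pot and per-treatment
#' summaries (mean of per-pot ratios, then averaged).
#'
#' @param plants Data frame with columns `treatment`, `soil`, `replicate`,
#'   `labeling` (`"direct"`, `"indirect"` or `"none"`), `dm_g_per_kg`,
#'   `p_conc_mg_per_g`, `activity_bq`, and either `elapsed_days` or
#'   `count_date` (ISO date; needs `reference_date` in `config`). An
#'   `uptake_mg_per_kg` column, when present, must equal dm x p_conc.
#' @param fertilizers Data frame with columns `name`, `dose_mg_p_per_kg`, and
#'   `sa_fert_bq_per_mg` (required for direct-labeled products).
#' @param seed_model A `seed_p_model`.
#' @param config A [run_config()] list; uses `half_life_days`,
#'   `reference_date`, `exclude_flagged`, `reference_treatment`,
#'   `no_p_treatment`.
#' @return An object of class `isopart_partition`: list with `results` (one
#'   row per pot: pdf_fertilizer, pdf_soil, pdf_seed, pdf_fertilizer_pct,
#'   recovery_pct, rae_pct, flags), `summary` (per treatment x soil means,
#'   sd, n), and `sa_reference` (per-soil NoP reference SA).
#' @export
partition_experiment <- function(plants, fertilizers, seed_model,
                                 config = run_config()) {
  req <- c("treatment", "soil", "replicate", "labeling",
           "dm_g_per_kg", "p_conc_mg_per_g", "activity_bq")
  miss <- setdiff(req, names(plants))
  if (length(miss)) {
    stop("plants table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  p <- plants
  p$uptake <- p$dm_g_per_kg * p$p_conc_mg_per_g
  if ("uptake_mg_per_kg" %in% names(p)) {
    bad <- abs(p$uptake_mg_per_kg - p$uptake) >
      1e-9 * pmax(1, abs(p$uptake))
    if (any(bad)) {
      stop("uptake_mg_per_kg inconsistent with dm x p_conc in row(s): ",
           paste(which(bad), collapse = ", "), call. = FALSE)
    }
  }
  if (any(p$uptake <= 0)) {
    stop("all records entering partitioning must have uptake > 0",
         call. = FALSE)
  }

  # decay correction at ingest
  if ("elapsed_days" %in% names(p)) {
    p$activity <- decay_correct(p$activity_bq, elapsed_days = p$elapsed_days,
                                half_life_days = config$half_life_days)
  } else if ("count_date" %in% names(p)) {
    if (is.null(config$reference_date)) {
      stop("plants table has `count_date` but config lacks `reference_date`",
           call. = FALSE)
    }
    p$activity <- decay_correct(p$activity_bq,
                                count_date = p$count_date,
                                reference_date = config$reference_date,
                                half_life_days = config$half_life_days)
  } else {
    p$activity <- p$activity_bq  # already corrected upstream
  }

  no_p <- config$no_p_treatment
  ref_trt <- config$reference_treatment
  dose_of <- function(trt) {
    i <- match(trt, fertilizers$name)
    if (is.na(i)) NA_real_ else fertilizers$dose_mg_p_per_kg[i]
  }
  sa_fert_of <- function(trt) {
    i <- match(trt, fertilizers$name)
    if (is.na(i)) NA_real_ else fertilizers$sa_fert_bq_per_mg[i]
  }

  out <- vector("list", nrow(p))
  sa_ref <- list()
  for (s in unique(p$soil)) {
    rows_nop <- which(p$soil == s & p$treatment == no_p)
    if (!length(rows_nop)) {
      stop("soil '", s, "' has no '", no_p,
           "' reference: indirect method cannot run", call. = FALSE)
    }
    sa_ref[[s]] <- sa_noP_reference(
      data.frame(activity = p$activity[rows_nop],
                 uptake = p$uptake[rows_nop]),
      seed_model)
  }

  for (i in seq_len(nrow(p))) {
    trt <- p$treatment[i]; s <- p$soil[i]
    u <- p$uptake[i]; act <- p$activity[i]
    flags <- character(0)
    seed <- predict_seed_p(u, seed_model)
    if (attr(seed, "clamped")) flags <- c(flags, "CLAMPED_SEED")
    seed <- as.numeric(seed)

    if (trt == no_p) {
      fert <- 0
      soil_p <- u - seed
    } else if (identical(p$labeling[i], "direct")) {
      sa_f <- sa_fert_of(trt)
      if (!is.finite(sa_f) || sa_f <= 0) {
        stop("direct-labeled treatment '", trt,
             "' lacks a positive sa_fert_bq_per_mg", call. = FALSE)
      }
      fert <- pdf_fertilizer_direct(act / u, sa_f, u)
      if (attr(fert, "impossible_ratio")) flags <- c(flags, "IMPOSSIBLE_RATIO")
      fert <- as.numeric(fert)
      soil_p <- u - fert - seed
      if (soil_p < 0) flags <- c(flags, "NEGATIVE_PDF_SOIL")
    } else {
      sa_plant <- act / (u - seed)
      soil_p <- pdf_soil_indirect(sa_plant, sa_ref[[s]], u, seed)
      fert <- pdf_fertilizer_indirect(u, soil_p, seed)
      if (attr(fert, "negative")) flags <- c(flags, "NEGATIVE_PDF_FERTILIZER")
      fert <- as.numeric(fert)
    }

    dose <- dose_of(trt)
    rec <- if (trt != no_p && is.finite(dose) && dose > 0) {
      fertilizer_recovery(fert, dose)
    } else NA_real_

    out[[i]] <- data.frame(
      treatment = trt, soil = s, replicate = p$replicate[i],
      labeling = p$labeling[i],
      uptake = u, pdf_fertilizer = fert, pdf_soil = soil_p, pdf_seed = seed,
      pdf_fertilizer_pct = fert / u * 100,
      recovery_pct = rec, rae_pct = NA_real_,
      flags = paste(flags, collapse = ";"),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)

  include <- if (isTRUE(config$exclude_flagged)) res$flags == "" else
    rep(TRUE, nrow(res))

  # RAE per pot against the mean reference-treatment recovery of the same soil
  for (s in unique(res$soil)) {
    ref_rows <- res$treatment == ref_trt & res$soil == s & include
    if (!any(ref_rows)) {
      warning("soil '", s, "': no '", ref_trt,
              "' records for RAE; RAE omitted", call. = FALSE)
      next
    }
    ref_mean <- mean(res$recovery_pct[ref_rows])
    tgt <- res$soil == s & !is.na(res$recovery_pct)
    res$rae_pct[tgt] <- relative_agronomic_efficiency(
      res$recovery_pct[tgt], ref_mean)
  }

  res_inc <- res[include, , drop = FALSE]
  agg_vars <- c("uptake", "pdf_fertilizer", "pdf_soil", "pdf_seed",
                "pdf_fertilizer_pct", "recovery_pct", "rae_pct")
  grp <- interaction(res_inc$treatment, res_inc$soil, drop = TRUE)
  summ <- do.call(rbind, lapply(levels(grp), function(g) {
    rows <- res_inc[grp == g, , drop = FALSE]
    cells <- lapply(agg_vars, function(v) {
      x <- rows[[v]][is.finite(rows[[v]])]
      c(mean = if (length(x)) mean(x) else NA_real_,
        sd = if (length(x) > 1) stats::sd(x) else NA_real_)
    })
    df <- data.frame(treatment = rows$treatment[1], soil = rows$soil[1],
                     n = nrow(rows), stringsAsFactors = FALSE)
    for (k in seq_along(agg_vars)) {
      df[[paste0(agg_vars[k], "_mean")]] <- cells[[k]][["mean"]]
      df[[paste0(agg_vars[k], "_sd")]] <- cells[[k]][["sd"]]
    }
    df
  }))
  rownames(summ) <- NULL

  structure(list(results = res, summary = summ,
                 sa_reference = unlist(sa_ref)),
            class = "isopart_partition")
}

#' @export
print.isopart_partition <- function(x, ...) {
  cat("P-source partition:", nrow(x$results), "pots,",
      nrow(x$summary), "treatment x soil groups\n")
  print(x$summary[, c("treatment", "soil", "n", "uptake_mean",
                      "pdf_fertilizer_pct_mean", "recovery_pct_mean",
                      "rae_pct_mean")], digits = 3)
  invisible(x)
}
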