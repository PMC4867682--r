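# Synthetic-data generator with embedded ground truth. Emulates the design
# the analysis assumes: a two-soil x seven-treatment x four-replicate pot
# experiment under indirect soil labeling (plus a direct-labeled mineral
# control), a five-rate direct-labeled sand-culture seed experiment, and
# six-timepoint exchange-kinetics series. Default design constants follow
# the emulated protocol: dose 30 mg P per kg, soil labeling 1.1 MBq per kg,
# direct-label SA 40 kBq per mg P, sampling times 1-90 min, solution:soil
# ratio 10 L per kg. All truth magnitudes are synthetic: chosen to be
# realistic for a P-deficient temperate soil, not reproductions of any
# measured value.

# multiplicative Gaussian noise truncated at zero
mult_noise <- function(x, cv) {
  if (cv == 0) return(x)
  x * pmax(stats::rnorm(length(x), 1, cv), 1e-6)
}

#' Simulate the direct-labeled seed-P experiment
#'
#' Sand culture fertilized at increasing rates with 33P-labeled mineral P
#' (constant total label, so fertilizer SA falls with rate); the sown seed
#' is the only unlabeled P source. Observable seed-derived P is
#' `uptake - activity / sa_fert`. The embedded truth is an exactly linear
#' seed rule `pdf_seed = a * uptake + b`; the zero-rate baseline uptake is
#' `b / (1 - a)` so that the unlabeled zero-rate pots (where all uptake is
#' seed-derived) fall on the same line.
#'
#' @param rates Applied P rates, mg P per kg sand.
#' @param seed_p_total Seed P input per pot, mg (cap on the seed
#'   contribution); default 0.71 as in the emulated design (five seeds of
#'   0.20 g at 3.49 mg P per g).
#' @param a,b Seed-rule slope and intercept (mg P per kg).
#' @param uptake_gain Increase of mean uptake per unit rate
#'   (mg P uptake per mg P applied).
#' @param replicates Pots per rate.
#' @param noise_cv CV of the multiplicative between-pot scatter in uptake
#'   (biological, so pots move along the calibration line) and of the
#'   measurement noise on the counted activity (which perturbs the derived
#'   seed P only). Measurement error is kept off the regressor so the
#'   calibration slope stays unbiased, as the downstream correction assumes.
#' @param label_bq_per_kg Total label applied with the fertilizer, Bq per kg.
#' @param seed RNG seed.
#' @return List with `data` (rate, replicate, uptake, sa_fert_bq_per_mg,
#'   activity_bq, pdf_seed) and `truth`.
#' @export
simulate_seed_experiment <- function(rates = c(0, 7.5, 15, 22.5, 30),
                                     seed_p_total = 0.71,
                                     a = 0.06, b = 0.28,
                                     uptake_gain = 0.025,
                                     replicates = 4, noise_cv = 0.05,
                                     label_bq_per_kg = 7.2e5, seed = 1L) {
  if (!length(rates)) stop("`rates` must be nonempty", call. = FALSE)
  if (any(rates < 0)) stop("`rates` must be nonnegative", call. = FALSE)
  if (seed_p_total <= 0) stop("`seed_p_total` must be > 0", call. = FALSE)
  set.seed(seed)
  u0 <- b / (1 - a)
  rows <- expand.grid(replicate = seq_len(replicates), rate = rates,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- rows[, c("rate", "replicate")]
  u_true <- mult_noise(u0 + uptake_gain * rows$rate, noise_cv)
  seed_true <- pmin(a * u_true + b, u_true, seed_p_total)
  fert_true <- u_true - seed_true
  sa_fert <- ifelse(rows$rate > 0, label_bq_per_kg / rows$rate, NA_real_)
  act_true <- ifelse(rows$rate > 0, fert_true * sa_fert, 0)

  act_obs <- mult_noise(act_true, noise_cv)
  pdf_seed_obs <- ifelse(rows$rate > 0, u_true - act_obs / sa_fert, u_true)

  data <- data.frame(rate = rows$rate, replicate = rows$replicate,
                     uptake = u_true, sa_fert_bq_per_mg = sa_fert,
                     activity_bq = act_obs, pdf_seed = pdf_seed_obs)
  truth <- list(a = a, b = b, seed_p_total = seed_p_total,
                baseline_uptake = u0, uptake_gain = uptake_gain,
                noise_cv = noise_cv, seed = seed)
  list(data = data, truth = truth)
}

#' Default ground truth for the synthetic pot experiment
#'
#' Treatment-level truth patterned in magnitude on a P-limited barley pot
#' trial (all values synthetic): fertilizer share of uptake, mean uptake per
#' soil, tissue P concentration, and fertilizer characterization used by the
#' regression report. Fertilizer-P solubility fractions are built so that
#' uptake increases with the readily available (H2O + NaHCO3) fraction and
#' decreases with the stable HCl fraction.
#'
#' @param dose_mg_per_kg Applied P dose for every fertilized treatment.
#' @param sa_soil_bq_per_mg SA of the labeled plant-available soil pool.
#' @param seed_a,seed_b Seed-rule coefficients.
#' @return List of class `isopart_truth` with `treatments` (data frame),
#'   `fertilizers`, seed rule, and design constants.
#' @export
default_pot_truth <- function(dose_mg_per_kg = 30,
                              sa_soil_bq_per_mg = 2e4,
                              seed_a = 0.06, seed_b = 0.28) {
  treatments <- data.frame(
    treatment = c("NoP", "MinP", "MinPdir", "Manure", "FishSludge",
                  "MeatBoneMeal", "WoodAsh"),
    labeling = c("indirect", "indirect", "direct", "indirect", "indirect",
                 "indirect", "indirect"),
    fert_share = c(0, 0.42, 0.38, 0.40, 0.29, 0.12, 0.24),
    uptake_mean_unlimed = c(6.0, 10.0, 10.2, 7.2, 7.6, 6.5, 7.2),
    uptake_mean_limed = c(6.5, 10.6, 11.0, 8.3, 8.7, 7.0, 7.7),
    p_conc = c(1.7, 2.0, 2.1, 1.8, 1.9, 1.8, 1.9),
    stringsAsFactors = FALSE)
  fertilizers <- data.frame(
    name = c("MinP", "MinPdir", "Manure", "FishSludge", "MeatBoneMeal",
             "WoodAsh"),
    total_p_g_per_kg = c(252, 252, 6, 21, 54, 17),
    po_pct = c(0, 0, 24, 14, 2, 0),
    p_h2o_pct = c(100, 100, 42, 19, 4, 0),
    p_nahco3_pct = c(0, 0, 33, 19, 5, 43),
    p_naoh_pct = c(0, 0, 4, 12, 3, 0),
    p_hcl_pct = c(0, 0, 2, 37, 88, 60),
    org_c_g_per_kg = c(0, 0, 393, 375, 266, 0.1),
    dose_mg_p_per_kg = dose_mg_per_kg,
    sa_fert_bq_per_mg = c(NA, 4e4, NA, NA, NA, NA),
    stringsAsFactors = FALSE)
  truth <- list(treatments = treatments, fertilizers = fertilizers,
                seed_a = seed_a, seed_b = seed_b,
                dose = dose_mg_per_kg, sa_soil = sa_soil_bq_per_mg)
  truth$recovery_true <- within(
    treatments[treatments$fert_share > 0, c("treatment", "fert_share")], {
      recovery_unlimed <- fert_share *
        treatments$uptake_mean_unlimed[match(treatment, treatments$treatment)] /
        dose_mg_per_kg * 100
      recovery_limed <- fert_share *
        treatments$uptake_mean_limed[match(treatment, treatments$treatment)] /
        dose_mg_per_kg * 100
    })
  class(truth) <- "isopart_truth"
  truth
}

#' Simulate the pot experiment
#'
#' Draws per-pot uptake around treatment means, splits it into fertilizer,
#' soil, and seed shares per the embedded truth, computes activities from a
#' single consistent mixing model (labeled soil pool for indirect records,
#' labeled fertilizer for the direct control), and emits decay-uncorrected
#' activities with elapsed times so ingestion exercises decay correction.
#'
#' @param truth A [default_pot_truth()] list (or compatible).
#' @param soils Soil labels.
#' @param replicates Pots per treatment x soil.
#' @param noise_cv_p CV of measurement noise on dry matter and tissue P.
#' @param noise_cv_activity CV of measurement noise on activities.
#' @param biological_cv CV of true between-pot uptake variation.
#' @param elapsed_days Days between soil labeling and scintillation
#'   counting (exercises decay correction).
#' @param half_life_days Isotope half-life.
#' @param seed RNG seed.
#' @return List with `plants` (plants.csv-shaped), `fertilizers`, `truth`.
#' @export
simulate_pot_experiment <- function(truth = default_pot_truth(),
                                    soils = c("unlimed", "limed"),
                                    replicates = 4,
                                    noise_cv_p = 0.05,
                                    noise_cv_activity = 0.02,
                                    biological_cv = 0.05,
                                    elapsed_days = 50,
                                    half_life_days = p33_half_life(),
                                    seed = 1L) {
  trt <- truth$treatments
  if (!all(c("NoP", "MinP") %in% trt$treatment)) {
    stop("truth must include NoP and MinP treatments", call. = FALSE)
  }
  set.seed(seed)
  a <- truth$seed_a; b <- truth$seed_b
  out <- list(); k <- 0L
  for (s in soils) {
    ucol <- paste0("uptake_mean_", s)
    if (!ucol %in% names(trt)) {
      stop("truth lacks uptake means for soil '", s, "'", call. = FALSE)
    }
    for (i in seq_len(nrow(trt))) {
      for (r in seq_len(replicates)) {
        u <- trt[[ucol]][i] * pmax(stats::rnorm(1, 1, biological_cv), 1e-6)
        seed_p <- min(a * u + b, u)
        fert <- trt$fert_share[i] * u
        soil_p <- u - fert - seed_p
        if (soil_p < 0) {
          stop("truth shares leave negative soil P for ",
               trt$treatment[i], call. = FALSE)
        }
        act <- if (trt$treatment[i] == "NoP") {
          truth$sa_soil * (u - seed_p)
        } else if (trt$labeling[i] == "direct") {
          sa_f <- truth$fertilizers$sa_fert_bq_per_mg[
            match(trt$treatment[i], truth$fertilizers$name)]
          fert * sa_f
        } else {
          truth$sa_soil * soil_p
        }
        dm <- u / trt$p_conc[i]
        k <- k + 1L
        out[[k]] <- data.frame(
          treatment = trt$treatment[i], soil = s, replicate = r,
          labeling = trt$labeling[i],
          dm_g_per_kg = mult_noise(dm, noise_cv_p),
          p_conc_mg_per_g = mult_noise(trt$p_conc[i], noise_cv_p),
          activity_bq = mult_noise(act, noise_cv_activity) /
            decay_factor(elapsed_days, half_life_days),
          elapsed_days = elapsed_days,
          stringsAsFactors = FALSE)
      }
    }
  }
  plants <- do.call(rbind, out)
  truth$noise <- list(p = noise_cv_p, activity = noise_cv_activity,
                      biological = biological_cv)
  truth$seed <- seed
  list(plants = plants, fertilizers = truth$fertilizers, truth = truth)
}

#' Simulate one exchange-kinetics series
#'
#' Forward-evaluates the kinetics model, scales by the injected activity,
#' applies multiplicative noise, and re-draws (up to a retry cap) any point
#' violating the series invariants (positivity, not exceeding R).
#'
#' @param m,n,c_p,pi_total,ratio Model parameters, see [predict_r_ratio()].
#' @param times Sampling times, minutes.
#' @param R_injected Injected activity, Bq per mL (protocol range 600-900).
#' @param noise_cv CV of multiplicative noise on r(t).
#' @param seed RNG seed (optional).
#' @param max_retry Redraw cap per point.
#' @return A [kinetics_series()].
#' @export
simulate_kinetics_series <- function(m, n, c_p, pi_total,
                                     times = c(1, 4, 10, 30, 60, 90),
                                     R_injected = 750, ratio = 10,
                                     noise_cv = 0, seed = NULL,
                                     max_retry = 100L) {
  if (!length(times)) stop("`times` must be nonempty", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  r_true <- R_injected * predict_r_ratio(times, m, n, c_p, pi_total, ratio)
  r_obs <- mult_noise(r_true, noise_cv)
  for (i in seq_along(r_obs)) {
    tries <- 0L
    while ((r_obs[i] <= 0 || r_obs[i] > R_injected) && tries < max_retry) {
      r_obs[i] <- mult_noise(r_true[i], noise_cv)
      tries <- tries + 1L
    }
    if (r_obs[i] <= 0 || r_obs[i] > R_injected) {
      r_obs[i] <- min(max(r_obs[i], 1e-9), R_injected)
    }
  }
  kinetics_series(times, r_obs, R_injected, c_p, pi_total, ratio,
                  monotone_tol = max(0.1, 5 * noise_cv))
}

#' Default ground truth for the synthetic incubation
#'
#' Per treatment x soil x day: true resin-extractable P, fertilizer-derived
#' fraction of resin P, and microbial P; per treatment x soil: exchange-
#' kinetics parameters. Magnitudes are realistic for a P-deficient soil and
#' entirely synthetic.
#'
#' @param soils Soil labels.
#' @param days Sampling days after fertilizer application.
#' @return Data frame of truth rows plus kinetics truth as attribute
#'   `kinetics`.
#' @export
default_incubation_truth <- function(soils = c("unlimed", "limed"),
                                     days = c(7, 21)) {
  trts <- c("NoP", "MinP", "Manure", "FishSludge", "MeatBoneMeal", "WoodAsh")
  base_resin <- c(NoP = 12, MinP = 21, Manure = 20, FishSludge = 17,
                  MeatBoneMeal = 18, WoodAsh = 16)
  pdff <- c(NoP = 0, MinP = 40, Manure = 35, FishSludge = 30,
            MeatBoneMeal = 20, WoodAsh = 35)
  pmic <- c(NoP = 5, MinP = 4, Manure = 9, FishSludge = 6,
            MeatBoneMeal = 7, WoodAsh = 6)
  rows <- expand.grid(treatment = trts, soil = soils, day = days,
                      stringsAsFactors = FALSE)
  rows$resin_p <- base_resin[rows$treatment] - ifelse(rows$day > 7, 4, 0)
  rows$pdff_pct <- ifelse(rows$treatment == "NoP", 0, pdff[rows$treatment])
  rows$pmic <- pmic[rows$treatment] + ifelse(rows$soil == "limed", 3, 0)
  rownames(rows) <- NULL
  kin <- expand.grid(treatment = trts, soil = soils, stringsAsFactors = FALSE)
  kin$m <- c(NoP = 0.27, MinP = 0.32, Manure = 0.29, FishSludge = 0.27,
             MeatBoneMeal = 0.27, WoodAsh = 0.26)[kin$treatment] -
    ifelse(kin$soil == "limed", 0.04, 0)
  kin$n <- c(NoP = 0.40, MinP = 0.38, Manure = 0.39, FishSludge = 0.39,
             MeatBoneMeal = 0.39, WoodAsh = 0.39)[kin$treatment] -
    ifelse(kin$soil == "limed", 0.02, 0)
  kin$c_p <- c(NoP = 0.09, MinP = 0.15, Manure = 0.13, FishSludge = 0.11,
               MeatBoneMeal = 0.10, WoodAsh = 0.13)[kin$treatment]
  attr(rows, "kinetics") <- kin
  rows
}

#' Simulate the incubation experiment (extractions and kinetics)
#'
#' Generates paired fumigated/non-fumigated resin extraction records and,
#' optionally, exchange-kinetics series consistent with the embedded truth.
#' The unfertilized reference extract carries the undiluted soil-pool SA;
#' fertilized extracts carry it diluted by the true fertilizer-derived
#' fraction.
#'
#' @param truth A [default_incubation_truth()] data frame.
#' @param replicates Replicates per group.
#' @param noise_cv CV of multiplicative noise on extract P and activity.
#' @param sa_reference_bq_per_mg Undiluted reference SA of the extractable
#'   pool.
#' @param sorption_factor True recovery fraction applied to the microbial
#'   flush.
#' @param soil_total_p,soil_organic_p,dose_mg_per_kg Build the inorganic-P
#'   basis `pi_total` for the kinetics series.
#' @param kinetics Also generate kinetics series (one per
#'   treatment x soil x replicate)?
#' @param seed RNG seed.
#' @return List with `extractions` (extractions.csv-shaped), `kinetics`
#'   (kinetics.csv-shaped long table or NULL), `truth`.
#' @export
simulate_incubation <- function(truth = default_incubation_truth(),
                                replicates = 4, noise_cv = 0.05,
                                sa_reference_bq_per_mg = 1e5,
                                sorption_factor = 1,
                                soil_total_p = 1024, soil_organic_p = 456,
                                dose_mg_per_kg = 30,
                                kinetics = TRUE, seed = 1L) {
  if (!"NoP" %in% truth$treatment) {
    stop("incubation design lacks the NoP reference", call. = FALSE)
  }
  set.seed(seed)
  out <- list(); k <- 0L
  for (i in seq_len(nrow(truth))) {
    sa <- sa_reference_bq_per_mg * (1 - truth$pdff_pct[i] / 100)
    for (r in seq_len(replicates)) {
      resin <- mult_noise(truth$resin_p[i], noise_cv)
      act <- mult_noise(sa * truth$resin_p[i], noise_cv)
      fum <- mult_noise(truth$resin_p[i] + truth$pmic[i] * sorption_factor,
                        noise_cv)
      k <- k + 1L
      out[[k]] <- data.frame(
        sample_id = sprintf("%s_%s_d%d_r%d", truth$treatment[i],
                            truth$soil[i], truth$day[i], r),
        treatment = truth$treatment[i], soil = truth$soil[i],
        replicate = r, day = truth$day[i],
        fumigated = c(FALSE, TRUE),
        extract_p = c(resin, fum),
        extract_activity = c(act, mult_noise(sa * truth$resin_p[i],
                                             noise_cv)),
        stringsAsFactors = FALSE)
    }
  }
  extractions <- do.call(rbind, out)

  kin_tab <- NULL
  if (kinetics) {
    kin <- attr(truth, "kinetics")
    rows <- list(); k <- 0L
    for (i in seq_len(nrow(kin))) {
      pi_total <- soil_total_p - soil_organic_p +
        if (kin$treatment[i] == "NoP") 0 else dose_mg_per_kg
      for (r in seq_len(replicates)) {
        ser <- simulate_kinetics_series(kin$m[i], kin$n[i], kin$c_p[i],
                                        pi_total, noise_cv = noise_cv / 2)
        k <- k + 1L
        rows[[k]] <- data.frame(
          sample_id = sprintf("kin_%s_%s_r%d", kin$treatment[i],
                              kin$soil[i], r),
          treatment = kin$treatment[i], soil = kin$soil[i], replicate = r,
          t_min = ser$times, r_bq = ser$r_t, R_bq = ser$R_injected,
          c_p_mg_per_l = ser$c_p, pi_total = ser$pi_total,
          stringsAsFactors = FALSE)
      }
    }
    kin_tab <- do.call(rbind, rows)
  }
  list(extractions = extractions, kinetics = kin_tab,
       truth = list(pools = truth, kinetics = attr(truth, "kinetics"),
                    sa_reference = sa_reference_bq_per_mg,
                    sorption_factor = sorption_factor,
                    noise_cv = noise_cv, seed = seed))
}
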