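#' Virtual cohort specification
#'
#' Parameters of the virtual weaning cohort: each patient gets a latent
#' deterioration label, a baseline GI score drawn from a group-conditional
#' normal (binormal model, so the theoretical AUC of GI vs label has the
#' closed form `pnorm((mu_pos - mu_neg) / sqrt(sd_pos^2 + sd_neg^2))`),
#' a tidal-volume pair (t0 and after-trial t2), and three phantom
#' specifications (t0 baseline, t1 T-piece, t2 recovery) whose analytic
#' indices realize the drawn score and the session effects.
#'
#' Default score distributions follow the study-type subgroup medians
#' (GI 46 in deteriorating vs 41 in stable patients) with a common SD of
#' 5.77 chosen so the theoretical AUC equals 0.73; the default t1 effects
#' reproduce the session pattern TIV 72%, dEELI -65%, RR +2.5 min^-1 and a
#' 1.37-fold GI inflation, with near-recovery at t2.
#'
#' @param n_patients cohort size (default 31).
#' @param deterioration_fraction expected fraction of deteriorating
#'   patients, in (0, 1) (default 13/31).
#' @param gi_pos,gi_neg `list(mean =, sd =)` of the baseline GI score
#'   (reported scale) in the deteriorating / stable group.
#' @param t1_effects `list(tiv_factor =, eeli_shift =, rr_increment =,
#'   gi_factor =)`: multiplicative TIV change, EELI shift in baseline-TIV
#'   units, RR increment (min^-1), and GI inflation factor at t1.
#' @param t2_effects same fields for the recovery session.
#' @param vt_model `list(mean_t0_pos =, mean_t0_neg =, sd_t0 =,
#'   drop_pos_mean =, drop_pos_sd =, rise_neg_mean =, rise_neg_sd =)`:
#'   baseline tidal volume (ml) by group and the group-conditional t2
#'   change; deteriorating patients lose at least 20 ml, stable ones never
#'   do.
#' @param rr_mean,rr_sd baseline respiratory rate distribution (min^-1).
#' @param noise_sd_fraction phantom noise SD as a fraction of the mean lung
#'   amplitude (default 0.05).
#' @param delay_spread_mean,delay_spread_sd per-patient two-group
#'   inspiratory delay spread (s). Default 0: a delayed pixel's DI sampled
#'   at the global breath landmarks shrinks by `cos(2*pi*delay/period)`, so
#'   nonzero delays bias the amplitude-map GI design; set a spread only
#'   when that bias is acceptable (regional-delay recovery has dedicated
#'   phantoms).
#' @param seed integer seed.
#' @return object of class `cohort_spec`; `$theoretical_auc` holds the
#'   binormal AUC implied by the score parameters.
#' @export
cohort_spec <- function(n_patients = 31,
                        deterioration_fraction = 13 / 31,
                        gi_pos = list(mean = 46, sd = 5.77),
                        gi_neg = list(mean = 41, sd = 5.77),
                        t1_effects = list(tiv_factor = 0.72,
                                          eeli_shift = -0.65,
                                          rr_increment = 2.5,
                                          gi_factor = 1.37),
                        t2_effects = list(tiv_factor = 0.99,
                                          eeli_shift = -0.01,
                                          rr_increment = 0.5,
                                          gi_factor = 0.96),
                        vt_model = list(mean_t0_pos = 531, mean_t0_neg = 425,
                                        sd_t0 = 80,
                                        drop_pos_mean = 57, drop_pos_sd = 25,
                                        rise_neg_mean = 55, rise_neg_sd = 40),
                        rr_mean = 23.5, rr_sd = 3,
                        noise_sd_fraction = 0.05,
                        delay_spread_mean = 0, delay_spread_sd = 0,
                        seed = 1L) {
  if (n_patients < 4)
    stop("n_patients too small: need at least 2 patients per outcome group",
         call. = FALSE)
  if (deterioration_fraction <= 0 || deterioration_fraction >= 1)
    stop("deterioration_fraction must be in (0, 1)", call. = FALSE)
  auc <- stats::pnorm((gi_pos$mean - gi_neg$mean) /
                        sqrt(gi_pos$sd^2 + gi_neg$sd^2))
  structure(list(n_patients = as.integer(n_patients),
                 deterioration_fraction = deterioration_fraction,
                 gi_pos = gi_pos, gi_neg = gi_neg,
                 t1_effects = t1_effects, t2_effects = t2_effects,
                 vt_model = vt_model, rr_mean = rr_mean, rr_sd = rr_sd,
                 noise_sd_fraction = noise_sd_fraction,
                 delay_spread_mean = delay_spread_mean,
                 delay_spread_sd = delay_spread_sd,
                 seed = as.integer(seed),
                 theoretical_auc = auc),
            class = "cohort_spec")
}

# low-level amplitude c for a half/half two-level map hitting raw GI target g
two_level_low <- function(g, amp_pattern) {
  if (g <= 0) return(1)
  f <- function(c) {
    a <- ifelse(amp_pattern, 1, c)
    sum(abs(a - stats::median(a))) / sum(a) - g
  }
  stats::uniroot(f, c(1e-6, 1 - 1e-9), tol = 1e-12)$root
}

#' Generate a virtual weaning cohort
#'
#' Draws labels, baseline GI scores and tidal volumes from a
#' [cohort_spec()], and (optionally) builds the three per-patient
#' [phantom_spec()] triplets whose analytic ground truth realizes them.
#' Amplitude maps are half/half two-level fields over the elliptical lung
#' support; the low level is solved so the map's analytic GI equals the
#' drawn score (clamped to a realizable maximum of 58 on the reported scale
#' so every support pixel stays in the 20%-of-max mask; the latent score
#' itself is never clamped). Session t1 scales the map by the TIV factor,
#' shifts the baseline by the EELI effect, raises the respiratory rate and
#' inflates the GI; t2 returns toward baseline.
#'
#' @param spec a [cohort_spec()].
#' @param include_phantoms build phantom spec triplets (default `TRUE`;
#'   set `FALSE` for large score-only Monte-Carlo cohorts).
#' @return object of class `eit_cohort`: list with `patients` (list of
#'   per-patient records: `subject_id`, `deteriorated` (latent),
#'   `gi_score`, `vt_t0`, `vt_t2`, `rr_t0`, `specs` (t0/t1/t2
#'   [phantom_spec()]s or `NULL`)), `theoretical_auc`, and `spec`.
#' @export
generate_cohort <- function(spec, include_phantoms = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_patients
  lab <- stats::runif(n) < spec$deterioration_fraction
  if (sum(lab) < 2 || sum(!lab) < 2)
    stop(sprintf(
      "realized cohort has %d positive / %d negative labels; >= 2 per group required (ROC undefined)",
      sum(lab), sum(!lab)), call. = FALSE)
  gi_score <- ifelse(lab,
                     stats::rnorm(n, spec$gi_pos$mean, spec$gi_pos$sd),
                     stats::rnorm(n, spec$gi_neg$mean, spec$gi_neg$sd))
  vm <- spec$vt_model
  vt_t0 <- pmax(stats::rnorm(n, ifelse(lab, vm$mean_t0_pos, vm$mean_t0_neg),
                             vm$sd_t0), 150)
  change <- ifelse(lab,
                   -pmax(stats::rnorm(n, vm$drop_pos_mean, vm$drop_pos_sd), 20),
                   pmax(stats::rnorm(n, vm$rise_neg_mean, vm$rise_neg_sd), -19))
  vt_t2 <- pmax(vt_t0 + change, 100)
  rr0 <- pmax(stats::rnorm(n, spec$rr_mean, spec$rr_sd), 12)
  delay_spread <- if (spec$delay_spread_mean == 0 && spec$delay_spread_sd == 0)
    numeric(n)
  else pmax(stats::rnorm(n, spec$delay_spread_mean, spec$delay_spread_sd), 0)
  phantom_seeds <- sample.int(2^31 - 1, 3 * n)

  patients <- vector("list", n)
  support <- lung_ellipses()
  # fixed alternating high/low assignment over the support (row-major parity)
  alt <- matrix(FALSE, 32, 32)
  alt[support] <- seq_len(sum(support)) %% 2 == 0
  for (i in seq_len(n)) {
    specs <- NULL
    if (include_phantoms)
      specs <- patient_phantoms(spec, gi_score[i], rr0[i], delay_spread[i],
                                support, alt,
                                phantom_seeds[(3 * i - 2):(3 * i)])
    patients[[i]] <- list(subject_id = sprintf("P%03d", i),
                          deteriorated = lab[i],
                          gi_score = gi_score[i],
                          vt_t0 = vt_t0[i], vt_t2 = vt_t2[i],
                          rr_t0 = rr0[i],
                          specs = specs)
  }
  structure(list(patients = patients,
                 theoretical_auc = spec$theoretical_auc,
                 spec = spec),
            class = "eit_cohort")
}

# three phantom_specs realizing a patient's score and session effects
patient_phantoms <- function(spec, gi_score, rr0, delay_spread,
                             support, alt, seeds) {
  g0 <- min(max(gi_score, 5), 58) / 100
  g1 <- min(g0 * spec$t1_effects$gi_factor, 0.58)
  g2 <- min(g0 * spec$t2_effects$gi_factor, 0.58)
  c0 <- two_level_low(g0, alt[support])
  c1 <- two_level_low(g1, alt[support])
  c2 <- two_level_low(g2, alt[support])
  m <- sum(support)
  map_for <- function(cl, scale) {
    a <- matrix(0, 32, 32)
    a[support] <- ifelse(alt[support], 1, cl) * scale
    a
  }
  sum_unit <- function(cl) sum(ifelse(alt[support], 1, cl))
  a0 <- map_for(c0, 1)
  tiv0 <- sum(a0)
  s1 <- spec$t1_effects$tiv_factor * tiv0 / sum_unit(c1)
  s2 <- spec$t2_effects$tiv_factor * tiv0 / sum_unit(c2)
  # two-group inspiratory delays on alternating rows, decoupled from the
  # amplitude pattern (zero by default, see cohort_spec)
  delays <- matrix(0, 32, 32)
  if (delay_spread > 0)
    delays[support] <- ifelse(row(delays)[support] %% 2 == 0, delay_spread, 0)
  mk <- function(amap, dmap, rr, eeli_px, seed, insp_frac = 0.5) {
    period <- 60 / rr
    phantom_spec(lung_amplitude_map = amap, delay_map = dmap,
                 respiratory_rate = rr, inspiration_fraction = insp_frac,
                 eeli_trajectory = eeli_px,
                 cardiac_rate = 90,
                 cardiac_amplitude = 0.05 * mean(amap[support]),
                 noise_sd = spec$noise_sd_fraction * mean(amap[support]),
                 sampling_rate = 20, duration = 13.5 * period,
                 seed = seed)
  }
  list(t0 = mk(a0, delays, rr0, 0, seeds[1]),
       t1 = mk(map_for(c1, s1), delays, rr0 + spec$t1_effects$rr_increment,
               spec$t1_effects$eeli_shift * tiv0 / m, seeds[2]),
       t2 = mk(map_for(c2, s2), delays, rr0 + spec$t2_effects$rr_increment,
               spec$t2_effects$eeli_shift * tiv0 / m, seeds[3]))
}

#' Latent scores and labels of a cohort
#'
#' Convenience accessor returning the per-patient baseline GI score, the
#' latent label, and the tidal-volume pair as a data frame (the ROC inputs
#' when the full movie pipeline is bypassed).
#'
#' @param cohort an `eit_cohort`.
#' @return data frame with columns `subject_id`, `gi_score`, `vt_t0`,
#'   `vt_t2`, `deteriorated`.
#' @export
cohort_scores <- function(cohort) {
  stopifnot(inherits(cohort, "eit_cohort"))
  do.call(rbind, lapply(cohort$patients, function(p)
    data.frame(subject_id = p$subject_id, gi_score = p$gi_score,
               vt_t0 = p$vt_t0, vt_t2 = p$vt_t2,
               deteriorated = p$deteriorated, stringsAsFactors = FALSE)))
}

#' Run the full pipeline over a cohort
#'
#' Generates each patient's three phantom movies, analyzes them with
#' [analyze_patient()], and returns per-session indices joined with the
#' tidal volumes and the deterioration label derived from them.
#'
#' @param cohort an `eit_cohort` generated with phantoms.
#' @param config an [eit_config()].
#' @param delta_ml deterioration threshold passed to
#'   [deterioration_label()].
#' @return list with `sessions` (stacked `session_indices` rows) and
#'   `patients` (one row per patient: baseline GI, VT pair, label).
#' @export
analyze_cohort <- function(cohort, config = eit_config(), delta_ml = 20) {
  stopifnot(inherits(cohort, "eit_cohort"))
  sess_rows <- list()
  pat_rows <- list()
  for (p in cohort$patients) {
    if (is.null(p$specs))
      stop("cohort was generated without phantoms (include_phantoms = FALSE)",
           call. = FALSE)
    seqs <- lapply(names(p$specs), function(lab)
      generate_phantom(p$specs[[lab]], session_label = lab,
                       subject_id = p$subject_id)$frames)
    names(seqs) <- names(p$specs)
    idx <- analyze_patient(seqs, config)
    sess_rows[[p$subject_id]] <- idx
    pat_rows[[p$subject_id]] <- data.frame(
      subject_id = p$subject_id,
      gi_baseline = idx$gi_reported[idx$session_label == "t0"],
      vt_t0 = p$vt_t0, vt_t2 = p$vt_t2,
      deteriorated = deterioration_label(p$vt_t0, p$vt_t2, delta_ml),
      stringsAsFactors = FALSE)
  }
  sessions <- do.call(rbind, sess_rows)
  rownames(sessions) <- NULL
  patients <- do.call(rbind, pat_rows)
  rownames(patients) <- NULL
  list(sessions = sessions, patients = patients)
}
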