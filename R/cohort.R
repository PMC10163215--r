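#' Design of a synthetic truth-labelled cohort
#'
#' Parameterises the synthetic-data generator. Kinetic constants are drawn
#' from bivariate log-normal distributions per complementarity class. The
#' default medians and log10 scales bracket the observed per-panel ranges of
#' the reference study (fully complementary interactions: median ka
#' 5e6 M^-1 s^-1, mismatched: median ka 5e2 -- a 10^4-fold median contrast);
#' the log10(ka)-log10(kd) correlations (0.83 full-complement, 0.57
#' mismatched) are the empirical correlations of the packaged
#' kinetic-constant table, see the methods vignette.
#'
#' @param n_carriers,n_noncarriers Sample counts (>= 0). Defaults 17 and 5,
#'   the shape of the reference clinical cohort.
#' @param panel Mutation panel label attached to every sample.
#' @param seed Master integer seed; each sample derives its own sub-seed.
#' @param conc Nominal analyte molarity used for simulation and fitting, M.
#'   The default is the clinical-sample working concentration: a 25 ng/uL
#'   extract diluted 200-fold, converted at a mean amplicon length of 250 bp
#'   (double-stranded), i.e. `mass_to_molar(dilute(25, 200), 250)`,
#'   about 7.6e-10 M.
#' @param kinetics List of per-class draw parameters, each with `median_ka`,
#'   `sd_log10_ka`, `median_kd`, `sd_log10_kd`, `rho`.
#' @param rmax Saturation response, RU.
#' @param noise_sd SPR noise, RU (default 0.5).
#' @param drift SPR drift, RU/s.
#' @param softness_full,softness_mismatch Layer softness per class; the
#'   defaults (1 vs 0) halve the mismatched dissipation slope.
#' @param qcmd_noise_f,qcmd_noise_D QCM-D noise levels (Hz, 1e-6 units).
#' @return Object of class `cohort_design`.
#' @export
cohort_design <- function(n_carriers = 17, n_noncarriers = 5,
                          panel = "5382insC", seed = 1,
                          conc = mass_to_molar(dilute(25, 200), 250,
                                               double_stranded = TRUE),
                          kinetics = list(
                            full_complement = list(
                              median_ka = 5e6, sd_log10_ka = 0.7,
                              median_kd = 1e-3, sd_log10_kd = 0.7,
                              rho = 0.83),
                            mismatched = list(
                              median_ka = 5e2, sd_log10_ka = 0.8,
                              median_kd = 4e-3, sd_log10_kd = 0.5,
                              rho = 0.57)),
                          rmax = 100, noise_sd = 0.5, drift = 0,
                          softness_full = 1, softness_mismatch = 0,
                          qcmd_noise_f = 0.1, qcmd_noise_D = 0.05) {
  stopifnot(n_carriers >= 0, n_noncarriers >= 0,
            all(c("full_complement", "mismatched") %in% names(kinetics)))
  for (cl in kinetics)
    stopifnot(cl$median_ka > 0, cl$median_kd > 0,
              cl$sd_log10_ka >= 0, cl$sd_log10_kd >= 0,
              abs(cl$rho) <= 1)
  structure(list(n_carriers = n_carriers, n_noncarriers = n_noncarriers,
                 panel = panel, seed = seed, conc = conc,
                 kinetics = kinetics, rmax = rmax, noise_sd = noise_sd,
                 drift = drift, softness_full = softness_full,
                 softness_mismatch = softness_mismatch,
                 qcmd_noise_f = qcmd_noise_f, qcmd_noise_D = qcmd_noise_D),
            class = "cohort_design")
}

#' Draw kinetic constants for one interaction class
#'
#' Bivariate log-normal draw of (ka, kd): log10 values are Gaussian with the
#' class medians as locations, the class log10 sds as scales and correlation
#' `rho`. A zero-sd design returns exactly the medians.
#'
#' @param class `"full_complement"` or `"mismatched"`.
#' @param design A `cohort_design`.
#' @param seed Integer seed (reproducible draw).
#' @return `kinetic_params` (Rmax from the design).
#' @export
draw_kinetics <- function(class = c("full_complement", "mismatched"),
                          design = cohort_design(), seed = 1) {
  class <- match.arg(class)
  p <- design$kinetics[[class]]
  z <- with_seed(seed, stats::rnorm(2L))
  z2 <- p$rho * z[1L] + sqrt(1 - p$rho^2) * z[2L]
  ka <- 10^(log10(p$median_ka) + p$sd_log10_ka * z[1L])
  kd <- 10^(log10(p$median_kd) + p$sd_log10_kd * z2)
  kinetic_params(ka, kd, design$rmax)
}

#' Convert a mass concentration of DNA to molarity
#'
#' molarity = conc / (length x per-nucleotide molar mass), with the standard
#' average masses 330 g mol^-1 per nucleotide (single-stranded) and
#' 660 g mol^-1 per base pair (double-stranded).
#'
#' @param conc Mass concentration, ng/uL (>= 0). (1 ng/uL = 1e-3 g/L.)
#' @param mean_fragment_length Fragment length, nt or bp (>= 1).
#' @param double_stranded Logical (default TRUE).
#' @return Molar concentration, M.
#' @export
#' @examples
#' mass_to_molar(0.13, 200)  # ~9.8e-10 M
mass_to_molar <- function(conc, mean_fragment_length,
                          double_stranded = TRUE) {
  if (any(!is.finite(conc)) || any(conc < 0))
    stop("conc must be >= 0", call. = FALSE)
  if (any(!is.finite(mean_fragment_length)) || any(mean_fragment_length < 1))
    stop("mean_fragment_length must be >= 1 nt", call. = FALSE)
  per_nt <- if (double_stranded) 660 else 330
  (conc * 1e-3) / (mean_fragment_length * per_nt)
}

#' Dilute a concentration by a factor
#'
#' @param conc Concentration (any unit).
#' @param factor Dilution factor (>= 1).
#' @return `conc / factor`.
#' @export
#' @examples
#' round_conc(dilute(25, 200))  # 0.13 ng/uL
dilute <- function(conc, factor) {
  if (any(!is.finite(factor)) || any(factor < 1))
    stop("dilution factor must be >= 1", call. = FALSE)
  conc / factor
}

#' Report a concentration at two decimals, half away from zero
#'
#' @param conc Concentration.
#' @param digits Decimals (default 2).
#' @return Rounded value.
#' @export
round_conc <- function(conc, digits = 2) round_half_out(conc, digits)

#' Generate a truth-labelled synthetic cohort
#'
#' Carrier samples draw their mutant-probe interaction from the fully
#' complementary kinetic regime, non-carriers from the mismatched regime;
#' each sample also receives the complementary-class draw for the wild-type
#' probe so dual-probe experiments can be simulated. Every sample carries a
#' simulated SPR sensorgram and QCM-D trace under the default 300 s / 600 s
#' hybridization schedule. Fully reproducible: sample i uses sub-seed
#' `seed * 1000 + i` (kept below 2^31).
#'
#' @param design A `cohort_design`.
#' @return Object of class `cohort`: list with `samples` (list of
#'   `cohort_sample`) and `manifest` (data.frame: sample_id, panel,
#'   true_status, ka_true, kd_true, softness, conc, seed).
#' @export
generate_cohort <- function(design = cohort_design()) {
  stopifnot(inherits(design, "cohort_design"))
  n <- design$n_carriers + design$n_noncarriers
  status <- rep(c("carrier", "non-carrier"),
                c(design$n_carriers, design$n_noncarriers))
  samples <- vector("list", n)
  rows <- vector("list", n)
  base <- (design$seed %% 1000000L) * 2000L
  for (i in seq_len(n)) {
    sid <- sprintf("SYN-%03d", i)
    carrier <- status[i] == "carrier"
    sub <- as.integer(base + 2L * i)
    params_mut <- draw_kinetics(
      if (carrier) "full_complement" else "mismatched", design, seed = sub)
    params_wt <- draw_kinetics(
      if (carrier) "mismatched" else "full_complement", design,
      seed = sub + 1L)
    softness <- if (carrier) design$softness_full else design$softness_mismatch
    schedule <- hybridization_schedule(design$conc)
    sg <- simulate_sensorgram(schedule, params_mut,
                              noise_sd = design$noise_sd,
                              drift = design$drift, seed = sub,
                              sample_id = sid, probe_id = "mutant")
    qt <- simulate_qcmd_trace(params_mut, design$conc, softness, schedule,
                              noise_sd_f = design$qcmd_noise_f,
                              noise_sd_D = design$qcmd_noise_D,
                              seed = sub + 1L, sample_id = sid)
    samples[[i]] <- structure(
      list(sample_id = sid, mutation_panel = design$panel,
           true_status = status[i], params_mut = params_mut,
           params_wt = params_wt, layer_softness = softness,
           sensorgram = sg, qcmd_trace = qt, conc = design$conc,
           seed = sub),
      class = "cohort_sample")
    rows[[i]] <- data.frame(
      sample_id = sid, panel = design$panel, true_status = status[i],
      ka_true = params_mut$ka, kd_true = params_mut$kd,
      softness = softness, conc = design$conc, seed = sub,
      stringsAsFactors = FALSE)
  }
  structure(list(samples = samples,
                 manifest = if (n) do.call(rbind, rows) else
                   data.frame(sample_id = character(0), panel = character(0),
                              true_status = character(0),
                              ka_true = numeric(0), kd_true = numeric(0),
                              softness = numeric(0), conc = numeric(0),
                              seed = integer(0)),
                 design = design),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d samples (%d carriers, %d non-carriers), panel %s\n",
              length(x$samples), x$design$n_carriers,
              x$design$n_noncarriers, x$design$panel))
  invisible(x)
}

#' Run the full genotyping pipeline on a synthetic cohort
#'
#' Rehearses the study end to end: fits every sample's sensorgram with the
#' 1:1 model, derives Ka, classifies against a synthetic-reference Ka (a
#' noise-free trace simulated at the full-complement class medians and
#' fitted like any sample), computes specificity and selectivity against the
#' truth labels, and reports the parameter-recovery error of the fits.
#' Samples whose fit does not converge (no measurable binding) are called
#' negative. QCM-D calls are evaluated alongside when `qcmd = TRUE`, against
#' the dissipation slope of the same noise-free reference sample.
#'
#' @param cohort A `cohort`.
#' @param threshold_factor Ka-rule factor (default 10).
#' @param call_params `qcmd_call_params` for the gravimetric calls.
#' @param qcmd Evaluate the QCM-D branch too? (default TRUE)
#' @return List with `summary` (per-assay specificity/selectivity and
#'   confusion counts), `calls` (data.frame), `recovery` (data.frame of
#'   relative errors of fitted ka/kd vs the drawn truth), `ka_reference`.
#' @export
run_study <- function(cohort, threshold_factor = 10,
                      call_params = qcmd_call_params(), qcmd = TRUE) {
  stopifnot(inherits(cohort, "cohort"))
  if (!length(cohort$samples)) stop("empty cohort", call. = FALSE)
  design <- cohort$design
  med <- design$kinetics$full_complement
  ref_params <- kinetic_params(med$median_ka, med$median_kd, design$rmax)
  schedule <- hybridization_schedule(design$conc)
  ref_fit <- fit_1to1(simulate_sensorgram(schedule, ref_params,
                                          sample_id = "reference"),
                      design$conc)
  if (!ref_fit$converged) stop("reference fit failed", call. = FALSE)
  ka_ref <- ref_fit$estimate$Ka
  ref_curve <- df_dd_slopes(simulate_qcmd_trace(
    ref_params, design$conc, design$softness_full, schedule,
    sample_id = "reference"))

  rows <- list(); rec <- list()
  for (s in cohort$samples) {
    fit <- fit_1to1(s$sensorgram, s$conc)
    rule <- classification_rule(ka_ref, threshold_factor)
    spr_call <- if (fit$converged)
      ka_threshold_call(fit$estimate$Ka, rule) else "negative"
    q_call <- NA_character_; q_r <- NA_real_
    if (qcmd) {
      qc <- qcmd_call(df_dd_slopes(s$qcmd_trace), ref_curve, call_params)
      q_call <- qc$call; q_r <- qc$evidence
    }
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = s$sample_id, panel = s$mutation_panel,
      true_status = s$true_status,
      Ka_fit = if (fit$converged) fit$estimate$Ka else NA_real_,
      spr_call = spr_call, qcmd_call = q_call, qcmd_evidence = q_r,
      converged = fit$converged, stringsAsFactors = FALSE)
    if (fit$converged)
      rec[[length(rec) + 1L]] <- data.frame(
        sample_id = s$sample_id,
        rel_err_ka = abs(fit$estimate$ka - s$params_mut$ka) / s$params_mut$ka,
        rel_err_kd = abs(fit$estimate$kd - s$params_mut$kd) / s$params_mut$kd,
        stringsAsFactors = FALSE)
  }
  calls <- do.call(rbind, rows)
  truth <- stats::setNames(calls$true_status == "carrier", calls$sample_id)
  has_pos <- any(truth); has_neg <- any(!truth)
  mk <- function(col) data.frame(sample_id = calls$sample_id,
                                 call = calls[[col]],
                                 stringsAsFactors = FALSE)
  summary <- list(
    n_carriers = sum(truth), n_noncarriers = sum(!truth),
    spr_specificity = if (has_neg) specificity(mk("spr_call"), truth) else NA,
    spr_selectivity = if (has_pos) selectivity(mk("spr_call"), truth) else NA)
  if (qcmd) {
    summary$qcmd_specificity <-
      if (has_neg) specificity(mk("qcmd_call"), truth) else NA
    summary$qcmd_selectivity <-
      if (has_pos) selectivity(mk("qcmd_call"), truth) else NA
  }
  list(summary = summary, calls = calls,
       recovery = if (length(rec)) do.call(rbind, rec) else NULL,
       ka_reference = ka_ref)
}
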