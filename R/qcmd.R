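#' Simulate a QCM-D hybridization trace
#'
#' Drives the fractional surface occupancy theta(t) with the same 1:1
#' Langmuir kinetics as the SPR simulator and converts it to
#' overtone-resolved frequency and dissipation shifts. In the Sauerbrey
#' (thin rigid film) convention the n-normalised frequency shift is
#' `delta_f_n(t) = -f_load * theta(t)` for every odd overtone n, where
#' `f_load` is the normalised shift at full coverage; dissipation responds
#' proportionally to the bound mass with a rigidity-dependent coefficient,
#' `delta_D_n(t) = s_rigid * (1 + layer_softness) * |delta_f_n(t)|`. The
#' simulator is deliberately the simplest model producing linear
#' dissipation-versus-frequency curves with a tunable slope -- which is all
#' the slope-comparison diagnostic consumes.
#'
#' @param params `kinetic_params` of the probe-target interaction.
#' @param conc Analyte concentration, M (> 0).
#' @param layer_softness Dimensionless >= 0; 0 gives the rigid-layer slope
#'   `s_rigid`, larger values give proportionally steeper dissipation.
#' @param schedule Injection schedule (see [hybridization_schedule()]).
#' @param noise_sd_f Gaussian noise on delta_f, Hz.
#' @param noise_sd_D Gaussian noise on delta_D, 1e-6 dissipation units.
#' @param seed Integer seed; mandatory when either noise level is > 0.
#' @param overtones Odd overtone numbers to report (default 3, 5, 7).
#' @param f_load Normalised frequency shift at full coverage, Hz (default 30,
#'   typical for oligonucleotide hybridization layers).
#' @param s_rigid Rigid-layer dissipation/frequency coefficient,
#'   1e-6 per Hz (default 0.05).
#' @param fundamental_frequency Crystal fundamental, Hz (default 4.95e6).
#' @param sample_id Metadata string.
#' @return Object of class `qcmd_trace`: list with `time` (s), `delta_f`
#'   and `delta_D` (matrices, one column per overtone, n-normalised),
#'   `overtones`, `phase`, `fundamental_frequency`, `sample_id`, `seed`.
#' @export
simulate_qcmd_trace <- function(params, conc, layer_softness = 0,
                                schedule = hybridization_schedule(conc),
                                noise_sd_f = 0, noise_sd_D = 0, seed = NULL,
                                overtones = c(3, 5, 7), f_load = 30,
                                s_rigid = 0.05,
                                fundamental_frequency = 4.95e6,
                                sample_id = NA_character_) {
  stopifnot(inherits(params, "kinetic_params"))
  if (!is.finite(layer_softness) || layer_softness < 0)
    stop("layer_softness must be >= 0", call. = FALSE)
  if (!length(overtones) || any(overtones %% 2 != 1) || any(overtones < 1))
    stop("overtones must be odd positive integers", call. = FALSE)
  if ((noise_sd_f > 0 || noise_sd_D > 0) && is.null(seed))
    stop("a seed is required when noise is added", call. = FALSE)
  .check_schedule(schedule)
  core <- .sensorgram_core(schedule, params, sampling_hz = 1)
  theta <- core$response / params$rmax
  n_t <- nrow(core)
  slope <- s_rigid * (1 + layer_softness)
  df <- matrix(rep(-f_load * theta, length(overtones)), ncol = length(overtones))
  dD <- matrix(rep(slope * f_load * theta, length(overtones)),
               ncol = length(overtones))
  if (noise_sd_f > 0 || noise_sd_D > 0) {
    noise <- with_seed(seed, list(
      f = matrix(stats::rnorm(n_t * length(overtones), 0, max(noise_sd_f, 0)),
                 ncol = length(overtones)),
      D = matrix(stats::rnorm(n_t * length(overtones), 0, max(noise_sd_D, 0)),
                 ncol = length(overtones))))
    if (noise_sd_f > 0) df <- df + noise$f
    if (noise_sd_D > 0) dD <- dD + noise$D
  }
  colnames(df) <- colnames(dD) <- paste0("n", overtones)
  structure(list(time = core$time, delta_f = df, delta_D = dD,
                 overtones = overtones, phase = core$phase,
                 fundamental_frequency = fundamental_frequency,
                 sample_id = sample_id,
                 seed = if (is.null(seed)) NA_integer_ else seed),
            class = "qcmd_trace")
}

#' @export
print.qcmd_trace <- function(x, ...) {
  cat(sprintf(
    "<qcmd_trace> %d points, overtones %s, f0 = %.3g MHz, sample %s\n",
    length(x$time), paste(x$overtones, collapse = ","),
    x$fundamental_frequency / 1e6, x$sample_id))
  invisible(x)
}

#' Sauerbrey areal mass from a frequency shift
#'
#' mass = -C_sauerbrey * delta_f / n. The conventional 17.7 ng cm^-2 Hz^-1
#' constant of 5 MHz AT-cut crystals is used as a documented approximation
#' for the 4.95 MHz crystals modelled here.
#'
#' @param delta_f Raw (non-normalised) frequency shift, Hz.
#' @param overtone Odd positive overtone number.
#' @param c_sauerbrey Mass-sensitivity constant, ng cm^-2 Hz^-1.
#' @return Areal mass, ng cm^-2 (positive under mass loading).
#' @export
sauerbrey_mass <- function(delta_f, overtone, c_sauerbrey = 17.7) {
  if (length(overtone) != 1L || !is.finite(overtone) || overtone < 1 ||
      overtone %% 2 != 1)
    stop("overtone must be an odd positive integer", call. = FALSE)
  -c_sauerbrey * delta_f / overtone
}

# O(1)-per-window SSE of the straight-line fit to (x, y) over [i, j], from
# prefix sums. Used by the dynamic-programming segmentation.
.seg_cost_fun <- function(x, y) {
  cx <- cumsum(x); cy <- cumsum(y)
  cxx <- cumsum(x * x); cyy <- cumsum(y * y); cxy <- cumsum(x * y)
  p <- function(c, i, j) c[j] - if (i > 1L) c[i - 1L] else 0
  function(i, j) {
    n <- j - i + 1
    sx <- p(cx, i, j); sy <- p(cy, i, j)
    sxx <- p(cxx, i, j) - sx * sx / n
    syy <- p(cyy, i, j) - sy * sy / n
    sxy <- p(cxy, i, j) - sx * sy / n
    if (sxx <= 0) return(syy)  # vertical data: best line is the mean
    max(syy - sxy * sxy / sxx, 0)
  }
}

#' Dissipation-versus-frequency slopes of a QCM-D trace
#'
#' Orders the (delta_f, delta_D) pairs of one overtone by time and fits
#' `n_segments` contiguous straight-line segments chosen by dynamic
#' programming to minimise the total squared error, plus a single global fit.
#' Slopes are reported as delta_D per unit of |delta_f| (dissipation gained
#' per Hz of mass loading), so a rigid layer of softness s has slope
#' `s_rigid * (1 + s)`.
#'
#' @param trace A `qcmd_trace`.
#' @param overtone Which overtone to analyse (default 3).
#' @param n_segments Number of contiguous segments (default 1).
#' @param min_seg Minimum points per segment (default 5).
#' @return Object of class `dfdd_curve`: `delta_f`, `delta_D`,
#'   `segment_breaks` (start indices of each segment), `segment_slopes`,
#'   `overall_slope`, `overtone`, `sample_id`.
#' @export
df_dd_slopes <- function(trace, overtone = 3, n_segments = 1, min_seg = 5) {
  stopifnot(inherits(trace, "qcmd_trace"))
  col <- match(paste0("n", overtone), colnames(trace$delta_f))
  if (is.na(col))
    stop("overtone ", overtone, " not present in trace", call. = FALSE)
  df <- trace$delta_f[, col]
  dD <- trace$delta_D[, col]
  n <- length(df)
  if (n < min_seg * n_segments)
    stop("need at least ", min_seg * n_segments, " points for ",
         n_segments, " segments", call. = FALSE)
  x <- -df  # positive frequency-shift magnitude
  y <- dD
  slope_of <- function(idx) {
    sxx <- sum((x[idx] - mean(x[idx]))^2)
    if (sxx <= 0) return(0)
    sum((x[idx] - mean(x[idx])) * (y[idx] - mean(y[idx]))) / sxx
  }
  overall <- slope_of(seq_len(n))
  if (n_segments == 1L) {
    breaks <- 1L
    slopes <- overall
  } else {
    cost <- .seg_cost_fun(x, y)
    K <- n_segments
    dp <- matrix(Inf, K, n)       # dp[k, j]: best cost of k segments over 1..j
    bt <- matrix(NA_integer_, K, n)
    for (j in min_seg:n) dp[1L, j] <- cost(1L, j)
    if (K > 1L) for (k in 2:K) {
      for (j in (k * min_seg):n) {
        is <- (((k - 1L) * min_seg) + 1L):(j - min_seg + 1L)
        vals <- dp[k - 1L, is - 1L] + vapply(is, cost, numeric(1L), j = j)
        m <- which.min(vals)
        dp[k, j] <- vals[m]
        bt[k, j] <- is[m]
      }
    }
    if (!is.finite(dp[K, n]))
      stop("segmentation infeasible for these sizes", call. = FALSE)
    breaks <- integer(K)
    j <- n
    for (k in K:2) {
      breaks[k] <- bt[k, j]
      j <- breaks[k] - 1L
    }
    breaks[1L] <- 1L
    ends <- c(breaks[-1L] - 1L, n)
    slopes <- vapply(seq_len(K),
                     function(k) slope_of(breaks[k]:ends[k]), numeric(1L))
  }
  structure(list(delta_f = df, delta_D = dD, segment_breaks = breaks,
                 segment_slopes = slopes, overall_slope = overall,
                 overtone = overtone, sample_id = trace$sample_id),
            class = "dfdd_curve")
}

#' @export
print.dfdd_curve <- function(x, ...) {
  cat(sprintf(
    "<dfdd_curve> overtone %d, %d points, overall slope %.4g (1e-6/Hz)\n  segments at %s with slopes %s\n",
    x$overtone, length(x$delta_f),
    x$overall_slope, paste(x$segment_breaks, collapse = ","),
    paste(signif(x$segment_slopes, 4), collapse = ", ")))
  invisible(x)
}

#' Tolerances of the gravimetric slope-comparison call
#'
#' @param tol_positive Relative slope difference below (or at) which a sample
#'   is called positive (matches the reference).
#' @param tol_ambiguous Upper bound of the ambiguous band.
#' @return Object of class `qcmd_call_params`.
#' @export
qcmd_call_params <- function(tol_positive = 0.15, tol_ambiguous = 0.35) {
  if (!(tol_positive > 0 && tol_positive < tol_ambiguous))
    stop("need 0 < tol_positive < tol_ambiguous", call. = FALSE)
  structure(list(tol_positive = tol_positive, tol_ambiguous = tol_ambiguous),
            class = "qcmd_call_params")
}

#' Gravimetric mutation call from dissipation-frequency slopes
#'
#' Compares the overall dissipation-versus-frequency slope of a sample with
#' the reference curve recorded for the fully complementary synthetic target:
#' r = |s_sample - s_ref| / |s_ref|. The sample is positive when its slope is
#' indistinguishable from the reference (r <= tol_positive), ambiguous inside
#' the (tol_positive, tol_ambiguous] band, and negative otherwise.
#'
#' @param sample_curve,reference_curve `dfdd_curve` objects.
#' @param call_params `qcmd_call_params`.
#' @return A `genotype_call` (assay `"QCMD"`) whose `evidence` is the
#'   relative slope difference r.
#' @export
qcmd_call <- function(sample_curve, reference_curve,
                      call_params = qcmd_call_params()) {
  stopifnot(inherits(sample_curve, "dfdd_curve"),
            inherits(reference_curve, "dfdd_curve"),
            inherits(call_params, "qcmd_call_params"))
  s_ref <- reference_curve$overall_slope
  if (!is.finite(s_ref) || s_ref == 0)
    stop("reference curve has zero slope", call. = FALSE)
  r <- abs(sample_curve$overall_slope - s_ref) / abs(s_ref)
  call <- if (r <= call_params$tol_positive) "positive"
          else if (r <= call_params$tol_ambiguous) "ambiguous"
          else "negative"
  genotype_call(sample_id = sample_curve$sample_id, panel = NA_character_,
                assay = "QCMD", call = call, evidence = r)
}

#' Calibrate the gravimetric call tolerances on a labelled set
#'
#' Grid search over (tol_positive, tol_ambiguous) maximising balanced
#' accuracy (mean of the positive-class and negative-class correct-call
#' rates; ambiguous counts as incorrect for both classes).
#'
#' @param slope_ratios Numeric vector of relative slope differences r, one
#'   per labelled sample.
#' @param truth Logical vector; `TRUE` for mutation-bearing samples.
#' @param grid_positive,grid_ambiguous Candidate tolerance grids.
#' @return The best `qcmd_call_params`, with the achieved balanced accuracy
#'   in attribute `"balanced_accuracy"`.
#' @export
calibrate_qcmd_tolerances <- function(slope_ratios, truth,
                                      grid_positive = seq(0.05, 0.45, 0.05),
                                      grid_ambiguous = seq(0.10, 0.90, 0.05)) {
  stopifnot(length(slope_ratios) == length(truth), is.logical(truth),
            any(truth), any(!truth))
  best <- NULL; best_ba <- -Inf
  for (tp in grid_positive) for (ta in grid_ambiguous[grid_ambiguous > tp]) {
    call_pos <- slope_ratios <= tp
    call_neg <- slope_ratios > ta
    ba <- mean(c(mean(call_pos[truth]), mean(call_neg[!truth])))
    if (ba > best_ba) { best_ba <- ba; best <- c(tp, ta) }
  }
  out <- qcmd_call_params(best[1L], best[2L])
  attr(out, "balanced_accuracy") <- best_ba
  out
}
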