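#' Write / read the sensorgram CSV dialect
#'
#' Columns `time_s,response_RU,phase`; UTF-8, '.' decimal separator, floats
#' at 12 significant digits so a write/read round trip is lossless at that
#' precision, deterministic byte-identical output for identical input.
#'
#' @param sensorgram A `sensorgram`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_sensorgram_csv <- function(sensorgram, path) {
  stopifnot(inherits(sensorgram, "sensorgram"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("time_s,response_RU,phase", con)
  writeLines(sprintf("%.12g,%.12g,%s", sensorgram$time,
                     sensorgram$response, sensorgram$phase), con)
  invisible(path)
}

.valid_phases <- c("baseline", "association", "dissociation", "regeneration")

#' @rdname write_sensorgram_csv
#' @param conc Analyte concentration to attach to the read sensorgram, M.
#' @export
read_sensorgram_csv <- function(path, conc = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  if (!length(lines) || !identical(lines[1L], "time_s,response_RU,phase"))
    stop("parse error at line 1: expected header 'time_s,response_RU,phase'",
         call. = FALSE)
  body <- lines[-1L]
  parts <- strsplit(body, ",", fixed = TRUE)
  bad <- which(lengths(parts) != 3L)
  if (length(bad))
    stop("parse error at line ", bad[1L] + 1L, ": expected 3 fields",
         call. = FALSE)
  time <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 1L)))
  resp <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  phase <- vapply(parts, `[[`, "", 3L)
  bad <- which(!is.finite(time) | !is.finite(resp))
  if (length(bad))
    stop("parse error at line ", bad[1L] + 1L, ": non-numeric value",
         call. = FALSE)
  bad <- which(!phase %in% .valid_phases)
  if (length(bad))
    stop("parse error at line ", bad[1L] + 1L, ": invalid phase '",
         phase[bad[1L]], "'", call. = FALSE)
  if (length(time) > 1L && any(diff(time) <= 0))
    stop("validation error: time must be strictly increasing", call. = FALSE)
  sg <- data.frame(time = time, response = resp, phase = phase,
                   stringsAsFactors = FALSE)
  attr(sg, "conc") <- conc
  attr(sg, "sample_id") <- NA_character_
  attr(sg, "probe_id") <- NA_character_
  attr(sg, "seed") <- NA_integer_
  class(sg) <- c("sensorgram", "data.frame")
  sg
}

#' Write / read the QCM-D CSV dialect
#'
#' Long format, one row per (time point, overtone):
#' `time_s,overtone,delta_f_Hz,delta_D_1e-6`.
#'
#' @param trace A `qcmd_trace`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_qcmd_csv <- function(trace, path) {
  stopifnot(inherits(trace, "qcmd_trace"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("time_s,overtone,delta_f_Hz,delta_D_1e-6", con)
  for (j in seq_along(trace$overtones))
    writeLines(sprintf("%.12g,%d,%.12g,%.12g", trace$time,
                       as.integer(trace$overtones[j]),
                       trace$delta_f[, j], trace$delta_D[, j]), con)
  invisible(path)
}

#' @rdname write_qcmd_csv
#' @param fundamental_frequency Crystal fundamental, Hz.
#' @export
read_qcmd_csv <- function(path, fundamental_frequency = 4.95e6) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "overtone", "delta_f_Hz", "delta_D_1e.6")
  if (!all(need %in% names(d)))
    stop("parse error: expected columns time_s,overtone,delta_f_Hz,",
         "delta_D_1e-6", call. = FALSE)
  ov <- sort(unique(d$overtone))
  if (any(ov %% 2 != 1)) stop("overtones must be odd", call. = FALSE)
  time <- sort(unique(d$time_s))
  df <- matrix(NA_real_, length(time), length(ov),
               dimnames = list(NULL, paste0("n", ov)))
  dD <- df
  for (j in seq_along(ov)) {
    sub <- d[d$overtone == ov[j], ]
    sub <- sub[order(sub$time_s), ]
    if (nrow(sub) != length(time))
      stop("validation error: overtone ", ov[j],
           " has a different time grid", call. = FALSE)
    df[, j] <- sub$delta_f_Hz
    dD[, j] <- sub$delta_D_1e.6
  }
  structure(list(time = time, delta_f = df, delta_D = dD, overtones = ov,
                 phase = rep(NA_character_, length(time)),
                 fundamental_frequency = fundamental_frequency,
                 sample_id = NA_character_, seed = NA_integer_),
            class = "qcmd_trace")
}

#' Write a fit report CSV
#'
#' Mirrors the column structure of the study's kinetic-constant table:
#' `sample_id, probe_id, ka, kd, Kd, Ka, se_ka, se_kd, rss, converged`.
#'
#' @param fits Named list of `fit_result` objects (names = sample ids), or a
#'   data.frame already in report shape.
#' @param path Output file.
#' @param probe_id Probe label column value (recycled).
#' @return The report data.frame, invisibly.
#' @export
write_fit_report_csv <- function(fits, path, probe_id = "mutant") {
  if (!is.data.frame(fits)) {
    rows <- lapply(names(fits), function(id) {
      f <- fits[[id]]
      if (f$converged)
        data.frame(sample_id = id, probe_id = probe_id,
                   ka = f$estimate$ka, kd = f$estimate$kd,
                   Kd = f$estimate$Kd, Ka = f$estimate$Ka,
                   se_ka = f$se[["ka"]], se_kd = f$se[["kd"]],
                   rss = f$rss, converged = TRUE, stringsAsFactors = FALSE)
      else
        data.frame(sample_id = id, probe_id = probe_id, ka = NA_real_,
                   kd = NA_real_, Kd = NA_real_, Ka = NA_real_,
                   se_ka = NA_real_, se_kd = NA_real_, rss = NA_real_,
                   converged = FALSE, stringsAsFactors = FALSE)
    })
    fits <- do.call(rbind, rows)
  }
  .write_csv_deterministic(fits, path)
  invisible(fits)
}

#' Write a cohort manifest CSV
#'
#' @param cohort A `cohort`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_manifest_csv <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort"))
  .write_csv_deterministic(cohort$manifest, path)
  invisible(path)
}

# Deterministic CSV writer: fixed column order, %.12g floats, UTF-8, LF.
.write_csv_deterministic <- function(d, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(names(d), collapse = ","), con)
  if (nrow(d)) {
    cols <- lapply(d, function(col) {
      if (is.double(col)) sprintf("%.12g", col) else as.character(col)
    })
    writeLines(do.call(paste, c(cols, sep = ",")), con)
  }
  invisible(path)
}

#' Study configuration
#'
#' A plain-list configuration (seeds, noise levels, threshold factor, QCM-D
#' tolerances, kinetic distribution parameters, output directory) that
#' round-trips losslessly through JSON.
#'
#' @param seed Master seed.
#' @param threshold_factor Ka-rule factor.
#' @param tol_positive,tol_ambiguous QCM-D call tolerances.
#' @param noise_sd SPR noise, RU.
#' @param n_carriers,n_noncarriers Cohort shape.
#' @param out_dir Output directory.
#' @param ... Further fields stored verbatim.
#' @return Object of class `study_config` (a list).
#' @export
study_config <- function(seed = 1, threshold_factor = 10,
                         tol_positive = 0.15, tol_ambiguous = 0.35,
                         noise_sd = 0.5, n_carriers = 17, n_noncarriers = 5,
                         out_dir = ".", ...) {
  structure(list(seed = seed, threshold_factor = threshold_factor,
                 tol_positive = tol_positive, tol_ambiguous = tol_ambiguous,
                 noise_sd = noise_sd, n_carriers = n_carriers,
                 n_noncarriers = n_noncarriers, out_dir = out_dir, ...),
            class = "study_config")
}

#' @rdname study_config
#' @param config A `study_config`.
#' @param path JSON file path.
#' @export
write_study_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname study_config
#' @export
read_study_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  structure(jsonlite::read_json(path, simplifyVector = TRUE),
            class = "study_config")
}
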