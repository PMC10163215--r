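#' Ka-threshold classification rule
#'
#' A sample is called mutation-positive when its association equilibrium
#' constant against the mutation-specific probe is at most one
#' `threshold_factor` below the Ka measured for the fully complementary
#' synthetic target of the same panel. The boundary is inclusive: Ka exactly
#' at `Ka_reference / threshold_factor` -- the outermost admissible
#' threshold, "a maximum of an order of magnitude lower" -- is positive.
#'
#' @param ka_reference Reference Ka, M^-1 (> 0), from the synthetic fully
#'   complementary target of the mutation panel.
#' @param threshold_factor Dimensionless >= 1 (default 10, one order of
#'   magnitude).
#' @return Object of class `classification_rule`.
#' @export
classification_rule <- function(ka_reference, threshold_factor = 10) {
  if (!is.finite(ka_reference) || ka_reference <= 0)
    stop("ka_reference must be > 0", call. = FALSE)
  if (!is.finite(threshold_factor) || threshold_factor < 1)
    stop("threshold_factor must be >= 1", call. = FALSE)
  structure(list(ka_reference = ka_reference,
                 threshold_factor = threshold_factor),
            class = "classification_rule")
}

#' One per-sample genotype call
#'
#' @param sample_id Sample identifier.
#' @param panel Mutation panel (e.g. `"5382insC"`).
#' @param assay `"SPR"`, `"QCMD"` or `"PCR"`.
#' @param call `"positive"`, `"negative"` or `"ambiguous"` (PCR calls are
#'   never ambiguous).
#' @param evidence Ka (SPR, M^-1) or relative slope difference (QCM-D);
#'   required for SPR/QCMD calls.
#' @return Object of class `genotype_call`.
#' @export
genotype_call <- function(sample_id, panel, assay = c("SPR", "QCMD", "PCR"),
                          call = c("positive", "negative", "ambiguous"),
                          evidence = NA_real_) {
  assay <- match.arg(assay)
  call <- match.arg(call)
  if (assay == "PCR" && call == "ambiguous")
    stop("PCR calls are never ambiguous", call. = FALSE)
  if (assay != "PCR" && !is.finite(evidence))
    stop("SPR/QCMD calls require numeric evidence", call. = FALSE)
  structure(list(sample_id = sample_id, panel = panel, assay = assay,
                 call = call, evidence = evidence),
            class = "genotype_call")
}

#' @export
print.genotype_call <- function(x, ...) {
  cat(sprintf("<genotype_call> %s [%s/%s]: %s (evidence %.3g)\n",
              x$sample_id, x$panel, x$assay, x$call, x$evidence))
  invisible(x)
}

#' Apply the Ka-threshold rule to one sample
#'
#' @param ka_sample Sample Ka, M^-1 (> 0).
#' @param rule A `classification_rule`.
#' @return `"positive"` if
#'   `ka_sample >= rule$ka_reference / rule$threshold_factor`, else
#'   `"negative"`.
#' @export
#' @examples
#' rule <- classification_rule(2.28e10)
#' ka_threshold_call(7.25e10, rule)  # "positive"
#' ka_threshold_call(4.65e5, rule)   # "negative"
ka_threshold_call <- function(ka_sample, rule) {
  stopifnot(inherits(rule, "classification_rule"))
  if (any(!is.finite(ka_sample)) || any(ka_sample <= 0))
    stop("ka_sample must be > 0", call. = FALSE)
  ifelse(ka_sample >= rule$ka_reference / rule$threshold_factor,
         "positive", "negative")
}

#' Classify a set of fitted samples against per-panel references
#'
#' @param fitted data.frame with columns `sample_id`, `panel`, `Ka`.
#' @param references Named numeric vector mapping panel -> reference Ka.
#' @param threshold_factor Passed to [classification_rule()].
#' @return List of `genotype_call` objects in input order.
#' @export
classify_cohort <- function(fitted, references, threshold_factor = 10) {
  stopifnot(is.data.frame(fitted),
            all(c("sample_id", "panel", "Ka") %in% names(fitted)))
  if (!nrow(fitted)) return(list())
  missing_ref <- setdiff(unique(fitted$panel), names(references))
  if (length(missing_ref))
    stop("no reference Ka for panel(s): ",
         paste(missing_ref, collapse = ", "), call. = FALSE)
  lapply(seq_len(nrow(fitted)), function(i) {
    rule <- classification_rule(references[[fitted$panel[i]]],
                                threshold_factor)
    genotype_call(fitted$sample_id[i], fitted$panel[i], "SPR",
                  ka_threshold_call(fitted$Ka[i], rule),
                  evidence = fitted$Ka[i])
  })
}

# Round half away from zero (94.1 = 16/17, 0.13 = 0.125 * ...): base round()
# rounds half to even, which would disagree with the printed values.
round_half_out <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Per-sample correctness over possibly repeated calls: a sample is correct
# only if every call made on it (across panels) matches its truth status.
.metric <- function(calls, truth, want_positive) {
  stopifnot(is.data.frame(calls),
            all(c("sample_id", "call") %in% names(calls)))
  ids <- names(truth)[truth == want_positive]
  ids <- intersect(ids, unique(calls$sample_id))
  if (!length(ids))
    stop("no truth-", if (want_positive) "positive" else "negative",
         " samples among the calls: metric undefined", call. = FALSE)
  target <- if (want_positive) "positive" else "negative"
  correct <- vapply(ids, function(id)
    all(calls$call[calls$sample_id == id] == target), logical(1L))
  list(pct = round_half_out(100 * sum(correct) / length(ids), 1),
       n_correct = sum(correct), n_total = length(ids))
}

#' Diagnostic specificity of a set of calls
#'
#' 100 x (truth-negative samples called negative in every panel tested) /
#' (all truth-negative samples), to one decimal (half away from zero).
#' Ambiguous calls count as not-correct.
#'
#' @param calls data.frame with columns `sample_id`, `call`.
#' @param truth Named logical vector: `TRUE` = mutation-bearing.
#' @return Percentage (numeric scalar) with attributes `n_correct`,
#'   `n_total`.
#' @export
specificity <- function(calls, truth) {
  m <- .metric(calls, truth, want_positive = FALSE)
  structure(m$pct, n_correct = m$n_correct, n_total = m$n_total)
}

#' Diagnostic selectivity (sensitivity) of a set of calls
#'
#' 100 x (truth-positive samples called positive) / (all truth-positive
#' samples), to one decimal (half away from zero). Ambiguous counts as
#' not-correct.
#'
#' @inheritParams specificity
#' @return Percentage with attributes `n_correct`, `n_total`.
#' @export
selectivity <- function(calls, truth) {
  m <- .metric(calls, truth, want_positive = TRUE)
  structure(m$pct, n_correct = m$n_correct, n_total = m$n_total)
}

# MD5 sums of the packaged fixtures, checked before any reference analysis.
.fixture_md5 <- c(
  table3_kinetics.csv = "ba4ad6c8b395875c415b66e1976283e8",
  table4_calls.csv    = "47416472b9845226d2d8da8c8298801e")

.fixture_path <- function(name) {
  system.file("extdata", name, package = "genosensr", mustWork = TRUE)
}

.check_fixture <- function(name) {
  path <- .fixture_path(name)
  sum <- unname(tools::md5sum(path))
  if (!identical(sum, unname(.fixture_md5[[name]])))
    stop("fixture ", name, " failed its integrity check (md5 ", sum, ")",
         call. = FALSE)
  path
}

#' Packaged kinetic-constant table
#'
#' The per-panel kinetic constants (synthetic target reference plus 20
#' patients, wild-type and mutant probe) shipped with the package.
#'
#' @return data.frame.
#' @export
reference_kinetics <- function() {
  utils::read.csv(.check_fixture("table3_kinetics.csv"),
                  check.names = FALSE, stringsAsFactors = FALSE)
}

#' Packaged genotyping-outcome table
#'
#' Per-sample QCM-D/SPR/PCR calls for the 22-patient clinical cohort
#' (17 mutation-bearing, 5 mutation-free; the five negatives recur across
#' panels and share a `sample_uid`).
#'
#' @return data.frame.
#' @export
reference_calls <- function() {
  utils::read.csv(.check_fixture("table4_calls.csv"),
                  check.names = FALSE, stringsAsFactors = FALSE)
}

#' Reproduce the reference-study arithmetic, classification and metrics
#'
#' Runs three checks against the packaged fixtures: (a) an arithmetic audit
#' of the kinetic-constant table (relative deviation of kd/ka from the
#' printed Kd and of 1/Kd from the printed Ka, for both probe columns of
#' every row); (b) the Ka-threshold rule (factor 10, boundary inclusive)
#' applied to every patient's mutant-probe Ka against the panel's synthetic
#' reference, compared with the labelled mutation status; (c) the four
#' cohort-level performance metrics recomputed from the outcome table.
#'
#' @param threshold_factor Threshold factor of the Ka rule (default 10).
#' @param audit_tol Relative tolerance of the arithmetic audit
#'   (default 0.015).
#' @return List with elements `audit` (data.frame of relative deviations
#'   plus `max_rel_dev` and `pass`), `concordance` (data.frame of calls
#'   plus `n_concordant`, `n_total`), and `metrics` (named list:
#'   `spr_specificity`, `spr_selectivity`, `qcmd_specificity`,
#'   `qcmd_selectivity`).
#' @export
reproduce_reference_results <- function(threshold_factor = 10,
                                        audit_tol = 0.015) {
  tab3 <- reference_kinetics()
  tab4 <- reference_calls()

  # (a) arithmetic audit, both probe columns
  audit <- do.call(rbind, lapply(c("wt", "mut"), function(pr) {
    ka <- tab3[[paste0("ka_", pr, "_probe")]]
    kd <- tab3[[paste0("kd_", pr, "_probe")]]
    Kd <- tab3[[paste0("Kd_", pr, "_probe")]]
    Ka <- tab3[[paste0("Ka_", pr, "_probe")]]
    data.frame(panel = tab3$panel, row_label = tab3$row_label, probe = pr,
               Kd_printed = Kd, Kd_computed = kd_equilibrium(ka, kd),
               rel_dev_Kd = abs(kd_equilibrium(ka, kd) - Kd) / Kd,
               Ka_printed = Ka, Ka_computed = ka_equilibrium(Kd),
               rel_dev_Ka = abs(ka_equilibrium(Kd) - Ka) / Ka,
               stringsAsFactors = FALSE)
  }))
  max_dev <- max(audit$rel_dev_Kd, audit$rel_dev_Ka)

  # (b) threshold classification of every patient row
  refs <- tab3[tab3$row_label == "Target", ]
  ref_ka <- stats::setNames(refs$Ka_mut_probe, refs$panel)
  pts <- tab3[tab3$row_label != "Target", ]
  calls <- classify_cohort(
    data.frame(sample_id = pts$row_label, panel = pts$panel,
               Ka = pts$Ka_mut_probe, stringsAsFactors = FALSE),
    ref_ka, threshold_factor)
  expected <- ifelse(pts$mutation_status == "with mut.",
                     "positive", "negative")
  got <- vapply(calls, `[[`, character(1L), "call")
  concordance <- data.frame(
    panel = pts$panel, sample = pts$row_label, Ka = pts$Ka_mut_probe,
    expected = expected, called = got, concordant = got == expected,
    stringsAsFactors = FALSE)

  # (c) cohort metrics from the outcome table
  truth <- !duplicated(tab4$sample_uid)
  truth <- stats::setNames(tab4$status[truth] == "mutation",
                           tab4$sample_uid[truth])
  metric_input <- function(col)
    data.frame(sample_id = tab4$sample_uid, call = tab4[[col]],
               stringsAsFactors = FALSE)
  spr <- metric_input("spr_call"); qcmd <- metric_input("qcmd_call")
  metrics <- list(
    spr_specificity = specificity(spr, truth),
    spr_selectivity = selectivity(spr, truth),
    qcmd_specificity = specificity(qcmd, truth),
    qcmd_selectivity = selectivity(qcmd, truth))

  list(audit = list(table = audit, max_rel_dev = max_dev,
                    tol = audit_tol, pass = max_dev <= audit_tol),
       concordance = list(table = concordance,
                          n_concordant = sum(concordance$concordant),
                          n_total = nrow(concordance)),
       metrics = metrics)
}
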