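trial_mandatory_cols <- function() {
  c("id", "arm", "age", "gender", "hy_stage", "moca", "mmse", "diabetes",
    "mi_history", "ihd_history", "dbs_history", "carer", "updrs", "fog",
    "falls_12m", "baseline_cost", "death_month", "followed_12m",
    "u_0", "u_3", "u_6")
}

#' Validate a wide-format trial dataset
#'
#' Checks the documented schema: mandatory columns present, arms labelled
#' `intervention`/`control`, utilities within the value-set range, resource
#' counts non-negative, EQ-5D-3L state columns (if present) made of digits
#' 1-3. Violations are reported with row and column coordinates.
#'
#' @param data data.frame to validate.
#' @param units unit-cost table defining expected resource items.
#' @return the data invisibly (classed `trial_data`); errors on violation.
#' @export
validate_trial_data <- function(data, units = default_unit_costs()) {
  missing_cols <- setdiff(trial_mandatory_cols(), names(data))
  if (length(missing_cols))
    stopf("validation error: missing mandatory column(s): %s",
          paste(missing_cols, collapse = ", "))
  bad_arm <- !data$arm %in% c("intervention", "control")
  if (any(bad_arm))
    stopf("validation error: invalid arm at row(s) %s",
          paste(head(which(bad_arm), 5), collapse = ", "))
  for (col in grep("^u_", names(data), value = TRUE)) {
    v <- data[[col]]
    bad <- !is.na(v) & (v < -0.594 - 1e-9 | v > 1 + 1e-9)
    if (any(bad))
      stopf("validation error: utility out of range in column %s, row(s) %s",
            col, paste(head(which(bad), 5), collapse = ", "))
  }
  count_cols <- intersect(as.vector(outer(units$item, c(3, 6, 12),
                                          item_count_col)), names(data))
  for (col in count_cols) {
    v <- data[[col]]
    bad <- !is.na(v) & v < 0
    if (any(bad))
      stopf("validation error: negative count in column %s, row(s) %s",
            col, paste(head(which(bad), 5), collapse = ", "))
  }
  for (col in grep("^eq5d_", names(data), value = TRUE)) {
    v <- data[[col]]
    bad <- !is.na(v) & !grepl("^[123]{5}$", v)
    if (any(bad))
      stopf("validation error: malformed EQ-5D state in column %s, row(s) %s",
            col, paste(head(which(bad), 5), collapse = ", "))
  }
  if (!inherits(data, "trial_data"))
    class(data) <- c("trial_data", class(data))
  invisible(data)
}

#' Write a trial dataset to CSV
#'
#' Wide format, one row per participant, timepoint-suffixed columns,
#' UTF-8, missing values as empty cells. Currency columns are 2016 GBP.
#'
#' @param data trial dataset.
#' @param path output file.
#' @return `path` invisibly.
#' @export
write_trial_csv <- function(data, path) {
  write.csv(as.data.frame(data), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read and validate a trial dataset from CSV
#'
#' @param path CSV written by [write_trial_csv()] (or matching the schema).
#' @param units unit-cost table for item validation.
#' @return validated `trial_data`.
#' @export
read_trial_csv <- function(path, units = default_unit_costs()) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  d <- read.csv(path, stringsAsFactors = FALSE,
                colClasses = c(id = "character"))
  eq_cols <- grep("^eq5d_", names(d), value = TRUE)
  for (col in eq_cols) d[[col]] <- as.character(d[[col]])
  # an all-NA numeric column (e.g. death_month with no deaths) reads as
  # logical; restore its declared type
  if ("death_month" %in% names(d)) d$death_month <- as.numeric(d$death_month)
  validate_trial_data(d, units)
  class(d) <- c("trial_data", "data.frame")
  d
}

#' Run manifest for reproducibility
#'
#' Captures everything needed to reproduce a run: package version, seed(s),
#' MD5 digests of input files, configuration hash, scenario list, timestamp.
#'
#' @param seed integer seed used for the run.
#' @param inputs named character vector of input file paths (digested).
#' @param config any list of settings (hashed after serialisation).
#' @param scenarios character vector of scenario ids.
#' @return list of class `run_manifest`.
#' @export
run_manifest <- function(seed, inputs = character(0), config = list(),
                         scenarios = character(0)) {
  digests <- if (length(inputs)) vapply(inputs, function(p)
    unname(md5sum(p)), character(1)) else character(0)
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(config, tf)  # scratch only; manifest stores the hash
  structure(list(package_version = as.character(packageVersion("trialcea")),
                 seed = seed,
                 input_digests = as.list(digests),
                 config_hash = unname(md5sum(tf)),
                 scenarios = scenarios,
                 timestamp = format(Sys.time(), tz = "UTC",
                                    "%Y-%m-%dT%H:%M:%SZ")),
            class = "run_manifest")
}

#' Write a full analysis result bundle
#'
#' Emits the standard CSV tables (arm means, bootstrap pairs, CEAC,
#' quadrant summary, intervention-cost audit) plus a JSON run manifest.
#' Every file is plain UTF-8; currency columns are 2016 GBP.
#'
#' @param result a `cea_result` from [run_cea()].
#' @param dir output directory (created if needed).
#' @return `dir` invisibly.
#' @export
write_cea_result <- function(result, dir) {
  stopifnot(inherits(result, "cea_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  est <- result$estimate
  am <- est$arm_means
  arm_tab <- data.frame(
    quantity = c("cost_control", "cost_intervention", "qaly_control",
                 "qaly_intervention", "delta_cost", "delta_qaly", "icer"),
    value = c(am$cost_control, am$cost_intervention, am$qaly_control,
              am$qaly_intervention, est$delta_cost, est$delta_qaly,
              est$icer$ratio))
  write.csv(arm_tab, file.path(dir, "arm_means.csv"), row.names = FALSE)
  pairs <- as.data.frame(est$pairs)
  pairs$quadrant <- est$quadrant
  write.csv(pairs, file.path(dir, "bootstrap_pairs.csv"), row.names = FALSE)
  write.csv(as.data.frame(result$ceac), file.path(dir, "ceac.csv"),
            row.names = FALSE)
  write.csv(ce_plane_quadrants(est), file.path(dir, "quadrants.csv"),
            row.names = FALSE)
  write.csv(result$cost_audit, file.path(dir, "intervention_cost_audit.csv"),
            row.names = FALSE)
  jsonlite::write_json(unclass(result$manifest),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Run the full base-case cost-utility analysis
#'
#' Orchestrates the whole pipeline on a (possibly incomplete) trial
#' dataset: item-level zero-fill, category costing, arm-wise multiple
#' imputation, Gamma/Gaussian GLMs with recycled predictions pooled over
#' imputations, bootstrap uncertainty, ICER and CEAC.
#'
#' @param data trial dataset.
#' @param units a `unit_cost_table`.
#' @param ledger a `cost_ledger` for the intervention cost.
#' @param spec a [cea_model_spec()].
#' @param horizon months (6 or 12).
#' @param B bootstrap iterations.
#' @param m imputations for the point estimate.
#' @param seed integer seed.
#' @param thresholds CEAC threshold grid.
#' @param ... passed to [bootstrap_pipeline()].
#' @return object of class `cea_result`: `estimate` (a `cea_estimate`),
#'   `ceac`, `quadrants`, `intervention_cost`, `cost_audit`, `manifest`.
#' @export
run_cea <- function(data, units = default_unit_costs(),
                    ledger = default_ledger(), spec = cea_model_spec(),
                    horizon = 6, B = 1000, m = 50, seed = 1,
                    thresholds = seq(0, 200000, by = 500), ...) {
  validate_trial_data(data, units)
  int_cost <- intervention_cost_per_patient(ledger, audit = TRUE)
  est <- bootstrap_pipeline(data, units, as.numeric(int_cost), spec,
                            horizon = horizon, B = B, m = m, seed = seed,
                            ...)
  curve <- ceac(est, thresholds)
  audit <- attr(int_cost, "audit")
  audit$sum <- NULL  # report 2 d.p. column only
  manifest <- run_manifest(seed,
                           config = list(horizon = horizon, B = B, m = m,
                                         spec = spec))
  structure(list(estimate = est, ceac = curve,
                 quadrants = ce_plane_quadrants(est),
                 intervention_cost = as.numeric(int_cost),
                 cost_audit = audit, manifest = manifest),
            class = "cea_result")
}

#' @export
print.cea_result <- function(x, ...) {
  cat(sprintf("Within-trial cost-utility analysis (intervention cost %0.2f GBP/patient)\n",
              x$intervention_cost))
  print(x$estimate)
  p30 <- x$ceac$prob_cost_effective[x$ceac$threshold == 30000]
  if (length(p30))
    cat(sprintf("  P(cost-effective at 30,000 GBP/QALY) = %0.3f\n", p30))
  invisible(x)
}
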