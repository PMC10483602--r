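cohort_schemas <- list(
  patients = c("patient_id", "site", "age", "sex", "ecog", "treatment",
               "metastasis_location", "tumour_location"),
  samples = c("sample_id", "patient_id", "draw_day"),
  ca199 = c("patient_id", "draw_day", "ca199_kU_per_L"),
  radiology = c("patient_id", "scan_day", "progression"),
  outcomes = c("patient_id", "pfs_day", "pfs_event", "os_day", "os_event"))

#' Write cohort tables to a directory
#'
#' Emits the five CSV tables (plus controls and the resolved configuration
#' as YAML for a simulated cohort).
#'
#' @param cohort a `ctmon_cohort` or compatible list of tables.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in names(cohort_schemas))
    write.csv(cohort[[nm]], file.path(dir, paste0(nm, ".csv")),
              row.names = FALSE)
  if (!is.null(cohort$controls))
    write.csv(data.frame(delta_cq = cohort$controls),
              file.path(dir, "controls.csv"), row.names = FALSE)
  if (!is.null(cohort$config)) {
    cfg <- cohort$config
    cfg$covariates <- lapply(cfg$covariates, function(x)
      if (is.null(names(x))) x else as.list(x))
    yaml::write_yaml(c(unclass(cfg), list(seed = cohort$seed)),
                     file.path(dir, "config.yaml"))
  }
  invisible(dir)
}

#' Read and validate cohort tables
#'
#' Reads the CSV tables written by [write_cohort()] (or prepared externally
#' in the same schema), validating required columns and referential
#' integrity; errors name the offending file and column.
#'
#' @param dir directory containing `patients.csv`, `samples.csv`,
#'   `ca199.csv`, `radiology.csv`, `outcomes.csv` and optionally
#'   `controls.csv`.
#' @return list of class `ctmon_cohort` (without latent/truth entries).
#' @export
read_cohort <- function(dir) {
  out <- list()
  for (nm in names(cohort_schemas)) {
    path <- file.path(dir, paste0(nm, ".csv"))
    if (!file.exists(path)) stop("missing cohort file: ", path)
    df <- read.csv(path, stringsAsFactors = FALSE)
    miss <- setdiff(cohort_schemas[[nm]], names(df))
    if (length(miss))
      stop(basename(path), ": missing column(s) ",
           paste(miss, collapse = ", "))
    out[[nm]] <- df
  }
  out$radiology$progression <- as.logical(out$radiology$progression)
  out$patients$ecog <- as.character(out$patients$ecog)
  for (cq in intersect(c("cq_pna_1", "cq_pna_2", "cq_nopna_1", "cq_nopna_2",
                         "ddcq"), names(out$samples)))
    out$samples[[cq]] <- as.numeric(out$samples[[cq]])
  for (nm in c("samples", "ca199", "radiology", "outcomes")) {
    orphan <- setdiff(out[[nm]]$patient_id, out$patients$patient_id)
    if (length(orphan))
      stop(nm, ".csv: patient_id not in patients.csv: ",
           paste(head(orphan, 5), collapse = ", "))
  }
  ctrl <- file.path(dir, "controls.csv")
  if (file.exists(ctrl)) out$controls <- read.csv(ctrl)$delta_cq
  class(out) <- "ctmon_cohort"
  out
}

#' Run the full monitoring analysis pipeline
#'
#' Executes quantification, baseline statistics, baseline and landmarked
#' survival analyses, the joint model, and serial monitoring on one cohort,
#' returning (and optionally writing) a seeded, reproducible report bundle.
#'
#' @param cohort a `ctmon_cohort` (from [generate_cohort()] or
#'   [read_cohort()]).
#' @param seed integer seed recorded in the report and used for the joint
#'   model.
#' @param landmark_day landmark for the 1-month analyses (days).
#' @param jm joint-model settings (`ctmon_jm_spec`), or `NULL` to skip the
#'   joint stage.
#' @param rule monitoring success rule.
#' @param out_dir optional directory for the JSON summary and CSV artifacts.
#' @return list of class `ctmon_report` with elements `quant`, `baseline`,
#'   `survival`, `joint` (unless skipped), `monitoring`, `meta`.
#' @export
run_pipeline <- function(cohort, seed = 1, landmark_day = 28,
                         jm = jm_spec(chains = 2, iter = 1500, burn = 500,
                                      thin = 2),
                         rule = "increase_or_persistence",
                         out_dir = NULL) {
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    message(sprintf("[%s] done in %.1fs", name,
                    as.numeric(Sys.time() - t0, units = "secs")))
    res
  }

  levels <- stage("quantify", {
    panel <- derive_cutoff(cohort$controls)
    quantify_samples(cohort$samples, panel)
  })
  # carry emitted ddcq when present (identical to quantified values for
  # amplified samples; emitted table is authoritative for the analyses)
  if ("ddcq" %in% names(cohort$samples)) {
    levels$ddcq <- cohort$samples$ddcq
  }

  baseline <- stage("baseline-stats", baseline_stats(cohort$patients, levels))

  survl <- stage("survival", {
    base <- levels[levels$draw_day == 0, ]
    det <- setNames(base$ddcq > 0, base$patient_id)
    oc <- cohort$outcomes[cohort$outcomes$patient_id %in% names(det), ]
    oc$detected <- as.numeric(det[oc$patient_id])
    run_one <- function(endpoint) {
      rec <- data.frame(patient_id = oc$patient_id,
                        event_time = oc[[paste0(endpoint, "_day")]],
                        event = oc[[paste0(endpoint, "_event")]],
                        detected = oc$detected)
      km <- lapply(split(rec, rec$detected), km_fit)
      lr <- logrank_test(rec, rec$detected)
      cx <- cox_fit(rec, "detected")
      lm28 <- landmark(rec, landmark_day)
      list(km_by_status = km, logrank = lr, cox = cx,
           landmark = list(day = landmark_day, n = nrow(lm28),
                           cox = if (length(unique(lm28$detected)) > 1)
                             cox_fit(lm28, "detected") else NULL))
    }
    list(pfs = run_one("pfs"), os = run_one("os"))
  })

  joint <- NULL
  if (!is.null(jm)) {
    joint <- stage("joint", {
      tabs <- cohort
      tabs$samples$ddcq <- levels$ddcq
      long <- prepare_longitudinal(tabs)
      surv <- data.frame(patient_id = cohort$outcomes$patient_id,
                         event_time = cohort$outcomes$pfs_day,
                         event = cohort$outcomes$pfs_event)
      surv <- surv[surv$patient_id %in% long$patient_id, ]
      W <- surv_design(cohort$patients[
        match(surv$patient_id, cohort$patients$patient_id), ])
      fit_joint(long, surv, W, spec = jm, seed = seed)
    })
  }

  monitoring <- stage("monitor", {
    tabs <- cohort
    tabs$samples$ddcq <- levels$ddcq
    mon <- monitor_ctdna(tabs, rule = rule)
    ca <- monitor_ca199(tabs, mon$eligible)
    list(ctdna = mon, ca199 = ca,
         lead_ctdna = lead_time_summary(mon$outcomes),
         lead_ca199 = lead_time_summary(ca),
         concordance = if (nrow(mon$outcomes))
           marker_concordance(mon$outcomes, ca) else NULL)
  })

  report <- structure(list(
    quant = levels, baseline = baseline, survival = survl, joint = joint,
    monitoring = monitoring,
    meta = list(seed = seed, landmark_day = landmark_day, rule = rule,
                n_patients = nrow(cohort$patients),
                package_version = as.character(
                  utils::packageVersion("ctmon")))),
    class = "ctmon_report")

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write.csv(levels, file.path(out_dir, "levels.csv"), row.names = FALSE)
    write.csv(baseline, file.path(out_dir, "baseline_stats.csv"),
              row.names = FALSE)
    write.csv(monitoring$ctdna$outcomes,
              file.path(out_dir, "monitoring.csv"), row.names = FALSE)
    jsonlite::write_json(report_summary(report),
                         file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

#' Flatten a report into a JSON-ready summary
#'
#' @param report a `ctmon_report`.
#' @return nested list of plain numbers/strings.
#' @export
report_summary <- function(report) {
  sv <- report$survival
  km_med <- function(k) lapply(k, function(x)
    list(median_days = x$median, ci = x$median_ci, n = x$n))
  out <- list(
    meta = report$meta,
    baseline = list(
      n_baseline = sum(report$quant$draw_day == 0),
      n_detected = sum(report$quant$ddcq[report$quant$draw_day == 0] > 0),
      fisher_p = setNames(
        as.list(report$baseline$p_value[!is.na(report$baseline$p_value)]),
        unique(report$baseline$variable))),
    survival = list(
      pfs = list(median_by_status = km_med(sv$pfs$km_by_status),
                 logrank_p = sv$pfs$logrank$p,
                 hr_detected = sv$pfs$cox$hr$hr[1]),
      os = list(median_by_status = km_med(sv$os$km_by_status),
                logrank_p = sv$os$logrank$p,
                hr_detected = sv$os$cox$hr$hr[1])),
    monitoring = list(
      n_eligible = report$monitoring$lead_ctdna$n_eligible,
      n_success = report$monitoring$lead_ctdna$n_success,
      median_lead_days = report$monitoring$lead_ctdna$median_lead,
      lead_p = report$monitoring$lead_ctdna$p_value,
      union_fraction = if (!is.null(report$monitoring$concordance))
        report$monitoring$concordance$union_fraction else NA))
  if (!is.null(report$joint))
    out$joint <- list(hr = unname(report$joint$alpha_hr["hr"]),
                      ci = unname(report$joint$alpha_hr[c("lower", "upper")]),
                      rhat_alpha = report$joint$rhat_alpha,
                      seed = report$joint$seed)
  out
}
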