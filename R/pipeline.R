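# Orchestration: derived measures -> group statistics -> single-case
# inference, with a run manifest and per-patient reports.

#' Run the full analysis pipeline
#'
#' Executes the stages in the order the analysis prescribes: CRLB QC and
#' corrections, head-size normalization, asymmetry indices, group-level
#' statistics, clinical correlations, then the single-case battery with
#' FWE correction and concordance labels for every patient. All result
#' tables are written to `out_dir` together with a JSON run manifest. The
#' run is idempotent: identical inputs, config and seed reproduce
#' byte-identical tables and the same manifest hash.
#'
#' @param cohort an `hc_cohort`.
#' @param reference list with `subjects` and `volumes` of an independent
#'   reference cohort for slope fitting; if `NULL` the study controls are
#'   used, with a warning.
#' @param config an [analysis_config()].
#' @param out_dir output directory; `NULL` skips writing.
#' @param input_paths optional named paths of the source files, recorded
#'   (hashed) in the manifest.
#' @return List of class `hc_results`: `derived`, `group`, `symmetry`,
#'   `correlations`, `case_results`, `concordance`, `manifest`.
#' @export
run_full_pipeline <- function(cohort, reference = NULL,
                              config = analysis_config(), out_dir = NULL,
                              input_paths = NULL) {
  stopifnot(inherits(cohort, "hc_cohort"))
  stage <- "derived_measures"
  res <- tryCatch({
    if (is.null(reference)) {
      warning("no independent reference cohort supplied; fitting slopes on study controls")
      ctrl <- cohort$subjects[cohort$subjects$group == "control", ]
      reference <- list(subjects = ctrl,
                        volumes = cohort$volumes[
                          cohort$volumes$subject_id %in% ctrl$subject_id, ])
    }
    slopes <- fit_reference_slopes(reference$volumes, reference$subjects)
    derived <- derive_measures(cohort, slopes, config)

    stage <- "group_stats"
    patients <- cohort$subjects$subject_id[cohort$subjects$group == "patient"]
    group <- NULL; corr <- NULL
    if (length(patients) == 0) {
      message("NOTE: no patients in cohort; group and case stages skipped")
    } else {
      group <- group_analysis(cohort, derived, config)
      corr <- clinical_correlations(cohort, derived, config)
    }

    stage <- "single_case_inference"
    case_results <- NULL; concordance <- NULL
    if (length(patients)) {
      case_list <- lapply(patients, function(p)
        run_case_battery(p, cohort, derived, config))
      case_results <- do.call(rbind, case_list)
      conc <- list()
      for (p in patients) {
        lat <- cohort$subjects$eeg_laterality[
          cohort$subjects$subject_id == p]
        r <- case_results[case_results$subject_id == p, , drop = FALSE]
        for (mod in c("volumetry", "mrs"))
          conc[[length(conc) + 1L]] <-
            classify_concordance(r, lat, mod, alpha = config$alpha)
      }
      concordance <- do.call(rbind, conc)
    }

    list(derived = derived, group = group,
         symmetry = if (!is.null(group)) attr(group, "symmetry"),
         correlations = corr, case_results = case_results,
         concordance = concordance, slopes = slopes)
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })

  manifest <- .build_manifest(config, input_paths, res)
  res$manifest <- manifest
  class(res) <- "hc_results"
  if (!is.null(out_dir)) write_pipeline_results(res, out_dir)
  res
}

# derived-measure long table for serialization
.derived_table <- function(derived) {
  vol <- derived$volumes
  mrs <- derived$mrs
  vol$table <- "volumes"
  mrs$table <- "mrs"
  list(volumes = vol, mrs = mrs, asymmetry = derived$asymmetry)
}

.results_tables <- function(res) {
  dt <- .derived_table(res$derived)
  tabs <- list(derived_volumes = dt$volumes, derived_mrs = dt$mrs,
               asymmetry = dt$asymmetry)
  if (!is.null(res$group)) tabs$group_results <- res$group
  if (!is.null(res$symmetry)) tabs$symmetry <- res$symmetry
  if (!is.null(res$correlations)) tabs$correlations <- res$correlations
  if (!is.null(res$case_results)) tabs$case_results <- res$case_results
  if (!is.null(res$concordance)) tabs$concordance <- res$concordance
  tabs
}

.build_manifest <- function(config, input_paths, res) {
  input_hashes <- if (!is.null(input_paths))
    as.list(tools::md5sum(unlist(input_paths))) else list()
  tabs <- .results_tables(res)
  table_hashes <- lapply(tabs, function(df) {
    tf <- tempfile(); on.exit(unlink(tf))
    .write_table(as.data.frame(df), tf)
    unname(tools::md5sum(tf))
  })
  cfg_json <- as.character(jsonlite::toJSON(unclass(config),
                                            auto_unbox = TRUE, digits = NA))
  tf <- tempfile(); on.exit(unlink(tf))
  writeLines(c(cfg_json, unlist(input_hashes), unlist(table_hashes)), tf)
  run_hash <- unname(tools::md5sum(tf))
  list(config = unclass(config), input_hashes = input_hashes,
       table_hashes = table_hashes, seed = config$rng_seed,
       version = as.character(utils::packageVersion("hippocase")),
       run_hash = run_hash,
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

#' Write all pipeline result tables and the manifest
#'
#' @param res an `hc_results`.
#' @param out_dir output directory (created if needed).
#' @return Named vector of written paths, invisibly.
#' @export
write_pipeline_results <- function(res, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  tabs <- .results_tables(res)
  paths <- character(0)
  for (nm in names(tabs)) {
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    write_results(as.data.frame(tabs[[nm]]), p,
                  dictionary = .table_dictionary(nm))
    paths[nm] <- p
  }
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(res$manifest, mp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  paths["manifest"] <- mp
  invisible(paths)
}

.table_dictionary <- function(name) {
  base <- c(
    note = "group-level p-values are reported uncorrected for multiplicity")
  switch(name,
    case_results = c(
      variable = "battery variable (hemisphere.measure or measure.asymmetry)",
      p_uncorrected = "sign-flip permutation p, uncorrected",
      fwe_significant = "survives family-wise correction over family_size variables",
      direction = "sign of case deviation from the control mean"),
    group_results = c(
      f_statistic = "ANCOVA F for the group term, controlling for age",
      base),
    correlations = c(
      r = "Pearson correlation (partial where age_adjusted)",
      tails = "one-tailed tests expect a positive association"),
    NULL)
}

#' Clinical correlation battery
#'
#' The correlation family of the group stage, run on patients: age at
#' onset (two-tailed) and epilepsy duration (age-adjusted partial) against
#' ipsilateral/contralateral subfield volumes; verbal-memory scores
#' against language-dominant-hemisphere subiculum volume (one-tailed,
#' positive expected) and left hippocampal glutamine (two-tailed). Pairs
#' with fewer than 4 complete observations are skipped.
#'
#' @param cohort an `hc_cohort`.
#' @param derived matching [derive_measures()] output.
#' @param config an [analysis_config()].
#' @return data.frame: `x`, `y`, `tails`, `age_adjusted`, `r`, `p`, `n`.
#' @export
clinical_correlations <- function(cohort, derived,
                                  config = analysis_config()) {
  subj <- cohort$subjects
  pat <- subj[subj$group == "patient", ]
  if (!nrow(pat)) return(NULL)
  vm <- variable_matrix(cohort, derived)
  rows <- list()
  add <- function(xname, x, yname, y, tails, age_adjust, age = NULL) {
    ok <- sum(!is.na(x) & !is.na(y) &
                (if (age_adjust) !is.na(age) else TRUE))
    if (ok < 4) return()
    ct <- tryCatch(correlate(x, y, tails = tails, age_adjust = age_adjust,
                             age = age),
                   error = function(e) NULL)
    if (is.null(ct)) return()
    rows[[length(rows) + 1L]] <<- data.frame(
      x = xname, y = yname, tails = tails, age_adjusted = age_adjust,
      r = ct$r, p = ct$p, n = ct$n, stringsAsFactors = FALSE)
  }
  # ipsi/contra subfield volumes vs onset and duration
  for (s in hc_subfields()) {
    ipsi <- contra <- rep(NA_real_, nrow(pat))
    for (i in seq_len(nrow(pat))) {
      mc <- map_ipsi_contra(vm[pat$subject_id[i], paste0("left.", s, ".volume")],
                            vm[pat$subject_id[i], paste0("right.", s, ".volume")],
                            pat$eeg_laterality[i])
      if (!is.null(mc$ipsilateral)) { ipsi[i] <- mc$ipsilateral
                                      contra[i] <- mc$contralateral }
    }
    add("age_at_onset", pat$age_at_onset, paste0("ipsi.", s, ".volume"),
        ipsi, "two", FALSE)
    add("duration", pat$duration, paste0("ipsi.", s, ".volume"), ipsi,
        "two", TRUE, age = pat$age)
    add("duration", pat$duration, paste0("contra.", s, ".volume"), contra,
        "two", TRUE, age = pat$age)
  }
  # memory associations
  dom_sub <- vapply(seq_len(nrow(pat)), function(i) {
    h <- pat$language_dominant_hemisphere[i]
    if (!h %in% c("left", "right")) return(NA_real_)
    vm[pat$subject_id[i], paste0(h, ".subiculum.volume")]
  }, numeric(1))
  add(paste0("dominant.subiculum.volume"), dom_sub,
      "z_story_recall_delayed", pat$z_story_recall_delayed, "one", FALSE)
  if ("left.Gln.conc" %in% names(vm))
    add("left.Gln.conc", vm[pat$subject_id, "left.Gln.conc"],
        "z_list_learning", pat$z_list_learning, "two", FALSE)
  if (!length(rows)) return(NULL)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
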