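# Synthetic cohorts with the statistical structure the analysis assumes:
# control distributions, TBV covariance, injected patient effects, QC
# artefacts and missing hemispheres. Default magnitudes are plausible
# placeholders for a 7T hippocampal study, documented as configuration,
# not claims.

#' Specification for the synthetic cohort generator
#'
#' @param n_controls,n_patients,n_reference cohort sizes (defaults 12, 12,
#'   25, the study design's sizes).
#' @param seed integer RNG seed; the whole cohort is deterministic given it.
#' @param control_means named list/vector of control means: subfield
#'   volumes in mm^3 and metabolite concentrations in umol/g.
#' @param control_cv coefficient of variation per variable class
#'   (`volume`, `metabolite`).
#' @param tbv_mean_by_sex named (F, M) mean total brain volumes, mm^3.
#' @param tbv_sd TBV standard deviation, mm^3.
#' @param hippo_tbv_slope mm^3 hippocampus per mm^3 brain.
#' @param effects list of effect specs, each a list with `target` (e.g.
#'   `"left.CA3"` or `"right.Gln"`), `kind` (`"multiplicative"` or
#'   `"sd_shift"`), `magnitude` (factor, or shift in control-SD units) and
#'   optional `applies_to` (`"all"`, `"eeg_laterality=left"`, or a vector
#'   of subject ids).
#' @param f_csf_shape beta shape parameters of the voxel CSF fraction.
#' @param crlb_ranges named list metabolite -> c(low, high) CRLB percent;
#'   defaults put GABA and Lac above the 50% rejection bound often enough
#'   to exercise the QC path.
#' @param missing_rate probability that a hemisphere record is missing
#'   (excluded with a reason).
#' @param noise_family `"lognormal"` (default; strictly positive and
#'   right-skewed, so the Box-Cox stage is non-trivial) or `"normal"`.
#' @param age_mean,age_sd common age distribution for both groups (the
#'   design is age-matched).
#' @return List of class `hc_generator_spec`.
#' @export
generator_spec <- function(n_controls = 12L, n_patients = 12L,
                           n_reference = 25L, seed = 1L,
                           control_means = NULL,
                           control_cv = c(volume = 0.08, metabolite = 0.10),
                           tbv_mean_by_sex = c(F = 1100000, M = 1250000),
                           tbv_sd = 100000,
                           hippo_tbv_slope = 0.002,
                           effects = list(),
                           f_csf_shape = c(2, 18),
                           crlb_ranges = NULL,
                           missing_rate = 0.04,
                           noise_family = c("lognormal", "normal"),
                           age_mean = 32, age_sd = 10) {
  noise_family <- match.arg(noise_family)
  if (is.null(control_means))
    control_means <- c(CA1 = 1300, CA2 = 120, CA3 = 100, DG = 800,
                       subiculum = 450,
                       tNAA = 10.5, Glu = 8.5, Gln = 3.0, tCho = 2.0,
                       tCr = 8.0, Ins = 6.5, GABA = 1.5, Lac = 0.8)
  if (is.null(crlb_ranges)) {
    crlb_ranges <- c(lapply(hc_metabolites(), function(m) c(3, 20)),
                     list(c(40, 90), c(45, 95)))
    names(crlb_ranges) <- hc_metabolites(all = TRUE)
  }
  spec <- list(n_controls = as.integer(n_controls),
               n_patients = as.integer(n_patients),
               n_reference = as.integer(n_reference),
               seed = as.integer(seed),
               control_means = control_means, control_cv = control_cv,
               tbv_mean_by_sex = tbv_mean_by_sex, tbv_sd = tbv_sd,
               hippo_tbv_slope = hippo_tbv_slope, effects = effects,
               f_csf_shape = f_csf_shape, crlb_ranges = crlb_ranges,
               missing_rate = missing_rate, noise_family = noise_family,
               age_mean = age_mean, age_sd = age_sd)
  .validate_generator_spec(spec)
  structure(spec, class = "hc_generator_spec")
}

.validate_generator_spec <- function(spec) {
  stopifnot(spec$n_controls >= 0, spec$n_patients >= 0,
            spec$n_reference >= 0, all(spec$control_cv > 0),
            spec$missing_rate >= 0, spec$missing_rate <= 1)
  known <- c(paste0(rep(hc_hemispheres(), each = length(hc_subfields())),
                    ".", hc_subfields()),
             paste0(rep(hc_hemispheres(),
                        each = length(hc_metabolites(all = TRUE))),
                    ".", hc_metabolites(all = TRUE)))
  for (e in spec$effects) {
    if (!all(c("target", "kind", "magnitude") %in% names(e)))
      stop("each effect needs target, kind, magnitude")
    if (!e$target %in% known)
      stop("effect on unknown variable: ", e$target,
           "; accepted: hemisphere.subfield or hemisphere.metabolite")
    if (!e$kind %in% c("multiplicative", "sd_shift"))
      stop("effect kind must be multiplicative or sd_shift")
    if (e$kind == "multiplicative" && e$magnitude <= 0)
      stop("multiplicative effect magnitude must be > 0")
  }
  invisible(spec)
}

# positive noise around mean m with coefficient of variation cv
.draw_pos <- function(n, m, cv, family) {
  if (family == "normal") {
    pmax(stats::rnorm(n, m, m * cv), m * 1e-3)
  } else {
    sdlog <- sqrt(log(1 + cv^2))
    stats::rlnorm(n, log(m) - sdlog^2 / 2, sdlog)
  }
}

.gen_subjects <- function(ids, group, spec) {
  n <- length(ids)
  if (n == 0L) {
    df <- data.frame(subject_id = character(), group = character(),
                     age = numeric(), sex = character(), tbv = numeric(),
                     age_at_onset = numeric(), duration = numeric(),
                     eeg_laterality = character(),
                     language_dominant_hemisphere = character(),
                     stringsAsFactors = FALSE)
    for (t in hc_memory_tests()) df[[paste0("z_", t)]] <- numeric()
    return(df)
  }
  sex <- sample(c("F", "M"), n, replace = TRUE)
  age <- pmin(pmax(stats::rnorm(n, spec$age_mean, spec$age_sd), 18), 60)
  tbv <- stats::rnorm(n, spec$tbv_mean_by_sex[sex], spec$tbv_sd)
  df <- data.frame(subject_id = ids, group = group, age = age, sex = sex,
                   tbv = tbv, age_at_onset = NA_real_, duration = NA_real_,
                   eeg_laterality = NA_character_,
                   language_dominant_hemisphere = "unknown",
                   stringsAsFactors = FALSE)
  for (t in hc_memory_tests())
    df[[paste0("z_", t)]] <- stats::rnorm(n, -0.5, 1)
  if (group == "patient") {
    onset <- pmax(age * stats::runif(n, 0.1, 0.8), 3)
    df$age_at_onset <- onset
    df$duration <- age - onset
    df$eeg_laterality <- sample(c("left", "right"), n, replace = TRUE)
    df$language_dominant_hemisphere <- sample(c("left", "right"), n,
                                              replace = TRUE,
                                              prob = c(0.9, 0.1))
  }
  df
}

# latent total hippocampal volume tracks TBV with the configured slope;
# subfields are fixed proportions of the latent total times positive noise
.gen_volumes <- function(subjects, spec) {
  sf <- hc_subfields()
  means <- spec$control_means[sf]
  props <- means / sum(means)
  cv <- spec$control_cv[["volume"]]
  rows <- list()
  for (i in seq_len(nrow(subjects))) {
    for (h in hc_hemispheres()) {
      tbv0 <- spec$tbv_mean_by_sex[[subjects$sex[i]]]
      latent <- sum(means) + spec$hippo_tbv_slope *
        (subjects$tbv[i] - tbv0) +
        stats::rnorm(1, 0, sum(means) * cv / 2)
      latent <- max(latent, sum(means) * 0.2)
      vols <- .draw_pos(length(sf), props * latent, cv, spec$noise_family)
      names(vols) <- sf
      row <- data.frame(subject_id = subjects$subject_id[i], hemisphere = h,
                        stringsAsFactors = FALSE)
      for (s in sf) row[[s]] <- vols[[s]]
      row$total_hippocampal_volume <- sum(vols)
      row$excluded <- FALSE
      row$exclude_reason <- NA_character_
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, rows)
}

.gen_mrs <- function(subjects, spec) {
  mets <- hc_metabolites(all = TRUE)
  cv <- spec$control_cv[["metabolite"]]
  rows <- list()
  for (i in seq_len(nrow(subjects))) {
    for (h in hc_hemispheres()) {
      conc <- vapply(mets, function(m)
        .draw_pos(1, spec$control_means[[m]], cv, spec$noise_family),
        numeric(1))
      crlb <- vapply(mets, function(m)
        stats::runif(1, spec$crlb_ranges[[m]][1], spec$crlb_ranges[[m]][2]),
        numeric(1))
      f_csf <- stats::rbeta(1, spec$f_csf_shape[1], spec$f_csf_shape[2])
      f_gm <- (1 - f_csf) * stats::runif(1, 0.55, 0.75)
      row <- data.frame(subject_id = subjects$subject_id[i], hemisphere = h,
                        stringsAsFactors = FALSE)
      for (m in mets) row[[m]] <- conc[[m]]
      for (m in mets) row[[paste0("crlb_", m)]] <- crlb[[m]]
      row$f_csf <- f_csf
      row$f_gm <- f_gm
      row$f_wm <- 1 - f_csf - f_gm
      row$excluded <- FALSE
      row$exclude_reason <- NA_character_
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, rows)
}

.effect_targets <- function(e, subjects) {
  sel <- if (is.null(e$applies_to) || identical(e$applies_to, "all")) {
    subjects$group == "patient"
  } else if (length(e$applies_to) == 1 && grepl("=", e$applies_to)) {
    kv <- strsplit(e$applies_to, "=", fixed = TRUE)[[1]]
    subjects$group == "patient" & subjects[[kv[1]]] == kv[2]
  } else {
    subjects$subject_id %in% e$applies_to
  }
  subjects$subject_id[sel]
}

#' Generate a synthetic cohort with ground truth
#'
#' Draws controls and patients from the configured control law (total
#' hippocampal volume covarying with TBV at the configured slope, subfield
#' volumes as fixed proportions of the total plus noise, metabolites from
#' the configured noise family with CRLB and CSF-fraction artefacts),
#' applies the injected patient effects on top of control draws, injects
#' missing hemispheres at `missing_rate`, and records every injected
#' effect in a ground-truth ledger for recovery scoring. Deterministic
#' given `spec$seed`.
#'
#' @param spec an [generator_spec()].
#' @return List with `cohort` (an `hc_cohort`), `truth` (data.frame
#'   ledger: subject_id, target, kind, magnitude, hemisphere) and `run_id`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "hc_generator_spec"))
  .with_seed(spec$seed, {
    ctrl <- .gen_subjects(sprintf("C%02d", seq_len(spec$n_controls)),
                          "control", spec)
    pat <- .gen_subjects(sprintf("P%02d", seq_len(spec$n_patients)),
                         "patient", spec)
    subjects <- rbind(ctrl, pat)
    volumes <- .gen_volumes(subjects, spec)
    mrs <- .gen_mrs(subjects, spec)

    truth <- list()
    for (e in spec$effects) {
      parts <- strsplit(e$target, ".", fixed = TRUE)[[1]]
      h <- parts[1]; v <- parts[2]
      ids <- .effect_targets(e, subjects)
      is_vol <- v %in% hc_subfields()
      cvk <- if (is_vol) "volume" else "metabolite"
      # sd_shift is in units of the variable's control-law SD. Subfields
      # carry the configured cv plus the shared latent-total noise
      # (sd = total_mean*cv/2, apportioned by the subfield proportion),
      # i.e. marginal cv*sqrt(1 + 1/4); metabolites carry cv alone.
      sd_v <- spec$control_means[[v]] * spec$control_cv[[cvk]] *
        (if (is_vol) sqrt(1.25) else 1)
      for (id in ids) {
        df <- if (is_vol) volumes else mrs
        i <- which(df$subject_id == id & df$hemisphere == h)
        old <- df[[v]][i]
        df[[v]][i] <- if (e$kind == "multiplicative") old * e$magnitude
                      else max(old + e$magnitude * sd_v, old * 1e-3)
        if (is_vol) {
          df$total_hippocampal_volume[i] <-
            df$total_hippocampal_volume[i] - old + df[[v]][i]
          volumes <- df
        } else mrs <- df
        truth[[length(truth) + 1L]] <- data.frame(
          subject_id = id, target = e$target, kind = e$kind,
          magnitude = e$magnitude, hemisphere = h, stringsAsFactors = FALSE)
      }
    }

    # missing hemispheres (signal dropout): drop measurement rows
    for (nm in c("volumes", "mrs")) {
      df <- get(nm)
      gone <- stats::runif(nrow(df)) < spec$missing_rate
      if (any(gone)) {
        df$excluded[gone] <- TRUE
        df$exclude_reason[gone] <- "signal dropout (simulated)"
        meas_cols <- setdiff(names(df),
                             c("subject_id", "hemisphere", "excluded",
                               "exclude_reason"))
        df[gone, meas_cols] <- NA
        assign(nm, df)
      }
    }

    cohort <- hc_cohort(subjects, volumes, mrs)
    truth_df <- if (length(truth)) do.call(rbind, truth) else
      data.frame(subject_id = character(), target = character(),
                 kind = character(), magnitude = numeric(),
                 hemisphere = character(), stringsAsFactors = FALSE)
    run_id <- .spec_hash(spec)
    attr(truth_df, "run_id") <- run_id
    list(cohort = cohort, truth = truth_df, run_id = run_id)
  })
}

.spec_hash <- function(spec) {
  js <- jsonlite::toJSON(unclass(spec), auto_unbox = TRUE, digits = NA)
  tf <- tempfile(); on.exit(unlink(tf))
  writeLines(as.character(js), tf)
  unname(tools::md5sum(tf))
}

#' Generate an independent reference cohort for slope fitting
#'
#' Same generative law as the study controls, but returned as a separate
#' cohort (all `control`, ids prefixed `REF`) so slope estimation never
#' reuses study controls. Requires `n_reference >= 12` so that each
#' sex x hemisphere cell can hold >= 3 subjects.
#'
#' @param spec an [generator_spec()].
#' @return List with `subjects` and `volumes` tables.
#' @export
generate_reference_cohort <- function(spec) {
  stopifnot(inherits(spec, "hc_generator_spec"))
  if (spec$n_reference < 12)
    stop("n_reference must be >= 12 (>= 3 per sex x hemisphere cell)")
  if (spec$tbv_sd == 0)
    warning("tbv_sd = 0: reference slopes cannot be estimated (zero TBV variance)")
  .with_seed(spec$seed + 104729L, {
    subjects <- .gen_subjects(sprintf("REF%02d", seq_len(spec$n_reference)),
                              "control", spec)
    # force both sexes represented adequately
    half <- ceiling(spec$n_reference / 2)
    subjects$sex <- rep(c("F", "M"), length.out = spec$n_reference)
    subjects$tbv <- stats::rnorm(spec$n_reference,
                                 spec$tbv_mean_by_sex[subjects$sex],
                                 spec$tbv_sd)
    volumes <- .gen_volumes(subjects, spec)
    list(subjects = subjects, volumes = volumes)
  })
}

#' Score recovery of injected effects
#'
#' Compares the battery's findings with the generator's ground-truth
#' ledger. Sensitivity: fraction of injected (subject, variable) effects
#' detected at the uncorrected level with the right direction. Specificity:
#' 1 minus the false-positive rate over untouched testable variables.
#' Laterality accuracy: among patients with effects confined to one
#' hemisphere, the fraction whose significant findings lateralize to the
#' injected side.
#'
#' @param results an `hc_case_results` covering all patients of the run.
#' @param truth the ground-truth ledger from [generate_cohort()].
#' @param alpha uncorrected level (default 0.05).
#' @param run_id optional run identifier to check against the ledger's.
#' @return List with `sensitivity` (overall + per variable), `specificity`,
#'   `laterality_accuracy`, and the counts behind them.
#' @export
score_recovery <- function(results, truth, alpha = 0.05, run_id = NULL) {
  if (!is.null(run_id) && !is.null(attr(truth, "run_id")) &&
      !identical(run_id, attr(truth, "run_id")))
    stop("run_id mismatch between results and ground-truth ledger")
  res <- results[results$testable, , drop = FALSE]
  # injected target "left.CA3" maps onto battery variable "left.CA3.volume"
  tgt_var <- function(target) {
    parts <- strsplit(target, ".", fixed = TRUE)[[1]]
    suffix <- if (parts[2] %in% hc_subfields()) ".volume" else ".conc"
    paste0(target, suffix)
  }
  truth$variable <- vapply(truth$target, tgt_var, character(1))
  key_truth <- paste(truth$subject_id, truth$variable)
  key_res <- paste(res$subject_id, res$variable)

  hit <- logical(nrow(truth))
  for (i in seq_len(nrow(truth))) {
    j <- match(key_truth[i], key_res)
    if (is.na(j)) next
    want_dir <- if (truth$kind[i] == "multiplicative") {
      if (truth$magnitude[i] < 1) "decreased" else "increased"
    } else if (truth$magnitude[i] < 0) "decreased" else "increased"
    hit[i] <- res$p_uncorrected[j] <= alpha && res$direction[j] == want_dir
  }
  sens <- if (nrow(truth)) mean(hit) else NA_real_
  sens_by_var <- if (nrow(truth))
    tapply(hit, truth$variable, mean) else NULL

  untouched <- !(key_res %in% key_truth) &
    !grepl("\\.asymmetry$", res$variable)
  spec_val <- if (any(untouched))
    1 - mean(res$p_uncorrected[untouched] <= alpha, na.rm = TRUE)
  else NA_real_

  lat_acc <- NA_real_
  pat_side <- tapply(truth$hemisphere, truth$subject_id,
                     function(h) if (length(unique(h)) == 1) unique(h)
                                 else NA_character_)
  pat_side <- pat_side[!is.na(pat_side)]
  if (length(pat_side)) {
    # lateralize by where significant findings predominate (majority rule;
    # no findings or a tie counts as incorrect)
    correct <- vapply(names(pat_side), function(id) {
      r <- res[res$subject_id == id &
                 !grepl("\\.asymmetry$", res$variable), , drop = FALSE]
      sig <- r[r$p_uncorrected <= alpha, , drop = FALSE]
      if (!nrow(sig)) return(FALSE)
      hems <- sub("\\..*$", "", sig$variable)
      n_inj <- sum(hems == pat_side[id])
      n_other <- sum(hems != pat_side[id])
      n_inj > n_other
    }, logical(1))
    lat_acc <- mean(correct)
  }
  list(sensitivity = sens, sensitivity_by_variable = sens_by_var,
       specificity = spec_val, laterality_accuracy = lat_acc,
       n_injected = nrow(truth), n_untouched = sum(untouched))
}
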