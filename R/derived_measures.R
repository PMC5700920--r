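# Deterministic per-subject corrections and indices.

#' Fit sex- and hemisphere-specific hippocampus-TBV reference slopes
#'
#' Ordinary least-squares regression of total hippocampal volume on total
#' brain volume (TBV), fitted separately in each (sex, hemisphere) cell of
#' an independent reference cohort of healthy volunteers. The fitted slope
#' and the cell's mean TBV drive the head-size covariance correction of
#' [adjust_total_volume()].
#'
#' @param reference_volumes volumes table of the reference cohort (same
#'   schema as an `hc_cohort` volumes element).
#' @param reference_subjects subjects table of the reference cohort; must
#'   carry `tbv`.
#' @return An object of class `hc_reference_slopes`: data.frame with one row
#'   per (sex, hemisphere) cell and columns `sex`, `hemisphere`, `slope`,
#'   `tbv_mean`, `n_reference`.
#' @export
fit_reference_slopes <- function(reference_volumes, reference_subjects) {
  vols <- reference_volumes[!reference_volumes$excluded, ]
  df <- merge(vols[, c("subject_id", "hemisphere",
                       "total_hippocampal_volume")],
              reference_subjects[, c("subject_id", "sex", "tbv")],
              by = "subject_id")
  df <- df[stats::complete.cases(df), ]
  cells <- expand.grid(sex = c("F", "M"), hemisphere = hc_hemispheres(),
                       stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sel <- df$sex == cells$sex[i] & df$hemisphere == cells$hemisphere[i]
    d <- df[sel, ]
    if (nrow(d) < 3)
      stop(sprintf("reference cell (%s, %s) has %d subjects; need >= 3",
                   cells$sex[i], cells$hemisphere[i], nrow(d)))
    if (stats::var(d$tbv) == 0)
      stop(sprintf("reference cell (%s, %s) has zero TBV variance",
                   cells$sex[i], cells$hemisphere[i]))
    fit <- stats::lm(total_hippocampal_volume ~ tbv, data = d)
    data.frame(sex = cells$sex[i], hemisphere = cells$hemisphere[i],
               slope = unname(stats::coef(fit)[2]),
               tbv_mean = mean(d$tbv), n_reference = nrow(d),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  structure(out, class = c("hc_reference_slopes", "data.frame"))
}

.slope_cell <- function(slopes, sex, hemisphere) {
  i <- which(slopes$sex == sex & slopes$hemisphere == hemisphere)
  if (length(i) != 1L)
    stop(sprintf("no reference slope for cell (%s, %s)", sex, hemisphere))
  slopes[i, ]
}

#' Head-size covariance correction of a total hippocampal volume
#'
#' Adjusted = Observed - slope * (TBV_subject - TBV_mean), with the slope
#' and reference mean TBV taken from the subject's (sex, hemisphere) cell.
#' The adjustment is the identity when the subject's TBV equals the
#' reference mean, and for a zero slope.
#'
#' @param observed observed total hippocampal volume (mm^3, > 0).
#' @param tbv_subject the subject's total brain volume (mm^3).
#' @param slopes an `hc_reference_slopes`.
#' @param sex,hemisphere cell selectors.
#' @return Adjusted total volume (mm^3).
#' @export
adjust_total_volume <- function(observed, tbv_subject, slopes, sex,
                                hemisphere) {
  if (!is.finite(observed) || observed <= 0)
    stop("observed volume must be a positive number")
  cell <- .slope_cell(slopes, sex, hemisphere)
  adjusted <- observed - cell$slope * (tbv_subject - cell$tbv_mean)
  if (!is.finite(adjusted) || adjusted <= 0)
    stop(sprintf(
      "adjusted volume %.1f <= 0 (observed %.1f, slope %.4g, TBV delta %.1f): implausible slope/TBV combination",
      adjusted, observed, cell$slope, tbv_subject - cell$tbv_mean))
  adjusted
}

#' Scale subfield volumes by the head-size correction factor
#'
#' All subfields of a hemisphere are multiplied by one scaling factor so
#' that subfield ratios are preserved exactly. In the default mode
#' (`adjusted_over_observed`) the factor is adjusted/observed total, so the
#' scaled volumes sum to the head-size-adjusted total. The inverse ratio
#' (`observed_over_adjusted`) is retained behind the config flag.
#'
#' @param volumes_row one row of a volumes table (named list/data.frame row
#'   with the subfield columns and `total_hippocampal_volume`).
#' @param adjusted_total output of [adjust_total_volume()].
#' @param mode `"adjusted_over_observed"` or `"observed_over_adjusted"`.
#' @return List with `scaling_factor`, `adjusted_total` and
#'   `scaled_subfields` (named numeric, NA where the raw value is missing).
#' @export
scale_subfields <- function(volumes_row, adjusted_total,
                            mode = c("adjusted_over_observed",
                                     "observed_over_adjusted")) {
  mode <- match.arg(mode)
  observed_total <- volumes_row[["total_hippocampal_volume"]]
  raw <- vapply(hc_subfields(), function(s) as.numeric(volumes_row[[s]]),
                numeric(1))
  if (is.na(observed_total)) {
    if (any(!is.na(raw)))
      stop("observed total volume missing but subfield volumes present; totals are required for scaling")
    stop("observed total volume missing")
  }
  if (!is.finite(adjusted_total) || adjusted_total <= 0)
    stop("adjusted_total must be > 0")
  factor <- if (mode == "adjusted_over_observed")
    adjusted_total / observed_total else observed_total / adjusted_total
  list(scaling_factor = factor,
       adjusted_total = adjusted_total,
       scaled_subfields = raw * factor)
}

#' CSF partial-volume correction of a metabolite concentration
#'
#' Metabolite concentrations are estimated over the whole VOI but CSF
#' contributes no metabolite signal; the measured value is rescaled to the
#' tissue fraction by multiplying by 1/(1 - FCSF).
#'
#' @param concentration measured concentration (umol/g).
#' @param f_csf CSF fraction of the VOI, in `[0, 1)`.
#' @return Corrected concentration (umol/g).
#' @export
csf_correct <- function(concentration, f_csf) {
  if (any(!is.finite(f_csf) | f_csf < 0 | f_csf >= 1))
    stop("f_csf must lie in [0, 1); a voxel that is all CSF has no tissue signal to correct")
  concentration / (1 - f_csf)
}

#' CRLB quality filter for a metabolite panel
#'
#' Marks each metabolite's estimate as reliable iff its Cramer-Rao lower
#' bound does not exceed `threshold` percent (strictly-greater rejection,
#' so a CRLB of exactly 50 passes at the default threshold). Reportability
#' is cohort-wide: a metabolite enters group or single-case statistics only
#' if it passes in both hemispheres of every non-excluded participant.
#'
#' @param mrs an mrs table (element of an `hc_cohort`).
#' @param threshold rejection threshold in percent (default 50).
#' @param report_threshold bound above which a kept metabolite draws a
#'   warning-level message (default 25); not a rejection.
#' @return The mrs table with logical `qc_pass_<metabolite>` columns added,
#'   plus an attribute `reportable`: named logical over all metabolites.
#' @export
crlb_filter <- function(mrs, threshold = 50, report_threshold = 25) {
  mets <- hc_metabolites(all = TRUE)
  reportable <- stats::setNames(logical(length(mets)), mets)
  active <- !mrs$excluded
  for (m in mets) {
    crlb <- mrs[[paste0("crlb_", m)]]
    if (any(!is.na(crlb) & crlb < 0)) stop("negative CRLB for ", m)
    pass <- !is.na(crlb) & crlb <= threshold
    mrs[[paste0("qc_pass_", m)]] <- pass
    reportable[m] <- nrow(mrs) > 0 && all(pass[active])
    n_warn <- sum(!is.na(crlb[active]) & crlb[active] > report_threshold &
                    pass[active])
    if (n_warn > 0)
      message(sprintf("WARN crlb_filter: %s kept but CRLB > %g%% in %d record(s)",
                      m, report_threshold, n_warn))
  }
  attr(mrs, "reportable") <- reportable
  mrs
}

#' Left-right asymmetry index
#'
#' `(L - R) / ((L + R) / 2)`: the normalized left-right difference, 0 for
#' symmetric measures, +2/-2 in the limit of a fully lateralized measure,
#' antisymmetric under hemisphere swap.
#'
#' @param left_value,right_value nonnegative measurements.
#' @return Dimensionless index in `[-2, 2]`.
#' @export
asymmetry_index <- function(left_value, right_value) {
  if (any(left_value + right_value <= 0, na.rm = TRUE))
    stop("asymmetry index undefined: L + R must be > 0")
  (left_value - right_value) / ((left_value + right_value) / 2)
}

#' Map left/right values to ipsilateral/contralateral
#'
#' @param left_value,right_value per-hemisphere values.
#' @param eeg_laterality `"left"` or `"right"` seizure-onset side;
#'   `"bilateral"` or `"unknown"` subjects cannot be pooled this way.
#' @return List with `ipsilateral` and `contralateral`; for
#'   bilateral/unknown laterality both elements are `NULL` and the
#'   exclusion is logged in attribute `reason`.
#' @export
map_ipsi_contra <- function(left_value, right_value, eeg_laterality) {
  if (is.na(eeg_laterality) ||
      !eeg_laterality %in% c("left", "right")) {
    return(structure(list(ipsilateral = NULL, contralateral = NULL),
                     reason = sprintf(
                       "excluded from ipsi/contra pooling: laterality '%s'",
                       as.character(eeg_laterality))))
  }
  if (eeg_laterality == "left")
    list(ipsilateral = left_value, contralateral = right_value)
  else
    list(ipsilateral = right_value, contralateral = left_value)
}

#' Memory-impairment flag
#'
#' Significant impairment on a neuropsychological test is defined as a
#' z-score of -1.34 or lower (inclusive).
#'
#' @param z test z-score(s).
#' @return Logical.
#' @export
memory_impairment_flag <- function(z) {
  if (any(!is.finite(z))) stop("z must be finite")
  z <= -1.34
}

#' VOI volume in millilitres
#'
#' @param dims cuboid voxel-of-interest dimensions in mm (length 3).
#' @return Volume in mL.
#' @export
voi_volume <- function(dims) {
  if (length(dims) != 3L || any(!is.finite(dims) | dims <= 0))
    stop("dims must be three positive lengths in mm")
  prod(dims) / 1000
}

# Cohort-level derivation -----------------------------------------------------

#' Compute derived measures for a whole cohort
#'
#' Applies the full deterministic stage to every usable hemisphere record:
#' head-size adjustment and subfield scaling of the volumes, CSF correction
#' and CRLB QC of the metabolites, and per-subject asymmetry indices of the
#' scaled/corrected values.
#'
#' @param cohort an `hc_cohort`.
#' @param slopes an `hc_reference_slopes` from an independent reference
#'   cohort.
#' @param config an [analysis_config()].
#' @return List of class `hc_derived` with data.frames `volumes` (per
#'   subject x hemisphere: scaling factor, adjusted total, scaled
#'   subfields), `mrs` (CSF-corrected concentrations and QC flags, plus a
#'   `reportable` attribute) and `asymmetry` (per subject x variable).
#' @export
derive_measures <- function(cohort, slopes, config = analysis_config()) {
  stopifnot(inherits(cohort, "hc_cohort"))
  subj <- cohort$subjects

  vol <- cohort$volumes
  vol$scaling_factor <- NA_real_
  vol$adjusted_total <- NA_real_
  for (s in hc_subfields()) vol[[paste0("scaled_", s)]] <- NA_real_
  for (i in seq_len(nrow(vol))) {
    if (vol$excluded[i]) next
    si <- match(vol$subject_id[i], subj$subject_id)
    if (is.na(subj$tbv[si]) || is.na(vol$total_hippocampal_volume[i])) next
    adj <- adjust_total_volume(vol$total_hippocampal_volume[i],
                               subj$tbv[si], slopes,
                               subj$sex[si], vol$hemisphere[i])
    sc <- scale_subfields(vol[i, ], adj, mode = config$scaling_mode)
    vol$scaling_factor[i] <- sc$scaling_factor
    vol$adjusted_total[i] <- sc$adjusted_total
    for (s in hc_subfields())
      vol[[paste0("scaled_", s)]][i] <- sc$scaled_subfields[[s]]
  }

  mrs <- crlb_filter(cohort$mrs, threshold = config$crlb_reject_threshold,
                     report_threshold = config$crlb_report_threshold)
  reportable <- attr(mrs, "reportable")
  for (m in hc_metabolites(all = TRUE)) {
    corr <- rep(NA_real_, nrow(mrs))
    ok <- !mrs$excluded & !is.na(mrs[[m]]) & !is.na(mrs$f_csf)
    corr[ok] <- csf_correct(mrs[[m]][ok], mrs$f_csf[ok])
    mrs[[paste0("corrected_", m)]] <- corr
  }

  asym <- .asymmetry_table(subj, vol, mrs, reportable)
  structure(list(volumes = vol, mrs = mrs, asymmetry = asym,
                 reportable = reportable, scaling_mode = config$scaling_mode),
            class = "hc_derived")
}

.asymmetry_table <- function(subj, vol, mrs, reportable) {
  rows <- list()
  for (id in subj$subject_id) {
    vl <- vol[vol$subject_id == id & vol$hemisphere == "left", ]
    vr <- vol[vol$subject_id == id & vol$hemisphere == "right", ]
    if (nrow(vl) == 1 && nrow(vr) == 1 && !vl$excluded && !vr$excluded) {
      for (s in hc_subfields()) {
        L <- vl[[paste0("scaled_", s)]]; R <- vr[[paste0("scaled_", s)]]
        if (!is.na(L) && !is.na(R) && L + R > 0)
          rows[[length(rows) + 1L]] <- data.frame(
            subject_id = id, variable = paste0(s, ".asymmetry"),
            index = asymmetry_index(L, R), stringsAsFactors = FALSE)
      }
    }
    ml <- mrs[mrs$subject_id == id & mrs$hemisphere == "left", ]
    mr <- mrs[mrs$subject_id == id & mrs$hemisphere == "right", ]
    if (nrow(ml) == 1 && nrow(mr) == 1 && !ml$excluded && !mr$excluded) {
      for (m in hc_metabolites()) {
        if (!isTRUE(reportable[m])) next
        L <- ml[[paste0("corrected_", m)]]; R <- mr[[paste0("corrected_", m)]]
        if (!is.na(L) && !is.na(R) && L + R > 0)
          rows[[length(rows) + 1L]] <- data.frame(
            subject_id = id, variable = paste0(m, ".asymmetry"),
            index = asymmetry_index(L, R), stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(data.frame(subject_id = character(), variable = character(),
                      index = numeric(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
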