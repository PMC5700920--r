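#' Analysis configuration
#'
#' Central container for the tunable parameters of the pipeline: the
#' significance level, tail convention and permutation budget of the
#' single-case tests, the subfield scaling-mode, and the CRLB quality
#' thresholds for metabolite reporting.
#'
#' @param alpha significance level for all tests (default 0.05).
#' @param tails `"two"` (default) or `"one"`; single-case tests report a
#'   direction either way.
#' @param n_max_exhaustive enumerate all `2^(n+1)` sign-flip patterns when
#'   that count does not exceed this bound; otherwise sample `n_mc`
#'   patterns (default `32768`, i.e. exhaustive up to 14 controls).
#' @param n_mc number of Monte-Carlo sign-flip draws (must be >= 100).
#' @param rng_seed integer master seed; per-test seeds are derived from it.
#' @param scaling_mode `"adjusted_over_observed"` (default; scales subfields
#'   by adjusted/observed total so the scaled total equals the head-size
#'   adjusted total) or `"observed_over_adjusted"` (the inverse ratio,
#'   retained for comparability with the as-printed description).
#' @param crlb_reject_threshold CRLB percentage above which a metabolite is
#'   not reliably detected (default 50; strictly-greater rejection).
#' @param crlb_report_threshold CRLB percentage above which a warning is
#'   logged even though the metabolite is kept (default 25).
#' @param boxcox_apply_to_asymmetry apply the Box-Cox step to asymmetry
#'   indices as well (default `FALSE`; asymmetry indices can be <= 0, in
#'   which case the transform errors).
#' @param fwe_method `"bonferroni"` (default) or `"maxstat"`.
#' @param age_residualize residualize measurements on age before the
#'   single-case tests (default `FALSE`; the study design age-matches
#'   groups instead).
#' @return An object of class `hc_config` (a validated list).
#' @export
analysis_config <- function(alpha = 0.05,
                            tails = c("two", "one"),
                            n_max_exhaustive = 32768L,
                            n_mc = 10000L,
                            rng_seed = 1L,
                            scaling_mode = c("adjusted_over_observed",
                                             "observed_over_adjusted"),
                            crlb_reject_threshold = 50,
                            crlb_report_threshold = 25,
                            boxcox_apply_to_asymmetry = FALSE,
                            fwe_method = c("bonferroni", "maxstat"),
                            age_residualize = FALSE) {
  tails <- match.arg(tails)
  scaling_mode <- match.arg(scaling_mode)
  fwe_method <- match.arg(fwe_method)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("alpha must be a single probability in (0, 1)")
  if (n_mc < 100)
    stop("n_mc must be >= 100")
  if (n_max_exhaustive < 2)
    stop("n_max_exhaustive must be >= 2")
  cfg <- list(
    alpha = alpha,
    tails = tails,
    n_max_exhaustive = as.integer(n_max_exhaustive),
    n_mc = as.integer(n_mc),
    rng_seed = as.integer(rng_seed),
    scaling_mode = scaling_mode,
    crlb_reject_threshold = crlb_reject_threshold,
    crlb_report_threshold = crlb_report_threshold,
    boxcox_apply_to_asymmetry = isTRUE(boxcox_apply_to_asymmetry),
    fwe_method = fwe_method,
    age_residualize = isTRUE(age_residualize)
  )
  structure(cfg, class = "hc_config")
}

#' Read an analysis configuration from a JSON file
#'
#' The file holds a flat JSON object whose keys are the arguments of
#' [analysis_config()]; absent keys take their defaults.
#'
#' @param path path to a JSON configuration file.
#' @return An `hc_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(analysis_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         "; accepted: ", paste(known, collapse = ", "))
  do.call(analysis_config, raw)
}

#' Write an analysis configuration to JSON
#' @param config an `hc_config`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "hc_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @export
print.hc_config <- function(x, ...) {
  cat("<hc_config>\n")
  for (k in names(x)) cat(sprintf("  %-26s %s\n", k, format(x[[k]])))
  invisible(x)
}

# Shared controlled vocabulary ------------------------------------------------

hc_subfields <- function() c("CA1", "CA2", "CA3", "DG", "subiculum")

# reported metabolites first, pre-QC-only ones last
hc_metabolites <- function(all = FALSE) {
  rep6 <- c("tNAA", "Glu", "Gln", "tCho", "tCr", "Ins")
  if (all) c(rep6, "GABA", "Lac") else rep6
}

hc_hemispheres <- function() c("left", "right")

# accepted aliases, normalized on ingest
hc_hemi_aliases <- function() {
  c(left = "left", right = "right",
    L = "left", R = "right", lh = "left", rh = "right",
    Left = "left", Right = "right", l = "left", r = "right")
}

normalize_hemisphere <- function(x) {
  al <- hc_hemi_aliases()
  out <- unname(al[match(as.character(x), names(al))])
  bad <- is.na(out) & !is.na(x)
  if (any(bad))
    stop("unknown hemisphere value(s): ",
         paste(unique(x[bad]), collapse = ", "),
         "; accepted: ", paste(names(al), collapse = ", "))
  out
}

hc_memory_tests <- function() {
  c("list_learning", "story_recall_delayed", "design_learning",
    "figure_recall")
}
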