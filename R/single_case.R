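# Single-case inference: Box-Cox preconditioning, sign-flipping permutation
# tests of one patient against a small control group, family-wise error
# correction, and laterality-concordance labelling.

#' Box-Cox power transformation
#'
#' `(x^lambda - 1)/lambda` for `lambda != 0`, `log(x)` for `lambda == 0`.
#' With `lambda = "mle"` the exponent is fitted by profile maximum
#' likelihood (continuous optimization of the normal-theory profile
#' log-likelihood over `[-5, 5]`) on the supplied sample; in the
#' single-case battery that sample is the pooled case + controls for one
#' variable. The transform is strictly increasing for any lambda, so ranks
#' are preserved.
#'
#' @param values positive reals.
#' @param lambda numeric exponent, or `"mle"` (default) to fit it.
#' @return List with `values` (transformed) and `lambda`.
#' @export
boxcox_transform <- function(values, lambda = "mle") {
  if (any(!is.finite(values) | values <= 0))
    stop("Box-Cox requires strictly positive values; exclude this variable from transformation (asymmetry indices are not transformed by default)")
  if (identical(lambda, "mle")) {
    lambda <- stats::optimize(.boxcox_loglik, c(-5, 5), x = values,
                              maximum = TRUE, tol = 1e-6)$maximum
  }
  if (!is.numeric(lambda) || length(lambda) != 1L)
    stop("lambda must be a single number or \"mle\"")
  tx <- if (abs(lambda) < 1e-12) log(values)
        else (values^lambda - 1) / lambda
  list(values = tx, lambda = lambda)
}

# profile log-likelihood of the Box-Cox model (normal errors, MLE variance)
.boxcox_loglik <- function(lambda, x) {
  n <- length(x)
  y <- if (abs(lambda) < 1e-12) log(x) else (x^lambda - 1) / lambda
  s2 <- stats::var(y) * (n - 1) / n
  if (s2 <= 0) return(-Inf)
  -n / 2 * log(s2) + (lambda - 1) * sum(log(x))
}

# Sign-flip engine ------------------------------------------------------------

# +/-1 pattern matrix: all 2^m rows (exhaustive) or n_mc random rows
.flip_patterns <- function(m, n_mc = NULL) {
  if (is.null(n_mc)) {
    B <- 2^m
    S <- matrix(1, B, m)
    for (j in seq_len(m))
      S[, j] <- rep(c(1, -1), each = 2^(j - 1), length.out = B)
    S
  } else {
    matrix(sample(c(1, -1), n_mc * m, replace = TRUE), n_mc, m)
  }
}

# vectorized case statistic over flip patterns. Residuals r are the pooled
# (case + controls) values minus their pooled mean mu; the case occupies
# index 1. For each pattern the pseudo-data is mu + s*r and the statistic
# is recomputed; squares of the flipped controls reduce to closed form
# because s^2 = 1.
.flip_stats <- function(mu, r, S) {
  m <- ncol(S)
  n <- m - 1L
  r_c <- r[-1]
  y1 <- mu + S[, 1] * r[1]
  Sr <- as.vector(S[, -1, drop = FALSE] %*% r_c)
  mean_c <- mu + Sr / n
  sumsq_c <- n * mu^2 + 2 * mu * Sr + sum(r_c^2)
  var_c <- (sumsq_c - n * mean_c^2) / (n - 1)
  var_c[var_c < 0] <- 0   # guard tiny negative round-off
  num <- y1 - mean_c
  denom <- sqrt(var_c) * sqrt(1 + 1 / n)
  t <- num / denom
  t[denom == 0 & num == 0] <- 0
  t[denom == 0 & num > 0] <- Inf
  t[denom == 0 & num < 0] <- -Inf
  t
}

# run body with a private, restorable RNG state
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(expr)
}

#' Sign-flipping permutation test of one case against a control group
#'
#' Tests whether a single patient's measurement deviates from the
#' distribution of a (small) control group. The observed statistic is the
#' standardized case deviation
#' `T = (x_case - mean(controls)) / (sd(controls) * sqrt(1 + 1/n))`
#' (the Crawford-Howell case-indicator contrast). The null is built by
#' reconstruction from residuals (Freedman-Lane): case and controls are
#' pooled, the pooled mean is subtracted, and the n+1 residuals — assumed
#' symmetric about zero, which the Box-Cox step is there to make plausible
#' — are shuffled; `T` is recomputed on each reconstructed pseudo-sample.
#'
#' Two shuffling schemes are provided:
#' \describe{
#'   \item{`perm_flip` (default)}{label permutations combined with sign
#'   flips, the scheme that permutation GLM software applies when both
#'   exchangeable errors and independent symmetric errors are assumed.
#'   Because `T` is invariant under rearrangements among the control
#'   slots, the distinct shufflings reduce to (which residual lands on the
#'   case slot) x (sign pattern): `(n+1) * 2^(n+1)` of them when
#'   exhaustive. Label exchange is what gives the test its power; see the
#'   package vignette.}
#'   \item{`flip_only`}{pure sign flipping of the n+1 residuals with the
#'   case label fixed: `2^(n+1)` patterns. Retained for reference and
#'   oracle testing; with a small control group its null inherits the
#'   case's own residual, making it so conservative that it cannot reject
#'   at conventional levels (see vignette).}
#' }
#'
#' Enumeration is exhaustive when `2^(n+1) <= n_max_exhaustive`, otherwise
#' `n_mc` shufflings are drawn uniformly. p-value conventions: exhaustive
#' enumeration includes the identity shuffling in numerator and
#' denominator (so p is never 0; the two-tailed floor is `2/null_size`);
#' Monte-Carlo uses `(b + 1)/(n_mc + 1)`. Ties count toward the numerator.
#'
#' @param case_value the patient's (already transformed, where applicable)
#'   value.
#' @param control_values numeric vector of >= 5 control values on the same
#'   scale.
#' @param tails `"two"` (default) or `"one"` (tail picked by the observed
#'   direction).
#' @param n_max_exhaustive enumerate all sign patterns while `2^(n+1)` does
#'   not exceed this.
#' @param n_mc Monte-Carlo shuffling count (>= 100) when not exhaustive.
#' @param seed RNG seed for Monte-Carlo draws.
#' @param shuffle `"perm_flip"` (default) or `"flip_only"`.
#' @return List with `statistic`, `direction` (`"decreased"`/`"increased"`),
#'   `p_uncorrected`, `null_size`, `null_mode`, `seed`, `n_controls`,
#'   `shuffle`.
#' @export
sign_flip_test <- function(case_value, control_values,
                           tails = c("two", "one"),
                           n_max_exhaustive = 32768L, n_mc = 10000L,
                           seed = 1L,
                           shuffle = c("perm_flip", "flip_only")) {
  tails <- match.arg(tails)
  shuffle <- match.arg(shuffle)
  n <- length(control_values)
  if (n < 5) stop("need >= 5 controls")
  if (any(!is.finite(c(case_value, control_values))))
    stop("non-finite input values")
  sd_c <- stats::sd(control_values)
  if (sd_c == 0) stop("zero control variance")
  if (n_mc < 100) stop("n_mc must be >= 100")

  t_obs <- (case_value - mean(control_values)) / (sd_c * sqrt(1 + 1 / n))
  direction <- if (t_obs < 0) "decreased" else "increased"

  pooled <- c(case_value, control_values)
  mu <- mean(pooled)
  r <- pooled - mu
  m <- n + 1L

  exhaustive <- (2^m) <= n_max_exhaustive
  if (exhaustive) {
    S <- .flip_patterns(m)
    t_flip <- if (shuffle == "flip_only") .flip_stats(mu, r, S)
      else unlist(lapply(seq_len(m), function(k)
        .flip_stats(mu, r[c(k, seq_len(m)[-k])], S)))
    p <- .flip_p(t_flip, t_obs, tails) / length(t_flip)
    list(statistic = t_obs, direction = direction, p_uncorrected = p,
         null_size = length(t_flip), null_mode = "exhaustive",
         seed = NA_integer_, n_controls = n, shuffle = shuffle)
  } else {
    t_flip <- .with_seed(seed, {
      S <- .flip_patterns(m, n_mc = n_mc)
      if (shuffle == "flip_only") .flip_stats(mu, r, S)
      else {
        k <- sample.int(m, n_mc, replace = TRUE)
        out <- numeric(n_mc)
        for (kk in unique(k)) {
          sel <- k == kk
          out[sel] <- .flip_stats(mu, r[c(kk, seq_len(m)[-kk])],
                                  S[sel, , drop = FALSE])
        }
        out
      }
    })
    b <- .flip_p(t_flip, t_obs, tails)
    p <- (b + 1) / (n_mc + 1)
    list(statistic = t_obs, direction = direction, p_uncorrected = p,
         null_size = as.integer(n_mc), null_mode = "monte_carlo",
         seed = as.integer(seed), n_controls = n, shuffle = shuffle)
  }
}

# exceedance count with a relative tie tolerance (ties count)
.flip_p <- function(t_flip, t_obs, tails) {
  tol <- 1e-8 * max(1, abs(t_obs))
  if (tails == "two") {
    sum(abs(t_flip) >= abs(t_obs) - tol)
  } else {
    sgn <- if (t_obs < 0) -1 else 1
    sum(sgn * t_flip >= sgn * t_obs - tol)
  }
}

# Battery ---------------------------------------------------------------------

# per-subject variable matrix from the derived measures; one column per
# battery variable, NA where a value is unusable
variable_matrix <- function(cohort, derived) {
  subj <- cohort$subjects
  ids <- subj$subject_id
  vars <- list()
  vol <- derived$volumes
  for (h in hc_hemispheres()) {
    for (s in hc_subfields()) {
      v <- rep(NA_real_, length(ids))
      rows <- vol[vol$hemisphere == h & !vol$excluded, ]
      v[match(rows$subject_id, ids)] <- rows[[paste0("scaled_", s)]]
      vars[[paste0(h, ".", s, ".volume")]] <- v
    }
  }
  mrs <- derived$mrs
  reportable <- derived$reportable
  for (h in hc_hemispheres()) {
    for (m in hc_metabolites()) {
      if (!isTRUE(reportable[m])) next
      v <- rep(NA_real_, length(ids))
      rows <- mrs[mrs$hemisphere == h & !mrs$excluded, ]
      keep <- rows[[paste0("qc_pass_", m)]]
      v[match(rows$subject_id[keep], ids)] <-
        rows[[paste0("corrected_", m)]][keep]
      vars[[paste0(h, ".", m, ".conc")]] <- v
    }
  }
  asym <- derived$asymmetry
  for (s in hc_subfields()) {
    v <- rep(NA_real_, length(ids))
    rows <- asym[asym$variable == paste0(s, ".asymmetry"), ]
    v[match(rows$subject_id, ids)] <- rows$index
    vars[[paste0(s, ".asymmetry")]] <- v
  }
  for (m in hc_metabolites()) {
    if (!isTRUE(reportable[m])) next
    v <- rep(NA_real_, length(ids))
    rows <- asym[asym$variable == paste0(m, ".asymmetry"), ]
    v[match(rows$subject_id, ids)] <- rows$index
    vars[[paste0(m, ".asymmetry")]] <- v
  }
  out <- as.data.frame(vars, check.names = FALSE)
  rownames(out) <- ids
  out
}

.variable_family <- function(variable) {
  if (grepl("\\.volume$", variable)) "subfield_volumes"
  else if (grepl("\\.conc$", variable)) "metabolites"
  else if (variable %in% paste0(hc_subfields(), ".asymmetry"))
    "subfield_asymmetry"
  else "metabolite_asymmetry"
}

#' Run the single-case battery for one patient
#'
#' Tests every battery variable (scaled subfield volumes per hemisphere,
#' CSF-corrected reportable metabolite concentrations per hemisphere, and
#' their asymmetry indices) of one patient against the control group with
#' [sign_flip_test()]. Volume and concentration variables are Box-Cox
#' transformed (exponent fitted on the pooled case + controls sample for
#' each variable); asymmetry indices are tested untransformed unless
#' `config$boxcox_apply_to_asymmetry` is set. Controls with excluded
#' hemispheres are dropped per variable (available-case analysis); a
#' variable with fewer than 5 usable controls is returned flagged
#' untestable rather than silently omitted.
#'
#' Family-wise error families follow the battery structure: all subfield
#' volumes (up to 10), all metabolite concentrations (up to 12), subfield
#' asymmetries (up to 5), metabolite asymmetries (up to 6).
#'
#' @param patient_id subject_id of a patient in the cohort.
#' @param cohort an `hc_cohort`.
#' @param derived the matching [derive_measures()] output.
#' @param config an [analysis_config()].
#' @param variables optional character vector restricting the battery.
#' @return data.frame of class `hc_case_results`, one row per variable:
#'   `subject_id`, `variable`, `family`, `family_size`, `observed`,
#'   `transformed`, `lambda`, `statistic`, `direction`, `p_uncorrected`,
#'   `fwe_significant`, `null_size`, `null_mode`, `seed`, `testable`,
#'   `note`.
#' @export
run_case_battery <- function(patient_id, cohort, derived,
                             config = analysis_config(),
                             variables = NULL) {
  vm <- variable_matrix(cohort, derived)
  if (!is.null(variables)) {
    unknown <- setdiff(variables, names(vm))
    if (length(unknown))
      stop("unknown battery variable(s): ", paste(unknown, collapse = ", "))
    vm <- vm[, variables, drop = FALSE]
  }
  subj <- cohort$subjects
  if (!patient_id %in% subj$subject_id[subj$group == "patient"])
    stop("patient_id not a patient in the cohort: ", patient_id)
  ctrl_ids <- subj$subject_id[subj$group == "control"]
  age <- stats::setNames(subj$age, subj$subject_id)

  rows <- vector("list", ncol(vm))
  for (k in seq_along(vm)) {
    vname <- names(vm)[k]
    fam <- .variable_family(vname)
    x_case <- vm[patient_id, vname]
    x_ctrl <- vm[ctrl_ids, vname]
    use <- !is.na(x_ctrl)
    res <- list(subject_id = patient_id, variable = vname, family = fam,
                family_size = NA_integer_, observed = x_case,
                transformed = NA_real_, lambda = NA_real_,
                statistic = NA_real_, direction = NA_character_,
                p_uncorrected = NA_real_, fwe_significant = NA,
                null_size = NA_integer_, null_mode = NA_character_,
                seed = NA_integer_, testable = FALSE, note = NA_character_)
    if (is.na(x_case)) {
      res$note <- "case value unavailable"
    } else if (sum(use) < 5) {
      res$note <- sprintf("untestable: %d usable controls (< 5)", sum(use))
    } else {
      xc <- x_ctrl[use]
      ids_used <- ctrl_ids[use]
      case_t <- x_case; ctrl_t <- xc; lam <- NA_real_
      do_bc <- fam %in% c("subfield_volumes", "metabolites") ||
        (config$boxcox_apply_to_asymmetry &&
           fam %in% c("subfield_asymmetry", "metabolite_asymmetry"))
      if (do_bc) {
        bc <- boxcox_transform(c(case_t, ctrl_t), lambda = "mle")
        lam <- bc$lambda
        case_t <- bc$values[1]
        ctrl_t <- bc$values[-1]
      }
      # optional nuisance regression happens on the transformed scale
      if (config$age_residualize) {
        fit <- stats::lm(y ~ a,
                         data = data.frame(y = ctrl_t, a = age[ids_used]))
        ctrl_t <- unname(stats::resid(fit))
        case_t <- case_t - unname(stats::predict(fit,
                    newdata = data.frame(a = age[[patient_id]])))
      }
      test_seed <- (config$rng_seed + 7919L * k) %% .Machine$integer.max
      tr <- sign_flip_test(case_t, ctrl_t, tails = config$tails,
                           n_max_exhaustive = config$n_max_exhaustive,
                           n_mc = config$n_mc, seed = test_seed)
      res$transformed <- case_t
      res$lambda <- lam
      res$statistic <- tr$statistic
      res$direction <- tr$direction
      res$p_uncorrected <- tr$p_uncorrected
      res$null_size <- tr$null_size
      res$null_mode <- tr$null_mode
      res$seed <- tr$seed
      res$testable <- TRUE
    }
    rows[[k]] <- as.data.frame(res, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  # family size = number of testable variables in each family
  for (f in unique(out$family)) {
    sel <- out$family == f
    out$family_size[sel] <- sum(out$testable[sel])
  }
  for (f in unique(out$family)) {
    sel <- out$family == f & out$testable
    if (!any(sel)) next
    fam_data <- NULL
    if (config$fwe_method == "maxstat")
      fam_data <- .family_data(out$variable[sel], patient_id, ctrl_ids, vm,
                               config)
    out[sel, ] <- fwe_correct(out[sel, , drop = FALSE],
                              method = config$fwe_method,
                              alpha = config$alpha,
                              family_data = fam_data,
                              n_max_exhaustive = config$n_max_exhaustive,
                              n_mc = config$n_mc,
                              seed = config$rng_seed)
  }
  class(out) <- c("hc_case_results", "data.frame")
  out
}

# transformed case/control data for a family, restricted to controls with
# complete data across the family (needed for shared flip patterns)
.family_data <- function(variables, patient_id, ctrl_ids, vm, config) {
  ctrl <- as.matrix(vm[ctrl_ids, variables, drop = FALSE])
  keep <- stats::complete.cases(ctrl)
  ctrl <- ctrl[keep, , drop = FALSE]
  case <- as.numeric(vm[patient_id, variables])
  for (j in seq_along(variables)) {
    fam <- .variable_family(variables[j])
    if (fam %in% c("subfield_volumes", "metabolites") ||
        (config$boxcox_apply_to_asymmetry)) {
      bc <- boxcox_transform(c(case[j], ctrl[, j]))
      case[j] <- bc$values[1]
      ctrl[, j] <- bc$values[-1]
    }
  }
  list(case = stats::setNames(case, variables), controls = ctrl)
}

#' Family-wise error correction of a single family of case tests
#'
#' `bonferroni` (default): a result is FWE-significant iff
#' `p_uncorrected <= alpha / family_size`. `maxstat`: the permutation-native
#' alternative — the joint null of the family's maximum `|T|` over sign-flip
#' patterns shared across variables; requires `family_data` (the transformed
#' case and control values of the family) and sets `p_fwe` to the tail
#' proportion of the max statistic.
#'
#' @param results rows of an `hc_case_results` belonging to one family.
#' @param method `"bonferroni"` or `"maxstat"`.
#' @param alpha family-wise level.
#' @param family_data for `maxstat`: list with `case` (named numeric) and
#'   `controls` (matrix, rows = controls).
#' @param n_max_exhaustive,n_mc,seed permutation budget for `maxstat`.
#' @return `results` with `fwe_significant` (and for maxstat `p_fwe`) set.
#' @export
fwe_correct <- function(results, method = c("bonferroni", "maxstat"),
                        alpha = 0.05, family_data = NULL,
                        n_max_exhaustive = 32768L, n_mc = 10000L,
                        seed = 1L) {
  method <- match.arg(method)
  testable <- results[results$testable, , drop = FALSE]
  if (length(unique(testable$family_size)) > 1L)
    stop("mixed family sizes within one correction call")
  if (method == "bonferroni") {
    results$fwe_significant[results$testable] <-
      testable$p_uncorrected <= alpha / testable$family_size
    return(results)
  }
  if (is.null(family_data))
    stop("maxstat correction needs family_data (case and control values)")
  case <- family_data$case[results$variable[results$testable]]
  ctrl <- family_data$controls[, results$variable[results$testable],
                               drop = FALSE]
  n <- nrow(ctrl)
  if (n < 5) stop("maxstat: fewer than 5 complete controls in the family")
  m <- n + 1L
  exhaustive <- (2^m) <= n_max_exhaustive
  # shufflings (perm_flip scheme) shared across the family's variables
  if (exhaustive) {
    S <- .flip_patterns(m)
    kvec <- rep(seq_len(m), each = nrow(S))
    S <- S[rep(seq_len(nrow(S)), times = m), , drop = FALSE]
  } else {
    ks <- .with_seed(seed, list(S = .flip_patterns(m, n_mc = n_mc),
                                k = sample.int(m, n_mc, replace = TRUE)))
    S <- ks$S; kvec <- ks$k
  }
  Tmat <- matrix(NA_real_, nrow(S), ncol(ctrl))
  t_obs <- numeric(ncol(ctrl))
  for (j in seq_len(ncol(ctrl))) {
    pooled <- c(case[j], ctrl[, j])
    mu <- mean(pooled)
    r <- pooled - mu
    for (kk in unique(kvec)) {
      sel <- kvec == kk
      Tmat[sel, j] <- .flip_stats(mu, r[c(kk, seq_len(m)[-kk])],
                                  S[sel, , drop = FALSE])
    }
    t_obs[j] <- (case[j] - mean(ctrl[, j])) /
      (stats::sd(ctrl[, j]) * sqrt(1 + 1 / n))
  }
  maxT <- apply(abs(Tmat), 1, max)
  p_fwe <- vapply(t_obs, function(t0) {
    tol <- 1e-8 * max(1, abs(t0))
    b <- sum(maxT >= abs(t0) - tol)
    if (exhaustive) b / nrow(S) else (b + 1) / (nrow(S) + 1)
  }, numeric(1))
  results$p_fwe <- NA_real_
  results$p_fwe[results$testable] <- p_fwe
  results$fwe_significant[results$testable] <- p_fwe <= alpha
  results
}

#' Laterality-concordance label for one patient and modality
#'
#' Summarizes where a patient's significant (uncorrected) findings lie
#' relative to the EEG seizure-onset side. Hemisphere attribution: a
#' significant `left.*`/`right.*` variable points to its own hemisphere; a
#' significant asymmetry variable points left when decreased (L
#' relatively smaller) and right when increased.
#'
#' Rules: no lateralized significant finding -> `uninformative`; findings
#' confined to the onset hemisphere -> `concordant`; confined to the
#' opposite hemisphere -> `discordant`; findings in both hemispheres ->
#' `bilateral` (which counts as `concordant` when the EEG onset itself is
#' bilateral). Unknown laterality withholds the label.
#'
#' @param results an `hc_case_results` (one patient).
#' @param eeg_laterality `"left"`, `"right"`, `"bilateral"` or `"unknown"`.
#' @param modality `"volumetry"` or `"mrs"`.
#' @param alpha uncorrected significance level (default 0.05).
#' @return data.frame row: `subject_id`, `modality`, `label`, `reason`.
#' @export
classify_concordance <- function(results, eeg_laterality,
                                 modality = c("volumetry", "mrs"),
                                 alpha = 0.05) {
  modality <- match.arg(modality)
  fams <- if (modality == "volumetry")
    c("subfield_volumes", "subfield_asymmetry")
  else c("metabolites", "metabolite_asymmetry")
  res <- results[results$family %in% fams & results$testable, , drop = FALSE]
  sid <- unique(results$subject_id)
  if (length(sid) != 1L) stop("results must belong to a single subject")
  if (is.na(eeg_laterality) || eeg_laterality == "unknown")
    return(data.frame(subject_id = sid, modality = modality,
                      label = NA_character_,
                      reason = "label withheld: unknown EEG laterality",
                      stringsAsFactors = FALSE))
  sig <- res[res$p_uncorrected <= alpha, , drop = FALSE]
  hemis <- character(0)
  for (i in seq_len(nrow(sig))) {
    v <- sig$variable[i]
    if (grepl("^left\\.", v)) hemis <- c(hemis, "left")
    else if (grepl("^right\\.", v)) hemis <- c(hemis, "right")
    else hemis <- c(hemis,
                    if (sig$direction[i] == "decreased") "left" else "right")
  }
  hemis <- unique(hemis)
  label <- if (length(hemis) == 0) "uninformative"
  else if (length(hemis) == 2) {
    if (eeg_laterality == "bilateral") "concordant" else "bilateral"
  } else if (eeg_laterality == "bilateral") {
    # unilateral findings against a bilateral focus: partial match only
    "discordant"
  } else if (hemis == eeg_laterality) "concordant" else "discordant"
  data.frame(subject_id = sid, modality = modality, label = label,
             reason = NA_character_, stringsAsFactors = FALSE)
}
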