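# Group-level comparisons, clinical correlations and segmentation
# reliability.

#' Shapiro-Wilk normality gate
#'
#' Assesses normality per group; a variable requires transformation when
#' the Shapiro-Wilk p falls below `alpha` in either group. When required,
#' the Box-Cox transform is applied jointly to both groups (a per-group
#' transform would break comparability).
#'
#' @param values_by_group named list of numeric vectors (one per group),
#'   each of length >= 3.
#' @param alpha gate level (default 0.05).
#' @return List with `status` (`"normal"` or `"transform_required"`) and
#'   `p_by_group`.
#' @export
normality_gate <- function(values_by_group, alpha = 0.05) {
  p <- vapply(values_by_group, function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 3) stop("normality gate needs n >= 3 per group")
    if (stats::sd(v) == 0) stop("constant values in a group")
    stats::shapiro.test(v)$p.value
  }, numeric(1))
  list(status = if (any(p < alpha)) "transform_required" else "normal",
       p_by_group = p)
}

#' ANCOVA group comparison controlling for age
#'
#' Linear model `value ~ age + group`; F and p are reported for the group
#' term (type-I and type-III coincide for this single-factor,
#' single-covariate design without interaction). If age is collinear with
#' group (e.g. identical ages within each group) a warning is emitted and
#' the covariate is dropped.
#'
#' @param values numeric outcome.
#' @param group factor/character with levels control/patient.
#' @param age numeric covariate.
#' @param transform_applied bookkeeping tag (`"none"` or `"boxcox"`).
#' @return data.frame row: `n_control`, `n_patient`, `f_statistic`, `p`,
#'   `covariates`, `transform_applied`.
#' @export
ancova_group <- function(values, group, age, transform_applied = "none") {
  keep <- !is.na(values) & !is.na(group) & !is.na(age)
  values <- values[keep]; group <- factor(group[keep]); age <- age[keep]
  if (nlevels(group) < 2 || any(table(group) == 0))
    stop("both groups must be nonempty")
  covars <- "age"
  # collinearity: age carries no information beyond group membership
  if (stats::var(stats::resid(stats::lm(age ~ group))) < 1e-12) {
    warning("age is collinear with group; covariate dropped")
    fit_full <- stats::lm(values ~ group)
    fit_red <- stats::lm(values ~ 1)
    covars <- character(0)
  } else {
    fit_full <- stats::lm(values ~ age + group)
    fit_red <- stats::lm(values ~ age)
  }
  an <- stats::anova(fit_red, fit_full)
  data.frame(n_control = sum(group == levels(group)[1]),
             n_patient = sum(group == levels(group)[2]),
             f_statistic = an$F[2], p = an$`Pr(>F)`[2],
             covariates = paste(covars, collapse = "+"),
             transform_applied = transform_applied,
             stringsAsFactors = FALSE)
}

#' Control-symmetry gate before ipsi/contra pooling
#'
#' Paired-samples t-test of left vs right control measurements; a variable
#' with p < `alpha` is asymmetric and excluded from pooled (hemisphere-
#' averaged / ipsi-contra) analyses, though it is still tested
#' per-hemisphere.
#'
#' @param left,right paired control measurements (equal length >= 3).
#' @param alpha gate level (default 0.05).
#' @return List with `status` (`"poolable"`/`"asymmetric"`), `t`, `p`, `n`.
#' @export
symmetry_gate <- function(left, right, alpha = 0.05) {
  if (length(left) != length(right)) stop("left/right must be paired")
  keep <- !is.na(left) & !is.na(right)
  left <- left[keep]; right <- right[keep]
  n <- length(left)
  if (n < 3) stop("symmetry gate needs >= 3 pairs")
  d <- left - right
  if (stats::sd(d) <= 1e-10 * max(1, abs(mean(d)))) {
    if (mean(d) == 0) return(list(status = "poolable", t = 0, p = 1, n = n))
    # constant nonzero difference: asymmetric at the test floor
    return(list(status = "asymmetric", t = sign(mean(d)) * Inf, p = 0,
                n = n))
  }
  tt <- stats::t.test(left, right, paired = TRUE)
  list(status = if (tt$p.value < alpha) "asymmetric" else "poolable",
       t = unname(tt$statistic), p = tt$p.value, n = n)
}

#' Pearson correlation with one-tailed and age-adjusted variants
#'
#' Two-tailed by default. One-tailed tests are fixed to the positive
#' direction (used for volume-memory pairs, where only a positive
#' association is expected). With `age_adjust = TRUE` the partial
#' correlation controlling for age is computed by residualizing both
#' variables on age (t-test on n - 3 df).
#'
#' @param x,y numeric vectors.
#' @param tails `"two"` (default) or `"one"`.
#' @param age_adjust partial out age?
#' @param age required when `age_adjust = TRUE`.
#' @return List with `r`, `p`, `n`, `df`, `tails`, `age_adjusted`.
#' @export
correlate <- function(x, y, tails = c("two", "one"), age_adjust = FALSE,
                      age = NULL) {
  tails <- match.arg(tails)
  keep <- !is.na(x) & !is.na(y)
  if (age_adjust) {
    if (is.null(age)) stop("age required when age_adjust = TRUE")
    keep <- keep & !is.na(age)
  }
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 4) stop("need >= 4 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance input")
  if (age_adjust) {
    age <- age[keep]
    rx <- stats::resid(stats::lm(x ~ age))
    ry <- stats::resid(stats::lm(y ~ age))
    # a variable fully explained by age has no partial association left
    if (stats::sd(rx) <= 1e-10 * stats::sd(x) ||
        stats::sd(ry) <= 1e-10 * stats::sd(y))
      return(list(r = 0, p = 1, n = n, df = n - 3, tails = tails,
                  age_adjusted = TRUE))
    r <- stats::cor(rx, ry)
    df <- n - 3
    tstat <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
    p <- if (tails == "two") 2 * stats::pt(-abs(tstat), df)
         else stats::pt(tstat, df, lower.tail = FALSE)
    return(list(r = r, p = min(p, 1), n = n, df = df, tails = tails,
                age_adjusted = TRUE))
  }
  alt <- if (tails == "two") "two.sided" else "greater"
  ct <- stats::cor.test(x, y, alternative = alt, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = n,
       df = unname(ct$parameter), tails = tails, age_adjusted = FALSE)
}

#' Segmentation reliability: repeated-measures ANOVA and ICC
#'
#' For repeat manual segmentations (two time points at least months apart)
#' this computes (i) a repeated-measures ANOVA over all subregion volumes
#' with within-subject factors time and subregion, reporting F and p for
#' the time main effect and the time x subregion interaction, and (ii) the
#' intraclass correlation for consistency of single measurements across
#' time — ICC(3,1), two-way mixed, consistency, single measurement — with
#' its 95% confidence interval, overall (units = subject x subregion) and
#' per subregion (units = subjects).
#'
#' @param data long data.frame with columns `subject_id`, `subregion`,
#'   `time` (two levels) and `volume`. Subjects missing any cell are
#'   dropped with a message.
#' @return List of class `hc_reliability`: `rm_anova` (data.frame with
#'   rows `time` and `time:subregion`), `icc`, `icc_ci`, `icc_by_subregion`.
#' @export
reliability <- function(data) {
  need <- c("subject_id", "subregion", "time", "volume")
  if (!all(need %in% names(data)))
    stop("data must have columns ", paste(need, collapse = ", "))
  data$time <- factor(data$time)
  data$subregion <- factor(data$subregion)
  data$subject_id <- factor(data$subject_id)
  if (nlevels(data$time) != 2) stop("exactly two time points required")
  # drop subjects with incomplete cells
  tab <- table(data$subject_id, data$time, data$subregion)
  complete <- apply(tab == 1, 1, all)
  if (any(!complete)) {
    message("WARN reliability: dropping subject(s) with missing cells: ",
            paste(names(complete)[!complete], collapse = ", "))
    data <- droplevels(data[data$subject_id %in% names(complete)[complete], ])
  }
  if (nlevels(data$subject_id) < 3) stop("need >= 3 complete subjects")

  fit <- stats::aov(volume ~ time * subregion +
                      Error(subject_id / (time * subregion)), data = data)
  sm <- summary(fit)
  total_ss <- sum((data$volume - mean(data$volume))^2)
  pull <- function(stratum, term) {
    tabs <- sm[[stratum]]
    if (is.null(tabs)) return(c(NA_real_, NA_real_))
    tb <- tabs[[1]]
    i <- match(term, trimws(rownames(tb)))
    if (is.na(i)) return(c(NA_real_, NA_real_))
    f <- tb[i, "F value"]; p <- tb[i, "Pr(>F)"]
    # an effect SS that is numerically zero relative to the data scale is
    # no effect, whatever the (equally tiny) error stratum says
    if (tb[i, "Sum Sq"] <= 1e-10 * total_ss) return(c(0, 1))
    if (is.na(f)) { f <- Inf; p <- 0 }
    c(f, p)
  }
  tm <- pull("Error: subject_id:time", "time")
  ix <- pull("Error: subject_id:time:subregion", "time:subregion")
  rm_anova <- data.frame(effect = c("time", "time:subregion"),
                         F = c(tm[1], ix[1]), p = c(tm[2], ix[2]),
                         stringsAsFactors = FALSE)

  wide <- stats::reshape(
    data[, c("subject_id", "subregion", "time", "volume")],
    idvar = c("subject_id", "subregion"), timevar = "time",
    direction = "wide")
  mat <- as.matrix(wide[, grep("^volume\\.", names(wide)), drop = FALSE])
  overall <- .icc31(mat)
  by_sub <- lapply(split(as.data.frame(mat), wide$subregion), function(d) {
    m <- as.matrix(d)
    if (nrow(m) >= 3) .icc31(m) else list(icc = NA_real_,
                                          ci = c(NA_real_, NA_real_))
  })
  structure(list(rm_anova = rm_anova, icc = overall$icc,
                 icc_ci = overall$ci,
                 icc_by_subregion = vapply(by_sub, `[[`, numeric(1), "icc"),
                 model = "two-way mixed, consistency, single measurement (ICC(3,1))"),
            class = "hc_reliability")
}

# ICC(3,1) from the two-way (units x raters) ANOVA decomposition, with the
# Shrout-Fleiss F-based 95% CI
.icc31 <- function(mat, conf = 0.95) {
  n <- nrow(mat); k <- ncol(mat)
  grand <- mean(mat)
  row_m <- rowMeans(mat); col_m <- colMeans(mat)
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  sse <- sum((mat - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  if (msr == 0 && mse == 0) stop("constant measurements; ICC undefined")
  icc <- if (mse == 0) 1 else (msr - mse) / (msr + (k - 1) * mse)
  if (mse == 0) return(list(icc = 1, ci = c(1, 1)))
  fval <- msr / mse
  df1 <- n - 1; df2 <- (n - 1) * (k - 1)
  fl <- fval / stats::qf(1 - (1 - conf) / 2, df1, df2)
  fu <- fval * stats::qf(1 - (1 - conf) / 2, df2, df1)
  list(icc = icc,
       ci = c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1)))
}

#' @export
print.hc_reliability <- function(x, ...) {
  cat("<hc_reliability>", x$model, "\n")
  cat(sprintf("  time        F = %.4g, p = %.3g\n",
              x$rm_anova$F[1], x$rm_anova$p[1]))
  cat(sprintf("  interaction F = %.4g, p = %.3g\n",
              x$rm_anova$F[2], x$rm_anova$p[2]))
  cat(sprintf("  ICC = %.3f (95%% CI %.3f-%.3f)\n",
              x$icc, x$icc_ci[1], x$icc_ci[2]))
  invisible(x)
}

#' Group-level analysis of every battery variable
#'
#' Runs the full group stage the way the Methods order prescribes:
#' Shapiro-Wilk gate per group, joint Box-Cox where required, then ANCOVA
#' controlling for age, for every testable battery variable. The control
#' symmetry gate is evaluated for each left/right pair and recorded.
#' No multiplicity correction is applied at group level (reported
#' uncorrected); every results header records that.
#'
#' @param cohort an `hc_cohort`.
#' @param derived matching [derive_measures()] output.
#' @param config an [analysis_config()].
#' @return data.frame: one row per variable with the ANCOVA output plus the
#'   normality and symmetry gate states.
#' @export
group_analysis <- function(cohort, derived, config = analysis_config()) {
  vm <- variable_matrix(cohort, derived)
  subj <- cohort$subjects
  grp <- subj$group[match(rownames(vm), subj$subject_id)]
  age <- subj$age[match(rownames(vm), subj$subject_id)]
  rows <- list()
  for (v in names(vm)) {
    vals <- vm[[v]]
    keep <- !is.na(vals)
    if (sum(keep & grp == "control") < 3 || sum(keep & grp == "patient") < 3)
      next
    gate <- normality_gate(split(vals[keep], grp[keep]),
                           alpha = config$alpha)
    transform_applied <- "none"
    use <- vals
    if (gate$status == "transform_required" && all(vals[keep] > 0)) {
      use[keep] <- boxcox_transform(vals[keep])$values
      transform_applied <- "boxcox"
    }
    row <- ancova_group(use[keep], grp[keep], age[keep],
                        transform_applied = transform_applied)
    row <- cbind(data.frame(variable = v, stringsAsFactors = FALSE), row,
                 data.frame(normality = gate$status,
                            stringsAsFactors = FALSE))
    rows[[length(rows) + 1L]] <- row
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(variable = character(), n_control = integer(),
               n_patient = integer(), f_statistic = numeric(),
               p = numeric(), covariates = character(),
               transform_applied = character(), normality = character(),
               stringsAsFactors = FALSE)
  # control symmetry per left/right pair
  base_vars <- unique(sub("^(left|right)\\.", "", grep("^(left|right)\\.",
                                                       names(vm),
                                                       value = TRUE)))
  sym <- lapply(base_vars, function(b) {
    l <- vm[[paste0("left.", b)]]; r <- vm[[paste0("right.", b)]]
    ctrl <- grp == "control"
    ok <- ctrl & !is.na(l) & !is.na(r)
    if (sum(ok) < 3) return(NULL)
    g <- symmetry_gate(l[ok], r[ok], alpha = config$alpha)
    data.frame(variable = b, status = g$status, t = g$t, p = g$p, n = g$n,
               stringsAsFactors = FALSE)
  })
  attr(out, "symmetry") <- do.call(rbind, sym[!vapply(sym, is.null,
                                                      logical(1))])
  rownames(out) <- NULL
  out
}
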