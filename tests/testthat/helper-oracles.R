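# Independent oracles used to freeze expected values. These deliberately
# avoid the package's vectorized closed forms: pseudo-samples are built
# explicitly and summarized with plain mean()/sd().

# brute-force sign-flip p over the full shuffling set
oracle_sign_flip <- function(case, ctrl, tails = "two",
                             shuffle = "flip_only") {
  n <- length(ctrl)
  m <- n + 1L
  pooled <- c(case, ctrl)
  mu <- mean(pooled)
  r <- pooled - mu
  tstat <- function(y) (y[1] - mean(y[-1])) / (sd(y[-1]) * sqrt(1 + 1 / n))
  t0 <- tstat(pooled)
  S <- as.matrix(expand.grid(rep(list(c(-1, 1)), m)))
  ks <- if (shuffle == "flip_only") 1L else seq_len(m)
  tf <- numeric(0)
  for (k in ks) {
    rk <- c(r[k], r[-k])
    tf <- c(tf, apply(S, 1, function(s) tstat(mu + s * rk)))
  }
  tol <- 1e-8 * max(1, abs(t0))
  if (tails == "two") mean(abs(tf) >= abs(t0) - tol)
  else {
    sgn <- if (t0 < 0) -1 else 1
    mean(sgn * tf >= sgn * t0 - tol)
  }
}

# grid-search Box-Cox profile likelihood
oracle_boxcox_lambda <- function(x, grid = seq(-5, 5, by = 0.005)) {
  n <- length(x)
  ll <- vapply(grid, function(l) {
    y <- if (abs(l) < 1e-12) log(x) else (x^l - 1) / l
    s2 <- sum((y - mean(y))^2) / n
    -n / 2 * log(s2) + (l - 1) * sum(log(x))
  }, numeric(1))
  grid[which.max(ll)]
}

# closed-form consistency ICC implied by variance components
oracle_icc <- function(sigma_b, sigma_e) sigma_b^2 / (sigma_b^2 + sigma_e^2)

# minimal valid three-subject cohort used across io tests
tiny_cohort_tables <- function() {
  subjects <- data.frame(
    subject_id = c("S1", "S2", "S3"),
    group = c("control", "control", "patient"),
    age = c(30, 40, 35), sex = c("F", "M", "F"),
    tbv = c(1.1e6, 1.25e6, 1.15e6),
    age_at_onset = c(NA, NA, 12), duration = c(NA, NA, 23),
    eeg_laterality = c(NA, NA, "left"),
    language_dominant_hemisphere = c("left", "left", "left"),
    z_list_learning = c(0.2, -0.1, -1.5),
    z_story_recall_delayed = c(0, 0.4, -2),
    z_design_learning = c(0.1, 0, -0.4),
    z_figure_recall = c(-0.2, 0.3, -1),
    stringsAsFactors = FALSE)
  hemi <- rep(c("left", "right"), 3)
  ids <- rep(subjects$subject_id, each = 2)
  volumes <- data.frame(
    subject_id = ids, hemisphere = hemi,
    CA1 = 1300 + seq_len(6) * 10, CA2 = 120 + seq_len(6),
    CA3 = 100 + seq_len(6), DG = 800 + seq_len(6) * 5,
    subiculum = 450 + seq_len(6) * 2,
    stringsAsFactors = FALSE)
  volumes$total_hippocampal_volume <-
    rowSums(volumes[, c("CA1", "CA2", "CA3", "DG", "subiculum")])
  volumes$excluded <- FALSE
  volumes$exclude_reason <- NA_character_
  mets <- c(tNAA = 10.5, Glu = 8.5, Gln = 3, tCho = 2, tCr = 8, Ins = 6.5,
            GABA = 1.5, Lac = 0.8)
  mrs <- data.frame(subject_id = ids, hemisphere = hemi,
                    stringsAsFactors = FALSE)
  for (mname in names(mets)) mrs[[mname]] <- mets[[mname]] + seq_len(6) / 10
  for (mname in names(mets))
    mrs[[paste0("crlb_", mname)]] <-
      if (mname %in% c("GABA", "Lac")) 60 else 10
  mrs$f_csf <- 0.1
  mrs$f_gm <- 0.6
  mrs$f_wm <- 0.3
  mrs$excluded <- FALSE
  mrs$exclude_reason <- NA_character_
  list(subjects = subjects, volumes = volumes, mrs = mrs)
}

# cohort whose controls have fixed means and a patient placed exactly on
# those means; used for "no effect -> no finding" checks
null_patient_cohort <- function(seed = 1, n_controls = 10) {
  spec <- generator_spec(n_controls = n_controls, n_patients = 1,
                         seed = seed, missing_rate = 0)
  generate_cohort(spec)
}
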