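# derived_measures: normalization, QC, indices

make_reference <- function(slope, intercept = 500, n_per_cell = 6,
                           noise_sd = 0, seed = 1) {
  set.seed(seed)
  sex <- rep(c("F", "M"), each = 2 * n_per_cell)
  ids <- sprintf("R%02d", seq_len(2 * n_per_cell))
  subjects <- data.frame(subject_id = ids, group = "control",
                         age = 30, sex = rep(c("F", "M"), each = n_per_cell),
                         tbv = rep(seq(1.0e6, 1.3e6,
                                       length.out = n_per_cell), 2),
                         stringsAsFactors = FALSE)
  rows <- expand.grid(subject_id = ids, hemisphere = c("left", "right"),
                      stringsAsFactors = FALSE)
  rows$total_hippocampal_volume <- intercept +
    slope * subjects$tbv[match(rows$subject_id, subjects$subject_id)] +
    rnorm(nrow(rows), 0, noise_sd)
  rows$excluded <- FALSE
  rows$exclude_reason <- NA_character_
  list(subjects = subjects, volumes = rows)
}

test_that("reference slopes recover a noiseless line exactly in every cell", {
  ref <- make_reference(slope = 0.002)
  slopes <- fit_reference_slopes(ref$volumes, ref$subjects)
  expect_equal(nrow(slopes), 4L)
  expect_equal(slopes$slope, rep(0.002, 4), tolerance = 1e-12)
  # slope 0: constant hippocampus, adjustment becomes the identity
  ref0 <- make_reference(slope = 0)
  s0 <- fit_reference_slopes(ref0$volumes, ref0$subjects)
  expect_equal(s0$slope, rep(0, 4), tolerance = 1e-12)
  expect_equal(adjust_total_volume(500, 2e6, s0, "F", "left"), 500)
})

test_that("reference slope errors: small cells and zero TBV variance", {
  ref <- make_reference(slope = 0.002)
  few <- ref$subjects$subject_id[ref$subjects$sex == "M"][1:4]
  keep <- !(ref$subjects$sex == "M" &
              !ref$subjects$subject_id %in% few[1:2])
  expect_error(fit_reference_slopes(ref$volumes[
    ref$volumes$subject_id %in% ref$subjects$subject_id[keep], ],
    ref$subjects[keep, ]), "\\(M, left\\)")
  flat <- ref
  flat$subjects$tbv <- 1.2e6
  flat$volumes$total_hippocampal_volume <- 500 + 0.002 * 1.2e6
  expect_error(fit_reference_slopes(flat$volumes, flat$subjects),
               "zero TBV variance")
})

test_that("noisy reference recovers the slope within 3 OLS standard errors", {
  set.seed(7)
  true_slope <- 0.0025
  ref <- make_reference(slope = true_slope, n_per_cell = 25, noise_sd = 150,
                        seed = 7)
  slopes <- fit_reference_slopes(ref$volumes, ref$subjects)
  for (i in seq_len(4)) {
    cell <- slopes[i, ]
    sel <- ref$subjects$sex == cell$sex
    d <- merge(ref$volumes[ref$volumes$hemisphere == cell$hemisphere, ],
               ref$subjects[sel, c("subject_id", "tbv")], by = "subject_id")
    # closed-form OLS standard error, computed independently
    bhat <- cov(d$tbv, d$total_hippocampal_volume) / var(d$tbv)
    res <- d$total_hippocampal_volume -
      mean(d$total_hippocampal_volume) - bhat * (d$tbv - mean(d$tbv))
    se <- sqrt(sum(res^2) / (nrow(d) - 2) /
                 sum((d$tbv - mean(d$tbv))^2))
    expect_lt(abs(cell$slope - true_slope), 3 * se)
  }
})

test_that("head-size adjustment follows the covariance-correction equation", {
  ref <- make_reference(slope = 0.002)
  slopes <- fit_reference_slopes(ref$volumes, ref$subjects)
  tbv_mean <- slopes$tbv_mean[slopes$sex == "F" &
                                slopes$hemisphere == "left"]
  # centering identity
  expect_equal(adjust_total_volume(3000, tbv_mean, slopes, "F", "left"),
               3000)
  # printed-equation arithmetic: 3000 - 0.002 * 100000 = 2800
  expect_equal(adjust_total_volume(3000, tbv_mean + 1e5, slopes, "F",
                                   "left"), 2800)
  expect_error(adjust_total_volume(100, tbv_mean + 1e6, slopes, "F",
                                   "left"), "implausible")
  expect_error(adjust_total_volume(3000, tbv_mean, slopes, "F", "medial"),
               "no reference slope")
})

test_that("subfield scaling preserves ratios in both modes", {
  row <- list(CA1 = 1200, CA2 = 120, CA3 = 100, DG = 900, subiculum = 680,
              total_hippocampal_volume = 3000)
  sc <- scale_subfields(row, adjusted_total = 2800)
  expect_equal(sc$scaling_factor, 2800 / 3000)
  expect_equal(unname(sc$scaled_subfields["CA1"]), 1120)
  # default mode: scaled total equals the adjusted total exactly
  expect_equal(sum(sc$scaled_subfields), 2800)
  sc2 <- scale_subfields(row, 2800, mode = "observed_over_adjusted")
  expect_equal(sc2$scaling_factor, 3000 / 2800)
  expect_equal(unname(sc2$scaled_subfields["CA1"]), 1200 * 3000 / 2800)
  same <- scale_subfields(row, 3000)
  expect_equal(same$scaling_factor, 1)
  expect_equal(unname(same$scaled_subfields["CA3"]), 100)
  # linearity over random draws
  set.seed(2)
  for (i in 1:20) {
    vols <- as.list(runif(5, 50, 2000))
    names(vols) <- c("CA1", "CA2", "CA3", "DG", "subiculum")
    vols$total_hippocampal_volume <- sum(unlist(vols))
    adj <- vols$total_hippocampal_volume * runif(1, 0.7, 1.3)
    s <- scale_subfields(vols, adj)
    expect_equal(sum(s$scaled_subfields),
                 s$scaling_factor * vols$total_hippocampal_volume,
                 tolerance = 1e-9)
  }
  row$total_hippocampal_volume <- NA
  expect_error(scale_subfields(row, 2800), "totals are required")
})

test_that("CSF correction is the printed multiplicative rescaling", {
  expect_equal(csf_correct(5, 0), 5)
  expect_equal(csf_correct(5, 0.5), 10)
  expect_error(csf_correct(5, 1), "f_csf")
  # strictly increasing in f_csf
  f <- seq(0, 0.9, by = 0.1)
  expect_true(all(diff(csf_correct(5, f)) > 0))
})

test_that("CRLB filter applies strict-greater rejection and cohort-wide reporting", {
  tabs <- tiny_cohort_tables()
  cohort <- hc_cohort(tabs$subjects, tabs$volumes, tabs$mrs)
  mrs <- cohort$mrs
  mrs$crlb_Gln <- c(60, 10, 10, 10, 10, 10)   # one bad record
  mrs$crlb_Glu <- 50                          # exactly at threshold
  out <- suppressMessages(crlb_filter(mrs))
  expect_false(out$qc_pass_Gln[1])
  expect_true(all(out$qc_pass_Gln[-1]))
  expect_true(all(out$qc_pass_Glu))           # strict > rejection
  rep <- attr(out, "reportable")
  expect_false(rep[["Gln"]])                  # one failure blocks the cohort
  expect_true(rep[["Glu"]])
  expect_false(rep[["GABA"]])                 # CRLB 60 everywhere
  mrs$crlb_tNAA[2] <- -1
  expect_error(crlb_filter(mrs), "negative CRLB")
  # warning level between report and reject thresholds
  mrs$crlb_tNAA[2] <- 30
  expect_message(crlb_filter(mrs), "tNAA kept but CRLB > 25")
})

test_that("asymmetry index matches the normalized difference formula", {
  expect_equal(asymmetry_index(100, 100), 0)
  expect_equal(asymmetry_index(150, 50), 1)
  expect_equal(asymmetry_index(50, 150), -1)
  expect_error(asymmetry_index(0, 0), "undefined")
  set.seed(5)
  L <- runif(200, 0, 100); R <- runif(200, 0, 100)
  ok <- L + R > 0
  ai <- asymmetry_index(L[ok], R[ok])
  expect_equal(ai, -asymmetry_index(R[ok], L[ok]))
  expect_true(all(abs(ai) <= 2))
})

test_that("ipsi/contra mapping follows the EEG-onset side", {
  expect_equal(map_ipsi_contra(10, 20, "left"),
               list(ipsilateral = 10, contralateral = 20))
  expect_equal(map_ipsi_contra(10, 20, "right"),
               list(ipsilateral = 20, contralateral = 10))
  out <- map_ipsi_contra(10, 20, "bilateral")
  expect_null(out$ipsilateral)
  expect_match(attr(out, "reason"), "bilateral")
})

test_that("memory impairment threshold is inclusive at z = -1.34", {
  expect_true(memory_impairment_flag(-1.34))
  expect_false(memory_impairment_flag(-1.33))
  expect_true(memory_impairment_flag(-2))
  expect_error(memory_impairment_flag(NaN), "finite")
})

test_that("VOI volume converts mm dimensions to mL", {
  expect_equal(voi_volume(c(10, 12, 28)), 3.36)
  expect_equal(voi_volume(c(10, 10, 10)), 1)
  expect_equal(voi_volume(c(1, 1, 1)), 0.001)
  expect_error(voi_volume(c(10, -1, 5)), "positive")
  expect_error(voi_volume(c(10, 10)), "three")
})
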