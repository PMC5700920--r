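# single_case_inference: Box-Cox, sign-flip engine, battery, FWE,
# concordance

test_that("Box-Cox branches and MLE behave", {
  expect_equal(boxcox_transform(5, lambda = 1)$values, 4)
  expect_equal(boxcox_transform(exp(1), lambda = 0)$values, 1)
  set.seed(31)
  x <- rlnorm(200)
  fit <- boxcox_transform(x)
  expect_lt(abs(fit$lambda), 0.25)                   # lognormal -> log
  expect_equal(fit$lambda, oracle_boxcox_lambda(x), tolerance = 0.01)
  # strictly increasing, rank preserving, for several lambdas
  xs <- sort(runif(50, 0.1, 10))
  for (l in c(-1.5, -0.3, 0, 0.7, 2))
    expect_true(all(diff(boxcox_transform(xs, l)$values) > 0))
  expect_error(boxcox_transform(c(1, -2)), "positive")
})

test_that("a case at the control mean of a symmetric sample is null", {
  ctrl <- c(-2, -1, 0, 1, 2)
  for (sh in c("perm_flip", "flip_only")) {
    r <- sign_flip_test(0, ctrl, shuffle = sh)
    expect_equal(r$statistic, 0)
    expect_equal(r$p_uncorrected, 1)
  }
})

test_that("exhaustive p matches the brute-force oracle in both schemes", {
  set.seed(17)
  for (i in 1:12) {
    n <- sample(c(5, 6, 8), 1)
    ctrl <- rnorm(n, 10, 2)
    case <- rnorm(1, 10 - sample(0:4, 1) * 2, 2)
    for (sh in c("flip_only", "perm_flip")) {
      for (tails in c("two", "one")) {
        got <- sign_flip_test(case, ctrl, tails = tails, shuffle = sh)
        expect_equal(got$p_uncorrected,
                     oracle_sign_flip(case, ctrl, tails, sh),
                     tolerance = 1e-12,
                     info = sprintf("n=%d %s %s", n, sh, tails))
      }
    }
  }
})

test_that("null-size bookkeeping and the attainable-p floor", {
  set.seed(19)
  ctrl <- rnorm(8, 100, 5)
  case <- 5000   # ~1000 control SDs out: only identity and its mirror tie
  r1 <- sign_flip_test(case, ctrl, shuffle = "flip_only")
  expect_equal(r1$null_size, 2^9)
  expect_equal(r1$p_uncorrected, 2 / 2^9)
  r2 <- sign_flip_test(case, ctrl, shuffle = "perm_flip")
  expect_equal(r2$null_size, 9 * 2^9)
  expect_equal(r2$p_uncorrected, 2 / (9 * 2^9))
  expect_equal(r2$direction, "increased")
})

test_that("Monte-Carlo p converges to the exhaustive value", {
  set.seed(23)
  within <- 0L
  n_seeds <- 60
  for (s in seq_len(n_seeds)) {
    ctrl <- rnorm(10, 50, 4)
    case <- rnorm(1, 44, 4)
    ex <- sign_flip_test(case, ctrl)$p_uncorrected
    mc <- sign_flip_test(case, ctrl, n_max_exhaustive = 2L, n_mc = 10000L,
                         seed = s)$p_uncorrected
    bound <- 3 * sqrt(ex * (1 - ex) / 10000) + 2 / 10001
    within <- within + (abs(mc - ex) <= bound)
  }
  expect_gte(within / n_seeds, 0.95)
  # Monte-Carlo mode is deterministic given its seed
  ctrl <- rnorm(10)
  a <- sign_flip_test(1.5, ctrl, n_max_exhaustive = 2L, seed = 7)
  b <- sign_flip_test(1.5, ctrl, n_max_exhaustive = 2L, seed = 7)
  expect_equal(a$null_mode, "monte_carlo")
  expect_identical(a$p_uncorrected, b$p_uncorrected)
})

test_that("one-tailed p never increases as the case moves away", {
  set.seed(41)
  for (rep in 1:3) {
    ctrl <- rnorm(9, 20, 3)
    for (sh in c("perm_flip", "flip_only")) {
      ps <- vapply(seq(0, 8, by = 0.5), function(d)
        sign_flip_test(mean(ctrl) - d, ctrl, tails = "one",
                       shuffle = sh)$p_uncorrected, numeric(1))
      expect_true(all(diff(ps) <= 1e-12))
    }
  }
})

test_that("sign-flip preconditions are enforced", {
  expect_error(sign_flip_test(1, rep(2, 8)), "zero control variance")
  expect_error(sign_flip_test(1, rnorm(4)), ">= 5 controls")
  expect_error(sign_flip_test(1, rnorm(8), n_max_exhaustive = 2L,
                              n_mc = 50), "n_mc")
})

test_that("battery on a null patient finds nothing and records families", {
  gen <- null_patient_cohort(seed = 8, n_controls = 12)
  ref <- generate_reference_cohort(generator_spec(seed = 8))
  slopes <- fit_reference_slopes(ref$volumes, ref$subjects)
  derived <- suppressMessages(derive_measures(gen$cohort, slopes))
  # place the patient exactly on the control means of every variable
  vm <- hippocase:::variable_matrix(gen$cohort, derived)
  res <- run_case_battery("P01", gen$cohort, derived)
  expect_s3_class(res, "hc_case_results")
  expect_setequal(unique(res$family),
                  c("subfield_volumes", "metabolites",
                    "subfield_asymmetry", "metabolite_asymmetry"))
  expect_equal(unique(res$family_size[res$family == "subfield_volumes"]),
               10L)
  expect_equal(unique(res$family_size[res$family == "metabolites"]), 12L)
  expect_equal(unique(res$family_size[res$family == "subfield_asymmetry"]),
               5L)
  expect_equal(unique(res$family_size[res$family ==
                                        "metabolite_asymmetry"]), 6L)
  # a patient drawn from the control law: no FWE-surviving result expected
  expect_false(any(res$fwe_significant[res$testable]))
})

test_that("battery flags variables with too few usable controls", {
  gen <- null_patient_cohort(seed = 9, n_controls = 6)
  cohort <- gen$cohort
  # exclude right-hemisphere volumes of most controls
  sel <- cohort$volumes$hemisphere == "right" &
    grepl("^C0[1-4]", cohort$volumes$subject_id)
  cohort$volumes$excluded[sel] <- TRUE
  ref <- generate_reference_cohort(generator_spec(seed = 9))
  slopes <- fit_reference_slopes(ref$volumes, ref$subjects)
  derived <- suppressMessages(derive_measures(cohort, slopes))
  res <- run_case_battery("P01", cohort, derived)
  bad <- res[res$variable == "right.CA1.volume", ]
  expect_false(bad$testable)
  expect_match(bad$note, "usable controls")
  expect_true("right.CA1.volume" %in% res$variable)  # present, not dropped
})

test_that("Bonferroni correction follows the family-size arithmetic", {
  mk <- function(p, fam_size) {
    data.frame(subject_id = "P", variable = paste0("v", seq_along(p)),
               family = "f", family_size = fam_size, p_uncorrected = p,
               fwe_significant = NA, testable = TRUE,
               stringsAsFactors = FALSE)
  }
  out <- fwe_correct(mk(c(0.004, 0.02), 10), alpha = 0.05)
  expect_equal(out$fwe_significant, c(TRUE, FALSE))  # 0.004 <= 0.005
  out5 <- fwe_correct(mk(0.02, 5), alpha = 0.05)
  expect_false(out5$fwe_significant)                  # 0.02 > 0.01
  out12 <- fwe_correct(mk(0.02, 12), alpha = 0.05)
  expect_false(out12$fwe_significant)                 # 0.02 > 0.05/12
  mixed <- rbind(mk(0.01, 5), mk(0.01, 6))
  expect_error(fwe_correct(mixed, alpha = 0.05), "mixed family sizes")
})

test_that("maxstat familywise error is calibrated on independent nulls", {
  set.seed(57)
  n <- 8; V <- 5
  reps <- 2000
  rej <- logical(reps)
  for (i in seq_len(reps)) {
    ctrl <- matrix(rnorm(n * V), n, V,
                   dimnames = list(NULL, paste0("v", 1:V)))
    case <- rnorm(V)
    res <- data.frame(subject_id = "P", variable = colnames(ctrl),
                      family = "f", family_size = V,
                      p_uncorrected = NA_real_, fwe_significant = NA,
                      testable = TRUE, stringsAsFactors = FALSE)
    out <- fwe_correct(res, method = "maxstat", alpha = 0.05,
                       family_data = list(case = setNames(case,
                                                          colnames(ctrl)),
                                          controls = ctrl))
    rej[i] <- any(out$fwe_significant)
  }
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})

test_that("concordance labelling follows the laterality rules", {
  mk <- function(vars, ps, dirs) {
    data.frame(subject_id = "P", variable = vars,
               family = ifelse(grepl("asymmetry", vars),
                               "subfield_asymmetry", "subfield_volumes"),
               family_size = 5L, p_uncorrected = ps, direction = dirs,
               fwe_significant = FALSE, testable = TRUE,
               stringsAsFactors = FALSE)
  }
  # left-onset, significant left.CA2 decrease only -> concordant
  r <- mk(c("left.CA2.volume", "right.CA2.volume"), c(0.02, 0.7),
          c("decreased", "decreased"))
  expect_equal(classify_concordance(r, "left", "volumetry")$label,
               "concordant")
  # right-onset, significant left.CA3 decrease only -> discordant
  r <- mk("left.CA3.volume", 0.01, "decreased")
  expect_equal(classify_concordance(r, "right", "volumetry")$label,
               "discordant")
  # nothing significant -> uninformative
  r <- mk("left.CA3.volume", 0.4, "decreased")
  expect_equal(classify_concordance(r, "left", "volumetry")$label,
               "uninformative")
  # findings in both hemispheres -> bilateral; concordant if EEG bilateral
  r <- mk(c("left.CA3.volume", "right.CA2.volume"), c(0.01, 0.03),
          c("decreased", "decreased"))
  expect_equal(classify_concordance(r, "left", "volumetry")$label,
               "bilateral")
  expect_equal(classify_concordance(r, "bilateral", "volumetry")$label,
               "concordant")
  # asymmetry direction points to a hemisphere
  r <- mk("CA1.asymmetry", 0.02, "decreased")   # L < R: points left
  expect_equal(classify_concordance(r, "left", "volumetry")$label,
               "concordant")
  # unknown laterality withholds the label
  out <- classify_concordance(r, "unknown", "volumetry")
  expect_true(is.na(out$label))
  expect_match(out$reason, "unknown")
})

test_that("rank preservation: fixed-lambda Box-Cox keeps case ordering", {
  set.seed(71)
  ctrl <- rlnorm(10, log(100), 0.1)
  cases <- seq(55, 95, by = 5)    # all below the control mean
  p_raw <- vapply(cases, function(x)
    sign_flip_test(x, ctrl, tails = "one")$p_uncorrected, numeric(1))
  bc <- boxcox_transform(ctrl, lambda = 0.33)
  p_bc <- vapply(cases, function(x)
    sign_flip_test(boxcox_transform(x, 0.33)$values, bc$values,
                   tails = "one")$p_uncorrected, numeric(1))
  expect_equal(rank(p_raw, ties.method = "min"),
               rank(p_bc, ties.method = "min"))
})
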