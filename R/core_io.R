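# Measurement-table schemas ---------------------------------------------------
#
# subjects: one row per participant; volumes / mrs: one row per participant x
# hemisphere. Missing hemispheres are represented as excluded rows, never
# dropped silently, so downstream n's are auditable.

.subject_cols <- function() {
  c("subject_id", "group", "age", "sex", "tbv", "age_at_onset", "duration",
    "eeg_laterality", "language_dominant_hemisphere",
    paste0("z_", hc_memory_tests()))
}

.volume_cols <- function() {
  c("subject_id", "hemisphere", hc_subfields(), "total_hippocampal_volume",
    "excluded", "exclude_reason")
}

.mrs_cols <- function() {
  c("subject_id", "hemisphere", hc_metabolites(all = TRUE),
    paste0("crlb_", hc_metabolites(all = TRUE)), "f_csf", "f_gm", "f_wm",
    "excluded", "exclude_reason")
}

#' Assemble and validate a cohort
#'
#' Bundles the three measurement tables into a validated cohort object.
#' Every invariant of the domain types is checked here so that no
#' partially-validated cohort reaches a downstream stage.
#'
#' @param subjects data.frame of demographics/covariates (one row per
#'   participant).
#' @param volumes data.frame of per-hemisphere subfield volumes in mm^3.
#' @param mrs data.frame of per-hemisphere metabolite concentrations
#'   (umol/g), CRLBs (%) and voxel tissue fractions.
#' @return An object of class `hc_cohort`: a list with elements `subjects`,
#'   `volumes`, `mrs`.
#' @export
hc_cohort <- function(subjects, volumes, mrs) {
  subjects <- .validate_subjects(as.data.frame(subjects))
  volumes <- .validate_hemi_table(as.data.frame(volumes), subjects,
                                  .volume_cols(), "volumes")
  mrs <- .validate_hemi_table(as.data.frame(mrs), subjects,
                              .mrs_cols(), "mrs")
  volumes <- .check_volumes(volumes)
  mrs <- .check_mrs(mrs)
  structure(list(subjects = subjects, volumes = volumes, mrs = mrs),
            class = "hc_cohort")
}

#' @export
print.hc_cohort <- function(x, ...) {
  n_pat <- sum(x$subjects$group == "patient")
  n_con <- sum(x$subjects$group == "control")
  cat(sprintf("<hc_cohort> %d controls, %d patients\n", n_con, n_pat))
  cat(sprintf("  volume rows: %d (%d excluded)  mrs rows: %d (%d excluded)\n",
              nrow(x$volumes), sum(x$volumes$excluded),
              nrow(x$mrs), sum(x$mrs$excluded)))
  invisible(x)
}

.fail_rows <- function(bad, table, what) {
  if (any(bad, na.rm = TRUE))
    stop(sprintf("%s: %s (row%s %s)", table, what,
                 if (sum(bad, na.rm = TRUE) > 1L) "s" else "",
                 paste(which(bad), collapse = ", ")), call. = FALSE)
}

.validate_subjects <- function(df) {
  need <- c("subject_id", "group", "age", "sex")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("subjects: missing required column(s): ",
         paste(miss, collapse = ", "))
  unknown <- setdiff(names(df), .subject_cols())
  if (length(unknown))
    stop("subjects: unknown column(s): ", paste(unknown, collapse = ", "),
         "; accepted: ", paste(.subject_cols(), collapse = ", "))
  for (col in setdiff(.subject_cols(), names(df)))
    df[[col]] <- rep(NA, nrow(df))
  df$subject_id <- as.character(df$subject_id)
  .fail_rows(duplicated(df$subject_id), "subjects", "duplicate subject_id")
  .fail_rows(!df$group %in% c("control", "patient"), "subjects",
             "group must be 'control' or 'patient'")
  .fail_rows(!df$sex %in% c("F", "M"), "subjects", "sex must be 'F' or 'M'")
  for (col in c("age", "tbv", "age_at_onset", "duration",
                paste0("z_", hc_memory_tests())))
    df[[col]] <- as.numeric(df[[col]])
  .fail_rows(!is.finite(df$age) | df$age <= 0, "subjects",
             "age must be a positive number")
  .fail_rows(!is.na(df$tbv) & df$tbv <= 0, "subjects", "tbv must be > 0")
  .fail_rows(!is.na(df$duration) & df$duration < 0, "subjects",
             "duration must be >= 0")
  .fail_rows(!is.na(df$age_at_onset) & df$age_at_onset > df$age, "subjects",
             "age_at_onset exceeds age")
  # controls carry no epilepsy fields
  ctrl <- df$group == "control"
  df$age_at_onset[ctrl] <- NA_real_
  df$duration[ctrl] <- NA_real_
  df$eeg_laterality[ctrl] <- NA_character_
  ok_lat <- c("left", "right", "bilateral", "unknown", NA)
  .fail_rows(!df$eeg_laterality %in% ok_lat, "subjects",
             "eeg_laterality must be left/right/bilateral/unknown")
  df$language_dominant_hemisphere[is.na(df$language_dominant_hemisphere)] <-
    "unknown"
  .fail_rows(!df$language_dominant_hemisphere %in%
               c("left", "right", "unknown"),
             "subjects", "language_dominant_hemisphere must be left/right/unknown")
  df[, .subject_cols()]
}

# shared structural checks for volumes / mrs tables
.validate_hemi_table <- function(df, subjects, cols, table) {
  need <- c("subject_id", "hemisphere")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(table, ": missing required column(s): ",
         paste(miss, collapse = ", "))
  unknown <- setdiff(names(df), cols)
  if (length(unknown))
    stop(table, ": unknown column(s): ", paste(unknown, collapse = ", "),
         "; accepted: ", paste(cols, collapse = ", "))
  df$subject_id <- as.character(df$subject_id)
  df$hemisphere <- normalize_hemisphere(df$hemisphere)
  .fail_rows(!df$subject_id %in% subjects$subject_id, table,
             "subject_id not present in subjects table")
  .fail_rows(duplicated(df[c("subject_id", "hemisphere")]), table,
             "duplicate subject x hemisphere")
  for (col in setdiff(cols, c(names(df), "excluded", "exclude_reason")))
    df[[col]] <- rep(NA_real_, nrow(df))
  if (is.null(df$excluded)) df$excluded <- rep(FALSE, nrow(df))
  df$excluded <- as.logical(df$excluded)
  df$excluded[is.na(df$excluded)] <- FALSE
  if (is.null(df$exclude_reason))
    df$exclude_reason <- rep(NA_character_, nrow(df))
  df$exclude_reason <- as.character(df$exclude_reason)
  # materialize missing hemispheres as excluded rows
  full <- expand.grid(subject_id = subjects$subject_id,
                      hemisphere = hc_hemispheres(),
                      stringsAsFactors = FALSE)
  key <- paste(df$subject_id, df$hemisphere)
  missing <- full[!paste(full$subject_id, full$hemisphere) %in% key, ,
                  drop = FALSE]
  if (nrow(missing)) {
    add <- df[rep(NA_integer_, nrow(missing)), , drop = FALSE]
    add$subject_id <- missing$subject_id
    add$hemisphere <- missing$hemisphere
    add$excluded <- TRUE
    add$exclude_reason <- "missing hemisphere row"
    df <- rbind(df, add)
  }
  df <- df[order(df$subject_id, df$hemisphere), cols, drop = FALSE]
  rownames(df) <- NULL
  df
}

.check_volumes <- function(df) {
  for (col in c(hc_subfields(), "total_hippocampal_volume")) {
    df[[col]] <- as.numeric(df[[col]])
    .fail_rows(!is.na(df[[col]]) & df[[col]] <= 0, "volumes",
               paste0(col, " must be > 0 when present"))
  }
  df
}

.check_mrs <- function(df) {
  mets <- hc_metabolites(all = TRUE)
  for (col in c(mets, paste0("crlb_", mets), "f_csf", "f_gm", "f_wm"))
    df[[col]] <- as.numeric(df[[col]])
  for (m in mets) {
    .fail_rows(!is.na(df[[m]]) & df[[m]] < 0, "mrs",
               paste0(m, " concentration must be >= 0"))
    crlb <- df[[paste0("crlb_", m)]]
    .fail_rows(!is.na(crlb) & crlb < 0, "mrs",
               paste0("crlb_", m, " must be >= 0"))
  }
  .fail_rows(!is.na(df$f_csf) & (df$f_csf < 0 | df$f_csf >= 1), "mrs",
             "f_csf must lie in [0, 1)")
  fsum <- df$f_csf + df$f_gm + df$f_wm
  .fail_rows(!is.na(fsum) & abs(fsum - 1) > 1e-6, "mrs",
             "f_csf + f_gm + f_wm must sum to 1 (tolerance 1e-6)")
  df
}

# Reading / writing -----------------------------------------------------------

.detect_sep <- function(path) {
  lines <- readLines(path, n = 50L)
  header <- lines[!startsWith(lines, "#")][1]
  if (is.na(header)) stop("no header line found in ", path)
  if (grepl("\t", header, fixed = TRUE)) "\t" else ","
}

.read_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- .detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          comment.char = "#", na.strings = c("NA", ""),
                          quote = "", colClasses = NA,
                          fileEncoding = "UTF-8")
  # unit tag on the tbv header: "(cm3)" values are converted to mm^3
  cm3 <- grep("^tbv\\s*\\(cm3\\)$", names(df))
  if (length(cm3)) {
    names(df)[cm3] <- "tbv"
    df$tbv <- as.numeric(df$tbv) * 1000
  }
  df
}

#' Read the measurement tables of a study
#'
#' Reads the three delimited text tables (comma- or tab-separated, detected
#' from the header line), normalizes hemisphere aliases (`L`, `R`, `lh`,
#' `rh`), converts a `tbv (cm3)` column to mm^3, and validates every
#' domain-type invariant. Rows that fail validation are reported with their
#' row numbers; unknown column names are a hard error listing the accepted
#' vocabulary.
#'
#' @param subjects_path,volumes_path,mrs_path paths to the three tables.
#' @return A validated [hc_cohort()].
#' @export
read_measurement_tables <- function(subjects_path, volumes_path, mrs_path) {
  hc_cohort(.read_table(subjects_path),
            .read_table(volumes_path),
            .read_table(mrs_path))
}

# full-precision formatter so write -> read -> write is byte-stable
.fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) return("NA")
    if (v == floor(v) && abs(v) < 1e15) return(sprintf("%.0f", v))
    sprintf("%.17g", v)
  }, character(1))
  out
}

.write_table <- function(df, path, dictionary = NULL) {
  out <- df
  for (col in names(out)) {
    if (is.numeric(out[[col]])) out[[col]] <- .fmt_num(out[[col]])
    else if (is.logical(out[[col]]))
      out[[col]] <- ifelse(is.na(out[[col]]), "NA",
                           ifelse(out[[col]], "TRUE", "FALSE"))
    else {
      out[[col]] <- as.character(out[[col]])
      out[[col]][is.na(out[[col]])] <- "NA"
    }
  }
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(dictionary))
    writeLines(sprintf("# %s: %s", names(dictionary), dictionary), con)
  writeLines(paste(names(out), collapse = "\t"), con)
  if (nrow(out))
    writeLines(do.call(paste, c(unname(out), sep = "\t")), con)
  invisible(path)
}

#' Write a cohort back to measurement tables
#'
#' Inverse of [read_measurement_tables()]: `subjects.tsv`, `volumes.tsv`
#' and `mrs.tsv` are written to `dir` at full precision, so a
#' write -> read -> write cycle is byte-identical.
#'
#' @param cohort an `hc_cohort`.
#' @param dir output directory (created if needed).
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "hc_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(subjects = file.path(dir, "subjects.tsv"),
             volumes = file.path(dir, "volumes.tsv"),
             mrs = file.path(dir, "mrs.tsv"))
  .write_table(cohort$subjects, paths["subjects"])
  .write_table(cohort$volumes, paths["volumes"])
  .write_table(cohort$mrs, paths["mrs"])
  invisible(paths)
}

#' Write a results table with a column dictionary header
#'
#' Serializes any flat results data.frame as a TSV preceded by `#`-prefixed
#' lines describing each column. An empty results set produces a
#' header-only file. Readers that skip `#` comments (including
#' [read_measurement_tables()]'s parser) round-trip the table.
#'
#' @param results a data.frame (possibly zero rows).
#' @param path output path.
#' @param dictionary optional named character vector `column -> description`;
#'   defaults to the column names themselves.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, dictionary = NULL) {
  results <- as.data.frame(results)
  if (is.null(dictionary)) {
    dictionary <- stats::setNames(names(results), names(results))
  }
  dictionary <- dictionary[names(dictionary) %in% names(results)]
  .write_table(results, path, dictionary = dictionary)
}
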