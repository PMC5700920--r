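# Human-readable per-patient reports mirroring the clinical results-table
# conventions: significant findings only, "inc" marks increases (decreases
# are the default reading), asterisks mark FWE survivors, "n.s." a modality
# with no significant finding.

#' Render a per-patient findings report
#'
#' A pure function of the result tables: regenerating the report from
#' saved tables reproduces it byte-identically.
#'
#' @param results an `hc_case_results` for one patient.
#' @param concordance optional concordance rows for the same patient.
#' @param alpha uncorrected significance level (default 0.05).
#' @return Character vector of report lines.
#' @export
render_patient_report <- function(results, concordance = NULL,
                                  alpha = 0.05) {
  sid <- unique(results$subject_id)
  if (length(sid) != 1L) stop("results must belong to a single patient")
  lines <- sprintf("Patient %s", sid)
  sections <- list(
    "Subfield volumes" = "subfield_volumes",
    "Subfield asymmetry" = "subfield_asymmetry",
    "Metabolite concentrations" = "metabolites",
    "Metabolite asymmetry" = "metabolite_asymmetry")
  fmt_p <- function(p) ifelse(p < 0.01, "p < 0.01",
                              sprintf("p = %.2f", p))
  for (title in names(sections)) {
    fam <- sections[[title]]
    r <- results[results$family == fam & results$testable, , drop = FALSE]
    sig <- r[r$p_uncorrected <= alpha, , drop = FALSE]
    if (!nrow(sig)) {
      lines <- c(lines, sprintf("  %s: n.s.", title))
      next
    }
    items <- vapply(seq_len(nrow(sig)), function(i) {
      lab <- sub("\\.(volume|conc)$", "", sig$variable[i])
      lab <- sub("\\.asymmetry$", "", lab)
      marker <- if (isTRUE(sig$fwe_significant[i])) "*" else ""
      dir <- if (grepl("asymmetry", sig$family[i])) {
        if (sig$direction[i] == "decreased") " (L < R)" else " (L > R)"
      } else if (sig$direction[i] == "increased") " (inc)" else ""
      sprintf("%s%s, %s%s", lab, marker, fmt_p(sig$p_uncorrected[i]), dir)
    }, character(1))
    lines <- c(lines, sprintf("  %s: %s", title,
                              paste(items, collapse = "; ")))
  }
  untest <- results[!results$testable, , drop = FALSE]
  if (nrow(untest))
    lines <- c(lines, sprintf("  Untestable: %s",
                              paste(untest$variable, collapse = ", ")))
  if (!is.null(concordance)) {
    for (i in seq_len(nrow(concordance))) {
      lab <- concordance$label[i]
      if (is.na(lab)) lab <- paste0("withheld (", concordance$reason[i], ")")
      lines <- c(lines, sprintf("  Concordance (%s): %s",
                                concordance$modality[i], lab))
    }
  }
  lines
}
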