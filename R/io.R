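# CSV dialects: assay records in, S0 / task tables out. Solubilities are
# log10 molar internally; micromolar inputs are converted at this boundary.

.requireColumns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop("malformed ", what, " CSV: missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
}

#' Read an assay CSV into records and compounds
#'
#' One row per measurement. Required columns: \code{compound_id},
#' \code{smiles}, \code{ph}, \code{solid_state}, \code{is_salt},
#' \code{acidic_pkas}, \code{basic_pkas} (semicolon-separated pKa lists)
#' and either \code{solubility_uM} or \code{log_s_molar}. Optional:
#' \code{censored} (none/below_lo/above_hi; inferred from the assay window
#' when absent) and \code{replicate_spread} (0 when absent).
#'
#' @param path CSV file path.
#' @param config a \code{\link{curationConfig}} (supplies the assay window
#'   for censoring inference).
#' @return list with \code{records} and \code{compounds} data.frames as
#'   consumed by \code{\link{curateS0}}.
#' @export
readAssayCsv <- function(path, config = curationConfig()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(compound_id = "character"))
  .requireColumns(df, c("compound_id", "smiles", "ph", "solid_state",
                        "is_salt", "acidic_pkas", "basic_pkas"), "assay")
  if (!("log_s_molar" %in% names(df))) {
    .requireColumns(df, "solubility_uM", "assay")
    df$log_s_molar <- log10(df$solubility_uM * 1e-6)
  }
  if (!("censored" %in% names(df))) {
    df$censored <- ifelse(df$log_s_molar < log10(config$assayLo), "below_lo",
                   ifelse(df$log_s_molar > log10(config$assayHi), "above_hi", "none"))
  }
  if (!("replicate_spread" %in% names(df))) df$replicate_spread <- 0
  for (col in c("acidic_pkas", "basic_pkas"))
    df[[col]] <- ifelse(is.na(df[[col]]), "", as.character(df[[col]]))
  records <- data.frame(compound_id = df$compound_id, ph = df$ph,
                        log_s = df$log_s_molar, solid_state = df$solid_state,
                        censored = df$censored,
                        replicate_spread = df$replicate_spread)
  compounds <- unique(data.frame(compound_id = df$compound_id,
                                 smiles = df$smiles,
                                 is_salt = as.logical(df$is_salt),
                                 acidic_pkas = df$acidic_pkas,
                                 basic_pkas = df$basic_pkas))
  if (anyDuplicated(compounds$compound_id))
    stop("inconsistent compound-level fields for a compound_id")
  list(records = records, compounds = compounds)
}

#' Write the curated S0 dataset
#' @param s0 the \code{s0} data.frame from \code{\link{curateS0}}.
#' @param path output CSV path.
#' @export
writeS0Csv <- function(s0, path) {
  out <- data.frame(compound_id = s0$compound_id, smiles = s0$smiles,
                    log_s0_molar = s0$log_s0_molar,
                    high_quality = as.integer(s0$high_quality))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a TaskTable as CSV
#'
#' One column per task plus a \code{<task>.observed} companion column;
#' unobserved values serialize as empty fields.
#'
#' @param tt a \linkS4class{TaskTable}.
#' @param path output CSV path.
#' @export
writeTaskTableCsv <- function(tt, path) {
  v <- taskValues(tt); o <- observedMask(tt)
  out <- data.frame(compound_id = compoundIds(tt))
  for (nm in taskNames()) {
    out[[nm]] <- ifelse(o[, nm], v[, nm], NA_real_)
    out[[paste0(nm, ".observed")]] <- as.integer(o[, nm])
  }
  out$high_quality_s0 <- as.integer(highQuality(tt))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a TaskTable written by \code{\link{writeTaskTableCsv}}
#' @param path CSV file path.
#' @return a \linkS4class{TaskTable}.
#' @export
readTaskTableCsv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(compound_id = "character"))
  .requireColumns(df, c("compound_id", taskNames(),
                        paste0(taskNames(), ".observed")), "task table")
  vals <- as.matrix(df[, taskNames()])
  rownames(vals) <- df$compound_id
  obs <- as.matrix(df[, paste0(taskNames(), ".observed")]) == 1
  dimnames(obs) <- dimnames(vals)
  colnames(obs) <- taskNames()
  hq <- if ("high_quality_s0" %in% names(df)) df$high_quality_s0 == 1
        else rep(FALSE, nrow(df))
  new("TaskTable", values = vals, observed = obs, highQuality = hq)
}
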