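# Curation of raw assay records into the S0 dataset and the merged
# eight-task training table.
#
# Records arrive as a data.frame (one row per measurement) and compounds as
# a data.frame (one row per compound, pKa lists as semicolon-separated
# strings). The pipeline applies, in order: solid-state / censoring / salt
# filters; the pH-selection rules for S0 derivation; Henderson-Hasselbalch
# back-calculation; the duplicate rule; and high-quality flagging.

#' Curation configuration
#'
#' @param duplicateThreshold log units; duplicate S0 values differing by at
#'   least this much drop the compound, otherwise the smaller value is kept
#'   (assumed more stable polymorph). Default 0.7.
#' @param zwitterionGap pH units; compounds with both acidic and basic
#'   groups are kept only when min(acidic pKa) - max(basic pKa) exceeds
#'   this gap. Default 2.
#' @param assayLo,assayHi assay dynamic range in molar (defaults 0.1 uM and
#'   600 uM).
#' @param maxRelevantPkas maximum relevant pKa's at the derivation pH
#'   (default 3).
#' @param hqSpreadTol log units; replicate spread at or below this keeps
#'   the high-quality flag. Default 0.5.
#' @param relevanceThreshold ionized-fraction threshold for pKa relevance.
#' @return a named list of class \code{CurationConfig}.
#' @export
curationConfig <- function(duplicateThreshold = 0.7, zwitterionGap = 2,
                           assayLo = 0.1e-6, assayHi = 600e-6,
                           maxRelevantPkas = 3L, hqSpreadTol = 0.5,
                           relevanceThreshold = 0.01) {
  stopifnot(duplicateThreshold > 0, zwitterionGap > 0,
            assayLo > 0, assayHi > assayLo, maxRelevantPkas > 0,
            hqSpreadTol > 0)
  structure(list(duplicateThreshold = duplicateThreshold,
                 zwitterionGap = zwitterionGap,
                 assayLo = assayLo, assayHi = assayHi,
                 maxRelevantPkas = as.integer(maxRelevantPkas),
                 hqSpreadTol = hqSpreadTol,
                 relevanceThreshold = relevanceThreshold),
            class = "CurationConfig")
}

.pkaString <- function(x) {
  if (length(x) == 0) "" else paste(format(x, digits = 10, trim = TRUE), collapse = ";")
}

.parsePkas <- function(s) {
  if (is.na(s) || !nzchar(trimws(s))) return(numeric(0))
  as.numeric(strsplit(trimws(s), ";", fixed = TRUE)[[1]])
}

#' Ionization model of one compound row
#'
#' @param entry one row of a compounds data.frame with columns
#'   \code{acidic_pkas} and \code{basic_pkas} (semicolon-separated).
#' @return an \linkS4class{IonizationModel}.
#' @export
compoundIonization <- function(entry) {
  IonizationModel(acidic = .parsePkas(entry$acidic_pkas),
                  basic = .parsePkas(entry$basic_pkas))
}

#' Filter assay records for S0 derivation
#'
#' Retains only records whose residual solid was confirmed crystalline and
#' whose value lies inside the assay dynamic range (uncensored); drops all
#' records of salt-form compounds. Order-preserving and deterministic.
#'
#' @param records data.frame with columns \code{compound_id}, \code{ph},
#'   \code{log_s}, \code{solid_state}, \code{censored},
#'   \code{replicate_spread}.
#' @param compounds data.frame with columns \code{compound_id},
#'   \code{is_salt} (and pKa columns, unused here).
#' @param config a \code{\link{curationConfig}}.
#' @return the retained subset of \code{records}.
#' @export
filterRecords <- function(records, compounds, config = curationConfig()) {
  if (nrow(records) == 0) return(records)
  salts <- compounds$compound_id[as.logical(compounds$is_salt)]
  keep <- records$solid_state == "crystalline" &
    records$censored == "none" &
    !(records$compound_id %in% salts)
  records[keep, , drop = FALSE]
}

.pkaGap <- function(model) min(acidicPkas(model)) - max(basicPkas(model))

#' Choose the record used to derive S0 for one compound
#'
#' Implements the pH-selection rules: acid-only compounds use the pH 2
#' record; base-only compounds the pH 7 record; compounds with both group
#' types use the record closest to the midpoint of min(acidic pKa) and
#' max(basic pKa) when the gap exceeds \code{zwitterionGap}, and are
#' discarded otherwise (this removes zwitterions); compounds with no pKa
#' take any record directly as S0. Compounds with more than
#' \code{maxRelevantPkas} relevant pKa's at the chosen pH are discarded.
#'
#' @param model the compound's \linkS4class{IonizationModel}.
#' @param records this compound's filtered records (rows at pH 2 / pH 7).
#' @param config a \code{\link{curationConfig}}.
#' @return list with \code{action} ("derive", "direct" or "discard"),
#'   \code{ph} (the chosen derivation pH, NA when discarded/direct),
#'   \code{records} (the rows used) and \code{reason} for discards.
#' @export
selectDerivationRecord <- function(model, records, config = curationConfig()) {
  na <- length(acidicPkas(model)); nb <- length(basicPkas(model))
  discard <- function(reason) list(action = "discard", ph = NA_real_,
                                   records = records[0, , drop = FALSE],
                                   reason = reason)
  if (nrow(records) == 0) return(discard("no_record"))
  if (na == 0 && nb == 0) {
    return(list(action = "direct", ph = NA_real_, records = records, reason = ""))
  }
  if (na > 0 && nb > 0) {
    gap <- .pkaGap(model)
    if (gap <= config$zwitterionGap) return(discard("zwitterion"))
    mid <- (min(acidicPkas(model)) + max(basicPkas(model))) / 2
    phs <- sort(unique(records$ph))
    # closest available pH to the midpoint; ties take the lower pH
    chosenPh <- phs[which.min(abs(phs - mid))]
  } else if (na > 0) {
    chosenPh <- 2
  } else {
    chosenPh <- 7
  }
  rows <- records[records$ph == chosenPh, , drop = FALSE]
  if (nrow(rows) == 0) return(discard(sprintf("missing_ph%g_record", chosenPh)))
  rel <- relevantPkas(model, chosenPh, config$relevanceThreshold)
  if (rel$nRelevant > config$maxRelevantPkas) return(discard("too_many_relevant_pkas"))
  list(action = "derive", ph = chosenPh, records = rows, reason = "")
}

#' Derive S0 from one chosen record
#'
#' @param model the compound's \linkS4class{IonizationModel}.
#' @param record one record row (with \code{log_s} and \code{ph}).
#' @param direct logical; TRUE for no-pKa compounds whose measured value is
#'   taken as S0 without back-calculation.
#' @param config a \code{\link{curationConfig}}.
#' @return log10 molar intrinsic solubility.
#' @export
deriveS0 <- function(model, record, direct = FALSE, config = curationConfig()) {
  if (direct) return(record$log_s)
  intrinsicFromMeasured(record$log_s, model, record$ph, config$relevanceThreshold)
}

#' Merge duplicate S0 values for one compound
#'
#' If the spread (max - min) is below the duplicate threshold the smallest
#' solubility is kept (assumed most stable polymorph); otherwise the
#' compound is dropped.
#'
#' @param values numeric S0 values (>= 1).
#' @param config a \code{\link{curationConfig}}.
#' @return list with \code{value} (numeric or NA) and \code{dropped}.
#' @export
mergeDuplicates <- function(values, config = curationConfig()) {
  stopifnot(length(values) >= 1)
  if (length(values) == 1L) return(list(value = values, dropped = FALSE))
  if (max(values) - min(values) < config$duplicateThreshold)
    list(value = min(values), dropped = FALSE)
  else
    list(value = NA_real_, dropped = TRUE)
}

#' High-quality flag for a compound's derivation records
#'
#' TRUE when every record used for derivation is crystalline, uncensored
#' and has replicate spread at or below the tolerance: the subset on which
#' test-set S0 performance is evaluated.
#'
#' @param records the rows used for this compound's S0.
#' @param tolerance replicate-spread tolerance, log units.
#' @return logical scalar.
#' @export
flagHighQuality <- function(records, tolerance = 0.5) {
  nrow(records) > 0 &&
    all(records$solid_state == "crystalline") &&
    all(records$censored == "none") &&
    all(records$replicate_spread <= tolerance)
}

#' Curate raw assay records into an S0 dataset
#'
#' Runs the full step-1 pipeline: record filtering, per-compound pH
#' selection, Henderson-Hasselbalch back-calculation, duplicate merging
#' and high-quality flagging. Output order follows the compound table.
#'
#' @param records raw records data.frame (see \code{\link{filterRecords}}).
#' @param compounds compound table with \code{compound_id}, \code{smiles},
#'   \code{is_salt}, \code{acidic_pkas}, \code{basic_pkas}.
#' @param config a \code{\link{curationConfig}}.
#' @return list with \code{s0} (data.frame: compound_id, smiles,
#'   log_s0_molar, high_quality) and \code{discarded} (data.frame:
#'   compound_id, reason).
#' @export
curateS0 <- function(records, compounds, config = curationConfig()) {
  filtered <- filterRecords(records, compounds, config)
  out <- vector("list", nrow(compounds))
  disc <- vector("list", nrow(compounds))
  for (i in seq_len(nrow(compounds))) {
    cmp <- compounds[i, , drop = FALSE]
    model <- compoundIonization(cmp)
    rows <- filtered[filtered$compound_id == cmp$compound_id, , drop = FALSE]
    sel <- selectDerivationRecord(model, rows, config)
    if (sel$action == "discard") {
      disc[[i]] <- data.frame(compound_id = cmp$compound_id, reason = sel$reason)
      next
    }
    s0s <- vapply(seq_len(nrow(sel$records)), function(k)
      deriveS0(model, sel$records[k, , drop = FALSE],
               direct = sel$action == "direct", config = config),
      numeric(1))
    merged <- mergeDuplicates(s0s, config)
    if (merged$dropped) {
      disc[[i]] <- data.frame(compound_id = cmp$compound_id, reason = "duplicate_disagreement")
      next
    }
    out[[i]] <- data.frame(
      compound_id = cmp$compound_id, smiles = cmp$smiles,
      log_s0_molar = merged$value,
      high_quality = flagHighQuality(sel$records, config$hqSpreadTol))
  }
  list(s0 = do.call(rbind, c(out[!vapply(out, is.null, logical(1))],
                             list(make.row.names = FALSE))),
       discarded = do.call(rbind, c(disc[!vapply(disc, is.null, logical(1))],
                                    list(make.row.names = FALSE))))
}

#' Build the merged eight-task table
#'
#' Outer union over compounds of the per-task datasets; the observation
#' mask records availability and missing entries are never imputed.
#'
#' @param taskSets named list of data.frames, one per task in
#'   \code{\link{taskNames}()} (tasks may be absent), each with columns
#'   \code{compound_id} and \code{value}; the \code{S0} frame may also
#'   carry \code{high_quality}.
#' @return a \linkS4class{TaskTable}.
#' @export
buildTaskTable <- function(taskSets) {
  tn <- taskNames()
  unknown <- setdiff(names(taskSets), tn)
  if (length(unknown)) stop("unknown task names: ", paste(unknown, collapse = ", "))
  for (nm in names(taskSets)) {
    ids <- taskSets[[nm]]$compound_id
    if (anyDuplicated(ids))
      stop("conflicting duplicates within task '", nm, "' after merging")
  }
  allIds <- unique(unlist(lapply(taskSets, function(d) d$compound_id)))
  vals <- matrix(NA_real_, length(allIds), length(tn),
                 dimnames = list(allIds, tn))
  obs <- matrix(FALSE, length(allIds), length(tn), dimnames = list(allIds, tn))
  for (nm in names(taskSets)) {
    d <- taskSets[[nm]]
    vals[d$compound_id, nm] <- d$value
    obs[d$compound_id, nm] <- TRUE
  }
  hq <- setNames(rep(FALSE, length(allIds)), allIds)
  if (!is.null(taskSets$S0) && !is.null(taskSets$S0$high_quality))
    hq[taskSets$S0$compound_id] <- as.logical(taskSets$S0$high_quality)
  new("TaskTable", values = vals, observed = obs, highQuality = unname(hq))
}
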