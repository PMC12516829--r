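# Stratified splitting on the high-quality flag, RMSE / R2 metrics, and
# the multi-trial mean (SD) reporting protocol. S0 performance is always
# reported on the high-quality members of the test set only.

#' Stratified train/validation/test split
#'
#' High-quality and ordinary compounds are each split at the given
#' fractions (validation and test counts rounded, remainder to train), so
#' high-quality S0 data is represented proportionally in all three sets.
#'
#' @param n number of compounds.
#' @param hqFlags logical length-n high-quality flags (the stratum).
#' @param fractions train/val/test fractions summing to 1.
#' @param seed RNG seed.
#' @return list with integer index vectors \code{train}, \code{val},
#'   \code{test} and the \code{seed}; disjoint, union = 1..n.
#' @export
stratifiedSplit <- function(n, hqFlags, fractions = c(0.70, 0.15, 0.15),
                            seed = 0L) {
  stopifnot(length(hqFlags) == n, abs(sum(fractions) - 1) < 1e-9,
            all(fractions >= 0))
  set.seed(seed)
  out <- list(train = integer(0), val = integer(0), test = integer(0))
  for (stratum in list(which(hqFlags), which(!hqFlags))) {
    m <- length(stratum)
    if (m == 0) next
    if (m < 3) {
      warning("stratum with ", m, " member(s): assigned entirely to train")
      out$train <- c(out$train, stratum)
      next
    }
    perm <- stratum[sample.int(m)]
    nVal <- round(m * fractions[2])
    nTest <- round(m * fractions[3])
    out$val <- c(out$val, perm[seq_len(nVal)])
    out$test <- c(out$test, perm[nVal + seq_len(nTest)])
    nHeld <- nVal + nTest
    out$train <- c(out$train, perm[seq_len(m - nHeld) + nHeld])
  }
  lapply(out, sort)
  list(train = sort(out$train), val = sort(out$val), test = sort(out$test),
       seed = seed)
}

#' Root mean squared error
#' @param y,yhat numeric vectors of equal length.
#' @return non-negative scalar.
#' @export
rmse <- function(y, yhat) {
  stopifnot(length(y) == length(yhat), length(y) >= 1)
  sqrt(mean((y - yhat)^2))
}

#' Coefficient of determination
#'
#' \eqn{R^2 = 1 - SS_{res}/SS_{tot}}; errors on zero-variance \code{y}.
#' @inheritParams rmse
#' @return scalar, at most 1.
#' @export
r2 <- function(y, yhat) {
  stopifnot(length(y) == length(yhat), length(y) >= 2)
  sstot <- sum((y - mean(y))^2)
  if (sstot == 0) stop("r2 undefined for zero-variance y")
  1 - sum((y - yhat)^2) / sstot
}

#' Repeated-split training protocol
#'
#' Runs \code{nTrials} independent split/train/evaluate cycles and reports
#' the per-metric mean and sample standard deviation (n-1 denominator).
#' Each trial: stratified 70/15/15 split on the high-quality flag, model
#' training, then S0 RMSE / R2 on the high-quality members of the test set
#' only, plus all-task RMSE over observed test entries.
#'
#' @param taskTable a \linkS4class{TaskTable}.
#' @param graphs list of \linkS4class{MolecularGraph}, parallel to rows.
#' @param config a \code{\link{modelConfig}}.
#' @param nTrials number of trials (>= 2).
#' @param seeds split seeds, one per trial.
#' @return list with \code{trials} (data.frame: seed, s0_rmse, s0_r2,
#'   n_eval, per-task RMSEs), \code{mean}, \code{sd} and \code{formatted}
#'   ("mean (sd)" strings).
#' @export
runTrials <- function(taskTable, graphs, config = modelConfig(),
                      nTrials = 5L, seeds = seq_len(nTrials)) {
  stopifnot(nTrials >= 2, length(seeds) == nTrials)
  hq <- highQuality(taskTable)
  targets <- taskValues(taskTable)
  observed <- observedMask(taskTable)
  rows <- vector("list", nTrials)
  for (i in seq_len(nTrials)) {
    sp <- stratifiedSplit(nrow(targets), hq, seed = seeds[i])
    fit <- trainGraphSolModel(taskTable, graphs, sp, config)
    preds <- predictTasks(fit$model, graphs[sp$test])
    testHq <- hq[sp$test] & observed[sp$test, "S0"]
    yS0 <- targets[sp$test, "S0"][testHq]
    pS0 <- preds[, "S0"][testHq]
    perTask <- vapply(taskNames(), function(tk) {
      o <- observed[sp$test, tk]
      if (sum(o) == 0) NA_real_ else rmse(targets[sp$test, tk][o], preds[o, tk])
    }, numeric(1))
    rows[[i]] <- data.frame(seed = seeds[i],
                            s0_rmse = if (length(yS0)) rmse(yS0, pS0) else NA_real_,
                            s0_r2 = if (length(yS0) >= 2) r2(yS0, pS0) else NA_real_,
                            n_eval = sum(testHq),
                            t(perTask))
  }
  trials <- do.call(rbind, rows)
  metrics <- setdiff(names(trials), c("seed", "n_eval"))
  mu <- vapply(trials[metrics], mean, numeric(1))
  sdv <- vapply(trials[metrics], stats::sd, numeric(1))
  list(trials = trials, mean = mu, sd = sdv,
       formatted = sprintf("%.2f (%.2f)", mu, sdv) |> setNames(metrics))
}

#' Write a trial report as CSV plus a text table
#'
#' @param report result of \code{\link{runTrials}}.
#' @param csvPath,txtPath output paths (NULL to skip either).
#' @export
writeTrialReport <- function(report, csvPath = NULL, txtPath = NULL) {
  if (!is.null(csvPath))
    utils::write.csv(report$trials, csvPath, row.names = FALSE)
  if (!is.null(txtPath)) {
    con <- file(txtPath, "w")
    on.exit(close(con))
    writeLines(c("metric\tRMSE (std)",
                 paste(names(report$formatted), report$formatted, sep = "\t")),
               con)
  }
  invisible(report)
}
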