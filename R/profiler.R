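# pH 0-12 solubility profiles from (predicted or derived) S0 and pKa's.
# At each grid point the relevance filter runs first; points where more
# than three pKa's are simultaneously relevant are left undetermined.

#' Compute a pH-solubility profile
#'
#' @param logS0 intrinsic solubility, log10 molar.
#' @param model an \linkS4class{IonizationModel}.
#' @param step grid step in pH units (default 0.1).
#' @param phRange profile limits (default 0 to 12).
#' @param threshold pKa relevance threshold.
#' @return a \linkS4class{SolubilityProfile}.
#' @examples
#' computeProfile(-6, IonizationModel(acidic = 4))
#' @export
computeProfile <- function(logS0, model, step = 0.1, phRange = c(0, 12),
                           threshold = 0.01) {
  stopifnot(step > 0, is.finite(logS0))
  grid <- seq(phRange[1], phRange[2], by = step)
  logS <- rep(NA_real_, length(grid))
  undet <- logical(length(grid))
  for (i in seq_along(grid)) {
    rel <- relevantPkas(model, grid[i], threshold)
    if (rel$nRelevant > 3L) {
      undet[i] <- TRUE
    } else {
      logS[i] <- logS0 + .logPhiExact(acidicPkas(rel$model),
                                      basicPkas(rel$model), grid[i])
    }
  }
  new("SolubilityProfile", phGrid = grid, logS = logS,
      undetermined = undet, logS0 = logS0)
}

#' Offset statistics between two profiles
#'
#' For two profiles of the same compound (same pKa's, same grid) the
#' pointwise difference is constant and equal to the difference of the two
#' S0 values; the reported max deviation from constancy quantifies how
#' exactly that holds.
#'
#' @param a,b \linkS4class{SolubilityProfile} objects on the same grid.
#' @return list with \code{meanOffset} and \code{maxDeviation} (max
#'   absolute departure of the pointwise difference from its mean).
#' @export
profileOffset <- function(a, b) {
  if (!isTRUE(all.equal(phGrid(a), phGrid(b))))
    stop("profiles must share the same pH grid")
  joint <- !undetermined(a) & !undetermined(b)
  if (!any(joint)) stop("profiles have no jointly determined points")
  d <- profileLogS(a)[joint] - profileLogS(b)[joint]
  list(meanOffset = mean(d), maxDeviation = max(abs(d - mean(d))))
}

#' Evaluate predicted S0 against derived S0 over a cohort
#'
#' For test compounds measured at both pH 2 and pH 7, compares the
#' model-predicted S0 with the assay-derived S0, reports the RMSE and the
#' error quantiles, and emits per-compound profile pairs plus the two
#' measured points for plotting.
#'
#' @param cohort data.frame with columns \code{compound_id},
#'   \code{log_s0_pred}, \code{log_s0_derived}, \code{acidic_pkas},
#'   \code{basic_pkas} (semicolon-separated), \code{log_s_ph2},
#'   \code{log_s_ph7}.
#' @param step profile grid step.
#' @return list with \code{perCompound} (data.frame adding
#'   \code{abs_error}), \code{rmse}, \code{q75} (75th percentile of
#'   absolute error), \code{fractionBelowQ75} and \code{profiles} (named
#'   list of \code{pred}/\code{derived} profile pairs).
#' @export
evaluateProfiles <- function(cohort, step = 0.1) {
  stopifnot(all(c("compound_id", "log_s0_pred", "log_s0_derived",
                  "acidic_pkas", "basic_pkas", "log_s_ph2", "log_s_ph7")
                %in% names(cohort)))
  err <- cohort$log_s0_pred - cohort$log_s0_derived
  absErr <- abs(err)
  q75 <- unname(stats::quantile(absErr, 0.75, type = 7))
  profiles <- lapply(seq_len(nrow(cohort)), function(i) {
    model <- IonizationModel(acidic = .parsePkas(cohort$acidic_pkas[i]),
                             basic = .parsePkas(cohort$basic_pkas[i]))
    list(pred = computeProfile(cohort$log_s0_pred[i], model, step),
         derived = computeProfile(cohort$log_s0_derived[i], model, step),
         measured = data.frame(ph = c(2, 7),
                               log_s = c(cohort$log_s_ph2[i],
                                         cohort$log_s_ph7[i])))
  })
  names(profiles) <- cohort$compound_id
  list(perCompound = cbind(cohort, abs_error = absErr),
       rmse = sqrt(mean(err^2)), q75 = q75,
       fractionBelowQ75 = mean(absErr <= q75), profiles = profiles)
}

#' Plot profile pairs with their measured points
#'
#' Line profiles from predicted and derived S0 plus the two measured
#' assay points per compound, one panel per compound.
#'
#' @param profiles named list of \code{pred}/\code{derived}/\code{measured}
#'   entries as produced by \code{\link{evaluateProfiles}}.
#' @param file optional device file (pdf or png by extension); NULL plots
#'   to the active device.
#' @param ncol panels per row.
#' @export
plotProfiles <- function(profiles, file = NULL, ncol = 3) {
  if (!is.null(file)) {
    if (grepl("\\.png$", file)) grDevices::png(file, 1200, 900)
    else grDevices::pdf(file, width = 10, height = 7.5)
  }
  n <- length(profiles)
  op <- graphics::par(mfrow = c(ceiling(n / ncol), min(n, ncol)),
                      mar = c(4, 4, 2, 1))
  # restore par while the device is still open, then close it
  on.exit({
    graphics::par(op)
    if (!is.null(file)) grDevices::dev.off()
  })
  for (id in names(profiles)) {
    p <- profiles[[id]]
    ylim <- range(profileLogS(p$pred), profileLogS(p$derived),
                  p$measured$log_s, na.rm = TRUE)
    plot(phGrid(p$derived), profileLogS(p$derived), type = "l", lwd = 2,
         xlab = "pH", ylab = "log S (molar)", main = id, ylim = ylim)
    graphics::lines(phGrid(p$pred), profileLogS(p$pred), lwd = 2, lty = 2,
                    col = "steelblue")
    graphics::points(p$measured$ph, p$measured$log_s, pch = 19,
                     col = "firebrick", cex = 1.2)
    graphics::legend("topleft", bty = "n", cex = 0.8,
                     legend = c("derived S0", "predicted S0", "measured"),
                     lty = c(1, 2, NA), pch = c(NA, NA, 19),
                     col = c("black", "steelblue", "firebrick"))
  }
  invisible(profiles)
}

#' Write profile pairs as CSV
#'
#' Long format: compound_id, ph, log_s_predicted, log_s_derived,
#' undetermined; undetermined points serialize as empty fields.
#'
#' @param profiles the \code{profiles} element of
#'   \code{\link{evaluateProfiles}}, or a named list of
#'   \code{pred}/\code{derived} pairs.
#' @param path output CSV path.
#' @export
writeProfilesCsv <- function(profiles, path) {
  rows <- lapply(names(profiles), function(id) {
    p <- profiles[[id]]
    undet <- undetermined(p$pred) | undetermined(p$derived)
    data.frame(compound_id = id, ph = phGrid(p$pred),
               log_s_predicted = ifelse(undet, NA, profileLogS(p$pred)),
               log_s_derived = ifelse(undet, NA, profileLogS(p$derived)),
               undetermined = as.integer(undet))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, na = "")
  invisible(path)
}
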