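# Synthetic assay generator: drug-like compounds with class-controlled
# ionization, true intrinsic solubilities, and censored noisy pH 2 / pH 7
# records with solid-state labels, salts and duplicates -- the statistical
# structure the curation pipeline assumes, so every stage is testable
# without proprietary data.
#
# SMILES are drawn from a vetted internal list of parseable drug-like
# scaffolds per class; pKa lists are assigned from the class, not
# perceived from the structure (documented limitation).

.scaffolds <- list(
  neutral = c(
    "CC(=O)Nc1ccc(OC)cc1", "COc1ccc(CCOC(C)=O)cc1",
    "Cn1cnc2c1c(=O)n(C)c(=O)n2C", "CC(C)OC(=O)c1ccccc1",
    "c1ccc(COc2ccccc2)cc1", "CCOC(=O)C1CCN(C(C)=O)CC1",
    "COc1ccc2cc(C(C)=O)ccc2c1", "CC1(C)OC(=O)c2ccccc2O1"),
  acid = c(
    "CC(C)Cc1ccc(cc1)C(C)C(=O)O", "CC(=O)Oc1ccccc1C(=O)O",
    "OC(=O)c1ccccc1Nc1ccccc1", "Oc1ccc(Cl)cc1C(=O)O",
    "CCCCc1ccc(cc1)C(=O)O", "OC(=O)COc1ccc2ccccc2c1",
    "CC1(C)SC2C(NC(=O)Cc3ccccc3)C(=O)N2C1C(=O)O"),
  base = c(
    "CN1CCC(CC1)c1ccccc1", "CCN(CC)CCNC(=O)c1ccc(N)cc1",
    "CN(C)CCCN1c2ccccc2CCc2ccccc21", "NCCc1ccccc1OC",
    "CN1CCN(CC1)c1ccccc1Cl", "CCN1CCCC1CNC(=O)c1ccccc1OC"),
  ampholyte = c(
    "NCCc1ccc(O)c(O)c1", "Nc1ccc(cc1)C(=O)OCCN",
    "OC(=O)c1ccccc1NCCN1CCCC1", "NCCCCC(N)C(=O)Oc1ccccc1",
    "OC(=O)c1cn(C2CC2)c2cc(N3CCNCC3)ccc2c1=O"),
  zwitterion = c(
    "NCC(=O)O", "NC(CC(=O)O)c1ccccc1", "OC(=O)C1CCCN1",
    "NCCCC(N)C(=O)O", "OC(=O)Cc1c[nH]c2ccccc12"))

# substituent prefixes used to diversify scaffolds into unique compounds;
# each is a valid SMILES prefix whose terminal atom bonds to the scaffold's
# first atom (ethers, halogens, nitrile, alkene, thioether, branched alkyl)
.decorations <- c("", "C", "CC", "CCC", "CC(C)", "CCCC", "OCC", "COCC",
                  "FC(F)(F)C", "ClCC", "BrCC", "C=CC", "N#CC", "OC(C)C",
                  "CSCC", "CC(C)(C)C")

#' Synthetic-data generator configuration
#'
#' Defaults describe the assay the generator emulates: pH 2 / pH 7
#' high-throughput solubility with a 0.1-600 uM dynamic range, analytical
#' noise of 0.3 log units, a mixed ionization-class population, and a
#' sparse eight-task target table.
#'
#' @param nCompounds number of compounds.
#' @param seed RNG seed; all draws are reproducible from it.
#' @param classMix named fractions (summing to 1) of
#'   neutral/acid/base/ampholyte/zwitterion compounds.
#' @param s0Mean,s0Sd true log10 molar S0 distribution (normal).
#' @param noiseSd per-replicate measurement noise, log units.
#' @param duplicateRate probability a compound-pH pair gets a second
#'   independent record.
#' @param saltRate fraction of compounds flagged as salt forms.
#' @param amorphousRate probability a record's residual solid is labelled
#'   non-crystalline (amorphous or unknown).
#' @param taskSparsity named observed fractions for the seven planted
#'   tasks (S0 availability comes from curation, not from this knob).
#' @return named list of class \code{GeneratorConfig}.
#' @export
generatorConfig <- function(nCompounds = 500L, seed = 0L,
                            classMix = c(neutral = 0.25, acid = 0.25,
                                         base = 0.25, ampholyte = 0.15,
                                         zwitterion = 0.10),
                            s0Mean = -5, s0Sd = 1.2, noiseSd = 0.3,
                            duplicateRate = 0.2, saltRate = 0.05,
                            amorphousRate = 0.1,
                            taskSparsity = c(sol_pH2 = 0.9, sol_pH7 = 0.9,
                                             sol_fassif = 0.5, logP = 0.7,
                                             `logD_2.6` = 0.4,
                                             `logD_7.4` = 0.6,
                                             `logD_10.5` = 0.4)) {
  stopifnot(abs(sum(classMix) - 1) < 1e-9, all(classMix >= 0),
            all(c(duplicateRate, saltRate, amorphousRate) >= 0),
            all(c(duplicateRate, saltRate, amorphousRate) <= 1),
            noiseSd >= 0, s0Sd > 0, nCompounds >= 1,
            all(taskSparsity >= 0 & taskSparsity <= 1))
  structure(list(nCompounds = as.integer(nCompounds), seed = as.integer(seed),
                 classMix = classMix, s0Mean = s0Mean, s0Sd = s0Sd,
                 noiseSd = noiseSd, duplicateRate = duplicateRate,
                 saltRate = saltRate, amorphousRate = amorphousRate,
                 taskSparsity = taskSparsity),
            class = "GeneratorConfig")
}

# class-consistent pKa draws; acid/base U[2,11], ampholytes constructed
# with gap > 2 and zwitterions with gap <= 2
.drawPkas <- function(class) {
  switch(class,
    neutral = list(acidic = numeric(0), basic = numeric(0)),
    acid = list(acidic = sort(stats::runif(sample(1:2, 1), 2, 11)),
                basic = numeric(0)),
    base = list(acidic = numeric(0),
                basic = sort(stats::runif(sample(1:2, 1), 2, 11),
                             decreasing = TRUE)),
    ampholyte = {
      b <- sort(stats::runif(sample(1:2, 1), 2, 8), decreasing = TRUE)
      aMin <- max(b) + 2 + stats::runif(1, 0.5, 3)
      nA <- sample(1:2, 1)
      list(acidic = sort(c(aMin, if (nA == 2) aMin + stats::runif(1, 0.5, 2))),
           basic = b)
    },
    zwitterion = {
      b <- stats::runif(1, 3, 10)
      list(acidic = b + stats::runif(1, -2, 2), basic = b)
    },
    stop("unknown class: ", class))
}

#' Generate synthetic compounds and their true intrinsic solubilities
#'
#' Class counts are exact (rounded from the configured mix); pKa's, salt
#' flags and true S0 values are drawn from the seeded generator. Every
#' compound gets a unique structure: each class's scaffolds are combined
#' with a panel of chemically varied substituent prefixes and, beyond
#' that, growing alkyl chains (always parseable, deterministic per class
#' index). True S0 is planted partly linear in
#' molecular size (larger molecules are less soluble) with a normal
#' residual, so the marginal distribution stays N(s0Mean, s0Sd) while the
#' structure carries learnable signal.
#'
#' @param config a \code{\link{generatorConfig}}.
#' @return list with \code{compounds} (data.frame: compound_id, smiles,
#'   is_salt, acidic_pkas, basic_pkas, class) and \code{trueS0} (named
#'   numeric).
#' @export
generateCompounds <- function(config = generatorConfig()) {
  set.seed(config$seed)
  n <- config$nCompounds
  counts <- diff(c(0, round(cumsum(config$classMix) * n)))
  classes <- sample(rep(names(config$classMix), counts))
  ids <- sprintf("CPD%05d", seq_len(n))
  classIdx <- stats::ave(seq_len(n), classes, FUN = seq_along)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    cls <- classes[i]
    pool <- .scaffolds[[cls]]
    j <- classIdx[i] - 1L
    scaffold <- pool[j %% length(pool) + 1L]
    k <- j %/% length(pool)
    deco <- .decorations[k %% length(.decorations) + 1L]
    cyc <- k %/% length(.decorations)   # homolog growth past the panel
    chain <- if (cyc > 0) paste0("C(", strrep("C", cyc), ")") else ""
    pk <- .drawPkas(cls)
    rows[[i]] <- data.frame(
      compound_id = ids[i],
      smiles = paste0(chain, deco, scaffold),
      is_salt = stats::runif(1) < config$saltRate,
      acidic_pkas = .pkaString(pk$acidic),
      basic_pkas = .pkaString(pk$basic),
      class = cls)
  }
  compounds <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  size <- .sizeProxy(compounds$smiles)
  sizeZ <- if (n > 1 && isTRUE(stats::sd(size) > 0))
    (size - mean(size)) / stats::sd(size) else rep(0, n)
  rho <- 0.8   # fraction of S0 spread carried by molecular size
  trueS0 <- config$s0Mean - rho * config$s0Sd * sizeZ +
    sqrt(1 - rho^2) * config$s0Sd * stats::rnorm(n)
  names(trueS0) <- ids
  list(compounds = compounds, trueS0 = trueS0)
}

# log Phi with the relevance filter and 3-pKa cap applied (never errors;
# compounds exceeding the cap are later discarded by curation anyway)
.cappedLogPhi <- function(model, ph, threshold = 0.01) {
  rel <- relevantPkas(model, ph, threshold)
  .logPhiExact(acidicPkas(rel$model), basicPkas(rel$model), ph)
}

#' Simulate assay records for generated compounds
#'
#' For each compound and pH in {2, 7}: the true solubility from the
#' speciation forward map plus one N(0, noiseSd) measurement error;
#' a second independent replicate draw sets the reported analytical
#' spread; censoring against the 0.1-600 uM window, solid-state labels
#' and duplicate records at the configured rates. RNG state continues from \code{\link{generateCompounds}}; call
#' \code{simulateDataset} for a fully seeded end-to-end draw.
#'
#' @param compounds,trueS0 output of \code{\link{generateCompounds}}.
#' @param config a \code{\link{generatorConfig}}.
#' @param assayLo,assayHi dynamic range, molar.
#' @return records data.frame as consumed by \code{\link{curateS0}}.
#' @export
simulateMeasurements <- function(compounds, trueS0,
                                 config = generatorConfig(),
                                 assayLo = 0.1e-6, assayHi = 600e-6) {
  lo <- log10(assayLo); hi <- log10(assayHi)
  rows <- list()
  for (i in seq_len(nrow(compounds))) {
    id <- compounds$compound_id[i]
    model <- compoundIonization(compounds[i, , drop = FALSE])
    for (ph in c(2, 7)) {
      truth <- trueS0[[id]] + .cappedLogPhi(model, ph)
      nRec <- 1L + (stats::runif(1) < config$duplicateRate)
      for (r in seq_len(nRec)) {
        # the record value is one draw at the full noise sd; the second
        # replicate only informs the reported analytical spread
        reps <- truth + stats::rnorm(2, 0, config$noiseSd)
        val <- reps[1]
        censored <- if (val < lo) "below_lo" else if (val > hi) "above_hi" else "none"
        solid <- if (stats::runif(1) < config$amorphousRate)
          sample(c("amorphous", "unknown"), 1) else "crystalline"
        rows[[length(rows) + 1L]] <- data.frame(
          compound_id = id, ph = ph,
          log_s = min(max(val, lo), hi),
          solid_state = solid, censored = censored,
          replicate_spread = abs(reps[1] - reps[2]))
      }
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

# crude molecular-size proxy used by the planted logP/logD structure
.sizeProxy <- function(smiles) nchar(gsub("[^A-Za-z]", "", smiles))

#' Simulate a complete dataset: compounds, records and planted task sets
#'
#' Planted targets for the seven non-S0 tasks: pH 2 / pH 7 / FaSSIF
#' solubilities follow the speciation physics (FaSSIF with a constant
#' biorelevant solubilization lift), and logP/logD are noisy linear
#' functions of the true S0 and a molecular-size proxy -- a planted linear
#' structure sufficient for multi-task learning tests, not partition
#' physics. Each task observes exactly round(n * sparsity) compounds.
#'
#' @param config a \code{\link{generatorConfig}}.
#' @return list with \code{compounds}, \code{records}, \code{taskSets}
#'   (per-task data.frames for \code{\link{buildTaskTable}}),
#'   \code{trueS0} and the \code{config}.
#' @export
simulateDataset <- function(config = generatorConfig()) {
  gen <- generateCompounds(config)
  records <- simulateMeasurements(gen$compounds, gen$trueS0, config)
  n <- nrow(gen$compounds)
  ids <- gen$compounds$compound_id
  size <- .sizeProxy(gen$compounds$smiles)
  s0 <- gen$trueS0
  noise <- function() stats::rnorm(n, 0, config$noiseSd)
  # measured-solubility tasks are reported within the assay dynamic range
  window <- function(x) pmin(pmax(x, log10(0.1e-6)), log10(600e-6))
  planted <- list(
    sol_pH2 = window(vapply(seq_len(n), function(i)
      s0[i] + .cappedLogPhi(compoundIonization(gen$compounds[i, ]), 2),
      numeric(1)) + noise()),
    sol_pH7 = window(vapply(seq_len(n), function(i)
      s0[i] + .cappedLogPhi(compoundIonization(gen$compounds[i, ]), 7),
      numeric(1)) + noise()),
    sol_fassif = s0 + 0.8 + noise(),
    logP = -0.9 * s0 - 1.5 + 0.05 * size + noise(),
    `logD_2.6` = -0.8 * s0 - 2.0 + 0.05 * size + noise(),
    `logD_7.4` = -0.85 * s0 - 1.2 + 0.04 * size + noise(),
    `logD_10.5` = -0.75 * s0 - 1.8 + 0.03 * size + noise())
  taskSets <- lapply(names(planted), function(nm) {
    k <- round(n * config$taskSparsity[[nm]])
    keep <- sort(sample.int(n, k))
    data.frame(compound_id = ids[keep], value = unname(planted[[nm]][keep]))
  })
  names(taskSets) <- names(planted)
  list(compounds = gen$compounds, records = records, taskSets = taskSets,
       trueS0 = gen$trueS0, config = config)
}

#' Write a simulated dataset in the assay CSV dialect
#'
#' One row per record with the compound-level columns repeated, as read
#' back by \code{\link{readAssayCsv}}.
#'
#' @param sim output of \code{\link{simulateDataset}}.
#' @param path output CSV path.
#' @export
writeAssayCsv <- function(sim, path) {
  cmp <- sim$compounds[match(sim$records$compound_id,
                             sim$compounds$compound_id), ]
  out <- data.frame(compound_id = sim$records$compound_id,
                    smiles = cmp$smiles,
                    ph = sim$records$ph,
                    log_s_molar = sim$records$log_s,
                    solid_state = sim$records$solid_state,
                    censored = sim$records$censored,
                    is_salt = as.integer(cmp$is_salt),
                    acidic_pkas = cmp$acidic_pkas,
                    basic_pkas = cmp$basic_pkas,
                    replicate_spread = sim$records$replicate_spread)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
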