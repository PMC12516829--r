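# Command-line entry point tying the stages together:
# simulate -> curate -> train -> predict -> profile -> evaluate.
# Thin argument handling over the package functions; every subcommand
# logs its parameters, row counts and seed, and returns an exit code.

.usage <- function() {
  paste(
    "usage: graphsol <subcommand> [options]",
    "",
    "subcommands:",
    "  simulate  --n N --seed S --out DIR        synthetic assay + task data",
    "  curate    --in assay.csv --out DIR        S0 dataset + task table",
    "            [--tasks task_sets.csv]",
    "  train     --tasks task_table.csv --compounds compounds.csv",
    "            --out model.rds [--seed S] [--epochs E] [--hidden H]",
    "            [--layers L] [--gamma G]",
    "  predict   --model model.rds --compounds compounds.csv --out preds.csv",
    "  profile   --in s0.csv --out profiles.csv [--step S]",
    "  evaluate  --pred preds.csv --s0 s0.csv --out metrics.csv",
    "  --help                                    this message",
    sep = "\n")
}

.parseFlags <- function(args) {
  flags <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--"))
      stop("unexpected argument: ", a, call. = FALSE)
    if (i == length(args) || startsWith(args[i + 1L], "--"))
      stop("flag ", a, " needs a value", call. = FALSE)
    flags[[substring(a, 3)]] <- args[i + 1L]
    i <- i + 2L
  }
  # a YAML config file supplies defaults; explicit flags override it
  if (!is.null(flags$config)) {
    # keep y/n-style keys (e.g. the "n" flag) as strings, not booleans
    keep <- list("bool#yes" = function(x) x, "bool#no" = function(x) x)
    cfg <- yaml::read_yaml(flags$config, handlers = keep)
    for (nm in names(cfg))
      if (is.null(flags[[nm]])) flags[[nm]] <- as.character(cfg[[nm]])
    flags$config <- NULL
  }
  flags
}

.need <- function(flags, nm) {
  if (is.null(flags[[nm]])) stop("missing required flag --", nm, call. = FALSE)
  flags[[nm]]
}

.log <- function(...) message("[graphsol] ", ...)

.cmdSimulate <- function(flags) {
  n <- as.integer(.need(flags, "n"))
  seed <- as.integer(.need(flags, "seed"))
  out <- .need(flags, "out")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  cfg <- generatorConfig(nCompounds = n, seed = seed)
  sim <- simulateDataset(cfg)
  writeAssayCsv(sim, file.path(out, "assay.csv"))
  utils::write.csv(data.frame(compound_id = names(sim$trueS0),
                              true_log_s0 = unname(sim$trueS0)),
                   file.path(out, "true_s0.csv"), row.names = FALSE)
  long <- do.call(rbind, lapply(names(sim$taskSets), function(nm)
    cbind(task = nm, sim$taskSets[[nm]])))
  utils::write.csv(long, file.path(out, "task_sets.csv"), row.names = FALSE)
  utils::write.csv(unique(sim$compounds[c("compound_id", "smiles")]),
                   file.path(out, "compounds.csv"), row.names = FALSE)
  .log("simulate: n=", n, " seed=", seed, " records=", nrow(sim$records),
       " -> ", out)
  0L
}

.cmdCurate <- function(flags) {
  inPath <- .need(flags, "in")
  out <- .need(flags, "out")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  assay <- readAssayCsv(inPath)
  cur <- curateS0(assay$records, assay$compounds)
  writeS0Csv(cur$s0, file.path(out, "s0.csv"))
  taskSets <- list(S0 = data.frame(compound_id = cur$s0$compound_id,
                                   value = cur$s0$log_s0_molar,
                                   high_quality = cur$s0$high_quality))
  if (!is.null(flags$tasks)) {
    long <- utils::read.csv(flags$tasks, stringsAsFactors = FALSE,
                            colClasses = c(compound_id = "character"))
    .requireColumns(long, c("task", "compound_id", "value"), "task sets")
    for (nm in unique(long$task))
      taskSets[[nm]] <- long[long$task == nm, c("compound_id", "value")]
  }
  tt <- buildTaskTable(taskSets)
  writeTaskTableCsv(tt, file.path(out, "task_table.csv"))
  .log("curate: ", nrow(assay$records), " records -> ", nrow(cur$s0),
       " S0 compounds (", sum(cur$s0$high_quality), " high-quality), ",
       nrow(cur$discarded %||% data.frame()), " discarded")
  0L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.readCompoundGraphs <- function(path, ids, rwSteps) {
  cmp <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(compound_id = "character"))
  .requireColumns(cmp, c("compound_id", "smiles"), "compounds")
  missing <- setdiff(ids, cmp$compound_id)
  if (length(missing))
    stop("compounds CSV lacks SMILES for ", length(missing), " compound(s)")
  smiles <- cmp$smiles[match(ids, cmp$compound_id)]
  cfg <- molgraphFeatures(rwSteps = rwSteps)
  graphs <- lapply(smiles, buildGraph, config = cfg)
  names(graphs) <- ids
  graphs
}

.cmdTrain <- function(flags) {
  tt <- readTaskTableCsv(.need(flags, "tasks"))
  seed <- as.integer(flags$seed %||% 1L)
  cfg <- modelConfig(seed = seed,
                     maxEpochs = as.integer(flags$epochs %||% 200L),
                     hiddenDim = as.integer(flags$hidden %||% 96L),
                     nLayers = as.integer(flags$layers %||% 4L),
                     decayGamma = as.numeric(flags$gamma %||% 0.6))
  graphs <- .readCompoundGraphs(.need(flags, "compounds"), compoundIds(tt),
                                cfg$rwSteps)
  sp <- stratifiedSplit(nrow(taskValues(tt)), highQuality(tt), seed = seed)
  fit <- trainGraphSolModel(tt, graphs, sp, cfg)
  saveGraphSolModel(fit$model, .need(flags, "out"))
  .log("train: ", length(sp$train), " train / ", length(sp$val),
       " val compounds, seed=", seed, ", best epoch ", fit$bestEpoch,
       " -> ", flags$out)
  0L
}

.cmdPredict <- function(flags) {
  model <- readGraphSolModel(.need(flags, "model"))
  cmp <- utils::read.csv(.need(flags, "compounds"), stringsAsFactors = FALSE,
                         colClasses = c(compound_id = "character"))
  .requireColumns(cmp, c("compound_id", "smiles"), "compounds")
  graphs <- .readCompoundGraphs(flags$compounds, cmp$compound_id,
                                model@config$rwSteps)
  preds <- predictTasks(model, graphs)
  out <- data.frame(compound_id = cmp$compound_id, preds)
  names(out) <- c("compound_id", taskNames())
  utils::write.csv(out, .need(flags, "out"), row.names = FALSE)
  .log("predict: ", nrow(out), " compounds -> ", flags$out)
  0L
}

.cmdProfile <- function(flags) {
  df <- utils::read.csv(.need(flags, "in"), stringsAsFactors = FALSE,
                        colClasses = c(compound_id = "character"))
  .requireColumns(df, c("compound_id", "log_s0_molar"), "profile input")
  if (is.null(df$acidic_pkas)) df$acidic_pkas <- ""
  if (is.null(df$basic_pkas)) df$basic_pkas <- ""
  step <- as.numeric(flags$step %||% 0.1)
  rows <- lapply(seq_len(nrow(df)), function(i) {
    model <- IonizationModel(acidic = .parsePkas(as.character(df$acidic_pkas[i])),
                             basic = .parsePkas(as.character(df$basic_pkas[i])))
    p <- computeProfile(df$log_s0_molar[i], model, step)
    data.frame(compound_id = df$compound_id[i], ph = phGrid(p),
               log_s = ifelse(undetermined(p), NA, profileLogS(p)),
               undetermined = as.integer(undetermined(p)))
  })
  utils::write.csv(do.call(rbind, rows), .need(flags, "out"),
                   row.names = FALSE, na = "")
  .log("profile: ", nrow(df), " compounds, step=", step, " -> ", flags$out)
  0L
}

.cmdEvaluate <- function(flags) {
  preds <- utils::read.csv(.need(flags, "pred"), stringsAsFactors = FALSE,
                           colClasses = c(compound_id = "character"))
  .requireColumns(preds, c("compound_id", "S0"), "predictions")
  s0 <- utils::read.csv(.need(flags, "s0"), stringsAsFactors = FALSE,
                        colClasses = c(compound_id = "character"))
  .requireColumns(s0, c("compound_id", "log_s0_molar", "high_quality"), "s0")
  m <- merge(preds[c("compound_id", "S0")], s0, by = "compound_id")
  hq <- m$high_quality == 1
  res <- data.frame(
    subset = c("all", "high_quality"),
    n = c(nrow(m), sum(hq)),
    rmse = c(rmse(m$log_s0_molar, m$S0),
             if (sum(hq)) rmse(m$log_s0_molar[hq], m$S0[hq]) else NA),
    r2 = c(r2(m$log_s0_molar, m$S0),
           if (sum(hq) >= 2) r2(m$log_s0_molar[hq], m$S0[hq]) else NA))
  utils::write.csv(res, .need(flags, "out"), row.names = FALSE)
  .log("evaluate: n=", nrow(m), " hq=", sum(hq), " rmse(all)=",
       round(res$rmse[1], 3), " -> ", flags$out)
  0L
}

#' Command-line entry point
#'
#' Dispatches the \code{simulate}, \code{curate}, \code{train},
#' \code{predict}, \code{profile} and \code{evaluate} subcommands (see
#' \code{inst/scripts/graphsol} for the Rscript wrapper). Returns the
#' process exit code: 0 on success, 1 on a data/processing error (for
#' example a malformed CSV, reported with the offending column), 2 on
#' usage errors.
#'
#' @param argv character vector of command-line arguments.
#' @return integer exit code, invisibly.
#' @export
graphSolMain <- function(argv = commandArgs(trailingOnly = TRUE)) {
  if (length(argv) == 0) {
    message(.usage())
    return(invisible(2L))
  }
  if (argv[1] %in% c("--help", "-h", "help")) {
    cat(.usage(), "\n")
    return(invisible(0L))
  }
  sub <- argv[1]
  handler <- switch(sub,
    simulate = .cmdSimulate, curate = .cmdCurate, train = .cmdTrain,
    predict = .cmdPredict, profile = .cmdProfile, evaluate = .cmdEvaluate,
    NULL)
  if (is.null(handler)) {
    message("unknown subcommand: ", sub, "\n", .usage())
    return(invisible(2L))
  }
  code <- tryCatch({
    flags <- .parseFlags(argv[-1])
    handler(flags)
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    if (grepl("flag|argument", conditionMessage(e))) 2L else 1L
  })
  invisible(code)
}
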