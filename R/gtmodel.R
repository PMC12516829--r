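# Multi-task graph transformer: GraphGPS-style blocks that run an
# edge-conditioned (GINE-style) message-passing branch and a global
# multi-head attention branch in parallel, with the attention weights
# modulated by an exponential hop-distance decay mask, followed by a
# feed-forward stage; random-walk structural encodings enter at the input
# projection; mean-pooled graph readout feeds eight independent linear
# regression heads trained under a homoscedastic-uncertainty-weighted loss.

#' Model configuration
#'
#' @param learningRate Adam learning rate (default 0.005).
#' @param rwSteps random-walk encoding steps (default 20).
#' @param maxEpochs training epoch budget (default 200).
#' @param earlyStopPatience epochs without validation improvement before
#'   stopping (default 30).
#' @param decayGamma attention decay base, in [0, 1] (default 0.6); 1 is
#'   vanilla unmasked attention, 0 restricts attention to each node itself.
#' @param nLayers number of GPS blocks (default 4).
#' @param hiddenDim node-state width (default 96; must be divisible by
#'   \code{nHeads}).
#' @param nHeads attention heads (default 4).
#' @param batchSize minibatch size (default 16; sized for desk-scale
#'   datasets where optimization steps per epoch are the binding
#'   constraint).
#' @param seed RNG seed controlling initialization and batch order.
#' @param regularizer uncertainty-loss regularizer: \code{"kendall"}
#'   (r(s) = s/2) or \code{"robust"} (r(s) = log(1+exp(s))).
#' @return named list of class \code{ModelConfig}.
#' @export
modelConfig <- function(learningRate = 0.005, rwSteps = 20L, maxEpochs = 200L,
                        earlyStopPatience = 30L, decayGamma = 0.6,
                        nLayers = 4L, hiddenDim = 96L, nHeads = 4L,
                        batchSize = 16L, seed = 1L,
                        regularizer = c("kendall", "robust")) {
  regularizer <- match.arg(regularizer)
  stopifnot(decayGamma >= 0, decayGamma <= 1, learningRate > 0,
            maxEpochs >= 1, earlyStopPatience >= 1, nLayers >= 1,
            hiddenDim >= 1, nHeads >= 1, batchSize >= 1, rwSteps >= 1,
            hiddenDim %% nHeads == 0)
  structure(list(learningRate = learningRate, rwSteps = as.integer(rwSteps),
                 maxEpochs = as.integer(maxEpochs),
                 earlyStopPatience = as.integer(earlyStopPatience),
                 decayGamma = decayGamma, nLayers = as.integer(nLayers),
                 hiddenDim = as.integer(hiddenDim), nHeads = as.integer(nHeads),
                 batchSize = as.integer(batchSize), seed = as.integer(seed),
                 regularizer = regularizer),
            class = "ModelConfig")
}

#' Exponential decay attention mask
#'
#' \eqn{mask_{ij} = \gamma^{d(i,j)}} with \eqn{d} the hop distance;
#' disconnected pairs (infinite distance) get 0, the diagonal is 1.
#'
#' @param hopDist n x n hop-distance matrix (Inf allowed).
#' @param gamma decay base in [0, 1].
#' @return n x n symmetric mask.
#' @export
decayMask <- function(hopDist, gamma) {
  if (!is.numeric(gamma) || length(gamma) != 1 || !is.finite(gamma) ||
      gamma < 0 || gamma > 1)
    stop("gamma must be a single value in [0, 1]")
  m <- gamma^hopDist            # 0^0 = 1 keeps the diagonal at 1 for gamma = 0
  m[is.infinite(hopDist)] <- 0
  m
}

#' The trained multi-task graph transformer
#'
#' @slot params named list of weight matrices.
#' @slot lossState per-task log-variance parameters s_t (length 8).
#' @slot config the \code{\link{modelConfig}} used.
#' @slot featureDims node/edge feature dimensions the model expects.
#' @slot norm per-task target standardization (\code{mean}, \code{sd})
#'   learned from the training split; predictions are returned on the
#'   original task scales.
#' @export
setClass("GraphSolModel",
  representation(params = "list", lossState = "numeric", config = "list",
                 featureDims = "integer", norm = "list"))

setMethod("show", "GraphSolModel", function(object) {
  cfg <- object@config
  cat("GraphSolModel:", cfg$nLayers, "GPS blocks, hidden", cfg$hiddenDim,
      ",", cfg$nHeads, "heads, gamma =", cfg$decayGamma, "\n")
  cat("  tasks:", paste(taskNames(), collapse = ", "), "\n")
})

.glorot <- function(nin, nout) {
  r <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -r, r), nin, nout)
}

#' Initialize a GraphSolModel
#'
#' Glorot-uniform weights, zero biases, unit layer-norm gains, zero
#' per-task log-variances; seeded by \code{config$seed}. With
#' \code{identityStart} (the default) each block's output projections
#' start at zero, so the untrained network is the identity on its node
#' states — a residual-friendly initialization that speeds up fitting;
#' set it to FALSE for fully random projections (useful when probing the
#' untrained forward pass itself).
#'
#' @param dNode,dEdge node / edge feature dimensions (take them from a
#'   built \linkS4class{MolecularGraph}).
#' @param config a \code{\link{modelConfig}}.
#' @param identityStart logical; zero-start the branch output projections.
#' @return a \linkS4class{GraphSolModel}.
#' @export
initGraphSolModel <- function(dNode, dEdge, config = modelConfig(),
                              identityStart = TRUE) {
  set.seed(config$seed)
  H <- config$hiddenDim
  dh <- H %/% config$nHeads
  p <- list(Win = .glorot(dNode, H), Wrw = .glorot(config$rwSteps, H),
            bin = matrix(0, 1, H))
  for (l in seq_len(config$nLayers)) {
    # with identityStart, branch output projections begin at zero so the
    # block starts as the identity map and residual paths grow as
    # training shapes them
    outInit <- function(nin, nout)
      if (identityStart) matrix(0, nin, nout) else .glorot(nin, nout)
    lp <- list(We = .glorot(max(dEdge, 1L), H),
               Wm1 = .glorot(H, H), bm1 = matrix(0, 1, H),
               Wm2 = outInit(H, H), bm2 = matrix(0, 1, H),
               ln1g = matrix(1, 1, H), ln1b = matrix(0, 1, H),
               bo = matrix(0, 1, H),
               ln2g = matrix(1, 1, H), ln2b = matrix(0, 1, H),
               Wf1 = .glorot(H, 2 * H), bf1 = matrix(0, 1, 2 * H),
               Wf2 = outInit(2 * H, H), bf2 = matrix(0, 1, H),
               ln3g = matrix(1, 1, H), ln3b = matrix(0, 1, H))
    for (h in seq_len(config$nHeads)) {
      lp[[paste0("Wq", h)]] <- .glorot(H, dh)
      lp[[paste0("Wk", h)]] <- .glorot(H, dh)
      lp[[paste0("Wv", h)]] <- .glorot(H, dh)
      lp[[paste0("Wo", h)]] <- outInit(dh, H)
    }
    names(lp) <- paste0("L", l, ".", names(lp))
    p <- c(p, lp)
  }
  p$Whead <- .glorot(H, 8L)
  p$bhead <- matrix(0, 1, 8L)
  new("GraphSolModel", params = p, lossState = rep(0, 8L),
      config = unclass(config),
      featureDims = c(node = as.integer(dNode), edge = as.integer(dEdge)),
      norm = list(mean = rep(0, 8), sd = rep(1, 8)))
}

# Per-graph constant structures used by every forward pass: node features,
# random-walk encoding, directed-edge selector matrices, edge features
# duplicated for both directions, and the decay mask.
.prepGraph <- function(graph, config) {
  n <- nAtoms(graph)
  el <- edgeList(graph)
  ef <- edgeFeatures(graph)
  de <- max(ncol(ef), 1L)
  if (nrow(el)) {
    src <- c(el[, 1], el[, 2])
    dst <- c(el[, 2], el[, 1])
    E2 <- length(src)
    Psrc <- matrix(0, E2, n); Psrc[cbind(seq_len(E2), src)] <- 1
    Pdst <- matrix(0, E2, n); Pdst[cbind(seq_len(E2), dst)] <- 1
    Ef <- rbind(ef, ef)
  } else {
    Psrc <- Pdst <- NULL
    Ef <- matrix(0, 0, de)
  }
  rw <- rwEncoding(graph)
  if (ncol(rw) < config$rwSteps)
    rw <- cbind(rw, matrix(0, n, config$rwSteps - ncol(rw)))
  list(n = n, X = nodeFeatures(graph), R = rw[, seq_len(config$rwSteps), drop = FALSE],
       Psrc = Psrc, Pdst = Pdst, Ef = Ef,
       mask = decayMask(hopDist(graph), config$decayGamma))
}

# One GPS block on the tape. h: n x H node-state node; P: named list of
# parameter nodes for this layer (unprefixed names); prep: .prepGraph output.
.gpsBlockTape <- function(tape, h, prep, P, config) {
  # (a) GINE-style message passing over bonds
  if (!is.null(prep$Psrc)) {
    Hsrc <- .adMM(tape, .adConst(tape, prep$Psrc), h)
    Eproj <- .adMM(tape, .adConst(tape, prep$Ef), P$We)
    msg <- .adRelu(tape, .adAdd(tape, Hsrc, Eproj))
    m <- .adMM(tape, .adConst(tape, t(prep$Pdst)), msg)
    u <- .adAdd(tape, h, m)
  } else {
    u <- h                       # no bonds: self path only
  }
  mp <- .adBias(tape, .adMM(tape, .adRelu(tape,
          .adBias(tape, .adMM(tape, u, P$Wm1), P$bm1)), P$Wm2), P$bm2)
  hmp <- .adLayerNorm(tape, .adAdd(tape, h, mp), P$ln1g, P$ln1b)

  # (b) global attention, decay-masked post-softmax and renormalized
  dh <- config$hiddenDim %/% config$nHeads
  att <- NULL
  for (k in seq_len(config$nHeads)) {
    Q <- .adMM(tape, h, P[[paste0("Wq", k)]])
    K <- .adMM(tape, h, P[[paste0("Wk", k)]])
    V <- .adMM(tape, h, P[[paste0("Wv", k)]])
    S <- .adCMul(tape, .adMM(tape, Q, .adTranspose(tape, K)), 1 / sqrt(dh))
    A <- .adSoftmaxRows(tape, S)
    An <- .adRowNorm(tape, .adCMul(tape, A, prep$mask))
    hk <- .adMM(tape, .adMM(tape, An, V), P[[paste0("Wo", k)]])
    att <- if (is.null(att)) hk else .adAdd(tape, att, hk)
  }
  att <- .adBias(tape, att, P$bo)
  hat <- .adLayerNorm(tape, .adAdd(tape, h, att), P$ln2g, P$ln2b)

  # combine branches, feed-forward, residual + norm
  hc <- .adAdd(tape, hmp, hat)
  ff <- .adBias(tape, .adMM(tape, .adRelu(tape,
          .adBias(tape, .adMM(tape, hc, P$Wf1), P$bf1)), P$Wf2), P$bf2)
  .adLayerNorm(tape, .adAdd(tape, hc, ff), P$ln3g, P$ln3b)
}

.layerParams <- function(pnodes, l) {
  pref <- paste0("L", l, ".")
  sel <- startsWith(names(pnodes), pref)
  out <- pnodes[sel]
  names(out) <- substring(names(out), nchar(pref) + 1L)
  out
}

# full forward pass on a tape; preps: list of .prepGraph outputs.
# Returns the N x 8 prediction node.
.forwardTape <- function(tape, pnodes, preps, config) {
  rows <- vector("list", length(preps))
  for (i in seq_along(preps)) {
    prep <- preps[[i]]
    h <- .adBias(tape, .adAdd(tape,
           .adMM(tape, .adConst(tape, prep$X), pnodes$Win),
           .adMM(tape, .adConst(tape, prep$R), pnodes$Wrw)), pnodes$bin)
    for (l in seq_len(config$nLayers))
      h <- .gpsBlockTape(tape, h, prep, .layerParams(pnodes, l), config)
    g <- .adMeanRows(tape, h)
    rows[[i]] <- .adBias(tape, .adMM(tape, g, pnodes$Whead), pnodes$bhead)
  }
  .adRbind(tape, rows)
}

.paramNodes <- function(tape, params, track = TRUE) {
  lapply(params, function(v) if (track) .adParam(tape, v) else .adConst(tape, v))
}

#' Run one GPS block on plain node states
#'
#' Value-only evaluation of a single block (message passing + decay-masked
#' attention + feed-forward) of a model, exposed for inspection and
#' contract tests.
#'
#' @param model a \linkS4class{GraphSolModel}.
#' @param graph a \linkS4class{MolecularGraph}.
#' @param nodeStates n x hiddenDim state matrix.
#' @param layer block index.
#' @return updated n x hiddenDim state matrix.
#' @export
gpsBlock <- function(model, graph, nodeStates, layer = 1L) {
  config <- model@config
  tape <- .tapeNew()
  pnodes <- .paramNodes(tape, model@params, track = FALSE)
  prep <- .prepGraph(graph, config)
  h <- .tapePush(tape, as.matrix(nodeStates))
  .gpsBlockTape(tape, h, prep, .layerParams(pnodes, layer), config)$value
}

#' Forward pass: predictions for a batch of graphs
#'
#' @param model a \linkS4class{GraphSolModel}.
#' @param graphs list of \linkS4class{MolecularGraph} objects.
#' @return numeric length(graphs) x 8 matrix, columns \code{\link{taskNames}()}.
#' @export
predictTasks <- function(model, graphs) {
  if (is(graphs, "MolecularGraph")) graphs <- list(graphs)
  dims <- model@featureDims
  for (g in graphs)
    if (ncol(nodeFeatures(g)) != dims[["node"]])
      stop("feature-dimension mismatch: graph has ", ncol(nodeFeatures(g)),
           " node features, model expects ", dims[["node"]])
  config <- model@config
  tape <- .tapeNew()
  pnodes <- .paramNodes(tape, model@params, track = FALSE)
  preps <- lapply(graphs, .prepGraph, config = config)
  out <- .forwardTape(tape, pnodes, preps, config)$value
  n <- nrow(out)
  out <- out * rep(model@norm$sd, each = n) + rep(model@norm$mean, each = n)
  colnames(out) <- taskNames()
  rownames(out) <- names(graphs)
  out
}

#' Uncertainty-weighted multi-task loss
#'
#' Masked per-task mean squared error combined with learnable per-task
#' log-variances: total \eqn{= \sum_t e^{-s_t} L_t + r(s_t)} over tasks
#' with at least one observed entry; \code{"kendall"} uses
#' \eqn{r(s) = s/2}, \code{"robust"} uses \eqn{r(s) = \log(1+e^s)}.
#' Unobserved entries never influence the loss.
#'
#' @param preds,targets numeric N x 8 matrices.
#' @param observed logical N x 8 mask.
#' @param s per-task log-variance parameters, length 8.
#' @param regularizer \code{"kendall"} or \code{"robust"}.
#' @return scalar loss.
#' @export
multitaskLoss <- function(preds, targets, observed, s = rep(0, 8),
                          regularizer = c("kendall", "robust")) {
  regularizer <- match.arg(regularizer)
  stopifnot(identical(dim(preds), dim(targets)),
            identical(dim(preds), dim(observed)), length(s) == ncol(preds))
  if (!any(observed)) {
    warning("no observed targets in batch; loss is 0")
    return(0)
  }
  total <- 0
  for (tk in seq_len(ncol(preds))) {
    o <- observed[, tk]
    if (!any(o)) next
    Lt <- mean((preds[o, tk] - targets[o, tk])^2)
    r <- if (regularizer == "kendall") s[tk] / 2 else log1p(exp(s[tk]))
    total <- total + exp(-s[tk]) * Lt + r
  }
  total
}

# tape version of the loss for training; targets NA-safe via the mask
.lossTape <- function(tape, predsNode, targets, observed, sNode, regularizer) {
  nObs <- colSums(observed)
  active <- as.numeric(nObs > 0)
  W <- sweep(observed * 1, 2, ifelse(nObs > 0, nObs, 1), "/")
  T0 <- targets; T0[!observed] <- 0
  diff <- .adCMul(tape, .adAdd(tape, predsNode, .adConst(tape, -T0)),
                  observed * 1)
  Lvec <- .adMM(tape, .adConst(tape, matrix(1, 1, nrow(targets))),
                .adCMul(tape, .adMul(tape, diff, diff), W))
  weighted <- .adMul(tape, .adExp(tape, .adNeg(tape, sNode)), Lvec)
  reg <- if (regularizer == "kendall") .adCMul(tape, sNode, 0.5)
         else .adSoftplus(tape, sNode)
  .adSum(tape, .adCMul(tape, .adAdd(tape, weighted, reg), matrix(active, 1)))
}

.adamInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

.adamStep <- function(params, grads, state, lr, b1 = 0.9, b2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g^2
    mhat <- state$m[[nm]] / (1 - b1^state$t)
    vhat <- state$v[[nm]] / (1 - b2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

#' Train the multi-task graph transformer
#'
#' Adam optimization of the uncertainty-weighted loss for at most
#' \code{maxEpochs} epochs with minibatches drawn in seeded random order;
#' validation loss is evaluated after every epoch and training stops once
#' it has not improved for \code{earlyStopPatience} epochs. The returned
#' model carries the weights of the best validation epoch. Fully
#' reproducible for a fixed seed on a fixed thread configuration.
#'
#' @param taskTable a \linkS4class{TaskTable}.
#' @param graphs list of \linkS4class{MolecularGraph}, parallel to the
#'   task-table rows (names matching \code{compoundIds(taskTable)}).
#' @param split list with integer indices \code{train} and \code{val}
#'   (e.g. from \code{\link{stratifiedSplit}}).
#' @param config a \code{\link{modelConfig}}.
#' @return list with \code{model} (a \linkS4class{GraphSolModel}),
#'   \code{history} (data.frame epoch/trainLoss/valLoss) and
#'   \code{bestEpoch}.
#' @export
trainGraphSolModel <- function(taskTable, graphs, split, config = modelConfig()) {
  if (length(split$train) == 0) stop("empty train split")
  if (length(intersect(split$train, split$val)))
    stop("train and validation splits must be disjoint")
  targets <- taskValues(taskTable)
  observed <- observedMask(taskTable)
  if (is.null(names(graphs))) names(graphs) <- compoundIds(taskTable)
  graphs <- graphs[compoundIds(taskTable)]
  set.seed(config$seed)
  dNode <- ncol(nodeFeatures(graphs[[1]]))
  dEdge <- ncol(edgeFeatures(graphs[[1]]))
  model <- initGraphSolModel(dNode, dEdge, config)
  # standardize each task on the training split; the loss and early
  # stopping operate on the standardized scale, predictions are mapped back
  trObs <- observed[split$train, , drop = FALSE]
  trVal <- targets[split$train, , drop = FALSE]
  tMean <- vapply(seq_len(8), function(tk) {
    o <- trObs[, tk]; if (any(o)) mean(trVal[o, tk]) else 0 }, numeric(1))
  tSd <- vapply(seq_len(8), function(tk) {
    o <- trObs[, tk]
    s <- if (sum(o) >= 2) stats::sd(trVal[o, tk]) else 1
    if (!is.finite(s) || s == 0) 1 else s }, numeric(1))
  targets <- sweep(sweep(targets, 2, tMean), 2, tSd, "/")
  model@norm <- list(mean = tMean, sd = tSd)
  params <- c(model@params, list(s = matrix(0, 1, 8)))
  preps <- lapply(graphs, .prepGraph, config = config)
  adam <- .adamInit(params)
  history <- data.frame(epoch = integer(0), trainLoss = numeric(0),
                        valLoss = numeric(0))
  best <- list(loss = Inf, epoch = 0L, params = params)
  valIdx <- split$val

  evalLoss <- function(params, idx) {
    if (length(idx) == 0) return(NA_real_)
    tape <- .tapeNew()
    pnodes <- .paramNodes(tape, params[names(params) != "s"], track = FALSE)
    preds <- .forwardTape(tape, pnodes, preps[idx], config)$value
    multitaskLoss(preds, targets[idx, , drop = FALSE],
                  observed[idx, , drop = FALSE], as.vector(params$s),
                  model@config$regularizer)
  }

  for (epoch in seq_len(config$maxEpochs)) {
    # linear warmup into a cosine decay, the schedule of the GPS-style
    # originals; the configured rate is the peak
    warmup <- min(10, config$maxEpochs %/% 10 + 1)
    lr <- if (epoch <= warmup) config$learningRate * epoch / warmup
          else config$learningRate *
            0.5 * (1 + cos(pi * (epoch - warmup) / (config$maxEpochs - warmup)))
    ord <- sample(split$train)
    batches <- base::split(ord, ceiling(seq_along(ord) / config$batchSize))
    epochLoss <- 0
    for (b in batches) {
      tape <- .tapeNew()
      pnodes <- .paramNodes(tape, params)
      predsNode <- .forwardTape(tape, pnodes[names(pnodes) != "s"],
                                preps[b], config)
      lossNode <- .lossTape(tape, predsNode, targets[b, , drop = FALSE],
                            observed[b, , drop = FALSE], pnodes$s,
                            config$regularizer)
      .adBackward(tape, lossNode)
      grads <- lapply(pnodes, function(n) n$grad)
      upd <- .adamStep(params, grads, adam, lr)
      params <- upd$params; adam <- upd$state
      epochLoss <- epochLoss + lossNode$value * length(b)
    }
    valLoss <- if (length(valIdx)) evalLoss(params, valIdx) else
      epochLoss / length(split$train)
    history <- rbind(history, data.frame(
      epoch = epoch, trainLoss = epochLoss / length(split$train),
      valLoss = valLoss))
    if (valLoss < best$loss) {
      best <- list(loss = valLoss, epoch = epoch, params = params)
    } else if (epoch - best$epoch >= config$earlyStopPatience) {
      break
    }
  }
  model@params <- best$params[names(best$params) != "s"]
  model@lossState <- as.vector(best$params$s)
  list(model = model, history = history, bestEpoch = best$epoch)
}

#' Save / load a trained model
#'
#' Checkpoints carry the weights, loss state and full configuration.
#'
#' @param model a \linkS4class{GraphSolModel}.
#' @param path file path (RDS).
#' @export
saveGraphSolModel <- function(model, path) {
  saveRDS(list(params = model@params, lossState = model@lossState,
               config = model@config, featureDims = model@featureDims,
               norm = model@norm), path)
  invisible(path)
}

#' @rdname saveGraphSolModel
#' @export
readGraphSolModel <- function(path) {
  x <- readRDS(path)
  new("GraphSolModel", params = x$params, lossState = x$lossState,
      config = x$config, featureDims = x$featureDims, norm = x$norm)
}
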