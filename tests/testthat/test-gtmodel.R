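# Graph transformer contracts: decay mask, block behavior, forward
# invariances, loss masking, gradients, training loop.

test_that("decay mask is gamma to the hop distance with the right limits", {
  hd <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3, 3)
  expect_equal(decayMask(hd, 0.5),
               matrix(c(1, .5, .25, .5, 1, .5, .25, .5, 1), 3, 3))
  expect_equal(decayMask(hd, 1), matrix(1, 3, 3))
  # gamma = 0 keeps only the diagonal
  expect_equal(decayMask(hd, 0), diag(3))
  # disconnected pairs get zero
  hd2 <- matrix(c(0, Inf, Inf, 0), 2, 2)
  expect_equal(decayMask(hd2, 0.6), diag(2))
  expect_equal(decayMask(hd2, 1), diag(2))
  expect_error(decayMask(hd, 1.2), "gamma")
  expect_error(decayMask(hd, -0.1), "gamma")
  # strict monotone decrease in distance for gamma < 1
  m <- decayMask(matrix(0:5, 1), 0.7)
  expect_true(all(diff(as.vector(m)) < 0))
})

test_that("gps block handles degenerate graphs and respects gamma = 0", {
  g1 <- buildGraph("C", molgraphFeatures(rwSteps = 4))
  cfg <- tinyConfig(seed = 5)
  m <- initGraphSolModel(ncol(nodeFeatures(g1)), ncol(edgeFeatures(g1)), cfg,
                         identityStart = FALSE)
  h1 <- matrix(rnorm(8), 1, 8)
  out <- gpsBlock(m, g1, h1)
  expect_equal(dim(out), dim(h1))
  expect_true(all(is.finite(out)))
  # gamma = 0: each node attends only to itself, so states of distant
  # nodes cannot leak through the attention branch of a path graph
  cfg0 <- tinyConfig(seed = 5, decayGamma = 0)
  g3 <- buildGraph("CCO", molgraphFeatures(rwSteps = 4))
  m0 <- initGraphSolModel(ncol(nodeFeatures(g3)), ncol(edgeFeatures(g3)), cfg0,
                          identityStart = FALSE)
  h <- matrix(rnorm(24), 3, 8)
  base <- gpsBlock(m0, g3, h)
  h2 <- h; h2[3, ] <- h2[3, ] + 10   # perturb the far node
  pert <- gpsBlock(m0, g3, h2)
  # node 1 is two hops from node 3: no attention path, only message
  # passing through node 2, which is unchanged at input
  expect_equal(base[1, ], pert[1, ], tolerance = 1e-8)
})

test_that("forward pass is invariant to batching and node relabeling", {
  cfg <- tinyConfig(seed = 8)
  smiles <- c("CCO", "c1ccccc1", "CC(=O)O", "CCN(CC)CC", "C1CC1", "CCCCO",
              "CNC", "COC")
  gs <- tinyGraphs(smiles)
  m <- initGraphSolModel(ncol(nodeFeatures(gs[[1]])),
                         ncol(edgeFeatures(gs[[1]])), cfg,
                         identityStart = FALSE)
  full <- predictTasks(m, gs)
  single <- predictTasks(m, gs[2])
  expect_equal(unname(full[2, ]), unname(single[1, ]), tolerance = 1e-5)
  # node-permuted copy: same molecule written from a different atom
  gA <- buildGraph("OCC", molgraphFeatures(rwSteps = 4))   # ethanol again
  expect_equal(unname(predictTasks(m, list(gA))[1, ]),
               unname(full[1, ]), tolerance = 1e-5)
  # distinct molecules do not collapse to one output
  expect_gt(max(abs(full[1, ] - full[2, ])), 1e-6)
  # feature-dimension mismatch is caught
  gBad <- buildGraph("CCO", molgraphFeatures(elements = c("C", "O"),
                                             rwSteps = 4))
  expect_error(predictTasks(m, list(gBad)), "feature-dimension")
})

test_that("gamma = 1 forward equals unmasked attention with identical weights", {
  cfg1 <- tinyConfig(seed = 9, decayGamma = 1)
  gs <- tinyGraphs(c("CC(=O)Oc1ccccc1C(=O)O"))
  m1 <- initGraphSolModel(ncol(nodeFeatures(gs[[1]])),
                          ncol(edgeFeatures(gs[[1]])), cfg1,
                          identityStart = FALSE)
  p1 <- predictTasks(m1, gs)
  # same weights, mask forced to all ones (pure softmax attention)
  prep <- GraphSol:::.prepGraph(gs[[1]], m1@config)
  expect_equal(prep$mask, matrix(1, nAtoms(gs[[1]]), nAtoms(gs[[1]])))
  tape <- GraphSol:::.tapeNew()
  pn <- GraphSol:::.paramNodes(tape, m1@params, track = FALSE)
  prep$mask <- matrix(1, nAtoms(gs[[1]]), nAtoms(gs[[1]]))
  raw <- GraphSol:::.forwardTape(tape, pn, list(prep), m1@config)$value
  expect_equal(unname(p1[1, ]), as.vector(raw), tolerance = 1e-6)
})

test_that("multitask loss masks unobserved entries exactly", {
  set.seed(41)
  preds <- matrix(rnorm(40), 5, 8)
  targets <- matrix(rnorm(40), 5, 8)
  obs <- matrix(runif(40) > 0.4, 5, 8)
  s <- rnorm(8, 0, 0.3)
  l0 <- multitaskLoss(preds, targets, obs, s)
  targets2 <- targets
  targets2[!obs] <- 1e6   # garbage where unobserved
  expect_identical(multitaskLoss(preds, targets2, obs, s), l0)
  # with s = 0 and the Kendall regularizer the loss is the sum of
  # per-task masked MSEs
  lsum <- sum(vapply(1:8, function(tk) {
    o <- obs[, tk]
    if (!any(o)) 0 else mean((preds[o, tk] - targets[o, tk])^2)
  }, numeric(1)))
  expect_equal(multitaskLoss(preds, targets, obs, rep(0, 8)), lsum)
  # perfect predictions leave only the regularizer
  oneTask <- matrix(FALSE, 5, 8); oneTask[, 3] <- TRUE
  expect_equal(multitaskLoss(targets, targets, oneTask, s), s[3] / 2)
  expect_equal(multitaskLoss(targets, targets, oneTask, s, "robust"),
               log1p(exp(s[3])))
  expect_warning(l <- multitaskLoss(preds, targets, matrix(FALSE, 5, 8), s),
                 "no observed")
  expect_equal(l, 0)
})

test_that("tape gradients match finite differences; unobserved gradient is zero", {
  set.seed(42)
  cfg <- tinyConfig(seed = 3, nLayers = 2L)
  gs <- tinyGraphs(c("CCO", "c1ccccc1C(=O)O"))
  m <- initGraphSolModel(ncol(nodeFeatures(gs[[1]])),
                         ncol(edgeFeatures(gs[[1]])), cfg,
                         identityStart = FALSE)
  params <- c(m@params, list(s = matrix(0.1, 1, 8)))
  targets <- matrix(rnorm(16), 2, 8)
  obs <- matrix(c(rep(TRUE, 8), rep(FALSE, 8)), 2, byrow = TRUE)
  preps <- lapply(gs, GraphSol:::.prepGraph, config = cfg)
  lossOf <- function(pp) {
    tape <- GraphSol:::.tapeNew()
    pn <- GraphSol:::.paramNodes(tape, pp, track = FALSE)
    preds <- GraphSol:::.forwardTape(tape, pn[names(pn) != "s"], preps,
                                     cfg)$value
    multitaskLoss(preds, targets, obs, as.vector(pp$s), "kendall")
  }
  tape <- GraphSol:::.tapeNew()
  pn <- GraphSol:::.paramNodes(tape, params)
  predsN <- GraphSol:::.forwardTape(tape, pn[names(pn) != "s"], preps, cfg)
  lossN <- GraphSol:::.lossTape(tape, predsN, targets, obs, pn$s, "kendall")
  GraphSol:::.adBackward(tape, lossN)
  expect_equal(lossN$value[1], lossOf(params), tolerance = 1e-12)
  eps <- 1e-6
  for (nm in c("Win", "L1.Wq1", "L1.ln3g", "L2.We", "Whead", "s")) {
    idx <- sample(length(params[[nm]]), min(3, length(params[[nm]])))
    for (i in idx) {
      up <- params; up[[nm]][i] <- up[[nm]][i] + eps
      dn <- params; dn[[nm]][i] <- dn[[nm]][i] - eps
      fd <- (lossOf(up) - lossOf(dn)) / (2 * eps)
      expect_equal(pn[[nm]]$grad[i], fd, tolerance = 1e-4)
    }
  }
  # gradient of the loss with respect to predictions at unobserved
  # entries is exactly zero (masking contract, not just approximately)
  predGrad <- local({
    tape2 <- GraphSol:::.tapeNew()
    pNode <- GraphSol:::.adParam(tape2, predsN$value)
    sNode <- GraphSol:::.adConst(tape2, params$s)
    l <- GraphSol:::.lossTape(tape2, pNode, targets, obs, sNode, "kendall")
    GraphSol:::.adBackward(tape2, l)
    pNode$grad
  })
  expect_identical(unname(predGrad[!obs]), rep(0, sum(!obs)))
})

test_that("training learns, stops early, and is reproducible", {
  set.seed(43)
  smiles <- paste0(strrep("C", 0:11), "CO")   # alcohol homolog series
  ids <- sprintf("m%02d", seq_along(smiles))
  s0 <- -2 - 0.35 * (0:11)                    # planted linear structure
  tt <- s0OnlyTable(ids, s0)
  gs <- tinyGraphs(setNames(smiles, ids))
  cfg <- tinyConfig(seed = 2, maxEpochs = 40L, earlyStopPatience = 40L,
                    batchSize = 4L)
  sp <- list(train = 1:9, val = 10:12)
  fit <- trainGraphSolModel(tt, gs, sp, cfg)
  # validation RMSE at the end beats the untrained model (epoch-0 state)
  m0 <- initGraphSolModel(ncol(nodeFeatures(gs[[1]])),
                          ncol(edgeFeatures(gs[[1]])), cfg)
  m0@norm <- fit$model@norm
  rmse0 <- rmse(s0[sp$val], predictTasks(m0, gs[sp$val])[, "S0"])
  rmse1 <- rmse(s0[sp$val], predictTasks(fit$model, gs[sp$val])[, "S0"])
  expect_lt(rmse1, rmse0)
  # same seed gives bitwise-identical history
  fit2 <- trainGraphSolModel(tt, gs, sp, cfg)
  expect_identical(fit$history, fit2$history)
  expect_identical(fit$model@params, fit2$model@params)
  # early stopping halts within patience epochs of the best epoch
  cfgES <- tinyConfig(seed = 2, maxEpochs = 40L, earlyStopPatience = 5L,
                      batchSize = 4L)
  fitES <- trainGraphSolModel(tt, gs, sp, cfgES)
  expect_lte(nrow(fitES$history), fitES$bestEpoch + 5L)
  expect_error(trainGraphSolModel(tt, gs, list(train = integer(0),
                                               val = 1:2), cfg),
               "empty train")
  expect_error(trainGraphSolModel(tt, gs, list(train = 1:5, val = 5:6), cfg),
               "disjoint")
})

test_that("model checkpoints round-trip through save/load", {
  cfg <- tinyConfig(seed = 12)
  gs <- tinyGraphs(c("CCO", "CCCN"))
  m <- initGraphSolModel(ncol(nodeFeatures(gs[[1]])),
                         ncol(edgeFeatures(gs[[1]])), cfg)
  path <- tempfile(fileext = ".rds")
  saveGraphSolModel(m, path)
  m2 <- readGraphSolModel(path)
  expect_equal(predictTasks(m2, gs), predictTasks(m, gs))
})
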