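# Minimal reverse-mode automatic differentiation on matrices.
#
# The graph transformer is trained with gradients from this tape rather
# than hand-derived per-layer formulas: each op records its parents and a
# backward closure; backward() walks the tape in reverse creation order,
# which is a valid topological order because the graph is built forward.
# Only nodes flagged `track` (parameters and their descendants) receive
# gradients. Values and gradients are plain numeric matrices.
#
# Internal: not part of the package API (tested directly via :::).

# nodes form a linked list (newest first) so pushes are O(1); backward
# walks the list, which is reverse creation order
.tapeNew <- function() {
  t <- new.env(parent = emptyenv())
  t$last <- NULL
  t
}

.tapePush <- function(tape, value, parents = NULL, backfn = NULL) {
  node <- new.env(parent = emptyenv())
  node$value <- value
  node$grad <- NULL
  node$backfn <- NULL
  node$track <- FALSE
  if (!is.null(backfn)) {
    for (p in parents) if (isTRUE(p$track)) { node$track <- TRUE; break }
    if (node$track) node$backfn <- backfn
  }
  node$prev <- tape$last
  tape$last <- node
  node
}

.adConst <- function(tape, v) .tapePush(tape, as.matrix(v))

.adParam <- function(tape, v) {
  node <- .tapePush(tape, as.matrix(v))
  node$track <- TRUE
  node
}

.accum <- function(p, g) {
  if (!isTRUE(p$track)) return(invisible())
  p$grad <- if (is.null(p$grad)) g else p$grad + g
  invisible()
}

.adBackward <- function(tape, root) {
  stopifnot(length(root$value) == 1L)
  root$grad <- matrix(1, 1, 1)
  node <- tape$last
  while (!is.null(node)) {
    if (!is.null(node$backfn) && !is.null(node$grad)) node$backfn(node)
    node <- node$prev
  }
  invisible()
}

.adMM <- function(tape, a, b) {
  .tapePush(tape, a$value %*% b$value, list(a, b), function(node) {
    g <- node$grad
    .accum(a, tcrossprod(g, b$value))
    .accum(b, crossprod(a$value, g))
  })
}

.adAdd <- function(tape, a, b) {
  .tapePush(tape, a$value + b$value, list(a, b), function(node) {
    .accum(a, node$grad)
    .accum(b, node$grad)
  })
}

# add a 1 x d row vector to every row of a
.adBias <- function(tape, a, b) {
  n <- nrow(a$value)
  .tapePush(tape, a$value + rep(as.vector(b$value), each = n), list(a, b),
            function(node) {
    .accum(a, node$grad)
    .accum(b, matrix(colSums(node$grad), 1))
  })
}

.adMul <- function(tape, a, b) {
  .tapePush(tape, a$value * b$value, list(a, b), function(node) {
    .accum(a, node$grad * b$value)
    .accum(b, node$grad * a$value)
  })
}

# elementwise multiply by a constant matrix/scalar
.adCMul <- function(tape, a, M) {
  .tapePush(tape, a$value * M, list(a), function(node) {
    .accum(a, node$grad * M)
  })
}

.adRelu <- function(tape, a) {
  .tapePush(tape, pmax(a$value, 0), list(a), function(node) {
    .accum(a, node$grad * (a$value > 0))
  })
}

.adExp <- function(tape, a) {
  .tapePush(tape, exp(a$value), list(a), function(node) {
    .accum(a, node$grad * node$value)
  })
}

.adNeg <- function(tape, a) .adCMul(tape, a, -1)

# log(1 + exp(x)), evaluated stably
.adSoftplus <- function(tape, a) {
  v <- a$value
  .tapePush(tape, pmax(v, 0) + log1p(exp(-abs(v))), list(a), function(node) {
    .accum(a, node$grad * (1 / (1 + exp(-v))))
  })
}

.adTranspose <- function(tape, a) {
  .tapePush(tape, t(a$value), list(a), function(node) {
    .accum(a, t(node$grad))
  })
}

# softmax over each row
.adSoftmaxRows <- function(tape, a) {
  v <- a$value
  rmax <- v[cbind(seq_len(nrow(v)), max.col(v, ties.method = "first"))]
  e <- exp(v - rmax)
  y <- e / rowSums(e)
  .tapePush(tape, y, list(a), function(node) {
    g <- node$grad
    .accum(a, y * (g - rowSums(g * y)))
  })
}

# divide each row by its sum (rows must have positive sums)
.adRowNorm <- function(tape, a) {
  s <- rowSums(a$value)
  y <- a$value / s
  .tapePush(tape, y, list(a), function(node) {
    g <- node$grad
    .accum(a, (g - rowSums(g * y)) / s)
  })
}

# row-wise layer normalization with learnable gain/offset (1 x d each)
.adLayerNorm <- function(tape, a, gain, offset, eps = 1e-5) {
  x <- a$value
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  n <- nrow(x)
  y <- xhat * rep(as.vector(gain$value), each = n) +
    rep(as.vector(offset$value), each = n)
  d <- ncol(x)
  .tapePush(tape, y, list(a, gain, offset), function(node) {
    g <- node$grad
    dxhat <- g * rep(as.vector(gain$value), each = nrow(x))
    dv <- rowSums(dxhat * xc) * (-0.5) * inv^3
    dmu <- rowSums(-dxhat) * inv + dv * rowMeans(-2 * xc)
    dx <- dxhat * inv + dv * 2 * xc / d + dmu / d
    .accum(a, dx)
    .accum(gain, matrix(colSums(g * xhat), 1))
    .accum(offset, matrix(colSums(g), 1))
  })
}

# column means of a as a 1 x d row
.adMeanRows <- function(tape, a) {
  n <- nrow(a$value)
  .tapePush(tape, matrix(colMeans(a$value), 1), list(a), function(node) {
    .accum(a, matrix(rep(node$grad / n, each = n), n))
  })
}

# stack 1 x d rows into an m x d matrix
.adRbind <- function(tape, rows) {
  .tapePush(tape, do.call(rbind, lapply(rows, function(r) r$value)), rows,
            function(node) {
    for (i in seq_along(rows))
      .accum(rows[[i]], node$grad[i, , drop = FALSE])
  })
}

.adSum <- function(tape, a) {
  .tapePush(tape, matrix(sum(a$value), 1, 1), list(a), function(node) {
    .accum(a, matrix(as.numeric(node$grad), nrow(a$value), ncol(a$value)))
  })
}
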