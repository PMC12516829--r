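# SMILES -> featurized molecular graph. Parsing and ring/aromaticity
# perception are delegated to ChemmineR/ChemmineOB (OpenBabel); hop
# distances come from igraph shortest paths; the random-walk structural
# encoding is computed here from the degree-normalized transition matrix.
#
# The SDF emitted by OpenBabel is kekulized and carries no implicit-H,
# hybridization or conjugation fields, so those node/edge features are
# reconstructed from the bond table with standard-valence rules. The whole
# feature set is configurable so an alternative featurization can be
# swapped in.

#' Molecular graph feature configuration
#'
#' @param elements element symbols that get their own one-hot slot; any
#'   other element maps to a shared "other" slot.
#' @param rwSteps number K of random-walk steps in the structural encoding.
#' @return named list of class \code{MolgraphFeatures}.
#' @export
molgraphFeatures <- function(elements = c("C", "N", "O", "S", "P",
                                          "F", "Cl", "Br", "I"),
                             rwSteps = 20L) {
  stopifnot(rwSteps >= 1)
  structure(list(elements = elements, rwSteps = as.integer(rwSteps)),
            class = "MolgraphFeatures")
}

# default valences for implicit-H reconstruction
.defaultValence <- c(C = 4, N = 3, O = 2, S = 2, P = 3,
                     F = 1, Cl = 1, Br = 1, I = 1, B = 3, Si = 4)

# MDL SDF charge codes -> formal charge
.sdfCharge <- function(code) {
  map <- c(`0` = 0, `1` = 3, `2` = 2, `3` = 1, `4` = 0, `5` = -1,
           `6` = -2, `7` = -3)
  out <- map[as.character(code)]
  out[is.na(out)] <- 0
  unname(out)
}

.parseSmiles <- function(smiles) {
  sdf <- tryCatch(suppressWarnings(ChemmineR::smiles2sdf(smiles)),
                  error = function(e)
                    stop("unparseable SMILES: '", smiles, "'", call. = FALSE))
  mol <- sdf[[1]]
  ab <- ChemmineR::atomblock(mol)
  if (is.null(ab) || nrow(ab) == 0)
    stop("unparseable SMILES (zero atoms): '", smiles, "'", call. = FALSE)
  bb <- ChemmineR::bondblock(mol)
  bonds <- if (is.null(bb) || nrow(bb) == 0 || ncol(bb) < 3) {
    matrix(numeric(0), 0, 4)   # bond-free molecule (dummy zero block)
  } else {
    bb <- as.matrix(bb)
    if (ncol(bb) < 4) bb <- cbind(bb, 0)
    bb <- bb[, 1:4, drop = FALSE]
    bb[bb[, 1] > 0 & bb[, 2] > 0, , drop = FALSE]   # drop dummy zero rows
  }
  elements <- sub("_\\d+$", "", rownames(ab))
  charges <- if ("C6" %in% colnames(ab)) .sdfCharge(ab[, "C6"])
             else rep(0, nrow(ab))
  # aromatic ring perception (rings up to 8 atoms)
  arAtoms <- logical(nrow(ab))
  if (nrow(bonds) > 0) {
    rr <- tryCatch(ChemmineR::rings(mol, upper = 8, type = "all", arom = TRUE),
                   error = function(e) list(RINGS = NULL, AROMATIC = NULL))
    if (!is.null(rr$AROMATIC) && any(rr$AROMATIC)) {
      idx <- unlist(lapply(rr$RINGS[rr$AROMATIC], function(r)
        as.integer(sub("^.*_", "", r))))
      arAtoms[idx] <- TRUE
    }
  }
  list(elements = elements, charges = charges, bonds = bonds,
       aromaticAtom = arAtoms)
}

#' Build a featurized molecular graph from SMILES
#'
#' One node per heavy atom (hydrogens implicit). Node features: element
#' one-hot, degree, formal charge, implied total H count, hybridization
#' one-hot (sp/sp2/sp3/other), aromaticity and ring membership. Edge
#' features: bond-order one-hot (single/double/triple/aromatic),
#' conjugation, ring membership, stereo flag. Hop distances and the
#' random-walk encoding are attached.
#'
#' @param smiles a SMILES string.
#' @param config a \code{\link{molgraphFeatures}} configuration.
#' @return a \linkS4class{MolecularGraph}.
#' @examples
#' g <- buildGraph("c1ccccc1")
#' nAtoms(g)
#' @export
buildGraph <- function(smiles, config = molgraphFeatures()) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  parsed <- .parseSmiles(smiles)
  n <- length(parsed$elements)
  bonds <- parsed$bonds
  nb <- nrow(bonds)
  orders <- if (nb) bonds[, 3] else numeric(0)
  stereo <- if (nb) bonds[, 4] != 0 else logical(0)

  # per-atom bond-order bookkeeping
  degree <- integer(n); valSum <- numeric(0)
  valSum <- numeric(n); nDouble <- integer(n); nTriple <- integer(n)
  if (nb) for (e in seq_len(nb)) {
    i <- bonds[e, 1]; j <- bonds[e, 2]; o <- orders[e]
    degree[c(i, j)] <- degree[c(i, j)] + 1L
    valSum[c(i, j)] <- valSum[c(i, j)] + o
    if (o == 2) nDouble[c(i, j)] <- nDouble[c(i, j)] + 1L
    if (o == 3) nTriple[c(i, j)] <- nTriple[c(i, j)] + 1L
  }

  # ring membership: an edge is in a ring iff it is not a bridge
  inRingEdge <- logical(nb); inRingAtom <- logical(n)
  ig <- igraph::make_empty_graph(n, directed = FALSE)
  if (nb) {
    ig <- igraph::add_edges(ig, as.vector(t(bonds[, 1:2, drop = FALSE])))
    br <- igraph::bridges(ig)
    inRingEdge <- !(seq_len(nb) %in% as.integer(br))
    if (any(inRingEdge))
      inRingAtom[unique(as.vector(bonds[inRingEdge, 1:2]))] <- TRUE
  }
  aromaticAtom <- parsed$aromaticAtom
  aromaticEdge <- if (nb) {
    aromaticAtom[bonds[, 1]] & aromaticAtom[bonds[, 2]] & inRingEdge
  } else logical(0)

  # implied H count from default valences, charge-adjusted
  defv <- .defaultValence[parsed$elements]
  defv[is.na(defv)] <- 0
  chargeAdj <- ifelse(parsed$elements %in% c("N", "O", "S", "P"),
                      parsed$charges, -abs(parsed$charges))
  nH <- pmax(0, defv + chargeAdj - valSum)

  hyb <- ifelse(nTriple > 0 | nDouble >= 2, "sp",
         ifelse(nDouble > 0 | aromaticAtom, "sp2",
         ifelse(degree > 0 | nH > 0, "sp3", "other")))

  els <- config$elements
  elemHot <- vapply(c(els, "other"), function(e)
    if (e == "other") as.numeric(!(parsed$elements %in% els))
    else as.numeric(parsed$elements == e), numeric(n))
  hybHot <- vapply(c("sp", "sp2", "sp3", "other"),
                   function(h) as.numeric(hyb == h), numeric(n))
  nodeF <- cbind(matrix(elemHot, nrow = n), degree, parsed$charges, nH,
                 matrix(hybHot, nrow = n), as.numeric(aromaticAtom),
                 as.numeric(inRingAtom))
  colnames(nodeF) <- c(paste0("elem_", c(els, "other")), "degree", "charge",
                       "num_h", paste0("hyb_", c("sp", "sp2", "sp3", "other")),
                       "aromatic", "in_ring")

  # conjugation: aromatic bonds, or single bonds joining two multiply
  # bonded atoms, or multiple bonds themselves
  multi <- nDouble > 0 | nTriple > 0 | aromaticAtom
  conj <- if (nb) {
    aromaticEdge | orders >= 2 |
      (multi[bonds[, 1]] & multi[bonds[, 2]])
  } else logical(0)
  edgeF <- cbind(as.numeric(orders == 1 & !aromaticEdge),
                 as.numeric(orders == 2 & !aromaticEdge),
                 as.numeric(orders == 3),
                 as.numeric(aromaticEdge),
                 as.numeric(conj), as.numeric(inRingEdge),
                 as.numeric(stereo))
  colnames(edgeF) <- c("single", "double", "triple", "aromatic",
                       "conjugated", "in_ring", "stereo")

  hd <- igraph::distances(ig)
  dimnames(hd) <- NULL
  el <- if (nb) {
    m <- t(apply(bonds[, 1:2, drop = FALSE], 1, sort))
    storage.mode(m) <- "integer"; m
  } else matrix(integer(0), 0, 2)

  adj <- matrix(0, n, n)
  if (nb) { adj[el] <- 1; adj[el[, 2:1, drop = FALSE]] <- 1 }
  rw <- randomWalkEncoding(adj, config$rwSteps)

  new("MolecularGraph", smiles = smiles, nodeFeatures = nodeF,
      edgeList = el, edgeFeatures = edgeF, hopDist = hd, rwEncoding = rw)
}

#' Random-walk structural encoding
#'
#' Entry (i, k) is the probability that a uniform random walk started at
#' node i returns to i in exactly k steps: the diagonal of the k-th power
#' of the degree-normalized transition matrix \eqn{P = D^{-1}A}. Isolated
#' nodes get all-zero rows; column 1 is all zero for simple graphs.
#'
#' @param x a \linkS4class{MolecularGraph} or a symmetric 0/1 adjacency
#'   matrix.
#' @param steps number of steps K.
#' @return n x K matrix of return probabilities.
#' @export
randomWalkEncoding <- function(x, steps = 20L) {
  stopifnot(steps >= 1)
  if (is(x, "MolecularGraph")) {
    n <- nAtoms(x)
    adj <- matrix(0, n, n)
    el <- edgeList(x)
    if (nrow(el)) { adj[el] <- 1; adj[el[, 2:1, drop = FALSE]] <- 1 }
  } else {
    adj <- as.matrix(x)
    n <- nrow(adj)
  }
  deg <- rowSums(adj)
  P <- adj / ifelse(deg > 0, deg, 1)   # isolated nodes: zero row
  out <- matrix(0, n, steps)
  M <- diag(n)
  for (k in seq_len(steps)) {
    M <- M %*% P
    out[, k] <- diag(M)
  }
  colnames(out) <- paste0("rw", seq_len(steps))
  out
}
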