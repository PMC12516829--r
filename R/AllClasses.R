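#' @import methods
NULL

#' Ionization model of a compound
#'
#' Holds the predicted acid dissociation constants of a compound, separated
#' into acidic pKa's (groups that deprotonate above their pKa) and basic
#' pKa's (groups that protonate below their pKa). Acidic pKa's are stored
#' sorted ascending and basic pKa's sorted descending, the order in which
#' they enter the cumulative speciation expansion.
#'
#' @slot acidicPkas numeric, acidic pKa values sorted ascending (pH units).
#' @slot basicPkas numeric, basic pKa values sorted descending (pH units).
#' @export
setClass("IonizationModel",
  representation(acidicPkas = "numeric", basicPkas = "numeric"),
  prototype(acidicPkas = numeric(0), basicPkas = numeric(0)))

setValidity("IonizationModel", function(object) {
  a <- object@acidicPkas
  b <- object@basicPkas
  if (length(a) && !all(is.finite(a))) return("acidic pKa values must be finite")
  if (length(b) && !all(is.finite(b))) return("basic pKa values must be finite")
  if (is.unsorted(a)) return("acidic pKa values must be sorted ascending")
  if (is.unsorted(rev(b))) return("basic pKa values must be sorted descending")
  TRUE
})

#' Construct an IonizationModel
#'
#' @param acidic numeric vector of acidic pKa values (any order).
#' @param basic numeric vector of basic pKa values (any order).
#' @return An \linkS4class{IonizationModel}; pKa's are sorted internally.
#' @examples
#' IonizationModel(acidic = 4.2, basic = c(8.1, 2.0))
#' @export
IonizationModel <- function(acidic = numeric(0), basic = numeric(0)) {
  if (!all(is.finite(acidic)) || !all(is.finite(basic)))
    stop("pKa values must be finite")
  new("IonizationModel",
      acidicPkas = sort(as.numeric(acidic)),
      basicPkas = sort(as.numeric(basic), decreasing = TRUE))
}

#' @describeIn IonizationModel-class acidic pKa's, ascending
#' @param object,x an \code{IonizationModel}
#' @export
acidicPkas <- function(x) x@acidicPkas

#' @describeIn IonizationModel-class basic pKa's, descending
#' @export
basicPkas <- function(x) x@basicPkas

#' @describeIn IonizationModel-class total number of pKa's
#' @export
nPkas <- function(x) length(x@acidicPkas) + length(x@basicPkas)

setMethod("show", "IonizationModel", function(object) {
  cat("IonizationModel:",
      length(object@acidicPkas), "acidic,",
      length(object@basicPkas), "basic\n")
  if (length(object@acidicPkas))
    cat("  acidic pKa:", paste(format(object@acidicPkas, digits = 3), collapse = ", "), "\n")
  if (length(object@basicPkas))
    cat("  basic pKa: ", paste(format(object@basicPkas, digits = 3), collapse = ", "), "\n")
})

#' Featurized molecular graph
#'
#' Graph representation of a molecule: one node per heavy atom, one
#' undirected edge per bond, numeric node and edge feature matrices, the
#' all-pairs shortest-path hop-count matrix (Inf between disconnected
#' components) and the random-walk structural encoding (k-step return
#' probabilities of a uniform random walk).
#'
#' @slot smiles the source SMILES string.
#' @slot nodeFeatures n_atoms x d_node numeric matrix.
#' @slot edgeList n_edges x 2 integer matrix of undirected bonds (i < j).
#' @slot edgeFeatures n_edges x d_edge numeric matrix.
#' @slot hopDist n x n hop-count matrix.
#' @slot rwEncoding n x K return-probability matrix.
#' @export
setClass("MolecularGraph",
  representation(smiles = "character", nodeFeatures = "matrix",
                 edgeList = "matrix", edgeFeatures = "matrix",
                 hopDist = "matrix", rwEncoding = "matrix"))

setValidity("MolecularGraph", function(object) {
  n <- nrow(object@nodeFeatures)
  if (n < 1) return("graph must have at least one atom")
  if (!identical(dim(object@hopDist), c(n, n))) return("hopDist must be n x n")
  if (nrow(object@rwEncoding) != n) return("rwEncoding must have one row per atom")
  hd <- object@hopDist
  if (any(diag(hd) != 0)) return("hopDist diagonal must be zero")
  if (!isTRUE(all.equal(hd, t(hd)))) return("hopDist must be symmetric")
  if (nrow(object@edgeList) > 0 &&
      (ncol(object@edgeList) != 2 || max(object@edgeList) > n))
    return("edgeList indices out of range")
  rw <- object@rwEncoding
  if (length(rw) && (min(rw) < -1e-12 || max(rw) > 1 + 1e-12))
    return("rwEncoding entries must lie in [0, 1]")
  TRUE
})

#' @describeIn MolecularGraph-class number of heavy atoms
#' @param x,object a \code{MolecularGraph}
#' @export
nAtoms <- function(x) nrow(x@nodeFeatures)

#' @describeIn MolecularGraph-class node feature matrix
#' @export
nodeFeatures <- function(x) x@nodeFeatures

#' @describeIn MolecularGraph-class edge feature matrix
#' @export
edgeFeatures <- function(x) x@edgeFeatures

#' @describeIn MolecularGraph-class undirected edge list (i < j)
#' @export
edgeList <- function(x) x@edgeList

#' @describeIn MolecularGraph-class hop-distance matrix
#' @export
hopDist <- function(x) x@hopDist

#' @describeIn MolecularGraph-class random-walk encoding matrix
#' @export
rwEncoding <- function(x) x@rwEncoding

setMethod("show", "MolecularGraph", function(object) {
  cat("MolecularGraph:", object@smiles, "\n")
  cat(" ", nAtoms(object), "atoms,", nrow(object@edgeList), "bonds;",
      ncol(object@nodeFeatures), "node features,",
      ncol(object@edgeFeatures), "edge features,",
      ncol(object@rwEncoding), "random-walk steps\n")
})

#' Sparse compound-by-task target table
#'
#' The merged multi-assay training table: a compound x 8 matrix of target
#' values (log10 molar for the solubility tasks, dimensionless for
#' logP/logD), a logical observation mask (missing targets are never
#' imputed), and the per-compound high-quality S0 flag used for stratified
#' splitting and test-set evaluation.
#'
#' @slot values numeric compound x task matrix (NA where unobserved).
#' @slot observed logical mask, same shape.
#' @slot highQuality logical per compound.
#' @export
setClass("TaskTable",
  representation(values = "matrix", observed = "matrix", highQuality = "logical"))

#' Canonical task names, in table column order
#' @export
taskNames <- function() c("S0", "sol_pH2", "sol_pH7", "sol_fassif",
                          "logP", "logD_2.6", "logD_7.4", "logD_10.5")

setValidity("TaskTable", function(object) {
  v <- object@values; o <- object@observed
  if (ncol(v) != 8L) return("TaskTable must have exactly 8 tasks")
  if (!identical(colnames(v), taskNames())) return("task columns must match taskNames()")
  if (!identical(dim(v), dim(o))) return("values and observed must match in shape")
  if (length(object@highQuality) != nrow(v))
    return("highQuality must have one flag per compound")
  if (any(!is.finite(v[o]))) return("every observed value must be finite")
  TRUE
})

#' @describeIn TaskTable-class target value matrix
#' @param x,object a \code{TaskTable}
#' @export
taskValues <- function(x) x@values

#' @describeIn TaskTable-class observation mask
#' @export
observedMask <- function(x) x@observed

#' @describeIn TaskTable-class per-compound high-quality S0 flag
#' @export
highQuality <- function(x) x@highQuality

#' @describeIn TaskTable-class compound ids (rownames)
#' @export
compoundIds <- function(x) rownames(x@values)

setMethod("show", "TaskTable", function(object) {
  cat("TaskTable:", nrow(object@values), "compounds x 8 tasks;",
      sum(object@observed), "observed values;",
      sum(object@highQuality), "high-quality S0 compounds\n")
  cat("  observed per task:\n")
  print(colSums(object@observed))
})

#' pH-solubility profile
#'
#' Solubility of one compound over a pH grid, reconstructed from an
#' intrinsic solubility and an ionization model. Grid points where more
#' than three pKa's are simultaneously relevant are left undetermined
#' (NA in \code{logS}, TRUE in \code{undetermined}).
#'
#' @slot phGrid ascending pH values.
#' @slot logS log10 molar solubility per grid point (NA if undetermined).
#' @slot undetermined logical mask.
#' @slot logS0 the intrinsic solubility the profile was built from.
#' @export
setClass("SolubilityProfile",
  representation(phGrid = "numeric", logS = "numeric",
                 undetermined = "logical", logS0 = "numeric"))

setValidity("SolubilityProfile", function(object) {
  g <- object@phGrid
  if (is.unsorted(g, strictly = TRUE)) return("phGrid must be strictly ascending")
  if (length(object@logS) != length(g) || length(object@undetermined) != length(g))
    return("logS and undetermined must match phGrid in length")
  det <- !object@undetermined
  if (any(!is.finite(object@logS[det]))) return("determined logS must be finite")
  if (any(object@logS[det] < object@logS0 - 1e-9))
    return("solubility can never fall below the intrinsic solubility")
  TRUE
})

#' @describeIn SolubilityProfile-class pH grid
#' @param x,object a \code{SolubilityProfile}
#' @export
phGrid <- function(x) x@phGrid

#' @describeIn SolubilityProfile-class log10 molar solubility values
#' @export
profileLogS <- function(x) x@logS

#' @describeIn SolubilityProfile-class undetermined-point mask
#' @export
undetermined <- function(x) x@undetermined

setMethod("show", "SolubilityProfile", function(object) {
  cat("SolubilityProfile: pH", min(object@phGrid), "-", max(object@phGrid),
      "(", length(object@phGrid), "points ),",
      sum(object@undetermined), "undetermined\n")
  cat("  log S0 =", format(object@logS0, digits = 4), "\n")
})
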