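#' @import methods
NULL

#' Molecule3D: a molecule as elements plus Cartesian coordinates
#'
#' Minimal 3D structure container. Coordinates are always in Angstrom; no
#' internal unit conversion is ever performed. Element symbols are
#' canonicalised (first letter upper case) and must belong to the known
#' periodic-table set.
#'
#' @slot elements character vector of element symbols, length N.
#' @slot coords numeric N x 3 matrix of Cartesian positions (Angstrom).
#' @slot role one of `"substrate"` or `"resolving_agent"`.
#' @slot atomIds character vector of stable per-atom identifiers.
#' @export
setClass("Molecule3D",
  representation(elements = "character", coords = "matrix",
                 role = "character", atomIds = "character"))

setValidity("Molecule3D", function(object) {
  n <- length(object@elements)
  if (n < 1L) return("molecule must contain at least one atom")
  if (!is.numeric(object@coords) || !identical(dim(object@coords), c(n, 3L)))
    return("coords must be an N x 3 numeric matrix matching elements")
  if (!all(is.finite(object@coords))) return("coordinates must be finite")
  if (!object@role %in% c("substrate", "resolving_agent"))
    return("role must be 'substrate' or 'resolving_agent'")
  bad <- setdiff(unique(object@elements), knownElements())
  if (length(bad))
    return(paste0("unknown element symbol(s): ", paste(bad, collapse = ", ")))
  if (length(object@atomIds) != n) return("atomIds must have one id per atom")
  if (anyDuplicated(object@atomIds)) return("atomIds must be unique")
  TRUE
})

#' SaltComplex: one diastereomeric acid-base complex
#'
#' A substrate enantiomer (R or S) posed against a single-enantiomer
#' resolving agent. Atom identifiers are unique across the whole complex.
#'
#' @slot substrate,agent [Molecule3D-class] objects.
#' @slot handedness `"R"` or `"S"`, the substrate enantiomer.
#' @export
setClass("SaltComplex",
  representation(substrate = "Molecule3D", agent = "Molecule3D",
                 handedness = "character"))

setValidity("SaltComplex", function(object) {
  if (!object@handedness %in% c("R", "S")) return("handedness must be 'R' or 'S'")
  ids <- c(object@substrate@atomIds, object@agent@atomIds)
  if (anyDuplicated(ids)) return("atom identifiers must be unique across the complex")
  if (object@substrate@role != "substrate") return("substrate slot must have role 'substrate'")
  if (object@agent@role != "resolving_agent") return("agent slot must have role 'resolving_agent'")
  TRUE
})

#' FrameSet: a conformer ensemble for one complex
#'
#' Frames stand in for molecular-dynamics snapshots of the acid-base pair.
#' At least two frames are required so that the standard deviation of the
#' snapshot representations is defined.
#'
#' @slot complexTemplate the [SaltComplex-class] the frames deform.
#' @slot frames list of N x 3 coordinate matrices (Angstrom), template order.
#' @export
setClass("FrameSet",
  representation(complexTemplate = "SaltComplex", frames = "list"))

setValidity("FrameSet", function(object) {
  n <- nAtoms(object@complexTemplate)
  if (length(object@frames) < 2L)
    return("a FrameSet needs at least 2 frames (std undefined otherwise)")
  ok <- vapply(object@frames, function(f)
    is.numeric(f) && identical(dim(f), c(n, 3L)) && all(is.finite(f)), logical(1))
  if (!all(ok)) return("every frame must be a finite N x 3 matrix with the template's atom count")
  TRUE
})

#' TrajectoryRep: per-atom mean||std atom-density representation
#'
#' One row per non-hydrogen atom of the complex; each row is the
#' concatenation of the mean and the (population) standard deviation of the
#' per-snapshot representation over the frames, length 2 x 3367 = 6734.
#'
#' @slot rep numeric matrix, heavy atoms x 6734.
#' @slot atomIds identifiers of the represented (heavy) atoms.
#' @slot frameCount number of frames aggregated.
#' @export
setClass("TrajectoryRep",
  representation(rep = "matrix", atomIds = "character", frameCount = "integer"))

setValidity("TrajectoryRep", function(object) {
  if (nrow(object@rep) != length(object@atomIds))
    return("one representation row per atom id required")
  if (!all(is.finite(object@rep))) return("representation must be finite")
  if (object@frameCount < 2L) return("frameCount must be >= 2")
  TRUE
})

#' Compressor: 6734 -> 20 dimensional reduction of per-atom representations
#'
#' Either a two-hidden-layer autoencoder (default) or a PCA projection,
#' trained on training-split atoms only; `fingerprint` records a hash of the
#' training matrix so leakage across folds is detectable.
#'
#' @slot kind `"autoencoder"` or `"pca"`.
#' @slot inputDim,latentDim integer dimensions.
#' @slot params fitted parameters (centring/scaling plus weights or rotation).
#' @slot fingerprint character hash of the training data.
#' @export
setClass("Compressor",
  representation(kind = "character", inputDim = "integer", latentDim = "integer",
                 params = "list", fingerprint = "character"))

#' PairTensors: model input for one resolution experiment
#'
#' Per-token (= per heavy atom of the complex) mean and absolute-difference
#' streams of the compressed representations of the two diastereomeric
#' complexes, plus the solvent descriptor vector.
#'
#' @slot atoms token atom identifiers (substrate atoms then agent atoms).
#' @slot meanStream,diffStream numeric T x latent matrices.
#' @slot solvent numeric solvent descriptor vector (may be length 0 before
#'   attachment).
#' @export
setClass("PairTensors",
  representation(atoms = "character", meanStream = "matrix",
                 diffStream = "matrix", solvent = "numeric"))

setValidity("PairTensors", function(object) {
  if (!identical(dim(object@meanStream), dim(object@diffStream)))
    return("mean and diff streams must have identical dimensions")
  if (nrow(object@meanStream) != length(object@atoms))
    return("one token per atom id required")
  if (any(object@diffStream < 0)) return("diff stream must be non-negative (absolute difference)")
  if (!all(is.finite(object@meanStream)) || !all(is.finite(object@diffStream)))
    return("streams must be finite")
  TRUE
})

#' WeightProvider: source of A1 features and pairwise weighting channels
#'
#' Wraps a deterministic function of the complex geometry that returns the
#' seven per-atom identity features and the seven pairwise weighting
#' channels multiplying the atom-density Gaussians.
#'
#' @slot name provider name (`"surrogate"` or `"external_file"`).
#' @slot fun function(complex, coords) -> list(a1, omega).
#' @export
setClass("WeightProvider",
  representation(name = "character", fun = "function"))

#' DualStreamModel: the dual-stream attention network
#'
#' Two parameter-independent transformer stacks over the mean and diff token
#' streams, pooled by cross-attention with the embedded solvent vector as the
#' single query, followed by a feedforward head (regression or
#' classification).
#'
#' @slot config model configuration list (see [modelConfig()]).
#' @slot params nested parameter list.
#' @slot frozen character vector of frozen top-level parameter groups.
#' @export
setClass("DualStreamModel",
  representation(config = "list", params = "list", frozen = "character"))
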