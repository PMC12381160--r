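#' Number of atoms
#' @param x a Molecule3D, SaltComplex or FrameSet
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' Element symbols
#' @param x a Molecule3D or SaltComplex
#' @export
setGeneric("elementsOf", function(x) standardGeneric("elementsOf"))

#' Cartesian coordinates (Angstrom)
#' @param x a Molecule3D or SaltComplex
#' @export
setGeneric("coordsOf", function(x) standardGeneric("coordsOf"))

#' Atom identifiers
#' @param x a Molecule3D, SaltComplex, TrajectoryRep or PairTensors
#' @export
setGeneric("atomIds", function(x) standardGeneric("atomIds"))

#' Number of frames
#' @param x a FrameSet or TrajectoryRep
#' @export
setGeneric("frameCount", function(x) standardGeneric("frameCount"))

#' Encode vectors into the compressed latent space
#' @param object a [Compressor-class]
#' @param x numeric matrix (rows = per-atom representations)
#' @export
setGeneric("encode", function(object, x) standardGeneric("encode"))

#' Reconstruct vectors from the compressed latent space
#' @param object a [Compressor-class]
#' @param z numeric matrix of latent rows
#' @export
setGeneric("decode", function(object, z) standardGeneric("decode"))

setMethod("nAtoms", "Molecule3D", function(x) length(x@elements))
setMethod("nAtoms", "SaltComplex", function(x) nAtoms(x@substrate) + nAtoms(x@agent))
setMethod("nAtoms", "FrameSet", function(x) nAtoms(x@complexTemplate))

setMethod("elementsOf", "Molecule3D", function(x) x@elements)
setMethod("elementsOf", "SaltComplex",
          function(x) c(x@substrate@elements, x@agent@elements))

setMethod("coordsOf", "Molecule3D", function(x) x@coords)
setMethod("coordsOf", "SaltComplex",
          function(x) rbind(x@substrate@coords, x@agent@coords))

setMethod("atomIds", "Molecule3D", function(x) x@atomIds)
setMethod("atomIds", "SaltComplex",
          function(x) c(x@substrate@atomIds, x@agent@atomIds))
setMethod("atomIds", "TrajectoryRep", function(x) x@atomIds)
setMethod("atomIds", "PairTensors", function(x) x@atoms)

setMethod("frameCount", "FrameSet", function(x) length(x@frames))
setMethod("frameCount", "TrajectoryRep", function(x) x@frameCount)

setMethod("show", "Molecule3D", function(object) {
  cat(sprintf("Molecule3D (%s): %d atoms [%s]\n", object@role,
              nAtoms(object), paste(utils::head(object@elements, 8), collapse = " ")))
})

setMethod("show", "SaltComplex", function(object) {
  cat(sprintf("SaltComplex (%s substrate): %d substrate + %d agent atoms\n",
              object@handedness, nAtoms(object@substrate), nAtoms(object@agent)))
})

setMethod("show", "FrameSet", function(object) {
  cat(sprintf("FrameSet: %d frames of a %d-atom complex\n",
              frameCount(object), nAtoms(object)))
})

setMethod("show", "TrajectoryRep", function(object) {
  cat(sprintf("TrajectoryRep: %d heavy atoms x %d (mean||std over %d frames)\n",
              nrow(object@rep), ncol(object@rep), object@frameCount))
})

setMethod("show", "Compressor", function(object) {
  cat(sprintf("Compressor (%s): %d -> %d\n", object@kind,
              object@inputDim, object@latentDim))
})

setMethod("show", "PairTensors", function(object) {
  cat(sprintf("PairTensors: %d tokens x %d, solvent dim %d\n",
              nrow(object@meanStream), ncol(object@meanStream),
              length(object@solvent)))
})

setMethod("show", "DualStreamModel", function(object) {
  cfg <- object@config
  cat(sprintf("DualStreamModel: %d block(s)/stream, %d head(s), dim %d, %s head%s\n",
              cfg$n_blocks, cfg$n_heads, cfg$token_dim, cfg$head_kind,
              if (length(object@frozen)) " [partially frozen]" else ""))
})
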