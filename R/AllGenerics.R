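#' Number of residues
#' @param x a CaTrace, Ensemble, ResidueProfile or related object
#' @return integer residue count
#' @export
setGeneric("nResidues", function(x) standardGeneric("nResidues"))

#' Number of frames in an ensemble
#' @param x an Ensemble
#' @return integer frame count
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' Coordinates
#' @param x a CaTrace (N x 3 matrix) or Ensemble (F x N x 3 array)
#' @return numeric coordinates in Angstrom
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' Residue identifiers
#' @param x an object carrying residue ids
#' @return data.frame with columns chain, resno, icode
#' @export
setGeneric("residueIds", function(x) standardGeneric("residueIds"))

#' Per-residue values of a profile
#' @param x a ResidueProfile or WeakSpotProfile
#' @return numeric vector
#' @export
setGeneric("profileValues", function(x) standardGeneric("profileValues"))

setGeneric("as.matrix")

setMethod("nResidues", "CaTrace", function(x) nrow(x@coords))
setMethod("nResidues", "Ensemble", function(x) dim(x@coords)[2])
setMethod("nResidues", "ResidueProfile", function(x) length(x@values))

setMethod("nFrames", "Ensemble", function(x) dim(x@coords)[1])

setMethod("coords", "CaTrace", function(x) x@coords)
setMethod("coords", "Ensemble", function(x) x@coords)

setMethod("residueIds", "CaTrace", function(x) x@ids)
setMethod("residueIds", "Ensemble", function(x) x@ids)
setMethod("residueIds", "ResidueProfile", function(x) x@ids)

setMethod("profileValues", "ResidueProfile", function(x) x@values)
setMethod("profileValues", "WeakSpotProfile", function(x) x@frequency)

#' Extract the matrix payload of a matrix-like result
#' @param x KirchhoffMatrix, PrsMatrix, CouplingMatrix or PathMatrix
#' @param ... unused
#' @return numeric matrix
#' @name as.matrix
#' @aliases as.matrix,KirchhoffMatrix-method as.matrix,PrsMatrix-method
#'   as.matrix,CouplingMatrix-method as.matrix,PathMatrix-method
#' @exportMethod as.matrix
setMethod("as.matrix", "KirchhoffMatrix", function(x, ...) x@mat)
setMethod("as.matrix", "PrsMatrix", function(x, ...) x@mat)
setMethod("as.matrix", "CouplingMatrix", function(x, ...) x@mat)
setMethod("as.matrix", "PathMatrix", function(x, ...) x@dist)

setMethod("show", "CaTrace", function(object) {
  cat(sprintf("CaTrace with %d residues (chain %s)\n",
              nResidues(object),
              paste(unique(object@ids$chain), collapse = ",")))
})

setMethod("show", "AtomStructure", function(object) {
  cat(sprintf("AtomStructure: %d atoms, %d residues, %d bonds (model %d)\n",
              nrow(object@atoms),
              nrow(unique(object@atoms[, c("chain", "resno", "icode")])),
              nrow(object@bonds), object@model))
})

setMethod("show", "Ensemble", function(object) {
  cat(sprintf("Ensemble: %d frames x %d residues\n",
              nFrames(object), nResidues(object)))
  if (length(object@provenance))
    cat("  provenance:", paste(names(object@provenance), collapse = ", "),
        "\n")
})

setMethod("show", "ResidueProfile", function(object) {
  u <- if (nzchar(object@units)) paste0(" [", object@units, "]") else ""
  cat(sprintf("ResidueProfile '%s'%s, %d residues (range %.4g..%.4g)\n",
              object@name, u, length(object@values),
              min(object@values), max(object@values)))
})

setMethod("show", "SquareWellModel", function(object) {
  cat(sprintf("SquareWellModel: %d tethers (%d bonded, %d native), rc = %g A\n",
              nrow(object@tethers), sum(object@tethers$type == "bond"),
              sum(object@tethers$type == "native"), object@params$rc))
})

setMethod("show", "Msa", function(object) {
  cat(sprintf("Msa: %d sequences x %d columns (reference: %s)\n",
              nrow(object@seqs), ncol(object@seqs),
              object@seqnames[object@ref]))
})

setMethod("show", "ResidueGraph", function(object) {
  cat(sprintf("ResidueGraph: %d nodes, %d edges (mode %s)\n",
              object@n, nrow(object@edges),
              object@meta$mode %||% "?"))
})

setMethod("show", "CommunitySet", function(object) {
  cat(sprintf("CommunitySet: %d communities%s%s\n",
              length(object@communities),
              if (object@overlapping) " (overlapping)" else "",
              if (!is.na(object@modularity))
                sprintf(", Q = %.4f", object@modularity) else ""))
})

setMethod("show", "ConstraintNetwork", function(object) {
  tab <- table(object@bars$type)
  cat(sprintf("ConstraintNetwork: %d bodies, %d constraints (%s)\n",
              object@nBodies, nrow(object@bars),
              paste(names(tab), tab, sep = ":", collapse = ", ")))
})

setMethod("show", "RigidDecomposition", function(object) {
  cat(sprintf(
    "RigidDecomposition: %d clusters, giant size %d, %d internal DOF\n",
    length(object@sizes), object@sizes[object@giant], object@dof))
})

`%||%` <- function(a, b) if (is.null(a)) b else a
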