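#' Accessors for gencorrnet containers
#'
#' Accessor generics for the S4 containers: trait labels, the correlation
#' matrix and its sampling covariance, per-pair p/q values, flip flags,
#' cluster membership and modularity, the concordance matrix, and the
#' effective degrees of freedom.
#'
#' @param x a gencorrnet S4 object.
#' @return The slot contents (labels, matrices, named vectors, or scalars).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("traitLabels", function(x) standardGeneric("traitLabels"))
#' @rdname accessors
#' @export
setGeneric("corrMat", function(x) standardGeneric("corrMat"))
#' @rdname accessors
#' @export
setGeneric("sampCov", function(x) standardGeneric("sampCov"))
#' @rdname accessors
#' @export
setGeneric("pValues", function(x) standardGeneric("pValues"))
#' @rdname accessors
#' @export
setGeneric("qValues", function(x) standardGeneric("qValues"))
#' @rdname accessors
#' @export
setGeneric("flippedTraits", function(x) standardGeneric("flippedTraits"))
#' @rdname accessors
#' @export
setGeneric("clusterMembership", function(x) standardGeneric("clusterMembership"))
#' @rdname accessors
#' @export
setGeneric("modularityQ", function(x) standardGeneric("modularityQ"))
#' @rdname accessors
#' @export
setGeneric("concMat", function(x) standardGeneric("concMat"))
#' @rdname accessors
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))
#' @rdname accessors
#' @export
setGeneric("effDf", function(x) standardGeneric("effDf"))

#' @rdname accessors
setMethod("traitLabels", "GenCorrMatrix", function(x) x@labels)
#' @rdname accessors
setMethod("traitLabels", "Partition", function(x) x@labels)
#' @rdname accessors
setMethod("traitLabels", "ConcordanceMatrix", function(x) x@labels)
#' @rdname accessors
setMethod("traitLabels", "EdgeList", function(x) x@labels)
#' @rdname accessors
setMethod("traitLabels", "SimulationConfig", function(x) x@labels)

#' @rdname accessors
setMethod("corrMat", "GenCorrMatrix", function(x) {
  S <- x@S
  dimnames(S) <- list(x@labels, x@labels)
  S
})
#' @rdname accessors
setMethod("sampCov", "GenCorrMatrix", function(x) x@V)
#' @rdname accessors
setMethod("pValues", "GenCorrMatrix", function(x) {
  p <- x@pvals
  dimnames(p) <- list(x@labels, x@labels)
  p
})
#' @rdname accessors
setMethod("qValues", "GenCorrMatrix", function(x) {
  q <- x@qvals
  dimnames(q) <- list(x@labels, x@labels)
  q
})
#' @rdname accessors
setMethod("flippedTraits", "GenCorrMatrix", function(x) {
  stats::setNames(x@flipped, x@labels)
})

#' @rdname accessors
setMethod("clusterMembership", "Partition", function(x) x@membership)
#' @rdname accessors
setMethod("modularityQ", "Partition", function(x) x@q)

#' @rdname accessors
setMethod("concMat", "ConcordanceMatrix", function(x) {
  C <- x@concordance
  dimnames(C) <- list(x@labels, x@labels)
  C
})

#' @rdname accessors
setMethod("edgeTable", "EdgeList", function(x) x@edges)

#' @rdname accessors
setMethod("effDf", "EffDfResult", function(x) x@meff)

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf("SimulationConfig: %d traits, %d SNPs, seed %d\n",
              object@nTraits, object@nSnps, object@seed))
  cat("  h2:", paste(signif(object@h2, 3), collapse = ", "), "\n")
  cat("  N :", paste(object@sampleSizes, collapse = ", "), "\n")
  off <- object@rg[lower.tri(object@rg)]
  if (length(off))
    cat("  rg (off-diagonal):", paste(signif(unique(off), 3), collapse = ", "), "\n")
})

setMethod("show", "FilterReport", function(object) {
  cat(sprintf(paste0("FilterReport: %d in, %d retained ",
                     "(maf %d, hwe %d, region %d, include-list %d removed)\n"),
              object@nInput, object@nRetained, object@nMaf, object@nHwe,
              object@nRegion, object@nInclude))
})

setMethod("show", "UnivariateFit", function(object) {
  cat(sprintf("UnivariateFit '%s': h2 = %.4g (SE %.3g, z = %.3g)\n",
              object@label, object@h2, object@h2Se, object@zH2))
  cat(sprintf("  intercept = %.4g (SE %.3g); mean chi2 = %.3g; %d SNPs, %d blocks\n",
              object@intercept, object@interceptSe, object@meanChi2,
              object@nSnps, object@nBlocks))
})

setMethod("show", "BivariateFit", function(object) {
  cat(sprintf("BivariateFit '%s' ~ '%s': rg = %s (SE %.3g, p = %.3g)\n",
              object@label1, object@label2,
              if (object@rgDefined) sprintf("%.4g", object@rg) else "undefined",
              object@rgSe, object@pRg))
  cat(sprintf("  gcov = %.4g (SE %.3g); cross-intercept = %.4g (SE %.3g)%s\n",
              object@gcov, object@gcovSe, object@crossIntercept,
              object@crossInterceptSe,
              if (isTRUE(object@rgOutOfRange)) "; rg outside [-1,1]" else ""))
})

setMethod("show", "GenCorrMatrix", function(object) {
  T <- length(object@labels)
  cat(sprintf("GenCorrMatrix: %d traits, vech dimension %d\n", T, T * (T + 1) / 2))
  off <- object@S[lower.tri(object@S)]
  cat(sprintf("  off-diagonal rg: range [%.3g, %.3g], %d missing\n",
              suppressWarnings(min(off, na.rm = TRUE)),
              suppressWarnings(max(off, na.rm = TRUE)), sum(is.na(off))))
  if (any(object@flipped))
    cat("  flipped:", paste(object@labels[object@flipped], collapse = ", "), "\n")
})

setMethod("show", "EdgeList", function(object) {
  cat(sprintf("EdgeList: %d vertices, %d edges\n",
              length(object@labels), nrow(object@edges)))
})

setMethod("show", "Partition", function(object) {
  k <- length(unique(object@membership))
  cat(sprintf("Partition: %d traits in %d clusters, q = %.4g\n",
              length(object@labels), k, object@q))
})

setMethod("show", "ConcordanceMatrix", function(object) {
  cat(sprintf("ConcordanceMatrix: %d traits, %d resamples\n",
              length(object@labels), object@nResamples))
  if (length(object@focal) == 1 && !is.na(object@focal))
    cat(sprintf("  focal trait: %s\n", object@focal))
})

setMethod("show", "EffDfResult", function(object) {
  cat(sprintf("EffDfResult (%s): m = %d, meff = %.4g, alpha %.4g -> %.4g\n",
              object@method, object@m, object@meff, object@alphaIn,
              object@alphaCorrected))
})
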