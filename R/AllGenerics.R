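#' @rdname GenotypeData-class
#' @param object,x a `GenotypeData`, `Pedigree` or `RelMatrix` object.
#' @export
setGeneric("genoCodes", function(x) standardGeneric("genoCodes"))

#' @rdname GenotypeData-class
#' @export
setGeneric("markerMap", function(x) standardGeneric("markerMap"))

#' @rdname GenotypeData-class
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname GenotypeData-class
#' @export
setGeneric("nIndividuals", function(x) standardGeneric("nIndividuals"))

#' @rdname GenotypeData-class
#' @export
setGeneric("nMarkers", function(x) standardGeneric("nMarkers"))

#' @rdname RelMatrix-class
#' @export
setGeneric("relMat", function(x) standardGeneric("relMat"))

#' @rdname RelMatrix-class
#' @export
setGeneric("relKind", function(x) standardGeneric("relKind"))

#' @rdname VarianceComponents-class
#' @export
setGeneric("vcEstimates", function(x) standardGeneric("vcEstimates"))

#' @rdname VarianceComponents-class
#' @export
setGeneric("vcSE", function(x) standardGeneric("vcSE"))

#' @rdname VarianceComponents-class
#' @export
setGeneric("vcProportions", function(x) standardGeneric("vcProportions"))

#' @rdname VarianceComponents-class
#' @export
setGeneric("isConverged", function(x) standardGeneric("isConverged"))

# ---- accessors ----

#' @rdname GenotypeData-class
#' @export
setMethod("genoCodes", "GenotypeData", function(x) x@codes)

#' @rdname GenotypeData-class
#' @export
setMethod("markerMap", "GenotypeData", function(x) x@map)

#' @rdname GenotypeData-class
#' @export
setMethod("sampleIds", "GenotypeData", function(x) rownames(x@codes))

#' @rdname GenotypeData-class
#' @export
setMethod("nIndividuals", "GenotypeData", function(x) nrow(x@codes))

#' @rdname GenotypeData-class
#' @export
setMethod("nMarkers", "GenotypeData", function(x) ncol(x@codes))

#' @rdname Pedigree-class
#' @param x a `Pedigree`.
#' @export
setMethod("nIndividuals", "Pedigree", function(x) length(x@id))

#' @rdname RelMatrix-class
#' @export
setMethod("relMat", "RelMatrix", function(x) x@mat)

#' @rdname RelMatrix-class
#' @export
setMethod("relKind", "RelMatrix", function(x) x@kind)

#' @rdname VarianceComponents-class
#' @export
setMethod("vcEstimates", "VarianceComponents", function(x) x@estimates)

#' @rdname VarianceComponents-class
#' @export
setMethod("vcSE", "VarianceComponents", function(x) x@se)

#' @rdname VarianceComponents-class
#' @export
setMethod("vcProportions", "VarianceComponents", function(x) x@proportions)

#' @rdname VarianceComponents-class
#' @export
setMethod("isConverged", "VarianceComponents", function(x) x@converged)

#' @rdname NullModelFit-class
#' @param x a `NullModelFit`.
#' @export
setMethod("isConverged", "NullModelFit", function(x) x@converged)

# ---- show methods ----

setMethod("show", "GenotypeData", function(object) {
  cat("GenotypeData:", nrow(object@codes), "individuals x",
      ncol(object@codes), "markers\n")
  chs <- unique(object@map$chrom)
  cat("  chromosomes:", paste(head(chs, 8), collapse = ", "),
      if (length(chs) > 8) "...\n" else "\n")
  miss <- mean(is.na(object@codes))
  cat(sprintf("  missing rate: %.4f\n", miss))
})

setMethod("show", "Pedigree", function(object) {
  n <- length(object@id)
  founders <- sum(is.na(object@sire) & is.na(object@dam))
  cat("Pedigree:", n, "individuals (", founders, "founders )\n")
  if (length(object@genotyped))
    cat("  genotyped subset:", length(object@genotyped), "individuals\n")
})

setMethod("show", "QCReport", function(object) {
  cat("Marker QC report\n")
  cat("  input:   ", object@nInput, "\n")
  cat("  removed: ", object@nRemovedMaf, "(MAF)",
      object@nRemovedCallrate, "(call rate)",
      object@nRemovedHwe, "(HWE)\n")
  cat("  retained:", object@nRetained, "\n")
})

setMethod("show", "RelMatrix", function(object) {
  cat("RelMatrix (", object@kind, "): ", nrow(object@mat), " x ",
      ncol(object@mat), "\n", sep = "")
  cat(sprintf("  mean diagonal: %.4f", mean(diag(object@mat))))
  if (!any(is.na(object@denom)))
    cat(sprintf("   denominator: %.4f", object@denom))
  cat("\n")
})

setMethod("show", "VarianceComponents", function(object) {
  cat("Variance components (AI-REML",
      if (object@converged) "converged" else "NOT converged", ")\n")
  out <- data.frame(estimate = object@estimates, SE = object@se,
                    proportion = object@proportions,
                    propSE = object@proportionsSE)
  print(round(out, 5))
  cat(sprintf("  logLik: %.4f  iterations: %d\n", object@loglik,
              nrow(object@trace)))
})

setMethod("show", "NullModelFit", function(object) {
  cat("Null polygenic model:",
      sprintf("sigma_g^2 = %.4f, sigma_e^2 = %.4f (%s)\n",
              object@sigmaG2, object@sigmaE2,
              if (object@converged) "converged" else "not converged"))
})

setMethod("show", "SireModelFit", function(object) {
  cat("Sire-model fit (", object@stage, ", trait ", object@trait, ")\n", sep = "")
  show(object@vc)
})

setMethod("show", "SimulationScenario", function(object) {
  cat("SimulationScenario:",
      sprintf("f = %.2f, h = %.2f, sigma_u^2 = %g, sigma_e^2 = %g\n",
              object@varFraction, object@dominanceRatio, object@sigmaU2,
              object@sigmaE2))
  cat("  QTN at", paste(format(object@qtnPositions, big.mark = ","),
                        collapse = ", "),
      "bp (target MAF", paste(object@qtnMafs, collapse = "/"), ")\n")
})
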