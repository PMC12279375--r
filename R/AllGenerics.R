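#' Residue-level view of an object
#'
#' @param x a \linkS4class{ProteinStructure} or \linkS4class{SasaProfile}.
#' @return data.frame with one row per residue.
#' @export
setGeneric("residues", function(x) standardGeneric("residues"))

#' Number of residues
#'
#' @param x a \linkS4class{ProteinStructure}.
#' @return integer residue count.
#' @export
setGeneric("nResidues", function(x) standardGeneric("nResidues"))

#' Contact pairs of a contact map
#'
#' @param x a \linkS4class{ContactMap}.
#' @return data.frame with columns \code{i}, \code{j}, \code{distance}.
#' @export
setGeneric("contacts", function(x) standardGeneric("contacts"))

#' Number of contacts in a contact map
#'
#' @param x a \linkS4class{ContactMap}.
#' @return integer contact count.
#' @export
setGeneric("contactCount", function(x) standardGeneric("contactCount"))

#' Points of an inhibition curve
#'
#' @param x an \linkS4class{InhibitionCurve}.
#' @return data.frame with columns \code{ratio}, \code{activity},
#'   \code{kind}.
#' @export
setGeneric("curvePoints", function(x) standardGeneric("curvePoints"))

# ---- methods -------------------------------------------------------------

#' @describeIn residues one row per residue with \code{resno} and
#'   \code{resid}.
#' @export
setMethod("residues", "ProteinStructure", function(x) {
  a <- x@atoms
  keep <- !duplicated(a$resno)
  data.frame(resno = a$resno[keep], resid = a$resid[keep],
             row.names = NULL)
})

#' @describeIn residues the per-residue SASA table.
#' @export
setMethod("residues", "SasaProfile", function(x) x@residues)

#' @describeIn nResidues residue count of a structure.
#' @export
setMethod("nResidues", "ProteinStructure",
          function(x) length(unique(x@atoms$resno)))

#' @describeIn contacts contact pairs as a data.frame.
#' @export
setMethod("contacts", "ContactMap", function(x) x@pairs)

#' @describeIn contactCount number of stored pairs.
#' @export
setMethod("contactCount", "ContactMap", function(x) nrow(x@pairs))

#' @describeIn curvePoints curve as a data.frame.
#' @export
setMethod("curvePoints", "InhibitionCurve", function(x) {
  data.frame(ratio = x@ratio, activity = x@activity, kind = x@kind)
})

#' Fitted coefficients of an ExpDec1 fit
#'
#' @param object an \linkS4class{ExpDec1Fit}.
#' @param ... ignored.
#' @return named numeric vector \code{c(y0, a1, t1)}.
#' @export
setMethod("coef", "ExpDec1Fit", function(object, ...) {
  c(y0 = object@y0, a1 = object@a1, t1 = object@t1)
})

#' Evaluate an ExpDec1 fit
#'
#' @param object an \linkS4class{ExpDec1Fit}.
#' @param newdata numeric vector of x values (isoform:FLp53 ratios).
#' @param ... ignored.
#' @return fitted values \code{y0 + a1 * exp(-x / t1)}.
#' @export
setMethod("predict", "ExpDec1Fit", function(object, newdata, ...) {
  object@y0 + object@a1 * exp(-newdata / object@t1)
})

setMethod("show", "ProteinStructure", function(object) {
  rn <- unique(object@atoms$resno)
  cat("ProteinStructure: chain", object@chain, "|",
      length(rn), "residues (", min(rn), "-", max(rn), "),",
      nrow(object@atoms), "atoms\n")
})

setMethod("show", "ContactMap", function(object) {
  cat("ContactMap:", nrow(object@pairs), "contacts | cutoff",
      object@cutoff, "A | min separation", object@minSeparation, "\n")
})

setMethod("show", "SasaProfile", function(object) {
  cat("SasaProfile:", nrow(object@residues), "residues | probe",
      object@probeRadius, "A |", object@nPoints, "sphere points\n")
})

setMethod("show", "InhibitionCurve", function(object) {
  cat("InhibitionCurve (", object@kind, "): ", length(object@ratio),
      " points, ratios ", paste(object@ratio, collapse = "/"), "\n",
      sep = "")
})

setMethod("show", "ExpDec1Fit", function(object) {
  cat(sprintf(
    "ExpDec1Fit: y = %.4g + %.4g * exp(-x/%.4g) | RSS %.4g | %s\n",
    object@y0, object@a1, object@t1, object@rss,
    if (object@nonIdentifiable) "non-identifiable"
    else if (object@converged) "converged" else "NOT converged"))
})

setMethod("show", "SubunitMix", function(object) {
  cat(sprintf(
    "SubunitMix: eFL %.3g, eIso %.3g | phi %.2f/%.2f | seq %.2f/%.2f\n",
    object@eFL, object@eIso, object@phiFL, object@phiIso,
    object@seqFL, object@seqIso))
})

setMethod("show", "Scenario", function(object) {
  cat("Scenario: kTrue", object@kTrue, paste0("(", object@mode, ")"),
      "| ratios", paste(object@ratios, collapse = "/"),
      "| n", object@nReplicates, "| seed", object@seed, "\n")
  cat("  C/N enrichment", object@cnEnrichment,
      "| caspase fold", object@caspaseFoldFL,
      "| ChIP:", paste(names(object@chipEnrichments),
                       object@chipEnrichments, sep = "=", collapse = " "),
      "\n")
})
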