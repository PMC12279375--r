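#' ProteinStructure: an ordered set of residues with atomic coordinates
#'
#' A single-chain protein structure in author (PDB) residue numbering.
#' Atoms are stored in a long data.frame; hetero and solvent records are
#' excluded at load time and alternate locations are already resolved to the
#' highest-occupancy conformer. Residue numbering follows the deposited
#' author numbering throughout, so p53 residue ranges such as the DBD
#' (94-292) or the aggregation-prone segment ILTIITL (251-257) can be used
#' directly.
#'
#' @slot atoms data.frame with one row per atom and columns \code{resno}
#'   (integer author residue number), \code{resid} (3-letter residue type),
#'   \code{elety} (atom name, e.g. \code{"CA"}), \code{element} (element
#'   symbol), \code{x}, \code{y}, \code{z} (coordinates in Angstrom) and
#'   \code{occ} (occupancy).
#' @slot chain single chain identifier the atoms came from.
#' @slot source character scratch note on provenance (file path or
#'   generator), not used computationally.
#'
#' @seealso [loadStructure()], [applyTruncation()], [genToyStructure()]
#' @exportClass ProteinStructure
setClass("ProteinStructure",
  representation(atoms = "data.frame", chain = "character",
                 source = "character"),
  prototype(atoms = data.frame(), chain = "A", source = "")
)

setValidity("ProteinStructure", function(object) {
  a <- object@atoms
  need <- c("resno", "resid", "elety", "element", "x", "y", "z", "occ")
  if (!all(need %in% names(a)))
    return(paste("atoms must have columns:", paste(need, collapse = ", ")))
  if (nrow(a) == 0L) return("structure contains no atoms")
  if (!all(is.finite(a$x) & is.finite(a$y) & is.finite(a$z)))
    return("non-finite atomic coordinates")
  rn <- unique(a$resno)
  if (any(diff(rn) <= 0))
    return("author residue numbers must be strictly increasing")
  TRUE
})

#' ContactMap: residue pairs in C-alpha contact
#'
#' The set of unordered residue pairs whose C-alpha atoms lie within a
#' distance cutoff, subject to a minimum sequence separation that keeps
#' trivial neighbours off the map. The default rule (8 A, separation >= 2)
#' is the classic C-alpha tertiary-contact definition used for the p53
#' core domain.
#'
#' @slot pairs data.frame with columns \code{i}, \code{j} (residue numbers,
#'   \code{i < j}) and \code{distance} (C-alpha distance in Angstrom).
#' @slot cutoff distance cutoff in Angstrom (inclusive).
#' @slot minSeparation minimum |i - j| for a pair to be counted.
#'
#' @seealso [computeContactMap()], [lostInterregionContacts()]
#' @exportClass ContactMap
setClass("ContactMap",
  representation(pairs = "data.frame", cutoff = "numeric",
                 minSeparation = "integer"),
  prototype(pairs = data.frame(i = integer(), j = integer(),
                               distance = numeric()),
            cutoff = 8.0, minSeparation = 2L)
)

setValidity("ContactMap", function(object) {
  p <- object@pairs
  if (!all(c("i", "j", "distance") %in% names(p)))
    return("pairs must have columns i, j, distance")
  if (length(object@cutoff) != 1L || object@cutoff <= 0)
    return("cutoff must be a single positive distance")
  if (nrow(p)) {
    if (any(p$i >= p$j)) return("pairs must be stored with i < j")
    if (any(abs(p$i - p$j) < object@minSeparation))
      return("pair violates the minimum sequence separation")
    if (any(p$distance > object@cutoff + 1e-9))
      return("pair distance exceeds the cutoff")
  }
  TRUE
})

#' SasaProfile: per-residue solvent-accessible surface area
#'
#' Absolute and relative solvent-accessible surface area (SASA) per residue
#' from the Shrake-Rupley rolling-probe algorithm. Relative SASA divides the
#' absolute value by a residue-type theoretical maximum, so fully extended
#' residues score near 1 (slightly above 1 is possible).
#'
#' @slot residues data.frame with columns \code{resno}, \code{resid},
#'   \code{sasa} (Angstrom^2) and \code{relSasa} (fraction of the
#'   residue-type maximum; NA for types without a tabulated maximum).
#' @slot probeRadius solvent probe radius in Angstrom (1.4 = water).
#' @slot nPoints number of quasi-uniform sphere points per atom.
#'
#' @seealso [computeSasa()], [exposedHydrophobics()]
#' @exportClass SasaProfile
setClass("SasaProfile",
  representation(residues = "data.frame", probeRadius = "numeric",
                 nPoints = "integer")
)

setValidity("SasaProfile", function(object) {
  r <- object@residues
  if (!all(c("resno", "resid", "sasa", "relSasa") %in% names(r)))
    return("residues must have columns resno, resid, sasa, relSasa")
  if (any(r$sasa < -1e-9)) return("absolute SASA must be non-negative")
  if (object@probeRadius < 0) return("probe radius must be non-negative")
  if (object@nPoints < 1L) return("nPoints must be positive")
  TRUE
})

#' InhibitionCurve: relative promoter activity versus isoform:FLp53 ratio
#'
#' Pairs of expression ratio (isoform:FLp53, with transfected plasmid amount
#' as the expression proxy) and relative promoter activity, normalized so
#' that FLp53 alone (ratio 0) has activity 1. Curves are either
#' \code{"experimental"} (from reporter assays) or \code{"theoretical"}
#' (from the tetramer stoichiometry model).
#'
#' @slot ratio numeric vector of isoform:FLp53 ratios, non-negative and
#'   strictly increasing.
#' @slot activity numeric vector of relative activities (same length).
#' @slot kind \code{"experimental"} or \code{"theoretical"}.
#'
#' @seealso [theoreticalInhibitionCurve()], [reporterInhibitionCurve()],
#'   [inferMinimalThreshold()]
#' @exportClass InhibitionCurve
setClass("InhibitionCurve",
  representation(ratio = "numeric", activity = "numeric", kind = "character")
)

setValidity("InhibitionCurve", function(object) {
  if (length(object@ratio) != length(object@activity))
    return("ratio and activity must have the same length")
  if (any(object@ratio < 0)) return("ratios must be non-negative")
  if (any(diff(object@ratio) <= 0))
    return("ratios must be strictly increasing")
  if (any(object@activity < 0)) return("activities must be non-negative")
  if (!object@kind %in% c("experimental", "theoretical"))
    return("kind must be 'experimental' or 'theoretical'")
  if (object@kind == "theoretical" && any(object@ratio == 0) &&
      abs(object@activity[object@ratio == 0] - 1) > 1e-9)
    return("theoretical curves must have activity 1 at ratio 0")
  TRUE
})

#' ExpDec1Fit: one-phase exponential decay fit
#'
#' Result of fitting \eqn{y = y_0 + A_1 \exp(-x/t_1)} (the Origin "ExpDec1"
#' parameterization) to an inhibition curve by unweighted nonlinear least
#' squares.
#'
#' @slot y0 plateau offset.
#' @slot a1 amplitude at x = 0 above the plateau.
#' @slot t1 decay constant in the units of x (isoform:FLp53 ratio).
#' @slot rss residual sum of squares.
#' @slot converged logical optimizer status.
#' @slot nonIdentifiable TRUE when y had essentially no variance so the
#'   decay parameters are meaningless (a1 ~ 0, t1 = Inf is returned).
#'
#' @seealso [fitExpDec1()]
#' @exportClass ExpDec1Fit
setClass("ExpDec1Fit",
  representation(y0 = "numeric", a1 = "numeric", t1 = "numeric",
                 rss = "numeric", converged = "logical",
                 nonIdentifiable = "logical")
)

setValidity("ExpDec1Fit", function(object) {
  if (!(object@t1 > 0)) return("t1 must be positive (Inf allowed)")
  TRUE
})

#' SubunitMix: an FLp53/isoform monomer pool with compartment corrections
#'
#' Expression levels of FLp53 and one isoform together with per-species
#' nuclear fractions and aggregation-sequestered fractions. The effective
#' nuclear pool of each species is
#' \code{expression * (1 - sequestered) * nuclearFraction}; only the nuclear
#' pools mix into transcription-competent tetramers.
#'
#' @slot eFL,eIso expression levels (arbitrary units; transfected plasmid
#'   amount is the usual proxy).
#' @slot phiFL,phiIso nuclear fractions in [0, 1].
#' @slot seqFL,seqIso aggregated (sequestered) fractions in [0, 1].
#'
#' @seealso [subunitMix()], [nuclearAdjustedFraction()]
#' @exportClass SubunitMix
setClass("SubunitMix",
  representation(eFL = "numeric", eIso = "numeric",
                 phiFL = "numeric", phiIso = "numeric",
                 seqFL = "numeric", seqIso = "numeric")
)

setValidity("SubunitMix", function(object) {
  if (object@eFL < 0 || object@eIso < 0)
    return("expression levels must be non-negative")
  if (object@eFL + object@eIso <= 0)
    return("at least one species must be expressed")
  fr <- c(object@phiFL, object@phiIso, object@seqFL, object@seqIso)
  if (any(fr < 0 | fr > 1)) return("fractions must lie in [0, 1]")
  TRUE
})

#' Scenario: ground-truth parameters for the synthetic-data generators
#'
#' A fully specified set of study conditions for the synthetic assays. The
#' defaults mirror the published observations the package quantifies: a
#' generating inactivation threshold of 3 isoform subunits per tetramer,
#' co-transfection ratios 0/1/5/10, triplicate measurements, a 1.5-fold
#' cytoplasm-to-nucleus enrichment of the isoforms relative to FLp53, and a
#' 2.5-fold caspase-3/7 induction by FLp53 over the empty-vector control.
#' Every generator derives its randomness from \code{seed}, so a fixed seed
#' gives identical tables.
#'
#' @slot kTrue generating inactivation threshold (isoform subunits per
#'   tetramer that abolish activity), in 1..4.
#' @slot mode activity mode, \code{"step"} or \code{"proportional"}.
#' @slot ratios isoform:FLp53 co-transfection ratios (first must be 0).
#' @slot nReplicates replicates per condition.
#' @slot cvReporter,cvFractionation,cvCaspase coefficients of variation of
#'   the multiplicative lognormal noise per assay.
#' @slot sdCt additive Gaussian noise SD on qPCR Ct values (cycles).
#' @slot cnEnrichment isoform cytoplasm-to-nucleus ratio relative to FLp53
#'   (FLp53 set as 1).
#' @slot cnRatioFL absolute FLp53 cytoplasm-to-nucleus ratio (p53 is
#'   predominantly nuclear, so < 1).
#' @slot caspaseFoldFL FLp53 caspase-3/7 induction fold over control.
#' @slot caspaseFoldWithIso residual fold when FLp53 is co-expressed with an
#'   isoform at 1:5.
#' @slot chipEnrichments named numeric, FLp53 ChIP fold enrichment per
#'   promoter (control = 1).
#' @slot chipIsoformEnrichment residual isoform enrichment (DNA binding is
#'   largely lost).
#' @slot chipInputFraction fraction of chromatin kept as qPCR input.
#' @slot controlLum baseline reporter luminescence of the empty-vector
#'   control (arbitrary units).
#' @slot foldActivationFL reporter fold activation by FLp53 alone over the
#'   empty-vector control.
#' @slot blankLum background (blank-reaction) caspase luminescence.
#' @slot signalLumControl caspase luminescence of the empty-vector control
#'   above blank.
#' @slot seed integer RNG seed.
#'
#' @seealso [Scenario()], [genReporterDataset()], [genChipDataset()],
#'   [genFractionationDataset()], [genCaspaseDataset()]
#' @exportClass Scenario
setClass("Scenario",
  representation(kTrue = "integer", mode = "character", ratios = "numeric",
                 nReplicates = "integer", cvReporter = "numeric",
                 cvFractionation = "numeric", cvCaspase = "numeric",
                 sdCt = "numeric", cnEnrichment = "numeric",
                 cnRatioFL = "numeric", caspaseFoldFL = "numeric",
                 caspaseFoldWithIso = "numeric",
                 chipEnrichments = "numeric",
                 chipIsoformEnrichment = "numeric",
                 chipInputFraction = "numeric", controlLum = "numeric",
                 foldActivationFL = "numeric", blankLum = "numeric",
                 signalLumControl = "numeric", seed = "integer")
)

setValidity("Scenario", function(object) {
  if (!object@kTrue %in% 1:4) return("kTrue must be in 1..4")
  if (!object@mode %in% c("step", "proportional"))
    return("mode must be 'step' or 'proportional'")
  if (length(object@ratios) < 2L || object@ratios[1] != 0 ||
      any(diff(object@ratios) <= 0))
    return("ratios must start at 0 and be strictly increasing")
  if (object@nReplicates < 1L) return("nReplicates must be >= 1")
  cvs <- c(object@cvReporter, object@cvFractionation, object@cvCaspase,
           object@sdCt)
  if (any(cvs < 0)) return("noise levels must be non-negative")
  if (object@cnEnrichment <= 0 || object@cnRatioFL <= 0)
    return("partition parameters must be positive")
  if (object@caspaseFoldFL <= 0) return("caspaseFoldFL must be positive")
  if (is.null(names(object@chipEnrichments)))
    return("chipEnrichments must be a named vector (per promoter)")
  if (object@chipInputFraction <= 0 || object@chipInputFraction > 1)
    return("chipInputFraction must be in (0, 1]")
  TRUE
})
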