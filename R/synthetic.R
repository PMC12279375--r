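#' Construct a Scenario of ground-truth study conditions
#'
#' The defaults reproduce the published study design and effect sizes: a
#' step inactivation threshold of 3 isoform subunits per tetramer,
#' co-transfection ratios 0/1/5/10, triplicates, isoform
#' cytoplasm-to-nucleus enrichment 1.5 relative to FLp53, FLp53 caspase
#' induction 2.5-fold over the empty-vector control, and illustrative
#' figure-scale ChIP enrichments (p21 > MDM2 > BAX ~ PUMA). Noise levels
#' default to CV 10% for luminescence-type readouts (20% for fractionation
#' band intensities) and 0.05 cycles for qPCR Ct values.
#'
#' @param kTrue generating inactivation threshold, default 3.
#' @param mode activity mode, default \code{"step"}.
#' @param ratios co-transfection ratios, default \code{c(0, 1, 5, 10)}.
#' @param nReplicates replicates per condition, default 3.
#' @param cvReporter,cvFractionation,cvCaspase lognormal noise CVs.
#' @param sdCt Gaussian Ct noise SD (cycles).
#' @param cnEnrichment isoform C/N ratio relative to FLp53, default 1.5.
#' @param cnRatioFL absolute FLp53 C/N ratio, default 0.5.
#' @param caspaseFoldFL FLp53 caspase fold over control, default 2.5.
#' @param caspaseFoldWithIso residual fold at 1:5 co-expression,
#'   default 1.3.
#' @param chipEnrichments named FLp53 fold enrichments per promoter.
#' @param chipIsoformEnrichment residual isoform enrichment, default 1.2.
#' @param chipInputFraction qPCR input fraction, default 0.05.
#' @param controlLum empty-vector reporter luminescence, default 100.
#' @param foldActivationFL FLp53 reporter fold activation, default 20.
#' @param blankLum blank caspase luminescence, default 500.
#' @param signalLumControl control caspase signal above blank,
#'   default 1000.
#' @param seed integer RNG seed, default 1.
#' @return a \linkS4class{Scenario}.
#' @examples
#' Scenario(seed = 7)
#' @export
Scenario <- function(kTrue = 3L, mode = "step",
                     ratios = c(0, 1, 5, 10), nReplicates = 3L,
                     cvReporter = 0.10, cvFractionation = 0.20,
                     cvCaspase = 0.10, sdCt = 0.05,
                     cnEnrichment = 1.5, cnRatioFL = 0.5,
                     caspaseFoldFL = 2.5, caspaseFoldWithIso = 1.3,
                     chipEnrichments = c(p21 = 8, MDM2 = 4, BAX = 2.5,
                                         PUMA = 2),
                     chipIsoformEnrichment = 1.2,
                     chipInputFraction = 0.05,
                     controlLum = 100, foldActivationFL = 20,
                     blankLum = 500, signalLumControl = 1000,
                     seed = 1L) {
  new("Scenario", kTrue = as.integer(kTrue), mode = mode,
      ratios = as.numeric(ratios), nReplicates = as.integer(nReplicates),
      cvReporter = cvReporter, cvFractionation = cvFractionation,
      cvCaspase = cvCaspase, sdCt = sdCt, cnEnrichment = cnEnrichment,
      cnRatioFL = cnRatioFL, caspaseFoldFL = caspaseFoldFL,
      caspaseFoldWithIso = caspaseFoldWithIso,
      chipEnrichments = chipEnrichments,
      chipIsoformEnrichment = chipIsoformEnrichment,
      chipInputFraction = chipInputFraction, controlLum = controlLum,
      foldActivationFL = foldActivationFL, blankLum = blankLum,
      signalLumControl = signalLumControl, seed = as.integer(seed))
}

# run code under a seed without disturbing the caller's RNG state
.withSeed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  code
}

# lognormal sdlog giving a multiplicative noise of the requested CV;
# meanlog 0, so the noise multiplier has median 1
.cvToSdlog <- function(cv) sqrt(log(1 + cv^2))

.lnoise <- function(n, cv) {
  if (cv == 0) rep(1, n) else rlnorm(n, meanlog = 0,
                                     sdlog = .cvToSdlog(cv))
}

#' Synthetic luciferase reporter dataset
#'
#' Emulates an FLp53/isoform co-transfection reporter titration: the true
#' relative activity at each ratio comes from the tetramer stoichiometry
#' model (\code{kTrue}, \code{mode}); replicate luminescence is
#' \code{controlLum * foldActivationFL * activity} (for p53 conditions) or
#' \code{controlLum} (empty-vector control) times multiplicative lognormal
#' noise of CV \code{cvReporter}.
#'
#' @param s a \linkS4class{Scenario}.
#' @return data.frame with columns \code{assay}, \code{condition},
#'   \code{ratio} (NA for the control rows), \code{replicate},
#'   \code{luminescence}, plus attribute \code{"trueActivity"} (named by
#'   ratio).
#' @examples
#' head(genReporterDataset(Scenario(cvReporter = 0)))
#' @export
genReporterDataset <- function(s) {
  stopifnot(is(s, "Scenario"))
  .withSeed(s@seed + 101L, {
    act <- vapply(isoformFraction(s@ratios), tetramerActivity,
                  numeric(1), k = s@kTrue, mode = s@mode)
    n <- s@nReplicates
    conds <- c("pcDNA3.1", paste0("ratio_", s@ratios))
    truth <- c(NA, s@controlLum * s@foldActivationFL * act)
    truth[1] <- s@controlLum
    rows <- do.call(rbind, lapply(seq_along(conds), function(ci) {
      data.frame(assay = "luciferase", condition = conds[ci],
                 ratio = if (ci == 1L) NA_real_ else s@ratios[ci - 1L],
                 replicate = seq_len(n),
                 luminescence = truth[ci] * .lnoise(n, s@cvReporter))
    }))
    attr(rows, "trueActivity") <- setNames(act, s@ratios)
    rows
  })
}

#' Synthetic ChIP-qPCR dataset
#'
#' Generates IP/input Ct pairs such that the percent-input arithmetic
#' recovers the scenario's fold enrichments: FLp53 binds each promoter with
#' its \code{chipEnrichments} fold over the empty-vector control, while the
#' truncated isoforms retain only \code{chipIsoformEnrichment}. Gaussian
#' noise of SD \code{sdCt} cycles is added to every Ct.
#'
#' @param s a \linkS4class{Scenario}.
#' @return data.frame with columns \code{assay}, \code{promoter},
#'   \code{construct}, \code{replicate}, \code{ct_ip}, \code{ct_input},
#'   \code{input_fraction}; attribute \code{"trueEnrichment"} is the
#'   promoter-by-construct fold matrix.
#' @export
genChipDataset <- function(s) {
  stopifnot(is(s, "Scenario"))
  .withSeed(s@seed + 202L, {
    proms <- names(s@chipEnrichments)
    constructs <- c("pcDNA3.1", "FLp53", "D133p53", "D160p53")
    folds <- rbind(pcDNA3.1 = rep(1, length(proms)),
                   FLp53 = s@chipEnrichments,
                   D133p53 = rep(s@chipIsoformEnrichment, length(proms)),
                   D160p53 = rep(s@chipIsoformEnrichment, length(proms)))
    colnames(folds) <- proms
    basePI <- 0.1      # control percent input
    ctInput0 <- 20     # true input Ct
    n <- s@nReplicates
    rows <- do.call(rbind, lapply(proms, function(pr) {
      do.call(rbind, lapply(constructs, function(cc) {
        pin <- basePI * folds[cc, pr]
        ctIp0 <- ctInput0 - log2(1 / s@chipInputFraction) -
          log2(pin / 100)
        data.frame(assay = "chip", promoter = pr, construct = cc,
                   replicate = seq_len(n),
                   ct_ip = ctIp0 + rnorm(n, 0, s@sdCt),
                   ct_input = ctInput0 + rnorm(n, 0, s@sdCt),
                   input_fraction = s@chipInputFraction)
      }))
    }))
    attr(rows, "trueEnrichment") <- folds
    rows
  })
}

#' Synthetic subcellular fractionation dataset
#'
#' Band intensities for cytoplasmic and nuclear fractions of FLp53 and the
#' two truncated isoforms. FLp53 has cytoplasm-to-nucleus ratio
#' \code{cnRatioFL}; the isoforms' C/N ratio is \code{cnEnrichment}-fold
#' higher. Signals and fraction markers each receive independent
#' multiplicative lognormal noise of CV \code{cvFractionation}, so the
#' geometric-mean estimator [estimateCnEnrichment()] is unbiased on the log
#' scale.
#'
#' @param s a \linkS4class{Scenario}.
#' @return data.frame with columns \code{assay}, \code{construct},
#'   \code{replicate}, \code{fraction}, \code{signal},
#'   \code{marker_signal}; attribute \code{"trueEnrichment"} is
#'   \code{cnEnrichment}.
#' @export
genFractionationDataset <- function(s) {
  stopifnot(is(s, "Scenario"))
  .withSeed(s@seed + 303L, {
    nucLevel <- 2.0   # arbitrary band-intensity scale
    cn <- c(FLp53 = s@cnRatioFL,
            D133p53 = s@cnRatioFL * s@cnEnrichment,
            D160p53 = s@cnRatioFL * s@cnEnrichment)
    n <- s@nReplicates
    rows <- do.call(rbind, lapply(names(cn), function(cc) {
      do.call(rbind, lapply(c("cytoplasm", "nucleus"), function(fr) {
        truth <- if (fr == "cytoplasm") nucLevel * cn[[cc]] else nucLevel
        data.frame(assay = "fractionation", construct = cc,
                   replicate = seq_len(n), fraction = fr,
                   signal = truth * .lnoise(n, s@cvFractionation),
                   marker_signal = 1.0 * .lnoise(n, s@cvFractionation))
      }))
    }))
    attr(rows, "trueEnrichment") <- s@cnEnrichment
    rows
  })
}

#' Synthetic caspase-3/7 luminescence dataset
#'
#' Luminescence is blank background plus signal: the empty-vector control
#' reads \code{blankLum + signalLumControl}, FLp53 multiplies the signal by
#' \code{caspaseFoldFL}, and the 1:5 FLp53+isoform co-expressions by
#' \code{caspaseFoldWithIso}. Whole readings receive multiplicative
#' lognormal noise of CV \code{cvCaspase}; blank-reaction rows are
#' included.
#'
#' @param s a \linkS4class{Scenario}.
#' @return data.frame with columns \code{assay}, \code{construct},
#'   \code{replicate}, \code{luminescence}; attribute \code{"trueFold"}
#'   names the generating folds.
#' @export
genCaspaseDataset <- function(s) {
  stopifnot(is(s, "Scenario"))
  .withSeed(s@seed + 404L, {
    folds <- c(pcDNA3.1 = 1, FLp53 = s@caspaseFoldFL,
               `FLp53+D133p53` = s@caspaseFoldWithIso,
               `FLp53+D160p53` = s@caspaseFoldWithIso)
    truth <- c(blank = s@blankLum,
               s@blankLum + s@signalLumControl * folds)
    n <- s@nReplicates
    rows <- do.call(rbind, lapply(names(truth), function(cc) {
      data.frame(assay = "caspase", construct = cc,
                 replicate = seq_len(n),
                 luminescence = truth[[cc]] * .lnoise(n, s@cvCaspase))
    }))
    attr(rows, "trueFold") <- folds
    rows
  })
}

#' Generate a toy protein structure with known geometry
#'
#' Two deterministic-by-seed geometries for testing the structure module:
#' \code{"ideal_helix"} places C-alpha atoms on a standard alpha-helical
#' spiral (rise 1.5 A per residue, 100 degrees per residue, radius 2.3 A),
#' whose contact set is known analytically (i, i+2..i+4 within 8 A; i,
#' i+10 beyond); \code{"compact_cluster"} rejection-samples positions
#' inside a sphere with a minimum inter-C-alpha distance of 3.8 A, giving
#' irregular globule-like contact sets for oracle comparisons. Residues
#' are alanines with a single C-alpha atom.
#'
#' @param nResidues number of residues (>= 3).
#' @param geometry \code{"ideal_helix"} (default) or
#'   \code{"compact_cluster"}.
#' @param seed RNG seed (used by the cluster geometry; the helix is fully
#'   deterministic).
#' @param firstResno author number of the first residue, default 1.
#' @return a \linkS4class{ProteinStructure}.
#' @examples
#' genToyStructure(20, "compact_cluster", seed = 3)
#' @export
genToyStructure <- function(nResidues,
                            geometry = c("ideal_helix",
                                         "compact_cluster"),
                            seed = 1L, firstResno = 1L) {
  geometry <- match.arg(geometry)
  nResidues <- as.integer(nResidues)
  if (nResidues < 3L) stop("nResidues must be >= 3")
  coords <- if (geometry == "ideal_helix") {
    i <- seq_len(nResidues) - 1L
    ang <- i * 100 * pi / 180
    cbind(x = 2.3 * cos(ang), y = 2.3 * sin(ang), z = 1.5 * i)
  } else {
    .withSeed(as.integer(seed) + 505L, {
      # sphere radius sized for ~38 A^3 per residue packing volume
      R <- max(6, (3 * nResidues * 3.8^3 / (4 * pi))^(1 / 3) * 1.35)
      pts <- matrix(NA_real_, nResidues, 3)
      for (ii in seq_len(nResidues)) {
        ok <- FALSE
        for (try in seq_len(5000L)) {
          p <- runif(3, -R, R)
          if (sum(p^2) > R^2) next
          if (ii > 1L) {
            d2 <- colSums((t(pts[seq_len(ii - 1L), , drop = FALSE]) -
                             p)^2)
            if (min(d2) < 3.8^2) next
          }
          pts[ii, ] <- p
          ok <- TRUE
          break
        }
        if (!ok)
          stop("could not pack ", nResidues,
               " residues at 3.8 A minimum distance; packing infeasible")
      }
      colnames(pts) <- c("x", "y", "z")
      pts
    })
  }
  resno <- seq.int(firstResno, length.out = nResidues)
  atoms <- data.frame(resno = as.integer(resno), resid = "ALA",
                      elety = "CA", element = "C",
                      x = coords[, "x"], y = coords[, "y"],
                      z = coords[, "z"], occ = 1, row.names = NULL)
  new("ProteinStructure", atoms = atoms, chain = "A",
      source = paste0("genToyStructure:", geometry))
}
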