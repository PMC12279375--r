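#' Normalize reporter luminescence to the empty-vector control
#'
#' Divides every replicate by the mean luminescence of the control-vector
#' condition (pcDNA3.1 in the published design), yielding relative reporter
#' activity; the control maps to 1 by construction. Summaries are mean, SD
#' and n per condition.
#'
#' @param table long-format data.frame with columns \code{condition},
#'   \code{replicate} and \code{luminescence} (a \code{ratio} column, if
#'   present, is carried through to the summary).
#' @param control condition label of the control vector, default
#'   \code{"pcDNA3.1"}.
#' @return list with \code{summary} (condition, mean, sd, n and optionally
#'   ratio) and \code{replicates} (input rows plus \code{relActivity}).
#' @examples
#' tab <- data.frame(condition = rep(c("pcDNA3.1", "FLp53"), each = 3),
#'                   replicate = rep(1:3, 2),
#'                   luminescence = c(100, 100, 100, 250, 250, 250))
#' normalizeReporter(tab)$summary
#' @export
normalizeReporter <- function(table, control = "pcDNA3.1") {
  need <- c("condition", "replicate", "luminescence")
  if (!all(need %in% names(table)))
    stop("table must have columns: ", paste(need, collapse = ", "))
  ctrl <- table$luminescence[table$condition == control]
  if (!length(ctrl))
    stop("control condition '", control, "' not present")
  cm <- mean(ctrl)
  if (!is.finite(cm) || cm <= 0)
    stop("control mean luminescence must be positive, got ", cm)
  reps <- table
  reps$relActivity <- reps$luminescence / cm
  conds <- unique(reps$condition)
  summ <- data.frame(
    condition = conds,
    mean = vapply(conds, function(cc)
      mean(reps$relActivity[reps$condition == cc]), numeric(1)),
    sd = vapply(conds, function(cc)
      sd(reps$relActivity[reps$condition == cc]), numeric(1)),
    n = vapply(conds, function(cc)
      sum(reps$condition == cc), integer(1)),
    row.names = NULL)
  if ("ratio" %in% names(table))
    summ$ratio <- table$ratio[match(conds, table$condition)]
  list(summary = summ, replicates = reps)
}

#' Experimental inhibition curve from a reporter table
#'
#' Builds the experimental inhibition curve of an FLp53/isoform titration:
#' replicates are normalized to the control vector, activities are averaged
#' per co-transfection ratio, and the curve is rescaled so the FLp53-alone
#' point (ratio 0) equals 1.
#'
#' @param table reporter table as in [normalizeReporter()], with a
#'   \code{ratio} column (NA for the control-vector rows, 0 for FLp53
#'   alone).
#' @param control control-vector condition label, default \code{"pcDNA3.1"}.
#' @return an \linkS4class{InhibitionCurve} of kind \code{"experimental"}.
#' @export
reporterInhibitionCurve <- function(table, control = "pcDNA3.1") {
  if (!"ratio" %in% names(table))
    stop("table must have a 'ratio' column")
  summ <- normalizeReporter(table, control = control)$summary
  summ <- summ[!is.na(summ$ratio), , drop = FALSE]
  if (!any(summ$ratio == 0))
    stop("table must include the ratio-0 (FLp53 alone) condition")
  summ <- summ[order(summ$ratio), , drop = FALSE]
  ref <- summ$mean[summ$ratio == 0]
  if (ref <= 0) stop("FLp53-alone activity must be positive")
  new("InhibitionCurve", ratio = summ$ratio,
      activity = summ$mean / ref, kind = "experimental")
}

#' ChIP-qPCR percent input
#'
#' Standard base-2 percent-input arithmetic: the input Ct is first adjusted
#' for the input dilution (\code{ctInput - log2(1/inputFraction)}), then
#' \eqn{100 \cdot 2^{ct_{input,adj} - ct_{IP}}}.
#'
#' @param ctIp IP-sample Ct values (vectorized).
#' @param ctInput matched input Ct values.
#' @param inputFraction fraction of chromatin used as input, in (0, 1].
#' @return percent input (percent of total chromatin recovered).
#' @examples
#' chipPercentInput(25, 20, 0.05)  # ~0.156 %
#' @export
chipPercentInput <- function(ctIp, ctInput, inputFraction) {
  if (any(!is.finite(ctIp)) || any(!is.finite(ctInput)))
    stop("Ct values must be finite")
  if (any(inputFraction <= 0) || any(inputFraction > 1))
    stop("inputFraction must be in (0, 1]")
  100 * 2^((ctInput - log2(1 / inputFraction)) - ctIp)
}

#' ChIP relative fold enrichment
#'
#' Percent input of a sample divided by the percent input of the control
#' (the empty-vector pcDNA3.1 sample is taken as 1 in the published
#' analysis).
#'
#' @inheritParams chipPercentInput
#' @param controlPercentInput percent input of the control sample (> 0);
#'   scalar or vector.
#' @return fold enrichment over the control.
#' @examples
#' pin <- chipPercentInput(22, 20, 0.05)
#' chipRelativeEnrichment(22, 20, 0.05, controlPercentInput = pin / 4)
#' @export
chipRelativeEnrichment <- function(ctIp, ctInput, inputFraction,
                                   controlPercentInput) {
  if (any(!is.finite(controlPercentInput)) ||
      any(controlPercentInput <= 0))
    stop("control percent input must be positive")
  chipPercentInput(ctIp, ctInput, inputFraction) / controlPercentInput
}

#' Per-promoter ChIP enrichment from a long-format Ct table
#'
#' Averages percent input over replicates per promoter and construct, then
#' expresses each construct relative to the control construct of the same
#' promoter.
#'
#' @param table data.frame with columns \code{promoter}, \code{construct},
#'   \code{replicate}, \code{ct_ip}, \code{ct_input},
#'   \code{input_fraction}.
#' @param control control construct label, default \code{"pcDNA3.1"}.
#' @return data.frame (promoter, construct, foldEnrichment, n).
#' @export
estimateChipEnrichment <- function(table, control = "pcDNA3.1") {
  need <- c("promoter", "construct", "replicate", "ct_ip", "ct_input",
            "input_fraction")
  if (!all(need %in% names(table)))
    stop("table must have columns: ", paste(need, collapse = ", "))
  table$percentInput <- chipPercentInput(table$ct_ip, table$ct_input,
                                         table$input_fraction)
  agg <- aggregate(percentInput ~ promoter + construct, data = table,
                   FUN = mean)
  nn <- aggregate(percentInput ~ promoter + construct, data = table,
                  FUN = length)
  agg$n <- nn$percentInput
  ctrl <- agg[agg$construct == control, c("promoter", "percentInput")]
  if (!nrow(ctrl)) stop("control construct '", control, "' not present")
  idx <- match(agg$promoter, ctrl$promoter)
  ctrlPI <- ctrl$percentInput[idx]
  if (any(is.na(ctrlPI)))
    stop("control construct missing for promoter(s): ",
         paste(unique(agg$promoter[is.na(ctrlPI)]), collapse = ", "))
  if (any(ctrlPI <= 0)) stop("control percent input must be positive")
  data.frame(promoter = agg$promoter, construct = agg$construct,
             foldEnrichment = agg$percentInput / ctrlPI, n = agg$n,
             row.names = NULL)
}

#' Annotate a sequence against the p53 response-element consensus
#'
#' Compares each decamer half-site of a response element with the canonical
#' p53 consensus RRRCWWGYYY (IUPAC: R = A/G, W = A/T, Y = C/T) and renders
#' the sequence with matched bases in uppercase and mismatches in
#' lowercase, mirroring the usual annotation of p53RE alignments. Half-sites
#' are assumed contiguous (zero spacer); sequences whose length is not a
#' multiple of 10 are rejected.
#'
#' @param sequence DNA string over A/C/G/T (case-insensitive), length a
#'   multiple of 10.
#' @return list with \code{match} (per-base logical), \code{display}
#'   (annotated string), \code{mismatchCount} and \code{nHalfSites}.
#' @examples
#' annotateResponseElement("GAACATGTCC")$mismatchCount  # 0
#' @export
annotateResponseElement <- function(sequence) {
  if (length(sequence) != 1L || !is.character(sequence))
    stop("sequence must be a single string")
  bases <- strsplit(toupper(sequence), "")[[1]]
  bad <- !bases %in% c("A", "C", "G", "T")
  if (any(bad))
    stop("non-ACGT character(s) at position(s): ",
         paste(which(bad), collapse = ", "))
  if (length(bases) %% 10 != 0)
    stop("sequence length ", length(bases),
         " is not a multiple of 10 (remainder ", length(bases) %% 10,
         "); p53REs are contiguous decamer half-sites")
  pattern <- strsplit("RRRCWWGYYY", "")[[1]]
  allowed <- strsplit(Biostrings::IUPAC_CODE_MAP[pattern], "")
  nSites <- length(bases) / 10
  patFull <- rep(seq_len(10), nSites)
  match <- vapply(seq_along(bases), function(i)
    bases[i] %in% allowed[[patFull[i]]], logical(1))
  display <- paste0(ifelse(match, bases, tolower(bases)), collapse = "")
  list(match = match, display = display,
       mismatchCount = sum(!match), nHalfSites = as.integer(nSites))
}

#' Marker-normalized cytoplasm-to-nucleus ratio
#'
#' Band intensities are first normalized to the fraction markers
#' (alpha-tubulin for cytoplasm, histone H3 for nucleus); the C/N ratio is
#' the quotient of the two normalized signals, optionally re-expressed
#' relative to a reference construct's C/N ratio (FLp53 set as 1 in the
#' published analysis).
#'
#' @param cytSignal,cytMarker cytoplasmic band and marker intensities
#'   (> 0; vectorized).
#' @param nucSignal,nucMarker nuclear band and marker intensities (> 0).
#' @param referenceRatio C/N ratio of the reference construct, default 1
#'   (no renormalization).
#' @return normalized C/N ratio.
#' @examples
#' fl <- fractionationCNRatio(1.0, 1.0, 2.0, 1.0)           # 0.5
#' fractionationCNRatio(1.5, 1.0, 2.0, 1.0, referenceRatio = fl)  # 1.5
#' @export
fractionationCNRatio <- function(cytSignal, cytMarker, nucSignal,
                                 nucMarker, referenceRatio = 1) {
  v <- c(cytSignal, cytMarker, nucSignal, nucMarker, referenceRatio)
  if (any(!is.finite(v)) || any(v <= 0))
    stop("all intensities and the reference ratio must be positive")
  ((cytSignal / cytMarker) / (nucSignal / nucMarker)) / referenceRatio
}

#' Geometric-mean C/N enrichment from a fractionation table
#'
#' Per replicate, computes the marker-normalized C/N ratio of each
#' construct; per construct, summarizes replicates by the geometric mean
#' (the natural location estimator under multiplicative band noise); then
#' expresses every construct relative to the reference construct, whose
#' value is 1 by construction.
#'
#' @param table data.frame with columns \code{construct},
#'   \code{replicate}, \code{fraction} (\code{"cytoplasm"} or
#'   \code{"nucleus"}), \code{signal}, \code{marker_signal}.
#' @param reference reference construct, default \code{"FLp53"}.
#' @return named numeric vector of C/N enrichment factors relative to the
#'   reference.
#' @export
estimateCnEnrichment <- function(table, reference = "FLp53") {
  need <- c("construct", "replicate", "fraction", "signal",
            "marker_signal")
  if (!all(need %in% names(table)))
    stop("table must have columns: ", paste(need, collapse = ", "))
  if (!reference %in% table$construct)
    stop("reference construct '", reference, "' not present")
  cyt <- table[table$fraction == "cytoplasm", , drop = FALSE]
  nuc <- table[table$fraction == "nucleus", , drop = FALSE]
  key <- function(d) paste(d$construct, d$replicate, sep = "|")
  idx <- match(key(cyt), key(nuc))
  if (anyNA(idx))
    stop("every construct/replicate needs both fractions")
  cn <- fractionationCNRatio(cyt$signal, cyt$marker_signal,
                             nuc$signal[idx], nuc$marker_signal[idx])
  gm <- tapply(log(cn), cyt$construct, mean)
  gm <- exp(gm)
  out <- gm / gm[[reference]]
  setNames(as.numeric(out), names(gm))
}

#' Caspase-3/7 fold activity with blank subtraction
#'
#' Background luminescence of the blank reaction is subtracted from sample
#' and control means before taking the ratio:
#' \code{(mean(sample) - mean(blank)) / (mean(control) - mean(blank))}.
#'
#' @param sampleLum sample luminescence replicates.
#' @param blankLum blank-reaction luminescence replicates.
#' @param controlLum control-vector luminescence replicates.
#' @return fold caspase activity over the control.
#' @examples
#' caspaseFold(3500, 500, 1700)  # 2.5
#' @export
caspaseFold <- function(sampleLum, blankLum, controlLum) {
  if (any(!is.finite(c(sampleLum, blankLum, controlLum))))
    stop("luminescence values must be finite")
  bl <- mean(blankLum)
  denom <- mean(controlLum) - bl
  if (denom <= 0)
    stop("control minus blank luminescence must be positive")
  num <- mean(sampleLum) - bl
  if (num < 0)
    warning("sample luminescence below blank; negative fold returned")
  num / denom
}

#' Caspase fold of one construct from a long-format table
#'
#' @param table data.frame with columns \code{construct},
#'   \code{replicate}, \code{luminescence}.
#' @param construct construct to quantify, default \code{"FLp53"}.
#' @param control control-vector construct, default \code{"pcDNA3.1"}.
#' @param blank blank-reaction label, default \code{"blank"}.
#' @return fold caspase activity over the control.
#' @export
estimateCaspaseFold <- function(table, construct = "FLp53",
                                control = "pcDNA3.1", blank = "blank") {
  need <- c("construct", "replicate", "luminescence")
  if (!all(need %in% names(table)))
    stop("table must have columns: ", paste(need, collapse = ", "))
  pick <- function(lbl) {
    v <- table$luminescence[table$construct == lbl]
    if (!length(v)) stop("no rows for construct '", lbl, "'")
    v
  }
  caspaseFold(pick(construct), pick(blank), pick(control))
}

#' Two-sample t-test
#'
#' Pooled-variance Student's t-test by default (two-sided), matching the
#' "Student's t-test" annotation of the quantified assays; a Welch variant
#' is available. Degenerate zero-variance inputs are handled explicitly:
#' equal means give t = 0, p = 1; unequal means give infinite t with p = 0
#' and a flag.
#'
#' @param a,b numeric replicate vectors, each of length >= 2.
#' @param variant \code{"student"} (default) or \code{"welch"}.
#' @return list with \code{statistic}, \code{df}, \code{p.value},
#'   \code{variant} and \code{degenerate} (TRUE when variance was zero).
#' @examples
#' twoSampleTTest(c(1, 2, 3), c(4, 5, 6))
#' @export
twoSampleTTest <- function(a, b, variant = c("student", "welch")) {
  variant <- match.arg(variant)
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 replicates")
  if (var(a) == 0 && var(b) == 0) {
    if (mean(a) == mean(b))
      return(list(statistic = 0, df = length(a) + length(b) - 2,
                  p.value = 1, variant = variant, degenerate = TRUE))
    return(list(statistic = sign(mean(a) - mean(b)) * Inf,
                df = length(a) + length(b) - 2, p.value = 0,
                variant = variant, degenerate = TRUE))
  }
  ht <- t.test(a, b, var.equal = (variant == "student"))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p.value = ht$p.value, variant = variant, degenerate = FALSE)
}
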