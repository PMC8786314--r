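## Photolabeling quantification: formula masses, diazirine photoadducts,
## acceptance filtering, apparent labeling efficiency, competition
## normalization.

## Element mass tables. Monoisotopic masses: CODATA/AME2020 values of the
## principal isotope. Average masses: IUPAC 2021 conventional standard
## atomic weights (S = 32.06, which reproduces the conventional +257.5 Da
## hexadecylthio adduct shift).
.monoMass <- c(C = 12.0, H = 1.0078250319, N = 14.0030740052,
               O = 15.9949146221, S = 31.97207069, F = 18.99840322,
               P = 30.97376151, Na = 22.98976928, K = 38.96370649)
.avgMass <- c(C = 12.011, H = 1.008, N = 14.007, O = 15.999, S = 32.06,
              F = 18.998403163, P = 30.973761998, Na = 22.98976928,
              K = 39.0983)

#' Parse a molecular formula string
#'
#' @param formula e.g. `"C17H21F3N2O3"`; element symbols with optional
#'   counts.
#' @return named integer vector of element counts.
#' @export
parseFormula <- function(formula) {
  if (!is.null(names(formula)))
    return(stats::setNames(as.integer(formula), names(formula)))
  if (!is.character(formula) || length(formula) != 1L)
    .stopf("formula must be a string or named vector")
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  parts <- regmatches(formula, gregexpr("[A-Z][a-z]?[0-9]*", formula))[[1]]
  if (!length(parts) || nchar(paste(parts, collapse = "")) != nchar(formula))
    .stopf("cannot parse formula '%s'", formula)
  el <- sub("[0-9]+$", "", parts)
  ct <- as.integer(ifelse(grepl("[0-9]+$", parts),
                          sub("^[A-Za-z]+", "", parts), "1"))
  out <- tapply(ct, el, sum)
  stats::setNames(as.integer(out), names(out))
}

#' Molecular mass of a formula
#'
#' @param formula formula string or named element-count vector.
#' @param mode `"monoisotopic"` (principal-isotope masses) or `"average"`
#'   (conventional standard atomic weights).
#' @return mass in Da.
#' @export
formulaMass <- function(formula, mode = c("monoisotopic", "average")) {
  mode <- match.arg(mode)
  counts <- parseFormula(formula)
  if (any(counts <= 0)) .stopf("element counts must be positive")
  tab <- if (mode == "monoisotopic") .monoMass else .avgMass
  unknown <- setdiff(names(counts), names(tab))
  if (length(unknown))
    .stopf("unknown element(s): %s", paste(unknown, collapse = ", "))
  sum(tab[names(counts)] * counts)
}

#' Photoadduct mass of a diazirine reagent
#'
#' Diazirine photolysis expels N2 and the resulting carbene inserts into the
#' target, so the adduct mass used as the variable-modification mass is the
#' parent's monoisotopic mass minus one N2.
#'
#' @param parent parent-compound formula (string or named vector).
#' @return adduct monoisotopic mass, Da.
#' @export
photoadductMass <- function(parent) {
  counts <- parseFormula(parent)
  if (is.na(counts["N"]) || counts[["N"]] < 2L)
    .stopf("not a diazirine: parent must contain at least N2")
  formulaMass(counts) - 2 * .monoMass[["N"]]
}

#' Acceptance filter for photolabeled peptides
#'
#' A labeled peptide is accepted only when (1) its retention time exceeds
#' that of the corresponding unlabeled peptide (the hydrophobic adduct must
#' elute later on reverse phase) and (2) its observed-vs-theoretical mass
#' error is below the ppm cutoff.
#'
#' @param labeled,unlabeled one-row records with `rt_min`, `observed_mass`,
#'   `theoretical_mass` (e.g. rows of a [genAUCTable()] table).
#' @param ppmCutoff mass-accuracy cutoff in ppm (default 10).
#' @return logical.
#' @export
acceptLabeledPeptide <- function(labeled, unlabeled, ppmCutoff = 10) {
  if (is.null(labeled) || is.null(unlabeled) || !nrow(labeled) ||
      !nrow(unlabeled))
    .stopf("both the labeled record and its unlabeled partner are required")
  ppm <- abs(labeled$observed_mass - labeled$theoretical_mass) /
    labeled$theoretical_mass * 1e6
  labeled$rt_min > unlabeled$rt_min & ppm < ppmCutoff
}

#' Apparent labeling efficiency
#'
#' `AUC(labeled) / (AUC(labeled) + AUC(unlabeled))` from extracted-ion-
#' chromatogram areas.
#'
#' @param aucLabeled,aucUnlabeled chromatogram areas (intensity x min).
#' @return fraction in \[0, 1\].
#' @export
labelingEfficiency <- function(aucLabeled, aucUnlabeled) {
  if (any(aucLabeled < 0) || any(aucUnlabeled < 0))
    .stopf("AUC values must be nonnegative")
  tot <- aucLabeled + aucUnlabeled
  if (any(tot == 0)) .stopf("undefined efficiency: both AUCs are zero")
  aucLabeled / tot
}

#' Per-replicate efficiency table from an AUC table
#'
#' @param table data.frame with columns `replicate`, `condition`, `peptide`,
#'   `labeled_flag`, `auc` (one labeled and one unlabeled row per replicate
#'   x condition x peptide).
#' @return data.frame `replicate`, `condition`, `peptide`, `efficiency`.
#' @export
efficiencyTable <- function(table) {
  key <- interaction(table$replicate, table$condition, table$peptide,
                     drop = TRUE)
  rows <- lapply(split(table, key), function(d) {
    aL <- sum(d$auc[d$labeled_flag])
    aU <- sum(d$auc[!d$labeled_flag])
    data.frame(replicate = d$replicate[1], condition = d$condition[1],
               peptide = d$peptide[1],
               efficiency = labelingEfficiency(aL, aU),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$replicate, out$condition), ]
  row.names(out) <- NULL
  out
}

#' Competition normalization of labeling efficiencies
#'
#' Divides each condition's apparent efficiency by the same replicate's
#' control efficiency — strictly replicate-wise, never pooling before
#' normalizing, so replicate-level scale differences cancel.
#'
#' @param effTable data.frame from [efficiencyTable()].
#' @param control condition label of the control (default "control").
#' @return `effTable` with an added `normalized_efficiency` column.
#' @export
competitionNormalize <- function(effTable, control = "control") {
  out <- effTable
  out$normalized_efficiency <- NA_real_
  for (r in unique(out$replicate)) {
    sel <- out$replicate == r
    ctrl <- out$efficiency[sel & out$condition == control]
    if (!length(ctrl))
      .stopf("replicate %s lacks a '%s' condition", r, control)
    out$normalized_efficiency[sel] <- out$efficiency[sel] / ctrl[1]
  }
  out
}
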