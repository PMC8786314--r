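## Per-residue lipid contact probabilities and helix aggregation.

#' Per-residue lipid contact probability
#'
#' For every protein residue (per subunit), the fraction of frames in which
#' any bead of the given lipid species lies within `cutoff` of any bead of
#' the residue (minimum-image distances under the per-frame box). The
#' cross-subunit mean is attached as the five-subunit average.
#'
#' @param traj an aligned [CGTrajectory-class] whose protein beads carry
#'   subunit labels.
#' @param species lipid species token (must have molecules in the system).
#' @param cutoff contact cutoff, Angstrom (default 5).
#' @return a [ContactProfile-class].
#' @export
contactProbability <- function(traj, species, cutoff = 5) {
  if (!isAligned(traj)) .stopf("trajectory must be aligned first")
  b <- traj@beads
  faSel <- !b$is_protein & b$species == species
  if (!any(faSel))
    .stopf("input error: no molecules of species '%s' in the system", species)
  protSel <- which(b$is_protein)
  key <- paste(b$residue_id[protSel], b$subunit[protSel], sep = "|")
  groups <- factor(key, levels = unique(key))
  nGroup <- nlevels(groups)

  nf <- dim(traj@coords)[3]
  hits <- integer(nGroup)
  fa <- traj@coords[faSel, , , drop = FALSE]
  pr <- traj@coords[protSel, , , drop = FALSE]
  gi <- as.integer(groups)
  for (f in seq_len(nf)) {
    hits <- hits + .cpp_residue_contacts(matrix(fa[, , f], ncol = 3),
                                         matrix(pr[, , f], ncol = 3),
                                         gi, nGroup, traj@box[f, ], cutoff)
  }
  info <- do.call(rbind, strsplit(levels(groups), "|", fixed = TRUE))
  first <- protSel[!duplicated(key)]
  prof <- data.frame(residue_id = as.integer(info[, 1]),
                     residue_name = b$residue_name[first],
                     subunit = info[, 2],
                     probability = hits / nf,
                     stringsAsFactors = FALSE, row.names = NULL)
  mp <- stats::aggregate(probability ~ residue_id, data = prof, FUN = mean)
  mp <- mp[order(mp$residue_id), ]
  row.names(mp) <- NULL
  methods::new("ContactProfile", profile = prof, meanProfile = mp,
               species = species, cutoff = cutoff, nFrames = nf)
}

#' Aggregate contact probabilities over helices
#'
#' Per helix group, the mean ("averaged") and sum ("cumulative") of the
#' member residues' cross-subunit mean contact probabilities.
#'
#' @param profile a [ContactProfile-class].
#' @param groups named list mapping helix name to residue-id vector.
#' @return data.frame with `helix`, `n_residues`, `mean_probability`,
#'   `cumulative_probability`.
#' @export
aggregateContacts <- function(profile, groups) {
  if (!length(groups)) .stopf("configuration error: no helix groups supplied")
  mp <- profile@meanProfile
  rows <- lapply(names(groups), function(h) {
    res <- groups[[h]]
    if (!length(res))
      .stopf("configuration error: helix group '%s' is empty", h)
    miss <- setdiff(res, mp$residue_id)
    if (length(miss))
      .stopf("configuration error: residue(s) %s of group '%s' not in profile",
             paste(utils::head(miss, 5), collapse = ", "), h)
    p <- mp$probability[match(res, mp$residue_id)]
    data.frame(helix = h, n_residues = length(res),
               mean_probability = mean(p), cumulative_probability = sum(p),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  row.names(out) <- NULL
  out
}
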