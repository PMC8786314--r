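## Trajectory input, canonicalization, and leaflet assignment.

#' Construct a CGTrajectory from parts
#'
#' Low-level constructor used by the readers and the synthetic generator.
#'
#' @param beads bead metadata data.frame (see [CGTrajectory-class]).
#' @param coords `n_beads x 3 x n_frames` array, Angstrom.
#' @param box `n_frames x 3` matrix of box lengths (Angstrom), or a length-3
#'   vector recycled over frames.
#' @param frameInterval time between frames, ns.
#' @param aligned logical canonicalization flag.
#' @return a [CGTrajectory-class].
#' @export
newCGTrajectory <- function(beads, coords, box, frameInterval = 1,
                            aligned = FALSE) {
  if (length(dim(coords)) == 2L)
    coords <- array(coords, c(nrow(coords), 3L, 1L))
  if (is.null(dim(box)))
    box <- matrix(box, nrow = dim(coords)[3], ncol = 3L, byrow = TRUE)
  beads$bead_index <- as.integer(beads$bead_index)
  methods::new("CGTrajectory", beads = beads, coords = coords, box = box,
               frameInterval = frameInterval, aligned = aligned)
}

## ---- species configuration ----

#' Read a species configuration
#'
#' The species configuration maps topology residue names to lipid species
#' tokens, flags headgroup beads, and marks protein residues. It is a YAML
#' mapping of residue name to a record with optional fields `species`
#' (defaults to the residue name), `headgroup_beads` (character vector of
#' bead names) and `protein` (logical).
#'
#' @param config path to a YAML file, or an already-parsed list.
#' @return normalized list keyed by residue name.
#' @export
readSpeciesConfig <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (!is.list(config) || is.null(names(config)))
    .stopf("species config must be a named mapping of residue names")
  lapply(stats::setNames(config, names(config)), function(x) {
    list(species = if (!is.null(x$species)) x$species else NA_character_,
         headgroup_beads = as.character(x$headgroup_beads %||% character()),
         protein = isTRUE(x$protein))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- GRO format ----

## GRO fixed-width reader. Returns raw atom records and per-frame coordinate
## matrices in Angstrom (GRO stores nm).
#' @noRd
.parseGRO <- function(lines) {
  frames <- list()
  boxes <- list()
  atoms <- NULL
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    nat <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(nat)) .stopf("GRO format error: bad atom count at line %d", i + 1L)
    rec <- lines[(i + 2L):(i + 1L + nat)]
    if (is.null(atoms)) {
      atoms <- data.frame(
        resid = as.integer(substr(rec, 1L, 5L)),
        resname = trimws(substr(rec, 6L, 10L)),
        atomname = trimws(substr(rec, 11L, 15L)),
        stringsAsFactors = FALSE)
    } else if (length(rec) != nrow(atoms)) {
      .stopf("GRO format error: frame %d has %d atoms, expected %d",
             length(frames) + 1L, length(rec), nrow(atoms))
    }
    xyz <- cbind(as.numeric(substr(rec, 21L, 28L)),
                 as.numeric(substr(rec, 29L, 36L)),
                 as.numeric(substr(rec, 37L, 44L))) * 10
    if (anyNA(xyz)) .stopf("GRO format error: unparseable coordinates")
    bx <- as.numeric(strsplit(trimws(lines[i + 2L + nat]), "\\s+")[[1]])[1:3] * 10
    frames[[length(frames) + 1L]] <- xyz
    boxes[[length(boxes) + 1L]] <- bx
    i <- i + 3L + nat
  }
  list(atoms = atoms, frames = frames,
       box = do.call(rbind, boxes))
}

#' Write a trajectory as a (multi-frame) GRO file
#'
#' Subunits need no special encoding: they are recovered on read from
#' restarts of the protein residue numbering. Coordinates are written in nm
#' at the format's native 0.001 nm precision.
#'
#' @param traj a [CGTrajectory-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeGRO <- function(traj, path) {
  b <- traj@beads
  co <- traj@coords
  nf <- dim(co)[3]
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (f in seq_len(nf)) {
    writeLines(sprintf("cg trajectory, t= %.3f",
                       (f - 1) * traj@frameInterval), con)
    writeLines(sprintf("%5d", nrow(b)), con)
    writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       b$residue_id %% 100000L, b$residue_name, b$bead_name,
                       b$bead_index %% 100000L,
                       co[, 1, f] / 10, co[, 2, f] / 10, co[, 3, f] / 10), con)
    writeLines(sprintf("%10.5f%10.5f%10.5f", traj@box[f, 1] / 10,
                       traj@box[f, 2] / 10, traj@box[f, 3] / 10), con)
  }
  invisible(path)
}

## ---- bead table assembly ----

## Build the canonical bead table from raw atom records plus species config.
#' @noRd
.makeBeadTable <- function(atoms, cfg) {
  unknown <- setdiff(unique(atoms$resname), names(cfg))
  if (length(unknown))
    .stopf("species configuration error: unknown residue name(s): %s",
           paste(unknown, collapse = ", "))
  entry <- cfg[atoms$resname]
  isProt <- vapply(entry, `[[`, TRUE, "protein")
  species <- vapply(entry, `[[`, "", "species")
  species[is.na(species)] <- atoms$resname[is.na(species)]
  species[isProt] <- "PROT"
  isHead <- mapply(function(e, an) an %in% e$headgroup_beads,
                   entry, atoms$atomname)

  n <- nrow(atoms)
  moleculeId <- integer(n)
  subunit <- character(n)
  ## Non-protein molecules: contiguous runs of identical (resid, resname).
  runKey <- paste(atoms$resid, atoms$resname)
  newRun <- c(TRUE, runKey[-1L] != runKey[-n])
  ## Protein: one molecule; subunits from restarts of residue numbering.
  if (any(isProt)) {
    pd <- atoms$resid[isProt]
    restart <- c(TRUE, diff(pd) < 0)
    ## a restart only at a genuinely new chain (numbering drops)
    suIdx <- cumsum(restart)
    if (max(suIdx) > 26L) .stopf("too many protein chains")
    subunit[isProt] <- LETTERS[suIdx]
    newRun[isProt] <- FALSE
    newRun[which(isProt)[1]] <- TRUE
  }
  moleculeId <- cumsum(newRun)
  data.frame(
    bead_index = seq_len(n),
    molecule_id = as.integer(moleculeId),
    species = species,
    residue_id = atoms$resid,
    residue_name = atoms$resname,
    subunit = subunit,
    bead_name = atoms$atomname,
    is_protein = isProt,
    is_headgroup = as.logical(isHead),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Load a coarse-grained trajectory
#'
#' Reads a GRO or PDB topology plus (optionally) a separate coordinate source
#' (multi-frame GRO, DCD, or a columnar container directory written by
#' [writeTrajectoryContainer]) and canonicalizes bead metadata using a species
#' configuration.
#'
#' @param topologyPath GRO or PDB file defining bead metadata (and, for GRO,
#'   one or more coordinate frames).
#' @param coordsPath optional trajectory file (multi-frame GRO or DCD); when
#'   `NULL`, frames come from `topologyPath`.
#' @param speciesConfig YAML path or list, see [readSpeciesConfig].
#' @param frameInterval time between stored frames, ns (default 1, the
#'   production save interval).
#' @return an unaligned [CGTrajectory-class].
#' @export
loadTrajectory <- function(topologyPath, coordsPath = NULL, speciesConfig,
                           frameInterval = 1) {
  cfg <- readSpeciesConfig(speciesConfig)
  ext <- tolower(tools::file_ext(topologyPath))
  if (ext == "gro") {
    gro <- .parseGRO(readLines(topologyPath))
    atoms <- gro$atoms
    frames <- gro$frames
    box <- gro$box
  } else if (ext == "pdb") {
    if (!requireNamespace("bio3d", quietly = TRUE))
      .stopf("reading PDB topologies requires the bio3d package")
    pdb <- bio3d::read.pdb(topologyPath)
    atoms <- data.frame(resid = pdb$atom$resno, resname = pdb$atom$resid,
                        atomname = pdb$atom$elety, stringsAsFactors = FALSE)
    frames <- list(cbind(pdb$atom$x, pdb$atom$y, pdb$atom$z))
    box <- matrix(rep(2 * apply(abs(frames[[1]]), 2, max), 1), nrow = 1)
  } else .stopf("unsupported topology format: %s", ext)

  if (!is.null(coordsPath)) {
    cext <- tolower(tools::file_ext(coordsPath))
    if (cext == "gro") {
      g2 <- .parseGRO(readLines(coordsPath))
      frames <- g2$frames
      box <- g2$box
    } else if (cext == "dcd") {
      if (!requireNamespace("bio3d", quietly = TRUE))
        .stopf("reading DCD trajectories requires the bio3d package")
      m <- bio3d::read.dcd(coordsPath)
      frames <- lapply(seq_len(nrow(m)), function(i)
        matrix(m[i, ], ncol = 3, byrow = TRUE))
      box <- matrix(rep(box[1, ], length(frames)), ncol = 3, byrow = TRUE)
    } else .stopf("unsupported coordinate format: %s", cext)
  }
  nb <- nrow(atoms)
  bad <- which(vapply(frames, nrow, 1L) != nb)
  if (length(bad))
    .stopf("format error: frame %d bead count differs from topology", bad[1])
  beads <- .makeBeadTable(atoms, cfg)
  coords <- array(unlist(frames), c(nb, 3L, length(frames)))
  newCGTrajectory(beads, coords, box, frameInterval = frameInterval,
                  aligned = FALSE)
}

## ---- alignment ----

## z of the bilayer midplane per frame: mean z of all lipid headgroup beads.
#' @noRd
.midplane <- function(traj) {
  nf <- dim(traj@coords)[3]
  sel <- !traj@beads$is_protein & traj@beads$is_headgroup
  if (!any(sel)) return(rep(0, nf))
  colMeans(matrix(traj@coords[sel, 3, ], sum(sel), nf))
}

#' Canonicalize frames to a protein-centered, z-normal coordinate frame
#'
#' Each frame is translated so the centroid of the transmembrane protein
#' beads (those within 25 Angstrom of the bilayer midplane) is at the origin,
#' lipids are re-imaged into the protein-centered cell, and the frame is
#' rotated about z by the least-squares in-plane rotation superposing the
#' protein beads onto the reference frame.
#'
#' @param traj a [CGTrajectory-class] with protein beads.
#' @param referenceFrame frame index defining the in-plane orientation.
#' @param tmHalfWidth half-width of the transmembrane slab (Angstrom).
#' @return the aligned [CGTrajectory-class].
#' @export
alignFrames <- function(traj, referenceFrame = 1L, tmHalfWidth = 25) {
  b <- traj@beads
  if (!any(b$is_protein)) .stopf("input error: trajectory has no protein beads")
  co <- traj@coords
  nf <- dim(co)[3]
  mid <- .midplane(traj)
  prot <- which(b$is_protein)
  lip <- which(!b$is_protein)

  centreFrame <- function(f) {
    xyz <- co[, , f]
    ## re-image protein beads around their first bead so a split image is whole
    ref <- xyz[prot[1], ]
    for (k in 1:3)
      xyz[prot, k] <- ref[k] + .wrapCoords(xyz[prot, k] - ref[k], traj@box[f, k])
    tm <- prot[abs(xyz[prot, 3] - mid[f]) < tmHalfWidth]
    if (!length(tm)) tm <- prot
    ctr <- colMeans(xyz[tm, , drop = FALSE])
    sweep(xyz, 2, ctr)
  }

  refXYZ <- centreFrame(referenceFrame)
  refP <- refXYZ[prot, 1:2, drop = FALSE]
  out <- co
  for (f in seq_len(nf)) {
    xyz <- if (f == referenceFrame) refXYZ else centreFrame(f)
    p <- xyz[prot, 1:2, drop = FALSE]
    ## least-squares rotation about z onto the reference
    ang <- atan2(sum(p[, 1] * refP[, 2] - p[, 2] * refP[, 1]),
                 sum(p[, 1] * refP[, 1] + p[, 2] * refP[, 2]))
    cs <- cos(ang); sn <- sin(ang)
    rot <- cbind(xyz[, 1] * cs - xyz[, 2] * sn,
                 xyz[, 1] * sn + xyz[, 2] * cs, xyz[, 3])
    ## re-image lipids into the protein-centered cell (after rotation, so
    ## undoing a rigid in-plane rotation is exact)
    for (k in 1:3) rot[lip, k] <- .wrapCoords(rot[lip, k], traj@box[f, k])
    out[, , f] <- rot
  }
  methods::initialize(traj, coords = out, aligned = TRUE)
}

## ---- leaflet assignment ----

#' Assign lipid molecules to bilayer leaflets, per frame
#'
#' A lipid is `"outer"` in a frame when the mean z of its headgroup beads
#' lies above the bilayer midplane (the mean z of all lipid headgroup beads
#' in that frame), else `"inner"`. The assignment is re-evaluated every frame
#' so flip-flop shows up as a label change.
#'
#' @param traj an aligned [CGTrajectory-class].
#' @return a [LeafletAssignment-class].
#' @export
assignLeaflets <- function(traj) {
  b <- traj@beads
  lipMol <- sort(unique(b$molecule_id[!b$is_protein]))
  headSel <- !b$is_protein & b$is_headgroup
  noHead <- setdiff(lipMol, unique(b$molecule_id[headSel]))
  if (length(noHead))
    .stopf("configuration error: lipid molecule(s) without headgroup beads: %s",
           paste(utils::head(noHead, 5), collapse = ", "))
  nf <- dim(traj@coords)[3]
  mid <- .midplane(traj)
  hz <- traj@coords[headSel, 3, , drop = FALSE][, 1, , drop = FALSE]
  hz <- matrix(hz, nrow = sum(headSel), ncol = nf)
  hmol <- b$molecule_id[headSel]
  ## per-molecule mean headgroup z, all frames at once
  mz <- rowsum(hz, group = hmol, reorder = TRUE) /
    as.vector(table(hmol)[as.character(sort(unique(hmol)))])
  lab <- ifelse(sweep(mz, 2, mid, `-`) > 0, "outer", "inner")
  methods::new("LeafletAssignment",
               moleculeId = as.integer(sort(unique(hmol))), leaflet = lab)
}

#' Summarize membrane composition
#'
#' @param traj a [CGTrajectory-class].
#' @param leaflets optional [LeafletAssignment-class]; when given, per-leaflet
#'   molecule counts use each molecule's modal label across frames.
#' @return a [CompositionTable-class].
#' @export
compositionTable <- function(traj, leaflets = NULL) {
  b <- traj@beads[!traj@beads$is_protein, ]
  mol <- b[!duplicated(b$molecule_id), c("molecule_id", "species")]
  cnt <- table(mol$species)
  sB <- vapply(names(cnt), function(s)
    nrow(b[b$species == s, ]) / cnt[[s]], 1)
  outer <- inner <- stats::setNames(rep(0L, length(cnt)), names(cnt))
  if (!is.null(leaflets)) {
    modal <- apply(leaflets@leaflet, 1, function(x)
      names(sort(table(x), decreasing = TRUE))[1])
    msp <- mol$species[match(leaflets@moleculeId, mol$molecule_id)]
    t2 <- table(factor(msp, names(cnt)), modal)
    if ("outer" %in% colnames(t2)) outer[rownames(t2)] <- t2[, "outer"]
    if ("inner" %in% colnames(t2)) inner[rownames(t2)] <- t2[, "inner"]
  } else {
    ## split evenly when no assignment is supplied (symmetric default)
    outer <- as.integer(ceiling(cnt / 2))
    inner <- as.integer(cnt) - outer
    names(outer) <- names(inner) <- names(cnt)
  }
  tb <- data.frame(species = names(cnt), nMol = as.integer(cnt),
                   molFraction = as.numeric(cnt) / sum(cnt),
                   beadsPerMol = as.numeric(sB),
                   nMolOuter = as.integer(outer), nMolInner = as.integer(inner),
                   stringsAsFactors = FALSE, row.names = NULL)
  methods::new("CompositionTable", table = tb, nLipids = sum(tb$nMol),
               meanArea = mean(traj@box[, 1] * traj@box[, 2]))
}

## ---- columnar container ----

.containerSchema <- 1L

#' Write a trajectory to a columnar on-disk container
#'
#' The container is a directory holding the bead table and long-format
#' coordinates as Feather files (TSV when the arrow package is unavailable)
#' plus a JSON metadata sidecar with a schema version.
#'
#' @param traj a [CGTrajectory-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeTrajectoryContainer <- function(traj, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nf <- dim(traj@coords)[3]
  nb <- dim(traj@coords)[1]
  long <- data.frame(frame = rep(seq_len(nf), each = nb),
                     bead_index = rep(seq_len(nb), nf),
                     x = as.vector(traj@coords[, 1, ]),
                     y = as.vector(traj@coords[, 2, ]),
                     z = as.vector(traj@coords[, 3, ]))
  useArrow <- requireNamespace("arrow", quietly = TRUE)
  if (useArrow) {
    arrow::write_feather(traj@beads, file.path(dir, "beads.feather"))
    arrow::write_feather(long, file.path(dir, "coords.feather"))
  } else {
    utils::write.table(traj@beads, file.path(dir, "beads.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(long, file.path(dir, "coords.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  meta <- list(schema = .containerSchema, format = if (useArrow) "feather" else "tsv",
               n_beads = nb, n_frames = nf,
               frame_interval_ns = traj@frameInterval, aligned = traj@aligned,
               box = apply(traj@box, 2, identity))
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read a trajectory from a columnar container
#'
#' @param dir directory written by [writeTrajectoryContainer].
#' @return a [CGTrajectory-class].
#' @export
readTrajectoryContainer <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  if (!identical(as.integer(meta$schema), .containerSchema))
    .stopf("unsupported container schema %s", meta$schema)
  if (meta$format == "feather") {
    beads <- as.data.frame(arrow::read_feather(file.path(dir, "beads.feather")))
    long <- as.data.frame(arrow::read_feather(file.path(dir, "coords.feather")))
  } else {
    beads <- utils::read.table(file.path(dir, "beads.tsv"), sep = "\t",
                               header = TRUE, stringsAsFactors = FALSE)
    long <- utils::read.table(file.path(dir, "coords.tsv"), sep = "\t",
                              header = TRUE)
  }
  nb <- meta$n_beads; nf <- meta$n_frames
  ord <- order(long$frame, long$bead_index)
  co <- array(0, c(nb, 3L, nf))
  co[, 1, ] <- long$x[ord]; co[, 2, ] <- long$y[ord]; co[, 3, ] <- long$z[ord]
  box <- matrix(unlist(meta$box), ncol = 3)
  newCGTrajectory(beads, co, box, frameInterval = meta$frame_interval_ns,
                  aligned = isTRUE(meta$aligned))
}
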