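## Configuration-driven orchestration of the analysis stages.

.pkgVersion <- function() as.character(utils::packageVersion("lipsite"))

#' Run a configured analysis pipeline
#'
#' Executes a list of stages in order, passing named intermediate objects
#' between them, writing stage outputs as TSV under the configured output
#' directory, and returning a manifest recording inputs, parameters, seeds,
#' package version and output checksums. Stage configurations are validated
#' up front (pre-flight): referenced inputs must be produced by an earlier
#' stage or exist on disk, and every stochastic stage must carry an explicit
#' seed.
#'
#' Supported stages: `synth_membrane` (seeded generator), `boundary`,
#' `enrich`, `contacts`, `affinity`, `gate`, `decay_fit`, `ec50_fit`,
#' `ic50_fit`, `ms_quant`.
#'
#' @param config YAML file path or list with `output_dir` and `stages`.
#' @return the manifest (list), invisibly written to
#'   `output_dir/manifest.json`.
#' @export
runPipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  outDir <- config$output_dir %||% "."
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  stages <- config$stages %||% list()

  ## ---- pre-flight validation ----
  known <- c("synth_membrane", "boundary", "enrich", "contacts", "affinity",
             "gate", "decay_fit", "ec50_fit", "ic50_fit", "ms_quant")
  stochastic <- c("synth_membrane", "affinity")
  avail <- character()
  for (i in seq_along(stages)) {
    sg <- stages[[i]]
    if (is.null(sg$stage) || !sg$stage %in% known)
      .stopf("config error: stage %d has unknown kind '%s'", i,
             sg$stage %||% "<missing>")
    if (sg$stage %in% stochastic && is.null(sg$seed))
      .stopf("config error: stochastic stage %d (%s) needs an explicit seed",
             i, sg$stage)
    for (ref in intersect(names(sg), c("traj", "input", "scheme"))) {
      v <- sg[[ref]]
      if (is.character(v) && !v %in% avail && !file.exists(v))
        .stopf("config error: stage %d (%s) references missing input '%s'",
               i, sg$stage, v)
    }
    if (!is.null(sg$output)) avail <- c(avail, sg$output)
  }

  ## ---- execution ----
  ws <- new.env(parent = emptyenv())
  outputs <- character()
  log <- character()
  resolve <- function(name, what = "object") {
    if (is.character(name) && exists(name, envir = ws)) get(name, envir = ws)
    else if (is.character(name) && file.exists(name)) name
    else .stopf("stage input '%s' not available", name)
  }
  emitTSV <- function(df, file) {
    path <- file.path(outDir, file)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    outputs <<- c(outputs, path)
    path
  }
  record <- list()
  for (i in seq_along(stages)) {
    sg <- stages[[i]]
    log <- c(log, sprintf("[stage %d] %s", i, sg$stage))
    res <- tryCatch(switch(sg$stage,
      synth_membrane = {
        args <- sg[setdiff(names(sg), c("stage", "output", "enhancements"))]
        args$enhancements <- sg$enhancements %||% list()
        spec <- do.call(membraneSpec, args)
        gen <- genMembraneTraj(spec)
        assign(sg$output %||% "traj", gen$trajectory, envir = ws)
        assign(paste0(sg$output %||% "traj", "_truth"), gen$groundTruth,
               envir = ws)
        writeGroundTruth(gen$groundTruth,
                         file.path(outDir, paste0(sg$output %||% "traj",
                                                  "_truth.yaml")))
        outputs <- c(outputs, file.path(outDir,
                                        paste0(sg$output %||% "traj",
                                               "_truth.yaml")))
        sprintf("%d frames", nFrames(gen$trajectory))
      },
      boundary = {
        traj <- resolve(sg$traj %||% "traj")
        br <- boundaryMetric(traj, shellCutoff = sg$shell_cutoff %||% 6)
        emitTSV(br@table, sg$file %||% "boundary_metric.tsv")
        "ok"
      },
      enrich = {
        traj <- resolve(sg$traj %||% "traj")
        lf <- assignLeaflets(traj)
        comp <- compositionTable(traj, lf)
        dm <- radialDensityMap(traj, lf, species = sg$species,
                               leaflet = sg$leaflet %||% "outer",
                               dr = sg$dr %||% 5,
                               dtheta = sg$dtheta %||% (pi / 15),
                               rMax = sg$r_max %||% 70)
        em <- enhancementMap(dm, comp)
        assign(sg$output %||% "enhancement", em, envir = ws)
        emitTSV(mapAsTable(em), sg$file %||%
                  sprintf("enhancement_%s_%s.tsv", sg$species,
                          sg$leaflet %||% "outer"))
        "ok"
      },
      contacts = {
        traj <- resolve(sg$traj %||% "traj")
        cp <- contactProbability(traj, species = sg$species,
                                 cutoff = sg$cutoff %||% 5)
        emitTSV(cp@profile, sg$file %||% "contacts.tsv")
        if (!is.null(sg$groups))
          emitTSV(aggregateContacts(cp, lapply(sg$groups, function(g)
            g[1]:g[2])), "contacts_helix_summary.tsv")
        "ok"
      },
      affinity = {
        traj <- resolve(sg$traj %||% "traj")
        lf <- assignLeaflets(traj)
        geo <- defineSiteSectors(traj, lapply(sg$helix_groups %||%
          list(M1 = c(199, 222), M2 = c(228, 250), M3 = c(256, 280),
               M4 = c(300, 320)), function(g) g[[1]]:g[[2]]))
        st <- siteTable(geo)
        rows <- list()
        for (j in seq_len(nrow(st))) {
          site <- st[j, ]
          if (!is.null(sg$sites) && !site$site %in% sg$sites) next
          hS <- occupancyHistogram(traj, lf, site, sg$species)
          hB <- bulkReferenceHistogram(traj, lf, sg$species, site$area,
                                       leaflet = site$leaflet,
                                       seed = sg$seed)
          for (est in c("threshold", "mean_ratio")) {
            a <- thresholdAffinity(hS, hB, temperature = sg$temp %||% 323,
                                   estimator = est)
            rows[[length(rows) + 1L]] <- data.frame(
              site = site$site, subunit = site$subunit,
              leaflet = site$leaflet, estimator = est, deltaG = a@deltaG,
              finite = a@finite, stringsAsFactors = FALSE)
          }
        }
        emitTSV(do.call(rbind, rows), sg$file %||% "affinity.tsv")
        "ok"
      },
      gate = {
        scheme <- buildScheme(resolve(sg$scheme))
        rows <- list()
        for (ic in as.numeric(sg$inhibitor_grid %||% 0)) {
          pr <- gatingProtocol(agonist = sg$agonist %||% 0.03,
                               inhibitor = ic,
                               duration = sg$duration %||% 25,
                               dt = sg$dt %||% 1e-5)
          obs <- currentObservables(integrateProtocol(scheme, pr))
          obs$inhibitor <- ic
          rows[[length(rows) + 1L]] <- obs
        }
        emitTSV(do.call(rbind, rows), sg$file %||% "gating_observables.tsv")
        "ok"
      },
      decay_fit = {
        tr <- utils::read.table(resolve(sg$input), sep = "\t", header = TRUE)
        fit <- fitCurrentDecay(tr)
        emitTSV(data.frame(A1 = fit@A1, tau1 = fit@tau1, A2 = fit@A2,
                           tau2 = fit@tau2, offset = fit@offset,
                           weighted_tau = fit@weightedTau,
                           model = fit@model, converged = fit@converged),
                sg$file %||% "decay_fit.tsv")
        "ok"
      },
      ec50_fit = {
        d <- utils::read.table(resolve(sg$input), sep = "\t", header = TRUE)
        fit <- fitHillEC50(d$conc_M, d$response)
        emitTSV(data.frame(ec50_M = fit@ec50, se = fit@ec50SE,
                           hill = fit@hill, rmax = fit@rmax),
                sg$file %||% "ec50_fit.tsv")
        "ok"
      },
      ic50_fit = {
        d <- utils::read.table(resolve(sg$input), sep = "\t", header = TRUE)
        fit <- fitIC50(d$conc_M, d$response)
        emitTSV(data.frame(ic50_M = fit@ec50, se = fit@ec50SE,
                           hill = fit@hill), sg$file %||% "ic50_fit.tsv")
        "ok"
      },
      ms_quant = {
        d <- utils::read.table(resolve(sg$input), sep = "\t", header = TRUE)
        eff <- competitionNormalize(efficiencyTable(d),
                                    control = sg$control %||% "control")
        emitTSV(eff, sg$file %||% "labeling_efficiency.tsv")
        "ok"
      }), error = function(e)
        .stopf("stage %d (%s) failed: %s", i, sg$stage, conditionMessage(e)))
    record[[i]] <- list(stage = sg$stage,
                        parameters = sg[setdiff(names(sg), "stage")],
                        status = res)
  }

  manifest <- list(version = .pkgVersion(), stages = record,
                   outputs = lapply(outputs, function(p)
                     list(path = p, md5 = unname(tools::md5sum(p)))))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log, file.path(outDir, "pipeline.log"))
  invisible(manifest)
}
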