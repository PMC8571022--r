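#' Generating maps resembling the canonical A-D archetypes
#'
#' Draws four average-referenced, unit-norm topographies as the canonical
#' archetype fields plus a smooth random perturbation, redrawing until all
#' pairwise |spatial correlations| stay below 0.85. Cohorts generated from
#' these maps keep the generator's class k aligned with analysis letter k,
#' so planted per-class effects surface under the intended letter after
#' canonical labelling.
#'
#' @param nChannels number of channels.
#' @param seed integer seed.
#' @param wobble perturbation amplitude relative to the archetype.
#' @param maxTries redraw attempts per map.
#' @return channels x 4 matrix with columns A-D.
#' @export
archetypeTemplateMaps <- function(nChannels, seed = 1L, wobble = 0.3,
                                  maxTries = 200L) {
  mont <- standardMontage(nChannels)
  arch <- canonicalArchetypes(mont$positions)@maps
  B <- harmonicBasis(mont$positions)
  withSeed(seed, {
    maps <- matrix(0, nChannels, 0)
    tries <- 0L
    while (ncol(maps) < 4L) {
      k <- ncol(maps) + 1L
      tries <- tries + 1L
      stopIfNot(tries <= maxTries, "could not separate archetype maps")
      pert <- drop(B %*% rnorm(ncol(B)))
      pert <- unitNorm(pert - mean(pert))
      v <- unitNorm(arch[, k] + wobble * pert)
      v <- unitNorm(v - mean(v))
      if (ncol(maps) && any(abs(apply(maps, 2, cor, y = v)) > 0.85)) next
      maps <- cbind(maps, v)
      tries <- 0L
    }
    colnames(maps) <- colnames(arch)
    maps
  })
}

pipelineDefaults <- function() list(
  targetRate = 250, low = 1, high = 40, notch = 50,
  flatlineS = 5, noiseSD = 4, minCorr = 0.8,
  windowS = 0.5, sdCut = 20, epochS = 2,
  K = 4, minDistanceMs = 10, maxPeaks = 800,
  alpha = 0.05, adjustMethod = "holm", varEqual = TRUE,
  seed = 1L, outputDir = NULL, manifest = NULL, simulate = NULL
)

#' Assemble a pipeline configuration
#'
#' All stage thresholds live here, once, with the standard analysis values
#' as defaults (250 Hz target rate; 1-40 Hz band-pass; 50 Hz notch; 5 s
#' flatline; 4 SD noise; 0.8 neighbour correlation; 0.5 s / 20 SD windows;
#' 2 s epochs; K = 4; alpha = 0.05). Unknown keys are rejected.
#'
#' @param ... overrides of the defaults.
#' @return a named list with class \code{pipelineConfig}.
#' @export
pipelineConfig <- function(...) {
  cfg <- pipelineDefaults()
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  stopIfNot(length(unknown) == 0,
            paste("unknown config keys:", paste(unknown, collapse = ", ")))
  cfg[names(over)] <- over
  structure(cfg, class = "pipelineConfig")
}

#' Read / write a pipeline configuration as YAML
#'
#' Round-trips losslessly; unknown keys in the file are rejected.
#'
#' @param path YAML file path.
#' @param config a \code{pipelineConfig}.
#' @return \code{loadPipelineConfig}: the config; \code{savePipelineConfig}:
#'   the path, invisibly.
#' @export
loadPipelineConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipelineConfig, vals)
}

#' @rdname loadPipelineConfig
#' @export
savePipelineConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Build a segmentation directly from a known label sequence
#'
#' Wraps a per-sample label vector (for example a generator's ground truth)
#' as a \linkS4class{MicrostateSegmentation}, splitting it into epochs, so
#' that parameter and transition extraction can run on it. GFP and
#' assignment correlations are set to 1 (parameters that depend on them,
#' i.e. GEV, are then nominal).
#'
#' @param labels integer label vector (1..K).
#' @param K number of classes.
#' @param samplingRate sampling rate in Hz.
#' @param epochS epoch length in seconds (the tail remainder is dropped);
#'   NULL keeps one single epoch.
#' @param classNames class names (default A, B, C, D, ...).
#' @return a \linkS4class{MicrostateSegmentation}.
#' @export
segmentationFromLabels <- function(labels, K, samplingRate, epochS = NULL,
                                   classNames = LETTERS[seq_len(K)]) {
  if (is.null(epochS)) {
    labs <- list(as.integer(labels))
  } else {
    ns <- round(epochS * samplingRate)
    nE <- length(labels) %/% ns
    stopIfNot(nE >= 1, "label sequence shorter than one epoch")
    labs <- lapply(seq_len(nE), function(e)
      as.integer(labels[((e - 1L) * ns + 1L):(e * ns)]))
  }
  ones <- lapply(labs, function(l) rep(1, length(l)))
  new("MicrostateSegmentation", labels = labs, corr = ones, gfp = ones,
      samplingRate = samplingRate, K = as.integer(K),
      classNames = classNames)
}

#' Simulate a two-group demonstration cohort
#'
#' Builds a cohort with the reference study's shape: \code{nRBD} patients
#' and \code{nHC} controls sharing one set of generating maps, with
#' plantable group effects on the per-class mean segment durations. RBDQ-HK
#' severity scores are drawn group-dependently (HC low, RBD >= 17, the
#' screening threshold), and each RBD subject's planted effect scales with
#' its score, so group differences, correlations and within-group
#' regressions all carry signal.
#'
#' @param nRBD,nHC group sizes (defaults 22 and 46).
#' @param effectSpec named list; \code{durationScale} is a named per-class
#'   factor applied to the RBD group's mean segment duration at maximum
#'   severity (e.g. \code{c(D = 0.85, B = 1.2)}). Empty spec = exchangeable
#'   groups.
#' @param seed master seed; per-subject seeds derive from it.
#' @param nChannels,samplingRate,duration,meanSegmentMs,noiseSigma
#'   per-subject generator settings.
#' @param dir optional directory: recordings are then written as
#'   BrainVision triplets plus \code{metadata.csv} and per-subject ground
#'   truth (JSON + segment-table CSV), and the manifest points at the
#'   files.
#' @return list with \code{meta} (data.frame subject_id, group,
#'   rbdqhk_score, age, sex, file), \code{templates} (generating maps),
#'   and, when \code{dir} is NULL, \code{recordings} and
#'   \code{groundTruths} lists.
#' @export
makeDemoCohort <- function(nRBD = 22L, nHC = 46L,
                           effectSpec = list(durationScale = c(D = 0.85,
                                                               B = 1.2)),
                           seed = 1L, nChannels = 19L, samplingRate = 250,
                           duration = 60, meanSegmentMs = 80,
                           noiseSigma = 0.1, dir = NULL) {
  bad <- setdiff(names(effectSpec), "durationScale")
  stopIfNot(length(bad) == 0,
            paste("unknown effectSpec keys:", paste(bad, collapse = ", ")))
  K <- 4L
  classNames <- LETTERS[1:K]
  templates <- archetypeTemplateMaps(nChannels,
                                     seed = deriveSeed(seed, 99L))
  n <- nRBD + nHC
  groups <- c(rep("RBD", nRBD), rep("HC", nHC))
  meta <- withSeed(deriveSeed(seed, 7L), data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    group = groups,
    rbdqhk_score = c(sample(17:90, nRBD, replace = TRUE),
                     sample(0:12, nHC, replace = TRUE)),
    age = round(rnorm(n, 56, 5)),
    sex = sample(c("F", "M"), n, replace = TRUE),
    stringsAsFactors = FALSE
  ))
  scale <- effectSpec$durationScale
  recs <- vector("list", n)
  gts <- vector("list", n)
  files <- character(n)
  for (s in seq_len(n)) {
    msm <- rep(meanSegmentMs, length.out = K)
    names(msm) <- classNames
    if (groups[s] == "RBD" && length(scale)) {
      sev <- (meta$rbdqhk_score[s] - 17) / (90 - 17)
      for (cl in names(scale))
        msm[cl] <- msm[cl] * (1 + (scale[[cl]] - 1) * sev)
    }
    cfg <- generatorConfig(nChannels = nChannels, nStates = K,
                           samplingRate = samplingRate, duration = duration,
                           meanSegmentMs = unname(msm),
                           noiseSigma = noiseSigma,
                           seed = deriveSeed(seed, s))
    sim <- simulateRecording(cfg, templates = templates)
    gts[[s]] <- sim$groundTruth
    if (is.null(dir)) {
      recs[[s]] <- sim$recording
    } else {
      base <- file.path(dir, meta$subject_id[s])
      writeBrainVision(sim$recording, base)
      files[s] <- paste0(base, ".vhdr")
      seg <- sim$groundTruth@segmentTable
      utils::write.csv(seg, paste0(base, "_segments.csv"),
                       row.names = FALSE)
      jsonlite::write_json(list(subject = meta$subject_id[s],
                                seed = cfg@seed,
                                meanSegmentMs = as.list(msm)),
                           paste0(base, "_truth.json"), auto_unbox = TRUE)
    }
  }
  if (!is.null(dir)) {
    meta$file <- files
    utils::write.csv(meta, file.path(dir, "metadata.csv"),
                     row.names = FALSE)
  }
  out <- list(meta = meta, templates = templates)
  if (is.null(dir)) {
    out$recordings <- recs
    out$groundTruths <- gts
  }
  out
}

#' Run the full microstate pipeline
#'
#' Executes simulate/ingest, preprocessing, per-subject AAHC, within-group
#' template alignment and averaging, canonical A-D labelling, per-subject
#' backfitting with the subject's group templates, parameter and transition
#' extraction, and the group statistics battery. Every stage is logged; a
#' failure aborts with the stage name and subject id.
#'
#' @param config a \code{\link{pipelineConfig}}. Input comes either from
#'   \code{config$simulate} (arguments for \code{\link{makeDemoCohort}}) or
#'   from \code{config$manifest}, a CSV with columns subject_id, group,
#'   rbdqhk_score and file (BrainVision .vhdr or .edf paths).
#' @return list with \code{meta}, \code{groupTemplates} (per group, with
#'   labelling correlations), \code{parameters}, \code{transitions},
#'   \code{report} (see \code{\link{groupComparisonReport}}), \code{gev}
#'   (per-group mean total GEV) and \code{log}. When
#'   \code{config$outputDir} is set, parameter and transition CSVs plus a
#'   JSON run report (with md5 checksums of all written artifacts) are
#'   written there.
#' @export
runPipeline <- function(config = pipelineConfig()) {
  stage <- function(name, sid, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed for subject %s: %s", name, sid,
                   conditionMessage(e)), call. = FALSE))
  }
  log <- list()
  if (!is.null(config$simulate)) {
    cohort <- do.call(makeDemoCohort,
                      c(config$simulate, list(seed = config$seed)))
    meta <- cohort$meta
    getRec <- function(s) cohort$recordings[[s]]
  } else if (!is.null(config$manifest)) {
    meta <- utils::read.csv(config$manifest, stringsAsFactors = FALSE)
    missing <- meta$file[!file.exists(meta$file)]
    stopIfNot(length(missing) == 0,
              paste("manifest refers to missing file(s):",
                    paste(missing, collapse = ", ")))
    getRec <- function(s) readRecording(meta$file[s])
  } else stop("config needs either a simulate spec or a manifest",
              call. = FALSE)
  n <- nrow(meta)
  epochsList <- vector("list", n)
  subjectSets <- vector("list", n)
  preproLog <- vector("list", n)
  for (s in seq_len(n)) {
    sid <- meta$subject_id[s]
    rec <- stage("ingest", sid, getRec(s))
    pp <- stage("preprocess", sid, preprocessRecording(
      rec, targetRate = config$targetRate, low = config$low,
      high = config$high, notch = config$notch,
      flatlineS = config$flatlineS, noiseSD = config$noiseSD,
      minCorr = config$minCorr, windowS = config$windowS,
      sdCut = config$sdCut, epochS = config$epochS))
    epochsList[[s]] <- pp$epochs
    preproLog[[s]] <- pp$log
    subjectSets[[s]] <- stage("subject-maps", sid, subjectTemplates(
      pp$epochs, k = config$K, minDistanceMs = config$minDistanceMs,
      maxPeaks = config$maxPeaks, source = sid))
  }
  log$preprocess <- preproLog
  # group templates
  mont <- standardMontage(length(epochsList[[1]]@channelNames))
  arch <- canonicalArchetypes(mont$positions,
                              epochsList[[1]]@channelNames)
  groups <- unique(as.character(meta$group))
  groupTemplates <- list()
  for (g in groups) {
    sel <- which(meta$group == g)
    aligned <- stage("group-maps", g, alignSubjectMaps(subjectSets[sel]))
    gm <- groupMeanTemplates(aligned, source = g)
    groupTemplates[[g]] <- stage("label-canonical", g,
                                 labelCanonical(gm, arch))
  }
  # backfit and parameters
  parameters <- vector("list", n)
  transitions <- vector("list", n)
  for (s in seq_len(n)) {
    sid <- meta$subject_id[s]
    g <- as.character(meta$group[s])
    seg <- stage("backfit", sid,
                 backfit(epochsList[[s]], groupTemplates[[g]]$templates))
    parameters[[s]] <- stage("parameters", sid, computeParameters(seg))
    transitions[[s]] <- stage("transitions", sid,
                              expectedTransitions(transitionMatrix(seg)))
  }
  gev <- vapply(groups, function(g)
    mean(vapply(parameters[meta$group == g],
                function(p) p@gevTotal, 0)), 0)
  report <- stage("stats", "-", groupComparisonReport(
    list(subjects = meta, parameters = parameters,
         transitions = transitions),
    alpha = config$alpha, adjustMethod = config$adjustMethod,
    varEqual = config$varEqual))
  out <- list(meta = meta, groupTemplates = groupTemplates,
              parameters = parameters, transitions = transitions,
              report = report, gev = gev, log = log)
  if (!is.null(config$outputDir)) {
    dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
    paramCsv <- file.path(config$outputDir, "parameters.csv")
    transCsv <- file.path(config$outputDir, "transitions.csv")
    utils::write.csv(exportParameters(meta, parameters), paramCsv,
                     row.names = FALSE)
    utils::write.csv(exportTransitions(meta, transitions), transCsv,
                     row.names = FALSE)
    files <- c(paramCsv, transCsv)
    runReport <- list(nSubjects = n, groups = as.list(table(meta$group)),
                      gev = as.list(gev),
                      artifacts = as.list(tools::md5sum(files)))
    jsonlite::write_json(runReport,
                         file.path(config$outputDir, "run_report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

# Tidy per-subject parameter table (one row per subject x class).
exportParameters <- function(meta, parameters) {
  rows <- NULL
  for (s in seq_along(parameters)) {
    p <- parameters[[s]]
    rows <- rbind(rows, data.frame(
      subject_id = meta$subject_id[s], group = meta$group[s],
      class = names(p@coveragePct), duration_ms = unname(p@durationMs),
      occurrence_per_s = unname(p@occurrencePerS),
      coverage_pct = unname(p@coveragePct),
      gev = unname(p@gevPerClass), stringsAsFactors = FALSE))
  }
  rows
}

# Tidy per-subject transition table (one row per subject x ordered pair).
exportTransitions <- function(meta, transitions) {
  rows <- NULL
  for (s in seq_along(transitions)) {
    tt <- transitions[[s]]
    nm <- tt@classNames
    K <- length(nm)
    for (j in seq_len(K)) for (i in seq_len(K)) {
      if (i == j) next
      rows <- rbind(rows, data.frame(
        subject_id = meta$subject_id[s], group = meta$group[s],
        from = nm[i], to = nm[j],
        observed_pct = tt@observedPct[i, j],
        expected_pct = tt@expectedPct[i, j], stringsAsFactors = FALSE))
    }
  }
  rows
}
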