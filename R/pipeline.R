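#' @include AllClasses.R habitat.R deformation.R texture.R shape.R
#' @include integration.R survival.R
NULL

#' Pipeline run configuration
#'
#' Central configuration for feature extraction and survival modeling.
#'
#' @param bandWidth annular band width in mm (default 5).
#' @param nBands number of annular bands (default 12).
#' @param regions tumor regions to analyze (default all four).
#' @param families descriptor families to extract
#'   (`"FB"`, `"FT"`, `"FS"`).
#' @param texture a [textureParams()] list.
#' @param texturePad padding (voxels) around the habitat bounding box used
#'   when cropping scenes for texture extraction.
#' @param bandReference `"region"` (default): annular bands are measured
#'   from the analyzed region's outer surface; `"habitat"`: always from the
#'   habitat surface. Both restrict bands to the parenchyma (brain minus
#'   habitat).
#' @param spearmanThreshold redundancy filter threshold (default 0.9).
#' @param alphaGrid elastic-net mixing grid (default `seq(0, 1, 0.02)`).
#' @param nFolds cross-validation folds (default 5).
#' @param thresholdRule risk threshold rule (`"median"` or `"mean"`).
#' @param shapeSigma mask smoothing (voxels) for shape features.
#' @param seed seed for fold assignment and any stochastic steps.
#' @return A list of class `rampConfig`.
#' @export
rampConfig <- function(bandWidth = 5, nBands = 12L,
                       regions = c("En", "Ed", "NC", "H"),
                       families = c("FB", "FT", "FS"),
                       texture = textureParams(), texturePad = 6L,
                       bandReference = c("region", "habitat"),
                       spearmanThreshold = 0.9,
                       alphaGrid = seq(0, 1, by = 0.02), nFolds = 5L,
                       thresholdRule = "median", shapeSigma = 1.5,
                       seed = 1L) {
  bandReference <- match.arg(bandReference)
  stopifnot(all(regions %in% .REGIONS), all(families %in% c("FB", "FT", "FS")))
  structure(list(bandWidth = bandWidth, nBands = as.integer(nBands),
                 regions = regions, families = families, texture = texture,
                 texturePad = as.integer(texturePad),
                 bandReference = bandReference,
                 spearmanThreshold = spearmanThreshold,
                 alphaGrid = alphaGrid, nFolds = as.integer(nFolds),
                 thresholdRule = thresholdRule, shapeSigma = shapeSigma,
                 seed = as.integer(seed)),
            class = "rampConfig")
}

#' Extract the integrated feature set for one subject
#'
#' Runs the full per-subject descriptor pipeline: z-normalization within
#' the brain mask, annular-band deformation statistics, texture maps over
#' the habitat (windowed families restricted to habitat voxels on a padded
#' crop), and the shape descriptor, then assembles F_I per region.
#'
#' @param scenes named list of [ImageScene-class] per protocol (names are
#'   protocol tags; all grids must match).
#' @param seg a [SegmentationMap-class].
#' @param field a [DeformationField-class] (required when `"FB"` is among
#'   the configured families).
#' @param config a [rampConfig()].
#' @return Named list (by region) of named feature vectors.
#' @export
extractSubjectFeatures <- function(scenes, seg, field = NULL,
                                   config = rampConfig()) {
  stopifnot(inherits(config, "rampConfig"))
  protos <- names(scenes)
  if (is.null(protos) || !all(protos %in% .PROTOCOLS))
    stop("scenes must be named with protocol tags")
  for (sc in scenes) .stopIfGeometryMismatch(sc, seg, "scene and segmentation")
  if ("FB" %in% config$families) {
    if (is.null(field)) stop("deformation family requested but no field given")
    .stopIfGeometryMismatch(field, seg, "field and segmentation")
  }
  sp <- spacing(seg)
  habitat <- buildHabitat(seg)
  brain <- brainMask(seg)
  centroid <- tumorCentroid(habitat, sp, origin(seg))
  normScenes <- lapply(scenes, zNormalize, mask = brain)

  # texture maps are shared across regions (all regions lie in the habitat)
  textureByProto <- NULL
  cropBB <- NULL
  if ("FT" %in% config$families) {
    cropBB <- .maskBBox(habitat, config$texturePad)
    habCrop <- .cropArray(habitat, cropBB)
    textureByProto <- lapply(normScenes, function(sc) {
      scCrop <- ImageScene(.cropArray(voxelData(sc), cropBB),
                           spacing = sp, origin = origin(sc),
                           protocol = protocol(sc))
      computeTextureMaps(scCrop, habCrop, config$texture)
    })
  }

  out <- list()
  for (rg in config$regions) {
    rmask <- regionMask(seg, rg)
    if (!any(rmask)) {
      warning("region ", rg, " is empty; skipped")
      next
    }
    fb <- NULL
    if ("FB" %in% config$families) {
      ref <- if (config$bandReference == "habitat") habitat else rmask
      bands <- buildAnnularBands(ref, brain, sp, width = config$bandWidth,
                                 nBands = config$nBands,
                                 origin = origin(seg), exclude = habitat)
      fbVec <- assembleFB(field, bands, centroid)
      fb <- setNames(lapply(protos, function(p) fbVec), protos)
    }
    ft <- NULL
    if ("FT" %in% config$families) {
      rCrop <- .cropArray(rmask, cropBB)
      ft <- lapply(textureByProto, summarizeTexture, region = rCrop)
    }
    fs <- NULL
    if ("FS" %in% config$families) {
      fs <- shapeDescriptor(rmask, normScenes[[1L]],
                            sigma = config$shapeSigma)
    }
    out[[rg]] <- .assembleAvailable(fb, ft, fs, protos)
  }
  out
}

# assemble whichever families are configured, preserving the FI order
.assembleAvailable <- function(fb, ft, fs, protos) {
  if (!is.null(fb) && !is.null(ft) && !is.null(fs))
    return(assembleFI(fb, ft, fs))
  out <- numeric(0)
  ordered <- .PROTOCOLS[.PROTOCOLS %in% protos]
  for (p in ordered) {
    if (!is.null(fb)) {
      v <- fb[[p]]; names(v) <- paste(p, "FB", names(v), sep = ".")
      out <- c(out, v)
    }
    if (!is.null(ft)) {
      v <- ft[[p]]; names(v) <- paste(p, "FT", names(v), sep = ".")
      out <- c(out, v)
    }
  }
  if (!is.null(fs)) {
    names(fs) <- paste("FS", names(fs), sep = ".")
    out <- c(out, fs)
  }
  out
}

#' Extract features for a cohort
#'
#' Streams through the subjects, extracts the per-region integrated
#' feature sets, and collects one table per region plus a run manifest.
#' Per-subject failures (geometry mismatches, missing labels) are
#' quarantined and logged in the manifest rather than aborting the run.
#'
#' @param cohort either a list of subjects -- each a list with elements
#'   `id`, `scenes`, `seg`, and optionally `field` -- or the `phantoms`
#'   element of [generateCohort()] (specs are materialized on the fly).
#' @param config a [rampConfig()].
#' @param protocols protocols to synthesize when materializing phantom
#'   specs.
#' @param verbose print per-subject progress.
#' @return List with `tables` (per-region data.frames with `subject_id`,
#'   `region`, feature columns) and `manifest` (config and feature hashes,
#'   per-subject status).
#' @export
runExtract <- function(cohort, config = rampConfig(),
                       protocols = "GdT1w", verbose = FALSE) {
  features <- list()
  status <- character(0)
  for (i in seq_along(cohort)) {
    subj <- cohort[[i]]
    id <- if (!is.null(names(cohort)) && nzchar(names(cohort)[i]))
      names(cohort)[i] else if (!is.null(subj$id)) subj$id else
        sprintf("subj%03d", i)
    res <- tryCatch({
      if (inherits(subj, "phantomSpec")) {
        ph <- generatePhantom(subj, protocols = protocols)
        extractSubjectFeatures(ph$scenes, ph$seg, ph$field, config)
      } else {
        extractSubjectFeatures(subj$scenes, subj$seg, subj$field, config)
      }
    }, error = function(e) e)
    if (inherits(res, "error")) {
      status[id] <- paste("failed:", conditionMessage(res))
    } else {
      status[id] <- "ok"
      features[[id]] <- res
    }
    if (verbose) message(id, ": ", status[id])
  }
  if (!length(features)) stop("no subject extracted successfully")
  regions <- config$regions
  tables <- list()
  for (rg in regions) {
    have <- Filter(function(f) !is.null(f[[rg]]), features)
    if (!length(have)) next
    vecs <- lapply(have, `[[`, rg)
    tables[[rg]] <- data.frame(subject_id = names(vecs), region = rg,
                               do.call(rbind, vecs), check.names = FALSE,
                               stringsAsFactors = FALSE)
    rownames(tables[[rg]]) <- NULL
  }
  manifest <- list(configHash = rlang::hash(config),
                   featureHash = rlang::hash(tables),
                   nSubjects = length(cohort),
                   status = status)
  list(tables = tables, manifest = manifest)
}

#' Train and evaluate the risk model on a train/test split
#'
#' Trains the redundancy filter and penalized Cox model on the training
#' subjects only, freezes the standardization, selected features,
#' coefficients, and threshold, then applies them unchanged to the test
#' subjects. Reports Kaplan-Meier tables, log-rank p, hazard ratio with
#' 95% CI, and the C-index for both halves.
#'
#' @param featureTable per-region data.frame from [runExtract()] (columns
#'   `subject_id`, `region`, features).
#' @param survivalTable data.frame with `subject_id`, `time_months`,
#'   `event`.
#' @param split list with character vectors `train` and `test` of subject
#'   ids; they must be disjoint.
#' @param config a [rampConfig()].
#' @return List with the fitted [RampCoxFit-class] (`fit`), kept feature
#'   names after filtering, and per-half results (`train`, `test`: scores,
#'   groups, km, logrank p, metrics).
#' @export
runModel <- function(featureTable, survivalTable, split,
                     config = rampConfig()) {
  if (length(intersect(split$train, split$test)))
    stop("train/test split overlaps")
  df <- merge(featureTable, survivalTable, by = "subject_id")
  missing <- setdiff(featureTable$subject_id, survivalTable$subject_id)
  if (length(missing))
    message(length(missing), " subject(s) lacked survival and were excluded")
  featCols <- setdiff(colnames(featureTable), c("subject_id", "region"))
  rownames(df) <- df$subject_id
  train <- intersect(split$train, df$subject_id)
  test <- intersect(split$test, df$subject_id)
  if (length(train) < 2L || length(test) < 1L)
    stop("split leaves too few subjects with survival data")
  Xt <- as.matrix(df[train, featCols, drop = FALSE])
  # training-only preprocessing: drop constants, then the Spearman filter
  keep <- featCols[apply(Xt, 2L, sd) > 0]
  kept <- spearmanFilter(Xt[, keep, drop = FALSE],
                         threshold = config$spearmanThreshold)
  fit <- fitPenalizedCox(Xt[, kept, drop = FALSE],
                         df[train, "time_months"], df[train, "event"],
                         alphaGrid = config$alphaGrid,
                         nFolds = config$nFolds, seed = config$seed,
                         thresholdRule = config$thresholdRule)
  evalHalf <- function(ids) {
    X <- as.matrix(df[ids, kept, drop = FALSE])
    scores <- rampScore(fit, X)
    groups <- suppressWarnings(dichotomize(scores, riskThreshold(fit)))
    lr <- if (nlevels(droplevels(groups)) == 2L)
      kmLogrank(df[ids, "time_months"], df[ids, "event"],
                droplevels(groups)) else
      list(km = NULL, chisq = NA_real_, df = NA_integer_, p = NA_real_)
    mets <- survivalMetrics(df[ids, "time_months"], df[ids, "event"],
                            scores, groups)
    list(ids = ids, scores = scores, groups = groups, km = lr$km,
         logrank = list(chisq = lr$chisq, p = lr$p), metrics = mets)
  }
  list(fit = fit, keptFeatures = kept,
       train = evalHalf(train), test = evalHalf(test))
}
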