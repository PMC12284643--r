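#' @include AllClasses.R utils-geometry.R habitat.R imaging-io.R
NULL

#' Specification of one synthetic phantom subject
#'
#' Defines a fully synthetic brain: an ellipsoidal brain, three nested
#' ellipsoidal tumor sub-compartments (necrotic core inside enhancing rim
#' inside edema), Gaussian-random-field intensity texture per compartment
#' and protocol, and an analytic, radially decaying displacement field
#' `u(c) = s * A * exp(-d(c)/lambda) * u_hat(c)` where `d` is the distance
#' from the habitat surface, `u_hat` the unit radial direction from the
#' tumor centroid, and `s` +1 (outward), -1 (inward), or a per-voxel random
#' sign (mixed).
#'
#' @param dims grid dimensions (default 40^3).
#' @param spacing voxel spacing in mm (default 3 mm isotropic).
#' @param brainSemiAxes brain ellipsoid semi-axes in mm.
#' @param tumorCenterOffset tumor center offset from the brain center (mm).
#' @param edemaSemiAxes outer (edema) tumor semi-axes in mm; the enhancing
#'   rim and necrotic core scale these by `enhancingScale` and `coreScale`.
#' @param enhancingScale,coreScale nested compartment scales (0 < core <
#'   enhancing < 1).
#' @param amplitude deformation amplitude `A` in mm.
#' @param decayLength decay length `lambda` in mm.
#' @param orientation `"outward"`, `"inward"`, or `"mixed"`.
#' @param textureCorrelation Gaussian-random-field correlation length (mm).
#' @param textureSd intensity noise standard deviation (arbitrary units).
#' @param seed integer seed; the same seed reproduces the phantom
#'   bit-identically.
#' @return A list of class `phantomSpec`.
#' @export
phantomSpec <- function(dims = c(40L, 40L, 40L), spacing = c(3, 3, 3),
                        brainSemiAxes = c(52, 52, 48),
                        tumorCenterOffset = c(0, -12, -10),
                        edemaSemiAxes = c(16, 14, 14),
                        enhancingScale = 0.72, coreScale = 0.4,
                        amplitude = 3, decayLength = 20,
                        orientation = c("outward", "inward", "mixed"),
                        textureCorrelation = 4, textureSd = 0.15,
                        seed = 1L) {
  orientation <- match.arg(orientation)
  stopifnot(amplitude >= 0, decayLength > 0,
            coreScale < enhancingScale, enhancingScale < 1)
  structure(list(dims = as.integer(dims), spacing = as.numeric(spacing),
                 brainSemiAxes = brainSemiAxes,
                 tumorCenterOffset = tumorCenterOffset,
                 edemaSemiAxes = edemaSemiAxes,
                 enhancingScale = enhancingScale, coreScale = coreScale,
                 amplitude = amplitude, decayLength = decayLength,
                 orientation = orientation,
                 textureCorrelation = textureCorrelation,
                 textureSd = textureSd, seed = as.integer(seed)),
            class = "phantomSpec")
}

# nominal compartment intensity means (arbitrary units) per protocol:
# background 0, parenchyma 1, then En / Ed / NC contrast typical of each
# sequence (enhancing bright on Gd-T1w, edema bright on T2w/FLAIR, core
# dark on Gd-T1w/FLAIR, cystic bright on T2w).
.PHANTOM_MEANS <- list(
  GdT1w = c(brain = 1.0, En = 1.8, Ed = 1.2, NC = 0.4),
  T2w   = c(brain = 1.0, En = 1.3, Ed = 1.7, NC = 1.9),
  FLAIR = c(brain = 1.0, En = 1.4, Ed = 1.8, NC = 0.5))

.insideEllipsoid <- function(grids, center, semi) {
  ((grids$x - center[1]) / semi[1])^2 +
    ((grids$y - center[2]) / semi[2])^2 +
    ((grids$z - center[3]) / semi[3])^2 <= 1
}

#' Generate one synthetic phantom subject
#'
#' @param spec a [phantomSpec()].
#' @param protocols protocol tags to synthesize (default all three).
#' @return List with `scenes` (named list of [ImageScene-class]), `seg`
#'   (a [SegmentationMap-class]), `field` (a [DeformationField-class]),
#'   and the `spec`.
#' @export
generatePhantom <- function(spec, protocols = .PROTOCOLS) {
  stopifnot(inherits(spec, "phantomSpec"))
  set.seed(spec$seed)
  d <- spec$dims
  sp <- spec$spacing
  grids <- .coordGrids(d, sp, c(0, 0, 0))
  boxCenter <- (d - 1) * sp / 2
  tumorCenter <- boxCenter + spec$tumorCenterOffset
  brain <- .insideEllipsoid(grids, boxCenter, spec$brainSemiAxes)
  ed <- .insideEllipsoid(grids, tumorCenter, spec$edemaSemiAxes)
  en <- .insideEllipsoid(grids, tumorCenter,
                         spec$edemaSemiAxes * spec$enhancingScale)
  nc <- .insideEllipsoid(grids, tumorCenter,
                         spec$edemaSemiAxes * spec$coreScale)
  if (any(ed & !brain)) stop("tumor exceeds the brain ellipsoid")
  labels <- array(0L, d)
  labels[ed] <- 2L
  labels[en] <- 1L
  labels[nc] <- 3L
  seg <- SegmentationMap(labels, brain, spacing = sp)
  habitat <- labels != 0L

  # per-compartment Gaussian-random-field textures, shared smoothing
  sigmaVox <- spec$textureCorrelation / sp
  scenes <- list()
  for (p in protocols) {
    noise <- array(rnorm(prod(d)), d)
    smooth <- .gaussSmooth(noise, sigmaVox)
    smooth <- smooth / sd(smooth)
    mu <- .PHANTOM_MEANS[[p]]
    vox <- array(0, d)
    vox[brain] <- mu["brain"]
    vox[labels == 2L] <- mu["Ed"]
    vox[labels == 1L] <- mu["En"]
    vox[labels == 3L] <- mu["NC"]
    vox[brain] <- vox[brain] + spec$textureSd * smooth[brain]
    scenes[[p]] <- ImageScene(vox, spacing = sp, protocol = p)
  }

  # analytic radially decaying displacement field
  centroid <- tumorCentroid(habitat, sp)
  dist <- distanceToMask(habitat, sp)
  rx <- grids$x - centroid[1]
  ry <- grids$y - centroid[2]
  rz <- grids$z - centroid[3]
  rn <- sqrt(rx^2 + ry^2 + rz^2)
  rn[rn == 0] <- 1
  mag <- spec$amplitude * exp(-dist / spec$decayLength)
  sgn <- switch(spec$orientation,
                outward = 1,
                inward = -1,
                mixed = array(sample(c(-1, 1), prod(d), replace = TRUE), d))
  fld <- array(0, c(d, 3L))
  fld[, , , 1] <- sgn * mag * rx / rn
  fld[, , , 2] <- sgn * mag * ry / rn
  fld[, , , 3] <- sgn * mag * rz / rn
  field <- DeformationField(fld, spacing = sp)

  list(scenes = scenes, seg = seg, field = field, spec = spec)
}

#' Specification of a synthetic cohort with ground-truth survival
#'
#' Per-subject phantom parameters are drawn from uniform ranges; survival
#' times follow an exponential proportional-hazards model whose linear
#' predictor is `beta . z`, with `z` the standardized latent generator
#' parameters named in `betas`. Censoring is administrative-uniform on
#' `(0, tau)` with `tau` calibrated so the expected censored fraction
#' matches `censoringRate`.
#'
#' @param n number of subjects (>= 2).
#' @param amplitudeRange range of the deformation amplitude `A` (mm).
#' @param sizeRange multiplicative range for the edema semi-axes.
#' @param decayRange range of the decay length `lambda` (mm).
#' @param betas named numeric vector of true log-hazard coefficients on
#'   the standardized latent parameters; names from
#'   `c("amplitude", "size", "decay")`.
#' @param medianSurvival baseline median survival in months.
#' @param censoringRate target censored fraction in `[0, 1)`.
#' @param orientation passed to each subject's [phantomSpec()].
#' @param dims,spacing phantom grid.
#' @param seed master seed; each subject derives its own stream.
#' @return A list of class `cohortSpec`.
#' @export
cohortSpec <- function(n, amplitudeRange = c(0.5, 6),
                       sizeRange = c(0.85, 1.2), decayRange = c(15, 25),
                       betas = c(amplitude = 1),
                       medianSurvival = 24, censoringRate = 0.3,
                       orientation = "outward",
                       dims = c(40L, 40L, 40L), spacing = c(3, 3, 3),
                       seed = 1L) {
  stopifnot(n >= 2, censoringRate >= 0, censoringRate < 1)
  if (length(betas) && !all(names(betas) %in% c("amplitude", "size",
                                                "decay")))
    stop("betas must be named after latent parameters: amplitude/size/decay")
  structure(list(n = as.integer(n), amplitudeRange = amplitudeRange,
                 sizeRange = sizeRange, decayRange = decayRange,
                 betas = betas, medianSurvival = medianSurvival,
                 censoringRate = censoringRate, orientation = orientation,
                 dims = as.integer(dims), spacing = as.numeric(spacing),
                 seed = as.integer(seed)),
            class = "cohortSpec")
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws per-subject phantom parameters, builds each subject's
#' [phantomSpec()], and simulates survival from the exponential
#' proportional-hazards model. The phantom volumes themselves are
#' generated lazily (each subject's spec is deterministic), so feature
#' extraction can stream through subjects.
#'
#' @param spec a [cohortSpec()].
#' @return List with `phantoms` (per-subject [phantomSpec()]s),
#'   `survival` (data.frame: subject_id, time_months, event), and
#'   `truth` (data.frame of latent parameters, hazards, and the uncensored
#'   event times).
#' @export
generateCohort <- function(spec) {
  stopifnot(inherits(spec, "cohortSpec"))
  set.seed(spec$seed)
  n <- spec$n
  amp <- runif(n, spec$amplitudeRange[1], spec$amplitudeRange[2])
  size <- runif(n, spec$sizeRange[1], spec$sizeRange[2])
  decay <- runif(n, spec$decayRange[1], spec$decayRange[2])
  latent <- cbind(amplitude = amp, size = size, decay = decay)
  lp <- rep(0, n)
  for (nm in names(spec$betas)) {
    z <- (latent[, nm] - mean(latent[, nm])) / sd(latent[, nm])
    lp <- lp + spec$betas[[nm]] * z
  }
  h0 <- log(2) / spec$medianSurvival
  hazard <- h0 * exp(lp)
  tEvent <- rexp(n, rate = hazard)
  if (spec$censoringRate > 0) {
    # administrative-uniform censoring horizon matching the target rate
    censFrac <- function(tau) {
      mean((1 - exp(-hazard * tau)) / (hazard * tau)) - spec$censoringRate
    }
    tau <- uniroot(censFrac, interval = c(1e-3, 1e6))$root
    tCens <- runif(n, 0, tau)
  } else {
    tCens <- rep(Inf, n)
  }
  event <- as.integer(tEvent <= tCens)
  time <- pmin(tEvent, tCens)
  ids <- sprintf("subj%03d", seq_len(n))
  subjSeeds <- as.integer((as.numeric(spec$seed) * 1000 + seq_len(n)) %%
                            2147483647)
  phantoms <- lapply(seq_len(n), function(i) {
    phantomSpec(dims = spec$dims, spacing = spec$spacing,
                edemaSemiAxes = c(16, 14, 14) * size[i],
                amplitude = amp[i], decayLength = decay[i],
                orientation = spec$orientation, seed = subjSeeds[i])
  })
  names(phantoms) <- ids
  list(phantoms = phantoms,
       survival = data.frame(subject_id = ids, time_months = time,
                             event = event, stringsAsFactors = FALSE),
       truth = data.frame(subject_id = ids, amplitude = amp, size = size,
                          decay = decay, linearPredictor = lp,
                          hazard = hazard, eventTime = tEvent,
                          censorTime = tCens, stringsAsFactors = FALSE))
}
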