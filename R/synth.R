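# Synthetic time-serial lesion cohort generator. Lesions are ellipsoids
# with a Gaussian-random-field texture on a lung-like background; the
# prognostic signal is planted in three per-day progression rates (volume,
# texture amplitude, peritumoral rim decay) whose weighted sum is the
# latent risk driving a proportional-hazards event-time generator.

#' Lesion appearance parameters
#'
#' @param centerMm lesion centre in world mm.
#' @param radiiMm ellipsoid semi-axes in mm (> 0).
#' @param coreIntensity tumor core intensity (HU-like).
#' @param textureScaleMm correlation length of the intensity noise (> 0).
#' @param textureAmplitude amplitude of the texture field.
#' @param rimGradient peritumoral intensity decay per mm (> 0): the rim
#'   falls from the core value back to lung background as
#'   `exp(-rimGradient * distance)`.
#' @return a `LesionParams` list.
#' @export
lesionParams <- function(centerMm, radiiMm, coreIntensity = -20,
                         textureScaleMm = 3, textureAmplitude = 60,
                         rimGradient = 0.25) {
  stopifnot(all(radiiMm > 0), textureScaleMm > 0)
  structure(list(centerMm = centerMm, radiiMm = radiiMm,
                 coreIntensity = coreIntensity,
                 textureScaleMm = textureScaleMm,
                 textureAmplitude = textureAmplitude,
                 rimGradient = rimGradient), class = "LesionParams")
}

#' Progression profile: per-day change rates and the latent risk
#'
#' The latent risk is a deterministic linear combination of the three
#' per-day rates (plus an optional baseline-texture term), with the
#' configured weights.
#'
#' @param volumeRatePerDay fractional volume change per day.
#' @param textureRatePerDay fractional change of texture amplitude per day.
#' @param periRatePerDay fractional change of rim decay per day.
#' @param baselineTextureZ standardized baseline texture amplitude
#'   (z-score), giving the baseline scans a weak prognostic signal.
#' @param weights named numeric: `volume`, `texture`, `peri`, `baseline`.
#' @return a `ProgressionProfile` list with `latentRisk`.
#' @export
progressionProfile <- function(volumeRatePerDay, textureRatePerDay,
                               periRatePerDay, baselineTextureZ = 0,
                               weights = c(volume = 260, texture = 170,
                                           peri = 240, baseline = 0.85)) {
  risk <- weights[["volume"]] * volumeRatePerDay +
    weights[["texture"]] * textureRatePerDay +
    weights[["peri"]] * periRatePerDay +
    weights[["baseline"]] * baselineTextureZ
  structure(list(volumeRatePerDay = volumeRatePerDay,
                 textureRatePerDay = textureRatePerDay,
                 periRatePerDay = periRatePerDay,
                 baselineTextureZ = baselineTextureZ,
                 latentRisk = risk), class = "ProgressionProfile")
}

# GRF texture: smoothed white noise, normalized to unit in-grid sd
.grf <- function(dim3, sigmaVox) {
  w <- array(rnorm(prod(dim3)), dim3)
  g <- .gaussian_blur_cpp(w, as.integer(dim3), rep(sigmaVox, 3))
  g / sd(g)
}

#' Simulate one baseline / follow-up scan pair
#'
#' Builds the F0 image from the lesion parameters, evolves volume, texture
#' amplitude and rim decay by the profile's per-day rates over the
#' interval, and renders F1 on the same grid using the same underlying
#' texture field (so feature deltas reflect the planted rates, not fresh
#' noise). The F1 lesion volume is `F0 volume * (1 + rate * days)`,
#' clipped below at `volumeFloor`. Identical seeds give identical voxels.
#'
#' @param params a [lesionParams()] object.
#' @param profile a [progressionProfile()] object.
#' @param intervalDays days between scans (>= 1).
#' @param gridSpec list with `dim` (3 integers) and optional `spacing`,
#'   `origin`.
#' @param seed integer seed.
#' @param background list of background options: `lungIntensity`,
#'   `noiseSd`, `wallIntensity`, `wallThicknessMm` (0 = no chest wall).
#' @param volumeFloor lower clip for the volume scale factor.
#' @return a [ScanPair-class] (lung mask excludes the chest wall slab).
#' @export
simulateLesionPair <- function(params, profile, intervalDays, gridSpec,
                               seed = 1,
                               background = list(), volumeFloor = 0.05) {
  bg <- modifyList(list(lungIntensity = -800, noiseSd = 30,
                        wallIntensity = 40, wallThicknessMm = 0),
                   background)
  d3 <- as.integer(gridSpec$dim)
  sp <- if (is.null(gridSpec$spacing)) c(1, 1, 1) else gridSpec$spacing
  org <- if (is.null(gridSpec$origin)) c(0, 0, 0) else gridSpec$origin

  sVol <- max(1 + profile$volumeRatePerDay * intervalDays, volumeFloor)
  radii1 <- params$radiiMm * sVol^(1 / 3)
  amp1 <- params$textureAmplitude *
    max(1 + profile$textureRatePerDay * intervalDays, 0.05)
  rim1 <- params$rimGradient *
    max(1 + profile$periRatePerDay * intervalDays, 0.05)

  # margin check: lesion + 10 mm dilation must stay inside the grid
  extent <- org + (d3 - 1) * sp
  maxR <- pmax(params$radiiMm, radii1)
  wall <- bg$wallThicknessMm
  lo <- params$centerMm - maxR - 10
  hi <- params$centerMm + maxR + 10
  if (any(lo < org + c(wall, 0, 0) + sp) || any(hi > extent - sp))
    stop("lesion plus 10 mm dilation margin exceeds the grid ",
         "(need [", paste(round(lo, 1), collapse = ","), "] to [",
         paste(round(hi, 1), collapse = ","), "] inside the lung region)")

  with_seed(seed, {
    tex <- .grf(d3, params$textureScaleMm / mean(sp))
    noise0 <- array(rnorm(prod(d3), sd = bg$noiseSd), d3)
    noise1 <- array(rnorm(prod(d3), sd = bg$noiseSd), d3)

    m0 <- .ellipsoid_mask(d3, sp, params$centerMm, params$radiiMm, org)
    m1 <- .ellipsoid_mask(d3, sp, params$centerMm, radii1, org)

    render <- function(mask, amp, rim, noise) {
      dist <- .edt_cpp(mask@values, d3, as.numeric(sp))
      decay <- exp(-rim * dist)
      vals <- bg$lungIntensity +
        (params$coreIntensity - bg$lungIntensity) * decay +
        amp * tex * decay + noise
      if (bg$wallThicknessMm > 0) {
        x <- org[1] + (seq_len(d3[1]) - 1) * sp[1]
        slab <- x < org[1] + bg$wallThicknessMm
        vals[slab, , ] <- bg$wallIntensity +
          noise[slab, , , drop = FALSE]
      }
      voxelGrid(vals, spacing = sp, origin = org)
    }
    f0 <- render(m0, params$textureAmplitude, params$rimGradient, noise0)
    f1 <- render(m1, amp1, rim1, noise1)

    lungArr <- array(TRUE, d3)
    if (bg$wallThicknessMm > 0) {
      x <- org[1] + (seq_len(d3[1]) - 1) * sp[1]
      lungArr[x < org[1] + bg$wallThicknessMm, , ] <- FALSE
    }
    new("ScanPair", f0 = f0, f0Mask = m0, f1 = f1, f1Mask = m1,
        lungMask = binaryMask(lungArr, sp, org),
        intervalDays = as.numeric(intervalDays))
  })
}

#' Simulate a progression-free survival outcome
#'
#' Event time is exponential with hazard proportional to
#' `exp(latentRisk)` (`baselineScale` = mean event time at risk 0, in
#' months); censoring time is uniform on `(0, censorWindow)`. Returns the
#' observed time and the event indicator.
#'
#' @param latentRisk scalar log-hazard offset.
#' @param baselineScale mean event time (months) at zero risk (> 0).
#' @param censorWindow upper bound of the uniform censoring time (months).
#' @param seed integer seed.
#' @return list with `time` (months, > 0) and `event` (0/1).
#' @export
simulateSurvival <- function(latentRisk, baselineScale = 10,
                             censorWindow = 300, seed = 1) {
  if (baselineScale <= 0) stop("baselineScale must be > 0")
  with_seed(seed, {
    tEvent <- rexp(length(latentRisk),
                   rate = exp(latentRisk) / baselineScale)
    tCens <- runif(length(latentRisk), 0, censorWindow)
    list(time = pmax(pmin(tEvent, tCens), 1e-6),
         event = as.integer(tEvent <= tCens))
  })
}

#' Perturb a mask to emulate a re-segmentation
#'
#' Displaces the mask boundary by a smooth random field bounded by
#' `boundaryJitterMm` (implemented on the signed Euclidean distance to the
#' boundary), emulating the intra-observer variability of a segmentation
#' repeated a month apart. Zero jitter returns the identical mask.
#'
#' @param mask a nonempty [BinaryMask-class].
#' @param boundaryJitterMm maximum boundary displacement in mm (>= 0).
#' @param seed integer seed.
#' @param diceFloor expected lower bound for Dice(original, perturbed);
#'   a warning is emitted when violated.
#' @return a perturbed [BinaryMask-class].
#' @export
perturbMask <- function(mask, boundaryJitterMm, seed = 1,
                        diceFloor = 0.90) {
  stopifnot(is(mask, "BinaryMask"), boundaryJitterMm >= 0)
  if (!any(mask@values)) stop("empty mask")
  if (boundaryJitterMm == 0) return(mask)
  d3 <- dim(mask@values)
  dOut <- .edt_cpp(mask@values, as.integer(d3), as.numeric(mask@spacing))
  dIn <- .edt_cpp(!mask@values, as.integer(d3), as.numeric(mask@spacing))
  signed <- dOut - dIn  # > 0 outside, < 0 inside
  u <- with_seed(seed, .grf(d3, 4))
  # scale so displacements use most of the +/- jitter band while staying
  # bounded by it
  u <- pmax(pmin(u / quantile(abs(u), 0.99), 1), -1)
  newArr <- array(signed <= boundaryJitterMm * u, d3)
  if (!any(newArr)) stop("perturbation emptied the mask")
  dice <- 2 * sum(newArr & mask@values) /
    (sum(newArr) + sum(mask@values))
  if (dice < diceFloor)
    warning("retest perturbation Dice ", round(dice, 3),
            " below floor ", diceFloor)
  binaryMask(newArr, mask@spacing, mask@origin)
}

# truncated log-normal sampler (resampling rejection)
.rlnorm_trunc <- function(n, meanlog, sdlog, lo, hi) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- rlnorm(n, meanlog, sdlog)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

#' Default synthetic cohort configuration
#'
#' Study conditions of the default cohort: 131 training + 41 validation
#' patients, inter-scan interval log-normal with median 35 days truncated
#' to 16--128 days, ~83% progression events, clinical covariates sampled
#' from marginal frequencies (independent of the latent risk unless
#' `clinicalVolumeEffect` is set), and image features whose per-day change
#' carries the planted signal. See `validateConfig()` for field checks.
#'
#' @return a named list of defaults.
#' @export
defaultCohortConfig <- function() {
  list(
    nTrain = 131, nValid = 41, nRetest = 30,
    intervalMin = 16, intervalMax = 128, intervalMedianDays = 35,
    intervalSdlog = 0.45,
    volumeMedianMl = 15, volumeSdlog = 0.5,
    volumeMinMl = 0.7, volumeMaxMl = 60,
    coreIntensity = -20, textureScaleMm = 3,
    textureAmplitudeMedian = 60, textureAmplitudeSdlog = 0.45,
    rimGradient = 0.25,
    lungIntensity = -800, noiseSd = 30,
    wallIntensity = 40, wallFraction = 0.3, wallThicknessMm = 6,
    volumeRateMean = -0.003, volumeRateSd = 0.004,
    textureRateSd = 0.004, periRateSd = 0.004,
    weightVolume = 260, weightTexture = 170, weightPeri = 240,
    weightBaseline = 0.85,
    baselineScale = 10, censorWindow = 300,
    retestJitterMm = 1.5,
    spacingMm = 1.0)
}

#' Simulate a time-serial imaging cohort
#'
#' Writes, per patient, the six NIfTI volumes
#' (`F0`, `F0_mask`, `F0_mask_retest`, `F1`, `F1_mask`, `lung_mask`) under
#' `<dir>/<patient_id>/` plus `clinical.csv`, `outcomes.csv`,
#' `intervals.csv` and a ground-truth `truth.csv` (latent risk and planted
#' rates) at the cohort root. Clinical covariates are sampled from fixed
#' marginal frequencies and are independent of the latent risk by default;
#' `clinicalVolumeEffect > 0` adds `effect * volumeMl` to the log-hazard.
#'
#' @param config list of overrides of [defaultCohortConfig()].
#' @param seed integer master seed.
#' @param dir output directory (`NULL` for in-memory only).
#' @param clinicalVolumeEffect optional log-hazard per mL of baseline
#'   volume (default 0 = clinical covariates uninformative).
#' @return (invisibly) a list with `clinical`, `outcomes`, `intervals`,
#'   `truth` data.frames and `patients` (a list of per-patient
#'   [ScanPair-class] + retest masks when `dir` is `NULL`).
#' @export
simulateCohort <- function(config = list(), seed = 1, dir = NULL,
                           clinicalVolumeEffect = 0) {
  cfg <- validateConfig(config)
  n <- cfg$nTrain + cfg$nValid
  if (n < 10) stop("cohort too small: need at least 10 patients")
  ids <- c(sprintf("train_%03d", seq_len(cfg$nTrain)),
           sprintf("valid_%03d", seq_len(cfg$nValid)))
  cohort <- c(rep("train", cfg$nTrain), rep("valid", cfg$nValid))

  draws <- with_seed(stageSeed(seed, "cohort_draws"), {
    interval <- round(.rlnorm_trunc(n, log(cfg$intervalMedianDays),
                                    cfg$intervalSdlog, cfg$intervalMin,
                                    cfg$intervalMax))
    volMl <- .rlnorm_trunc(n, log(cfg$volumeMedianMl), cfg$volumeSdlog,
                           cfg$volumeMinMl, cfg$volumeMaxMl)
    ampl <- rlnorm(n, log(cfg$textureAmplitudeMedian),
                   cfg$textureAmplitudeSdlog)
    vr <- rnorm(n, cfg$volumeRateMean, cfg$volumeRateSd)
    tr <- rnorm(n, 0, cfg$textureRateSd)
    pr <- rnorm(n, 0, cfg$periRateSd)
    anis <- matrix(runif(3 * n, 0.85, 1.15), ncol = 3)
    wall <- runif(n) < cfg$wallFraction
    list(interval = interval, volMl = volMl, ampl = ampl, vr = vr,
         tr = tr, pr = pr, anis = anis, wall = wall)
  })

  clinical <- with_seed(stageSeed(seed, "cohort_clinical"), {
    data.frame(
      patient_id = ids,
      sex = sample(c("female", "male"), n, TRUE, prob = c(0.565, 0.435)),
      age = round(runif(n, 32, 84)),
      smoking = sample(c("no", "yes"), n, TRUE, prob = c(0.75, 0.25)),
      ethnicity = sample(c("han", "minority"), n, TRUE,
                         prob = c(0.59, 0.41)),
      t_stage = sample(c("T1", "T2", "T3", "T4"), n, TRUE,
                       prob = c(0.058, 0.07, 0.134, 0.738)),
      n_stage = sample(c("N0", "N1", "N2", "N3"), n, TRUE,
                       prob = c(0.11, 0.256, 0.384, 0.25)),
      m_stage = sample(c("M0", "M1"), n, TRUE, prob = c(0.04, 0.96)),
      tki_drug = sample(c("afatinib", "erlotinib", "gefitinib",
                          "icotinib", "osimertinib"), n, TRUE,
                        prob = c(0.029, 0.035, 0.576, 0.308, 0.052)),
      baseline_volume_ml = NA_real_,
      stringsAsFactors = FALSE)
  })

  weights <- c(volume = cfg$weightVolume, texture = cfg$weightTexture,
               peri = cfg$weightPeri, baseline = cfg$weightBaseline)

  truth <- data.frame(patient_id = ids, cohort = cohort,
                      volume_rate = draws$vr, texture_rate = draws$tr,
                      peri_rate = draws$pr, latent_risk = NA_real_)

  if (!is.null(dir)) dir.create(dir, recursive = TRUE,
                                showWarnings = FALSE)
  patients <- if (is.null(dir)) vector("list", n) else NULL
  outcomes <- data.frame(patient_id = ids, pfs_months = NA_real_,
                         event = NA_integer_)

  for (i in seq_len(n)) {
    rMm <- (3 * draws$volMl[i] * 1000 / (4 * pi))^(1 / 3)
    radii <- rMm * draws$anis[i, ]
    radii <- radii * (draws$volMl[i] * 1000 /
                        (4 / 3 * pi * prod(radii)))^(1 / 3)
    zAmp <- (log(draws$ampl[i]) - log(cfg$textureAmplitudeMedian)) /
      cfg$textureAmplitudeSdlog
    prof <- progressionProfile(draws$vr[i], draws$tr[i], draws$pr[i],
                               baselineTextureZ = zAmp,
                               weights = weights)
    truth$latent_risk[i] <- prof$latentRisk

    sVol <- max(1 + prof$volumeRatePerDay * draws$interval[i], 0.05)
    maxRad <- max(radii) * max(1, sVol)^(1 / 3)
    wallMm <- if (draws$wall[i]) cfg$wallThicknessMm else 0
    half <- ceiling(maxRad + 10 + 3)
    d3 <- c(2 * half + 1 + ceiling(wallMm), 2 * half + 1, 2 * half + 1)
    center <- c(half + wallMm, half, half) * cfg$spacingMm

    pair <- simulateLesionPair(
      lesionParams(center, radii, cfg$coreIntensity, cfg$textureScaleMm,
                   draws$ampl[i], cfg$rimGradient),
      prof, draws$interval[i],
      gridSpec = list(dim = d3, spacing = rep(cfg$spacingMm, 3)),
      seed = stageSeed(seed, paste0("lesion_", ids[i])),
      background = list(lungIntensity = cfg$lungIntensity,
                        noiseSd = cfg$noiseSd,
                        wallIntensity = cfg$wallIntensity,
                        wallThicknessMm = wallMm))
    retest <- perturbMask(pair@f0Mask, cfg$retestJitterMm,
                          seed = stageSeed(seed,
                                           paste0("retest_", ids[i])))

    volMl <- maskVolumeMl(pair@f0Mask)
    clinical$baseline_volume_ml[i] <- volMl
    risk <- prof$latentRisk + clinicalVolumeEffect * volMl
    sv <- simulateSurvival(risk, cfg$baselineScale, cfg$censorWindow,
                           seed = stageSeed(seed,
                                            paste0("surv_", ids[i])))
    outcomes$pfs_months[i] <- sv$time
    outcomes$event[i] <- sv$event

    if (!is.null(dir)) {
      pdir <- file.path(dir, ids[i])
      dir.create(pdir, showWarnings = FALSE)
      writeVolume(pair@f0, file.path(pdir, "F0.nii.gz"))
      writeVolume(pair@f0Mask, file.path(pdir, "F0_mask.nii.gz"))
      writeVolume(retest, file.path(pdir, "F0_mask_retest.nii.gz"))
      writeVolume(pair@f1, file.path(pdir, "F1.nii.gz"))
      writeVolume(pair@f1Mask, file.path(pdir, "F1_mask.nii.gz"))
      writeVolume(pair@lungMask, file.path(pdir, "lung_mask.nii.gz"))
    } else {
      patients[[i]] <- list(pair = pair, retest = retest)
    }
  }

  intervals <- data.frame(patient_id = ids, diff_days = draws$interval)
  if (!is.null(dir)) {
    write.csv(clinical, file.path(dir, "clinical.csv"), row.names = FALSE)
    write.csv(outcomes, file.path(dir, "outcomes.csv"), row.names = FALSE)
    write.csv(intervals, file.path(dir, "intervals.csv"),
              row.names = FALSE)
    write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
    write.csv(data.frame(patient_id = ids, cohort = cohort),
              file.path(dir, "cohorts.csv"), row.names = FALSE)
  }
  invisible(list(clinical = clinical, outcomes = outcomes,
                 intervals = intervals, truth = truth,
                 cohort = cohort, patients = patients))
}
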