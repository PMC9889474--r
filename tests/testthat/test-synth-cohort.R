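# Synthetic cohort generator: lesion evolution, survival, retest masks.

small_grid <- function(r = 10, wall = 0) {
  half <- ceiling(r * 1.2 + 13)
  list(dim = c(2 * half + 1 + wall, 2 * half + 1, 2 * half + 1),
       center = c(half + wall, half, half))
}

test_that("lesion pair: zero rates leave the mask unchanged, planted
           volume growth is recovered, seeds are reproducible", {
  gs <- small_grid(12)
  p <- lesionParams(gs$center, c(12, 12, 12))
  prof0 <- progressionProfile(0, 0, 0)
  sp <- simulateLesionPair(p, prof0, 40, list(dim = gs$dim), seed = 3)
  expect_equal(sum(gridValues(scanMask(sp, "F1"))),
               sum(gridValues(scanMask(sp, "F0"))))

  # 1%/day for 50 days: 10 mL -> 15 mL within voxelization tolerance
  r10 <- (3 * 10000 / (4 * pi))^(1 / 3)
  gs2 <- small_grid(r10 * 1.2)
  p2 <- lesionParams(gs2$center, rep(r10, 3))
  prof <- progressionProfile(0.01, 0, 0)
  sp2 <- simulateLesionPair(p2, prof, 50, list(dim = gs2$dim), seed = 3)
  v0 <- maskVolumeMl(scanMask(sp2, "F0"))
  v1 <- maskVolumeMl(scanMask(sp2, "F1"))
  expect_lt(abs(v1 - v0 * 1.5) / (v0 * 1.5), 0.03)

  sp3 <- simulateLesionPair(p2, prof, 50, list(dim = gs2$dim), seed = 3)
  expect_identical(gridValues(scanGrid(sp2, "F0")),
                   gridValues(scanGrid(sp3, "F0")))
  expect_identical(gridValues(scanGrid(sp2, "F1")),
                   gridValues(scanGrid(sp3, "F1")))
})

test_that("lesion too close to the grid boundary raises the margin
           error", {
  p <- lesionParams(c(15, 15, 15), c(10, 10, 10))
  expect_error(simulateLesionPair(p, progressionProfile(0, 0, 0), 30,
                                  list(dim = c(31, 31, 31))),
               "margin|grid")
})

test_that("true mask-derived volume delta recovers the planted rate
           within 10% for lesions >= 10 mm diameter", {
  for (s in 1:5) {
    withr::with_seed(s, {
      rate <- runif(1, -0.006, 0.008)
      days <- sample(20:90, 1)
      if (abs(rate) < 0.001) rate <- 0.002
      gs <- small_grid(9)
      p <- lesionParams(gs$center, c(9, 8, 8.5))
      sp <- simulateLesionPair(p, progressionProfile(rate, 0, 0), days,
                               list(dim = gs$dim), seed = s + 10)
      v0 <- maskVolumeMl(scanMask(sp, "F0"))
      v1 <- maskVolumeMl(scanMask(sp, "F1"))
      est <- (v1 - v0) / (v0 * days)
      expect_lt(abs(est - rate) / abs(rate), 0.10)
    })
  }
})

test_that("survival generator: infinite censor window gives all events,
           Cox recovers a unit log-hazard-ratio, and the default censor
           window yields ~83% events", {
  sv <- simulateSurvival(rep(0, 500), 10, censorWindow = 1e9, seed = 2)
  expect_equal(mean(sv$event), 1)
  expect_error(simulateSurvival(0, baselineScale = -1), "> 0")

  g <- rep(0:1, 1000)
  sv2 <- simulateSurvival(g * 1.0, 10, censorWindow = 1e9, seed = 5)
  fit <- survival::coxph(survival::Surv(sv2$time, sv2$event) ~ g)
  expect_lt(abs(unname(coef(fit)) - 1.0), 0.15)

  cfg <- defaultCohortConfig()
  risks <- withr::with_seed(8, {
    cfg$weightVolume * rnorm(2000, cfg$volumeRateMean, cfg$volumeRateSd) +
      cfg$weightTexture * rnorm(2000, 0, cfg$textureRateSd) +
      cfg$weightPeri * rnorm(2000, 0, cfg$periRateSd) +
      cfg$weightBaseline * rnorm(2000)
  })
  sv3 <- simulateSurvival(risks, cfg$baselineScale, cfg$censorWindow,
                          seed = 9)
  expect_lt(abs(mean(sv3$event) - 0.83), 0.05)
})

test_that("planted monotonicity: latent risk anticorrelates with event
           times", {
  cfg <- defaultCohortConfig()
  risks <- withr::with_seed(12, {
    cfg$weightVolume * rnorm(500, cfg$volumeRateMean, cfg$volumeRateSd) +
      cfg$weightTexture * rnorm(500, 0, cfg$textureRateSd) +
      cfg$weightPeri * rnorm(500, 0, cfg$periRateSd) +
      cfg$weightBaseline * rnorm(500)
  })
  sv <- simulateSurvival(risks, cfg$baselineScale, cfg$censorWindow,
                         seed = 3)
  ev <- sv$event == 1
  ct <- cor.test(risks[ev], sv$time[ev], method = "spearman",
                 exact = FALSE)
  expect_lt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.01)
})

test_that("retest perturbation: zero jitter is identity, 1 mm jitter on a
           10 mm sphere keeps Dice >= 0.90, seeds reproduce", {
  m <- sphere_mask(10, margin = 6)
  expect_identical(perturbMask(m, 0, seed = 1), m)
  p1 <- perturbMask(m, 1, seed = 7)
  dice <- 2 * sum(gridValues(p1) & gridValues(m)) /
    (sum(gridValues(p1)) + sum(gridValues(m)))
  expect_gte(dice, 0.90)
  p2 <- perturbMask(m, 2, seed = 7)
  expect_identical(gridValues(p2),
                   gridValues(perturbMask(m, 2, seed = 7)))
  expect_error(perturbMask(binaryMask(array(FALSE, c(4, 4, 4))), 1),
               "empty")
})

test_that("cohort simulation: correct counts, interval bounds, CSV layout
           and byte-identical regeneration", {
  dir1 <- tempfile("coh_a_"); dir2 <- tempfile("coh_b_")
  cfg <- list(nTrain = 8, nValid = 4, volumeMedianMl = 4,
              volumeMaxMl = 8)
  sim1 <- simulateCohort(cfg, seed = 6, dir = dir1)
  sim2 <- simulateCohort(cfg, seed = 6, dir = dir2)
  expect_length(list.dirs(dir1, recursive = FALSE), 12)
  expect_equal(nrow(sim1$clinical), 12)
  expect_equal(nrow(sim1$outcomes), 12)
  expect_true(all(sim1$intervals$diff_days >= 16))
  expect_true(all(sim1$intervals$diff_days <= 128))
  expect_true(all(file.exists(file.path(
    dir1, sim1$clinical$patient_id[1],
    c("F0.nii.gz", "F0_mask.nii.gz", "F0_mask_retest.nii.gz",
      "F1.nii.gz", "F1_mask.nii.gz", "lung_mask.nii.gz")))))
  # determinism: identical config + seed reproduce identical volumes
  f <- file.path(sim1$clinical$patient_id[3], "F1.nii.gz")
  expect_identical(gridValues(readVolume(file.path(dir1, f))),
                   gridValues(readVolume(file.path(dir2, f))))
  expect_identical(sim1$outcomes, sim2$outcomes)
  expect_error(simulateCohort(list(nTrain = 4, nValid = 2), seed = 1),
               "at least 10")
  unlink(c(dir1, dir2), recursive = TRUE)
})
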