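test_that("Navon rasters respect the stimulus geometry and the background grid", {
  e_g <- render_navon("E", "Global", 0.05)
  lit <- which(e_g$raster == 1, arr.ind = TRUE)
  expect_lte(diff(range(lit[, "col"])) + 1, 40)   # <= 2.0 DVA wide
  expect_lte(diff(range(lit[, "row"])) + 1, 106)  # <= 5.3 DVA high
  expect_true(all(e_g$raster %in% c(0, 1)))

  bg <- navon_background(0.05)
  for (letter in c("E", "U")) for (level in c("Global", "Local")) {
    s <- render_navon(letter, level, 0.05)
    expect_true(all(s$raster <= bg$raster),
                label = paste(letter, level, "subset of background"))
  }

  # same call twice is identical; E and U differ within the background
  expect_identical(render_navon("E", "Global", 0.05)$raster, e_g$raster)
  u_g <- render_navon("U", "Global", 0.05)
  xored <- xor(e_g$raster == 1, u_g$raster == 1)
  expect_gt(sum(xored), 0)
  expect_true(all(bg$raster[xored] == 1))

  expect_error(render_navon("E", "Global", 0.5), "coarse")
  expect_error(render_navon("Z", "Global", 0.05))
})

test_that("retinotopic maps tile the 4-DVA disc evenly across hemispheres", {
  m <- build_retinotopic_map(400, 4.0, seed = 1)
  expect_true(all(m$eccentricity <= 4.0))
  expect_equal(unname(table(m$hemisphere)), c(200L, 200L), ignore_attr = TRUE)
  expect_identical(m$quadrant, vf_quadrant(m$vf_x, m$vf_y))
  # contralateral convention
  expect_true(all(m$vf_x[m$hemisphere == "L"] > 0))
  expect_true(all(m$vf_x[m$hemisphere == "R"] < 0))
  # eccentricity is consistent with coordinates
  expect_equal(m$eccentricity, sqrt(m$vf_x^2 + m$vf_y^2), tolerance = 1e-12)

  expect_identical(build_retinotopic_map(400, 4.0, seed = 1), m)
  m2 <- build_retinotopic_map(400, 4.0, seed = 2)
  expect_false(all(m2$vf_x == m$vf_x))
  expect_error(build_retinotopic_map(6), "even integer")
  expect_error(build_retinotopic_map(9), "even integer")
})

test_that("block schedules have 3 blocks per condition per run and 44 s blocks", {
  sch <- make_block_schedule(5, seed = 3)
  expect_equal(sum(sch$condition == "EG"), 15)
  # block components: 1 s cue + 19 s baseline + 20 s stimulation + 4 s report
  expect_true(all(sch$stim_onset_s - sch$block_onset_s == 20))
  expect_true(all(sch$report_onset_s - sch$block_onset_s == 40))
  expect_true(all(diff(sch$block_onset_s[sch$run == 1]) == 44))
  for (r in unique(sch$run))
    expect_equal(sort(table(sch$condition[sch$run == r])),
                 sort(c(EG = 3, EL = 3, UG = 3, UL = 3)), ignore_attr = TRUE)
  # order is randomized by seed but the multiset never changes
  sch_b <- make_block_schedule(5, seed = 4)
  expect_equal(table(sch_b$condition), table(sch$condition))
  expect_error(make_block_schedule(3), "4 or 5")
})

test_that("cohort generation is reproducible and planted effects appear in raw correlations", {
  map <- small_map()
  sch <- small_schedule()
  coh1 <- simulate_cohort(3, map, sch, effect_spec("level_topology"), seed = 9)
  coh2 <- simulate_cohort(3, map, sch, effect_spec("level_topology"), seed = 9)
  expect_identical(coh1$subjects[[2]]$runs[[1]]$bold,
                   coh2$subjects[[2]]$runs[[1]]$bold)

  # planted interhemispheric increment for Global only: the mean
  # interhemispheric correlation of the generated series (direct Pearson on
  # long concatenated stimulation epochs) is higher under EG than EL
  eff <- effect_spec("null",
                     planted_network = list(EG = c(interhemispheric = 0.3)))
  inter <- outer(map$hemisphere, map$hemisphere, `!=`)
  ut <- upper.tri(inter)
  mean_r <- function(cond) {
    segs <- lapply(1:12, function(s) {
      coh <- simulate_cohort(2, map, small_schedule(4, seed = s),
                             eff, seed = 100 + s)
      condition_series(coh$subjects[[1]], coh$schedule, cond, "raw")$data
    })
    M <- stats::cor(do.call(rbind, segs))
    mean(M[inter & ut])
  }
  expect_gt(mean_r("EG"), mean_r("EL") + 0.003)
})

test_that("zero-noise limit collapses subjects onto the shared evoked response", {
  map <- small_map(16)
  sch <- small_schedule()
  eff <- effect_spec("level_topology", idio_sd = 0, bg_sd = 1e-10)
  coh <- simulate_cohort(3, map, sch, eff, seed = 21)
  b1 <- coh$subjects[[1]]$runs[[1]]$bold
  b2 <- coh$subjects[[3]]$runs[[1]]$bold
  expect_lt(max(abs(b1 - b2)), 1e-6 * max(abs(b1)))
  # with identical series the CR matrix equals the within-subject matrix
  # (segment the raw bold directly: per-subject confound regression would
  # reintroduce subject-specific projections of the shared signal)
  raw_series <- function(s)
    segment_concatenate(lapply(s$runs, `[[`, "bold"), sch, "EG")
  s1 <- raw_series(coh$subjects[[1]])
  others <- lapply(coh$subjects[-1], raw_series)
  expect_equal(unclass(common_response_matrix(s1, others)),
               unclass(within_subject_matrix(s1)), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("non-positive-definite planted covariance is reported with its condition", {
  map <- small_map(16)
  eff <- effect_spec("null", planted_network = list(UG = c(LRup = 5)))
  expect_error(simulate_cohort(2, map, small_schedule(), eff, seed = 1),
               "condition UG")
})

test_that("synthetic gaze trajectories are bounded, centered and reproducible", {
  s <- render_navon("E", "Global", 0.05)
  g0 <- simulate_gaze(s, 5, dispersion = 0, seed = 1)
  lit <- which(s$raster == 1, arr.ind = TRUE)
  cx <- mean(lit[, "col"]) + (1280 - ncol(s$raster)) / 2
  cy <- mean(lit[, "row"]) + (1024 - nrow(s$raster)) / 2
  expect_true(all(g0$fixations$x == cx) && all(g0$fixations$y == cy))

  for (seed in 1:10) {
    g <- simulate_gaze(s, 50, dispersion = 40, seed = seed)
    expect_lte(sum(g$fixations$duration_ms), 20000)
    expect_true(all(g$fixations$duration_ms > 0))
    expect_true(all(g$fixations$x >= 1 & g$fixations$x <= 1280))
  }
  expect_identical(simulate_gaze(s, 20, 10, seed = 7),
                   simulate_gaze(s, 20, 10, seed = 7))
  empty <- s; empty$raster[] <- 0L
  expect_error(simulate_gaze(empty, 5, 1, seed = 1), "empty")
})
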