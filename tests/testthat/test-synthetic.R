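small_spec <- function(...) {
  cohort_spec(n_persons = c(healthy = 2L, MCI = 2L, PwD = 2L),
              trajectories_per_person = 4L, ...)
}

test_that("the generated layout matches the deployment it emulates", {
  lay <- generate_layout(seed = 3)
  m <- lay$map
  expect_equal(nrow(m), 67L)
  expect_equal(sum(m$kind == "motion"), 51L)
  expect_equal(sum(m$kind == "door"), 16L)
  # same seed, same map; different seed, different jitter
  expect_identical(generate_layout(seed = 3), lay)
  expect_false(identical(generate_layout(seed = 4)$map$x, m$x))
  # adjacent-sensor spacing stays below 3 m
  d <- as.matrix(dist(cbind(m$x, m$y)))
  diag(d) <- Inf
  expect_lt(max(apply(d, 1, min)), 3)
  # sensors inside the footprint
  expect_true(all(m$x >= 0 & m$x <= lay$width))
  expect_true(all(m$y >= 0 & m$y <= lay$height))
  expect_error(generate_layout(seed = 1, width = 3, height = 3),
               "too small")
})

test_that("generated pattern paths satisfy their own detector predicate", {
  lay <- generate_layout(seed = 2)
  set.seed(10)
  for (i in 1:15) {
    pace <- generate_pattern_path("pacing", lay, moves = sample(3:8, 1))
    expect_gte(detect_travel_patterns(pace)[["pacing"]], 1L)
    lap <- generate_pattern_path("lapping", lay, circuits = sample(2:4, 1))
    expect_gte(detect_travel_patterns(lap)[["lapping"]], 1L)
    dir <- generate_pattern_path("direct", lay)
    idx <- match(dir, lay$lattice$s_id)
    dir_tr <- make_traj(seq_along(dir), lay$lattice$x[idx],
                        lay$lattice$y[idx], s_id = dir)
    expect_equal(unname(detect_travel_patterns(dir_tr)), c(0L, 0L, 0L))
  }
  for (i in 1:10) {
    rnd <- generate_pattern_path("random", lay)
    idx <- match(rnd, lay$lattice$s_id)
    tr <- make_traj(seq_along(rnd), lay$lattice$x[idx], lay$lattice$y[idx],
                    s_id = rnd)
    expect_gte(detect_travel_patterns(tr)[["random"]], 1L)
  }
  # constructive lapping shape: cycle repeated then closed
  set.seed(1)
  lap <- generate_pattern_path("lapping", lay, start = c(2L, 2L),
                               circuits = 2L)
  cyc_len <- (length(lap) - 1L) / 2L
  expect_gte(cyc_len, 3L)
  expect_equal(lap[1:cyc_len], lap[cyc_len + (1:cyc_len)])
  expect_equal(lap[length(lap)], lap[1L])
})

test_that("a simulated person-day is deterministic and honestly annotated", {
  lay <- generate_layout(seed = 1)
  spec <- small_spec()
  d1 <- simulate_person_day("MCI", spec, lay, seed = 77)
  d2 <- simulate_person_day("MCI", spec, lay, seed = 77)
  expect_identical(d1, d2)
  d3 <- simulate_person_day("MCI", spec, lay, seed = 78)
  expect_false(identical(d1$events, d3$events))
  expect_equal(nrow(d1$truth), spec$trajectories_per_person)
  # all events are known sensors, times strictly ordered after sorting
  expect_true(all(d1$events$s_id %in% lay$map$s_id))
  expect_true(!is.unsorted(d1$events$t))
})

test_that("without injected noise, cleaning is the identity", {
  lay <- generate_layout(seed = 6)
  spec <- small_spec(noise_rate = 0)
  for (cl in COG_CLASSES) {
    day <- simulate_person_day(cl, spec, lay, seed = 42)
    h <- to_position_history(day$events, lay$map)
    expect_equal(nrow(clean_positions(h)), nrow(h), info = cl)
  }
})

test_that("injected teleports are removed and boundaries recovered exactly", {
  lay <- generate_layout(seed = 8)
  spec <- small_spec(noise_rate = 5)
  removed <- 0L; total <- 0L
  for (seed in 1:10) {
    day <- simulate_person_day("PwD", spec, lay, seed = seed)
    h <- to_position_history(day$events, lay$map)
    hc <- clean_positions(h)
    noise_kept <- sum(hc$t %in% day$noise_t)
    removed <- removed + length(day$noise_t) - noise_kept
    total <- total + length(day$noise_t)
    # segmentation recovers the embedded trajectory boundaries
    tl <- segment_trajectories(hc, t_s = 120)
    expect_equal(length(tl), nrow(day$truth))
    expect_equal(vapply(tl, function(tr) tr$t[1L], 0), day$truth$start_t,
                 tolerance = 1e-9)
  }
  expect_gte(removed / total, 0.95)
})

test_that("impaired-class days carry more wander episodes than healthy days", {
  lay <- generate_layout(seed = 9)
  pwd_spec <- small_spec()
  n_pwd <- 0L; n_h <- 0L
  for (seed in 1:20) {
    d_p <- simulate_person_day("PwD", pwd_spec, lay, seed = seed)
    d_h <- simulate_person_day("healthy", pwd_spec, lay, seed = 1000 + seed)
    n_pwd <- n_pwd + sum(d_p$patterns$pacing + d_p$patterns$random +
                           d_p$patterns$lapping)
    n_h <- n_h + sum(d_h$patterns$pacing + d_h$patterns$random +
                       d_h$patterns$lapping)
  }
  expect_gt(n_pwd, n_h)
})

test_that("post-cleaning speeds stay within the simulated support", {
  lay <- generate_layout(seed = 10)
  spec <- small_spec()
  vs <- c()
  for (seed in 1:5) {
    day <- simulate_person_day("healthy", spec, lay, seed = seed)
    hc <- clean_positions(to_position_history(day$events, lay$map))
    vs <- c(vs, sqrt(diff(hc$x)^2 + diff(hc$y)^2) / diff(hc$t))
  }
  expect_gte(length(vs), 100)
  expect_true(all(vs >= 0 & vs <= 15))
  # bulk of apparent speeds near true walking speed despite timing jitter
  expect_gt(median(vs), 0.5)
  expect_lt(median(vs), 2)
})

test_that("cohorts are labeled, reproducible and validated", {
  spec <- cohort_spec(n_persons = c(healthy = 3L, MCI = 2L, PwD = 2L),
                      trajectories_per_person = 3L, seed = 21)
  co <- generate_cohort(spec)
  expect_equal(nrow(co$persons), 7L)
  expect_equal(as.integer(table(co$persons$class)[c("healthy", "MCI", "PwD")]),
               c(3L, 2L, 2L))
  co2 <- generate_cohort(spec)
  expect_identical(co$manifest, co2$manifest)
  expect_identical(co$days, co2$days)
  expect_error(generate_cohort(cohort_spec(n_persons = c(healthy = 2L,
                                                         MCI = 0L,
                                                         PwD = 2L))),
               ">= 2 persons")
  # written cohort reads back through the ingestion path
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  m <- load_sensor_map(file.path(dir, "sensors.csv"))
  expect_equal(nrow(m), 67L)
  ev <- load_event_stream(file.path(dir, "events_P001.csv"))
  expect_equal(nrow(ev), nrow(co$days$P001$events))
  expect_equal(ev$t, co$days$P001$events$t, tolerance = 1e-3)
})

test_that("the numeric-feature baseline separates a well-split tiny cohort", {
  co <- generate_cohort(cohort_spec(n_persons = c(healthy = 4, MCI = 4,
                                                  PwD = 4),
                                    trajectories_per_person = 6L, seed = 13))
  nfe <- cohort_nfe_table(co, t_s = 120)
  expect_equal(nrow(nfe), 12L)
  expect_true(all(c("pacing_count", "lapping_count", "random_count",
                    "mean_jerk", "mean_straightness",
                    "sharp_angle_count") %in% names(nfe)))
  res <- nfe_reference_classifier(nfe, seed = 1)
  # daily wandering counts separate these classes far above chance
  expect_gte(mean(res$predictions$predicted == res$predictions$truth), 0.6)
})
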