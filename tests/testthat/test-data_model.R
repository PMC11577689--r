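test_that("subject records validate measurement and path structure", {
  g <- fig1_graph()
  expect_error(
    subject_record(1, c(1, 1), c(0, 0), path = rbind(c(0, 0)), censor_time = 2),
    "strictly increasing"
  )
  expect_error(
    subject_record(1, numeric(0), numeric(0), path = rbind(c(0, 0)), censor_time = 2),
    "at least one"
  )
  expect_error(
    subject_record(1, 1, 0, path = rbind(c(0, 0)), censor_time = 0.5),
    "after the censoring time"
  )
  expect_error(
    subject_record(1, 1, 0, path = rbind(c(0, 0), c(3, 2)), censor_time = 4,
                   graph = g),
    "not permitted"
  )
})

test_that("event-file paths are reconstructed from counting-process rows", {
  g <- fig1_graph()
  long <- data.frame(id = 1, time = c(1, 3, 5, 7), value = c(0.4, 0.6, 0.5, 0.7),
                     age = 0.2)
  ev <- data.frame(
    id = 1,
    from = c(0, 0, 0, 2, 2), to = c(1, 2, 4, 3, 4),
    tstart = c(0, 0, 0, 4, 4), tstop = c(4, 4, 4, 8, 8),
    status = c(0, 1, 0, 0, 1)
  )
  lf <- tempfile(fileext = ".csv"); ef <- tempfile(fileext = ".csv")
  write.csv(long, lf, row.names = FALSE); write.csv(ev, ef, row.names = FALSE)
  dat <- read_joint_data(lf, ef, g)
  s <- dat$subjects[[1]]
  expect_equal(unname(s$path), rbind(c(0, 0), c(2, 4), c(4, 8)))
  expect_equal(s$censor_time, 8)
  expect_equal(s$w, c(age = 0.2))

  # censored without any transition
  ev0 <- data.frame(id = 2, from = 0, to = c(1, 2, 4), tstart = 0, tstop = 6,
                    status = 0)
  long0 <- data.frame(id = 2, time = 2, value = 0.1, age = 0)
  write.csv(long0, lf, row.names = FALSE); write.csv(ev0, ef, row.names = FALSE)
  s0 <- read_joint_data(lf, ef, g)$subjects[[1]]
  expect_equal(nrow(s0$path), 1L)
  expect_equal(s0$censor_time, 6)
})

test_that("write -> read round trip returns identical records", {
  dat <- toy_data_single(n = 12, seed = 4)
  lf <- tempfile(fileext = ".csv"); ef <- tempfile(fileext = ".csv")
  write_joint_data(dat, lf, ef)
  dat2 <- read_joint_data(lf, ef, dat$graph)
  expect_length(dat2$subjects, 12L)
  for (i in seq_len(12)) {
    s1 <- dat$subjects[[i]]; s2 <- dat2$subjects[[i]]
    expect_equal(s2$obs_times, s1$obs_times)
    expect_equal(s2$obs_values, s1$obs_values)
    expect_equal(unname(s2$path), unname(s1$path))
    expect_equal(s2$censor_time, s1$censor_time)
    expect_equal(unname(s2$w), unname(s1$w))
  }
})

test_that("block datasets implement concurrent and historical index sets", {
  g <- fig1_graph()
  dat <- joint_data(list(example_subject(g)), g)
  blk3 <- competing_risk_blocks(g)[[3]] # initial state 2
  conc <- build_block_dataset(dat, blk3, longitudinal_strategy("concurrent"))
  expect_equal(conc$members, 1L)
  expect_equal(conc$entry, 4)
  expect_equal(conc$exit, 8)
  expect_equal(conc$event_target, 4L)
  expect_equal(dat$subjects[[1]]$obs_times[conc$long_index[[1]]], c(5, 7))
  hist <- build_block_dataset(dat, blk3, longitudinal_strategy("historical"))
  expect_equal(dat$subjects[[1]]$obs_times[hist$long_index[[1]]], c(1, 3, 5, 7))

  # measurement at exactly the entry time belongs to the exited state
  s2 <- subject_record(2, c(0, 4, 6), c(0, 0, 0), w = c(age = 0),
                       path = rbind(c(0, 0), c(2, 4), c(4, 8)),
                       censor_time = 8, graph = g)
  dat2 <- joint_data(list(s2), g)
  conc2 <- build_block_dataset(dat2, blk3, longitudinal_strategy("concurrent"))
  expect_equal(dat2$subjects[[1]]$obs_times[conc2$long_index[[1]]], 6)

  # concurrent falls back to historical when the block holds no measurement
  s3 <- subject_record(3, c(0, 2), c(0, 0), w = c(age = 0),
                       path = rbind(c(0, 0), c(2, 4), c(4, 8)),
                       censor_time = 8, graph = g)
  dat3 <- joint_data(list(s3), g)
  conc3 <- build_block_dataset(dat3, blk3, longitudinal_strategy("concurrent"))
  expect_equal(conc3$long_index[[1]], c(1L, 2L))
})

test_that("subjects censored in the initial state appear only in that block", {
  g <- fig1_graph()
  s <- subject_record(1, 1, 0.5, w = c(age = 0), path = rbind(c(0, 0)),
                      censor_time = 6, graph = g)
  dat <- joint_data(list(s), g)
  blocks <- competing_risk_blocks(g)
  sizes <- vapply(blocks, function(b) {
    length(build_block_dataset(dat, b)$members)
  }, 0L)
  expect_equal(sizes, c(1L, 0L, 0L, 0L))
})

test_that("single-transition views censor competing events at the same exit", {
  g <- fig1_graph()
  dat <- joint_data(list(example_subject(g)), g)
  bd <- build_block_dataset(dat, competing_risk_blocks(g)[[3]])
  sv4 <- single_transition_view(bd, 4)
  expect_equal(sv4$event, 1L)
  expect_equal(sv4$exit, 8)
  sv3 <- single_transition_view(bd, 3)
  expect_equal(sv3$event, 0L)
  expect_equal(sv3$exit, 8)
  expect_error(single_transition_view(bd, 1), "not a terminal state")
})

test_that("block exposures, ST event counts and index-set nesting hold on simulated data", {
  cfg <- model1_preset(40, seed = 21)
  dat <- simulate_joint_data(cfg)
  g <- dat$graph
  blocks <- competing_risk_blocks(g)
  bds_h <- lapply(blocks, function(b) {
    build_block_dataset(dat, b, longitudinal_strategy("historical"))
  })
  bds_c <- lapply(blocks, function(b) {
    build_block_dataset(dat, b, longitudinal_strategy("concurrent"))
  })
  for (i in seq_along(dat$subjects)) {
    s <- dat$subjects[[i]]
    expo <- 0
    for (bd in bds_h) {
      m <- match(i, bd$members)
      if (!is.na(m)) expo <- expo + bd$exit[m] - bd$entry[m]
    }
    abs_idx <- which(s$path[, 1] %in% absorbing_states(g))
    expected <- if (length(abs_idx) > 0) unname(s$path[abs_idx[1], 2]) else s$censor_time
    expect_equal(expo, expected)
  }
  for (bi in seq_along(blocks)) {
    bd <- bds_h[[bi]]
    # exactly one ST event for subjects with an event, none for censored
    ev_count <- Reduce(`+`, lapply(blocks[[bi]]$terminal_states, function(k) {
      single_transition_view(bd, k)$event
    }))
    expect_equal(ev_count, as.integer(!is.na(bd$event_target)))
    # concurrent index sets nest in historical (equal for fallback subjects)
    bc <- bds_c[[bi]]
    for (m in seq_along(bc$members)) {
      mh <- match(bc$members[m], bd$members)
      expect_true(all(bc$long_index[[m]] %in% bd$long_index[[mh]]))
    }
  }
})
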