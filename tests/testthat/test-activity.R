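# Hierarchical daily categorization and weekly trajectory construction.

test_that("therapy levels follow the hierarchical rules", {
  expect_equal(unname(categorize_day(zero_day())), c(1L, 1L))
  # one step and one action together is highly engaged
  expect_equal(categorize_day(make_day(steps_started = 1, actions_done = 1))[["therapy"]], 4L)
  expect_equal(categorize_day(make_day(steps_started = 2))[["therapy"]], 4L)
  expect_equal(categorize_day(make_day(actions_done = 3))[["therapy"]], 4L)
  # exactly one step or one action is engaged
  expect_equal(categorize_day(make_day(steps_started = 1))[["therapy"]], 3L)
  expect_equal(categorize_day(make_day(actions_done = 1))[["therapy"]], 3L)
  # visits without content engagement are passive
  expect_equal(unname(categorize_day(make_day(visited_therapy = 1))), c(2L, 1L))
  expect_equal(categorize_day(make_day(visited_suggested_content = 1))[["therapy"]], 2L)
  # active days outrank their own visits
  expect_equal(categorize_day(make_day(steps_started = 1, visited_therapy = 1))[["therapy"]], 3L)
})

test_that("social levels follow the hierarchical rules", {
  # contribution always wins
  for (col in c("newsfeed_posts", "newsfeed_comments", "talk_it_out_posts")) {
    day <- make_day(likes_made = 5, visited_newsfeed = 1)
    day[[col]] <- 1
    expect_equal(categorize_day(day)[["social"]], 4L)
  }
  # likes/reactions without contribution are moderate, even alongside visits
  expect_equal(unname(categorize_day(make_day(likes_made = 2, visited_newsfeed = 1))),
               c(1L, 3L))
  expect_equal(categorize_day(make_day(reactions_made = 1))[["social"]], 3L)
  # visits only are passive, on any of the four social pages
  for (col in c("visited_messages", "visited_notifications",
                "visited_newsfeed", "visited_talk_it_out")) {
    day <- zero_day()
    day[[col]] <- 1
    expect_equal(unname(categorize_day(day)), c(1L, 2L))
  }
})

test_that("negative counts are rejected and flags validated", {
  expect_error(categorize_day(make_day(steps_started = -1)), "negative")
  expect_error(categorize_log(make_day(visited_therapy = 2)), "0/1 flag")
})

test_that("weekly score is the maximum daily level in each 7-day block", {
  # passive (2) then engaged (3) inside week 1 scores 3
  ws <- weekly_scores(c(2, 5), therapy_level = c(2, 3), social_level = c(1, 1))
  expect_equal(ws$therapy[1], 3L)
  expect_equal(ws$social[1], 1L)
  # block boundaries: day 8 belongs to week 1, day 9 opens week 2
  ws <- weekly_scores(c(8, 9), c(2, 4), c(1, 1))
  expect_equal(ws$therapy[1:2], c(2L, 4L))
  # missing weeks default to inactive
  expect_equal(weekly_scores(integer(0), integer(0), integer(0))$therapy,
               rep(1L, 22))
  # day 1 (induction) never contributes; days beyond the window are ignored
  ws <- weekly_scores(c(1, 156), c(4, 4), c(4, 4))
  expect_equal(ws$therapy, rep(1L, 22))
  expect_equal(ws$social, rep(1L, 22))
  expect_error(weekly_scores(2, 1, 1, n_weeks = 0), "positive")
})

test_that("the default window spans days 2-155: 154 days, 22 weeks", {
  start_day <- 2L
  n_weeks <- 22L
  last_day <- start_day + 7L * n_weeks - 1L
  expect_equal(last_day, 155L)
  expect_equal(last_day - start_day + 1L, 154L)
  ws <- weekly_scores(start_day:last_day, rep(2L, 154), rep(2L, 154))
  expect_length(ws$therapy, 22)
  expect_length(ws$social, 22)
})

test_that("trajectory matrix matches a hand-computed 2-user toy log", {
  log <- make_log(
    # U1: engaged therapy day 3 (week 1), passive social day 10 (week 2)
    make_day(steps_started = 1, user_id = "U1", day_index = 3),
    make_day(visited_newsfeed = 1, user_id = "U1", day_index = 10),
    # U2: active social day 2, highly engaged therapy day 155 (week 22)
    make_day(newsfeed_posts = 2, user_id = "U2", day_index = 2),
    make_day(steps_started = 1, actions_done = 1, user_id = "U2", day_index = 155))
  tm <- build_trajectory_matrix(log)
  expect_s3_class(tm, "trajectory_matrix")
  expect_equal(tm$users, c("U1", "U2"))
  exp_t_u1 <- rep(1L, 22); exp_t_u1[1] <- 3L
  exp_s_u1 <- rep(1L, 22); exp_s_u1[2] <- 2L
  exp_t_u2 <- rep(1L, 22); exp_t_u2[22] <- 4L
  exp_s_u2 <- rep(1L, 22); exp_s_u2[1] <- 4L
  expect_equal(unname(tm$therapy["U1", ]), exp_t_u1)
  expect_equal(unname(tm$social["U1", ]), exp_s_u1)
  expect_equal(unname(tm$therapy["U2", ]), exp_t_u2)
  expect_equal(unname(tm$social["U2", ]), exp_s_u2)
  m <- as.matrix(tm)
  expect_equal(dim(m), c(2L, 44L))
  expect_equal(unname(m["U2", "t_w22"]), 4)
})

test_that("trajectory matrix is invariant to input row order", {
  g <- generate_usage_logs(default_archetypes(), n_users = 6, n_days = 155,
                           seed = 21)
  tm1 <- build_trajectory_matrix(g$log)
  set.seed(1)
  tm2 <- build_trajectory_matrix(g$log[sample(nrow(g$log)), ])
  expect_identical(tm1$therapy, tm2$therapy)
  expect_identical(tm1$social, tm2$social)
})

test_that("induction-only logs yield all-inactive trajectories", {
  log <- make_log(make_day(steps_started = 3, newsfeed_posts = 2,
                           user_id = "U1", day_index = 1),
                  make_day(actions_done = 2, user_id = "U2", day_index = 1))
  tm <- build_trajectory_matrix(log)
  expect_true(all(tm$therapy == 1) && all(tm$social == 1))
  expect_setequal(tm$inactive, c("U1", "U2"))
})

test_that("duplicate (user, day) rows are rejected with a report", {
  log <- make_log(make_day(user_id = "U1", day_index = 2),
                  make_day(user_id = "U1", day_index = 2))
  expect_error(build_trajectory_matrix(log), "duplicate")
})

test_that("adding activity to a day never decreases weekly scores", {
  set.seed(99)
  counts <- usage_count_vars <- c("steps_started", "actions_done",
                                  "newsfeed_posts", "newsfeed_comments",
                                  "talk_it_out_posts", "likes_made",
                                  "reactions_made")
  flags <- setdiff(usage_variables(), counts)
  for (rep in 1:50) {
    day <- zero_day()
    # random starting activity
    for (v in sample(usage_variables(), sample(0:4, 1)))
      day[[v]] <- if (v %in% counts) sample(0:3, 1) else 1
    base <- categorize_day(as.data.frame(day))
    # add one unit of activity somewhere
    v <- sample(usage_variables(), 1)
    day[[v]] <- if (v %in% counts) day[[v]] + 1 else 1
    bumped <- categorize_day(as.data.frame(day))
    expect_gte(bumped[["therapy"]], base[["therapy"]])
    expect_gte(bumped[["social"]], base[["social"]])
  }
})

test_that("trajectory CSV round-trips through write/read", {
  g <- generate_usage_logs(default_archetypes(), n_users = 5, n_days = 155,
                           seed = 31)
  tm <- build_trajectory_matrix(g$log)
  path <- tempfile(fileext = ".csv")
  write_trajectories(tm, path, header = "provenance line")
  tm2 <- read_trajectories(path)
  expect_identical(tm$therapy, tm2$therapy)
  expect_identical(tm$social, tm2$social)
  expect_identical(tm$users, tm2$users)
})
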