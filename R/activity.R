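# Hierarchical 2D daily activity categorization and weekly trajectory
# construction.
#
# Raw platform metrics describe, for one user on one day, how much they did
# on the therapy side (interactive modules, "steps", and their behavioural
# tasks, "actions") and on the social-network side (posts, comments,
# problem-solving forum posts, likes, reactions, plus passive page visits).
# Each user-day is mapped to an ordinal activity level on each dimension:
#   1 = inactive, 2 = passive (visits only), 3 = engaged (therapy) /
#   moderate (social), 4 = highly engaged (therapy) / active (social).

#' Raw daily system-use variable names
#'
#' Column names of the 13 per-day usage metrics, in canonical order: four
#' therapy-related variables followed by nine social-networking variables.
#' `steps_started`, `actions_done` and the post/comment/like/reaction
#' variables are nonnegative counts; `visited_*` variables are 0/1 flags.
#'
#' @return Character vector of length 13.
#' @export
usage_variables <- function() {
  c("steps_started", "actions_done",
    "visited_suggested_content", "visited_therapy",
    "newsfeed_posts", "newsfeed_comments", "talk_it_out_posts",
    "likes_made", "reactions_made",
    "visited_messages", "visited_notifications",
    "visited_newsfeed", "visited_talk_it_out")
}

usage_count_vars <- function() {
  c("steps_started", "actions_done", "newsfeed_posts", "newsfeed_comments",
    "talk_it_out_posts", "likes_made", "reactions_made")
}

usage_flag_vars <- function() setdiff(usage_variables(), usage_count_vars())

validate_usage_log <- function(log, require_ids = TRUE) {
  need <- usage_variables()
  if (require_ids) need <- c("user_id", "day_index", need)
  missing_cols <- setdiff(need, names(log))
  if (length(missing_cols) > 0)
    stopf("usage log is missing columns: %s", paste(missing_cols, collapse = ", "))
  for (v in usage_count_vars())
    if (any(log[[v]] < 0, na.rm = TRUE))
      stopf("negative count in column '%s'", v)
  for (v in usage_flag_vars())
    if (!all(log[[v]] %in% c(0, 1)))
      stopf("column '%s' must be a 0/1 flag", v)
  if (require_ids) {
    if (any(log$day_index < 1)) stopf("day_index must be >= 1")
    dup <- duplicated(log[, c("user_id", "day_index")])
    if (any(dup))
      stopf("duplicate (user_id, day_index) rows: %d found (first: user %s day %d)",
            sum(dup), log$user_id[dup][1], log$day_index[dup][1])
  }
  invisible(log)
}

categorize_therapy <- function(steps, actions, vis_therapy, vis_suggested) {
  high    <- steps > 1 | actions > 1 | (steps >= 1 & actions >= 1)
  engaged <- !high & (steps + actions == 1)
  passive <- !high & !engaged & (vis_therapy > 0 | vis_suggested > 0)
  1L + passive * 1L + engaged * 2L + high * 3L
}

categorize_social <- function(posts, comments, tio, likes, reactions,
                              vis_msg, vis_notif, vis_news, vis_tio) {
  active   <- (posts + comments + tio) >= 1
  moderate <- !active & (likes + reactions) >= 1
  passive  <- !active & !moderate &
    (vis_msg > 0 | vis_notif > 0 | vis_news > 0 | vis_tio > 0)
  1L + passive * 1L + moderate * 2L + active * 3L
}

#' Categorize one day of raw usage into hierarchical activity levels
#'
#' Maps the 13 raw daily metrics onto an ordinal (therapy, social) activity
#' pair. Levels, on both dimensions, are 1 = inactive, 2 = passive (page
#' visits only), 3 = engaged with therapy / moderate social use, and
#' 4 = highly engaged with therapy / active social contribution. The
#' categorization is hierarchical: a day always receives the highest level
#' whose condition it meets.
#'
#' Therapy: level 4 when more than one step was started, more than one
#' action done, or at least one of each; level 3 when exactly one step was
#' started or exactly one action done (and nothing more); level 2 when no
#' steps/actions but the therapy homepage or moderator-suggested content was
#' visited; level 1 otherwise. Social: level 4 when the user contributed at
#' least one newsfeed post, comment, or problem-solving forum post; level 3
#' when they did not contribute but liked or reacted to at least one item;
#' level 2 when they only visited social pages (newsfeed, forum, private
#' messages, notifications); level 1 otherwise.
#'
#' @param row A one-row data.frame (or named list) containing the columns of
#'   [usage_variables()]. Negative counts are rejected.
#' @return Named integer vector `c(therapy = , social = )`, each in 1..4.
#' @seealso [categorize_log()] for whole-table categorization.
#' @examples
#' day <- as.list(setNames(rep(0, 13), usage_variables()))
#' day$likes_made <- 2
#' day$visited_newsfeed <- 1
#' categorize_day(day)  # therapy 1, social 3
#' @export
categorize_day <- function(row) {
  row <- as.data.frame(row[usage_variables()])
  validate_usage_log(row, require_ids = FALSE)
  c(therapy = categorize_therapy(row$steps_started, row$actions_done,
                                 row$visited_therapy, row$visited_suggested_content),
    social = categorize_social(row$newsfeed_posts, row$newsfeed_comments,
                               row$talk_it_out_posts, row$likes_made,
                               row$reactions_made, row$visited_messages,
                               row$visited_notifications, row$visited_newsfeed,
                               row$visited_talk_it_out))
}

#' Categorize every row of a usage log
#'
#' Vectorized version of [categorize_day()]: appends `therapy_level` and
#' `social_level` columns to a usage-log table.
#'
#' @param log Data frame with `user_id`, `day_index` and the 13 raw metric
#'   columns ([usage_variables()]). `(user_id, day_index)` must be unique.
#' @return The input with two integer level columns appended.
#' @export
categorize_log <- function(log) {
  validate_usage_log(log)
  log$therapy_level <- categorize_therapy(
    log$steps_started, log$actions_done,
    log$visited_therapy, log$visited_suggested_content)
  log$social_level <- categorize_social(
    log$newsfeed_posts, log$newsfeed_comments, log$talk_it_out_posts,
    log$likes_made, log$reactions_made, log$visited_messages,
    log$visited_notifications, log$visited_newsfeed, log$visited_talk_it_out)
  log
}

#' Aggregate daily activity levels into weekly trajectory scores
#'
#' Weekly scores are the maximum daily activity level observed in each
#' 7-day block, computed separately for the therapy and social dimensions.
#' Weeks are fixed 7-day blocks of each user's own trial involvement,
#' anchored at `start_day`; with the defaults (`start_day = 2`,
#' `n_weeks = 22`) the window covers days 2-155, i.e. 154 days = 22 weeks.
#' Day 1 is each user's platform induction and never contributes. Days with
#' no record count as inactive (level 1), so a week with no activity scores
#' 1, not missing.
#'
#' @param day_index Integer vector of 1-based day indices.
#' @param therapy_level,social_level Integer vectors of daily levels (1-4)
#'   parallel to `day_index`.
#' @param start_day First day of the aggregation window (default 2, skipping
#'   the induction day).
#' @param n_weeks Number of 7-day blocks (default 22).
#' @return List with integer vectors `therapy` and `social`, each of length
#'   `n_weeks` with values in 1..4.
#' @examples
#' # one passive-therapy day and one engaged-therapy day in week 1 -> 3
#' weekly_scores(c(2, 5), therapy_level = c(2, 3), social_level = c(1, 1))$therapy[1]
#' @export
weekly_scores <- function(day_index, therapy_level, social_level,
                          start_day = 2L, n_weeks = 22L) {
  if (n_weeks <= 0) stopf("n_weeks must be positive")
  if (any(day_index < 1)) stopf("day indices must be >= 1")
  stopifnot(length(therapy_level) == length(day_index),
            length(social_level) == length(day_index))
  last_day <- start_day + 7L * n_weeks - 1L
  keep <- day_index >= start_day & day_index <= last_day
  therapy <- rep(1L, n_weeks)
  social <- rep(1L, n_weeks)
  if (any(keep)) {
    wk <- (day_index[keep] - start_day) %/% 7L + 1L
    tmax <- tapply(therapy_level[keep], wk, max)
    smax <- tapply(social_level[keep], wk, max)
    therapy[as.integer(names(tmax))] <- as.integer(tmax)
    social[as.integer(names(smax))] <- as.integer(smax)
  }
  list(therapy = therapy, social = social)
}

#' Build the joint weekly trajectory matrix from a usage log
#'
#' Applies [categorize_day()] to every user-day, then [weekly_scores()] per
#' user, producing one 2-dimensional weekly trajectory (therapy and social,
#' `n_weeks` ordinal scores each) per user. Users appear in sorted id order.
#' Users with no rows inside the aggregation window are retained with
#' all-inactive (all level 1) trajectories and listed in the `inactive`
#' attribute-style field so callers can report them.
#'
#' @param log Usage-log data frame (see [categorize_log()]).
#' @inheritParams weekly_scores
#' @return Object of class `trajectory_matrix`: list with `users` (character),
#'   `therapy` and `social` (integer matrices, users x weeks), `start_day`,
#'   `n_weeks`, and `inactive` (ids of users with no in-window activity
#'   record). `as.matrix()` flattens it to the users x (2 * n_weeks) numeric
#'   matrix used for clustering.
#' @export
build_trajectory_matrix <- function(log, start_day = 2L, n_weeks = 22L) {
  log <- categorize_log(log)
  users <- sort(unique(as.character(log$user_id)))
  therapy <- matrix(1L, length(users), n_weeks,
                    dimnames = list(users, paste0("w", seq_len(n_weeks))))
  social <- therapy
  idx <- split(seq_len(nrow(log)), as.character(log$user_id))
  for (u in users) {
    i <- idx[[u]]
    ws <- weekly_scores(log$day_index[i], log$therapy_level[i],
                        log$social_level[i], start_day, n_weeks)
    therapy[u, ] <- ws$therapy
    social[u, ] <- ws$social
  }
  inactive <- users[rowSums(therapy > 1) + rowSums(social > 1) == 0]
  structure(
    list(users = users, therapy = therapy, social = social,
         start_day = as.integer(start_day), n_weeks = as.integer(n_weeks),
         inactive = inactive),
    class = "trajectory_matrix")
}

#' @export
as.matrix.trajectory_matrix <- function(x, ...) {
  m <- cbind(x$therapy, x$social)
  colnames(m) <- c(paste0("t_", colnames(x$therapy)),
                   paste0("s_", colnames(x$social)))
  rownames(m) <- x$users
  storage.mode(m) <- "double"
  m
}

#' @export
print.trajectory_matrix <- function(x, ...) {
  cat(sprintf("Joint weekly trajectory matrix: %d users x 2 dimensions x %d weeks\n",
              length(x$users), x$n_weeks))
  cat(sprintf("  window: days %d-%d of trial involvement\n",
              x$start_day, x$start_day + 7L * x$n_weeks - 1L))
  cat(sprintf("  mean weekly level: therapy %.2f, social %.2f\n",
              mean(x$therapy), mean(x$social)))
  if (length(x$inactive) > 0)
    cat(sprintf("  %d user(s) with no in-window activity (all-inactive trajectory)\n",
                length(x$inactive)))
  invisible(x)
}

#' Write / read a trajectory matrix as wide CSV
#'
#' Columns: `user_id`, `t_w1..t_wN` (therapy), `s_w1..s_wN` (social). Lines
#' starting with `#` are treated as comments, allowing provenance headers.
#'
#' @param x A `trajectory_matrix`.
#' @param path File path.
#' @param header Optional character vector of comment lines (written
#'   prefixed by `# `).
#' @return `write_trajectories()` returns `path` invisibly;
#'   `read_trajectories()` returns a `trajectory_matrix`.
#' @export
write_trajectories <- function(x, path, header = NULL) {
  m <- as.matrix(x)
  df <- data.frame(user_id = rownames(m), m, check.names = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header) > 0) writeLines(paste("#", header), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  tcols <- grep("^t_w", names(df), value = TRUE)
  scols <- grep("^s_w", names(df), value = TRUE)
  if (length(tcols) == 0 || length(tcols) != length(scols))
    stopf("file does not look like a trajectory CSV: %s", path)
  ord <- order(df$user_id)
  df <- df[ord, ]
  users <- as.character(df$user_id)
  n_weeks <- length(tcols)
  therapy <- as.matrix(df[, tcols])
  social <- as.matrix(df[, scols])
  dimnames(therapy) <- list(users, paste0("w", seq_len(n_weeks)))
  dimnames(social) <- dimnames(therapy)
  storage.mode(therapy) <- "integer"
  storage.mode(social) <- "integer"
  inactive <- users[rowSums(therapy > 1) + rowSums(social > 1) == 0]
  structure(list(users = users, therapy = therapy, social = social,
                 start_day = 2L, n_weeks = n_weeks, inactive = inactive),
            class = "trajectory_matrix")
}
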