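# Reading measures from scan paths, filter protocols, and partitioning.

fix_path <- function(regions, durations_ms, gap = 0) {
  ends <- cumsum(durations_ms / 1000 + gap)
  data.frame(region_index = regions,
             start = ends - durations_ms / 1000,
             end = ends)
}

test_that("monotone paths give equal scan-path/first-pass/go-past", {
  p <- fix_path(c(1, 2, 3), c(200, 200, 200))
  sp <- scan_path_durations(p)
  expect_equal(sp$region_index, c(1, 2, 3))
  expect_equal(sp$duration_ms, c(200, 200, 200))
  expect_equal(first_pass_durations(p), sp)
  gp <- go_past_durations(p)
  # last region has no rightward exit: unresolved, excluded
  expect_equal(gp$region_index, c(1, 2))
  expect_equal(gp$duration_ms, sp$duration_ms[1:2])
  expect_equal(attr(gp, "unresolved"), 3)
})

test_that("regressive path visits are traced per the definitions", {
  # regions [2,1,2]: three visits, each its own scan-path duration
  p <- fix_path(c(2, 1, 2), c(200, 150, 100))
  sp <- scan_path_durations(p)
  expect_equal(sp$region_index, c(2, 1, 2))
  expect_equal(sp$duration_ms, c(200, 150, 100))
  # first-pass: 2 entered at record start (leftward); 1 entered from the
  # right; final 2 already visited
  fp <- first_pass_durations(p)
  expect_equal(fp$region_index, 2)
  expect_equal(fp$duration_ms, 200)

  # same-region refixations merge into one visit
  p2 <- fix_path(c(2, 2, 3), c(100, 150, 120))
  sp2 <- scan_path_durations(p2)
  expect_equal(sp2$region_index, c(2, 3))
  expect_equal(sp2$duration_ms, c(250, 120))

  # visit entered from the right is not a first pass
  p3 <- fix_path(c(1, 3, 2, 4), c(100, 100, 100, 100))
  fp3 <- first_pass_durations(p3)
  expect_false(2 %in% fp3$region_index)

  # second visit to a region is not a first pass
  p4 <- fix_path(c(1, 2, 1, 2), c(100, 100, 100, 100))
  fp4 <- first_pass_durations(p4)
  expect_equal(fp4$region_index, c(1, 2))
})

test_that("go-past spans regressions until a rightward exit", {
  p <- fix_path(c(1, 2, 1, 3), c(200, 150, 100, 80))
  gp <- go_past_durations(p)
  expect_equal(gp$duration_ms[gp$region_index == 2], 250)  # 150 + 100
  expect_equal(gp$duration_ms[gp$region_index == 1], 200)
  expect_equal(attr(gp, "unresolved"), 3)
  # go-past >= first-pass wherever both are defined
  fp <- first_pass_durations(p)
  shared <- intersect(gp$region_index, fp$region_index)
  for (r in shared)
    expect_gte(gp$duration_ms[gp$region_index == r][1],
               fp$duration_ms[fp$region_index == r][1])
})

test_that("go-past >= first-pass on random paths (property)", {
  set.seed(42)
  for (i in 1:50) {
    n <- sample(3:12, 1)
    regions <- pmax(0, cumsum(sample(c(-1, 1, 1, 2), n, replace = TRUE)))
    p <- fix_path(regions, runif(n, 80, 400))
    sp <- scan_path_durations(p)
    fp <- first_pass_durations(p)
    gp <- go_past_durations(p)
    expect_true(all(fp$duration_ms > 0))
    # every first-pass visit is a scan-path visit with the same duration
    expect_true(all(fp$duration_ms %in% sp$duration_ms))
    for (r in intersect(gp$region_index, fp$region_index))
      expect_gte(gp$duration_ms[gp$region_index == r][1],
                 fp$duration_ms[fp$region_index == r][1] - 1e-9)
  }
})

test_that("degenerate and invalid paths are handled", {
  expect_equal(nrow(scan_path_durations(fix_path(integer(0), numeric(0)))), 0)
  bad <- data.frame(region_index = c(1, 2), start = c(0, 0.1),
                    end = c(0.2, 0.3))
  expect_error(scan_path_durations(bad), "non-overlapping")
  bad2 <- data.frame(region_index = 1, start = 0.2, end = 0.2)
  expect_error(scan_path_durations(bad2), "end > start")
})

test_that("grouped measure computation splits by participant and text", {
  fx <- rbind(
    data.frame(participant_id = "p1", text_id = "t1",
               region_index = c(1, 2), start_s = c(0, 0.2),
               end_s = c(0.2, 0.4)),
    data.frame(participant_id = "p2", text_id = "t1",
               region_index = c(2, 1, 2), start_s = c(0, 0.2, 0.35),
               end_s = c(0.2, 0.35, 0.5)))
  out <- reading_measures(fx, "scanpath")
  expect_equal(nrow(out), 5)
  expect_equal(sum(out$participant_id == "p2"), 3)
})

test_that("filters exclude by first matching rule with per-rule counts", {
  rs <- data.frame(
    participant_id = rep(c("p1", "p2"), each = 3),
    duration_ms = c(50, 500, 3500, 400, 500, 600),
    sentence_boundary = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE),
    accuracy = rep(c(1, 0.5), each = 3))
  # Brown-style RT bounds alone
  res <- apply_filters(rs[1:3, ], filter_preset("brown"))
  expect_equal(res$kept$duration_ms, 500)
  expect_equal(res$log$n_excluded[res$log$rule == "rt_too_short"], 1L)
  expect_equal(res$log$n_excluded[res$log$rule == "rt_too_long"], 1L)

  # participant below 5/8 comprehension loses all responses
  cfg <- filter_config(rt_min = 100, rt_max = 3000,
                       exclude_sentence_boundary = TRUE,
                       min_accuracy = 5 / 8)
  res2 <- apply_filters(rs, cfg)
  expect_false("p2" %in% res2$kept$participant_id)
  # p2's boundary row is attributed to the earlier boundary rule, the
  # remaining two to the accuracy rule
  expect_equal(res2$log$n_excluded[res2$log$rule == "low_accuracy"], 2L)
  expect_equal(res2$log$n_excluded[res2$log$rule == "sentence_boundary"], 1L)

  # all rules disabled: identity
  res3 <- apply_filters(rs, filter_config())
  expect_equal(nrow(res3$kept), nrow(rs))
  expect_equal(sum(res3$log$n_excluded), 0L)

  # a rule requiring missing metadata names itself
  expect_error(apply_filters(rs[, c("participant_id", "duration_ms")],
                             filter_preset("dundee")), "blink")
})

test_that("saccade, blink, correctness, and minimum-count rules work", {
  rs <- data.frame(
    participant_id = c(rep("p1", 4), rep("p2", 4)),
    duration_ms = rep(300, 8),
    blink = c(TRUE, rep(FALSE, 7)),
    saccade_len = c(0, 25, -25, 0, 0, 0, 0, 0),
    correct = c(TRUE, TRUE, TRUE, FALSE, rep(TRUE, 4)))
  cfg <- filter_config(max_saccade_len = 20, exclude_blinks = TRUE,
                       correct_only = TRUE, min_rts_per_participant = 2)
  res <- apply_filters(rs, cfg)
  expect_equal(res$log$n_excluded[res$log$rule == "blink"], 1L)
  expect_equal(res$log$n_excluded[res$log$rule == "outlier_saccade"], 2L)
  expect_equal(res$log$n_excluded[res$log$rule == "incorrect_response"], 1L)
  # p1 falls to 0 responses < 2: excluded wholesale
  expect_false("p1" %in% res$kept$participant_id)
  expect_equal(nrow(res$kept), 4L)
})

test_that("partition follows i = (s + p) mod 4 exactly", {
  expect_equal(assign_partition(0, 0), "train")
  expect_equal(assign_partition(0, 1), "train")
  expect_equal(assign_partition(1, 1), "validation")
  expect_equal(assign_partition(3, 0), "test")
  expect_error(assign_partition(-1, 0), ">= 0")
  # complete grid with both dimensions multiples of 4: exact 1/2, 1/4, 1/4
  g <- expand.grid(p = 0:7, s = 0:11)
  lab <- assign_partition(g$p, g$s)
  expect_equal(unname(table(lab)["train"] / length(lab)), 0.5)
  expect_equal(unname(table(lab)["validation"] / length(lab)), 0.25)
  expect_equal(unname(table(lab)["test"] / length(lab)), 0.25)
})
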