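test_that("the people-counting rule scores exact, off-by-one and other", {
  expect_equal(score_people_count(5, 5), 1.0)
  expect_equal(score_people_count(4, 5), 0.5)
  expect_equal(score_people_count(6, 5), 0.5)
  expect_equal(score_people_count(7, 5), 0.0)
  expect_equal(score_people_count(0, 0), 1.0)
})

test_that("set scoring is intersection over union of normalized tokens", {
  expect_equal(score_set(c("surgeon", "nurse"), c("surgeon", "anesthetist")),
               1 / 3)
  expect_equal(score_set(c("a", "b"), c("b", "a")), 1.0)
  expect_equal(score_set(c("a"), c("b")), 0.0)
  expect_equal(score_set(character(0), character(0)), 1.0)
  expect_equal(score_set(c("Drill", "SAW "), c("saw", "drill")), 1.0)
})

test_that("single-label scoring is exact match after normalization", {
  expect_equal(score_label("yes", "yes"), 1.0)
  expect_equal(score_label("drilling", "sawing"), 0.0)
  expect_equal(score_label("Yes.", "yes"), 1.0)
})

test_that("relative-error tiers are strict as printed", {
  expect_equal(score_relative(2.1, 2.0), 1.0)   # 5% error
  expect_equal(score_relative(2.3, 2.0), 0.5)   # 15% error
  expect_equal(score_relative(3.0, 2.0), 0.0)   # 50% error
  expect_equal(score_relative(2.2, 2.0), 0.5)   # exactly 10%: strict <
  expect_equal(score_relative(2.5, 2.0), 0.0)   # exactly 25%: strict <
  expect_equal(score_relative(0, 0), 1.0)
  expect_equal(score_relative(0.1, 0), 0.0)
})

test_that("box IoU matches hand-computed overlaps and is symmetric", {
  expect_equal(iou_box(c(0, 0, 100, 100), c(0, 25, 100, 125)), 0.6)
  expect_equal(iou_box(c(0, 0, 100, 100), c(0, 70, 100, 170)), 3000 / 17000)
  expect_equal(iou_box(c(0, 0, 10, 10), c(0, 0, 10, 10)), 1.0)
  expect_equal(iou_box(c(0, 0, 10, 10), c(20, 20, 30, 30)), 0.0)
  expect_equal(iou_box(c(0, 0, 10, 10), c(5, 5, 5, 5)), 0.0)  # degenerate
  set.seed(12)
  for (i in 1:200) {
    a <- c(sort(runif(2, 0, 100)), sort(runif(2, 0, 100)))[c(1, 3, 2, 4)]
    b <- c(sort(runif(2, 0, 100)), sort(runif(2, 0, 100)))[c(1, 3, 2, 4)]
    expect_equal(iou_box(a, b), iou_box(b, a))
    expect_true(iou_box(a, b) >= 0 && iou_box(a, b) <= 1)
  }
})

test_that("tiered 2D-box scoring applies inclusive thresholds", {
  expect_equal(score_box_2d(c(0, 25, 100, 125), c(0, 0, 100, 100)), 0.75)
  expect_equal(score_box_2d(c(0, 70, 100, 170), c(0, 0, 100, 100)), 0.25)
  expect_equal(score_box_2d(c(0, 90, 100, 190), c(0, 0, 100, 100)), 0.0)
  expect_equal(score_box_2d(c(0, 0, 100, 100), c(0, 0, 100, 100)), 1.0)
  # IoU exactly 0.5 takes the 0.75 tier (inclusive)
  expect_equal(iou_box(c(0, 0, 100, 50), c(0, 0, 100, 100)), 0.5)
  expect_equal(score_box_2d(c(0, 0, 100, 50), c(0, 0, 100, 100)), 0.75)
  # monotone non-decreasing in IoU
  shifts <- seq(0, 100, by = 5)
  scores <- vapply(shifts, function(s)
    score_box_2d(c(0, s, 100, 100 + s), c(0, 0, 100, 100)), numeric(1))
  expect_true(all(diff(scores) <= 0))
})

test_that("scene-graph scoring is macro F1 over predicate classes", {
  truth <- list(c("s", "holding", "drill"), c("n", "assisting", "s"))
  pred <- list(c("s", "holding", "drill"), c("s", "cutting", "p"))
  expect_equal(score_scene_graph(pred, truth), 1 / 3)
  expect_equal(score_scene_graph(truth, truth), 1.0)
  expect_equal(score_scene_graph(list(), truth), 0.0)
  expect_equal(score_scene_graph(list(), list()), 1.0)
  # a triplet with the right predicate but wrong arguments earns nothing
  wrong <- list(c("x", "holding", "y"), c("n", "assisting", "s"))
  expect_equal(score_scene_graph(wrong, truth), 0.5)
})

test_that("sequence scoring equals one minus normalized token edit distance", {
  expect_equal(score_sequence(c("table", "surgeon", "nurse"),
                              c("surgeon", "table", "nurse")), 1 / 3)
  expect_equal(score_sequence(c("a", "b"), c("a", "b")), 1.0)
  expect_equal(score_sequence(character(0), character(0)), 1.0)
  expect_equal(score_sequence(c("a"), character(0)), 0.0)
})

test_that("token edit distance agrees with an independent DP oracle on 1000 random pairs", {
  # utils::adist on strings with tokens mapped to single characters is the
  # independent implementation
  set.seed(77)
  alphabet <- letters[1:8]
  for (i in 1:1000) {
    a <- sample(alphabet, sample(0:8, 1), replace = TRUE)
    b <- sample(alphabet, sample(0:8, 1), replace = TRUE)
    d_pkg <- orqa:::token_edit_distance(a, b)
    d_oracle <- utils::adist(paste(a, collapse = ""),
                             paste(b, collapse = ""))[1, 1]
    expect_equal(d_pkg, as.numeric(d_oracle))
  }
})

test_that("BLEU-1 is clipped unigram precision times the brevity penalty", {
  expect_equal(score_bleu1("heart rate 72 bpm", "heart rate 72 bpm"), 1.0)
  expect_equal(score_bleu1("heart rate 72", "heart rate 72 bpm"),
               exp(1 - 4 / 3), tolerance = 1e-9)
  expect_equal(round(score_bleu1("heart rate 72", "heart rate 72 bpm"), 3),
               0.717)
  expect_equal(score_bleu1("abc def", "ghi jkl"), 0.0)
  expect_equal(score_bleu1("", "heart rate"), 0.0)
  # clipping: repeated candidate words count at most their reference count
  expect_equal(score_bleu1("the the the", "the cat"), 1 / 3)
})

test_that("score dispatch covers all 23 tasks and returns [0,1]", {
  reps <- representative_answers()
  for (task in orqa_tasks()$task) {
    truth <- reps[[task]]
    s <- score_item(task, truth, truth)
    expect_equal(s, 1.0, info = task)
  }
  # parse failures and tag mismatches score zero
  expect_equal(score_item("people_counting", answer_parse_failure("x"),
                          answer_count(3)), 0.0)
  expect_equal(score_item("people_counting", answer_label("five"),
                          answer_count(5)), 0.0)
})

test_that("point-answer tasks score by diagonal-normalized euclidean error", {
  cfg <- scoring_config(room_extent = c(8, 6, 3), image_size = c(640, 480))
  diag3 <- sqrt(sum(c(8, 6, 3)^2))
  # error just under 10% of the room diagonal: full credit
  p <- answer_point3(c(0, 0, 1))
  q <- answer_point3(c(0.09 * diag3, 0, 1))
  expect_equal(score_item("localization_3d", q, p, cfg), 1.0)
  q2 <- answer_point3(c(0.2 * diag3, 0, 1))
  expect_equal(score_item("localization_3d", q2, p, cfg), 0.5)
  q3 <- answer_point3(c(0.4 * diag3, 0, 1))
  expect_equal(score_item("localization_3d", q3, p, cfg), 0.0)
  diag2 <- sqrt(640^2 + 480^2)  # 800
  g <- answer_point2(c(100, 100))
  g2 <- answer_point2(c(100 + 0.05 * diag2, 100))
  expect_equal(score_item("gaze_location", g2, g, cfg), 1.0)
})

test_that("a hand-built six-item benchmark aggregates to its hand average", {
  bench <- data.table::data.table(
    qa_id = sprintf("q%d", 1:6),
    task = c("people_counting", "people_counting", "distance_3d",
             "is_completed", "tool_detection", "localization_2d"),
    answer_text = c("5", "3", "2.0", "yes", "drill, saw", "0,0,100,100"),
    source_tag = c("a", "a", "a", "b", "b", "b"))
  preds <- data.table::data.table(
    qa_id = sprintf("q%d", 1:6),
    answer_text = c("5", "4", "2.3", "no", "drill", "0,25,100,125"))
  # hand scores: 1.0, 0.5, 0.5, 0.0, 0.5, 0.75 -> mean 0.5416667
  rep <- score_benchmark(bench, preds, scoring_config(resamples = 100),
                         seed = 1)
  expect_equal(rep$overall$mean, mean(c(1, 0.5, 0.5, 0, 0.5, 0.75)))
  expect_equal(rep$per_dataset[source_tag == "a"]$mean, mean(c(1, 0.5, 0.5)))
  expect_equal(rep$per_task[task == "people_counting"]$mean, 0.75)
  expect_equal(rep$n, 6L)
  expect_equal(rep$parse_failure_rate, 0)
})

test_that("scoring ground truth against itself is a fixed point at 1.0", {
  pool <- small_pool()
  set.seed(5)
  bench <- pool[sample.int(nrow(pool), 800)]
  self <- bench[, c("qa_id", "answer_text")]
  rep <- score_benchmark(bench, self, scoring_config(resamples = 50),
                         seed = 1)
  expect_equal(rep$overall$mean, 1.0)
  expect_true(all(rep$per_task$mean == 1.0))
  expect_setequal(unique(bench$task), rep$per_task$task)
})

test_that("missing predictions score zero and are counted", {
  bench <- data.table::data.table(
    qa_id = c("q1", "q2"), task = "people_counting",
    answer_text = c("5", "5"), source_tag = "a")
  preds <- data.table::data.table(qa_id = "q1", answer_text = "5")
  rep <- score_benchmark(bench, preds, scoring_config(resamples = 10),
                         seed = 1)
  expect_equal(rep$overall$mean, 0.5)
  expect_equal(rep$parse_failure_rate, 0.5)
  # predictions for unknown ids are an error
  bad <- data.table::data.table(qa_id = "zzz", answer_text = "5")
  expect_error(score_benchmark(bench, bad, scoring_config()), "unknown")
})

test_that("bootstrap intervals bracket the mean, are seeded, and match a binomial oracle", {
  expect_equal(unname(bootstrap_ci(rep(0.7, 50), seed = 1)), c(0.7, 0.7))
  x <- c(0.2, 0.8, 0.5, 1.0, 0.0, 0.3)
  ci1 <- bootstrap_ci(x, resamples = 500, seed = 9)
  ci2 <- bootstrap_ci(x, resamples = 500, seed = 9)
  expect_identical(ci1, ci2)
  expect_lte(ci1[["lo"]], mean(x))
  expect_gte(ci1[["hi"]], mean(x))
  expect_warning(ci0 <- bootstrap_ci(0.4), "fewer than 2")
  expect_equal(unname(ci0), c(0.4, 0.4))
  # Bernoulli(0.5), n = 1000: percentile interval of resampled means should
  # match a direct binomial simulation of sample means
  set.seed(123)
  scores <- as.numeric(runif(1000) < 0.5)
  ci <- bootstrap_ci(scores, resamples = 1000, seed = 4)
  oracle_means <- rbinom(4000, 1000, mean(scores)) / 1000
  oracle <- quantile(oracle_means, c(0.025, 0.975), names = FALSE)
  expect_lt(abs(ci[["lo"]] - oracle[1]), 0.012)
  expect_lt(abs(ci[["hi"]] - oracle[2]), 0.012)
})
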