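#' Scoring configuration
#'
#' Houses the fixed task-specific rule parameters of the composite 0-1
#' benchmark score: the count rule (1.0 exact, 0.5 off by one), the
#' relative-error tiers (1.0 for errors < 10%, 0.5 for < 25%, 0 beyond;
#' strict inequalities), the tiered 2D-box IoU rule (1.0 for IoU >= 0.75,
#' 0.75 for >= 0.5, 0.5 for >= 0.25, 0.25 for >= 0.125; inclusive
#' thresholds), and the bootstrap settings (1,000 resamples, 95% level).
#' `room_extent` and `image_size` normalize the error of 3D-point and
#' gaze-point answers (Euclidean error over the room/image diagonal), the
#' only two tasks whose rule is not pinned down by the printed scheme.
#'
#' @param resamples bootstrap resamples
#' @param level confidence level
#' @param room_extent,image_size scene dimensions used for point-error
#'   normalization; defaults match [sim_config()]
#' @return list of class `orqa_scoring_config`
#' @export
scoring_config <- function(resamples = 1000, level = 0.95,
                           room_extent = c(8, 6, 3),
                           image_size = c(640, 480)) {
  structure(list(
    rel_tiers = c(0.10, 0.25), rel_scores = c(1.0, 0.5),
    iou_tiers = c(0.75, 0.50, 0.25, 0.125),
    iou_scores = c(1.0, 0.75, 0.5, 0.25),
    resamples = as.integer(resamples), level = level,
    room_extent = as.numeric(room_extent),
    image_size = as.numeric(image_size)),
    class = "orqa_scoring_config")
}

#' Per-task scoring rules
#'
#' Primitive rules of the composite score. All return a value in `[0, 1]`.
#'
#' `score_people_count()`: 1.0 for an exact count, 0.5 if off by one, 0.0
#' otherwise. `score_set()`: intersection-over-union of normalized token
#' sets (both empty scores 1.0). `score_label()`: exact match of
#' normalized tokens. `score_relative()`: tiered relative error, 1.0 below
#' 10%, 0.5 below 25% (strict), 0.0 beyond; a zero truth scores 1.0 only
#' for a zero prediction. `score_box_2d()`: tiered box IoU with inclusive
#' thresholds 0.75/0.5/0.25/0.125. `score_scene_graph()`: macro F1 over
#' predicate classes of exactly-matching triplets. `score_sequence()`:
#' `1 - d / max(len)` with token-level Levenshtein distance `d` (both
#' empty scores 1.0). `score_bleu1()`: clipped unigram precision times the
#' brevity penalty `exp(min(0, 1 - r/c))`.
#'
#' @param pred,truth predicted and ground-truth payloads (see details)
#' @param config an [scoring_config()]
#' @return a score in `[0, 1]`
#' @name scoring-rules
NULL

#' @rdname scoring-rules
#' @export
score_people_count <- function(pred, truth) {
  stopifnot(truth >= 0, pred >= 0)
  d <- abs(as.numeric(pred) - as.numeric(truth))
  if (d == 0) 1.0 else if (d == 1) 0.5 else 0.0
}

#' @rdname scoring-rules
#' @export
score_set <- function(pred, truth) {
  pred <- unique(norm_token(pred)); truth <- unique(norm_token(truth))
  pred <- pred[nzchar(pred)]; truth <- truth[nzchar(truth)]
  u <- length(union(pred, truth))
  if (u == 0L) return(1.0)
  length(intersect(pred, truth)) / u
}

#' @rdname scoring-rules
#' @export
score_label <- function(pred, truth) {
  as.numeric(identical(norm_token(pred), norm_token(truth)))
}

#' @rdname scoring-rules
#' @export
score_relative <- function(pred, truth, config = scoring_config()) {
  pred <- as.numeric(pred); truth <- as.numeric(truth)
  if (truth == 0) return(as.numeric(pred == 0))
  tier_relative(abs(pred - truth) / abs(truth), config)
}

tier_relative <- function(err, config) {
  if (err < config$rel_tiers[1]) config$rel_scores[1]
  else if (err < config$rel_tiers[2]) config$rel_scores[2]
  else 0.0
}

#' Intersection over union of two axis-aligned boxes
#'
#' Boxes are `c(x1, y1, x2, y2)` with `x1 < x2`, `y1 < y2`. Degenerate
#' (zero-area) boxes yield IoU 0 unless both are degenerate and equal.
#'
#' @param a,b boxes
#' @return IoU in `[0, 1]`
#' @export
iou_box <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  stopifnot(length(a) == 4, length(b) == 4)
  area <- function(z) max(0, z[3] - z[1]) * max(0, z[4] - z[2])
  aa <- area(a); ab <- area(b)
  if (aa == 0 && ab == 0) return(as.numeric(all(a == b)))
  iw <- min(a[3], b[3]) - max(a[1], b[1])
  ih <- min(a[4], b[4]) - max(a[2], b[2])
  inter <- max(0, iw) * max(0, ih)
  un <- aa + ab - inter
  if (un <= 0) 0.0 else inter / un
}

#' @rdname scoring-rules
#' @export
score_box_2d <- function(pred, truth, config = scoring_config()) {
  iou <- iou_box(pred, truth)
  hit <- which(iou >= config$iou_tiers)
  if (length(hit) == 0L) 0.0 else config$iou_scores[hit[1]]
}

triplet_keys <- function(trips) {
  vapply(trips, function(tr) paste(norm_token(tr), collapse = "|"), "")
}

#' @rdname scoring-rules
#' @export
score_scene_graph <- function(pred, truth) {
  pk <- triplet_keys(pred); tk <- triplet_keys(truth)
  ppred <- vapply(pred, function(tr) norm_token(tr[2]), "")
  tpred <- vapply(truth, function(tr) norm_token(tr[2]), "")
  classes <- union(ppred, tpred)
  if (length(classes) == 0L) return(1.0)
  f1s <- vapply(classes, function(cl) {
    p_cl <- unique(pk[ppred == cl]); t_cl <- unique(tk[tpred == cl])
    tp <- length(intersect(p_cl, t_cl))
    if (tp == 0L) return(0.0)
    prec <- tp / length(p_cl); rec <- tp / length(t_cl)
    2 * prec * rec / (prec + rec)
  }, numeric(1))
  mean(f1s)
}

# Token-level Levenshtein distance (unit insert/delete/substitute costs).
token_edit_distance <- function(a, b) {
  n <- length(a); m <- length(b)
  if (n == 0L) return(m)
  if (m == 0L) return(n)
  prev <- 0:m
  for (i in seq_len(n)) {
    cur <- numeric(m + 1L)
    cur[1] <- i
    for (j in seq_len(m)) {
      cost <- if (a[i] == b[j]) 0 else 1
      cur[j + 1L] <- min(prev[j + 1L] + 1, cur[j] + 1, prev[j] + cost)
    }
    prev <- cur
  }
  prev[m + 1L]
}

#' @rdname scoring-rules
#' @export
score_sequence <- function(pred, truth) {
  pred <- norm_token(pred); truth <- norm_token(truth)
  pred <- pred[nzchar(pred)]; truth <- truth[nzchar(truth)]
  L <- max(length(pred), length(truth))
  if (L == 0L) return(1.0)
  1 - token_edit_distance(pred, truth) / L
}

#' @rdname scoring-rules
#' @export
score_bleu1 <- function(pred, truth) {
  ptok <- strsplit(norm_text(pred), " ", fixed = TRUE)[[1]]
  ttok <- strsplit(norm_text(truth), " ", fixed = TRUE)[[1]]
  ptok <- ptok[nzchar(ptok)]; ttok <- ttok[nzchar(ttok)]
  if (length(ptok) == 0L) return(0.0)
  if (length(ttok) == 0L) return(0.0)
  ref_counts <- table(ttok)
  cand_counts <- table(ptok)
  clipped <- sum(vapply(names(cand_counts), function(w) {
    min(cand_counts[[w]], if (w %in% names(ref_counts)) ref_counts[[w]]
                          else 0L)
  }, numeric(1)))
  precision <- clipped / length(ptok)
  bp <- exp(min(0, 1 - length(ttok) / length(ptok)))
  precision * bp
}

# ---------------------------------------------------------------------------
# Dispatch

#' Score one prediction against one ground truth
#'
#' Dispatches to the task's rule. A parse failure or tag mismatch scores
#' 0.0 for every rule.
#'
#' @param task task id
#' @param pred,truth `orqa_answer` objects
#' @param config an [scoring_config()]
#' @return score in `[0, 1]`
#' @export
score_item <- function(task, pred, truth, config = scoring_config()) {
  rule <- task_rule(task)
  expected <- task_answer_tag(task)
  if (!inherits(pred, "orqa_answer") || pred$tag != expected) return(0.0)
  stopifnot(inherits(truth, "orqa_answer"), truth$tag == expected)
  switch(rule,
    count = score_people_count(pred$value, truth$value),
    set = score_set(pred$value, truth$value),
    label = score_label(pred$value, truth$value),
    relative = score_relative(pred$value, truth$value, config),
    box_tiers = score_box_2d(pred$value, truth$value, config),
    relative_point3 = {
      err <- distance_3d(pred$value, truth$value) /
        sqrt(sum(config$room_extent^2))
      tier_relative(err, config)
    },
    relative_point2 = {
      err <- sqrt(sum((pred$value - truth$value)^2)) /
        sqrt(sum(config$image_size^2))
      tier_relative(err, config)
    },
    macro_f1 = score_scene_graph(pred$value, truth$value),
    levenshtein = score_sequence(pred$value, truth$value),
    bleu1 = score_bleu1(pred$value, truth$value),
    stop("no rule for task: ", task)
  )
}

#' Percentile bootstrap confidence interval of a mean
#'
#' Nonparametric bootstrap: resamples the item scores with replacement and
#' takes percentiles of the resampled means.
#'
#' @param item_scores numeric vector
#' @param resamples number of bootstrap resamples
#' @param level confidence level
#' @param seed integer seed
#' @return `c(lo, hi)`; with fewer than 2 items a degenerate
#'   `(mean, mean)` interval is returned with a warning
#' @export
bootstrap_ci <- function(item_scores, resamples = 1000, level = 0.95,
                         seed = 1) {
  n <- length(item_scores)
  if (n < 2L) {
    warning("fewer than 2 items: degenerate interval")
    m <- if (n == 1L) item_scores else NA_real_
    return(c(lo = m, hi = m))
  }
  old <- .Random.seed_safe()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  means <- vapply(seq_len(resamples), function(i)
    mean(item_scores[sample.int(n, n, replace = TRUE)]), numeric(1))
  a <- (1 - level) / 2
  q <- stats::quantile(means, c(a, 1 - a), names = FALSE)
  c(lo = q[1], hi = q[2])
}

#' Score a benchmark against a prediction set
#'
#' Parses each prediction's text with the lenient [parse_answer()], scores
#' it with the task's rule, and aggregates at three levels: per task, per
#' source dataset, and overall. The overall mean is the micro average over
#' items (a per-task macro average is also reported). Missing or
#' unparseable predictions score 0.0 and are counted in the parse-failure
#' rate. Confidence intervals come from [bootstrap_ci()].
#'
#' @param benchmark an `orqa_benchmark` or a QA `data.table`
#' @param predictions `data.table`/data.frame with `qa_id` and
#'   `answer_text` (free text, parsed per task)
#' @param config an [scoring_config()]
#' @param seed seed for the bootstrap
#' @return an `orqa_score_report` with elements `overall`, `per_task`,
#'   `per_dataset`, `items`, `n`, `parse_failure_rate`
#' @export
score_benchmark <- function(benchmark, predictions,
                            config = scoring_config(), seed = 1) {
  pairs <- if (inherits(benchmark, "orqa_benchmark")) benchmark$pairs
           else data.table::as.data.table(benchmark)
  if (nrow(pairs) == 0L) stop("empty benchmark: nothing to score")
  predictions <- data.table::as.data.table(predictions)
  stopifnot(all(c("qa_id", "answer_text") %in% names(predictions)))
  unknown <- setdiff(predictions$qa_id, pairs$qa_id)
  if (length(unknown) > 0)
    stop(length(unknown), " predictions reference unknown qa_ids")
  bad_task <- setdiff(pairs$task, .orqa_task_registry$task)
  if (length(bad_task) > 0)
    stop("unknown task in benchmark: ", paste(bad_task, collapse = ", "))

  pred_text <- stats::setNames(predictions$answer_text, predictions$qa_id)
  n <- nrow(pairs)
  scores <- numeric(n)
  failed <- logical(n)
  for (i in seq_len(n)) {
    task <- pairs$task[i]
    truth <- parse_answer(pairs$answer_text[i], task)
    txt <- pred_text[pairs$qa_id[i]]
    if (is.na(txt)) {  # missing prediction
      failed[i] <- TRUE
      next
    }
    pred <- parse_answer(txt, task)
    if (pred$tag == "parse_failure") {
      failed[i] <- TRUE
      next
    }
    scores[i] <- score_item(task, pred, truth, config)
  }

  items <- data.table::data.table(qa_id = pairs$qa_id, task = pairs$task,
                                  source_tag = pairs$source_tag,
                                  score = scores, parse_failed = failed)
  agg <- function(dt, by, seed0) {
    cells <- split(dt, by = by, sorted = TRUE)
    out <- lapply(seq_along(cells), function(k) {
      s <- cells[[k]]$score
      ci <- suppressWarnings(bootstrap_ci(s, config$resamples, config$level,
                                          seed = seed0 + k))
      data.table::data.table(cell = names(cells)[k], n = length(s),
                             mean = mean(s), ci_lo = ci[1], ci_hi = ci[2])
    })
    out <- data.table::rbindlist(out)
    data.table::setnames(out, "cell", by)
    out
  }
  per_task <- agg(items, "task", seed + 1000L)
  per_dataset <- agg(items, "source_tag", seed + 2000L)
  ci_all <- bootstrap_ci(items$score, config$resamples, config$level, seed)
  structure(list(
    overall = list(mean = mean(items$score), ci_lo = ci_all[1],
                   ci_hi = ci_all[2], macro_task_mean = mean(per_task$mean)),
    per_task = per_task, per_dataset = per_dataset, items = items,
    n = n, parse_failure_rate = mean(failed)),
    class = "orqa_score_report")
}

#' @export
print.orqa_score_report <- function(x, ...) {
  cat(sprintf("<orqa_score_report> %d items\n", x$n))
  cat(sprintf("  overall: %.3f (95%% CI [%.3f, %.3f]); task macro %.3f\n",
              x$overall$mean, x$overall$ci_lo, x$overall$ci_hi,
              x$overall$macro_task_mean))
  cat(sprintf("  parse failures: %.1f%%\n", 100 * x$parse_failure_rate))
  cat("  per task:\n")
  pt <- x$per_task
  for (i in seq_len(nrow(pt)))
    cat(sprintf("    %-28s %.3f [%.3f, %.3f] (n=%d)\n", pt$task[i],
                pt$mean[i], pt$ci_lo[i], pt$ci_hi[i], pt$n[i]))
  cat("  per dataset:\n")
  pd <- x$per_dataset
  for (i in seq_len(nrow(pd)))
    cat(sprintf("    %-28s %.3f [%.3f, %.3f] (n=%d)\n", pd$source_tag[i],
                pd$mean[i], pd$ci_lo[i], pd$ci_hi[i], pd$n[i]))
  invisible(x)
}

#' Write a score report as JSON
#'
#' @param report an `orqa_score_report`
#' @param path output file
#' @export
write_score_report <- function(report, path) {
  out <- list(overall = report$overall,
              per_task = report$per_task,
              per_dataset = report$per_dataset,
              n = report$n,
              parse_failure_rate = report$parse_failure_rate)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
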