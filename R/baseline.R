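#' Fit the most-frequent-answer statistical baseline
#'
#' A trivial reference predictor that always predicts, per task, the most
#' frequent training answer: the modal full answer for categorical, set,
#' sequence, triplet and text tasks ("no" will typically win binary
#' predicates), the arithmetic mean for scalar tasks (e.g. the average 3D
#' distance for distance queries), and the coordinate-wise mean for box
#' and point tasks. Ties break to the lexicographically smallest
#' serialization, so the fit is deterministic.
#'
#' @param train_pool QA `data.table` (typically the train split)
#' @return an `orqa_baseline`: `data.table` with `task`, `answer_text`
#' @export
fit_baseline <- function(train_pool) {
  pool <- data.table::as.data.table(train_pool)
  stopifnot(nrow(pool) > 0)
  missing <- setdiff(.orqa_task_registry$task, unique(pool$task))
  if (length(missing) > 0)
    warning("tasks absent from training pool (omitted from baseline): ",
            paste(missing, collapse = ", "))
  fit_one <- function(sub) {
    task <- sub$task[1]
    tag <- task_answer_tag(task)
    if (tag == "scalar") {
      m <- mean(as.numeric(sub$answer_text))
      serialize_answer(answer_scalar(m, task_units(task)))
    } else if (tag %in% c("box", "point2", "point3")) {
      k <- switch(tag, box = 4L, point2 = 2L, point3 = 3L)
      m <- matrix(as.numeric(unlist(data.table::tstrsplit(
        sub$answer_text, ",", fixed = TRUE)[seq_len(k)])), ncol = k)
      mu <- colMeans(m)
      ctor <- switch(tag, box = answer_box, point2 = answer_point2,
                     point3 = answer_point3)
      serialize_answer(ctor(mu))
    } else {
      counts <- table(sub$answer_text)
      top <- names(counts)[counts == max(counts)]
      sort(top)[1]
    }
  }
  subs <- split(pool, by = "task", sorted = TRUE)
  model <- data.table::data.table(
    task = names(subs),
    answer_text = vapply(subs, fit_one, ""))
  structure(model, class = c("orqa_baseline", class(model)))
}

#' Predict with the statistical baseline
#'
#' One prediction per benchmark QA, constant within each task. Tasks the
#' model was never fitted on yield empty predictions (which score 0).
#'
#' @param model an `orqa_baseline`
#' @param benchmark an `orqa_benchmark` or QA `data.table`
#' @return `data.table` with `qa_id`, `answer_text`, valid input to
#'   [score_benchmark()]
#' @export
predict_baseline <- function(model, benchmark) {
  pairs <- if (inherits(benchmark, "orqa_benchmark")) benchmark$pairs
           else data.table::as.data.table(benchmark)
  lookup <- stats::setNames(model$answer_text, model$task)
  txt <- lookup[pairs$task]
  txt[is.na(txt)] <- ""
  data.table::data.table(qa_id = pairs$qa_id, answer_text = unname(txt))
}

#' Uniform-random reference guesser
#'
#' The no-information floor: for each QA, predicts an answer drawn
#' uniformly from the task's answer *space*, not from the benchmark's
#' empirical answer distribution (which would hand the guesser exactly the
#' distributional information the statistical baseline exists to measure).
#' Component vocabularies and numeric ranges are taken from the benchmark;
#' the draw within them is uniform: yes/no at 50/50, counts and scalars
#' uniform over the observed range, boxes and points uniform over the
#' image, sets as uniform random subsets of the vocabulary, sequences as
#' random orderings of such subsets, triplet lists as random
#' (subject, predicate, object) combinations, and text as random words
#' from the observed word vocabulary.
#'
#' @param benchmark an `orqa_benchmark` or QA `data.table`
#' @param seed integer seed
#' @return `data.table` with `qa_id`, `answer_text`
#' @export
predict_random <- function(benchmark, seed = 1) {
  pairs <- if (inherits(benchmark, "orqa_benchmark")) benchmark$pairs
           else data.table::as.data.table(benchmark)
  old <- .Random.seed_safe()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  spaces <- lapply(split(pairs, by = "task", sorted = TRUE), answer_space)
  txt <- vapply(seq_len(nrow(pairs)), function(i) {
    sample_answer_space(spaces[[pairs$task[i]]])
  }, "")
  data.table::data.table(qa_id = pairs$qa_id, answer_text = txt)
}

# Summarize the answer space of one task from its ground-truth answers.
answer_space <- function(sub) {
  task <- sub$task[1]
  tag <- task_answer_tag(task)
  txt <- sub$answer_text
  sp <- list(tag = tag, task = task)
  if (tag %in% c("count", "scalar")) {
    v <- as.numeric(txt)
    sp$range <- range(v)
  } else if (tag %in% c("box", "point2", "point3")) {
    k <- switch(tag, box = 4L, point2 = 2L, point3 = 3L)
    m <- matrix(as.numeric(unlist(data.table::tstrsplit(
      txt, ",", fixed = TRUE)[seq_len(k)])), ncol = k)
    sp$lo <- apply(m, 2, min); sp$hi <- apply(m, 2, max)
  } else if (tag %in% c("set", "sequence")) {
    sp$vocab <- unique(unlist(strsplit(txt, ", ", fixed = TRUE)))
    sp$vocab <- setdiff(sp$vocab, "none")
  } else if (tag == "triplets") {
    trips <- regmatches(txt, gregexpr("\\(([^()]*)\\)", txt))
    parts <- strsplit(gsub("[()]", "", unlist(trips)), ",")
    parts <- parts[lengths(parts) == 3L]
    sp$subj <- unique(vapply(parts, `[`, "", 1))
    sp$pred <- unique(vapply(parts, `[`, "", 2))
    sp$obj <- unique(vapply(parts, `[`, "", 3))
    sp$len <- range(lengths(regmatches(txt, gregexpr("\\(", txt))))
  } else if (tag == "text") {
    sp$words <- unique(unlist(strsplit(txt, " ", fixed = TRUE)))
    sp$len <- range(lengths(strsplit(txt, " ", fixed = TRUE)))
  } else {
    sp$vocab <- unique(txt)
  }
  sp
}

sample_answer_space <- function(sp) {
  pick <- function(v) v[sample.int(length(v), 1L)]
  switch(sp$tag,
    binary = pick(c("yes", "no")),
    count = as.character(sample(sp$range[1]:sp$range[2], 1L)),
    scalar = fmt_num(round(stats::runif(1, sp$range[1], sp$range[2]), 2)),
    box = {
      xs <- sort(stats::runif(2, sp$lo[1], sp$hi[3]))
      ys <- sort(stats::runif(2, sp$lo[2], sp$hi[4]))
      paste(round(c(xs[1], ys[1], xs[2], ys[2])), collapse = ",")
    },
    point2 = paste(round(stats::runif(2, sp$lo, sp$hi), 1), collapse = ","),
    point3 = paste(round(stats::runif(3, sp$lo, sp$hi), 2), collapse = ","),
    set = {
      keep <- sp$vocab[stats::runif(length(sp$vocab)) < 0.5]
      if (length(keep) == 0L) "none" else paste(sort(keep), collapse = ", ")
    },
    sequence = {
      keep <- sample(sp$vocab)[stats::runif(length(sp$vocab)) < 0.5]
      if (length(keep) == 0L) "none" else paste(keep, collapse = ", ")
    },
    triplets = {
      k <- sample(sp$len[1]:sp$len[2], 1L)
      paste(vapply(seq_len(k), function(i)
        sprintf("(%s,%s,%s)", pick(sp$subj), pick(sp$pred), pick(sp$obj)),
        ""), collapse = "; ")
    },
    text = paste(sample(sp$words, sample(sp$len[1]:sp$len[2], 1L),
                        replace = TRUE), collapse = " "),
    pick(sp$vocab)  # label and other categorical tags
  )
}

#' Write / read predictions as JSONL
#'
#' One `{"qa_id": ..., "answer_text": ...}` object per line.
#'
#' @param predictions `data.table` with `qa_id`, `answer_text`
#' @param path file path
#' @export
write_predictions <- function(predictions, path) {
  lines <- sprintf('{"qa_id":%s,"answer_text":%s}',
                   vapply(predictions$qa_id, jsonlite::toJSON, "",
                          auto_unbox = TRUE),
                   vapply(predictions$answer_text, jsonlite::toJSON, "",
                          auto_unbox = TRUE))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_predictions
#' @export
read_predictions <- function(path) {
  rows <- lapply(readLines(path), jsonlite::fromJSON)
  data.table::data.table(
    qa_id = vapply(rows, `[[`, "", "qa_id"),
    answer_text = vapply(rows, `[[`, "", "answer_text"))
}
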