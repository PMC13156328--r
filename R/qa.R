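#' Euclidean distance between two 3D points
#'
#' @param p,q numeric length-3 vectors in meters
#' @return distance in meters
#' @export
distance_3d <- function(p, q) {
  p <- as.numeric(p); q <- as.numeric(q)
  stopifnot(length(p) == 3, length(q) == 3, all(is.finite(c(p, q))))
  sqrt(sum((p - q)^2))
}

#' Detect a sterility breach in a scene graph
#'
#' A breach is any contact-class predicate (`touching`, `holding`,
#' `grasping`) linking a sterile team member to a non-sterile entity, in
#' either triplet direction. Predicates outside the known vocabulary are
#' ignored with a warning.
#'
#' @param triplets list of `c(subject, predicate, object)` class tokens
#' @param entities list of entity states carrying `class` and `sterile`
#' @return `"yes"` or `"no"`
#' @export
detect_sterility_breach <- function(triplets, entities) {
  if (length(triplets) == 0L) return("no")
  sterile <- stats::setNames(vapply(entities, `[[`, logical(1), "sterile"),
                             vapply(entities, `[[`, "", "class"))
  is_sterile_person <- function(cl)
    cl %in% .person_classes && isTRUE(sterile[[cl]])
  is_nonsterile <- function(cl) identical(sterile[[cl]], FALSE)
  for (tr in triplets) {
    if (!tr[2] %in% .known_predicates) {
      warning("ignoring unknown predicate: ", tr[2])
      next
    }
    if (!tr[2] %in% .contact_predicates) next
    if ((is_sterile_person(tr[1]) && is_nonsterile(tr[3])) ||
        (is_sterile_person(tr[3]) && is_nonsterile(tr[1])))
      return("yes")
  }
  "no"
}

#' Resolve a gaze point to the entity looked at
#'
#' Returns the class of the box containing the gaze point in the given
#' view; when several boxes contain it, the smallest-area box wins (ties
#' broken by class name). Boxes are half-open: a point lies in
#' `[x1, x2) x [y1, y2)`.
#'
#' @param point pixel `c(x, y)`
#' @param entities list of entity states with `boxes_2d`
#' @param view_id which view's boxes to use
#' @return entity class token, or `"none"`
#' @export
resolve_gaze_target <- function(point, entities, view_id) {
  best <- NULL; best_area <- Inf
  for (e in entities) {
    b <- e$boxes_2d[[view_id]]
    if (is.null(b)) next
    if (point[1] >= b[1] && point[1] < b[3] &&
        point[2] >= b[2] && point[2] < b[4]) {
      area <- (b[3] - b[1]) * (b[4] - b[2])
      if (area < best_area ||
          (area == best_area && !is.null(best) && e$class < best)) {
        best <- e$class; best_area <- area
      }
    }
  }
  if (is.null(best)) "none" else best
}

#' Temporal workflow queries
#'
#' `time_until()` gives the seconds from `t` until the named phase starts;
#' `phase_progress()` gives the percent progress through the phase active
#' at `t`; `next_robot_step()` gives the finite-state successor of the
#' current robot step (the terminal step maps to `"end"`).
#'
#' @param timeline an `orqa_timeline` from [simulate_case()]
#' @param t time in seconds
#' @param action a phase token of the timeline
#' @return seconds / percent / step token
#' @export
time_until <- function(timeline, t, action) {
  spans <- timeline$phases
  i <- match(action, spans$token)
  if (is.na(i)) stop("unknown action: ", action)
  spans$t_start[i] - t
}

#' @rdname time_until
#' @export
phase_progress <- function(timeline, t) {
  spans <- timeline$phases
  i <- span_at(spans, t)
  100 * (t - spans$t_start[i]) / (spans$t_end[i] - spans$t_start[i])
}

#' @rdname time_until
#' @param record a timepoint record carrying a robot state
#' @export
next_robot_step <- function(record, timeline) {
  steps <- timeline$robot_steps
  i <- record$robot$step_index
  if (i >= length(steps)) "end" else steps[i + 1L]
}

ref_view_id <- function(timeline) timeline$views[[1]]$id

record_entity <- function(record, class) {
  for (e in record$entities) if (e$class == class) return(e)
  NULL
}

#' Derive the canonical answer for a task at a timepoint
#'
#' Pure function of the stored scene record (plus its timeline for
#' temporal context): calling it twice yields the identical answer. Tasks
#' whose required annotations are absent from the record (because the
#' source's modality profile disables them) return `NULL` — a skip signal,
#' not an error.
#'
#' @param task a task id from [orqa_tasks()]
#' @param record a timepoint record
#' @param timeline the record's `orqa_timeline`
#' @param args binding arguments for parameterized tasks: `entity`,
#'   `subject`/`object`, `a`/`b`, `action`, `attribute`
#' @return an `orqa_answer`, or `NULL` when the task does not apply
#' @export
derive_answer <- function(task, record, timeline, args = list()) {
  switch(task,
    people_counting = {
      if (is.null(record$entities)) return(NULL)
      cls <- vapply(record$entities, `[[`, "", "class")
      n <- sum(cls %in% .person_classes)
      if (n == 0L) return(NULL)
      answer_count(n)
    },
    role_detection = {
      cls <- vapply(record$entities, `[[`, "", "class")
      roles <- intersect(cls, .person_classes)
      if (length(roles) == 0L) return(NULL)
      answer_set(roles)
    },
    interaction_detection = {
      for (tr in record$triplets)
        if (tr[1] == args$subject && tr[3] == args$object)
          return(answer_label(tr[2]))
      NULL
    },
    attribute_detection = {
      e <- record_entity(record, args$entity)
      v <- e$attributes[[args$attribute]]
      if (is.null(v)) NULL else answer_label(v)
    },
    action_detection = {
      if (is.null(record$phase)) NULL else answer_label(record$phase)
    },
    estimate_time_until = {
      dt <- time_until(timeline, record$t, args$action)
      if (dt < 0) return(NULL)  # already started: ask is_completed instead
      answer_scalar(dt, "s")
    },
    estimate_status = {
      if (is.null(record$phase_progress)) return(NULL)
      answer_scalar(record$phase_progress, "percent")
    },
    is_completed = {
      i <- match(args$action, timeline$phases$token)
      if (is.na(i)) return(NULL)
      if (timeline$phases$t_start[i] > record$t) return(NULL)  # still future
      answer_binary(timeline$phases$t_end[i] <= record$t)
    },
    is_base_array_visible = {
      if (is.null(record$robot)) return(NULL)
      answer_binary(record$robot$base_array_visible)
    },
    is_robot_calibrated = {
      if (is.null(record$robot)) return(NULL)
      answer_binary(record$robot$calibrated)
    },
    sterility_breach_detection = {
      if (is.null(record$triplets) || is.null(record$robot)) return(NULL)
      answer_binary(detect_sterility_breach(record$triplets,
                                            record$entities))
    },
    robot_step_detection = {
      if (is.null(record$robot)) return(NULL)
      answer_label(record$robot$current_step)
    },
    next_robot_step_estimation = {
      if (is.null(record$robot)) return(NULL)
      answer_label(next_robot_step(record, timeline))
    },
    localization_2d = {
      e <- record_entity(record, args$entity)
      b <- e$boxes_2d[[ref_view_id(timeline)]]
      if (is.null(b)) NULL else answer_box(b)
    },
    localization_3d = {
      e <- record_entity(record, args$entity)
      if (is.null(e$position_3d)) NULL else answer_point3(e$position_3d)
    },
    distance_3d = {
      ea <- record_entity(record, args$a)
      eb <- record_entity(record, args$b)
      if (is.null(ea$position_3d) || is.null(eb$position_3d)) return(NULL)
      answer_scalar(distance_3d(ea$position_3d, eb$position_3d), "m")
    },
    tool_detection = {
      if (is.null(record$tools_in_use)) return(NULL)
      answer_set(record$tools_in_use)
    },
    scene_graph_generation = {
      if (is.null(record$triplets)) return(NULL)
      answer_triplets(record$triplets)
    },
    entity_detection = {
      cls <- vapply(record$entities, `[[`, "", "class")
      if (length(cls) == 0L) return(NULL)
      answer_set(cls)
    },
    sorted_entity_detection = {
      vid <- ref_view_id(timeline)
      cls <- cx <- c()
      for (e in record$entities) {
        b <- e$boxes_2d[[vid]]
        if (!is.null(b)) {
          cls <- c(cls, e$class)
          cx <- c(cx, (b[1] + b[3]) / 2)
        }
      }
      if (length(cls) < 2L) return(NULL)
      answer_sequence(cls[order(cx, cls)])
    },
    gaze_location = {
      if (is.null(record$gaze)) return(NULL)
      answer_point2(record$gaze$point)
    },
    gaze_object_detection = {
      if (is.null(record$gaze)) return(NULL)
      answer_label(record$gaze$target_entity)
    },
    monitor_text_recognition = {
      if (is.null(record$monitor_text)) return(NULL)
      answer_text(record$monitor_text)
    },
    stop("unknown task: ", task)
  )
}

fill_template <- function(template, args) {
  for (nm in names(args))
    template <- sub(paste0("{", nm, "}"), gsub("_", " ", args[[nm]]),
                    template, fixed = TRUE)
  template
}

# Enumerate (binding args, slug) pairs for a task at a record.
task_bindings <- function(task, record, timeline) {
  none <- list(list(args = list(), slug = ""))
  switch(task,
    interaction_detection = {
      seen <- character(0); out <- list()
      for (tr in record$triplets) {
        key <- paste(tr[1], tr[3], sep = "|")
        if (key %in% seen) next
        seen <- c(seen, key)
        out <- c(out, list(list(args = list(subject = tr[1], object = tr[3]),
                                slug = paste(tr[1], tr[3], sep = "-"))))
      }
      out
    },
    attribute_detection = {
      out <- list()
      for (e in record$entities) {
        for (at in names(e$attributes))
          out <- c(out, list(list(args = list(entity = e$class,
                                              attribute = at),
                                  slug = paste(e$class, at, sep = "-"))))
      }
      out
    },
    localization_2d = , localization_3d = {
      lapply(record$entities, function(e)
        list(args = list(entity = e$class), slug = e$class))
    },
    distance_3d = {
      cls <- vapply(record$entities, `[[`, "", "class")
      pers <- intersect(cls, .person_classes)
      if ("operating_table" %in% cls) pers2 <- c(pers, "operating_table")
      else pers2 <- pers
      if (length(pers2) < 2L) return(list())
      prs <- utils::combn(sort(pers2), 2, simplify = FALSE)
      prs <- utils::head(prs, 10L)
      lapply(prs, function(p)
        list(args = list(a = p[1], b = p[2]),
             slug = paste(p[1], p[2], sep = "-")))
    },
    estimate_time_until = {
      fut <- timeline$phases$token[timeline$phases$t_start > record$t]
      lapply(fut, function(ph) list(args = list(action = ph), slug = ph))
    },
    is_completed = {
      past <- timeline$phases$token[timeline$phases$t_start <= record$t]
      lapply(past, function(ph) list(args = list(action = ph), slug = ph))
    },
    none
  )
}

#' Generate all question-answer pairs for one timepoint
#'
#' Instantiates every supported (task, binding) combination at the record,
#' derives the canonical answer, and fills the task's question template.
#' Tasks gated out by the source's modality profile are never emitted.
#'
#' @param record a timepoint record
#' @param timeline the record's `orqa_timeline`
#' @param tasks task ids to consider (defaults to all 23; unsupported ones
#'   skip silently)
#' @return a `data.table`, one row per QA pair: `qa_id`, `task`,
#'   `template_id`, `question`, `answer_tag`, `answer_text`, `units`,
#'   `source_tag`, `case_id`, `t`
#' @export
generate_for_timepoint <- function(record, timeline,
                                   tasks = orqa_tasks()$task) {
  templates <- stats::setNames(.orqa_task_registry$template,
                               .orqa_task_registry$task)
  rows_task <- character(0); rows_slug <- character(0)
  rows_q <- character(0); rows_ans <- character(0)
  for (task in tasks) {
    template <- templates[[task]]
    for (bind in task_bindings(task, record, timeline)) {
      ans <- derive_answer(task, record, timeline, bind$args)
      if (is.null(ans)) next
      rows_task <- c(rows_task, task)
      rows_slug <- c(rows_slug, bind$slug)
      rows_q <- c(rows_q, fill_template(template, bind$args))
      rows_ans <- c(rows_ans, serialize_answer(ans))
    }
  }
  if (length(rows_task) == 0L) return(NULL)
  qa_id <- sprintf("%s__t%04d__%s%s", record$case_id, record$index,
                   rows_task,
                   ifelse(nzchar(rows_slug), paste0("__", rows_slug), ""))
  data.table::data.table(
    qa_id = qa_id, task = rows_task,
    template_id = paste0(rows_task, "_v1"),
    question = rows_q,
    answer_tag = task_answer_tag(rows_task),
    answer_text = rows_ans,
    units = task_units(rows_task),
    source_tag = record$source_tag, case_id = record$case_id,
    t = record$t)
}

#' Generate the full QA pool of a corpus
#'
#' Runs [generate_for_timepoint()] over every timepoint of every case and
#' attaches the case-level split label from the corpus manifest.
#'
#' @param corpus an `orqa_corpus` from [simulate_corpus()]
#' @param verbose print per-source progress
#' @return a keyed `data.table` of QA pairs (see
#'   [generate_for_timepoint()]) with an extra `split` column
#' @export
generate_qa_pool <- function(corpus, verbose = FALSE) {
  stopifnot(inherits(corpus, "orqa_corpus"))
  chunks <- vector("list", length(corpus$timelines))
  for (k in seq_along(corpus$timelines)) {
    tl <- corpus$timelines[[k]]
    profile <- corpus$config$source_profiles[[tl$source_tag]]
    tasks <- supported_tasks(profile)
    case_rows <- lapply(tl$timepoints, generate_for_timepoint,
                        timeline = tl, tasks = tasks)
    chunks[[k]] <- data.table::rbindlist(case_rows)
    if (verbose && k %% 20L == 0L)
      message("  generated ", k, "/", length(corpus$timelines), " cases")
  }
  pool <- data.table::rbindlist(chunks)
  pool <- merge(pool, corpus$manifest[, c("case_id", "split")],
                by = "case_id", all.x = TRUE, sort = FALSE)
  data.table::setkeyv(pool, "qa_id")
  pool[]
}

#' Write / read a QA collection as JSONL
#'
#' One JSON object per line: `qa_id`, `task`, `question`,
#' `answer` (`tag`, `value`, `units`), `source_tag`, `case_id`, `t`,
#' `template_id`, `split`.
#'
#' @param pool a QA `data.table`
#' @param path output file
#' @export
write_qa_jsonl <- function(pool, path) {
  lines <- vapply(seq_len(nrow(pool)), function(i) {
    r <- pool[i]
    jsonlite::toJSON(list(
      qa_id = r$qa_id, task = r$task, question = r$question,
      answer = list(tag = r$answer_tag, value = r$answer_text,
                    units = if (is.na(r$units)) NULL else r$units),
      source_tag = r$source_tag, case_id = r$case_id, t = r$t,
      template_id = r$template_id,
      split = if (is.null(r$split) || is.na(r$split)) NULL else r$split),
      auto_unbox = TRUE, null = "null")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_qa_jsonl
#' @param path JSONL file to read
#' @export
read_qa_jsonl <- function(path) {
  lines <- readLines(path)
  rows <- lapply(lines, function(l) {
    o <- jsonlite::fromJSON(l)
    data.table::data.table(
      qa_id = o$qa_id, task = o$task, template_id = o$template_id,
      question = o$question, answer_tag = o$answer$tag,
      answer_text = as.character(o$answer$value),
      units = if (is.null(o$answer$units)) NA_character_ else o$answer$units,
      source_tag = o$source_tag, case_id = o$case_id, t = o$t,
      split = if (is.null(o$split)) NA_character_ else o$split)
  })
  out <- data.table::rbindlist(rows)
  data.table::setkeyv(out, "qa_id")
  out[]
}
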