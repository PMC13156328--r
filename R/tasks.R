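#' The 23 benchmark tasks
#'
#' Closed registry of the clinical question-answering tasks the benchmark
#' covers, from people counting through monitor text recognition. Each task
#' declares its answer tag (see [answer-values]), the units of scalar
#' answers, the scoring rule applied by [score_benchmark()], the modality
#' flags a source profile must provide before the task is generated for that
#' source, and the single question template used (with `{slot}` fills).
#'
#' Modality gating: `requires_all` flags must all be enabled and at least
#' one `requires_any` flag (when non-empty) must be enabled in the source's
#' modality profile. Robot-state, sterility and monitor-text tasks thereby
#' only arise from the profile that models the fully-instrumented robotic
#' OR; gaze tasks only from egocentric capture.
#'
#' @return a `data.table` with one row per task: `task`, `answer_tag`,
#'   `units`, `rule`, `template`, `requires_all`, `requires_any`
#' @export
orqa_tasks <- function() {
  copy_dt(.orqa_task_registry)
}

copy_dt <- function(x) data.table::copy(x)

.task_row <- function(task, answer_tag, units, rule, template,
                      requires_all = character(0),
                      requires_any = character(0)) {
  data.table::data.table(task = task, answer_tag = answer_tag, units = units,
                         rule = rule, template = template,
                         requires_all = list(requires_all),
                         requires_any = list(requires_any))
}

.orqa_task_registry <- data.table::rbindlist(list(
  .task_row("people_counting", "count", NA, "count",
            "How many people are in the OR?",
            requires_all = "multiview_boxes"),
  .task_row("role_detection", "set", NA, "set",
            "Which clinical roles are present in the OR?",
            requires_all = c("multiview_boxes", "roles")),
  .task_row("interaction_detection", "label", NA, "label",
            "What is the interaction between the {subject} and the {object}?",
            requires_all = "scene_graphs"),
  .task_row("attribute_detection", "label", NA, "label",
            "What is the {attribute} of the {entity}?",
            requires_all = "attributes"),
  .task_row("action_detection", "label", NA, "label",
            "What is the current action?",
            requires_all = "phases"),
  .task_row("estimate_time_until", "scalar", "s", "relative",
            "How many seconds until {action}?",
            requires_all = "phases"),
  .task_row("estimate_status", "scalar", "percent", "relative",
            "What is the progress in percent of the current action?",
            requires_all = "phases"),
  .task_row("is_completed", "binary", NA, "label",
            "Was {action} already performed?",
            requires_all = "phases"),
  .task_row("is_base_array_visible", "binary", NA, "label",
            "Is the robot base array visible?",
            requires_all = "robot_log"),
  .task_row("is_robot_calibrated", "binary", NA, "label",
            "Is the robot calibrated?",
            requires_all = "robot_log"),
  .task_row("sterility_breach_detection", "binary", NA, "label",
            "Is there a sterility breach?",
            requires_all = c("scene_graphs", "robot_log")),
  .task_row("robot_step_detection", "label", NA, "label",
            "What is the current robot step?",
            requires_all = "robot_log"),
  .task_row("next_robot_step_estimation", "label", NA, "label",
            "What is the next robot step?",
            requires_all = "robot_log"),
  .task_row("localization_2d", "box", NA, "box_tiers",
            "Where is the {entity} in the image?",
            requires_any = c("multiview_boxes", "tool_boxes")),
  .task_row("localization_3d", "point3", "m", "relative_point3",
            "Where is the {entity} located in the OR?",
            requires_all = "points_3d"),
  .task_row("distance_3d", "scalar", "m", "relative",
            "What is the distance between the {a} and the {b} in meters?",
            requires_all = "points_3d"),
  .task_row("tool_detection", "set", NA, "set",
            "Which tools are currently in use?",
            requires_any = c("tool_boxes", "robot_log")),
  .task_row("scene_graph_generation", "triplets", NA, "macro_f1",
            "What is the current scene graph?",
            requires_all = "scene_graphs"),
  .task_row("entity_detection", "set", NA, "set",
            "Which entities are currently in the OR?",
            requires_any = c("multiview_boxes", "tool_boxes")),
  .task_row("sorted_entity_detection", "sequence", NA, "levenshtein",
            "Which entities are in the OR, from left to right?",
            requires_any = c("multiview_boxes", "tool_boxes")),
  .task_row("gaze_location", "point2", "px", "relative_point2",
            "Where is the surgeon looking in the image?",
            requires_all = "gaze"),
  .task_row("gaze_object_detection", "label", NA, "label",
            "What is the surgeon looking at?",
            requires_all = c("gaze", "tool_boxes")),
  .task_row("monitor_text_recognition", "text", NA, "bleu1",
            "What information is shown on the monitor?",
            requires_all = "monitor_text")
))
data.table::setkey(.orqa_task_registry, task)

task_field <- function(task, field) {
  i <- match(task, .orqa_task_registry$task)
  if (anyNA(i)) stop("unknown task: ", paste(task[is.na(i)], collapse = ", "))
  .orqa_task_registry[[field]][i]
}

#' @rdname orqa_tasks
#' @param task task id(s)
#' @export
task_answer_tag <- function(task) task_field(task, "answer_tag")

#' @rdname orqa_tasks
#' @export
task_units <- function(task) task_field(task, "units")

#' @rdname orqa_tasks
#' @export
task_rule <- function(task) task_field(task, "rule")

#' Tasks a modality profile supports
#'
#' @param profile a modality profile (see [modality_profile()])
#' @return character vector of task ids generated for sources with this
#'   profile
#' @export
supported_tasks <- function(profile) {
  reg <- .orqa_task_registry
  ok <- vapply(seq_len(nrow(reg)), function(i) {
    alls <- reg$requires_all[[i]]
    anys <- reg$requires_any[[i]]
    all(unlist(profile[alls], use.names = FALSE)) &&
      (length(anys) == 0L || any(unlist(profile[anys], use.names = FALSE)))
  }, logical(1))
  reg$task[ok]
}
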