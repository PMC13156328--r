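# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

small_config <- function(seed = 11) {
  sim_config(n_cases_per_source = 4, timepoints_per_case = 12, seed = seed)
}

small_corpus <- function() {
  cached("small_corpus", function() simulate_corpus(small_config()))
}

small_pool <- function() {
  cached("small_pool", function() generate_qa_pool(small_corpus()))
}

# A hand-built timepoint record with full modalities, for unit tests of
# answer derivation that need exact known geometry.
hand_record <- function() {
  mk_ent <- function(class, box, pos, sterile, attrs = NULL)
    list(entity_id = paste0("case/", class), class = class,
         attributes = attrs, position_3d = pos,
         boxes_2d = if (is.null(box)) NULL else list(view1 = box),
         sterile = sterile)
  entities <- list(
    mk_ent("head_surgeon", c(100, 50, 180, 300), c(0, 0, 1.2), TRUE),
    mk_ent("scrub_nurse", c(300, 60, 360, 290), c(1, 1, 1.2), TRUE),
    mk_ent("anaesthetist", c(500, 70, 560, 280), c(3, 2, 1.2), FALSE),
    mk_ent("patient", c(200, 200, 450, 320), c(0.5, 0.5, 1.0), TRUE),
    mk_ent("drill", c(150, 150, 180, 190), c(0.2, 0.1, 1.05), TRUE,
           attrs = list(color = "blue")),
    mk_ent("tool_cart", c(40, 100, 90, 250), c(-2, -1, 0.6), FALSE))
  list(case_id = "hand_case", source_tag = "mmor_like", index = 3, t = 150,
       entities = entities,
       triplets = list(c("head_surgeon", "holding", "drill"),
                       c("scrub_nurse", "assisting", "head_surgeon"),
                       c("patient", "lying_on", "operating_table")),
       phase = "drilling", phase_progress = 50,
       robot = list(current_step = "leg_registration", step_index = 3L,
                    calibrated = FALSE, base_array_visible = TRUE,
                    completed_steps = c("docking", "registration_setup")),
       gaze = list(point = c(165, 170), target_entity = "drill"),
       tools_in_use = "drill",
       monitor_text = "hr 72 bpm spo2 98 pct nibp 120 over 80",
       transcript_tail = c("suction please"))
}

hand_timeline <- function() {
  phases <- data.table::data.table(
    token = c("preparation", "incision", "drilling", "sawing",
              "implant_placement", "closing"),
    t_start = c(0, 60, 100, 200, 260, 320),
    t_end = c(60, 100, 200, 260, 320, 400))
  steps <- c("docking", "registration_setup", "leg_registration",
             "calibration_check", "planning_adjustment", "bone_cutting",
             "implant_trialing", "undocking")
  list(case_id = "hand_case", source_tag = "mmor_like",
       image_size = c(640L, 480L), room_extent = c(8, 6, 3),
       views = list(list(id = "view1")),
       phases = phases, robot_steps = steps,
       timepoints = list())
}

# Random probability vector of length k.
rand_prob <- function(k) {
  x <- stats::runif(k, min = 1e-6)
  x / sum(x)
}

# One representative canonical answer per task, with fixed payloads.
representative_answers <- function() {
  list(
    people_counting = answer_count(4),
    role_detection = answer_set(c("head_surgeon", "scrub_nurse")),
    interaction_detection = answer_label("holding"),
    attribute_detection = answer_label("blue"),
    action_detection = answer_label("drilling"),
    estimate_time_until = answer_scalar(30, "s"),
    estimate_status = answer_scalar(50, "percent"),
    is_completed = answer_binary("yes"),
    is_base_array_visible = answer_binary("no"),
    is_robot_calibrated = answer_binary("yes"),
    sterility_breach_detection = answer_binary("no"),
    robot_step_detection = answer_label("docking"),
    next_robot_step_estimation = answer_label("end"),
    localization_2d = answer_box(c(12, 30, 88, 140)),
    localization_3d = answer_point3(c(1.25, -0.5, 1.1)),
    distance_3d = answer_scalar(1.37, "m"),
    tool_detection = answer_set(c("drill", "saw")),
    scene_graph_generation = answer_triplets(
      list(c("head_surgeon", "holding", "drill"),
           c("scrub_nurse", "assisting", "head_surgeon"))),
    entity_detection = answer_set(c("drill", "patient", "head_surgeon")),
    sorted_entity_detection = answer_sequence(c("tool_cart", "head_surgeon",
                                                "patient")),
    gaze_location = answer_point2(c(165, 170)),
    gaze_object_detection = answer_label("drill"),
    monitor_text_recognition = answer_text("hr 72 bpm spo2 98 pct")
  )
}
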