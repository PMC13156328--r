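#' Modality profile of a pseudo-source
#'
#' Each synthetic data source exposes only a subset of annotation
#' modalities, mirroring how public OR datasets differ: some provide
#' multi-view person boxes and 3D positions, some scene graphs with
#' clinical roles and attributes, some egocentric tool boxes with gaze,
#' and the fully instrumented robotic OR additionally provides robot state
#' logs, tracking, audio transcripts and monitor text.
#'
#' @param multiview_boxes,points_3d,scene_graphs,roles,attributes,phases,gaze,tool_boxes,robot_log,tracking,audio_transcript,monitor_text logical flags
#' @return a named logical list of class `orqa_profile`
#' @export
modality_profile <- function(multiview_boxes = FALSE, points_3d = FALSE,
                             scene_graphs = FALSE, roles = FALSE,
                             attributes = FALSE, phases = FALSE,
                             gaze = FALSE, tool_boxes = FALSE,
                             robot_log = FALSE, tracking = FALSE,
                             audio_transcript = FALSE, monitor_text = FALSE) {
  p <- list(multiview_boxes = multiview_boxes, points_3d = points_3d,
            scene_graphs = scene_graphs, roles = roles,
            attributes = attributes, phases = phases, gaze = gaze,
            tool_boxes = tool_boxes, robot_log = robot_log,
            tracking = tracking, audio_transcript = audio_transcript,
            monitor_text = monitor_text)
  stopifnot(all(vapply(p, is.logical, logical(1))))
  if (!(p$multiview_boxes || p$tool_boxes))
    stop("a profile needs at least one visual modality ",
         "(multiview_boxes or tool_boxes)")
  structure(p, class = "orqa_profile")
}

#' Default pseudo-source profiles
#'
#' Four profiles modelled on the annotation scope of the public OR dataset
#' families: `mvor_like` (multi-view boxes, 3D positions, phases),
#' `fourdor_like` (adds scene graphs, roles, attributes), `egosurgery_like`
#' (single egocentric view with tool boxes, gaze, phases), and `mmor_like`
#' (all modalities, including robot log, tracking, transcripts and monitor
#' text).
#'
#' @return named list of [modality_profile()] objects
#' @export
default_source_profiles <- function() {
  list(
    mvor_like = modality_profile(multiview_boxes = TRUE, points_3d = TRUE,
                                 phases = TRUE),
    fourdor_like = modality_profile(multiview_boxes = TRUE, points_3d = TRUE,
                                    phases = TRUE, scene_graphs = TRUE,
                                    roles = TRUE, attributes = TRUE),
    egosurgery_like = modality_profile(tool_boxes = TRUE, gaze = TRUE,
                                       phases = TRUE),
    mmor_like = modality_profile(multiview_boxes = TRUE, points_3d = TRUE,
                                 phases = TRUE, scene_graphs = TRUE,
                                 roles = TRUE, attributes = TRUE,
                                 gaze = TRUE, tool_boxes = TRUE,
                                 robot_log = TRUE, tracking = TRUE,
                                 audio_transcript = TRUE,
                                 monitor_text = TRUE)
  )
}

#' Simulation configuration
#'
#' @param n_cases_per_source surgical cases simulated per pseudo-source
#' @param timepoints_per_case annotated timepoints per case
#' @param source_profiles named list of [modality_profile()]s
#' @param room_extent room size in meters `(x, y, z)`; origin at the
#'   room-floor center, so x spans `[-x/2, x/2]` etc.
#' @param image_size image size in pixels `(w, h)`; boxes use 0-based pixel
#'   coordinates, `(x1, y1)` inclusive top-left, `(x2, y2)` exclusive
#'   bottom-right
#' @param n_views number of ceiling cameras for multi-view sources
#' @param seed integer master seed; every case derives its own stream from
#'   `(seed, source_tag, case_index)` so cases are independently
#'   reproducible
#' @param dt seconds between consecutive timepoints
#' @param breach_case_fraction fraction of robot-OR cases containing at
#'   least one sterility-breach interval
#' @param robot_steps ordered token list of the robot workflow
#'   finite-state sequence
#' @param phases ordered token list of surgical phases
#' @return a list of class `orqa_sim_config`
#' @export
sim_config <- function(n_cases_per_source = 4, timepoints_per_case = 25,
                       source_profiles = default_source_profiles(),
                       room_extent = c(8, 6, 3), image_size = c(640, 480),
                       n_views = 3, seed = 1, dt = 5,
                       breach_case_fraction = 0.5,
                       robot_steps = c("docking", "registration_setup",
                                       "leg_registration",
                                       "calibration_check",
                                       "planning_adjustment", "bone_cutting",
                                       "implant_trialing", "undocking"),
                       phases = c("preparation", "incision", "drilling",
                                  "sawing", "implant_placement", "closing")) {
  stopifnot(n_cases_per_source >= 1, timepoints_per_case >= 1, n_views >= 1,
            length(room_extent) == 3, all(room_extent > 0),
            length(image_size) == 2, all(image_size >= 64),
            dt > 0, breach_case_fraction >= 0, breach_case_fraction <= 1,
            length(robot_steps) >= 2, length(phases) >= 2)
  stopifnot(length(source_profiles) >= 1, !is.null(names(source_profiles)))
  lapply(source_profiles, function(p) stopifnot(inherits(p, "orqa_profile")))
  structure(list(n_cases_per_source = as.integer(n_cases_per_source),
                 timepoints_per_case = as.integer(timepoints_per_case),
                 source_profiles = source_profiles,
                 room_extent = as.numeric(room_extent),
                 image_size = as.integer(image_size),
                 n_views = as.integer(n_views), seed = as.integer(seed),
                 dt = as.numeric(dt),
                 breach_case_fraction = breach_case_fraction,
                 robot_steps = robot_steps, phases = phases),
            class = "orqa_sim_config")
}

# Stable small-integer seed for a (seed, source, case) stream; < 2^31.
derive_seed <- function(seed, source_tag, case_index) {
  h <- sum(utf8ToInt(source_tag) * seq_along(utf8ToInt(source_tag)))
  ((abs(seed) %% 100000L) * 20011 + (h %% 10007) * 101 +
     case_index * 7919) %% 2147483629 + 1
}

# ---------------------------------------------------------------------------
# Camera geometry

#' Build pinhole camera views
#'
#' Ceiling cameras are placed near the room corners looking at the room
#' center; the egocentric view sits at head height near the table. Each
#' view is a pinhole camera: a 3D point `p` maps to pixel
#' `u = f * x_c / z_c + w/2`, `v = f * y_c / z_c + h/2`, where
#' `(x_c, y_c, z_c) = R (p - c)` are camera coordinates.
#'
#' @param n_views number of ceiling views (ignored when `ego = TRUE`)
#' @param room_extent,image_size as in [sim_config()]
#' @param f focal length in pixels
#' @param ego if `TRUE`, return a single egocentric view
#' @return list of view geometries (`id`, `f`, `c`, `R`, `image_size`)
#' @export
make_views <- function(n_views, room_extent, image_size, f = 520,
                       ego = FALSE) {
  target <- c(0, 0, 1)
  if (ego) {
    pos <- c(0, -room_extent[2] / 2 + 1.2, 1.7)
    return(list(pinhole_view("view1", pos, target, f, image_size)))
  }
  hx <- room_extent[1] / 2 - 0.4
  hy <- room_extent[2] / 2 - 0.4
  z <- room_extent[3] - 0.2
  corners <- list(c(-hx, -hy, z), c(hx, -hy, z), c(-hx, hy, z), c(hx, hy, z))
  lapply(seq_len(n_views), function(i) {
    pinhole_view(paste0("view", i), corners[[(i - 1L) %% 4L + 1L]],
                 target, f, image_size)
  })
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' @rdname make_views
#' @param id view identifier
#' @param pos camera position (meters)
#' @param target point the camera looks at
#' @param rotation optional explicit 3x3 rotation (rows: image-x, image-y,
#'   optical axis); overrides the look-at construction
#' @export
pinhole_view <- function(id, pos, target, f, image_size, rotation = NULL) {
  if (f <= 0) stop("degenerate view geometry: focal length must be positive")
  if (is.null(rotation)) {
    fwd <- target - pos
    nf <- sqrt(sum(fwd^2))
    if (nf < 1e-9) stop("degenerate view geometry: camera at its target")
    fwd <- fwd / nf
    up0 <- if (abs(fwd[3]) > 0.999) c(0, 1, 0) else c(0, 0, 1)
    right <- cross3(fwd, up0)
    right <- right / sqrt(sum(right^2))
    down <- cross3(fwd, right)
    rotation <- rbind(right, down, fwd)
  }
  stopifnot(all(dim(rotation) == c(3, 3)))
  list(id = id, f = f, c = as.numeric(pos), R = rotation,
       image_size = as.integer(image_size))
}

# Vectorized projection of entity centers to clipped boxes in one view.
# positions: n x 3 matrix; extents: length-n max entity size (m).
# Returns n x 4 matrix of boxes, NA rows where the entity is behind the
# camera or projects fully outside the image.
project_entities <- function(positions, extents, view) {
  n <- nrow(positions)
  pc <- sweep(positions, 2, view$c) %*% t(view$R)
  w <- view$image_size[1]; h <- view$image_size[2]
  z <- pc[, 3]
  ok <- z > 0.1
  u <- view$f * pc[, 1] / z + w / 2
  v <- view$f * pc[, 2] / z + h / 2
  s <- view$f * (extents / 2) / z
  box <- cbind(u - s, v - s, u + s, v + s)
  box[, c(1, 3)] <- pmin(pmax(box[, c(1, 3)], 0), w)
  box[, c(2, 4)] <- pmin(pmax(box[, c(2, 4)], 0), h)
  box <- round(box)
  ok <- ok & (box[, 3] - box[, 1] >= 1) & (box[, 4] - box[, 2] >= 1)
  box[!ok, ] <- NA_real_
  box
}

#' Project a 3D position to 2D boxes in every view
#'
#' @param position_3d point in meters
#' @param extent_3d entity size in meters (max dimension drives box size)
#' @param views list of view geometries from [make_views()]
#' @return named list (by view id) of `c(x1, y1, x2, y2)` boxes; a view in
#'   which the entity is not visible maps to `NULL`
#' @export
project_to_views <- function(position_3d, extent_3d, views) {
  pos <- matrix(as.numeric(position_3d), nrow = 1)
  ext <- max(as.numeric(extent_3d))
  out <- lapply(views, function(v) {
    b <- project_entities(pos, ext, v)[1, ]
    if (anyNA(b)) NULL else as.numeric(b)
  })
  names(out) <- vapply(views, `[[`, "", "id")
  out
}

# ---------------------------------------------------------------------------
# Entity catalogue (class constants live in aaa-catalogue.R)

entity_extent <- function(class) {
  if (class %in% c(.staff_roles, "head_surgeon")) 0.6
  else if (class == "patient") 1.8
  else if (class %in% .tools) 0.3
  else if (class == "monitor") 0.7
  else 1.2
}

entity_sterile <- function(class) {
  class %in% c(.sterile_roles, "patient", .tools)
}

# Contiguous random partition of [0, total] into one span per token.
random_spans <- function(tokens, total) {
  w <- stats::rgamma(length(tokens), shape = 2) + 0.5
  w <- w / sum(w)
  edges <- c(0, cumsum(w) * total)
  data.table::data.table(token = tokens,
                         t_start = edges[-length(edges)],
                         t_end = edges[-1])
}

span_at <- function(spans, t) {
  i <- findInterval(t, spans$t_start, rightmost.closed = FALSE)
  pmin(pmax(i, 1L), nrow(spans))
}

# ---------------------------------------------------------------------------

#' Simulate one synthetic surgical case
#'
#' Generates an ordered timeline of annotated timepoints for one case of
#' one pseudo-source: entities with 3D positions and per-view 2D boxes,
#' scene-graph triplets, surgical phases forming a contiguous partition of
#' the timeline, a robot workflow advancing through a fixed step sequence,
#' gaze fixations on the tool in use, sterility flags with optional breach
#' intervals, monitor text and a speech-transcript tail. Fields disabled in
#' the source's modality profile are absent (`NULL`) in every record.
#' Deterministic for fixed `(seed, source_tag, case_index)`.
#'
#' @param config an [sim_config()]
#' @param source_tag name of a profile in `config$source_profiles`
#' @param case_index 1-based case number within the source
#' @return a `orqa_timeline`: list with `case_id`, `source_tag`, `phases`
#'   and `robot_spans` tables, `views`, and `timepoints` (list of records)
#' @export
simulate_case <- function(config, source_tag, case_index) {
  stopifnot(inherits(config, "orqa_sim_config"))
  profile <- config$source_profiles[[source_tag]]
  if (is.null(profile))
    stop("unknown source_tag '", source_tag, "': no modality profile")
  old <- .Random.seed_safe()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(config$seed, source_tag, case_index))

  n_t <- config$timepoints_per_case
  ts <- (seq_len(n_t) - 1) * config$dt
  total <- n_t * config$dt
  case_id <- sprintf("%s_case%03d", source_tag, case_index)
  ego <- !profile$multiview_boxes && profile$tool_boxes
  views <- make_views(config$n_views, config$room_extent, config$image_size,
                      ego = ego)

  # --- entity roster -------------------------------------------------------
  n_extra <- sample(2:4, 1)
  persons <- c("head_surgeon", "patient", sample(.staff_roles, n_extra))
  classes <- if (profile$multiview_boxes) c(persons, .furniture, .tools)
             else .tools
  n_e <- length(classes)
  tool_color <- stats::setNames(sample(.tool_colors, length(.tools)), .tools)

  rx <- config$room_extent[1] / 2 - 0.4
  ry <- config$room_extent[2] / 2 - 0.4
  base_z <- vapply(classes, function(cl) {
    if (cl == "patient") 1.0
    else if (cl %in% c(persons, "monitor")) 1.2
    else if (cl %in% .tools) 1.05
    else 0.6
  }, numeric(1))
  # staff and peripheral equipment anywhere in the room; the operating
  # table, the patient and the instruments cluster in the central sterile
  # field, as they do in a real OR
  base_xy <- cbind(stats::runif(n_e, -rx, rx), stats::runif(n_e, -ry, ry))
  central <- classes %in% .tools
  base_xy[central, ] <- cbind(stats::runif(sum(central), -1.5, 1.5),
                              stats::runif(sum(central), -1.2, 1.2))
  tbl <- classes == "operating_table"
  base_xy[tbl, ] <- stats::runif(2 * sum(tbl), -0.8, 0.8)
  pat <- classes == "patient"
  if (any(pat) && any(tbl))
    base_xy[pat, ] <- base_xy[tbl, ] + stats::runif(2, -0.3, 0.3)
  is_mobile <- classes %in% c("head_surgeon", .staff_roles, .tools)

  # bounded random walk => continuous motion, bounded per-step displacement
  pos <- array(0, dim = c(n_t, n_e, 3))
  for (e in seq_len(n_e)) {
    if (is_mobile[e]) {
      dx <- matrix(stats::runif(n_t * 2, -0.12, 0.12), ncol = 2)
      dx[1, ] <- 0
      xy <- cbind(pmin(pmax(base_xy[e, 1] + cumsum(dx[, 1]), -rx), rx),
                  pmin(pmax(base_xy[e, 2] + cumsum(dx[, 2]), -ry), ry))
    } else {
      xy <- matrix(rep(base_xy[e, ], each = n_t), ncol = 2)
    }
    pos[, e, ] <- cbind(xy, base_z[e])
  }
  extents <- vapply(classes, entity_extent, numeric(1))
  sterile <- vapply(classes, entity_sterile, logical(1))

  # staff drift in and out; patient, head surgeon, furniture, tools stay
  present <- matrix(TRUE, n_t, n_e)
  drift <- classes %in% .staff_roles
  present[, drift] <- matrix(stats::runif(n_t * sum(drift)) < 0.85,
                             n_t, sum(drift))

  # --- workflow ------------------------------------------------------------
  phase_spans <- random_spans(config$phases, total)
  robot_spans <- random_spans(config$robot_steps, total)
  calib_idx <- match("calibration_check", config$robot_steps)
  if (is.na(calib_idx)) calib_idx <- 1L
  base_visible <- stats::runif(n_t) < 0.85

  breach_case <- profile$robot_log &&
    stats::runif(1) < config$breach_case_fraction
  breach_win <- if (breach_case) {
    start <- stats::runif(1, 0, 0.8) * total
    c(start, start + 0.18 * total)
  } else c(-1, -1)

  # monitor vitals random walk
  hr <- round(pmin(pmax(cumsum(c(stats::runif(1, 62, 95),
                                 stats::rnorm(n_t - 1, 0, 1.5))), 50), 120))
  spo2 <- round(pmin(pmax(cumsum(c(stats::runif(1, 95, 99),
                                   stats::rnorm(n_t - 1, 0, 0.4))), 90), 100))
  sys <- round(pmin(pmax(cumsum(c(stats::runif(1, 105, 135),
                                  stats::rnorm(n_t - 1, 0, 2))), 90), 160))
  dia <- round(pmin(pmax(cumsum(c(stats::runif(1, 62, 88),
                                  stats::rnorm(n_t - 1, 0, 1.5))), 50), 100))

  spoken <- ifelse(stats::runif(n_t) < 0.4,
                   sample(.phrasebook, n_t, replace = TRUE), NA)

  # per-timepoint tool usage
  ph_idx <- span_at(phase_spans, ts)
  tools_by_t <- lapply(seq_len(n_t), function(i) {
    tl <- .phase_tools[[phase_spans$token[ph_idx[i]]]]
    tl <- if (is.na(tl)) {
      if (stats::runif(1) < 0.5) sample(.tools, 1) else character(0)
    } else tl
    if (length(tl) && stats::runif(1) < 0.25)
      tl <- unique(c(tl, sample(.tools, 1)))
    tl
  })

  # --- assemble records ----------------------------------------------------
  boxes_enabled <- profile$multiview_boxes || profile$tool_boxes
  box_classes <- if (profile$multiview_boxes) classes else
    intersect(classes, .tools)
  timepoints <- vector("list", n_t)
  for (i in seq_len(n_t)) {
    t <- ts[i]
    pres <- present[i, ]
    pmat <- matrix(pos[i, , ], ncol = 3)
    boxes <- if (boxes_enabled) {
      lapply(views, function(v) project_entities(pmat, extents, v))
    } else NULL

    entities <- lapply(which(pres), function(e) {
      cl <- classes[e]
      b2 <- NULL
      if (boxes_enabled && cl %in% box_classes) {
        b2 <- lapply(seq_along(views), function(vi) {
          b <- boxes[[vi]][e, ]
          if (anyNA(b)) NULL else as.numeric(b)
        })
        names(b2) <- vapply(views, `[[`, "", "id")
        b2 <- Filter(Negate(is.null), b2)
        if (length(b2) == 0L) b2 <- NULL
      }
      list(entity_id = sprintf("%s/%s", case_id, cl),
           class = cl,
           attributes = if (profile$attributes && cl %in% .tools)
             list(color = tool_color[[cl]]) else NULL,
           position_3d = if (profile$points_3d) as.numeric(pmat[e, ])
                         else NULL,
           boxes_2d = b2,
           sterile = sterile[e])
    })
    ent_classes <- vapply(entities, `[[`, "", "class")

    phase <- phase_spans$token[ph_idx[i]]
    prog <- 100 * (t - phase_spans$t_start[ph_idx[i]]) /
      (phase_spans$t_end[ph_idx[i]] - phase_spans$t_start[ph_idx[i]])

    triplets <- NULL
    if (profile$scene_graphs) {
      trips <- list()
      if (all(c("patient", "operating_table") %in% ent_classes))
        trips <- c(trips, list(c("patient", "lying_on", "operating_table")))
      if ("head_surgeon" %in% ent_classes) {
        for (tl in intersect(tools_by_t[[i]], ent_classes))
          trips <- c(trips, list(c("head_surgeon", "holding", tl)))
        if ("patient" %in% ent_classes && phase != "preparation")
          trips <- c(trips, list(c("head_surgeon", .phase_verbs[[phase]],
                                   "patient")))
      }
      if (all(c("scrub_nurse", "head_surgeon") %in% ent_classes))
        trips <- c(trips, list(c("scrub_nurse", "assisting", "head_surgeon")))
      if (all(c("anaesthetist", "patient") %in% ent_classes))
        trips <- c(trips, list(c("anaesthetist", "monitoring", "patient")))
      if (all(c("circulating_nurse", "tool_cart") %in% ent_classes) &&
          i %% 3L == 0L)
        trips <- c(trips, list(c("circulating_nurse", "touching",
                                 "tool_cart")))
      if (breach_case && t >= breach_win[1] && t <= breach_win[2] &&
          all(c("head_surgeon", "tool_cart") %in% ent_classes))
        trips <- c(trips, list(c("head_surgeon", "touching", "tool_cart")))
      triplets <- trips
    }

    robot <- NULL
    if (profile$robot_log) {
      k <- span_at(robot_spans, t)
      robot <- list(current_step = config$robot_steps[k],
                    step_index = k,
                    calibrated = k > calib_idx,
                    base_array_visible = base_visible[i],
                    completed_steps = if (k > 1L)
                      config$robot_steps[seq_len(k - 1L)] else character(0))
    }

    gaze <- NULL
    if (profile$gaze) {
      w <- views[[1]]$image_size[1]; h <- views[[1]]$image_size[2]
      tl <- intersect(tools_by_t[[i]], ent_classes)
      pt <- NULL
      if (length(tl)) {
        e <- entities[[match(tl[1], ent_classes)]]
        b <- e$boxes_2d[[views[[1]]$id]]
        if (!is.null(b))
          pt <- c((b[1] + b[3]) / 2, (b[2] + b[4]) / 2) + stats::rnorm(2, 0, 6)
      }
      if (is.null(pt)) pt <- c(stats::runif(1, 0, w), stats::runif(1, 0, h))
      pt <- round(c(pmin(pmax(pt[1], 0), w - 1), pmin(pmax(pt[2], 0), h - 1)))
      gaze <- list(point = pt,
                   target_entity = resolve_gaze_target(pt, entities,
                                                       views[[1]]$id))
    }

    timepoints[[i]] <- list(
      case_id = case_id, source_tag = source_tag, index = i, t = t,
      entities = entities,
      triplets = triplets,
      phase = if (profile$phases) phase else NULL,
      phase_progress = if (profile$phases) prog else NULL,
      robot = robot,
      gaze = gaze,
      tools_in_use = if (profile$tool_boxes || profile$robot_log)
        intersect(tools_by_t[[i]], ent_classes) else NULL,
      monitor_text = if (profile$monitor_text)
        sprintf("hr %d bpm spo2 %d pct nibp %d over %d",
                hr[i], spo2[i], sys[i], dia[i]) else NULL,
      transcript_tail = if (profile$audio_transcript) {
        said <- spoken[seq_len(i)]
        said <- said[!is.na(said)]
        utils::tail(said, 5)
      } else NULL
    )
  }

  structure(list(case_id = case_id, source_tag = source_tag,
                 image_size = config$image_size,
                 room_extent = config$room_extent,
                 views = views,
                 phases = phase_spans,
                 robot_steps = if (profile$robot_log) config$robot_steps
                               else NULL,
                 robot_spans = if (profile$robot_log) robot_spans else NULL,
                 breach_case = breach_case,
                 timepoints = timepoints),
            class = "orqa_timeline")
}

.Random.seed_safe <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Assign cases to train/validation/test splits
#'
#' Splits are assigned per case (never per timepoint) so that no scene ever
#' contributes to two splits. Within each source the target counts follow
#' the largest-remainder rounding of `n * ratios`, applied to a seeded
#' shuffle of the case ids.
#'
#' @param cases data.frame with columns `case_id`, `source_tag`
#' @param ratios length-3 numeric summing to 1 (train, val, test)
#' @param seed integer seed for the shuffle
#' @return `data.table` with columns `case_id`, `source_tag`, `split`
#' @export
assign_splits <- function(cases, ratios = c(train = 0.8, val = 0.1,
                                            test = 0.1), seed = 1) {
  cases <- data.table::as.data.table(cases)
  stopifnot(all(c("case_id", "source_tag") %in% names(cases)),
            length(ratios) == 3, abs(sum(ratios) - 1) < 1e-9)
  if (is.null(names(ratios))) names(ratios) <- c("train", "val", "test")
  cnt <- cases[, .N, by = "source_tag"]
  if (any(cnt$N < 3))
    stop("need at least 3 cases per source to form three splits")
  old <- .Random.seed_safe()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  out <- lapply(split(cases, by = "source_tag", sorted = TRUE), function(cs) {
    ord <- order(stats::runif(nrow(cs)))
    counts <- largest_remainder(nrow(cs), ratios)
    cs$split[ord] <- rep(names(ratios), counts)
    cs
  })
  data.table::rbindlist(out)
}

#' Largest-remainder apportionment of n into integer counts
#'
#' @param n total count
#' @param weights non-negative weights (normalized internally)
#' @return integer vector summing to `n`, names kept
#' @export
largest_remainder <- function(n, weights) {
  w <- weights / sum(weights)
  exact <- n * w
  base <- floor(exact)
  rem <- round(n - sum(base))
  if (rem > 0) {
    idx <- order(-(exact - base), seq_along(w))[seq_len(rem)]
    base[idx] <- base[idx] + 1
  }
  stats::setNames(as.integer(base), names(weights))
}

#' Simulate a full multi-source corpus
#'
#' Runs [simulate_case()] for every (source, case index) pair of the
#' configuration and assigns case-level splits.
#'
#' @param config an [sim_config()]
#' @param split_ratios passed to [assign_splits()]
#' @return an `orqa_corpus`: list with `timelines` (named by case id) and
#'   `manifest` (`case_id`, `source_tag`, `split`)
#' @export
simulate_corpus <- function(config,
                            split_ratios = c(train = 0.8, val = 0.1,
                                             test = 0.1)) {
  stopifnot(inherits(config, "orqa_sim_config"))
  sources <- names(config$source_profiles)
  timelines <- list()
  for (src in sources) {
    for (ci in seq_len(config$n_cases_per_source)) {
      tl <- simulate_case(config, src, ci)
      timelines[[tl$case_id]] <- tl
    }
  }
  cases <- data.table::data.table(
    case_id = names(timelines),
    source_tag = vapply(timelines, `[[`, "", "source_tag"))
  manifest <- assign_splits(cases, split_ratios, seed = config$seed)
  structure(list(timelines = timelines, manifest = manifest,
                 config = config),
            class = "orqa_corpus")
}

#' @export
print.orqa_corpus <- function(x, ...) {
  cat(sprintf("<orqa_corpus> %d cases, %d sources\n",
              length(x$timelines),
              length(unique(x$manifest$source_tag))))
  print(x$manifest[, .N, by = c("source_tag", "split")])
  invisible(x)
}

timeline_json <- function(timeline) {
  keep <- timeline[c("case_id", "source_tag", "image_size", "room_extent",
                     "breach_case", "robot_steps", "timepoints")]
  keep$phases <- as.list(timeline$phases)
  jsonlite::toJSON(keep, auto_unbox = TRUE, digits = NA, null = "null")
}

#' Write / read a corpus as JSON
#'
#' One JSON file per case plus a JSONL manifest (`case_id`, `source_tag`,
#' `split`).
#'
#' @param corpus an `orqa_corpus`
#' @param dir output directory (created if needed)
#' @return `write_corpus` returns `dir` invisibly; `read_corpus` returns
#'   the manifest together with the per-case JSON (as parsed lists)
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (tl in corpus$timelines) {
    writeLines(timeline_json(tl), file.path(dir, paste0(tl$case_id, ".json")))
  }
  man <- corpus$manifest
  lines <- vapply(seq_len(nrow(man)), function(i) {
    jsonlite::toJSON(as.list(man[i]), auto_unbox = TRUE)
  }, "")
  writeLines(lines, file.path(dir, "manifest.jsonl"))
  invisible(dir)
}

#' @rdname write_corpus
#' @export
read_corpus <- function(dir) {
  man_lines <- readLines(file.path(dir, "manifest.jsonl"))
  manifest <- data.table::rbindlist(
    lapply(man_lines, function(l) jsonlite::fromJSON(l)))
  cases <- lapply(manifest$case_id, function(cid) {
    jsonlite::fromJSON(file.path(dir, paste0(cid, ".json")),
                       simplifyVector = FALSE)
  })
  names(cases) <- manifest$case_id
  list(manifest = manifest, cases = cases)
}
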