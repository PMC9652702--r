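SCHEMA_VERSION <- "1.0"

#' Write a scenario to YAML
#'
#' Serialises the full world description (workspace, medium, types,
#' particles, goals, seed, simulator config) under a versioned schema.
#'
#' @param sc an `oet_scenario`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_scenario <- function(sc, path) {
  doc <- list(
    schema_version = SCHEMA_VERSION,
    seed = sc$seed,
    safety_margin = sc$safety_margin,
    workspace = list(nx = sc$workspace$nx, ny = sc$workspace$ny,
                     cell_size = sc$workspace$cell_size,
                     origin = as.numeric(sc$workspace$origin)),
    medium = unclass(sc$medium),
    sim = unclass(sc$sim),
    types = lapply(sc$types, unclass),
    particles = lapply(seq_len(nrow(sc$particles)), function(i) {
      as.list(sc$particles[i, ])
    }),
    goals = lapply(seq_len(nrow(sc$goals)), function(i) {
      g <- as.list(sc$goals[i, ])
      if (is.na(g$required_type)) g$required_type <- NULL
      g
    }))
  yaml::write_yaml(doc, path, precision = 15L)
  invisible(path)
}

#' Read a scenario from YAML
#' @param path YAML file written by [write_scenario()].
#' @return An `oet_scenario`.
#' @export
read_scenario <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$schema_version)) {
    stop("not a scenario file: missing schema_version")
  }
  ws <- workspace(doc$workspace$nx, doc$workspace$ny, doc$workspace$cell_size,
                  unlist(doc$workspace$origin))
  med <- do.call(medium, doc$medium)
  types <- lapply(doc$types, function(t) do.call(particle_type, t))
  sim <- do.call(sim_config, doc$sim)
  particles <- do.call(rbind, lapply(doc$particles, function(p) {
    data.frame(id = p$id, type = p$type, x = p$x, y = p$y, status = p$status,
               goal_id = p$goal_id %||% NA_integer_)
  }))
  goals <- if (length(doc$goals)) {
    do.call(rbind, lapply(doc$goals, function(g) {
      data.frame(id = g$id, x = g$x, y = g$y,
                 required_type = g$required_type %||% NA_character_)
    }))
  } else {
    data.frame(id = integer(0), x = numeric(0), y = numeric(0),
               required_type = character(0))
  }
  scenario(ws, med, particles, goals, types, seed = doc$seed,
           safety_margin = doc$safety_margin, sim = sim)
}

#' Write a trajectory log to CSV / JSON lines
#'
#' The trajectory goes to `<stem>_trajectory.csv` (columns time_s,
#' particle_id, x_um, y_um, status), the event log to
#' `<stem>_events.jsonl` (one JSON object per line), and the run summary
#' to `<stem>_summary.json`.
#'
#' @param log an `oet_task_log` from [run_task()].
#' @param stem output path stem (directories must exist).
#' @return Character vector of the files written, invisibly.
#' @export
write_task_log <- function(log, stem) {
  traj_path <- paste0(stem, "_trajectory.csv")
  ev_path <- paste0(stem, "_events.jsonl")
  sum_path <- paste0(stem, "_summary.json")
  utils::write.csv(log$trajectory, traj_path, row.names = FALSE)
  con <- file(ev_path, "w")
  on.exit(close(con))
  ev <- log$events
  for (i in seq_len(nrow(ev))) {
    writeLines(jsonlite::toJSON(as.list(ev[i, ]), auto_unbox = TRUE), con)
  }
  jsonlite::write_json(log$summary, sum_path, auto_unbox = TRUE, digits = NA)
  invisible(c(traj_path, ev_path, sum_path))
}

#' Write a matching as JSON
#' @param matching an `oet_matching`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_matching <- function(matching, path) {
  pairs <- as.list(matching$pairs[!is.na(matching$pairs)])
  jsonlite::write_json(
    list(pairs = pairs, total_cost = matching$total_cost,
         converged = matching$converged),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write / read a frame as 8-bit grayscale PNG
#' @param frame an `oet_frame`.
#' @param path PNG path.
#' @return `path` (write) or an `oet_frame` (read).
#' @export
write_frame <- function(frame, path) {
  png::writePNG(pmin(pmax(unclass(frame), 0), 1), path)
  invisible(path)
}

#' @rdname write_frame
#' @param pixel_size um/px to attach on read.
#' @export
read_frame <- function(path, pixel_size = 1) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  structure(img, pixel_size = pixel_size, timestamp = NA_real_,
            class = c("oet_frame", "matrix", "array"))
}
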