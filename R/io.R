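# Plain-text round-tripping of trial tables, weights tables and schedules.
# All writers stamp a header comment `# redyn <schema> v1 hash=<config hash>`
# so outputs are self-identifying and reruns are diffable.

.write_stamped_csv <- function(df, path, schema, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# redyn %s v1 hash=%s", schema, hash), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Write a simulated participant's trial samples to CSV
#'
#' Long format, one row per time sample of each force-channel trial:
#' `participant, phase, workspace, condition, direction, rep, t, vx, vy,
#' lateral`.  Null-field and force-field trials are schedule metadata only
#' and are carried by the schedule file.
#'
#' @param participant A `redyn_participant` (see [simulate_participant()]).
#' @param path Output file.
#' @param id Participant identifier stored in the table.
#' @return The path, invisibly.
#' @export
write_trials <- function(participant, path, id = 1L) {
  stopifnot(inherits(participant, "redyn_participant"))
  df <- cbind(participant = id, participant$samples)
  .write_stamped_csv(df, path, "trials",
                     config_hash(list(attr(participant, "experiment"),
                                      attr(participant, "seed"), id)))
}

#' Read a trial-sample table written by [write_trials()]
#'
#' Validates the schema and errors naming any missing column.
#'
#' @param path CSV file.
#' @return Data frame of trial samples.
#' @export
read_trials <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  required <- c("participant", "phase", "workspace", "condition",
                "direction", "rep", "t", "vx", "vy", "lateral")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(missing_cols, collapse = ", ")))
  }
  df
}

#' Write a frame-weights table to CSV
#'
#' Columns: `direction, w_cartesian, w_joint, w_object, model, seed`.
#'
#' @param weights A `frame_weights` data frame.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_weights <- function(weights, path) {
  df <- data.frame(direction = weights$direction,
                   w_cartesian = weights$cartesian,
                   w_joint = weights$joint,
                   w_object = weights$object,
                   model = attr(weights, "model") %||% NA_character_,
                   seed = attr(weights, "seed") %||% NA_integer_)
  .write_stamped_csv(df, path, "weights", config_hash(df))
}

#' Read a frame-weights table
#' @param path CSV file written by [write_weights()].
#' @return A `frame_weights` data frame.
#' @export
read_weights <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  structure(data.frame(direction = df$direction, cartesian = df$w_cartesian,
                       joint = df$w_joint, object = df$w_object),
            class = c("frame_weights", "data.frame"),
            model = df$model[1], seed = df$seed[1])
}

#' Write a trial schedule as JSON
#' @param schedule A [build_schedule()] data frame.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_schedule_json <- function(schedule, path) {
  payload <- list(schema = "redyn schedule v1",
                  experiment = attr(schedule, "experiment"),
                  seed = attr(schedule, "seed"),
                  hash = config_hash(schedule),
                  trials = schedule)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
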