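#' @title Prosthesis controller state machine
#'
#' @description
#' The controller moves through five states — `sitting`, `standing_up`,
#' `standing`, `moving`, `sitting_down` — along a fixed transition graph:
#' sitting and standing are connected only through the stand-up/sit-down
#' transitional states, standing and moving are connected directly, and
#' there is no edge between sitting and moving. Gait inference runs only in
#' the `moving` state; while sitting, the legs are held motionless and only
#' an EMG stand-up intention is acted on. Requests without a legal edge
#' (e.g. a sit-down intention while moving) are ignored by design: the user
#' must first stop and stand.
#'
#' @name controller
NULL

CONTROLLER_STATES <- c("sitting", "standing_up", "standing", "moving",
                       "sitting_down")

# Legal edges (from -> to), self-loops implicit.
CONTROLLER_EDGES <- matrix(c(
  "sitting",      "standing_up",
  "standing_up",  "standing",
  "standing",     "sitting_down",
  "sitting_down", "sitting",
  "standing",     "moving",
  "moving",       "standing"), ncol = 2L, byrow = TRUE,
  dimnames = list(NULL, c("from", "to")))

#' Controller transition edges
#'
#' @return Two-column character matrix of the legal (from, to) state
#'   transitions (self-loops implied).
#' @export
controller_edges <- function() CONTROLLER_EDGES

#' Construct a controller state
#'
#' @param current One of `sitting`, `standing_up`, `standing`, `moving`,
#'   `sitting_down`.
#' @return Object of class `controller_state`.
#' @export
controller_state <- function(current = "sitting") {
  assert_that(current %in% CONTROLLER_STATES, "unknown state: %s", current)
  structure(list(current = current, pending_action = NULL),
            class = "controller_state")
}

#' Advance the controller by one frame
#'
#' Applies the transition rules to the current frame's recognizer outputs:
#' \itemize{
#'   \item sitting + stand-up intention: begin the stand-up procedure;
#'   \item standing + sit-down intention: begin the sit-down procedure
#'     (intention takes precedence over a simultaneous swing);
#'   \item standing + leg swing: enter `moving` and start gait inference;
#'   \item moving + stillness: return to `standing`, stop gait inference;
#'   \item transitional states complete on `action_complete`.
#' }
#' All other requests are ignored (no edge in the transition graph); the
#' ignored inputs are reported so callers can log them.
#'
#' @param state A [controller_state()].
#' @param inputs List of logical flags for the current frame:
#'   `standup_intent`, `sitdown_intent`, `swing`, `still`,
#'   `action_complete` (missing flags default to `FALSE`).
#' @return List with `state` (new [controller_state()]), `action`
#'   (`"stand_up"`, `"sit_down"`, `"start_gait_inference"`,
#'   `"stop_gait_inference"` or `NULL`) and `ignored` (character vector of
#'   requests without a legal edge).
#' @export
controller_step <- function(state, inputs = list()) {
  stopifnot(inherits(state, "controller_state"))
  g <- function(nm) isTRUE(inputs[[nm]])
  cur <- state$current
  new <- cur; action <- NULL; ignored <- character(0)

  if (cur == "sitting") {
    if (g("standup_intent")) { new <- "standing_up"; action <- "stand_up" }
    if (g("sitdown_intent")) ignored <- c(ignored, "sitdown_intent")
    if (g("swing")) ignored <- c(ignored, "swing")
  } else if (cur == "standing_up") {
    if (g("action_complete")) new <- "standing"
  } else if (cur == "standing") {
    if (g("sitdown_intent")) {
      new <- "sitting_down"; action <- "sit_down"
      if (g("swing")) ignored <- c(ignored, "swing")
    } else if (g("swing")) {
      new <- "moving"; action <- "start_gait_inference"
    }
    if (g("standup_intent")) ignored <- c(ignored, "standup_intent")
  } else if (cur == "moving") {
    if (g("still")) { new <- "standing"; action <- "stop_gait_inference" }
    if (g("sitdown_intent")) ignored <- c(ignored, "sitdown_intent")
    if (g("standup_intent")) ignored <- c(ignored, "standup_intent")
  } else if (cur == "sitting_down") {
    if (g("action_complete")) new <- "sitting"
  }

  list(state = controller_state(new), action = action, ignored = ignored)
}

#' Per-frame leg-swing detector
#'
#' Flags frame `t` when either thigh's angular speed has exceeded
#' `threshold` (degrees/s, absolute) for at least `min_frames` consecutive
#' frames ending at `t`. Used for the standing-to-moving transition.
#'
#' @param omega_L,omega_R Thigh angular-speed series in degrees/s.
#' @param threshold Speed threshold (default 20 deg/s).
#' @param min_frames Consecutive frames required (default 3).
#' @return Logical series.
#' @export
detect_swing <- function(omega_L, omega_R, threshold = 20, min_frames = 3L) {
  fast <- abs(omega_L) > threshold | abs(omega_R) > threshold
  rolling_sum(as.numeric(fast), min_frames) >= min_frames
}

#' Per-frame stillness detector
#'
#' Flags frame `t` when both thighs' angular speeds have stayed below
#' `threshold` (degrees/s, absolute) for at least `hold_s` seconds ending
#' at `t`. Used for the moving-to-standing transition.
#'
#' @param omega_L,omega_R Thigh angular-speed series in degrees/s.
#' @param fs Sampling rate in Hz.
#' @param threshold Speed threshold (default 5 deg/s).
#' @param hold_s Hold duration in seconds (default 1).
#' @return Logical series.
#' @export
detect_still <- function(omega_L, omega_R, fs, threshold = 5, hold_s = 1) {
  hold <- max(1L, as.integer(round(hold_s * fs)))
  slow <- abs(omega_L) < threshold & abs(omega_R) < threshold
  rolling_sum(as.numeric(slow), hold) >= hold
}
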