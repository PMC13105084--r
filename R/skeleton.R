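#' The 17-keypoint skeleton
#'
#' Keypoint names, edge list, hinge joints (elbows/knees), and the joint
#' subsets used downstream: 5 face joints, 12 body joints (used for the
#' pairwise-distance features and the center of mass), and 13 height/speed
#' joints (nose + body).
#'
#' @return a list with `names`, `edges` (m x 2 integer matrix), `hinges`
#'   (list of (a, joint, b) index triplets), `face`, `body`, `height_speed`
#' @export
skeleton_def <- function() {
  nm <- c("nose", "left_eye", "right_eye", "left_ear", "right_ear",
          "left_shoulder", "right_shoulder", "left_elbow", "right_elbow",
          "left_wrist", "right_wrist", "left_hip", "right_hip",
          "left_knee", "right_knee", "left_ankle", "right_ankle")
  edges <- rbind(
    c(1, 2), c(1, 3), c(2, 4), c(3, 5),
    c(6, 7), c(6, 8), c(8, 10), c(7, 9), c(9, 11),
    c(12, 13), c(6, 12), c(7, 13),
    c(12, 14), c(14, 16), c(13, 15), c(15, 17))
  hinges <- list(
    left_elbow = c(6, 8, 10), right_elbow = c(7, 9, 11),
    left_knee = c(12, 14, 16), right_knee = c(13, 15, 17))
  list(names = nm, edges = edges, hinges = hinges,
       face = 1:5, body = 6:17, height_speed = c(1, 6:17))
}

## canonical quadrupedal posture template in body-local coordinates:
## x forward, y left, z up, origin at the trunk center. Units: m.
base_posture <- function() {
  p <- rbind(
    nose           = c( 0.30,  0.00,  0.12),
    left_eye       = c( 0.27,  0.03,  0.15),
    right_eye      = c( 0.27, -0.03,  0.15),
    left_ear       = c( 0.22,  0.05,  0.14),
    right_ear      = c( 0.22, -0.05,  0.14),
    left_shoulder  = c( 0.15,  0.08,  0.05),
    right_shoulder = c( 0.15, -0.08,  0.05),
    left_elbow     = c( 0.19,  0.09, -0.08),
    right_elbow    = c( 0.19, -0.09, -0.08),
    left_wrist     = c( 0.16,  0.09, -0.20),
    right_wrist    = c( 0.16, -0.09, -0.20),
    left_hip       = c(-0.15,  0.07,  0.05),
    right_hip      = c(-0.15, -0.07,  0.05),
    left_knee      = c(-0.20,  0.09, -0.08),
    right_knee     = c(-0.16, -0.09, -0.08),
    left_ankle     = c(-0.14,  0.09, -0.20),
    right_ankle    = c(-0.14, -0.09, -0.20))
  unname(p)
}

## per-syllable posture variant: crouch scales limb z, stretch scales x,
## head_pitch tilts the face block. Returns a 17 x 3 matrix.
syllable_posture <- function(crouch = 1, stretch = 1, head_pitch = 0) {
  p <- base_posture()
  limb <- 8:17
  p[limb, 3] <- p[limb, 3] * crouch
  p[, 1] <- p[, 1] * stretch
  if (head_pitch != 0) {
    face <- 1:5
    hc <- c(0.22, 0, 0.12)  # pivot near the neck
    R <- rot_y(head_pitch)
    p[face, ] <- sweep(sweep(p[face, ], 2, hc) %*% t(R), 2, hc, "+")
  }
  p
}

rot_z <- function(a) {
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}
rot_y <- function(a) {
  matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
}
rot_x <- function(a) {
  matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
}
## yaw-pitch-roll (intrinsic z-y-x) rotation
rot_ypr <- function(yaw, pitch, roll) rot_z(yaw) %*% rot_y(pitch) %*% rot_x(roll)
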