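# Constant-velocity Kalman filter over box observations, in the standard
# SORT parameterisation: state (cx, cy, s, r, vcx, vcy, vs) where s is box
# area and r the (constant) aspect ratio; observation (cx, cy, s, r).
# Noise covariances are the published SORT defaults: the tracker modifies
# SORT's logic (coasting, re-association), not its filter tuning.

.kf_F <- local({
  F <- diag(7)
  F[1, 5] <- F[2, 6] <- F[3, 7] <- 1
  F
})
.kf_H <- cbind(diag(4), matrix(0, 4, 3))
.kf_Q <- diag(c(1, 1, 1, 1, 0.01, 0.01, 1e-4))
.kf_R <- diag(c(1, 1, 10, 10))
.kf_P0 <- diag(c(10, 10, 10, 10, 1e4, 1e4, 1e4))

box_to_z <- function(box) {
  w <- box[3] - box[1]
  h <- box[4] - box[2]
  c((box[1] + box[3]) / 2, (box[2] + box[4]) / 2, w * h, w / h)
}

z_to_box <- function(x) {
  s <- max(x[3], 1e-6)   # area clamped to a minimum to keep the box valid
  r <- max(x[4], 1e-6)
  w <- sqrt(s * r)
  h <- s / w
  c(x[1] - w / 2, x[2] - h / 2, x[1] + w / 2, x[2] + h / 2)
}

kf_new <- function(box) {
  list(x = c(box_to_z(box), 0, 0, 0), P = .kf_P0)
}

kf_predict <- function(kf) {
  # keep the predicted area positive: zero the area velocity if it would
  # drive s non-positive this step
  if (kf$x[7] + kf$x[3] <= 0) kf$x[7] <- 0
  kf$x <- drop(.kf_F %*% kf$x)
  kf$P <- .kf_F %*% kf$P %*% t(.kf_F) + .kf_Q
  kf
}

kf_update <- function(kf, box) {
  z <- box_to_z(box)
  y <- z - drop(.kf_H %*% kf$x)
  S <- .kf_H %*% kf$P %*% t(.kf_H) + .kf_R
  K <- kf$P %*% t(.kf_H) %*% solve(S)
  kf$x <- kf$x + drop(K %*% y)
  kf$P <- (diag(7) - K %*% .kf_H) %*% kf$P
  kf
}

kf_box <- function(kf) z_to_box(kf$x)
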