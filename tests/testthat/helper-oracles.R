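# Independent oracles used to cross-check the package's geometry and
# alignment code. These deliberately avoid the code paths they validate.

# rotation matrix -> unit quaternion (w, x, y, z), Shepperd's method
quat_from_rot <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] > R[2, 2] && R[1, 1] > R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s, (R[1, 2] + R[2, 1]) / s,
           (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] > R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s, 0.25 * s,
           (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, 0.25 * s)
  }
  q / sqrt(sum(q^2))
}

# rotation angle (deg) of a single rotation, via its quaternion
quat_rotation_angle <- function(R) {
  q <- quat_from_rot(R)
  2 * acos(min(1, abs(q[1]))) * 180 / pi
}

# angular distance (deg) between two rotations, via quaternion inner product
quat_distance <- function(Ra, Rb) {
  qa <- quat_from_rot(Ra)
  qb <- quat_from_rot(Rb)
  2 * acos(min(1, abs(sum(qa * qb)))) * 180 / pi
}

# axis of rotation from the quaternion vector part (unit; NULL if angle ~ 0)
quat_axis <- function(R) {
  q <- quat_from_rot(R)
  if (q[1] < 0) q <- -q
  v <- q[2:4]
  n <- sqrt(sum(v^2))
  if (n < 1e-12) return(NULL)
  v / n
}

# Haar-ish random rotation from a normalized Gaussian quaternion
random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# direct definition-based RMSD (no superposition)
rmsd_direct <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

# Needleman-Wunsch / Gotoh global alignment score with affine gaps
# (gap of length L costs gap_open + L * gap_ext), small-n oracle
nw_score <- function(s1, s2, match = 2, mismatch = -1, gap_open = 5,
                     gap_ext = 1) {
  a <- strsplit(s1, "")[[1]]
  b <- strsplit(s2, "")[[1]]
  n <- length(a); m <- length(b)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); Ix <- M; Iy <- M
  M[1, 1] <- 0
  for (i in 2:(n + 1)) Ix[i, 1] <- -gap_open - (i - 1) * gap_ext
  for (j in 2:(m + 1)) Iy[1, j] <- -gap_open - (j - 1) * gap_ext
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (a[i - 1] == b[j - 1]) match else mismatch
      M[i, j] <- max(M[i - 1, j - 1], Ix[i - 1, j - 1], Iy[i - 1, j - 1]) + s
      Ix[i, j] <- max(M[i - 1, j] - gap_open - gap_ext, Ix[i - 1, j] - gap_ext)
      Iy[i, j] <- max(M[i, j - 1] - gap_open - gap_ext, Iy[i, j - 1] - gap_ext)
    }
  }
  max(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
}

rand_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n, TRUE),
                              collapse = "")
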