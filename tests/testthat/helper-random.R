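# Seeded random geometry generators used across test files.

random_unit <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

random_point <- function(scale = 50) stats::runif(3, -scale, scale)

# a random axis and a random plane containing it
random_axis_and_plane <- function() {
  axis <- long_axis(random_point(), random_unit(), stats::runif(1, 20, 120))
  u <- random_unit()
  u_perp <- u - sum(u * axis$direction) * axis$direction
  while (sqrt(sum(u_perp^2)) < 1e-3) {
    u <- random_unit()
    u_perp <- u - sum(u * axis$direction) * axis$direction
  }
  list(axis = axis, plane = plane(axis$base, cross(axis$direction, u_perp)))
}

cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

random_landmarks <- function() {
  repeat {
    lm <- try(landmark_set(random_point(), random_point(), random_point()),
              silent = TRUE)
    if (!inherits(lm, "try-error")) return(lm)
  }
}

# tiny random volume
random_volume <- function(d = c(9, 9, 9), spacing = 1, origin = c(0, 0, 0)) {
  volume(array(stats::runif(prod(d)), dim = d), spacing, origin)
}
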