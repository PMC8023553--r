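# small internal geometry / RNG helpers

# run code under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# rotation matrices about coordinate axes (angle in degrees)
rot_x <- function(a) {
  a <- deg2rad(a)
  matrix(c(1, 0, 0, 0, cos(a), -sin(a), 0, sin(a), cos(a)), 3, 3, byrow = TRUE)
}
rot_z <- function(a) {
  a <- deg2rad(a)
  matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3, byrow = TRUE)
}

# uniformly distributed random rotation matrix (QR of Gaussian matrix)
random_rotation <- function() {
  qr_res <- qr(matrix(stats::rnorm(9), 3, 3))
  q <- qr.Q(qr_res)
  d <- sign(diag(qr.R(qr_res)))
  q <- q %*% diag(d)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

vnorm <- function(v) sqrt(sum(v^2))

# angle between two vectors, degrees in [0, 180]
angle_between <- function(u, v) {
  ct <- sum(u * v) / (vnorm(u) * vnorm(v))
  rad2deg(acos(pmin(1, pmax(-1, ct))))
}
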