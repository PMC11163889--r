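# Internal helpers shared across modules.

# Scanner (world) anatomical directions. All geometry lives in NIfTI RAS
# millimetre space: +x = right, +y = anterior, +z = superior/cranial.
.DIR_LEFT     <- c(-1, 0, 0)
.DIR_ANTERIOR <- c(0, 1, 0)
.DIR_CRANIAL  <- c(0, 0, 1)

scanner_directions <- function() {
  list(left = .DIR_LEFT, anterior = .DIR_ANTERIOR, cranial = .DIR_CRANIAL)
}

# Run `expr` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive a reproducible child seed (< 2^31) from a base seed and a label.
child_seed <- function(seed, label) {
  if (is.null(seed)) return(NULL)
  h <- sum(utf8ToInt(as.character(label)) * seq_along(utf8ToInt(as.character(label))))
  (as.double(seed) * 48271 + h * 7919) %% 2147483587
}

vnorm <- function(v) sqrt(sum(v * v))

unit <- function(v) {
  n <- vnorm(v)
  if (n < .Machine$double.eps) stop("cannot normalise a zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Rotation matrix from extrinsic Euler angles (degrees) about world x, y, z,
# applied in that order: R = Rz %*% Ry %*% Rx.
euler_rotation <- function(angles_deg) {
  stopifnot(length(angles_deg) == 3)
  a <- angles_deg * pi / 180
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

piecewise_linear <- function(anchors_age, anchors_value, age) {
  stats::approx(anchors_age, anchors_value, xout = age, rule = 2)$y
}

`%||%` <- function(a, b) if (is.null(a)) b else a
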