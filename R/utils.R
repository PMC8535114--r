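## small vector helpers shared across modules

vnorm <- function(x) sqrt(sum(x * x))

unitize <- function(x) {
  n <- vnorm(x)
  if (n == 0) abort("cannot normalize a zero vector")
  x / n
}

check_vec3 <- function(x, name = deparse(substitute(x))) {
  if (!is.numeric(x) || length(x) != 3L || !all(is.finite(x))) {
    abort(sprintf("`%s` must be a finite numeric 3-vector", name))
  }
  as.numeric(x)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

## rotation taking +z to `axis` (unit); columns are the coil-frame basis in
## world coordinates
frame_from_axis <- function(axis) {
  w <- unitize(axis)
  seed <- if (abs(w[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- unitize(seed - sum(seed * w) * w) # Gram-Schmidt: u tracks world x
  v <- cross3(w, u)
  cbind(u, v, w, deparse.level = 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
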