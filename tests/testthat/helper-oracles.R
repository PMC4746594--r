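# independent oracles used across the suite: deliberately naive
# implementations that share no code with the package internals

# window variance by explicit double loop (interior pixels only)
bfVariance <- function(img, r) {
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(NA_real_, nr, nc)
  for (i in (r + 1):(nr - r)) {
    for (j in (r + 1):(nc - r)) {
      out[i, j] <- var(as.vector(img[(i - r):(i + r), (j - r):(j + r)]))
    }
  }
  out
}

# P(|U1 - U2| <= a) for two independent uniform points in a disc of radius R
# (numeric integration of the known pair-distance density)
pcloseDisc <- function(a, R) {
  f <- function(s) (2 * s / R^2) * (2 / pi) *
    (acos(s / (2 * R)) - (s / (2 * R)) * sqrt(1 - (s / (2 * R))^2))
  stats::integrate(f, 0, a)$value
}

# tour length of a fixed visiting order
tourLength <- function(x, y, order, start) {
  px <- c(start[1], x[order]); py <- c(start[2], y[order])
  sum(sqrt(diff(px)^2 + diff(py)^2))
}

# exact TSP-path optimum by full enumeration (n <= 7)
bfBestTour <- function(x, y, start) {
  n <- length(x)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  min(vapply(perms(seq_len(n)), function(o) tourLength(x, y, o, start), 0))
}

# count points within radius of a centre by direct looping
bfCircleCount <- function(x, y, cx, cy, radius) {
  n <- 0L
  for (i in seq_along(x)) {
    if (sqrt((x[i] - cx)^2 + (y[i] - cy)^2) <= radius) n <- n + 1L
  }
  n
}
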