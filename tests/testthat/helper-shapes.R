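# rasterizers and small builders shared across tests

rasterDisc <- function(r, n = 2 * r + 11) {
  cc <- (n + 1) / 2
  outer(seq_len(n), seq_len(n),
        function(i, j) (i - cc)^2 + (j - cc)^2 <= r^2)
}

rasterEllipse <- function(a, b, n = 2 * max(a, b) + 11) {
  cc <- (n + 1) / 2
  outer(seq_len(n), seq_len(n),
        function(i, j) ((i - cc) / b)^2 + ((j - cc) / a)^2 <= 1)
}

rasterSquare <- function(side, n = side + 20) {
  m <- matrix(FALSE, n, n)
  o <- floor((n - side) / 2)
  m[o + seq_len(side), o + seq_len(side)] <- TRUE
  m
}

maskLabels <- function(mask) {
  SegmentationLabels(matrix(as.integer(mask), nrow(mask), ncol(mask)))
}

# dense-quadrature oracle for the incremental AUC of a piecewise-linear
# curve: integrate max(g(t) - baseline, 0) on a fine grid
iaucOracle <- function(times, glucose, dt = 0.002) {
  b <- mean(glucose[times <= 0])
  tt <- seq(0, max(times), by = dt)
  g <- approx(times, glucose, xout = tt)$y
  y <- pmax(g - b, 0)
  sum((y[-1] + y[-length(y)]) / 2) * dt
}
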