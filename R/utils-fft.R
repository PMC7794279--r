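# Frequency-domain helpers shared by the pyramid and the stimulus generators.
# All spectra are handled in "centered" layout (DC at [n/2 + 1, n/2 + 1]) so
# that spectral cropping/padding is a contiguous block operation.

fft2 <- function(x) stats::fft(x)

ifft2 <- function(X) stats::fft(X, inverse = TRUE) / length(X)

fftshift2 <- function(X) {
  d <- dim(X)
  i <- c(seq(d[1] %/% 2 + 1, d[1]), seq_len(d[1] %/% 2))
  j <- c(seq(d[2] %/% 2 + 1, d[2]), seq_len(d[2] %/% 2))
  X[i, j, drop = FALSE]
}

ifftshift2 <- function(X) {
  d <- dim(X)
  i <- c(seq(d[1] - d[1] %/% 2 + 1, d[1]), seq_len(d[1] - d[1] %/% 2))
  j <- c(seq(d[2] - d[2] %/% 2 + 1, d[2]), seq_len(d[2] - d[2] %/% 2))
  X[i, j, drop = FALSE]
}

# Angular frequency coordinates for an n-point DFT in centered layout,
# in radians per sample: (-n/2, ..., n/2 - 1) * 2*pi/n for even n.
freq_axis <- function(n) {
  stopifnot(n %% 2 == 0)
  (seq_len(n) - (n %/% 2 + 1)) * (2 * pi / n)
}

# Polar frequency grids (centered layout). Returns radius and angle matrices.
polar_grid <- function(nr, nc) {
  fy <- freq_axis(nr)
  fx <- freq_axis(nc)
  r <- sqrt(outer(fy^2, fx^2, `+`))
  th <- atan2(outer(fy, rep(1, nc)), outer(rep(1, nr), fx))
  list(r = r, theta = th)
}

# Central block of a centered spectrum (downsampling by 2 in each dimension).
crop_spectrum <- function(X) {
  d <- dim(X)
  i <- seq(d[1] %/% 4 + 1, 3 * d[1] %/% 4)
  j <- seq(d[2] %/% 4 + 1, 3 * d[2] %/% 4)
  X[i, j, drop = FALSE]
}

# Amplitude-preserving 2x upsampling by spectral zero-padding. Operates on a
# real- or complex-valued spatial map; returns a map of twice the size whose
# values interpolate the input (band-limited interpolation with circular
# boundary). The factor 4 compensates the DFT length change.
upsample2_spectral <- function(x) {
  X <- fftshift2(fft2(as.matrix(x)))
  d <- dim(X)
  out <- matrix(0 + 0i, 2 * d[1], 2 * d[2])
  i <- seq(d[1] %/% 2 + 1, d[1] %/% 2 + d[1])
  j <- seq(d[2] %/% 2 + 1, d[2] %/% 2 + d[2])
  out[i, j] <- X * 4
  y <- ifft2(ifftshift2(out))
  if (is.complex(x)) y else Re(y)
}

# Block-average downsampling of a real map by an integer factor.
block_downsample <- function(x, factor) {
  if (factor == 1) return(x)
  d <- dim(x)
  stopifnot(d[1] %% factor == 0, d[2] %% factor == 0)
  nr <- d[1] %/% factor
  nc <- d[2] %/% factor
  # sum over factor x factor blocks via matrix products
  A <- matrix(0, nr, d[1])
  A[cbind(rep(seq_len(nr), each = factor), seq_len(d[1]))] <- 1
  B <- matrix(0, d[2], nc)
  B[cbind(seq_len(d[2]), rep(seq_len(nc), each = factor))] <- 1
  (A %*% x %*% B) / factor^2
}

# Circular 2-D shift by (dr, dc) (positive = down/right).
circ_shift2 <- function(x, dr, dc) {
  d <- dim(x)
  i <- ((seq_len(d[1]) - 1 - dr) %% d[1]) + 1
  j <- ((seq_len(d[2]) - 1 - dc) %% d[2]) + 1
  x[i, j, drop = FALSE]
}

# Weighted circular cross-correlation map: ccor_at(cc, di, dj) equals
# sum_t a(t) * b(t circularly shifted by (di, dj)).
w_ccor_map <- function(a, b) Re(ifft2(fft2(a) * Conj(fft2(b))))

ccor_at <- function(cc, di, dj) {
  d <- dim(cc)
  cc[(di %% d[1]) + 1, (dj %% d[2]) + 1]
}
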