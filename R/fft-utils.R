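# Internal spectral helpers: periodic Gaussian random fields and periodic
# (circular) convolution with a disc kernel, both via stats::fft.

# Squared spatial frequency grid (cycles per pixel) for an nr x nc lattice.
fft_freq_sq <- function(nr, nc) {
  fr <- 0:(nr - 1L)
  fr[fr > nr / 2] <- fr[fr > nr / 2] - nr
  fc <- 0:(nc - 1L)
  fc[fc > nc / 2] <- fc[fc > nc / 2] - nc
  outer((fr / nr)^2, (fc / nc)^2, "+")
}

# White noise smoothed with an exact (spectral) Gaussian kernel of standard
# deviation sigma_px pixels, periodic boundary. Uses the current RNG stream.
gaussian_random_field <- function(nr, nc, sigma_px) {
  noise <- matrix(stats::rnorm(nr * nc), nr, nc)
  H <- exp(-2 * pi^2 * sigma_px^2 * fft_freq_sq(nr, nc))
  Re(stats::fft(stats::fft(noise) * H, inverse = TRUE)) / (nr * nc)
}

# FFT of a wrapped disc indicator kernel (centre at element [1,1]).
disc_kernel_fft <- function(radius_px, nr, nc) {
  k <- matrix(0, nr, nc)
  r <- ceiling(radius_px)
  off <- -r:r
  rows <- ((off %% nr) + nr) %% nr + 1L
  cols <- ((off %% nc) + nc) %% nc + 1L
  d2 <- outer(off^2, off^2, "+")
  k[rows, cols] <- k[rows, cols] + (d2 <= radius_px^2)
  stats::fft(k)
}

# Circular convolution of mat with a kernel given by its FFT.
circ_convolve <- function(mat, kernel_fft) {
  Re(stats::fft(stats::fft(mat) * kernel_fft, inverse = TRUE)) /
    (nrow(mat) * ncol(mat))
}
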