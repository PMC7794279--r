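# Shared fixtures, built once per test run. Kept small: the statistic
# engine is exercised at reduced resolutions, with geometry scaled by the
# pixels-per-degree factor.

fix_noise_img <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      val <<- with_seed_test(101, gray_image(matrix(stats::runif(128 * 128), 128, 128)))
    }
    val
  }
})

fix_texture <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      val <<- generate_texture(procedural_texture_params(size_px = 256,
                                                         rng_seed = 42),
                               px_per_deg = 6)
    }
    val
  }
})

with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# plain (unweighted) sample skewness
sample_skew <- function(m) {
  v <- as.vector(unclass(m))
  mu <- mean(v)
  mean((v - mu)^3) / stats::sd(v)^3
}

fas_of <- function(img) Mod(stats::fft(unclass(img)))

rel_fas_err <- function(a, b) {
  fa <- fas_of(a); fb <- fas_of(b)
  sqrt(sum((fa - fb)^2)) / sqrt(sum(fb^2))
}
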