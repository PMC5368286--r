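# Shared in-code fixtures; everything deterministic.

# small solid-ellipsoid CT in air
ellipsoid_ct <- function(shape = c(24, 24, 24), spacing = c(2, 2, 2),
                         hu_in = 40, hu_out = -1000, semi_frac = 0.4) {
  ext <- (shape - 1) * spacing
  ctr <- ext / 2
  co <- expand.grid(x = (seq_len(shape[1]) - 1) * spacing[1],
                    y = (seq_len(shape[2]) - 1) * spacing[2],
                    z = (seq_len(shape[3]) - 1) * spacing[3])
  inside <- ((co$x - ctr[1]) / (semi_frac * ext[1]))^2 +
    ((co$y - ctr[2]) / (semi_frac * ext[2]))^2 +
    ((co$z - ctr[3]) / (semi_frac * ext[3]))^2 <= 1
  v <- array(hu_out, shape)
  v[array(inside, shape)] <- hu_in
  list(vol = vol_image(v, spacing = spacing),
       inside = array(inside, shape))
}

# linear world-coordinate ramp volume f(x, y, z) = a*x (mm)
ramp_volume <- function(shape = c(16, 16, 16), spacing = c(2, 2, 2),
                        a = 2) {
  xs <- (seq_len(shape[1]) - 1) * spacing[1]
  v <- array(rep(a * xs, times = shape[2] * shape[3]), shape)
  vol_image(v, spacing = spacing)
}

full_mask <- function(vol) {
  bin_mask(array(TRUE, dim(vol$values)), like = vol)
}

# tiny standard phantom for fast registration/fusion tests
small_spec <- function(...) {
  phantom_spec(shape = c(32L, 32L, 32L), spacing_mm = c(3, 3, 3), ...)
}

# smooth random dose pair for gamma tests (reference + perturbed eval)
random_dose_pair <- function(seed, shape = c(20, 20, 20),
                             spacing = c(2.5, 2.5, 2.5)) {
  set.seed(seed)
  sm <- function() {
    f <- array(rnorm(prod(shape)), shape)
    array(masct:::cpp_gauss3d(as.numeric(f), shape, rep(2.5, 3)), shape)
  }
  base <- sm()
  ref <- 2 + 1.5 * (base - min(base)) / diff(range(base))
  ev <- ref * (1 + 0.02 * sm()) + 0.02 * sm()
  ev[ev < 0] <- 0
  list(ref = vol_image(ref, spacing = spacing, modality = "DOSE"),
       eval = vol_image(ev, spacing = spacing, modality = "DOSE"))
}
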