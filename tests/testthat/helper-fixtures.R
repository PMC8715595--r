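# Shared fixtures, built in code. Phantoms are cached per test run because
# several files reuse the same ones.

fixture_env <- new.env(parent = emptyenv())

# desk-scale 2D phantom spec used throughout the tests
spec2d <- function(...) phantom_spec(grid_shape = c(64, 64, 1), ...)

cached <- function(key, builder) {
  if (is.null(fixture_env[[key]])) fixture_env[[key]] <- builder()
  fixture_env[[key]]
}

phantom2d <- function(seed = 0) {
  cached(paste0("phantom2d_", seed), function() generate_phantom(spec2d(), seed))
}

subject2d <- function(seed = 0) {
  cached(paste0("subject2d_", seed),
         function() preprocess_subject(generate_subject(spec2d(), seed)))
}

# a zero-magnitude simulator: identity affine, no elastic displacement
identity_simulator <- function() {
  reg <- list(affine = affine_ranges(rotation = c(0, 0), scale = c(1, 1),
                                     shear = c(0, 0), translation = c(0, 0)),
              elastic = elastic_spec(max_displacement = 0))
  simulator_config(small = reg, large = reg, large_fraction = 0)
}

# smooth random volume (low-frequency, every window non-constant)
smooth_volume <- function(shape, seed = 1, spacing = c(1, 1, 1)) {
  rng <- hr_rng(seed)
  raw <- with_rng(rng, rnorm(prod(shape)))
  sm <- hybridreg:::cpp_gauss_smooth(raw, shape, c(2, 2, 2))
  volume(array(sm + 0.05 * raw, shape), spacing)
}

# brute-force windowed squared-NCC oracle (border-clamped windows)
ncc_loop_oracle <- function(ref, pred, r, eps) {
  d <- dim(ref)
  tot <- 0
  for (z in seq_len(d[3])) for (y in seq_len(d[2])) for (x in seq_len(d[1])) {
    xi <- pmin(pmax(x + (-r[1]:r[1]), 1), d[1])
    yi <- pmin(pmax(y + (-r[2]:r[2]), 1), d[2])
    zi <- pmin(pmax(z + (-r[3]:r[3]), 1), d[3])
    rw <- ref[xi, yi, zi]; pw <- pred[xi, yi, zi]
    C <- sum((rw - mean(rw)) * (pw - mean(pw)))
    tot <- tot + C^2 / (sum((rw - mean(rw))^2) * sum((pw - mean(pw))^2) + eps)
  }
  -tot / prod(d)
}

# per-voxel field-loss loop oracle (mm)
field_loss_loop_oracle <- function(pred, gold) {
  dm <- dim(pred$vectors)
  tot <- 0
  for (z in seq_len(dm[3])) for (y in seq_len(dm[2])) for (x in seq_len(dm[1])) {
    dv <- (pred$vectors[x, y, z, ] - gold$vectors[x, y, z, ]) * pred$spacing
    tot <- tot + sqrt(sum(dv^2))
  }
  tot / prod(dm[1:3])
}

# nearest-neighbour shift-with-clamp oracle for constant integer fields
shift_clamp_oracle <- function(arr, shift) {
  d <- dim(arr)
  out <- array(0, d)
  for (z in seq_len(d[3])) for (y in seq_len(d[2])) for (x in seq_len(d[1]))
    out[x, y, z] <- arr[min(max(x + shift[1], 1), d[1]),
                        min(max(y + shift[2], 1), d[2]),
                        min(max(z + shift[3], 1), d[3])]
  out
}

constant_field <- function(shape, u, spacing = c(1, 1, 1)) {
  displacement_field(array(rep(u, each = prod(shape)), c(shape, 3L)), spacing)
}
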