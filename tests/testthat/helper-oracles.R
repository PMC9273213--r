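# Independent oracles used against the package implementations.

# Pearson correlation straight from the definition, no shortcuts shared with
# the implementation path beyond base arithmetic.
brute_pcc <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  num <- 0; sx <- 0; sy <- 0
  for (i in seq_len(n)) {
    num <- num + (x[i] - mx) * (y[i] - my)
    sx <- sx + (x[i] - mx)^2
    sy <- sy + (y[i] - my)^2
  }
  num / sqrt(sx * sy)
}

# Exact two-sided Mann-Whitney p by enumerating every assignment of the
# pooled observations to group A (tie-free inputs only).
enum_mw <- function(a, b) {
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  u_of <- function(av, bv) sum(outer(av, bv, ">")) + 0.5 * sum(outer(av, bv, "=="))
  u_obs <- u_of(a, b)
  combos <- utils::combn(na + nb, na)
  us <- apply(combos, 2, function(ix) u_of(pooled[ix], pooled[-ix]))
  p_le <- mean(us <= u_obs)
  p_ge <- mean(us >= u_obs)
  list(u = u_obs, p = min(1, 2 * min(p_le, p_ge)))
}

# Nearest-seed assignment by exhaustive Euclidean distance; ties to the
# lower label.
nearest_seed_oracle <- function(seeds, dim) {
  pos <- which(seeds > 0)
  labs <- seeds[pos]
  sr <- ((pos - 1) %% dim[1]) + 1
  sc <- ((pos - 1) %/% dim[1]) + 1
  out <- matrix(0L, dim[1], dim[2])
  for (r in seq_len(dim[1])) for (c in seq_len(dim[2])) {
    d <- (sr - r)^2 + (sc - c)^2
    best <- which(d == min(d))
    out[r, c] <- min(labs[best])
  }
  out
}

# Small, fast generator settings for unit tests.
small_params <- function(...) {
  args <- list(image_height = 160, image_width = 160, n_cells_per_field = 2,
               n_fields = 2, cell_radius_range = c(26, 32),
               nucleus_radius_range = c(8, 11), mito_filament_count = 8,
               mito_filament_length = 45, seed = 42)
  do.call(synth_params, utils::modifyList(args, list(...)))
}

# One noise-free cell truth rendered in isolation, for measurement tests.
single_cell_field <- function(theta, seed = 7, background = c(0, 0, 0)) {
  p <- synth_params(image_height = 128, image_width = 128,
                    n_cells_per_field = 1, n_fields = 1,
                    cell_radius_range = c(30, 34),
                    nucleus_radius_range = c(9, 11),
                    misloc_fraction = theta, transfected_prob = 1,
                    shot_noise = FALSE, read_noise_sd = 0,
                    background_plane_coeffs = background, seed = seed)
  tr <- withr::with_seed(seed, mitoloc:::place_field_cells(p))
  f <- withr::with_seed(seed + 1, render_field(tr, p))
  list(params = p, truths = tr, field = f)
}
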