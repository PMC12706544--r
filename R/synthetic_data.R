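# Colonoscopy-like phantom generator: a pink-tinted multi-octave textured
# background ("mucosa"), one smoothly bounded bright lesion blob per frame
# (deformed ellipse with low-order radial harmonics), additive sensor noise,
# and a distribution-shifted variant standing in for a held-out imaging centre.

# fixed appearance multipliers defining the shifted domain
SHIFT_MULTIPLIERS <- list(
  background_texture_scale = 2.0, # coarser texture
  lesion_contrast          = 0.6, # washed-out lesions
  noise_sigma              = 1.5, # noisier sensor
  boundary_softness        = 1.5, # blurrier lesion rim
  harmonic_amp             = 1.3, # more irregular lesion outlines
  brightness_offset        = 0.12 # globally brighter frames
)

#' Configuration of the phantom generator
#'
#' @param image_size square output size in pixels.
#' @param n_images number of samples the dataset should contain.
#' @param lesion_area_fraction_range `(low, high)` bounds on lesion area as a
#'   fraction of the frame.
#' @param lesion_contrast additive intensity offset of the lesion over the
#'   background, on the `[0, 1]` scale.
#' @param background_texture_scale characteristic texture cell size in pixels
#'   of the coarsest background octave.
#' @param noise_sigma standard deviation of additive Gaussian pixel noise.
#' @param boundary_softness width in pixels of the smooth lesion rim.
#' @param domain `"source"` (training centres) or `"shifted"` (held-out
#'   centre stand-in).
#' @param seed integer seed; generation is a pure function of the config.
#' @param harmonic_amp maximum amplitude of the radial harmonic deformation of
#'   the lesion outline.
#' @param brightness numeric base luminance offset of the background.
#' @return a `phantom_config` list.
#' @export
phantom_config <- function(image_size = 256L, n_images = 100L,
                           lesion_area_fraction_range = c(0.03, 0.18),
                           lesion_contrast = 0.35,
                           background_texture_scale = 16,
                           noise_sigma = 0.03,
                           boundary_softness = 2.0,
                           domain = c("source", "shifted"),
                           seed = 1L,
                           harmonic_amp = 0.15,
                           brightness = 0.0) {
  domain <- match.arg(domain)
  stopifnot(
    image_size >= 8, n_images >= 1,
    length(lesion_area_fraction_range) == 2L,
    lesion_area_fraction_range[1L] > 0,
    lesion_area_fraction_range[1L] < lesion_area_fraction_range[2L],
    lesion_area_fraction_range[2L] < 1,
    background_texture_scale > 0, noise_sigma >= 0, boundary_softness >= 0,
    harmonic_amp >= 0
  )
  structure(list(
    image_size = as.integer(image_size), n_images = as.integer(n_images),
    lesion_area_fraction_range = as.numeric(lesion_area_fraction_range),
    lesion_contrast = lesion_contrast,
    background_texture_scale = background_texture_scale,
    noise_sigma = noise_sigma, boundary_softness = boundary_softness,
    domain = domain, seed = as.integer(seed),
    harmonic_amp = harmonic_amp, brightness = brightness
  ), class = "phantom_config")
}

#' Derive the distribution-shifted variant of a source config
#'
#' Applies fixed, documented multipliers to the appearance statistics of a
#' source-domain configuration (coarser texture, x2; reduced lesion contrast,
#' x0.6; increased noise, x1.5; softer lesion rim, x1.5; more irregular
#' outlines, x1.3; a +0.12 global brightness offset). Lesion geometry sampling
#' is otherwise unchanged, so masks follow the same generative logic and only
#' the appearance distribution moves.
#'
#' @param cfg a source-domain [phantom_config()].
#' @return a `phantom_config` with `domain = "shifted"`.
#' @export
shift_domain <- function(cfg) {
  stopifnot(inherits(cfg, "phantom_config"))
  if (cfg$domain != "source") stop("shift_domain: config is already shifted")
  m <- SHIFT_MULTIPLIERS
  cfg$background_texture_scale <- cfg$background_texture_scale * m$background_texture_scale
  cfg$lesion_contrast <- cfg$lesion_contrast * m$lesion_contrast
  cfg$noise_sigma <- cfg$noise_sigma * m$noise_sigma
  cfg$boundary_softness <- cfg$boundary_softness * m$boundary_softness
  cfg$harmonic_amp <- cfg$harmonic_amp * m$harmonic_amp
  cfg$brightness <- cfg$brightness + m$brightness_offset
  cfg$domain <- "shifted"
  cfg
}

# smooth multi-octave value-noise field in [-0.5, 0.5]-ish range, mean ~0
value_noise_field <- function(size, cell, octaves = 3L) {
  acc <- matrix(0, size, size)
  amp <- 1
  total <- 0
  for (o in seq_len(octaves)) {
    n_cells <- max(2L, as.integer(ceiling(size / cell)) + 1L)
    grid <- matrix(runif(n_cells^2) - 0.5, n_cells, n_cells)
    # bilinear interpolation of the coarse grid onto the pixel lattice
    pos <- (seq_len(size) - 1) / (size - 1) * (n_cells - 1) + 1
    i0 <- pmin(floor(pos), n_cells - 1); fi <- pos - i0
    r1 <- grid[i0, , drop = FALSE]; r2 <- grid[i0 + 1, , drop = FALSE]
    rows <- r1 * (1 - fi) + r2 * fi
    c1 <- rows[, i0, drop = FALSE]; c2 <- rows[, i0 + 1, drop = FALSE]
    field <- sweep(c1, 2, 1 - fi, "*") + sweep(c2, 2, fi, "*")
    acc <- acc + amp * field
    total <- total + amp
    amp <- amp / 2
    cell <- cell / 2
  }
  acc / total
}

# soft lesion support: alpha in (0,1), 0.5-level set = geometric outline
lesion_alpha <- function(size, center, r0, harm, softness) {
  xs <- matrix(rep(seq_len(size), each = size), size, size) # column index
  ys <- matrix(rep(seq_len(size), times = size), size, size) # row index
  dx <- xs - center[2L]
  dy <- ys - center[1L]
  rho <- sqrt(dx^2 + dy^2)
  phi <- atan2(dy, dx)
  rboundary <- r0 * (1 + harm$a2 * cos(2 * phi + harm$p2) +
                       harm$a3 * cos(3 * phi + harm$p3) +
                       harm$a4 * cos(4 * phi + harm$p4))
  soft <- max(softness, 1e-6)
  sigmoid((rboundary - rho) / soft)
}

#' Generate one phantom image/mask pair
#'
#' Deterministic in `(cfg$seed, cfg$domain, index)`. The image is an RGB array
#' `(H, W, 3)` in `[0, 1]`; the mask is a binary `(H, W)` matrix whose
#' foreground is a single connected blob with area inside the configured
#' fraction range (the mask thresholds the smooth lesion support at the
#' half-transition level, so it traces the geometric outline regardless of rim
#' softness).
#'
#' @param cfg a [phantom_config()].
#' @param index 1-based sample index within the dataset.
#' @return a `segmentation_sample` list with `id`, `image`, `mask`.
#' @export
make_phantom <- function(cfg, index) {
  stopifnot(inherits(cfg, "phantom_config"), index >= 1)
  size <- cfg$image_size
  # geometry and appearance draw from independent named streams, so domain
  # shift (which perturbs appearance parameters) provably leaves the
  # mask-generation logic untouched
  geo <- with_local_seed(derive_seed(cfg$seed, "phantom_geometry", index), {
    afrac <- runif(1, cfg$lesion_area_fraction_range[1L],
                   cfg$lesion_area_fraction_range[2L])
    list(
      afrac = afrac,
      harm = list(a2 = runif(1, 0, cfg$harmonic_amp),
                  a3 = runif(1, 0, cfg$harmonic_amp * 0.7),
                  a4 = runif(1, 0, cfg$harmonic_amp * 0.5),
                  p2 = runif(1, 0, 2 * pi), p3 = runif(1, 0, 2 * pi),
                  p4 = runif(1, 0, 2 * pi)),
      center_u = runif(2)
    )
  })
  r0 <- sqrt(geo$afrac * size^2 / pi)
  harm <- geo$harm
  rmax <- r0 * (1 + harm$a2 + harm$a3 + harm$a4)
  margin <- rmax + cfg$boundary_softness * 2 + 1
  if (2 * margin >= size) {
    stop(sprintf(
      "make_phantom: lesion (max radius %.1f px) cannot fit inside a %d px frame",
      rmax, size
    ))
  }
  center <- margin + geo$center_u * (size - 2 * margin)
  alpha <- lesion_alpha(size, center, r0, harm, cfg$boundary_softness)
  # one analytic correction of the radius so the realized mask area lands
  # inside the configured range (harmonics inflate area by ~sum(a_k^2)/2)
  area <- sum(alpha >= 0.5) / size^2
  if (area > 0) {
    r0c <- r0 * sqrt(geo$afrac / area)
    if (abs(r0c - r0) / r0 > 1e-3) {
      alpha <- lesion_alpha(size, center, r0c, harm, cfg$boundary_softness)
    }
  }
  mask <- (alpha >= 0.5) * 1

  img <- with_local_seed(derive_seed(cfg$seed, paste0("appearance_", cfg$domain),
                                     index), {
    # background: pink mucosa tint + smooth texture
    tex <- value_noise_field(size, cfg$background_texture_scale)
    base <- c(0.62, 0.38, 0.36) + cfg$brightness
    chan_gain <- c(0.35, 0.25, 0.22)
    img <- array(0, c(size, size, 3L))
    for (ch in 1:3) img[, , ch] <- base[ch] + chan_gain[ch] * tex
    # render lesion: reddish-bright offset with the configured contrast
    lesion_gain <- c(1.0, 0.55, 0.5)
    for (ch in 1:3) {
      img[, , ch] <- img[, , ch] + cfg$lesion_contrast * lesion_gain[ch] * alpha
    }
    if (cfg$noise_sigma > 0) {
      img <- img + array(rnorm(length(img), sd = cfg$noise_sigma), dim(img))
    }
    clamp(img, 0, 1)
  })
  structure(list(
    id = sprintf("%s_%05d", cfg$domain, as.integer(index)),
    image = img, mask = mask
  ), class = "segmentation_sample")
}

#' Generate a phantom dataset
#'
#' @param cfg a [phantom_config()]; `cfg$n_images` samples are produced with
#'   ids embedding the domain and index.
#' @return list of `segmentation_sample` objects.
#' @export
make_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "phantom_config"))
  lapply(seq_len(cfg$n_images), function(i) make_phantom(cfg, i))
}
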