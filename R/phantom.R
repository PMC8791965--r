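#' Configuration for the synthetic fetal-brain phantom
#'
#' The phantom emulates the data regime the regression network is designed
#' for: a bright, centrally located object (the "brain") whose size and
#' internal texture complexity both grow monotonically with a latent age
#' label, embedded in dimmer background clutter (maternal tissue proxy) and
#' additive Gaussian noise. Each subject is rendered as three independent
#' plane stacks (axial, coronal, sagittal); slices away from the middle
#' shrink the object as a 2D section of an ellipsoid would, so the middle
#' slice always carries the largest object area.
#'
#' @param image_size Pixels per (square) side. Must be at least 64.
#' @param age_range Two-element numeric, `[min_days, max_days]`. The default
#'   spans 19 to 39 gestational weeks expressed in days.
#' @param object_radius_map Function mapping age in days to the two ellipse
#'   semi-axes in pixels, `function(age) c(a, b)`. Must be strictly
#'   increasing in both axes over `age_range`. The default scales linearly
#'   from 10% to 25% (a) and 8% to 20% (b) of the image side.
#' @param texture_frequency_map Function mapping age in days to the spatial
#'   frequency (cycles per image side) of the object's internal sinusoidal
#'   texture, a coarse proxy for progressive gyrification. Default: linear
#'   from 2 to 12 cycles.
#' @param clutter_count Number of dimmer background ellipses per slice.
#' @param noise_sd Standard deviation of additive Gaussian noise, in
#'   intensity units (images live in `[0, 1]`).
#' @param center_jitter_sd Standard deviation in pixels of the object's
#'   random displacement from the image center (drawn once per plane).
#' @param slices_per_plane Number of slices per plane stack; odd, at least 5.
#' @param seed Integer seed recorded in the config (cohort-level functions
#'   use it as the default cohort seed).
#'
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(image_size = 64L,
                           age_range = c(19 * 7, 39 * 7),
                           object_radius_map = NULL,
                           texture_frequency_map = NULL,
                           clutter_count = 6L,
                           noise_sd = 0.05,
                           center_jitter_sd = 0.03 * image_size,
                           slices_per_plane = 9L,
                           seed = 1L) {
  assert_number(image_size, "image_size", lower = 64)
  if (length(age_range) != 2L || !is.numeric(age_range) ||
      age_range[1] >= age_range[2]) {
    abort("`age_range` must be c(min_days, max_days) with min < max.")
  }
  assert_number(clutter_count, "clutter_count", lower = 0)
  assert_number(noise_sd, "noise_sd", lower = 0)
  assert_number(center_jitter_sd, "center_jitter_sd", lower = 0)
  assert_number(slices_per_plane, "slices_per_plane", lower = 5)
  if (slices_per_plane %% 2 == 0) {
    abort("`slices_per_plane` must be odd.")
  }

  amin <- age_range[1]; amax <- age_range[2]
  rel <- function(age) (age - amin) / (amax - amin)
  if (is.null(object_radius_map)) {
    object_radius_map <- function(age) {
      t <- rel(age)
      c(a = (0.10 + 0.15 * t) * image_size,
        b = (0.08 + 0.12 * t) * image_size)
    }
  }
  if (is.null(texture_frequency_map)) {
    texture_frequency_map <- function(age) 2 + 10 * rel(age)
  }

  # strict monotonicity of the radius map over the age range
  grid <- seq(amin, amax, length.out = 25)
  rr <- vapply(grid, object_radius_map, numeric(2))
  if (any(diff(rr[1, ]) <= 0) || any(diff(rr[2, ]) <= 0)) {
    abort("`object_radius_map` must be strictly increasing over `age_range`.")
  }

  structure(
    list(image_size = as.integer(image_size),
         age_range = as.numeric(age_range),
         object_radius_map = object_radius_map,
         texture_frequency_map = texture_frequency_map,
         clutter_count = as.integer(clutter_count),
         noise_sd = noise_sd,
         center_jitter_sd = center_jitter_sd,
         slices_per_plane = as.integer(slices_per_plane),
         seed = as.integer(seed)),
    class = "phantom_config"
  )
}

phantom_planes <- c("axial", "coronal", "sagittal")

# Render one slice: background + clutter, object ellipse drawn on top.
# `scale` shrinks the object's semi-axes for off-middle slices.
render_slice <- function(size, center, axes, scale, freq, theta,
                         clutter, noise_sd, with_noise = TRUE) {
  img <- matrix(0.12, size, size)
  # clutter ellipses (dimmer, drawn first so the object overwrites them)
  rows <- matrix(rep(seq_len(size) - 1, size), size, size)
  cols <- matrix(rep(seq_len(size) - 1, each = size), size, size)
  if (!is.null(clutter) && nrow(clutter) > 0) {
    for (i in seq_len(nrow(clutter))) {
      cl <- clutter[i, ]
      d <- ((rows - cl[["cy"]]) / cl[["a"]])^2 +
           ((cols - cl[["cx"]]) / cl[["b"]])^2
      img[d <= 1] <- cl[["val"]]
    }
  }
  a <- axes[1] * scale; b <- axes[2] * scale
  if (a >= 1 && b >= 1) {
    u <- rows - center[1]; v <- cols - center[2]
    inside <- (u / a)^2 + (v / b)^2 <= 1
    # band-limited internal texture, rotated by theta
    w1 <- u * cos(theta) + v * sin(theta)
    w2 <- -u * sin(theta) + v * cos(theta)
    tex <- 0.5 + 0.5 * sin(2 * pi * freq * w1 / size) *
                       sin(2 * pi * freq * w2 / size)
    img[inside] <- 0.65 + 0.30 * tex[inside]
  }
  if (with_noise && noise_sd > 0) {
    img <- img + matrix(rnorm(size^2, 0, noise_sd), size, size)
  }
  clamp01(img)
}

#' Generate one synthetic phantom subject
#'
#' Deterministic in `(config, age_days, seed)`: calling twice with the same
#' arguments yields bit-identical subjects. Each of the three planes gets an
#' independently jittered object center, its own clutter field and noise;
#' the binary truth mask marks the analytic object ellipse on the middle
#' slice of each plane.
#'
#' @param config A [phantom_config()].
#' @param age_days Age label in days; must lie within `config$age_range`.
#' @param seed Integer seed for this subject.
#' @param subject_id Identifier string stored in the subject.
#' @param site_tag Site label (used by domain-shift experiments).
#' @return An object of class `phantom_subject`: a list with `subject_id`,
#'   `age_days`, `planes` (named list of `image_size` x `image_size` x
#'   `slices_per_plane` arrays), `truth_masks` (named list of logical
#'   matrices for the middle slices) and `site_tag`.
#' @export
generate_subject <- function(config, age_days, seed,
                             subject_id = sprintf("subj_%06d", seed %% 1e6),
                             site_tag = "source") {
  stopifnot(inherits(config, "phantom_config"))
  if (age_days < config$age_range[1] || age_days > config$age_range[2]) {
    abort(sprintf(
      "age_days = %.1f is outside the configured age range [%.1f, %.1f].",
      age_days, config$age_range[1], config$age_range[2]))
  }
  size <- config$image_size
  S <- config$slices_per_plane
  mid <- (S + 1L) %/% 2L
  axes <- config$object_radius_map(age_days)
  freq <- config$texture_frequency_map(age_days)
  ctr0 <- c((size - 1) / 2, (size - 1) / 2)

  with_seed(seed, {
    planes <- list(); masks <- list()
    for (pl in phantom_planes) {
      center <- ctr0 + rnorm(2, 0, config$center_jitter_sd)
      theta <- runif(1, 0, pi)
      clutter <- NULL
      if (config$clutter_count > 0) {
        clutter <- cbind(
          cy  = runif(config$clutter_count, 0, size - 1),
          cx  = runif(config$clutter_count, 0, size - 1),
          a   = runif(config$clutter_count, 0.04, 0.12) * size,
          b   = runif(config$clutter_count, 0.04, 0.12) * size,
          val = runif(config$clutter_count, 0.20, 0.45)
        )
      }
      # slices section an ellipsoid whose half-depth exceeds the stack, so
      # every slice keeps some object and the middle slice is largest
      depth <- (S + 1) / 2
      stack <- array(0, dim = c(size, size, S))
      for (s in seq_len(S)) {
        off <- s - mid
        scale <- sqrt(max(0, 1 - (off / depth)^2))
        stack[, , s] <- render_slice(size, center, axes, scale, freq, theta,
                                     clutter, config$noise_sd)
      }
      rows <- matrix(rep(seq_len(size) - 1, size), size, size)
      cols <- matrix(rep(seq_len(size) - 1, each = size), size, size)
      mask <- ((rows - center[1]) / axes[1])^2 +
              ((cols - center[2]) / axes[2])^2 <= 1
      if (!any(mask)) abort("Degenerate phantom: empty truth mask.")
      planes[[pl]] <- stack
      masks[[pl]] <- mask
    }
    structure(
      list(subject_id = subject_id, age_days = as.numeric(age_days),
           planes = planes, truth_masks = masks, site_tag = site_tag),
      class = "phantom_subject"
    )
  })
}

#' Generate a cohort of phantom subjects
#'
#' Ages are sampled uniformly over the configured range, or with a sampler
#' skewed against the oldest 15% of the range to mimic the scarcity of
#' late-third-trimester scans in clinical cohorts (the skewed sampler puts
#' probability 0.05 on the top 15% of the range and 0.95 below it).
#' Per-subject seeds are derived reproducibly from `seed`.
#'
#' @param config A [phantom_config()].
#' @param n Number of subjects (at least 1).
#' @param seed Cohort seed; defaults to `config$seed`.
#' @param sampler `"uniform"` or `"skewed"`.
#' @param site_tag Site label applied to every subject.
#' @param dir If not `NULL`, subjects are written to disk (see
#'   [write_subject()]) and the manifest carries file paths; otherwise the
#'   manifest carries the subjects themselves in a list-column.
#' @param format Image format when writing, `"nifti"` or `"png"`.
#' @return A tibble manifest with columns `subject_id`, `age_days`,
#'   `site_tag` and either a `subject` list-column or per-plane path columns
#'   (`path_axial`, `path_coronal`, `path_sagittal`).
#' @export
generate_cohort <- function(config, n, seed = config$seed,
                            sampler = c("uniform", "skewed"),
                            site_tag = "source", dir = NULL,
                            format = c("nifti", "png")) {
  stopifnot(inherits(config, "phantom_config"))
  sampler <- match.arg(sampler)
  format <- match.arg(format)
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    abort("`n` must be a positive integer.")
  }
  n <- as.integer(n)
  amin <- config$age_range[1]; amax <- config$age_range[2]
  draws <- with_seed(seed, {
    ages <- if (sampler == "uniform") {
      runif(n, amin, amax)
    } else {
      knot <- amin + 0.85 * (amax - amin)
      top <- runif(n) < 0.05
      ifelse(top, runif(n, knot, amax), runif(n, amin, knot))
    }
    list(ages = ages, seeds = sample.int(.Machine$integer.max - 1L, n))
  })

  subjects <- purrr::map(seq_len(n), function(i) {
    generate_subject(config, draws$ages[i], draws$seeds[i],
                     subject_id = sprintf("subj_%04d", i),
                     site_tag = site_tag)
  })
  manifest <- tibble::tibble(
    subject_id = purrr::map_chr(subjects, "subject_id"),
    age_days = purrr::map_dbl(subjects, "age_days"),
    site_tag = site_tag
  )
  if (is.null(dir)) {
    manifest$subject <- subjects
  } else {
    paths <- purrr::map(subjects, write_subject, dir = dir, format = format)
    for (pl in phantom_planes) {
      manifest[[paste0("path_", pl)]] <- purrr::map_chr(paths, pl)
    }
    readr::write_csv(manifest, file.path(dir, "manifest.csv"))
  }
  manifest
}

#' Degrade a phantom subject to emulate a domain-shifted acquisition site
#'
#' Applies, in order: an affine contrast rescale, a motion-ghosting proxy
#' (a circularly shifted copy of the image blended in), and extra additive
#' Gaussian noise. Intensities are deliberately not clipped here; clipping
#' happens only at export quantization. Age label and truth masks are
#' untouched.
#'
#' @param subject A `phantom_subject`.
#' @param contrast_scale Multiplicative intensity factor, must be positive.
#' @param extra_noise_sd Additional Gaussian noise sd (non-negative).
#' @param ghosting_amplitude Blend weight `g` in
#'   `(1 - g) * image + g * shifted image`; `0` disables ghosting.
#' @param ghost_shift Circular shift of the ghost copy, in pixels along the
#'   image width.
#' @param site_tag New site label for the degraded subject.
#' @param seed Seed for the added noise.
#' @return A new `phantom_subject`.
#' @export
degrade <- function(subject, contrast_scale = 1, extra_noise_sd = 0,
                    ghosting_amplitude = 0, ghost_shift = 8L,
                    site_tag = "degraded", seed = 1L) {
  stopifnot(inherits(subject, "phantom_subject"))
  if (contrast_scale <= 0) abort("`contrast_scale` must be positive.")
  if (extra_noise_sd < 0) abort("`extra_noise_sd` must be non-negative.")
  if (ghosting_amplitude < 0 || ghosting_amplitude > 1) {
    abort("`ghosting_amplitude` must lie in [0, 1].")
  }
  out <- subject
  out$site_tag <- site_tag
  with_seed(seed, {
    for (pl in names(subject$planes)) {
      x <- subject$planes[[pl]] * contrast_scale
      if (ghosting_amplitude > 0) {
        sh <- ((seq_len(dim(x)[2]) - 1 - ghost_shift) %% dim(x)[2]) + 1
        x <- (1 - ghosting_amplitude) * x + ghosting_amplitude * x[, sh, , drop = FALSE]
      }
      if (extra_noise_sd > 0) {
        x <- x + array(rnorm(length(x), 0, extra_noise_sd), dim = dim(x))
      }
      out$planes[[pl]] <- x
    }
  })
  out
}

#' Degrade every subject of an in-memory cohort manifest
#'
#' @param manifest A manifest tibble with a `subject` list-column.
#' @param ... Passed to [degrade()]; per-subject seeds are derived from
#'   `seed`.
#' @param seed Seed from which per-subject noise seeds are derived.
#' @return The manifest with degraded subjects and updated `site_tag`.
#' @export
degrade_cohort <- function(manifest, ..., site_tag = "degraded", seed = 1L) {
  stopifnot(is.data.frame(manifest), "subject" %in% names(manifest))
  seeds <- derive_seeds(seed, nrow(manifest))
  manifest$subject <- purrr::map2(
    manifest$subject, seeds,
    function(s, sd_i) degrade(s, ..., site_tag = site_tag, seed = sd_i))
  manifest$site_tag <- site_tag
  manifest
}

#' @export
print.phantom_subject <- function(x, ...) {
  cat(sprintf("<phantom_subject %s: age %.1f d, site %s, %d planes of %s>\n",
              x$subject_id, x$age_days, x$site_tag, length(x$planes),
              paste(dim(x$planes[[1]]), collapse = "x")))
  invisible(x)
}
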