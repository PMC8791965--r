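#' Construct a plane slab
#'
#' A slab is the network's input unit: an odd number of adjacent slices from
#' one anatomical plane, stored as a `height x width x n_slices` array.
#'
#' @param pixels Numeric array `height x width x n_slices` (a matrix is
#'   promoted to a single-slice array).
#' @param plane One of `"axial"`, `"coronal"`, `"sagittal"`.
#' @param subject_id Identifier carried along for error messages and
#'   prediction tables.
#' @return An object of class `plane_slab`.
#' @export
plane_slab <- function(pixels, plane = "axial", subject_id = "unknown") {
  if (is.matrix(pixels)) pixels <- array(pixels, dim = c(dim(pixels), 1L))
  if (length(dim(pixels)) != 3L) {
    abort("`pixels` must be a height x width x n_slices array.")
  }
  plane <- match.arg(plane, phantom_planes)
  structure(list(pixels = pixels, plane = plane,
                 n_slices = dim(pixels)[3], subject_id = subject_id),
            class = "plane_slab")
}

#' @export
print.plane_slab <- function(x, ...) {
  cat(sprintf("<plane_slab %s/%s: %s>\n", x$subject_id, x$plane,
              paste(dim(x$pixels), collapse = "x")))
  invisible(x)
}

# 0-based index of the middle slice: floor((L-1)/2), the "lower middle"
# for even-length stacks.
middle_index <- function(L) (L - 1L) %/% 2L

#' Select the middle slices of a stack
#'
#' Returns the middle slice plus `floor(n_slices / 2)` immediate neighbors
#' on each side, in ascending slice order. The middle of an even-length
#' stack is the lower of the two central slices.
#'
#' @param stack A `height x width x L` array, or a `phantom_subject` plane.
#' @param n_slices 1, 3 or 5.
#' @param plane,subject_id Metadata attached to the resulting slab.
#' @return A [plane_slab()] with `n_slices` slices.
#' @export
select_slices <- function(stack, n_slices, plane = "axial",
                          subject_id = "unknown") {
  if (!n_slices %in% c(1L, 3L, 5L)) {
    abort("`n_slices` must be 1, 3 or 5.")
  }
  if (length(dim(stack)) != 3L) abort("`stack` must be a 3D array.")
  L <- dim(stack)[3]
  if (L < n_slices) {
    abort(sprintf("Subject %s: stack has %d slices, fewer than n_slices = %d.",
                  subject_id, L, n_slices))
  }
  mid0 <- middle_index(L)
  half <- n_slices %/% 2L
  idx0 <- (mid0 - half):(mid0 + half)
  if (idx0[1] < 0L || idx0[length(idx0)] > L - 1L) {
    abort(sprintf("Subject %s: slice window exceeds the stack.", subject_id))
  }
  plane_slab(stack[, , idx0 + 1L, drop = FALSE], plane, subject_id)
}

# Symmetric zero-padding up to at least `size` per spatial dimension;
# odd remainders pad one extra pixel on the bottom/right.
pad_to <- function(pixels, size) {
  d <- dim(pixels)
  ph <- max(0L, size - d[1]); pw <- max(0L, size - d[2])
  if (ph == 0L && pw == 0L) return(pixels)
  out <- array(0, dim = c(d[1] + ph, d[2] + pw, d[3]))
  r0 <- ph %/% 2L; c0 <- pw %/% 2L
  out[r0 + seq_len(d[1]), c0 + seq_len(d[2]), ] <- pixels
  out
}

#' Crop a slab to a square window
#'
#' Random mode draws one offset per slab, shared across slices (matching
#' augmentation applied to a multi-slice input); center mode is
#' deterministic. Inputs smaller than `size` are symmetrically zero-padded
#' first, so no subject is ever discarded for size.
#'
#' @param slab A [plane_slab()].
#' @param size Output side length in pixels.
#' @param mode `"center"` or `"random"`.
#' @param seed Seed used in random mode.
#' @return A `size x size` [plane_slab()].
#' @export
crop <- function(slab, size, mode = c("center", "random"), seed = 1L) {
  stopifnot(inherits(slab, "plane_slab"))
  mode <- match.arg(mode)
  px <- pad_to(slab$pixels, size)
  d <- dim(px)
  if (mode == "center") {
    r0 <- (d[1] - size) %/% 2L
    c0 <- (d[2] - size) %/% 2L
  } else {
    off <- with_seed(seed, c(sample.int(d[1] - size + 1L, 1L),
                             sample.int(d[2] - size + 1L, 1L))) - 1L
    r0 <- off[1]; c0 <- off[2]
  }
  plane_slab(px[r0 + seq_len(size), c0 + seq_len(size), , drop = FALSE],
             slab$plane, slab$subject_id)
}

#' Normalize a slab by its own sample mean and standard deviation
#'
#' Moments are computed jointly over all pixels of all slices, preserving
#' inter-slice intensity relations; the result has mean 0 and sd 1.
#' The operation is idempotent and invariant to positive affine rescaling
#' of the input.
#'
#' @param slab A [plane_slab()].
#' @return The normalized [plane_slab()].
#' @export
normalize_sample <- function(slab) {
  stopifnot(inherits(slab, "plane_slab"))
  x <- slab$pixels
  s <- sqrt(mean((x - mean(x))^2))  # population moments: {0,2} -> {-1,+1}
  if (!is.finite(s) || s == 0) {
    abort(sprintf("Subject %s: constant slab cannot be normalized.",
                  slab$subject_id))
  }
  slab$pixels <- (x - mean(x)) / s
  slab
}

#' Split a manifest into train / validation / test partitions
#'
#' Subject-level assignment: every plane of a subject shares its partition,
#' so no subject leaks across partitions. Counts follow the floor rule:
#' `floor(n * f_train)` train, `floor(n * f_val)` validation, remainder
#' test.
#'
#' @param manifest A manifest tibble with a `subject_id` column.
#' @param fractions Named or positional numeric triple (train, val, test)
#'   summing to 1.
#' @param seed Integer seed; the assignment is deterministic given it.
#' @return A tibble with columns `subject_id` and `partition` (factor with
#'   levels train/val/test); fractions and seed are kept as attributes.
#' @export
split_dataset <- function(manifest, fractions = c(0.70, 0.10, 0.20),
                          seed = 1L) {
  stopifnot(is.data.frame(manifest), "subject_id" %in% names(manifest))
  n <- nrow(manifest)
  if (n == 0L) abort("Empty manifest cannot be split.")
  if (abs(sum(fractions) - 1) > 1e-8 || length(fractions) != 3L) {
    abort("`fractions` must be three values summing to 1.")
  }
  n_train <- floor(n * fractions[1])
  n_val <- floor(n * fractions[2])
  ord <- with_seed(seed, sample.int(n))
  part <- rep("test", n)
  part[ord[seq_len(n_train)]] <- "train"
  if (n_val > 0) part[ord[n_train + seq_len(n_val)]] <- "val"
  out <- tibble::tibble(
    subject_id = manifest$subject_id,
    partition = factor(part, levels = c("train", "val", "test"))
  )
  attr(out, "fractions") <- unname(fractions)
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Split an external-site manifest for fine-tuning
#'
#' `floor(fraction * n)` subjects form the adaptation set used for
#' fine-tuning; the remainder is held out for testing. Mirrors the
#' 20% / 80% external-validation protocol.
#'
#' @param manifest A manifest tibble with a `subject_id` column.
#' @param fraction Adaptation fraction, default 0.20.
#' @param seed Integer seed.
#' @return A list with tibbles `adapt` and `test` (rows of `manifest`).
#' @export
finetune_split <- function(manifest, fraction = 0.20, seed = 1L) {
  stopifnot(is.data.frame(manifest), "subject_id" %in% names(manifest))
  n <- nrow(manifest)
  if (n < 5L) {
    abort("At least 5 subjects are required to form an adaptation set.")
  }
  if (fraction <= 0 || fraction >= 1) abort("`fraction` must be in (0, 1).")
  n_adapt <- floor(fraction * n)
  ord <- with_seed(seed, sample.int(n))
  idx <- ord[seq_len(n_adapt)]
  list(adapt = manifest[sort(idx), , drop = FALSE],
       test = manifest[sort(setdiff(seq_len(n), idx)), , drop = FALSE])
}

#' Prepare model-ready slabs for every subject of a manifest
#'
#' For each subject and requested plane: select the middle `n_slices`
#' slices, crop to `size` and normalize. Returns a tibble with one slab
#' list-column per plane, ready for [train_model()] and
#' [multiplane_predict()].
#'
#' @param manifest Manifest tibble with a `subject` list-column (in-memory
#'   phantoms) or per-plane path columns (see [read_volume()]).
#' @param planes Character vector of planes to prepare.
#' @param n_slices 1, 3 or 5.
#' @param size Crop side length.
#' @param crop_mode `"center"` or `"random"`.
#' @param seed Seed for random crops (one derived seed per subject).
#' @return A tibble `subject_id`, `age_days`, and `slab_<plane>`
#'   list-columns.
#' @export
prepare_dataset <- function(manifest, planes = phantom_planes, n_slices = 3L,
                            size = 64L, crop_mode = "center", seed = 1L) {
  stopifnot(is.data.frame(manifest))
  n <- nrow(manifest)
  seeds <- derive_seeds(seed, max(n, 1L))
  out <- tibble::tibble(subject_id = manifest$subject_id,
                        age_days = manifest$age_days)
  for (pl in planes) {
    out[[paste0("slab_", pl)]] <- purrr::map(seq_len(n), function(i) {
      stack <- if ("subject" %in% names(manifest)) {
        manifest$subject[[i]]$planes[[pl]]
      } else {
        read_volume(manifest[[paste0("path_", pl)]][i])
      }
      sl <- select_slices(stack, n_slices, plane = pl,
                          subject_id = manifest$subject_id[i])
      sl <- crop(sl, size, mode = crop_mode, seed = seeds[i])
      normalize_sample(sl)
    })
  }
  out
}
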