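#' Read an image stack from disk
#'
#' Accepts a NIfTI file (slices ordered along the third axis) or a
#' directory of PNG slices (ordered by the natural numeric order of their
#' file names). Integer-typed NIfTI volumes are rescaled to `[0, 1]` by
#' their type maximum (8- or 16-bit), matching the quantization applied at
#' export; float volumes are returned as stored. DICOM series are not
#' supported by this build and raise an explicit error.
#'
#' @param path A `.nii`/`.nii.gz` file or a directory of `.png` slices.
#' @return A numeric `height x width x n_slices` array.
#' @export
read_volume <- function(path) {
  if (dir.exists(path)) {
    pngs <- list.files(path, pattern = "\\.png$", full.names = TRUE)
    if (length(pngs) == 0L) {
      if (length(list.files(path, pattern = "\\.dcm$")) > 0L) {
        abort("DICOM series reading is not supported; convert to NIfTI or PNG.")
      }
      abort(sprintf("No PNG slices found in '%s'.", path))
    }
    num <- as.numeric(gsub("\\D", "", basename(pngs)))
    pngs <- pngs[order(num, basename(pngs))]
    slices <- purrr::map(pngs, function(p) {
      im <- png::readPNG(p)
      if (length(dim(im)) == 3L) im <- apply(im[, , 1:3, drop = FALSE], c(1, 2), mean)
      im
    })
    d <- dim(slices[[1]])
    if (!all(purrr::map_lgl(slices, ~ identical(dim(.x), d)))) {
      abort("PNG slices have inconsistent dimensions.")
    }
    array(unlist(slices), dim = c(d, length(slices)))
  } else if (grepl("\\.nii(\\.gz)?$", path)) {
    if (!file.exists(path)) abort(sprintf("File '%s' not found.", path))
    hdr <- RNifti::niftiHeader(path)
    img <- RNifti::readNifti(path)
    x <- array(as.numeric(img), dim = dim(img))
    if (length(dim(x)) == 2L) x <- array(x, dim = c(dim(x), 1L))
    if (dim(x)[3] < 1L) abort("Volume has no slices.")
    if (hdr$datatype == 512L) x <- x / 65535
    if (hdr$datatype == 2L) x <- x / 255
    x
  } else if (grepl("\\.(dcm|jpg|jpeg)$", path, ignore.case = TRUE)) {
    abort("DICOM/JPG inputs are not supported; convert to NIfTI or PNG.")
  } else {
    abort(sprintf("Unrecognized volume path '%s'.", path))
  }
}

#' Write a phantom subject's plane stacks to disk
#'
#' NIfTI stacks are quantized to 16-bit, PNG stacks to 8-bit; intensities
#' are clipped to `[0, 1]` before quantization.
#'
#' @param subject A `phantom_subject`.
#' @param dir Output directory (a `subject_id` subdirectory is created).
#' @param format `"nifti"` or `"png"`.
#' @return Named character vector of per-plane paths.
#' @export
write_subject <- function(subject, dir, format = c("nifti", "png")) {
  format <- match.arg(format)
  sdir <- file.path(dir, subject$subject_id)
  dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (pl in names(subject$planes)) {
    x <- clamp01(subject$planes[[pl]])
    if (format == "nifti") {
      p <- file.path(sdir, paste0(pl, ".nii.gz"))
      RNifti::writeNifti(round(x * 65535), p, datatype = "uint16")
    } else {
      p <- file.path(sdir, pl)
      dir.create(p, showWarnings = FALSE)
      for (s in seq_len(dim(x)[3])) {
        png::writePNG(round(x[, , s] * 255) / 255,
                      file.path(p, sprintf("s%03d.png", s)))
      }
    }
    paths[pl] <- p
  }
  paths
}

#' Read / write a cohort manifest
#'
#' Manifests are CSV files with a header: `subject_id` (unique),
#' `age_days` (> 0), `site_tag`, and per-plane path columns. A column
#' `age_weeks` is accepted on read and converted to days.
#'
#' @param path CSV path.
#' @return A tibble manifest.
#' @export
read_manifest <- function(path) {
  m <- readr::read_csv(path, show_col_types = FALSE)
  if ("age_weeks" %in% names(m) && !"age_days" %in% names(m)) {
    m$age_days <- m$age_weeks * 7
    m$age_weeks <- NULL
  }
  if (!all(c("subject_id", "age_days") %in% names(m))) {
    abort("Manifest needs `subject_id` and `age_days` columns.")
  }
  if (anyDuplicated(m$subject_id)) abort("Duplicate subject_id in manifest.")
  if (any(m$age_days <= 0)) abort("All `age_days` must be positive.")
  path_cols <- grep("^path_", names(m), value = TRUE)
  if (length(path_cols) == 0L) {
    abort("Manifest needs at least one `path_<plane>` column.")
  }
  m
}

#' @rdname read_manifest
#' @param manifest A manifest tibble (path columns only; in-memory
#'   `subject` list-columns are dropped).
#' @export
write_manifest <- function(manifest, path) {
  manifest$subject <- NULL
  readr::write_csv(manifest, path)
  invisible(path)
}

#' Read and validate a run configuration
#'
#' A single YAML document with optional sections `phantom`, `preprocess`,
#' `model`, `train`, `finetune` and `eval`; unknown sections are rejected
#' before any computation. Every random element must name its seed.
#'
#' @param path YAML file path.
#' @return A validated `ga_run_config` list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  allowed <- c("phantom", "preprocess", "model", "train", "finetune", "eval")
  extra <- setdiff(names(cfg), allowed)
  if (length(extra)) {
    abort(sprintf("Unknown config section(s): %s.",
                  paste(extra, collapse = ", ")))
  }
  structure(cfg, class = "ga_run_config")
}

#' Stable hash of a configuration object
#'
#' Changes iff any field changes; recorded in run logs so outputs can be
#' traced to their exact configuration.
#'
#' @param config Any list-like configuration.
#' @return A 32-character MD5 string.
#' @export
config_hash <- function(config) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  yaml::write_yaml(config, tf)
  unname(tools::md5sum(tf))
}
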