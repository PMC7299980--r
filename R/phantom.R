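#' Phantom subtraction-image specification
#'
#' Geometry and intensity parameters for a synthetic subtraction image: a
#' radially symmetric lesion blob added to a constant background with
#' additive Gaussian noise. The phantom is a statistical stand-in for a
#' CESM subtraction view, not a realistic mammogram: its purpose is that
#' the noiseless lesion maximum and background mean are analytic, so ROI
#' measurement can be validated exactly.
#'
#' @param width,height Image dimensions in pixels.
#' @param background_mean Constant background intensity (> 0), in raw
#'   intensity units.
#' @param background_sd Gaussian noise standard deviation; 0 gives a
#'   noiseless phantom.
#' @param center Lesion centre as `c(row, col)` (1-based pixel indices).
#' @param radius Lesion radius in pixels.
#' @param bit_depth Bits per pixel for file output (intensities must fit
#'   `[0, 2^bit_depth - 1]`).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(width = 128, height = 128,
                         background_mean = 1000, background_sd = 1,
                         center = c(height %/% 2 + 1, width %/% 2 + 1),
                         radius = 20, bit_depth = 16) {
  if (width <= 0 || height <= 0 || radius <= 0) {
    abort("Phantom dimensions and radius must be positive.",
          class = "cesmr_spec_error")
  }
  if (background_mean <= 0) {
    abort("`background_mean` must be > 0 (it is the CNR denominator).",
          class = "cesmr_spec_error")
  }
  if (background_sd < 0) {
    abort("`background_sd` must be >= 0.", class = "cesmr_spec_error")
  }
  structure(list(width = as.integer(width), height = as.integer(height),
                 background_mean = background_mean,
                 background_sd = background_sd,
                 center = center, radius = radius,
                 bit_depth = as.integer(bit_depth)),
            class = "phantom_spec")
}

# Renders one view: constant background + quartic blob of peak `amplitude`
# at the centre pixel + optional Gaussian noise. Returns image and masks.
render_view <- function(amplitude, spec) {
  max_val <- 2^spec$bit_depth - 1
  if (spec$background_mean + amplitude > max_val) {
    abort(sprintf("Peak intensity %.1f overflows %d-bit range [0, %d].",
                  spec$background_mean + amplitude, spec$bit_depth, max_val),
          class = "cesmr_render_error")
  }
  rows <- matrix(seq_len(spec$height), spec$height, spec$width)
  cols <- matrix(seq_len(spec$width), spec$height, spec$width, byrow = TRUE)
  d <- sqrt((rows - spec$center[1])^2 + (cols - spec$center[2])^2)
  blob <- amplitude * pmax(1 - (d / spec$radius)^2, 0)^2
  dim(blob) <- dim(d)
  img <- spec$background_mean + blob
  if (spec$background_sd > 0) {
    img <- img + rnorm(length(img), sd = spec$background_sd)
    img <- pmin(pmax(img, 0), max_val)
  }
  list(image = img,
       lesion = d <= spec$radius,
       background = d >= spec$radius + 8)
}

#' Render a pair of phantom subtraction views with known CNR targets
#'
#' Builds the two sequential projections (CC then MLO by default) of one
#' synthetic lesion so that ROI measurement with [measure_roi()] recovers
#' the requested CNRs: the lesion blob's peak amplitude is
#' `target * background_mean`, hence in the noiseless limit
#' `(Sa - Sb)/Sb` equals the target exactly. With the default noise level
#' measured CNRs stay within about 0.3 percentage points of the targets.
#'
#' @param target_cnr1,target_cnr2 Non-negative CNR targets for the former
#'   and latter projection, as dimensionless ratios (0.10 = 10%).
#' @param spec A [phantom_spec()].
#' @param seed Integer seed for the noise draw.
#' @param views Character vector of two view labels, former first.
#' @param times Acquisition times (seconds since injection), former first;
#'   must be strictly increasing.
#' @return A list of class `cesm_phantom_pair` with element `views`, a list
#'   of two lists each holding `image` (numeric matrix), `lesion` and
#'   `background` (logical masks), `view`, `time`.
#' @examples
#' pair <- render_phantom_pair(0.10, 0.05, phantom_spec(background_sd = 0))
#' with(pair$views[[1]], measure_roi(image, lesion, background))
#' @export
render_phantom_pair <- function(target_cnr1, target_cnr2,
                                spec = phantom_spec(), seed = 1L,
                                views = c("CC", "MLO"),
                                times = c(120, 224)) {
  if (target_cnr1 < 0 || target_cnr2 < 0) {
    abort("CNR targets must be >= 0.", class = "cesmr_argument_error")
  }
  if (diff(times) <= 0) {
    abort("`times` must be strictly increasing (former view first).",
          class = "cesmr_argument_error")
  }
  targets <- c(target_cnr1, target_cnr2)
  out <- withr::with_seed(seed, {
    purrr::map(1:2, function(i) {
      v <- render_view(targets[i] * spec$background_mean, spec)
      v$view <- views[i]
      v$time <- times[i]
      v
    })
  })
  structure(list(views = out, targets = targets, spec = spec, seed = seed),
            class = "cesm_phantom_pair")
}

#' Write phantom pairs to disk with a JSON manifest
#'
#' Writes each view as a 16-bit grayscale TIFF and its ROI masks as 8-bit
#' TIFFs (nonzero = inside), plus a `manifest.json` linking lesion id to
#' view files, ROI files and acquisition timestamps.
#'
#' @param pairs Named list of [render_phantom_pair()] results; names are
#'   lesion ids.
#' @param dir Output directory (created if needed).
#' @return Path to the manifest file, invisibly.
#' @export
write_phantom_set <- function(pairs, dir) {
  if (is.null(names(pairs)) || any(names(pairs) == "")) {
    abort("`pairs` must be a named list (names are lesion ids).",
          class = "cesmr_argument_error")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- purrr::imap(pairs, function(pair, id) {
    max_val <- 2^pair$spec$bit_depth - 1
    views <- purrr::imap(pair$views, function(v, i) {
      stem <- sprintf("%s_view%d_%s", id, i, v$view)
      files <- list(image = paste0(stem, ".tif"),
                    lesion_mask = paste0(stem, "_lesion.tif"),
                    background_mask = paste0(stem, "_background.tif"))
      tiff::writeTIFF(round(v$image) / max_val, file.path(dir, files$image),
                      bits.per.sample = 16L)
      tiff::writeTIFF(v$lesion * 1, file.path(dir, files$lesion_mask),
                      bits.per.sample = 8L)
      tiff::writeTIFF(v$background * 1, file.path(dir, files$background_mask),
                      bits.per.sample = 8L)
      c(list(view = v$view, time = v$time), files)
    })
    list(lesion_id = id, bit_depth = pair$spec$bit_depth, views = views)
  })
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(unname(manifest), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a phantom set back from its manifest
#'
#' @param dir Directory containing `manifest.json` and the TIFF files
#'   written by [write_phantom_set()].
#' @return A named list of per-lesion view lists mirroring the structure of
#'   [render_phantom_pair()]'s `views` element (image matrices on the raw
#'   integer intensity scale, logical masks, view label, time).
#' @export
read_phantom_set <- function(dir) {
  path <- file.path(dir, "manifest.json")
  if (!file.exists(path)) {
    abort(paste0("No manifest.json under ", dir), class = "cesmr_io_error")
  }
  manifest <- jsonlite::read_json(path)
  out <- purrr::map(manifest, function(entry) {
    max_val <- 2^entry$bit_depth - 1
    purrr::map(entry$views, function(v) {
      list(image = round(tiff::readTIFF(file.path(dir, v$image)) * max_val),
           lesion = tiff::readTIFF(file.path(dir, v$lesion_mask)) > 0,
           background = tiff::readTIFF(file.path(dir, v$background_mask)) > 0,
           view = v$view, time = v$time)
    })
  })
  stats::setNames(out, purrr::map_chr(manifest, "lesion_id"))
}
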