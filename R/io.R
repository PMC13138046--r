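# Delimited-text and TIFF plumbing. Calibration (pixel size, z-step) always
# comes from an explicit argument or a sidecar YAML, never silently from
# TIFF tags.

detect_delim <- function(path) {
  first <- readLines(path, n = 1)
  if (lengths(regmatches(first, gregexpr("\t", first))) > 0) "\t" else ","
}

read_sweep_table <- function(path, required) {
  check_that(file.exists(path), "io", "file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = detect_delim(path),
                           check.names = FALSE)
  missing <- setdiff(required, names(tab))
  check_that(length(missing) == 0, "io", "missing column(s) in ", path, ": ",
             paste(missing, collapse = ", "))
  tab
}

#' Read a rheometer time sweep from delimited text
#'
#' Expects a header row with columns `time_s`, `G_prime_Pa`, `G_loss_Pa`;
#' comma or tab delimited (auto-detected).
#'
#' @param path File path.
#' @return A [time_sweep()].
#' @export
read_time_sweep <- function(path) {
  tab <- read_sweep_table(path, c("time_s", "G_prime_Pa", "G_loss_Pa"))
  time_sweep(tab$time_s, tab$G_prime_Pa, tab$G_loss_Pa)
}

#' Read an endpoint frequency sweep from delimited text
#'
#' Expects a header row with columns `freq_Hz`, `G_prime_Pa`, `G_loss_Pa`.
#'
#' @param path File path.
#' @return A [frequency_sweep()].
#' @export
read_frequency_sweep <- function(path) {
  tab <- read_sweep_table(path, c("freq_Hz", "G_prime_Pa", "G_loss_Pa"))
  ord <- order(tab$freq_Hz)
  frequency_sweep(tab$freq_Hz[ord], tab$G_prime_Pa[ord], tab$G_loss_Pa[ord])
}

#' Write a time sweep to delimited text
#'
#' @param sweep A [time_sweep()].
#' @param path Output path (CSV).
#' @export
write_time_sweep <- function(sweep, path) {
  utils::write.csv(data.frame(time_s = sweep$t, G_prime_Pa = sweep$gprime,
                              G_loss_Pa = sweep$gdoubleprime),
                   path, row.names = FALSE)
  invisible(path)
}

#' Write a frequency sweep to delimited text
#'
#' @param sweep A [frequency_sweep()].
#' @param path Output path (CSV).
#' @export
write_frequency_sweep <- function(sweep, path) {
  utils::write.csv(data.frame(freq_Hz = sweep$f, G_prime_Pa = sweep$gprime,
                              G_loss_Pa = sweep$gdoubleprime),
                   path, row.names = FALSE)
  invisible(path)
}

channel_to_tiff <- function(arr, path) {
  rng <- range(arr)
  scale <- if (diff(rng) == 0) 1 else diff(rng)
  pages <- lapply(seq_len(dim(arr)[3]), function(z) {
    (arr[, , z] - rng[1]) / scale
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  c(min = rng[1], scale = scale)
}

tiff_to_channel <- function(path, min, scale) {
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- array(0, c(dim(pages[[1]]), length(pages)))
  for (z in seq_along(pages)) arr[, , z] <- pages[[z]] * scale + min
  arr
}

#' Write a fibril stack as multi-page TIFF plus sidecar YAML
#'
#' Channels go to `<prefix>_reflectance.tif` and (when present)
#' `<prefix>_fluorescence.tif`, normalised to [0, 1]; the sidecar
#' `<prefix>.yaml` records the calibration and the normalisation so that
#' [read_stack()] restores intensities exactly. Ground truth, when carried
#' by the stack, is written to `<prefix>_truth.json` with coordinates in
#' micrometres.
#'
#' @param stack A `fibril_stack`.
#' @param prefix Output path prefix.
#' @param placement Optional `particle_placement` whose true centroids are
#'   included in the truth JSON.
#' @return The sidecar path, invisibly.
#' @export
write_stack <- function(stack, prefix, placement = NULL) {
  meta <- list(pixel_size_um = stack$pixel_size, z_step_um = stack$z_step,
               n_slices = dim(stack$reflectance)[3],
               shape_px = dim(stack$reflectance)[1:2],
               channel_order = "reflectance, fluorescence")
  nm <- channel_to_tiff(stack$reflectance, paste0(prefix, "_reflectance.tif"))
  meta$reflectance <- list(min = unname(nm["min"]), scale = unname(nm["scale"]))
  if (!is.null(stack$fluorescence)) {
    nm <- channel_to_tiff(stack$fluorescence,
                          paste0(prefix, "_fluorescence.tif"))
    meta$fluorescence <- list(min = unname(nm["min"]),
                              scale = unname(nm["scale"]))
  }
  yaml::write_yaml(meta, paste0(prefix, ".yaml"))
  if (!is.null(stack$truth)) {
    ps <- stack$pixel_size
    truth <- list(
      centerlines_um = lapply(stack$truth$centerlines, function(s) {
        if (nrow(s)) unname(as.matrix(s)) * ps else list()
      }),
      junctions_um = lapply(stack$truth$junctions, function(j) {
        if (nrow(j)) list(x = j$x * ps, y = j$y * ps) else list()
      })
    )
    if (!is.null(placement) && !is.null(placement$true_centroids)) {
      tc <- placement$true_centroids
      truth$centroids <- list(x_um = tc$x * ps, y_um = tc$y * ps,
                              slice = tc$slice)
    }
    jsonlite::write_json(truth, paste0(prefix, "_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(paste0(prefix, ".yaml"))
}

#' Read a fibril stack written by [write_stack()]
#'
#' @param prefix Path prefix used at write time.
#' @return A `fibril_stack` (without ground truth).
#' @export
read_stack <- function(prefix) {
  side <- paste0(prefix, ".yaml")
  check_that(file.exists(side), "io", "sidecar not found: ", side)
  meta <- yaml::read_yaml(side)
  refl <- tiff_to_channel(paste0(prefix, "_reflectance.tif"),
                          meta$reflectance$min, meta$reflectance$scale)
  fl <- NULL
  if (!is.null(meta$fluorescence)) {
    fl <- tiff_to_channel(paste0(prefix, "_fluorescence.tif"),
                          meta$fluorescence$min, meta$fluorescence$scale)
  }
  structure(list(reflectance = refl, fluorescence = fl,
                 pixel_size = meta$pixel_size_um, z_step = meta$z_step_um,
                 truth = NULL),
            class = "fibril_stack")
}
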