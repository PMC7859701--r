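#' Write a simulated scene to disk
#'
#' Each channel is written as a (multi-page, for z-stacks) 32-bit float
#' TIFF, scaled into \[0, 1\], with a JSON sidecar `scene.json` carrying
#' the pixel calibration, per-channel intensity scale factors, the
#' ground-truth manifest and the scene layout.
#'
#' @param scene a `tz_scene`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir) {
  check_that(inherits(scene, "tz_scene"), "scene must be a tz_scene")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(modality = scene$truth$modality,
               pixel_size_um = scene$truth$pixel_size_um,
               z_step_um = scene$truth$z_step_um,
               channels = list(),
               truth = scene$truth[setdiff(names(scene$truth), "modality")],
               layout = scene$layout)
  for (nm in names(scene$channels)) {
    ch <- scene$channels[[nm]]
    sc <- max(1, max(if (inherits(ch, "plane_image")) ch$pixels else ch$voxels))
    path <- file.path(dir, paste0(nm, ".tif"))
    if (inherits(ch, "plane_image")) {
      tiff::writeTIFF(ch$pixels / sc, path, bits.per.sample = 32)
    } else {
      pages <- lapply(seq_len(dim(ch$voxels)[3]),
                      function(k) ch$voxels[, , k] / sc)
      tiff::writeTIFF(pages, path, bits.per.sample = 32)
    }
    meta$channels[[nm]] <- list(file = basename(path), scale = sc)
  }
  jsonlite::write_json(meta, file.path(dir, "scene.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a scene written by [write_scene]
#'
#' @param dir directory containing the channel TIFFs and `scene.json`.
#' @return A `tz_scene`.
#' @export
read_scene <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "scene.json"),
                              simplifyVector = TRUE)
  channels <- list()
  for (nm in names(meta$channels)) {
    info <- meta$channels[[nm]]
    pages <- tiff::readTIFF(file.path(dir, info$file), all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    pages <- lapply(pages, function(p) p * info$scale)
    channels[[nm]] <- if (length(pages) == 1) {
      plane_image(pages[[1]], meta$pixel_size_um, channel = nm)
    } else {
      volume_stack(array(unlist(pages),
                         dim = c(dim(pages[[1]]), length(pages))),
                   meta$pixel_size_um, meta$z_step_um, channel = nm)
    }
  }
  truth <- do.call(scene_truth, c(list(modality = meta$modality),
                                  meta$truth[!vapply(meta$truth, is.null, TRUE)]))
  layout <- meta$layout
  structure(list(channels = channels, truth = truth, layout = layout),
            class = "tz_scene")
}
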