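#' Signed-distance geometry from a binary segmentation mask
#'
#' Converts a binary voxel mask (nonzero = fluid lumen) into a level-set
#' geometry: the mask is reduced to its largest 6-connected fluid component,
#' and the signed distance is the exact Euclidean distance to the nearest
#' fluid voxel minus the distance to the nearest solid voxel (negative in
#' fluid), honouring anisotropic spacing.
#'
#' @param mask logical/integer 3-D array; nonzero marks lumen voxels.
#' @param spacing voxel size triple (m); anisotropy is honoured.
#' @param origin lower corner of the voxel grid (m).
#' @param patch_faces character vector of domain faces where the lumen is
#'   open and a patch should be attached: subset of `"zlo"`, `"zhi"`.
#' @param extension_cells patch cut-plane depth (cells) from those faces.
#' @return A `levelset_geometry`.
#' @export
levelset_from_mask <- function(mask, spacing, origin = c(0, 0, 0),
                               patch_faces = character(),
                               extension_cells = 6) {
  d <- dim(mask)
  if (length(d) != 3) stop("mask must be a 3-D array", call. = FALSE)
  m <- as.integer(mask != 0)
  if (!any(m == 1)) stop("input error: empty mask (no fluid)", call. = FALSE)
  if (all(m == 1)) stop("input error: all-fluid mask (no wall)", call. = FALSE)
  spacing <- rep_len(as.numeric(spacing), 3)
  m <- largest_component_cpp(m, d)
  phi <- edt_signed_cpp(m, d, spacing)
  dim(phi) <- d
  grid <- cartesian_grid(d, spacing, origin)
  geom <- levelset_geometry(grid, phi)
  for (f in patch_faces) {
    if (f == "zlo") {
      k <- extension_cells + 1L
      geom <- add_patch(geom, "zlo", axis = -3L, k_ct = k,
                        mask2d = geom$phi[, , k] < 0)
    } else if (f == "zhi") {
      k <- d[3] - extension_cells
      geom <- add_patch(geom, "zhi", axis = 3L, k_ct = k,
                        mask2d = geom$phi[, , k] < 0)
    } else {
      stop("unsupported patch face: ", f, call. = FALSE)
    }
  }
  geom
}

#' Write a binary voxel mask as raw bytes plus a JSON sidecar
#'
#' Emulates a segmentation export: little-endian uint8 voxel stream in
#' column-major (x fastest) order, with dims/spacing/origin in
#' `<prefix>.json`.
#'
#' @param mask logical/integer 3-D array.
#' @param spacing,origin voxel size and lower corner (m).
#' @param prefix output path prefix; writes `<prefix>.raw` and
#'   `<prefix>.json`.
#' @export
write_mask_raw <- function(mask, spacing, origin = c(0, 0, 0), prefix) {
  d <- dim(mask)
  con <- file(paste0(prefix, ".raw"), "wb")
  writeBin(as.raw(as.integer(mask != 0)), con)
  close(con)
  meta <- list(dims = as.integer(d),
               spacing_m = rep_len(as.numeric(spacing), 3),
               origin_m = rep_len(as.numeric(origin), 3),
               dtype = "uint8", order = "column-major")
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' Read a raw voxel mask written by [write_mask_raw()]
#'
#' @param prefix path prefix of the `.raw`/`.json` pair.
#' @return List with `mask` (integer array), `spacing`, `origin`.
#' @export
read_mask_raw <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  d <- as.integer(meta$dims)
  con <- file(paste0(prefix, ".raw"), "rb")
  on.exit(close(con))
  v <- readBin(con, "raw", n = prod(d))
  if (length(v) != prod(d))
    stop("format error: raw mask size does not match sidecar dims",
         call. = FALSE)
  mask <- array(as.integer(v), d)
  list(mask = mask, spacing = meta$spacing_m, origin = meta$origin_m)
}
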