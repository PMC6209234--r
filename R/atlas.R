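#' Metadata for the 34-component resting-state functional atlas
#'
#' The reference atlas is assembled from four published local parcellations:
#' 10 parietal components (5 superior parietal lobule, 5 inferior parietal
#' lobule), 2 temporoparietal-junction components, 12 ventral frontal
#' components and 10 dorsal frontal components. Each row carries the
#' component's short code, its sub-atlas and a free-text anatomical label.
#'
#' @return a data frame with columns `id`, `sub_atlas`, `component`,
#'   `anatomical_area` (34 rows).
#' @export
atlas_table <- function() {
  path <- system.file("extdata", "atlas_components.tsv", package = "asdcad",
                      mustWork = TRUE)
  read_tsv(path)
}

#' Assemble an atlas registry from a label volume and metadata
#'
#' Binds component metadata to the voxel masks of an integer label volume.
#' Label value 0 is background; values `1..n` must each be present and each
#' metadata row must describe exactly one of them.
#'
#' @param label_volume integer 3D array with values `0..n`.
#' @param metadata data frame with columns `id`, `component` and optionally
#'   `sub_atlas`, `anatomical_area`; defaults to [atlas_table()].
#' @return an object of class `atlas_registry`: list of components, each with
#'   `id`, `name`, `sub_atlas`, `anatomical_area` and `mask` (voxel indices),
#'   plus the label volume and grid shape.
#' @export
build_registry <- function(label_volume, metadata = atlas_table()) {
  if (!all(c("id", "component") %in% names(metadata))) {
    stop("metadata must have columns 'id' and 'component'", call. = FALSE)
  }
  ids <- sort(metadata$id)
  if (!identical(ids, seq_along(ids))) {
    stop("metadata ids must be 1..n with no gaps or duplicates", call. = FALSE)
  }
  if (anyDuplicated(metadata$component)) {
    stop("duplicate component names in metadata", call. = FALSE)
  }
  metadata <- metadata[order(metadata$id), , drop = FALSE]
  components <- lapply(seq_along(ids), function(i) {
    mask <- which(label_volume == metadata$id[i])
    if (!length(mask)) {
      stop(sprintf("label %d ('%s') is empty in the label volume",
                   metadata$id[i], metadata$component[i]), call. = FALSE)
    }
    list(id = metadata$id[i], name = metadata$component[i],
         sub_atlas = if ("sub_atlas" %in% names(metadata))
           metadata$sub_atlas[i] else NA_character_,
         anatomical_area = if ("anatomical_area" %in% names(metadata))
           metadata$anatomical_area[i] else NA_character_,
         mask = mask)
  })
  structure(list(components = components,
                 label_volume = label_volume,
                 grid_shape = dim(label_volume)),
            class = "atlas_registry")
}

#' @export
print.atlas_registry <- function(x, ...) {
  subs <- vapply(x$components, `[[`, character(1), "sub_atlas")
  cat(sprintf("Atlas registry: %d components on grid %s\n",
              length(x$components), paste(x$grid_shape, collapse = "x")))
  if (!all(is.na(subs))) {
    tab <- table(subs)
    cat("  sub-atlases:",
        paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
length.atlas_registry <- function(x) length(x$components)

#' Generic metadata for a phantom atlas
#'
#' Convenience metadata table for synthetic label volumes whose areas have no
#' anatomical identity.
#'
#' @param n_areas number of areas.
#' @return a data frame usable as `metadata` in [build_registry()].
#' @export
phantom_atlas_table <- function(n_areas) {
  data.frame(id = seq_len(n_areas),
             sub_atlas = "phantom",
             component = sprintf("A%02d", seq_len(n_areas)),
             anatomical_area = sprintf("synthetic area %d", seq_len(n_areas)))
}

#' Match decomposition spatial maps to atlas components
#'
#' For every atlas component, computes the Pearson correlation between the
#' component's binary mask and each spatial map (both z-scored over the
#' in-brain voxels) and selects the map with the maximal correlation
#' magnitude (decomposition maps carry an arbitrary sign). The same map may
#' serve several components; ties break toward the lowest map index, and the
#' recorded correlation keeps its sign (no flipping). Matching is invariant
#' to positive rescaling of any map.
#'
#' @param spatial_maps numeric matrix, maps x voxels (e.g. the `sources` of a
#'   fitted [fit_group_pica()] model), on the registry's voxel grid.
#' @param registry an [build_registry()] result.
#' @param in_brain voxel indices over which to correlate; default all voxels
#'   with a nonzero atlas label.
#' @return an object of class `component_assignment`: data frame with columns
#'   `area_id`, `component`, `map_index`, `correlation`.
#' @export
match_components <- function(spatial_maps, registry, in_brain = NULL) {
  stopifnot(inherits(registry, "atlas_registry"))
  if (is.vector(spatial_maps)) spatial_maps <- matrix(spatial_maps, nrow = 1)
  if (ncol(spatial_maps) != prod(registry$grid_shape)) {
    stop("spatial maps and atlas are not on the same voxel grid",
         call. = FALSE)
  }
  if (nrow(spatial_maps) < 1) stop("need at least one spatial map", call. = FALSE)
  if (is.null(in_brain)) in_brain <- which(registry$label_volume != 0)
  z <- function(v) {
    s <- stats::sd(v)
    if (s == 0) return(NULL)
    (v - mean(v)) / s
  }
  zmaps <- lapply(seq_len(nrow(spatial_maps)), function(i) {
    z(spatial_maps[i, in_brain])
  })
  usable <- !vapply(zmaps, is.null, logical(1))
  if (!all(usable)) {
    warning(sprintf("excluding %d zero-variance map(s): %s",
                    sum(!usable), paste(which(!usable), collapse = ", ")))
  }
  if (!any(usable)) stop("all spatial maps have zero variance", call. = FALSE)
  m <- length(in_brain)
  rows <- lapply(registry$components, function(comp) {
    mask <- z(as.numeric(in_brain %in% comp$mask))
    if (is.null(mask)) {
      stop(sprintf("component '%s' has zero variance over the in-brain voxels",
                   comp$name), call. = FALSE)
    }
    cors <- rep(0, nrow(spatial_maps))
    for (i in which(usable)) {
      cors[i] <- sum(mask * zmaps[[i]]) / (m - 1)
    }
    # selection is by correlation magnitude (decomposition maps carry an
    # arbitrary sign); the recorded value keeps the sign
    best <- which.max(abs(cors))  # first (lowest) index on ties
    data.frame(area_id = comp$id, component = comp$name,
               map_index = best, correlation = cors[best])
  })
  out <- do.call(rbind, rows)
  class(out) <- c("component_assignment", "data.frame")
  out
}

#' @export
print.component_assignment <- function(x, ...) {
  cat(sprintf("Component assignment: %d atlas areas -> %d distinct maps\n",
              nrow(x), length(unique(x$map_index))))
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}
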