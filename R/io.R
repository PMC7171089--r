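#' Read a volume from NIfTI or multi-page TIFF
#'
#' NIfTI voxel spacing is taken from the header `pixdim` and interpreted in
#' micrometres (the package's working unit). A TIFF stack must be accompanied
#' by a JSON sidecar `<path>.json` holding at least `spacing_um` (length 3);
#' a stack without spacing metadata is an error, never silently defaulted.
#'
#' @param path file path ending in `.nii`, `.nii.gz`, `.tif` or `.tiff`.
#' @return a [volume()] (axis order x, y, z; z = sectioning axis).
#' @export
read_volume <- function(path) {
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::readNifti(path)
    arr <- as.array(img)
    if (length(dim(arr)) != 3L)
      stop("expected a 3D NIfTI volume, got rank ", length(dim(arr)),
           call. = FALSE)
    sp <- abs(RNifti::pixdim(img))[1:3]
    if (any(!is.finite(sp)) || any(sp <= 0))
      stop("NIfTI header carries no usable voxel spacing (pixdim <= 0)",
           call. = FALSE)
    return(volume(arr, spacing = sp))
  }
  if (grepl("\\.tiff?$", path)) {
    sidecar <- paste0(path, ".json")
    if (!file.exists(sidecar))
      stop("TIFF stack has no spacing sidecar (expected ", sidecar, ")",
           call. = FALSE)
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (is.null(meta$spacing_um) || length(meta$spacing_um) != 3)
      stop("sidecar must contain `spacing_um` with 3 values", call. = FALSE)
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    d <- c(dim(pages[[1]])[2], dim(pages[[1]])[1], length(pages))
    arr <- array(0, d)
    for (k in seq_along(pages)) arr[, , k] <- t(pages[[k]])
    scale <- if (is.null(meta$intensity_scale)) 1 else meta$intensity_scale
    v <- volume(arr * scale, spacing = as.numeric(meta$spacing_um))
    return(v)
  }
  stop("unrecognised volume format: ", path, call. = FALSE)
}

#' Write a volume to NIfTI or multi-page TIFF
#'
#' NIfTI stores arbitrary numeric data losslessly (spacing in the header
#' `pixdim`, micrometres). The TIFF writer stores nonnegative integer-valued
#' data as 16-bit pages with a JSON sidecar carrying `spacing_um`; use NIfTI
#' for floating-point intensities.
#'
#' @param v a [volume()].
#' @param path destination ending in `.nii`, `.nii.gz`, `.tif` or `.tiff`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  stopifnot(inherits(v, "volume"))
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::asNifti(v$data * 1)
    RNifti::pixdim(img) <- v$spacing
    RNifti::writeNifti(img, path)
    return(invisible(path))
  }
  if (grepl("\\.tiff?$", path)) {
    dat <- v$data
    if (any(dat %% 1 != 0) || any(dat < 0) || max(dat) > 65535)
      stop("TIFF writer handles nonnegative integers <= 65535; use NIfTI ",
           "for floating-point volumes", call. = FALSE)
    pages <- lapply(seq_len(dim(dat)[3]),
                    function(k) t(dat[, , k]) / 65535)
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
    jsonlite::write_json(list(spacing_um = v$spacing, origin_um = v$origin),
                         paste0(path, ".json"), auto_unbox = FALSE,
                         digits = NA)
    return(invisible(path))
  }
  stop("unrecognised volume format: ", path, call. = FALSE)
}

#' Read / write a detected-cell table
#'
#' Cell tables are TSV with columns `x_um`, `y_um`, `z_um`, `section_index`
#' (0-based index of the 2D section the cell was detected in) and `channel`.
#'
#' @param path TSV path.
#' @return tibble with the five columns above.
#' @export
read_cells <- function(path) {
  tb <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("x_um", "y_um", "z_um", "section_index", "channel")
  missing <- setdiff(req, names(tb))
  if (length(missing))
    stop("cell table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(tb$x_um) | !is.finite(tb$y_um) | !is.finite(tb$z_um)))
    stop("cell coordinates must be finite", call. = FALSE)
  if (any(tb$section_index < 0))
    stop("section_index must be >= 0", call. = FALSE)
  tb
}

#' @rdname read_cells
#' @param cells tibble of cells.
#' @export
write_cells <- function(cells, path) {
  readr::write_tsv(cells, path, progress = FALSE)
  invisible(path)
}

#' Read a region ontology from JSON
#'
#' The ontology is a rooted tree of anatomical regions, each node
#' `{id, acronym, name, parent_id}` with `parent_id = null` at the single
#' root. Ids must be unique, every parent must exist, and the graph must be
#' acyclic.
#'
#' @param path JSON file holding a list of node objects.
#' @return tibble with columns `id`, `acronym`, `name`, `parent_id` (NA at
#'   the root) and `depth` (root = 0).
#' @export
read_ontology <- function(path) {
  nodes <- jsonlite::read_json(path, simplifyVector = TRUE)
  ont <- tibble::tibble(
    id = as.integer(nodes$id),
    acronym = as.character(nodes$acronym),
    name = as.character(nodes$name),
    parent_id = suppressWarnings(as.integer(nodes$parent_id))
  )
  validate_ontology(ont)
}

#' @rdname read_ontology
#' @param ontology ontology tibble.
#' @export
write_ontology <- function(ontology, path) {
  jsonlite::write_json(
    ontology[, c("id", "acronym", "name", "parent_id")], path,
    auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Validate an ontology tibble and compute node depths
#' @param ont tibble with id, acronym, name, parent_id.
#' @return the tibble with a `depth` column, nodes in the input order.
#' @export
validate_ontology <- function(ont) {
  if (anyDuplicated(ont$id))
    stop("duplicate ontology ids: ",
         paste(unique(ont$id[duplicated(ont$id)]), collapse = ", "),
         call. = FALSE)
  roots <- which(is.na(ont$parent_id))
  if (length(roots) != 1L)
    stop("ontology must have exactly one root (found ", length(roots), ")",
         call. = FALSE)
  unknown <- setdiff(ont$parent_id[!is.na(ont$parent_id)], ont$id)
  if (length(unknown))
    stop("parent_id refers to unknown node(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  # depth by repeated parent hops; a cycle never reaches the root
  depth <- rep(NA_integer_, nrow(ont))
  depth[roots] <- 0L
  parent_pos <- match(ont$parent_id, ont$id)
  for (step in seq_len(nrow(ont))) {
    todo <- which(is.na(depth) & !is.na(depth[parent_pos]))
    if (!length(todo)) break
    depth[todo] <- depth[parent_pos[todo]] + 1L
  }
  if (anyNA(depth))
    stop("ontology contains a cycle or unreachable node(s): ids ",
         paste(ont$id[is.na(depth)], collapse = ", "), call. = FALSE)
  ont$depth <- depth
  ont
}

#' All descendant ids of a node (excluding the node itself)
#' @param ontology validated ontology tibble.
#' @param id node id.
#' @return integer vector of descendant ids.
#' @export
ontology_descendants <- function(ontology, id) {
  out <- integer(0)
  frontier <- id
  repeat {
    kids <- ontology$id[!is.na(ontology$parent_id) &
                          ontology$parent_id %in% frontier]
    if (!length(kids)) break
    out <- c(out, kids)
    frontier <- kids
  }
  out
}
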