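#' Detect cells in a 2D section
#'
#' Deliberately simple threshold-plus-connected-components detector so the
#' pipeline can run end to end from images: pixels above `threshold` are
#' grouped into connected components (EBImage), components within the area
#' bounds are reported at their centroids. Real studies would plug a trained
#' detector in behind the same cell-table interface.
#'
#' @param section numeric 2D matrix (x, y), one imaging section.
#' @param threshold intensity threshold; a threshold outside the image's
#'   dynamic range yields a warning and an empty result.
#' @param min_area,max_area component area bounds in pixels.
#' @param spacing_um pixel spacing (x, y) in um, default `c(20, 20)`.
#' @param section_index 0-based index of this section (sets `z_um` via
#'   `section_spacing_um`).
#' @param section_spacing_um section step in um, default 50.
#' @param channel channel id stored with each cell.
#' @return cell tibble (`x_um`, `y_um`, `z_um`, `section_index`, `channel`,
#'   `area_px`).
#' @export
detect_cells_2d <- function(section, threshold, min_area = 1,
                            max_area = Inf, spacing_um = c(20, 20),
                            section_index = 0L, section_spacing_um = 50,
                            channel = 1L) {
  stopifnot(is.matrix(section))
  empty <- tibble::tibble(x_um = numeric(0), y_um = numeric(0),
                          z_um = numeric(0), section_index = integer(0),
                          channel = integer(0), area_px = numeric(0))
  rng <- range(section)
  if (threshold < rng[1] || threshold > rng[2]) {
    warning("threshold ", threshold, " outside image dynamic range [",
            rng[1], ", ", rng[2], "]", call. = FALSE)
    return(empty)
  }
  mask <- EBImage::bwlabel(section > threshold)
  n <- max(mask)
  if (n == 0) return(empty)
  lab <- as.vector(mask)
  keep <- lab > 0
  area <- tabulate(lab[keep], nbins = n)
  d <- dim(section)
  ix <- rep.int(seq_len(d[1]), d[2])
  iy <- rep(seq_len(d[2]), each = d[1])
  cx <- rowsum(ix[keep], lab[keep])[, 1] / area
  cy <- rowsum(iy[keep], lab[keep])[, 1] / area
  ok <- area >= min_area & area <= max_area
  tibble::tibble(
    x_um = (cx[ok] - 0.5) * spacing_um[1],
    y_um = (cy[ok] - 0.5) * spacing_um[2],
    z_um = (section_index + 0.5) * section_spacing_um,
    section_index = as.integer(section_index),
    channel = as.integer(channel),
    area_px = area[ok])
}

#' Detect cells through a volume, section by section
#'
#' @param v a [volume()]; each z-plane is treated as one section.
#' @inheritParams detect_cells_2d
#' @return combined cell tibble across sections.
#' @export
detect_cells <- function(v, threshold, min_area = 1, max_area = Inf,
                         channel = 1L) {
  d <- dim(v$data)
  out <- lapply(seq_len(d[3]) - 1L, function(k) {
    sec <- v$data[, , k + 1L]
    rng <- range(sec)
    if (threshold < rng[1] || threshold > rng[2]) return(NULL)
    detect_cells_2d(sec, threshold, min_area, max_area,
                    spacing_um = v$spacing[1:2], section_index = k,
                    section_spacing_um = v$spacing[3], channel = channel)
  })
  dplyr::bind_rows(out)
}
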