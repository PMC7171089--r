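#' Left-right symmetry score of a volume
#'
#' Pearson correlation between a volume and its mirror about the mid-x
#' plane: 1 for a perfectly mirror-symmetric brain, -1 for a mirror-negated
#' one. Used to pick the best reference subject when building an average
#' template (higher is better-framed).
#'
#' @param v a [volume()].
#' @return score in `[-1, 1]`.
#' @export
symmetry_score <- function(v) {
  a <- as.vector(v$data)
  if (stats::sd(a) == 0)
    stop("symmetry score undefined for a constant-intensity volume",
         call. = FALSE)
  stats::cor(a, as.vector(mirror_x(v)$data))
}

# rescale intensities so the 1st-99th percentile range maps to [0, 1]
normalize_intensity <- function(v, probs = c(0.01, 0.99)) {
  q <- stats::quantile(as.vector(v$data), probs, names = FALSE)
  if (q[2] <= q[1]) stop("degenerate intensity range", call. = FALSE)
  volume(pmin(pmax((v$data - q[1]) / (q[2] - q[1]), 0), 1),
         v$spacing, v$origin)
}

#' Build an age-specific average template
#'
#' Registers every subject to the chosen reference, intensity-normalizes
#' each registered subject (1st-99th percentile rescaling, robust to
#' acquisition gain differences), and voxelwise-averages on the reference
#' grid. One-pass averaging: the reference is chosen once (e.g. the subject
#' with the best [symmetry_score()]) and not iteratively refined.
#'
#' @param subjects list of [volume()] objects (>= 2).
#' @param reference a [volume()]; the template inherits its grid.
#' @param config a [registration_config()].
#' @return the average template [volume()], with the per-subject transforms
#'   in attribute `"transforms"`.
#' @export
build_template <- function(subjects, reference,
                           config = registration_config()) {
  if (length(subjects) < 2)
    stop("need at least 2 subjects to average", call. = FALSE)
  transforms <- vector("list", length(subjects))
  acc <- array(0, dim(reference$data))
  for (i in seq_along(subjects)) {
    t_i <- tryCatch(register(reference, subjects[[i]], config),
                    error = function(e)
                      stop("registration failed for subject ", i, ": ",
                           conditionMessage(e), call. = FALSE))
    transforms[[i]] <- t_i
    warped <- apply_to_volume(t_i, subjects[[i]], grid = reference)
    acc <- acc + normalize_intensity(warped)$data
  }
  out <- volume(acc / length(subjects), reference$spacing, reference$origin)
  attr(out, "transforms") <- transforms
  out
}

#' Propagate anatomical labels from one template to another
#'
#' Registers the source template to the target (so the recovered transform
#' resamples source-space content onto the target grid) and carries the
#' label volume across with nearest-neighbour interpolation. When the
#' morphological gap is large (e.g. adult to youngest age), pass the
#' intermediate-age template as `via`: labels then travel source -> via ->
#' target through two composed registrations, each bridging a smaller shape
#' difference.
#'
#' @param labels [label_volume()] aligned to `source_template`.
#' @param source_template,target_template [volume()] templates.
#' @param via optional intermediate-age [volume()].
#' @param config a [registration_config()].
#' @return labels on the target grid (no label absent from the input can
#'   appear).
#' @export
propagate_labels <- function(labels, source_template, target_template,
                             via = NULL, config = registration_config()) {
  stopifnot(inherits(labels, "label_volume"))
  if (is.null(via)) {
    t1 <- register(target_template, source_template, config)
    return(apply_to_labels(t1, labels, grid = target_template))
  }
  t_mid <- register(via, source_template, config)
  labels_mid <- apply_to_labels(t_mid, labels, grid = via)
  via_fitted <- apply_to_volume(t_mid, source_template, grid = via)
  t_tgt <- register(target_template, via_fitted, config)
  apply_to_labels(t_tgt, labels_mid, grid = target_template)
}
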