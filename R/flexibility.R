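#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Finds the proper rotation and translation that minimize the RMSD
#' between a mobile coordinate set and a reference, via singular value
#' decomposition of the cross-covariance matrix with the usual determinant
#' sign correction so reflections are never applied.
#'
#' @param mobile,reference Numeric `n x 3` matrices of matched positions
#'   (Angstrom), `n >= 3`, not all collinear.
#' @return A list with `coords` (the transformed mobile coordinates),
#'   `rotation` (3x3, determinant +1), `translation` (length-3), and
#'   `rmsd` (the minimized value, Angstrom).
#' @export
kabsch_superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile)
  reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)) || ncol(mobile) != 3) {
    abort("`mobile` and `reference` must be matching n x 3 matrices")
  }
  n <- nrow(mobile)
  if (n < 3) abort("superposition needs at least 3 positions")
  mc <- colMeans(mobile)
  rc <- colMeans(reference)
  m0 <- sweep(mobile, 2, mc)
  r0 <- sweep(reference, 2, rc)
  h <- crossprod(m0, r0)  # 3x3 cross-covariance
  sv <- svd(h)
  if (sum(sv$d > 1e-8 * max(sv$d, .Machine$double.eps)) < 2) {
    abort("degenerate (collinear or coincident) coordinates: superposition is ill-defined")
  }
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  aligned <- m0 %*% t(rot) + matrix(rc, n, 3, byrow = TRUE)
  rmsd <- sqrt(sum((aligned - reference)^2) / n)
  list(
    coords = aligned,
    rotation = rot,
    translation = as.numeric(rc - rot %*% mc),
    rmsd = rmsd
  )
}

# long coordinate tibble -> list of frame matrices (n_res x 3)
coord_frames <- function(coords) {
  frames <- sort(unique(coords$frame))
  ids <- unique(coords$residue_id)
  ord <- order(coords$frame, match(coords$residue_id, ids))
  xyz <- as.matrix(coords[ord, c("x", "y", "z")])
  n_res <- length(ids)
  list(
    ids = ids,
    frames = lapply(seq_along(frames), function(t) {
      xyz[seq((t - 1) * n_res + 1, t * n_res), , drop = FALSE]
    })
  )
}

#' Per-residue root-mean-square fluctuation
#'
#' Computes `RMSF_i = sqrt(mean_t ||x_i(t) - xbar_i||^2)` from a
#' coordinate trajectory. With `align = TRUE` (default) every frame is
#' first superposed onto frame 1, and with `reference = "mean"` a single
#' refinement pass re-superposes all frames onto the resulting mean
#' structure before the fluctuations are measured, making the profile
#' invariant to whole-molecule rigid motion.
#'
#' @param coords A long coordinate tibble (`frame`, `residue_id`, `x`,
#'   `y`, `z`), e.g. from [sim_coordinates()] or read from a TSV.
#' @param align Superpose frames before measuring fluctuation.
#' @param reference `"mean"` (one refinement pass toward the mean
#'   structure, default) or `"frame0"` (superpose onto the first frame
#'   only).
#' @return A tibble with columns `residue_id` and `rmsf` (Angstrom).
#' @export
rmsf_profile <- function(coords, align = TRUE,
                         reference = c("mean", "frame0")) {
  reference <- match.arg(reference)
  cf <- coord_frames(coords)
  frames <- cf$frames
  if (length(frames) < 2) abort("RMSF needs at least 2 frames")
  if (align) {
    frames <- lapply(frames, function(f) kabsch_superpose(f, frames[[1]])$coords)
    if (reference == "mean") {
      mean_xyz <- Reduce(`+`, frames) / length(frames)
      frames <- lapply(frames, function(f) kabsch_superpose(f, mean_xyz)$coords)
    }
  }
  mean_xyz <- Reduce(`+`, frames) / length(frames)
  sq <- Reduce(`+`, lapply(frames, function(f) rowSums((f - mean_xyz)^2)))
  tibble::tibble(
    residue_id = cf$ids,
    rmsf = sqrt(sq / length(frames))
  )
}
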