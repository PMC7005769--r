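#' Seeded synthetic inputs for the order-disorder concordance pipeline
#'
#' The generators in this family produce inputs with the statistical
#' structure the analysis assumes, so every downstream stage can be tested
#' without molecular-dynamics runs or predictor servers. A latent
#' per-residue flexibility profile `phi` in `[0, 1]` drives everything:
#' secondary-structure labels fluctuate across frames at a rate increasing
#' in `phi`, predictor accuracy and confidence decrease in `phi`, disorder
#' scores increase in `phi` (except inside planted "blind" regions), and
#' coordinate fluctuation amplitude increases in `phi`. All generators are
#' deterministic for a fixed seed.
#'
#' @name synthetic-data
NULL

# Evaluate code under a fixed RNG seed without disturbing the caller's
# RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Geometric run length with support >= 1 and the given mean.
rgeom_run <- function(n, mean) {
  if (mean < 1) abort("run means must be >= 1")
  1L + stats::rgeom(n, prob = 1 / mean)
}

#' Generate a synthetic reference structure with a latent flexibility profile
#'
#' Draws a secondary-structure label string as alternating runs of
#' structured (helix or strand) and coil states, with geometrically
#' distributed run lengths, and assigns each residue a latent flexibility
#' `phi`: high inside coil runs (when `coil_flexible = TRUE`) and inside
#' any explicitly planted regions, low inside structured runs, plus a small
#' uniform jitter clipped to `[0, 1]`. The maximal blocks of high base
#' `phi` are returned as the planted ground-truth regions for
#' region-recovery checks.
#'
#' @param length Chain length in residues (>= 10). Chains of about
#'   200 residues are the intended scale.
#' @param helix_run_mean,beta_run_mean,coil_run_mean Mean run length (in
#'   residues, >= 1) of helix, strand, and coil runs.
#' @param mix Named weights for choosing each structured run's kind,
#'   e.g. `c(helix = 0.5, beta = 0.5)`; must sum to 1.
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @param phi_high,phi_low Base flexibility assigned to flexible and rigid
#'   residues before jitter.
#' @param phi_noise Half-width of the uniform jitter added to `phi`.
#' @param planted_regions Optional tibble of 1-based inclusive intervals
#'   (`start`, `end`) forced to high flexibility regardless of their labels.
#' @param coil_flexible If `TRUE` (default) coil runs get `phi_high`; set
#'   `FALSE` to confine high flexibility to `planted_regions`, which gives
#'   crisp block boundaries for region-recovery tests.
#'
#' @return A list with elements `reference` (tibble `residue_id`, `aa`,
#'   `label`), `phi` (tibble `residue_id`, `phi`), and `planted` (region
#'   tibble of the maximal high-flexibility blocks, kind
#'   `"planted_flexible"`).
#' @export
sim_reference <- function(length = 200,
                          helix_run_mean = 8,
                          beta_run_mean = 5,
                          coil_run_mean = 4,
                          mix = c(helix = 0.5, beta = 0.5),
                          seed = 1L,
                          phi_high = 0.9,
                          phi_low = 0.1,
                          phi_noise = 0.05,
                          planted_regions = NULL,
                          coil_flexible = TRUE) {
  if (length < 10) abort("`length` must be at least 10 residues")
  if (abs(sum(mix) - 1) > 1e-8) abort("`mix` weights must sum to 1")
  if (any(c(helix_run_mean, beta_run_mean, coil_run_mean) < 1)) {
    abort("run means must be >= 1")
  }
  with_seed(seed, {
    labels <- character(0)
    structured <- TRUE
    while (base::length(labels) < length) {
      if (structured) {
        kind <- sample(names(mix), 1L, prob = mix)
        run <- if (kind == "helix") {
          rep("H", rgeom_run(1L, helix_run_mean))
        } else {
          rep("E", rgeom_run(1L, beta_run_mean))
        }
      } else {
        run <- rep("C", rgeom_run(1L, coil_run_mean))
      }
      labels <- c(labels, run)
      structured <- !structured
    }
    labels <- labels[seq_len(length)]

    aa <- sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                   "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"),
                 length, replace = TRUE)

    base_phi <- ifelse(labels == "C" & coil_flexible, phi_high, phi_low)
    if (!is.null(planted_regions) && nrow(planted_regions) > 0) {
      if (any(planted_regions$start < 1) || any(planted_regions$end > length)) {
        abort("planted regions fall outside the sequence")
      }
      for (i in seq_len(nrow(planted_regions))) {
        base_phi[planted_regions$start[i]:planted_regions$end[i]] <- phi_high
      }
    }
    phi <- pmin(pmax(base_phi + runif(length, -phi_noise, phi_noise), 0), 1)

    high <- base_phi == phi_high
    planted <- if (any(high)) {
      r <- rle(high)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      tibble::tibble(
        protein_id = "synthetic",
        start = starts[r$values],
        end = ends[r$values],
        kind = "planted_flexible",
        score = vapply(which(r$values), function(j) {
          mean(phi[starts[j]:ends[j]])
        }, double(1))
      )
    } else {
      empty_regions()
    }

    list(
      reference = tibble::tibble(
        residue_id = seq_len(length), aa = aa, label = labels
      ),
      phi = tibble::tibble(residue_id = seq_len(length), phi = phi),
      planted = planted
    )
  })
}

#' Simulate a secondary-structure label trajectory
#'
#' Starting from the reference labels at frame 1, each residue's label
#' flips between consecutive frames with per-residue probability
#' `f = f_min + (f_max - f_min) * phi`; on a flip the new label is drawn
#' uniformly from the seven other Q8 states, so high-flexibility residues
#' produce short label runs and low longevity. Frame times advance by
#' 200 ps per frame, emulating a trajectory sampled every 200 ps.
#'
#' @param reference Reference tibble from [sim_reference()] (columns
#'   `residue_id`, `label`).
#' @param phi Flexibility tibble (`residue_id`, `phi`).
#' @param n_frames Number of frames (>= 2); 1500 frames corresponds to the
#'   window scale the longevity statistic targets.
#' @param f_min,f_max Flip probabilities at `phi = 0` and `phi = 1`;
#'   `0 <= f_min <= f_max <= 1`.
#' @param seed Integer seed.
#'
#' @return A long label-trajectory tibble (`frame`, `time_ps`,
#'   `residue_id`, `label`), the same shape [read_label_matrix()] returns.
#' @export
sim_trajectory <- function(reference, phi, n_frames = 1500,
                           f_min = 0.01, f_max = 0.9, seed = 1L) {
  if (n_frames < 2) abort("`n_frames` must be >= 2")
  if (!(f_min >= 0 && f_min <= f_max && f_max <= 1)) {
    abort("need 0 <= f_min <= f_max <= 1")
  }
  stopifnot(nrow(reference) == nrow(phi))
  n_res <- nrow(reference)
  f <- f_min + (f_max - f_min) * phi$phi

  with_seed(seed, {
    lab_idx <- matrix(0L, nrow = n_frames, ncol = n_res)
    lab_idx[1, ] <- match(reference$label, Q8_STATES)
    for (t in 2:n_frames) {
      cur <- lab_idx[t - 1, ]
      flip <- runif(n_res) < f
      nxt <- cur
      if (any(flip)) {
        r <- sample.int(7L, sum(flip), replace = TRUE)
        c_f <- cur[flip]
        nxt[flip] <- ifelse(r < c_f, r, r + 1L)  # uniform over the 7 other states
      }
      lab_idx[t, ] <- nxt
    }
    tibble::tibble(
      frame = rep(seq_len(n_frames), each = n_res),
      time_ps = rep(200 * (seq_len(n_frames) - 1), each = n_res),
      residue_id = rep(reference$residue_id, times = n_frames),
      label = Q8_STATES[as.vector(t(lab_idx))]
    )
  })
}

#' Simulate secondary-structure predictor output
#'
#' Each residue is predicted correctly with probability
#' `a = a_max - (a_max - a_min) * phi`, so accuracy decreases with
#' flexibility; wrong predictions are uniform over the remaining classes.
#' The emitted label receives probability mass
#' `q = 0.5 + conf_gain * (a - 0.5)` and the remaining mass is spread
#' uniformly over the other classes, so confidence tracks accuracy.
#'
#' @param reference Reference tibble (`residue_id`, `aa`, `label`, Q8
#'   codes).
#' @param phi Flexibility tibble.
#' @param a_max,a_min Correctness probabilities at `phi = 0` and
#'   `phi = 1`; `0 <= a_min <= a_max <= 1`.
#' @param conf_gain Gain tying emitted-label mass to accuracy; must keep
#'   `q` within `(1/n_classes, 1]` so the emitted label is the argmax.
#' @param scheme `"q3"` or `"q8"`.
#' @param seed Integer seed.
#' @param predictor Name recorded on the output.
#'
#' @return A prediction tibble in the same shape as
#'   [read_prediction_table()].
#' @export
sim_predictions <- function(reference, phi, a_max = 0.9, a_min = 0.5,
                            conf_gain = 0.8, scheme = c("q3", "q8"),
                            seed = 1L, predictor = "synthetic") {
  scheme <- match.arg(scheme)
  if (!(a_min >= 0 && a_min <= a_max && a_max <= 1)) {
    abort("need 0 <= a_min <= a_max <= 1")
  }
  states <- if (scheme == "q3") Q3_STATES else Q8_STATES
  n_cls <- length(states)
  ref_labels <- if (scheme == "q3") q8_to_q3(reference$label) else reference$label
  a <- a_max - (a_max - a_min) * phi$phi
  q <- 0.5 + conf_gain * (a - 0.5)
  if (any(q <= 1 / n_cls) || any(q > 1)) {
    abort(sprintf(
      "`conf_gain` = %g puts emitted-label mass outside (1/%d, 1]",
      conf_gain, n_cls
    ))
  }
  with_seed(seed, {
    correct <- runif(nrow(reference)) < a
    ref_idx <- match(ref_labels, states)
    emit_idx <- ref_idx
    if (any(!correct)) {
      r <- sample.int(n_cls - 1L, sum(!correct), replace = TRUE)
      c_w <- ref_idx[!correct]
      emit_idx[!correct] <- ifelse(r < c_w, r, r + 1L)
    }
    probs <- matrix((1 - q) / (n_cls - 1L), nrow = nrow(reference), ncol = n_cls)
    probs[cbind(seq_len(nrow(reference)), emit_idx)] <- q
    out <- tibble::tibble(
      residue_id = reference$residue_id,
      aa = reference$aa,
      label = states[emit_idx]
    )
    for (j in seq_len(n_cls)) out[[paste0("p_", states[j])]] <- probs[, j]
    attr(out, "scheme") <- scheme
    attr(out, "predictor_name") <- predictor
    out
  })
}

#' Simulate per-residue disorder predictor scores
#'
#' Each predictor's score is a logistic transform of the latent
#' flexibility, `plogis(slope * (phi - 0.5))`, plus Gaussian noise, clipped
#' to `[0, 1]`. Inside any `blind_regions` the score is computed as if
#' `phi = 0.1` there, planting regions that are flexible yet invisible to
#' the predictors — the ground truth for discordant-region recovery.
#' Each predictor uses a distinct sub-stream (`seed + predictor index`).
#'
#' @param phi Flexibility tibble (`residue_id`, `phi`).
#' @param n_predictors Number of predictors to emulate (>= 1).
#' @param slope Logistic slope tying score to flexibility.
#' @param noise_sd Standard deviation of the additive Gaussian noise.
#' @param blind_regions Optional region tibble (`start`, `end`, 1-based
#'   inclusive residue positions) where predictors are blind.
#' @param seed Integer seed.
#'
#' @return A long tibble with columns `predictor`, `residue_id`, `score`.
#' @export
sim_disorder <- function(phi, n_predictors = 3, slope = 8, noise_sd = 0.05,
                         blind_regions = NULL, seed = 1L) {
  if (n_predictors < 1) abort("`n_predictors` must be >= 1")
  eff_phi <- phi$phi
  if (!is.null(blind_regions) && nrow(blind_regions) > 0) {
    for (i in seq_len(nrow(blind_regions))) {
      hit <- phi$residue_id >= blind_regions$start[i] &
        phi$residue_id <= blind_regions$end[i]
      eff_phi[hit] <- 0.1
    }
  }
  mu <- stats::plogis(slope * (eff_phi - 0.5))
  purrr::map_dfr(seq_len(n_predictors), function(j) {
    with_seed(seed + j, {
      tibble::tibble(
        predictor = sprintf("disorder_%d", j),
        residue_id = phi$residue_id,
        score = pmin(pmax(mu + rnorm(length(mu), sd = noise_sd), 0), 1)
      )
    })
  })
}

#' Simulate a coordinate trajectory with flexibility-scaled fluctuation
#'
#' The mean structure is an ideal helix-like curve (1.5 A rise and 2.3 A
#' radius per residue); each frame adds isotropic Gaussian noise with
#' per-residue per-axis standard deviation
#' `sigma = sigma_min + (sigma_max - sigma_min) * phi`, so RMSF grows with
#' flexibility (closed form `RMSF = sigma * sqrt(3)`). With
#' `rigid_motion = TRUE` every frame is additionally rotated and translated
#' by a random rigid transform, exercising superposition.
#'
#' @param phi Flexibility tibble (`residue_id`, `phi`).
#' @param sigma_min,sigma_max Fluctuation amplitudes (A) at `phi = 0` and
#'   `phi = 1`.
#' @param n_frames Number of frames (>= 2).
#' @param rigid_motion Add a random whole-molecule rigid transform per
#'   frame.
#' @param seed Integer seed.
#'
#' @return A long coordinate tibble with columns `frame`, `residue_id`,
#'   `x`, `y`, `z` (Angstrom).
#' @export
sim_coordinates <- function(phi, sigma_min = 0.5, sigma_max = 3,
                            n_frames = 2000, rigid_motion = FALSE, seed = 1L) {
  if (n_frames < 2) abort("`n_frames` must be >= 2")
  if (sigma_min > sigma_max) abort("need sigma_min <= sigma_max")
  n_res <- nrow(phi)
  idx <- seq_len(n_res)
  theta <- idx * (100 * pi / 180)  # ~100 degrees of twist per residue
  mean_xyz <- cbind(2.3 * cos(theta), 2.3 * sin(theta), 1.5 * idx)
  sigma <- sigma_min + (sigma_max - sigma_min) * phi$phi

  with_seed(seed, {
    # all fluctuation noise is drawn before any rigid transform, so the
    # same seed yields the same internal motion with and without
    # rigid_motion
    frames <- purrr::map(seq_len(n_frames), function(t) {
      mean_xyz + matrix(rnorm(3L * n_res, sd = rep(sigma, 3L)), ncol = 3L)
    })
    if (rigid_motion) {
      frames <- purrr::map(frames, function(xyz) {
        rot <- random_rotation()
        shift <- runif(3, -10, 10)
        xyz %*% t(rot) + matrix(shift, n_res, 3, byrow = TRUE)
      })
    }
    tibble::tibble(
      frame = rep(seq_len(n_frames), each = n_res),
      residue_id = rep(phi$residue_id, times = n_frames),
      x = unlist(lapply(frames, function(m) m[, 1]), use.names = FALSE),
      y = unlist(lapply(frames, function(m) m[, 2]), use.names = FALSE),
      z = unlist(lapply(frames, function(m) m[, 3]), use.names = FALSE)
    )
  })
}

# Uniform random proper rotation via QR of a Gaussian matrix.
random_rotation <- function() {
  qr_out <- qr(matrix(rnorm(9), 3, 3))
  q <- qr.Q(qr_out)
  d <- diag(qr.R(qr_out))
  q <- q %*% diag(sign(d))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
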