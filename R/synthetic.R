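#' Synthetic DWI signals with known NODDI ground truth
#'
#' Generates noisy signal replicates from [predict_signal()] for every
#' parameter set in a grid, together with a machine-readable ground-truth
#' table, for fitter-recovery experiments.
#'
#' @param param_grid list of [noddi_params()] objects.
#' @param scheme an [make_noddi_scheme()] acquisition scheme.
#' @param snr signal-to-noise ratio for [add_noise()]; `Inf` gives exact
#'   model signals.
#' @param n_replicates noisy replicates per parameter set.
#' @param rng_seed integer seed.
#' @return list with `signals` (matrix, one column per parameter set x
#'   replicate) and `truth` (data frame with `param_id`, `replicate`,
#'   `v_ic`, `kappa`, `odi`, `v_iso`, `v_dot`).
#' @export
generate_dwi_truth_set <- function(param_grid, scheme, snr = 50,
                                   n_replicates = 1, rng_seed = 1) {
  stopifnot(length(param_grid) >= 1,
            all(vapply(param_grid, inherits, TRUE, "noddi_params")))
  n_col <- length(param_grid) * n_replicates
  signals <- matrix(NA_real_, nrow(scheme), n_col)
  truth <- vector("list", n_col)
  col <- 0L
  for (pi in seq_along(param_grid)) {
    prm <- param_grid[[pi]]
    clean <- predict_signal(prm, scheme)
    for (r in seq_len(n_replicates)) {
      col <- col + 1L
      signals[, col] <- add_noise(clean, scheme, snr = snr,
                                  rng_seed = rng_seed + col)
      truth[[col]] <- data.frame(param_id = pi, replicate = r,
                                 v_ic = prm$v_ic, kappa = prm$kappa,
                                 odi = prm$odi, v_iso = prm$v_iso,
                                 v_dot = prm$v_dot)
    }
  }
  list(signals = signals, truth = do.call(rbind, truth))
}

#' Effect model for the synthetic repopulation study
#'
#' Fixture parameters describing a depletion-repopulation experiment:
#' microglial counts collapse under CSF1R inhibition and recover over days
#' 1, 3 and 7 after withdrawal, while mean ODI co-varies linearly with
#' count. Neuron and astrocyte counts carry no day effect. The numeric
#' defaults are declared fixture values chosen so the qualitative
#' significance pattern of a depletion-repopulation experiment emerges
#' (day 1 and 3 counts clearly below control, day 7 near control); they are
#' not estimates of any real data set.
#'
#' @param control_count_mean,control_count_sd control microglial counts per
#'   field.
#' @param depletion_fractions named fractions of the control mean remaining
#'   in treated animals on days 0, 1, 3 and 7 post-withdrawal
#'   (non-decreasing over days).
#' @param neuron_count_mean,neuron_count_sd,astro_count_mean,astro_count_sd
#'   day-invariant densities of the negative-control cell types.
#' @param control_odi_mean,odi_sd baseline mean ODI and its biological +
#'   measurement noise.
#' @param odi_slope ODI change per unit microglial count
#'   (`ODI = baseline + slope * (count - control mean) + noise`).
#' @param n_per_group animals per group per day.
#' @return object of class `effect_model`.
#' @export
effect_model <- function(control_count_mean = 300, control_count_sd = 40,
                         depletion_fractions = c(`0` = 0.02, `1` = 0.15,
                                                 `3` = 0.5, `7` = 0.95),
                         neuron_count_mean = 500, neuron_count_sd = 50,
                         astro_count_mean = 200, astro_count_sd = 30,
                         control_odi_mean = 0.45, odi_sd = 0.015,
                         odi_slope = 2.5e-4, n_per_group = 6) {
  stopifnot(control_count_sd > 0, odi_sd > 0,
            all(depletion_fractions >= 0), all(depletion_fractions <= 1),
            !is.unsorted(depletion_fractions), n_per_group >= 2)
  structure(list(control_count_mean = control_count_mean,
                 control_count_sd = control_count_sd,
                 depletion_fractions = depletion_fractions,
                 neuron_count_mean = neuron_count_mean,
                 neuron_count_sd = neuron_count_sd,
                 astro_count_mean = astro_count_mean,
                 astro_count_sd = astro_count_sd,
                 control_odi_mean = control_odi_mean, odi_sd = odi_sd,
                 odi_slope = odi_slope, n_per_group = n_per_group),
            class = "effect_model")
}

#' Generate a synthetic repopulation-study table
#'
#' Draws per-animal microglial, neuron and astrocyte counts and mean ODI
#' for a two-arm (control / treated) design sampled at days 0, 1, 3 and 7
#' post-withdrawal, following an [effect_model()]. Counts are truncated at
#' zero; ODI is clamped to (0, 1).
#'
#' @param model an [effect_model()].
#' @param rng_seed integer seed.
#' @return data frame with columns `animal_id`, `group`, `day`,
#'   `microglia_count`, `neuron_count`, `astrocyte_count`, `mean_ODI`.
#' @export
generate_repopulation_study <- function(model = effect_model(),
                                        rng_seed = 1) {
  stopifnot(inherits(model, "effect_model"))
  days <- as.numeric(names(model$depletion_fractions))
  n <- model$n_per_group
  withr::with_seed(rng_seed, {
    rows <- list()
    id <- 0L
    for (grp in c("control", "treated")) {
      for (d in days) {
        frac <- if (grp == "control") 1 else
          model$depletion_fractions[[as.character(d)]]
        counts <- pmax(0, rnorm(n, model$control_count_mean * frac,
                                model$control_count_sd))
        odi <- model$control_odi_mean +
          model$odi_slope * (counts - model$control_count_mean) +
          rnorm(n, 0, model$odi_sd)
        rows[[length(rows) + 1]] <- data.frame(
          animal_id = sprintf("A%02d", id + seq_len(n)),
          group = grp, day = d,
          microglia_count = counts,
          neuron_count = pmax(0, rnorm(n, model$neuron_count_mean,
                                       model$neuron_count_sd)),
          astrocyte_count = pmax(0, rnorm(n, model$astro_count_mean,
                                          model$astro_count_sd)),
          mean_ODI = pmin(pmax(odi, 1e-6), 1 - 1e-6))
        id <- id + n
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Generate a fluorescence-like cell image with known count
#'
#' Places `n_cells` non-overlapping bright discs on a noisy background,
#' mimicking a thresholdable single-channel fluorescence field; used as
#' ground truth for [count_particles()].
#'
#' @param n_cells number of discs (ground-truth count).
#' @param field_size image edge, pixels.
#' @param cell_radius disc radius, pixels.
#' @param background_noise_sd Gaussian noise standard deviation added to the
#'   whole field.
#' @param background_level,cell_amplitude background mean and disc height,
#'   intensity units.
#' @param rng_seed integer seed.
#' @param max_attempts rejection-sampling budget per disc.
#' @return list with `image` (numeric matrix), `count` (the ground truth),
#'   and `centers` (n x 2 matrix of disc centers).
#' @export
generate_cell_image <- function(n_cells, field_size = 512, cell_radius = 4,
                                background_noise_sd = 5,
                                background_level = 100,
                                cell_amplitude = 500, rng_seed = 1,
                                max_attempts = 10000) {
  disc_area <- pi * cell_radius^2
  if (n_cells * disc_area > 0.3 * field_size^2)
    stop("placement infeasible: requested discs cover more than 30% of ",
         "the field")
  withr::with_seed(rng_seed, {
    img <- matrix(rnorm(field_size^2, background_level,
                        background_noise_sd),
                  field_size, field_size)
    centers <- matrix(NA_real_, max(n_cells, 1), 2)[seq_len(n_cells), ,
                                                    drop = FALSE]
    placed <- 0L
    lo <- cell_radius + 2
    hi <- field_size - cell_radius - 1
    for (i in seq_len(n_cells)) {
      ok <- FALSE
      for (att in seq_len(max_attempts)) {
        p <- runif(2, lo, hi)
        if (placed > 0) {
          d2 <- colSums((t(centers[seq_len(placed), , drop = FALSE]) - p)^2)
          if (any(d2 < (2 * cell_radius + 2)^2)) next
        }
        centers[i, ] <- p
        placed <- placed + 1L
        ok <- TRUE
        break
      }
      if (!ok) stop("placement failed after attempt budget (placed ",
                    placed, " of ", n_cells, ")")
      rr <- seq(max(1, floor(p[1] - cell_radius)),
                min(field_size, ceiling(p[1] + cell_radius)))
      cc <- seq(max(1, floor(p[2] - cell_radius)),
                min(field_size, ceiling(p[2] + cell_radius)))
      d2 <- outer((rr - p[1])^2, (cc - p[2])^2, "+")
      img[rr, cc] <- img[rr, cc] + cell_amplitude * (d2 <= cell_radius^2)
    }
    list(image = img, count = n_cells, centers = centers)
  })
}
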