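## Synthetic studies with planted ground truth.
##
## The generator emulates the regime of a bilateral deep-brain-stimulation
## cohort in template space: electrodes implanted around a common midline
## target with millimetre placement jitter, inverse-square point-source
## E-fields, a bundle-structured tractogram in which exactly one bundle is
## predictive, a latent-component BOLD connectome with one outcome-coupled
## component, and outcomes generated as a noisy monotone function of field
## overlap with a planted sweet (and optionally sour) region. Every
## generator is a pure function of (spec, seed).

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Synthetic cohort specification
#'
#' Defaults state the emulated world once: 60 patients, a 41 x 41 x 31 grid
#' at 1.5 mm centred on the mid-sagittal plane, bilateral targets at
#' (+/-7, 1, -6) mm with 2 mm placement jitter, 2-5 mA per-hemisphere
#' currents, a sweet sphere of radius 4 mm at (4.8, -0.9, -3.6) mm (near the
#' right lead) with unit
#' effect weight, a sour sphere at (-5.5, 0, -1) mm (near the left lead, so
#' both hemispheres carry outcome-relevant exposure) with weight 0.5, and
#' outcome noise with SD equal to half the scaled signal SD (24.4 on the
#' percent scale whose signal SD is 48.8).
#'
#' @param n_patients cohort size (>= 4).
#' @param shape,spacing grid voxel counts and isotropic spacing (mm).
#' @param target right-hemisphere implant target, world mm (left = x-flip).
#' @param placement_jitter_sd electrode placement SD per axis (mm).
#' @param amplitude_range per-hemisphere current range (mA).
#' @param sweet_center,sweet_radius,sweet_weight planted sweet region.
#' @param sour_center,sour_radius,sour_weight planted sour region
#'   (`sour_weight = 0` disables it).
#' @param outcome_mean,outcome_sd location/scale of the percent-improvement
#'   signal.
#' @param noise_sd outcome noise SD, percent units.
#' @param sigma medium conductivity (S/m).
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 60L,
                        shape = c(41L, 41L, 31L), spacing = 1.5,
                        target = c(7, 1, -6), placement_jitter_sd = 2,
                        amplitude_range = c(2, 5),
                        sweet_center = c(4.8, -0.9, -3.6), sweet_radius = 4,
                        sweet_weight = 1,
                        sour_center = c(-5.5, 0, -1), sour_radius = 4,
                        sour_weight = 0.5,
                        outcome_mean = -38.6, outcome_sd = 48.8,
                        noise_sd = 24.4, sigma = 0.2) {
  stopifnot(n_patients >= 4L, sweet_weight > 0, sour_weight >= 0)
  spec <- list(n_patients = as.integer(n_patients), shape = as.integer(shape),
               spacing = spacing, target = target,
               placement_jitter_sd = placement_jitter_sd,
               amplitude_range = amplitude_range,
               sweet_center = sweet_center, sweet_radius = sweet_radius,
               sweet_weight = sweet_weight,
               sour_center = sour_center, sour_radius = sour_radius,
               sour_weight = sour_weight,
               outcome_mean = outcome_mean, outcome_sd = outcome_sd,
               noise_sd = noise_sd, sigma = sigma)
  grid <- make_grid(spec$shape, spec$spacing)
  half <- spec$spacing * (spec$shape - 1L) / 2
  inside <- function(ctr, rad) all(abs(ctr) + rad <= half)
  if (!inside(sweet_center, sweet_radius)) stop("sweet region outside grid")
  if (sour_weight > 0 && !inside(sour_center, sour_radius))
    stop("sour region outside grid")
  structure(spec, class = "cohort_spec")
}

sphere_mask <- function(grid, center, radius) {
  xyz <- grid_coords(grid)
  d2 <- (xyz[, 1L] - center[1L])^2 + (xyz[, 2L] - center[2L])^2 +
        (xyz[, 3L] - center[3L])^2
  array(d2 <= radius^2, dim = dim(grid$values))
}

#' Synthetic tractogram specification
#'
#' Bundles are smooth arcs: each has three control points interpolated by a
#' quadratic Bezier curve; fibers are the centerline plus a per-fiber rigid
#' offset and smooth along-fiber wander, both scaled by `fiber_jitter_sd`.
#' Bundle 1 is the designated predictive bundle and runs through the sweet
#' region center, roughly parallel to the right lead; bundle 2 (the default
#' event-driving bundle of the flashback generator) hugs the LEFT lead the
#' same way, a couple of millimetres lateral-anterior of its contacts, so
#' its stimulation exposure is decoupled from the outcome signal (which the
#' right-hemisphere sweet region drives); remaining bundles arc through
#' random interior points at least `min_separation` mm from the sweet center
#' and from both implant targets (they emulate remote white matter; the
#' electrode corridor holds exactly the two structured bundles).
#'
#' @param cspec a [cohort_spec()] (geometry source).
#' @param n_bundles number of bundles (>= 2).
#' @param fibers_per_bundle fibers per bundle.
#' @param fiber_jitter_sd fiber spread around the centerline (mm).
#' @param min_separation distractor clearance from the sweet center (mm).
#' @param seed seed for the distractor control points.
#' @return object of class `tract_spec` with a `centerlines` list of 3 x 3
#'   control-point matrices, `predictive_bundle = 1`, `commissure_bundle = 2`.
#' @export
tract_spec <- function(cspec, n_bundles = 10L, fibers_per_bundle = 50L,
                       fiber_jitter_sd = 1, min_separation = 8, seed = 1L) {
  stopifnot(n_bundles >= 2L, fibers_per_bundle >= 1L)
  half <- cspec$spacing * (cspec$shape - 1L) / 2
  sc <- cspec$sweet_center
  lt <- cspec$target * c(-1, 1, 1)
  centerlines <- vector("list", n_bundles)
  # fornix-like: ascends through the sweet center, hugging the right lead
  # near the contact plane so a sizable share of its fibers clears the
  # coverage filter
  centerlines[[1L]] <- rbind(cspec$target + c(0.5, -1, -7), sc,
                             sc + c(-1.8, 2.9, 9.6))
  # event bundle: hugs the left lead across its contact span
  centerlines[[2L]] <- rbind(lt + c(1.5, 2, -7), lt + c(2, 1.5, 1), lt + c(1, -4, 9))
  with_seed(seed, {
    keep_out <- rbind(sc, cspec$target, lt)
    b <- 3L
    while (b <= n_bundles) {
      mid <- stats::runif(3, -0.6 * half, 0.6 * half)
      dirn <- stats::rnorm(3)
      dirn <- dirn / sqrt(sum(dirn^2)) * stats::runif(1, 12, 20)
      bend <- stats::rnorm(3, sd = 4)
      ctrl <- rbind(mid - dirn, mid + bend, mid + dirn)
      # clearance holds along the whole arc, not just its midpoint
      path <- bezier_points(ctrl, 15L)
      dmin <- min(vapply(seq_len(nrow(keep_out)), function(r)
        min(sqrt(rowSums(sweep(path, 2L, keep_out[r, ])^2))), numeric(1L)))
      if (dmin < min_separation) next
      centerlines[[b]] <- ctrl
      b <- b + 1L
    }
  })
  structure(list(n_bundles = as.integer(n_bundles),
                 fibers_per_bundle = as.integer(fibers_per_bundle),
                 fiber_jitter_sd = fiber_jitter_sd,
                 centerlines = centerlines,
                 predictive_bundle = 1L, commissure_bundle = 2L),
            class = "tract_spec")
}

bezier_points <- function(ctrl, n = 21L) {
  if (nrow(ctrl) < 2L) stop("degenerate centerline: need >= 2 control points")
  t <- seq(0, 1, length.out = n)
  if (nrow(ctrl) == 2L)
    return(outer(1 - t, ctrl[1L, ]) + outer(t, ctrl[2L, ]))
  outer((1 - t)^2, ctrl[1L, ]) + outer(2 * t * (1 - t), ctrl[2L, ]) +
    outer(t^2, ctrl[3L, ])
}

#' Generate a bundle-structured tractogram
#'
#' @param tspec a [tract_spec()].
#' @param seed seed for fiber jitter.
#' @param points_per_fiber samples per fiber polyline.
#' @return a [tractogram()] with per-fiber `bundle` labels.
#' @export
generate_tractogram <- function(tspec, seed = 1L, points_per_fiber = 21L) {
  stopifnot(inherits(tspec, "tract_spec"))
  with_seed(seed, {
    streamlines <- vector("list", tspec$n_bundles * tspec$fibers_per_bundle)
    bundle <- integer(length(streamlines))
    idx <- 0L
    for (b in seq_len(tspec$n_bundles)) {
      cl <- bezier_points(tspec$centerlines[[b]], points_per_fiber)
      for (f in seq_len(tspec$fibers_per_bundle)) {
        idx <- idx + 1L
        offset <- stats::rnorm(3L, sd = tspec$fiber_jitter_sd)
        wander <- apply(matrix(stats::rnorm(3L * points_per_fiber,
                                            sd = tspec$fiber_jitter_sd / 3),
                               ncol = 3L), 2L, smooth_cumsum)
        streamlines[[idx]] <- cl +
          matrix(offset, points_per_fiber, 3L, byrow = TRUE) + wander
        bundle[idx] <- b
      }
    }
    tractogram(streamlines, bundle = bundle)
  })
}

## Low-frequency wander: smoothed, zero-mean random walk.
smooth_cumsum <- function(x) {
  s <- cumsum(x) / sqrt(seq_along(x))
  s <- stats::filter(s, rep(1 / 5, 5), sides = 2L)
  s[is.na(s)] <- 0
  as.numeric(s - mean(s))
}

#' Generate a synthetic cohort of E-fields and outcomes
#'
#' Per patient: bilateral contacts at the mirrored targets plus Gaussian
#' placement jitter (resampled up to 100 times if a contact falls outside
#' the grid), per-hemisphere currents uniform in `amplitude_range`, the
#' summed bilateral point-source field, and
#' `effect = sweet_weight * mean(E | sweet) - sour_weight * mean(E | sour)`.
#' Improvement is the standardized effect scaled to
#' `outcome_mean + outcome_sd * z` plus Gaussian noise (`noise_sd`);
#' baselines are uniform on the 12-24 ADAS-cog inclusion band and follow-ups
#' are back-computed.
#'
#' @param cspec a [cohort_spec()].
#' @param seed integer seed.
#' @return list with `cohort` ([cohort_table()]), `fields` (list of
#'   [efield_image()]), `grid`, and `truth` (sweet/sour masks, contact
#'   positions, currents, noiseless effect).
#' @export
generate_cohort <- function(cspec, seed = 1L) {
  stopifnot(inherits(cspec, "cohort_spec"))
  grid <- make_grid(cspec$shape, cspec$spacing)
  half <- cspec$spacing * (cspec$shape - 1L) / 2
  sweet <- sphere_mask(grid, cspec$sweet_center, cspec$sweet_radius)
  sour <- if (cspec$sour_weight > 0)
    sphere_mask(grid, cspec$sour_center, cspec$sour_radius)
  targets <- rbind(cspec$target, cspec$target * c(-1, 1, 1))
  with_seed(seed, {
    n <- cspec$n_patients
    contacts <- array(NA_real_, c(n, 2L, 3L))
    currents <- matrix(stats::runif(2L * n, cspec$amplitude_range[1L],
                                    cspec$amplitude_range[2L]), n, 2L)
    fields <- vector("list", n)
    effect <- numeric(n)
    for (i in seq_len(n)) {
      srcs <- vector("list", 2L)
      for (h in 1:2) {
        for (try in seq_len(100L)) {
          pos <- targets[h, ] + stats::rnorm(3L, sd = cspec$placement_jitter_sd)
          if (all(abs(pos) <= half)) break
          if (try == 100L) stop("electrode placement outside grid after 100 tries")
        }
        contacts[i, h, ] <- pos
        srcs[[h]] <- point_source(pos, currents[i, h])
      }
      E <- simulate_efield(srcs, grid, sigma = cspec$sigma,
                           patient_id = sprintf("P%03d", i))
      fields[[i]] <- E
      effect[i] <- cspec$sweet_weight * mean(E$grid$values[sweet]) -
        if (!is.null(sour)) cspec$sour_weight * mean(E$grid$values[sour]) else 0
    }
    z <- (effect - mean(effect)) / stats::sd(effect)
    improvement <- cspec$outcome_mean + cspec$outcome_sd * z +
      stats::rnorm(n, sd = cspec$noise_sd)
    baseline <- stats::runif(n, 12, 24)
    followup <- baseline * (1 - improvement / 100)
    cohort <- cohort_table(sprintf("P%03d", seq_len(n)), baseline, followup)
    list(cohort = cohort, fields = fields, grid = grid,
         truth = list(sweet_mask = sweet, sour_mask = sour,
                      sweet_center = cspec$sweet_center,
                      sour_center = if (!is.null(sour)) cspec$sour_center,
                      contacts = contacts, currents = currents,
                      effect = effect, improvement = improvement,
                      seed = as.integer(seed)))
  })
}

#' Generate a latent-component synthetic connectome
#'
#' Masked voxel timeseries are mixtures of a spatially uniform common mode
#' (the rs-fMRI global signal; it also keeps seed norms comparable across
#' patients) and `k_components` independent latent series with Gaussian
#' spatial loadings, plus white noise. Long, low-noise series emulate the
#' averaging of a many-subject normative connectome. Every component is
#' a bilateral, hemispherically mirrored pair of blobs (normative networks
#' are largely symmetric, and symmetry keeps the left/right stimulation
#' balance -- which is unrelated to outcome -- from coupling into every
#' component's seed loading). Component 1 is the planted outcome network, a
#' bilateral blob pair on the sweet region and its mirror, so network
#' recovery is testable. Component 2 is a strong "stimulation corridor"
#' network dorsal along the leads: most across-patient variance in seed
#' connectivity reflects where the field sits rather than outcome, and this
#' outcome-unrelated variance keeps seed norms from being a monotone
#' function of the planted component's exposure (which would otherwise leak
#' a global anticorrelation into every voxel). The remaining blob pairs are
#' placed pseudorandomly at least 15 mm from both implant targets.
#'
#' The mask emulates a gray-matter mask: it keeps (every `mask_stride`-th)
#' voxel within 10 mm of any blob center or its mirror, so the map decile
#' used in recovery checks ranges over network-bearing territory rather
#' than empty space.
#'
#' @param cspec a [cohort_spec()].
#' @param k_components number of latent components (>= 2).
#' @param n_samples timeseries length (>= 50).
#' @param noise_sd white-noise SD relative to unit-variance latents.
#' @param global_loading uniform loading of the common mode.
#' @param loading_sd_mm Gaussian blob scale (SD, mm).
#' @param mask_stride keep every `mask_stride`-th voxel per axis in the mask
#'   (keeps the voxel count tractable at desk scale).
#' @param seed integer seed.
#' @return list with `connectome` ([connectome()]), `truth` (per-component
#'   loading matrix over masked voxels, blob centers, coupled component
#'   index = 1).
#' @export
generate_connectome <- function(cspec, k_components = 4L, n_samples = 1000L,
                                noise_sd = 0.05, global_loading = 0.5,
                                loading_sd_mm = 4,
                                mask_stride = 2L, seed = 1L) {
  stopifnot(k_components >= 2L, n_samples >= 50L)
  stopifnot(k_components >= 2L)
  grid <- make_grid(cspec$shape, cspec$spacing)
  shape <- dim(grid$values)
  half <- cspec$spacing * (cspec$shape - 1L) / 2
  with_seed(seed, {
    centers <- matrix(NA_real_, k_components, 3L)
    centers[1L, ] <- cspec$sweet_center
    centers[2L, ] <- cspec$target + c(0, 0, 6)  # stimulation corridor
    k <- 3L
    while (k <= k_components) {
      ctr <- stats::runif(3L, -0.6 * half, 0.6 * half)
      if (min(sqrt(sum((ctr - cspec$target)^2)),
              sqrt(sum((ctr - cspec$target * c(-1, 1, 1))^2))) < 15) next
      centers[k, ] <- ctr
      k <- k + 1L
    }
    all_centers <- rbind(centers, if (cspec$sour_weight > 0) cspec$sour_center)
    lattice <- array(FALSE, shape)
    keep <- function(n) seq(1L, n, by = mask_stride)
    lattice[keep(shape[1L]), keep(shape[2L]), keep(shape[3L])] <- TRUE
    xyz_all <- grid_coords(grid)
    near <- rep(FALSE, nrow(xyz_all))
    for (r in seq_len(nrow(all_centers))) for (sgn in c(1, -1)) {
      ctr <- all_centers[r, ] * c(sgn, 1, 1)
      near <- near | rowSums(sweep(xyz_all, 2L, ctr)^2) <= 100
    }
    mask <- lattice & array(near, shape)
    xyz <- xyz_all[which(mask), , drop = FALSE]
    blob_pair <- function(ctr) {
      d2 <- rowSums(sweep(xyz, 2L, ctr)^2)
      d2m <- rowSums(sweep(xyz, 2L, ctr * c(-1, 1, 1))^2)
      exp(-d2 / (2 * loading_sd_mm^2)) + exp(-d2m / (2 * loading_sd_mm^2))
    }
    loadings <- vapply(seq_len(k_components), function(k) blob_pair(centers[k, ]),
                       numeric(nrow(xyz)))
    loadings[, 2L] <- 2 * loadings[, 2L]
    latents <- matrix(stats::rnorm(k_components * n_samples), k_components)
    common <- stats::rnorm(n_samples)
    series <- loadings %*% latents +
      matrix(global_loading * common, nrow(xyz), n_samples, byrow = TRUE) +
      matrix(stats::rnorm(nrow(xyz) * n_samples, sd = noise_sd), nrow(xyz))
    list(connectome = connectome(mask, series, affine = grid$affine),
         truth = list(loadings = loadings, centers = centers,
                      global_loading = global_loading,
                      coupled_component = 1L, seed = as.integer(seed)))
  })
}

#' Generate outcomes coupled to the planted network component
#'
#' The cohort's main outcome model runs through sweet/sour field overlap;
#' its correlation with any fingerprint-visible quantity is capped well
#' below 1 by amplitude variance the (scale-invariant) fingerprints cannot
#' see. For network-recovery testing this helper generates outcomes from
#' the quantity the network level can in principle observe: each patient's
#' E-weighted exposure of the planted component's loading map, standardized
#' and scaled exactly like the cohort outcome model (same mean, SD and
#' noise).
#'
#' @param cspec the [cohort_spec()] (outcome scale and noise).
#' @param cohort_data a [generate_cohort()] result (the E-fields).
#' @param conn_data a [generate_connectome()] result.
#' @param seed integer seed for the outcome noise.
#' @return list with `improvement` (percent) and `exposure` (the noiseless
#'   per-patient component exposure).
#' @export
generate_network_outcomes <- function(cspec, cohort_data, conn_data, seed = 1L) {
  mask <- conn_data$connectome$mask
  L1 <- conn_data$truth$loadings[, conn_data$truth$coupled_component]
  exposure <- vapply(cohort_data$fields, function(E) {
    w <- E$grid$values[mask]
    sum(w / sum(w) * L1)
  }, numeric(1L))
  with_seed(seed, {
    z <- (exposure - mean(exposure)) / stats::sd(exposure)
    improvement <- cspec$outcome_mean + cspec$outcome_sd * z +
      stats::rnorm(length(z), sd = cspec$noise_sd)
    list(improvement = improvement, exposure = exposure)
  })
}

#' Generate intraoperative flashback probes
#'
#' Every patient x side x contact x amplitude combination becomes one probe:
#' the varied electrode is driven at one of `n_amplitudes` steps between 1
#' and 10 mA at one of `n_contacts` contacts (stacked dorsally at 3 mm
#' spacing above the implanted ventral-most contact), while the contralateral
#' electrode keeps its chronic setting (`chronic_mA` at its ventral contact)
#' -- emulating test stimulation on one lead at a time. The default
#' (60 patients x 2 sides x 4 contacts x 4 amplitudes = 1920 probes)
#' emulates the published regime of roughly two thousand stimulation
#' volumes.
#'
#' Event probability follows `plogis(alpha + beta * peakE)` where `peakE` is
#' the probe's peak field magnitude on the designated bundle (default: the
#' left paralead bundle 2) and `alpha` is calibrated by root finding so the
#' marginal event rate matches `target_rate`.
#'
#' @param cohort_data a [generate_cohort()] result.
#' @param tract a [generate_tractogram()] result (with bundle labels).
#' @param bundle_index designated event-driving bundle.
#' @param n_contacts contacts per electrode.
#' @param n_amplitudes amplitude steps between 1 and 10 mA.
#' @param chronic_mA fixed contralateral current during testing.
#' @param beta logistic slope per V/mm (0 = events independent of the field).
#' @param target_rate marginal event rate (default 0.03, emulating a
#'   66-in-2054 regime).
#' @param sigma conductivity (S/m).
#' @param seed integer seed (event draws).
#' @param weights optional precomputed `W` from a previous call with the same
#'   cohort/tractogram geometry (the weight matrix is seed-independent).
#' @return list with `probes` ([probe_set()] plus a `side` column), `W`
#'   (probes x fibers peak-weight matrix from the analytic field), `truth`
#'   (designated fiber indices, `peakE`, `alpha`, `beta`).
#' @export
generate_flashback_probes <- function(cohort_data, tract, bundle_index = 2L,
                                      n_contacts = 4L, n_amplitudes = 4L,
                                      chronic_mA = 3, beta = 15,
                                      target_rate = 0.03, sigma = 0.2,
                                      seed = 1L, weights = NULL) {
  stopifnot(!is.null(tract$bundle))
  if (!bundle_index %in% tract$bundle) stop("designated bundle not present")
  contacts <- cohort_data$truth$contacts
  n <- dim(contacts)[1L]
  amps <- seq(1, 10, length.out = n_amplitudes)
  probes <- expand.grid(amp_idx = seq_len(n_amplitudes),
                        contact = seq_len(n_contacts) - 1L,
                        side = 1:2, patient = seq_len(n))
  W <- if (!is.null(weights)) weights else {
    fl <- flatten_tractogram(tract, default_step(cohort_data$grid))
    nf <- n_fibers(tract)
    by_fiber <- split(seq_len(nrow(fl$points)), fl$fiber)
    point_field <- function(pos) {  # V/mm per mA at every fiber point
      d2 <- (fl$points[, 1L] - pos[1L])^2 + (fl$points[, 2L] - pos[2L])^2 +
            (fl$points[, 3L] - pos[3L])^2
      1 / (4 * pi * sigma * pmax(d2, 0.25))
    }
    out <- matrix(0, nrow(probes), nf)
    row <- 0L
    for (p in seq_len(n)) for (s in 1:2) {
      fixed <- chronic_mA * point_field(contacts[p, 3L - s, ])
      for (cc in seq_len(n_contacts)) {
        varied <- point_field(contacts[p, s, ] + c(0, 0, 3 * (cc - 1L)))
        for (a in seq_len(n_amplitudes)) {
          row <- row + 1L
          v <- amps[a] * varied + fixed
          out[row, ] <- vapply(by_fiber, function(ii) max(v[ii]), numeric(1L))
        }
      }
    }
    out
  }
  des_fibers <- which(tract$bundle == bundle_index)
  peakE <- apply(W[, des_fibers, drop = FALSE], 1L, max)
  alpha <- if (beta == 0) stats::qlogis(target_rate) else {
    lo <- -abs(beta) * max(peakE) - 50
    stats::uniroot(function(a) mean(stats::plogis(a + beta * peakE)) - target_rate,
                   c(lo, 50), tol = 1e-10)$root
  }
  with_seed(seed, {
    event <- stats::runif(nrow(probes)) < stats::plogis(alpha + beta * peakE)
    ps <- probe_set(sprintf("P%03d", probes$patient), probes$contact,
                    amps[probes$amp_idx], event)
    ps$side <- c("right", "left")[probes$side]
    list(probes = ps, W = W,
         truth = list(designated_fibers = des_fibers, peakE = peakE,
                      alpha = alpha, beta = beta, seed = as.integer(seed)))
  })
}
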