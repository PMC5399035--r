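# Synthetic cohort generation: three diagnostic groups (HC, SCD, MCI)
# of subjects whose source-space alpha oscillations carry a known
# area-pair PLV structure, projected to magnetometer sensors through
# the spherical forward model, with ages, neuropsychological-like
# scores and hippocampal-volume-like covariates.

GROUPS <- c("HC", "SCD", "MCI")

#' Specification of a synthetic cohort with known connectivity structure
#'
#' Collects every parameter of the generative model. Defaults encode the
#' emulated study conditions: three groups of 39/41/51 subjects, 4-s
#' epochs at 1,000 Hz, per-group clean-epoch counts of 47.6 +/- 7.3
#' (HC), 46.2 +/- 9.4 (SCD) and 42.2 +/- 7.0 (MCI) truncated at the
#' 15-epoch inclusion minimum, group ages of 70.4 +/- 3.7, 71.6 +/- 4.5
#' and 73.0 +/- 3.7 years, normalized hippocampal volumes of
#' 5.0/5.0/4.4 (x 1e-3) with the MCI group lowered, and an effect
#' geometry of 3 hyper-synchronized anterior edges plus 14
#' hypo-synchronized posterior edges in SCD and MCI relative to HC, the
#' posterior decrease being more pronounced in MCI.
#'
#' @param n_subjects named integer vector, subjects per group.
#' @param atlas area table (see [toy_atlas]).
#' @param sources_per_area point sources per area.
#' @param rate sampling rate (Hz).
#' @param epoch_seconds epoch length (s).
#' @param n_epochs either a single count used for every subject, or a
#'   list with `mean`, `sd` (per group) and `min`.
#' @param base_plv baseline area-pair PLV for cross-area pairs, given as
#'   a named list with `anterior`, `posterior`, `between` levels, or a
#'   full area x area matrix (unit diagonal).
#' @param within_area_plv target PLV between distinct sources of the
#'   same area.
#' @param group_effects data.frame with columns `area_a`, `area_b`,
#'   `group`, `delta` (added to the baseline PLV of that edge for that
#'   group); `NULL` for the default effect geometry, an empty data.frame
#'   for a null cohort.
#' @param subject_plv_sd between-subject SD of each edge's target PLV.
#' @param iaf_mean,iaf_sd population distribution of the individual
#'   alpha frequency (Hz).
#' @param age_mean,age_sd per-group age distributions (years).
#' @param hip_mean,hip_sd per-group normalized hippocampal volume.
#' @param score_model list of score definitions (name, intercept,
#'   edges data.frame(area_a, area_b, coef), noise_sd); `NULL` for the
#'   default MMSE-like and BNT-like scores.
#' @param phase_noise_sd,ar_tau phase-noise parameters (see
#'   [simulate_coupled_phases]).
#' @param sensor_noise relative sensor noise: SD of additive white
#'   sensor noise as a fraction of the RMS of the clean sensor signal.
#' @param n_sensors number of magnetometers on the spherical cap.
#' @param seed integer seed (mandatory).
#' @return a `ground_truth_spec` object.
#' @export
ground_truth_spec <- function(n_subjects = c(HC = 39L, SCD = 41L, MCI = 51L),
                              atlas = toy_atlas(),
                              sources_per_area = 2L,
                              rate = 1000,
                              epoch_seconds = 4,
                              n_epochs = list(mean = c(HC = 47.6, SCD = 46.2, MCI = 42.2),
                                              sd = c(HC = 7.3, SCD = 9.4, MCI = 7.0),
                                              min = 15L),
                              base_plv = list(anterior = 0.22, posterior = 0.30,
                                              between = 0.12),
                              within_area_plv = 0.45,
                              group_effects = NULL,
                              subject_plv_sd = 0.03,
                              iaf_mean = 9.4, iaf_sd = 0.5,
                              age_mean = c(HC = 70.4, SCD = 71.6, MCI = 73.0),
                              age_sd = c(HC = 3.7, SCD = 4.5, MCI = 3.7),
                              hip_mean = c(HC = 5.0e-3, SCD = 5.0e-3, MCI = 4.4e-3),
                              hip_sd = c(HC = 0.5e-3, SCD = 0.7e-3, MCI = 0.7e-3),
                              score_model = NULL,
                              phase_noise_sd = 2,
                              ar_tau = 0.5,
                              sensor_noise = 0.1,
                              n_sensors = 60L,
                              seed) {
  if (missing(seed)) stop("`seed` is mandatory in a cohort specification", call. = FALSE)
  stopifnot(all(GROUPS %in% names(n_subjects)))
  if (length(unique(atlas$area)) < 2L) {
    stop("atlas must define at least 2 areas", call. = FALSE)
  }
  if (is.null(group_effects)) group_effects <- default_group_effects(atlas)
  base_mat <- build_base_plv(atlas, base_plv)
  check_effects(base_mat, group_effects, atlas)
  spec <- list(
    n_subjects = n_subjects[GROUPS], atlas = atlas,
    sources_per_area = as.integer(sources_per_area),
    rate = rate, epoch_seconds = epoch_seconds, n_epochs = n_epochs,
    base_plv = base_mat, within_area_plv = within_area_plv,
    group_effects = group_effects, subject_plv_sd = subject_plv_sd,
    iaf_mean = iaf_mean, iaf_sd = iaf_sd,
    age_mean = age_mean[GROUPS], age_sd = age_sd[GROUPS],
    hip_mean = hip_mean[GROUPS], hip_sd = hip_sd[GROUPS],
    score_model = score_model %||% default_score_model(atlas),
    phase_noise_sd = phase_noise_sd, ar_tau = ar_tau,
    sensor_noise = sensor_noise, n_sensors = as.integer(n_sensors),
    seed = as.integer(seed)
  )
  class(spec) <- "ground_truth_spec"
  spec
}

# Baseline area-pair PLV matrix with unit diagonal.
build_base_plv <- function(atlas, base_plv) {
  if (is.matrix(base_plv)) {
    stopifnot(nrow(base_plv) == nrow(atlas), isSymmetric(unname(base_plv)))
    dimnames(base_plv) <- list(atlas$area, atlas$area)
    if (any(diag(base_plv) != 1)) stop("base_plv must have unit diagonal", call. = FALSE)
    return(base_plv)
  }
  n <- nrow(atlas)
  m <- matrix(base_plv$between, n, n, dimnames = list(atlas$area, atlas$area))
  ant <- atlas$region == "anterior"
  m[ant, ant] <- base_plv$anterior
  m[!ant, !ant] <- base_plv$posterior
  diag(m) <- 1
  m
}

# Default effect geometry: 3 anterior edges up, 14 posterior edges down
# for both SCD and MCI relative to HC; the posterior decrease is larger
# in MCI, and three of the posterior edges are spared in SCD (11 down).
default_group_effects <- function(atlas) {
  ant <- atlas$area[atlas$region == "anterior"]
  post <- atlas$area[atlas$region == "posterior"]
  ant_pairs <- utils::combn(ant[c(1, 3, 5)], 2)        # lFMC, lParaC, lITG
  post_pairs <- utils::combn(post, 2)[, 1:14, drop = FALSE]
  eff <- rbind(
    data.frame(area_a = ant_pairs[1, ], area_b = ant_pairs[2, ],
               group = "SCD", delta = 0.15),
    data.frame(area_a = ant_pairs[1, ], area_b = ant_pairs[2, ],
               group = "MCI", delta = 0.15),
    data.frame(area_a = post_pairs[1, 1:11], area_b = post_pairs[2, 1:11],
               group = "SCD", delta = -0.12),
    data.frame(area_a = post_pairs[1, ], area_b = post_pairs[2, ],
               group = "MCI", delta = -0.18)
  )
  rownames(eff) <- NULL
  eff
}

check_effects <- function(base_mat, effects, atlas) {
  if (nrow(effects) == 0L) return(invisible(TRUE))
  stopifnot(all(c("area_a", "area_b", "group", "delta") %in% names(effects)))
  bad <- !(effects$area_a %in% atlas$area) | !(effects$area_b %in% atlas$area)
  if (any(bad)) stop("group_effects reference unknown areas", call. = FALSE)
  if (!all(effects$group %in% GROUPS)) stop("unknown group in group_effects", call. = FALSE)
  tgt <- base_mat[cbind(effects$area_a, effects$area_b)] + effects$delta
  if (any(tgt < 0 | tgt > 1)) {
    stop("a group effect pushes a target PLV outside [0, 1]", call. = FALSE)
  }
  invisible(TRUE)
}

# Default linear score model: posterior connectivity supports general
# cognition and naming (positive weights), anterior hyper-synchronization
# degrades naming (negative weight).
default_score_model <- function(atlas) {
  post <- atlas$area[atlas$region == "posterior"]
  ant <- atlas$area[atlas$region == "anterior"]
  list(
    list(name = "MMSE", intercept = 25.5, noise_sd = 1.1,
         edges = data.frame(area_a = post[c(1, 3)], area_b = post[c(2, 4)],
                            coef = c(6, 6))),
    list(name = "BNT", intercept = 45, noise_sd = 6,
         edges = data.frame(area_a = c(post[1], post[3], ant[1]),
                            area_b = c(post[2], post[4], ant[3]),
                            coef = c(15, 15, -20)))
  )
}

#' Per-group ground-truth edge PLV matrices implied by a specification
#'
#' @param spec a `ground_truth_spec`.
#' @return named list of area x area matrices (HC, SCD, MCI).
#' @export
ground_truth_edges <- function(spec) {
  out <- list()
  for (g in GROUPS) {
    m <- spec$base_plv
    eff <- spec$group_effects[spec$group_effects$group == g, , drop = FALSE]
    if (nrow(eff) > 0L) {
      for (i in seq_len(nrow(eff))) {
        m[eff$area_a[i], eff$area_b[i]] <- m[eff$area_a[i], eff$area_b[i]] + eff$delta[i]
        m[eff$area_b[i], eff$area_a[i]] <- m[eff$area_a[i], eff$area_b[i]]
      }
    }
    out[[g]] <- m
  }
  out
}

# Expand an area-level target matrix to source level: distinct sources
# of the same area couple at `within_area_plv`, cross-area source pairs
# inherit the area-pair target.
expand_to_sources <- function(area_mat, labels, within_area_plv) {
  n <- length(labels)
  m <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      m[i, j] <- if (i == j) 1
      else if (labels[i] == labels[j]) within_area_plv
      else area_mat[labels[i], labels[j]]
    }
  }
  m
}

#' Generate a synthetic three-group MEG-like cohort
#'
#' Draws subjects group by group: per-subject target edge PLVs (group
#' truth plus between-subject jitter), phase series realizing them,
#' cosine source signals, spherical-model magnetometer projections with
#' additive sensor noise, and covariates (age, scores, hippocampal
#' volume). Deterministic given the specification seed.
#'
#' @param spec a [ground_truth_spec].
#' @return a `meg_cohort`: list with `subjects` (list of subject
#'   records), `geometry` (sources, labels, sensors, leadfield truth),
#'   `ground_truth` (per-group edge matrices, effect table, score
#'   model), and `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "ground_truth_spec"))
  geom_seed <- derive_seed(spec$seed, 1L)
  src <- place_area_sources(spec$atlas, spec$sources_per_area, seed = geom_seed)
  sensors <- cap_sensor_array(spec$n_sensors)
  L <- sphere_leadfield(src$positions, src$orientations,
                        sensors$positions, sensors$orientations)
  truth <- ground_truth_edges(spec)
  samples_per_epoch <- round(spec$epoch_seconds * spec$rate)
  area_names <- spec$atlas$area
  pair_idx <- which(upper.tri(spec$base_plv), arr.ind = TRUE)

  subjects <- list()
  sid <- 0L
  for (g in GROUPS) {
    for (i in seq_len(spec$n_subjects[[g]])) {
      sid <- sid + 1L
      s_seed <- derive_seed(spec$seed, 100L + sid)
      rec <- local_seed(s_seed, {
        n_ep <- if (is.list(spec$n_epochs)) {
          max(spec$n_epochs$min,
              round(stats::rnorm(1, spec$n_epochs$mean[[g]], spec$n_epochs$sd[[g]])))
        } else as.integer(spec$n_epochs)
        age <- stats::rnorm(1, spec$age_mean[[g]], spec$age_sd[[g]])
        hip <- stats::rnorm(1, spec$hip_mean[[g]], spec$hip_sd[[g]])
        iaf <- stats::rnorm(1, spec$iaf_mean, spec$iaf_sd)
        # subject-level deviation of each edge from the group truth
        m <- truth[[g]]
        jit <- stats::rnorm(nrow(pair_idx), 0, spec$subject_plv_sd)
        m[pair_idx] <- pmin(0.95, pmax(0.02, m[pair_idx] + jit))
        m[lower.tri(m)] <- t(m)[lower.tri(m)]
        list(n_ep = n_ep, age = age, hip = hip, iaf = iaf, edge_truth = m)
      })
      # project the jittered target onto the feasible coupling set; the
      # projected matrix is the subject's realized ground truth
      src_target <- expand_to_sources(rec$edge_truth, src$labels, spec$within_area_plv)
      R <- nearest_feasible_coupling(plv_to_coupling_raw(src_target, spec$phase_noise_sd))
      realized <- coupling_to_plv(R, spec$phase_noise_sd)
      for (a in seq_along(area_names)) {
        for (b in seq_along(area_names)) {
          if (a < b) {
            ia <- which(src$labels == area_names[a])
            ib <- which(src$labels == area_names[b])
            rec$edge_truth[a, b] <- rec$edge_truth[b, a] <-
              mean(realized[ia, ib])
          }
        }
      }
      # scores: linear in the subject's true edge PLVs plus noise
      scores <- local_seed(derive_seed(s_seed, 7L), {
        out <- numeric(length(spec$score_model))
        names(out) <- vapply(spec$score_model, `[[`, character(1), "name")
        for (j in seq_along(spec$score_model)) {
          sc <- spec$score_model[[j]]
          v <- sc$intercept
          for (k in seq_len(nrow(sc$edges))) {
            v <- v + sc$edges$coef[k] *
              rec$edge_truth[sc$edges$area_a[k], sc$edges$area_b[k]]
          }
          out[j] <- v + stats::rnorm(1, 0, sc$noise_sd)
        }
        out
      })
      phases <- simulate_phases_from_coupling(
        R, n_samples = rec$n_ep * samples_per_epoch,
        rate = spec$rate, center_freq = rec$iaf,
        phase_noise_sd = spec$phase_noise_sd, ar_tau = spec$ar_tau,
        seed = derive_seed(s_seed, 11L)
      )
      sig <- phases_to_source_signals(phases)
      sensor <- L %*% sig
      if (spec$sensor_noise > 0) {
        rms <- sqrt(mean(sensor^2))
        sensor <- sensor + local_seed(derive_seed(s_seed, 13L),
          matrix(stats::rnorm(length(sensor), sd = spec$sensor_noise * rms),
                 nrow(sensor), ncol(sensor)))
      }
      epochs <- segment_epochs(sensor, spec$rate, spec$epoch_seconds,
                               sensors$positions, sensors$orientations)
      subjects[[sid]] <- list(
        subject_id = sprintf("S%03d", sid),
        group = g,
        age = rec$age,
        scores = scores,
        hippocampal_volume = rec$hip,
        iaf_true = rec$iaf,
        edge_plv_true = rec$edge_truth,
        sensor_epochs = epochs
      )
    }
  }
  structure(
    list(
      subjects = subjects,
      geometry = list(atlas = spec$atlas, source_positions = src$positions,
                      source_orientations = src$orientations,
                      source_labels = src$labels,
                      sensor_positions = sensors$positions,
                      sensor_orientations = sensors$orientations,
                      leadfield = L),
      ground_truth = list(edges = truth, effects = spec$group_effects,
                          score_model = spec$score_model,
                          area_names = area_names),
      spec = spec
    ),
    class = "meg_cohort"
  )
}

#' @export
print.meg_cohort <- function(x, ...) {
  grp <- table(factor(vapply(x$subjects, `[[`, character(1), "group"), GROUPS))
  cat(sprintf("<meg_cohort> %d subjects (%s), %d sources / %d areas, %d sensors\n",
              length(x$subjects),
              paste(sprintf("%s: %d", names(grp), grp), collapse = ", "),
              nrow(x$geometry$source_positions),
              length(unique(x$geometry$source_labels)),
              nrow(x$geometry$sensor_positions)))
  invisible(x)
}

#' Covariate table of a cohort
#'
#' @param cohort a `meg_cohort`.
#' @return data.frame with subject_id, group, age, scores and
#'   hippocampal volume (one row per subject).
#' @export
cohort_covariates <- function(cohort) {
  rows <- lapply(cohort$subjects, function(s) {
    data.frame(subject_id = s$subject_id, group = s$group, age = s$age,
               t(s$scores), hippocampal_volume = s$hippocampal_volume,
               n_epochs = n_epochs(s$sensor_epochs),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$group <- factor(out$group, levels = GROUPS)
  out
}

#' Write a cohort to a directory of plain-text files
#'
#' One directory per subject with the epoched sensor data as CSV
#' (long format: epoch, channel, then one column per sample), a single
#' covariate CSV for the cohort, the ground truth as JSON and the sensor
#' geometry as CSV.
#'
#' @param cohort a `meg_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort_covariates(cohort),
                   file.path(dir, "covariates.csv"), row.names = FALSE)
  geom <- cohort$geometry
  utils::write.csv(
    data.frame(label = geom$source_labels, geom$source_positions,
               geom$source_orientations),
    file.path(dir, "sources.csv"), row.names = FALSE)
  utils::write.csv(
    data.frame(geom$sensor_positions, geom$sensor_orientations),
    file.path(dir, "sensors.csv"), row.names = FALSE)
  gt <- cohort$ground_truth
  jsonlite::write_json(
    list(edges = lapply(gt$edges, function(m) as.data.frame(as.table(m))),
         effects = gt$effects, area_names = gt$area_names,
         seed = cohort$spec$seed),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  for (s in cohort$subjects) {
    sd_ <- file.path(dir, s$subject_id)
    dir.create(sd_, showWarnings = FALSE)
    d <- s$sensor_epochs$data
    flat <- do.call(rbind, lapply(seq_len(dim(d)[1]), function(e) {
      cbind(epoch = e, channel = seq_len(dim(d)[2]), d[e, , , drop = TRUE])
    }))
    utils::write.csv(as.data.frame(flat), file.path(sd_, "epochs.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(rate = s$sensor_epochs$rate, group = s$group,
                              subject_id = s$subject_id),
                         file.path(sd_, "meta.json"), auto_unbox = TRUE)
  }
  invisible(dir)
}
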