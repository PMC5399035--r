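# End-to-end orchestration: generate (or accept) a cohort, preprocess,
# detect the alpha band, beamform, estimate area PLV connectivity, and
# run the group statistics, with a manifest recording every parameter.

#' Default pipeline configuration
#'
#' @param seed master seed (mandatory for a valid config).
#' @return a nested list understood by [run_pipeline].
#' @export
default_config <- function(seed = NULL) {
  list(
    seed = seed,
    band = list(mode = "sample-average",      # or "per-subject"
                search_range = c(6, 13)),
    filter = list(order = 1800L, pad_samples = 2000L),
    # amplitude/jump z thresholds; the jump threshold is set above the
    # heavy right tail that clean narrowband oscillations produce in the
    # first-difference statistic (instantaneous-frequency fluctuations),
    # while still catching order-of-magnitude artifact spikes
    artifact = list(amplitude_z = 8, jump_z = 12),
    min_epochs = 15L,
    beamformer = list(regularization = 0.05,
                      orientation = "fixed"), # or "max-power"
    connectivity = list(pad_samples = 2000L),
    stats = list(n_perm = 10000L, Q = 0.05),
    rsn = default_rsn_definitions()
  )
}

#' Validate a pipeline configuration
#'
#' @param config a configuration list (see [default_config]).
#' @return character vector of problems; empty when the config is valid.
#' @export
validate_config <- function(config) {
  errs <- character(0)
  add <- function(msg) errs <<- c(errs, msg)
  if (is.null(config$seed) || !is.numeric(config$seed) || length(config$seed) != 1L) {
    add("`seed` is missing or not a single number")
  }
  if (!is.null(config$stats)) {
    Q <- config$stats$Q
    if (is.null(Q) || Q <= 0 || Q >= 1) add("`stats$Q` must lie in (0, 1)")
    np <- config$stats$n_perm
    if (is.null(np) || np < 100) add("`stats$n_perm` must be at least 100")
  } else add("`stats` section missing")
  bm <- config$band$mode
  if (is.null(bm) || !bm %in% c("sample-average", "per-subject")) {
    add("`band$mode` must be 'sample-average' or 'per-subject'")
  }
  if (!is.null(config$filter)) {
    if ((config$filter$order %||% 0) <= 0) add("`filter$order` must be positive")
    if ((config$filter$pad_samples %||% -1) < 0) add("`filter$pad_samples` must be >= 0")
  }
  if ((config$min_epochs %||% 0) < 1) add("`min_epochs` must be >= 1")
  if (!is.null(config$rsn)) {
    if (length(intersect(config$rsn$aDMN, config$rsn$pDMN)) > 0L) {
      add("aDMN and pDMN must be disjoint")
    }
    short <- names(config$rsn)[vapply(config$rsn, length, 1L) < 2L]
    if (length(short) > 0L) add(paste("RSN(s) with fewer than 2 members:",
                                      paste(short, collapse = ", ")))
  }
  errs
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; keys override [default_config].
#' @return validated configuration list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  config <- utils::modifyList(default_config(), user)
  errs <- validate_config(config)
  if (length(errs) > 0L) {
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "),
         call. = FALSE)
  }
  config
}

# Per-subject analysis: artifact rejection, band-pass, covariance,
# LCMV, Hilbert phases, area PLV.  `band` may be NULL to stop after
# IAF detection (first pass of the sample-average banding mode).
analyze_subject <- function(subject, geometry, config, band = NULL) {
  ep <- subject$sensor_epochs
  rej <- reject_artifact_epochs(ep, config$artifact$amplitude_z,
                                config$artifact$jump_z)
  ep <- rej$epochs
  if (!enforce_min_epochs(ep, config$min_epochs)) {
    return(list(excluded = TRUE, n_epochs = n_epochs(ep),
                rejection_log = rej$log))
  }
  if (is.null(band)) {
    spec <- power_spectrum(ep, posterior_channels(ep))
    iaf <- detect_iaf(spec, config$band$search_range)
    return(list(excluded = FALSE, iaf = iaf, epochs = ep,
                rejection_log = rej$log))
  }
  filt <- bandpass_fir(ep, band, config$filter$order, config$filter$pad_samples)
  C <- epoch_covariance(filt)
  labels <- geometry$source_labels
  if (identical(config$beamformer$orientation, "max-power")) {
    Lfree <- sphere_leadfield(geometry$source_positions, NULL,
                              geometry$sensor_positions,
                              geometry$sensor_orientations)
    coll <- max_power_orientation(Lfree, C, config$beamformer$regularization)
    L <- coll$leadfield
  } else {
    L <- geometry$leadfield
  }
  bf <- lcmv_weights(L, C, config$beamformer$regularization)
  src <- apply_weights(bf, filt)
  ph <- hilbert_phase(src, config$connectivity$pad_samples, rate = ep$rate)
  conn <- plv_area(ph, labels)
  list(excluded = FALSE, connectivity = conn, filter = bf,
       n_epochs = n_epochs(ep), rejection_log = rej$log)
}

#' Run the full resting-state connectivity pipeline
#'
#' Executes, for every subject of a (given or generated) cohort:
#' artifact rejection and the minimum-epoch rule, posterior-channel IAF
#' detection, band definition (sample-average IAF by default), zero-
#' phase FIR band-pass, LCMV beamforming on the epoch-averaged
#' covariance, Hilbert phases and area-averaged PLV; then edge-wise
#' permutation ANCOVA with FDR and Tukey contrasts, RSN comparisons,
#' beamformer-weight leakage diagnostics, hippocampal-volume ANCOVA and
#' score correlations. Deterministic given `config$seed`.
#'
#' @param config configuration list (see [default_config]); must
#'   validate.
#' @param cohort a `meg_cohort`; when `NULL`, one is generated from
#'   `spec`.
#' @param spec optional [ground_truth_spec] used when `cohort` is NULL.
#' @param out_dir optional directory for CSV/JSON artifacts.
#' @return a `pipeline_result` list: `band`, `connectivity` (subjects x
#'   edges), `edge_stats`, `rsn`, `leakage`, `hippocampus`,
#'   `correlations`, `design`, `group_matrices`, `manifest`.
#' @export
run_pipeline <- function(config, cohort = NULL, spec = NULL, out_dir = NULL) {
  errs <- validate_config(config)
  if (length(errs) > 0L) {
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "),
         call. = FALSE)
  }
  if (is.null(cohort)) {
    if (is.null(spec)) stop("either a cohort or a generator spec is required",
                            call. = FALSE)
    cohort <- generate_cohort(spec)
  }
  geometry <- cohort$geometry

  # pass 1: inclusion + IAF per subject
  first <- lapply(cohort$subjects, function(s) {
    tryCatch(analyze_subject(s, geometry, config, band = NULL),
             error = function(e) stop(sprintf("subject %s, preprocessing: %s",
                                              s$subject_id, conditionMessage(e)),
                                      call. = FALSE))
  })
  included <- !vapply(first, `[[`, logical(1), "excluded")
  if (sum(included) < 6L) stop("fewer than 6 subjects pass the epoch rule", call. = FALSE)
  iafs <- vapply(first[included], `[[`, numeric(1), "iaf")
  band_mode <- config$band$mode
  sample_band <- define_band(mean(iafs))

  # pass 2: connectivity per included subject
  subjects <- cohort$subjects[included]
  results <- vector("list", length(subjects))
  for (i in seq_along(subjects)) {
    band_i <- if (band_mode == "per-subject") define_band(first[included][[i]]$iaf)
    else sample_band
    results[[i]] <- tryCatch(
      analyze_subject(subjects[[i]], geometry, config, band = band_i),
      error = function(e) stop(sprintf("subject %s, connectivity: %s",
                                       subjects[[i]]$subject_id,
                                       conditionMessage(e)), call. = FALSE))
  }

  area_names <- results[[1]]$connectivity$area_names
  ut <- which(upper.tri(results[[1]]$connectivity$plv), arr.ind = TRUE)
  edge_names <- paste(area_names[ut[, 1]], area_names[ut[, 2]], sep = "--")
  conn_mat <- t(vapply(results, function(r) r$connectivity$plv[ut],
                       numeric(nrow(ut))))
  colnames(conn_mat) <- edge_names
  leak_mat <- t(vapply(results, function(r) {
    weight_correlation_matrix(r$filter, geometry$source_labels)[ut]
  }, numeric(nrow(ut))))
  colnames(leak_mat) <- edge_names

  design <- make_design(
    group = vapply(subjects, `[[`, character(1), "group"),
    age = vapply(subjects, `[[`, numeric(1), "age"),
    subject_ids = vapply(subjects, `[[`, character(1), "subject_id")
  )

  n_perm <- config$stats$n_perm
  Q <- config$stats$Q
  seed <- config$seed
  es <- edge_stats(conn_mat, design, n_perm, Q, seed = derive_seed(seed, 21L))
  leak <- edge_stats(leak_mat, design, n_perm, Q, seed = derive_seed(seed, 22L))

  rsn_vals <- vapply(results, function(r) {
    vapply(config$rsn, function(m) rsn_average(r$connectivity, m), numeric(1))
  }, numeric(length(config$rsn)))
  rsn_vals <- t(rsn_vals)
  rsn_tests <- lapply(seq_along(config$rsn), function(k) {
    compare_scalar_ancova(rsn_vals[, k], design, n_perm,
                          seed = derive_seed(seed, 30L + k),
                          name = names(config$rsn)[k])
  })
  names(rsn_tests) <- names(config$rsn)

  hip <- vapply(subjects, `[[`, numeric(1), "hippocampal_volume")
  hip_test <- compare_scalar_ancova(hip, design, n_perm,
                                    seed = derive_seed(seed, 40L),
                                    name = "hippocampal_volume")

  scores <- do.call(rbind, lapply(subjects, function(s) s$scores))
  scores <- cbind(scores, hippocampal_volume = hip)
  cors <- correlate_scores(conn_mat, scores, Q)

  # group mean / SD connectivity matrices
  group_matrices <- lapply(GROUPS, function(g) {
    sel <- design$group == g
    m_mean <- s_sd <- matrix(NA_real_, length(area_names), length(area_names),
                             dimnames = list(area_names, area_names))
    m_mean[ut] <- colMeans(conn_mat[sel, , drop = FALSE])
    s_sd[ut] <- apply(conn_mat[sel, , drop = FALSE], 2, stats::sd)
    m_mean[cbind(ut[, 2], ut[, 1])] <- m_mean[ut]
    s_sd[cbind(ut[, 2], ut[, 1])] <- s_sd[ut]
    list(mean = m_mean, sd = s_sd)
  })
  names(group_matrices) <- GROUPS

  # analytic link significance per group (on the group-mean PLV)
  T_seg <- results[[1]]$connectivity$T
  link_sig <- lapply(GROUPS, function(g) {
    pm <- group_matrices[[g]]$mean[ut]
    p <- plv_significance(pm, T_seg)
    fdr_bh(p, Q)$rejected
  })
  names(link_sig) <- GROUPS

  manifest <- list(
    seed = seed, n_perm = n_perm, Q = Q, band_mode = band_mode,
    band = list(iaf = sample_band$iaf, low = sample_band$low_edge,
                high = sample_band$high_edge),
    filter = config$filter, beamformer = config$beamformer,
    min_epochs = config$min_epochs,
    n_subjects_included = sum(included),
    n_subjects_excluded = sum(!included),
    areas = area_names
  )

  result <- structure(list(
    band = sample_band, iafs = iafs, design = design,
    connectivity = conn_mat, edge_stats = es,
    leakage = list(values = leak_mat, stats = leak),
    rsn = list(values = rsn_vals, tests = rsn_tests),
    hippocampus = hip_test, correlations = cors,
    group_matrices = group_matrices, link_significant = link_sig,
    manifest = manifest
  ), class = "pipeline_result")

  if (!is.null(out_dir)) write_pipeline_result(result, out_dir)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  n_disc <- sum(x$edge_stats$table$fdr_rejected)
  cat(sprintf(
    "<pipeline_result> %d subjects, band %.3g-%.3g Hz (IAF %.3g Hz), %d edges, %d FDR discoveries\n",
    nrow(x$design), x$band$low_edge, x$band$high_edge, x$band$iaf,
    ncol(x$connectivity), n_disc))
  invisible(x)
}

#' Write pipeline artifacts to a directory
#'
#' Edge statistics, pairwise contrasts, RSN tests, correlations, group
#' mean/SD matrices and the run manifest, all as CSV/JSON.
#'
#' @param result a `pipeline_result`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_pipeline_result <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$edge_stats$table,
                   file.path(dir, "edge_stats.csv"), row.names = FALSE)
  if (!is.null(result$edge_stats$pairwise)) {
    utils::write.csv(result$edge_stats$pairwise,
                     file.path(dir, "edge_pairwise.csv"), row.names = FALSE)
  }
  utils::write.csv(result$correlations,
                   file.path(dir, "score_correlations.csv"), row.names = FALSE)
  rsn_tab <- do.call(rbind, lapply(names(result$rsn$tests), function(nm) {
    t_ <- result$rsn$tests[[nm]]
    data.frame(network = nm, F = t_$F, p = t_$p, stringsAsFactors = FALSE)
  }))
  utils::write.csv(rsn_tab, file.path(dir, "rsn_stats.csv"), row.names = FALSE)
  for (g in names(result$group_matrices)) {
    utils::write.csv(result$group_matrices[[g]]$mean,
                     file.path(dir, sprintf("connectivity_mean_%s.csv", g)))
    utils::write.csv(result$group_matrices[[g]]$sd,
                     file.path(dir, sprintf("connectivity_sd_%s.csv", g)))
  }
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
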