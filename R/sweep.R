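#' Dispersion-delay sweep configuration
#'
#' The second-scan timing of FPA2 is swept over dispersion delays
#' `d_values` (default 0 to 13.5 s in 1.5 s steps, labeled t1..t10). A
#' timing is "optimum" when its FPA2-vs-MSM Pearson correlation exceeds
#' `r_threshold_mean` for subject-level circular-ROI means and
#' `r_threshold_voxel` for pooled voxelwise values in the polygonal ROIs.
#'
#' @param d_values dispersion delays, seconds; non-empty, non-negative,
#'   increasing.
#' @param r_threshold_mean correlation cutoff for circular-ROI means
#'   (default 0.90).
#' @param r_threshold_voxel correlation cutoff for voxelwise values
#'   (default 0.70).
#' @return a `sweep_config` object.
#' @export
sweep_config <- function(d_values = seq(0, 13.5, by = 1.5),
                         r_threshold_mean = 0.90,
                         r_threshold_voxel = 0.70) {
  if (length(d_values) < 1) stop("d_values must be non-empty")
  if (any(d_values < 0)) stop("d_values must be non-negative")
  if (length(d_values) > 1 && any(diff(d_values) <= 0)) {
    stop("d_values must be increasing")
  }
  structure(list(d_values = as.numeric(d_values),
                 r_threshold_mean = r_threshold_mean,
                 r_threshold_voxel = r_threshold_voxel),
            class = "sweep_config")
}

# longest contiguous run of TRUE; first such run on ties; integer(0) if none
max_contig_run <- function(pass) {
  r <- rle(pass)
  if (!any(r$values)) return(integer(0))
  len <- ifelse(r$values, r$lengths, 0L)
  k <- which.max(len)
  start <- if (k == 1) 1L else sum(r$lengths[seq_len(k - 1)]) + 1L
  seq.int(start, start + r$lengths[k] - 1L)
}

# per-subject measurements used by the sweep: maps are reduced to circular-ROI
# means and polygonal voxel vectors per tissue
measure_subject_map <- function(map, masks) {
  list(
    circ = c(carcinoma = unname(map_stats(map, masks$carcinoma_circ)["mean"]),
             parenchyma = unname(map_stats(map, masks$parenchyma_circ)["mean"])),
    vox = list(carcinoma = map$bf[masks$carcinoma_poly$mask],
               parenchyma = map$bf[masks$parenchyma_poly$mask])
  )
}

#' Run the FPA-vs-MSM acquisition-timing sweep over a cohort
#'
#' For every subject: extracts the aortic AIF (baseline from the pre-trigger
#' frames), computes the MSM reference map, the FPA1 map (second scan at the
#' AIF peak) and one FPA2 map per dispersion delay in `sweep$d_values`. For
#' every timing it then reports, pooling carcinoma and parenchyma:
#'
#' * `r_mean_rois` — Pearson r between FPA and MSM subject-level circular-ROI
#'   mean BF (needs >= 2 subjects; `NA` and a degeneracy flag otherwise);
#' * `r_voxelwise` — Pearson r between FPA and MSM over all voxels of the
#'   polygonal ROIs of all subjects;
#' * per-tissue BF mean/SD across subjects for both ROI kinds, and the
#'   carcinoma-vs-parenchyma Student t-test on circular-ROI means and on
#'   pooled polygonal voxels.
#'
#' Timing sensitivity is summarized per tissue as the coefficient of
#' variation of circular-ROI mean BF across the FPA2 timings, computed per
#' subject and averaged (primary), with a cohort-mean variant and polygonal
#' variants alongside. The optimum range is the longest contiguous run of
#' timings whose correlations exceed both sweep thresholds (a mean-only run
#' is also reported).
#'
#' Subjects whose AIF never crosses the trigger threshold are skipped with a
#' warning and listed in the result.
#'
#' @param cohort list of `synthetic_subject` objects (or any objects with
#'   `series` and the five standard masks).
#' @param sweep a [sweep_config()].
#' @param fpa_cfg template [fpa_config()]; its variant/dispersion are
#'   overridden per timing.
#' @param msm_cfg an [msm_config()].
#' @return a `sweep_result` list: `records` (one data.frame row per timing),
#'   `bf_table` (timing x tissue x ROI kind mean/SD), `cov` (per-tissue COV
#'   summaries, percent), `optimum` (labels and d-range), `skipped`,
#'   `n_subjects`, plus the configurations used.
#' @export
run_sweep <- function(cohort, sweep = sweep_config(),
                      fpa_cfg = fpa_config(variant = "fpa2"),
                      msm_cfg = msm_config()) {
  if (length(cohort) < 1) stop("cohort must be non-empty")
  need <- c("aorta", "carcinoma_circ", "carcinoma_poly",
            "parenchyma_circ", "parenchyma_poly")

  d_values <- sweep$d_values
  labels <- c("fpa1", paste0("t", seq_along(d_values)))
  measures <- vector("list", length(cohort))
  skipped <- integer(0)

  for (i in seq_along(cohort)) {
    subj <- cohort[[i]]
    if (!all(need %in% names(subj$masks))) {
      stop(sprintf("subject %d is missing masks: %s", i,
                   paste(setdiff(need, names(subj$masks)), collapse = ", ")))
    }
    aif0 <- extract_tac(subj$series, subj$masks$aorta)
    tb <- tryCatch(find_tbase(aif0, fpa_cfg$trigger_threshold),
                   error = function(e) NA_integer_)
    if (is.na(tb)) {
      warning(sprintf("subject %d skipped: trigger never fired", i))
      skipped <- c(skipped, i)
      next
    }
    aif <- extract_tac(subj$series, subj$masks$aorta, tbase = tb)
    compartment <- roi_mask(
      subj$masks$carcinoma_poly$mask | subj$masks$parenchyma_poly$mask,
      "pancreas", "polygonal"
    )

    msm <- msm_map(subj$series, aif, msm_cfg)
    per_timing <- vector("list", length(labels))
    names(per_timing) <- labels
    for (lab in labels) {
      cfg <- fpa_cfg
      if (lab == "fpa1") {
        cfg$variant <- "fpa1"
      } else {
        cfg$variant <- "fpa2"
        cfg$dispersion_d <- d_values[match(lab, labels) - 1L]
      }
      per_timing[[lab]] <- measure_subject_map(
        fpa_map(subj$series, aif, cfg, compartment), subj$masks
      )
    }
    measures[[i]] <- list(msm = measure_subject_map(msm, subj$masks),
                          fpa = per_timing)
  }

  keep <- setdiff(seq_along(cohort), skipped)
  if (length(keep) == 0) stop("all subjects skipped: trigger never fired")
  measures <- measures[keep]
  n_sub <- length(measures)
  tissues <- c("carcinoma", "parenchyma")

  msm_circ <- t(vapply(measures, function(m) m$msm$circ, numeric(2)))
  msm_vox <- lapply(tissues, function(ts)
    unlist(lapply(measures, function(m) m$msm$vox[[ts]]), use.names = FALSE))
  names(msm_vox) <- tissues

  records <- do.call(rbind, lapply(labels, function(lab) {
    fpa_circ <- t(vapply(measures, function(m) m$fpa[[lab]]$circ, numeric(2)))
    fpa_vox <- lapply(tissues, function(ts)
      unlist(lapply(measures, function(m) m$fpa[[lab]]$vox[[ts]]), use.names = FALSE))
    names(fpa_vox) <- tissues

    r_mean <- if (n_sub >= 2) pearson(as.vector(fpa_circ), as.vector(msm_circ)) else NA_real_
    r_vox <- pearson(unlist(fpa_vox, use.names = FALSE),
                     unlist(msm_vox, use.names = FALSE))
    tc <- if (n_sub >= 2) {
      tissue_contrast(fpa_circ[, "carcinoma"], fpa_circ[, "parenchyma"])
    } else {
      c(t = NA_real_, p = NA_real_)
    }
    tv <- tissue_contrast(fpa_vox$carcinoma, fpa_vox$parenchyma)
    data.frame(
      timing = lab,
      d = if (lab == "fpa1") NA_real_ else d_values[match(lab, labels) - 1L],
      r_mean_rois = r_mean, r_voxelwise = r_vox,
      t_circ = tc[["t"]], p_circ = tc[["p"]], p_voxel = tv[["p"]],
      stringsAsFactors = FALSE
    )
  }))
  rownames(records) <- NULL

  bf_table <- do.call(rbind, lapply(labels, function(lab) {
    do.call(rbind, lapply(tissues, function(ts) {
      circ <- vapply(measures, function(m) m$fpa[[lab]]$circ[[ts]], numeric(1))
      vox_means <- vapply(measures, function(m) mean(m$fpa[[lab]]$vox[[ts]]), numeric(1))
      data.frame(timing = lab, tissue = ts,
                 roi_kind = c("circular", "polygonal"),
                 mean = c(mean(circ), mean(vox_means)),
                 sd = c(stats::sd(circ), stats::sd(vox_means)),
                 stringsAsFactors = FALSE)
    }))
  }))
  msm_rows <- do.call(rbind, lapply(tissues, function(ts) {
    circ <- msm_circ[, ts]
    vox_means <- vapply(measures, function(m) mean(m$msm$vox[[ts]]), numeric(1))
    data.frame(timing = "msm", tissue = ts,
               roi_kind = c("circular", "polygonal"),
               mean = c(mean(circ), mean(vox_means)),
               sd = c(stats::sd(circ), stats::sd(vox_means)),
               stringsAsFactors = FALSE)
  }))
  bf_table <- rbind(bf_table, msm_rows)
  rownames(bf_table) <- NULL

  # COV across FPA2 timings of circular/polygonal-ROI mean BF, per tissue
  fpa2_labels <- setdiff(labels, "fpa1")
  cov_summary <- function(get_value) {
    per_subject <- vapply(measures, function(m) {
      cov_percent(vapply(fpa2_labels, function(lab) get_value(m, lab), numeric(1)))
    }, numeric(1))
    cohort_means <- vapply(fpa2_labels, function(lab) {
      mean(vapply(measures, function(m) get_value(m, lab), numeric(1)))
    }, numeric(1))
    c(per_subject_mean = mean(per_subject), cohort_mean = cov_percent(cohort_means))
  }
  cov <- list(
    carcinoma = cov_summary(function(m, lab) m$fpa[[lab]]$circ[["carcinoma"]]),
    parenchyma = cov_summary(function(m, lab) m$fpa[[lab]]$circ[["parenchyma"]]),
    carcinoma_poly = cov_summary(function(m, lab) mean(m$fpa[[lab]]$vox$carcinoma)),
    parenchyma_poly = cov_summary(function(m, lab) mean(m$fpa[[lab]]$vox$parenchyma))
  )

  fpa2 <- records[records$timing != "fpa1", ]
  pass_mean <- !is.na(fpa2$r_mean_rois) & fpa2$r_mean_rois > sweep$r_threshold_mean
  pass_both <- pass_mean & fpa2$r_voxelwise > sweep$r_threshold_voxel
  run_both <- max_contig_run(pass_both)
  run_mean <- max_contig_run(pass_mean)
  optimum <- list(
    labels = fpa2$timing[run_both],
    d_range = if (length(run_both)) range(fpa2$d[run_both]) else c(NA_real_, NA_real_),
    labels_mean_only = fpa2$timing[run_mean],
    d_range_mean_only = if (length(run_mean)) range(fpa2$d[run_mean]) else c(NA_real_, NA_real_)
  )

  structure(list(records = records, bf_table = bf_table, cov = cov,
                 optimum = optimum, skipped = skipped, n_subjects = n_sub,
                 degenerate_mean_r = n_sub < 2,
                 sweep = sweep, fpa_cfg = fpa_cfg, msm_cfg = msm_cfg),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> %d subjects (%d skipped), %d FPA2 timings\n",
              x$n_subjects, length(x$skipped), sum(x$records$timing != "fpa1")))
  print(x$records, digits = 3)
  cat(sprintf("COV (per-subject mean, %%): carcinoma %.1f, parenchyma %.1f\n",
              x$cov$carcinoma[["per_subject_mean"]],
              x$cov$parenchyma[["per_subject_mean"]]))
  if (length(x$optimum$labels)) {
    cat(sprintf("optimum timings: %s (d = %g..%g s)\n",
                paste(x$optimum$labels, collapse = ", "),
                x$optimum$d_range[1], x$optimum$d_range[2]))
  } else {
    cat("optimum timings: none passed both correlation thresholds\n")
  }
  invisible(x)
}

#' Recommended second-scan delay window after the trigger
#'
#' Translates the optimum dispersion-delay range of a sweep into the
#' second-scan delay window after `t_base` via `t_p = t_i/2 + d` applied to
#' the first and last optimum delays.
#'
#' @param result a `sweep_result` from [run_sweep()], or a list with an
#'   `optimum$d_range` element.
#' @param t_i injection duration, seconds.
#' @return numeric `c(lower, upper)` in seconds after `t_base`.
#' @examples
#' # d in [7.5, 12] with t_i = 16 s gives a 15.5-20.0 s window
#' @export
optimum_delay_window <- function(result, t_i) {
  d_range <- result$optimum$d_range
  if (is.null(d_range) || any(is.na(d_range))) stop("empty optimum range")
  c(compute_tp(t_i, d_range[1]), compute_tp(t_i, d_range[2]))
}
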