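#' Integer truth-label volume of a phantom spec
#'
#' Assigns label `i` to the full (one-sided) support of the `i`-th effect
#' blob. This volume plays the role an anatomical parcellation plays for
#' real data: ROI construction ([combine_labels()], [symmetrize()]) and
#' cluster localization resolve against it.
#'
#' @param spec A [phantom_spec()] (or a `cohort`, whose spec is used).
#' @return List with `volume` (integer-label `vol`) and `labels`
#'   (data.frame: id, name, tissue).
#' @export
truth_label_volume <- function(spec) {
  if (inherits(spec, "cohort")) spec <- spec$spec
  lab <- array(0, dim = spec$grid_shape)
  rows <- NULL
  for (i in seq_along(spec$effect_blobs)) {
    nm <- names(spec$effect_blobs)[i]
    b <- spec$effect_blobs[[nm]]
    p <- one_sided_profile(spec, b)
    lab[p > 0] <- i
    rows <- rbind(rows, data.frame(id = i, name = nm, tissue = b$tissue,
                                   stringsAsFactors = FALSE))
  }
  list(volume = vol(lab, centered_affine(spec$grid_shape,
                                         spec$voxel_size_mm), "phantom"),
       labels = rows)
}

#' Default study configuration
#'
#' Analysis parameters of the standard asymmetry study: 10 mm FWHM
#' smoothing of the AI maps, cluster-forming voxel p of 0.001, cluster FWE
#' level 0.05, cluster-mass statistic, age and gender as nuisance
#' covariates, and the monaural speech-in-noise score as the behavioral
#' covariate for the ROI-restricted correlation.
#'
#' @param ... Overrides for any configuration entry.
#' @return A named list.
#' @export
study_config <- function(...) {
  cfg <- list(
    tissues = c("GM", "WM"),
    eps = 0.05,
    fwhm_mm = 10,
    cluster_forming_p = 0.001,
    cluster_alpha = 0.05,
    statistic = "mass",
    B = 999,
    seed = 1L,
    covariates = c("age", "gender"),
    behavioral_covariate = "score_monaural",
    correlation_tissues = c("GM", "WM"),
    connectivity = 18)
  over <- list(...)
  cfg[names(over)] <- over
  if (!(cfg$cluster_forming_p > 0 && cfg$cluster_forming_p < 1) ||
      !(cfg$cluster_alpha > 0 && cfg$cluster_alpha < 1))
    stop("config error: probabilities must lie in (0, 1)")
  cfg
}

#' Run the full asymmetry study on a cohort
#'
#' Executes the study replica end to end: (1) cohort simulation (or use of
#' a supplied cohort); (2) smoothed GM/WM asymmetry-index maps; (3)
#' per-group one-sample asymmetry inference with age and gender
#' covariates; (4) the two-sample group contrast; (5) ROI-restricted
#' (small-volume-corrected) correlation between the behavioral covariate
#' and AI, per group; (6) post-hoc characterization at the strongest
#' group-difference peak (tissue-value extraction at the mirrored pair,
#' Group-by-Hemisphere ANOVA with LSD, Levene test on AI values). Outputs
#' and a provenance manifest are written under `out_dir` when given.
#'
#' By default both age and gender stay in the correlation design alongside
#' the behavioral covariate (set `covariates = character()` in the config
#' to drop them).
#'
#' @param spec A [phantom_spec()] used to simulate the cohort, or an
#'   existing `cohort`.
#' @param config A [study_config()] list.
#' @param out_dir Optional output directory for tables, maps, report and
#'   manifest.
#' @return A `study_run` list: `cohort`, `config`, `ai` (per tissue, list
#'   of per-subject `asym_map`s), `one_sample` (per tissue, per group),
#'   `two_sample` (per tissue), `correlation` (per tissue, per group),
#'   `posthoc`, `roi`, `out_dir`.
#' @export
run_study <- function(spec, config = study_config(), out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  ## (1) cohort
  cohort <- stage("simulate", {
    if (inherits(spec, "cohort")) spec
    else simulate_cohort(spec, tissues = config$tissues)
  })
  sp <- cohort$spec
  subjects <- cohort$subjects

  ## (2) AI maps
  ai <- stage("asymmetry_maps", {
    out <- list()
    for (tis in config$tissues) {
      maps <- if (tis == "GM") cohort$gm_maps else cohort$wm_maps
      out[[tis]] <- lapply(maps, function(v)
        smooth_ai(compute_ai(v, eps = config$eps, source_tissue = tis),
                  config$fwhm_mm))
    }
    out
  })

  ## (3) per-group one-sample asymmetry
  one_sample <- stage("one_sample", {
    out <- list()
    for (tis in config$tissues) {
      out[[tis]] <- list()
      for (g in c("control", "patient")) {
        rows <- which(subjects$group == g)
        des <- glm_design(subjects[rows, , drop = FALSE], "one_sample",
                          covariates = config$covariates)
        out[[tis]][[g]] <- permutation_fwe(
          ai[[tis]][rows], des, B = config$B,
          cluster_forming_p = config$cluster_forming_p,
          cluster_alpha = config$cluster_alpha,
          statistic = config$statistic,
          connectivity = config$connectivity, seed = config$seed)
      }
    }
    out
  })

  ## (4) two-sample group contrast
  two_sample <- stage("two_sample", {
    out <- list()
    des <- glm_design(subjects, "two_sample",
                      covariates = config$covariates)
    for (tis in config$tissues)
      out[[tis]] <- permutation_fwe(
        ai[[tis]], des, B = config$B,
        cluster_forming_p = config$cluster_forming_p,
        cluster_alpha = config$cluster_alpha,
        statistic = config$statistic,
        connectivity = config$connectivity, seed = config$seed)
    out
  })

  ## (5) ROI-restricted correlation per group
  truth_labels <- truth_label_volume(sp)
  correlation <- stage("correlation", {
    out <- list()
    for (tis in intersect(config$correlation_tissues, config$tissues)) {
      ids <- truth_labels$labels$id[truth_labels$labels$tissue == tis]
      if (!length(ids)) next
      roi <- symmetrize(combine_labels(truth_labels$volume, ids,
                                       name = paste0(tis, "_roi")), "union")
      out[[tis]] <- list(roi = roi)
      for (g in c("control", "patient")) {
        rows <- which(subjects$group == g)
        des <- glm_design(subjects[rows, , drop = FALSE], "covariate",
                          covariates = config$covariates,
                          covariate = config$behavioral_covariate)
        out[[tis]][[g]] <- small_volume_correct(
          ai[[tis]][rows], des, roi$mask, B = config$B,
          cluster_forming_p = config$cluster_forming_p,
          cluster_alpha = config$cluster_alpha,
          statistic = config$statistic,
          connectivity = config$connectivity, seed = config$seed)
      }
    }
    out
  })

  ## (6) post-hoc at the strongest group-difference peak
  posthoc <- stage("posthoc", {
    out <- list()
    for (tis in config$tissues) {
      tab <- two_sample[[tis]]$clusters
      if (!nrow(tab)) next
      best <- tab[which.max(tab$t_max), ]
      peak <- c(best$peak_x, best$peak_y, best$peak_z)
      tissue_maps <- if (tis == "GM") cohort$gm_maps else cohort$wm_maps
      smoothed <- lapply(tissue_maps, smooth_gaussian,
                         fwhm_mm = config$fwhm_mm)
      ex <- extract_peak_values(smoothed, peak, subjects$group)
      ai_at_peak <- vapply(ai[[tis]], function(m) {
        ijk <- world_to_voxel(m$ai, peak)
        m$ai$data[ijk[1] + 1L, ijk[2] + 1L, ijk[3] + 1L]
      }, numeric(1))
      out[[tis]] <- list(
        peak_mm = peak,
        extraction = ex,
        anova = anova_group_by_hemisphere(ex),
        levene = levene_test(ai_at_peak, subjects$group))
    }
    out
  })

  run <- structure(list(cohort = cohort, config = config, ai = ai,
                        one_sample = one_sample, two_sample = two_sample,
                        correlation = correlation, posthoc = posthoc,
                        truth_labels = truth_labels, out_dir = out_dir),
                   class = "study_run")
  if (!is.null(out_dir)) write_study_outputs(run, out_dir)
  run
}

write_study_outputs <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(run$cohort$subjects, file.path(out_dir, "subjects.csv"),
                   row.names = FALSE)
  for (tis in names(run$two_sample))
    utils::write.csv(run$two_sample[[tis]]$clusters,
                     file.path(out_dir, sprintf("two_sample_%s.csv", tis)),
                     row.names = FALSE)
  for (tis in names(run$one_sample))
    for (g in names(run$one_sample[[tis]]))
      utils::write.csv(run$one_sample[[tis]][[g]]$clusters,
                       file.path(out_dir,
                                 sprintf("one_sample_%s_%s.csv", tis, g)),
                       row.names = FALSE)
  for (tis in names(run$correlation))
    for (g in intersect(names(run$correlation[[tis]]),
                        c("control", "patient")))
      utils::write.csv(run$correlation[[tis]][[g]]$clusters,
                       file.path(out_dir,
                                 sprintf("correlation_%s_%s.csv", tis, g)),
                       row.names = FALSE)
  for (tis in names(run$posthoc))
    utils::write.csv(run$posthoc[[tis]]$extraction,
                     file.path(out_dir, sprintf("peak_values_%s.csv", tis)),
                     row.names = FALSE)
  writeLines(study_report(run), file.path(out_dir, "report.txt"))
  files <- setdiff(list.files(out_dir, recursive = TRUE), "manifest.json")
  manifest <- list(
    package = "vbmasym",
    version = as.character(utils::packageVersion("vbmasym")),
    seed = run$config$seed,
    config = run$config[c("tissues", "eps", "fwhm_mm", "cluster_forming_p",
                          "cluster_alpha", "statistic", "B", "seed",
                          "covariates", "behavioral_covariate")],
    files = lapply(files, function(f)
      list(path = f,
           md5 = unname(tools::md5sum(file.path(out_dir, f))))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' Format a study run as a plain-text report
#'
#' Produces cluster tables in the layout of a standard asymmetry-study
#' results table (region label, cluster size, corrected cluster-level p,
#' corrected voxel-level p, peak t, peak coordinates in mm, hemisphere),
#' with region labels resolved against the truth label volume, plus the
#' post-hoc ANOVA and Levene summaries.
#'
#' @param run A `study_run` from [run_study()].
#' @return Character vector of report lines.
#' @export
study_report <- function(run) {
  lab_vol <- run$truth_labels$volume
  lab_tab <- run$truth_labels$labels
  region_of <- function(x, y, z) {
    ijk <- tryCatch(world_to_voxel(lab_vol, c(x, y, z)),
                    error = function(e) NULL)
    if (is.null(ijk)) return("outside-grid")
    id <- lab_vol$data[ijk[1] + 1L, ijk[2] + 1L, ijk[3] + 1L]
    if (id == 0) "unlabelled" else lab_tab$name[lab_tab$id == id]
  }
  fmt_table <- function(tab, title) {
    out <- c(sprintf("== %s ==", title))
    if (!nrow(tab)) return(c(out, "  (no suprathreshold clusters)"))
    for (i in seq_len(nrow(tab))) {
      r <- tab[i, ]
      out <- c(out, sprintf(
        "  %-14s k=%5d  p.clust=%.4f  p.vox=%.4f  Tmax=%6.2f  peak=(%+.0f, %+.0f, %+.0f) mm  %s%s",
        region_of(r$peak_x, r$peak_y, r$peak_z), r$size, r$p_cluster_fwe,
        r$p_voxel_fwe, r$t_max, r$peak_x, r$peak_y, r$peak_z, r$side,
        if (isTRUE(r$significant)) "  *" else ""))
    }
    out
  }
  lines <- c("Voxel-based asymmetry study report",
             sprintf("cluster-forming p = %g, cluster FWE alpha = %g, statistic = %s, B = %d",
                     run$config$cluster_forming_p, run$config$cluster_alpha,
                     run$config$statistic, run$config$B), "")
  for (tis in names(run$one_sample))
    for (g in names(run$one_sample[[tis]]))
      lines <- c(lines, fmt_table(run$one_sample[[tis]][[g]]$clusters,
                                  sprintf("%s asymmetry, %s group", tis, g)),
                 "")
  for (tis in names(run$two_sample))
    lines <- c(lines, fmt_table(run$two_sample[[tis]]$clusters,
                                sprintf("%s asymmetry, group difference", tis)),
               "")
  for (tis in names(run$correlation))
    for (g in intersect(names(run$correlation[[tis]]),
                        c("control", "patient")))
      lines <- c(lines,
                 fmt_table(run$correlation[[tis]][[g]]$clusters,
                           sprintf("%s asymmetry ~ %s, %s group (SVC)", tis,
                                   run$config$behavioral_covariate, g)), "")
  for (tis in names(run$posthoc)) {
    ph <- run$posthoc[[tis]]
    lines <- c(lines,
               sprintf("== %s post-hoc at peak (%+.0f, %+.0f, %+.0f) mm ==",
                       tis, ph$peak_mm[1], ph$peak_mm[2], ph$peak_mm[3]))
    an <- ph$anova$anova
    for (i in seq_len(nrow(an)))
      lines <- c(lines, sprintf("  %-18s F(%d,%d) = %7.3f, p = %.4f",
                                an$effect[i], an$df1[i], an$df2[i],
                                an$F[i], an$p[i]))
    lsd <- ph$anova$lsd
    for (i in seq_len(nrow(lsd)))
      lines <- c(lines, sprintf("  LSD %-28s diff = %+.4f, t(%d) = %6.2f, p = %.4f",
                                lsd$comparison[i], lsd$estimate[i],
                                lsd$df[i], lsd$t[i], lsd$p[i]))
    lines <- c(lines, sprintf("  Levene (%s-centered) W = %.3f, p = %.4f",
                              ph$levene$center, ph$levene$W, ph$levene$p),
               "")
  }
  lines
}

#' @export
print.study_run <- function(x, ...) {
  cat(paste(study_report(x), collapse = "\n"), "\n")
  invisible(x)
}
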