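#' Per-subject regional morphometry from surfaces and label volume
#'
#' Computes the four regional measures for one subject from a corresponded
#' surface pair and a label volume: per-region median thickness
#' ([vertex_thickness()]), per-region outer surface area ([surface_area()]),
#' per-region volume ([region_volume()]), and per-region median depth
#' ([sp_depth()] against an [inflate_surface()] reference).
#'
#' @param pair labeled [surface_pair()].
#' @param volume [label_volume()] with labels `region + 17 * (hemi == "R")`
#'   as produced by [voxelize_labels()].
#' @param region_names names for label ids 1..17.
#' @param inflate_iterations iterations for the depth reference surface.
#' @param exclude region labels to drop.
#' @return long data.frame `region, hemisphere, metric, value`.
#' @export
subject_morphometry <- function(pair, volume, region_names = sp_region_names(),
                                inflate_iterations = 60L, exclude = NULL) {
  lab <- pair$outer$vertex_labels
  hemi <- pair$outer$vertex_hemi
  if (is.null(lab) || is.null(hemi)) stop("outer surface must carry labels and hemispheres")
  key <- lab + ifelse(hemi == "R", 17L, 0L)

  thick <- vertex_thickness(pair)
  infl <- inflate_surface(pair$outer, iterations = inflate_iterations)
  depth <- sp_depth(pair$outer, infl)
  areas <- surface_area(pair$outer, labels = key)$by_region
  vols <- region_volume(volume)$by_region

  med_t <- regional_median(thick, key, exclude = exclude)
  med_d <- regional_median(depth, key, exclude = exclude)
  row_for <- function(k, metric, val) {
    k <- as.integer(k)
    data.frame(region = region_names[(k - 1L) %% 17L + 1L],
               hemisphere = ifelse(k > 17L, "R", "L"),
               metric = metric, value = unname(val))
  }
  out <- rbind(row_for(names(med_t), "thickness", med_t),
               row_for(names(areas), "area", areas),
               row_for(names(vols), "volume", vols),
               row_for(names(med_d), "depth", med_d))
  rownames(out) <- NULL
  out
}

#' Pipeline run configuration
#'
#' @param cohort a [cohort_config()] describing a synthetic cohort, or `NULL`
#'   when `input_dir` is given.
#' @param input_dir directory with `subjects.csv` / `measures.csv` (see
#'   [read_cohort()]).
#' @param metrics measures analyzed for growth/asymmetry.
#' @param cluster_metrics measures whose trajectories are clustered.
#' @param boundary trimester boundary in weeks (default 27).
#' @param alpha FDR level (default 0.05).
#' @param k_candidates candidate cluster counts.
#' @param override_k optional named list metric -> fixed k.
#' @param seed RANSAC seed used for every robust fit (default 42).
#' @param out_dir optional output directory for CSV/JSON result tables.
#' @return object of class `sp_run_config`.
#' @export
run_config <- function(cohort = cohort_config(), input_dir = NULL,
                       metrics = sp_metrics(),
                       cluster_metrics = c("thickness", "area", "volume"),
                       boundary = 27, alpha = 0.05, k_candidates = 2:6,
                       override_k = list(), seed = 42L, out_dir = NULL) {
  if (is.null(cohort) && is.null(input_dir)) stop("need a cohort config or an input_dir")
  if (!is.null(input_dir) && !dir.exists(input_dir)) stop("input_dir does not exist")
  structure(list(cohort = cohort, input_dir = input_dir, metrics = metrics,
                 cluster_metrics = cluster_metrics, boundary = boundary,
                 alpha = alpha, k_candidates = k_candidates,
                 override_k = override_k, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "sp_run_config")
}

# value vector for one region x hemisphere x metric cell, subject-aligned
cell_values <- function(measures, subjects, region, hemisphere, metric) {
  mm <- measures[measures$region == region & measures$hemisphere == hemisphere &
                   measures$metric == metric, ]
  mm$value[match(subjects$subject_id, mm$subject_id)]
}

# covariate-adjusted values for every cell of one subject subset.
# order: GA, residual brain volume; thickness additionally depth (itself
# adjusted for GA and residual brain volume within the same subset).
# ga_window, when given, switches to the group-mean path: the GA step is
# standardized to a uniform grid over the window and, because residual
# brain volume and adjusted depth are orthogonalized to GA by construction,
# it is applied after them so the standardized group mean carries the final
# residual precision that the confidence intervals assume.
adjusted_cells <- function(measures, subjects, metrics, seed, ga_window = NULL) {
  rbv <- residual_brain_volume(subjects$brain_volume_mm3, subjects$ga_weeks,
                               seed = seed)
  ga <- subjects$ga_weeks
  rg <- if (is.null(ga_window)) NULL
        else list(ga = seq(ga_window[1], ga_window[2], length.out = 101))
  cells <- list()
  regions <- unique(measures$region)
  depth_adj <- list()
  if ("depth" %in% unique(measures$metric)) {
    for (r in regions) for (h in c("L", "R")) {
      y <- cell_values(measures, subjects, r, h, "depth")
      covs <- if (is.null(ga_window)) list(ga = ga, rbv = rbv)
              else list(rbv = rbv, ga = ga)
      depth_adj[[paste(r, h)]] <-
        residualize(y, covs, seed = seed, ref_grid = rg)$residuals
    }
  }
  for (m in metrics) for (r in regions) for (h in c("L", "R")) {
    y <- cell_values(measures, subjects, r, h, m)
    covs <- list(ga = ga, rbv = rbv)
    if (m == "thickness" && length(depth_adj))
      covs$depth <- depth_adj[[paste(r, h)]]
    if (!is.null(ga_window)) covs <- covs[c(setdiff(names(covs), "ga"), "ga")]
    cells[[paste(m, r, h, sep = "|")]] <-
      residualize(y, covs, seed = seed, ref_grid = rg)$residuals
  }
  list(cells = cells, rbv = rbv, depth_adj = depth_adj)
}

#' Run the full regional growth and asymmetry analysis
#'
#' Executes, in order: cohort acquisition (synthetic generation or CSV
#' input); residual brain volume; whole-brain ANCOVA per metric (GA, sex,
#' residual brain volume, and their sex interactions) plus a
#' repeated-measures ANCOVA of regional thickness with region and hemisphere
#' as within-subject factors; trimester percent change per region x
#' hemisphere x metric with homotopic Z-tests (FDR across regions within
#' metric); the asymmetry suite (per-subject AI, lateralization tests
#' overall and per trimester group, paired homotopic t-tests, AI-change
#' Z-tests, each FDR-corrected across regions within metric); and Ward
#' clustering of baseline-normalized growth-rate trajectories per metric with
#' silhouette selection, per-cluster trajectory metrics, and the bilateral
#' cluster-symmetry matrix. All robust fits use the configured seed.
#'
#' @param config an [run_config()].
#' @return object of class `sp_pipeline` holding every stage's tables; when
#'   `config$out_dir` is set the tables are also written as CSV/JSON together
#'   with a run log.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "sp_run_config"))
  t0 <- Sys.time()
  seed <- config$seed
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
  }

  ## 1. data
  dat <- stage("input", {
    if (!is.null(config$input_dir)) {
      co <- read_cohort(config$input_dir)
      list(subjects = co$subjects, measures = co$measures, truth = NULL,
           cohort_seed = NA_integer_)
    } else {
      co <- generate_cohort(config$cohort)
      list(subjects = co$subjects, measures = co$measures, truth = co$truth,
           cohort_seed = config$cohort$seed)
    }
  })
  subjects <- dat$subjects
  measures <- dat$measures
  regions <- unique(measures$region)

  ## 2. residual brain volume + whole-brain ANCOVA
  rbv <- stage("residualization",
               residual_brain_volume(subjects$brain_volume_mm3,
                                     subjects$ga_weeks, seed = seed))
  ancova_tabs <- stage("ancova", {
    wb <- subjects
    wb$rbv <- rbv
    wb$sex <- ifelse(wb$sex %in% c("M", "F"), wb$sex, NA)
    out <- list()
    for (m in intersect(config$metrics, unique(measures$metric))) {
      mm <- measures[measures$metric == m, ]
      agg <- if (m %in% c("area", "volume")) {
        stats::aggregate(value ~ subject_id, mm, sum)
      } else {
        stats::aggregate(value ~ subject_id, mm, stats::median)
      }
      wb$y <- agg$value[match(wb$subject_id, agg$subject_id)]
      out[[m]] <- sp_ancova(wb, "y",
                            covariates = c("ga_weeks", "rbv"),
                            factors = "sex",
                            interactions = c("ga_weeks:sex", "rbv:sex"))
    }
    # regional repeated-measures model for thickness
    if ("thickness" %in% config$metrics) {
      th <- measures[measures$metric == "thickness", ]
      th$ga_weeks <- subjects$ga_weeks[match(th$subject_id, subjects$subject_id)]
      th$rbv <- rbv[match(th$subject_id, subjects$subject_id)]
      out$thickness_regional <- sp_ancova(
        th, "value",
        covariates = c("ga_weeks", "rbv"),
        factors = c("region", "hemisphere"),
        interactions = c("region:ga_weeks", "region:hemisphere"),
        subject = "subject_id", within = c("region", "hemisphere"))
    }
    out
  })

  ## 3. trimester growth comparison
  grp <- stage("grouping",
               assign_trimester_group(subjects$ga_weeks, config$boundary))
  growth <- stage("percent_change", {
    windows <- list(late2 = c(22, config$boundary),
                    early3 = c(config$boundary, 32))
    adj_by_group <- lapply(levels(grp), function(g) {
      sub <- subjects[grp == g, ]
      adjusted_cells(measures[measures$subject_id %in% sub$subject_id, ],
                     sub, config$metrics, seed, ga_window = windows[[g]])$cells
    })
    names(adj_by_group) <- levels(grp)
    rows <- list(); zrows <- list()
    for (m in config$metrics) for (r in regions) {
      pcs <- list()
      for (h in c("L", "R")) {
        key <- paste(m, r, h, sep = "|")
        pc <- percent_change(adj_by_group$late2[[key]],
                             adj_by_group$early3[[key]])
        pcs[[h]] <- pc
        rows[[paste(m, r, h)]] <-
          data.frame(metric = m, region = r, hemisphere = h, pc = pc$pc,
                     se = pc$se, ci_lo = pc$ci95[1], ci_hi = pc$ci95[2],
                     m_late2 = pc$m1, m_early3 = pc$m2,
                     n_late2 = pc$group_ns[1], n_early3 = pc$group_ns[2])
      }
      zt <- if (isTRUE(pcs$L$se < 1e-8) && isTRUE(pcs$R$se < 1e-8)) {
        # degenerate noiseless case: identical pcs count as no difference
        d <- pcs$R$pc - pcs$L$pc
        list(z = if (abs(d) < 1e-8) 0 else Inf * sign(d),
             p = if (abs(d) < 1e-8) 1 else 0)
      } else homotopic_growth_ztest(pcs$L, pcs$R)
      zrows[[paste(m, r)]] <- data.frame(metric = m, region = r,
                                         z = zt$z, p = zt$p)
    }
    pc_tab <- do.call(rbind, rows); rownames(pc_tab) <- NULL
    z_tab <- do.call(rbind, zrows); rownames(z_tab) <- NULL
    z_tab$q <- NA_real_
    for (m in unique(z_tab$metric)) {
      i <- z_tab$metric == m
      z_tab$q[i] <- bh_fdr(z_tab$p[i], config$alpha)$q
    }
    list(percent_change = pc_tab, homotopic_z = z_tab,
         adjusted_by_group = adj_by_group)
  })

  ## 4. asymmetry suite
  asym <- stage("asymmetry", {
    adj_all <- adjusted_cells(measures, subjects, config$metrics, seed)$cells
    ai_long <- list(); lat <- list(); paired <- list(); change <- list()
    for (m in config$metrics) {
      ai_tab <- do.call(rbind, lapply(regions, function(r) {
        L <- adj_all[[paste(m, r, "L", sep = "|")]]
        R <- adj_all[[paste(m, r, "R", sep = "|")]]
        data.frame(metric = m, region = r, subject_id = subjects$subject_id,
                   group = as.character(grp), ai = asymmetry_index(L, R))
      }))
      ai_long[[m]] <- ai_tab
      lt <- lateralization_suite(ai_tab[, c("region", "ai")], config$alpha)
      lt$metric <- m
      lat[[m]] <- lt
      pr <- do.call(rbind, lapply(regions, function(r) {
        L <- adj_all[[paste(m, r, "L", sep = "|")]]
        R <- adj_all[[paste(m, r, "R", sep = "|")]]
        pt <- paired_homotopic_test(L, R)
        data.frame(metric = m, region = r, t_stat = pt$t_stat, p = pt$p,
                   cohens_d = pt$cohens_d, mean_diff = pt$mean_diff)
      }))
      pr$q <- bh_fdr(pr$p, config$alpha)$q
      paired[[m]] <- pr
      # AI change between trimester groups (group-wise adjusted values)
      ch <- do.call(rbind, lapply(regions, function(r) {
        ai1 <- with(growth, asymmetry_index(
          adjusted_by_group$late2[[paste(m, r, "L", sep = "|")]],
          adjusted_by_group$late2[[paste(m, r, "R", sep = "|")]]))
        ai2 <- with(growth, asymmetry_index(
          adjusted_by_group$early3[[paste(m, r, "L", sep = "|")]],
          adjusted_by_group$early3[[paste(m, r, "R", sep = "|")]]))
        zt <- ai_change_ztest(ai1, ai2)
        data.frame(metric = m, region = r, delta_ai = zt$delta_ai,
                   z = zt$z, p = zt$p)
      }))
      ch$q <- bh_fdr(ch$p, config$alpha)$q
      change[[m]] <- ch
    }
    list(ai = do.call(rbind, ai_long),
         lateralization = do.call(rbind, lat),
         paired = do.call(rbind, paired),
         ai_change = do.call(rbind, change))
  })

  ## 5. trajectory clustering
  traj <- stage("trajectories", {
    rbv_all <- rbv
    ga <- subjects$ga_weeks
    depth_adj <- list()
    if ("depth" %in% unique(measures$metric)) {
      for (r in regions) for (h in c("L", "R")) {
        y <- cell_values(measures, subjects, r, h, "depth")
        depth_adj[[paste(r, h)]] <-
          residualize(y, list(ga = ga, rbv = rbv_all), seed = seed)$residuals
      }
    }
    out <- list()
    for (m in config$cluster_metrics) {
      mat <- NULL; ids <- character()
      fits <- list()
      for (r in regions) for (h in c("L", "R")) {
        y <- cell_values(measures, subjects, r, h, m)
        covs <- list(rbv = rbv_all)
        if (m == "thickness" && length(depth_adj))
          covs$depth <- depth_adj[[paste(r, h)]]
        yc <- residualize(y, covs, seed = seed)$residuals
        fit <- fit_growth_model(ga, yc, seed = seed)
        prof <- growth_profile(fit)
        mat <- rbind(mat, prof$rate)
        ids <- c(ids, paste(r, h, sep = "|"))
        fits[[paste(r, h, sep = "|")]] <- fit
      }
      rownames(mat) <- ids
      cl <- ward_cluster(mat, k_candidates = config$k_candidates,
                         override_k = config$override_k[[m]])
      lab_df <- data.frame(region = sub("\\|.*", "", ids),
                           hemisphere = sub(".*\\|", "", ids),
                           cluster = unname(cl$labels))
      sym <- bilateral_symmetry(lab_df)
      out[[m]] <- list(rates = mat, clusters = cl, labels = lab_df,
                       symmetry = sym, fits = fits)
    }
    out
  })

  res <- structure(list(subjects = subjects, measures = measures,
                        truth = dat$truth, rbv = rbv, group = grp,
                        ancova = ancova_tabs,
                        percent_change = growth$percent_change,
                        homotopic_z = growth$homotopic_z,
                        asymmetry = asym, trajectories = traj,
                        config = config,
                        runtime_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
                   class = "sp_pipeline")
  if (!is.null(config$out_dir)) write_pipeline(res, config$out_dir)
  res
}

#' @export
print.sp_pipeline <- function(x, ...) {
  cat(sprintf("sp_pipeline: %d subjects, %d regions, metrics %s (%.1f s)\n",
              nrow(x$subjects), length(unique(x$measures$region)),
              paste(x$config$metrics, collapse = "/"), x$runtime_s))
  for (m in names(x$trajectories)) {
    cl <- x$trajectories[[m]]$clusters
    cat(sprintf("  %s: k = %d, mean PC %.1f%%\n", m, cl$k,
                mean(x$percent_change$pc[x$percent_change$metric == m],
                     na.rm = TRUE)))
  }
  invisible(x)
}

#' Write pipeline result tables
#'
#' Flat CSV tables plus a JSON run log (seeds and decision parameters) and a
#' JSON linkage/cluster summary per metric.
#'
#' @param result an [run_pipeline()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_pipeline <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$percent_change, file.path(dir, "percent_change.csv"),
                   row.names = FALSE)
  utils::write.csv(result$homotopic_z, file.path(dir, "homotopic_z.csv"),
                   row.names = FALSE)
  utils::write.csv(result$asymmetry$lateralization,
                   file.path(dir, "lateralization.csv"), row.names = FALSE)
  utils::write.csv(result$asymmetry$paired, file.path(dir, "paired_tests.csv"),
                   row.names = FALSE)
  utils::write.csv(result$asymmetry$ai_change, file.path(dir, "ai_change.csv"),
                   row.names = FALSE)
  for (m in names(result$ancova))
    utils::write.csv(as.data.frame(result$ancova[[m]]),
                     file.path(dir, paste0("ancova_", m, ".csv")),
                     row.names = FALSE)
  cl_summary <- lapply(result$trajectories, function(tr) {
    list(k = tr$clusters$k,
         silhouette_by_k = as.list(tr$clusters$silhouette_by_k),
         labels = stats::setNames(as.list(tr$labels$cluster),
                                  paste(tr$labels$region, tr$labels$hemisphere)),
         cluster_metrics = tr$clusters$cluster_metrics,
         symmetry = apply(tr$symmetry, 1, as.list, simplify = FALSE),
         merge_tree = if (!is.null(tr$clusters$hclust))
           list(merge = apply(tr$clusters$hclust$merge, 1, as.list, simplify = FALSE),
                height = tr$clusters$hclust$height) else NULL)
  })
  jsonlite::write_json(cl_summary, file.path(dir, "clusters.json"),
                       auto_unbox = TRUE, digits = NA)
  log <- list(timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
              ransac_seed = result$config$seed,
              cohort_seed = if (!is.null(result$config$cohort))
                result$config$cohort$seed else NA,
              boundary = result$config$boundary,
              alpha = result$config$alpha,
              k_candidates = result$config$k_candidates,
              metrics = result$config$metrics,
              cluster_metrics = result$config$cluster_metrics,
              n_subjects = nrow(result$subjects),
              runtime_s = result$runtime_s)
  jsonlite::write_json(log, file.path(dir, "run_log.json"), auto_unbox = TRUE)
  invisible(dir)
}
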