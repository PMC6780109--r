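#' Load and validate a project configuration
#'
#' A project is described by a single YAML document (or an equivalent named
#' list) holding the paths, picker grids, classifier settings, score
#' weights, integration and annotation settings, the global seed and the
#' worker count. Defaults are filled in for everything not specified.
#'
#' @param config path to a YAML file, or a named list.
#' @return an object of class `"project_config"`.
#' @export
project_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(
    output_dir = "peakforge_project",
    seed = 1,
    n_workers = 1,
    simulate = list(n_compounds = 20, rt_range = c(0, 300), scan_hz = 5,
                    n_train_runs = 2, n_opt_runs = 2, n_study_runs = 4,
                    snr_spread = TRUE),
    groups = NULL,
    pickers = list(
      matched_filter = list(grid = list(fwhm = c(1, 2, 4),
                                        snthresh = c(2, 5, 10),
                                        step = c(0.5, 1, 2)),
                            fixed = list(max_per_eic = 10)),
      cwt = list(grid = list(peakwidth_min = c(0.8, 1.5, 2.5),
                             peakwidth_max = c(4, 6, 10),
                             snthresh = c(2, 5, 10)),
                 fixed = list(prefilter_k = 3, prefilter_i = 100,
                              max_per_eic = 10))),
    classifier = list(window_s = 8, n_mz = 10, n_t = 41, auto_label = FALSE,
                      n_target = 700),
    weights = as.list(unclass(score_weights())),
    integration = list(min_mz = 3, dedup_rt_tol = 2, merge_rt_tol = 2,
                       merge_min_spec_sim = 0.8),
    annotation = list(ri_window = 1.5, min_similarity = 0.9),
    alkanes = list(carbons = 8:14, rts = NULL))
  cfg <- utils::modifyList(defaults, config)
  train_ids <- sprintf("train_%02d", seq_len(cfg$simulate$n_train_runs))
  opt_ids <- sprintf("opt_%02d", seq_len(cfg$simulate$n_opt_runs))
  if (length(intersect(train_ids, opt_ids))) {
    warnf("training and optimisation sample sets overlap")
  }
  cfg$train_ids <- train_ids
  cfg$opt_ids <- opt_ids
  cfg$study_ids <- sprintf("study_%02d", seq_len(cfg$simulate$n_study_runs))
  if (is.null(cfg$groups)) {
    half <- ceiling(length(cfg$study_ids) / 2)
    cfg$groups <- stats::setNames(
      rep(c("case", "control"), c(half, length(cfg$study_ids) - half)),
      cfg$study_ids)
  } else {
    cfg$groups <- unlist(cfg$groups)
  }
  structure(cfg, class = "project_config")
}

workflow_steps <- function() {
  c("simulate", "sample_training", "export_sheets", "train", "optimize",
    "pick", "integrate", "annotate", "stats")
}

art <- function(cfg, ...) file.path(cfg$output_dir, ...)

require_artifact <- function(path, produced_by) {
  if (!file.exists(path)) {
    stopf("missing artifact '%s'; run step '%s' first", path, produced_by)
  }
  path
}

write_manifest <- function(cfg, step, inputs, outputs, seed) {
  m <- list(step = step, seed = seed,
            config_hash = fnv1a32(yaml::as.yaml(unclass(cfg))),
            package_version = as.character(utils::packageVersion("peakforge")),
            inputs = inputs, outputs = outputs,
            written = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(m, art(cfg, sprintf("manifest_%s.json", step)),
                       auto_unbox = TRUE, pretty = TRUE)
}

# peaks <-> CSV (columns mirror the detected-peak fields; m/z lists joined
# with ';')
#' Serialise detected peaks to CSV
#' @param peaks list of [gc_peak()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_detected_peaks <- function(peaks, path) {
  d <- peaks_df(peaks)
  d$mz_list <- vapply(peaks, function(p) paste(sprintf("%.4f", p$mz), collapse = ";"), "")
  d$height_list <- vapply(peaks, function(p) paste(sprintf("%.4f", p$height), collapse = ";"), "")
  d$area_list <- vapply(peaks, function(p) paste(sprintf("%.4f", p$area), collapse = ";"), "")
  utils::write.csv(d, path, row.names = FALSE)  # params ids contain commas
  invisible(path)
}

#' Read detected peaks back from CSV
#' @param path CSV written by [write_detected_peaks()].
#' @return list of [gc_peak()].
#' @export
read_detected_peaks <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(d)), function(i) {
    num <- function(s) as.double(strsplit(s, ";")[[1]])
    gc_peak(algorithm = strsplit(d$algorithm[i], ";")[[1]][1],
            sample_id = d$sample_id[i],
            rt_apex = d$rt_apex[i], rt_start = d$rt_start[i],
            rt_end = d$rt_end[i], mz = num(d$mz_list[i]),
            height = num(d$height_list[i]), area = num(d$area_list[i]),
            class_label = if (is.na(d$class_label[i]) || d$class_label[i] == "")
              NA_character_ else d$class_label[i],
            params_id = d$params_id[i])
  })
}

#' Run one workflow step
#'
#' Orchestrates the six-stage pipeline (simulation stands in for raw data
#' acquisition): training-set generation, window export for labelling,
#' classifier training, parameter optimisation, full-dataset picking,
#' integration, annotation and group statistics. Every step validates its
#' upstream artifacts (naming the step to run first when one is missing),
#' derives its own seed from the global seed, and writes a JSON manifest.
#' Re-running a step with unchanged inputs and seed reproduces its CSV
#' outputs byte for byte. Per-sample picking tasks are independent; outputs
#' are keyed by sample id.
#'
#' @param step one of `simulate`, `sample_training`, `export_sheets`,
#'   `train`, `optimize`, `pick`, `integrate`, `annotate`, `stats`.
#' @param config a [project_config()] (or something coercible).
#' @param seed optional override of the config seed.
#' @return invisible list of paths written by the step.
#' @export
run_step <- function(step, config, seed = NULL) {
  step <- match.arg(step, workflow_steps())
  cfg <- if (inherits(config, "project_config")) config else project_config(config)
  seed <- as.integer(seed %||% cfg$seed)
  step_seed <- derive_seed(seed, match(step, workflow_steps()))
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- switch(step,
    simulate = step_simulate(cfg, step_seed),
    sample_training = step_sample_training(cfg, step_seed),
    export_sheets = step_export_sheets(cfg),
    train = step_train(cfg, step_seed),
    optimize = step_optimize(cfg, step_seed),
    pick = step_pick(cfg),
    integrate = step_integrate(cfg),
    annotate = step_annotate(cfg),
    stats = step_stats(cfg))
  write_manifest(cfg, step, out$inputs, out$outputs, step_seed)
  invisible(out$outputs)
}

sim_cal <- function(cfg) {
  rts <- cfg$alkanes$rts
  if (is.null(rts)) {
    rr <- cfg$simulate$rt_range
    rts <- seq(rr[1] + 5, rr[2] - 5, length.out = length(cfg$alkanes$carbons))
  }
  ri_calibration(cfg$alkanes$carbons, rts)
}

step_simulate <- function(cfg, seed) {
  dir.create(art(cfg, "runs"), showWarnings = FALSE)
  sc <- cfg$simulate
  compounds <- random_compound_set(sc$n_compounds, rt_range = sc$rt_range,
                                   seed = derive_seed(seed, 1))
  ids <- c(cfg$train_ids, cfg$opt_ids, cfg$study_ids)
  outs <- character(0)
  for (i in seq_along(ids)) {
    # group effect: scale a third of the compounds in 'case' study samples
    cps <- compounds
    if (ids[i] %in% names(cfg$groups) && cfg$groups[[ids[i]]] == "case") {
      for (k in seq_along(cps)) {
        if (k %% 3 == 0) cps[[k]]$max_intensity <- cps[[k]]$max_intensity * 2
      }
    }
    sim <- simulate_run(cps, noise = noise_model(), rt_range = sc$rt_range,
                        scan_hz = sc$scan_hz, seed = derive_seed(seed, 10 + i),
                        sample_id = ids[i])
    p <- art(cfg, "runs", paste0(ids[i], ".mzML"))
    write_mzml(sim$run, p)
    tp <- art(cfg, "runs", paste0("truth_", ids[i], ".csv"))
    utils::write.csv(sim$truth, tp, row.names = FALSE, quote = FALSE)
    outs <- c(outs, p, tp)
  }
  cal <- sim_cal(cfg)
  lib <- library_from_compounds(compounds, cal)
  lp <- art(cfg, "library.msp")
  write_msp(lapply(lib, function(r) list(id = r$name, rt_apex = 0,
                                         rt_start = -1, rt_end = 1,
                                         ri = r$ri, mz = r$mz,
                                         height = r$intensity)), lp)
  ap <- art(cfg, "alkanes.csv")
  utils::write.csv(data.frame(carbon = cal$carbons, rt = cal$rts), ap,
                   row.names = FALSE, quote = FALSE)
  list(inputs = list(), outputs = c(outs, lp, ap))
}

load_runs <- function(cfg, ids, need_step = "simulate") {
  stats::setNames(lapply(ids, function(id) {
    read_raw(require_artifact(art(cfg, "runs", paste0(id, ".mzML")), need_step))
  }), ids)
}

project_grids <- function(cfg) {
  stats::setNames(lapply(names(cfg$pickers), function(alg) {
    pc <- cfg$pickers[[alg]]
    expand_param_grid(alg, pc$grid, pc$fixed %||% list())
  }), names(cfg$pickers))
}

step_sample_training <- function(cfg, seed) {
  runs <- load_runs(cfg, cfg$train_ids)
  cl <- cfg$classifier
  res <- sample_training_peaks(unname(runs), project_grids(cfg),
                               n_target = cl$n_target, seed = seed,
                               window_s = cl$window_s, n_mz = cl$n_mz,
                               n_t = cl$n_t)
  dir.create(art(cfg, "windows"), showWarnings = FALSE)
  wp <- art(cfg, "windows", "windows.csv")
  rows <- lapply(seq_along(res$windows), function(i) {
    w <- res$windows[[i]]
    data.frame(window_id = attr(w, "window_id"),
               channel = seq_along(w$mz_centers), mz = w$mz_centers,
               rt0 = w$rt_grid[1], dt = diff(w$rt_grid[1:2]),
               intensities = apply(w$intensities, 1L, function(r)
                 paste(sprintf("%.4f", r), collapse = ";")),
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), wp, row.names = FALSE, quote = FALSE)
  mp <- art(cfg, "windows", "windows_meta.csv")
  utils::write.csv(res$meta, mp, row.names = FALSE, quote = FALSE)
  list(inputs = art(cfg, "runs", paste0(cfg$train_ids, ".mzML")),
       outputs = c(wp, mp))
}

load_windows <- function(cfg) {
  wp <- require_artifact(art(cfg, "windows", "windows.csv"), "sample_training")
  d <- utils::read.csv(wp, stringsAsFactors = FALSE)
  ids <- unique(d$window_id)
  stats::setNames(lapply(ids, function(id) {
    rows <- d[d$window_id == id, ]
    rows <- rows[order(rows$channel), ]
    m <- t(vapply(rows$intensities,
                  function(s) as.double(strsplit(s, ";")[[1]]),
                  numeric(length(strsplit(rows$intensities[1], ";")[[1]]))))
    rownames(m) <- NULL
    w <- peak_window(m, mz_centers = rows$mz,
                     rt_grid = rows$rt0[1] + rows$dt[1] * (seq_len(ncol(m)) - 1L))
    attr(w, "window_id") <- id
    w
  }), ids)
}

step_export_sheets <- function(cfg) {
  windows <- load_windows(cfg)
  tpl <- export_annotation_sheet(unname(windows), art(cfg, "sheets"))
  list(inputs = art(cfg, "windows", "windows.csv"), outputs = tpl)
}

step_train <- function(cfg, seed) {
  windows <- load_windows(cfg)
  lab_path <- art(cfg, "labels.csv")
  if (!file.exists(lab_path)) {
    if (isTRUE(cfg$classifier$auto_label)) {
      lab <- data.frame(window_id = names(windows),
                        label = vapply(windows, check_window_class, ""),
                        stringsAsFactors = FALSE)
      utils::write.csv(lab, lab_path, row.names = FALSE, quote = FALSE)
    } else {
      stopf("labels file missing ('%s'); run export_sheets and label windows",
            lab_path)
    }
  }
  labels <- read_label_file(lab_path)
  meta <- utils::read.csv(require_artifact(art(cfg, "windows", "windows_meta.csv"),
                                           "sample_training"),
                          stringsAsFactors = FALSE)
  outs <- character(0)
  for (alg in names(cfg$pickers)) {
    ids <- meta$window_id[meta$algorithm == alg]
    sel <- labels[labels$window_id %in% ids, ]
    ws <- unname(windows[sel$window_id])
    labs <- sel$label
    # top up classes that the sampled peaks under-represent with template
    # windows, so that every class stays learnable
    tab <- table(factor(labs, levels = CLASS_LEVELS))
    for (cl in CLASS_LEVELS[tab < 7]) {
      k <- 7L - tab[[cl]]
      for (j in seq_len(k)) {
        ws <- c(ws, list(generate_class_window(
          cl, n_mz = cfg$classifier$n_mz, n_t = cfg$classifier$n_t,
          snr = 50, seed = derive_seed(seed, 100 + match(cl, CLASS_LEVELS) * 10 + j),
          window_s = cfg$classifier$window_s)))
        labs <- c(labs, cl)
      }
    }
    clf <- train_classifier(ws, labs, algorithm_id = alg,
                            seed = derive_seed(seed, match(alg, names(cfg$pickers))),
                            training_samples = unique(meta$sample_id))
    cp <- art(cfg, sprintf("classifier_%s.rds", alg))
    saveRDS(clf, cp)
    outs <- c(outs, cp)
  }
  list(inputs = c(art(cfg, "windows", "windows.csv"), lab_path),
       outputs = outs)
}

load_classifier <- function(cfg, alg) {
  readRDS(require_artifact(art(cfg, sprintf("classifier_%s.rds", alg)), "train"))
}

step_optimize <- function(cfg, seed) {
  runs <- load_runs(cfg, cfg$opt_ids)
  grids <- project_grids(cfg)
  weights <- do.call(score_weights, cfg$weights)
  best <- list()
  outs <- character(0)
  for (alg in names(grids)) {
    res <- grid_search(alg, grids[[alg]], unname(runs), load_classifier(cfg, alg),
                       weights = weights)
    op <- art(cfg, sprintf("optimization_%s.csv", alg))
    write_optimization_csv(res, op)
    best[[alg]] <- res$best$values
    outs <- c(outs, op)
  }
  bp <- art(cfg, "best_params.yaml")
  yaml::write_yaml(best, bp)
  list(inputs = art(cfg, "runs", paste0(cfg$opt_ids, ".mzML")),
       outputs = c(outs, bp))
}

step_pick <- function(cfg) {
  bp <- require_artifact(art(cfg, "best_params.yaml"), "optimize")
  best <- yaml::read_yaml(bp)
  runs <- load_runs(cfg, cfg$study_ids)
  dir.create(art(cfg, "picked"), showWarnings = FALSE)
  outs <- character(0)
  for (alg in names(best)) {
    params <- picker_params(alg, best[[alg]])
    for (id in cfg$study_ids) {
      pk <- group_pseudospectra(run_picker(runs[[id]], params),
                                rt_tol = cfg$integration$dedup_rt_tol / 2)
      pp <- art(cfg, "picked", sprintf("%s_%s.csv", alg, id))
      write_detected_peaks(pk, pp)
      outs <- c(outs, pp)
    }
  }
  list(inputs = bp, outputs = outs)
}

step_integrate <- function(cfg) {
  runs <- load_runs(cfg, cfg$study_ids)
  icfg <- do.call(integration_config, cfg$integration)
  per_sample <- list()
  accounting <- NULL
  for (id in cfg$study_ids) {
    sets <- list()
    for (alg in names(cfg$pickers)) {
      pp <- require_artifact(art(cfg, "picked", sprintf("%s_%s.csv", alg, id)),
                             "pick")
      pk <- read_detected_peaks(pp)
      pk <- classify_peaks(load_classifier(cfg, alg), pk, runs[[id]])
      sets[[alg]] <- pk
    }
    fps <- integrate_peaks(sets, icfg)
    per_sample[[id]] <- fps
    accounting <- rbind(accounting, c(sample = id, fps$accounting))
  }
  tab <- align_across_samples(lapply(per_sample, `[[`, "high"), icfg)
  cal <- ri_calibration_from_csv(require_artifact(art(cfg, "alkanes.csv"),
                                                  "simulate"))
  tab$features$ri <- round(as.double(calibrate_ri(cal, tab$features$rt_apex_s)), 2)
  outs <- c(art(cfg, "final_high.csv"), art(cfg, "final_high.msp"),
            art(cfg, "final_review.csv"), art(cfg, "final_noise.csv"),
            art(cfg, "integration_accounting.csv"))
  write_peak_csv(tab, outs[1], areas = TRUE)
  write_msp(tab, outs[2])
  rev_tab <- align_across_samples(lapply(per_sample, `[[`, "review"), icfg)
  noise_tab <- align_across_samples(lapply(per_sample, `[[`, "noise"), icfg)
  write_peak_csv(rev_tab, outs[3])
  write_peak_csv(noise_tab, outs[4])
  utils::write.csv(as.data.frame(accounting), outs[5], row.names = FALSE,
                   quote = FALSE)
  list(inputs = art(cfg, "picked"), outputs = outs)
}

ri_calibration_from_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  ri_calibration(d$carbon, d$rt)
}

load_feature_table <- function(cfg) {
  hp <- require_artifact(art(cfg, "final_high.csv"), "integrate")
  d <- utils::read.csv(hp, stringsAsFactors = FALSE, check.names = FALSE)
  meta_cols <- c("feature_id", "rt_apex_s", "rt_start_s", "rt_end_s", "ri",
                 "n_mz", "class_label", "source_algorithms")
  samples <- setdiff(names(d), meta_cols)
  list(csv = d, samples = samples)
}

step_annotate <- function(cfg) {
  lib <- read_msp(require_artifact(art(cfg, "library.msp"), "simulate"))
  cal <- ri_calibration_from_csv(require_artifact(art(cfg, "alkanes.csv"),
                                                  "simulate"))
  acfg <- do.call(annotation_config, cfg$annotation)
  hp <- require_artifact(art(cfg, "final_high.csv"), "integrate")
  msp <- read_msp(require_artifact(art(cfg, "final_high.msp"), "integrate"))
  d <- utils::read.csv(hp, stringsAsFactors = FALSE)
  feats <- lapply(seq_len(nrow(d)), function(i) {
    rec <- msp[[match(d$feature_id[i], vapply(msp, `[[`, "", "name"))]]
    list(id = d$feature_id[i], rt_apex = d$rt_apex_s[i],
         mz = rec$mz, height = rec$intensity, ri = d$ri[i],
         rt_start = d$rt_start_s[i], rt_end = d$rt_end_s[i],
         class_label = d$class_label[i], algorithms = d$source_algorithms[i],
         intensities = stats::setNames(0, "x"), areas_by_sample = stats::setNames(0, "x"))
  })
  hits <- annotate_features(structure(feats, class = "feature_list_raw"),
                            lib, cal, acfg)
  ap <- art(cfg, "annotation.csv")
  utils::write.csv(hits, ap, row.names = FALSE, quote = FALSE)
  list(inputs = c(hp, art(cfg, "library.msp")), outputs = ap)
}

step_stats <- function(cfg) {
  ft <- load_feature_table(cfg)
  d <- ft$csv
  height <- as.matrix(d[, ft$samples, drop = FALSE])
  tab <- structure(list(
    features = data.frame(feature_id = d$feature_id),
    height = height, area = height, samples = ft$samples),
    class = "feature_table")
  stats_df <- compute_group_stats(tab, cfg$groups)
  sp <- art(cfg, "stats.csv")
  utils::write.csv(stats_df, sp, row.names = FALSE, quote = FALSE)
  list(inputs = art(cfg, "final_high.csv"), outputs = sp)
}
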