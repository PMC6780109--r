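# Shared fixtures. Heavy objects (training corpus, classifiers, grid
# searches) are computed once per session and reused across test files.

.shared_cache <- new.env(parent = emptyenv())

shared_fixture <- function(name, expr) {
  if (is.null(.shared_cache[[name]])) .shared_cache[[name]] <- force(expr)
  .shared_cache[[name]]
}

# ---- small building blocks --------------------------------------------------

# a minimal two-compound noiseless run
tiny_run <- function(seed = 3, sample_id = "tiny") {
  cps <- list(
    compound_spec("c1", 150, cbind(c(73, 147, 207), c(1, 0.6, 0.3))),
    compound_spec("c2", 180, cbind(c(85, 129, 243), c(1, 0.5, 0.2)),
                  max_intensity = 5e4))
  simulate_run(cps, noise = noise_model(0, 0, 1e6, 0, 0, 0),
               rt_range = c(100, 250), scan_hz = 5, seed = seed,
               sample_id = sample_id)
}

# hand-built peak for integration tests
make_peak <- function(rt, mz, height = rep(100, length(mz)),
                      label = "B", alg = "matched_filter", sample = "s1",
                      id = NA_character_) {
  gc_peak(algorithm = alg, sample_id = sample, rt_apex = rt,
          rt_start = rt - 2, rt_end = rt + 2, mz = mz, height = height,
          class_label = label, id = id)
}

# brute-force connected components of an explicit adjacency rule
oracle_components <- function(n, is_edge) {
  comp <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] != 0L) next
    cur <- cur + 1L
    queue <- i
    comp[i] <- cur
    while (length(queue)) {
      a <- queue[[1]]; queue <- queue[-1]
      for (b in seq_len(n)) {
        if (comp[b] == 0L && is_edge(a, b)) {
          comp[b] <- cur
          queue <- c(queue, b)
        }
      }
    }
  }
  comp
}

# quick 105-window classifier for unit tests
small_classifier <- function() {
  shared_fixture("clf_small", {
    corpus <- generate_training_corpus(n_per_class = 15, seed = 2, snr = 50)
    suppressWarnings(train_classifier(corpus$windows, corpus$labels,
                                      "matched_filter", seed = 1))
  })
}

# ---- session-level heavy fixtures (study conditions) ------------------------

# balanced 700-window corpus at snr 50, seed 1
acc_corpus <- function() {
  shared_fixture("corpus", generate_training_corpus(n_per_class = 100,
                                                    seed = 1, snr = 50))
}

# deterministic stratified 70/30 split of the corpus
acc_split <- function() {
  shared_fixture("split", {
    corpus <- acc_corpus()
    idx <- withr::with_seed(42, {
      unlist(lapply(split(seq_along(corpus$labels), corpus$labels),
                    function(ii) sort(sample(ii, round(0.7 * length(ii))))))
    })
    list(train = sort(unname(idx)),
         test = setdiff(seq_along(corpus$labels), idx))
  })
}

acc_classifier <- function(alg = "matched_filter") {
  shared_fixture(paste0("clf_", alg), {
    corpus <- acc_corpus()
    sp <- acc_split()
    suppressWarnings(train_classifier(
      corpus$windows[sp$train], corpus$labels[sp$train],
      algorithm_id = alg, seed = if (alg == "matched_filter") 1 else 2))
  })
}

# two-run optimisation set: 12 compounds, default noise, slight RT shift
acc_opt_runs <- function() {
  shared_fixture("opt_runs", {
    cps <- random_compound_set(12, rt_range = c(0, 300), seed = 21)
    lapply(1:2, function(i) {
      simulate_run(cps, rt_range = c(0, 300), scan_hz = 5, seed = 100 + i,
                   sample_id = sprintf("opt_%02d", i),
                   rt_shift = (i - 1) * 0.3)$run
    })
  })
}

acc_grid_points <- function(alg) {
  if (alg == "matched_filter") {
    expand_param_grid("matched_filter",
                      list(fwhm = c(1, 2, 4), snthresh = c(2, 5, 10),
                           step = c(0.5, 1, 2)),
                      fixed = list(max_per_eic = 10))
  } else {
    expand_param_grid("cwt",
                      list(peakwidth_min = c(0.8, 1.5, 2.5),
                           peakwidth_max = c(4, 6, 10),
                           snthresh = c(2, 5, 10)),
                      fixed = list(prefilter_k = 3, prefilter_i = 100,
                                   max_per_eic = 10))
  }
}

acc_grid_search <- function(alg) {
  shared_fixture(paste0("grid_", alg), {
    grid_search(alg, acc_grid_points(alg), acc_opt_runs(), acc_classifier(alg))
  })
}

# 30-compound study run, seed 7, with both pickers at optimised parameters
acc_e2e <- function() {
  shared_fixture("e2e", {
    cps <- random_compound_set(30, rt_range = c(0, 300), seed = 7)
    sim <- simulate_run(cps, rt_range = c(0, 300), scan_hz = 5, seed = 7,
                        sample_id = "study_01")
    runs <- list(study_01 = sim$run)
    picked <- list()
    for (alg in c("matched_filter", "cwt")) {
      pk <- group_pseudospectra(run_picker(sim$run, acc_grid_search(alg)$best),
                                rt_tol = 1)
      picked[[alg]] <- classify_peaks(acc_classifier(alg), pk, runs)
    }
    list(sim = sim, compounds = cps, picked = picked,
         true_apex = unique(sim$truth[, c("compound", "rt_apex_s")])$rt_apex_s)
  })
}
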