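# Filtering, duplicate removal, merging, partitioning, alignment, statistics

# hand-enumerated 12-peak fixture: known duplicates and m/z counts.
# mf set: p1/p2 duplicates at ~100 s (B > E); p3 lone; p4 has 2 m/z (filtered);
#         p5/p6 co-eluting but spectrally distinct; p7 noise D at 200 s
# cwt set: q1 ~ p1 duplicate across algorithms; q2 lone; q3 has 1 m/z
#          (filtered); q4 review G; q5 noise D at 250 s
twelve_peak_fixture <- function() {
  mf <- list(
    make_peak(100.0, c(73, 147, 207), c(100, 50, 25), "B", id = "p1"),
    make_peak(100.5, c(73, 147, 207), c(80, 40, 20), "E", id = "p2"),
    make_peak(120.0, c(85, 129, 243), c(60, 30, 10), "A", id = "p3"),
    make_peak(130.0, c(91, 117), c(50, 25), "B", id = "p4"),
    make_peak(140.0, c(55, 70, 100), c(40, 30, 20), "C", id = "p5"),
    make_peak(140.4, c(201, 229, 257), c(40, 30, 20), "B", id = "p6"),
    make_peak(200.0, c(60, 75, 90), c(5, 5, 5), "D", id = "p7"))
  cwt <- list(
    make_peak(100.2, c(73, 147, 207), c(90, 45, 22), "B", alg = "cwt", id = "q1"),
    make_peak(160.0, c(111, 133, 159), c(70, 35, 15), "B", alg = "cwt", id = "q2"),
    make_peak(170.0, 77, 30, "B", alg = "cwt", id = "q3"),
    make_peak(180.0, c(120, 150, 180), c(20, 15, 10), "G", alg = "cwt", id = "q4"),
    make_peak(250.0, c(66, 82, 99), c(6, 6, 6), "D", alg = "cwt", id = "q5"))
  list(matched_filter = mf, cwt = cwt)
}

test_that("the minimum-m/z filter keeps boundary cases and matches enumeration", {
  fx <- twelve_peak_fixture()
  kept <- filter_min_mz(fx$matched_filter, 3)
  expect_length(kept, 6L)  # p4 (2 m/z) rejected
  expect_false("p4" %in% vapply(kept, `[[`, "", "id"))
  expect_length(filter_min_mz(fx$cwt, 3), 4L)  # q3 (1 m/z) rejected
  # boundary: exactly min_mz fragments are kept
  expect_length(filter_min_mz(list(make_peak(10, c(1, 2, 3))), 3), 1L)
  # brute-force enumeration oracle on a random fixture
  set.seed(5)
  rand <- lapply(1:30, function(i) {
    make_peak(i * 5, sample(50:300, sample(1:6, 1)))
  })
  for (k in 1:5) {
    expect_length(filter_min_mz(rand, k),
                  sum(vapply(rand, function(p) length(p$mz) >= k, TRUE)))
  }
})

test_that("within-algorithm deduplication keeps the best class and respects RT", {
  fx <- twelve_peak_fixture()
  cfg <- integration_config()
  dd <- dedup_within(fx$matched_filter, cfg)
  ids <- vapply(dd, `[[`, "", "id")
  expect_true("p1" %in% ids)   # B beats E among the 100 s duplicates
  expect_false("p2" %in% ids)
  expect_true(all(c("p5", "p6") %in% ids))  # co-eluting but dissimilar spectra
  expect_equal(attr(dd, "n_collapsed"), 1L)
  # peaks 10 s apart both survive
  two <- list(make_peak(100, c(73, 147, 207), id = "a"),
              make_peak(110, c(73, 147, 207), id = "b"))
  expect_length(dedup_within(two, cfg), 2L)
  # component-count oracle on a random fixture
  set.seed(31)
  rand <- lapply(1:25, function(i) {
    make_peak(runif(1, 0, 60), c(73, 147, 207), c(100, 50, 25) * runif(1, .5, 2))
  })
  dd2 <- dedup_within(rand, cfg)
  apex <- vapply(rand, `[[`, 0, "rt_apex")
  comp <- oracle_components(25, function(a, b) {
    abs(apex[a] - apex[b]) <= cfg$dedup_rt_tol &&
      peakforge:::peak_cosine(rand[[a]], rand[[b]]) >= cfg$merge_min_spec_sim
  })
  expect_length(dd2, length(unique(comp)))
  # idempotence
  expect_length(dedup_within(dd2, cfg), length(dd2))
})

test_that("cross-algorithm merging unions provenance and passes lone peaks", {
  fx <- twelve_peak_fixture()
  cfg <- integration_config()
  dd <- lapply(fx, dedup_within, cfg = cfg)
  merged <- merge_across(dd, cfg)
  # p1 ~ q1 collapse into one feature with both algorithms recorded
  both <- Filter(function(p) length(p$provenance$algorithms) == 2L, merged)
  expect_length(both, 1L)
  expect_setequal(both[[1]]$provenance$algorithms, c("matched_filter", "cwt"))
  expect_equal(both[[1]]$id, "p1")  # B with the larger summed intensity
  # disjoint sets pass through: component oracle over the pooled peaks
  pool <- c(dd[[1]], dd[[2]])
  apex <- vapply(pool, `[[`, 0, "rt_apex")
  comp <- oracle_components(length(pool), function(a, b) {
    abs(apex[a] - apex[b]) <= cfg$merge_rt_tol &&
      peakforge:::peak_cosine(pool[[a]], pool[[b]]) >= cfg$merge_min_spec_sim
  })
  expect_length(merged, length(unique(comp)))
  # merging disjoint lists is the union
  d1 <- lapply(1:4, function(i) make_peak(i * 10, c(73, 147, 207), alg = "x"))
  d2 <- lapply(1:5, function(i) make_peak(300 + i * 10, c(85, 129, 243), alg = "y"))
  expect_length(merge_across(list(d1, d2), cfg), 9L)
  # idempotence
  expect_length(merge_across(list(merged), cfg), length(merged))
})

test_that("partitioning is exhaustive and rejects unlabelled peaks", {
  peaks <- lapply(seq_along(LETTERS[1:7]), function(i) {
    make_peak(i * 10, c(73, 147, 207), label = LETTERS[i])
  })
  parts <- partition_by_class(peaks)
  expect_length(parts$high, 3L)
  expect_length(parts$review, 3L)
  expect_length(parts$noise, 1L)
  allb <- lapply(1:3, function(i) make_peak(i * 10, c(73, 147), label = "B"))
  pb <- partition_by_class(allb)
  expect_length(pb$high, 3L)
  expect_length(pb$review, 0L)
  bad <- list(make_peak(10, 73, label = NA_character_))
  expect_error(partition_by_class(bad), "unlabelled")
})

test_that("the five-way conservation identity holds on the hand fixture", {
  fx <- twelve_peak_fixture()
  fps <- integrate_peaks(fx, integration_config())
  a <- fps$accounting
  expect_equal(unname(a["input"]), 12)
  expect_equal(unname(a["dropped_min_mz"]), 2)       # p4, q3
  expect_equal(unname(a["collapsed_duplicates"]), 2) # p2 within, q1 across
  expect_equal(unname(a["high"]), 5)    # p1(+q1), p3, p5, p6, q2
  expect_equal(unname(a["review"]), 1)  # q4
  expect_equal(unname(a["noise"]), 2)   # p7, q5
  expect_equal(unname(a["input"]),
               unname(a["dropped_min_mz"] + a["collapsed_duplicates"] +
                        a["high"] + a["review"] + a["noise"]))
  expect_true(all(vapply(fps$high, `[[`, "", "class_label") %in% c("A", "B", "C")))
})

test_that("cross-sample alignment builds the expected feature table", {
  cfg <- integration_config()
  # one identical feature in 5 samples
  sets <- setNames(lapply(1:5, function(s) {
    list(make_peak(100 + runif(1, -0.3, 0.3), c(73, 147, 207),
                   c(100, 50, 25) * s, sample = paste0("s", s)))
  }), paste0("s", 1:5))
  set.seed(1)
  tab <- align_across_samples(sets, cfg)
  expect_equal(nrow(tab$features), 1L)
  expect_equal(sum(tab$detected), 5L)
  expect_true(all(tab$height[1, ] > 0))
  # a sample-unique feature yields a single non-zero cell
  sets$s3 <- c(sets$s3, list(make_peak(200, c(91, 117, 143),
                                       sample = "s3")))
  tab2 <- align_across_samples(sets, cfg)
  expect_equal(nrow(tab2$features), 2L)
  uniq <- which(tab2$features$rt_apex_s > 150)
  expect_equal(sum(tab2$detected[uniq, ]), 1L)
  expect_equal(unname(tab2$height[uniq, "s3"]), 300)
})

test_that("alignment row count matches an independent greedy oracle", {
  cfg <- integration_config()
  set.seed(23)
  samples <- paste0("s", 1:4)
  sets <- setNames(lapply(samples, function(s) {
    lapply(1:5, function(i) {
      make_peak(20 * i + runif(1, -0.5, 0.5), c(73, 147, 207) + i,
                c(100, 50, 25) * runif(1, 0.5, 2), sample = s)
    })
  }), samples)
  tab <- align_across_samples(sets, cfg)
  # oracle: independent greedy clustering, most intense seed first,
  # one member per sample within the RT and similarity gates
  pool <- do.call(c, unname(sets))
  psmp <- unlist(lapply(samples, function(s) rep(s, 5)))
  inten <- vapply(pool, function(p) sum(p$height), 0)
  apex <- vapply(pool, `[[`, 0, "rt_apex")
  free <- rep(TRUE, length(pool))
  n_clusters <- 0L
  while (any(free)) {
    seed_i <- which(free)[which.max(inten[free])]
    n_clusters <- n_clusters + 1L
    for (s in samples) {
      elig <- which(free & psmp == s & abs(apex - apex[seed_i]) <= cfg$merge_rt_tol)
      elig <- elig[vapply(elig, function(j) {
        peakforge:::peak_cosine(pool[[seed_i]], pool[[j]]) >= cfg$merge_min_spec_sim
      }, TRUE)]
      if (length(elig)) free[elig[which.max(inten[elig])]] <- FALSE
    }
    free[seed_i] <- FALSE
  }
  expect_equal(nrow(tab$features), n_clusters)
})

test_that("group statistics follow the sign convention and flag zero groups", {
  mkt <- function(m) {
    structure(list(features = data.frame(feature_id = paste0("F", seq_len(nrow(m)))),
                   height = m, area = m, samples = colnames(m)),
              class = "feature_table")
  }
  m <- rbind(c(20, 20, 10, 10), c(10, 10, 20, 20), c(15, 15, 15, 15),
             c(0, 0, 12, 18))
  colnames(m) <- c("a1", "a2", "b1", "b2")
  groups <- c(a1 = "case", a2 = "case", b1 = "ctrl", b2 = "ctrl")
  st <- compute_group_stats(mkt(m), groups)
  expect_equal(st$fold_change[1], 2.0)
  expect_equal(st$fold_change[2], -2.0)
  expect_equal(st$fold_change[3], 1.0)
  expect_equal(st$p_value[3], 1)
  expect_true(is.na(st$p_value[4]))
  expect_match(st$flag[4], "zero")
  expect_error(compute_group_stats(mkt(m), c(a1 = "x", a2 = "x", b1 = "x",
                                             b2 = "x")), "2 conditions")
  expect_error(compute_group_stats(mkt(m[, 1:3]),
                                   c(a1 = "case", a2 = "case", b1 = "ctrl")),
               ">= 2 samples")
})
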