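# Design-grid enumeration, masked truth-set simulation, caller emulator.

test_that("grid enumeration is the exhaustive Cartesian product", {
  g <- design_grid(normal_covs = c(30, 60), tumour_covs = c(20, 60, 100),
                   vafs = c(0.1, 0.5), t_thresholds = c(10, 100))
  pts <- enumerate_grid(g)
  expect_equal(nrow(pts), 2 * 3 * 2 * 2)
  expect_equal(nrow(unique(pts)), nrow(pts))
  expect_equal(nrow(enumerate_grid(g, include_threshold = FALSE)), 12L)
  # deterministic ordering
  expect_identical(pts, enumerate_grid(g))
  g1 <- design_grid(30, 60, 0.2, 5)
  expect_equal(nrow(enumerate_grid(g1)), 1L)
  expect_error(design_grid(numeric(), 60, 0.2, 5), "non-empty")
})

test_that("the published grid has 891 pairs and 10,692 permutations", {
  g <- published_design_grid()
  expect_equal(nrow(enumerate_grid(g, include_threshold = FALSE)), 891L)
  expect_equal(nrow(enumerate_grid(g)), 10692L)
})

test_that("genome mask excludes masked and telomeric intervals", {
  mask <- genome_mask(c(chrA = 1000L),
                      masked = data.frame(chrom = "chrA", start = 401,
                                          end = 500),
                      telomere_flank = 100)
  iv <- mask$allowed
  expect_equal(iv$start, c(101, 501))
  expect_equal(iv$end, c(400, 900))

  mini <- miniature_genome()
  expect_true(all(mini$allowed$start >= 1))
  expect_true(all(mini$allowed$end <=
                    mini$chrom_lengths[mini$allowed$chrom]))
})

test_that("truth simulation honours counts, masks and determinism", {
  spec <- truth_set_spec(somatic_per_type = 20, germline_per_type = 40,
                         length_range = c(50, 5000))
  mask <- miniature_genome()
  tr <- simulate_truth_sets(spec, mask, seed = 5)
  expect_equal(nrow(tr$somatic), 120L)
  expect_equal(nrow(tr$germline), 240L)
  expect_equal(unname(table(tr$somatic$sv_type)[c("DEL", "DINS", "DUP",
                                                  "FINS", "INV", "TRA")]),
               rep(20L, 6), ignore_attr = TRUE)
  # every breakend inside an allowed interval
  in_allowed <- function(chrom, pos) {
    vapply(seq_along(chrom), function(i) {
      iv <- mask$allowed[mask$allowed$chrom == chrom[i], ]
      any(pos[i] >= iv$start & pos[i] <= iv$end)
    }, logical(1))
  }
  for (cs in tr) {
    expect_true(all(in_allowed(cs$chrom1, cs$pos1)))
    expect_true(all(in_allowed(cs$chrom2, cs$pos2)))
    expect_true(all(cs$sv_length >= 50 & cs$sv_length <= 5000))
  }
  # non-overlap of occupied footprints within a set
  occ <- as.data.frame(tr$somatic)
  occ <- occ[occ$sv_type != "FINS", ]
  starts <- ifelse(occ$sv_type %in% c("DINS", "TRA"), occ$pos2, occ$pos1)
  by_chr <- split(data.frame(s = starts,
                             e = starts + occ$sv_length),
                  ifelse(occ$sv_type %in% c("DINS", "TRA"),
                         occ$chrom2, occ$chrom1))
  for (d in by_chr) {
    d <- d[order(d$s), ]
    if (nrow(d) > 1) expect_true(all(d$s[-1] > d$e[-nrow(d)]))
  }
  # determinism
  tr2 <- simulate_truth_sets(spec, mask, seed = 5)
  expect_identical(as.data.frame(tr$somatic), as.data.frame(tr2$somatic))
  tr3 <- simulate_truth_sets(spec, mask, seed = 6)
  expect_false(identical(as.data.frame(tr$somatic),
                         as.data.frame(tr3$somatic)))
  # zero counts
  tr0 <- simulate_truth_sets(truth_set_spec(0, 0), mask, seed = 1)
  expect_equal(nrow(tr0$somatic), 0L)
  # impossible request errors out
  tiny <- genome_mask(c(chrA = 2000L))
  expect_error(simulate_truth_sets(truth_set_spec(50, 0), tiny, seed = 1),
               "capacity")
})

test_that("a forced-deterministic emulator reproduces the truth exactly", {
  spec <- truth_set_spec(10, 10, length_range = c(50, 500))
  mask <- miniature_genome()
  tr <- simulate_truth_sets(spec, mask, seed = 3)
  prof <- builtin_profiles()$manta_like
  prof$emulator$beta0 <- 50  # detection probability ~ 1
  prof$emulator$jitter_scale <- 0
  prof$emulator$fp_rate <- 0
  prof$emulator$germline_leak <- 0
  point <- list(vaf = 0.5, tumour_cov = 60, normal_cov = 60)
  calls <- emulate_caller(tr$somatic, tr$germline, point, prof, mask,
                          seed = 1)
  expect_equal(nrow(calls), nrow(tr$somatic))
  mm <- compute_metrics(classify_calls(tr$somatic, calls, 0, prof))
  expect_equal(mm$sensitivity, 1)
  expect_equal(mm$precision, 1)
  # detection probability forced to zero: empty callset, missing precision
  prof$emulator$beta0 <- -50
  calls0 <- emulate_caller(tr$somatic, tr$germline, point, prof, mask,
                           seed = 1)
  expect_equal(nrow(calls0), 0L)
  mm0 <- compute_metrics(classify_calls(tr$somatic, calls0, 0, prof))
  expect_equal(mm0$sensitivity, 0)
  expect_true(is.na(mm0$precision))
})

test_that("replicate detection rates match the closed-form probability", {
  spec <- truth_set_spec(10, 0, length_range = c(50, 500))
  mask <- miniature_genome()
  tr <- simulate_truth_sets(spec, mask, seed = 13)
  prof <- builtin_profiles()$delly_like
  prof$emulator$fp_rate <- 0
  prof$emulator$germline_leak <- 0
  prof$emulator$jitter_scale <- 0
  point <- list(vaf = 0.3, tumour_cov = 40, normal_cov = 60)
  p <- svperf:::emulator_detection_p(prof$emulator, point$vaf,
                                     point$tumour_cov, point$normal_cov)
  n_rep <- 300
  hits <- vapply(seq_len(n_rep), function(r) {
    nrow(emulate_caller(tr$somatic, tr$germline, point, prof, mask,
                        seed = 1000 + r))
  }, numeric(1))
  rate <- sum(hits) / (n_rep * nrow(tr$somatic))
  se <- sqrt(p * (1 - p) / (n_rep * nrow(tr$somatic)))
  expect_lt(abs(rate - p), 3 * se)
})

test_that("expected emulated sensitivity is monotone in VAF and coverage", {
  prof <- builtin_profiles()$manta_like
  vafs <- c(0.05, 0.1, 0.2, 0.4, 0.8, 1)
  s_vaf <- emulator_expected_sensitivity(prof, vafs, 60, 60, 100)
  expect_true(all(diff(s_vaf) >= 0))
  tcovs <- c(20, 40, 60, 80, 100)
  s_cov <- emulator_expected_sensitivity(prof, 0.2, tcovs, 60, 100)
  expect_true(all(diff(s_cov) >= 0))
})

test_that("evaluation tables are complete, monotone in T, deterministic", {
  g <- design_grid(normal_covs = 60, tumour_covs = c(30, 60),
                   vafs = c(0.1, 0.5), t_thresholds = c(0, 10, 100))
  spec <- truth_set_spec(15, 15, length_range = c(50, 500))
  mask <- miniature_genome()
  tr <- simulate_truth_sets(spec, mask, seed = 2)
  profs <- builtin_profiles()[c("manta_like", "svaba_like")]
  tab <- build_evaluation_table(g, tr, profs, mask, seed = 4)
  expect_s3_class(tab, "svperf_eval_table")
  expect_equal(nrow(tab), 2 * 2 * 2 * 3)  # profiles x pairs x thresholds
  # within each (callset, vaf, cov) slice sensitivity non-decreasing in T
  for (sl in split(as.data.frame(tab),
                   tab[c("callset", "vaf", "tumour_cov")])) {
    sl <- sl[order(sl$t_threshold), ]
    expect_true(all(diff(sl$sensitivity) >= 0))
  }
  tab2 <- build_evaluation_table(g, tr, profs, mask, seed = 4)
  expect_identical(as.data.frame(tab), as.data.frame(tab2))
  # per-type tables carry one row per truth type plus the overall row
  g1 <- design_grid(60, 60, 0.5, c(10, 100))
  tab_pt <- build_evaluation_table(g1, tr, profs["manta_like"], mask,
                                   seed = 4, per_type = TRUE)
  expect_equal(nrow(tab_pt), 2 * 7)
  expect_setequal(unique(tab_pt$sv_type_scope),
                  c("ALL", "DEL", "DUP", "INV", "DINS", "FINS", "TRA"))

  # zero jitter: sensitivity independent of T
  prof0 <- builtin_profiles()["manta_like"]
  prof0$manta_like$emulator$jitter_scale <- 0
  tab0 <- build_evaluation_table(g, tr, prof0, mask, seed = 4)
  for (sl in split(as.data.frame(tab0),
                   tab0[c("vaf", "tumour_cov")])) {
    expect_equal(length(unique(sl$sensitivity)), 1L)
  }
})
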