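test_that("target covariance places the planted Fisher-z shift exactly", {
  # one between-community planted edge on a small parcellation: the cell is
  # tanh(atanh(base_between_r) + delta_z) and no repair is needed
  spec <- tiny_cohort_spec()
  labels <- spec$parcellation$label
  comm <- spec$parcellation$community
  pair <- c(labels[comm == 1][1], labels[comm == 2][1])
  eff <- effect_spec(edges = rbind(pair), delta_z = -0.4)
  tg <- build_target_covariance(spec, eff, "group1", "tp2")
  expect_equal(tg[pair[1], pair[2]], tanh(atanh(0.05) - 0.4),
               tolerance = 1e-12)
  expect_equal(attr(tg, "projection_delta"), 0)
  # leakage check: every other design cell is identical to the base matrix
  base <- build_target_covariance(spec, eff, "group2", "tp1")
  for (cell in list(c("group1", "tp1"), c("group2", "tp2")))
    expect_equal(build_target_covariance(spec, eff, cell[1], cell[2]), base)
  expect_false(isTRUE(all.equal(tg, base)))
})

test_that("zero effect and degenerate parcellation give trivial targets", {
  spec <- tiny_cohort_spec()
  eff0 <- effect_spec(edges = matrix(character(0), 0, 2), delta_z = 0)
  cells <- list(c("group1", "tp1"), c("group1", "tp2"),
                c("group2", "tp1"), c("group2", "tp2"))
  tgs <- lapply(cells, function(cl)
    build_target_covariance(spec, eff0, cl[1], cl[2]))
  for (k in 2:4) expect_equal(tgs[[k]], tgs[[1]])

  # every ROI its own community, zero between-community correlation
  iso <- cohort_spec(n_group1 = 2, n_group2 = 2, n_rois = 6, n_volumes = 20,
                     parcellation = data.frame(label = letters[1:6],
                                               community = 1:6),
                     base_within_r = 0.35, base_between_r = 0,
                     seed = 1)
  tg <- build_target_covariance(iso, effect_spec(edges = matrix(character(0), 0, 2)),
                                "group1", "tp1")
  expect_equal(unname(tg), diag(6), tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("effect edges outside the ROI set are rejected by name", {
  spec <- tiny_cohort_spec()
  eff <- effect_spec(edges = rbind(c("roi.001", "nowhere")))
  expect_error(build_target_covariance(spec, eff, "group1", "tp2"), "nowhere")
  expect_error(effect_spec(edges = rbind(c("a", "a"))), "self-edge")
  expect_error(effect_spec(edges = rbind(c("a", "b"), c("b", "a"))),
               "duplicate")
})

test_that("default 129-ROI target with the 11 planted edges stays near-SPD", {
  spec <- cohort_spec(seed = 3)
  tg <- build_target_covariance(spec, effect_spec(), "group1", "tp2")
  expect_lt(attr(tg, "projection_delta"), 0.01)
  expect_gt(min(eigen(tg, symmetric = TRUE, only.values = TRUE)$values), 5e-7)
  expect_equal(unname(diag(tg)), rep(1, 129))
})

test_that("generated time series are deterministic and correctly shaped", {
  spec <- tiny_cohort_spec()
  tg <- build_target_covariance(spec,
                                effect_spec(edges = matrix(character(0), 0, 2)),
                                "group1", "tp1")
  a <- generate_timeseries(tg, spec, 7L)
  b <- generate_timeseries(tg, spec, 7L)
  expect_identical(a, b)
  expect_equal(dim(a$data), c(16, 64))
  expect_equal(rownames(a$nuisance), c("wm", "csf"))
  c2 <- generate_timeseries(tg, spec, 8L)
  expect_false(identical(a$data, c2$data))
  expect_error(generate_timeseries(diag(-1, 16), spec, 1L),
               "positive definite")
})

test_that("default spec yields the full acquisition length", {
  spec <- cohort_spec(n_rois = 34, seed = 2)
  tg <- build_target_covariance(spec, effect_spec(delta_z = 0),
                                "group2", "tp1")
  ts <- generate_timeseries(tg, spec, 1L)
  expect_equal(ncol(ts$data), 242)
})

test_that("with nuisance and drift disabled the empirical correlations track the target", {
  spec <- cohort_spec(n_group1 = 2, n_group2 = 2, n_rois = 10,
                      n_volumes = 5000, nuisance_amplitude = 0,
                      drift_order = 0,
                      parcellation = generic_parcellation(10, 3), seed = 11)
  tg <- build_target_covariance(spec,
                                effect_spec(edges = matrix(character(0), 0, 2)),
                                "group1", "tp1")
  ts <- generate_timeseries(tg, spec, 1L)
  emp <- cor(t(ts$data))
  expect_lt(max(abs(emp - tg)), 0.06)
})

test_that("structural connectomes are noisy symmetric copies of the backbone", {
  spec <- tiny_cohort_spec(structural_flip_rate = 0)
  eff <- effect_spec(edges = matrix(character(0), 0, 2))
  truth <- list(planted_edges = eff$edges,
                backbone_template = make_backbone_template(spec, eff))
  mats <- generate_structural_cohort(spec, truth)
  expect_length(mats, 9)
  for (m in mats) expect_identical(m, truth$backbone_template)
  # consensus of an all-template cohort recovers the template
  cb <- consensus_binary(mats, 0.5)
  expect_equal(cb$mask, truth$backbone_template)
})

test_that("flip rate is honoured and planted edges survive flipping", {
  spec <- cohort_spec(n_group1 = 13, n_group2 = 13, n_rois = 10,
                      n_volumes = 20, structural_flip_rate = 0.4,
                      parcellation = generic_parcellation(10, 2), seed = 5)
  eff <- effect_spec(edges = rbind(c("roi.001", "roi.006")), delta_z = -0.4)
  truth <- list(planted_edges = eff$edges,
                backbone_template = make_backbone_template(spec, eff))
  mats <- generate_structural_cohort(spec, truth)
  up <- upper.tri(truth$backbone_template)
  prot <- matrix(FALSE, 10, 10, dimnames = dimnames(truth$backbone_template))
  prot["roi.001", "roi.006"] <- prot["roi.006", "roi.001"] <- TRUE
  flips <- vapply(mats, function(m) {
    expect_equal(max(abs(m - t(m))), 0)
    expect_equal(m[prot], c(1L, 1L))  # planted edge never flipped off
    mean((m != truth$backbone_template)[up & !prot])
  }, numeric(1))
  expect_lt(abs(mean(flips) - 0.4), 0.05)
})

test_that("a full cohort bundle is complete, reproducible and leak-free", {
  spec <- cohort_spec(n_rois = 34, n_volumes = 40, seed = 9)
  eff <- effect_spec()  # 11 default edges
  coh <- generate_cohort(spec, eff)
  expect_equal(nrow(coh$subjects), 26)
  expect_length(coh$ts, 26)
  expect_equal(sum(vapply(coh$ts, length, integer(1))), 52)
  expect_equal(table(coh$subjects$group)[["group1"]], 14)

  coh2 <- generate_cohort(spec, eff)
  expect_identical(coh$ts, coh2$ts)
  expect_identical(coh$structural, coh2$structural)
  coh3 <- generate_cohort(cohort_spec(n_rois = 34, n_volumes = 40, seed = 10),
                          eff)
  expect_false(identical(coh$ts, coh3$ts))

  # planted edges are a subset of the backbone template
  idx <- cbind(match(eff$edges[, 1], rownames(coh$truth$backbone_template)),
               match(eff$edges[, 2], rownames(coh$truth$backbone_template)))
  expect_true(all(coh$truth$backbone_template[idx] == 1))
  # no-leakage: control and baseline targets are free of the effect
  expect_equal(coh$truth$targets[["group2.tp2"]],
               coh$truth$targets[["group1.tp1"]])
})

test_that("cohort serialization round-trips through TSV/JSON", {
  dir <- withr::local_tempdir()
  spec <- tiny_cohort_spec()
  coh <- generate_cohort(spec, effect_spec(edges = matrix(character(0), 0, 2)))
  write_cohort(coh, dir)
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  expect_equal(nrow(man$subjects), 9)
  ts <- read_timeseries_tsv(file.path(dir, "sub01_tp1_timeseries.tsv"),
                            tr_seconds = spec$tr_seconds)
  expect_equal(ts$data, coh$ts$sub01$tp1$data, tolerance = 1e-8)
  expect_equal(ts$nuisance, coh$ts$sub01$tp1$nuisance, tolerance = 1e-8)
  m <- read_matrix_tsv(file.path(dir, "sub03_structural.tsv"))
  expect_equal(m, coh$structural$sub03 * 1.0)
})
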