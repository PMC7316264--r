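make_obs <- function(y1, y2, g1) {
  ns <- length(y1)
  data.frame(subject = rep(sprintf("s%02d", seq_len(ns)), 2),
             group = rep(ifelse(g1, "group1", "group2"), 2),
             timepoint = rep(c("tp1", "tp2"), each = ns),
             value = c(y1, y2), stringsAsFactors = FALSE)
}

test_that("p-value kernels satisfy the F/t identity and edge cases", {
  expect_equal(p_from_t(0, 10), 1.0)
  expect_equal(p_from_f(0, 1, 10), 1.0)
  for (t in c(0.1, 0.5, 1.3, 2.34, 5, 9.7))
    for (df in c(1, 5, 13, 24, 100))
      expect_equal(p_from_f(t^2, 1, df), p_from_t(t, df), tolerance = 1e-10)
  expect_error(p_from_t(1, 0.5), "degrees of freedom")
  expect_error(p_from_f(1, 0, 10), "degrees of freedom")
})

test_that("the mixed ANOVA engine reproduces trivial and planted designs", {
  g1 <- rep(c(TRUE, FALSE), c(5, 4))
  flat <- mixed_anova_2x2(make_obs(rep(1, 9), rep(1, 9), g1))
  expect_equal(flat$F_inter, 0)
  expect_equal(flat$p_inter, 1)
  expect_equal(flat$F_group, 0)
  expect_equal(flat$p_group, 1)
  expect_equal(flat$df, c(1, 7))

  # pure interaction: group1 drops by delta, group2 unchanged, tiny noise
  set.seed(51)
  y1 <- rnorm(9, sd = 1e-3)
  y2 <- y1 - ifelse(g1, 0.5, 0) + rnorm(9, sd = 1e-3)
  planted <- mixed_anova_2x2(make_obs(y1, y2, g1))
  expect_gt(planted$F_inter, 1e3)
  expect_lt(planted$p_inter, 1e-8)

  incomplete <- make_obs(y1, y2, g1)[-3, ]
  expect_error(mixed_anova_2x2(incomplete), "missing a timepoint")
})

test_that("interaction F is the squared two-sample t on change scores", {
  set.seed(52)
  for (i in 1:100) {
    n1 <- sample(3:10, 1); n2 <- sample(3:10, 1)
    g1 <- rep(c(TRUE, FALSE), c(n1, n2))
    y1 <- rnorm(n1 + n2); y2 <- rnorm(n1 + n2)
    fit <- mixed_anova_2x2(make_obs(y1, y2, g1))
    d <- y2 - y1
    tt <- t.test(d[g1], d[!g1], var.equal = TRUE)
    expect_equal(fit$F_inter, unname(tt$statistic)^2, tolerance = 1e-8)
    expect_equal(fit$p_inter, tt$p.value, tolerance = 1e-8)
  }
})

test_that("the engine matches R's least-squares aov decomposition when balanced", {
  set.seed(53)
  for (i in 1:40) {
    n <- sample(3:8, 1)
    g1 <- rep(c(TRUE, FALSE), each = n)
    y1 <- rnorm(2 * n, mean = ifelse(g1, 0.3, 0))
    y2 <- rnorm(2 * n, mean = ifelse(g1, -0.2, 0.1))
    fit <- mixed_anova_2x2(make_obs(y1, y2, g1))
    ora <- oracle_aov_mixed(y1, y2, g1)
    expect_equal(fit$F_group, ora$F_group, tolerance = 1e-8)
    expect_equal(fit$F_time, ora$F_time, tolerance = 1e-8)
    expect_equal(fit$F_inter, ora$F_inter, tolerance = 1e-8)
  }
})

test_that("BH step-up flags match a hand-executed oracle", {
  expect_equal(sum(bh_fdr(c(0.001, 0.02, 0.03, 0.04, 0.2), 0.05)), 4)
  expect_equal(sum(bh_fdr(rep(1, 10), 0.05)), 0)
  expect_true(bh_fdr(0.04, 0.05))
  set.seed(54)
  for (i in 1:50) {
    p <- runif(sample(c(1, 5, 50, 500), 1))^sample(1:3, 1)
    q <- sample(c(0.01, 0.05, 0.1), 1)
    flags <- bh_fdr(p, q)
    expect_identical(flags, oracle_bh(p, q))
    # BH rejections always contain the Bonferroni rejections
    expect_true(all(flags[p <= q / length(p)]))
  }
  expect_error(bh_fdr(c(0.5, 1.2), 0.05), "0, 1")
  expect_error(bh_fdr(0.5, 0), "level q")
})

test_that("post-hoc t-tests match t.test and honour the degenerate convention", {
  set.seed(55)
  g1 <- rep(c(TRUE, FALSE), c(6, 5))
  y1 <- rnorm(11); y2 <- rnorm(11, 0.3)
  ph <- posthoc_edge(y1, y2, g1)
  expect_equal(ph$t_paired_g1,
               unname(t.test(y2[g1], y1[g1], paired = TRUE)$statistic),
               tolerance = 1e-10)
  expect_equal(ph$p_unpaired_tp2,
               t.test(y2[g1], y2[!g1], var.equal = TRUE)$p.value,
               tolerance = 1e-10)

  # hand-computed 4-subject paired t: diffs of group1 = (.1,.3,.2,.4)
  g <- rep(c(TRUE, FALSE), c(4, 4))
  a1 <- c(0, 0, 0, 0, 1, 1, 1, 1)
  a2 <- c(0.1, 0.3, 0.2, 0.4, 1, 1, 1, 1)
  d <- a2[1:4] - a1[1:4]
  ph2 <- posthoc_edge(a1, a2, g)
  expect_equal(ph2$t_paired_g1, mean(d) / (sd(d) / sqrt(4)), tolerance = 1e-12)
  # identical tp1/tp2 values in group2: t = 0, p = 1 by convention
  expect_equal(ph2$t_paired_g2, 0)
  expect_equal(ph2$p_paired_g2, 1)

  # group1 shifts, group2 does not (tiny noise)
  set.seed(56)
  b1 <- rnorm(11, sd = 1e-3)
  b2 <- b1 + ifelse(g1, -0.4, 0) + rnorm(11, sd = 1e-3)
  ph3 <- posthoc_edge(b1, b2, g1)
  expect_lt(ph3$p_paired_g1, 1e-6)
  expect_lt(abs(ph3$t_paired_g2), 10)  # group2 shows no systematic change
  expect_error(posthoc_edge(b1[1:7], b2[1:7], g1[1:7]), "2 subjects")
})

make_fm_cohort <- function(zlist1, zlist2, labels) {
  # build per-subject functional matrices from flat upper-triangle values
  n <- length(labels)
  to_fm <- function(vals) {
    z <- matrix(0, n, n, dimnames = list(labels, labels))
    z[upper.tri(z)] <- vals
    z[lower.tri(z)] <- t(z)[lower.tri(z)]
    functional_matrix(z, labels)
  }
  mapply(function(a, b) list(tp1 = to_fm(a), tp2 = to_fm(b)),
         zlist1, zlist2, SIMPLIFY = FALSE)
}

test_that("edgewise scan flags a hugely shifted edge and its 2-node component", {
  set.seed(57)
  labels <- sprintf("r%02d", 1:8)
  n_edges <- 8 * 7 / 2
  ns <- 12
  g1 <- rep(c(TRUE, FALSE), each = 6)
  z1 <- lapply(1:ns, function(i) rnorm(n_edges, sd = 0.02))
  z2 <- mapply(function(z, g) {
    out <- z + rnorm(n_edges, sd = 0.02)
    if (g) out[1] <- out[1] - 2   # edge r01--r02
    out
  }, z1, g1, SIMPLIFY = FALSE)
  fmats <- make_fm_cohort(z1, z2, labels)
  names(fmats) <- sprintf("s%02d", 1:ns)
  subjects <- data.frame(subject = names(fmats),
                         group = ifelse(g1, "group1", "group2"))
  scan <- edgewise_scan(fmats, subjects, q = 0.05)
  expect_equal(nrow(scan$table), n_edges)
  flagged <- scan$table[scan$table$fdr_sig, ]
  expect_equal(nrow(flagged), 1)
  expect_equal(sort(c(flagged$node1, flagged$node2)), c("r01", "r02"))
  expect_equal(scan$component_summary$n_nodes, 2)
  expect_equal(scan$component_summary$n_components, 1)
  # post-hocs attached only on flagged edges
  expect_false(is.na(flagged$p_paired_g1))
  expect_true(all(is.na(scan$table$p_paired_g1[!scan$table$fdr_sig])))
  # flagged interaction agrees with a scalar engine run on that edge
  key <- edge_keys(scan$table$node1, scan$table$node2)
  e <- which(key == "r01--r02")
  y1 <- vapply(names(fmats), function(s) fmats[[s]]$tp1$z["r01", "r02"],
               numeric(1))
  y2 <- vapply(names(fmats), function(s) fmats[[s]]$tp2$z["r01", "r02"],
               numeric(1))
  fit <- mixed_anova_2x2(make_obs(y1, y2, g1))
  expect_equal(scan$table$F_inter[e], fit$F_inter, tolerance = 1e-10)
})

test_that("the interaction degrees of freedom follow the cohort size", {
  spec <- tiny_cohort_spec(seed = 58)
  coh <- generate_cohort(spec, effect_spec(edges = matrix(character(0), 0, 2)))
  fmats <- preprocess_cohort(coh, preproc_config(discard = 2))
  scan <- edgewise_scan(fmats, coh$subjects)
  expect_equal(unique(scan$table$df2), 9 - 2)
})

test_that("a backbone mask restricts the tested family", {
  spec <- tiny_cohort_spec(seed = 59)
  coh <- generate_cohort(spec, effect_spec(edges = matrix(character(0), 0, 2)))
  fmats <- preprocess_cohort(coh, preproc_config(discard = 2))
  backbone <- consensus_binary(coh$structural)
  scan <- edgewise_scan(fmats, coh$subjects, mask = backbone)
  expect_equal(nrow(scan$table),
               sum(backbone$mask[upper.tri(backbone$mask)]))
})

test_that("network-level ANOVAs run per metric and detect planted strength loss", {
  spec <- cohort_spec(n_group1 = 5, n_group2 = 4, n_rois = 16,
                      n_volumes = 200, seed = 60)
  labels <- spec$parcellation$label
  # a same-community node set, so the planted decrease sits on dense edges
  net_members <- labels[spec$parcellation$community == 1][1:4]
  pairs <- t(combn(net_members, 2))
  coh <- generate_cohort(spec, effect_spec(edges = pairs, delta_z = -0.35))
  res <- analyze_cohort(coh, preproc = preproc_config(discard = 2),
                        networks = list(N = network_definition("N",
                                                               net_members)))
  expect_length(res$network_anovas, 3)  # 3 metrics x 1 network
  strength <- res$network_anovas$N.strength
  expect_lt(strength$anova$p_inter, 0.01)
  expect_lt(strength$posthoc$p_paired_g1, 0.05)

  # constant metric across all cells gives p = 1 everywhere
  tab <- res$metric_table
  tab$strength <- 1
  flat <- network_metric_anova(tab, "strength", "N")
  expect_equal(flat$anova$p_inter, 1)
  expect_equal(flat$anova$p_group, 1)
  expect_error(network_metric_anova(tab, "strength", "missing"),
               "not in metric table")
})
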