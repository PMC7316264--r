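#' Two-tailed p-value from a Student-t statistic
#'
#' `p = 2 * SF_t(|t|; df)` with `SF_t` the survival function of the t
#' distribution.
#'
#' @param t t statistic.
#' @param df degrees of freedom (>= 1).
#' @return two-tailed p-value.
#' @export
p_from_t <- function(t, df) {
  if (any(df < 1)) stop2("t-test degrees of freedom must be >= 1")
  2 * pt(abs(t), df, lower.tail = FALSE)
}

#' p-value from an F statistic
#'
#' `p = SF_F(F; df1, df2)`; for `df1 = 1` this equals
#' `p_from_t(sqrt(F), df2)`.
#'
#' @param f F statistic (>= 0).
#' @param df1,df2 numerator / denominator degrees of freedom (>= 1).
#' @return upper-tail p-value.
#' @export
p_from_f <- function(f, df1, df2) {
  if (any(df1 < 1) || any(df2 < 1)) stop2("F-test degrees of freedom must be >= 1")
  pf(f, df1, df2, lower.tail = FALSE)
}

# column variances of a matrix
col_vars <- function(x) {
  n <- nrow(x)
  mu <- colMeans(x)
  colSums((x - rep(mu, each = n))^2) / (n - 1)
}

# Vectorized mixed 2x2 (Group between, Timepoint within) ANOVA core.
# y1, y2: subjects x K matrices of the two within-subject measurements;
# g1: logical vector marking group-1 subjects. The between-subject stratum
# tests Group on per-subject means; the within-subject stratum tests
# Timepoint (unweighted mean of group change scores, i.e. Type III) and the
# interaction (difference of group change scores) on per-subject change
# scores with a pooled variance. All three F have df (1, N - 2).
mixed_anova_core <- function(y1, y2, g1) {
  n1 <- sum(g1); n2 <- sum(!g1); nn <- n1 + n2
  if (n1 < 2 || n2 < 2) stop2("need at least 2 subjects per group")
  d <- y2 - y1
  m <- (y1 + y2) / 2
  inv <- 1 / n1 + 1 / n2
  dfe <- nn - 2

  md1 <- colMeans(d[g1, , drop = FALSE])
  md2 <- colMeans(d[!g1, , drop = FALSE])
  s2d <- ((n1 - 1) * col_vars(d[g1, , drop = FALSE]) +
          (n2 - 1) * col_vars(d[!g1, , drop = FALSE])) / dfe
  f_inter <- (md1 - md2)^2 / (s2d * inv)
  f_time <- ((md1 + md2) / 2)^2 / (s2d * inv / 4)

  mm1 <- colMeans(m[g1, , drop = FALSE])
  mm2 <- colMeans(m[!g1, , drop = FALSE])
  s2m <- ((n1 - 1) * col_vars(m[g1, , drop = FALSE]) +
          (n2 - 1) * col_vars(m[!g1, , drop = FALSE])) / dfe
  f_group <- (mm1 - mm2)^2 / (s2m * inv)

  # 0/0 (all values equal): F = 0, p = 1 by convention; a nonzero effect
  # with zero residual variance stays Inf (p = 0)
  f_group[is.nan(f_group)] <- 0
  f_time[is.nan(f_time)] <- 0
  f_inter[is.nan(f_inter)] <- 0
  data.frame(F_group = f_group, p_group = p_from_f(f_group, 1, dfe),
             F_time = f_time, p_time = p_from_f(f_time, 1, dfe),
             F_inter = f_inter, p_inter = p_from_f(f_inter, 1, dfe),
             df1 = 1, df2 = dfe)
}

#' Mixed two-way (Group x Timepoint) ANOVA
#'
#' Classical 2 (between) x 2 (within) mixed-design ANOVA: the Group main
#' effect is tested on per-subject means in the between-subject error
#' stratum; the Timepoint main effect and the Group x Timepoint interaction
#' are tested on per-subject change scores in the within-subject stratum.
#' All three F statistics carry df (1, N - 2); the interaction F is exactly
#' the square of the pooled-variance two-sample t comparing change scores
#' between groups.
#'
#' @param obs data.frame with columns `subject`, `group` (two levels),
#'   `timepoint` (`"tp1"`, `"tp2"`) and `value`; every subject needs both
#'   timepoints.
#' @return object of class `anova_result`: list with `F_group`, `F_time`,
#'   `F_inter`, matching p-values, and `df = c(1, N - 2)`.
#' @export
mixed_anova_2x2 <- function(obs) {
  need <- c("subject", "group", "timepoint", "value")
  if (!all(need %in% names(obs))) stop2("obs needs columns %s",
                                        paste(need, collapse = ", "))
  subs <- unique(obs$subject)
  grp_levels <- sort(unique(obs$group))
  if (length(grp_levels) != 2) stop2("need exactly 2 groups")
  y1 <- y2 <- numeric(length(subs))
  g1 <- logical(length(subs))
  for (k in seq_along(subs)) {
    rows <- obs[obs$subject == subs[k], ]
    v1 <- rows$value[rows$timepoint == "tp1"]
    v2 <- rows$value[rows$timepoint == "tp2"]
    if (length(v1) != 1 || length(v2) != 1)
      stop2("subject %s is missing a timepoint", subs[k])
    y1[k] <- v1; y2[k] <- v2
    g1[k] <- rows$group[1] == grp_levels[1]
  }
  res <- mixed_anova_core(cbind(y1), cbind(y2), g1)
  structure(list(F_group = res$F_group, p_group = res$p_group,
                 F_time = res$F_time, p_time = res$p_time,
                 F_inter = res$F_inter, p_inter = res$p_inter,
                 df = c(1, res$df2)),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("Group:       F(%d,%d) = %.3f, p = %.4f\n", x$df[1], x$df[2],
              x$F_group, x$p_group))
  cat(sprintf("Timepoint:   F(%d,%d) = %.3f, p = %.4f\n", x$df[1], x$df[2],
              x$F_time, x$p_time))
  cat(sprintf("Interaction: F(%d,%d) = %.3f, p = %.4f\n", x$df[1], x$df[2],
              x$F_inter, x$p_inter))
  invisible(x)
}

#' Benjamini-Hochberg step-up significance flags
#'
#' Rejects the k smallest p-values where
#' `k = max{ i : p_(i) <= i * q / m }`.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @param q FDR level in (0, 1).
#' @return logical vector of rejection flags.
#' @export
bh_fdr <- function(pvals, q = 0.05) {
  if (q <= 0 || q >= 1) stop2("FDR level q must be in (0, 1)")
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1))
    stop2("p-values must be in [0, 1]")
  p.adjust(pvals, method = "BH") <= q
}

# one-sample t on differences; zero spread with zero mean gives t = 0
paired_t_stat <- function(diff) {
  n <- length(diff)
  se <- sd(diff) / sqrt(n)
  m <- mean(diff)
  t <- if (se == 0) { if (m == 0) 0 else sign(m) * Inf } else m / se
  list(t = t, df = n - 1, p = p_from_t(t, n - 1))
}

# pooled-variance two-sample t with the same zero-spread convention
pooled_t_stat <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  s2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  se <- sqrt(s2 * (1 / n1 + 1 / n2))
  m <- mean(x) - mean(y)
  t <- if (se == 0) { if (m == 0) 0 else sign(m) * Inf } else m / se
  list(t = t, df = n1 + n2 - 2, p = p_from_t(t, n1 + n2 - 2))
}

#' Post-hoc t-tests for one edge or metric
#'
#' Uncorrected two-tailed tests: a paired t (tp2 vs tp1) within each group
#' and a pooled-variance unpaired t (group1 vs group2) at each timepoint.
#' Degenerate zero-variance cells yield t = 0, p = 1 when the mean
#' difference is also zero.
#'
#' @param y1,y2 per-subject values at tp1 / tp2.
#' @param g1 logical vector marking group-1 subjects.
#' @return one-row data.frame with t and p for the four tests.
#' @export
posthoc_edge <- function(y1, y2, g1) {
  if (sum(g1) < 2 || sum(!g1) < 2) stop2("need at least 2 subjects per group")
  pg1 <- paired_t_stat(y2[g1] - y1[g1])
  pg2 <- paired_t_stat(y2[!g1] - y1[!g1])
  u1 <- pooled_t_stat(y1[g1], y1[!g1])
  u2 <- pooled_t_stat(y2[g1], y2[!g1])
  data.frame(
    t_paired_g1 = pg1$t, p_paired_g1 = pg1$p,
    t_paired_g2 = pg2$t, p_paired_g2 = pg2$p,
    t_unpaired_tp1 = u1$t, p_unpaired_tp1 = u1$p,
    t_unpaired_tp2 = u2$t, p_unpaired_tp2 = u2$p)
}

#' Edge-wise mixed ANOVA scan with FDR control
#'
#' Runs the mixed 2x2 ANOVA on every upper-triangle edge of the functional
#' connectivity matrices, corrects the interaction p-values with
#' Benjamini-Hochberg across the whole edge family, assembles the flagged
#' edges into connected components, and attaches uncorrected post-hoc
#' t-tests for the flagged edges.
#'
#' @param fmats named list (per subject) of lists with `tp1`/`tp2`
#'   [functional_matrix()] entries, on the Fisher-z scale.
#' @param subjects data.frame with columns `subject`, `group`.
#' @param q FDR level (default 0.05).
#' @param mask optional [consensus_backbone()]; when supplied, the tested
#'   family is restricted to backbone edges (default: all upper-triangle
#'   edges).
#' @return object of class `edge_stats_table`: list with `table` (per-edge
#'   data.frame), `q`, and `component_summary` (flagged edge/node counts,
#'   node list, per-component membership).
#' @export
edgewise_scan <- function(fmats, subjects, q = 0.05, mask = NULL) {
  subs <- subjects$subject
  first <- fmats[[subs[1]]]$tp1
  labels <- first$roi_labels
  n <- length(labels)
  up <- upper_pairs(n)
  if (!is.null(mask)) {
    if (!identical(mask$roi_labels %||% labels, labels))
      stop2("mask labels do not match functional matrices")
    keep <- mask$mask[up] != 0
    up <- up[keep, , drop = FALSE]
  }
  flat <- function(fm, s, tp) {
    if (is.null(fm)) stop2("missing functional matrix for %s %s", s, tp)
    if (!identical(fm$roi_labels, labels))
      stop2("ROI labels of subject %s differ from the first subject", s)
    fm$z[up]
  }
  y1 <- t(vapply(subs, function(s) flat(fmats[[s]]$tp1, s, "tp1"),
                 numeric(nrow(up))))
  y2 <- t(vapply(subs, function(s) flat(fmats[[s]]$tp2, s, "tp2"),
                 numeric(nrow(up))))
  grp_levels <- sort(unique(subjects$group))
  g1 <- subjects$group == grp_levels[1]
  res <- mixed_anova_core(y1, y2, g1)
  res$fdr_sig <- bh_fdr(res$p_inter, q)
  tab <- data.frame(node1 = labels[up[, 1]], node2 = labels[up[, 2]],
                    res[c("F_group", "p_group", "F_time", "p_time",
                          "F_inter", "p_inter", "df1", "df2", "fdr_sig")],
                    stringsAsFactors = FALSE)

  ph_cols <- c("t_paired_g1", "p_paired_g1", "t_paired_g2", "p_paired_g2",
               "t_unpaired_tp1", "p_unpaired_tp1",
               "t_unpaired_tp2", "p_unpaired_tp2")
  tab[ph_cols] <- NA_real_
  for (e in which(tab$fdr_sig))
    tab[e, ph_cols] <- posthoc_edge(y1[, e], y2[, e], g1)

  flagged <- tab[tab$fdr_sig, c("node1", "node2"), drop = FALSE]
  if (nrow(flagged)) {
    g <- igraph::graph_from_data_frame(flagged, directed = FALSE)
    comp <- igraph::components(g)
    membership <- split(names(comp$membership), comp$membership)
    summary <- list(n_edges = nrow(flagged),
                    n_nodes = length(comp$membership),
                    nodes = sort(names(comp$membership)),
                    n_components = comp$no,
                    components = unname(membership))
  } else {
    summary <- list(n_edges = 0L, n_nodes = 0L, nodes = character(0),
                    n_components = 0L, components = list())
  }
  structure(list(table = tab, q = q, component_summary = summary),
            class = "edge_stats_table")
}

#' @export
print.edge_stats_table <- function(x, ...) {
  cs <- x$component_summary
  cat(sprintf(paste0("<edge_stats_table> %d edges tested, %d flagged at ",
                     "BH-FDR q = %.2f (%d nodes, %d component(s))\n"),
              nrow(x$table), cs$n_edges, x$q, cs$n_nodes, cs$n_components))
  invisible(x)
}

#' Mixed ANOVA on one network metric
#'
#' Applies the same 2x2 mixed-design engine used edge-wise to a network
#' summary measure (strength, global or local efficiency) for one network,
#' with the standard post-hoc t-tests.
#'
#' @param metric_table output of [compute_metric_table()].
#' @param metric one of `"strength"`, `"e_glob"`, `"e_loc"`.
#' @param network network name present in the table.
#' @return list with `anova` ([mixed_anova_2x2()] result) and `posthoc`
#'   ([posthoc_edge()] row).
#' @export
network_metric_anova <- function(metric_table, metric, network) {
  metric <- match.arg(metric, c("strength", "e_glob", "e_loc"))
  sel <- metric_table[metric_table$network == network, ]
  if (!nrow(sel)) stop2("network '%s' not in metric table", network)
  obs <- data.frame(subject = sel$subject, group = sel$group,
                    timepoint = sel$timepoint, value = sel[[metric]],
                    stringsAsFactors = FALSE)
  fit <- mixed_anova_2x2(obs)
  wide <- obs[obs$timepoint == "tp1", c("subject", "group")]
  y1 <- obs$value[match(paste(wide$subject, "tp1"),
                        paste(obs$subject, obs$timepoint))]
  y2 <- obs$value[match(paste(wide$subject, "tp2"),
                        paste(obs$subject, obs$timepoint))]
  g1 <- wide$group == sort(unique(wide$group))[1]
  list(metric = metric, network = network, anova = fit,
       posthoc = posthoc_edge(y1, y2, g1))
}
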