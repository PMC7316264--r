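# Independent brute-force oracles used to validate the graph and ANOVA
# kernels. These deliberately avoid the package's code paths: shortest paths
# are found by exhaustive simple-path enumeration, efficiencies by direct
# evaluation of the published formulas on oracle distances, and the mixed
# ANOVA by R's own least-squares aov() decomposition.

# all-pairs shortest path lengths by exhaustive simple-path enumeration
oracle_shortest_paths <- function(len) {
  n <- nrow(len)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  best_path <- function(i, j) {
    res <- Inf
    rec <- function(cur, visited, acc) {
      if (acc >= res) return(invisible())
      if (cur == j) { res <<- acc; return(invisible()) }
      for (k in seq_len(n)) {
        if (!visited[k] && is.finite(len[cur, k])) {
          visited[k] <- TRUE
          rec(k, visited, acc + len[cur, k])
          visited[k] <- FALSE
        }
      }
    }
    v <- rep(FALSE, n); v[i] <- TRUE
    rec(i, v, 0)
    res
  }
  if (n > 1)
    for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n))
      d[i, j] <- d[j, i] <- best_path(i, j)
  dimnames(d) <- dimnames(len)
  d
}

oracle_lengths <- function(w) {
  len <- ifelse(w > 0, 1 / w, Inf)
  diag(len) <- 0
  len
}

oracle_global_eff <- function(w) {
  n <- nrow(w)
  d <- oracle_shortest_paths(oracle_lengths(w))
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

oracle_local_eff <- function(w) {
  n <- nrow(w)
  nodal <- sapply(seq_len(n), function(i) {
    nb <- setdiff(which(w[i, ] > 0), i)
    k <- length(nb)
    if (k < 2) return(0)
    d <- oracle_shortest_paths(oracle_lengths(w[nb, nb, drop = FALSE]))
    acc <- 0
    for (a in seq_len(k)) for (b in seq_len(k)) {
      if (a == b || !is.finite(d[a, b])) next
      acc <- acc + (w[i, nb[a]] * w[i, nb[b]] / d[a, b])^(1 / 3)
    }
    acc / (k * (k - 1))
  })
  mean(nodal)
}

# hand-executed Benjamini-Hochberg step-up
oracle_bh <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  pass <- which(ps <= seq_len(m) * q / m)
  if (!length(pass)) return(rep(FALSE, m))
  p <= ps[max(pass)]
}

# classical mixed-design ANOVA via R's least-squares aov() (balanced designs)
oracle_aov_mixed <- function(y1, y2, g1) {
  ns <- length(y1)
  df <- data.frame(
    value = c(y1, y2),
    timepoint = factor(rep(c("tp1", "tp2"), each = ns)),
    subject = factor(rep(seq_len(ns), 2)),
    group = factor(rep(ifelse(g1, "g1", "g2"), 2)))
  fit <- summary(stats::aov(value ~ group * timepoint + Error(subject),
                            data = df))
  between <- fit[["Error: subject"]][[1]]
  within <- fit[["Error: Within"]][[1]]
  rn_b <- trimws(rownames(between))
  rn_w <- trimws(rownames(within))
  list(F_group = between[rn_b == "group", "F value"],
       F_time = within[rn_w == "timepoint", "F value"],
       F_inter = within[rn_w == "group:timepoint", "F value"])
}

# random symmetric weight matrix on n nodes; weights drawn from `pool`
# (0 = absent edge)
random_weight_graph <- function(n, pool = c(0, 0.25, 0.5, 1)) {
  w <- matrix(0, n, n)
  up <- upper.tri(w)
  w[up] <- sample(pool, sum(up), replace = TRUE)
  w[lower.tri(w)] <- t(w)[lower.tri(w)]
  dimnames(w) <- list(paste0("n", seq_len(n)), paste0("n", seq_len(n)))
  w
}

# small fast synthetic cohort for module tests
tiny_cohort_spec <- function(seed = 1, ...) {
  cohort_spec(n_group1 = 5, n_group2 = 4, n_rois = 16, n_volumes = 64,
              seed = seed, ...)
}

edge_keys <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "--")
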