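#' Specification of a synthetic two-group, two-timepoint cohort
#'
#' Captures the stated world the generator emulates: an experimental group of
#' 14 and a control group of 12 subjects, each scanned twice (129 ROIs, 242
#' volumes at TR = 2 s), with a modular base correlation structure, additive
#' white-matter/CSF-like nuisance signals, low-order polynomial scanner
#' drift, and per-subject structural connectomes that are noisy realizations
#' of a common backbone.
#'
#' @param n_group1 experimental-group size (default 14).
#' @param n_group2 control-group size (default 12).
#' @param n_rois number of regions (default 129).
#' @param n_volumes number of acquired volumes per scan (default 242).
#' @param tr_seconds repetition time in seconds (default 2).
#' @param parcellation data.frame with columns `label`, `community`; defaults
#'   to [default_parcellation()] (or a generic one when `n_rois` is small).
#' @param base_within_r Pearson correlation between ROIs of one community
#'   (default 0.35).
#' @param base_between_r correlation between ROIs of different communities
#'   (default 0.05).
#' @param nuisance_amplitude amplitude of each shared nuisance signal as a
#'   fraction of the unit BOLD standard deviation (default 0.3).
#' @param drift_order polynomial degree of per-ROI scanner drift (default 2).
#' @param structural_flip_rate probability that any one off-diagonal cell of
#'   the structural backbone is flipped in an individual connectome
#'   (default 0.05).
#' @param seed integer master seed; every random draw derives from it.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_group1 = 14, n_group2 = 12, n_rois = 129,
                        n_volumes = 242, tr_seconds = 2.0,
                        parcellation = NULL,
                        base_within_r = 0.35, base_between_r = 0.05,
                        nuisance_amplitude = 0.3, drift_order = 2,
                        structural_flip_rate = 0.05, seed = 1L) {
  if (n_group1 + n_group2 < 4) stop2("need at least 4 subjects in total")
  if (!(base_between_r >= 0 && base_between_r < base_within_r &&
        base_within_r < 1))
    stop2("require 0 <= base_between_r < base_within_r < 1")
  if (structural_flip_rate < 0 || structural_flip_rate >= 0.5)
    stop2("structural_flip_rate must be in [0, 0.5)")
  if (is.null(parcellation)) {
    parcellation <- if (n_rois >= 34) default_parcellation(n_rois)
                    else generic_parcellation(n_rois)
  }
  if (nrow(parcellation) != n_rois)
    stop2("parcellation has %d rows but n_rois = %d",
          nrow(parcellation), n_rois)
  if (anyDuplicated(parcellation$label)) stop2("duplicate ROI labels")
  structure(list(n_group1 = n_group1, n_group2 = n_group2, n_rois = n_rois,
                 n_volumes = n_volumes, tr_seconds = tr_seconds,
                 parcellation = parcellation,
                 base_within_r = base_within_r,
                 base_between_r = base_between_r,
                 nuisance_amplitude = nuisance_amplitude,
                 drift_order = drift_order,
                 structural_flip_rate = structural_flip_rate,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generic unnamed parcellation for small simulations
#'
#' @param n_rois number of regions.
#' @param n_communities number of equal-size communities.
#' @return data.frame with `label` and `community` columns.
#' @export
generic_parcellation <- function(n_rois, n_communities = max(2L, n_rois %/% 8L)) {
  data.frame(label = sprintf("roi.%03d", seq_len(n_rois)),
             community = rep_len(seq_len(n_communities), n_rois),
             stringsAsFactors = FALSE)
}

#' Planted Group x Timepoint connectivity effect
#'
#' The effect is an additive shift `delta_z` on the Fisher-z scale applied to
#' the listed edges in the experimental group at timepoint 2 only, modelling
#' an intervention-specific connectivity decrease.
#'
#' @param edges two-column character matrix (or data.frame) of ROI label
#'   pairs; default [default_effect_edges()]. May have zero rows (null
#'   cohort).
#' @param delta_z signed Fisher-z change (default -0.4).
#' @return object of class `effect_spec`.
#' @export
effect_spec <- function(edges = default_effect_edges(), delta_z = -0.4) {
  edges <- as.matrix(edges)
  if (length(edges) && ncol(edges) != 2) stop2("edges must have two columns")
  if (length(edges)) {
    if (any(edges[, 1] == edges[, 2]))
      stop2("self-edge in effect specification: %s", edges[edges[,1]==edges[,2], 1][1])
    keys <- edge_key(edges[, 1], edges[, 2])
    if (anyDuplicated(keys))
      stop2("duplicate effect edge: %s", keys[duplicated(keys)][1])
  }
  structure(list(edges = edges, delta_z = delta_z, applies_to = "interaction"),
            class = "effect_spec")
}

# row/col indices of the effect edges in a label vector; errors name the edge
effect_indices <- function(effect, labels) {
  if (!length(effect$edges)) return(matrix(integer(0), ncol = 2))
  i <- match(effect$edges[, 1], labels)
  j <- match(effect$edges[, 2], labels)
  bad <- which(is.na(i) | is.na(j))
  if (length(bad))
    stop2("effect edge outside ROI set: %s -- %s",
          effect$edges[bad[1], 1], effect$edges[bad[1], 2])
  cbind(i, j)
}

#' Target correlation matrix for one design cell
#'
#' Off-diagonal entries start at the community-determined base correlation
#' (`base_within_r` within a community, `base_between_r` between); for the
#' experimental group at timepoint 2 the planted edges are shifted by
#' `delta_z` on the Fisher-z scale and mapped back with `tanh`. If the
#' resulting matrix is not positive definite it is repaired by eigenvalue
#' clipping at 1e-6 followed by re-normalization to unit diagonal; the repair
#' must move non-planted cells by less than 0.01, otherwise generation stops.
#'
#' @param spec a [cohort_spec()].
#' @param effect an [effect_spec()].
#' @param group `"group1"` (experimental) or `"group2"` (control).
#' @param timepoint `"tp1"` or `"tp2"`.
#' @return correlation matrix with ROI dimnames; attribute
#'   `projection_delta` records the largest absolute change the positive
#'   definite repair made to any non-planted cell (0 when no repair ran).
#' @export
build_target_covariance <- function(spec, effect, group, timepoint) {
  group <- match.arg(group, c("group1", "group2"))
  timepoint <- match.arg(timepoint, c("tp1", "tp2"))
  labels <- spec$parcellation$label
  comm <- spec$parcellation$community
  n <- length(labels)
  within <- outer(comm, comm, "==")
  r <- ifelse(within, spec$base_within_r, spec$base_between_r)
  z <- atanh(r)
  if (group == "group1" && timepoint == "tp2" && length(effect$edges)) {
    idx <- effect_indices(effect, labels)
    z[idx] <- z[idx] + effect$delta_z
    z[idx[, c(2, 1), drop = FALSE]] <- z[idx]
  }
  target <- tanh(z)
  diag(target) <- 1
  dimnames(target) <- list(labels, labels)

  planted <- matrix(FALSE, n, n)
  if (length(effect$edges)) {
    idx <- effect_indices(effect, labels)
    planted[idx] <- TRUE
    planted[idx[, c(2, 1), drop = FALSE]] <- TRUE
  }
  delta <- 0
  ev <- eigen(target, symmetric = TRUE)
  if (min(ev$values) < 1e-6) {
    lam <- pmax(ev$values, 1e-6)
    fixed <- ev$vectors %*% (lam * t(ev$vectors))
    d <- 1 / sqrt(diag(fixed))
    fixed <- fixed * tcrossprod(d)
    diag(fixed) <- 1
    dimnames(fixed) <- dimnames(target)
    untouched <- !planted
    diag(untouched) <- FALSE
    delta <- max(abs(fixed[untouched] - target[untouched]))
    if (delta >= 0.01)
      stop2(paste0("positive-definite repair perturbs non-planted cells by ",
                   "%.3g (>= 0.01); effect too strong for this base structure"),
            delta)
    target <- fixed
  }
  attr(target, "projection_delta") <- delta
  target
}

# smooth unit-variance nuisance signal (AR(1), phi = 0.5)
nuisance_signal <- function(n) {
  x <- stats::filter(rnorm(n), 0.5, method = "recursive")
  as.numeric(x) / sqrt(1 / (1 - 0.25))
}

#' Simulate one subject/timepoint ROI time series
#'
#' Draws `n_volumes` samples from a zero-mean multivariate normal with the
#' given target correlation matrix, then adds (a) two shared nuisance signals
#' ("white-matter-like" and "CSF-like"), each scaled by `nuisance_amplitude`
#' and added identically to every ROI while the clean channels are recorded
#' in the `nuisance` slot, and (b) an independent random polynomial drift of
#' degree `drift_order` per ROI. Deterministic given (`spec$seed`,
#' `subject_seed`).
#'
#' @param target symmetric positive-definite correlation matrix with ROI
#'   dimnames.
#' @param spec a [cohort_spec()].
#' @param subject_seed small integer distinguishing subjects/timepoints.
#' @return a [subject_ts()] with nuisance channels `wm` and `csf`.
#' @export
generate_timeseries <- function(target, spec, subject_seed) {
  check_square_symmetric(target, "target correlation matrix", tol = 1e-8)
  ch <- tryCatch(chol(target),
                 error = function(e) stop2("target matrix is not positive definite"))
  set.seed(derive_seed(spec$seed, subject_seed))
  nt <- spec$n_volumes
  n <- nrow(target)
  x <- matrix(rnorm(nt * n), nt, n) %*% ch      # volumes x ROI, unit variance
  wm <- nuisance_signal(nt)
  csf <- nuisance_signal(nt)
  if (spec$nuisance_amplitude > 0)
    x <- x + spec$nuisance_amplitude * (wm + csf)
  if (spec$drift_order > 0) {
    basis <- poly(seq_len(nt), degree = spec$drift_order)  # orthonormal cols
    coef <- matrix(rnorm(spec$drift_order * n, sd = 0.5 * sqrt(nt)),
                   spec$drift_order, n)
    x <- x + basis %*% coef
  }
  subject_ts(t(x), rownames(target), spec$tr_seconds,
             nuisance = rbind(wm = wm, csf = csf))
}

#' Structural backbone template implied by the community structure
#'
#' Edges within a community are always present; between-community edges are
#' present with probability `p_between` (drawn once, deterministically from
#' the master seed); every planted effect edge is forced present so that
#' planted functional changes survive backbone masking.
#'
#' @param spec a [cohort_spec()].
#' @param effect an [effect_spec()].
#' @param p_between density of between-community structural connections
#'   (default 0.3).
#' @return symmetric binary matrix with zero diagonal and ROI dimnames.
#' @export
make_backbone_template <- function(spec, effect, p_between = 0.3) {
  labels <- spec$parcellation$label
  comm <- spec$parcellation$community
  n <- length(labels)
  set.seed(derive_seed(spec$seed, 0L))
  tmpl <- matrix(0L, n, n, dimnames = list(labels, labels))
  up <- upper_pairs(n)
  within <- comm[up[, 1]] == comm[up[, 2]]
  keep <- within | (runif(nrow(up)) < p_between)
  tmpl[up[keep, , drop = FALSE]] <- 1L
  tmpl[lower.tri(tmpl)] <- t(tmpl)[lower.tri(tmpl)]
  if (length(effect$edges)) {
    idx <- effect_indices(effect, labels)
    tmpl[idx] <- 1L
    tmpl[idx[, c(2, 1), drop = FALSE]] <- 1L
  }
  diag(tmpl) <- 0L
  tmpl
}

#' Simulate individual structural connectomes around a common backbone
#'
#' Each subject's binary matrix is the backbone template with every
#' off-diagonal cell flipped independently with probability
#' `structural_flip_rate` (symmetry preserved); planted effect edges are
#' never flipped off.
#'
#' @param spec a [cohort_spec()].
#' @param truth a ground-truth list holding `backbone_template` and
#'   `planted_edges` (see [generate_cohort()]).
#' @return list of symmetric binary matrices, one per subject.
#' @export
generate_structural_cohort <- function(spec, truth) {
  tmpl <- truth$backbone_template
  check_square_symmetric(tmpl, "backbone template")
  if (any(diag(tmpl) != 0)) stop2("backbone template has nonzero diagonal")
  labels <- rownames(tmpl)
  n <- nrow(tmpl)
  n_sub <- spec$n_group1 + spec$n_group2
  up <- upper_pairs(n)
  prot <- matrix(FALSE, n, n)
  if (length(truth$planted_edges)) {
    idx <- effect_indices(list(edges = truth$planted_edges), labels)
    prot[idx] <- TRUE
    prot[idx[, c(2, 1), drop = FALSE]] <- TRUE
  }
  lapply(seq_len(n_sub), function(s) {
    set.seed(derive_seed(spec$seed, 100L + s))
    flip <- runif(nrow(up)) < spec$structural_flip_rate
    m <- tmpl
    ij <- up[flip, , drop = FALSE]
    m[ij] <- 1L - m[ij]
    m[ij[, c(2, 1), drop = FALSE]] <- m[ij]
    m[prot] <- 1L                      # planted edges stay present
    diag(m) <- 0L
    m
  })
}

#' Generate a complete synthetic cohort
#'
#' Produces, reproducibly from `spec$seed`: one [subject_ts()] per subject
#' and timepoint, one binary structural connectome per subject, the four
#' design-cell target correlation matrices, the backbone template, and a
#' manifest of group membership.
#'
#' @param spec a [cohort_spec()].
#' @param effect an [effect_spec()]; use `effect_spec(edges =
#'   matrix(character(0), 0, 2))` for a null cohort.
#' @return object of class `synthetic_cohort`: a list with elements `spec`,
#'   `effect`, `subjects` (data.frame: subject, group), `ts` (per subject, a
#'   list with `tp1`/`tp2`), `structural`, and `truth` (planted edges,
#'   per-cell targets, backbone template).
#' @export
generate_cohort <- function(spec, effect = effect_spec()) {
  labels <- spec$parcellation$label
  effect_indices(effect, labels)  # validate edges early
  targets <- list()
  for (g in c("group1", "group2"))
    for (tp in c("tp1", "tp2"))
      targets[[paste(g, tp, sep = ".")]] <-
        build_target_covariance(spec, effect, g, tp)

  n_sub <- spec$n_group1 + spec$n_group2
  subjects <- data.frame(
    subject = sprintf("sub%02d", seq_len(n_sub)),
    group = rep(c("group1", "group2"), c(spec$n_group1, spec$n_group2)),
    stringsAsFactors = FALSE)

  ts <- vector("list", n_sub)
  names(ts) <- subjects$subject
  for (s in seq_len(n_sub)) {
    g <- subjects$group[s]
    ts[[s]] <- list(
      tp1 = generate_timeseries(targets[[paste(g, "tp1", sep = ".")]],
                                spec, 2L * s - 1L),
      tp2 = generate_timeseries(targets[[paste(g, "tp2", sep = ".")]],
                                spec, 2L * s))
  }

  truth <- list(planted_edges = effect$edges,
                delta_z = effect$delta_z,
                targets = targets,
                backbone_template = make_backbone_template(spec, effect))
  structural <- generate_structural_cohort(spec, truth)
  names(structural) <- subjects$subject

  structure(list(spec = spec, effect = effect, subjects = subjects,
                 ts = ts, structural = structural, truth = truth),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_cohort> %d + %d subjects x 2 timepoints, ",
                     "%d ROIs x %d volumes, %d planted edge(s)\n"),
              x$spec$n_group1, x$spec$n_group2, x$spec$n_rois,
              x$spec$n_volumes, nrow(x$truth$planted_edges %||% matrix(0, 0, 2))))
  invisible(x)
}

#' Write a synthetic cohort to a directory of TSV/JSON files
#'
#' Layout: `<subject>_tp<k>_timeseries.tsv` (volumes x ROIs + nuisance
#' columns), `<subject>_structural.tsv`, `backbone_template.tsv`,
#' `networks.json` and `manifest.json` (groups, seed, planted edge list).
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @param networks optional named list of [network_definition()]s to include.
#' @return invisibly, the manifest list.
#' @export
write_cohort <- function(cohort, dir, networks = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (s in cohort$subjects$subject) {
    for (tp in c("tp1", "tp2")) {
      f <- file.path(dir, sprintf("%s_%s_timeseries.tsv", s, tp))
      write_timeseries_tsv(cohort$ts[[s]][[tp]], f)
      files <- c(files, f)
    }
    f <- file.path(dir, sprintf("%s_structural.tsv", s))
    write_matrix_tsv(cohort$structural[[s]], f)
    files <- c(files, f)
  }
  write_matrix_tsv(cohort$truth$backbone_template,
                   file.path(dir, "backbone_template.tsv"))
  if (!is.null(networks))
    write_networks_json(networks, file.path(dir, "networks.json"))
  manifest <- list(
    subjects = cohort$subjects,
    seed = cohort$spec$seed,
    tr_seconds = cohort$spec$tr_seconds,
    n_volumes = cohort$spec$n_volumes,
    planted_edges = as.data.frame(cohort$truth$planted_edges,
                                  stringsAsFactors = FALSE),
    delta_z = cohort$truth$delta_z)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
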