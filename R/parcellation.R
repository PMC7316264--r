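#' Default 129-region cortical parcellation with community structure
#'
#' Builds the label set used by the synthetic cohort generator: a fixed list
#' of anatomically named regions (inferior frontal, superior temporal,
#' inferior parietal, attentional-network nodes, ...) in both hemispheres,
#' padded with generic parcels up to `n_rois`, each assigned to one of eight
#' lobe-by-hemisphere communities. The community assignment drives the
#' modular base covariance of simulated BOLD series (dense within-community
#' correlation, sparse between).
#'
#' @param n_rois total number of regions (default 129; must be at least the
#'   number of named anatomical regions, 34).
#' @return data.frame with columns `label` (character, unique) and
#'   `community` (integer community id).
#' @export
default_parcellation <- function(n_rois = 129) {
  named <- c(
    # right hemisphere
    "ctx.rh.IFG.opercularis", "ctx.rh.IFG.triangularis",
    "ctx.rh.STG.posterior", "ctx.rh.STG.anterior", "ctx.rh.STG.middle",
    "ctx.rh.TG.lateral",
    "ctx.rh.IPL.supramarginal.1", "ctx.rh.IPL.supramarginal.2",
    "ctx.rh.IPL.supramarginal.3", "ctx.rh.TPJ",
    "ctx.rh.insula.anterior", "ctx.rh.insula.posterior",
    "ctx.rh.MFG.caudal", "ctx.rh.FEF", "ctx.rh.IPS", "ctx.rh.SPL",
    "subc.rh.pallidum",
    # left hemisphere
    "ctx.lh.IFG.opercularis", "ctx.lh.IFG.triangularis",
    "ctx.lh.OFG.medial", "ctx.lh.FG.anterior", "ctx.lh.STS.posterior",
    "ctx.lh.STG.posterior", "ctx.lh.STG.middle", "ctx.lh.TG.lateral",
    "ctx.lh.IPL.supramarginal.1", "ctx.lh.IPL.supramarginal.2",
    "ctx.lh.TPJ", "ctx.lh.insula.anterior", "ctx.lh.insula.posterior",
    "ctx.lh.MFG.caudal", "ctx.lh.FEF", "ctx.lh.IPS", "ctx.lh.SPL"
  )
  if (n_rois < length(named))
    stop2("n_rois must be >= %d (number of named regions)", length(named))
  n_extra <- n_rois - length(named)
  extra <- sprintf("ctx.%s.parcel.%02d",
                   rep(c("rh", "lh"), length.out = n_extra),
                   seq_len(n_extra))
  labels <- c(named, extra)

  community_of <- function(lab) {
    hemi <- if (grepl("\\.rh\\.", lab)) 0L else 1L
    base <- if (grepl("IFG|MFG|OFG|FEF|insula", lab)) 1L
      else if (grepl("STG|STS|TG\\.|FG\\.", lab)) 3L
      else if (grepl("IPL|TPJ|IPS|SPL", lab)) 5L
      else 7L  # generic / subcortical
    base + hemi
  }
  data.frame(label = labels,
             community = vapply(labels, community_of, integer(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Named node set over a parcellation
#'
#' @param name network identifier, e.g. "VAN" or "DAN".
#' @param members character vector of ROI labels belonging to the network.
#' @param labels optional full parcellation label vector; when given, every
#'   member must occur in it.
#' @return object of class `network_definition`.
#' @export
network_definition <- function(name, members, labels = NULL) {
  if (length(members) < 1) stop2("network '%s' has no members", name)
  if (anyDuplicated(members))
    stop2("network '%s' has duplicate members", name)
  if (!is.null(labels)) {
    missing <- setdiff(members, labels)
    if (length(missing))
      stop2("network '%s' members not in parcellation: %s",
            name, paste(missing, collapse = ", "))
  }
  structure(list(name = name, members = as.character(members)),
            class = "network_definition")
}

#' @export
print.network_definition <- function(x, ...) {
  cat(sprintf("<network_definition> %s: %d ROIs\n", x$name, length(x$members)))
  invisible(x)
}

#' Default ventral and dorsal attentional network definitions
#'
#' The ventral attentional network (VAN) contains 19 regions (10 right,
#' 9 left: inferior frontal, supramarginal/temporo-parietal, insular and
#' caudal middle-frontal parcels); the dorsal attentional network (DAN)
#' contains 6 regions (frontal eye field, intraparietal sulcus and superior
#' parietal lobule in each hemisphere).
#'
#' @param labels optional parcellation label vector used for validation.
#' @return named list of `network_definition` objects (`VAN`, `DAN`).
#' @export
default_networks <- function(labels = default_parcellation()$label) {
  van <- c(
    "ctx.rh.IFG.opercularis", "ctx.rh.IFG.triangularis",
    "ctx.rh.IPL.supramarginal.1", "ctx.rh.IPL.supramarginal.2",
    "ctx.rh.IPL.supramarginal.3", "ctx.rh.TPJ",
    "ctx.rh.insula.anterior", "ctx.rh.insula.posterior",
    "ctx.rh.MFG.caudal", "ctx.rh.STG.middle",
    "ctx.lh.IFG.opercularis", "ctx.lh.IFG.triangularis",
    "ctx.lh.IPL.supramarginal.1", "ctx.lh.IPL.supramarginal.2",
    "ctx.lh.TPJ", "ctx.lh.insula.anterior", "ctx.lh.insula.posterior",
    "ctx.lh.MFG.caudal", "ctx.lh.STG.middle"
  )
  dan <- c("ctx.rh.FEF", "ctx.rh.IPS", "ctx.rh.SPL",
           "ctx.lh.FEF", "ctx.lh.IPS", "ctx.lh.SPL")
  list(VAN = network_definition("VAN", van, labels),
       DAN = network_definition("DAN", dan, labels))
}

#' Default planted-effect edge set: a bilateral fronto-temporal subnetwork
#'
#' Eleven edges between 13 nodes, every edge touching one of four inferior
#' frontal parcels; used as the default location of the planted
#' Group x Timepoint connectivity decrease so that recovery experiments probe
#' a realistic, hub-centred subnetwork.
#'
#' @return two-column character matrix of ROI label pairs.
#' @export
default_effect_edges <- function() {
  e <- rbind(
    c("ctx.rh.IFG.opercularis",  "ctx.rh.STG.posterior"),
    c("ctx.rh.IFG.triangularis", "ctx.rh.STG.posterior"),
    c("ctx.rh.IFG.opercularis",  "ctx.rh.STG.anterior"),
    c("ctx.rh.IFG.opercularis",  "ctx.rh.TG.lateral"),
    c("ctx.lh.OFG.medial",       "ctx.lh.IFG.triangularis"),
    c("subc.rh.pallidum",        "ctx.lh.IFG.opercularis"),
    c("ctx.lh.IFG.opercularis",  "ctx.lh.FG.anterior"),
    c("ctx.rh.IFG.opercularis",  "ctx.lh.STS.posterior"),
    c("ctx.rh.IFG.triangularis", "ctx.lh.STG.posterior"),
    c("ctx.rh.IFG.opercularis",  "ctx.lh.STG.posterior"),
    c("ctx.rh.IFG.opercularis",  "ctx.lh.TG.lateral")
  )
  colnames(e) <- c("node1", "node2")
  e
}

#' Write / read network definitions as JSON
#'
#' The on-disk format is a JSON object mapping network name to the array of
#' member ROI labels.
#'
#' @param networks named list of `network_definition` objects.
#' @param path file path.
#' @export
write_networks_json <- function(networks, path) {
  obj <- lapply(networks, function(n) n$members)
  names(obj) <- vapply(networks, function(n) n$name, character(1))
  jsonlite::write_json(obj, path, pretty = TRUE)
  invisible(path)
}

#' @rdname write_networks_json
#' @param labels optional parcellation labels for validation.
#' @export
read_networks_json <- function(path, labels = NULL) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- lapply(names(obj), function(nm)
    network_definition(nm, obj[[nm]], labels))
  names(out) <- names(obj)
  out
}
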