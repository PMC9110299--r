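#' Filter array probes down to fCpG candidates
#'
#' Applies the probe-level filters used before heterogeneity ranking:
#' retain type II probes only (type I probes have a different beta-value
#' distribution), drop sex chromosomes, drop cross-reactive probes, keep
#' 'open sea' loci (further than `island_distance_kb` from any CpG island),
#' and — when per-sample total intensities are supplied — drop loci whose
#' intensity is not above `min_intensity` in every sample (guarding against
#' incomplete probe binding at low DNA input).
#'
#' @param beta loci x samples matrix of beta values with locus rownames.
#' @param manifest data frame with one row per locus; columns `probe_id`,
#'   `design_type` ("I"/"II"), `chr`, `cross_reactive` (logical), and
#'   either `island_relation` (with "OpenSea" marking open sea) or
#'   `island_distance` in bp.
#' @param intensity optional loci x samples matrix of total probe
#'   intensities aligned with `beta`.
#' @param min_intensity intensity threshold (exclusive).
#' @param island_distance_kb open-sea distance threshold in kb (exclusive).
#' @return List with `beta` (the filtered matrix) and `counts`, the number
#'   of loci surviving each successive filter stage.
#' @export
fmc_filter_probes <- function(beta, manifest, intensity = NULL,
                              min_intensity = 1200, island_distance_kb = 4) {
  loci <- rownames(beta)
  if (is.null(loci)) stop("beta must have locus rownames", call. = FALSE)
  missing <- setdiff(loci, manifest$probe_id)
  if (length(missing))
    stop("manifest is missing loci: ", paste(missing, collapse = ", "),
         call. = FALSE)
  man <- manifest[match(loci, manifest$probe_id), ]
  counts <- c(input = length(loci))

  keep <- man$design_type == "II"
  counts["type_II"] <- sum(keep)
  if (!any(keep)) warning("no type II probes remain", call. = FALSE)

  autosomal <- !(sub("^chr", "", man$chr) %in% c("X", "Y"))
  keep <- keep & autosomal
  counts["autosomal"] <- sum(keep)

  keep <- keep & !isTRUE_vec(man$cross_reactive)
  counts["not_cross_reactive"] <- sum(keep)

  open_sea <- if ("island_relation" %in% names(man)) {
    man$island_relation %in% c("OpenSea", "open_sea", "opensea")
  } else if ("island_distance" %in% names(man)) {
    man$island_distance > island_distance_kb * 1000
  } else {
    stop("manifest needs island_relation or island_distance", call. = FALSE)
  }
  keep <- keep & open_sea
  counts["open_sea"] <- sum(keep)

  if (!is.null(intensity)) {
    ok <- apply(intensity[loci, , drop = FALSE] > min_intensity, 1, all)
    keep <- keep & ok
    counts["intensity"] <- sum(keep)
  } else {
    warning("no intensity data supplied; intensity filter skipped",
            call. = FALSE)
  }
  list(beta = beta[keep, , drop = FALSE], counts = counts)
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' Intraindividual heterogeneity score per locus
#'
#' For each locus, takes the standard deviation of beta across each
#' individual's samples (crypts) and averages these standard deviations
#' across individuals with at least two samples. Loci that fluctuate
#' independently per crypt score high; regulated or constant loci score
#' near zero. Also reports the cohort mean beta per locus.
#'
#' @param beta loci x samples matrix.
#' @param individual character/factor vector mapping each sample (column)
#'   to its donor.
#' @return Data frame with columns `locus`, `score`, `mean_beta`.
#' @export
fmc_score_heterogeneity <- function(beta, individual) {
  if (length(individual) != ncol(beta))
    stop("individual must map every sample column", call. = FALSE)
  individual <- as.character(individual)
  counts <- table(individual)
  use <- names(counts)[counts >= 2]
  if (!length(use))
    stop("no individual has >= 2 samples", call. = FALSE)
  sds <- vapply(use, function(ind) {
    apply(beta[, individual == ind, drop = FALSE], 1, sd)
  }, numeric(nrow(beta)))
  sds <- matrix(sds, nrow = nrow(beta))
  data.frame(locus = rownames(beta), score = rowMeans(sds),
             mean_beta = rowMeans(beta), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Select fCpG loci from heterogeneity scores
#'
#' Keeps the top `top_fraction` of loci by heterogeneity score (ties at the
#' cut broken deterministically by locus id) and then removes loci whose
#' cohort mean beta falls outside `mean_range`; the bounds are inclusive
#' (a mean of exactly 0.40 or 0.60 is retained).
#'
#' @param scores data frame from [fmc_score_heterogeneity()].
#' @param top_fraction fraction of loci to keep by score (default 5%).
#' @param mean_range inclusive cohort-mean-beta window.
#' @return Character vector of selected locus ids, sorted.
#' @export
fmc_select_fcpgs <- function(scores, top_fraction = 0.05,
                             mean_range = c(0.4, 0.6)) {
  if (nrow(scores) == 0) {
    warning("no loci to select from", call. = FALSE)
    return(character(0))
  }
  n_keep <- floor(nrow(scores) * top_fraction)
  ord <- order(-scores$score, scores$locus)
  top <- scores[ord[seq_len(n_keep)], ]
  sel <- top$locus[top$mean_beta >= mean_range[1] &
                     top$mean_beta <= mean_range[2]]
  sort(unique(sel))
}

#' Intersect fCpG panels from different tissues
#'
#' @param panel_a,panel_b character vectors of locus ids.
#' @return Loci present in both, in `panel_a`'s order.
#' @export
fmc_intersect_panels <- function(panel_a, panel_b) {
  panel_a[panel_a %in% panel_b]
}
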