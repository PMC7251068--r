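# Connectome container and the standard preparation steps the spreading
# model diffuses over: template averaging, top-fraction thresholding with
# rescaling, and the Euclidean-distance similarity baseline.

new_connectome <- function(weights, regions, modality,
                           preprocessing = list()) {
  stopifnot(is.matrix(weights), nrow(weights) == ncol(weights))
  if (!is_symmetric_num(weights)) stopf("connectome weights must be symmetric")
  if (any(weights < 0)) stopf("connectome weights must be nonnegative")
  diag(weights) <- 0
  rn <- regions$name
  if (nrow(weights) != length(rn)) {
    stopf("connectome has %d regions but region table has %d",
          nrow(weights), length(rn))
  }
  dimnames(weights) <- list(rn, rn)
  structure(list(weights = weights, regions = regions,
                 modality = modality, preprocessing = preprocessing),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  nz <- x$weights[upper.tri(x$weights)]
  cat(sprintf("Connectome: %d regions, modality '%s', density %.3f, weight range [%.3g, %.3g]\n",
              nrow(x$weights), x$modality, mean(nz > 0),
              min(x$weights), max(x$weights)))
  if (length(x$preprocessing)) {
    cat("  preprocessing:",
        paste(names(x$preprocessing), unlist(x$preprocessing),
              sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Simulate a synthetic connectome
#'
#' Generates a seeded, symmetric, nonnegative connectome over a region
#' table. Edge propensity decays with inter-centroid Euclidean distance
#' (multiplied by lognormal weight noise); the strongest `density` fraction
#' of off-diagonal connections is retained, homotopic edges are set to at
#' least `homotopic_strength`, and surviving weights are min-max scaled to
#' (0, 1]. This stands in for template structural/functional connectomes:
#' distance-dependent connection strength plus strong homotopic coupling are
#' the two gross features of real templates the spreading analyses rely on.
#'
#' @param regions A [build_region_table()] region table.
#' @param density Target off-diagonal nonzero fraction, in (0, 1].
#' @param homotopic_strength Pre-scaling weight floor for homotopic edges
#'   (on the scale of the distance kernel, whose maximum is 1).
#' @param limbic_homotopic_strength Separate floor for the limbic
#'   (medial temporal) homotopic pairs. Defaults to `homotopic_strength`;
#'   set it near 0 for a tractography-like template in which
#'   interhemispheric medial-temporal connectivity is sparse — the regime
#'   in which epicenter lateralization is identifiable.
#' @param limbic_bundle_strength Floor for within-hemisphere edges among
#'   the limbic set (the entorhinal-hippocampal circuit), guaranteeing
#'   the seed chain is wired regardless of kernel noise.
#' @param seed Integer seed.
#' @param length_scale Distance-decay scale in mm.
#' @return A `connectome` with modality `"synthetic"`.
#' @export
simulate_connectome <- function(regions, density = 0.10,
                                homotopic_strength = 0.35,
                                limbic_homotopic_strength = homotopic_strength,
                                limbic_bundle_strength = 0.15,
                                seed = 1L, length_scale = 10) {
  stopifnot(inherits(regions, "region_table"))
  if (!(density > 0 && density <= 1)) stopf("density must be in (0, 1]")
  xyz <- as.matrix(regions[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  w <- exp(-d / length_scale)
  n <- nrow(w)
  # Edge-strength noise is drawn once per within-hemisphere edge and
  # mirrored, like a subject-averaged template: both hemispheres share
  # the same internal topology, and interhemispheric structure is
  # carried by the homotopic edges alone (non-homotopic interhemispheric
  # kernel weights are negligible at these distances).
  k <- n %/% 2L
  if (!identical(regions$base_name[seq_len(k)],
                 regions$base_name[k + seq_len(k)])) {
    stopf("region table must list left then right hemispheres in matching order")
  }
  noise <- with_seed(seed, {
    mh <- matrix(0, k, k)
    mh[upper.tri(mh)] <- stats::rlnorm(k * (k - 1) / 2, sdlog = 0.5)
    mh <- mh + t(mh)
    m <- matrix(1, n, n)
    m[seq_len(k), seq_len(k)] <- mh
    m[k + seq_len(k), k + seq_len(k)] <- mh
    m
  })
  w <- w * noise
  pairs <- homotopic_pairs(regions, cortical_only = FALSE)
  limbic_base <- unique(regions$base_name[regions$limbic])
  for (i in seq_len(nrow(pairs))) {
    hsi <- if (pairs$base_name[i] %in% limbic_base) {
      limbic_homotopic_strength
    } else {
      homotopic_strength
    }
    l <- pairs$left_id[i]; r <- pairs$right_id[i]
    w[l, r] <- w[r, l] <- max(w[l, r], hsi)
  }
  # Within-hemisphere medial-temporal bundle: the entorhinal-hippocampus
  # (perforant path) edge gets the full floor; the remaining limbic
  # pairs get half, so the circuit is always wired without short-cutting
  # the staged progression through amygdala/parahippocampal cortex.
  for (h in c("L", "R")) {
    idx <- which(regions$limbic & regions$hemisphere == h)
    for (a in idx) for (b in idx) {
      if (a >= b) next
      pairfloor <- if (all(regions$base_name[c(a, b)] %in%
                           c("entorhinal", "hippocampus"))) {
        limbic_bundle_strength
      } else {
        limbic_bundle_strength / 2
      }
      w[a, b] <- w[b, a] <- max(w[a, b], pairfloor)
    }
  }
  diag(w) <- 0
  # Retain the strongest `density` fraction of unique off-diagonal
  # entries, always including the maximum spanning tree so the graph
  # stays connected (as real template connectomes are) even when dense
  # local clusters would otherwise exhaust the quota.
  ut <- which(upper.tri(w))
  keep_n <- max(1L, round(density * length(ut)))
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE)
  mst <- igraph::mst(g, weights = -igraph::E(g)$weight)
  mst_el <- igraph::as_edgelist(mst, names = FALSE)
  mst_idx <- (pmax(mst_el[, 1], mst_el[, 2]) - 1L) * n +
    pmin(mst_el[, 1], mst_el[, 2])          # upper-triangle linear index
  ord <- ut[order(w[ut], decreasing = TRUE)]
  keep_idx <- union(mst_idx, ord)[seq_len(max(keep_n, length(mst_idx)))]
  drop_idx <- setdiff(ut, keep_idx)
  w[drop_idx] <- 0
  w[lower.tri(w)] <- t(w)[lower.tri(w)]
  surv <- w[w > 0]
  if (length(surv)) {
    rng <- range(surv)
    # map surviving weights to (0, 1] keeping zeros at zero
    w[w > 0] <- if (diff(rng) > 0) {
      0.05 + 0.95 * (w[w > 0] - rng[1]) / diff(rng)
    } else 1
  }
  new_connectome(w, regions, "synthetic",
                 list(density = density,
                      homotopic_strength = homotopic_strength,
                      limbic_homotopic_strength = limbic_homotopic_strength,
                      seed = seed))
}

#' Average connectomes into a template
#'
#' Elementwise mean of same-shaped weight matrices, the standard way
#' single-subject connectivity matrices are combined into a template.
#'
#' @param matrices A list of numeric matrices (or `connectome` objects)
#'   sharing shape and region order.
#' @param regions Region table for the result; taken from the first
#'   `connectome` input if omitted.
#' @param modality Modality tag for the result.
#' @return A `connectome` whose weights are the elementwise mean.
#' @export
average_connectomes <- function(matrices, regions = NULL,
                                modality = "structural") {
  stopifnot(length(matrices) >= 1)
  ws <- lapply(matrices, function(m) {
    if (inherits(m, "connectome")) m$weights else m
  })
  if (is.null(regions)) {
    isc <- vapply(matrices, inherits, logical(1), "connectome")
    if (!any(isc)) stopf("regions must be supplied when averaging bare matrices")
    regions <- matrices[[which(isc)[1]]]$regions
  }
  dims <- vapply(ws, dim, integer(2))
  if (any(dims != dims[, 1])) stopf("matrices differ in shape")
  avg <- Reduce(`+`, ws) / length(ws)
  new_connectome(avg, regions, modality, list(n_averaged = length(ws)))
}

#' Threshold a connectome to its strongest connections and rescale
#'
#' Retains only the top `top_fraction` of unique off-diagonal connections
#' (ranked over the upper triangle; ties broken by stable index order) and
#' min-max scales the survivors to \[0, 1\]. This mirrors the usual
#' preparation of functional connectivity templates before diffusion
#' modelling.
#'
#' @param x A `connectome`, or a symmetric weight matrix (then `regions`
#'   is required).
#' @param top_fraction Fraction of connections retained, in (0, 1].
#' @param regions Region table when `x` is a bare matrix.
#' @return A `connectome` with weights in \[0, 1\] and the threshold
#'   recorded in its preprocessing provenance.
#' @export
threshold_and_scale <- function(x, top_fraction = 0.10, regions = NULL) {
  if (!(top_fraction > 0 && top_fraction <= 1)) {
    stopf("top_fraction must be in (0, 1]")
  }
  if (inherits(x, "connectome")) {
    regions <- x$regions
    modality <- x$modality
    w <- x$weights
  } else {
    if (is.null(regions)) stopf("regions required for a bare matrix")
    modality <- "structural"
    w <- x
  }
  if (!is_symmetric_num(w)) stopf("input must be symmetric")
  diag(w) <- 0
  ut <- which(upper.tri(w))
  keep_n <- max(1L, round(top_fraction * length(ut)))
  # order(-w) with stable index tie-break
  ord <- order(w[ut], -seq_along(ut), decreasing = TRUE)
  w[ut[ord[-seq_len(keep_n)]]] <- 0
  w[lower.tri(w)] <- t(w)[lower.tri(w)]
  # Scale by the maximum so survivors land in (0, 1]; unlike full min-max
  # this keeps the weakest survivor nonzero, making the operation
  # idempotent at a fixed top_fraction.
  if (any(w > 0)) w <- w / max(w)
  new_connectome(w, regions, modality,
                 list(threshold_fraction = top_fraction,
                      scaling = "max_normalized"))
}

#' Euclidean-distance similarity matrix
#'
#' Pairwise Euclidean distances between region centroids, normalized to
#' \[0, 1\] by the largest off-diagonal distance and inverted
#' (1 - d / max(d)), so coincident centroids score 1 and the most distant
#' pair 0. Used as the extracellular-spread alternative to a connectome:
#' diffusing over it tests whether proximity alone explains the regional
#' pattern.
#'
#' @param regions A region table with centroid columns.
#' @return A `connectome` with modality `"distance"`.
#' @export
distance_similarity <- function(regions) {
  stopifnot(inherits(regions, "region_table"))
  xyz <- as.matrix(regions[, c("x", "y", "z")])
  if (anyNA(xyz)) stopf("centroids missing")
  d <- as.matrix(stats::dist(xyz))
  s <- 1 - d / max(d[upper.tri(d)])
  s <- pmin(pmax(s, 0), 1)
  diag(s) <- 0
  new_connectome(s, regions, "distance",
                 list(scaling = "max_normalized_inverted"))
}
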