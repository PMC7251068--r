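# Atlas fixture: DKT-derived region table with hemisphere, tissue class,
# limbic and Braak-stage annotations, plus synthetic bilateral-symmetric
# centroids.

# The 31 Mindboggle-compliant DKT cortical labels (per hemisphere).
.dkt_cortical <- c(
  "caudal anterior cingulate", "caudal middle frontal", "cuneus",
  "entorhinal", "fusiform", "inferior parietal", "inferior temporal",
  "isthmus cingulate", "lateral occipital", "lateral orbitofrontal",
  "lingual", "medial orbitofrontal", "middle temporal", "parahippocampal",
  "paracentral", "pars opercularis", "pars orbitalis", "pars triangularis",
  "pericalcarine", "postcentral", "posterior cingulate", "precentral",
  "precuneus", "rostral anterior cingulate", "rostral middle frontal",
  "superior frontal", "superior parietal", "superior temporal",
  "supramarginal", "transverse temporal", "insula"
)

# Subcortical grey-matter structures treated as cortical-set members
# (tau-bearing medial temporal structures) vs the remaining subcortical set.
.mtl_subcortical <- c("hippocampus", "amygdala")
.deep_subcortical <- c("thalamus", "caudate", "putamen", "pallidum",
                       "accumbens", "ventral dc")

# Approximate staging of neurofibrillary-tangle appearance per base label.
# Stage 1 transentorhinal, 2 hippocampal, 3 limbic/medial temporal,
# 4 association limbic cortex, 5 association isocortex, 6 primary cortex.
.braak_map <- c(
  "entorhinal" = 1L,
  "hippocampus" = 2L,
  "parahippocampal" = 3L, "fusiform" = 3L, "lingual" = 3L, "amygdala" = 3L,
  "middle temporal" = 4L, "caudal anterior cingulate" = 4L,
  "rostral anterior cingulate" = 4L, "posterior cingulate" = 4L,
  "isthmus cingulate" = 4L, "insula" = 4L, "inferior temporal" = 4L,
  "superior frontal" = 5L, "lateral orbitofrontal" = 5L,
  "medial orbitofrontal" = 5L, "caudal middle frontal" = 5L,
  "rostral middle frontal" = 5L, "pars opercularis" = 5L,
  "pars orbitalis" = 5L, "pars triangularis" = 5L, "lateral occipital" = 5L,
  "supramarginal" = 5L, "inferior parietal" = 5L, "superior parietal" = 5L,
  "precuneus" = 5L, "superior temporal" = 5L, "transverse temporal" = 5L,
  "pericalcarine" = 6L, "postcentral" = 6L, "cuneus" = 6L,
  "precentral" = 6L, "paracentral" = 6L
)

.limbic_labels <- c("entorhinal", "hippocampus", "amygdala",
                    "parahippocampal")

#' Build the packaged atlas region table
#'
#' Constructs the region table used throughout the package: a DKT-derived
#' label set with hemisphere, tissue class, limbic flag, Braak-stage ROI
#' assignment and synthetic (mirrored, seeded) centroid coordinates. The
#' cortical set comprises 31 cortical labels per hemisphere plus bilateral
#' hippocampus and amygdala (66 regions, 33 homotopic pairs); the full set
#' adds six deep subcortical structures per hemisphere (78 regions).
#'
#' Centroids are synthetic: two mirrored hemispheric point clouds on a
#' sphere-like layout. Only relative distances between them are meaningful
#' (they drive the distance-similarity baseline and the synthetic
#' connectome), not anatomical location.
#'
#' @param atlas_mode `"cortical66"` for the 66-region cortical set or
#'   `"full78"` for the full cortical + subcortical set.
#' @param coordinate_seed Integer seed controlling the synthetic centroid
#'   jitter.
#' @return A `data.frame` of class `region_table` with columns `region_id`,
#'   `name`, `base_name`, `hemisphere` (`"L"`/`"R"`), `tissue_class`
#'   (`"cortical"`/`"subcortical"`), `limbic` (logical), `braak_stage`
#'   (integer 1-6, `NA` for deep subcortical regions) and centroid
#'   coordinates `x`, `y`, `z` in mm.
#' @examples
#' regions <- build_region_table("cortical66")
#' nrow(regions)            # 66
#' sum(regions$limbic)      # 8 (entorhinal, hippocampus, amygdala,
#'                          #    parahippocampal, bilaterally)
#' @export
build_region_table <- function(atlas_mode = c("cortical66", "full78"),
                               coordinate_seed = 1L) {
  atlas_mode <- match.arg(atlas_mode)
  cort <- c(.dkt_cortical, .mtl_subcortical)
  base <- if (atlas_mode == "full78") c(cort, .deep_subcortical) else cort

  tab <- data.frame(
    base_name = rep(base, times = 2L),
    hemisphere = rep(c("L", "R"), each = length(base)),
    stringsAsFactors = FALSE
  )
  tab$name <- paste(ifelse(tab$hemisphere == "L", "left", "right"),
                    tab$base_name)
  tab$tissue_class <- ifelse(tab$base_name %in% .dkt_cortical,
                             "cortical", "subcortical")
  tab$limbic <- tab$base_name %in% .limbic_labels
  tab$braak_stage <- unname(.braak_map[tab$base_name])

  # Deterministic layered layout, mirrored across hemispheres. The
  # longitudinal (y) coordinate follows the staging axis — stage-1 regions
  # sit at the medial-temporal end and primary cortex at the far end —
  # matching the real geometry in which tangle stage tracks distance from
  # the medial temporal lobe; lateral (x) and axial (z) positions are
  # seeded jitter. Deep subcortical structures sit centrally. Only
  # relative distances are meaningful.
  k <- length(base)
  stage_of <- unname(.braak_map[base])
  pos <- with_seed(coordinate_seed, {
    y <- ifelse(is.na(stage_of),
                stats::rnorm(k, mean = 55, sd = 6),
                70 - 26 * (stage_of - 1) - 14 * (stage_of == 6) +
                  stats::rnorm(k, sd = 5))
    x <- ifelse(is.na(stage_of),
                10 + abs(stats::rnorm(k, sd = 5)),
                28 + stats::rnorm(k, sd = 8))
    z <- stats::rnorm(k, sd = 12)
    cbind(x = pmax(x, 5), y = y, z = z)
  })
  xyz <- rbind(pos, pos)
  xyz[seq_len(k), "x"] <- -xyz[seq_len(k), "x"]  # left hemisphere mirrored
  tab$x <- xyz[, "x"]
  tab$y <- xyz[, "y"]
  tab$z <- xyz[, "z"]

  # Order: left then right, cortical-set order as listed.
  tab$region_id <- seq_len(nrow(tab))
  tab <- tab[, c("region_id", "name", "base_name", "hemisphere",
                 "tissue_class", "limbic", "braak_stage", "x", "y", "z")]
  class(tab) <- c("region_table", "data.frame")
  tab
}

#' Homotopic region pairs
#'
#' Returns one row per homotopic (left/right) pair of regions, identified by
#' a shared base label.
#'
#' @param regions A [build_region_table()] region table.
#' @param cortical_only If `TRUE` (default), restrict to the cortical-set
#'   pairs (33 pairs for the 66-region set).
#' @return A `data.frame` with columns `base_name`, `left_id`, `right_id`.
#' @export
homotopic_pairs <- function(regions, cortical_only = TRUE) {
  stopifnot(inherits(regions, "region_table"))
  tab <- regions
  if (cortical_only) {
    keep <- tab$tissue_class == "cortical" | tab$base_name %in% .mtl_subcortical
    tab <- tab[keep, ]
  }
  left <- tab[tab$hemisphere == "L", ]
  right <- tab[tab$hemisphere == "R", ]
  right <- right[match(left$base_name, right$base_name), ]
  stopifnot(!anyNA(right$region_id))
  data.frame(base_name = left$base_name,
             left_id = left$region_id,
             right_id = right$region_id,
             stringsAsFactors = FALSE)
}

#' @export
print.region_table <- function(x, ...) {
  cat(sprintf("Region table: %d regions (%d cortical, %d subcortical), %d homotopic pairs\n",
              nrow(x), sum(x$tissue_class == "cortical"),
              sum(x$tissue_class == "subcortical"),
              nrow(homotopic_pairs(x, cortical_only = FALSE))))
  NextMethod()
}

#' Write / read a region table as TSV
#'
#' @param regions A region table.
#' @param path Output TSV path.
#' @return `read_region_table()` returns a `region_table`;
#'   `write_region_table()` returns `path` invisibly.
#' @export
write_region_table <- function(regions, path) {
  stopifnot(inherits(regions, "region_table"))
  utils::write.table(as.data.frame(regions), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_region_table
#' @export
read_region_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  tab$braak_stage <- as.integer(tab$braak_stage)
  class(tab) <- c("region_table", "data.frame")
  tab
}
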