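#' Region atlas: canonical region ordering per measure class
#'
#' A `pbsi_atlas` fixes the identity and order of the feature columns every
#' profile is built from: 100 cortical parcels (Schaefer-100-style,
#' hemisphere-prefixed, seven functional networks) and 14 subcortical
#' structures (left/right thalamus, caudate, putamen, pallidum, hippocampus,
#' amygdala, accumbens area). All tables and profiles in the package are
#' reordered to this canonical order before any computation, so Spearman
#' profile correlations are always taken over identically ordered vectors.
#'
#' @param cortical_regions character vector of cortical parcel identifiers.
#' @param subcortical_regions character vector of subcortical identifiers.
#' @return An object of class `pbsi_atlas`: a list with elements
#'   `cortical` and `subcortical` (character vectors).
#' @examples
#' atl <- default_atlas()
#' length(atl$cortical)     # 100
#' length(atl$subcortical)  # 14
#' @export
region_atlas <- function(cortical_regions, subcortical_regions) {
  cortical_regions <- as.character(cortical_regions)
  subcortical_regions <- as.character(subcortical_regions)
  if (anyDuplicated(cortical_regions))
    stop("cortical region identifiers must be unique", call. = FALSE)
  if (anyDuplicated(subcortical_regions))
    stop("subcortical region identifiers must be unique", call. = FALSE)
  if (length(cortical_regions) < 3L || length(subcortical_regions) < 3L)
    stop("atlas needs at least 3 regions per measure class", call. = FALSE)
  structure(list(cortical = cortical_regions,
                 subcortical = subcortical_regions),
            class = "pbsi_atlas")
}

#' @rdname region_atlas
#' @export
default_atlas <- function() {
  # Schaefer-style 7-network parcel names, 50 per hemisphere.
  networks <- c(Vis = 8L, SomMot = 8L, DorsAttn = 7L, SalVentAttn = 7L,
                Limbic = 4L, Cont = 7L, Default = 9L)
  stopifnot(sum(networks) == 50L)
  cortical <- unlist(lapply(c("LH", "RH"), function(h) {
    unlist(lapply(names(networks), function(nw) {
      sprintf("%s_%s_%d", h, nw, seq_len(networks[[nw]]))
    }))
  }), use.names = FALSE)
  structures <- c("Thalamus", "Caudate", "Putamen", "Pallidum",
                  "Hippocampus", "Amygdala", "Accumbens-area")
  subcortical <- unlist(lapply(c("Left", "Right"), function(h) {
    paste(h, structures, sep = "-")
  }), use.names = FALSE)
  region_atlas(cortical, subcortical)
}

#' Region identifiers for one measure class
#'
#' @param atlas a `pbsi_atlas`.
#' @param measure_class one of `"thickness"`, `"area"`, `"volume"`,
#'   `"subcortical"`. The three cortical measure classes share the cortical
#'   parcel list; `"subcortical"` uses the subcortical list.
#' @return character vector of region identifiers in canonical order.
#' @export
atlas_regions <- function(atlas, measure_class) {
  stopifnot(inherits(atlas, "pbsi_atlas"))
  measure_class <- match.arg(measure_class, MEASURE_CLASSES)
  if (measure_class == "subcortical") atlas$subcortical else atlas$cortical
}

#' @export
print.pbsi_atlas <- function(x, ...) {
  cat(sprintf("<pbsi_atlas> %d cortical parcels, %d subcortical regions\n",
              length(x$cortical), length(x$subcortical)))
  invisible(x)
}

# Canonical measure-class order used everywhere downstream.
MEASURE_CLASSES <- c("thickness", "area", "volume", "subcortical")
CORTICAL_CLASSES <- c("thickness", "area", "volume")
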