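# Canonical 95-region volumetric schema.
#
# Feature index r is positional in this ordered set; every table, percentile
# profile and coefficient vector in the package is aligned to it.

# Display names of the 95 cortical and subcortical regions shared by the
# cohorts this pipeline targets (FastSurfer-style segmentation output,
# left/right cortical parcels plus subcortical structures, ventricles, CSF
# and WM hypointensities).
.REGION_NAMES_RAW <- c(
  "3rd Ventricle", "4th Ventricle", "Brain Stem", "CSF",
  "Left accumbens area", "Left amygdala", "Left caudal anterior cingulate",
  "Left caudal middle frontal", "Left caudate", "Left cerebellum cortex",
  "Left cerebellum white matter", "Left cerebral white matter",
  "Left choroid plexus", "Left cuneus", "Left entorhinal", "Left fusiform",
  "Left hippocampus", "Left inferior lateral ventricle",
  "Left inferior parietal", "Left inferior temporal", "Left insula",
  "Left isthmus cingulate", "Left lateral occipital",
  "Left lateral orbitofrontal", "Left lateral ventricle", "Left lingual",
  "Left medial orbitofrontal", "Left middle temporal", "Left pallidum",
  "Left paracentral", "Left parahippocampal", "Left pars opercularis",
  "Left pars orbitalis", "Left pars triangularis", "Left pericalcarine",
  "Left postcentral", "Left posterior cingulate", "Left precentral",
  "Left precuneus", "Left putamen", "Left rostral anterior cingulate",
  "Left rostral middle frontal", "Left superior frontal",
  "Left superior parietal", "Left superior temporal", "Left supramarginal",
  "Left-Thalamus", "Left transverse temporal", "Left ventral DC",
  "Right accumbens area", "Right amygdala", "Right caudal anterior cingulate",
  "Right caudal middle frontal", "Right caudate", "Right cerebellum cortex",
  "Right cerebellum white matter", "Right cerebral white matter",
  "Right choroid plexus", "Right cuneus", "Right entorhinal",
  "Right fusiform", "Right hippocampus", "Right inferior lateral ventricle",
  "Right inferior parietal", "Right inferior temporal", "Right insula",
  "Right isthmus cingulate", "Right lateral occipital",
  "Right lateral orbitofrontal", "Right lateral ventricle", "Right lingual",
  "Right medial orbitofrontal", "Right middle temporal", "Right pallidum",
  "Right paracentral", "Right parahippocampal", "Right pars opercularis",
  "Right pars orbitalis", "Right pars triangularis", "Right pericalcarine",
  "Right postcentral", "Right posterior cingulate", "Right precentral",
  "Right precuneus", "Right putamen", "Right rostral anterior cingulate",
  "Right rostral middle frontal", "Right superior frontal",
  "Right superior parietal", "Right superior temporal", "Right supramarginal",
  "Right-Thalamus", "Right transverse temporal", "Right ventral DC",
  "WM hypointensities"
)

#' Canonical brain region set
#'
#' The ordered set of 95 region names the pipeline operates on: bilateral
#' cortical parcels, subcortical structures, ventricular/CSF spaces, brain
#' stem and white-matter hypointensities, as produced by FastSurfer-style
#' whole-brain segmentation. The order is fixed (alphabetical on the
#' normalized keys, see [region_key()]) and defines the positional feature
#' index used by percentile profiles and classifier coefficients.
#'
#' Matching of externally supplied names (file headers, user vectors) is
#' case- and whitespace-insensitive and treats `-`/`_` as spaces, so
#' `"Left-Inf-Lat-Vent"`-style labels must be mapped upstream but
#' `"left  inferior lateral ventricle"` or `"Left_inferior_lateral_ventricle"`
#' resolve to the canonical `"Left inferior lateral ventricle"`.
#'
#' @return Character vector of length 95, in canonical order.
#' @examples
#' length(brain_regions())
#' head(brain_regions())
#' @export
brain_regions <- function() {
  .REGION_NAMES_RAW
}

#' Normalize region names to a matching key
#'
#' Lower-cases, maps `-` and `_` to spaces, and collapses runs of
#' whitespace, so cosmetic variants of a canonical region name compare
#' equal. Used by all loaders; exported for users mapping their own
#' segmentation output onto the canonical set.
#'
#' @param x Character vector of region names.
#' @return Character vector of normalized keys, same length as `x`.
#' @examples
#' region_key("Left_inferior  lateral ventricle")
#' @export
region_key <- function(x) {
  x <- tolower(as.character(x))
  x <- gsub("[-_]+", " ", x)
  x <- gsub("[[:space:]]+", " ", x)
  trimws(x)
}

# Resolve arbitrary labels to canonical display names; NA where no match.
match_regions <- function(x, regions = brain_regions()) {
  regions[match(region_key(x), region_key(regions))]
}
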