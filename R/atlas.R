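#' Atlas specification tables
#'
#' An atlas specification maps integer region labels (as found in a label
#' volume) to region names and an anatomical grouping (lobe, hemisphere).
#' The bundled default is a 90-region cortical/subcortical parcellation in
#' the automated-anatomical-labelling numbering, with each region assigned
#' to one of six lobes (frontal, temporal, limbic, subcortical, occipital,
#' parietal) and one hemisphere. The mapping ships as an editable TSV so a
#' different lobe assignment or atlas can be swapped in as data.
#'
#' @param path path to a TSV with columns `region_id`, `region_name`,
#'   `lobe`, `hemisphere`. Defaults to the bundled 90-region table.
#' @return a `data.frame` of class `atlas_spec`.
#' @examples
#' atlas <- read_atlas()
#' table(atlas$lobe)
#' @export
read_atlas <- function(path = NULL) {
  path <- path %||% system.file("extdata", "atlas_aal90.tsv",
                                package = "bagpipe", mustWork = TRUE)
  atlas <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_atlas(atlas)
}

#' @rdname read_atlas
#' @export
default_atlas <- function() read_atlas()

lobe_levels <- c("frontal", "temporal", "limbic", "subcortical",
                 "occipital", "parietal")

validate_atlas <- function(atlas) {
  need <- c("region_id", "region_name", "lobe", "hemisphere")
  missing <- setdiff(need, names(atlas))
  if (length(missing))
    stop("atlas table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(atlas$region_id))
    stop("atlas region_id values must be unique", call. = FALSE)
  if (any(atlas$region_id <= 0) || any(atlas$region_id != round(atlas$region_id)))
    stop("atlas region_id values must be positive integers", call. = FALSE)
  bad <- setdiff(unique(atlas$lobe), lobe_levels)
  if (length(bad))
    stop("unknown lobe label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  bad <- setdiff(unique(atlas$hemisphere), c("left", "right"))
  if (length(bad))
    stop("unknown hemisphere label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  class(atlas) <- c("atlas_spec", "data.frame")
  atlas
}

# Canonical feature-column names for an atlas, in atlas order.
region_columns <- function(atlas) sprintf("region_%d", atlas$region_id)
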