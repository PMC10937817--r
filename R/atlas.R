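#' Load the packaged Destrieux region table
#'
#' Returns the fixed 148-region Destrieux cortical parcellation (74 gyral and
#' sulcal regions per hemisphere) used throughout the package. Region names
#' are FreeSurfer \code{aparc.a2009s} label strings with an \code{lh_}/\code{rh_}
#' hemisphere prefix (e.g. \code{"lh_S_temporal_sup"}). Each region carries a
#' \code{lobe_group} assignment splitting the cortex into 30 temporal
#' (15 per hemisphere) and 118 extratemporal regions.
#'
#' @return A data frame with columns \code{region_id} (integer 0..147),
#'   \code{name}, \code{hemisphere} (\code{"left"}/\code{"right"}),
#'   \code{kind} (\code{"gyral"}/\code{"sulcal"}) and \code{lobe_group}
#'   (\code{"temporal"}/\code{"extratemporal"}).
#' @examples
#' atlas <- load_atlas()
#' table(atlas$hemisphere)
#' table(atlas$lobe_group)
#' @export
load_atlas <- function() {
  path <- system.file("extdata", "destrieux_regions.tsv", package = "hbrnorm")
  if (!nzchar(path) || !file.exists(path)) {
    stop("packaged atlas table not found; installation is corrupt", call. = FALSE)
  }
  atlas <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("region_id", "name", "hemisphere", "kind", "lobe_group")
  if (!all(required %in% names(atlas)) ||
      nrow(atlas) != 148L ||
      anyDuplicated(atlas$name) ||
      !all(table(atlas$hemisphere) == 74L) ||
      sum(atlas$lobe_group == "temporal") != 30L) {
    stop("packaged atlas table is corrupt", call. = FALSE)
  }
  atlas
}

#' Build a logical region mask
#'
#' Selects regions by hemisphere, lobe group, and/or an explicit name list.
#' Multiple selectors are combined with AND; a zero-length \code{names}
#' vector selects nothing.
#'
#' @param atlas Region table from \code{\link{load_atlas}}.
#' @param hemisphere Optional, \code{"left"} or \code{"right"}.
#' @param lobe_group Optional, \code{"temporal"} or \code{"extratemporal"}.
#' @param names Optional character vector of region names. Unknown names are
#'   an error; names may use dots in place of underscores/hyphens
#'   (FreeSurfer table-export dialect).
#' @return Logical vector of length 148, ordered as the atlas.
#' @examples
#' atlas <- load_atlas()
#' sum(region_mask(atlas, hemisphere = "left"))      # 74
#' sum(region_mask(atlas, lobe_group = "temporal"))  # 30
#' @export
region_mask <- function(atlas, hemisphere = NULL, lobe_group = NULL, names = NULL) {
  mask <- rep(TRUE, nrow(atlas))
  if (!is.null(hemisphere)) {
    hemisphere <- match.arg(hemisphere, c("left", "right"))
    mask <- mask & atlas$hemisphere == hemisphere
  }
  if (!is.null(lobe_group)) {
    lobe_group <- match.arg(lobe_group, c("temporal", "extratemporal"))
    mask <- mask & atlas$lobe_group == lobe_group
  }
  if (!is.null(names)) {
    canon <- canonical_region_names(names, atlas$name)
    bad <- names[is.na(canon)]
    if (length(bad)) {
      stop("unknown region name(s): ", paste(unique(bad), collapse = ", "),
           call. = FALSE)
    }
    mask <- mask & atlas$name %in% canon
  }
  mask
}

# Map region names in common dialects (dots for underscores/hyphens, "&" for
# "and") onto the canonical packaged labels. Returns NA for unmatched names.
canonical_region_names <- function(x, canonical) {
  squash <- function(v) tolower(gsub("and", "", gsub("[^a-z0-9]", "", tolower(v))))
  idx <- match(squash(x), squash(canonical))
  canonical[idx]
}

# Indices (atlas row order) of the left and right superior temporal sulcus.
sts_indices <- function(atlas) {
  list(left  = which(atlas$name == "lh_S_temporal_sup"),
       right = which(atlas$name == "rh_S_temporal_sup"))
}
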