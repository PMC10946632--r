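#' Convert BraTS labels to nested evaluation region channels
#'
#' The three evaluation subregions are cumulative unions of the raw labels:
#' whole tumor WT = \{1, 2, 4\}, tumor core TC = \{1, 4\}, enhancing tumor
#' ET = \{4\}, so ET is nested in TC is nested in WT.
#'
#' @param labels a `label_volume` or a plain integer 3-D array of BraTS
#'   labels.
#' @return a `region_channels` object: list of binary arrays `wt`, `tc`,
#'   `et` sharing the label shape.
#' @export
encode_regions <- function(labels) {
  lab <- if (inherits(labels, "label_volume")) labels$labels else labels
  structure(list(
    wt = (lab == 1L | lab == 2L | lab == 4L) * 1L,
    tc = (lab == 1L | lab == 4L) * 1L,
    et = (lab == 4L) * 1L
  ), class = "region_channels")
}

#' Convert region channels back to a BraTS label map
#'
#' Overlaps are resolved with precedence ET > TC > WT: a voxel inside ET
#' becomes 4, otherwise inside TC becomes 1, otherwise inside WT becomes 2.
#'
#' @param regions a `region_channels` object.
#' @return an integer 3-D array of labels in \{0, 1, 2, 4\}.
#' @export
decode_regions <- function(regions) {
  lab <- array(0L, dim = dim(regions$wt))
  lab[regions$wt == 1L] <- 2L
  lab[regions$tc == 1L] <- 1L
  lab[regions$et == 1L] <- 4L
  lab
}

region_names <- function() c("wt", "tc", "et")
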