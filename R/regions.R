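#' The 15 regions of the vole social brain
#'
#' Default node set for connectome construction: the social decision-making
#' network (social behavior network plus mesolimbic reward system) extended
#' with the anterior cingulate cortex (ACC) and the paraventricular nucleus
#' of the hypothalamus (PVN).
#'
#' @return Character vector of 15 region abbreviations, in the package's
#'   canonical order.
#' @export
#' @examples
#' vsb_regions()
vsb_regions <- function() {
  c("ACC", "AH", "BLA", "BNST", "CA2", "CP", "LS", "MeA", "mPOA",
    "NAcc", "PAG", "PVN", "VMH", "VP", "VTA")
}

#' Anatomical grouping of the vole-social-brain regions
#'
#' Coarse anatomical groups used to organise radial innervation summaries.
#'
#' @return A data.frame with columns `region` and `group`.
#' @export
vsb_region_groups <- function() {
  data.frame(
    region = vsb_regions(),
    group = c(
      "cortex",        # ACC
      "hypothalamus",  # AH
      "amygdala",      # BLA
      "amygdala",      # BNST (extended amygdala)
      "hippocampus",   # CA2
      "striatum",      # CP
      "septum",        # LS
      "amygdala",      # MeA
      "hypothalamus",  # mPOA
      "striatum",      # NAcc
      "midbrain",      # PAG
      "hypothalamus",  # PVN
      "hypothalamus",  # VMH
      "striatum",      # VP (pallidum, grouped with ventral striatum)
      "midbrain"       # VTA
    ),
    stringsAsFactors = FALSE
  )
}
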