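#' Default tree allometry coefficients
#'
#' Power-law allometries mapping stem diameter (DBH, cm) to tree height,
#' crown radius, crown depth, total branch surface area and total leaf area.
#' Standard tropical forms; coefficients are deliberately simple because the
#' epiphyte model only consumes voxel summaries of the stand, so relative
#' realism (size structure, canopy depth, surface per tree) is what matters.
#'
#' @return Named list of coefficients: `h_coef`, `h_pow` (height, m, from
#'   DBH cm), `cr_coef`, `cr_pow` (crown radius, m), `crown_depth_frac`
#'   (fraction of height), `ba_coef`, `ba_pow` (branch surface area, m2,
#'   from DBH/10), `la_coef`, `la_pow` (leaf area, m2, from DBH/10).
#' @export
default_allometry <- function() {
  list(
    h_coef = 3.3, h_pow = 0.6,
    cr_coef = 0.5, cr_pow = 0.55,
    crown_depth_frac = 0.35,
    ba_coef = 0.8, ba_pow = 2.0,
    la_coef = 9, la_pow = 2
  )
}

# Vectorized allometry: dbh (cm) -> structural columns.
# Height is capped at the canopy ceiling; crown is kept within
# [height - crown_depth, height].
tree_allometry <- function(dbh, allom = default_allometry(), canopy_height = 50) {
  height <- pmin(canopy_height, allom$h_coef * dbh^allom$h_pow)
  crown_depth <- allom$crown_depth_frac * height
  data.frame(
    height = height,
    crown_radius = allom$cr_coef * dbh^allom$cr_pow,
    crown_depth = crown_depth,
    branch_area = allom$ba_coef * (dbh / 10)^allom$ba_pow,
    leaf_area = allom$la_coef * (dbh / 10)^allom$la_pow
  )
}
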