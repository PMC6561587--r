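# Sodium-channel placement: uniform (U) and end-localized (NU) conductance
# fields with exactly conserved whole-cell conductance.
#
# With p the fraction of channels moved to the junctional region Gamma_j,
#   g on Gamma_r = (1 - p) gbar
#   g on Gamma_j = (1 - p) gbar + p (A_c / A_j) gbar
# so that the quadrature total sum_i g_i A_i equals A_c gbar for every p
# (the uniform total).  A_c and A_j are the quadrature areas of the cell
# membrane and of the junctional region of that cell.

#' Channel distribution specification
#'
#' @param p fraction of sodium channels moved to the cell ends, in [0, 1];
#'   p = 0 is the uniform distribution.
#' @param region `"horizontal_ends"` (connector faces parallel to x; the
#'   default used for 4 um cell distances) or `"vertical_ends"` (x-normal
#'   end faces; used for nanometre-cleft runs).
#' @param gbar default conductance density (mS/cm^2); `NULL` takes the
#'   active ionic model's sodium conductance.
#' @param area_override optional replacement membrane area A_c* (cm^2) used
#'   in place of the actual A_c (cell-length experiments keep the channel
#'   count per cell constant this way); `NULL` for none.
#' @return An object of class `emi_channel_dist`.
#' @export
channel_distribution <- function(p = 0,
                                 region = c("horizontal_ends",
                                            "vertical_ends"),
                                 gbar = NULL, area_override = NULL) {
  region <- match.arg(region)
  if (p < 0 || p > 1) stop("p must lie in [0, 1]")
  if (!is.null(gbar) && gbar <= 0) stop("gbar must be positive")
  if (!is.null(area_override) && area_override <= 0) {
    stop("area_override must be positive")
  }
  structure(list(p = p, region = region, gbar = gbar,
                 area_override = area_override),
            class = "emi_channel_dist")
}

#' Assign the per-node sodium conductance field
#'
#' @param mesh an `emi_mesh`.
#' @param dist an [channel_distribution()] object.
#' @param model ionic model supplying the default gbar_Na when
#'   `dist$gbar` is `NULL`.
#' @return Numeric vector of g_Na (mS/cm^2) over `mesh$memb$node`, with the
#'   per-cell quadrature areas attached as attributes `A_c` and `A_j`.
#' @export
assign_gna <- function(mesh, dist, model = NULL) {
  gbar <- dist$gbar
  if (is.null(gbar)) {
    if (is.null(model)) stop("either dist$gbar or a model must be given")
    gbar <- model$gbar_na
  }
  quad <- membrane_areas(mesh)
  cellv <- mesh$memb$cell
  A_c <- quad$A_c
  A_eff <- if (!is.null(dist$area_override)) {
    rep(dist$area_override, length(A_c))
  } else A_c
  g <- rep((1 - dist$p) * gbar, length(quad$A))
  if (dist$p > 0) {
    sel <- junction_region(mesh, dist$region)
    A_j <- as.numeric(rowsum(quad$A * sel, cellv))
    if (any(A_j <= 0)) stop("junctional region with zero area (A_j = 0)")
    g[sel] <- g[sel] + dist$p * (A_eff[cellv[sel]] / A_j[cellv[sel]]) * gbar
  } else if (!is.null(dist$area_override)) {
    # uniform case with area override: scale so the channel count matches
    g <- g * (A_eff[cellv] / A_c[cellv])
  }
  attr(g, "A_c") <- A_c
  attr(g, "A_j") <- if (dist$p > 0) {
    as.numeric(rowsum(quad$A * junction_region(mesh, dist$region), cellv))
  } else NULL
  attr(g, "gbar") <- gbar
  g
}

#' Rescale a distribution for a different cell length
#'
#' Keeps the number of sodium channels per cell constant when the cell
#' membrane area changes: the conductance density is computed with the
#' default-cell area A_c* in place of the actual area (non-uniform case), or
#' scaled by A_c*/A_c uniformly (uniform case).
#'
#' @param dist an `emi_channel_dist`.
#' @param A_c_default reference membrane area A_c* (cm^2).
#' @return The distribution with `area_override` set.
#' @export
rescale_for_cell_length <- function(dist, A_c_default) {
  if (A_c_default <= 0) stop("A_c_default must be positive")
  dist$area_override <- A_c_default
  dist
}
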