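# Internal helpers: conditions, tristate tokens, voxel geometry, 3D morphology.

#' @importFrom stats rnorm runif rbinom sd median pchisq dbinom
#' @importFrom utils read.csv write.csv head tail
NULL

lirads_abort <- function(message, class, call = sys.call(-1), ...) {
  stop(structure(
    class = c(class, "lirads_error", "error", "condition"),
    list(message = message, call = call, ...)
  ))
}

lirads_warn <- function(message, class = "lirads_warning") {
  warning(structure(
    class = c(class, "lirads_warning", "warning", "condition"),
    list(message = message, call = NULL)
  ))
}

PHASES <- c("native", "arterial", "portal_venous", "delayed")

TRISTATE <- c("yes", "no", "not_evaluable")

#' Validate a tristate token
#'
#' Manual LI-RADS feature entries (enhancing capsule, ancillary features) take
#' one of three values: `"yes"`, `"no"`, or `"not_evaluable"`.
#'
#' @param x character scalar to validate.
#' @param what field name used in the error message.
#' @return the validated token, invisibly usable.
#' @export
as_tristate <- function(x, what = "feature") {
  if (length(x) != 1L || is.na(x) || !x %in% TRISTATE) {
    lirads_abort(
      sprintf("%s must be one of %s (got %s)", what,
              paste(dQuote(TRISTATE, FALSE), collapse = ", "),
              deparse(as.character(x))),
      class = "lirads_format_error"
    )
  }
  x
}

tristate_yes <- function(x) identical(x, "yes")

# Voxel index (1-based) <-> physical mm. Physical coordinate of voxel i is
# (i - 1) * spacing: the first voxel centre sits at the origin.
voxel_to_mm <- function(idx, spacing) (idx - 1) * rep(spacing, length.out = length(idx))
mm_to_voxel <- function(mm, spacing) mm / rep(spacing, length.out = length(mm)) + 1

# Squared physical distance of every voxel in `dim`-shaped grid from point
# `center_mm`; returns a 3D array. Used for spheres/ellipsoids/ROIs.
dist2_grid <- function(dim, spacing, center_mm) {
  dx <- ((seq_len(dim[1]) - 1) * spacing[1] - center_mm[1])^2
  dy <- ((seq_len(dim[2]) - 1) * spacing[2] - center_mm[2])^2
  dz <- ((seq_len(dim[3]) - 1) * spacing[3] - center_mm[3])^2
  outer(outer(dx, dy, `+`), dz, `+`)
}

# Axis-aligned ellipsoid mask: (x/a)^2 + (y/b)^2 + (z/c)^2 <= 1.
ellipsoid_mask <- function(dim, spacing, center_mm, radii_mm) {
  nx <- ((seq_len(dim[1]) - 1) * spacing[1] - center_mm[1])^2 / radii_mm[1]^2
  ny <- ((seq_len(dim[2]) - 1) * spacing[2] - center_mm[2])^2 / radii_mm[2]^2
  nz <- ((seq_len(dim[3]) - 1) * spacing[3] - center_mm[3])^2 / radii_mm[3]^2
  outer(outer(nx, ny, `+`), nz, `+`) <= 1
}

# --- 3D binary morphology on logical arrays ---------------------------------
# Shift-based implementations; no package on the stack offers 3D morphology
# with the connectivities needed here.

shift_mask <- function(m, d) {
  # shift logical 3D array by integer offset d (length 3), zero-padded
  out <- array(FALSE, dim(m))
  src <- dst <- vector("list", 3)
  for (a in 1:3) {
    n <- dim(m)[a]
    if (d[a] >= 0) { dst[[a]] <- seq_len(n - d[a]) + d[a]; src[[a]] <- seq_len(n - d[a]) }
    else           { dst[[a]] <- seq_len(n + d[a]);        src[[a]] <- seq_len(n + d[a]) - d[a] }
    if (length(dst[[a]]) == 0L) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
  out
}

offsets_cross6 <- function() {
  rbind(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))
}

offsets_full26 <- function() {
  g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  g[rowSums(abs(g)) > 0, , drop = FALSE]
}

dilate3d <- function(m, offsets = offsets_cross6()) {
  out <- m
  for (i in seq_len(nrow(offsets))) out <- out | shift_mask(m, offsets[i, ])
  out
}

erode3d <- function(m, offsets = offsets_cross6()) {
  out <- m
  for (i in seq_len(nrow(offsets))) {
    # voxel survives only if neighbour (treating outside as background) is set
    out <- out & shift_mask(m, offsets[i, ])
  }
  out
}

close3d <- function(m, offsets = offsets_cross6()) erode3d(dilate3d(m, offsets), offsets)

# Frontier flood fill over a logical 3D array from linear seed indices.
# Works on a zero-padded copy so neighbour offsets never wrap across faces.
flood3d <- function(mask, seed_idx, connectivity = 26) {
  d <- dim(mask)
  pd <- d + 2L
  pmask <- array(FALSE, pd)
  pmask[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask
  ai <- arrayInd(seed_idx, d) + 1L
  pseed <- (ai[, 3] - 1L) * pd[1] * pd[2] + (ai[, 2] - 1L) * pd[1] + ai[, 1]
  offs <- if (connectivity == 26) offsets_full26() else offsets_cross6()
  loff <- offs[, 1] + offs[, 2] * pd[1] + offs[, 3] * pd[1] * pd[2]
  visited <- logical(prod(pd))
  frontier <- pseed[pmask[pseed]]
  visited[frontier] <- TRUE
  while (length(frontier)) {
    cand <- unique(as.vector(outer(frontier, loff, `+`)))
    cand <- cand[pmask[cand] & !visited[cand]]
    visited[cand] <- TRUE
    frontier <- cand
  }
  vis <- array(visited, pd)
  vis[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
}

# Fill internal cavities: background not reachable from the volume border
# (6-connectivity) belongs to the mask.
fill_holes3d <- function(m) {
  bg <- !m
  d <- dim(m)
  border <- array(FALSE, d)
  border[c(1, d[1]), , ] <- TRUE
  border[, c(1, d[2]), ] <- TRUE
  border[, , c(1, d[3])] <- TRUE
  seeds <- which(border & bg)
  if (!length(seeds)) return(m)
  reach <- flood3d(bg, seeds, connectivity = 6)
  m | (bg & !reach)
}

# Largest connected component, 26-connectivity.
largest_component3d <- function(m) {
  remaining <- m
  best <- NULL; best_n <- 0L
  while (any(remaining)) {
    comp <- flood3d(remaining, which(remaining)[1], connectivity = 26)
    n <- sum(comp)
    if (n > best_n) { best <- comp; best_n <- n }
    remaining <- remaining & !comp
  }
  if (is.null(best)) m else best
}

round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}
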