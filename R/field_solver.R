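#' @title Quasi-static volume-conductor solver
#' @description Solves div(sigma grad Phi) = 0 on a voxelized layered slab by
#'   a cell-centred finite-volume discretisation with harmonic-mean face
#'   conductances. Current is injected as a uniform Neumann flux over the
#'   active disc footprints on the skin surface; the bottom face is the
#'   grounded return (Dirichlet Phi = 0) by default. The field is the
#'   negative gradient of the potential; Emax, Eavg and Eint summarise its
#'   magnitude over the innervated region.
#' @name field_solver
NULL

#' Build the voxel grid for a subject model and electrode configuration
#'
#' Vertical cell edges are aligned to the four layer interfaces so every
#' cell lies in exactly one tissue layer; each layer spans at least 2 cells.
#' Per-cell conductivity is the real effective Cole-Cole conductivity of the
#' owning layer at the model's effective frequency.
#'
#' @param model a `fingertip_model`
#' @param config an `electrode_config`
#' @param resolution list with `dx_mm` (lateral cell size) and `layer_cells`
#'   (vertical cell count per layer); defaults from the run configuration
#' @return a `voxel_grid`: cell-centre coordinates `xc`, `yc`, `zc` (mm, z
#'   increasing with depth, surface at z = 0), spacings, per-z `layer_index`,
#'   3-D `sigma` array (S/m), and the electrode `layout`
#' @export
build_grid <- function(model, config,
                       resolution = default_run_config()$solver) {
  stopifnot(inherits(model, "fingertip_model"),
            inherits(config, "electrode_config"))
  layout <- electrode_centers(config)
  ext <- model$lateral_extent_mm
  span_x <- 2 * (config$diameter_mm + config$spacing_mm) + config$diameter_mm
  span_y <- (config$diameter_mm + config$spacing_mm) + config$diameter_mm
  if (span_x + 6 > ext[1] || span_y + 6 > ext[2])
    stop("array bounding rectangle plus 3 mm margin exceeds lateral extent")
  dx <- resolution$dx_mm
  nx <- max(4L, as.integer(round(ext[1] / dx)))
  ny <- max(4L, as.integer(round(ext[2] / dx)))
  xc <- (seq_len(nx) - (nx + 1) / 2) * dx
  yc <- (seq_len(ny) - (ny + 1) / 2) * dx

  ncell <- as.integer(resolution$layer_cells)
  if (length(ncell) != 4 || any(ncell < 2))
    stop("resolution must give at least 2 vertical cells in every layer")
  th <- vapply(model$layers, function(L) L$thickness_mm, numeric(1))
  dz <- numeric(0); layer_index <- integer(0)
  for (i in seq_along(th)) {
    dz <- c(dz, rep(th[i] / ncell[i], ncell[i]))
    layer_index <- c(layer_index, rep(i, ncell[i]))
  }
  zedge <- cumsum(c(0, dz))
  zc <- (zedge[-1] + zedge[-length(zedge)]) / 2
  nz <- length(zc)

  sig_layer <- vapply(model$layers, function(L)
    effective_conductivity(L$cole_cole, model$effective_frequency_hz),
    numeric(1))
  if (any(sig_layer <= 0)) stop("non-positive layer conductivity")
  sigma <- array(rep(sig_layer[layer_index], each = nx * ny),
                 dim = c(nx, ny, nz))

  structure(
    list(xc = xc, yc = yc, zc = zc, dx = dx, dy = dx, dz = dz,
         layer_index = layer_index, sigma = sigma, layout = layout,
         config = config, subject = model$subject,
         frequency_hz = model$effective_frequency_hz),
    class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid: %d x %d x %d cells, dx %.2f mm, %s>\n",
              length(x$xc), length(x$yc), length(x$zc), x$dx,
              config_label(x$config)))
  invisible(x)
}

# Map from (i,j,k) to linear index, column-major in (x, y, z)
.vg_id <- function(i, j, k, nx, ny) i + (j - 1L) * nx + (k - 1L) * nx * ny

# Top-surface cell weights for a source specification.
# active = integer electrode indices (1..6) -> binary disc masks;
# active = "full_face" -> every surface cell (plate-electrode harness).
.surface_weights <- function(grid, active) {
  nx <- length(grid$xc); ny <- length(grid$yc)
  w <- matrix(0, nx, ny)
  if (identical(active, "full_face")) {
    w[] <- 1
  } else {
    active <- as.integer(active)
    stopifnot(length(active) >= 1, all(active >= 1), all(active <= 6))
    r <- grid$config$diameter_mm / 2
    cx <- outer(grid$xc, rep(1, ny))
    cy <- outer(rep(1, nx), grid$yc)
    for (e in active) {
      ctr <- grid$layout$centers[e, ]
      w[(cx - ctr[1])^2 + (cy - ctr[2])^2 <= r^2] <- 1
    }
    if (!any(w > 0))
      stop("no grid cell falls inside an active disc; refine the grid")
  }
  w / sum(w)
}

#' Solve the quasi-static potential
#'
#' @param grid a `voxel_grid`
#' @param active integer electrode indices (1..6) driven as sources, or
#'   `"full_face"` for a uniform plate over the whole surface (test harness)
#' @param current_mA total injected current in mA (0 to 10, the device
#'   range); split uniformly over the active disc footprint cells
#' @param tol residual tolerance used for the conservation/residual checks
#' @param return_spec `"bottom_face"` (grounded distal face, default) or
#'   `list(electrode = idx)` to sink the current through one array disc with
#'   the reference pinned there
#' @return a `potential_field`: `phi` (nx x ny x nz array, V),
#'   `injected_current_mA`, `residual` (relative), plus the grid
#' @export
solve_potential <- function(grid, active, current_mA,
                            tol = default_run_config()$solver$tol,
                            return_spec = "bottom_face") {
  stopifnot(inherits(grid, "voxel_grid"))
  if (current_mA < 0 || current_mA > 10)
    stop("current must be within the 0-10 mA device range")
  nx <- length(grid$xc); ny <- length(grid$yc); nz <- length(grid$zc)
  N <- nx * ny * nz
  dx <- grid$dx * 1e-3; dy <- grid$dy * 1e-3; dz <- grid$dz * 1e-3
  sig <- grid$sigma

  ID <- array(seq_len(N), dim = c(nx, ny, nz))
  dz3 <- array(rep(dz, each = nx * ny), dim = c(nx, ny, nz))

  # face conductances (harmonic mean), fully vectorised per axis
  ia <- as.vector(ID[-nx, , , drop = FALSE])
  ib <- as.vector(ID[-1, , , drop = FALSE])
  gx <- as.vector((dy * dz3[-nx, , , drop = FALSE]) /
                  (dx / (2 * sig[-nx, , , drop = FALSE]) +
                   dx / (2 * sig[-1, , , drop = FALSE])))
  ja <- as.vector(ID[, -ny, , drop = FALSE])
  jb <- as.vector(ID[, -1, , drop = FALSE])
  gy <- as.vector((dx * dz3[, -ny, , drop = FALSE]) /
                  (dy / (2 * sig[, -ny, , drop = FALSE]) +
                   dy / (2 * sig[, -1, , drop = FALSE])))
  ka <- as.vector(ID[, , -nz, drop = FALSE])
  kb <- as.vector(ID[, , -1, drop = FALSE])
  gz <- as.vector((dx * dy) /
                  (dz3[, , -nz, drop = FALSE] / (2 * sig[, , -nz, drop = FALSE]) +
                   dz3[, , -1, drop = FALSE] / (2 * sig[, , -1, drop = FALSE])))

  fa <- c(ia, ja, ka); fb <- c(ib, jb, kb); fg <- c(gx, gy, gz)

  # source: Neumann flux into top-layer cells
  I_A <- current_mA * 1e-3
  w <- .surface_weights(grid, active)
  b <- numeric(N)
  top_ids <- as.vector(ID[, , 1])
  b[top_ids] <- as.vector(w) * I_A

  extra_i <- integer(0); extra_g <- numeric(0)
  if (identical(return_spec, "bottom_face")) {
    # Dirichlet Phi = 0 on the bottom face via half-cell conductance to ground
    extra_i <- as.vector(ID[, , nz])
    extra_g <- as.vector(dx * dy * sig[, , nz] / (dz[nz] / 2))
  } else if (is.list(return_spec) && !is.null(return_spec$electrode)) {
    wr <- .surface_weights(grid, return_spec$electrode)
    b[top_ids] <- b[top_ids] - as.vector(wr) * I_A
    extra_i <- top_ids[which.max(as.vector(wr))]
    extra_g <- max(fg) * 1e8   # penalty reference pin
  } else stop("unknown return_spec")

  # duplicate (i, j) triplets are summed by sparseMatrix
  A <- Matrix::sparseMatrix(
    i = c(fa, fb, fa, fb, extra_i),
    j = c(fb, fa, fa, fb, extra_i),
    x = c(-fg, -fg, fg, fg, extra_g),
    dims = c(N, N))
  As <- Matrix::forceSymmetric(A)
  phi <- as.numeric(Matrix::solve(Matrix::Cholesky(As), b))
  resid <- if (sum(abs(b)) == 0) 0 else
    sqrt(sum((as.numeric(A %*% phi) - b)^2)) / sqrt(sum(b^2))
  if (resid > 10 * tol)
    stop(sprintf("solver residual %.3e exceeds tolerance", resid))

  structure(
    list(phi = array(phi, dim = c(nx, ny, nz)),
         injected_current_mA = current_mA,
         residual = resid, grid = grid, active = active,
         return_spec = return_spec),
    class = "potential_field")
}

#' @export
print.potential_field <- function(x, ...) {
  cat(sprintf("<potential_field: %.2f mA, residual %.2e, max |Phi| %.3g V>\n",
              x$injected_current_mA, x$residual, max(abs(x$phi))))
  invisible(x)
}

#' Net vertical current through a horizontal cut (diagnostic)
#'
#' Sums the discrete fluxes through the faces between vertical cell layers
#' `k` and `k + 1`. With the grounded bottom face this equals the injected
#' current for every cut (discrete conservation).
#'
#' @param p a `potential_field`
#' @param k cut index, 1 <= k < nz
#' @return current in mA (positive downward)
#' @export
plane_current_mA <- function(p, k) {
  g <- p$grid
  nx <- length(g$xc); ny <- length(g$yc); nz <- length(g$zc)
  stopifnot(k >= 1, k < nz)
  dzm <- g$dz * 1e-3
  Axy <- (g$dx * 1e-3) * (g$dy * 1e-3)
  G <- Axy / (dzm[k] / (2 * g$sigma[, , k]) +
              dzm[k + 1] / (2 * g$sigma[, , k + 1]))
  sum(G * (p$phi[, , k] - p$phi[, , k + 1])) * 1e3
}

#' Electric field from a solved potential
#'
#' E = -grad(Phi), evaluated by central differences at interior cell centres
#' (one-sided at boundaries) on the possibly non-uniform grid.
#'
#' @param p a `potential_field`
#' @return an `efield`: component arrays `ex`, `ey`, `ez` and magnitude
#'   `mag`, all in V/m
#' @export
electric_field <- function(p) {
  stopifnot(inherits(p, "potential_field"))
  g <- p$grid
  phi <- p$phi
  xm <- g$xc * 1e-3; ym <- g$yc * 1e-3; zm <- g$zc * 1e-3
  d_axis <- function(arr, coords, axis) {
    n <- dim(arr)[axis]
    out <- array(0, dim(arr))
    pick <- function(idx, ax) {
      sel <- list(quote(expr =), quote(expr =), quote(expr =))
      sel[[ax]] <- idx
      do.call(`[`, c(list(arr), sel, list(drop = FALSE)))
    }
    asn <- function(idx, ax, val) {
      sel <- list(quote(expr =), quote(expr =), quote(expr =))
      sel[[ax]] <- idx
      do.call(`[<-`, c(list(out), sel, list(value = val)))
    }
    if (n == 1) return(out)
    # interior central differences
    if (n > 2) {
      num <- pick(3:n, axis) - pick(1:(n - 2), axis)
      den <- coords[3:n] - coords[1:(n - 2)]
      sh <- dim(num)
      den_arr <- array(rep(den, each = prod(sh[seq_len(axis - 1)])), sh)
      out <- asn(2:(n - 1), axis, num / den_arr)
    }
    out <- asn(1, axis, (pick(2, axis) - pick(1, axis)) /
                          (coords[2] - coords[1]))
    out <- asn(n, axis, (pick(n, axis) - pick(n - 1, axis)) /
                          (coords[n] - coords[n - 1]))
    out
  }
  ex <- -d_axis(phi, xm, 1)
  ey <- -d_axis(phi, ym, 2)
  ez <- -d_axis(phi, zm, 3)
  structure(list(ex = ex, ey = ey, ez = ez,
                 mag = sqrt(ex^2 + ey^2 + ez^2), grid = g),
            class = "efield")
}

#' Field-magnitude summary features
#'
#' Emax is the maximum field magnitude over the region, Eavg the
#' volume-weighted mean, and Eint the volume integral sum(|E| dV). The
#' default region is all tissue below the stratum corneum, where the
#' innervated layers lie and contact-edge cells cannot dominate Emax.
#'
#' @param field an `efield`
#' @param grid the `voxel_grid` the field was computed on
#' @param region `"below_stratum_corneum"` (default) or `"all"`
#' @return a `field_features` list: `e_max` (V/m), `e_avg` (V/m), `e_int`
#'   (V m^2), `region`
#' @export
extract_field_features <- function(field, grid = field$grid,
                                   region = "below_stratum_corneum") {
  stopifnot(inherits(field, "efield"))
  keep_z <- switch(region,
    below_stratum_corneum = which(grid$layer_index >= 2L),
    all = seq_along(grid$zc),
    stop("unknown region tag: ", region))
  if (!length(keep_z)) stop("empty feature region")
  mag <- field$mag[, , keep_z, drop = FALSE]
  dV <- (grid$dx * 1e-3) * (grid$dy * 1e-3) * (grid$dz[keep_z] * 1e-3)
  vol <- array(rep(dV, each = dim(mag)[1] * dim(mag)[2]), dim(mag))
  e_int <- sum(mag * vol)
  structure(list(e_max = max(mag), e_avg = e_int / sum(vol), e_int = e_int,
                 region = region),
            class = "field_features")
}

#' Interpolate the potential at arbitrary points
#'
#' Trilinear interpolation of Phi at the given (x, y, z) positions (mm).
#' Because Phi is referenced to the grounded face, this equals the line
#' integral of -E from the reference to each point.
#'
#' @param p a `potential_field`
#' @param points n x 3 matrix of coordinates in mm (columns x, y, z)
#' @return numeric vector of potentials in V
#' @export
sample_potential <- function(p, points) {
  stopifnot(inherits(p, "potential_field"))
  points <- matrix(points, ncol = 3)
  g <- p$grid
  interp1 <- function(coords, v) {
    n <- length(coords)
    if (v < coords[1] - 1e-9 || v > coords[n] + 1e-9)
      stop("point outside grid domain")
    v <- min(max(v, coords[1]), coords[n])
    i <- findInterval(v, coords, rightmost.closed = TRUE)
    i <- min(max(i, 1L), n - 1L)
    t <- (v - coords[i]) / (coords[i + 1] - coords[i])
    list(i = i, t = t)
  }
  out <- numeric(nrow(points))
  for (r in seq_len(nrow(points))) {
    ix <- interp1(g$xc, points[r, 1])
    iy <- interp1(g$yc, points[r, 2])
    iz <- interp1(g$zc, points[r, 3])
    acc <- 0
    for (a in 0:1) for (b in 0:1) for (cc in 0:1) {
      wgt <- (if (a) ix$t else 1 - ix$t) *
             (if (b) iy$t else 1 - iy$t) *
             (if (cc) iz$t else 1 - iz$t)
      acc <- acc + wgt * p$phi[ix$i + a, iy$i + b, iz$i + cc]
    }
    out[r] <- acc
  }
  out
}
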