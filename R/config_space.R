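#' @title Candidate electrode geometries
#' @description The candidate space is a 6 x 6 grid of disc-electrode
#'   diameters D (2.0--4.5 mm) and edge-to-edge spacings Q (0.5--3.0 mm) at
#'   0.5 mm increments, each realised as a 3 x 2 circular array on the
#'   fingertip. Q is a gap, not a centre-to-centre distance.
#' @name config_space
NULL

.D_GRID <- seq(2.0, 4.5, by = 0.5)
.Q_GRID <- seq(0.5, 3.0, by = 0.5)

#' Construct an electrode configuration
#'
#' @param diameter_mm disc diameter D in mm; one of 2.0, 2.5, ..., 4.5
#' @param spacing_mm edge-to-edge gap Q in mm; one of 0.5, 1.0, ..., 3.0
#' @return an object of class `electrode_config` with fields `diameter_mm`,
#'   `spacing_mm`, `rows` (3) and `cols` (2)
#' @export
electrode_config <- function(diameter_mm, spacing_mm) {
  stopifnot(length(diameter_mm) == 1, length(spacing_mm) == 1)
  if (!any(abs(.D_GRID - diameter_mm) < 1e-9))
    stop("diameter_mm must lie on the 2.0-4.5 mm grid at 0.5 mm steps")
  if (!any(abs(.Q_GRID - spacing_mm) < 1e-9))
    stop("spacing_mm must lie on the 0.5-3.0 mm grid at 0.5 mm steps")
  structure(
    list(diameter_mm = diameter_mm, spacing_mm = spacing_mm,
         rows = 3L, cols = 2L),
    class = "electrode_config"
  )
}

#' @export
print.electrode_config <- function(x, ...) {
  cat(sprintf("<electrode_config %s: D = %.1f mm, Q = %.1f mm, 3 x 2 array>\n",
              config_label(x), x$diameter_mm, x$spacing_mm))
  invisible(x)
}

#' Enumerate the 36 candidate configurations
#'
#' Deterministic D-major order (D ascending, then Q ascending), so downstream
#' ranking ties always break the same way.
#'
#' @return list of 36 `electrode_config` objects
#' @export
enumerate_configs <- function() {
  out <- vector("list", length(.D_GRID) * length(.Q_GRID))
  i <- 1L
  for (D in .D_GRID) for (Q in .Q_GRID) {
    out[[i]] <- electrode_config(D, Q)
    i <- i + 1L
  }
  out
}

#' Tabulate the candidate space
#'
#' @return data.frame with columns `label`, `diameter_mm`, `spacing_mm`,
#'   `area_cm2` in enumeration order
#' @export
config_table <- function() {
  cfgs <- enumerate_configs()
  data.frame(
    label = vapply(cfgs, config_label, character(1)),
    diameter_mm = vapply(cfgs, function(c) c$diameter_mm, numeric(1)),
    spacing_mm = vapply(cfgs, function(c) c$spacing_mm, numeric(1)),
    area_cm2 = vapply(cfgs, bounding_area_cm2, numeric(1)),
    stringsAsFactors = FALSE
  )
}

.fmt_dq <- function(x) {
  # "3.5" stays "3.5"; "1.0" becomes "1"
  s <- formatC(x, format = "f", digits = 1)
  sub("\\.0$", "", s)
}

#' Render the DxQy label of a configuration
#'
#' @param c an `electrode_config`
#' @return label such as "D3.5Q1" or "D2Q2.5" (trailing ".0" dropped)
#' @export
config_label <- function(c) {
  stopifnot(inherits(c, "electrode_config"))
  paste0("D", .fmt_dq(c$diameter_mm), "Q", .fmt_dq(c$spacing_mm))
}

#' Parse a DxQy label
#'
#' @param label label such as "D4Q3"
#' @return the corresponding `electrode_config`
#' @export
parse_config_label <- function(label) {
  stopifnot(is.character(label), length(label) == 1)
  m <- regmatches(label, regexec("^D([0-9.]+)Q([0-9.]+)$", label))[[1]]
  if (length(m) != 3) stop("malformed configuration label: ", label)
  electrode_config(as.numeric(m[2]), as.numeric(m[3]))
}

#' Bounding-rectangle coverage area of the array
#'
#' The 3 x 2 array of discs with pitch D + Q spans a rectangle of
#' (2D + Q) x (3D + 2Q) mm^2; this interpretation reproduces both printed
#' coverage-area endpoints (0.315 and 2.34 cm^2).
#'
#' @param c an `electrode_config`
#' @return area in cm^2
#' @export
bounding_area_cm2 <- function(c) {
  stopifnot(inherits(c, "electrode_config"))
  D <- c$diameter_mm; Q <- c$spacing_mm
  (2 * D + Q) * (3 * D + 2 * Q) / 100
}

#' Disc-centre layout of the 3 x 2 array
#'
#' Centres lie on a uniform grid with pitch D + Q in both axes, centred at
#' the origin of the skin-surface plane. The 3-electrode axis is x, the
#' 2-electrode axis is y.
#'
#' @param c an `electrode_config`
#' @return an `array_layout`: `centers` (6 x 2 matrix, mm), `pitch_row`,
#'   `pitch_col` (mm)
#' @export
electrode_centers <- function(c) {
  stopifnot(inherits(c, "electrode_config"))
  pitch <- c$diameter_mm + c$spacing_mm
  xs <- (seq_len(3) - 2) * pitch          # -pitch, 0, +pitch
  ys <- (seq_len(2) - 1.5) * pitch        # -pitch/2, +pitch/2
  # row-major electrode numbering: (x1,y1),(x1,y2),(x2,y1),...
  centers <- cbind(x = rep(xs, each = 2), y = rep(ys, times = 3))
  structure(
    list(centers = centers, pitch_row = pitch, pitch_col = pitch,
         config = c),
    class = "array_layout"
  )
}

#' @export
print.array_layout <- function(x, ...) {
  cat(sprintf("<array_layout: 6 centres, pitch %.1f mm>\n", x$pitch_row))
  invisible(x)
}
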