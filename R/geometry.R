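#' Parametric bone-implant channel layout
#'
#' Describes the 2D channel between the alveolar bone wall and a threaded
#' implant surface. Defaults are a 10.0 x 1.5 mm channel whose right wall
#' carries 10 implant threads, each 1.0 mm high and 0.5 mm deep.
#'
#' @param domain_height Channel height in mm.
#' @param domain_width Channel width in mm.
#' @param n_threads Number of implant threads on the right wall.
#' @param thread_height Height of one thread (mm).
#' @param thread_depth Depth of one thread, i.e. how far it protrudes into
#'   the channel (mm).
#' @param thread_profile Thread cross-section: `"triangular"` (isosceles,
#'   apex at the thread peak; the default), `"rectangular"`, or
#'   `"trapezoidal"` (peak edge half the thread height).
#' @return An object of class `implant_layout`.
#' @export
build_layout <- function(domain_height = 10.0, domain_width = 1.5,
                         n_threads = 10L, thread_height = 1.0,
                         thread_depth = 0.5,
                         thread_profile = c("triangular", "rectangular",
                                            "trapezoidal")) {
  thread_profile <- match.arg(thread_profile)
  n_threads <- as.integer(n_threads)
  lens <- c(domain_height = domain_height, domain_width = domain_width,
            thread_height = thread_height, thread_depth = thread_depth)
  if (any(!is.finite(lens)) || any(lens <= 0))
    stop("all lengths must be strictly positive")
  if (n_threads < 0) stop("n_threads must be >= 0")
  if (n_threads * thread_height > domain_height + 1e-9)
    stop(sprintf("threads do not fit: %d x %g mm > %g mm domain height",
                 n_threads, thread_height, domain_height))
  if (thread_depth >= domain_width)
    stop("thread_depth must be smaller than domain_width")
  structure(list(domain_height = domain_height, domain_width = domain_width,
                 n_threads = n_threads, thread_height = thread_height,
                 thread_depth = thread_depth, thread_profile = thread_profile),
            class = "implant_layout")
}

#' @export
print.implant_layout <- function(x, ...) {
  cat(sprintf("implant channel layout: %.1f x %.1f mm, %d %s thread(s) %.1f x %.1f mm\n",
              x$domain_height, x$domain_width, x$n_threads, x$thread_profile,
              x$thread_height, x$thread_depth))
  invisible(x)
}

# vertices (x, y) in mm of thread k (1-based), counter-clockwise
thread_polygon <- function(layout, k) {
  W <- layout$domain_width
  d <- layout$thread_depth
  h <- layout$thread_height
  y0 <- (k - 1) * h
  switch(layout$thread_profile,
    triangular = cbind(x = c(W, W, W - d),
                       y = c(y0, y0 + h, y0 + h / 2)),
    rectangular = cbind(x = c(W, W, W - d, W - d),
                        y = c(y0, y0 + h, y0 + h, y0)),
    trapezoidal = cbind(x = c(W, W, W - d, W - d),
                        y = c(y0, y0 + h, y0 + 3 * h / 4, y0 + h / 4)))
}

# exact area (mm^2) of one thread polygon (shoelace)
thread_area <- function(layout) {
  if (layout$n_threads == 0) return(0)
  p <- thread_polygon(layout, 1)
  n <- nrow(p)
  i2 <- c(2:n, 1)
  abs(sum(p[, 1] * p[i2, 2] - p[i2, 1] * p[, 2])) / 2
}

# is each point (x, y) inside the solid of any thread?
point_in_threads <- function(layout, x, y) {
  W <- layout$domain_width
  d <- layout$thread_depth
  h <- layout$thread_height
  if (layout$n_threads == 0) return(rep(FALSE, length(x)))
  k <- floor(y / h)                    # thread index (0-based) under each point
  inside <- k >= 0 & k < layout$n_threads
  yc <- (k + 0.5) * h                  # thread mid-height
  xedge <- switch(layout$thread_profile,
    triangular = W - d * (1 - 2 * abs(y - yc) / h),
    rectangular = rep(W - d, length(x)),
    trapezoidal = {
      # wall between base corner and peak corner; linear flank
      t <- pmin(1, pmax(0, (abs(y - yc) - h / 4) / (h / 4)))
      W - d * (1 - t)
    })
  inside & x > xedge
}

#' Rasterize a layout to a uniform structured quadrilateral mesh
#'
#' Cells whose centers lie inside a thread polygon are marked solid. The mesh
#' uses a cell-centered, 0-origin convention: x in \[0, width\] with the
#' implant on the right wall, y in \[0, height\] with bulk flow upward.
#'
#' @param layout An `implant_layout`.
#' @param cell_size Uniform cell edge length in mm. Must divide both domain
#'   dimensions (to rounding) and resolve the threads (`cell_size <
#'   thread_depth` when threads are present).
#' @return An object of class `implant_mesh` with fields `nx`, `ny`,
#'   `cell_size` (mm), cell-center coordinates `x`, `y` (mm), logical
#'   `is_fluid` matrix, and the `layout`. Zones are attached by
#'   [assign_zones()].
#' @export
rasterize <- function(layout, cell_size) {
  stopifnot(inherits(layout, "implant_layout"))
  if (!is.finite(cell_size) || cell_size <= 0) stop("cell_size must be positive")
  if (layout$n_threads > 0 && cell_size >= layout$thread_depth)
    stop("cell_size must be smaller than thread_depth to resolve the threads")
  nx <- round(layout$domain_width / cell_size)
  ny <- round(layout$domain_height / cell_size)
  if (abs(nx * cell_size - layout$domain_width) > 1e-6 * layout$domain_width ||
      abs(ny * cell_size - layout$domain_height) > 1e-6 * layout$domain_height)
    stop("cell_size must divide the domain width and height")
  x <- (seq_len(nx) - 0.5) * cell_size
  y <- (seq_len(ny) - 0.5) * cell_size
  xy <- expand.grid(x = x, y = y)
  solid <- matrix(point_in_threads(layout, xy$x, xy$y), nx, ny)
  structure(list(layout = layout, nx = nx, ny = ny, cell_size = cell_size,
                 x = x, y = y, is_fluid = !solid, zone = NULL, depth_m = 1.0),
            class = "implant_mesh")
}

#' Partition fluid cells into interfacial and outer zones
#'
#' The interfacial zone is the fluid region between the implant body and the
#' vertical line joining the thread peaks (cells whose center x-coordinate is
#' at or beyond `domain_width - thread_depth`); all other fluid cells are the
#' outer zone.
#'
#' @param mesh An `implant_mesh` from [rasterize()].
#' @param layout The layout the mesh was rasterized from (defaults to the one
#'   stored in the mesh).
#' @return The mesh with a `zone` character matrix (`"interfacial"`,
#'   `"outer"`, or `NA` for solid cells).
#' @export
assign_zones <- function(mesh, layout = mesh$layout) {
  stopifnot(inherits(mesh, "implant_mesh"))
  xline <- layout$domain_width - layout$thread_depth
  zone <- matrix(NA_character_, mesh$nx, mesh$ny)
  interfacial <- matrix(mesh$x >= xline - 1e-12, mesh$nx, mesh$ny)
  zone[mesh$is_fluid] <- ifelse(interfacial[mesh$is_fluid], "interfacial", "outer")
  mesh$zone <- zone
  mesh
}

#' Convenience: rasterize and assign zones in one call
#' @inheritParams rasterize
#' @return A zoned `implant_mesh`.
#' @export
build_mesh <- function(layout, cell_size) {
  assign_zones(rasterize(layout, cell_size))
}

#' @export
print.implant_mesh <- function(x, ...) {
  cat(sprintf("implant mesh: %d x %d cells of %.3g mm (%d fluid, %d solid)\n",
              x$nx, x$ny, x$cell_size, sum(x$is_fluid), sum(!x$is_fluid)))
  if (!is.null(x$zone))
    cat(sprintf("  interfacial: %d cells, outer: %d cells\n",
                sum(x$zone == "interfacial", na.rm = TRUE),
                sum(x$zone == "outer", na.rm = TRUE)))
  invisible(x)
}

#' Mesh areas (mm^2)
#'
#' @param mesh A (zoned) `implant_mesh`.
#' @return A list with `cell_area`, `fluid_area`, `solid_area`,
#'   `interfacial_area`, `outer_area` (all mm^2; zone areas `NA` until
#'   [assign_zones()] has run) and the exact polygon `solid_area_exact`.
#' @export
mesh_areas <- function(mesh) {
  a <- mesh$cell_size^2
  list(cell_area = a,
       fluid_area = sum(mesh$is_fluid) * a,
       solid_area = sum(!mesh$is_fluid) * a,
       interfacial_area = if (is.null(mesh$zone)) NA_real_ else
         sum(mesh$zone == "interfacial", na.rm = TRUE) * a,
       outer_area = if (is.null(mesh$zone)) NA_real_ else
         sum(mesh$zone == "outer", na.rm = TRUE) * a,
       solid_area_exact = mesh$layout$n_threads * thread_area(mesh$layout))
}

#' Boundary face tags
#'
#' Tags every boundary face of the fluid region: the left edge is the
#' alveolar bone, the bottom edge the blood inlet, the top edge the blood
#' outlet, and the right edge plus all faces touching thread solids the
#' implant surface.
#'
#' @param mesh An `implant_mesh`.
#' @return A data.frame with one row per boundary face: `i`, `j` (1-based
#'   cell indices of the adjacent fluid cell), `side` (`"W"`, `"E"`, `"S"`,
#'   `"N"`) and `tag`.
#' @export
boundary_faces <- function(mesh) {
  nx <- mesh$nx; ny <- mesh$ny
  fl <- mesh$is_fluid
  out <- list()
  add <- function(i, j, side, tag) {
    if (length(i)) out[[length(out) + 1]] <<- data.frame(i = i, j = j,
                                                         side = side, tag = tag)
  }
  # domain edges (only where the edge cell is fluid)
  jW <- which(fl[1, ]);  add(rep(1L, length(jW)), jW, "W", "ALVEOLAR_BONE")
  jE <- which(fl[nx, ]); add(rep(nx, length(jE)), jE, "E", "IMPLANT_SURFACE")
  iS <- which(fl[, 1]);  add(iS, rep(1L, length(iS)), "S", "BLOOD_INLET")
  iN <- which(fl[, ny]); add(iN, rep(ny, length(iN)), "N", "BLOOD_OUTLET")
  # faces between fluid and thread solid
  solid <- !fl
  for (side in c("W", "E", "S", "N")) {
    di <- switch(side, W = -1L, E = 1L, S = 0L, N = 0L)
    dj <- switch(side, W = 0L, E = 0L, S = -1L, N = 1L)
    ii <- rep(seq_len(nx), ny); jj <- rep(seq_len(ny), each = nx)
    ok <- fl & matrix(ii + di >= 1 & ii + di <= nx & jj + dj >= 1 & jj + dj <= ny,
                      nx, ny)
    nb <- matrix(FALSE, nx, ny)
    nb[ok] <- solid[cbind(ii[ok] + di, jj[ok] + dj)]
    w <- which(nb, arr.ind = TRUE)
    add(w[, 1], w[, 2], side, "IMPLANT_SURFACE")
  }
  do.call(rbind, out)
}

# interfacial-zone indicator as integer matrix (for the solver core)
interfacial_matrix <- function(mesh) {
  if (is.null(mesh$zone)) stop("mesh has no zones; call assign_zones() first")
  z <- matrix(0L, mesh$nx, mesh$ny)
  z[which(mesh$zone == "interfacial")] <- 1L
  z
}

solid_matrix <- function(mesh) {
  matrix(as.integer(!mesh$is_fluid), mesh$nx, mesh$ny)
}
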