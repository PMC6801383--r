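#' Rendering parameters for ball-and-stick snapshots
#'
#' Defaults follow the tuned depiction settings used throughout the
#' pipeline: 280-degree angle increments, 100 molecules per structure-file
#' chunk, 100% zoom, atom spheres at 23% of the van der Waals radius,
#' 14.5 mAngstrom bond cylinders, 0.4 Angstrom minimum bond distance and
#' 0.8 Angstrom bond tolerance, 256x256 RGB PNG output.
#'
#' @param angle_step numeric length-3 (or length-1, recycled) rotation
#'   increments in degrees for the x, y, z axes; each in (0, 360].
#' @param mps molecules per structure-file chunk (affects IO batching
#'   only, never image content).
#' @param zf zoom factor in percent: the molecule's bounding sphere at
#'   zero rotation spans `zf`% of the image edge.
#' @param at atom sphere radius as percent of the van der Waals radius.
#' @param br bond cylinder radius in milli-Angstrom.
#' @param mbd minimum bond distance in Angstrom.
#' @param bt bond tolerance in Angstrom.
#' @param pixel image edge length in pixels.
#' @param background background color, RGB triple in `[0, 1]`.
#' @return an object of class `render_params`.
#' @export
render_params <- function(angle_step = c(280, 280, 280), mps = 100,
                          zf = 100, at = 23, br = 14.5, mbd = 0.4,
                          bt = 0.8, pixel = 256,
                          background = c(1, 1, 1)) {
  if (length(angle_step) == 1L) angle_step <- rep(angle_step, 3L)
  stopifnot(length(angle_step) == 3L)
  if (any(!is.finite(angle_step)) || any(angle_step <= 0) ||
      any(angle_step > 360))
    stop("angle_step components must be in (0, 360]")
  if (mps < 1 || zf <= 0 || at <= 0 || br <= 0 || mbd <= 0 || bt <= 0 ||
      pixel <= 0)
    stop("mps, zf, at, br, mbd, bt and pixel must all be positive")
  structure(list(angle_step = as.numeric(angle_step), mps = as.integer(mps),
                 zf = zf, at = at, br = br, mbd = mbd, bt = bt,
                 pixel = as.integer(pixel),
                 background = as.numeric(background)),
            class = "render_params")
}

#' Enumerate the rotation grid for a snapshot run
#'
#' Per axis the angle set is `{i * step : i >= 0, i * step < 360}`; the
#' result is the Cartesian product over the three axes in lexicographic
#' `(rx, ry, rz)` order, so the number of rotations is
#' `prod(ceiling(360 / step))` - e.g. 1 at step 360, 8 at 280, 27 at 176,
#' 216 at 60 and 1000 at 38.
#'
#' @param angle_step length-3 (or length-1) numeric vector of degree steps
#'   in (0, 360].
#' @return data.frame with columns `rx`, `ry`, `rz` in degrees.
#' @export
enumerate_rotations <- function(angle_step) {
  if (length(angle_step) == 1L) angle_step <- rep(angle_step, 3L)
  stopifnot(length(angle_step) == 3L)
  if (any(!is.finite(angle_step)) || any(angle_step <= 0) ||
      any(angle_step > 360))
    stop("angle_step components must be in (0, 360]")
  axis_angles <- lapply(angle_step, function(s) {
    k <- ceiling(360 / s)
    seq(0, by = s, length.out = k)
  })
  g <- expand.grid(rz = axis_angles[[3L]], ry = axis_angles[[2L]],
                   rx = axis_angles[[1L]])
  out <- g[, c("rx", "ry", "rz")]
  rownames(out) <- NULL
  out
}

#' Distance-based bond perception
#'
#' Atoms `i < j` are bonded iff
#' `mbd <= d(i, j) <= r_cov(i) + r_cov(j) + bt`, with covalent radii from
#' the package's documented table. Pairs closer than `mbd` are flagged as
#' steric clashes (warning) and not bonded.
#'
#' @param elements character vector of element symbols.
#' @param coords numeric n x 3 coordinate matrix (Angstrom).
#' @param mbd minimum bond distance in Angstrom.
#' @param bt bond tolerance in Angstrom.
#' @return integer matrix with columns `i`, `j` (i < j).
#' @export
perceive_bonds <- function(elements, coords, mbd = 0.4, bt = 0.8) {
  coords <- as.matrix(coords)
  n <- length(elements)
  if (nrow(coords) != n) stop("elements and coords disagree in length")
  r <- covalent_radius(elements)
  if (n < 2L) return(matrix(integer(0), ncol = 2L,
                            dimnames = list(NULL, c("i", "j"))))
  d <- as.matrix(stats::dist(coords))
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  dij <- d[pairs]
  rmax <- r[pairs[, 1L]] + r[pairs[, 2L]] + bt
  clash <- dij < mbd & dij <= rmax
  if (any(clash))
    warning(sum(clash), " atom pair(s) closer than the minimum bond ",
            "distance (steric clash); not bonded")
  keep <- dij >= mbd & dij <= rmax
  out <- pairs[keep, , drop = FALSE]
  out <- out[order(out[, 1L], out[, 2L]), , drop = FALSE]
  storage.mode(out) <- "integer"
  dimnames(out) <- list(NULL, c("i", "j"))
  out
}

# Rotation matrix: x-axis rotation, then y, then z (right-handed axes),
# angles in degrees.
.rotation_matrix <- function(rx, ry, rz) {
  a <- rx * pi / 180; b <- ry * pi / 180; c0 <- rz * pi / 180
  Rx <- matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3L)
  Ry <- matrix(c(cos(b), 0, -sin(b), 0, 1, 0, sin(b), 0, cos(b)), 3L)
  Rz <- matrix(c(cos(c0), sin(c0), 0, -sin(c0), cos(c0), 0, 0, 0, 1), 3L)
  Rz %*% Ry %*% Rx
}

# Per-molecule scale (pixels per Angstrom), frozen at the zero-rotation
# view: the bounding sphere (atom centers + sphere radii) spans zf% of the
# image edge.
.molecule_scale <- function(mol, params) {
  ctr <- colMeans(mol$coords)
  rel <- sweep(mol$coords, 2L, ctr)
  sph <- params$at / 100 * vdw_radius(mol$elements)
  rad <- max(sqrt(rowSums(rel^2)) + sph)
  if (rad <= 0) rad <- 1
  (params$zf / 100) * params$pixel / (2 * rad)
}

.light_dir <- c(1, -1, 2) / sqrt(6)  # fixed directional light (unit)

#' Render one ball-and-stick snapshot
#'
#' Rotates the molecule about its centroid (x-axis rotation, then y, then
#' z; right-handed axes), projects orthographically, and rasterises atom
#' spheres (CPK colors, radius `at`% of the van der Waals radius, Lambert
#' shading from a fixed light) and bond cylinders (flat shaded, colored
#' half by each end atom) into an exactly `pixel x pixel` RGB array with a
#' z-buffer. The projection scale is frozen at the zero-rotation view so
#' all rotations of one molecule are mutually comparable. Rendering is a
#' pure function: identical inputs give identical arrays.
#'
#' @param mol a [mol3d()] with 3D coordinates; bonds are taken from the
#'   molecule (use [perceive_bonds()] upstream if absent).
#' @param rotation numeric length-3 `(rx, ry, rz)` in degrees.
#' @param params a [render_params()].
#' @return numeric array `pixel x pixel x 3` with values in `[0, 1]`.
#' @export
render_snapshot <- function(mol, rotation = c(0, 0, 0),
                            params = render_params()) {
  n <- length(mol$elements)
  if (n == 0L) stop("empty molecule")
  px <- params$pixel
  scale <- .molecule_scale(mol, params)
  ctr <- colMeans(mol$coords)
  R <- .rotation_matrix(rotation[1L] %% 360, rotation[2L] %% 360,
                        rotation[3L] %% 360)
  xyz <- sweep(mol$coords, 2L, ctr) %*% t(R)
  # image coordinates: column = x, row = y (top-down), depth = z (towards
  # the viewer; larger wins the z-buffer)
  cx <- xyz[, 1L] * scale + (px + 1) / 2
  cy <- -xyz[, 2L] * scale + (px + 1) / 2
  cz <- xyz[, 3L] * scale
  sph_px <- params$at / 100 * vdw_radius(mol$elements) * scale
  col_atom <- cpk_color(mol$elements)

  img <- array(rep(params$background, each = px * px), c(px, px, 3L))
  zbuf <- matrix(-Inf, px, px)

  put <- function(rows, cols, depth, rgb) {
    idx <- cbind(rows, cols)
    upd <- depth > zbuf[idx]
    if (!any(upd)) return(invisible())
    idx <- idx[upd, , drop = FALSE]
    zbuf[idx] <<- depth[upd]
    for (ch in 1:3) img[cbind(idx, ch)] <<- rgb[upd, ch]
  }

  draw_sphere <- function(a) {
    r <- max(sph_px[a], 0.75)
    lo_c <- max(1L, floor(cx[a] - r)); hi_c <- min(px, ceiling(cx[a] + r))
    lo_r <- max(1L, floor(cy[a] - r)); hi_r <- min(px, ceiling(cy[a] + r))
    if (lo_c > hi_c || lo_r > hi_r) return(invisible())
    cols <- seq.int(lo_c, hi_c); rows <- seq.int(lo_r, hi_r)
    dx <- matrix(cols - cx[a], length(rows), length(cols), byrow = TRUE)
    dy <- matrix(rows - cy[a], length(rows), length(cols))
    d2 <- dx * dx + dy * dy
    inside <- d2 <= r * r
    if (!any(inside)) return(invisible())
    h <- sqrt(pmax(r * r - d2[inside], 0))
    # unit surface normal at each covered pixel
    nx <- dx[inside] / r; ny <- -dy[inside] / r; nz <- h / r
    lam <- pmax(nx * .light_dir[1L] + ny * .light_dir[2L] +
                  nz * .light_dir[3L], 0)
    # high ambient: enough curvature cue to read as 3D while keeping the
    # CPK hue of each sphere nearly constant for downstream classification
    shade <- 0.65 + 0.35 * lam
    rgb <- outer(shade, col_atom[a, ])
    rc <- which(inside, arr.ind = TRUE)
    put(rows[rc[, 1L]], cols[rc[, 2L]], cz[a] + h, rgb)
  }

  draw_bond <- function(i, j) {
    r <- max(params$br / 1000 * scale, 0.6)
    x1 <- cx[i]; y1 <- cy[i]; x2 <- cx[j]; y2 <- cy[j]
    lo_c <- max(1L, floor(min(x1, x2) - r)); hi_c <- min(px, ceiling(max(x1, x2) + r))
    lo_r <- max(1L, floor(min(y1, y2) - r)); hi_r <- min(px, ceiling(max(y1, y2) + r))
    if (lo_c > hi_c || lo_r > hi_r) return(invisible())
    cols <- seq.int(lo_c, hi_c); rows <- seq.int(lo_r, hi_r)
    pxm <- matrix(cols, length(rows), length(cols), byrow = TRUE)
    pym <- matrix(rows, length(rows), length(cols))
    vx <- x2 - x1; vy <- y2 - y1
    len2 <- vx * vx + vy * vy
    t <- if (len2 < 1e-12) matrix(0, nrow(pxm), ncol(pxm)) else
      pmin(pmax(((pxm - x1) * vx + (pym - y1) * vy) / len2, 0), 1)
    ddx <- pxm - (x1 + t * vx); ddy <- pym - (y1 + t * vy)
    inside <- ddx * ddx + ddy * ddy <= r * r
    if (!any(inside)) return(invisible())
    tin <- t[inside]
    depth <- cz[i] + tin * (cz[j] - cz[i])
    half <- tin <= 0.5
    rgb <- matrix(0, sum(inside), 3L)
    rgb[half, ] <- matrix(col_atom[i, ], sum(half), 3L, byrow = TRUE)
    rgb[!half, ] <- matrix(col_atom[j, ], sum(!half), 3L, byrow = TRUE)
    rgb <- rgb * 0.85  # flat cylinder shade
    rc <- which(inside, arr.ind = TRUE)
    put(rows[rc[, 1L]], cols[rc[, 2L]], depth, rgb)
  }

  if (nrow(mol$bonds) > 0L)
    for (b in seq_len(nrow(mol$bonds))) draw_bond(mol$bonds[b, 1L],
                                                  mol$bonds[b, 2L])
  for (a in order(cz)) draw_sphere(a)
  img
}

#' Render a molecule set over the full rotation grid
#'
#' Renders every molecule at every rotation of
#' [enumerate_rotations()]`(params$angle_step)`, writing PNG files named
#' `<mol_id>_<rx>_<ry>_<rz>.png` and a manifest CSV. Molecules are
#' processed in chunks of `params$mps` structures (IO batching only).
#' Per-molecule render failures are logged in the `failures` attribute and
#' skipped; the pipeline continues.
#'
#' @param mols list of [mol3d()] objects with 3D coordinates.
#' @param labels character vector of binary labels, parallel to `mols`
#'   (optional; `NA` if missing).
#' @param params a [render_params()].
#' @param outdir output directory (created if needed).
#' @return the manifest data.frame (`mol_id`, `rx`, `ry`, `rz`, `path`,
#'   `label`), invisibly carrying a `failures` attribute; also written to
#'   `file.path(outdir, "manifest.csv")`.
#' @export
snap_dataset <- function(mols, labels = NULL, params = render_params(),
                         outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  rot <- enumerate_rotations(params$angle_step)
  if (is.null(labels)) labels <- rep(NA_character_, length(mols))
  stopifnot(length(labels) == length(mols))
  rows <- list()
  failures <- character(0)
  if (length(mols) > 0L) {
    chunks <- split(seq_along(mols), ceiling(seq_along(mols) / params$mps))
    for (chunk in chunks) {
      for (k in chunk) {
        mol <- mols[[k]]
        mrows <- tryCatch({
          out <- vector("list", nrow(rot))
          for (q in seq_len(nrow(rot))) {
            img <- render_snapshot(mol, as.numeric(rot[q, ]), params)
            fn <- sprintf("%s_%g_%g_%g.png", mol$mol_id,
                          rot$rx[q], rot$ry[q], rot$rz[q])
            png::writePNG(img, file.path(outdir, fn))
            out[[q]] <- data.frame(
              mol_id = mol$mol_id, rx = rot$rx[q], ry = rot$ry[q],
              rz = rot$rz[q], path = file.path(outdir, fn),
              label = labels[k], stringsAsFactors = FALSE)
          }
          out
        }, error = function(e) {
          failures <<- c(failures, paste0(mol$mol_id, ": ",
                                          conditionMessage(e)))
          NULL
        })
        if (!is.null(mrows)) rows <- c(rows, mrows)
      }
    }
  }
  manifest <- if (length(rows)) do.call(rbind, rows) else
    data.frame(mol_id = character(0), rx = numeric(0), ry = numeric(0),
               rz = numeric(0), path = character(0), label = character(0),
               stringsAsFactors = FALSE)
  utils::write.csv(manifest, file.path(outdir, "manifest.csv"),
                   row.names = FALSE)
  attr(manifest, "failures") <- failures
  invisible(manifest)
}
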