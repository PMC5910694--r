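# Triangulated surface meshes: construction from label volumes, signed
# volume, ray casting and STL/PLY I/O. Vertices are world-frame mm.

#' Construct a surface mesh
#'
#' @param vertices n x 3 matrix of vertex positions (mm, world frame)
#' @param faces m x 3 integer matrix of 1-based vertex indices; triangles
#'   are wound counter-clockwise seen from outside
#' @param label optional compartment label carried along
#' @return object of class `myo_mesh`
#' @export
surface_mesh <- function(vertices, faces, label = NA_integer_) {
  vertices <- matrix(as.numeric(vertices), ncol = 3)
  faces <- matrix(as.integer(faces), ncol = 3)
  if (nrow(faces) > 0 && (min(faces) < 1 || max(faces) > nrow(vertices))) {
    stop("face indices out of range")
  }
  structure(list(vertices = vertices, faces = faces, label = label),
            class = "myo_mesh")
}

#' @export
print.myo_mesh <- function(x, ...) {
  cat(sprintf("<myo_mesh> %d vertices, %d triangles, label %s\n",
              nrow(x$vertices), nrow(x$faces), format(x$label)))
  invisible(x)
}

# Net directed-edge balance per undirected edge: zero for a boundary-free
# (watertight) surface. Voxel-face meshes can be watertight yet
# non-manifold at diagonally touching voxels (an edge shared by 4 faces,
# 2 in each direction), which is fine for divergence-theorem volumes.
mesh_edge_imbalance <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  sgn <- ifelse(e[, 1] < e[, 2], 1L, -1L)
  tapply(sgn, key, sum)
}

#' Test whether a mesh is closed
#'
#' A mesh is closed (watertight) when every directed edge is matched by an
#' opposite directed edge, i.e. the surface has no boundary. For manifold
#' meshes this is the usual "every edge shared by exactly two triangles";
#' voxel-boundary meshes may additionally contain watertight non-manifold
#' edges (four incident faces) where voxels touch diagonally.
#'
#' @param mesh a `myo_mesh`
#' @return logical scalar
#' @export
mesh_is_closed <- function(mesh) {
  all(mesh_edge_imbalance(mesh) == 0L)
}

#' Enclosed volume of a closed mesh
#'
#' Divergence-theorem signed volume, \eqn{\sum \det(v_1, v_2, v_3)/6} over
#' triangles, reported as an absolute value and converted mm^3 to cm^3, so
#' the result does not depend on global orientation.
#'
#' @param mesh a closed `myo_mesh` with vertices in mm
#' @return volume in cm^3
#' @export
mesh_volume <- function(mesh) {
  imb <- mesh_edge_imbalance(mesh)
  if (any(imb != 0L)) {
    bad <- names(imb)[imb != 0L]
    stop("mesh is not closed; boundary edges (vertex pairs): ",
         paste(utils::head(bad, 10), collapse = ", "),
         if (length(bad) > 10) sprintf(" ... and %d more", length(bad) - 10) else "")
  }
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  det6 <- a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
    a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
    a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
  abs(sum(det6) / 6) / 1000
}

# signed version (mm^3), used to assert outward orientation in tests
mesh_signed_volume_mm3 <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
        a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
        a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
}

# Voxel-boundary surface extraction --------------------------------------
# Emits two triangles per exposed voxel face. The resulting mesh is exactly
# closed and outward-oriented, and its enclosed volume equals the
# voxel-count volume exactly.

#' Extract the boundary surface of a voxel mask
#'
#' @param mask 3D logical array (TRUE = inside)
#' @param affine 4x4 voxel-to-world affine (voxel-centre convention)
#' @param label label stored on the mesh
#' @return a closed, outward-oriented `myo_mesh` in world mm
#' @export
surface_from_mask <- function(mask, affine, label = NA_integer_) {
  if (!any(mask)) stop("mask is empty; no surface to extract")
  d <- dim(mask)
  # corner (i,j,k) of voxel v is at continuous voxel coord v - 1.5 + offset
  # (0-based voxel centres); enumerate exposed faces via shifts
  quads <- list()
  face_defs <- list(
    # dir, corner offsets (4 corners, CCW seen from outside along +dir)
    list(d = c(1, 0, 0), o = rbind(c(1, 0, 0), c(1, 1, 0), c(1, 1, 1), c(1, 0, 1))),
    list(d = c(-1, 0, 0), o = rbind(c(0, 0, 0), c(0, 0, 1), c(0, 1, 1), c(0, 1, 0))),
    list(d = c(0, 1, 0), o = rbind(c(0, 1, 0), c(0, 1, 1), c(1, 1, 1), c(1, 1, 0))),
    list(d = c(0, -1, 0), o = rbind(c(0, 0, 0), c(1, 0, 0), c(1, 0, 1), c(0, 0, 1))),
    list(d = c(0, 0, 1), o = rbind(c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))),
    list(d = c(0, 0, -1), o = rbind(c(0, 0, 0), c(0, 1, 0), c(1, 1, 0), c(1, 0, 0)))
  )
  corner_keys <- character(0)
  corner_list <- list()
  quad_idx <- list()
  key_env <- new.env(hash = TRUE, parent = emptyenv())
  n_corners <- 0L
  get_corner <- function(cijk) {
    key <- paste(cijk, collapse = ",")
    id <- key_env[[key]]
    if (is.null(id)) {
      n_corners <<- n_corners + 1L
      id <- n_corners
      key_env[[key]] <- id
      corner_list[[id]] <<- cijk
    }
    id
  }
  for (fd in face_defs) {
    # neighbour in direction +d sits at index i + d = shift3(mask, -d)[i]
    exposed <- mask & !shift3(mask, -fd$d[1], -fd$d[2], -fd$d[3], fill = FALSE)
    idx <- which(exposed, arr.ind = TRUE)
    if (nrow(idx) == 0) next
    for (r in seq_len(nrow(idx))) {
      vox <- idx[r, ]
      ids <- integer(4)
      for (cc in 1:4) {
        # integer corner grid coordinates (voxel 1-based -> corner 0-based*2)
        ids[cc] <- get_corner(vox - 1L + fd$o[cc, ])
      }
      quad_idx[[length(quad_idx) + 1L]] <- ids
    }
  }
  corners <- do.call(rbind, corner_list)
  # corner grid coordinate c corresponds to continuous voxel coord c - 0.5
  verts <- voxel_to_world(affine, corners - 0.5)
  quads <- do.call(rbind, quad_idx)
  faces <- rbind(
    quads[, c(1, 2, 3), drop = FALSE],
    quads[, c(1, 3, 4), drop = FALSE]
  )
  m <- surface_mesh(verts, faces, label = label)
  # affines with negative determinant flip orientation; normalise to outward
  if (mesh_signed_volume_mm3(m) < 0) {
    m$faces <- m$faces[, c(1, 3, 2)]
  }
  m
}

# Icosphere ---------------------------------------------------------------

#' Triangulated sphere by icosahedron subdivision
#'
#' @param radius sphere radius (mm)
#' @param subdivisions number of 4-to-1 triangle subdivisions (>= 0)
#' @param center sphere centre (mm)
#' @return a closed `myo_mesh`
#' @export
icosphere <- function(radius = 1, subdivisions = 3, center = c(0, 0, 0)) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  for (s in seq_len(subdivisions)) {
    mid_env <- new.env(hash = TRUE, parent = emptyenv())
    nv <- nrow(v)
    vlist <- lapply(seq_len(nv), function(i) v[i, ])
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      id <- mid_env[[key]]
      if (is.null(id)) {
        nv <<- nv + 1L
        id <- nv
        mid_env[[key]] <- id
        vlist[[id]] <<- unit(vlist[[a]] + vlist[[b]])
      }
      id
    }
    newf <- matrix(0L, nrow(f) * 4, 3)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; c_ <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c_); ca <- midpoint(c_, a)
      newf[(i - 1) * 4 + 1:4, ] <- rbind(
        c(a, ab, ca), c(b, bc, ab), c(c_, ca, bc), c(ab, bc, ca)
      )
    }
    v <- do.call(rbind, vlist)
    f <- newf
  }
  surface_mesh(sweep(v * radius, 2, center, "+"), f)
}

# Ray casting -------------------------------------------------------------

#' Nearest ray-mesh intersection
#'
#' Moller-Trumbore intersection of a single ray with every triangle;
#' returns the nearest strictly positive hit.
#'
#' @param origin ray origin (mm)
#' @param direction ray direction (need not be unit; distances are returned
#'   in units of `|direction|`)
#' @param mesh a `myo_mesh`
#' @param eps minimum admissible ray parameter
#' @return list with `hit` (logical), `t` (ray parameter), `point` (mm) and
#'   `face` (triangle index); `t` and `point` are `NA` on a miss
#' @export
ray_mesh_intersection <- function(origin, direction, mesh, eps = 1e-9) {
  v <- mesh$vertices
  f <- mesh$faces
  p0 <- v[f[, 1], , drop = FALSE]
  e1 <- v[f[, 2], , drop = FALSE] - p0
  e2 <- v[f[, 3], , drop = FALSE] - p0
  dmat <- matrix(direction, nrow(f), 3, byrow = TRUE)
  pvec <- cbind(
    dmat[, 2] * e2[, 3] - dmat[, 3] * e2[, 2],
    dmat[, 3] * e2[, 1] - dmat[, 1] * e2[, 3],
    dmat[, 1] * e2[, 2] - dmat[, 2] * e2[, 1]
  )
  det <- rowSums(e1 * pvec)
  tvec <- matrix(origin, nrow(f), 3, byrow = TRUE) - p0
  ok <- abs(det) > 1e-12
  u <- rowSums(tvec * pvec) / det
  qvec <- cbind(
    tvec[, 2] * e1[, 3] - tvec[, 3] * e1[, 2],
    tvec[, 3] * e1[, 1] - tvec[, 1] * e1[, 3],
    tvec[, 1] * e1[, 2] - tvec[, 2] * e1[, 1]
  )
  vv <- rowSums(dmat * qvec) / det
  tt <- rowSums(e2 * qvec) / det
  valid <- ok & u >= -1e-10 & vv >= -1e-10 & (u + vv) <= 1 + 1e-10 & tt > eps
  if (!any(valid)) {
    return(list(hit = FALSE, t = NA_real_, point = rep(NA_real_, 3),
                face = NA_integer_))
  }
  i <- which(valid)[which.min(tt[valid])]
  list(hit = TRUE, t = tt[i], point = origin + tt[i] * direction,
       face = i)
}

# Parity point-in-mesh test with a fixed non-axis-aligned direction (avoids
# grazing voxel-face edges of axis-aligned meshes).
point_in_mesh <- function(point, mesh) {
  dir <- unit(c(0.57715342, 0.33127442, 0.74646383))
  v <- mesh$vertices
  f <- mesh$faces
  p0 <- v[f[, 1], , drop = FALSE]
  e1 <- v[f[, 2], , drop = FALSE] - p0
  e2 <- v[f[, 3], , drop = FALSE] - p0
  dmat <- matrix(dir, nrow(f), 3, byrow = TRUE)
  pvec <- cbind(
    dmat[, 2] * e2[, 3] - dmat[, 3] * e2[, 2],
    dmat[, 3] * e2[, 1] - dmat[, 1] * e2[, 3],
    dmat[, 1] * e2[, 2] - dmat[, 2] * e2[, 1]
  )
  det <- rowSums(e1 * pvec)
  tvec <- matrix(point, nrow(f), 3, byrow = TRUE) - p0
  u <- rowSums(tvec * pvec) / det
  qvec <- cbind(
    tvec[, 2] * e1[, 3] - tvec[, 3] * e1[, 2],
    tvec[, 3] * e1[, 1] - tvec[, 1] * e1[, 3],
    tvec[, 1] * e1[, 2] - tvec[, 2] * e1[, 1]
  )
  vv <- rowSums(dmat * qvec) / det
  tt <- rowSums(e2 * qvec) / det
  hits <- sum(abs(det) > 1e-12 & u >= 0 & vv >= 0 & (u + vv) <= 1 & tt > 1e-9)
  (hits %% 2) == 1
}

# STL / PLY I/O ------------------------------------------------------------

#' Write a mesh as ASCII STL
#'
#' @param mesh a `myo_mesh`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_stl <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid myotract", con)
  for (i in seq_len(nrow(f))) {
    a <- v[f[i, 1], ]; b <- v[f[i, 2], ]; c_ <- v[f[i, 3], ]
    n <- cross3(b - a, c_ - a)
    nn <- vnorm(n)
    if (nn > 0) n <- n / nn
    writeLines(c(
      sprintf("  facet normal %.9g %.9g %.9g", n[1], n[2], n[3]),
      "    outer loop",
      sprintf("      vertex %.9g %.9g %.9g", a[1], a[2], a[3]),
      sprintf("      vertex %.9g %.9g %.9g", b[1], b[2], b[3]),
      sprintf("      vertex %.9g %.9g %.9g", c_[1], c_[2], c_[3]),
      "    endloop",
      "  endfacet"
    ), con)
  }
  writeLines("endsolid myotract", con)
  invisible(path)
}

#' Read an ASCII STL mesh
#'
#' Vertices repeated across facets are merged on exact coordinate equality.
#'
#' @param path STL file path
#' @return a `myo_mesh`
#' @export
read_stl <- function(path) {
  lines <- readLines(path)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  coords <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(p) {
    as.numeric(p[2:4])
  }))
  if (nrow(coords) %% 3 != 0) stop("malformed STL: vertex count not multiple of 3")
  key <- apply(coords, 1, function(r) paste(sprintf("%.9g", r), collapse = ","))
  uidx <- !duplicated(key)
  verts <- coords[uidx, , drop = FALSE]
  id <- match(key, key[uidx])
  faces <- matrix(id, ncol = 3, byrow = TRUE)
  surface_mesh(verts, faces)
}

#' Write a mesh as ASCII PLY
#'
#' @param mesh a `myo_mesh`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_ply <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "ply", "format ascii 1.0", "comment myotract",
    sprintf("element vertex %d", nrow(v)),
    "property double x", "property double y", "property double z",
    sprintf("element face %d", nrow(f)),
    "property list uchar int vertex_indices",
    "end_header"
  ), con)
  writeLines(sprintf("%.12g %.12g %.12g", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  invisible(path)
}

#' Read an ASCII PLY mesh
#'
#' @param path PLY file path
#' @return a `myo_mesh`
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  if (lines[1] != "ply") stop("not a PLY file: ", path)
  hdr_end <- which(lines == "end_header")[1]
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", lines, value = TRUE)[1]))
  nf <- as.integer(sub("element face ", "", grep("^element face", lines, value = TRUE)[1]))
  vlines <- lines[(hdr_end + 1):(hdr_end + nv)]
  flines <- lines[(hdr_end + nv + 1):(hdr_end + nv + nf)]
  verts <- do.call(rbind, lapply(strsplit(vlines, "\\s+"), function(p) as.numeric(p[1:3])))
  faces <- do.call(rbind, lapply(strsplit(flines, "\\s+"), function(p) as.integer(p[2:4]) + 1L))
  surface_mesh(verts, faces)
}
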