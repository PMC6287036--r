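#' Triangulated surface mesh
#'
#' Constructs a closed, oriented triangulated surface mesh in millimetre
#' coordinates. Meshes carry the heart (epicardial) or torso geometry used by
#' the forward model and the pose optimizer. Faces are stored 1-based; the
#' constructor checks index validity and, for closed surfaces, repairs the
#' face orientation so that all normals point outward (positive signed
#' enclosed volume), which the boundary-element solid-angle signs rely on.
#'
#' @param nodes numeric matrix, n x 3, node coordinates in mm.
#' @param faces integer matrix, m x 3, vertex indices (1-based).
#' @param name label used in provenance records.
#' @param closed if `TRUE` (default) the mesh must be a closed 2-manifold
#'   (every edge shared by exactly two faces); an open surface is an error.
#' @return an object of class `trimesh` with elements `nodes`, `faces`, `name`.
#' @examples
#' tet <- trimesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
#'                rbind(c(1, 3, 2), c(1, 2, 4), c(2, 3, 4), c(1, 4, 3)))
#' signed_volume(tet)
#' @export
trimesh <- function(nodes, faces, name = "mesh", closed = TRUE) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(nodes) != 3L) stop("nodes must be an n x 3 matrix")
  if (ncol(faces) != 3L) stop("faces must be an m x 3 matrix")
  if (anyNA(nodes) || anyNA(faces)) stop("mesh contains missing values")
  if (min(faces) < 1L || max(faces) > nrow(nodes))
    stop("face indices out of range")
  dimnames(nodes) <- NULL
  dimnames(faces) <- NULL
  m <- structure(list(nodes = nodes, faces = faces, name = name),
                 class = "trimesh")
  if (closed) {
    check_closed(m)
    m <- orient_outward(m)
  }
  m
}

#' @export
print.trimesh <- function(x, ...) {
  cat(sprintf("trimesh '%s': %d nodes, %d faces", x$name, nrow(x$nodes),
              nrow(x$faces)))
  vol <- tryCatch(signed_volume(x), error = function(e) NA_real_)
  if (!is.na(vol)) cat(sprintf(", enclosed volume %.1f mm^3", vol))
  cat("\n")
  invisible(x)
}

# every undirected edge must be shared by exactly two faces
check_closed <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  cnt <- table(key)
  if (any(cnt != 2L))
    stop("open surface: ", sum(cnt != 2L),
         " edge(s) not shared by exactly 2 faces")
  invisible(TRUE)
}

#' Signed enclosed volume of a closed mesh
#'
#' Sum of signed tetrahedron volumes `det(v1, v2, v3) / 6` over faces;
#' positive when faces are consistently oriented with outward normals.
#'
#' @param mesh a [trimesh].
#' @return signed volume in mm^3.
#' @export
signed_volume <- function(mesh) {
  v1 <- mesh$nodes[mesh$faces[, 1], , drop = FALSE]
  v2 <- mesh$nodes[mesh$faces[, 2], , drop = FALSE]
  v3 <- mesh$nodes[mesh$faces[, 3], , drop = FALSE]
  cr <- cbind(v2[, 2] * v3[, 3] - v2[, 3] * v3[, 2],
              v2[, 3] * v3[, 1] - v2[, 1] * v3[, 3],
              v2[, 1] * v3[, 2] - v2[, 2] * v3[, 1])
  sum(rowSums(v1 * cr)) / 6
}

# Make face windings globally consistent (BFS over shared edges), then flip
# everything if the signed volume is negative.
orient_outward <- function(mesh) {
  f <- mesh$faces
  nf <- nrow(f)
  edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  keys <- edge_key(e[, 1], e[, 2])
  face_of_edge <- split(rep(seq_len(nf), 3L), keys)
  adj <- vector("list", nf)
  for (fs in face_of_edge) {
    if (length(fs) == 2L) {
      adj[[fs[1]]] <- c(adj[[fs[1]]], fs[2])
      adj[[fs[2]]] <- c(adj[[fs[2]]], fs[1])
    }
  }
  directed <- function(face) {
    rbind(face[c(1, 2)], face[c(2, 3)], face[c(3, 1)])
  }
  seen <- rep(FALSE, nf)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue)) {
    cur <- queue[1L]
    queue <- queue[-1L]
    de_cur <- directed(f[cur, ])
    for (nb in adj[[cur]]) {
      if (seen[nb]) next
      de_nb <- directed(f[nb, ])
      # consistent orientation: the shared edge appears in opposite directions
      same_dir <- any(apply(de_cur, 1, function(a)
        any(de_nb[, 1] == a[1] & de_nb[, 2] == a[2])))
      if (same_dir) f[nb, ] <- f[nb, c(1, 3, 2)]
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
  }
  if (!all(seen)) stop("mesh has more than one connected component")
  mesh$faces <- f
  if (signed_volume(mesh) < 0) mesh$faces <- f[, c(1, 3, 2)]
  mesh
}

#' Read a surface mesh from file
#'
#' Supports OFF and ASCII legacy VTK polydata, the two plain-text formats the
#' package reads and writes. On read the face orientation is normalized to
#' outward normals; an open surface is an error unless `closed = FALSE`.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"off"` or `"vtk"`.
#' @param name mesh label; defaults to the file name.
#' @param closed require a closed 2-manifold surface (default `TRUE`).
#' @return a [trimesh].
#' @seealso [write_mesh()]
#' @export
read_mesh <- function(path, format = c("auto", "off", "vtk"), name = NULL,
                      closed = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, off = "off", vtk = "vtk",
                     stop("cannot infer mesh format from extension '", ext, "'"))
  }
  if (is.null(name)) name <- basename(path)
  parsed <- switch(format, off = read_off(path), vtk = read_vtk(path))
  trimesh(parsed$nodes, parsed$faces, name = name, closed = closed)
}

read_off <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines) || toupper(lines[1]) != "OFF")
    stop("not an OFF file: missing OFF header")
  counts <- scan(text = lines[2], quiet = TRUE)
  nv <- counts[1]
  nf <- counts[2]
  body <- scan(text = paste(lines[-(1:2)], collapse = "\n"), quiet = TRUE)
  nodes <- matrix(body[seq_len(3 * nv)], ncol = 3, byrow = TRUE)
  rest <- body[-seq_len(3 * nv)]
  faces <- matrix(NA_integer_, nf, 3)
  pos <- 1
  for (i in seq_len(nf)) {
    k <- rest[pos]
    if (k != 3) stop("OFF reader supports triangles only (face with ", k,
                     " vertices)")
    faces[i, ] <- rest[pos + 1:3] + 1L  # OFF is 0-based
    pos <- pos + k + 1
  }
  list(nodes = nodes, faces = faces)
}

read_vtk <- function(path) {
  lines <- readLines(path)
  up <- toupper(lines)
  if (!any(grepl("ASCII", up))) stop("VTK reader supports ASCII files only")
  ip <- grep("^POINTS", up)
  if (!length(ip)) stop("not a VTK polydata file: no POINTS section")
  nv <- as.integer(strsplit(trimws(lines[ip[1]]), "\\s+")[[1]][2])
  ifc <- grep("^POLYGONS", up)
  if (!length(ifc)) stop("not a VTK polydata file: no POLYGONS section")
  nf <- as.integer(strsplit(trimws(lines[ifc[1]]), "\\s+")[[1]][2])
  pts <- scan(text = paste(lines[(ip[1] + 1):(ifc[1] - 1)], collapse = "\n"),
              quiet = TRUE)
  nodes <- matrix(pts[seq_len(3 * nv)], ncol = 3, byrow = TRUE)
  body <- scan(text = paste(lines[(ifc[1] + 1):length(lines)], collapse = "\n"),
               quiet = TRUE, n = 4 * nf)
  conn <- matrix(body, ncol = 4, byrow = TRUE)
  if (any(conn[, 1] != 3)) stop("VTK reader supports triangles only")
  list(nodes = nodes, faces = conn[, 2:4] + 1L)  # VTK is 0-based
}

#' Write a surface mesh to file
#'
#' @param mesh a [trimesh].
#' @param path output file path.
#' @param format `"auto"` (by extension), `"off"` or `"vtk"`.
#' @return `path`, invisibly.
#' @seealso [read_mesh()]
#' @export
write_mesh <- function(mesh, path, format = c("auto", "off", "vtk")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, off = "off", vtk = "vtk",
                     stop("cannot infer mesh format from extension '", ext, "'"))
  }
  nv <- nrow(mesh$nodes)
  nf <- nrow(mesh$faces)
  fmt_nodes <- apply(mesh$nodes, 1, function(r)
    paste(formatC(r, format = "g", digits = 17), collapse = " "))
  f0 <- mesh$faces - 1L
  if (format == "off") {
    out <- c("OFF", paste(nv, nf, 0), fmt_nodes,
             paste(3, f0[, 1], f0[, 2], f0[, 3]))
  } else {
    out <- c("# vtk DataFile Version 3.0", mesh$name, "ASCII",
             "DATASET POLYDATA", paste("POINTS", nv, "double"), fmt_nodes,
             paste("POLYGONS", nf, 4 * nf),
             paste(3, f0[, 1], f0[, 2], f0[, 3]))
  }
  writeLines(out, path)
  invisible(path)
}

#' Node-wise RMSD between two corresponding meshes
#'
#' Square root of the mean squared per-node Euclidean displacement between two
#' meshes with identical node correspondence — the geometric accuracy metric
#' used to score corrected against true heart geometries.
#'
#' @param a,b [trimesh] objects with identical node counts and correspondence.
#' @return RMSD in mm (nonnegative scalar).
#' @export
mesh_rmsd <- function(a, b) {
  if (nrow(a$nodes) != nrow(b$nodes))
    stop("meshes have different node counts (", nrow(a$nodes), " vs ",
         nrow(b$nodes), ")")
  sqrt(mean(rowSums((a$nodes - b$nodes)^2)))
}

#' Do two closed surfaces intersect?
#'
#' `TRUE` if any node of `inner` lies outside (or on) `outer`, or if any
#' triangle of one surface crosses a triangle of the other. Point containment
#' uses parity ray casting with deterministic direction re-jitter on
#' degenerate hits; coincident surfaces are reported as intersecting.
#'
#' @param inner,outer closed [trimesh] objects.
#' @param on_tol distance (mm) below which a node counts as lying on `outer`.
#' @return logical scalar.
#' @export
surfaces_intersect <- function(inner, outer, on_tol = 1e-9) {
  status <- .pts_in_mesh(inner$nodes, outer$nodes, outer$faces, on_tol)
  if (any(status != 1L)) return(TRUE)  # outside or on the surface
  .any_tri_intersect(inner$nodes, inner$faces, outer$nodes, outer$faces)
}

#' Triangulated sphere and ellipsoid meshes
#'
#' Subdivided-icosahedron spheres and their affinely scaled ellipsoids.
#' Subdivision level `k` gives `20 * 4^k` faces (level 2: 162 nodes, 320
#' faces) — the problem sizes used throughout the synthetic experiments.
#'
#' @param level subdivision level (nonnegative integer).
#' @param radius sphere radius in mm.
#' @param semiaxes length-3 vector of ellipsoid semi-axes in mm.
#' @param center length-3 center in mm.
#' @param name mesh label.
#' @return a [trimesh].
#' @export
mesh_icosphere <- function(level = 2, radius = 1, center = c(0, 0, 0),
                           name = "icosphere") {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  t, 0), c(1,  t, 0), c(-1, -t, 0), c(1, -t, 0),
    c(0, -1,  t), c(0, 1,  t), c(0, -1, -t), c(0, 1, -t),
    c( t, 0, -1), c(t, 0,  1), c(-t, 0, -1), c(-t, 0,  1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (i in seq_len(level)) {
    mid <- new.env(parent = emptyenv())
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      got <- mid[[key]]
      if (!is.null(got)) return(got)
      m <- v[a, ] + v[b, ]
      v <<- rbind(v, m / sqrt(sum(m^2)))
      mid[[key]] <- nrow(v)
      nrow(v)
    }
    nf <- matrix(0L, 4 * nrow(f), 3)
    for (k in seq_len(nrow(f))) {
      a <- f[k, 1]; b <- f[k, 2]; cc <- f[k, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      nf[4 * k - 3, ] <- c(a, ab, ca)
      nf[4 * k - 2, ] <- c(b, bc, ab)
      nf[4 * k - 1, ] <- c(cc, ca, bc)
      nf[4 * k, ] <- c(ab, bc, ca)
    }
    f <- nf
  }
  trimesh(sweep(v * radius, 2, center, "+"), f, name = name)
}

#' @rdname mesh_icosphere
#' @export
mesh_ellipsoid <- function(level = 2, semiaxes = c(1, 1, 1),
                           center = c(0, 0, 0), name = "ellipsoid") {
  s <- mesh_icosphere(level, radius = 1, name = name)
  s$nodes <- sweep(sweep(s$nodes, 2, semiaxes, "*"), 2, center, "+")
  s
}

#' Latitude-longitude (UV) sphere mesh
#'
#' Closed triangulated sphere with `n_lat` interior latitude rings of
#' `n_lon` nodes plus two pole nodes (`n_lat * n_lon + 2` nodes,
#' `2 * n_lon * n_lat` faces). Unlike the icosphere, node counts can be
#' chosen freely, which sets the electrode count when all surface nodes are
#' electrodes.
#'
#' @param n_lat number of latitude rings (excluding poles).
#' @param n_lon nodes per ring.
#' @inheritParams mesh_icosphere
#' @return a [trimesh].
#' @export
mesh_uvsphere <- function(n_lat = 16, n_lon = 18, radius = 1,
                          center = c(0, 0, 0), name = "uvsphere") {
  th <- pi * seq_len(n_lat) / (n_lat + 1)  # colatitude of each ring
  ph <- 2 * pi * (seq_len(n_lon) - 1) / n_lon
  ring <- function(t) cbind(sin(t) * cos(ph), sin(t) * sin(ph),
                            rep(cos(t), n_lon))
  nodes <- rbind(c(0, 0, 1), do.call(rbind, lapply(th, ring)), c(0, 0, -1))
  idx <- function(i, j) as.integer(1 + (i - 1) * n_lon + (j - 1) %% n_lon + 1)
  faces <- matrix(0L, 0, 3)
  top <- t(vapply(seq_len(n_lon), function(j)
    c(1L, idx(1, j), idx(1, j + 1)), integer(3)))
  bot <- t(vapply(seq_len(n_lon), function(j)
    c(nrow(nodes), idx(n_lat, j + 1), idx(n_lat, j)), integer(3)))
  mid <- list()
  for (i in seq_len(n_lat - 1)) {
    for (j in seq_len(n_lon)) {
      mid[[length(mid) + 1]] <- rbind(
        c(idx(i, j), idx(i + 1, j), idx(i + 1, j + 1)),
        c(idx(i, j), idx(i + 1, j + 1), idx(i, j + 1)))
    }
  }
  faces <- rbind(top, do.call(rbind, mid), bot)
  trimesh(sweep(nodes * radius, 2, center, "+"), faces, name = name)
}
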