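#' Tube mesh: stacked contour rings with an apex cap
#'
#' The surface representation used by the initializer and the 3D snake: `M`
#' rings of `N` vertices each (ordered along the long axis from the ring next
#' to the apex to the basal ring), stitched into triangle bands, closed at the
#' apical end by a triangle fan to a single apex vertex, and open at the base.
#' Vertices are in world coordinates (mm).
#'
#' @param ring_pts `M x N x 3` array of ring vertex coordinates (mm); ring 1 is
#'   apical-most, ring `M` basal-most.
#' @param apex_pt Length-3 apex vertex (mm).
#' @return An object of class `tube_mesh` with fields `vertices` (`(MN+1) x 3`),
#'   `faces` (`F x 3`, 1-based, consistently wound), `ring_index` (`M x N`
#'   vertex ids), `apex` (vertex id), `n_rings`, `n_points`.
#' @examples
#' rp <- array(0, c(3, 8, 3))
#' th <- seq(0, 2 * pi, length.out = 9)[1:8]
#' for (r in 1:3) {
#'   rp[r, , 1] <- 10 * cos(th); rp[r, , 2] <- 10 * sin(th); rp[r, , 3] <- r
#' }
#' m <- make_tube_mesh(rp, apex_pt = c(0, 0, 0))
#' nrow(m$vertices)  # 3 * 8 + 1
#' @export
make_tube_mesh <- function(ring_pts, apex_pt) {
  stopifnot(is.array(ring_pts), length(dim(ring_pts)) == 3, dim(ring_pts)[3] == 3)
  M <- dim(ring_pts)[1]
  N <- dim(ring_pts)[2]
  if (M < 2) stop("need at least 2 rings to build a tube mesh", call. = FALSE)
  if (N < 3) stop("need at least 3 points per ring", call. = FALSE)
  verts <- matrix(0, M * N + 1, 3)
  ring_index <- matrix(seq_len(M * N), nrow = M, ncol = N, byrow = TRUE)
  for (r in seq_len(M)) verts[ring_index[r, ], ] <- ring_pts[r, , ]
  apex <- M * N + 1L
  verts[apex, ] <- as.numeric(apex_pt)

  ip1 <- c(2:N, 1L)  # next angular index, wrapping
  # bands between ring r (apical side) and r + 1
  quads <- vector("list", M - 1)
  for (r in seq_len(M - 1)) {
    a <- ring_index[r, ]
    b <- ring_index[r, ip1]
    cc <- ring_index[r + 1, ip1]
    d <- ring_index[r + 1, ]
    quads[[r]] <- rbind(cbind(a, b, cc), cbind(a, cc, d))
  }
  cap <- cbind(rep(apex, N), ring_index[1, ip1], ring_index[1, ])
  faces <- do.call(rbind, c(quads, list(cap)))
  dimnames(faces) <- NULL
  storage.mode(faces) <- "integer"
  structure(list(vertices = verts, faces = faces, ring_index = ring_index,
                 apex = apex, n_rings = M, n_points = N),
            class = "tube_mesh")
}

#' @exportS3Method base::print
print.tube_mesh <- function(x, ...) {
  cat(sprintf("<tube_mesh> %d rings x %d points + apex: %d vertices, %d faces\n",
              x$n_rings, x$n_points, nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Directed edge table of a mesh
#'
#' @param mesh A `tube_mesh` (or any list with a `faces` matrix).
#' @return Integer matrix of directed edges (one row per face edge).
#' @export
mesh_edges <- function(mesh) {
  f <- mesh$faces
  rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
}

#' Euler characteristic V - E + F
#'
#' Undirected edges are counted once. For a tube mesh open at the base this is
#' 1 (a topological disc).
#'
#' @param mesh A `tube_mesh`.
#' @return Integer.
#' @export
euler_characteristic <- function(mesh) {
  de <- mesh_edges(mesh)
  und <- paste(pmin(de[, 1], de[, 2]), pmax(de[, 1], de[, 2]))
  nrow(mesh$vertices) - length(unique(und)) + nrow(mesh$faces)
}

#' Check manifoldness and consistent winding
#'
#' Every interior (shared) edge must appear in exactly two faces with opposite
#' direction; boundary edges in exactly one face.
#'
#' @param mesh A `tube_mesh`.
#' @return List with `ok` (logical), `n_boundary_edges`, `n_interior_edges`.
#' @export
check_mesh_consistency <- function(mesh) {
  de <- mesh_edges(mesh)
  key_dir <- paste(de[, 1], de[, 2])
  key_und <- paste(pmin(de[, 1], de[, 2]), pmax(de[, 1], de[, 2]))
  if (anyDuplicated(key_dir) > 0) {
    return(list(ok = FALSE, n_boundary_edges = NA_integer_,
                n_interior_edges = NA_integer_))
  }
  cnt <- table(key_und)
  ok <- all(cnt <= 2)
  list(ok = ok,
       n_boundary_edges = sum(cnt == 1),
       n_interior_edges = sum(cnt == 2))
}

face_cross <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
        e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
        e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
}

#' Total surface area of a mesh (mm^2)
#' @param mesh A `tube_mesh`.
#' @export
mesh_surface_area <- function(mesh) {
  cr <- face_cross(mesh)
  sum(sqrt(rowSums(cr^2))) / 2
}

#' Area-weighted random point sample of a mesh surface
#'
#' Draws faces proportionally to area and points uniformly within each face
#' (uniform barycentric coordinates), giving a uniform surface sample for
#' surface-distance evaluation.
#'
#' @param mesh A `tube_mesh`.
#' @param n Number of points.
#' @param seed Optional integer seed for reproducible sampling.
#' @return `n x 3` matrix of surface points (mm).
#' @export
sample_surface <- function(mesh, n = 5000, seed = NULL) {
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  cr <- face_cross(mesh)
  area <- sqrt(rowSums(cr^2)) / 2
  fi <- sample.int(nrow(mesh$faces), n, replace = TRUE, prob = area)
  r1 <- sqrt(stats::runif(n))
  r2 <- stats::runif(n)
  w1 <- 1 - r1
  w2 <- r1 * (1 - r2)
  w3 <- r1 * r2
  v <- mesh$vertices
  f <- mesh$faces[fi, , drop = FALSE]
  w1 * v[f[, 1], , drop = FALSE] +
    w2 * v[f[, 2], , drop = FALSE] +
    w3 * v[f[, 3], , drop = FALSE]
}

#' Enclosed volume of a tube mesh (ml)
#'
#' The open base is closed by a triangle fan to the basal-ring centroid, then
#' the signed-tetrahedron (divergence theorem) sum gives the enclosed volume.
#' Reported in millilitres (mm^3 / 1000).
#'
#' @param mesh A `tube_mesh`.
#' @return Volume in ml.
#' @export
enclosed_volume_ml <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  base_ids <- mesh$ring_index[mesh$n_rings, ]
  centroid <- colMeans(v[base_ids, , drop = FALSE])
  ip1 <- c(2:length(base_ids), 1L)
  vc <- rbind(v, centroid)
  cid <- nrow(vc)
  # base cap wound opposite to the apex cap so the closed surface is consistent
  base_faces <- cbind(rep(cid, length(base_ids)), base_ids, base_ids[ip1])
  fall <- rbind(f, base_faces)
  a <- vc[fall[, 1], , drop = FALSE]
  b <- vc[fall[, 2], , drop = FALSE]
  cc <- vc[fall[, 3], , drop = FALSE]
  det6 <- a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
    a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
    a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])
  abs(sum(det6)) / 6 / 1000
}

# ---- ASCII PLY IO ----

#' Write a mesh as ASCII PLY
#'
#' @param mesh A `tube_mesh` (or list with `vertices` and `faces`).
#' @param path Output `.ply` path.
#' @return `path`, invisibly.
#' @export
write_ply <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  hdr <- c("ply", "format ascii 1.0",
           "comment echosnake tube mesh",
           sprintf("element vertex %d", nrow(v)),
           "property float x", "property float y", "property float z",
           sprintf("element face %d", nrow(f)),
           "property list uchar int vertex_indices",
           "end_header")
  vl <- sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3])
  fl <- sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L)
  writeLines(c(hdr, vl, fl), path)
  invisible(path)
}

#' Read an ASCII PLY mesh
#'
#' Returns vertices and faces only; ring structure is not stored in PLY, so the
#' result is a plain mesh list (class `ply_mesh`), sufficient for metric
#' evaluation.
#'
#' @param path `.ply` path.
#' @return List with `vertices` (`V x 3`) and `faces` (`F x 3`, 1-based).
#' @export
read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (lines[1] != "ply") stop("not a PLY file: ", path, call. = FALSE)
  end <- match("end_header", lines)
  hdr <- lines[seq_len(end)]
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", hdr, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face", hdr, value = TRUE)))
  vlines <- lines[(end + 1):(end + nv)]
  v <- matrix(as.numeric(unlist(strsplit(vlines, "\\s+"))), ncol = 3, byrow = TRUE)
  faces <- NULL
  if (nf > 0) {
    flines <- lines[(end + nv + 1):(end + nv + nf)]
    fm <- matrix(as.integer(unlist(strsplit(flines, "\\s+"))), ncol = 4, byrow = TRUE)
    if (any(fm[, 1] != 3)) stop("only triangle PLY faces are supported", call. = FALSE)
    faces <- fm[, 2:4, drop = FALSE] + 1L
  }
  structure(list(vertices = v, faces = faces), class = "ply_mesh")
}
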