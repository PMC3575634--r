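#' Read a surface mesh from STL or PLY
#'
#' Dispatches on file extension (`.stl`, `.ply`). STL may be ASCII or
#' binary (auto-detected); PLY must be ASCII. STL carries no shared
#' vertex indexing, so coincident vertices are merged to 1e-6 mm on read.
#' Neither format carries unit metadata: coordinates are assumed to be
#' millimetres (a note is logged when `options(femfit.verbose = TRUE)`).
#'
#' @param path mesh file path.
#' @return a `fem_mesh`.
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) stop_femfit("io", "mesh file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  femfit_log("reading %s; no unit metadata in %s, assuming mm", path, ext)
  switch(ext,
    stl = read_stl(path),
    ply = read_ply(path),
    stop_femfit("io", "unsupported mesh format '.%s' (use STL or PLY)", ext)
  )
}

read_stl <- function(path) {
  con <- file(path, "rb")
  head <- readBin(con, "raw", 80)
  close(con)
  is_ascii <- identical(rawToChar(head[1:5]), "solid") &&
    any(grepl("facet", readLines(path, n = 20, warn = FALSE), fixed = TRUE))
  tri <- if (is_ascii) read_stl_ascii(path) else read_stl_binary(path)
  stl_index(tri)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex", lines, value = TRUE)
  nums <- lapply(strsplit(trimws(vl), "\\s+"), function(x) as.numeric(x[2:4]))
  do.call(rbind, nums)
}

read_stl_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 80)
  nt <- readBin(con, "integer", 1, size = 4, endian = "little")
  raw <- readBin(con, "raw", nt * 50)
  # each record: 12 floats (48 bytes) + uint16 attribute
  m <- matrix(raw, nrow = 50)
  fl <- readBin(as.vector(m[1:48, ]), "numeric", nt * 12, size = 4,
                endian = "little")
  f <- matrix(fl, ncol = 12, byrow = TRUE)
  # drop the per-facet normal, keep the 9 vertex coordinates
  v <- f[, 4:12, drop = FALSE]
  t(matrix(t(v), nrow = 3))
}

# turn a 3m x 3 triangle-soup matrix into an indexed mesh
stl_index <- function(tri) {
  key <- paste(round(tri[, 1], 6), round(tri[, 2], 6), round(tri[, 3], 6))
  uk <- !duplicated(key)
  verts <- tri[uk, , drop = FALSE]
  idx <- match(key, key[uk])
  faces <- matrix(idx, ncol = 3, byrow = TRUE)
  new_mesh(verts, faces)
}

#' Write a mesh as STL
#'
#' @param mesh a `fem_mesh`.
#' @param path output path.
#' @param binary write binary STL (default) or ASCII.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path, binary = TRUE) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  e1 <- b - a
  e2 <- c_ - a
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(n^2))
  len[len < 1e-30] <- 1
  n <- n / len
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.raw(rep(0, 80)), con)
    writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
    rec <- t(cbind(n, a, b, c_))  # 12 floats per facet
    for (i in seq_len(nrow(f))) {
      writeBin(rec[, i], con, size = 4, endian = "little")
      writeBin(as.raw(c(0, 0)), con)
    }
  } else {
    fmt <- function(m) sprintf("%.9g %.9g %.9g", m[, 1], m[, 2], m[, 3])
    out <- c("solid femfit",
             as.vector(rbind(
               paste0("  facet normal ", fmt(n)),
               "    outer loop",
               paste0("      vertex ", fmt(a)),
               paste0("      vertex ", fmt(b)),
               paste0("      vertex ", fmt(c_)),
               "    endloop",
               "  endfacet")),
             "endsolid femfit")
    writeLines(out, path)
  }
  invisible(path)
}

#' Write a mesh as ASCII PLY
#' @inheritParams write_stl
#' @export
write_ply <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  header <- c("ply", "format ascii 1.0", "comment femfit",
              sprintf("element vertex %d", nrow(v)),
              "property double x", "property double y", "property double z",
              sprintf("element face %d", nrow(f)),
              "property list uchar int vertex_indices", "end_header")
  vl <- sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3])
  fl <- sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L)
  writeLines(c(header, vl, fl), path)
  invisible(path)
}

read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  end <- match("end_header", lines)
  if (is.na(end)) stop_femfit("io", "not an ASCII PLY file: %s", path)
  header <- lines[seq_len(end)]
  if (!any(grepl("^format ascii", header)))
    stop_femfit("io", "only ASCII PLY is supported: %s", path)
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex", header, value = TRUE)[1]))
  nf <- as.integer(sub("element face ", "",
                       grep("^element face", header, value = TRUE)[1]))
  vl <- lines[end + seq_len(nv)]
  fl <- lines[end + nv + seq_len(nf)]
  verts <- matrix(as.numeric(unlist(strsplit(trimws(vl), "\\s+"))),
                  ncol = length(strsplit(trimws(vl[1]), "\\s+")[[1]]),
                  byrow = TRUE)[, 1:3, drop = FALSE]
  ff <- lapply(strsplit(trimws(fl), "\\s+"), function(x) {
    n <- as.integer(x[1])
    if (n != 3L) stop_femfit("io", "non-triangular PLY face")
    as.integer(x[2:4]) + 1L
  })
  new_mesh(verts, do.call(rbind, ff))
}
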