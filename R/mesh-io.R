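# Mesh file I/O: PLY (ASCII + binary little-endian), STL (ASCII + binary),
# OFF (ASCII). Per-vertex material labels travel as a PLY vertex property
# named "material" (0/1).

ply_type_size <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
                   short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
                   int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
                   float = 4L, float32 = 4L, double = 8L, float64 = 8L)

ply_read_scalar <- function(raw, off, type) {
  sz <- ply_type_size[[type]]
  bytes <- raw[(off + 1):(off + sz)]
  val <- switch(type,
    char = , int8 = readBin(bytes, "integer", 1, 1, signed = TRUE, endian = "little"),
    uchar = , uint8 = readBin(bytes, "integer", 1, 1, signed = FALSE, endian = "little"),
    short = , int16 = readBin(bytes, "integer", 1, 2, signed = TRUE, endian = "little"),
    ushort = , uint16 = readBin(bytes, "integer", 1, 2, signed = FALSE, endian = "little"),
    int = , int32 = , uint = , uint32 =
      readBin(bytes, "integer", 1, 4, endian = "little"),
    float = , float32 = readBin(bytes, "double", 1, 4, endian = "little"),
    double = , float64 = readBin(bytes, "double", 1, 8, endian = "little"))
  list(value = as.numeric(val), off = off + sz)
}

fmt_error <- function(path, offset, what) {
  stop(sprintf("format error in '%s' at byte offset %d: %s", path, offset, what),
       call. = FALSE)
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character()
  header_bytes <- 0L
  repeat {
    ln <- readLines(con, n = 1L, warn = FALSE)
    if (length(ln) == 0L)
      fmt_error(path, header_bytes, "PLY header truncated (no end_header)")
    header_bytes <- header_bytes + nchar(ln, type = "bytes") + 1L
    header <- c(header, trimws(ln))
    if (trimws(ln) == "end_header") break
    if (length(header) > 1000L)
      fmt_error(path, header_bytes, "PLY header too long or unterminated")
  }
  if (header[1] != "ply") fmt_error(path, 0L, "missing 'ply' magic")
  fmt_line <- grep("^format ", header, value = TRUE)
  if (length(fmt_line) != 1L) fmt_error(path, 0L, "missing format line")
  fmt <- strsplit(fmt_line, "\\s+")[[1]][2]
  if (!fmt %in% c("ascii", "binary_little_endian"))
    fmt_error(path, 0L, paste("unsupported PLY format:", fmt))

  # parse element declarations
  elements <- list()
  cur <- NULL
  for (ln in header) {
    tok <- strsplit(ln, "\\s+")[[1]]
    if (tok[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property" && !is.null(cur)) {
      if (tok[2] == "list") {
        cur$props[[length(cur$props) + 1L]] <-
          list(name = tok[5], list = TRUE, count_type = tok[3], type = tok[4])
      } else {
        cur$props[[length(cur$props) + 1L]] <-
          list(name = tok[3], list = FALSE, type = tok[2])
      }
    }
  }
  if (!is.null(cur)) elements[[cur$name]] <- cur
  if (is.null(elements$vertex))
    fmt_error(path, header_bytes, "no vertex element")

  if (fmt == "ascii") {
    body <- readLines(con, warn = FALSE)
    body <- body[nzchar(trimws(body))]
    pos <- 0L
    out <- list()
    for (el in elements) {
      if (pos + el$count > length(body))
        fmt_error(path, header_bytes, sprintf("element '%s' truncated", el$name))
      rows <- body[(pos + 1L):(pos + el$count)]
      pos <- pos + el$count
      if (any(vapply(el$props, function(p) p$list, TRUE))) {
        # list element (faces): first number is the count
        vals <- lapply(strsplit(trimws(rows), "\\s+"), as.numeric)
        out[[el$name]] <- vals
      } else {
        mat <- matrix(as.numeric(unlist(strsplit(trimws(rows), "\\s+"))),
                      nrow = el$count, byrow = TRUE)
        colnames(mat) <- vapply(el$props, function(p) p$name, "")
        out[[el$name]] <- mat
      }
    }
  } else {
    raw <- readBin(con, "raw", n = file.size(path))
    off <- 0L
    out <- list()
    for (el in elements) {
      is_list <- vapply(el$props, function(p) p$list, TRUE)
      if (!any(is_list)) {
        types <- vapply(el$props, function(p) p$type, "")
        if (all(types %in% c("float", "float32"))) {
          np <- length(types)
          need <- 4L * np * el$count
          if (off + need > length(raw))
            fmt_error(path, header_bytes + off, sprintf("element '%s' truncated", el$name))
          vals <- readBin(raw[(off + 1):(off + need)], "double",
                          n = np * el$count, size = 4L, endian = "little")
          off <- off + need
          mat <- matrix(vals, ncol = np, byrow = TRUE)
        } else {
          mat <- matrix(0, el$count, length(el$props))
          for (i in seq_len(el$count)) {
            for (j in seq_along(el$props)) {
              if (off + ply_type_size[[el$props[[j]]$type]] > length(raw))
                fmt_error(path, header_bytes + off, sprintf("element '%s' truncated", el$name))
              r <- ply_read_scalar(raw, off, el$props[[j]]$type)
              mat[i, j] <- r$value
              off <- r$off
            }
          }
        }
        colnames(mat) <- vapply(el$props, function(p) p$name, "")
        out[[el$name]] <- mat
      } else {
        rows <- vector("list", el$count)
        for (i in seq_len(el$count)) {
          row <- numeric()
          for (p in el$props) {
            if (p$list) {
              r <- ply_read_scalar(raw, off, p$count_type)
              cnt <- as.integer(r$value); off <- r$off
              row <- c(row, cnt)
              for (k in seq_len(cnt)) {
                if (off + ply_type_size[[p$type]] > length(raw))
                  fmt_error(path, header_bytes + off, sprintf("element '%s' truncated", el$name))
                r2 <- ply_read_scalar(raw, off, p$type)
                row <- c(row, r2$value); off <- r2$off
              }
            } else {
              r <- ply_read_scalar(raw, off, p$type)
              row <- c(row, r$value); off <- r$off
            }
          }
          rows[[i]] <- row
        }
        out[[el$name]] <- rows
      }
    }
  }

  vm <- out$vertex
  need <- c("x", "y", "z")
  if (!all(need %in% colnames(vm)))
    fmt_error(path, header_bytes, "vertex element lacks x/y/z properties")
  vertices <- vm[, need, drop = FALSE]
  material <- if ("material" %in% colnames(vm)) as.numeric(vm[, "material"]) else NULL
  faces <- NULL
  if (!is.null(out$face) && length(out$face) > 0L) {
    fl <- out$face
    cnts <- vapply(fl, function(r) r[1], 0)
    if (any(cnts != 3))
      fmt_error(path, header_bytes, "non-triangular face encountered")
    faces <- matrix(as.integer(unlist(lapply(fl, function(r) r[2:4]))) + 1L,
                    ncol = 3L, byrow = TRUE)
  } else {
    faces <- matrix(integer(), 0, 3)
  }
  surface_mesh(vertices, faces, material)
}

read_off <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L || lines[1] != "OFF")
    fmt_error(path, 0L, "missing OFF magic")
  counts <- as.integer(strsplit(lines[2], "\\s+")[[1]])
  nv <- counts[1]; nf <- counts[2]
  if (is.na(nv) || is.na(nf) || length(lines) < 2L + nv + nf)
    fmt_error(path, 0L, "OFF body truncated")
  vm <- matrix(as.numeric(unlist(strsplit(lines[3:(2 + nv)], "\\s+"))),
               nrow = nv, byrow = TRUE)[, 1:3, drop = FALSE]
  faces <- matrix(integer(), 0, 3)
  if (nf > 0L) {
    fl <- lapply(strsplit(lines[(3 + nv):(2 + nv + nf)], "\\s+"), as.integer)
    if (any(vapply(fl, function(r) r[1], 0L) != 3L))
      fmt_error(path, 0L, "non-triangular face in OFF")
    faces <- matrix(unlist(lapply(fl, function(r) r[2:4])) + 1L,
                    ncol = 3L, byrow = TRUE)
  }
  surface_mesh(vm, faces)
}

read_stl <- function(path) {
  head_raw <- readBin(path, "raw", n = min(file.size(path), 512L))
  head_txt <- rawToChar(head_raw[head_raw != as.raw(0)])
  is_ascii <- grepl("^\\s*solid", head_txt) && grepl("facet", head_txt)
  if (is_ascii) {
    lines <- readLines(path, warn = FALSE)
    vlines <- grep("^\\s*vertex\\s", lines, value = TRUE)
    if (length(vlines) == 0L || length(vlines) %% 3L != 0L)
      fmt_error(path, 0L, "ASCII STL vertex count not a multiple of 3")
    coords <- matrix(as.numeric(unlist(lapply(
      strsplit(trimws(vlines), "\\s+"), function(t) t[2:4]))),
      ncol = 3L, byrow = TRUE)
  } else {
    raw <- readBin(path, "raw", n = file.size(path))
    if (length(raw) < 84L) fmt_error(path, length(raw), "binary STL truncated")
    ntri <- readBin(raw[81:84], "integer", 1, 4, endian = "little")
    need <- 84L + 50L * ntri
    if (length(raw) < need)
      fmt_error(path, length(raw), "binary STL body truncated")
    coords <- matrix(0, 3L * ntri, 3L)
    for (i in seq_len(ntri)) {
      off <- 84L + 50L * (i - 1L)
      vals <- readBin(raw[(off + 13L):(off + 48L)], "double", n = 9L,
                      size = 4L, endian = "little")
      coords[(3L * i - 2L):(3L * i), ] <- matrix(vals, 3L, 3L, byrow = TRUE)
    }
  }
  ntri <- nrow(coords) / 3L
  faces <- matrix(seq_len(3L * ntri), ncol = 3L, byrow = TRUE)
  surface_mesh(coords, faces)
}

#' Load a surface mesh from file
#'
#' Supported dialects: PLY (ASCII and binary little-endian), STL (ASCII
#' and binary), OFF (ASCII). The mesh is cleaned on load: duplicate
#' vertices merged within 1e-9 mm and degenerate faces dropped; vertex
#' order is otherwise preserved. A PLY vertex property named "material"
#' is returned as per-vertex material labels.
#'
#' @param path file path.
#' @param format one of `"ply"`, `"stl"`, `"off"`; inferred from the file
#'   extension when `NULL`.
#' @return a `surface_mesh`.
#' @export
load_mesh <- function(path, format = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (is.null(format))
    format <- tolower(tools::file_ext(path))
  format <- tolower(format)
  mesh <- switch(format,
    ply = read_ply(path),
    stl = read_stl(path),
    off = read_off(path),
    stop(sprintf("unsupported mesh format: %s", format), call. = FALSE))
  if (n_vertices(mesh) == 0L)
    stop("invalid input: empty mesh", call. = FALSE)
  clean_mesh(mesh)
}

#' Write a surface mesh to file
#'
#' PLY output carries the per-vertex "material" property when labels are
#' present. PLY can be written in ASCII or binary little-endian; STL and
#' OFF are written in ASCII.
#'
#' @param mesh a `surface_mesh`.
#' @param path output file path.
#' @param format one of `"ply"`, `"stl"`, `"off"`; inferred from the
#'   extension when `NULL`.
#' @param binary write binary PLY (ignored for other formats).
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = NULL, binary = FALSE) {
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  format <- tolower(format)
  v <- mesh$vertices
  f <- mesh$faces
  if (format == "ply") {
    has_mat <- !is.null(mesh$material)
    hdr <- c("ply",
             sprintf("format %s 1.0",
                     if (binary) "binary_little_endian" else "ascii"),
             sprintf("element vertex %d", nrow(v)),
             "property double x", "property double y", "property double z",
             if (has_mat) "property double material",
             sprintf("element face %d", nrow(f)),
             "property list uchar int vertex_indices",
             "end_header")
    if (binary) {
      con <- file(path, "wb")
      on.exit(close(con))
      writeLines(hdr, con, sep = "\n")
      vm <- if (has_mat) cbind(v, mesh$material) else v
      writeBin(as.vector(t(vm)), con, size = 8L, endian = "little")
      for (i in seq_len(nrow(f))) {
        writeBin(as.raw(3L), con)
        writeBin(as.integer(f[i, ] - 1L), con, size = 4L, endian = "little")
      }
    } else {
      vm <- if (has_mat) cbind(v, mesh$material) else v
      vtxt <- apply(vm, 1, function(r) paste(format(r, digits = 17), collapse = " "))
      ftxt <- apply(f - 1L, 1, function(r) paste(c(3L, r), collapse = " "))
      writeLines(c(hdr, vtxt, ftxt), path)
    }
  } else if (format == "off") {
    vtxt <- apply(v, 1, function(r) paste(format(r, digits = 17), collapse = " "))
    ftxt <- apply(f - 1L, 1, function(r) paste(c(3L, r), collapse = " "))
    writeLines(c("OFF", sprintf("%d %d 0", nrow(v), nrow(f)), vtxt, ftxt), path)
  } else if (format == "stl") {
    nrm <- face_normals(mesh)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid mesh", con)
    for (i in seq_len(nrow(f))) {
      writeLines(sprintf("  facet normal %.9g %.9g %.9g",
                         nrm[i, 1], nrm[i, 2], nrm[i, 3]), con)
      writeLines("    outer loop", con)
      for (k in 1:3) {
        p <- v[f[i, k], ]
        writeLines(sprintf("      vertex %.17g %.17g %.17g", p[1], p[2], p[3]), con)
      }
      writeLines(c("    endloop", "  endfacet"), con)
    }
    writeLines("endsolid mesh", con)
  } else {
    stop(sprintf("unsupported mesh format: %s", format), call. = FALSE)
  }
  invisible(path)
}
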