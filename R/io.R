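# Readers/writers for the three cloud formats in the interface contract:
# PLY (ascii 1.0 and binary_little_endian 1.0), PCD v0.7 (ascii), and
# whitespace-delimited XYZ. No PLY/PCD parser ships with the pre-installed
# R stack, so these are written here against the format specifications.
# ASCII output uses 9 significant digits so write -> read round trips are
# stable to well below 1e-6 m.

PLY_SIZES <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
               short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
               int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
               float = 4L, float32 = 4L, double = 8L, float64 = 8L)
PLY_INT <- c("char", "uchar", "int8", "uint8", "short", "ushort", "int16",
             "uint16", "int", "uint", "int32", "uint32")

guess_format <- function(path, format = NULL) {
  if (!is.null(format)) {
    format <- tolower(format)
    if (!format %in% c("ply", "pcd", "xyz")) {
      stop("unknown format '", format, "': use \"ply\", \"pcd\" or \"xyz\"")
    }
    return(format)
  }
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("ply", "pcd", "xyz")) {
    stop("cannot infer cloud format from extension '", ext,
         "'; pass format = \"ply\", \"pcd\" or \"xyz\"")
  }
  ext
}

#' Read a point cloud from file
#'
#' @param path file path.
#' @param format one of `"ply"`, `"pcd"`, `"xyz"`; inferred from the file
#'   extension when `NULL`.
#' @return a [point_cloud()]. A PLY integer property named `label` is mapped
#'   onto the cloud's labels.
#' @export
read_cloud <- function(path, format = NULL) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  format <- guess_format(path, format)
  switch(format,
         ply = read_ply(path),
         pcd = read_pcd(path),
         xyz = read_xyz(path))
}

#' Write a point cloud to file
#'
#' @param cloud a [point_cloud()].
#' @param path destination path.
#' @param format one of `"ply"`, `"pcd"`, `"xyz"`; inferred from extension.
#' @param binary for PLY only: write `binary_little_endian` (doubles) instead
#'   of ASCII.
#' @export
write_cloud <- function(cloud, path, format = NULL, binary = FALSE) {
  stopifnot(is_point_cloud(cloud))
  format <- guess_format(path, format)
  switch(format,
         ply = write_ply(cloud, path, binary = binary),
         pcd = write_pcd(cloud, path),
         xyz = write_xyz(cloud, path))
  invisible(path)
}

# --- XYZ ------------------------------------------------------------------

read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  lineno <- which(keep)
  toks <- strsplit(trimws(lines[keep]), "\\s+")
  n <- length(toks)
  if (n == 0L) return(point_cloud(matrix(numeric(0), 0L, 3L)))
  bad <- which(lengths(toks) < 3L)
  if (length(bad)) {
    stop("XYZ parse error at line ", lineno[bad[1L]],
         ": expected 3 coordinates")
  }
  vals <- suppressWarnings(
    vapply(toks, function(t) as.numeric(t[1:3]), numeric(3)))
  nab <- which(colSums(is.na(vals)) > 0L)
  if (length(nab)) {
    stop("XYZ parse error at line ", lineno[nab[1L]], ": non-numeric field")
  }
  point_cloud(t(vals))
}

write_xyz <- function(cloud, path) {
  p <- cloud$points
  writeLines(sprintf("%.9g %.9g %.9g", p[, 1L], p[, 2L], p[, 3L]), path)
}

# --- PLY ------------------------------------------------------------------

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character(0)
  repeat {
    ln <- readLines(con, n = 1L)
    if (length(ln) == 0L) stop("PLY parse error: unexpected end of header")
    header <- c(header, ln)
    if (trimws(ln) == "end_header") break
    if (length(header) > 1000L) stop("PLY parse error: header too long")
  }
  if (trimws(header[1L]) != "ply") stop("PLY parse error at line 1: magic")
  fmt_line <- grep("^format ", trimws(header), value = TRUE)
  if (length(fmt_line) != 1L) stop("PLY parse error: missing format line")
  fmt <- strsplit(trimws(fmt_line), "\\s+")[[1L]][2L]
  if (!fmt %in% c("ascii", "binary_little_endian")) {
    stop("PLY parse error: unsupported format '", fmt, "'")
  }
  # collect elements in order; only a single 'vertex' element is supported
  n_vertex <- NA_integer_
  props <- character(0); types <- character(0)
  cur_elem <- ""
  for (i in seq_along(header)) {
    tk <- strsplit(trimws(header[i]), "\\s+")[[1L]]
    if (!length(tk)) next
    if (tk[1L] == "element") {
      cur_elem <- tk[2L]
      cnt <- suppressWarnings(as.integer(tk[3L]))
      if (is.na(cnt)) stop("PLY parse error at line ", i, ": element count")
      if (cur_elem == "vertex") {
        n_vertex <- cnt
      } else if (cnt > 0L) {
        stop("PLY parse error: unsupported element '", cur_elem, "'")
      }
    } else if (tk[1L] == "property" && cur_elem == "vertex") {
      if (tk[2L] == "list") {
        stop("PLY parse error: list property on vertex element")
      }
      if (!tk[2L] %in% names(PLY_SIZES)) {
        stop("PLY parse error at line ", i, ": unknown type '", tk[2L], "'")
      }
      types <- c(types, tk[2L])
      props <- c(props, tk[3L])
    }
  }
  if (is.na(n_vertex)) stop("PLY parse error: no vertex element")
  ixyz <- match(c("x", "y", "z"), props)
  if (any(is.na(ixyz))) stop("PLY parse error: missing x/y/z properties")

  if (n_vertex == 0L) return(point_cloud(matrix(numeric(0), 0L, 3L)))

  if (fmt == "ascii") {
    lines <- readLines(con, n = n_vertex)
    if (length(lines) < n_vertex) {
      stop("PLY parse error: expected ", n_vertex, " vertex records, got ",
           length(lines))
    }
    toks <- strsplit(trimws(lines), "\\s+")
    short <- which(lengths(toks) < length(props))
    if (length(short)) {
      stop("PLY parse error at vertex record ", short[1L],
           ": too few fields")
    }
    tab <- t(vapply(toks, function(t) {
      suppressWarnings(as.numeric(t[seq_along(props)]))
    }, numeric(length(props))))
    if (anyNA(tab)) {
      stop("PLY parse error at vertex record ",
           which(rowSums(is.na(tab)) > 0L)[1L], ": non-numeric field")
    }
  } else {
    sizes <- PLY_SIZES[types]
    rec <- sum(sizes)
    raw <- readBin(con, "raw", n = n_vertex * rec)
    if (length(raw) < n_vertex * rec) {
      stop("PLY parse error: truncated binary vertex data")
    }
    offs <- c(0L, cumsum(sizes))
    tab <- matrix(0, n_vertex, length(props))
    for (j in seq_along(props)) {
      sel <- outer((offs[j] + 1L):offs[j + 1L],
                   (seq_len(n_vertex) - 1L) * rec, `+`)
      bytes <- raw[as.vector(sel)]
      what <- if (types[j] %in% PLY_INT) "integer" else "double"
      signed <- !grepl("^u", types[j])
      tab[, j] <- readBin(bytes, what, n = n_vertex, size = sizes[j],
                          signed = if (sizes[j] < 4L) signed else TRUE,
                          endian = "little")
    }
  }
  labels <- NULL
  ilab <- match("label", props)
  if (!is.na(ilab)) labels <- as.integer(tab[, ilab])
  point_cloud(tab[, ixyz, drop = FALSE], labels = labels)
}

write_ply <- function(cloud, path, binary = FALSE) {
  p <- cloud$points
  lab <- cloud$labels
  has_lab <- !is.null(lab)
  if (has_lab && !is.numeric(lab)) lab <- as.integer(factor(lab))
  coord_type <- if (binary) "double" else "float"
  header <- c(
    "ply",
    sprintf("format %s 1.0",
            if (binary) "binary_little_endian" else "ascii"),
    sprintf("element vertex %d", nrow(p)),
    sprintf("property %s x", coord_type),
    sprintf("property %s y", coord_type),
    sprintf("property %s z", coord_type),
    if (has_lab) "property int label",
    "end_header")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(header, con)
  if (nrow(p) == 0L) return(invisible(path))
  if (binary) {
    for (i in seq_len(nrow(p))) {
      writeBin(as.numeric(p[i, ]), con, size = 8L, endian = "little")
      if (has_lab) writeBin(as.integer(lab[i]), con, size = 4L,
                            endian = "little")
    }
  } else {
    recs <- sprintf("%.9g %.9g %.9g", p[, 1L], p[, 2L], p[, 3L])
    if (has_lab) recs <- paste(recs, as.integer(lab))
    writeLines(recs, con)
  }
  invisible(path)
}

# --- PCD ------------------------------------------------------------------

read_pcd <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr_keys <- c("VERSION", "FIELDS", "SIZE", "TYPE", "COUNT", "WIDTH",
                "HEIGHT", "VIEWPOINT", "POINTS", "DATA")
  hdr <- list()
  data_at <- NA_integer_
  for (i in seq_along(lines)) {
    tk <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    if (startsWith(tk[1L], "#")) next
    if (tk[1L] %in% hdr_keys) {
      hdr[[tk[1L]]] <- tk[-1L]
      if (tk[1L] == "DATA") { data_at <- i; break }
    } else {
      stop("PCD parse error at line ", i, ": unexpected token '",
           tk[1L], "'")
    }
  }
  if (is.na(data_at)) stop("PCD parse error: no DATA line")
  if (tolower(hdr$DATA[1L]) != "ascii") {
    stop("PCD parse error: only DATA ascii is supported")
  }
  fields <- hdr$FIELDS
  ixyz <- match(c("x", "y", "z"), fields)
  if (any(is.na(ixyz))) stop("PCD parse error: FIELDS must include x y z")
  n <- as.integer(hdr$POINTS[1L] %||% hdr$WIDTH[1L])
  if (is.na(n)) stop("PCD parse error: missing POINTS count")
  body <- lines[seq.int(data_at + 1L, length.out = length(lines) - data_at)]
  if (length(body) < n) {
    stop("PCD parse error: expected ", n, " records, got ", length(body))
  }
  toks <- strsplit(trimws(body[seq_len(n)]), "\\s+")
  bad <- which(lengths(toks) < length(fields))
  if (length(bad)) {
    stop("PCD parse error at record ", bad[1L], ": too few fields")
  }
  tab <- t(vapply(toks, function(t) {
    suppressWarnings(as.numeric(t[seq_along(fields)]))
  }, numeric(length(fields))))
  if (anyNA(tab)) {
    stop("PCD parse error at record ",
         which(rowSums(is.na(tab)) > 0L)[1L], ": non-numeric field")
  }
  point_cloud(tab[, ixyz, drop = FALSE])
}

write_pcd <- function(cloud, path) {
  p <- cloud$points
  n <- nrow(p)
  header <- c(
    "# .PCD v0.7 - Point Cloud Data file format",
    "VERSION 0.7",
    "FIELDS x y z",
    "SIZE 4 4 4",
    "TYPE F F F",
    "COUNT 1 1 1",
    sprintf("WIDTH %d", n),
    "HEIGHT 1",
    "VIEWPOINT 0 0 0 1 0 0 0",
    sprintf("POINTS %d", n),
    "DATA ascii")
  body <- if (n) sprintf("%.9g %.9g %.9g", p[, 1L], p[, 2L], p[, 3L])
  writeLines(c(header, body), path)
}
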