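## Point cloud / mesh / sample-table I/O.
##
## PLY support covers ASCII and binary little-endian files with an x/y/z
## vertex element; extra scalar vertex properties (intensity, color, normals)
## are preserved when present but never required. nx/ny/nz properties are
## re-attached as normals on read. No installed package reads PLY, so the
## format is parsed here.

.ply_type_size <- c(char = 1L, int8 = 1L, uchar = 1L, uint8 = 1L,
                    short = 2L, int16 = 2L, ushort = 2L, uint16 = 2L,
                    int = 4L, int32 = 4L, uint = 4L, uint32 = 4L,
                    float = 4L, float32 = 4L, double = 8L, float64 = 8L)

.ply_read_scalar <- function(raw_mat, offset, type, n) {
  size <- .ply_type_size[[type]]
  bytes <- as.vector(raw_mat[offset + seq_len(size), , drop = FALSE])
  what <- if (type %in% c("float", "float32", "double", "float64")) "double" else "integer"
  signed <- !(type %in% c("uchar", "uint8", "ushort", "uint16", "uint", "uint32"))
  if (type %in% c("uint", "uint32")) {
    v <- readBin(bytes, "integer", n = n, size = 4L, endian = "little")
    v <- ifelse(v < 0, v + 2^32, as.numeric(v))
    return(v)
  }
  readBin(bytes, what, n = n, size = size, signed = signed, endian = "little")
}

.parse_ply_header <- function(raw) {
  marker <- charToRaw("end_header")
  idx <- which(raw == marker[1])
  hdr_end <- NA_integer_
  for (i in idx) {
    if (i + length(marker) - 1L <= length(raw) &&
        identical(raw[i:(i + length(marker) - 1L)], marker)) {
      hdr_end <- i + length(marker) - 1L
      break
    }
  }
  if (is.na(hdr_end)) stop("not a PLY file (no end_header)")
  # consume exactly one line ending (never more: the payload is binary)
  if (hdr_end < length(raw) && raw[hdr_end + 1L] == as.raw(13L))
    hdr_end <- hdr_end + 1L
  if (hdr_end < length(raw) && raw[hdr_end + 1L] == as.raw(10L))
    hdr_end <- hdr_end + 1L
  header <- strsplit(rawToChar(raw[seq_len(hdr_end)]), "\r?\n")[[1]]
  if (!grepl("^ply", header[1])) stop("not a PLY file (missing 'ply' magic)")
  fmt_line <- grep("^format ", header, value = TRUE)
  if (!length(fmt_line)) stop("PLY header missing format line")
  format <- strsplit(fmt_line[1], "\\s+")[[1]][2]
  if (!format %in% c("ascii", "binary_little_endian"))
    stop("unsupported PLY format: ", format)

  elements <- list()
  cur <- NULL
  for (line in header) {
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (!length(tok)) next
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
  list(format = format, elements = elements, data_start = hdr_end + 1L)
}

.read_ply <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  hdr <- .parse_ply_header(raw)
  out <- list(vertex = NULL, face = NULL)

  if (hdr$format == "ascii") {
    txt <- strsplit(rawToChar(raw[hdr$data_start:length(raw)]), "\r?\n")[[1]]
    txt <- txt[nzchar(trimws(txt))]
    pos <- 0L
    for (el in hdr$elements) {
      lines <- txt[pos + seq_len(el$count)]
      pos <- pos + el$count
      if (el$name == "vertex") {
        vals <- matrix(scan(text = lines, quiet = TRUE),
                       nrow = el$count, byrow = TRUE)
        colnames(vals) <- vapply(el$props, `[[`, "", "name")
        out$vertex <- vals
      } else if (el$name == "face") {
        rows <- lapply(strsplit(trimws(lines), "\\s+"), as.integer)
        cnt <- vapply(rows, `[[`, 0L, 1L)
        if (any(cnt != 3L)) stop("only triangular faces are supported")
        out$face <- do.call(rbind, lapply(rows, function(r) r[2:4])) + 1L
      }
    }
  } else {
    offset <- hdr$data_start - 1L
    for (el in hdr$elements) {
      has_list <- any(vapply(el$props, `[[`, TRUE, "list"))
      if (!has_list) {
        sizes <- vapply(el$props, function(p) .ply_type_size[[p$type]], 0L)
        rec <- sum(sizes)
        nbytes <- rec * el$count
        block <- raw[offset + seq_len(nbytes)]
        offset <- offset + nbytes
        if (el$name != "vertex") next
        rm_ <- matrix(block, nrow = rec)
        off <- c(0L, cumsum(sizes))
        vals <- matrix(0, nrow = el$count, ncol = length(el$props))
        for (j in seq_along(el$props))
          vals[, j] <- .ply_read_scalar(rm_, off[j], el$props[[j]]$type, el$count)
        colnames(vals) <- vapply(el$props, `[[`, "", "name")
        out$vertex <- vals
      } else {
        if (el$name != "face")
          stop("unsupported binary PLY: list property outside face element")
        p <- el$props[[1]]
        csize <- .ply_type_size[[p$count_type]]
        isize <- .ply_type_size[[p$type]]
        rec <- csize + 3L * isize
        nbytes <- rec * el$count
        block <- raw[offset + seq_len(nbytes)]
        offset <- offset + nbytes
        rm_ <- matrix(block, nrow = rec)
        cnt <- .ply_read_scalar(rm_, 0L, p$count_type, el$count)
        if (any(cnt != 3)) stop("only triangular faces are supported")
        idx <- matrix(0L, nrow = el$count, ncol = 3L)
        for (j in 0:2)
          idx[, j + 1L] <- .ply_read_scalar(rm_, csize + j * isize, p$type, el$count)
        out$face <- idx + 1L
      }
    }
  }
  out
}

#' Read a point cloud from PLY or XYZ text
#'
#' Accepts PLY (ASCII or binary little-endian, element `vertex` with x/y/z
#' properties) or whitespace-separated XYZ text (at least 3 numeric columns;
#' extra columns ignored). Rows with non-finite coordinates are rejected with
#' a warning and counted in `attr(cloud, "rejected_rows")`; they never abort
#' the read. PLY `nx`/`ny`/`nz` properties are attached as normals, and other
#' extra vertex properties are preserved in `cloud$extra`.
#'
#' @param path input file.
#' @param unit declared length unit of the file (`"m"`, `"cm"` or `"mm"`);
#'   point cloud files carry no unit metadata, so it must be declared here.
#' @param format `"auto"` (PLY magic sniffing), `"ply"` or `"xyz"`.
#' @param id sample label; defaults to the file name.
#' @return a [point_cloud()].
#' @export
read_point_cloud <- function(path, unit = c("m", "cm", "mm"),
                             format = c("auto", "ply", "xyz"),
                             id = NULL) {
  unit <- match.arg(unit)
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read file: ", path)
  if (is.null(id)) id <- basename(path)
  if (format == "auto") {
    magic <- readBin(path, "raw", n = 3L)
    format <- if (identical(rawToChar(magic), "ply")) "ply" else "xyz"
  }

  if (format == "ply") {
    ply <- .read_ply(path)
    if (is.null(ply$vertex)) stop("PLY file has no vertex element")
    v <- ply$vertex
    need <- c("x", "y", "z")
    if (!all(need %in% colnames(v))) stop("PLY vertex element lacks x/y/z")
    pts <- v[, need, drop = FALSE]
  } else {
    tab <- tryCatch(
      read.table(path, header = FALSE, comment.char = "#",
                 stringsAsFactors = FALSE, fill = TRUE),
      error = function(e) stop("cannot parse XYZ file: ", conditionMessage(e)))
    if (ncol(tab) < 3L) stop("XYZ file needs at least 3 columns")
    pts <- suppressWarnings(
      matrix(as.numeric(as.matrix(tab[, 1:3])), ncol = 3L))
    v <- pts
    colnames(v) <- c("x", "y", "z")
  }

  ok <- rowSums(is.finite(pts)) == 3L
  n_rej <- sum(!ok)
  if (n_rej > 0)
    warning(sprintf("%d row(s) with non-finite coordinates rejected", n_rej))
  pts <- pts[ok, , drop = FALSE]
  if (nrow(pts) == 0L) stop("no valid points in ", path)

  extra_cols <- setdiff(colnames(v), c("x", "y", "z", "nx", "ny", "nz"))
  extra <- if (length(extra_cols))
    as.data.frame(v[ok, extra_cols, drop = FALSE]) else NULL
  cloud <- point_cloud(pts, unit = unit, id = id, extra = extra)
  if (all(c("nx", "ny", "nz") %in% colnames(v)))
    cloud <- set_normals(cloud, v[ok, c("nx", "ny", "nz"), drop = FALSE])
  attr(cloud, "rejected_rows") <- n_rej
  cloud
}

.ply_header_lines <- function(format, n_vertex, prop_names, n_face = NULL) {
  c("ply",
    paste("format", format, "1.0"),
    "comment written by disctls",
    paste("element vertex", n_vertex),
    paste("property double", prop_names),
    if (!is.null(n_face)) c(paste("element face", n_face),
                            "property list uchar int vertex_indices"),
    "end_header")
}

.write_ply <- function(path, vert, faces = NULL, binary = FALSE) {
  fmt <- if (binary) "binary_little_endian" else "ascii"
  hdr <- .ply_header_lines(fmt, nrow(vert), colnames(vert),
                           if (!is.null(faces)) nrow(faces))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  if (binary) {
    writeBin(as.vector(t(vert)), con, size = 8L, endian = "little")
    if (!is.null(faces)) {
      ib <- writeBin(as.integer(t(faces) - 1L), raw(), size = 4L, endian = "little")
      ib <- matrix(ib, nrow = 12L)
      rec <- rbind(matrix(as.raw(3L), nrow = 1L, ncol = ncol(ib)), ib)
      writeBin(as.vector(rec), con)
    }
  } else {
    writeLines(apply(vert, 1, function(r) paste(sprintf("%.17g", r), collapse = " ")),
               con, sep = "\n")
    if (!is.null(faces))
      writeLines(paste(3L, faces[, 1] - 1L, faces[, 2] - 1L, faces[, 3] - 1L),
                 con, sep = "\n")
  }
  invisible(path)
}

#' Write a point cloud to PLY or XYZ
#'
#' Coordinates (and normals, if present) are written as doubles, so binary
#' PLY round-trips bit-for-bit and ASCII round-trips to the printed precision
#' (17 significant digits, i.e. exactly for doubles).
#'
#' @param cloud a [point_cloud()].
#' @param path output file.
#' @param format one of `"ply_ascii"`, `"ply_binary"`, `"xyz"`.
#' @return `path`, invisibly.
#' @export
write_point_cloud <- function(cloud, path,
                              format = c("ply_ascii", "ply_binary", "xyz")) {
  format <- match.arg(format)
  stopifnot(inherits(cloud, "point_cloud"))
  vert <- cloud$points
  nrm <- cloud_normals(cloud)
  if (!is.null(nrm)) vert <- cbind(vert, nrm)
  if (!is.null(cloud$extra))
    vert <- cbind(vert, as.matrix(cloud$extra))
  if (format == "xyz") {
    writeLines(apply(vert, 1, function(r) paste(sprintf("%.17g", r), collapse = " ")),
               path)
    return(invisible(path))
  }
  .write_ply(path, vert, binary = (format == "ply_binary"))
}

#' Read a triangle mesh from PLY
#' @param path PLY file with vertex and face elements.
#' @param unit declared length unit of the coordinates.
#' @return a [triangle_mesh()].
#' @export
read_mesh <- function(path, unit = c("m", "cm", "mm")) {
  unit <- match.arg(unit)
  if (!file.exists(path)) stop("cannot read file: ", path)
  ply <- .read_ply(path)
  if (is.null(ply$vertex) || is.null(ply$face))
    stop("PLY file must contain vertex and face elements")
  triangle_mesh(ply$vertex[, c("x", "y", "z"), drop = FALSE], ply$face,
                unit = unit)
}

#' Write a triangle mesh to PLY
#' @param mesh a [triangle_mesh()].
#' @param path output file.
#' @param format `"ply_ascii"` or `"ply_binary"`.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = c("ply_binary", "ply_ascii")) {
  format <- match.arg(format)
  stopifnot(inherits(mesh, "triangle_mesh"))
  .write_ply(path, mesh$vertices, mesh$faces,
             binary = (format == "ply_binary"))
}

#' Read a paired-volume sample table
#'
#' CSV with header columns `id`, `species`, `estimated_volume` (cm^3) and
#' `rep1` (plus optional `rep2`, `rep3`): the 1-3 water-displacement replicate
#' measurements in cm^3. The reference volume is the arithmetic mean of the
#' replicates. Rows with non-positive estimated or replicate volumes are
#' rejected with a warning and counted in `attr(x, "rejected_rows")`.
#'
#' @param path CSV file.
#' @return a `disc_samples` data.frame with columns id, species,
#'   estimated_volume, rep1..rep3 and reference_volume.
#' @export
read_samples_table <- function(path) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "species", "estimated_volume", "rep1")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("sample table missing required column(s): ", paste(miss, collapse = ", "))
  for (r in c("rep2", "rep3")) if (!r %in% names(tab)) tab[[r]] <- NA_real_
  reps <- as.matrix(tab[, c("rep1", "rep2", "rep3")])
  storage.mode(reps) <- "double"
  tab$estimated_volume <- as.numeric(tab$estimated_volume)

  ok_est <- is.finite(tab$estimated_volume) & tab$estimated_volume > 0
  ok_rep <- apply(reps, 1, function(r) {
    r <- r[!is.na(r)]
    length(r) >= 1 && all(is.finite(r) & r > 0)
  })
  ok <- ok_est & ok_rep
  n_rej <- sum(!ok)
  if (n_rej > 0)
    warning(sprintf("%d sample row(s) rejected (non-positive or missing volumes)", n_rej))
  tab <- tab[ok, , drop = FALSE]
  if (nrow(tab) == 0L) stop("no valid sample rows in ", path)
  tab$reference_volume <- rowMeans(tab[, c("rep1", "rep2", "rep3")], na.rm = TRUE)
  rownames(tab) <- NULL
  out <- tab[, c("id", "species", "estimated_volume",
                 "rep1", "rep2", "rep3", "reference_volume")]
  class(out) <- c("disc_samples", "data.frame")
  attr(out, "rejected_rows") <- n_rej
  out
}

#' Write a paired-volume sample table
#' @param samples a `disc_samples` data.frame (see [read_samples_table()]).
#' @param path output CSV file.
#' @return `path`, invisibly.
#' @export
write_samples_table <- function(samples, path) {
  cols <- intersect(c("id", "species", "estimated_volume", "rep1", "rep2", "rep3"),
                    names(samples))
  write.csv(samples[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
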