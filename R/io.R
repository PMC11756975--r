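## Point-cloud and biomass-table I/O.
##
## PLY (ascii / binary_little_endian) and LAS 1.2 are read and written with
## minimal hand-rolled parsers (no reader for either exists in the installed
## R stack). LAZ is not supported: no codec is available, and attempting to
## read one raises a clear error.

.ply_type_size <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
                    short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
                    int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
                    float = 4L, float32 = 4L, double = 8L, float64 = 8L)

.read_bin_prop <- function(raw_block, type, offset, stride, n) {
  size <- .ply_type_size[[type]]
  idx <- rep.int(offset + seq_len(size), n) +
    rep((seq_len(n) - 1L) * stride, each = size)
  bytes <- raw_block[idx]
  switch(type,
    char = , int8 = as.numeric(readBin(bytes, "integer", n, size = 1L, signed = TRUE)),
    uchar = , uint8 = as.numeric(readBin(bytes, "integer", n, size = 1L, signed = FALSE)),
    short = , int16 = as.numeric(readBin(bytes, "integer", n, size = 2L, signed = TRUE, endian = "little")),
    ushort = , uint16 = as.numeric(readBin(bytes, "integer", n, size = 2L, signed = FALSE, endian = "little")),
    int = , int32 = as.numeric(readBin(bytes, "integer", n, size = 4L, endian = "little")),
    uint = , uint32 = {
      v <- readBin(bytes, "integer", n, size = 4L, endian = "little")
      ifelse(v < 0, v + 2^32, as.numeric(v))
    },
    float = , float32 = readBin(bytes, "numeric", n, size = 4L, endian = "little"),
    double = , float64 = readBin(bytes, "numeric", n, size = 8L, endian = "little"),
    stop("unsupported PLY property type: ", type)
  )
}

.read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!identical(trimws(magic), "ply")) stop("not a PLY file: ", path)
  fmt <- NULL
  elements <- list()      # name -> count
  props <- list()         # per element: data.frame(name, type)
  cur <- NULL
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("unexpected end of PLY header in ", path)
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(tok) == 0L || tok[1] == "comment") next
    if (tok[1] == "format") fmt <- tok[2]
    else if (tok[1] == "element") {
      cur <- tok[2]
      elements[[cur]] <- as.integer(tok[3])
      props[[cur]] <- data.frame(name = character(), type = character())
    } else if (tok[1] == "property") {
      if (tok[2] == "list") {
        props[[cur]] <- rbind(props[[cur]],
                              data.frame(name = tok[5], type = "list"))
      } else {
        props[[cur]] <- rbind(props[[cur]],
                              data.frame(name = tok[3], type = tok[2]))
      }
    } else if (tok[1] == "end_header") break
  }
  if (is.null(fmt)) stop("PLY header has no format line: ", path)
  if (!"vertex" %in% names(elements)) stop("PLY file has no vertex element: ", path)
  if (which(names(elements) == "vertex") != 1L)
    stop("PLY vertex element must come first: ", path)
  n <- elements[["vertex"]]
  vp <- props[["vertex"]]
  if (any(vp$type == "list")) stop("list properties on vertices are not supported")
  cols <- list()
  if (n > 0L) {
    if (fmt == "ascii") {
      tab <- matrix(scan(con, what = numeric(), n = n * nrow(vp), quiet = TRUE),
                    nrow = n, byrow = TRUE)
      for (j in seq_len(nrow(vp))) cols[[vp$name[j]]] <- tab[, j]
    } else if (fmt == "binary_little_endian") {
      sizes <- .ply_type_size[vp$type]
      stride <- sum(sizes)
      raw_block <- readBin(con, "raw", n * stride)
      if (length(raw_block) < n * stride) stop("truncated PLY vertex data: ", path)
      off <- c(0L, cumsum(sizes))[seq_len(nrow(vp))]
      for (j in seq_len(nrow(vp)))
        cols[[vp$name[j]]] <- .read_bin_prop(raw_block, vp$type[j], off[j], stride, n)
    } else stop("unsupported PLY format: ", fmt)
  } else {
    for (nm in vp$name) cols[[nm]] <- numeric(0)
  }
  need <- c("x", "y", "z")
  if (!all(need %in% names(cols))) stop("PLY vertex element lacks x/y/z")
  coords <- cbind(cols$x, cols$y, cols$z)
  rgb <- NULL
  if (all(c("red", "green", "blue") %in% names(cols)))
    rgb <- cbind(cols$red, cols$green, cols$blue)
  labels <- NULL
  lab_name <- intersect(c("label", "classification", "scalar_label"), names(cols))
  if (length(lab_name)) labels <- as.integer(cols[[lab_name[1]]])
  point_cloud(coords, rgb = rgb, labels = labels)
}

.write_ply <- function(cloud, path, binary = TRUE) {
  n <- nrow(cloud$coords)
  has_rgb <- !is.null(cloud$rgb)
  has_lab <- !is.null(cloud$labels)
  hdr <- c("ply",
           sprintf("format %s 1.0", if (binary) "binary_little_endian" else "ascii"),
           sprintf("element vertex %d", n),
           "property double x", "property double y", "property double z",
           if (has_rgb) c("property uchar red", "property uchar green",
                          "property uchar blue"),
           if (has_lab) "property int label",
           "end_header")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  if (n == 0L) return(invisible(path))
  if (binary) {
    for (i in seq_len(n)) {
      writeBin(as.numeric(cloud$coords[i, ]), con, size = 8L, endian = "little")
      if (has_rgb) writeBin(as.raw(round(cloud$rgb[i, ])), con)
      if (has_lab) writeBin(as.integer(cloud$labels[i]), con, size = 4L,
                            endian = "little")
    }
  } else {
    rows <- apply(cloud$coords, 1L, function(r) paste(sprintf("%.17g", r), collapse = " "))
    if (has_rgb) rows <- paste(rows, apply(cloud$rgb, 1L, function(r)
      paste(as.integer(round(r)), collapse = " ")))
    if (has_lab) rows <- paste(rows, cloud$labels)
    writeLines(rows, con)
  }
  invisible(path)
}

# LAS 1.2 classification codes <-> package labels.
# 2 (ground) -> 1; 4 (medium vegetation, what this package writes for the
# vegetation class) -> 2; every other code -> 0 (unlabeled).
.las_class_to_label <- function(cls) {
  out <- integer(length(cls))
  out[cls == 2L] <- 1L
  out[cls == 4L] <- 2L
  out
}

.read_las <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  sig <- readBin(con, "raw", 4L)
  if (!identical(rawToChar(sig), "LASF")) stop("not a LAS file: ", path)
  hdr_rest <- readBin(con, "raw", 223L)
  u16 <- function(raw, at) readBin(raw[at:(at + 1L)], "integer", 1L, size = 2L,
                                   signed = FALSE, endian = "little")
  u32 <- function(raw, at) {
    v <- readBin(raw[at:(at + 3L)], "integer", 1L, size = 4L, endian = "little")
    if (v < 0) v + 2^32 else v
  }
  f64 <- function(raw, at) readBin(raw[at:(at + 7L)], "numeric", 1L, size = 8L,
                                   endian = "little")
  # offsets below are relative to hdr_rest (file byte 5 = index 1)
  off_points <- u32(hdr_rest, 93L)
  fmt <- as.integer(hdr_rest[101L])
  if (fmt > 127L) fmt <- fmt - 128L  # tolerate compressed-format flag
  if (fmt > 3L) stop("unsupported LAS point format ", fmt, " (LAZ is not supported)")
  reclen <- u16(hdr_rest, 102L)
  npts <- u32(hdr_rest, 104L)
  scale <- c(f64(hdr_rest, 128L), f64(hdr_rest, 136L), f64(hdr_rest, 144L))
  offs <- c(f64(hdr_rest, 152L), f64(hdr_rest, 160L), f64(hdr_rest, 168L))
  seek(con, off_points)
  raw_block <- readBin(con, "raw", npts * reclen)
  if (length(raw_block) < npts * reclen) stop("truncated LAS point data: ", path)
  if (npts == 0L) return(point_cloud(matrix(numeric(0), ncol = 3)))
  geti32 <- function(off) {
    idx <- rep.int(off + 1:4, npts) + rep((seq_len(npts) - 1L) * reclen, each = 4L)
    readBin(raw_block[idx], "integer", npts, size = 4L, endian = "little")
  }
  getu8 <- function(off) as.integer(raw_block[off + 1L + (seq_len(npts) - 1L) * reclen])
  getu16 <- function(off) {
    idx <- rep.int(off + 1:2, npts) + rep((seq_len(npts) - 1L) * reclen, each = 2L)
    readBin(raw_block[idx], "integer", npts, size = 2L, signed = FALSE,
            endian = "little")
  }
  coords <- cbind(geti32(0L) * scale[1] + offs[1],
                  geti32(4L) * scale[2] + offs[2],
                  geti32(8L) * scale[3] + offs[3])
  cls <- bitwAnd(getu8(15L), 31L)  # low 5 bits per LAS 1.2
  rgb <- NULL
  if (fmt %in% c(2L, 3L)) {
    rgb_off <- if (fmt == 2L) 20L else 28L
    rgb <- cbind(getu16(rgb_off), getu16(rgb_off + 2L), getu16(rgb_off + 4L)) / 257
  }
  point_cloud(coords, rgb = rgb, labels = .las_class_to_label(cls))
}

.write_las <- function(cloud, path) {
  n <- nrow(cloud$coords)
  has_rgb <- !is.null(cloud$rgb)
  fmt <- if (has_rgb) 2L else 0L
  reclen <- if (has_rgb) 26L else 20L
  scale <- 1e-7
  offs <- if (n > 0) apply(cloud$coords, 2L, min) else c(0, 0, 0)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("LASF", con, 4L, eos = NULL)
  writeBin(rep(0L, 2L), con, size = 2L, endian = "little")     # source id, encoding
  writeBin(raw(16L), con)                                      # GUID
  writeBin(as.raw(c(1L, 2L)), con)                             # version 1.2
  writeChar(formatC("quadratvol", width = 32L, flag = "-"), con, 32L, eos = NULL)
  writeChar(formatC("quadratvol", width = 32L, flag = "-"), con, 32L, eos = NULL)
  writeBin(c(1L, 2026L), con, size = 2L, endian = "little")    # day, year
  writeBin(227L, con, size = 2L, endian = "little")            # header size
  writeBin(227L, con, size = 4L, endian = "little")            # offset to points
  writeBin(0L, con, size = 4L, endian = "little")              # n VLRs
  writeBin(as.raw(fmt), con)
  writeBin(as.integer(reclen), con, size = 2L, endian = "little")
  writeBin(as.integer(n), con, size = 4L, endian = "little")
  writeBin(rep(0L, 5L), con, size = 4L, endian = "little")     # by return
  writeBin(rep(scale, 3L), con, size = 8L, endian = "little")
  writeBin(as.numeric(offs), con, size = 8L, endian = "little")
  rng <- if (n > 0) apply(cloud$coords, 2L, range) else matrix(0, 2L, 3L)
  writeBin(as.numeric(c(rng[2, 1], rng[1, 1], rng[2, 2], rng[1, 2],
                        rng[2, 3], rng[1, 3])), con, size = 8L, endian = "little")
  if (n == 0L) return(invisible(path))
  cls <- rep(1L, n)  # unclassified
  if (!is.null(cloud$labels)) {
    cls[cloud$labels == 1L] <- 2L  # ground
    cls[cloud$labels == 2L] <- 4L  # medium vegetation
  }
  ixyz <- round(sweep(cloud$coords, 2L, offs) / scale)
  if (any(abs(ixyz) > 2^31 - 1)) stop("coordinates exceed LAS integer range")
  rec <- raw(n * reclen)
  put <- function(bytes, off, width) {
    idx <- rep.int(off + seq_len(width), n) + rep((seq_len(n) - 1L) * reclen, each = width)
    rec[idx] <<- bytes
  }
  put(writeBin(as.integer(ixyz[, 1]), raw(), size = 4L, endian = "little"), 0L, 4L)
  put(writeBin(as.integer(ixyz[, 2]), raw(), size = 4L, endian = "little"), 4L, 4L)
  put(writeBin(as.integer(ixyz[, 3]), raw(), size = 4L, endian = "little"), 8L, 4L)
  put(writeBin(rep(0L, n), raw(), size = 2L, endian = "little"), 12L, 2L)  # intensity
  put(as.raw(rep(9L, n)), 14L, 1L)  # return 1 of 1
  put(as.raw(cls), 15L, 1L)
  put(as.raw(rep(0L, n)), 16L, 1L)  # scan angle
  put(as.raw(rep(0L, n)), 17L, 1L)  # user data
  put(writeBin(rep(0L, n), raw(), size = 2L, endian = "little"), 18L, 2L)
  if (has_rgb) {
    v <- round(cloud$rgb * 257)
    put(writeBin(as.integer(v[, 1]), raw(), size = 2L, endian = "little"), 20L, 2L)
    put(writeBin(as.integer(v[, 2]), raw(), size = 2L, endian = "little"), 22L, 2L)
    put(writeBin(as.integer(v[, 3]), raw(), size = 2L, endian = "little"), 24L, 2L)
  }
  writeBin(rec, con)
  invisible(path)
}

.read_xyz <- function(path) {
  if (file.size(path) == 0L) return(point_cloud(matrix(numeric(0), ncol = 3)))
  tab <- utils::read.table(path, header = FALSE)
  if (ncol(tab) < 3L) stop("XYZ file needs at least 3 columns: ", path)
  rgb <- if (ncol(tab) >= 6L) as.matrix(tab[, 4:6]) else NULL
  point_cloud(as.matrix(tab[, 1:3]), rgb = rgb)
}

.write_xyz <- function(cloud, path) {
  m <- cloud$coords
  if (!is.null(cloud$rgb)) m <- cbind(m, round(cloud$rgb))
  rows <- apply(m, 1L, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(rows, path)
  invisible(path)
}

#' Read a point cloud from PLY, LAS or ASCII XYZ
#'
#' Format is taken from `format_hint` when given, otherwise from the file
#' extension, otherwise sniffed from the leading magic bytes. Coordinates are
#' returned in meters. LAS classification code 2 (ground) maps to label 1 and
#' code 4 (medium vegetation, the code this package writes for vegetation) to
#' label 2; all other codes map to unlabeled.
#'
#' @param path file path.
#' @param format_hint one of `"ply"`, `"las"`, `"xyz"`, or `NULL` to infer.
#' @return a [point_cloud()]. An empty file yields a cloud with zero points.
#' @export
read_point_cloud <- function(path, format_hint = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0L) return(point_cloud(matrix(numeric(0), ncol = 3)))
  fmt <- format_hint
  if (is.null(fmt)) {
    ext <- tolower(tools::file_ext(path))
    fmt <- switch(ext, ply = "ply", las = "las", laz = "laz",
                  xyz = "xyz", txt = "xyz", asc = "xyz", NULL)
  }
  if (is.null(fmt)) {
    head4 <- readBin(path, "raw", 4L)
    lead <- rawToChar(head4[head4 != as.raw(0)])
    fmt <- if (startsWith(lead, "ply")) "ply"
           else if (identical(lead, "LASF")) "las" else "xyz"
  }
  if (identical(fmt, "laz"))
    stop("LAZ (compressed LAS) is not supported; decompress to LAS first")
  switch(fmt,
         ply = .read_ply(path),
         las = .read_las(path),
         xyz = .read_xyz(path),
         stop("unknown point-cloud format: ", fmt))
}

#' Write a point cloud to PLY, LAS or ASCII XYZ
#'
#' @param cloud a [point_cloud()].
#' @param path output path; format from extension unless `format` is given.
#' @param format `"ply"`, `"las"` or `"xyz"`.
#' @param binary for PLY: write `binary_little_endian` (default) or ascii.
#' @return the path, invisibly.
#' @export
write_point_cloud <- function(cloud, path, format = NULL, binary = TRUE) {
  stopifnot(inherits(cloud, "point_cloud"))
  if (is.null(format)) {
    format <- switch(tolower(tools::file_ext(path)),
                     ply = "ply", las = "las", xyz = "xyz", txt = "xyz",
                     stop("cannot infer output format from path: ", path))
  }
  switch(format,
         ply = .write_ply(cloud, path, binary = binary),
         las = .write_las(cloud, path),
         xyz = .write_xyz(cloud, path),
         stop("unknown point-cloud format: ", format))
}

#' Read a per-plot biomass table
#'
#' Expects a CSV with header `plot_id,annual_g,perennial_g,forb_g,litter_g`
#' (dry weights in grams). Derived columns `vegetation_total_g`
#' (annual + perennial + forb) and `total_g` (vegetation + litter) are added.
#'
#' @param path CSV path.
#' @return a data.frame, one row per plot.
#' @export
read_biomass_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("plot_id", "annual_g", "perennial_g", "forb_g", "litter_g")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("biomass table lacks columns: ", paste(miss, collapse = ", "))
  comp <- c("annual_g", "perennial_g", "forb_g", "litter_g")
  if (anyNA(tab[comp]))
    stop("biomass table has missing component weights (rows: ",
         paste(which(!complete.cases(tab[comp])), collapse = ", "), ")")
  if (any(as.matrix(tab[comp]) < 0))
    stop("biomass weights must be non-negative")
  if (anyDuplicated(tab$plot_id))
    stop("duplicate plot_id in biomass table: ",
         paste(unique(tab$plot_id[duplicated(tab$plot_id)]), collapse = ", "))
  tab$vegetation_total_g <- tab$annual_g + tab$perennial_g + tab$forb_g
  tab$total_g <- tab$vegetation_total_g + tab$litter_g
  tab
}

#' @rdname read_biomass_table
#' @param tab a biomass data.frame as returned by [read_biomass_table()].
#' @export
write_biomass_table <- function(tab, path) {
  utils::write.csv(tab[c("plot_id", "annual_g", "perennial_g", "forb_g",
                         "litter_g")], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
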