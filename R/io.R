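# File IO: NIfTI-1 volumes (minimal reader/writer -- no NIfTI package is
# assumed), PNG/PGM photographs, versioned chain files, FLIRT matrices.

# ---- NIfTI-1 ---------------------------------------------------------------

NIFTI_TYPES <- list(`2` = list(what = "integer", size = 1, signed = FALSE),
                    `4` = list(what = "integer", size = 2, signed = TRUE),
                    `8` = list(what = "integer", size = 4, signed = TRUE),
                    `16` = list(what = "double", size = 4, signed = TRUE),
                    `64` = list(what = "double", size = 8, signed = TRUE))

#' Read / write NIfTI-1 volumes
#'
#' A deliberately minimal NIfTI-1 implementation (no NIfTI package is
#' available in the target environment): uncompressed single-file `.nii`,
#' data types uint8/int16/int32/float32/float64, sform affine (written with
#' `sform_code = 1`; qform ignored on read, falling back to a pixdim
#' diagonal when no sform is present). Data and affine round-trip to
#' `1e-6`.
#'
#' @param path file path (`.nii`).
#' @return [load_volume()] returns a *volume handle*: list with `data` (3D
#'   array), `affine` (4x4 voxel-to-mm), `pixdim`.
#' @export
load_volume <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 348)
  sizeof <- readBin(hdr[1:4], "integer", 1, 4)
  endian <- "little"
  if (sizeof != 348L) {
    sizeof <- readBin(hdr[1:4], "integer", 1, 4, endian = "big")
    if (sizeof != 348L) stop("not a NIfTI-1 file: ", path)
    endian <- "big"
  }
  rint <- function(off, n, size = 2)
    readBin(hdr[(off + 1):(off + n * size)], "integer", n, size,
            endian = endian)
  rflt <- function(off, n)
    readBin(hdr[(off + 1):(off + n * 4)], "double", n, 4, endian = endian)
  dim0 <- rint(40, 8)
  ndim <- dim0[1]
  if (ndim < 3) stop("expected a 3D volume")
  shape <- dim0[2:4]
  datatype <- rint(70, 1)
  pixdim <- rflt(76, 8)[2:4]
  vox_offset <- rflt(108, 1)
  scl_slope <- rflt(112, 1)
  scl_inter <- rflt(116, 1)
  sform_code <- rint(254, 1)
  srow <- matrix(rflt(280, 12), 3, 4, byrow = TRUE)
  tinfo <- NIFTI_TYPES[[as.character(datatype)]]
  if (is.null(tinfo)) stop("unsupported NIfTI datatype: ", datatype)
  seek(con, where = vox_offset, origin = "start")
  n <- prod(shape)
  data <- readBin(con, tinfo$what, n, size = tinfo$size,
                  signed = tinfo$signed, endian = endian)
  if (scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    data <- data * scl_slope + scl_inter
  affine <- if (sform_code > 0) rbind(srow, c(0, 0, 0, 1)) else
    diag(c(pixdim, 1))
  structure(list(data = array(as.double(data), shape), affine = affine,
                 pixdim = pixdim), class = "hs_volume")
}

#' @rdname load_volume
#' @param volume a volume handle, a 3D [tensor_image()], or a 3D array (the
#'   latter needs `affine`).
#' @param affine 4x4 voxel-to-mm matrix (required for bare arrays).
#' @param datatype `"float64"` (default) or `"float32"`.
#' @export
save_volume <- function(volume, path, affine = NULL,
                        datatype = c("float64", "float32")) {
  datatype <- match.arg(datatype)
  if (inherits(volume, "hs_volume")) {
    data <- volume$data; affine <- volume$affine
  } else if (inherits(volume, "hs_image")) {
    data <- volume$data
    affine <- rbind(cbind(diag(volume$resolution), volume$domain$origin),
                    c(0, 0, 0, 1))
  } else {
    data <- as.array(volume)
    if (is.null(affine)) stop("affine required when saving a bare array")
  }
  stopifnot(length(dim(data)) == 3)
  shape <- dim(data)
  pixdim <- sqrt(colSums(affine[1:3, 1:3]^2))
  code <- if (datatype == "float64") 64L else 16L
  size <- if (datatype == "float64") 8L else 4L
  hdr <- raw(348)
  put <- function(off, x, what, sz) {
    b <- writeBin(x, raw(), size = sz, endian = "little")
    hdr[(off + 1):(off + length(b))] <<- b
  }
  put(0, 348L, "integer", 4)
  put(40, as.integer(c(3, shape, 1, 1, 1, 1)), "integer", 2)
  put(70, code, "integer", 2)
  put(72, as.integer(8 * size), "integer", 2)
  put(76, c(1, pixdim, 1, 1, 1, 1), "double", 4)
  put(108, 352, "double", 4)        # vox_offset
  put(112, 1, "double", 4)          # scl_slope
  put(116, 0, "double", 4)          # scl_inter
  put(252, 1L, "integer", 2)        # qform_code (unused but valid)
  put(254, 1L, "integer", 2)        # sform_code
  put(280, as.double(t(affine[1:3, ])), "double", 4)
  hdr[345:348] <- as.raw(c(0x6e, 0x2b, 0x31, 0x00))   # "n+1"
  tmp <- paste0(path, ".tmp")
  con <- file(tmp, "wb")
  writeBin(hdr, con)
  writeBin(raw(4), con)             # extension flag
  writeBin(as.double(data), con, size = size, endian = "little")
  close(con)
  file.rename(tmp, path)
  invisible(path)
}

#' Convert a volume handle to a tensor image
#'
#' The axis-aligned scaling part of the affine becomes the internal chain;
#' any rotational part plus the offset go into the external chain, so grid
#' index to world mm mapping reproduces the affine exactly.
#' @param volume a volume handle from [load_volume()].
#' @export
volume_image <- function(volume) {
  A <- volume$affine
  sp <- sqrt(colSums(A[1:3, 1:3]^2))
  R <- A[1:3, 1:3] %*% diag(1 / sp)
  ext <- if (max(abs(R - diag(3))) < 1e-9 && max(abs(A[1:3, 4])) < 1e-12)
    transform_chain() else transform_chain(affine3d(R, A[1:3, 4]))
  tensor_image(volume$data, sp, origin = c(0, 0, 0), external = ext)
}

# ---- photographs -----------------------------------------------------------

LUMA <- c(0.2126, 0.7152, 0.0722)   # Rec. 709

#' Read / write 2D photographs
#'
#' PNG (via the \pkg{png} package) and plain PGM (P2/P5) are supported.
#' Pixel (0,0) is the top-left corner of the file; the first array axis is
#' the image x (column) direction, the second axis y (row, increasing
#' downward). RGB images are converted to grayscale with Rec. 709 luma
#' weights when `grayscale = TRUE`. A mm/pixel resolution is mandatory.
#'
#' @param path image file (`.png`, `.pgm`).
#' @param mm_per_pixel resolution of the photograph (mm).
#' @param grayscale collapse RGB to luma.
#' @return a [tensor_image()] with values in `[0, 1]`.
#' @export
load_photo <- function(path, mm_per_pixel = NULL, grayscale = TRUE) {
  if (is.null(mm_per_pixel))
    stop("photo resolution is required: supply mm_per_pixel")
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    a <- png::readPNG(path)
    if (length(dim(a)) == 3) {
      if (grayscale) {
        nch <- min(dim(a)[3], 3)
        w <- LUMA[1:nch] / sum(LUMA[1:nch])
        a <- Reduce(`+`, lapply(seq_len(nch), function(c) a[, , c] * w[c]))
      } else a <- a[, , 1]
    }
    data <- t(a)                     # file rows -> second axis
  } else if (ext == "pgm") {
    data <- read_pgm(path)
  } else {
    stop("unsupported photo format: .", ext,
         " (PNG and PGM are supported)")
  }
  tensor_image(data, mm_per_pixel)
}

#' @rdname load_photo
#' @param image a 2D [tensor_image()] or matrix (values clipped to [0, 1]
#'   for PNG).
#' @export
save_photo <- function(image, path) {
  data <- if (inherits(image, "hs_image")) image$data else as.matrix(image)
  ext <- tolower(tools::file_ext(path))
  tmp <- paste0(path, ".tmp")
  if (ext == "png") {
    png::writePNG(t(pmin(pmax(data, 0), 1)), tmp)
  } else if (ext == "pgm") {
    write_pgm(data, tmp)
  } else stop("unsupported photo format: .", ext)
  file.rename(tmp, path)
  invisible(path)
}

read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  token <- function() {
    repeat {
      ch <- readChar(con, 1, useBytes = TRUE)
      if (!length(ch)) stop("truncated PGM")
      if (ch == "#") repeat {
        ch <- readChar(con, 1, useBytes = TRUE)
        if (ch == "\n") break
      }
      if (!grepl("^\\s$", ch)) break
    }
    out <- ch
    repeat {
      ch <- readChar(con, 1, useBytes = TRUE)
      if (!length(ch) || grepl("^\\s$", ch)) break
      out <- paste0(out, ch)
    }
    out
  }
  magic <- token()
  w <- as.integer(token()); h <- as.integer(token())
  mx <- as.integer(token())
  if (magic == "P2") {
    vals <- scan(con, what = integer(), n = w * h, quiet = TRUE)
  } else if (magic == "P5") {
    vals <- as.integer(readBin(con, "raw", w * h))
  } else stop("not a PGM file")
  matrix(vals / mx, w, h)            # column-major: x fastest, matches t()
}

write_pgm <- function(data, path) {
  v <- round(pmin(pmax(data, 0), 1) * 255)
  con <- file(path, "wb")
  writeChar(sprintf("P2\n%d %d\n255\n", nrow(data), ncol(data)), con,
            eos = NULL)
  writeLines(apply(matrix(as.integer(v), nrow(data)), 2,
                   paste, collapse = " "), con)
  close(con)
}

# ---- chain serialisation ---------------------------------------------------

CHAIN_FORMAT <- "histoslice-chain/1"

num_out <- function(x) sprintf("%.17g", as.numeric(x))   # bit-exact decimal
num_in <- function(s) as.numeric(s)

tf_to_list <- function(tf) {
  base <- list(type = tf$type)
  extra <- switch(tf$type,
    rotation2d = list(angle = num_out(tf$angle), centre = num_out(tf$centre)),
    isotropic_scale = list(factor = num_out(tf$factor)),
    translation = list(offset = num_out(tf$offset)),
    affine2d = list(A = num_out(tf$A), b = num_out(tf$b)),
    affine3d = list(A = num_out(tf$A), b = num_out(tf$b)),
    rotation3d = list(angles = num_out(tf$angles), centre = num_out(tf$centre)),
    embed_2d_3d = list(),
    project_3d_2d = list(),
    dense_field = list(dim = dim(tf$u), u = num_out(tf$u),
                       spacing = num_out(tf$spacing),
                       origin = num_out(tf$origin),
                       ref_chain = if (is.null(tf$ref_chain)) NULL else
                         lapply(tf$ref_chain$members, tf_to_list)),
    cp_field = list(points = num_out(tf$points), k = nrow(tf$points),
                    disp = num_out(tf$disp), sigma = num_out(tf$sigma),
                    components = tf$components),
    dense_map23 = list(dim = dim(tf$targets), targets = num_out(tf$targets),
                       spacing = num_out(tf$spacing),
                       origin = num_out(tf$origin)),
    stop("cannot serialise transformation type: ", tf$type))
  c(base, extra)
}

tf_from_list <- function(l) {
  switch(l$type,
    rotation2d = rotation2d(num_in(l$angle), num_in(l$centre)),
    isotropic_scale = isotropic_scale(num_in(l$factor)),
    translation = translation(num_in(l$offset)),
    affine2d = affine2d(matrix(num_in(l$A), 2, 2), num_in(l$b)),
    affine3d = affine3d(matrix(num_in(l$A), 3, 3), num_in(l$b)),
    rotation3d = rotation3d(num_in(l$angles), num_in(l$centre)),
    embed_2d_3d = embed_2d_3d(),
    project_3d_2d = project_3d_2d(),
    dense_field = dense_displacement_field(
      array(num_in(l$u), unlist(l$dim)), num_in(l$spacing), num_in(l$origin),
      ref_chain = if (is.null(l$ref_chain)) NULL else
        do.call(transform_chain, lapply(l$ref_chain, tf_from_list))),
    cp_field = control_point_field(matrix(num_in(l$points), l$k),
                                   matrix(num_in(l$disp), l$k),
                                   num_in(l$sigma), l$components),
    dense_map23 = dense_map_2d3d(array(num_in(l$targets), unlist(l$dim)),
                                 num_in(l$spacing), num_in(l$origin)),
    stop("unknown transformation type in chain file: ", l$type))
}

#' Save / load transformation chains
#'
#' Chains are stored as versioned JSON with every numeric parameter encoded
#' as a 17-significant-digit decimal string, which round-trips IEEE doubles
#' bit-exactly. Unknown format versions and truncated/corrupt files are
#' rejected with distinct errors.
#'
#' @param chain a [transform_chain()] (a bare transformation is wrapped).
#' @param path file path.
#' @export
save_chain <- function(chain, path) {
  if (inherits(chain, "hs_transformation")) chain <- transform_chain(chain)
  stopifnot(inherits(chain, "hs_chain"))
  doc <- list(format = CHAIN_FORMAT,
              members = lapply(chain$members, tf_to_list))
  tmp <- paste0(path, ".tmp")
  jsonlite::write_json(doc, tmp, auto_unbox = TRUE, null = "null",
                       digits = NA)
  file.rename(tmp, path)
  invisible(path)
}

#' @rdname save_chain
#' @export
load_chain <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path),
                  error = function(e)
                    stop("corrupt or unreadable chain file: ",
                         conditionMessage(e), call. = FALSE))
  if (is.null(doc$format) || !identical(doc$format, CHAIN_FORMAT))
    stop("unsupported chain file version: ",
         if (is.null(doc$format)) "<missing>" else doc$format)
  do.call(transform_chain, lapply(doc$members, tf_from_list))
}

# ---- FLIRT matrices --------------------------------------------------------

flirt_space <- function(vol) {
  # voxel -> FLIRT mm: scaling by voxel size, with an x-flip for
  # neurological (positive-determinant) orientations
  pd <- sqrt(colSums(vol$affine[1:3, 1:3]^2))
  S <- diag(c(pd, 1))
  if (det(vol$affine[1:3, 1:3]) > 0) {
    nx <- dim(vol$data)[1]
    S[1, 1] <- -pd[1]
    S[1, 4] <- (nx - 1) * pd[1]
  }
  S
}

#' Import a FLIRT matrix as a physical-space affine
#'
#' FLIRT matrices act between the tool's internal mm spaces (voxel
#' coordinates scaled by voxel size, x-flipped for neurological-handed
#' volumes). Given the source and target volume geometries the matrix is
#' converted to an affine between the volumes' physical (world) mm spaces,
#' suitable for appending to a transformation chain.
#'
#' @param matrix_path path to the 4x4 whitespace text matrix, or a 4x4
#'   matrix.
#' @param source,target volume handles ([load_volume()]).
#' @return an [affine3d()] transformation (full 4x4 in attribute
#'   `"matrix"`).
#' @export
import_flirt <- function(matrix_path, source, target) {
  M <- if (is.matrix(matrix_path)) matrix_path else
    as.matrix(utils::read.table(matrix_path))
  dimnames(M) <- NULL
  stopifnot(all(dim(M) == c(4, 4)))
  if (abs(det(M[1:3, 1:3])) < 1e-12) stop("FLIRT matrix is not invertible")
  W <- target$affine %*% solve(flirt_space(target)) %*% M %*%
    flirt_space(source) %*% solve(source$affine)
  out <- affine3d(W[1:3, 1:3], W[1:3, 4])
  attr(out, "matrix") <- W
  out
}

#' @rdname import_flirt
#' @param tf an [affine3d()] produced by [import_flirt()].
#' @export
export_flirt <- function(tf, source, target, path = NULL) {
  W <- rbind(cbind(tf$A, tf$b), c(0, 0, 0, 1))
  M <- flirt_space(target) %*% solve(target$affine) %*% W %*%
    source$affine %*% solve(flirt_space(source))
  if (!is.null(path)) {
    utils::write.table(format(M, digits = 17), path, row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
    invisible(path)
  } else M
}
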