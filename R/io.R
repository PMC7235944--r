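#' Read a 3D volume
#'
#' Supported formats: multi-page TIFF or a directory of single-slice TIFFs
#' (`tiff_stack`), MetaImage header + raw (`mhd`) and NIfTI (`nifti`,
#' `.nii`/`.nii.gz`). The in-memory axis order is always `[z, y, x]`
#' regardless of format. Voxel spacing is taken from file metadata where the
#' format carries it (MHD, NIfTI); TIFF stacks carry none, so `voxel_size`
#' is required there. The morphometry assumes isotropic voxels: anisotropic
#' metadata spacing is an error unless `voxel_size` overrides it.
#'
#' On-disk 8-bit masks use 0/255; on reading, values strictly greater than
#' half the maximum on-disk value map to foreground 1, which guards against
#' lossy intermediate formats.
#'
#' @param path File (or, for TIFF, optionally a directory of slices).
#' @param format One of `"auto"`, `"tiff_stack"`, `"mhd"`, `"nifti"`.
#' @param voxel_size Optional isotropic voxel size in mm, overriding (or,
#'   for TIFF, supplying) the metadata spacing.
#' @return A `voxel_image`.
#' @export
read_volume <- function(path, format = c("auto", "tiff_stack", "mhd", "nifti"),
                        voxel_size = NULL) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  img <- switch(format,
    tiff_stack = read_tiff_stack(path, voxel_size),
    mhd = read_mhd(path, voxel_size),
    nifti = read_nifti_volume(path, voxel_size),
    stop("unknown format: ", format))
  img
}

#' Write a 3D volume
#'
#' Binary images are written as 8-bit 0/255; other images as 32-bit float
#' (TIFF, values must lie in `[0, 1]`) or 64-bit float (MHD, NIfTI). MHD raw
#' data is stored x-fastest.
#'
#' @param img A `voxel_image`.
#' @param path Output file; format inferred from the extension unless given.
#' @param format One of `"auto"`, `"tiff_stack"`, `"mhd"`, `"nifti"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(img, path,
                         format = c("auto", "tiff_stack", "mhd", "nifti")) {
  if (!inherits(img, "voxel_image")) stop("expected a voxel_image")
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  switch(format,
    tiff_stack = write_tiff_stack(img, path),
    mhd = write_mhd(img, path),
    nifti = write_nifti_volume(img, path),
    stop("unknown format: ", format))
  invisible(path)
}

guess_format <- function(path) {
  if (dir.exists(path)) return("tiff_stack")
  low <- tolower(path)
  if (grepl("\\.(tif|tiff)$", low)) return("tiff_stack")
  if (grepl("\\.mhd$", low)) return("mhd")
  if (grepl("\\.nii(\\.gz)?$", low)) return("nifti")
  stop("cannot infer volume format from '", path, "'")
}

check_isotropic <- function(spacing, voxel_size, path) {
  if (!is.null(voxel_size)) return(voxel_size)
  rng <- range(spacing)
  if (diff(rng) > 1e-9 * max(rng))
    stop(sprintf(
      "unsupported geometry: anisotropic voxels (%s) in '%s'; %s",
      paste(format(spacing), collapse = " x "), path,
      "resample first or pass `voxel_size` to override"))
  spacing[1]
}

# values > half the on-disk foreground value -> 1
binarize_mask <- function(a) {
  mx <- max(a)
  if (mx == 0) return(array(0L, dim = dim(a)))
  array(as.integer(a > mx / 2), dim = dim(a))
}

looks_binary <- function(a) {
  u <- unique(as.vector(a))
  length(u) <= 2L && all(u %in% c(0, 1) | u %in% c(0, 255))
}

## ---- TIFF stack ----

read_tiff_stack <- function(path, voxel_size) {
  if (is.null(voxel_size))
    stop("TIFF carries no voxel spacing; pass `voxel_size` (mm)")
  slices <- if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(tif|tiff)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) == 0L) stop("no TIFF slices found in '", path, "'")
    lapply(files, function(f) tiff::readTIFF(f))
  } else {
    s <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(s)) s <- list(s)
    s
  }
  d <- dim(slices[[1]])
  a <- array(0, dim = c(length(slices), d[1], d[2]))
  for (z in seq_along(slices)) a[z, , ] <- slices[[z]]
  # readTIFF rescales 8-bit to [0,1]; a 0/255 mask arrives as 0/1
  if (looks_binary(a)) {
    voxel_image(binarize_mask(a), voxel_size, binary = TRUE)
  } else {
    voxel_image(a, voxel_size, binary = FALSE)
  }
}

write_tiff_stack <- function(img, path) {
  a <- img$data
  if (!img$is_binary && (min(a) < 0 || max(a) > 1))
    stop("grayscale TIFF output requires values in [0, 1]")
  slices <- lapply(seq_len(dim(a)[1]), function(z)
    matrix(as.numeric(a[z, , ]), nrow = dim(a)[2]))
  bits <- if (img$is_binary) 8L else 32L
  tiff::writeTIFF(slices, path, bits.per.sample = bits)
}

## ---- MetaImage (MHD + RAW) ----

read_mhd <- function(path, voxel_size) {
  lines <- readLines(path, warn = FALSE)
  kv <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^\\s*([A-Za-z]+)\\s*=\\s*(.*)$", ln))[[1]]
    if (length(m) == 3L) kv[[m[2]]] <- trimws(m[3])
  }
  need <- c("DimSize", "ElementType", "ElementDataFile")
  if (!all(need %in% names(kv)))
    stop("format error: '", path, "' is not a valid MHD header")
  dims_xyz <- as.integer(strsplit(kv$DimSize, "\\s+")[[1]])
  if (length(dims_xyz) != 3L) stop("only 3D MHD volumes are supported")
  spacing <- if (!is.null(kv$ElementSpacing))
    as.numeric(strsplit(kv$ElementSpacing, "\\s+")[[1]]) else c(1, 1, 1)
  h <- check_isotropic(spacing, voxel_size, path)
  raw_path <- file.path(dirname(path), kv$ElementDataFile)
  n <- prod(dims_xyz)
  con <- file(raw_path, "rb")
  on.exit(close(con))
  vals <- switch(kv$ElementType,
    MET_UCHAR = as.numeric(readBin(con, "integer", n = n, size = 1,
                                   signed = FALSE)),
    MET_SHORT = as.numeric(readBin(con, "integer", n = n, size = 2,
                                   signed = TRUE, endian = "little")),
    MET_FLOAT = readBin(con, "double", n = n, size = 4, endian = "little"),
    MET_DOUBLE = readBin(con, "double", n = n, size = 8, endian = "little"),
    stop("unsupported MHD ElementType: ", kv$ElementType))
  if (length(vals) != n) stop("format error: raw file '", raw_path,
                              "' shorter than DimSize promises")
  a_xyz <- array(vals, dim = dims_xyz)          # x fastest on disk
  a <- aperm(a_xyz, c(3, 2, 1))                 # -> (z, y, x)
  origin <- if (!is.null(kv$Offset))
    as.numeric(strsplit(kv$Offset, "\\s+")[[1]]) else c(0, 0, 0)
  if (kv$ElementType == "MET_UCHAR" && looks_binary(a))
    voxel_image(binarize_mask(a), h, binary = TRUE, origin = origin)
  else
    voxel_image(a, h, binary = FALSE, origin = origin)
}

write_mhd <- function(img, path) {
  d <- dim(img$data)                            # (z, y, x)
  raw_name <- paste0(tools::file_path_sans_ext(basename(path)), ".raw")
  etype <- if (img$is_binary) "MET_UCHAR" else "MET_DOUBLE"
  header <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    sprintf("DimSize = %d %d %d", d[3], d[2], d[1]),
    sprintf("ElementSpacing = %.12g %.12g %.12g", img$voxel_size,
            img$voxel_size, img$voxel_size),
    sprintf("Offset = %.12g %.12g %.12g", img$origin[1], img$origin[2],
            img$origin[3]),
    sprintf("ElementType = %s", etype),
    sprintf("ElementDataFile = %s", raw_name))
  writeLines(header, path)
  a_xyz <- aperm(img$data, c(3, 2, 1))          # x fastest on disk
  con <- file(file.path(dirname(path), raw_name), "wb")
  on.exit(close(con))
  if (img$is_binary)
    writeBin(as.raw(as.vector(a_xyz) * 255L), con)
  else
    writeBin(as.numeric(as.vector(a_xyz)), con, size = 8, endian = "little")
}

## ---- NIfTI ----

read_nifti_volume <- function(path, voxel_size) {
  nii <- RNifti::readNifti(path)
  a_xyz <- as.array(nii)
  if (length(dim(a_xyz)) != 3L) stop("only 3D NIfTI volumes are supported")
  pd <- RNifti::pixdim(nii)[1:3]
  h <- check_isotropic(pd, voxel_size, path)
  a <- aperm(a_xyz, c(3, 2, 1))
  if (looks_binary(a))
    voxel_image(binarize_mask(a), h, binary = TRUE)
  else
    voxel_image(a, h, binary = FALSE)
}

write_nifti_volume <- function(img, path) {
  a_xyz <- aperm(img$data, c(3, 2, 1))
  storage.mode(a_xyz) <- if (img$is_binary) "integer" else "double"
  nii <- RNifti::asNifti(a_xyz)
  RNifti::pixdim(nii) <- rep(img$voxel_size, 3)
  RNifti::writeNifti(nii, path)
}
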