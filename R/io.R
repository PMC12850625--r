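# Dataset container I/O.
#
# Single-file binary container ("mrsb", MRS binary) used for CSI datasets
# and field sets:
#
#   bytes 0-7   magic "MRSBIN01"
#   bytes 8-15  little-endian uint stored as double: JSON header byte length L
#   next L      UTF-8 JSON header: {kind, arrays: [{name, dims, complex}],
#               attrs: {...}}
#   payload     arrays in header order, float64 little-endian; complex arrays
#               interleaved (re, im) in column-major element order
#
# The layout is self-describing and lossless for double-precision data. The
# logical content of a CSI file mirrors /csi/data [Nx,Ny,Nz,Nch,Nfid],
# /csi/noise [Ns,Nch] plus the attrs nucleus, dwell_s, fov_mm, voxel_mm,
# f0_mhz, carrier_ppm, axes convention.

MRSB_MAGIC <- "MRSBIN01"

write_mrsb <- function(path, kind, arrays, attrs) {
  specs <- lapply(names(arrays), function(nm) {
    a <- arrays[[nm]]
    list(name = nm, dims = as.integer(dim(a) %||% length(a)),
         complex = is.complex(a))
  })
  header <- jsonlite::toJSON(list(kind = kind, arrays = specs, attrs = attrs),
                             auto_unbox = TRUE, digits = NA)
  raw_header <- charToRaw(as.character(header))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(MRSB_MAGIC), con)
  writeBin(as.numeric(length(raw_header)), con, size = 8, endian = "little")
  writeBin(raw_header, con)
  for (nm in names(arrays)) {
    a <- arrays[[nm]]
    v <- if (is.complex(a)) as.numeric(rbind(as.vector(Re(a)), as.vector(Im(a))))
         else as.numeric(a)
    writeBin(v, con, size = 8, endian = "little")
  }
  invisible(path)
}

read_mrsb <- function(path, expect_kind = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", n = 8))
  if (!identical(magic, MRSB_MAGIC)) stop("not an mrsicoil container: ", path)
  hlen <- readBin(con, "numeric", n = 1, size = 8, endian = "little")
  header <- jsonlite::fromJSON(rawToChar(readBin(con, "raw", n = hlen)),
                               simplifyDataFrame = FALSE)
  if (!is.null(expect_kind) && !identical(header$kind, expect_kind))
    stop("container holds '", header$kind, "', expected '", expect_kind, "'")
  arrays <- list()
  for (sp in header$arrays) {
    dims <- as.integer(unlist(sp$dims))
    nel <- prod(dims)
    if (isTRUE(sp$complex)) {
      v <- readBin(con, "numeric", n = 2 * nel, size = 8, endian = "little")
      a <- complex(real = v[seq(1, length(v), 2)],
                   imaginary = v[seq(2, length(v), 2)])
    } else {
      a <- readBin(con, "numeric", n = nel, size = 8, endian = "little")
    }
    if (length(dims) > 1L) dim(a) <- dims
    arrays[[sp$name]] <- a
  }
  list(kind = header$kind, arrays = arrays, attrs = header$attrs)
}

need_attr <- function(attrs, name, numeric = FALSE) {
  if (is.null(attrs[[name]])) stop("container lacks required attribute '",
                                   name, "'")
  v <- attrs[[name]]
  if (numeric) as.double(unlist(v)) else v    # JSON may narrow to integer
}

#' Read and write CSI datasets
#'
#' Lossless round trip of a [csi_dataset()] through the package's
#' single-file binary container (see the header of `io.R` for the byte-level
#' layout). Complex data are stored as interleaved float64 pairs; all
#' acquisition attributes travel with the arrays and missing required
#' attributes raise an error naming the attribute.
#'
#' @param ds a [csi_dataset()].
#' @param path file path.
#' @return `read_csi` returns a [csi_dataset()]; `write_csi` the path,
#'   invisibly.
#' @export
write_csi <- function(ds, path) {
  stopifnot(inherits(ds, "csi_dataset"))
  arrays <- list(`csi/data` = ds$data)
  if (!is.null(ds$noise_scan)) arrays$`csi/noise` <- ds$noise_scan
  attrs <- list(nucleus = ds$nucleus, dwell_s = ds$dwell, fov_mm = ds$fov_mm,
                voxel_mm = ds$voxel_mm, f0_mhz = ds$f0_mhz,
                carrier_ppm = ds$carrier_ppm,
                axes = "frequency increases with spectral index; carrier at floor(n/2)+1")
  write_mrsb(path, "csi", arrays, attrs)
}

#' @rdname write_csi
#' @export
read_csi <- function(path) {
  x <- read_mrsb(path, "csi")
  if (is.null(x$arrays$`csi/data`)) stop("container lacks /csi/data")
  at <- x$attrs
  csi_dataset(x$arrays$`csi/data`,
              voxel_mm = need_attr(at, "voxel_mm", numeric = TRUE),
              fov_mm = need_attr(at, "fov_mm", numeric = TRUE),
              nucleus = need_attr(at, "nucleus"),
              dwell = need_attr(at, "dwell_s", numeric = TRUE),
              noise_scan = x$arrays$`csi/noise`,
              f0_mhz = need_attr(at, "f0_mhz", numeric = TRUE),
              carrier_ppm = need_attr(at, "carrier_ppm", numeric = TRUE))
}

#' Read and write field sets
#'
#' Same container as [write_csi()] with layout `fields/e`
#' `[Nch,Nx,Ny,Nz,3]`, `fields/b1m` `[Nch,Nx,Ny,Nz]`, `fields/sigma`
#' `[Nx,Ny,Nz]` and attributes `frequency_hz`, `voxel_m3`.
#'
#' @param fs a [field_set()].
#' @param path file path.
#' @export
write_field_set <- function(fs, path) {
  stopifnot(inherits(fs, "field_set"))
  write_mrsb(path, "fields",
             list(`fields/e` = fs$e_fields, `fields/b1m` = fs$b1_minus,
                  `fields/sigma` = fs$conductivity),
             list(frequency_hz = fs$frequency, voxel_m3 = fs$voxel_volume))
}

#' @rdname write_field_set
#' @export
read_field_set <- function(path) {
  x <- read_mrsb(path, "fields")
  for (nm in c("fields/e", "fields/b1m", "fields/sigma"))
    if (is.null(x$arrays[[nm]])) stop("container lacks /", nm)
  field_set(x$arrays$`fields/e`, x$arrays$`fields/b1m`,
            x$arrays$`fields/sigma`,
            voxel_volume = need_attr(x$attrs, "voxel_m3", numeric = TRUE),
            frequency = need_attr(x$attrs, "frequency_hz", numeric = TRUE))
}

#' Serialize a spectral model to and from JSON
#'
#' @param model a [spectral_model()].
#' @param path file path.
#' @export
write_spectral_model <- function(model, path) {
  stopifnot(inherits(model, "spectral_model"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_spectral_model
#' @export
read_spectral_model <- function(path) {
  x <- jsonlite::fromJSON(path)
  spectral_model(as.data.frame(x$resonances), n_points = x$n_points,
                 bandwidth = x$bandwidth, carrier_ppm = x$carrier_ppm,
                 f0_mhz = x$f0_mhz)
}

#' Write a scalar 3D map as NIfTI-1
#'
#' For SNR and SNR-ratio maps; voxel size is carried into the NIfTI header.
#'
#' @param map real 3D array.
#' @param voxel_mm length-3 voxel size in mm.
#' @param path output path (`.nii` or `.nii.gz`).
#' @export
write_map_nifti <- function(map, voxel_mm, path) {
  img <- RNifti::asNifti(map)
  RNifti::pixdim(img) <- voxel_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}
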