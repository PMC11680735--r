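#' Read an image volume from NIfTI or DICOM
#'
#' Reads a NIfTI file (`.nii`/`.nii.gz`) or a DICOM series (a directory of
#' slice files, or a single file). Voxel spacing is taken from the header.
#' DICOM slices are ordered by ImagePositionPatient projected on the slice
#' normal, falling back to InstanceNumber. The reader never reorients or
#' resamples; a 4th NIfTI dimension (e.g. b-values) is preserved.
#'
#' @param path file or directory path.
#' @param format_hint optional `"nifti"` or `"dicom"`; inferred from the path
#'   when omitted.
#' @param plane acquisition plane recorded on the returned volume.
#' @return an [image_volume].
#' @export
read_image_volume <- function(path, format_hint = NULL, plane = "coronal") {
  if (!file.exists(path)) stop("no such file or directory: ", path)
  fmt <- format_hint %||%
    (if (dir.exists(path) || grepl("\\.dcm$", path, ignore.case = TRUE)) "dicom"
     else "nifti")
  switch(match.arg(fmt, c("nifti", "dicom")),
         nifti = read_nifti_volume(path, plane),
         dicom = read_dicom_series(path, plane))
}

read_nifti_volume <- function(path, plane) {
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("unreadable NIfTI header in ", path,
                                           ": ", conditionMessage(e)))
  arr <- array(as.numeric(img), dim(img))
  if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
  sp <- RNifti::pixdim(img)[1:3]
  image_volume(arr, spacing = sp, plane = plane,
               meta = list(source = path, format = "nifti"))
}

#' Write an image volume to NIfTI
#'
#' Real volumes are written as a single NIfTI file with the spacing in the
#' header pixdim. Complex volumes are written as a magnitude/phase pair with
#' `_mag` and `_ph` suffixes (phase in radians), the most portable convention.
#'
#' @param vol an [image_volume].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return invisibly, the path(s) written.
#' @export
write_image_volume <- function(vol, path) {
  stopifnot(inherits(vol, "image_volume"))
  if (!dir.exists(dirname(path))) stop("parent directory does not exist: ",
                                       dirname(path))
  write1 <- function(arr, p) {
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- vol$spacing
    RNifti::writeNifti(img, p)
    p
  }
  if (vol$is_complex || is.complex(vol$data)) {
    stem <- sub("\\.nii(\\.gz)?$", "", path)
    ext <- if (grepl("\\.nii\\.gz$", path)) ".nii.gz" else ".nii"
    paths <- c(write1(Mod(vol$data), paste0(stem, "_mag", ext)),
               write1(Arg(vol$data), paste0(stem, "_ph", ext)))
    return(invisible(paths))
  }
  invisible(write1(vol$data, path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- minimal DICOM support ---------------------------------------------------
# No DICOM reader ships with this R installation, so the few tags the pipeline
# needs are parsed directly: explicit-VR little-endian, uncompressed pixel data.

dicom_read_element <- function(con) {
  grp <- readBin(con, "integer", 1, size = 2, signed = FALSE, endian = "little")
  if (length(grp) == 0) return(NULL)
  ele <- readBin(con, "integer", 1, size = 2, signed = FALSE, endian = "little")
  vr <- rawToChar(readBin(con, "raw", 2))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    readBin(con, "raw", 2)  # reserved
    len <- readBin(con, "integer", 1, size = 4, endian = "little")
  } else {
    len <- readBin(con, "integer", 1, size = 2, signed = FALSE, endian = "little")
  }
  list(tag = sprintf("%04x,%04x", grp, ele), vr = vr, len = len)
}

read_dicom_file <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  pre <- readBin(con, "raw", 132)
  if (length(pre) < 132 || rawToChar(pre[129:132]) != "DICM")
    stop("not a DICOM file (missing DICM magic): ", path)
  out <- list()
  repeat {
    el <- dicom_read_element(con)
    if (is.null(el)) break
    val <- switch(el$vr,
      US = readBin(con, "integer", el$len / 2, size = 2, signed = FALSE,
                   endian = "little"),
      UL = readBin(con, "integer", el$len / 4, size = 4, endian = "little"),
      OW = , OB = readBin(con, "raw", el$len),
      {
        raw <- readBin(con, "raw", el$len)
        trimws(rawToChar(raw))
      })
    out[[el$tag]] <- val
    if (el$tag == "7fe0,0010") break
  }
  out
}

parse_ds <- function(x) as.numeric(strsplit(x %||% "", "\\\\")[[1]])

read_dicom_series <- function(path, plane) {
  files <- if (dir.exists(path))
    list.files(path, full.names = TRUE, pattern = "\\.dcm$", ignore.case = TRUE)
  else path
  if (length(files) == 0) stop("no DICOM files found in ", path)
  slices <- lapply(files, read_dicom_file)
  uids <- vapply(slices, function(s) s[["0020,000e"]] %||% "", "")
  if (length(unique(uids[nzchar(uids)])) > 1)
    stop("mixed DICOM series in directory (multiple SeriesInstanceUID): ", path)
  s1 <- slices[[1]]
  nr <- s1[["0028,0010"]]; nc <- s1[["0028,0011"]]
  bits <- s1[["0028,0100"]] %||% 16L
  if (is.null(nr) || is.null(nc)) stop("corrupt DICOM header (no Rows/Columns): ",
                                       files[1])
  # order by position projected on the slice normal; fallback InstanceNumber
  ord <- order(vapply(slices, function(s) {
    ipp <- parse_ds(s[["0020,0032"]])
    iop <- parse_ds(s[["0020,0037"]])
    if (length(ipp) == 3 && length(iop) == 6) {
      n <- c(iop[2] * iop[6] - iop[3] * iop[5],
             iop[3] * iop[4] - iop[1] * iop[6],
             iop[1] * iop[5] - iop[2] * iop[4])
      sum(ipp * n)
    } else as.numeric(s[["0020,0013"]] %||% NA)
  }, 0))
  slices <- slices[ord]
  arr <- array(0, c(nc, nr, length(slices)))
  for (k in seq_along(slices)) {
    px <- slices[[k]][["7fe0,0010"]]
    if (is.null(px)) stop("DICOM file without pixel data: ", files[ord[k]])
    v <- readBin(px, "integer", length(px) / (bits / 8), size = bits / 8,
                 signed = FALSE, endian = "little")
    slope <- as.numeric(slices[[k]][["0028,1053"]] %||% "1")
    inter <- as.numeric(slices[[k]][["0028,1052"]] %||% "0")
    arr[, , k] <- matrix(v * slope + inter, nrow = nc, ncol = nr)
  }
  ps <- parse_ds(s1[["0028,0030"]])
  dz <- as.numeric(s1[["0018,0088"]] %||% s1[["0018,0050"]] %||% "1")
  sp <- c(if (length(ps) == 2) rev(ps) else c(1, 1), dz)
  image_volume(arr, spacing = sp, plane = plane,
               meta = list(source = path, format = "dicom",
                           n_slices = length(slices)))
}

# fixture generator for tests only: one explicit-VR LE slice, 16-bit pixels
write_dicom_slice <- function(path, pixels, instance_number, series_uid = "1.2.3",
                              pixel_spacing = c(1, 1), slice_thickness = 1,
                              position = c(0, 0, instance_number)) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con); writeChar("DICM", con, eos = NULL)
  put <- function(grp, ele, vr, value) {
    writeBin(as.integer(c(grp, ele)), con, size = 2, endian = "little")
    writeChar(vr, con, eos = NULL)
    if (vr %in% c("OB", "OW")) {
      writeBin(raw(2), con)
      writeBin(as.integer(length(value)), con, size = 4, endian = "little")
      writeBin(value, con)
    } else if (vr == "US") {
      writeBin(2L, con, size = 2, endian = "little")
      writeBin(as.integer(value), con, size = 2, endian = "little")
    } else {
      s <- as.character(value)
      if (nchar(s) %% 2 == 1) s <- paste0(s, " ")
      writeBin(nchar(s), con, size = 2, endian = "little")
      writeChar(s, con, eos = NULL)
    }
  }
  put(0x0020, 0x000e, "UI", series_uid)
  put(0x0020, 0x0013, "IS", as.character(instance_number))
  put(0x0020, 0x0032, "DS", paste(position, collapse = "\\"))
  put(0x0020, 0x0037, "DS", "1\\0\\0\\0\\1\\0")
  put(0x0028, 0x0010, "US", nrow(pixels))
  put(0x0028, 0x0011, "US", ncol(pixels))
  put(0x0028, 0x0030, "DS", paste(pixel_spacing, collapse = "\\"))
  put(0x0018, 0x0050, "DS", as.character(slice_thickness))
  put(0x0028, 0x0100, "US", 16L)
  px <- writeBin(as.integer(round(t(pixels))), raw(), size = 2, endian = "little")
  put(0x7fe0, 0x0010, "OW", px)
  invisible(path)
}

# ---- MRD-style HDF5 raw container -------------------------------------------
# Flat dialect defined by this package's phantom writer:
#   /header/{kind,dwell_s,tr_ms,te_ms,prescribed_flip_deg,center_freq_hz}
#   /acquisitions/{data_real,data_imag,ppm_offset[,traj]}

#' Read a raw acquisition from an MRD-style HDF5 container
#'
#' @param path HDF5 file written by [write_raw_mrd()] (or a registered plugin
#'   reader via [read_raw()]).
#' @return a [raw_acquisition]; FID trains come back in acquisition order with
#'   gas/dissolved excitations tagged by their `ppm_offset`.
#' @export
read_raw_mrd <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ls <- tryCatch(rhdf5::h5ls(path, recursive = TRUE),
                 error = function(e) stop("unreadable HDF5 container: ", path))
  have <- paste0(ls$group, "/", ls$name)
  need <- c("/header/kind", "/header/dwell_s", "/acquisitions/data_real",
            "/acquisitions/data_imag", "/acquisitions/ppm_offset")
  missing <- setdiff(need, have)
  if (length(missing))
    stop("unsupported raw-data dialect; missing keys: ",
         paste(missing, collapse = ", "))
  g <- function(k, default = NA_real_) {
    if (k %in% have) rhdf5::h5read(path, k) else default
  }
  re <- g("/acquisitions/data_real"); im <- g("/acquisitions/data_imag")
  if (length(re) == 0) stop("empty raw container: ", path)
  samples <- matrix(complex(real = re, imaginary = im), nrow = nrow(re))
  traj <- if ("/acquisitions/traj" %in% have) g("/acquisitions/traj") else NULL
  raw_acquisition(kind = as.character(g("/header/kind")), samples = samples,
                  trajectory = traj, dwell_s = as.numeric(g("/header/dwell_s")),
                  tr_ms = as.numeric(g("/header/tr_ms")),
                  te_ms = as.numeric(g("/header/te_ms")),
                  prescribed_flip_deg = as.numeric(g("/header/prescribed_flip_deg")),
                  center_freq_hz = as.numeric(g("/header/center_freq_hz")),
                  ppm_offset = as.numeric(g("/acquisitions/ppm_offset")))
}

#' Write a raw acquisition to an MRD-style HDF5 container
#'
#' @param raw a [raw_acquisition].
#' @param path output `.h5` path.
#' @return invisibly, `path`.
#' @export
write_raw_mrd <- function(raw, path) {
  stopifnot(inherits(raw, "raw_acquisition"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5createGroup(path, "header")
  rhdf5::h5createGroup(path, "acquisitions")
  w <- function(k, v) rhdf5::h5write(v, path, k)
  w("/header/kind", raw$kind)
  w("/header/dwell_s", raw$dwell_s)
  w("/header/tr_ms", raw$tr_ms)
  w("/header/te_ms", raw$te_ms)
  w("/header/prescribed_flip_deg", raw$prescribed_flip_deg)
  w("/header/center_freq_hz", raw$center_freq_hz)
  w("/acquisitions/data_real", Re(raw$samples))
  w("/acquisitions/data_imag", Im(raw$samples))
  w("/acquisitions/ppm_offset", raw$ppm_offset)
  if (!is.null(raw$trajectory)) w("/acquisitions/traj", raw$trajectory)
  rhdf5::h5closeAll()
  invisible(path)
}

# ---- vendor-format plugin registry ------------------------------------------

.raw_readers <- new.env(parent = emptyenv())

#' Register a raw-data reader plugin
#'
#' Vendor-proprietary raw formats are not parsed by this package; instead a
#' callable returning a [raw_acquisition] can be registered against a file
#' extension and is dispatched by [read_raw()].
#'
#' @param extension file extension without dot, e.g. `"dat"`.
#' @param reader function of one argument (the path) returning a
#'   [raw_acquisition].
#' @export
register_raw_reader <- function(extension, reader) {
  stopifnot(is.function(reader))
  assign(tolower(extension), reader, envir = .raw_readers)
  invisible(NULL)
}

#' Read raw data, dispatching on extension
#'
#' `.h5`/`.mrd` go through [read_raw_mrd()]; other extensions require a
#' registered plugin.
#' @param path input file.
#' @return a [raw_acquisition].
#' @export
read_raw <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("h5", "mrd", "hdf5")) return(read_raw_mrd(path))
  if (exists(ext, envir = .raw_readers))
    return(get(ext, envir = .raw_readers)(path))
  stop("no reader registered for extension '.", ext,
       "'; see register_raw_reader()")
}

# ---- metrics export ---------------------------------------------------------

#' Export a result bundle to disk
#'
#' Writes one machine-readable `metrics.json` (sorted keys, so re-export of
#' the same bundle is byte-identical), flat CSV tables for per-bin
#' percentages, and every map in the bundle as NIfTI.
#'
#' @param bundle a result object from any analysis stage (or a bare list).
#' @param out_dir output directory, created if needed.
#' @return data frame manifest of written files with md5 checksums.
#' @export
export_metrics <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(out_dir, 2) != 0) stop("output directory not writable: ", out_dir)
  scal <- list(); tabs <- list(); maps <- list()
  walk <- function(x, prefix = character()) {
    for (nm in names(x)) {
      v <- x[[nm]]; key <- paste(c(prefix, nm), collapse = ".")
      if (inherits(v, "bin_map")) {
        tabs[[key]] <<- data.frame(bin = v$bin_names,
                                   percentage = as.numeric(v$percentages))
        maps[[paste0(key, "_labels")]] <<- v$labels
        scal[[paste0(key, ".edges")]] <<- v$bin_edges
      } else if (inherits(v, "image_volume")) {
        maps[[key]] <<- v$data
      } else if (is.array(v) && length(dim(v)) >= 3) {
        maps[[key]] <<- v
      } else if (is.data.frame(v)) {
        tabs[[key]] <<- v
      } else if (is.list(v)) {
        walk(v, c(prefix, nm))
      } else if (is.numeric(v) || is.character(v) || is.logical(v)) {
        scal[[key]] <<- v
      }
    }
  }
  if (length(bundle)) walk(unclass(bundle))
  if (length(scal)) scal <- scal[order(names(scal))]
  json_path <- file.path(out_dir, "metrics.json")
  jsonlite::write_json(scal, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files <- json_path
  for (nm in names(tabs)) {
    p <- file.path(out_dir, paste0(gsub("[^A-Za-z0-9_.]", "_", nm), ".csv"))
    utils::write.csv(tabs[[nm]], p, row.names = FALSE)
    files <- c(files, p)
  }
  for (nm in names(maps)) {
    p <- file.path(out_dir, paste0(gsub("[^A-Za-z0-9_.]", "_", nm), ".nii.gz"))
    arr <- maps[[nm]]
    if (is.complex(arr)) arr <- Mod(arr)
    img <- RNifti::asNifti(arr)
    RNifti::writeNifti(img, p)
    files <- c(files, p)
  }
  data.frame(file = files, md5 = as.character(tools::md5sum(files)),
             row.names = NULL)
}
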