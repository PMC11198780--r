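#' Read and write 3D volumes (NIfTI / NRRD)
#'
#' `read_volume()` loads a `.nii`, `.nii.gz`, or `.nrrd` file into a
#' [volume()], populating spacing, origin, and direction from the header.
#' `write_volume()` performs the inverse; round trips are lossless for
#' double-precision data. Only strictly 3D images are accepted.
#'
#' NIfTI files go through the RNifti codec (the sform/qform affine supplies
#' the world frame). NRRD support covers the common subset this package
#' itself writes: attached raw or gzip encodings, little-endian,
#' float/double types, `space directions` / `space origin` fields.
#'
#' @param path file path; format chosen by extension.
#' @param vol a [volume()].
#' @return `read_volume()` returns a [volume()]; `write_volume()` returns
#'   `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".nii.gz")
#' write_volume(volume(array(1, c(4, 4, 4))), f)
#' read_volume(f)
#' @export
read_volume <- function(path) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.nrrd$", path, ignore.case = TRUE))
    return(read_nrrd(path))
  if (!grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE))
    stop("unsupported volume format (expected .nii, .nii.gz or .nrrd): ",
         path, call. = FALSE)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("non-3D image (", length(d), " dimensions): ", path, call. = FALSE)
  xf <- RNifti::xform(img)
  lin <- xf[1:3, 1:3]
  spacing <- sqrt(colSums(lin^2))
  volume(array(as.numeric(img), d), spacing = spacing,
         origin = xf[1:3, 4], direction = sweep(lin, 2, spacing, "/"))
}

#' @rdname read_volume
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "ceph_volume"))
  if (grepl("\\.nrrd$", path, ignore.case = TRUE))
    return(write_nrrd(vol, path))
  if (!grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE))
    stop("unsupported volume format (expected .nii, .nii.gz or .nrrd): ",
         path, call. = FALSE)
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$spacing  # before sform: sform<- keeps scales
  xf <- rbind(cbind(vol$direction %*% diag(vol$spacing), vol$origin),
              c(0, 0, 0, 1))
  img <- RNifti::`sform<-`(img, structure(xf, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

# --- minimal NRRD codec (no NRRD package exists in this R stack) ----------

parse_nrrd_vectors <- function(s) {
  m <- gregexpr("\\(([^)]*)\\)", s)[[1]]
  vecs <- regmatches(s, list(m))[[1]]
  lapply(vecs, function(v)
    as.numeric(strsplit(gsub("[()]", "", v), ",")[[1]]))
}

read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!grepl("^NRRD", magic))
    stop("not an NRRD file: ", path, call. = FALSE)
  fields <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L)
      stop("NRRD header ended without data section: ", path, call. = FALSE)
    if (line == "") break
    if (grepl("^#", line)) next
    kv <- regmatches(line, regexec("^([^:]+): *(.*)$", line))[[1]]
    if (length(kv) == 3L) fields[[trimws(kv[2])]] <- kv[3]
  }
  ndim <- as.integer(fields[["dimension"]])
  if (is.na(ndim) || ndim != 3L)
    stop("non-3D image (dimension ", fields[["dimension"]], "): ", path,
         call. = FALSE)
  sizes <- as.integer(strsplit(trimws(fields[["sizes"]]), "\\s+")[[1]])
  type <- tolower(fields[["type"]])
  size_b <- switch(type, "double" = 8L, "float" = 4L,
                   stop("unsupported NRRD type: ", type, call. = FALSE))
  enc <- tolower(fields[["encoding"]])
  n <- prod(sizes)
  payload <- readBin(con, "raw", n = file.info(path)$size)
  if (enc %in% c("gzip", "gz")) {
    payload <- memDecompress(payload, type = "gzip")
  } else if (enc != "raw") {
    stop("unsupported NRRD encoding: ", enc, call. = FALSE)
  }
  vals <- readBin(payload, "double", n = n, size = size_b,
                  endian = "little")
  spacing <- rep(1, 3); direction <- diag(3); origin <- c(0, 0, 0)
  if (!is.null(fields[["space directions"]])) {
    cols <- parse_nrrd_vectors(fields[["space directions"]])
    lin <- do.call(cbind, cols)
    spacing <- sqrt(colSums(lin^2))
    direction <- sweep(lin, 2, spacing, "/")
  }
  if (!is.null(fields[["space origin"]]))
    origin <- parse_nrrd_vectors(fields[["space origin"]])[[1]]
  volume(array(vals, sizes), spacing = spacing, origin = origin,
         direction = direction)
}

write_nrrd <- function(vol, path) {
  lin <- vol$direction %*% diag(vol$spacing)
  vecstr <- function(v) sprintf("(%s)", paste(format(v, digits = 17),
                                              collapse = ","))
  hdr <- c("NRRD0004",
           "# written by cephmark",
           "type: double",
           "dimension: 3",
           "space dimension: 3",
           paste("sizes:", paste(dim(vol$data), collapse = " ")),
           paste("space directions:", vecstr(lin[, 1]), vecstr(lin[, 2]),
                 vecstr(lin[, 3])),
           paste("space origin:", vecstr(vol$origin)),
           "endian: little",
           "encoding: gzip",
           "")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  raw <- writeBin(as.numeric(vol$data), raw(), size = 8L, endian = "little")
  writeBin(memCompress(raw, type = "gzip"), con)
  invisible(path)
}

#' Read and write landmark coordinate tables
#'
#' Landmark files always store world coordinates in mm (never voxel
#' indices), so annotations survive resampling. Two dialects are supported:
#' CSV with header `id,x,y,z` where absent landmarks are simply missing
#' rows, and JSON `{"id": [x, y, z] | null}` where absence is an explicit
#' null.
#'
#' @param path file path (`.csv` or `.json`).
#' @param schema schema name or id vector the file must conform to; unknown
#'   or duplicate ids are a parse error (with the offending row named).
#' @param set a [landmark_set()].
#' @param digits decimal places written to CSV (at least 3 for sub-micron mm
#'   fidelity; default 6).
#' @return `read_landmarks()` returns a [landmark_set()].
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write_landmarks(landmark_set(list(N = c(0, 85, 30)), "toy8"), f)
#' read_landmarks(f, schema = "toy8")
#' @export
read_landmarks <- function(path, schema = "clinical46") {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  ids <- schema_ids(schema)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    lst <- jsonlite::read_json(path, simplifyVector = FALSE)
    coords <- lapply(lst, function(v) if (is.null(v)) NULL else
      as.numeric(unlist(v)))
    names(coords) <- names(lst)
    bad <- setdiff(names(coords), ids)
    if (length(bad))
      stop("unknown landmark id(s) in ", path, ": ",
           paste(bad, collapse = ", "), call. = FALSE)
    if (anyDuplicated(names(coords)))
      stop("duplicate landmark id(s) in ", path, call. = FALSE)
    return(landmark_set(coords, schema = schema))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("id", "x", "y", "z") %in% names(df)))
    stop("landmark CSV must have columns id,x,y,z: ", path, call. = FALSE)
  dup <- which(duplicated(df$id))
  if (length(dup))
    stop("duplicate landmark id '", df$id[dup[1]], "' at row ", dup[1] + 1L,
         " of ", path, call. = FALSE)
  bad <- which(!df$id %in% ids)
  if (length(bad))
    stop("unknown landmark id '", df$id[bad[1]], "' at row ", bad[1] + 1L,
         " of ", path, call. = FALSE)
  nonnum <- which(!is.finite(df$x) | !is.finite(df$y) | !is.finite(df$z))
  if (length(nonnum))
    stop("malformed coordinates at row ", nonnum[1] + 1L, " of ", path,
         call. = FALSE)
  m <- as.matrix(df[, c("x", "y", "z")])
  rownames(m) <- df$id
  landmark_set(m, schema = schema)
}

#' @rdname read_landmarks
#' @export
write_landmarks <- function(set, path, digits = 6) {
  stopifnot(inherits(set, "landmark_set"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    lst <- lapply(rownames(set$coords), function(id) {
      v <- lm_coord(set, id)
      if (is.null(v)) NULL else round(unname(v), digits)
    })
    names(lst) <- rownames(set$coords)
    jsonlite::write_json(lst, path, null = "null", digits = NA,
                         auto_unbox = FALSE)
    return(invisible(path))
  }
  pres <- present_ids(set)
  df <- data.frame(id = pres,
                   x = round(set$coords[pres, 1], digits),
                   y = round(set$coords[pres, 2], digits),
                   z = round(set$coords[pres, 3], digits))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
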