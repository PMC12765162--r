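#' Write an encoded series as NIfTI + JSON sidecar
#'
#' Serializes the 4D encoded acquisition as a NIfTI-1 volume (x, y, z,
#' volume) with echoes fastest-varying, then encoding rows, and a JSON
#' sidecar recording the protocol (`HadamardOrder`, `PLDs_ms`,
#' `SubBolusDurations_ms`, `EchoTimes_ms`, `NoiseSD`, `Seed`).
#'
#' @param e An `encoded_series`.
#' @param dims Spatial grid (3 integers) whose product equals the voxel
#'   axis length of `e$data`.
#' @param prefix Output path prefix; writes `<prefix>.nii.gz` and
#'   `<prefix>.json`.
#' @return Invisibly, the two paths written.
#' @export
write_encoded_series <- function(e, dims, prefix) {
  dims <- as.integer(dims)
  nv <- prod(dims)
  d <- e$data
  if (dim(d)[3] != nv) stop("dims do not match the voxel axis")
  n_row <- dim(d)[1]; n_te <- dim(d)[2]
  # volume index = (row - 1) * n_te + te  (TE fastest)
  vol <- array(0, dim = c(dims, n_row * n_te))
  for (i in seq_len(n_row)) for (j in seq_len(n_te)) {
    vol[, , , (i - 1) * n_te + j] <- array(d[i, j, ], dim = dims)
  }
  nii_path <- paste0(prefix, ".nii.gz")
  json_path <- paste0(prefix, ".json")
  RNifti::writeNifti(vol, nii_path)
  side <- list(HadamardOrder = e$protocol$had_order,
               PLDs_ms = e$protocol$plds,
               SubBolusDurations_ms = rep(e$protocol$sbd,
                                          e$protocol$had_order - 1),
               EchoTimes_ms = e$protocol$tes,
               NoiseSD = e$noise_sd,
               Seed = if (is.null(e$seed)) NA else e$seed)
  jsonlite::write_json(side, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(nii_path, json_path))
}

#' Read an encoded series written by [write_encoded_series()]
#'
#' @param prefix Path prefix used at write time.
#' @return An `encoded_series` (data restored to row x TE x voxel order)
#'   plus a `dims` field with the spatial grid.
#' @export
read_encoded_series <- function(prefix) {
  nii_path <- paste0(prefix, ".nii.gz")
  json_path <- paste0(prefix, ".json")
  side <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  required <- c("HadamardOrder", "PLDs_ms", "SubBolusDurations_ms",
                "EchoTimes_ms")
  missing <- setdiff(required, names(side))
  if (length(missing))
    stop("sidecar ", json_path, " is missing required field(s): ",
         paste(missing, collapse = ", "))
  vol <- as.array(RNifti::readNifti(nii_path))
  dims <- dim(vol)[1:3]
  n_row <- side$HadamardOrder
  n_te <- length(side$EchoTimes_ms)
  if (dim(vol)[4] != n_row * n_te)
    stop("volume count does not match HadamardOrder x EchoTimes")
  nv <- prod(dims)
  d <- array(0, dim = c(n_row, n_te, nv))
  for (i in seq_len(n_row)) for (j in seq_len(n_te)) {
    d[i, j, ] <- as.vector(vol[, , , (i - 1) * n_te + j])
  }
  protocol <- asl_protocol(
    name = paste0("HAD", n_row), had_order = n_row,
    plds = side$PLDs_ms, sbd = side$SubBolusDurations_ms[1],
    tes = side$EchoTimes_ms)
  structure(list(data = d, baseline = NULL, protocol = protocol,
                 noise_sd = side$NoiseSD,
                 seed = if (is.null(side$Seed) || is.na(side$Seed)) NULL
                        else side$Seed,
                 dims = dims),
            class = "encoded_series")
}

#' Write a decoded series as NIfTI + JSON sidecar
#'
#' Serializes the per-sub-bolus difference signals as a 4D NIfTI volume
#' (echoes fastest, then sub-boluses) with a sidecar recording
#' `SubBolusPLDs_ms` alongside the protocol fields.
#'
#' @param d A `decoded_series`.
#' @param dims Spatial grid (3 integers).
#' @param prefix Output path prefix.
#' @return Invisibly, the two paths written.
#' @export
write_decoded_series <- function(d, dims, prefix) {
  dims <- as.integer(dims)
  nv <- prod(dims)
  if (dim(d$dm)[3] != nv) stop("dims do not match the voxel axis")
  n_sb <- dim(d$dm)[1]; n_te <- dim(d$dm)[2]
  vol <- array(0, dim = c(dims, n_sb * n_te))
  for (i in seq_len(n_sb)) for (j in seq_len(n_te)) {
    vol[, , , (i - 1) * n_te + j] <- array(d$dm[i, j, ], dim = dims)
  }
  nii_path <- paste0(prefix, ".nii.gz")
  json_path <- paste0(prefix, ".json")
  RNifti::writeNifti(vol, nii_path)
  side <- list(HadamardOrder = d$protocol$had_order,
               SubBolusPLDs_ms = d$protocol$plds,
               SubBolusDurations_ms = rep(d$protocol$sbd,
                                          d$protocol$had_order - 1),
               EchoTimes_ms = d$protocol$tes)
  jsonlite::write_json(side, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(nii_path, json_path))
}

#' Write fitted parameter maps as NIfTI files + TSV summary
#'
#' Writes `<prefix>_CBF.nii.gz`, `<prefix>_ATT.nii.gz`,
#' `<prefix>_Tex.nii.gz` plus `<prefix>_fit.tsv` summarizing convergence
#' and residuals.
#'
#' @param pmap A `parameter_map` from [fit_volume()].
#' @param prefix Output path prefix.
#' @return Invisibly, the paths written.
#' @export
write_parameter_map <- function(pmap, prefix) {
  paths <- c(CBF = paste0(prefix, "_CBF.nii.gz"),
             ATT = paste0(prefix, "_ATT.nii.gz"),
             Tex = paste0(prefix, "_Tex.nii.gz"))
  RNifti::writeNifti(pmap$cbf_map, paths["CBF"])
  RNifti::writeNifti(pmap$att_map, paths["ATT"])
  RNifti::writeNifti(pmap$tex_map, paths["Tex"])
  summ <- data.frame(
    n_mask = sum(pmap$gm_mask),
    n_converged = sum(pmap$converged_mask),
    median_rss = stats::median(pmap$rss_map[pmap$gm_mask], na.rm = TRUE))
  tsv <- paste0(prefix, "_fit.tsv")
  write_tsv(summ, tsv)
  invisible(c(paths, fit = tsv))
}

#' Tab-separated table I/O
#'
#' UTF-8, tab-separated, header row, no quoting surprises; the read side
#' keeps strings as character so factor levels are re-imposed by the
#' statistics layer.
#'
#' @param x Data frame.
#' @param path File path.
#' @return `write_tsv` returns the path invisibly; `read_tsv` the data
#'   frame.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, colClasses = NA,
                    na.strings = "NA", fileEncoding = "UTF-8",
                    check.names = FALSE)
}
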