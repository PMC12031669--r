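# List-mode and image I/O.
#
# List-mode files are plain CSV. Images and sinograms are stored as flat
# little-endian float32 binaries with a JSON sidecar (<file>.json) recording
# shape, spacing and role, so any tool can read them back.

#' Write / read list-mode triples
#'
#' CSV with columns `lor_index` (0-based on disk), `tof_bin`, `tau_ns` and
#' optional `truth_class`.
#'
#' @param events Data.frame with `lor`, `tof_bin`, `tau` (1-based `lor`).
#' @param path Output file.
#' @return `write_triples` returns `path` invisibly; `read_triples` the
#'   events data.frame (1-based `lor`).
#' @export
write_triples <- function(events, path) {
  out <- data.table::data.table(lor_index = events$lor - 1L,
                                tof_bin = events$tof_bin,
                                tau_ns = events$tau)
  if (!is.null(events$truth_class)) out$truth_class <- events$truth_class
  data.table::fwrite(out, path)
  invisible(path)
}

#' @rdname write_triples
#' @export
read_triples <- function(path) {
  dt <- data.table::fread(path)
  need <- c("lor_index", "tof_bin", "tau_ns")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop("malformed triples file ", path, ": missing column(s) ",
         paste(miss, collapse = ", "))
  ev <- data.frame(lor = dt$lor_index + 1L, tof_bin = dt$tof_bin,
                   tau = dt$tau_ns)
  if ("truth_class" %in% names(dt)) ev$truth_class <- dt$truth_class
  ev
}

#' Write / read a singles stream
#'
#' CSV with columns `time_ns`, `crystal`, `energy_keV`, `kind`, `decay_id`.
#'
#' @param singles Data.frame from [simulate_singles()].
#' @param path File path.
#' @return `write_singles` returns `path` invisibly; `read_singles` the
#'   singles data.frame.
#' @export
write_singles <- function(singles, path) {
  data.table::fwrite(data.table::data.table(
    time_ns = singles$time, crystal = singles$crystal,
    energy_keV = singles$energy, kind = singles$kind,
    decay_id = singles$decay_id), path)
  invisible(path)
}

#' @rdname write_singles
#' @export
read_singles <- function(path) {
  dt <- data.table::fread(path)
  need <- c("time_ns", "crystal", "energy_keV", "kind")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop("malformed singles file ", path, ": missing column(s) ",
         paste(miss, collapse = ", "))
  data.frame(time = dt$time_ns, crystal = dt$crystal,
             energy = dt$energy_keV, kind = dt$kind,
             decay_id = if ("decay_id" %in% names(dt)) dt$decay_id
                        else NA_integer_)
}

#' Write / read an image as flat float32 + JSON sidecar
#'
#' @param img An [image_grid()].
#' @param path Binary file path (sidecar written to `<path>.json`).
#' @return `write_image` returns `path` invisibly; `read_image` an
#'   [image_grid()].
#' @export
write_image <- function(img, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(img$values), con, size = 4L, endian = "little")
  jsonlite::write_json(list(shape = c(img$nx, img$ny),
                            spacing_mm = img$spacing, dtype = "float32",
                            role = img$role),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_image
#' @export
read_image <- function(path) {
  side <- paste0(path, ".json")
  if (!file.exists(side)) stop("missing image sidecar ", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  for (f in c("shape", "spacing_mm", "dtype"))
    if (is.null(meta[[f]]))
      stop("malformed image sidecar ", side, ": missing field '", f, "'")
  if (!identical(meta$dtype, "float32"))
    stop("malformed image sidecar ", side, ": unsupported dtype '",
         meta$dtype, "'")
  n <- prod(meta$shape)
  con <- file(path, "rb")
  on.exit(close(con))
  v <- readBin(con, numeric(), n = n, size = 4L, endian = "little")
  if (length(v) != n)
    stop("image file ", path, " shorter than sidecar shape ",
         paste(meta$shape, collapse = "x"))
  image_grid(meta$shape[1], meta$shape[2], meta$spacing_mm,
             matrix(v, meta$shape[1], meta$shape[2]),
             role = if (is.null(meta$role)) "image" else meta$role)
}

#' Write / read a TOF sinogram as flat float32 + JSON sidecar
#'
#' @param sino A [tof_sinogram()].
#' @param path Binary file path.
#' @param geom A [ring_geometry()] (for reading).
#' @return `write_sinogram` returns `path` invisibly; `read_sinogram` a
#'   [tof_sinogram()].
#' @export
write_sinogram <- function(sino, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(sino$values, con, size = 4L, endian = "little")
  jsonlite::write_json(list(n_lors = sino$n_lors,
                            n_tof_bins = sino$n_tof_bins, dtype = "float32",
                            role = sino$role),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_sinogram
#' @export
read_sinogram <- function(path, geom) {
  side <- paste0(path, ".json")
  if (!file.exists(side)) stop("missing sinogram sidecar ", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  if (is.null(meta$n_lors) || is.null(meta$n_tof_bins))
    stop("malformed sinogram sidecar ", side,
         ": missing n_lors / n_tof_bins")
  if (meta$n_lors != geom$n_lors || meta$n_tof_bins != geom$n_tof_bins)
    stop("sinogram ", path, " does not match the geometry (",
         meta$n_lors, "x", meta$n_tof_bins, " vs ", geom$n_lors, "x",
         geom$n_tof_bins, ")")
  con <- file(path, "rb")
  on.exit(close(con))
  v <- readBin(con, numeric(), n = meta$n_lors * meta$n_tof_bins,
               size = 4L, endian = "little")
  tof_sinogram(geom, v, role = if (is.null(meta$role)) "counts"
                               else meta$role)
}

#' Serialise / restore a decay model config block
#'
#' Config files carry lifetimes (ns), not rates; rates are recomputed.
#'
#' @param model A [decay_model()].
#' @return `decay_model_to_config`: a plain list `{labels, intensities,
#'   lifetimes_ns}`; `decay_model_from_config` the rebuilt [decay_model()].
#' @export
decay_model_to_config <- function(model) {
  list(labels = model$labels, intensities = model$intensities,
       lifetimes_ns = model$lifetimes)
}

#' @rdname decay_model_to_config
#' @param config A list as produced by `decay_model_to_config`.
#' @export
decay_model_from_config <- function(config) {
  decay_model(config$intensities, config$lifetimes_ns, config$labels)
}

#' Write a provenance record for a run
#'
#' @param path Output JSON path.
#' @param config Arbitrary serialisable configuration list.
#' @param seed Seed used.
#' @return `path`, invisibly.
#' @export
write_provenance <- function(path, config, seed = NULL) {
  jsonlite::write_json(list(
    package = "simplepli",
    version = as.character(utils::packageVersion("simplepli")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config_hash = sum(utf8ToInt(jsonlite::toJSON(config, auto_unbox = TRUE,
                                                 digits = NA))),
    config = config), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
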