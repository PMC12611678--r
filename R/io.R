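# On-disk formats: EDF recordings, the float32+JSON epoch store, graph
# serialization and model checkpoints.

.edf_pad <- function(x, width) {
  s <- formatC(as.character(x), width = -width)
  substr(s, 1, width)
}

#' Write a Recording to an EDF file
#'
#' Minimal EDF writer (16-bit, one-second data records), used mainly to build
#' test fixtures and small exports. The recording length must be a whole
#' number of seconds.
#'
#' @param rec a [recording()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  sig <- rec$signal
  C <- nrow(sig)
  if (ncol(sig) %% rec$fs != 0)
    stopf("EDF writer needs a whole number of 1-s records")
  n_rec <- ncol(sig) / rec$fs
  phys_max <- pmax(apply(abs(sig), 1, max), 1)
  phys_min <- -phys_max
  dig_max <- 32767L
  dig_min <- -32768L
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeChar(.edf_pad(x, width), con, nchars = width,
                                     eos = NULL)
  wr("0", 8)
  wr(rec$patient_id, 80)
  wr("spasmgraph export", 80)
  wr("01.01.24", 8)
  wr("00.00.00", 8)
  wr(256 * (C + 1), 8)
  wr("", 44)
  wr(n_rec, 8)
  wr("1", 8)
  wr(C, 4)
  for (ch in rec$channel_names) wr(ch, 16)
  for (i in seq_len(C)) wr("", 80)
  for (i in seq_len(C)) wr("uV", 8)
  for (i in seq_len(C)) wr(format(phys_min[i], digits = 6), 8)
  for (i in seq_len(C)) wr(format(phys_max[i], digits = 6), 8)
  for (i in seq_len(C)) wr(dig_min, 8)
  for (i in seq_len(C)) wr(dig_max, 8)
  for (i in seq_len(C)) wr("", 80)
  for (i in seq_len(C)) wr(rec$fs, 8)
  for (i in seq_len(C)) wr("", 32)
  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1) * rec$fs + 1):(r * rec$fs)
    for (i in seq_len(C)) {
      dig <- round((sig[i, cols] - phys_min[i]) / scale[i]) + dig_min
      writeBin(as.integer(dig), con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF/EDF+ recording
#'
#' Parses the EDF header and 16-bit data records, applies per-channel physical
#' scaling (values are returned in microvolts; millivolt channels are
#' converted) and normalizes channel labels (upper case, whitespace stripped,
#' montage aliases applied). Annotation signals are dropped. All retained
#' channels must share one sampling rate.
#'
#' @param path path to an EDF file.
#' @return a [recording()].
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stopf("cannot read EDF file: %s", path)
  sz <- file.info(path)$size
  if (sz < 256) stopf("cannot read EDF file (truncated header): %s", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8)                       # version
  patient_id <- rd(80)
  rd(80); rd(8); rd(8)
  header_bytes <- as.integer(rd(8))
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1 || sz < 256 * (ns + 1))
    stopf("cannot read EDF file (truncated signal headers): %s", path)
  fld <- function(width) vapply(seq_len(ns), function(i) rd(width), "")
  labels <- fld(16)
  fld(80)                     # transducer
  dims <- fld(8)
  phys_min <- as.numeric(fld(8))
  phys_max <- as.numeric(fld(8))
  dig_min <- as.numeric(fld(8))
  dig_max <- as.numeric(fld(8))
  fld(80)                     # prefiltering
  nsamp <- as.integer(fld(8))
  fld(32)
  keep <- !grepl("ANNOTATION", toupper(labels))
  if (!any(keep)) stopf("no signal channels in EDF file: %s", path)
  rec_bytes <- 2 * sum(nsamp)
  avail <- (sz - header_bytes) %/% rec_bytes
  if (is.na(n_rec) || n_rec < 0) n_rec <- avail
  if (avail < n_rec)
    stopf("cannot read EDF file (truncated data records): %s", path)
  if (length(unique(nsamp[keep])) != 1)
    stopf("unsupported EDF file: channels have differing sampling rates")
  fs <- nsamp[keep][1] / rec_dur
  Cn <- sum(keep)
  Tn <- n_rec * nsamp[keep][1]
  sig <- matrix(0, Cn, Tn)
  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  for (r in seq_len(n_rec)) {
    ci <- 0
    for (i in seq_len(ns)) {
      dig <- readBin(con, "integer", n = nsamp[i], size = 2, signed = TRUE,
                     endian = "little")
      if (length(dig) < nsamp[i])
        stopf("cannot read EDF file (truncated data records): %s", path)
      if (keep[i]) {
        ci <- ci + 1
        cols <- ((r - 1) * nsamp[i] + 1):(r * nsamp[i])
        sig[ci, cols] <- (dig - dig_min[i]) * scale[i] + phys_min[i]
      }
    }
  }
  unit <- toupper(dims[keep])
  sig[unit == "MV", ] <- sig[unit == "MV", , drop = FALSE] * 1000
  recording(sig, labels[keep], fs, patient_id)
}

#' Read an annotation CSV
#'
#' Expects columns `onset_s`, `duration_s`, `label`.
#'
#' @param path CSV file path.
#' @return annotation data frame.
#' @export
read_annotations_csv <- function(path) {
  ann <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("onset_s", "duration_s", "label")
  if (!all(req %in% names(ann)))
    stopf("annotation CSV needs columns: %s", paste(req, collapse = ", "))
  ann[, req]
}

#' Parse seizure intervals from a CHB-MIT-style summary text
#'
#' Extracts `Seizure ... Start Time: <n> seconds` / `End Time` pairs for one
#' recording file from a patient summary file.
#'
#' @param path summary text file.
#' @param file_name recording file name the intervals belong to (e.g.
#'   `"chb01_03.edf"`).
#' @return annotation data frame (`onset_s`, `duration_s`, `label`).
#' @export
read_chb_summary <- function(path, file_name) {
  lines <- readLines(path, warn = FALSE)
  fstart <- grep("^File Name:", lines)
  blk <- lines
  if (length(fstart)) {
    hit <- fstart[grepl(file_name, lines[fstart], fixed = TRUE)]
    if (!length(hit)) stopf("file %s not found in summary %s", file_name, path)
    to <- c(fstart[-1] - 1, length(lines))[match(hit, fstart)]
    blk <- lines[hit:to]
  }
  st <- as.numeric(sub(".*Start Time:\\s*(\\d+) sec.*", "\\1",
                       grep("Seizure.*Start Time", blk, value = TRUE)))
  en <- as.numeric(sub(".*End Time:\\s*(\\d+) sec.*", "\\1",
                       grep("Seizure.*End Time", blk, value = TRUE)))
  data.frame(onset_s = st, duration_s = en - st,
             label = rep("seizure", length(st)))
}

#' Persist an EpochSet to a directory
#'
#' Writes a raw little-endian float32 tensor (`epochs.bin`, column-major over
#' channels x samples x epochs) plus a JSON sidecar (`epochs.json`) carrying
#' all metadata. The layout is portable and language-agnostic.
#'
#' @param es an [epoch_set()].
#' @param dir output directory (created if needed).
#' @return path of the JSON manifest, invisibly.
#' @export
write_epochs <- function(es, dir) {
  if (!inherits(es, "EpochSet")) stopf("es must be an EpochSet")
  d <- dim(es$epochs)
  if (length(es$labels) != d[3])
    stopf("%d labels for %d epochs", length(es$labels), d[3])
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  bin <- file.path(dir, "epochs.bin")
  con <- file(bin, "wb")
  writeBin(as.numeric(es$epochs), con, size = 4, endian = "little")
  close(con)
  manifest <- file.path(dir, "epochs.json")
  meta <- list(n_epochs = d[3], n_channels = d[1], n_samples = d[2],
               fs = es$fs, epoch_length_s = es$epoch_length_s,
               channel_names = es$channel_names,
               labels = es$labels, patient_ids = es$patient_ids,
               dtype = "float32", byte_order = "little",
               layout = "column-major C x T x n_epochs")
  jsonlite::write_json(meta, manifest, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Read an EpochSet written by [write_epochs()]
#'
#' @param path directory or manifest path.
#' @return an `EpochSet`.
#' @export
read_epochs <- function(path) {
  manifest <- if (dir.exists(path)) file.path(path, "epochs.json") else path
  meta <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  bin <- file.path(dirname(manifest), "epochs.bin")
  n <- meta$n_channels * meta$n_samples * meta$n_epochs
  con <- file(bin, "rb")
  v <- readBin(con, "numeric", n = n, size = 4, endian = "little")
  close(con)
  if (length(v) != n) stopf("epoch store %s is truncated", bin)
  arr <- array(v, dim = c(meta$n_channels, meta$n_samples, meta$n_epochs))
  epoch_set(arr, meta$labels, meta$patient_ids, meta$fs, meta$channel_names,
            meta$epoch_length_s)
}

#' Serialize a ChannelGraph
#'
#' JSON header (`<prefix>.json`: channel names, modality, dimensions) plus a
#' float32 binary block (`<prefix>.bin`: edge-weight matrix then node
#' features, column-major).
#'
#' @param g a [channel_graph()].
#' @param prefix output path prefix (without extension).
#' @return the JSON path, invisibly.
#' @export
write_channel_graph <- function(g, prefix) {
  meta <- list(modality = g$modality, channel_names = g$channel_names,
               n_channels = nrow(g$weights), n_features = ncol(g$node_features),
               dtype = "float32", byte_order = "little")
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  con <- file(paste0(prefix, ".bin"), "wb")
  writeBin(c(as.numeric(g$weights), as.numeric(g$node_features)), con,
           size = 4, endian = "little")
  close(con)
  invisible(paste0(prefix, ".json"))
}

#' Read a ChannelGraph written by [write_channel_graph()]
#' @param prefix path prefix used at write time.
#' @return a `ChannelGraph`.
#' @export
read_channel_graph <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  C <- meta$n_channels
  Fd <- meta$n_features
  con <- file(paste0(prefix, ".bin"), "rb")
  v <- readBin(con, "numeric", n = C * C + C * Fd, size = 4, endian = "little")
  close(con)
  channel_graph(matrix(v[-(1:(C * C))], C, Fd),
                matrix(v[1:(C * C)], C, C),
                meta$modality, meta$channel_names, validate = FALSE)
}

# --- checkpoints ------------------------------------------------------------

# Flatten a nested list of numeric leaves into a named flat list
# ("a.b.c" path names), preserving dims.
flatten_leaves <- function(x, prefix = character()) {
  if (is.list(x)) {
    out <- list()
    for (nm in names(x))
      out <- c(out, flatten_leaves(x[[nm]], c(prefix, nm)))
    return(out)
  }
  stats::setNames(list(x), paste(prefix, collapse = "."))
}

# Rebuild a nested list from dotted leaf names.
unflatten_leaves <- function(leaves) {
  assign_path <- function(x, path, value) {
    if (length(path) == 1) {
      x[[path]] <- value
    } else {
      x[[path[1]]] <- assign_path(x[[path[1]]] %||% list(), path[-1], value)
    }
    x
  }
  out <- list()
  for (nm in names(leaves))
    out <- assign_path(out, strsplit(nm, ".", fixed = TRUE)[[1]], leaves[[nm]])
  out
}

#' Save a model checkpoint
#'
#' Flat map of named parameter tensors (float64 binary, bit-exact round trip)
#' plus a JSON header echoing the model configuration, region map and tensor
#' shapes.
#'
#' @param params model parameter list (see [init_model_params()]).
#' @param cfg the [model_config()] used.
#' @param path output path prefix (writes `<path>.json` and `<path>.bin`).
#' @param rmap optional region map (named channel -> region vector).
#' @return the JSON path, invisibly.
#' @export
save_checkpoint <- function(params, cfg, path, rmap = NULL) {
  leaves <- flatten_leaves(params)
  dims <- lapply(leaves, function(v) dim(v) %||% length(v))
  offs <- cumsum(c(0, vapply(leaves, length, 1L)))
  meta <- list(config = unclass(cfg), region_map = as.list(rmap),
               tensors = lapply(seq_along(leaves), function(i)
                 list(name = names(leaves)[i], dim = as.integer(dims[[i]]),
                      offset = offs[i])))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  con <- file(paste0(path, ".bin"), "wb")
  writeBin(unlist(lapply(leaves, as.numeric)), con, size = 8,
           endian = "little")
  close(con)
  invisible(paste0(path, ".json"))
}

#' Load a model checkpoint written by [save_checkpoint()]
#'
#' @param path path prefix used at save time.
#' @return list with `params`, `cfg` and `rmap`.
#' @export
load_checkpoint <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = FALSE)
  con <- file(paste0(path, ".bin"), "rb")
  total <- sum(vapply(meta$tensors, function(t) prod(unlist(t$dim)), 1))
  v <- readBin(con, "numeric", n = total, size = 8, endian = "little")
  close(con)
  leaves <- list()
  for (t in meta$tensors) {
    d <- unlist(t$dim)
    n <- prod(d)
    vals <- v[(t$offset + 1):(t$offset + n)]
    leaves[[t$name]] <- if (length(d) > 1) array(vals, dim = d) else vals
  }
  cfg <- lapply(meta$config, function(x) unlist(x))
  class(cfg) <- "model_config"
  rmap <- unlist(meta$region_map)
  list(params = unflatten_leaves(leaves), cfg = cfg,
       rmap = if (length(rmap)) rmap else NULL)
}
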