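# File interfaces: multi-page TIFF for frames and time lapses (with a JSON
# sidecar for metadata, intensity scale, and synthetic ground truth), TSV
# count tables, CSV toxicity plates and lane profiles.

#' Write frames as a multi-page TIFF with a JSON sidecar
#'
#' Pixel intensities (AU) are stored as 32-bit floats scaled into `[0, 1]`
#' by a common factor recorded in the sidecar, which also carries per-frame
#' metadata and, when present, the synthetic ground truth.
#'
#' @param frames A list of [frame()] objects (or a single frame).
#' @param path Output TIFF path; the sidecar is written at `<path>.json`.
#' @param scale Intensity scale (AU mapping to 1.0); defaults to the
#'   maximum pixel value across frames.
#'
#' @return `path`, invisibly.
#' @export
write_frames_tiff <- function(frames, path, scale = NULL) {
  if (inherits(frames, "fq_frame")) frames <- list(frames)
  if (is.null(scale))
    scale <- max(1e-12, vapply(frames, function(f) max(f$pixels), numeric(1)))
  tiff::writeTIFF(lapply(frames, function(f) f$pixels / scale), path,
                  bits.per.sample = 32L, reduce = FALSE)
  meta <- list(
    scale = scale,
    frames = lapply(frames, function(f) {
      gt <- attr(f, "ground_truth")
      m <- list(time_h = f$time_h, condition = f$condition,
                replicate = f$replicate, channel = f$channel)
      if (!is.null(gt)) m$ground_truth <- gt
      m
    }))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  invisible(path)
}

# Rebuild a data.frame from a JSON list of row objects.
rows_to_df <- function(rows, template = NULL) {
  if (length(rows) == 0L) return(template)
  do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
}

#' Read frames from a multi-page TIFF written by [write_frames_tiff()]
#'
#' @param path TIFF path (sidecar expected at `<path>.json`).
#' @return A list of [frame()] objects (ground truth re-attached when the
#'   sidecar carries it).
#' @export
read_frames_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar))
    jsonlite::read_json(sidecar, simplifyVector = FALSE) else NULL
  lapply(seq_along(pages), function(i) {
    m <- if (!is.null(meta)) meta$frames[[i]] else list()
    px <- pages[[i]] * if (!is.null(meta)) meta$scale else 1
    fr <- frame(px,
                time_h = if (!is.null(m$time_h)) m$time_h else NA_real_,
                condition = if (!is.null(m$condition)) m$condition else "none",
                replicate = if (!is.null(m$replicate)) m$replicate else 1L,
                channel = if (!is.null(m$channel)) m$channel else "RFP")
    if (!is.null(m$ground_truth)) {
      gt <- m$ground_truth
      gt$cells <- rows_to_df(gt$cells)
      if (!is.null(gt$foci))
        gt$foci <- rows_to_df(gt$foci,
                              template = data.frame(cell = integer(0),
                                                    row = numeric(0),
                                                    col = numeric(0)))
      attr(fr, "ground_truth") <- gt
    }
    fr
  })
}

#' Write / read a tRNA count table as TSV
#'
#' Columns: `transcript_id`, `family`, `mapping_class`, then one count
#' column per sample named `<condition>_<replicate>`.
#'
#' @param table A count table.
#' @param path TSV path.
#' @return `path` (write) or the count table (read).
#' @export
write_count_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_table
#' @export
read_count_table <- function(path) {
  out <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  attr(out, "samples") <- count_samples(out)
  out
}

#' Write / read a toxicity plate as CSV
#'
#' Columns: `condition`, `replicate`, `pre_lysis`, `post_lysis`.
#'
#' @param plate A toxicity plate `data.frame`.
#' @param path CSV path.
#' @return `path` (write) or the plate (read).
#' @export
write_toxicity_csv <- function(plate, path) {
  utils::write.csv(plate[, c("condition", "replicate", "pre_lysis",
                             "post_lysis")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_toxicity_csv
#' @export
read_toxicity_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read lane profiles as CSV
#'
#' Long format with columns `condition`, `position_mm`, `signal`.
#'
#' @param lanes A named list of lanes (see [generate_lane_profiles()]).
#' @param path CSV path.
#' @return `path` (write) or a named list of lanes (read).
#' @export
write_lanes_csv <- function(lanes, path) {
  long <- do.call(rbind, lapply(lanes, function(l)
    data.frame(condition = l$condition, position_mm = l$position,
               signal = l$signal, stringsAsFactors = FALSE)))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_lanes_csv
#' @export
read_lanes_csv <- function(path) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  lanes <- lapply(split(long, long$condition), function(d)
    list(position = d$position_mm, signal = d$signal,
         condition = d$condition[1L]))
  lanes[unique(long$condition)]
}

#' Render segmentation masks to a PNG
#'
#' Aggregate area is drawn solid white on black, with the cell outlines in
#' blue, mirroring the mask images used to report aggregation time courses.
#' Requires the `png` package.
#'
#' @param seg An `fq_seg` with masks retained.
#' @param path PNG path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(seg, path) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("the `png` package is required for mask export", call. = FALSE)
  if (is.null(seg$cell_mask))
    stop("segmentation was run with `keep_masks = FALSE`", call. = FALSE)
  cm <- seg$cell_mask
  # cell outline: cell pixels bordering background (4-neighbourhood)
  nr <- nrow(cm); nc <- ncol(cm)
  pad <- rbind(FALSE, cbind(FALSE, cm, FALSE), FALSE)
  interior <- pad[2:(nr + 1), 2:(nc + 1)] &
    pad[1:nr, 2:(nc + 1)] & pad[3:(nr + 2), 2:(nc + 1)] &
    pad[2:(nr + 1), 1:nc] & pad[2:(nr + 1), 3:(nc + 2)]
  outline <- cm & !interior
  img <- array(0, dim = c(nr, nc, 3L))
  img[, , 3][outline] <- 1                       # blue outline
  for (ch in 1:3) img[, , ch][seg$aggregate_mask] <- 1  # white aggregates
  png::writePNG(img, path)
  invisible(path)
}
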