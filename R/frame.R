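#' Construct a fluorescence frame
#'
#' A frame is a single-channel grayscale fluorescence image (a numeric matrix
#' of non-negative intensities in arbitrary units, AU) together with its
#' acquisition metadata: hours post-transfection, experimental condition
#' (tRNA allele x reporter allele), biological replicate, and channel.
#'
#' @param pixels Numeric matrix of finite, non-negative intensities (AU).
#' @param time_h Hours post-transfection (may be `NA` for single time points).
#' @param condition Condition label, e.g. `"AGA/FUS"`.
#' @param replicate Replicate identifier.
#' @param channel Channel label (default `"RFP"`).
#'
#' @return An object of class `fq_frame`.
#' @export
frame <- function(pixels, time_h = NA_real_, condition = "none",
                  replicate = 1L, channel = "RFP") {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  if (length(pixels) == 0L)
    stop("`pixels` must be non-empty", call. = FALSE)
  if (anyNA(pixels) || any(!is.finite(pixels)))
    stop("pixel intensities must be finite", call. = FALSE)
  if (any(pixels < 0))
    stop("pixel intensities must be non-negative", call. = FALSE)
  structure(
    list(pixels = pixels, time_h = as.numeric(time_h),
         condition = as.character(condition), replicate = replicate,
         channel = as.character(channel)),
    class = "fq_frame")
}

#' @export
print.fq_frame <- function(x, ...) {
  cat(sprintf("<fq_frame> %d x %d px, condition=%s, replicate=%s, t=%s h\n",
              nrow(x$pixels), ncol(x$pixels), x$condition,
              as.character(x$replicate),
              ifelse(is.na(x$time_h), "NA", format(x$time_h))))
  invisible(x)
}

as_pixels <- function(x) {
  if (inherits(x, "fq_frame")) x$pixels
  else if (is.matrix(x) && is.numeric(x)) x
  else stop("expected an `fq_frame` or a numeric matrix", call. = FALSE)
}
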