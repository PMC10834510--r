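#' Mean squared error between two depth frames
#'
#' `MSE = (1/(m*n)) * sum((I_orig - I_comp)^2)` over all m x n pixels,
#' with differences taken in double precision so the full +/-65535 range
#' is represented exactly. By default every pixel enters the sum,
#' including zero-valued (invalid) pixels; set `mask_invalid = TRUE` to
#' restrict the comparison to pixels that are nonzero in both frames.
#'
#' @param orig,comp [depth_frame()] objects of equal dimensions.
#' @param mask_invalid if `TRUE`, pixels that are 0 (sensor dropout) in
#'   either frame are excluded from the mean.
#' @return Non-negative scalar MSE.
#' @export
frame_mse <- function(orig, comp, mask_invalid = FALSE) {
  stopifnot(inherits(orig, "depth_frame"), inherits(comp, "depth_frame"))
  if (!identical(dim(orig$values), dim(comp$values)))
    stop("frames have mismatched dimensions", call. = FALSE)
  a <- as.numeric(orig$values); b <- as.numeric(comp$values)
  if (mask_invalid) {
    keep <- orig$values > 0L & comp$values > 0L
    if (!any(keep)) return(0)
    a <- a[keep]; b <- b[keep]
  }
  mean((a - b)^2)
}

#' Peak signal-to-noise ratio for 16-bit depth
#'
#' `PSNR = 10 * log10(65535^2 / MSE)` decibels. The peak is fixed at
#' 65535 (the full 16-bit range) regardless of depth-range mode. An MSE
#' of 0 (exact reconstruction) yields `Inf`, the "lossless" sentinel.
#'
#' @param mse non-negative mean squared error.
#' @return PSNR in dB; `Inf` when `mse == 0`.
#' @export
#' @examples
#' psnr(1)        # 96.33 dB
#' psnr(65535^2)  # 0 dB
psnr <- function(mse) {
  if (length(mse) != 1L || is.na(mse) || mse < 0)
    stop("'mse' must be a single non-negative number", call. = FALSE)
  if (mse == 0) return(Inf)
  10 * log10(65535^2 / mse)
}

#' Quality report for an original/reconstruction pair of sequences
#'
#' Computes the pooled MSE over all pixels of all frames (not the mean
#' of per-frame PSNRs), one PSNR from that pooled MSE, and attaches the
#' compression ratio. Pooling matches how a single quality figure is
#' quoted for a whole recording.
#'
#' @param orig,comp [depth_sequence()] objects with equal frame counts
#'   and dimensions.
#' @param raw_bytes,encoded_bytes byte sizes used for the compression
#'   ratio; pass `NULL` to omit the ratio.
#' @param mask_invalid passed to [frame_mse()].
#' @return An object of class `quality_report`: list with `mse`,
#'   `psnr_db`, `compression_ratio` (or `NA`), `n_frames`, `exact`.
#' @export
sequence_quality <- function(orig, comp, raw_bytes = NULL, encoded_bytes = NULL,
                             mask_invalid = FALSE) {
  stopifnot(inherits(orig, "depth_sequence"), inherits(comp, "depth_sequence"))
  if (length(orig$frames) != length(comp$frames))
    stop("sequences have different frame counts", call. = FALSE)
  if (!identical(dim(orig$frames[[1L]]$values), dim(comp$frames[[1L]]$values)))
    stop("sequences have mismatched dimensions", call. = FALSE)
  mses <- mapply(frame_mse, orig$frames, comp$frames,
                 MoreArgs = list(mask_invalid = mask_invalid))
  # equal pixel counts per frame => pooled MSE is the plain mean
  mse <- mean(mses)
  ratio <- if (!is.null(raw_bytes) && !is.null(encoded_bytes))
    compression_ratio(raw_bytes, encoded_bytes) else NA_real_
  quality_report(mse = mse, psnr_db = psnr(mse), compression_ratio = ratio,
                 n_frames = length(orig$frames))
}

#' @rdname sequence_quality
#' @param mse,psnr_db,compression_ratio,n_frames report fields.
#' @export
quality_report <- function(mse, psnr_db, compression_ratio = NA_real_,
                           n_frames = 1L) {
  structure(
    list(mse = mse, psnr_db = psnr_db, compression_ratio = compression_ratio,
         n_frames = as.integer(n_frames), exact = (mse == 0)),
    class = "quality_report"
  )
}

#' @export
print.quality_report <- function(x, ...) {
  p <- if (is.infinite(x$psnr_db)) "Inf (exact)" else sprintf("%.2f", x$psnr_db)
  r <- if (is.na(x$compression_ratio)) "-" else sprintf("%.2fx", x$compression_ratio)
  cat(sprintf("<quality_report> %d frames | MSE %.6g | PSNR %s dB | ratio %s | exact: %s\n",
              x$n_frames, x$mse, p, r, x$exact))
  invisible(x)
}

#' Serialize a quality report to JSON
#'
#' An infinite PSNR (exact reconstruction) is written as JSON `null`,
#' since JSON has no infinity literal; the `exact` flag disambiguates.
#'
#' @param report a `quality_report`.
#' @param path optional output file; when `NULL` the JSON string is
#'   returned.
#' @return The JSON string (invisibly when written to file).
#' @export
quality_report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "quality_report"))
  x <- unclass(report)
  if (is.infinite(x$psnr_db)) x$psnr_db <- NULL
  if (is.na(x$compression_ratio)) x$compression_ratio <- NULL
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}
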