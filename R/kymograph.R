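#' Kymograph container
#'
#' A posterior-aligned kymograph: an intensity matrix with rows = frames and
#' columns = space (posterior/tail-bud end at column 1), plus the acquisition
#' metadata needed by the amplitude pipeline.
#'
#' @param intensity Numeric matrix, rows = time frames, columns = space.
#' @param frame_interval_min Time between frames, minutes.
#' @param px_size_um Pixel size along the spatial axis, micrometers.
#' @param seven_somite_frame Frame index (1-based) of the 7-somite stage; wave
#'   counting starts here.
#' @param temperature_label Optional free-text label (e.g. "21.5C") used to
#'   pick the clock-period window.
#' @return An object of class `kymograph`.
#' @export
kymograph <- function(intensity, frame_interval_min, px_size_um,
                      seven_somite_frame, temperature_label = NA_character_) {
  if (!is.matrix(intensity) || !is.numeric(intensity))
    stop("intensity must be a numeric matrix")
  seven_somite_frame <- as.integer(seven_somite_frame)
  if (seven_somite_frame < 1L || seven_somite_frame > nrow(intensity))
    stop("seven_somite_frame outside the frame range")
  stopifnot(is.numeric(frame_interval_min), frame_interval_min > 0,
            is.numeric(px_size_um), px_size_um > 0)
  structure(list(intensity = intensity,
                 frame_interval_min = frame_interval_min,
                 px_size_um = px_size_um,
                 seven_somite_frame = seven_somite_frame,
                 temperature_label = as.character(temperature_label)),
            class = "kymograph")
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("Kymograph: %d frames x %d px (%.3g min/frame, %.3g um/px)\n",
              nrow(x$intensity), ncol(x$intensity), x$frame_interval_min,
              x$px_size_um))
  cat(sprintf("  7-somite stage at frame %d; temperature: %s\n",
              x$seven_somite_frame, x$temperature_label))
  invisible(x)
}

#' @export
dim.kymograph <- function(x) dim(x$intensity)

.sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

#' Read and write kymographs (16-bit TIFF or CSV, with JSON sidecar)
#'
#' The on-disk form is a grayscale image (rows = time, columns = space,
#' posterior at column 1) as 16-bit TIFF or a plain CSV matrix, plus a JSON
#' sidecar holding `frame_interval_min`, `px_size_um`, `seven_somite_frame`,
#' `temperature_label` and (TIFF only) `intensity_scale`, the factor the
#' intensities were divided by to fit the 16-bit range.
#'
#' @param path Image path; format follows the extension (`.tif`/`.tiff` or
#'   `.csv`).
#' @param sidecar Sidecar JSON path; defaults to `path` with a `.json`
#'   extension.
#' @return `read_kymograph` returns a [kymograph()]; `write_kymograph`
#'   returns `path` invisibly.
#' @export
read_kymograph <- function(path, sidecar = .sidecar_path(path)) {
  if (!file.exists(sidecar))
    stop("kymograph sidecar not found: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  need <- c("frame_interval_min", "px_size_um", "seven_somite_frame")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    stop("sidecar missing required key(s): ", paste(miss, collapse = ", "))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path, as.is = FALSE)
    scale <- if (!is.null(meta$intensity_scale)) meta$intensity_scale else 1
    mat <- img * scale
  } else if (ext == "csv") {
    mat <- as.matrix(utils::read.csv(path, header = FALSE))
    dimnames(mat) <- NULL
  } else stop("unsupported kymograph format: .", ext)
  kymograph(mat, meta$frame_interval_min, meta$px_size_um,
            meta$seven_somite_frame,
            if (is.null(meta$temperature_label)) NA_character_ else
              meta$temperature_label)
}

#' @rdname read_kymograph
#' @param kymo A [kymograph()].
#' @export
write_kymograph <- function(kymo, path, sidecar = .sidecar_path(path)) {
  stopifnot(inherits(kymo, "kymograph"))
  ext <- tolower(tools::file_ext(path))
  meta <- list(frame_interval_min = kymo$frame_interval_min,
               px_size_um = kymo$px_size_um,
               seven_somite_frame = kymo$seven_somite_frame,
               temperature_label = kymo$temperature_label)
  if (ext %in% c("tif", "tiff")) {
    # writeTIFF stores [0,1]; record the divisor so reads recover raw units
    scale <- max(kymo$intensity, 1e-12)
    meta$intensity_scale <- scale
    tiff::writeTIFF(pmin(pmax(kymo$intensity / scale, 0), 1), path,
                    bits.per.sample = 16L)
  } else if (ext == "csv") {
    utils::write.table(kymo$intensity, path, sep = ",", row.names = FALSE,
                       col.names = FALSE)
  } else stop("unsupported kymograph format: .", ext)
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# bilinear interpolation of a frame image at fractional (x, y); image indexed
# [row = y, col = x], 1-based
.bilinear <- function(img, x, y) {
  x0 <- floor(x); y0 <- floor(y)
  x0 <- pmin(pmax(x0, 1L), ncol(img) - 1L)
  y0 <- pmin(pmax(y0, 1L), nrow(img) - 1L)
  fx <- x - x0; fy <- y - y0
  img[cbind(y0, x0)] * (1 - fx) * (1 - fy) +
    img[cbind(y0, x0 + 1L)] * fx * (1 - fy) +
    img[cbind(y0 + 1L, x0)] * (1 - fx) * fy +
    img[cbind(y0 + 1L, x0 + 1L)] * fx * fy
}

#' Build a kymograph from a time-lapse stack along a line of interest
#'
#' Samples each frame along a polyline at unit (1 px) arc-length steps and
#' averages the intensity across a band of `width_px` samples perpendicular
#' to the line, reproducing the LOI-interpolator construction. The first
#' polyline vertex is taken as the posterior end and maps to column 1.
#'
#' @param stack Numeric 3-D array `[frame, y, x]`.
#' @param loi Two-column matrix of polyline vertices `(x, y)` in pixel
#'   coordinates, posterior end first.
#' @param width_px Band width in pixels (default 15).
#' @param frame_interval_min,px_size_um,seven_somite_frame,temperature_label
#'   Metadata passed to [kymograph()].
#' @return A [kymograph()] whose rows are frames and whose columns step along
#'   the polyline from the posterior end.
#' @export
build_kymograph <- function(stack, loi, width_px = 15L,
                            frame_interval_min = 5, px_size_um = 2.6,
                            seven_somite_frame = 1L,
                            temperature_label = NA_character_) {
  stopifnot(is.array(stack), length(dim(stack)) == 3L,
            is.matrix(loi), ncol(loi) == 2L, nrow(loi) >= 2L,
            width_px >= 1L)
  nf <- dim(stack)[1L]; ny <- dim(stack)[2L]; nx <- dim(stack)[3L]
  # arc-length parameterization at unit steps
  seg <- diff(loi)
  seg_len <- sqrt(rowSums(seg^2))
  cum <- c(0, cumsum(seg_len))
  total <- cum[length(cum)]
  s <- seq(0, total, by = 1)
  px <- stats::approx(cum, loi[, 1L], xout = s)$y
  py <- stats::approx(cum, loi[, 2L], xout = s)$y
  # unit tangents (central differences), normals rotate by 90 degrees
  tx <- c(px[2L] - px[1L], (px[-(1:2)] - px[-((length(px) - 1):length(px))]) / 2,
          px[length(px)] - px[length(px) - 1L])
  ty <- c(py[2L] - py[1L], (py[-(1:2)] - py[-((length(py) - 1):length(py))]) / 2,
          py[length(py)] - py[length(py) - 1L])
  tn <- sqrt(tx^2 + ty^2); tx <- tx / tn; ty <- ty / tn
  offs <- seq_len(width_px) - (width_px + 1) / 2
  xs <- outer(-ty, offs) + px   # length(s) x width_px sample coordinates
  ys <- outer(tx, offs) + py
  if (any(xs < 1 | xs > nx | ys < 1 | ys > ny)) {
    bad <- which(rowSums(xs < 1 | xs > nx | ys < 1 | ys > ny) > 0)[1L]
    stop("LOI band exits the image near arc-length ", s[bad], " px")
  }
  mat <- matrix(NA_real_, nf, length(s))
  for (f in seq_len(nf)) {
    img <- stack[f, , ]
    vals <- .bilinear(img, as.vector(xs), as.vector(ys))
    mat[f, ] <- rowMeans(matrix(vals, nrow = length(s)))
  }
  kymograph(mat, frame_interval_min, px_size_um, seven_somite_frame,
            temperature_label)
}
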