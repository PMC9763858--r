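#' Image stack container
#'
#' A time-ordered stack of 2D intensity frames (camera counts) with physical
#' metadata. Frames are stored as an `H x W x T` numeric array; a pixel's
#' center lies at integer 0-based coordinates `(x, y) = (col, row)` and its
#' physical position is `index * pixel_size_nm`.
#'
#' @param frames numeric array `H x W x T` (a matrix is treated as `T = 1`),
#'   non-negative intensity values.
#' @param pixel_size_nm physical pixel size, nm/pixel.
#' @param frame_interval_s frame interval, seconds.
#' @param t0_frame 0-based index of the first laser-exposed frame.
#' @return an object of class `image_stack`.
#' @export
image_stack <- function(frames, pixel_size_nm, frame_interval_s = 1 / 77,
                        t0_frame = 0L) {
  if (is.matrix(frames)) frames <- array(frames, dim = c(dim(frames), 1L))
  stopifnot(is.array(frames), length(dim(frames)) == 3)
  if (!is.numeric(pixel_size_nm) || length(pixel_size_nm) != 1 || pixel_size_nm <= 0)
    stop("pixel_size_nm must be a positive scalar")
  if (frame_interval_s <= 0) stop("frame_interval_s must be positive")
  n_t <- dim(frames)[3]
  if (n_t < 1) stop("stack must contain at least one frame")
  t0_frame <- as.integer(t0_frame)
  if (t0_frame < 0 || t0_frame >= n_t) stop("t0_frame must be in [0, T)")
  structure(list(frames = frames,
                 pixel_size_nm = as.numeric(pixel_size_nm),
                 frame_interval_s = as.numeric(frame_interval_s),
                 t0_frame = t0_frame),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("image_stack: %d frames of %d x %d px, %.3g nm/px, %.4g s/frame, t0 = %d\n",
              d[3], d[1], d[2], x$pixel_size_nm, x$frame_interval_s, x$t0_frame))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$frames)

n_frames <- function(stack) dim(stack$frames)[3]

get_frame <- function(stack, t) stack$frames[, , t + 1L, drop = TRUE]

#' Read a TIFF / OME-TIFF image stack
#'
#' Frames are loaded in acquisition order as raw camera counts. The pixel
#' size is taken, in order of precedence, from an explicit
#' `pixel_size_nm` override, an OME-XML `PhysicalSizeX` attribute in the
#' TIFF ImageDescription tag (OME default unit um, honoured via
#' `PhysicalSizeXUnit`), or a JSON sidecar `<path>.meta.json` written by
#' [write_image_stack()]. Missing pixel size with no override is an error:
#' metadata is never silently defaulted.
#'
#' @param path TIFF file path.
#' @param pixel_size_nm,frame_interval_s,t0_frame optional metadata
#'   overrides; overrides win over file metadata.
#' @return an [image_stack()].
#' @export
read_image_stack <- function(path, pixel_size_nm = NULL,
                             frame_interval_s = NULL, t0_frame = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  planes <- tryCatch(tiff::readTIFF(path, all = TRUE, info = TRUE, as.is = TRUE),
                     error = function(e) stop("unreadable TIFF '", path, "': ",
                                              conditionMessage(e), call. = FALSE))
  if (!is.list(planes)) planes <- list(planes)
  if (length(planes) == 0) stop("unreadable TIFF '", path, "': no image planes")
  meta <- list()
  desc <- attr(planes[[1]], "description")
  if (!is.null(desc)) meta <- c(meta, parse_ome_pixel_size(desc))
  sidecar <- paste0(path, ".meta.json")
  if (file.exists(sidecar)) {
    sc <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    for (k in setdiff(names(sc), names(meta))) meta[[k]] <- sc[[k]]
  }
  if (!is.null(pixel_size_nm)) meta$pixel_size_nm <- pixel_size_nm
  if (!is.null(frame_interval_s)) meta$frame_interval_s <- frame_interval_s
  if (!is.null(t0_frame)) meta$t0_frame <- t0_frame
  if (is.null(meta$pixel_size_nm))
    stop("no pixel size in file metadata and no pixel_size_nm override supplied")
  h <- nrow(planes[[1]]); w <- ncol(planes[[1]])
  if (any(!vapply(planes, function(p) nrow(p) == h && ncol(p) == w, logical(1))))
    stop("inconsistent plane dimensions in '", path, "'")
  frames <- array(0, dim = c(h, w, length(planes)))
  for (i in seq_along(planes)) frames[, , i] <- planes[[i]]
  image_stack(frames,
              pixel_size_nm = meta$pixel_size_nm,
              frame_interval_s = if (is.null(meta$frame_interval_s)) 1 / 77
                                 else meta$frame_interval_s,
              t0_frame = if (is.null(meta$t0_frame)) 0L else meta$t0_frame)
}

# Extract PhysicalSizeX (nm) from an OME-XML ImageDescription string.
parse_ome_pixel_size <- function(desc) {
  m <- regmatches(desc, regexpr('PhysicalSizeX="[0-9.eE+-]+"', desc))
  if (length(m) == 0) return(list())
  val <- as.numeric(sub('PhysicalSizeX="([0-9.eE+-]+)"', "\\1", m))
  un <- regmatches(desc, regexpr('PhysicalSizeXUnit="[^"]*"', desc))
  unit <- if (length(un) == 0) "µm"
          else sub('PhysicalSizeXUnit="([^"]*)"', "\\1", un)
  scale <- switch(unit, "nm" = 1, "µm" = 1e3, "um" = 1e3, "mm" = 1e6, 1e3)
  list(pixel_size_nm = val * scale)
}

#' Write an image stack as a multi-page TIFF with a metadata sidecar
#'
#' Counts are stored as 16-bit samples, so integer values in `[0, 65535]`
#' round-trip exactly. Physical metadata (pixel size, frame interval, t0)
#' goes into `<path>.meta.json`, which [read_image_stack()] picks up
#' automatically.
#'
#' @param stack an [image_stack()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  mx <- 65535
  vals <- stack$frames
  if (any(vals < 0)) stop("negative counts cannot be written")
  if (any(vals > mx)) stop("counts exceed 16-bit range")
  planes <- lapply(seq_len(n_frames(stack)),
                   function(i) stack$frames[, , i] / mx)
  tiff::writeTIFF(planes, path, bits.per.sample = 16L, compression = "deflate")
  jsonlite::write_json(list(pixel_size_nm = stack$pixel_size_nm,
                            frame_interval_s = stack$frame_interval_s,
                            t0_frame = stack$t0_frame),
                       paste0(path, ".meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a region-of-interest mask
#'
#' Accepts a single-plane TIFF (non-zero pixels = inside the cell) or a CSV
#' of polygon vertices with columns `x_px`, `y_px`, rasterised onto the
#' given frame dimensions by even-odd point-in-polygon tests at pixel
#' centers.
#'
#' @param path TIFF or CSV file.
#' @param dim_hw frame dimensions `c(H, W)`; required for polygon CSVs.
#' @return a logical `H x W` matrix.
#' @export
read_roi_mask <- function(path, dim_hw = NULL) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    poly <- utils::read.csv(path)
    if (!all(c("x_px", "y_px") %in% names(poly)))
      stop("polygon CSV must have columns x_px, y_px")
    if (is.null(dim_hw)) stop("dim_hw required to rasterise a polygon ROI")
    xs <- rep(0:(dim_hw[2] - 1), each = dim_hw[1])
    ys <- rep(0:(dim_hw[1] - 1), times = dim_hw[2])
    inside <- point_in_polygon(xs, ys, poly$x_px, poly$y_px)
    matrix(inside, nrow = dim_hw[1], ncol = dim_hw[2])
  } else {
    m <- tiff::readTIFF(path, as.is = TRUE)
    if (length(dim(m)) == 3) m <- m[, , 1]
    m != 0
  }
}

# Even-odd rule point-in-polygon, vectorized over query points.
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    cross <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}
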