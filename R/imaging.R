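# Scanned-page preprocessing: grid/box detection, binarization, cropping,
# and rescaling to the standardized 128 x 128 character images.

#' Grid layout of designated answer boxes
#'
#' Box rectangles in pixel coordinates (x = column, y = row, 1-based,
#' inclusive), in reading order (row-major).
#'
#' @param rows,cols grid shape.
#' @param box_px inner box side length in pixels.
#' @param margin page margin before the first box.
#' @param gap spacing between adjacent boxes.
#' @return A list with `rows`, `cols` and a tibble `boxes`
#'   (`row`, `col`, `x0`, `y0`, `x1`, `y1`).
#' @export
grid_layout <- function(rows, cols, box_px = 96L, margin = 24L, gap = 10L) {
  g <- expand.grid(col = seq_len(cols), row = seq_len(rows))
  step <- box_px + gap
  boxes <- tibble::tibble(
    row = g$row, col = g$col,
    x0 = margin + (g$col - 1L) * step + 1L,
    y0 = margin + (g$row - 1L) * step + 1L)
  boxes$x1 <- boxes$x0 + box_px - 1L
  boxes$y1 <- boxes$y0 + box_px - 1L
  list(rows = rows, cols = cols, box_px = box_px, margin = margin,
       gap = gap, boxes = boxes)
}

#' Construct a scan-page object
#'
#' @param pixels `(H, W)` grayscale or `(H, W, 3)` color array in `[0, 1]`.
#' @param layout a [grid_layout()].
#' @param page_id identifier used in error messages and file names.
#' @return A `scan_page` object.
#' @export
scan_page <- function(pixels, layout, page_id = "page") {
  d <- dim(pixels)
  stopifnot(length(d) %in% c(2L, 3L))
  if (max(layout$boxes$x1) > d[2] || max(layout$boxes$y1) > d[1])
    stop("layout boxes exceed page bounds for ", page_id)
  structure(list(pixels = pixels, layout = layout, page_id = page_id),
            class = "scan_page")
}

# Rec. 601 luminance for color arrays; identity for grayscale.
luminance <- function(pixels) {
  if (length(dim(pixels)) == 2) return(pixels)
  0.299 * pixels[, , 1] + 0.587 * pixels[, , 2] + 0.114 * pixels[, , 3]
}

#' Binarize a grayscale image
#'
#' Otsu's global threshold on luminance. The stroke (ink) class maps to 1
#' and the background to 0; polarity is resolved by taking the minority
#' class as ink, which selects the dark class on a light-background scan
#' (ink is sparse) and makes re-binarization of an already-binary image
#' (black background, white strokes) the identity. A constant image yields
#' all zeros.
#'
#' @param img `(H, W)` grayscale matrix in `[0, 1]` (color arrays are
#'   converted via luminance first).
#' @return An integer matrix of the same shape with values in {0, 1}.
#' @export
binarize <- function(img) {
  img <- luminance(img)
  if (diff(range(img)) < 1e-6) return(matrix(0L, nrow(img), ncol(img)))
  thr <- EBImage::otsu(EBImage::Image(img), range = range(img))
  dark <- img < thr
  ink <- if (sum(dark) <= length(img) / 2) dark else !dark
  out <- matrix(0L, nrow(img), ncol(img))
  out[ink] <- 1L
  out
}

# Sobel gradient magnitude (edge strength map).
edge_magnitude <- function(gray) {
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3)
  gx <- EBImage::filter2(EBImage::Image(gray), kx)
  gy <- EBImage::filter2(EBImage::Image(gray), t(kx))
  sqrt(EBImage::imageData(gx)^2 + EBImage::imageData(gy)^2)
}

# centers of runs of above-threshold positions in a projection profile;
# a 1-px printed line yields an edge response on both of its sides, so
# centers closer than min_sep merge into one line estimate
profile_lines <- function(profile, thr, min_sep = 4) {
  on <- profile > thr
  if (!any(on)) return(numeric(0))
  r <- rle(on)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  centers <- (starts[r$values] + ends[r$values]) / 2
  merged <- numeric(0); group <- centers[1]
  for (c in centers[-1]) {
    if (c - group[length(group)] <= min_sep) group <- c(group, c)
    else { merged <- c(merged, mean(group)); group <- c }
  }
  c(merged, mean(group))
}

grid_not_found <- function(page_id, detail) {
  stop(structure(class = c("dysditect_grid_not_found", "error", "condition"),
                 list(message = sprintf("grid not found on page '%s': %s",
                                        page_id, detail),
                      call = NULL)))
}

#' Detect the answer-box grid on a scanned page
#'
#' Edge-magnitude projection profiles locate the printed horizontal and
#' vertical grid lines; boxes are the interiors between adjacent lines
#' (the printed border is excluded). When detection does not recover the
#' expected `rows x cols` grid, either a structured grid-not-found error is
#' raised (naming the page) or, with `fallback = TRUE`, the declared layout
#' coordinates are used instead.
#'
#' @param page a `scan_page`.
#' @param fallback use the declared layout when detection fails.
#' @param border_trim pixels trimmed inside each detected line.
#' @return A tibble of crop rectangles (`x0`, `y0`, `x1`, `y1`) in reading
#'   order, one per designated box.
#' @export
detect_boxes <- function(page, fallback = FALSE, border_trim = 2L) {
  stopifnot(inherits(page, "scan_page"))
  lay <- page$layout
  gray <- luminance(page$pixels)
  edges <- edge_magnitude(gray)
  vprof <- colSums(edges) / nrow(edges)   # vertical lines
  hprof <- rowSums(edges) / ncol(edges)   # horizontal lines
  thr_v <- max(vprof) * 0.5
  thr_h <- max(hprof) * 0.5
  xs <- profile_lines(vprof, thr_v)
  ys <- profile_lines(hprof, thr_h)
  # every box prints its own border, so a full grid shows 2*cols vertical
  # and 2*rows horizontal line centers
  ok <- length(xs) == 2 * lay$cols && length(ys) == 2 * lay$rows &&
    max(vprof) > 1e-3
  if (!ok) {
    if (!fallback)
      grid_not_found(page$page_id,
                     sprintf("found %d vertical and %d horizontal lines, expected %d and %d",
                             length(xs), length(ys), 2 * lay$cols, 2 * lay$rows))
    return(tibble::tibble(x0 = lay$boxes$x0, y0 = lay$boxes$y0,
                          x1 = lay$boxes$x1, y1 = lay$boxes$y1))
  }
  g <- expand.grid(col = seq_len(lay$cols), row = seq_len(lay$rows))
  tibble::tibble(
    x0 = round(xs[2 * g$col - 1] + border_trim),
    y0 = round(ys[2 * g$row - 1] + border_trim),
    x1 = round(xs[2 * g$col] - border_trim),
    y1 = round(ys[2 * g$row] - border_trim))
}

#' Crop one box and rescale to a standardized character image
#'
#' The crop is binarized (Otsu, ink = 1), rescaled with bilinear
#' interpolation to `size` x `size` ignoring aspect ratio (boxes are
#' near-square), and re-binarized at 0.5.
#'
#' @param page a `scan_page`.
#' @param rect one crop rectangle (`x0`, `y0`, `x1`, `y1`).
#' @param size output side length.
#' @return A `size` x `size` integer matrix in {0, 1}.
#' @export
crop_rescale <- function(page, rect, size = 128L) {
  d <- dim(page$pixels)
  if (rect$x0 < 1 || rect$y0 < 1 || rect$x1 > d[2] || rect$y1 > d[1] ||
      rect$x0 > rect$x1 || rect$y0 > rect$y1)
    stop("crop rectangle outside page bounds for ", page$page_id)
  crop <- luminance(page$pixels)[rect$y0:rect$y1, rect$x0:rect$x1, drop = FALSE]
  bin <- binarize(crop)
  if (all(bin == 0L)) return(matrix(0L, size, size))
  res <- EBImage::resize(EBImage::Image(bin * 1.0), w = size, h = size,
                         filter = "bilinear")
  out <- matrix(0L, size, size)
  out[EBImage::imageData(res) >= 0.5] <- 1L
  out
}

#' Preprocess a full dictation page into character images
#'
#' Detects (or falls back to) the box grid, crops and rescales every box,
#' and optionally writes per-character PNGs plus a manifest.
#'
#' @param page a `scan_page`.
#' @param participant_id id recorded in the manifest.
#' @param size output image side length.
#' @param out_dir if non-NULL, write `{participant}_{index}.png` files there.
#' @param fallback passed to [detect_boxes()] (a declared layout replaces
#'   manual checking when line detection fails).
#' @return A list: `images` (list of binary matrices in reading order) and
#'   `manifest` (tibble: `participant_id`, `position_index`, `path`,
#'   `blank_flag`).
#' @export
preprocess_page <- function(page, participant_id = page$page_id,
                            size = 128L, out_dir = NULL, fallback = TRUE) {
  rects <- detect_boxes(page, fallback = fallback)
  images <- vector("list", nrow(rects))
  rows <- vector("list", nrow(rects))
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(nrow(rects))) {
    img <- crop_rescale(page, rects[i, ], size = size)
    images[[i]] <- img
    path <- if (!is.null(out_dir)) {
      p <- file.path(out_dir, sprintf("%s_%02d.png", participant_id, i - 1L))
      png::writePNG(matrix(as.double(img), nrow(img), ncol(img)), p)
      p
    } else NA_character_
    rows[[i]] <- tibble::tibble(participant_id = participant_id,
                                position_index = i - 1L, path = path,
                                blank_flag = mean(img) < 0.005)
  }
  list(images = images, manifest = dplyr::bind_rows(rows))
}

#' Render a synthetic scan page from character images
#'
#' Draws the printed box grid (dark borders on a light page) and stamps
#' each character's ink into its designated box. Used to exercise the
#' preprocessing chain end to end without scanner hardware.
#'
#' @param char_images list of binary character matrices (ink = 1), one per
#'   box in reading order; shorter lists leave trailing boxes empty.
#' @param layout a [grid_layout()].
#' @param page_id identifier for the resulting page.
#' @param ink gray level of handwriting ink.
#' @param paper gray level of the page background.
#' @return A `scan_page` with a 3-channel pixel array.
#' @export
render_scan_page <- function(char_images, layout, page_id = "page",
                             ink = 0.15, paper = 0.97) {
  H <- layout$margin * 2L + layout$rows * layout$box_px +
    (layout$rows - 1L) * layout$gap
  W <- layout$margin * 2L + layout$cols * layout$box_px +
    (layout$cols - 1L) * layout$gap
  gray <- matrix(paper, H, W)
  b <- layout$boxes
  for (i in seq_len(nrow(b))) {
    x0 <- b$x0[i]; x1 <- b$x1[i]; y0 <- b$y0[i]; y1 <- b$y1[i]
    gray[c(y0 - 1L, y1 + 1L), (x0 - 1L):(x1 + 1L)] <- 0.05  # border
    gray[(y0 - 1L):(y1 + 1L), c(x0 - 1L, x1 + 1L)] <- 0.05
    if (i <= length(char_images) && !is.null(char_images[[i]])) {
      ch <- char_images[[i]]
      side <- min(y1 - y0 + 1L, x1 - x0 + 1L, dim(ch))
      ch <- ch[seq_len(side), seq_len(side), drop = FALSE]
      sub <- gray[y0:(y0 + side - 1L), x0:(x0 + side - 1L)]
      sub[ch == 1L] <- ink
      gray[y0:(y0 + side - 1L), x0:(x0 + side - 1L)] <- sub
    }
  }
  scan_page(array(rep(gray, 3L), dim = c(H, W, 3L)), layout, page_id)
}
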