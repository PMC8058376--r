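# Percentage infarct area (PIA) from binary lesion / hemisphere mask pairs:
# PIA = 100 x lesion area / ipsilateral hemisphere area. Works on masks, not
# raw histology; segmentation of stained sections is upstream and out of
# scope. Pixel size cancels in the ratio and is ignored.

#' Pair a lesion mask with its hemisphere mask
#'
#' @param lesion,hemisphere Binary masks (logical or 0/1 numeric matrices) of
#'   identical dimensions. Every lesion pixel must lie inside the hemisphere
#'   and the hemisphere must be non-empty.
#' @return A `lesion_mask_pair` object.
#' @export
lesion_mask_pair <- function(lesion, hemisphere) {
  lesion <- as_mask(lesion)
  hemisphere <- as_mask(hemisphere)
  if (!identical(dim(lesion), dim(hemisphere))) {
    stop("lesion and hemisphere masks must have identical dimensions", call. = FALSE)
  }
  if (!any(hemisphere)) stop("hemisphere mask is empty", call. = FALSE)
  if (any(lesion & !hemisphere)) {
    stop("lesion pixels found outside the hemisphere mask", call. = FALSE)
  }
  structure(list(lesion = lesion, hemisphere = hemisphere),
            class = "lesion_mask_pair")
}

as_mask <- function(m) {
  if (is.data.frame(m)) m <- as.matrix(m)
  stopifnot(is.matrix(m))
  if (is.numeric(m)) {
    if (any(!m %in% c(0, 1))) stop("mask values must be 0/1", call. = FALSE)
    m <- m > 0
  }
  stopifnot(is.logical(m))
  m
}

#' @export
print.lesion_mask_pair <- function(x, ...) {
  cat(sprintf("<lesion_mask_pair> %d x %d px, lesion %d px, hemisphere %d px\n",
              nrow(x$lesion), ncol(x$lesion), sum(x$lesion), sum(x$hemisphere)))
  invisible(x)
}

#' Percentage infarct area
#'
#' `PIA = 100 * lesion pixel count / hemisphere pixel count`.
#'
#' @param m A [lesion_mask_pair()], or a lesion mask (then `hemisphere` must
#'   be given).
#' @param hemisphere Optional hemisphere mask when `m` is a bare lesion mask.
#' @return The percentage, a number in `[0, 100]`.
#' @examples
#' hemi <- matrix(1, 100, 100)
#' les <- matrix(0, 100, 100); les[1:50, 1:50] <- 1
#' percent_infarct_area(lesion_mask_pair(les, hemi)) # 25
#' @export
percent_infarct_area <- function(m, hemisphere = NULL) {
  if (!inherits(m, "lesion_mask_pair")) m <- lesion_mask_pair(m, hemisphere)
  100 * sum(m$lesion) / sum(m$hemisphere)
}

#' Generate a synthetic lesion/hemisphere mask pair
#'
#' The hemisphere is an ellipse filling the frame; the lesion grows from a
#' random interior seed pixel by uniform 4-neighborhood dilation, taking a
#' partial final ring (nearest-to-seed pixels first) so the lesion pixel
#' count hits the target percentage exactly (up to 1 px rounding).
#'
#' @param nrow,ncol Mask dimensions in pixels.
#' @param target_pia Target percentage in `[0, 100]`.
#' @param seed Integer seed for the lesion origin.
#' @return A [lesion_mask_pair()].
#' @examples
#' m <- generate_lesion_mask(120, 120, target_pia = 46.22, seed = 1)
#' percent_infarct_area(m)
#' @export
generate_lesion_mask <- function(nrow, ncol, target_pia, seed = 1) {
  if (target_pia < 0 || target_pia > 100) {
    stop("target_pia must lie in [0, 100]", call. = FALSE)
  }
  if (nrow < 8 || ncol < 8) stop("mask too small to place a lesion", call. = FALSE)
  rr <- matrix(seq_len(nrow), nrow, ncol)
  cc <- matrix(seq_len(ncol), nrow, ncol, byrow = TRUE)
  cy <- (nrow + 1) / 2; cx <- (ncol + 1) / 2
  hemi <- ((rr - cy) / (0.45 * nrow))^2 + ((cc - cx) / (0.45 * ncol))^2 <= 1
  target_px <- round(target_pia / 100 * sum(hemi))
  les <- matrix(FALSE, nrow, ncol)
  if (target_px == 0) return(lesion_mask_pair(les, hemi))

  interior <- which(hemi &
    ((rr - cy) / (0.45 * nrow))^2 + ((cc - cx) / (0.45 * ncol))^2 <= 0.5)
  origin <- withr::with_seed(as.integer(seed), sample(interior, 1))
  les[origin] <- TRUE
  dilate4 <- function(m) {
    out <- m
    out[-1, ] <- out[-1, ] | m[-nrow(m), ]
    out[-nrow(m), ] <- out[-nrow(m), ] | m[-1, ]
    out[, -1] <- out[, -1] | m[, -ncol(m)]
    out[, -ncol(m)] <- out[, -ncol(m)] | m[, -1]
    out
  }
  oy <- rr[origin]; ox <- cc[origin]
  while (sum(les) < target_px) {
    grown <- dilate4(les) & hemi
    ring <- which(grown & !les)
    if (length(ring) == 0) {
      stop("lesion growth exhausted the hemisphere before reaching the target",
           call. = FALSE)
    }
    need <- target_px - sum(les)
    if (length(ring) > need) {
      d2 <- (rr[ring] - oy)^2 + (cc[ring] - ox)^2
      ring <- ring[order(d2, ring)][seq_len(need)]
    }
    les[ring] <- TRUE
  }
  lesion_mask_pair(les, hemi)
}

#' Read / write binary masks as PNG
#'
#' Masks travel as 8-bit grayscale PNG with 0 = background and 255 =
#' foreground (values above 0.5 are foreground on read).
#'
#' @param mask Logical matrix.
#' @param path PNG path.
#' @return `write_mask_png()` the path invisibly; `read_mask_png()` a logical
#'   matrix.
#' @export
write_mask_png <- function(mask, path) {
  mask <- as_mask(mask)
  png::writePNG(mask * 1, path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img > 0.5
}
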