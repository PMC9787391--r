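# Video and image input/output.
#
# AVI support is a minimal RIFF reader/writer for uncompressed 24-bit RGB
# ('DIB ') streams, the interchange format the acquisition software in this
# workflow records. Frames are stored bottom-up in BGR order with rows padded
# to 4 bytes, per the DIB convention. Still images (PNG/TIFF/JPEG) are read
# through EBImage and wrapped as 1-frame clips.

.still_exts <- c("png", "tif", "tiff", "jpg", "jpeg")

#' Read a video or still image
#'
#' Reads an uncompressed RGB24 AVI file into a [video_clip], or a still image
#' (PNG/TIFF/JPEG) as a 1-frame clip with \code{fps = NA} (single-image mode).
#'
#' @param path path to an AVI file or a still image.
#' @param fps optional frame-rate override replacing the container metadata.
#' @return A [video_clip].
#' @export
read_video <- function(path, fps = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(sub(".*\\.", "", basename(path)))
  clip <- if (ext %in% .still_exts) read_still(path) else read_avi(path)
  if (!is.null(fps)) clip$fps <- as.numeric(fps)
  clip
}

read_still <- function(path) {
  img <- tryCatch(EBImage::readImage(path),
                  error = function(e) stop("cannot decode image '", path, "': ",
                                           conditionMessage(e)))
  a <- EBImage::imageData(img)            # [x, y] or [x, y, channels], 0..1
  if (length(dim(a)) == 2L) a <- array(rep(a, 3L), c(dim(a), 3L))
  if (dim(a)[3L] > 3L) a <- a[, , 1:3, drop = FALSE]
  fr <- aperm(a, c(2L, 1L, 3L))           # EBImage is x,y; we use row,col
  fr <- array(as.integer(round(fr * 255)), dim(fr))
  fr[fr < 0L] <- 0L; fr[fr > 255L] <- 255L
  video_clip(list(fr), fps = NA_real_, bit_depth = 8L)
}

# ---- RIFF helpers -----------------------------------------------------------

.u32 <- function(x) writeBin(as.integer(x), raw(), size = 4L, endian = "little")
.u16 <- function(x) writeBin(as.integer(x), raw(), size = 2L, endian = "little")
.fourcc <- function(s) charToRaw(s)
.chunk <- function(id, payload) {
  stopifnot(nchar(id) == 4L)
  out <- c(.fourcc(id), .u32(length(payload)), payload)
  if (length(payload) %% 2L == 1L) out <- c(out, as.raw(0L))  # word alignment
  out
}
.list_chunk <- function(type, payload) .chunk("LIST", c(.fourcc(type), payload))

frame_to_dib <- function(fr) {
  h <- dim(fr)[1L]; w <- dim(fr)[2L]
  stride <- 4L * ((3L * w + 3L) %/% 4L)
  buf <- matrix(as.raw(0L), nrow = stride, ncol = h)
  # bottom-up rows, BGR pixel order
  for (ch in 1:3) {                     # ch 1=B,2=G,3=R in file order
    src <- fr[, , 4L - ch]              # R=3 -> file ch offset 2 etc.
    buf[seq.int(ch + 2L - 2L, by = 3L, length.out = w), ] <-
      matrix(as.raw(t(src[h:1, , drop = FALSE])), nrow = w)
  }
  as.vector(buf)
}

dib_to_frame <- function(bytes, w, h) {
  stride <- 4L * ((3L * w + 3L) %/% 4L)
  if (length(bytes) < stride * h) stop("truncated frame data")
  m <- matrix(bytes[seq_len(stride * h)], nrow = stride)
  fr <- array(0L, c(h, w, 3L))
  for (ch in 1:3) {
    v <- matrix(as.integer(m[seq.int(ch, by = 3L, length.out = w), ]),
                nrow = w, ncol = h)
    fr[, , 4L - ch] <- t(v)[h:1, , drop = FALSE]
  }
  fr
}

#' Write a clip as an uncompressed RGB24 AVI file
#'
#' Lossless by construction (raw DIB frames), so overlay inspection and
#' read-back round-trips are faithful.
#'
#' @param clip a [video_clip] (8-bit).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_video <- function(clip, path) {
  stopifnot(is_video_clip(clip))
  if (clip$bit_depth != 8L) stop("AVI writer supports 8-bit clips only")
  fps <- if (is.na(clip$fps)) 25 else clip$fps
  w <- clip$width; h <- clip$height
  stride <- 4L * ((3L * w + 3L) %/% 4L)
  frame_bytes <- stride * h

  avih <- c(.u32(round(1e6 / fps)), .u32(frame_bytes * ceiling(fps)),
            .u32(0L), .u32(0x10L),                  # AVIF_HASINDEX
            .u32(clip$frame_count), .u32(0L), .u32(1L), .u32(frame_bytes),
            .u32(w), .u32(h), .u32(rep(0L, 4L)))
  strh <- c(.fourcc("vids"), .fourcc("DIB "), .u32(0L), .u16(0L), .u16(0L),
            .u32(0L), .u32(1000L), .u32(round(fps * 1000)), .u32(0L),
            .u32(clip$frame_count), .u32(frame_bytes), .u32(-1L), .u32(0L),
            .u16(c(0L, 0L, w, h)))
  strf <- c(.u32(40L), .u32(w), .u32(h), .u16(1L), .u16(24L), .u32(0L),
            .u32(frame_bytes), .u32(2835L), .u32(2835L), .u32(0L), .u32(0L))
  hdrl <- .list_chunk("hdrl", c(.chunk("avih", avih),
                                .list_chunk("strl", c(.chunk("strh", strh),
                                                      .chunk("strf", strf)))))
  movi_payload <- raw(0)
  offsets <- integer(clip$frame_count)
  pos <- 4L                                          # after 'movi' fourcc
  chunks <- vector("list", clip$frame_count)
  for (i in seq_len(clip$frame_count)) {
    chunks[[i]] <- .chunk("00db", frame_to_dib(clip$frames[[i]]))
    offsets[i] <- pos
    pos <- pos + length(chunks[[i]])
  }
  movi <- .list_chunk("movi", do.call(c, chunks))
  idx1 <- do.call(c, lapply(seq_len(clip$frame_count), function(i)
    c(.fourcc("00db"), .u32(0x10L), .u32(offsets[i]), .u32(frame_bytes))))
  body <- c(.fourcc("AVI "), hdrl, movi, .chunk("idx1", idx1))
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(c(.fourcc("RIFF"), .u32(length(body)), body), con)
  invisible(path)
}

read_u32 <- function(bytes, at) {
  sum(as.integer(bytes[at + 0:3]) * c(1, 256, 65536, 16777216))
}

read_avi <- function(path) {
  bytes <- readBin(path, raw(), n = file.size(path))
  if (length(bytes) < 12L || rawToChar(bytes[1:4]) != "RIFF" ||
      rawToChar(bytes[9:12]) != "AVI ")
    stop("cannot decode '", path, "': not a RIFF/AVI file")
  w <- NULL; h <- NULL; bitcount <- NULL; compression <- NULL
  fps <- NA_real_; frames <- list()

  walk <- function(from, to) {
    p <- from
    while (p + 8L <= to) {
      id <- rawToChar(bytes[p + 0:3])
      sz <- read_u32(bytes, p + 4L)
      body_start <- p + 8L
      if (body_start + sz - 1L > to) sz <- to - body_start + 1L  # tolerate truncation
      if (id == "LIST") {
        walk(body_start + 4L, body_start + sz - 1L)
      } else if (id == "strh") {
        if (rawToChar(bytes[body_start + 0:3]) == "vids") {
          scale <- read_u32(bytes, body_start + 20L)
          rate <- read_u32(bytes, body_start + 24L)
          if (scale > 0 && rate > 0) fps <<- rate / scale
        }
      } else if (id == "strf" && is.null(w)) {
        w <<- read_u32(bytes, body_start + 4L)
        h <<- read_u32(bytes, body_start + 8L)
        bitcount <<- read_u32(bytes, body_start + 14L) %% 65536L
        compression <<- read_u32(bytes, body_start + 16L)
      } else if (grepl("^..(db|dc)$", id) && sz > 0L) {
        frames[[length(frames) + 1L]] <<- bytes[body_start:(body_start + sz - 1L)]
      }
      p <- body_start + sz + (sz %% 2L)
    }
  }
  walk(13L, length(bytes))

  if (is.null(w) || is.null(h)) stop("cannot decode '", path, "': no stream format")
  if (!is.null(compression) && compression != 0L)
    stop("cannot decode '", path, "': compressed AVI streams are not supported ",
         "(only uncompressed RGB24)")
  if (!identical(bitcount, 24L) && !identical(bitcount, 24))
    stop("cannot decode '", path, "': only 24-bit RGB frames are supported")
  if (length(frames) == 0L) stop("cannot decode '", path, "': zero frames")
  video_clip(lapply(frames, dib_to_frame, w = w, h = h), fps = fps, bit_depth = 8L)
}

# ---- overlay rendering ------------------------------------------------------

# boundary of a mask: mask pixels with at least one 4-neighbour outside the mask
mask_boundary <- function(mask) {
  if (!any(mask)) return(mask)
  h <- nrow(mask); w <- ncol(mask)
  pad <- function(dr, dc) {
    out <- matrix(FALSE, h, w)
    rs <- seq_len(h) + dr; cs <- seq_len(w) + dc
    ok_r <- rs >= 1L & rs <= h; ok_c <- cs >= 1L & cs <= w
    out[ok_r, ok_c] <- mask[rs[ok_r], cs[ok_c]]
    out
  }
  interior <- mask & pad(-1L, 0L) & pad(1L, 0L) & pad(0L, -1L) & pad(0L, 1L)
  mask & !interior
}

overlay_frame <- function(fr, vessel_mask = NULL, exclusion_mask = NULL,
                          alpha = 0.5) {
  out <- fr
  maxv <- 255L
  if (!is.null(exclusion_mask) && any(exclusion_mask)) {
    for (ch in 1:3) {
      plane <- out[, , ch]
      tint <- c(maxv, 0L, maxv)[ch]                 # purple
      plane[exclusion_mask] <- as.integer(round(
        (1 - alpha) * plane[exclusion_mask] + alpha * tint))
      out[, , ch] <- plane
    }
  }
  if (!is.null(vessel_mask) && any(vessel_mask)) {
    b <- mask_boundary(vessel_mask)
    for (ch in 1:3) {
      plane <- out[, , ch]
      plane[b] <- c(0L, maxv, 0L)[ch]               # green boundary
      out[, , ch] <- plane
    }
  }
  out
}

#' Write an overlay video for manual verification
#'
#' Renders each original frame with the computed vessel boundary in green and
#' the saturation-exclusion zone tinted purple, then writes the result as an
#' uncompressed AVI so it can be inspected frame by frame.
#'
#' @param clip the original [video_clip].
#' @param segs list of segmented frames (see [segment_video]), one per frame.
#' @param path output AVI path.
#' @return \code{path}, invisibly.
#' @export
write_overlay_video <- function(clip, segs, path) {
  stopifnot(is_video_clip(clip))
  if (length(segs) != clip$frame_count)
    stop("need one segmented frame per clip frame (got ", length(segs),
         " for ", clip$frame_count, " frames)")
  frames <- vector("list", clip$frame_count)
  for (i in seq_len(clip$frame_count)) {
    s <- segs[[i]]
    if (!identical(dim(s$vessel_mask), c(clip$height, clip$width)))
      stop("mask dimensions of frame ", i, " do not match the clip")
    frames[[i]] <- overlay_frame(clip$frames[[i]], s$vessel_mask, s$exclusion_mask)
  }
  write_video(video_clip(frames, fps = clip$fps, bit_depth = clip$bit_depth), path)
}
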