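# Image ingestion. On-disk format of record is portable anymap (PGM/PPM,
# ASCII or binary) because the runtime carries no PNG/JPEG decoder of its own;
# if the `png` / `jpeg` packages happen to be installed those formats are read
# too. Color images are collapsed to luminance with the ITU-R 601 weights.

#' Read a portable anymap image (PGM/PPM, ASCII or binary)
#'
#' Grayscale maps are returned as-is; color maps are collapsed to ITU-R 601
#' luminance. Values are scaled to \[0, 1\] by the file's maxval.
#'
#' @param path file with magic P2, P3, P5 or P6.
#' @return numeric matrix (rows = image rows) in \[0, 1\].
#' @export
read_pnm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 2L))
  if (!magic %in% c("P2", "P3", "P5", "P6")) {
    stop("unsupported PNM magic '", magic, "' in ", path)
  }
  # header tokens (width, height, maxval) with '#' comments allowed
  toks <- integer(0)
  buf <- character(0)
  in_comment <- FALSE
  while (length(toks) < 3L) {
    ch <- rawToChar(readBin(con, "raw", 1L))
    if (length(ch) == 0L || ch == "") stop("truncated PNM header in ", path)
    if (in_comment) {
      if (ch == "\n") in_comment <- FALSE
    } else if (ch == "#") {
      in_comment <- TRUE
    } else if (grepl("[0-9]", ch)) {
      buf <- c(buf, ch)
    } else if (length(buf) > 0L) {
      toks <- c(toks, as.integer(paste(buf, collapse = "")))
      buf <- character(0)
    }
  }
  w <- toks[1]; h <- toks[2]; maxval <- toks[3]
  nch <- if (magic %in% c("P3", "P6")) 3L else 1L
  n <- w * h * nch
  vals <- if (magic %in% c("P2", "P3")) {
    as.numeric(scan(con, what = double(), n = n, quiet = TRUE))
  } else if (maxval < 256L) {
    as.numeric(readBin(con, "integer", n = n, size = 1L, signed = FALSE))
  } else {
    as.numeric(readBin(con, "integer", n = n, size = 2L, signed = FALSE,
                       endian = "big"))
  }
  if (length(vals) != n) stop("truncated PNM payload in ", path)
  if (nch == 3L) {
    # ITU-R 601 luminance
    r <- vals[seq(1L, n, 3L)]; g <- vals[seq(2L, n, 3L)]; b <- vals[seq(3L, n, 3L)]
    vals <- 0.299 * r + 0.587 * g + 0.114 * b
  }
  img <- matrix(vals, nrow = h, ncol = w, byrow = TRUE) / maxval
  img
}

#' Write a grayscale image as ASCII PGM (P2)
#'
#' @param img numeric matrix with values in \[0, 1\].
#' @param path output path.
#' @param maxval quantization maximum (default 255).
#' @export
write_pgm <- function(img, path, maxval = 255L) {
  q <- round(pmin(pmax(img, 0), 1) * maxval)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(img), nrow(img)), as.character(maxval)), con)
  apply(q, 1L, function(r) writeLines(paste(r, collapse = " "), con))
  invisible(path)
}

read_image_any <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("pgm", "ppm", "pnm")) return(read_pnm(path))
  if (ext %in% c("png") && requireNamespace("png", quietly = TRUE)) {
    a <- png::readPNG(path)
  } else if (ext %in% c("jpg", "jpeg") && requireNamespace("jpeg", quietly = TRUE)) {
    a <- jpeg::readJPEG(path)
  } else {
    stop("no decoder available for '", ext, "' (", path, ")")
  }
  if (length(dim(a)) == 3L) {
    ch <- dim(a)[3]
    if (ch >= 3L) {
      a <- 0.299 * a[, , 1] + 0.587 * a[, , 2] + 0.114 * a[, , 3]
    } else {
      a <- a[, , 1]
    }
  }
  a
}

#' Bilinear image resize
#'
#' @param img numeric matrix.
#' @param height,width target size.
#' @return resized matrix.
#' @export
resize_bilinear <- function(img, height, width) {
  h <- nrow(img); w <- ncol(img)
  if (h == height && w == width) return(img)
  # map target pixel centers into source coordinates
  ry <- if (height == 1L) rep(1, height) else seq(1, h, length.out = height)
  rx <- if (width == 1L) rep(1, width) else seq(1, w, length.out = width)
  y0 <- pmin(floor(ry), h - 1L); y1 <- y0 + 1L; fy <- ry - y0
  x0 <- pmin(floor(rx), w - 1L); x1 <- x0 + 1L; fx <- rx - x0
  if (h == 1L) { y0 <- y1 <- rep(1L, height); fy <- rep(0, height) }
  if (w == 1L) { x0 <- x1 <- rep(1L, width); fx <- rep(0, width) }
  A <- img[y0, x0, drop = FALSE]; B <- img[y0, x1, drop = FALSE]
  C <- img[y1, x0, drop = FALSE]; D <- img[y1, x1, drop = FALSE]
  FY <- matrix(fy, height, width); FX <- matrix(fx, height, width, byrow = TRUE)
  A * (1 - FY) * (1 - FX) + B * (1 - FY) * FX + C * FY * (1 - FX) + D * FY * FX
}

#' Load an image directory as a labeled image set
#'
#' Expects `root_dir/<class_name>/*.{pgm,ppm,png,jpg,jpeg}`; class ids are
#' assigned by lexicographic subdirectory order. Undecodable files are skipped
#' with a warning; a class with no decodable image is an error.
#'
#' @param root_dir directory with one subdirectory per class.
#' @param image_size `c(height, width)` all images are resized to (bilinear).
#' @return object of class `hfsof_imageset`: `images` (list of matrices in
#'   \[0,1\]), `labels` (0-based), `class_names`, `source_paths`.
#' @export
load_image_dataset <- function(root_dir, image_size = c(64L, 64L)) {
  dirs <- sort(list.dirs(root_dir, recursive = FALSE))
  if (length(dirs) < 2L) stop("no classes found (need >= 2 subdirectories)")
  images <- list(); labels <- integer(0); paths <- character(0)
  class_names <- basename(dirs)
  for (ci in seq_along(dirs)) {
    files <- sort(list.files(dirs[ci], full.names = TRUE,
                             pattern = "\\.(pgm|ppm|pnm|png|jpg|jpeg)$",
                             ignore.case = TRUE))
    ok <- 0L
    for (f in files) {
      img <- tryCatch(read_image_any(f), error = function(e) {
        warning("skipping undecodable image ", f, ": ", conditionMessage(e))
        NULL
      })
      if (is.null(img)) next
      if (any(!is.finite(img))) stop("non-finite pixel values in ", f)
      images[[length(images) + 1L]] <- resize_bilinear(img, image_size[1], image_size[2])
      labels <- c(labels, ci - 1L)
      paths <- c(paths, f)
      ok <- ok + 1L
    }
    if (ok == 0L) stop("class '", class_names[ci], "' has no decodable images")
  }
  structure(list(images = images, labels = labels, class_names = class_names,
                 source_paths = paths),
            class = "hfsof_imageset")
}

#' Flatten an image set into a feature dataset
#'
#' Images on integer scales are divided by their dtype maximum (255 or 65535)
#' so values lie in \[0,1\]; images already in \[0,1\] pass through. Each image
#' is then row-major flattened so feature `px_r_c` is pixel (row r, column c).
#'
#' @param raw an `hfsof_imageset` from [load_image_dataset()] or
#'   [generate_phantoms()].
#' @return an [hfsof_dataset] with M = height * width features.
#' @export
to_feature_dataset <- function(raw) {
  if (length(raw$images) == 0L) stop("empty image set")
  dm <- dim(raw$images[[1]])
  X <- t(vapply(raw$images, function(im) {
    if (any(!is.finite(im))) stop("non-finite pixel values")
    mx <- max(im)
    if (mx > 1) im <- im / (if (mx <= 255) 255 else 65535)
    as.numeric(t(im))  # row-major flatten
  }, numeric(prod(dm))))
  fn <- as.vector(t(outer(seq_len(dm[1]), seq_len(dm[2]),
                          function(r, c) sprintf("px_%03d_%03d", r, c))))
  hfsof_dataset(X, raw$labels, feature_names = fn, class_names = raw$class_names)
}
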