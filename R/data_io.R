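# Image/mask I/O, dataset splits, patch extraction and tiled stitching.
#
# Coordinate convention: patch origins are 0-based (row, col) with half-open
# extents, so a size-64 patch at origin (0, 0) covers rows 1..64 in R
# indexing.

ext_of <- function(path) tolower(tools::file_ext(path))

# read a raster into an [0,1] array (H x W or H x W x C)
read_raster <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read '%s': file not found", path))
  e <- ext_of(path)
  img <- switch(e,
    png = png::readPNG(path),
    tif = , tiff = tiff::readTIFF(path),
    jpg = , jpeg = jpeg::readJPEG(path),
    ppm = , pgm = read_pnm(path),
    gif = read_gif(path),
    stop(sprintf("unsupported raster format '.%s' (%s)", e, path)))
  if (is.integer(img)) img <- img / 255
  img
}

# minimal netpbm reader (P2/P3/P5/P6)
read_pnm <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  tok <- function() {
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0L) stop("truncated PNM header")
      if (ch == "#") repeat {
        ch <- readChar(con, 1L, useBytes = TRUE)
        if (length(ch) == 0L || ch == "\n") break
      } else if (!grepl("[ \t\r\n]", ch)) break
    }
    out <- ch
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0L || grepl("[ \t\r\n]", ch)) break
      out <- paste0(out, ch)
    }
    out
  }
  magic <- tok()
  if (!magic %in% c("P2", "P3", "P5", "P6")) stop("unsupported PNM magic ", magic)
  W <- as.integer(tok()); H <- as.integer(tok()); mx <- as.integer(tok())
  nch <- if (magic %in% c("P3", "P6")) 3L else 1L
  n <- W * H * nch
  vals <- if (magic %in% c("P5", "P6")) {
    if (mx < 256) as.integer(readBin(con, "raw", n))
    else readBin(con, "integer", n, size = 2L, signed = FALSE, endian = "big")
  } else scan(con, integer(), n = n, quiet = TRUE)
  v <- vals / mx
  if (nch == 1L) matrix(v, H, W, byrow = TRUE)
  else aperm(array(v, c(3L, W, H)), c(3L, 2L, 1L))
}

# GIF has no native R reader in this stack; convert through the Python
# imaging library on PATH when available.
read_gif <- function(path) {
  py <- Sys.which("python")
  if (py == "") stop("reading GIF requires a 'python' with Pillow on PATH")
  tmp <- tempfile(fileext = ".png")
  code <- sprintf(
    "from PIL import Image; Image.open(r'%s').convert('RGB').save(r'%s')",
    path, tmp)
  st <- system2(py, c("-c", shQuote(code)), stdout = FALSE, stderr = FALSE)
  if (st != 0L || !file.exists(tmp)) stop("GIF conversion via python failed for ", path)
  on.exit(unlink(tmp))
  png::readPNG(tmp)
}

to_rgb <- function(img) {
  if (length(dim(img)) == 2L) return(array(rep(img, 3L), c(dim(img), 3L)))
  if (dim(img)[3L] >= 4L) img <- img[, , 1:3, drop = FALSE]
  if (dim(img)[3L] == 1L) return(array(rep(img[, , 1L], 3L), c(dim(img)[1:2], 3L)))
  img
}

to_gray <- function(img) {
  if (length(dim(img)) == 3L) img[, , 1L] else img
}

#' Load a co-registered image/mask pair
#'
#' Reads a fundus image (or phantom) and its binary vessel ground truth,
#' rescales intensities to [0,1], replicates grayscale images to 3 channels
#' and binarizes the mask (and optional field-of-view mask) at the midpoint.
#'
#' @param image_path Path to the image (PNG/TIFF/JPEG/PPM/PGM/GIF).
#' @param mask_path Path to the vessel mask.
#' @param fov_path Optional path to the field-of-view mask.
#' @param id Source identifier; defaults to the image file name.
#' @return An object of class `"image_pair"`.
#' @export
load_image_pair <- function(image_path, mask_path, fov_path = NULL, id = NULL) {
  image <- to_rgb(read_raster(image_path))
  mask <- 1 * (to_gray(read_raster(mask_path)) > 0.5)
  if (!identical(dim(image)[1:2], dim(mask)[1:2]))
    stop(sprintf("image is %dx%d but mask is %dx%d",
                 dim(image)[1L], dim(image)[2L], dim(mask)[1L], dim(mask)[2L]))
  fov <- NULL
  if (!is.null(fov_path) && !is.na(fov_path) && nzchar(fov_path)) {
    fov <- 1 * (to_gray(read_raster(fov_path)) > 0.5)
    if (!identical(dim(fov), dim(mask)))
      stop("field-of-view mask size does not match the image")
  }
  structure(list(image = image, mask = mask, fov = fov,
                 source_id = if (is.null(id)) basename(image_path) else id),
            class = "image_pair")
}

#' @export
print.image_pair <- function(x, ...) {
  cat(sprintf("image pair '%s': %dx%d, vessel fraction %.3f%s\n",
              x$source_id, dim(x$mask)[1L], dim(x$mask)[2L],
              mean(x$mask), if (is.null(x$fov)) "" else ", with FOV"))
  invisible(x)
}

#' Dataset manifests
#'
#' A manifest is a JSON file listing, per image id, the image/mask/fov paths
#' and an optional split label.  Relative paths are resolved against the
#' manifest's directory.
#'
#' @param manifest A data frame with columns `id`, `image`, `mask`,
#'   optionally `fov` and `split`.
#' @param path Manifest file path.
#' @param dataset Dataset name stored in the manifest.
#' @return `read_manifest()` returns the data frame (with resolved paths);
#'   `write_manifest()` returns `path` invisibly.
#' @export
write_manifest <- function(manifest, path, dataset = "custom") {
  stopifnot(all(c("id", "image", "mask") %in% names(manifest)))
  jsonlite::write_json(list(dataset = dataset, images = manifest), path,
                       dataframe = "rows", auto_unbox = TRUE, null = "null",
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  df <- m$images
  base <- dirname(normalizePath(path))
  for (col in intersect(c("image", "mask", "fov"), names(df))) {
    p <- df[[col]]
    rel <- !is.na(p) & nzchar(p) & !grepl("^(/|[A-Za-z]:)", p)
    df[[col]][rel] <- file.path(base, p[rel])
  }
  attr(df, "dataset") <- m$dataset
  df
}

load_manifest_pairs <- function(path, split = NULL) {
  df <- read_manifest(path)
  if (!is.null(split) && "split" %in% names(df))
    df <- df[!is.na(df$split) & df$split == split, , drop = FALSE]
  lapply(seq_len(nrow(df)), function(i)
    load_image_pair(df$image[i], df$mask[i],
                    if ("fov" %in% names(df)) df$fov[i] else NULL,
                    id = df$id[i]))
}

#' Train/test split of the benchmark datasets
#'
#' STARE has no official division: the first 10 images (by sorted id) train
#' and the last 10 test.  DRIVE uses the official 20/20 division: ids 1-20
#' are the test set, ids 21-40 the training set.
#'
#' @param name `"STARE"` or `"DRIVE"`.
#' @param ids Character vector of image ids (20 for STARE, 40 for DRIVE).
#' @return A list with `train` and `test` id vectors.
#' @export
split_dataset <- function(name = c("STARE", "DRIVE"), ids) {
  name <- match.arg(toupper(name), c("STARE", "DRIVE"))
  ids <- sort(as.character(ids))
  if (name == "STARE") {
    if (length(ids) != 20L)
      stop(sprintf("STARE split expects 20 ids, got %d", length(ids)))
    list(train = ids[1:10], test = ids[11:20])
  } else {
    if (length(ids) != 40L)
      stop(sprintf("DRIVE split expects 40 ids, got %d", length(ids)))
    list(train = ids[21:40], test = ids[1:20])
  }
}

grid_origins <- function(n, size, stride) {
  o <- seq(0L, n - size, by = stride)
  if (tail(o, 1L) != n - size) o <- c(o, n - size)
  as.integer(o)
}

#' Extract fixed-size patches from an image pair
#'
#' @param pair An `"image_pair"`.
#' @param size Patch side in pixels (64 in the published pipeline).
#' @param strategy `"random"` (seeded uniform origins, the training default)
#'   or `"grid"` (stride lattice with the last row/column snapped inside
#'   bounds, used for tiled inference).
#' @param n Number of random patches.
#' @param stride Grid stride.
#' @param seed Seed for the random strategy.
#' @param min_fov With a FOV mask, random patches covering less than this
#'   FOV fraction are rejected (avoids training on pure border).
#' @return An object of class `"patch_set"`: list of patches, each holding
#'   `image` (`size x size x 3`), `mask` (`size x size`), 0-based `row`/`col`
#'   origin and the `source_id`.
#' @export
extract_patches <- function(pair, size = 64L, strategy = c("random", "grid"),
                            n = 500L, stride = 32L, seed = NULL,
                            min_fov = 0.5) {
  stopifnot(inherits(pair, "image_pair"))
  strategy <- match.arg(strategy)
  H <- dim(pair$mask)[1L]; W <- dim(pair$mask)[2L]
  size <- as.integer(size)
  if (H < size || W < size)
    stop(sprintf("image %dx%d is smaller than the %d patch", H, W, size))
  if (strategy == "grid") {
    og <- expand.grid(row = grid_origins(H, size, stride),
                      col = grid_origins(W, size, stride))
  } else {
    old <- get_rng_state(); on.exit(restore_rng_state(old))
    if (!is.null(seed)) set.seed(seed)
    rows <- integer(0); cols <- integer(0)
    tries <- 0L
    while (length(rows) < n && tries < 50L * n) {
      need <- n - length(rows)
      r <- sample.int(H - size + 1L, need, replace = TRUE) - 1L
      c <- sample.int(W - size + 1L, need, replace = TRUE) - 1L
      if (!is.null(pair$fov)) {
        keep <- vapply(seq_along(r), function(i)
          mean(pair$fov[r[i] + 1:size, c[i] + 1:size]) >= min_fov, logical(1))
        r <- r[keep]; c <- c[keep]
      }
      rows <- c(rows, r); cols <- c(cols, c)
      tries <- tries + need
    }
    if (length(rows) < n)
      stop("could not place the requested number of patches inside the FOV")
    og <- data.frame(row = rows[seq_len(n)], col = cols[seq_len(n)])
  }
  patches <- lapply(seq_len(nrow(og)), function(i) {
    r <- og$row[i]; c <- og$col[i]
    list(image = pair$image[r + 1:size, c + 1:size, , drop = FALSE],
         mask = pair$mask[r + 1:size, c + 1:size],
         row = r, col = c, source_id = pair$source_id)
  })
  structure(list(patches = patches, size = size, source_id = pair$source_id),
            class = "patch_set")
}

#' @export
print.patch_set <- function(x, ...) {
  cat(sprintf("patch set: %d patches of %dx%d from '%s'\n",
              length(x$patches), x$size, x$size, x$source_id))
  invisible(x)
}

rot90ccw <- function(m) t(m)[rev(seq_len(ncol(m))), , drop = FALSE]

apply_geom <- function(m, op, shift = NULL) {
  switch(op,
    hflip = m[, rev(seq_len(ncol(m))), drop = FALSE],
    vflip = m[rev(seq_len(nrow(m))), , drop = FALSE],
    rot90 = rot90ccw(m),
    rot180 = rot90ccw(rot90ccw(m)),
    rot270 = rot90ccw(rot90ccw(rot90ccw(m))),
    translate = {
      out <- matrix(0, nrow(m), ncol(m))
      dr <- shift[1L]; dc <- shift[2L]
      sr <- seq_len(nrow(m)); sc <- seq_len(ncol(m))
      tr <- sr + dr; tc <- sc + dc
      kr <- tr >= 1L & tr <= nrow(m); kc <- tc >= 1L & tc <= ncol(m)
      out[tr[kr], tc[kc]] <- m[sr[kr], sc[kc]]
      out
    },
    stop(sprintf("unknown augmentation op '%s'", op)))
}

#' Augment a patch
#'
#' Applies the listed geometric ops (in order) identically to image and
#' mask.  Flips and right-angle rotations are pure pixel permutations;
#' translation shifts with zero fill, so the mask stays binary.
#'
#' @param patch A list with `image` (`H x W x 3`) and `mask` (`H x W`), as
#'   produced by [extract_patches()].
#' @param ops Character vector from `hflip`, `vflip`, `rot90`, `rot180`,
#'   `rot270`, `translate`.
#' @param shift Integer `(rows, cols)` shift for `translate`; when missing,
#'   drawn uniformly from [-8, 8] per axis (seeded by `seed`).
#' @param seed Optional seed for the random shift.
#' @return The augmented patch (same structure).
#' @export
augment <- function(patch, ops, shift = NULL, seed = NULL) {
  known <- c("hflip", "vflip", "rot90", "rot180", "rot270", "translate")
  bad <- setdiff(ops, known)
  if (length(bad) > 0L)
    stop(sprintf("unknown augmentation op '%s'", bad[1L]))
  for (op in ops) {
    if (op == "translate" && is.null(shift)) {
      if (!is.null(seed)) {
        old <- get_rng_state()
        set.seed(seed)
        shift <- sample(-8:8, 2L, replace = TRUE)
        restore_rng_state(old)
      } else {
        shift <- sample(-8:8, 2L, replace = TRUE)
      }
    }
    img <- patch$image
    chans <- lapply(seq_len(dim(img)[3L]), function(c)
      apply_geom(img[, , c], op, shift))
    patch$image <- array(unlist(chans), c(dim(chans[[1L]]), dim(img)[3L]))
    patch$mask <- apply_geom(patch$mask, op, shift)
  }
  patch
}

#' Stitch tiled predictions into a full-size probability map
#'
#' Overlapping tiles are averaged per pixel; pixels covered by no tile are
#' `NA` (flagged invalid).
#'
#' @param tiles List of lists with `prob` (matrix) and 0-based `row`/`col`
#'   origins.
#' @param full_shape Integer `(height, width)` of the output.
#' @return A list with `prob` (matrix, `NA` where uncovered) and `coverage`
#'   (tile count per pixel).
#' @export
stitch_predictions <- function(tiles, full_shape) {
  H <- full_shape[1L]; W <- full_shape[2L]
  acc <- matrix(0, H, W); cnt <- matrix(0L, H, W)
  for (tl in tiles) {
    p <- tl$prob
    r <- tl$row; c <- tl$col
    if (r < 0L || c < 0L || r + nrow(p) > H || c + ncol(p) > W)
      stop(sprintf("tile at (%d,%d) of %dx%d exceeds the %dx%d canvas",
                   r, c, nrow(p), ncol(p), H, W))
    ri <- r + seq_len(nrow(p)); ci <- c + seq_len(ncol(p))
    acc[ri, ci] <- acc[ri, ci] + p
    cnt[ri, ci] <- cnt[ri, ci] + 1L
  }
  prob <- acc / cnt
  prob[cnt == 0L] <- NA_real_
  list(prob = prob, coverage = cnt)
}

#' Threshold a probability map
#'
#' Strictly-greater-than convention: a pixel at exactly the threshold is
#' background.
#'
#' @param prob Numeric array/matrix with values in [0,1] (`NA` allowed).
#' @param threshold Decision threshold (default 0.5).
#' @return Binary array of the same shape (`NA` preserved).
#' @export
binarize <- function(prob, threshold = 0.5) {
  rng <- range(prob, na.rm = TRUE)
  if (rng[1L] < 0 || rng[2L] > 1) stop("probabilities must lie in [0,1]")
  out <- 1 * (prob > threshold)
  out
}

#' Write a probability map as an 8-bit PNG
#'
#' Pixel value = `round(255 * p)`; `NA` pixels are written as 0.
#'
#' @param prob Probability matrix in [0,1].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_probability_png <- function(prob, path) {
  p <- prob
  p[is.na(p)] <- 0
  png::writePNG(round(255 * p) / 255, path)
  invisible(path)
}
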