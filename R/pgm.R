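# Plain-text PGM (P2) export for slice previews and feature-map montages:
# dependency-free and diff-able, at the cost of file size. Intended for
# quick inspection, not archival storage.

#' Write a matrix as a plain-text PGM image
#'
#' Values are min-max normalized to 0..maxval unless `normalize = FALSE`
#' (then clipped from `[0,1]`).
#'
#' @param img numeric matrix (rows = image rows)
#' @param path output file
#' @param maxval grey levels (default 255)
#' @param normalize min-max normalize per image
#' @export
write_pgm <- function(img, path, maxval = 255L, normalize = TRUE) {
  stopifnot(is.matrix(img))
  if (normalize) {
    rng <- range(img)
    img <- if (diff(rng) > 0) (img - rng[1]) / diff(rng) else img * 0
  } else {
    img <- clip01(img)
  }
  q <- round(img * maxval)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", sprintf("%d %d", ncol(q), nrow(q)),
               as.character(maxval)), con)
  write(t(q), file = con, ncolumns = ncol(q))
  invisible(path)
}

# Tile a (H, W, C) stack (or single matrix) into one near-square grid,
# each tile normalized independently, 1-px separators.
write_pgm_montage <- function(maps, path, maxval = 255L) {
  if (is.matrix(maps)) maps <- array(maps, c(dim(maps), 1L))
  d <- dim(maps)
  nc <- ceiling(sqrt(d[3]))
  nr <- ceiling(d[3] / nc)
  grid <- matrix(0, nr * (d[1] + 1) - 1, nc * (d[2] + 1) - 1)
  for (i in seq_len(d[3])) {
    tile <- maps[, , i]
    rng <- range(tile)
    tile <- if (diff(rng) > 0) (tile - rng[1]) / diff(rng) else tile * 0
    r0 <- ((i - 1) %/% nc) * (d[1] + 1)
    c0 <- ((i - 1) %% nc) * (d[2] + 1)
    grid[r0 + seq_len(d[1]), c0 + seq_len(d[2])] <- tile
  }
  write_pgm(grid, path, maxval, normalize = FALSE)
}

#' Export a slice pair as a side-by-side preview image
#'
#' Writes HR | LR (bicubic) | absolute residual as one PGM triptych.
#'
#' @param pair a `slice_pair`
#' @param path output file
#' @export
write_pair_preview <- function(pair, path) {
  stopifnot(inherits(pair, "slice_pair"))
  res <- abs(pair$hr - pair$lr)
  res <- if (max(res) > 0) res / max(res) else res
  sep <- matrix(1, nrow(pair$hr), 1)
  write_pgm(cbind(pair$hr, sep, pair$lr, sep, res), path, normalize = FALSE)
}
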