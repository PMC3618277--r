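## genome-binned density tracks and blockwise correlation profiles

#' Bin variant counts into fixed-width genome windows
#'
#' Windows of `window_size` bp tile each contig from offset 0 (the last
#' window may be short); a variant is counted in the window containing its
#' start offset.  Counts are returned per variant class plus an
#' `"all"` class.
#'
#' @param variants variant table.
#' @param contig_lengths named integer vector of contig lengths.
#' @param window_size window width in bp (> 0).
#' @return `data.table` (`contig`, `class`, `window` (0-based index),
#'   `start`, `end`, `count`) including zero-count windows.
#' @export
bin_counts <- function(variants, contig_lengths, window_size) {
  if (window_size <= 0L) stop("window_size must be > 0")
  grid <- rbindlist(lapply(names(contig_lengths), function(ctg) {
    nw <- ceiling(contig_lengths[[ctg]] / window_size)
    data.table(contig = ctg, window = seq_len(nw) - 1L)
  }))
  classes <- c("all", VTYPES)
  grid <- grid[, .(class = classes), by = .(contig, window)]
  v <- copy(variants)[, window := start %/% as.integer(window_size)]
  cnt <- rbind(
    v[, .(count = .N), by = .(contig, window, class = vtype)],
    v[, .(count = .N), by = .(contig, window)][, class := "all"],
    use.names = TRUE
  )
  out <- merge(grid, cnt, by = c("contig", "window", "class"), all.x = TRUE)
  out[is.na(count), count := 0L]
  out[, start := window * as.integer(window_size)]
  out[, end := pmin(start + as.integer(window_size),
                    contig_lengths[contig])]
  setorder(out, contig, class, window)
  out[]
}

#' Extract one class's aligned count vector from a track
#'
#' @param track a [bin_counts()] result.
#' @param cls variant class label.
#' @return numeric vector ordered by contig and window.
#' @export
track_counts <- function(track, cls) {
  track[class == cls][order(contig, window)]$count
}

#' Blockwise Pearson correlation of two window tracks
#'
#' The aligned tracks are cut into disjoint blocks of `block` consecutive
#' windows (a trailing partial block is dropped unless `keep_partial`);
#' within each block the Pearson correlation of the two count vectors is
#' computed.  Blocks where either vector is constant yield `NA` (an
#' undefined marker, not a number).
#'
#' @param x,y aligned numeric count vectors (equal length).
#' @param block windows per block (>= 3).
#' @param keep_partial keep a trailing block shorter than `block`?
#' @return `data.table` (`block`, `from`, `to`, `r`).
#' @export
blockwise_correlation <- function(x, y, block = 100L, keep_partial = FALSE) {
  if (length(x) != length(y)) stop("alignment error: track length mismatch")
  if (block < 3L) stop("block must be >= 3")
  n_full <- length(x) %/% block
  idx <- seq_len(n_full * block)
  grp <- rep(seq_len(n_full), each = block)
  if (keep_partial && length(x) %% block >= 3L) {
    extra <- seq(n_full * block + 1L, length(x))
    idx <- c(idx, extra)
    grp <- c(grp, rep(n_full + 1L, length(extra)))
  }
  rs <- vapply(split(idx, grp), function(i) {
    if (sd(x[i]) == 0 || sd(y[i]) == 0) NA_real_ else cor(x[i], y[i])
  }, numeric(1L))
  bl <- as.integer(names(rs))
  data.table(block = bl,
             from = vapply(split(idx, grp), min, integer(1L)),
             to = vapply(split(idx, grp), max, integer(1L)),
             r = unname(rs))
}

#' Per-window proportion track (e.g. novel / total)
#'
#' @param num,den aligned numeric count vectors.
#' @return numeric vector with `NA` where `den == 0` (0/0 undefined).
#' @export
proportion_track <- function(num, den) {
  if (length(num) != length(den)) stop("alignment error")
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

#' Write a window track as BED (count as score)
#'
#' @param track a [bin_counts()] result (one class).
#' @param path output file.
#' @export
write_bed <- function(track, path) {
  fwrite(track[, .(contig, start, end,
                   name = paste0(class, "_", window), score = count)],
         path, sep = "\t", col.names = FALSE)
  invisible(path)
}
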