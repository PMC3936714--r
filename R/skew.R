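# Nucleotide-disparity (GC/AT skew) corroboration of origin positions.
#
# On a circular replicon replicated bidirectionally, the leading strand
# accumulates a G-over-C excess, so the cumulative (G - C) curve switches
# direction at the origin and terminus: its global extrema flank the
# origin/terminus pair. Because the running sum is anchored at coordinate 0
# of the record, only the extrema positions are meaningful on a circle, not
# the curve's absolute values.

#' Compute windowed and cumulative GC/AT skew
#'
#' Windowed skew is `(G - C)/(G + C)` (and `(A - T)/(A + T)`) over sliding
#' windows; windows wrap on circular replicons. The cumulative track is the
#' running sum of per-step `(G - C)` counts from coordinate 0, so its final
#' value equals the replicon's total `G - C`.
#'
#' @param replicon A [replicon()].
#' @param window Window size in bp for the windowed skews.
#' @param step Step between window starts in bp.
#' @return A `SkewTrack` list: `positions` (window starts), `gc_skew`,
#'   `at_skew`, `cum_gc`, plus the parameters.
#' @export
compute_skew <- function(replicon, window = 1000L, step = 100L) {
  stopifnot(inherits(replicon, "Replicon"), window <= replicon$length,
            step >= 1L)
  L <- replicon$length
  circ <- replicon$topology == "circular"
  ch <- strsplit(replicon$sequence, "")[[1]]
  pg <- c(0L, cumsum(ch == "G"))
  pc <- c(0L, cumsum(ch == "C"))
  pa <- c(0L, cumsum(ch == "A"))
  pt <- c(0L, cumsum(ch == "T"))
  cnt <- function(pre, s, e) {  # count in [s, e), wrapping past L
    if (e <= L) pre[e + 1L] - pre[s + 1L]
    else (pre[L + 1L] - pre[s + 1L]) + pre[e - L + 1L]
  }
  starts <- seq.int(0L, L - 1L, by = step)
  if (!circ) starts <- starts[starts + window <= L]
  n <- length(starts)
  gc_skew <- at_skew <- cum_gc <- numeric(n)
  for (i in seq_len(n)) {
    s <- starts[i]
    g <- cnt(pg, s, s + window); c_ <- cnt(pc, s, s + window)
    a <- cnt(pa, s, s + window); t_ <- cnt(pt, s, s + window)
    gc_skew[i] <- if (g + c_ > 0) (g - c_) / (g + c_) else 0
    at_skew[i] <- if (a + t_ > 0) (a - t_) / (a + t_) else 0
    e <- min(s + step, L)  # non-overlapping step blocks tile the replicon
    cum_gc[i] <- (pg[e + 1L] - pg[s + 1L]) - (pc[e + 1L] - pc[s + 1L])
  }
  structure(list(replicon_id = replicon$id, positions = starts,
                 gc_skew = gc_skew, at_skew = at_skew,
                 cum_gc = cumsum(cum_gc),
                 window = as.integer(window), step = as.integer(step)),
            class = "SkewTrack")
}

#' @export
print.SkewTrack <- function(x, ...) {
  cat(sprintf("<SkewTrack> %s: %d windows (window %d bp, step %d bp)\n",
              x$replicon_id, length(x$positions), x$window, x$step))
  invisible(x)
}

#' Positions of the cumulative-skew extrema
#'
#' The global minimum and maximum of the cumulative `(G - C)` track; under
#' bidirectional replication these flank the origin/terminus pair. Ties are
#' broken toward the lowest coordinate.
#'
#' @param track A [compute_skew()] track.
#' @return Named numeric vector `c(min_position, max_position)` in bp.
#' @export
skew_extrema <- function(track) {
  stopifnot(inherits(track, "SkewTrack"), length(track$positions) > 0L)
  c(min_position = track$positions[which.min(track$cum_gc)],
    max_position = track$positions[which.max(track$cum_gc)])
}
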