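# Marker-frequency analysis: profiles, smoothing, peak calling,
# deletion-strain comparison, and origin-usage fitting.

#' Build a marker-frequency profile from two-channel signals
#'
#' Each replicate's channels are scaled so the stationary channel has median
#' 1 (a robust, scale-free normalisation; the ratio itself is invariant to
#' any common scaling of a replicate's two channels), the per-probe
#' exponential:stationary ratio is formed, and replicate ratios are averaged
#' per probe. Probes with a non-positive signal in a replicate are dropped
#' from that replicate with a warning.
#'
#' @param signals A `SignalTable` from [simulate_marker_frequency()] or read
#'   from TSV; must cover exactly one replicon.
#' @param replicon_length Length of the replicon (taken from the signal
#'   table's attribute when present).
#' @return An object of class `MarkerProfile`: `replicon_id`, sorted
#'   `positions`, replicate-averaged `ratio`, `n_replicates`,
#'   `replicon_length`.
#' @export
make_profile <- function(signals, replicon_length = NULL) {
  signals <- as.data.frame(signals)
  stopifnot(all(c("replicon_id", "position", "exp_signal", "stat_signal",
                  "replicate") %in% names(signals)))
  rid <- unique(signals$replicon_id)
  if (length(rid) != 1L) {
    stop("signals span multiple replicons; split by replicon_id first",
         call. = FALSE)
  }
  if (is.null(replicon_length)) {
    replicon_length <- attr(signals, "replicon_length")
  }
  bad <- signals$exp_signal <= 0 | signals$stat_signal <= 0
  if (any(bad)) {
    warning(sprintf("dropping %d probe measurement(s) with non-positive signal",
                    sum(bad)))
    signals <- signals[!bad, , drop = FALSE]
  }
  if (!nrow(signals)) stop("all probes dropped", call. = FALSE)

  reps <- split(signals, signals$replicate)
  ratio_by_rep <- lapply(reps, function(s) {
    m <- median(s$stat_signal)
    data.frame(position = s$position,
               ratio = (s$exp_signal / m) / (s$stat_signal / m))
  })
  merged <- do.call(rbind, ratio_by_rep)
  agg <- stats::aggregate(ratio ~ position, data = merged, FUN = mean)
  agg <- agg[order(agg$position), ]
  structure(list(replicon_id = rid,
                 positions = agg$position,
                 ratio = agg$ratio,
                 n_replicates = length(reps),
                 replicon_length = replicon_length),
            class = "MarkerProfile")
}

#' @export
print.MarkerProfile <- function(x, ...) {
  cat(sprintf("<MarkerProfile> %s: %d probes, %d replicate(s), ratio %.3f-%.3f\n",
              x$replicon_id, length(x$positions), x$n_replicates,
              min(x$ratio), max(x$ratio)))
  invisible(x)
}

#' Smooth a marker-frequency profile
#'
#' Centred moving average of the log2 ratios over a window of probes, with
#' circular wrap-around (replicons are circular). `window = 1` is the
#' identity.
#'
#' @param p A [make_profile()] object.
#' @param window Odd window size in probes.
#' @return A smoothed `MarkerProfile`.
#' @export
smooth_profile <- function(p, window = 5L) {
  stopifnot(inherits(p, "MarkerProfile"))
  if (window < 1L || window %% 2L == 0L) {
    stop("window must be odd and >= 1", call. = FALSE)
  }
  if (window == 1L) return(p)
  y <- log2(p$ratio)
  sm <- as.numeric(stats::filter(y, rep(1 / window, window), sides = 2,
                                 circular = TRUE))
  p$ratio <- 2^sm
  p
}

# Candidate local maxima of a circular series, one apex per plateau
# (apex = lowest coordinate of the plateau; downstream selection prefers the
# highest probe by construction since plateaus are flat).
circular_local_maxima <- function(y) {
  n <- length(y)
  if (n < 3L) return(integer())
  yl <- y[c(n, seq_len(n - 1L))]
  yr <- y[c(seq.int(2L, n), 1L)]
  cand <- which(y >= yl & y >= yr & (y > yl | y > yr))
  cand
}

# Topographic prominence of candidate i on a circular series: descend on
# each side until a strictly higher point; the key saddle is the higher of
# the two path minima. For the global maximum the reference is the global
# minimum. Returns prominence, height over the lower base, and base indices.
circular_prominence <- function(y, i) {
  n <- length(y)
  walk <- function(step) {
    m <- y[i]
    base <- i
    j <- i
    for (s in seq_len(n - 1L)) {
      j <- ((j - 1L + step) %% n) + 1L
      if (y[j] > y[i]) return(list(min = m, base = base, found = TRUE))
      if (y[j] < m) {
        m <- y[j]
        base <- j
      }
    }
    list(min = m, base = base, found = FALSE)
  }
  left <- walk(-1L)
  right <- walk(1L)
  if (!left$found && !right$found) {
    gm <- which.min(y)
    return(list(prominence = y[i] - y[gm], height = y[i] - y[gm],
                left_base = gm, right_base = gm))
  }
  list(prominence = y[i] - max(left$min, right$min),
       height = y[i] - min(left$min, right$min),
       left_base = left$base, right_base = right$base)
}

#' Call origin peaks on a marker-frequency profile
#'
#' Local maxima of the circular log2 profile with topographic prominence at
#' least `min_prominence` are kept greedily in order of decreasing
#' prominence, subject to a minimum circular separation between apexes.
#' Run the profile through [smooth_profile()] first for noisy data.
#'
#' @param p A (smoothed) `MarkerProfile`.
#' @param min_prominence Minimum prominence in log2 units.
#' @param min_separation Minimum apex separation in bp.
#' @return An `MFAPeak` data frame: `position` (apex bp), `height` (log2
#'   above the lower flanking trough), `span_start`, `span_end` (bp of the
#'   flanking troughs) and `prominence` (log2 above the key saddle).
#' @export
call_peaks <- function(p, min_prominence = 0.1, min_separation = 50000) {
  stopifnot(inherits(p, "MarkerProfile"))
  y <- log2(p$ratio)
  pos <- p$positions
  n <- length(y)
  empty <- data.frame(position = numeric(), height = numeric(),
                      span_start = numeric(), span_end = numeric(),
                      prominence = numeric())
  cand <- circular_local_maxima(y)
  if (!length(cand)) return(empty)
  info <- lapply(cand, function(i) circular_prominence(y, i))
  prom <- vapply(info, `[[`, numeric(1), "prominence")
  keep <- prom >= min_prominence
  cand <- cand[keep]
  info <- info[keep]
  prom <- prom[keep]
  if (!length(cand)) return(empty)
  ord <- order(-prom, pos[cand])
  L <- p$replicon_length
  sel <- integer()
  for (j in ord) {
    apex <- pos[cand[j]]
    if (!length(sel) ||
        all(circular_distance(apex, pos[cand[sel]], L) >= min_separation)) {
      sel <- c(sel, j)
    }
  }
  sel <- sel[order(pos[cand[sel]])]
  data.frame(position = pos[cand[sel]],
             height = vapply(info[sel], `[[`, numeric(1), "height"),
             span_start = pos[vapply(info[sel], `[[`, numeric(1),
                                     "left_base")],
             span_end = pos[vapply(info[sel], `[[`, numeric(1),
                                   "right_base")],
             prominence = prom[sel])
}

# Probe indices covered by a (possibly wrapping) peak span.
span_indices <- function(positions, span_start, span_end) {
  if (span_start <= span_end) {
    which(positions >= span_start & positions <= span_end)
  } else {
    which(positions >= span_start | positions <= span_end)
  }
}

#' Compare origin peaks between a reference and a mutant strain
#'
#' For each reference peak, the mutant's peak height is measured on the same
#' span as apex-over-saddle: the mutant log2 ratio at the reference apex
#' minus the higher of its values at the two reference trough positions
#' (so a monotone mutant profile across the span, the signature of passive
#' replication by a remaining origin, scores near zero). The peak is `lost`
#' when this height is below half the reference prominence and below
#' `min_prominence`; otherwise `retained`.
#'
#' @param reference,mutant `MarkerProfile`s on the same array design.
#' @param peaks Peaks called on `reference` with [call_peaks()].
#' @param min_prominence Absolute floor in log2 units.
#' @return Data frame `position`, `mutant_height`, `status`
#'   (`"retained"`/`"lost"`).
#' @export
compare_strains <- function(reference, mutant, peaks, min_prominence = 0.1) {
  stopifnot(inherits(reference, "MarkerProfile"),
            inherits(mutant, "MarkerProfile"))
  if (!identical(reference$positions, mutant$positions)) {
    stop("profiles are on different probe grids", call. = FALSE)
  }
  ym <- log2(mutant$ratio)
  pos <- reference$positions
  status <- character(nrow(peaks))
  mh <- numeric(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    apex_idx <- which.min(abs(pos - peaks$position[i]))
    base_idx <- c(which.min(abs(pos - peaks$span_start[i])),
                  which.min(abs(pos - peaks$span_end[i])))
    mh[i] <- ym[apex_idx] - max(ym[base_idx])
    lost <- mh[i] < 0.5 * peaks$prominence[i] && mh[i] < min_prominence
    status[i] <- if (lost) "lost" else "retained"
  }
  data.frame(position = peaks$position, mutant_height = mh, status = status,
             stringsAsFactors = FALSE)
}

#' Fit per-origin firing probabilities to a marker-frequency profile
#'
#' Inverse problem for the population forward model: a grid search over
#' per-origin firing probabilities and the fork time scale
#' `t_ter/tau` (terminus replication time over doubling time; the
#' replication-speed parameter the profile shape depends on) minimising the
#' squared log2 error between the observed profile and the closed-form
#' expected profile. Origins are assumed to be able to fire at cell birth
#' (no firing delays) -- a simplification that keeps the fit identifiable.
#'
#' @param p A `MarkerProfile`.
#' @param origin_positions Known origin positions in bp (1-4 origins).
#' @param p_grid Candidate firing probabilities.
#' @param t_grid Candidate `t_ter/tau` values, where
#'   `t_ter = (L/2)/fork_speed`.
#' @return A `UsageFit` list: `firing_prob` (named by origin position),
#'   `fork_time_scale`, and `rss`.
#' @export
fit_origin_usage <- function(p, origin_positions,
                             p_grid = seq(0, 1, by = 0.05),
                             t_grid = seq(0.2, 2.0, by = 0.1)) {
  stopifnot(inherits(p, "MarkerProfile"), length(origin_positions) >= 1L,
            length(origin_positions) <= 4L)
  pos <- p$positions
  L <- p$replicon_length
  snapped <- vapply(origin_positions, function(o) {
    i <- which.min(circular_distance(pos, o %% L, L))
    pos[i]
  }, numeric(1))
  if (any(snapped != origin_positions)) {
    warning("origin position(s) off the probe grid; snapped to nearest probe")
  }
  k <- length(snapped)
  obs <- log2(p$ratio)
  frac <- t(vapply(snapped, function(o) {
    circular_distance(pos, o, L) / (L / 2)
  }, numeric(length(pos))))  # k x npos, distance as fraction of half-length

  combos <- as.matrix(expand.grid(rep(list(p_grid), k)))
  nsub <- 2^k
  W <- matrix(0, nrow(combos), nsub)
  for (m in 0:(nsub - 1)) {
    bits <- bitwAnd(m, 2^(seq_len(k) - 1)) > 0
    w <- rep(1, nrow(combos))
    for (j in seq_len(k)) {
      w <- w * if (bits[j]) combos[, j] else 1 - combos[, j]
    }
    W[, m + 1] <- w
  }

  best <- list(rss = Inf)
  for (theta in t_grid) {
    CS <- matrix(1, nsub, length(pos))
    for (m in 1:(nsub - 1)) {
      bits <- bitwAnd(m, 2^(seq_len(k) - 1)) > 0
      sel <- which(bits)
      tS <- if (length(sel) == 1L) frac[sel, ] else
        do.call(pmin, lapply(sel, function(i) frac[i, ]))
      CS[m + 1, ] <- 1 + pmin(pmax(2^(1 - theta * tS) - 1, 0), 1)
    }
    E <- W %*% CS
    rss <- rowSums((log2(E) - rep(obs, each = nrow(E)))^2)
    i <- which.min(rss)
    if (rss[i] < best$rss) {
      best <- list(rss = rss[i], p = combos[i, ], theta = theta)
    }
  }
  structure(list(firing_prob = setNames(as.numeric(best$p),
                                        as.character(snapped)),
                 fork_time_scale = best$theta,
                 rss = best$rss),
            class = "UsageFit")
}

#' @export
print.UsageFit <- function(x, ...) {
  cat("<UsageFit>\n  firing probabilities:\n")
  for (nm in names(x$firing_prob)) {
    cat(sprintf("    origin @ %s bp: %.2f\n", nm, x$firing_prob[[nm]]))
  }
  cat(sprintf("  t_ter/tau: %.2f   rss: %.4f\n", x$fork_time_scale, x$rss))
  invisible(x)
}
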