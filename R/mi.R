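#' Configuration of the mutual-information estimator
#'
#' Free parameters of the adaptive inter-spike-interval partition MI
#' estimator: the minimum number of events a contact must have for its
#' train to be estimable at all, the target number of pooled events per
#' partition cell (which sets the cell width through the mean pooled
#' inter-spike interval), and the cap applied to per-cell counts before the
#' plug-in estimate (capping bounds the joint alphabet and hence the
#' plug-in bias, which grows with the support size).
#'
#' @param min_events_per_contact Trains shorter than this return a
#'   not-estimable marker (`NA`) rather than 0. Default 5.
#' @param target_events_per_cell Sets the cell width to
#'   `target_events_per_cell` times the mean pooled inter-spike interval.
#'   Default 1: cells at the mean-ISI scale act as coincidence detectors,
#'   which maximizes sensitivity to event-timing coupling while keeping
#'   the plug-in bias of independent trains negligible.
#' @param count_cap Per-cell counts are recorded as `min(n, count_cap)`.
#'   Default 2 (alphabet 0, 1, >=2); capping bounds the joint alphabet and
#'   hence the plug-in bias.
#' @return A list of class `mi_config`.
#' @export
mi_config <- function(min_events_per_contact = 5, target_events_per_cell = 1,
                      count_cap = 2) {
  stopifnot(min_events_per_contact >= 1, target_events_per_cell >= 1,
            count_cap >= 1)
  structure(list(min_events_per_contact = as.integer(min_events_per_contact),
                 target_events_per_cell = as.integer(target_events_per_cell),
                 count_cap = as.integer(count_cap)),
            class = "mi_config")
}

#' Adaptive-partition cell counts for a pair of event trains
#'
#' Implements the partition underlying [estimate_mi()]: the recording is
#' divided into contiguous cells of equal width `target` times the mean
#' pooled inter-spike interval (`target * duration / n_pooled`), anchored
#' at the first pooled event. The width therefore adapts to the joint
#' event density of the pair -- sparse pairs get wide cells, dense pairs
#' narrow ones, holding the expected pooled count per cell at `target` --
#' and the anchoring makes the cell counts invariant to a common time
#' shift of both trains. Returned counts are raw (uncapped).
#'
#' Equal widths matter: cells with data-dependent variable widths would
#' make both trains' counts covary with the local width, which reads as
#' spurious mutual information between independent trains.
#'
#' @param x,y Sorted onset-time vectors (seconds).
#' @param duration_s Recording duration in seconds.
#' @param target Target mean pooled events per cell.
#' @return Data frame with one row per cell: `n_x`, `n_y` counts.
#' @export
mi_cell_counts <- function(x, y, duration_s, target = 1) {
  cc <- mi_counts(x, y, duration_s, target)
  data.frame(n_x = cc$n_x, n_y = cc$n_y)
}

mi_counts <- function(x, y, duration_s, target) {
  pooled <- sort(c(x, y))
  n <- length(pooled)
  width <- target * duration_s / n
  if (n < 2L || width >= duration_s) {
    bounds <- c(0, duration_s)
  } else {
    # equal-width grid spanning the first to the last pooled event: with
    # all interior boundaries tied to the first event, the cell counts are
    # invariant to a common time shift of both trains (empty leading or
    # trailing stretches of the recording never add cells)
    cuts <- seq(pooled[1], pooled[n], by = width)
    bounds <- unique(c(0, cuts, duration_s))
  }
  list(n_x = count_in_cells(x, bounds), n_y = count_in_cells(y, bounds))
}

count_in_cells <- function(t, bounds) {
  k <- length(bounds) - 1L
  idx <- findInterval(t, bounds, rightmost.closed = TRUE, left.open = TRUE)
  idx[idx < 1L] <- 1L   # events exactly at 0 fall in the first cell
  idx[idx > k] <- k
  tabulate(idx, nbins = k)
}

# TRUE when train a sorts strictly before train b (length, then values).
train_before <- function(a, b) {
  if (length(a) != length(b)) return(length(a) < length(b))
  d <- which(a != b)
  if (!length(d)) return(FALSE)
  a[d[1]] < b[d[1]]
}

# Plug-in mutual information (bits) of a paired count sample.
plugin_mi <- function(nx, ny) {
  k <- length(nx)
  nxl <- max(nx) - min(nx) + 1L
  nyl <- max(ny) - min(ny) + 1L
  joint <- tabulate((nx - min(nx)) * nyl + (ny - min(ny)) + 1L,
                    nbins = nxl * nyl)
  px <- tabulate(nx - min(nx) + 1L, nbins = nxl) / k
  py <- tabulate(ny - min(ny) + 1L, nbins = nyl) / k
  pj <- joint / k
  mi <- 0
  for (ii in seq_len(nxl)) {
    if (px[ii] == 0) next
    for (jj in seq_len(nyl)) {
      p <- pj[(ii - 1L) * nyl + jj]
      if (p > 0 && py[jj] > 0)
        mi <- mi + p * log2(p / (px[ii] * py[jj]))
    }
  }
  max(mi, 0)
}

# Plug-in entropy (bits) of a count sample; the MI(x, x) identity oracle.
plugin_entropy <- function(nx) {
  p <- as.numeric(table(nx)) / length(nx)
  -sum(p * log2(p))
}

#' Mutual information between two event onset trains
#'
#' Estimates the mutual information, in bits, between two point-process
#' event trains. The recording is partitioned into cells adapted to the
#' pooled inter-spike-interval structure (see [mi_cell_counts()]); per-cell
#' event counts of the two trains, capped at `count_cap`, form a paired
#' categorical sample whose plug-in mutual information is returned. The
#' estimator is exactly symmetric in its arguments, invariant to a common
#' time shift of both trains, and non-negative. For identical trains it
#' equals the plug-in entropy of the (capped) cell-count histogram.
#'
#' Trains shorter than `min_events_per_contact` are flagged not estimable
#' (`NA_real_`), distinct from an estimated zero.
#'
#' @param x,y Numeric vectors of onset times in seconds, sorted ascending.
#' @param duration_s Recording duration (seconds), > 0.
#' @param config An [mi_config()].
#' @return Mutual information in bits, or `NA_real_` when not estimable.
#' @export
estimate_mi <- function(x, y, duration_s, config = mi_config()) {
  stopifnot(duration_s > 0)
  if (length(x) < config$min_events_per_contact ||
      length(y) < config$min_events_per_contact)
    return(NA_real_)
  # canonical argument order so estimate_mi(x, y) == estimate_mi(y, x)
  # exactly, down to floating-point summation order
  if (train_before(y, x)) { tmp <- x; x <- y; y <- tmp }
  cc <- mi_counts(x, y, duration_s, config$target_events_per_cell)
  if (length(cc$n_x) < 2L) return(0)
  plugin_mi(pmin(cc$n_x, config$count_cap), pmin(cc$n_y, config$count_cap))
}
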