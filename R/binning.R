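# Partition observed carrier positions into contiguous bins of roughly equal
# carrier count.
#
# The scan statistic is computed per bin, so bins must (i) jointly cover
# every observed carrier position, (ii) never split the carriers observed at
# a single position (founder hotspots stay together), and (iii) hold counts
# as close to equal as the hotspot structure allows. No algorithm is forced
# by the equal-count goal alone; this implementation cuts at empirical
# quantiles of the carrier-position multiset and then repairs boundaries
# locally, moving a cut one observed position left or right whenever that
# reduces the max - min bin-count spread.

bin_counts_from_cuts <- function(cum, cuts) {
  diff(c(0L, cum[cuts], cum[length(cum)]))
}

quantile_cuts <- function(counts, k) {
  m <- length(counts)
  if (k == 1L) {
    return(integer(0))
  }
  cum <- cumsum(counts)
  N <- cum[m]
  cuts <- integer(k - 1L)
  prev <- 0L
  for (j in seq_len(k - 1L)) {
    lo <- prev + 1L
    hi <- m - (k - j) # leave >= 1 position per remaining bin
    target <- j * N / k
    cand <- lo:hi
    cuts[j] <- cand[which.min(abs(cum[cand] - target))]
    prev <- cuts[j]
  }
  cuts
}

repair_cuts <- function(counts, cuts, max_pass = 20L) {
  m <- length(counts)
  cum <- cumsum(counts)
  spread <- function(cc) {
    b <- bin_counts_from_cuts(cum, cc)
    max(b) - min(b)
  }
  best <- spread(cuts)
  for (pass in seq_len(max_pass)) {
    improved <- FALSE
    for (j in seq_along(cuts)) {
      for (delta in c(-1L, 1L)) {
        cand <- cuts
        cand[j] <- cuts[j] + delta
        lo <- if (j == 1L) 1L else cand[j - 1L] + 1L
        hi <- if (j == length(cuts)) m - 1L else cand[j + 1L] - 1L
        if (cand[j] < lo || cand[j] > hi) next
        s <- spread(cand)
        if (s < best) {
          cuts <- cand
          best <- s
          improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  cuts
}

#' Build near-equal-carrier bins over observed CDS positions
#'
#' @param positions carrier-position multiset: a data frame with one row per
#'   carrier (columns `base`, optional `offset`). All carriers observed at
#'   one position always land in one bin.
#' @param n_bins number of bins; alternatively give `carriers_per_bin` and
#'   the bin count is `round(n_carriers / carriers_per_bin)` (at least 1).
#' @param carriers_per_bin target carriers per bin, used when `n_bins` is
#'   `NULL`. Default 60 (the scale at which the scan was designed:
#'   roughly 58 carriers/bin for BRCA1, 42 for BRCA2).
#' @return data frame with columns `bin`, `n_carriers`, `start`, `end`
#'   (position tokens), and `start_base`, `start_offset`, `end_base`,
#'   `end_offset`. Bins are sorted, non-overlapping, and span observed
#'   positions only (gaps between consecutive bins are expected).
#' @export
build_bins <- function(positions, n_bins = NULL, carriers_per_bin = 60) {
  if (!is.data.frame(positions) || is.null(positions$base)) {
    stop_rorscan("positions must be a data frame with a 'base' column", "config_error")
  }
  off <- positions$offset %||% rep(0L, nrow(positions))
  N <- nrow(positions)
  if (N == 0L) stop_rorscan("no carrier positions to bin", "config_error")
  key <- cds_numkey(positions$base, off)
  ord <- order(key)
  key <- key[ord]
  ubase <- positions$base[ord]
  uoff <- off[ord]
  keep <- !duplicated(key)
  counts <- as.integer(table(factor(key, levels = key[keep])))
  ubase <- ubase[keep]
  uoff <- uoff[keep]
  m <- length(counts)

  if (is.null(n_bins)) n_bins <- max(1L, as.integer(round(N / carriers_per_bin)))
  n_bins <- as.integer(n_bins)
  if (n_bins < 1L) stop_rorscan("n_bins must be >= 1", "config_error")
  if (n_bins > m) {
    stop_rorscan(
      sprintf("cannot form %d bins from %d distinct positions", n_bins, m),
      "infeasible_binning"
    )
  }

  cuts <- repair_cuts(counts, quantile_cuts(counts, n_bins))
  hi <- c(cuts, m)
  lo <- c(1L, cuts + 1L)
  data.frame(
    bin = seq_len(n_bins),
    n_carriers = bin_counts_from_cuts(cumsum(counts), cuts),
    start = format_cds_position(ubase[lo], uoff[lo]),
    end = format_cds_position(ubase[hi], uoff[hi]),
    start_base = ubase[lo],
    start_offset = uoff[lo],
    end_base = ubase[hi],
    end_offset = uoff[hi],
    stringsAsFactors = FALSE
  )
}

#' Assign positions to bins
#'
#' @param positions data frame with `base` / optional `offset`.
#' @param bins bin table from [build_bins()].
#' @return integer bin index per row of `positions`; `NA` for positions
#'   falling in a gap between bins (possible only for positions not used to
#'   build the bins).
#' @export
bin_assign <- function(positions, bins) {
  off <- positions$offset %||% rep(0L, nrow(positions))
  key <- cds_numkey(positions$base, off)
  starts <- cds_numkey(bins$start_base, bins$start_offset)
  ends <- cds_numkey(bins$end_base, bins$end_offset)
  idx <- findInterval(key, starts)
  idx[idx == 0L] <- NA_integer_
  inside <- !is.na(idx) & key <= ends[pmax(idx, 1L)]
  idx[!inside] <- NA_integer_
  idx
}
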