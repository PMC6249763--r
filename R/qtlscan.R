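# Bulked-segregant |Delta(SNP-index)| scan: per-SNP indices from two pools'
# allele depths, sliding-window means (1-Mb windows, 20-kb steps by
# default), a genome-wide top-quantile threshold over window means, merged
# candidate intervals, and AGP-aware projection of intervals back onto the
# scaffold pieces they contain.

#' SNP-index of one pool
#'
#' Alternate-allele depth fraction, alt / (ref + alt); NA at zero total
#' depth (such rows are excluded from the scan).
#'
#' @param ref_d,alt_d read depths (vectors allowed).
#' @return numeric in \[0, 1\] or NA.
#' @export
snp_index <- function(ref_d, alt_d) {
  tot <- ref_d + alt_d
  ifelse(tot > 0, alt_d / tot, NA_real_)
}

#' |Delta(SNP-index)| per SNP
#'
#' Absolute between-pool difference of SNP-indices; the magnitude is used
#' (rather than the signed difference) so that loci segregating in either
#' phase of a heterozygous cross are picked up equally.
#'
#' @param tbl a [pool_depth_table()].
#' @return `tbl` with columns `index1`, `index2`, `abs_delta`; rows where
#'   either pool has zero depth are dropped.
#' @export
abs_delta <- function(tbl) {
  i1 <- snp_index(tbl$ref1, tbl$alt1)
  i2 <- snp_index(tbl$ref2, tbl$alt2)
  out <- as.data.frame(tbl)
  out$index1 <- i1
  out$index2 <- i2
  out$abs_delta <- abs(i1 - i2)
  out[!is.na(out$abs_delta), , drop = FALSE]
}

#' Sliding windows over a chromosome
#'
#' Windows start at 1, 1 + step, ...; the trailing windows are truncated at
#' `chrom_len` (every start <= `chrom_len` yields a window).
#'
#' @param chrom_len chromosome length (bp, >= 1).
#' @param window window size (bp).
#' @param step increment (bp), <= window.
#' @return data.frame (start, end), 1-based inclusive.
#' @export
sliding_windows <- function(chrom_len, window = 1e6, step = 2e4) {
  if (chrom_len < 1) stop_format("chrom_len must be >= 1")
  if (!(window >= step && step > 0)) stop_format("need window >= step > 0")
  starts <- seq(1, chrom_len, by = step)
  data.frame(start = as.integer(starts),
             end = as.integer(pmin(starts + window - 1, chrom_len)))
}

#' Windowed mean |Delta(SNP-index)|
#'
#' @param tbl a [pool_depth_table()].
#' @param chrom_lens named vector of chromosome lengths (default: max SNP
#'   position per chromosome).
#' @param window,step window geometry, see [sliding_windows()].
#' @return data.frame (chrom, start, end, n_snps, mean_abs_delta); the mean
#'   is NA for empty windows.
#' @export
window_scan <- function(tbl, chrom_lens = NULL, window = 1e6, step = 2e4) {
  d <- abs_delta(tbl)
  if (is.null(chrom_lens)) {
    chrom_lens <- tapply(d$pos, d$chrom, max)
  }
  out <- vector("list", length(chrom_lens))
  for (i in seq_along(chrom_lens)) {
    ch <- names(chrom_lens)[i]
    win <- sliding_windows(chrom_lens[[i]], window = window, step = step)
    sub <- d[d$chrom == ch, , drop = FALSE]
    sub <- sub[order(sub$pos), , drop = FALSE]
    cs <- c(0, cumsum(sub$abs_delta))
    lo <- findInterval(win$start - 1L, sub$pos)  # SNPs at pos < start
    hi <- findInterval(win$end, sub$pos)         # SNPs at pos <= end
    n <- hi - lo
    out[[i]] <- data.frame(chrom = ch, start = win$start, end = win$end,
                           n_snps = n,
                           mean_abs_delta = ifelse(n > 0, (cs[hi + 1L] - cs[lo + 1L]) / n,
                                                   NA_real_),
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Genome-wide top-fraction threshold over window means
#'
#' @param stats a [window_scan()] table.
#' @param fraction top fraction selected (default 0.005, i.e. top 0.5%).
#' @return the (1 - fraction) quantile of non-missing window means.
#' @export
threshold_top <- function(stats, fraction = 0.005) {
  v <- stats$mean_abs_delta[!is.na(stats$mean_abs_delta)]
  if (length(v) == 0L) stop_format("all windows are empty")
  unname(quantile(v, 1 - fraction))
}

#' Candidate intervals from above-threshold windows
#'
#' Windows with mean |Delta(SNP-index)| at or above the threshold are merged
#' per chromosome when they overlap or are book-ended (adjacent); the
#' resulting intervals are the candidate regions. With an AGP, each interval
#' is also cut into the scaffold pieces it spans.
#'
#' @param stats a [window_scan()] table.
#' @param threshold from [threshold_top()].
#' @param agp optional `agp` whose object ids match `stats$chrom`.
#' @return data.frame (chrom, start, end, length, peak, n_windows); when
#'   `agp` is given, a `pieces` list-column of [agp_pieces()] frames.
#' @export
candidate_intervals <- function(stats, threshold, agp = NULL) {
  hit <- stats[!is.na(stats$mean_abs_delta) &
                 stats$mean_abs_delta >= threshold, , drop = FALSE]
  out <- list()
  for (ch in unique(hit$chrom)) {
    sub <- hit[hit$chrom == ch, , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    cur_s <- sub$start[1L]; cur_e <- sub$end[1L]
    cur_peak <- sub$mean_abs_delta[1L]; cur_n <- 1L
    flush <- function() {
      data.frame(chrom = ch, start = cur_s, end = cur_e,
                 length = cur_e - cur_s + 1L, peak = cur_peak,
                 n_windows = cur_n, stringsAsFactors = FALSE)
    }
    if (nrow(sub) > 1L) for (i in 2L:nrow(sub)) {
      if (sub$start[i] <= cur_e + 1L) {
        cur_e <- max(cur_e, sub$end[i])
        cur_peak <- max(cur_peak, sub$mean_abs_delta[i])
        cur_n <- cur_n + 1L
      } else {
        out[[length(out) + 1L]] <- flush()
        cur_s <- sub$start[i]; cur_e <- sub$end[i]
        cur_peak <- sub$mean_abs_delta[i]; cur_n <- 1L
      }
    }
    out[[length(out) + 1L]] <- flush()
  }
  out <- do.call(rbind, out)
  if (!is.null(out) && !is.null(agp))
    out$pieces <- lapply(seq_len(nrow(out)), function(i)
      agp_pieces(agp, out$chrom[i], out$start[i], out$end[i]))
  out
}

#' Full QTL-seq scan
#'
#' Convenience wrapper: [window_scan()], [threshold_top()] and
#' [candidate_intervals()] in one call.
#'
#' @inheritParams window_scan
#' @inheritParams threshold_top
#' @inheritParams candidate_intervals
#' @return list(windows, threshold, intervals).
#' @export
qtlseq_scan <- function(tbl, chrom_lens = NULL, window = 1e6, step = 2e4,
                        fraction = 0.005, agp = NULL) {
  win <- window_scan(tbl, chrom_lens = chrom_lens, window = window, step = step)
  thr <- threshold_top(win, fraction = fraction)
  list(windows = win, threshold = thr,
       intervals = candidate_intervals(win, thr, agp = agp))
}
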