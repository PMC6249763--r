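# Marker quality control for GBS-genotyped CP populations: depth masking,
# alphabet check, missingness/integrity filters, segregation chi-square test,
# and per-scaffold redundancy reduction. The cascade reproduces the filtering
# used to arrive at the qualified marker set loaded into map construction.

#' QC parameters
#'
#' Defaults follow common GBS practice for mid-size F1 populations: calls at
#' depth outside 5..1500 (inclusive) are treated as missing; a marker is
#' removed when missing in more than 10 individuals or genotyped in less than
#' 95% of offspring; segregation is tested against the class ratio by
#' chi-square at alpha = 0.05; at most five markers, evenly spread, are kept
#' per scaffold.
#'
#' @param depth_min,depth_max inclusive per-call depth bounds.
#' @param max_missing_individuals missing-count removal threshold (strictly
#'   greater removes).
#' @param min_integrity minimum genotyped fraction (strictly less removes).
#' @param distortion_alpha chi-square significance level.
#' @param max_snps_per_scaffold redundancy cap per scaffold.
#' @return list of class `qc_params`.
#' @export
qc_params <- function(depth_min = 5L, depth_max = 1500L,
                      max_missing_individuals = 10L, min_integrity = 0.95,
                      distortion_alpha = 0.05, max_snps_per_scaffold = 5L) {
  stopifnot(depth_min <= depth_max, min_integrity > 0, min_integrity <= 1,
            distortion_alpha > 0, distortion_alpha < 1,
            max_snps_per_scaffold >= 1L)
  structure(list(depth_min = depth_min, depth_max = depth_max,
                 max_missing_individuals = max_missing_individuals,
                 min_integrity = min_integrity,
                 distortion_alpha = distortion_alpha,
                 max_snps_per_scaffold = max_snps_per_scaffold),
            class = "qc_params")
}

#' Mask calls by read depth
#'
#' Calls whose depth falls outside `[depth_min, depth_max]` (bounds
#' inclusive) become missing; calls outside their segregation-class alphabet
#' (abnormal bases) are also masked.
#'
#' @param gm a [genotype_matrix()].
#' @param params [qc_params()].
#' @return a [genotype_matrix()] with masked calls.
#' @export
depth_mask <- function(gm, params = qc_params()) {
  calls <- gm$calls
  bad <- gm$depths < params$depth_min | gm$depths > params$depth_max
  calls[bad] <- MISSING_CALL
  for (cls in unique(gm$markers$seg_class)) {
    rows <- gm$markers$seg_class == cls
    ok <- c(SEG_ALPHABET[[cls]], MISSING_CALL)
    sub <- calls[rows, , drop = FALSE]
    sub[!sub %in% ok] <- MISSING_CALL
    calls[rows, ] <- sub
  }
  genotype_matrix(gm$markers, calls, gm$depths)
}

#' Chi-square test of segregation distortion
#'
#' Pearson chi-square of the observed class counts against the Mendelian
#' expectation for the marker class (1:1 for lm x ll and nn x np, 1:2:1 for
#' hk x hk), without continuity correction; df = classes - 1.
#'
#' @param counts named or positional non-negative counts, in alphabet order
#'   (e.g. `c(lm = 50, ll = 50)` or `c(hh = 25, hk = 50, kk = 25)`).
#' @param seg_class one of `"lmxll"`, `"nnxnp"`, `"hkxhk"`.
#' @return list(chi2, p).
#' @export
chi_square_segregation <- function(counts, seg_class) {
  ratio <- SEG_RATIO[[seg_class]]
  if (is.null(ratio)) stop_format("unknown seg_class: %s", seg_class)
  if (length(counts) != length(ratio) || any(counts < 0))
    stop_format("need %d non-negative class counts for %s", length(ratio), seg_class)
  if (sum(counts) == 0) stop_format("zero total count")
  ht <- suppressWarnings(chisq.test(counts, p = ratio / sum(ratio), correct = FALSE))
  list(chi2 = unname(ht$statistic), p = unname(ht$p.value))
}

seg_counts <- function(calls_row, seg_class) {
  alpha <- SEG_ALPHABET[[seg_class]]
  vapply(alpha, function(a) sum(calls_row == a), integer(1))
}

#' Missingness and integrity filter
#'
#' A marker is removed when its missing-call count exceeds
#' `max_missing_individuals` or its genotyped fraction falls below
#' `min_integrity`; the two rules act independently (OR).
#'
#' @param gm a depth-masked [genotype_matrix()].
#' @param params [qc_params()].
#' @return list(retained, removed) of marker ids.
#' @export
missing_and_integrity_filter <- function(gm, params = qc_params()) {
  n_missing <- rowSums(gm$calls == MISSING_CALL)
  integrity <- 1 - n_missing / gm$n_offspring
  drop <- n_missing > params$max_missing_individuals |
    integrity < params$min_integrity
  list(retained = gm$markers$marker_id[!drop],
       removed = gm$markers$marker_id[drop])
}

#' Reduce marker redundancy per scaffold
#'
#' When a scaffold carries more than `k` qualified markers, keep the marker
#' nearest each of `k` target positions evenly spaced over the occupied span
#' (endpoints inclusive). Distance ties break toward the lower position;
#' markers are never selected twice.
#'
#' @param positions marker bp positions on the scaffold.
#' @param ids marker ids, parallel to `positions`.
#' @param k maximum markers to keep.
#' @return selected marker ids (all, when `length(ids) <= k`).
#' @export
reduce_redundancy <- function(positions, ids, k = 5L) {
  stopifnot(length(positions) == length(ids))
  if (length(ids) <= k) return(ids)
  ord <- order(positions, ids)
  positions <- positions[ord]
  ids <- ids[ord]
  targets <- seq(min(positions), max(positions), length.out = k)
  taken <- logical(length(ids))
  out <- character(k)
  for (t_i in seq_len(k)) {
    d <- abs(positions - targets[t_i])
    d[taken] <- Inf
    # which.min takes the first (= lowest-position) minimum
    pick <- which.min(d)
    taken[pick] <- TRUE
    out[t_i] <- ids[pick]
  }
  out
}

#' Run the full marker QC cascade
#'
#' Order of operations: depth/alphabet masking, missingness + integrity
#' removal, segregation chi-square removal at `distortion_alpha`, then
#' per-scaffold redundancy reduction.
#'
#' @param gm a [genotype_matrix()].
#' @param params [qc_params()].
#' @return list with `matrix` (filtered, masked [genotype_matrix()]) and
#'   `report` (a `qc_report`: per-rule removal counts, retained ids, and the
#'   per-marker chi-square table).
#' @export
run_marker_qc <- function(gm, params = qc_params()) {
  n_in <- nrow(gm$calls)
  masked <- depth_mask(gm, params)
  mi <- missing_and_integrity_filter(masked, params)
  keep1 <- masked$markers$marker_id %in% mi$retained

  chi <- data.frame(marker_id = masked$markers$marker_id,
                    chi2 = NA_real_, p = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(masked$markers))) {
    cnt <- seg_counts(masked$calls[i, ], masked$markers$seg_class[i])
    if (sum(cnt) > 0) {
      ht <- chi_square_segregation(cnt, masked$markers$seg_class[i])
      chi$chi2[i] <- ht$chi2
      chi$p[i] <- ht$p
    }
  }
  distorted <- !is.na(chi$p) & chi$p < params$distortion_alpha
  keep2 <- keep1 & !distorted

  kept_idx <- which(keep2)
  mk <- masked$markers[kept_idx, , drop = FALSE]
  sel <- unlist(lapply(split(seq_len(nrow(mk)), mk$scaffold), function(rows) {
    rows[mk$marker_id[rows] %in%
           reduce_redundancy(mk$pos[rows], mk$marker_id[rows],
                             params$max_snps_per_scaffold)]
  }), use.names = FALSE)
  keep_final <- sort(kept_idx[sel])

  out <- genotype_matrix(masked$markers[keep_final, , drop = FALSE],
                         masked$calls[keep_final, , drop = FALSE],
                         masked$depths[keep_final, , drop = FALSE])
  report <- structure(list(
    n_input = n_in,
    removed_missing_or_integrity = sum(!keep1),
    removed_distorted = sum(keep1 & distorted),
    removed_redundant = length(kept_idx) - length(keep_final),
    n_retained = length(keep_final),
    retained = masked$markers$marker_id[keep_final],
    chi_square = chi), class = "qc_report")
  stopifnot(report$n_retained + report$removed_missing_or_integrity +
              report$removed_distorted + report$removed_redundant == n_in)
  list(matrix = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(paste0("marker QC: %d in; removed %d (missing/integrity), ",
                     "%d (distorted), %d (redundant); %d retained\n"),
              x$n_input, x$removed_missing_or_integrity, x$removed_distorted,
              x$removed_redundant, x$n_retained))
  invisible(x)
}

#' Write a QC report table
#'
#' @param report a `qc_report` from [run_marker_qc()].
#' @param path output TSV.
#' @export
write_qc_report <- function(report, path) {
  chi <- report$chi_square
  chi$retained <- chi$marker_id %in% report$retained
  write_tsv(chi, path)
}
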