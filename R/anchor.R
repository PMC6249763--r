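# Weighted multi-map consensus anchoring: assign each scaffold to a
# chromosome by weighted marker majority, place it by weight-averaged
# normalised map position, order the scaffolds of a chromosome to maximise
# collinearity J = sum_k w_k * rho_k (rho_k = Spearman correlation between
# map-k marker cM and the marker order induced by the scaffold ordering),
# and orient multi-marker scaffolds from the within-scaffold bp~cM trend.
# Deterministic throughout: exact enumeration for small groups, a
# steepest-ascent pairwise-swap hill-climb otherwise, ties broken by
# scaffold id.

#' Spearman rank correlation
#'
#' Average ranks for ties; errors on fewer than two observations.
#'
#' @param x,y equal-length numeric vectors.
#' @return rho in \[-1, 1\] (NA when either side has no variance).
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L)
    stop_format("spearman_rho needs two vectors of equal length >= 2")
  suppressWarnings(cor(x, y, method = "spearman"))
}

# marker table: one row per (map, marker) with map index, weight, lg, cm,
# scaffold, pos
marker_table <- function(maps) {
  do.call(rbind, lapply(seq_along(maps), function(k) {
    p <- maps[[k]]$placements
    if (nrow(p) == 0L) return(NULL)
    data.frame(map = k, map_name = maps[[k]]$name, weight = maps[[k]]$weight,
               p, stringsAsFactors = FALSE)
  }))
}

#' Assign a scaffold to a chromosome by weighted marker majority
#'
#' The chromosome with the largest sum over maps of (map weight x marker
#' count on that LG) wins; a tie, or no markers, gives 0 (unplaced).
#'
#' @param mt marker table rows for one scaffold (internal format of
#'   [build_anchor_plan()]); exposed for testing via
#'   `assign_chromosome(maps = ..., scaffold = ...)`.
#' @param maps list of [genetic_map()]s (alternative interface).
#' @param scaffold scaffold id when `maps` is given.
#' @return chromosome integer (0 = unplaced).
#' @export
assign_chromosome <- function(mt = NULL, maps = NULL, scaffold = NULL) {
  if (is.null(mt)) {
    mt <- marker_table(maps)
    mt <- mt[mt$scaffold == scaffold, , drop = FALSE]
  }
  if (is.null(mt) || nrow(mt) == 0L) return(0L)
  score <- tapply(mt$weight, mt$lg, sum)
  top <- max(score)
  winners <- names(score)[score == top]
  if (length(winners) != 1L) return(0L)
  as.integer(winners)
}

# Normalised per-map scaffold positions on one chromosome. lg_span is
# computed over the whole map (all markers of that LG), not just the group.
consensus_positions <- function(scaffolds, chrom, maps) {
  w_sum <- numeric(length(scaffolds))
  acc <- numeric(length(scaffolds))
  for (k in seq_along(maps)) {
    p <- maps[[k]]$placements
    on_lg <- p[p$lg == chrom, , drop = FALSE]
    if (nrow(on_lg) == 0L) next
    span <- range(on_lg$cm)
    for (i in seq_along(scaffolds)) {
      cm <- on_lg$cm[on_lg$scaffold == scaffolds[i]]
      if (length(cm) == 0L) next
      pos <- if (diff(span) > 0) (mean(cm) - span[1]) / diff(span) else 0.5
      acc[i] <- acc[i] + maps[[k]]$weight * pos
      w_sum[i] <- w_sum[i] + maps[[k]]$weight
    }
  }
  ifelse(w_sum > 0, acc / w_sum, NA_real_)
}

#' Weighted consensus position of scaffolds on a chromosome
#'
#' Per map, a scaffold sits at the mean cM of its markers on the chromosome's
#' LG, normalised by that LG's cM span to \[0, 1\]; the consensus position is
#' the map-weight average over the maps containing the scaffold.
#'
#' @param scaffolds character vector of scaffold ids.
#' @param chrom chromosome (LG) number.
#' @param maps list of [genetic_map()]s.
#' @return numeric vector of consensus positions in \[0, 1\].
#' @export
consensus_position <- function(scaffolds, chrom, maps) {
  consensus_positions(scaffolds, chrom, maps)
}

# Per-map marker lists for one chromosome group, pre-resolved to scaffold
# indices; used by the ordering objective.
group_markers <- function(scaffolds, chrom, maps) {
  lapply(seq_along(maps), function(k) {
    p <- maps[[k]]$placements
    p <- p[p$lg == chrom & p$scaffold %in% scaffolds, , drop = FALSE]
    list(weight = maps[[k]]$weight, cm = p$cm,
         scaf_idx = match(p$scaffold, scaffolds))
  })
}

# J(ordering) for a permutation expressed as positions: pos_of[i] = rank of
# scaffold i in the ordering.
ordering_objective <- function(pos_of, gmarks) {
  j <- 0
  for (g in gmarks) {
    if (length(g$cm) < 2L) next
    y <- pos_of[g$scaf_idx]
    if (length(unique(g$cm)) < 2L || length(unique(y)) < 2L) next
    rho <- suppressWarnings(cor(g$cm, y, method = "spearman"))
    if (!is.na(rho)) j <- j + g$weight * rho
  }
  j
}

permutations_lex <- function(v) {
  n <- length(v)
  if (n == 1L) return(list(v))
  out <- list()
  for (i in seq_len(n))
    out <- c(out, lapply(permutations_lex(v[-i]), function(p) c(v[i], p)))
  out
}

#' Order the scaffolds of a chromosome to maximise collinearity
#'
#' Maximises J = sum_k w_k rho_k over scaffold orderings, rho_k being the
#' Spearman correlation between map-k marker cM and the marker rank induced
#' by the ordering (markers of one scaffold share its rank; ties averaged).
#' Groups of up to `exact_limit` scaffolds are solved by exhaustive
#' enumeration in lexicographic scaffold-id order (first optimum kept);
#' larger groups start from the consensus-position sort and apply a
#' steepest-ascent hill-climb over all pairwise swaps until no swap improves
#' J. Fully deterministic.
#'
#' @param scaffolds scaffold ids of one chromosome group.
#' @param chrom chromosome (LG) number.
#' @param maps list of [genetic_map()]s.
#' @param exact_limit largest group solved by enumeration (default 8).
#' @return list(order = scaffold ids in order, J = attained objective).
#' @export
order_scaffolds <- function(scaffolds, chrom, maps, exact_limit = 8L) {
  scaffolds <- sort(unique(scaffolds))
  n <- length(scaffolds)
  gmarks <- group_markers(scaffolds, chrom, maps)
  if (n == 1L)
    return(list(order = scaffolds, J = ordering_objective(1, gmarks)))
  if (n <= exact_limit) {
    best <- NULL
    best_j <- -Inf
    for (perm in permutations_lex(seq_len(n))) {
      pos_of <- integer(n)
      pos_of[perm] <- seq_len(n)
      j <- ordering_objective(pos_of, gmarks)
      if (j > best_j + 1e-12) {
        best_j <- j
        best <- perm
      }
    }
    return(list(order = scaffolds[best], J = best_j))
  }
  # hill-climb from the consensus-position sort (ties by id)
  cpos <- consensus_positions(scaffolds, chrom, maps)
  perm <- order(cpos, scaffolds)
  pos_of <- integer(n)
  pos_of[perm] <- seq_len(n)
  cur <- ordering_objective(pos_of, gmarks)
  repeat {
    best_gain <- 0
    best_swap <- NULL
    for (a in seq_len(n - 1L)) for (b in (a + 1L):n) {
      cand <- pos_of
      cand[perm[a]] <- b
      cand[perm[b]] <- a
      j <- ordering_objective(cand, gmarks)
      if (j - cur > best_gain + 1e-12) {
        best_gain <- j - cur
        best_swap <- c(a, b)
      }
    }
    if (is.null(best_swap)) break
    a <- best_swap[1]; b <- best_swap[2]
    tmp <- perm[a]; perm[a] <- perm[b]; perm[b] <- tmp
    pos_of[perm] <- seq_len(n)
    cur <- cur + best_gain
  }
  list(order = scaffolds[perm], J = cur)
}

#' Orient a scaffold from the within-scaffold bp ~ cM trend
#'
#' The orientation score is sum_k w_k rho_k where rho_k is the Spearman
#' correlation between marker bp positions on the scaffold and their cM
#' positions in map k (markers on the assigned LG only). Positive gives
#' `"+"`, negative `"-"`; a zero score or fewer than two markers at distinct
#' positions gives `"?"`.
#'
#' @param scaffold scaffold id.
#' @param chrom assigned chromosome.
#' @param maps list of [genetic_map()]s.
#' @return `"+"`, `"-"` or `"?"`.
#' @export
orient_scaffold <- function(scaffold, chrom, maps) {
  score <- 0
  informative <- FALSE
  for (k in seq_along(maps)) {
    p <- maps[[k]]$placements
    p <- p[p$lg == chrom & p$scaffold == scaffold, , drop = FALSE]
    if (nrow(p) < 2L) next
    if (length(unique(p$pos)) < 2L || length(unique(p$cm)) < 2L) next
    rho <- suppressWarnings(cor(p$pos, p$cm, method = "spearman"))
    if (is.na(rho)) next
    informative <- TRUE
    score <- score + maps[[k]]$weight * rho
  }
  if (!informative || abs(score) < 1e-12) return("?")
  if (score > 0) "+" else "-"
}

#' Build a full anchoring plan from weighted genetic maps
#'
#' Runs chromosome assignment, consensus positioning, collinearity-maximising
#' ordering and orientation for every scaffold carrying at least one mapped
#' marker; scaffolds without markers (or with tied LG evidence) go to
#' chromosome 0, unordered and unoriented. Markers on a losing LG of a
#' conflicted scaffold are excluded from positioning.
#'
#' @param maps list of [genetic_map()]s (weights taken from the maps).
#' @param scaffolds optional [scaffold_set()]; its scaffolds are included in
#'   the plan even when unmapped.
#' @param exact_limit passed to [order_scaffolds()].
#' @return an `anchor_plan` data.frame: scaffold_id, chrom (0 = unplaced),
#'   order_index (NA for chrom 0), orientation, n_markers (distinct markers
#'   on the assigned LG across maps), consensus_pos, plus per-map marker
#'   counts in columns `n_<map name>`.
#' @export
build_anchor_plan <- function(maps, scaffolds = NULL, exact_limit = 8L) {
  mt <- marker_table(maps)
  ids <- sort(unique(c(mt$scaffold,
                       if (!is.null(scaffolds)) scaffolds$scaffold_id)))
  chrom <- vapply(ids, function(s)
    assign_chromosome(mt[mt$scaffold == s, , drop = FALSE]), integer(1))
  plan <- data.frame(scaffold_id = ids, chrom = chrom,
                     order_index = NA_integer_, orientation = "?",
                     n_markers = 0L, consensus_pos = NA_real_,
                     stringsAsFactors = FALSE)
  for (k in seq_along(maps)) {
    p <- maps[[k]]$placements
    cnt <- vapply(seq_along(ids), function(i)
      sum(p$scaffold == ids[i] & p$lg == chrom[i]), integer(1))
    plan[[paste0("n_", maps[[k]]$name)]] <- cnt
  }
  on_lg <- mt[mt$lg == chrom[match(mt$scaffold, ids)], , drop = FALSE]
  n_mark <- tapply(on_lg$marker_id, on_lg$scaffold,
                   function(m) length(unique(m)))
  plan$n_markers[match(names(n_mark), ids)] <- as.integer(n_mark)
  zero <- ids[chrom == 0L]
  if (length(zero)) {                      # unplaced: count markers on any LG
    sub <- mt[mt$scaffold %in% zero, , drop = FALSE]
    if (nrow(sub)) {
      nm0 <- tapply(sub$marker_id, sub$scaffold, function(m) length(unique(m)))
      plan$n_markers[match(names(nm0), ids)] <- as.integer(nm0)
    }
  }
  for (c_i in sort(unique(chrom[chrom > 0L]))) {
    grp <- ids[chrom == c_i]
    res <- order_scaffolds(grp, c_i, maps, exact_limit = exact_limit)
    rows <- match(res$order, plan$scaffold_id)
    plan$order_index[rows] <- seq_along(rows)
    plan$consensus_pos[rows] <-
      consensus_positions(res$order, c_i, maps)
    plan$orientation[rows] <- vapply(res$order, orient_scaffold, character(1),
                                     chrom = c_i, maps = maps)
  }
  plan <- plan[order(plan$chrom, plan$order_index, plan$scaffold_id), , drop = FALSE]
  rownames(plan) <- NULL
  class(plan) <- c("anchor_plan", "data.frame")
  plan
}

#' Concordance between the consensus order and each input map
#'
#' For every (map, chromosome): the Spearman correlation between the map's
#' marker cM and the marker rank induced by the consensus plan (scaffold
#' order, then within-scaffold bp respecting orientation).
#'
#' @param plan an `anchor_plan`.
#' @param maps list of [genetic_map()]s.
#' @return data.frame (map, chrom, n_markers, rho); rho NA when fewer than
#'   two shared markers.
#' @export
compare_maps <- function(plan, maps) {
  out <- list()
  for (k in seq_along(maps)) {
    p <- maps[[k]]$placements
    for (c_i in sort(unique(plan$chrom[plan$chrom > 0L]))) {
      pl <- plan[plan$chrom == c_i, , drop = FALSE]
      m <- p[p$lg == c_i & p$scaffold %in% pl$scaffold_id, , drop = FALSE]
      rho <- NA_real_
      if (nrow(m) >= 2L) {
        oi <- pl$order_index[match(m$scaffold, pl$scaffold_id)]
        ori <- pl$orientation[match(m$scaffold, pl$scaffold_id)]
        within <- ifelse(ori == "-", -m$pos, m$pos)
        cons_rank <- order(order(oi, within))
        if (length(unique(m$cm)) >= 2L && length(unique(cons_rank)) >= 2L)
          rho <- spearman_rho(m$cm, cons_rank)
      }
      out[[length(out) + 1L]] <- data.frame(
        map = maps[[k]]$name, chrom = c_i, n_markers = nrow(m), rho = rho,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Write an anchor plan or concordance table to TSV
#'
#' @param x data.frame (`anchor_plan` or [compare_maps()] output).
#' @param path output file.
#' @export
write_anchor_plan <- function(x, path) write_tsv(as.data.frame(x), path)

#' Read an anchor plan written by [write_anchor_plan()]
#'
#' @param path TSV path.
#' @return an `anchor_plan` data.frame.
#' @export
read_anchor_plan <- function(path) {
  df <- read_tsv_strict(path, c("scaffold_id", "chrom", "order_index",
                                "orientation", "n_markers", "consensus_pos"),
                        "anchor plan")
  df$scaffold_id <- as.character(df$scaffold_id)
  df$orientation <- as.character(df$orientation)
  class(df) <- c("anchor_plan", "data.frame")
  df
}
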