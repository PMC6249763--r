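# Pseudo-chromosome construction from an anchor plan: ordered scaffolds
# concatenated with a fixed N spacer (default 100 bp, a conventional
# map-derived-join gap), "-" scaffolds reverse-complemented, "?" treated as
# "+" in sequence but preserved in the AGP. Plus the assembly and map summary
# statistics used to report such builds (N50/L50, anchored/oriented
# partitions, markers per Mb, per-LG map statistics).

#' Build pseudo-chromosomes and AGP from an anchor plan
#'
#' @param plan an `anchor_plan` from [build_anchor_plan()].
#' @param scaffolds a [scaffold_set()]; sequences optional (length-only sets
#'   give a sequence-free bundle with exact coordinates).
#' @param gap_len spacer between consecutive scaffolds (bp, default 100).
#' @param maps optional list of [genetic_map()]s; when given, markers are
#'   projected to chromosome coordinates.
#' @param chrom_prefix prefix for object names (default `"chr"`).
#' @return an `assembly_bundle`: `chromosomes` (chrom, length, n_scaffolds,
#'   scaffold_bases), `agp`, `sequences` (named character or NULL),
#'   `unplaced` (chrom-0 scaffold ids, kept as separate records),
#'   `projections` (marker, chrom, chrom_pos) or NULL.
#' @export
build_pseudochromosomes <- function(plan, scaffolds, gap_len = 100L,
                                    maps = NULL, chrom_prefix = "chr") {
  missing <- setdiff(plan$scaffold_id, scaffolds$scaffold_id)
  if (length(missing))
    stop_format("scaffold in plan missing from scaffold set: %s", missing[1L])
  idx <- match(plan$scaffold_id, scaffolds$scaffold_id)
  plan_len <- scaffolds$length[idx]
  have_seq <- !anyNA(scaffolds$sequence)

  chroms <- sort(unique(plan$chrom[plan$chrom > 0L]))
  agp <- list()
  seqs <- if (have_seq) character(0) else NULL
  chrom_tab <- data.frame(chrom = integer(0), length = integer(0),
                          n_scaffolds = integer(0), scaffold_bases = numeric(0))
  for (c_i in chroms) {
    rows <- which(plan$chrom == c_i)
    rows <- rows[order(plan$order_index[rows])]
    obj <- paste0(chrom_prefix, c_i)
    a <- agp_object(obj, plan$scaffold_id[rows], plan_len[rows],
                    plan$orientation[rows], gap_len = gap_len)
    agp[[length(agp) + 1L]] <- a
    scaf_bases <- sum(plan_len[rows])
    chrom_tab <- rbind(chrom_tab, data.frame(
      chrom = c_i, length = max(a$object_end),
      n_scaffolds = length(rows), scaffold_bases = scaf_bases))
    if (have_seq) {
      parts <- vapply(rows, function(r) {
        s <- scaffolds$sequence[idx[r]]
        if (identical(plan$orientation[r], "-")) revcomp(s) else s
      }, character(1))
      seqs[obj] <- paste(parts, collapse = strrep("N", gap_len))
    }
  }
  agp <- do.call(rbind, agp)
  class(agp) <- c("agp", "data.frame")

  unplaced <- plan$scaffold_id[plan$chrom == 0L]
  if (have_seq && length(unplaced))
    seqs[unplaced] <- scaffolds$sequence[match(unplaced, scaffolds$scaffold_id)]

  projections <- NULL
  if (!is.null(maps)) projections <- project_markers(plan, agp, maps)

  structure(list(chromosomes = chrom_tab, agp = agp, sequences = seqs,
                 unplaced = unplaced, gap_len = as.integer(gap_len),
                 projections = projections),
            class = "assembly_bundle")
}

#' @export
print.assembly_bundle <- function(x, ...) {
  cat(sprintf("assembly_bundle: %d pseudo-chromosomes (%s bp), %d unplaced scaffolds\n",
              nrow(x$chromosomes),
              format(sum(x$chromosomes$length), big.mark = ","),
              length(x$unplaced)))
  invisible(x)
}

# Project map markers through the AGP onto chromosome coordinates.
project_markers <- function(plan, agp, maps) {
  mt <- marker_table(maps)
  mt <- mt[!duplicated(mt$marker_id), , drop = FALSE]
  w <- agp[agp$component_type == "W", , drop = FALSE]
  j <- match(mt$scaffold, w$component_id)
  keep <- !is.na(j)
  mt <- mt[keep, , drop = FALSE]
  j <- j[keep]
  fwd <- w$orientation[j] != "-"
  chrom_pos <- ifelse(fwd, w$object_beg[j] + (mt$pos - w$component_beg[j]),
                      w$object_beg[j] + (w$component_end[j] - mt$pos))
  data.frame(marker_id = mt$marker_id, chrom = w$object_id[j],
             chrom_pos = as.integer(chrom_pos), stringsAsFactors = FALSE)
}

#' Rebuild chromosome sequences from AGP + scaffolds
#'
#' Cross-validation helper: reconstructs every AGP object from component
#' sequences and gap rows; byte-identical to the bundle sequences by
#' construction.
#'
#' @param agp an `agp` data.frame.
#' @param scaffolds a [scaffold_set()] with sequences.
#' @return named character vector of object sequences.
#' @export
sequences_from_agp <- function(agp, scaffolds) {
  validate_agp(agp)
  out <- character(0)
  for (obj in unique(agp$object_id)) {
    rows <- agp[agp$object_id == obj, , drop = FALSE]
    rows <- rows[order(rows$part_number), , drop = FALSE]
    parts <- vapply(seq_len(nrow(rows)), function(i) {
      if (rows$component_type[i] == "N") return(strrep("N", rows$gap_length[i]))
      s <- scaffolds$sequence[scaffolds$scaffold_id == rows$component_id[i]]
      if (length(s) != 1L || is.na(s))
        stop_format("no sequence for component %s", rows$component_id[i])
      s <- substr(s, rows$component_beg[i], rows$component_end[i])
      if (identical(rows$orientation[i], "-")) revcomp(s) else s
    }, character(1))
    out[obj] <- paste(parts, collapse = "")
  }
  out
}

#' N50 and L50 of a set of lengths
#'
#' N50: the largest length such that pieces at least that long hold >= 50%
#' of the total bases; L50: how many of the largest pieces are needed to
#' reach 50%.
#'
#' @param lengths numeric vector of piece lengths.
#' @return list(n50, l50).
#' @export
n50_stats <- function(lengths) {
  stopifnot(length(lengths) > 0, all(lengths > 0))
  s <- sort(lengths, decreasing = TRUE)
  cum <- cumsum(s)
  i <- which(cum >= sum(s) / 2)[1L]
  list(n50 = s[i], l50 = i)
}

#' Marker density per megabase
#'
#' @param n_markers marker count.
#' @param bases base count of the partition the markers sit on.
#' @return markers per Mb, rounded to one decimal.
#' @export
markers_per_mb <- function(n_markers, bases) {
  round(n_markers / (bases / 1e6), 1)
}

#' Assembly partition statistics
#'
#' Summarises the anchored / oriented / unanchored partitions of a build:
#' scaffold counts (total and by marker class 1 / 2 / 3 / >=4), total bases,
#' N50 and L50, distinct marker counts, markers per Mb, and the percentage
#' of the assembled genome size.
#'
#' @param plan an `anchor_plan`.
#' @param scaffolds a [scaffold_set()] covering the plan.
#' @param genome_total_bp total assembled genome size (>= anchored bases);
#'   default: total bases of `scaffolds`.
#' @return data.frame with one row per partition.
#' @export
assembly_stats <- function(plan, scaffolds, genome_total_bp = NULL) {
  len <- scaffolds$length[match(plan$scaffold_id, scaffolds$scaffold_id)]
  if (anyNA(len)) stop_format("plan scaffold missing from scaffold set")
  if (is.null(genome_total_bp)) genome_total_bp <- sum(as.numeric(scaffolds$length))
  anchored <- plan$chrom > 0L
  oriented <- anchored & plan$orientation %in% c("+", "-")
  if (sum(as.numeric(len[anchored])) > genome_total_bp)
    stop_format("genome_total_bp smaller than anchored bases")
  part_row <- function(name, sel) {
    bases <- sum(as.numeric(len[sel]))
    n_mark <- sum(plan$n_markers[sel])
    ns <- if (any(sel)) n50_stats(len[sel]) else list(n50 = NA, l50 = NA)
    cls <- plan$n_markers[sel]
    data.frame(partition = name, n_scaffolds = sum(sel),
               with_1_marker = sum(cls == 1L), with_2_markers = sum(cls == 2L),
               with_3_markers = sum(cls == 3L), with_4plus_markers = sum(cls >= 4L),
               n_markers = n_mark, total_bases = bases,
               n50 = ns$n50, l50 = ns$l50,
               markers_per_mb = if (bases > 0) markers_per_mb(n_mark, bases) else NA_real_,
               pct_of_genome = round(100 * bases / genome_total_bp, 2),
               stringsAsFactors = FALSE)
  }
  # unanchored partition counts markers on unplaced scaffolds (all LGs)
  rbind(part_row("anchored", anchored),
        part_row("oriented", oriented),
        part_row("unanchored", !anchored))
}

#' Per-LG genetic map statistics
#'
#' Per linkage group: marker count, map length (max - min cM), average
#' marker spacing (length / marker count, one decimal), largest adjacent
#' gap, and counts of gaps above 5 and 10 cM; plus a totals row (length
#' summed, average = total length / total markers, max gap = overall max).
#'
#' @param map a [genetic_map()].
#' @return data.frame with one row per LG and an `"all"` row.
#' @export
map_stats <- function(map) {
  p <- map$placements
  per_lg <- lapply(sort(unique(p$lg)), function(lg) {
    cm <- sort(p$cm[p$lg == lg])
    gaps <- if (length(cm) > 1L) diff(cm) else 0
    data.frame(lg = as.character(lg), n_markers = length(cm),
               length_cm = max(cm) - min(cm),
               avg_cm = round((max(cm) - min(cm)) / length(cm), 1),
               max_gap_cm = max(gaps),
               gaps_over_5 = sum(gaps > 5), gaps_over_10 = sum(gaps > 10),
               stringsAsFactors = FALSE)
  })
  per_lg <- do.call(rbind, per_lg)
  total <- data.frame(lg = "all", n_markers = sum(per_lg$n_markers),
                      length_cm = sum(per_lg$length_cm),
                      avg_cm = round(sum(per_lg$length_cm) / sum(per_lg$n_markers), 1),
                      max_gap_cm = max(per_lg$max_gap_cm),
                      gaps_over_5 = sum(per_lg$gaps_over_5),
                      gaps_over_10 = sum(per_lg$gaps_over_10),
                      stringsAsFactors = FALSE)
  rbind(per_lg, total)
}
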