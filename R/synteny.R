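# Reciprocal-best-hit homolog pairing from two directed protein-similarity
# hit tables, and per-chromosome-pair collinearity (homolog counts and
# absolute Spearman correlation of gene positions — absolute because the
# relative orientation of two assemblies is arbitrary).

best_hit_per_query <- function(hits, e_max) {
  h <- hits[hits$evalue <= e_max, , drop = FALSE]
  if (nrow(h) == 0L)
    return(data.frame(query = character(0), subject = character(0)))
  # score desc, then e-value asc, then subject id: deterministic best
  h <- h[order(h$query, -h$score, h$evalue, h$subject), , drop = FALSE]
  h[!duplicated(h$query), c("query", "subject")]
}

#' Reciprocal best hits
#'
#' A pair (a, b) is kept iff b is a's best hit in the A->B table and a is
#' b's best hit in the B->A table, both hits at e-value <= `e_max`. Score
#' ties break by lower e-value then lexicographic subject id, so the result
#' is deterministic and symmetric in the two genomes.
#'
#' @param ab,ba hit tables (data.frames with query, subject, evalue, score;
#'   see [read_hits()]), A->B and B->A respectively.
#' @param e_max e-value ceiling (default 1e-7).
#' @return data.frame (gene_a, gene_b).
#' @export
reciprocal_best_hits <- function(ab, ba, e_max = 1e-7) {
  best_ab <- best_hit_per_query(ab, e_max)
  best_ba <- best_hit_per_query(ba, e_max)
  back <- best_ba$subject[match(best_ab$subject, best_ba$query)]
  keep <- !is.na(back) & back == best_ab$query
  out <- data.frame(gene_a = best_ab$query[keep], gene_b = best_ab$subject[keep],
                    stringsAsFactors = FALSE)
  out[order(out$gene_a), , drop = FALSE]
}

#' Chromosome correspondence of homolog pairs
#'
#' For every chromosome pair with at least one homolog pair: the pair count
#' and the absolute Spearman correlation of gene positions (NA with fewer
#' than two pairs). Also reports each A-chromosome's dominant partner (the
#' B chromosome with most shared homologs).
#'
#' @param pairs [reciprocal_best_hits()] output.
#' @param pos_a,pos_b gene position tables (gene, chrom, pos), e.g. from
#'   [read_gene_positions()].
#' @return list with `matrix` (chrom_a, chrom_b, n_pairs, abs_rho) and
#'   `dominant` (chrom_a, chrom_b, n_pairs, abs_rho of the dominant pair).
#' @export
chromosome_correspondence <- function(pairs, pos_a, pos_b) {
  ia <- match(pairs$gene_a, pos_a$gene)
  ib <- match(pairs$gene_b, pos_b$gene)
  if (anyNA(ia) || anyNA(ib))
    stop_format("position missing for paired gene (e.g. %s)",
                c(pairs$gene_a[is.na(ia)], pairs$gene_b[is.na(ib)])[1L])
  df <- data.frame(chrom_a = pos_a$chrom[ia], pos_a = pos_a$pos[ia],
                   chrom_b = pos_b$chrom[ib], pos_b = pos_b$pos[ib],
                   stringsAsFactors = FALSE)
  key <- split(seq_len(nrow(df)), paste(df$chrom_a, df$chrom_b, sep = "\r"))
  mat <- do.call(rbind, lapply(key, function(rows) {
    rho <- if (length(rows) >= 2L)
      abs(suppressWarnings(cor(df$pos_a[rows], df$pos_b[rows],
                               method = "spearman")))
    else NA_real_
    data.frame(chrom_a = df$chrom_a[rows[1L]], chrom_b = df$chrom_b[rows[1L]],
               n_pairs = length(rows), abs_rho = rho, stringsAsFactors = FALSE)
  }))
  mat <- mat[order(mat$chrom_a, mat$chrom_b), , drop = FALSE]
  rownames(mat) <- NULL
  dominant <- do.call(rbind, lapply(split(mat, mat$chrom_a), function(m) {
    m[order(-m$n_pairs, m$chrom_b), , drop = FALSE][1L, , drop = FALSE]
  }))
  rownames(dominant) <- NULL
  list(matrix = mat, dominant = dominant)
}

#' Dot-plot export of homolog positions
#'
#' @param pairs,pos_a,pos_b as in [chromosome_correspondence()].
#' @param path output TSV (gene_a, chrom_a, pos_a, gene_b, chrom_b, pos_b).
#' @export
write_dotplot <- function(pairs, pos_a, pos_b, path) {
  ia <- match(pairs$gene_a, pos_a$gene)
  ib <- match(pairs$gene_b, pos_b$gene)
  write_tsv(data.frame(gene_a = pairs$gene_a, chrom_a = pos_a$chrom[ia],
                       pos_a = pos_a$pos[ia], gene_b = pairs$gene_b,
                       chrom_b = pos_b$chrom[ib], pos_b = pos_b$pos[ib]),
            path)
}
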