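# Tab-separated readers/writers for the tabular formats the pipeline touches:
# genetic maps, genotype matrices with depths, two-pool allele-depth tables,
# 12-column protein-hit tables and gene position tables. Dialect: tab
# separator, "." for missing fields, UTF-8, 1-based inclusive coordinates.

NA_TOKEN <- "."

read_tsv_strict <- function(path, required, what) {
  df <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   na.strings = NA_TOKEN, check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop_format("%s %s: missing column(s) %s", what, path,
                paste(missing, collapse = ", "))
  df
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, na = NA_TOKEN, fileEncoding = "UTF-8")
  invisible(path)
}

# Genetic maps --------------------------------------------------------------

#' Construct a genetic map
#'
#' A genetic map is a named, weighted set of marker placements: linkage group
#' (LG), genetic position in centimorgans, and the scaffold coordinate the
#' marker was called on. The weight is used when several maps are merged into
#' a consensus.
#'
#' @param name map label (e.g. the cross it came from).
#' @param weight positive merge weight.
#' @param placements data.frame with columns `marker_id`, `lg`, `cm`,
#'   `scaffold`, `pos` (1-based bp on the scaffold).
#' @param n_lg number of linkage groups expected (default 17).
#' @return a `genetic_map` object; placements sorted by (lg, cm, marker_id).
#' @export
genetic_map <- function(name, weight, placements, n_lg = 17L) {
  assert_scalar_number(weight, "weight", min = 1e-9)
  req <- c("marker_id", "lg", "cm", "scaffold", "pos")
  missing <- setdiff(req, names(placements))
  if (length(missing))
    stop_format("map placements lack column(s): %s", paste(missing, collapse = ", "))
  p <- placements[req]
  p$marker_id <- as.character(p$marker_id)
  p$lg <- as.integer(p$lg)
  p$cm <- as.numeric(p$cm)
  p$scaffold <- as.character(p$scaffold)
  p$pos <- as.integer(p$pos)
  if (anyDuplicated(p$marker_id))
    stop_format("map %s: duplicated marker id %s", name,
                p$marker_id[duplicated(p$marker_id)][1L])
  if (any(is.na(p$lg)) || any(p$lg < 1L) || any(p$lg > n_lg))
    stop_format("map %s: lg outside 1..%d", name, n_lg)
  if (any(!is.finite(p$cm)) || any(p$cm < 0))
    stop_format("map %s: cm must be finite and non-negative", name)
  if (any(is.na(p$pos)) || any(p$pos < 1L))
    stop_format("map %s: scaffold pos must be >= 1", name)
  p <- p[order(p$lg, p$cm, p$marker_id), , drop = FALSE]
  rownames(p) <- NULL
  structure(list(name = name, weight = weight, placements = p, n_lg = n_lg),
            class = "genetic_map")
}

#' @export
print.genetic_map <- function(x, ...) {
  cat(sprintf("genetic_map '%s' (weight %g): %d markers on %d LGs\n",
              x$name, x$weight, nrow(x$placements),
              length(unique(x$placements$lg))))
  invisible(x)
}

#' Read a genetic map from TSV
#'
#' @param path TSV with header `marker_id  lg  cm  scaffold  pos`.
#' @inheritParams genetic_map
#' @return a [genetic_map()].
#' @export
read_genetic_map <- function(path, name, weight, n_lg = 17L) {
  df <- read_tsv_strict(path, c("marker_id", "lg", "cm", "scaffold", "pos"),
                        "genetic map")
  genetic_map(name, weight, df, n_lg = n_lg)
}

#' Write a genetic map to TSV
#'
#' @param map a [genetic_map()].
#' @param path output file.
#' @export
write_genetic_map <- function(map, path) {
  write_tsv(map$placements, path)
}

# Genotype matrices ---------------------------------------------------------

SEG_ALPHABET <- list(lmxll = c("lm", "ll"),
                     nnxnp = c("nn", "np"),
                     hkxhk = c("hh", "hk", "kk"))
SEG_RATIO <- list(lmxll = c(1, 1), nnxnp = c(1, 1), hkxhk = c(1, 2, 1))
MISSING_CALL <- "--"

#' Construct a genotype matrix
#'
#' Offspring genotype calls of an outcross (CP) population with per-call read
#' depths. Markers segregate as lm x ll or nn x np (testcross, offspring 1:1)
#' or hk x hk (intercross, offspring hh:hk:kk = 1:2:1); missing calls are
#' `"--"`.
#'
#' @param markers data.frame with columns `marker_id`, `seg_class`
#'   (lmxll/nnxnp/hkxhk), `scaffold`, `pos`.
#' @param calls character matrix, markers x offspring.
#' @param depths integer matrix of the same shape, read depth per call.
#' @return a `genotype_matrix` object.
#' @export
genotype_matrix <- function(markers, calls, depths) {
  req <- c("marker_id", "seg_class", "scaffold", "pos")
  missing <- setdiff(req, names(markers))
  if (length(missing))
    stop_format("genotype markers lack column(s): %s", paste(missing, collapse = ", "))
  if (!all(markers$seg_class %in% names(SEG_ALPHABET)))
    stop_format("unknown seg_class: %s",
                setdiff(markers$seg_class, names(SEG_ALPHABET))[1L])
  calls <- as.matrix(calls)
  depths <- as.matrix(depths)
  if (!identical(dim(calls), dim(depths)) || nrow(calls) != nrow(markers))
    stop_format("calls/depths dimensions disagree with markers")
  if (any(depths < 0L, na.rm = TRUE)) stop_format("depths must be >= 0")
  rownames(calls) <- rownames(depths) <- markers$marker_id
  colnames(depths) <- colnames(calls)
  structure(list(markers = markers[req], calls = calls,
                 depths = depths, n_offspring = ncol(calls)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d markers x %d offspring (%.1f%% missing)\n",
              nrow(x$calls), ncol(x$calls),
              100 * mean(x$calls == MISSING_CALL)))
  invisible(x)
}

#' Read / write genotype matrices
#'
#' On disk: one row per marker; columns `marker_id`, `seg_class`, `scaffold`,
#' `pos`, then per offspring a call column `<id>` and a depth column
#' `<id>.d`.
#'
#' @param path TSV path.
#' @return [genotype_matrix()] for the reader; the path, invisibly, for the
#'   writer.
#' @export
read_genotypes <- function(path) {
  df <- read_tsv_strict(path, c("marker_id", "seg_class", "scaffold", "pos"),
                        "genotype table")
  others <- setdiff(names(df), c("marker_id", "seg_class", "scaffold", "pos"))
  dcols <- grep("\\.d$", others, value = TRUE)
  ccols <- setdiff(others, dcols)
  if (!setequal(paste0(ccols, ".d"), dcols))
    stop_format("genotype table %s: call/depth columns do not pair up", path)
  calls <- as.matrix(df[ccols])
  calls[is.na(calls)] <- MISSING_CALL
  depths <- as.matrix(df[paste0(ccols, ".d")])
  colnames(depths) <- ccols
  storage.mode(depths) <- "integer"
  genotype_matrix(df[c("marker_id", "seg_class", "scaffold", "pos")], calls, depths)
}

#' @param gm a [genotype_matrix()].
#' @rdname read_genotypes
#' @export
write_genotypes <- function(gm, path) {
  depths <- gm$depths
  colnames(depths) <- paste0(colnames(gm$calls), ".d")
  write_tsv(cbind(gm$markers, as.data.frame(gm$calls), as.data.frame(depths)),
            path)
}

# Pool depth tables ---------------------------------------------------------

#' Construct / read / write a two-pool allele depth table
#'
#' Per-SNP reference and alternate read depths for two phenotype-contrasted
#' offspring bulks, the input of the |Delta(SNP-index)| scan.
#'
#' @param df data.frame with columns `chrom`, `pos` (1-based), `ref1`,
#'   `alt1`, `ref2`, `alt2`.
#' @return a `pool_depth_table` data.frame sorted by (chrom, pos).
#' @export
pool_depth_table <- function(df) {
  req <- c("chrom", "pos", "ref1", "alt1", "ref2", "alt2")
  missing <- setdiff(req, names(df))
  if (length(missing))
    stop_format("pool depth table lacks column(s): %s", paste(missing, collapse = ", "))
  out <- df[req]
  out$chrom <- as.character(out$chrom)
  for (cl in req[-1]) out[[cl]] <- as.integer(out[[cl]])
  if (any(as.matrix(out[req[-(1:2)]]) < 0L, na.rm = TRUE))
    stop_format("pool depths must be >= 0")
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("pool_depth_table", "data.frame")
  out
}

#' @param path TSV path.
#' @rdname pool_depth_table
#' @export
read_pool_depths <- function(path) {
  pool_depth_table(read_tsv_strict(
    path, c("chrom", "pos", "ref1", "alt1", "ref2", "alt2"), "pool depth table"))
}

#' @param tbl a `pool_depth_table`.
#' @rdname pool_depth_table
#' @export
write_pool_depths <- function(tbl, path) {
  write_tsv(as.data.frame(tbl), path)
}

# Protein hit tables and gene positions --------------------------------------

#' Read a 12-column tabular protein alignment hit table
#'
#' The standard tabular alignment output: query, subject, identity, length,
#' mismatches, gap opens, qstart, qend, sstart, send, e-value, bitscore.
#' Only query, subject, e-value and bitscore are used downstream.
#'
#' @param path tabular hits file (no header).
#' @return data.frame (query, subject, evalue, score).
#' @export
read_hits <- function(path) {
  df <- read.delim(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 12L)
    stop_format("hit table %s: expected >= 12 columns, got %d", path, ncol(df))
  out <- data.frame(query = as.character(df[[1]]), subject = as.character(df[[2]]),
                    evalue = as.numeric(df[[11]]), score = as.numeric(df[[12]]),
                    stringsAsFactors = FALSE)
  if (any(out$score < 0)) stop_format("hit table %s: negative scores", path)
  out
}

#' Read gene positions
#'
#' @param path TSV with header `gene  chrom  start  end`; the gene position
#'   used for synteny is the span midpoint.
#' @return data.frame (gene, chrom, pos).
#' @export
read_gene_positions <- function(path) {
  df <- read_tsv_strict(path, c("gene", "chrom", "start", "end"), "gene positions")
  data.frame(gene = as.character(df$gene), chrom = as.character(df$chrom),
             pos = (as.numeric(df$start) + as.numeric(df$end)) / 2,
             stringsAsFactors = FALSE)
}
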