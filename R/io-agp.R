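# AGP v2.1 representation of how scaffolds and spacer gaps tile assembled
# objects. Internally an `agp` data.frame with typed columns; on disk the
# standard 9-column tab-separated dialect (gap rows: gap_type "scaffold",
# linkage "yes", evidence "map").

agp_df <- function(object_id, object_beg, object_end, part_number,
                   component_type, component_id, component_beg, component_end,
                   orientation, gap_length, gap_type, linkage) {
  out <- data.frame(object_id = as.character(object_id),
                    object_beg = as.integer(object_beg),
                    object_end = as.integer(object_end),
                    part_number = as.integer(part_number),
                    component_type = as.character(component_type),
                    component_id = as.character(component_id),
                    component_beg = as.integer(component_beg),
                    component_end = as.integer(component_end),
                    orientation = as.character(orientation),
                    gap_length = as.integer(gap_length),
                    gap_type = as.character(gap_type),
                    linkage = as.character(linkage),
                    stringsAsFactors = FALSE)
  class(out) <- c("agp", "data.frame")
  out
}

#' Validate AGP tiling
#'
#' Checks that within every object the parts tile `1..object_end` contiguously
#' (no holes, no overlaps), that spans are positive, and that component spans
#' match object spans.
#'
#' @param agp an `agp` data.frame.
#' @return `agp`, invisibly, or an error naming the object and coordinate.
#' @export
validate_agp <- function(agp) {
  if (any(agp$object_end < agp$object_beg))
    stop_format("object_end < object_beg in object %s",
                agp$object_id[agp$object_end < agp$object_beg][1L])
  for (obj in unique(agp$object_id)) {
    rows <- agp[agp$object_id == obj, , drop = FALSE]
    rows <- rows[order(rows$part_number), , drop = FALSE]
    expect_beg <- 1L
    for (i in seq_len(nrow(rows))) {
      if (rows$object_beg[i] != expect_beg)
        stop_format("object %s: tiling %s at coordinate %d (part %d starts at %d)",
                    obj, if (rows$object_beg[i] > expect_beg) "hole" else "overlap",
                    expect_beg, rows$part_number[i], rows$object_beg[i])
      span <- rows$object_end[i] - rows$object_beg[i] + 1L
      if (rows$component_type[i] == "W") {
        cspan <- rows$component_end[i] - rows$component_beg[i] + 1L
        if (cspan != span)
          stop_format("object %s part %d: component span %d != object span %d",
                      obj, rows$part_number[i], cspan, span)
      } else if (rows$gap_length[i] != span) {
        stop_format("object %s part %d: gap length %d != object span %d",
                    obj, rows$part_number[i], rows$gap_length[i], span)
      }
      expect_beg <- rows$object_end[i] + 1L
    }
  }
  invisible(agp)
}

#' Assemble AGP rows for one object from ordered components
#'
#' @param object_id object (pseudo-chromosome) name.
#' @param component_id character vector of scaffold ids, in order.
#' @param component_len integer vector of scaffold lengths.
#' @param orientation per-scaffold `"+"`, `"-"` or `"?"`.
#' @param gap_len spacer inserted between consecutive scaffolds (bp); 0
#'   suppresses gap rows.
#' @return an `agp` data.frame.
#' @export
agp_object <- function(object_id, component_id, component_len, orientation,
                       gap_len = 100L) {
  n <- length(component_id)
  stopifnot(length(component_len) == n, length(orientation) == n, n >= 1L)
  rows <- vector("list", 2L * n - 1L)
  pos <- 1L
  part <- 1L
  for (i in seq_len(n)) {
    len <- as.integer(component_len[i])
    rows[[part]] <- list("W", component_id[i], 1L, len, orientation[i], NA_integer_, pos)
    pos <- pos + len
    part <- part + 1L
    if (i < n && gap_len > 0L) {
      rows[[part]] <- list("N", NA_character_, NA_integer_, NA_integer_,
                           NA_character_, as.integer(gap_len), pos)
      pos <- pos + as.integer(gap_len)
      part <- part + 1L
    }
  }
  rows <- rows[seq_len(part - 1L)]
  m <- length(rows)
  get <- function(k) sapply(rows, `[[`, k)
  beg <- as.integer(get(7))
  span <- ifelse(get(1) == "W", as.integer(get(4)), as.integer(get(6)))
  out <- agp_df(object_id = rep(object_id, m), object_beg = beg,
                object_end = beg + span - 1L, part_number = seq_len(m),
                component_type = as.character(get(1)),
                component_id = as.character(get(2)),
                component_beg = as.integer(get(3)),
                component_end = as.integer(get(4)),
                orientation = as.character(get(5)),
                gap_length = as.integer(get(6)),
                gap_type = ifelse(get(1) == "N", "scaffold", NA_character_),
                linkage = ifelse(get(1) == "N", "yes", NA_character_))
  validate_agp(out)
  out
}

#' Write AGP v2.1
#'
#' The tiling invariant is asserted on every write.
#'
#' @param agp an `agp` data.frame (possibly several objects).
#' @param path output file.
#' @export
write_agp <- function(agp, path) {
  validate_agp(agp)
  w <- agp$component_type == "W"
  col6 <- ifelse(w, agp$component_id, as.character(agp$gap_length))
  col7 <- ifelse(w, as.character(agp$component_beg), agp$gap_type)
  col8 <- ifelse(w, as.character(agp$component_end), agp$linkage)
  col9 <- ifelse(w, agp$orientation, "map")
  out <- data.frame(agp$object_id, agp$object_beg, agp$object_end,
                    agp$part_number, agp$component_type, col6, col7, col8, col9)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##agp-version\t2.1", con)
  write.table(out, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read AGP v2.1
#'
#' @param path AGP file written by [write_agp()] or compatible.
#' @return an `agp` data.frame, validated.
#' @export
read_agp <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) != 9L))
    stop_format("AGP rows must have 9 tab-separated fields (%s)", path)
  m <- do.call(rbind, fields)
  w <- m[, 5] == "W"
  out <- agp_df(object_id = m[, 1], object_beg = m[, 2], object_end = m[, 3],
                part_number = m[, 4], component_type = m[, 5],
                component_id = ifelse(w, m[, 6], NA_character_),
                component_beg = ifelse(w, m[, 7], NA),
                component_end = ifelse(w, m[, 8], NA),
                orientation = ifelse(w, m[, 9], NA_character_),
                gap_length = ifelse(w, NA, m[, 6]),
                gap_type = ifelse(w, NA_character_, m[, 7]),
                linkage = ifelse(w, NA_character_, m[, 8]))
  validate_agp(out)
  out
}

#' Project an object interval onto its scaffold pieces
#'
#' Maps a 1-based inclusive interval on an assembled object back to the
#' scaffold coordinates that the AGP places there, honouring component
#' orientation (`"?"` is treated as `"+"`).
#'
#' @param agp an `agp` data.frame.
#' @param object_id object to cut.
#' @param start,end 1-based inclusive interval on the object.
#' @return data.frame (scaffold_id, piece_start, piece_end, piece_len),
#'   piece coordinates 1-based inclusive on the scaffold.
#' @export
agp_pieces <- function(agp, object_id, start, end) {
  rows <- agp[agp$object_id == object_id & agp$component_type == "W", , drop = FALSE]
  rows <- rows[rows$object_end >= start & rows$object_beg <= end, , drop = FALSE]
  rows <- rows[order(rows$object_beg), , drop = FALSE]
  n <- nrow(rows)
  out <- data.frame(scaffold_id = character(n), piece_start = integer(n),
                    piece_end = integer(n), piece_len = integer(n),
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    ov_beg <- max(start, rows$object_beg[i])
    ov_end <- min(end, rows$object_end[i])
    if (identical(rows$orientation[i], "-")) {
      p_start <- rows$component_end[i] - (ov_end - rows$object_beg[i])
      p_end <- rows$component_end[i] - (ov_beg - rows$object_beg[i])
    } else {
      p_start <- rows$component_beg[i] + (ov_beg - rows$object_beg[i])
      p_end <- rows$component_beg[i] + (ov_end - rows$object_beg[i])
    }
    out$scaffold_id[i] <- rows$component_id[i]
    out$piece_start[i] <- p_start
    out$piece_end[i] <- p_end
    out$piece_len[i] <- p_end - p_start + 1L
  }
  out
}
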