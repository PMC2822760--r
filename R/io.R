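# On-disk formats. All genomic intervals are 0-based half-open both on disk
# and in memory; conversion to IRanges' 1-based closed convention happens only
# inside the two interval helpers below. FR values are serialized with 6
# significant digits; downstream comparisons always use tolerances.

#' Read a probe annotation table
#'
#' BED-like TSV with header and columns `chrom`, `start`, `end`, `probe_id`
#' and optionally `gene`. Input not in genome order is sorted silently (with a
#' message); malformed intervals and duplicate probe ids are rejected with the
#' offending line.
#'
#' @param path File path.
#' @return A `probe_grid`.
#' @export
read_probe_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (ncol(df) < 4) stop("probe table needs >= 4 columns", call. = FALSE)
  names(df)[1:4] <- c("chrom", "start", "end", "probe_id")
  if (ncol(df) >= 5) names(df)[5] <- "gene" else df$gene <- NA_character_
  df$gene <- as.character(df$gene)
  bad <- which(df$end <= df$start)
  if (length(bad))
    stop("malformed interval (end <= start) at line ", bad[1] + 1L, " of ", path,
         call. = FALSE)
  if (anyDuplicated(df$probe_id))
    stop("duplicate probe_id in ", path, call. = FALSE)
  o <- genome_order(df$chrom, df$start)
  if (!identical(o, seq_len(nrow(df)))) {
    message("probe table not in genome order; sorting")
    df <- df[o, , drop = FALSE]
    rownames(df) <- NULL
  }
  as_probe_grid(df[, c("chrom", "start", "end", "probe_id", "gene")])
}

#' @rdname read_probe_table
#' @param grid A `probe_grid` to write.
#' @export
write_probe_table <- function(grid, path) {
  write.table(as.data.frame(grid), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a fluorescence-ratio matrix
#'
#' TSV with a header row of sample ids and `probe_id` as first column. Rows
#' are aligned to `grid` order; probes present in the grid but absent from the
#' file become all-missing rows (logged); probes absent from the grid are an
#' error. Empty cells are recorded as missing (`NA`), never zero.
#'
#' @param path File path.
#' @param grid The `probe_grid` the matrix belongs to.
#' @return Numeric matrix, rownames = probe ids in grid order, colnames =
#'   sample ids.
#' @export
read_fr_matrix <- function(path, grid) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "probe_id") stop("first column must be probe_id", call. = FALSE)
  ids <- df$probe_id
  if (anyDuplicated(names(df)[-1])) stop("duplicate sample ids in header", call. = FALSE)
  unknown <- setdiff(ids, grid$probe_id)
  if (length(unknown))
    stop("probe(s) absent from grid: ", paste(head(unknown, 3), collapse = ", "),
         call. = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- ids
  missing_rows <- setdiff(grid$probe_id, ids)
  if (length(missing_rows))
    message(length(missing_rows), " grid probe(s) absent from matrix; recorded as missing")
  out <- matrix(NA_real_, nrow(grid), ncol(m),
                dimnames = list(grid$probe_id, colnames(m)))
  out[ids, ] <- m
  out
}

#' @rdname read_fr_matrix
#' @param fr Numeric matrix to write (rownames = probe ids).
#' @export
write_fr_matrix <- function(fr, path) {
  df <- data.frame(probe_id = rownames(fr), signif(fr, 6),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a sample sheet
#'
#' TSV with columns `sample_id`, `class`, `sex`. Classes come from the closed
#' vocabulary `CP, AP, BCL, BCM, BCmix, unclassified, control`; sex from
#' `M, F, unknown`. Duplicate sample ids are rejected.
#'
#' @param path File path.
#' @return data.frame sample sheet.
#' @export
read_sample_sheet <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "class", "sex")
  if (!all(need %in% names(df)))
    stop("sample sheet needs columns ", paste(need, collapse = ", "), call. = FALSE)
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id", call. = FALSE)
  bad <- setdiff(unique(df$class), sample_classes())
  if (length(bad)) stop("unknown class(es): ", paste(bad, collapse = ", "), call. = FALSE)
  bad <- setdiff(unique(df$sex), c("M", "F", "unknown"))
  if (length(bad)) stop("unknown sex value(s): ", paste(bad, collapse = ", "), call. = FALSE)
  df[, need]
}

#' @rdname read_sample_sheet
#' @param samples Sample sheet to write.
#' @export
write_sample_sheet <- function(samples, path) {
  write.table(samples, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

empty_cnv_mask <- function() {
  structure(data.frame(chrom = character(), start = numeric(), end = numeric(),
                       stringsAsFactors = FALSE),
            merged = TRUE, class = c("cnv_mask", "data.frame"))
}

# union of 0-based half-open intervals, per chromosome, via IRanges::reduce
merge_intervals <- function(df) {
  if (!nrow(df)) return(empty_cnv_mask())
  pieces <- lapply(unique(df$chrom[genome_order(df$chrom, df$start)]), function(ch) {
    sub <- df[df$chrom == ch, , drop = FALSE]
    r <- IRanges::reduce(IRanges::IRanges(sub$start + 1, sub$end))
    data.frame(chrom = ch, start = IRanges::start(r) - 1, end = IRanges::end(r),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  structure(out, merged = TRUE, class = c("cnv_mask", "data.frame"))
}

#' Load a CNV mask from a BED file
#'
#' Headerless BED (>= 3 columns) of known copy-number-variable regions. After
#' loading, intervals are sorted and overlap-merged per chromosome, so masking
#' downstream is a plain interval-overlap test. An empty file yields an empty
#' mask (masking becomes the identity).
#'
#' @param path BED file path.
#' @return A `cnv_mask` data.frame (`chrom`, `start`, `end`) with attribute
#'   `merged = TRUE`.
#' @export
load_cnv_mask <- function(path) {
  txt <- readLines(path, warn = FALSE)
  txt <- txt[nzchar(trimws(txt))]
  if (!length(txt)) return(empty_cnv_mask())
  df <- read.table(text = txt, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("CNV mask BED needs >= 3 columns", call. = FALSE)
  df <- df[, 1:3]
  names(df) <- c("chrom", "start", "end")
  if (!is.numeric(df$start) || !is.numeric(df$end))
    stop("malformed BED line in ", path, call. = FALSE)
  if (any(df$end <= df$start))
    stop("malformed interval (end <= start) at line ",
         which(df$end <= df$start)[1], " of ", path, call. = FALSE)
  merge_intervals(df)
}

#' @rdname load_cnv_mask
#' @param mask A `cnv_mask` to write (3-column headerless BED).
#' @export
write_cnv_mask <- function(mask, path) {
  if (!nrow(mask)) { writeLines(character(0), path); return(invisible(path)) }
  write.table(format(as.data.frame(mask), scientific = FALSE, trim = TRUE),
              path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Serialize a merge tree as Newick
#'
#' Writes an `hclust` sample dendrogram as a Newick string in which each
#' branch length is the difference between the parent's and the child's merge
#' height (leaves sit at height 0), so two leaves merged at height 1 become
#' `(A:1,B:1);`. A single label is serialized as the degenerate tree `A;`.
#'
#' @param tree An `hclust` object, or a single character label.
#' @param path Optional file to write to.
#' @param digits Significant digits for branch lengths.
#' @return The Newick string, invisibly if `path` is given.
#' @export
write_newick <- function(tree, path = NULL, digits = 6) {
  if (is.character(tree) && length(tree) == 1) {
    s <- paste0(quote_label(tree), ";")
  } else {
    stopifnot(inherits(tree, "hclust"))
    labs <- tree$labels %||% as.character(seq_len(nrow(tree$merge) + 1))
    if (anyDuplicated(labs)) stop("duplicate leaf labels", call. = FALSE)
    node <- function(i, parent_h) {
      if (i < 0) paste0(quote_label(labs[-i]), ":", signif(parent_h, digits))
      else {
        h <- tree$height[i]
        paste0("(", node(tree$merge[i, 1], h), ",", node(tree$merge[i, 2], h),
               "):", signif(parent_h - h, digits))
      }
    }
    root <- nrow(tree$merge)
    h <- tree$height[root]
    s <- paste0("(", node(tree$merge[root, 1], h), ",",
                node(tree$merge[root, 2], h), ");")
  }
  if (!is.null(path)) { writeLines(s, path); return(invisible(s)) }
  s
}

quote_label <- function(x) {
  if (grepl("[ (),:;'\\[\\]]", x)) paste0("'", gsub("'", "''", x), "'") else x
}

#' Read a region definition table
#'
#' TSV with header and columns `name`, `chrom`, `start`, `end`, `role`
#' (`primary`/`secondary`), as produced by [default_signature_regions()].
#'
#' @param path File path.
#' @return data.frame of region definitions.
#' @export
read_region_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "chrom", "start", "end", "role")
  if (!all(need %in% names(df)))
    stop("region table needs columns ", paste(need, collapse = ", "), call. = FALSE)
  if (anyDuplicated(df$name)) stop("duplicate region names", call. = FALSE)
  if (any(df$end <= df$start)) stop("malformed region interval", call. = FALSE)
  bad <- setdiff(unique(df$role), c("primary", "secondary"))
  if (length(bad)) stop("unknown role(s): ", paste(bad, collapse = ", "), call. = FALSE)
  df
}
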