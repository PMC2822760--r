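#' Hierarchical clustering of samples on selected probes
#'
#' Agglomerative clustering of sample columns (default average linkage on
#' Euclidean distances), as used to display the class structure of the
#' selected probe set. Missing cells are imputed by the probe-wise median
#' (logged); clustering is deterministic given the input values.
#'
#' @param x Selected probes x samples matrix (>= 2 samples, no all-missing
#'   column).
#' @param linkage Agglomeration method passed to [stats::hclust()].
#' @param metric Distance metric passed to [stats::dist()].
#' @return list of class `sample_clustering`: `order` (leaf order, left to
#'   right), `tree` (`hclust`), `n_imputed`.
#' @export
hierarchical_cluster <- function(x, linkage = "average", metric = "euclidean") {
  if (ncol(x) < 2) stop("need >= 2 samples to cluster", call. = FALSE)
  all_missing <- colSums(!is.na(x)) == 0
  if (any(all_missing))
    stop("all-missing sample column(s): ",
         paste(colnames(x)[all_missing], collapse = ", "), call. = FALSE)
  n_imputed <- sum(is.na(x))
  if (n_imputed) {
    message(n_imputed, " missing cell(s) imputed by probe-wise median")
    for (i in which(rowSums(is.na(x)) > 0)) {
      x[i, is.na(x[i, ])] <- median(x[i, ], na.rm = TRUE)
    }
  }
  tree <- hclust(dist(t(x), method = metric), method = linkage)
  structure(list(order = tree$labels[tree$order], tree = tree,
                 n_imputed = n_imputed),
            class = "sample_clustering")
}

#' Cut a sample clustering into k groups
#'
#' @param clustering A [hierarchical_cluster()] result.
#' @param k Number of clusters.
#' @return Named integer vector of cluster memberships.
#' @export
cut_clusters <- function(clustering, k = 2) {
  cutree(clustering$tree, k = k)
}

#' Per-sample deletion flag for a genomic region
#'
#' A sample is flagged `deleted` when at least `min_fraction` of the probes
#' overlapping the region carry call `-1` (missing calls count against the
#' fraction), `no_data` when every region probe is missing for that sample,
#' `not_deleted` otherwise.
#'
#' @param calls A [call_matrix()].
#' @param grid Matching `probe_grid`.
#' @param region One-row data.frame (or list) with `name`, `chrom`, `start`,
#'   `end`; must overlap at least one probe.
#' @param min_fraction Fraction of region probes required (default 0.5).
#' @return Named character vector over samples with values
#'   `deleted` / `not_deleted` / `no_data`.
#' @export
region_deletion_flag <- function(calls, grid, region, min_fraction = 0.5) {
  idx <- probes_in_region(grid, region$chrom, region$start, region$end)
  if (!length(idx))
    stop("region '", region$name, "' overlaps no probe", call. = FALSE)
  sub <- calls[idx, , drop = FALSE]
  n_probe <- length(idx)
  n_del <- colSums(sub == -1L, na.rm = TRUE)
  n_miss <- colSums(is.na(sub))
  flag <- ifelse(n_miss == n_probe, "no_data",
                 ifelse(n_del >= min_fraction * n_probe, "deleted", "not_deleted"))
  setNames(flag, colnames(calls))
}

#' Region deletion flags for a whole region set
#'
#' @param calls A [call_matrix()].
#' @param grid Matching `probe_grid`.
#' @param regions Region definition data.frame (`name`, `chrom`, `start`,
#'   `end`, `role`), e.g. [default_signature_regions()].
#' @param min_fraction Passed to [region_deletion_flag()].
#' @return Character matrix, samples x regions.
#' @export
signature_flags <- function(calls, grid, regions, min_fraction = 0.5) {
  m <- vapply(seq_len(nrow(regions)), function(i)
    region_deletion_flag(calls, grid, regions[i, ], min_fraction),
    character(ncol(calls)))
  colnames(m) <- regions$name
  m
}

#' Classify concomitant 7p/9p loss per sample
#'
#' A sample carries the concomitant loss exactly when every secondary-role
#' region is flagged `deleted` (the primary antigen-receptor/IKZF1 regions
#' characterize the lymphoid signature itself; the secondary regions define
#' the additional shared segmental loss). Flagging more regions as deleted can
#' therefore never revoke a concomitant call.
#'
#' @param flags Samples x regions flag matrix from [signature_flags()].
#' @param regions The region definitions used to compute `flags`.
#' @return list of class `signature_call`: `flags`, `concomitant` (named
#'   logical), `regions`.
#' @export
classify_concomitant <- function(flags, regions) {
  sec <- regions$name[regions$role == "secondary"]
  conc <- if (length(sec)) {
    apply(flags[, sec, drop = FALSE] == "deleted", 1, all)
  } else setNames(rep(TRUE, nrow(flags)), rownames(flags))  # vacuous
  structure(list(flags = flags, concomitant = conc, regions = regions),
            class = "signature_call")
}

#' Cohort summary of region deletions in a target class
#'
#' Counts, per region, how many samples of the target class are flagged
#' deleted, plus the concomitant-loss count, giving the per-region fractions
#' used to characterize the lymphoid deletion signature.
#'
#' @param signature A [classify_concomitant()] result.
#' @param samples Sample sheet.
#' @param target_class Character vector of classes to summarize (default the
#'   lymphoid classes).
#' @return data.frame of class `cohort_summary`: `region`, `n_deleted`,
#'   `n_no_data`, `n_class`, `fraction` (NA when the class is empty), with a
#'   final `concomitant` row.
#' @export
cohort_summary <- function(signature, samples, target_class = c("BCL", "BCmix")) {
  ids <- samples$sample_id[samples$class %in% target_class]
  fl <- signature$flags[ids, , drop = FALSE]
  n_class <- length(ids)
  region <- colnames(signature$flags)
  n_del <- if (n_class) colSums(fl == "deleted") else setNames(integer(length(region)), region)
  n_nd <- if (n_class) colSums(fl == "no_data") else setNames(integer(length(region)), region)
  out <- data.frame(region = region,
                    n_deleted = as.integer(n_del),
                    n_no_data = as.integer(n_nd),
                    n_class = n_class,
                    fraction = if (n_class) n_del / n_class else NA_real_,
                    row.names = NULL, stringsAsFactors = FALSE)
  conc <- signature$concomitant[ids]
  out <- rbind(out, data.frame(region = "concomitant",
                               n_deleted = as.integer(sum(conc)),
                               n_no_data = 0L, n_class = n_class,
                               fraction = if (n_class) sum(conc) / n_class else NA_real_,
                               stringsAsFactors = FALSE))
  class(out) <- c("cohort_summary", "data.frame")
  out
}
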