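#' Build an ordered probe grid over a genome
#'
#' Allocates `n_probes` oligonucleotide probes to chromosomes proportionally to
#' their lengths (largest-remainder rounding, ties to the earlier chromosome),
#' placing them evenly with a small uniform jitter. Adjacency downstream (runs
#' of neighbouring probes) is defined by this grid and never crosses a
#' chromosome boundary. Coordinates are 0-based half-open throughout.
#'
#' @param genome_spec Chromosome lengths in bp: a named numeric vector, or a
#'   data.frame with columns `chrom` and `length`.
#' @param n_probes Total number of probes (>= 2).
#' @param seed Integer seed for the jitter, or `NULL` to draw from the current
#'   RNG stream (used when called inside [simulate_cohort()]).
#' @param probe_length Probe footprint in bp (default 60, oligo arrays).
#' @param jitter Jitter amplitude as a fraction of the inter-probe spacing;
#'   must stay below 0.5 so starts remain strictly increasing.
#' @return A `probe_grid`: data.frame with columns `chrom`, `start`, `end`,
#'   `probe_id`, `gene`, sorted in genome order, with strictly increasing
#'   starts within each chromosome and unique probe ids.
#' @export
#' @examples
#' g <- build_probe_grid(c(chr1 = 3e6, chr2 = 1e6), 100, seed = 1)
#' table(g$chrom)   # 75 / 25 by proportional allocation
build_probe_grid <- function(genome_spec, n_probes, seed = NULL,
                             probe_length = 60L, jitter = 0.2) {
  spec <- as_genome_spec(genome_spec)
  if (length(n_probes) != 1L || is.na(n_probes) || n_probes < 2)
    stop_config("n_probes must be a single integer >= 2")
  if (any(spec$length <= 0)) stop_config("chromosome lengths must be positive")
  if (jitter < 0 || jitter >= 0.5) stop_config("jitter must be in [0, 0.5)")
  n_probes <- as.integer(n_probes)

  # largest-remainder apportionment
  quota <- n_probes * spec$length / sum(spec$length)
  base <- floor(quota)
  left <- n_probes - sum(base)
  if (left > 0) {
    pick <- order(-(quota - base), seq_along(quota))[seq_len(left)]
    base[pick] <- base[pick] + 1
  }

  with_seed(seed, {
    pieces <- lapply(seq_len(nrow(spec)), function(i) {
      n_c <- base[i]
      if (n_c == 0) return(NULL)
      L <- spec$length[i]
      spacing <- L / n_c
      centre <- (seq_len(n_c) - 0.5) * spacing
      start <- round(centre + runif(n_c, -jitter, jitter) * spacing)
      start <- pmin(pmax(start, 0), max(L - probe_length, 0))
      # guard against collisions when spacing is only a few bp
      if (any(diff(start) <= 0)) {
        start <- sort(start)
        while (any(d <- diff(start) <= 0)) start[which(d) + 1L] <- start[which(d) + 1L] + 1
      }
      data.frame(chrom = spec$chrom[i], start = start,
                 end = pmin(start + probe_length, L),
                 stringsAsFactors = FALSE)
    })
    grid <- do.call(rbind, pieces)
    grid <- grid[genome_order(grid$chrom, grid$start), , drop = FALSE]
    grid$probe_id <- sprintf("P%06d", seq_len(nrow(grid)))
    grid$gene <- NA_character_
    rownames(grid) <- NULL
    as_probe_grid(grid)
  })
}

as_genome_spec <- function(genome_spec) {
  if (is.data.frame(genome_spec)) {
    stopifnot(all(c("chrom", "length") %in% names(genome_spec)))
    data.frame(chrom = as.character(genome_spec$chrom),
               length = as.numeric(genome_spec$length),
               stringsAsFactors = FALSE)
  } else if (is.numeric(genome_spec) && !is.null(names(genome_spec))) {
    data.frame(chrom = names(genome_spec), length = as.numeric(genome_spec),
               stringsAsFactors = FALSE)
  } else stop_config("genome_spec must be a named numeric vector or a data.frame(chrom, length)")
}

as_probe_grid <- function(df) {
  validate_probe_grid(df)
  class(df) <- c("probe_grid", "data.frame")
  df
}

validate_probe_grid <- function(grid) {
  need <- c("chrom", "start", "end", "probe_id")
  if (!all(need %in% names(grid)))
    stop("probe grid needs columns ", paste(need, collapse = ", "), call. = FALSE)
  if (anyDuplicated(grid$probe_id))
    stop("duplicate probe_id in probe grid", call. = FALSE)
  bad <- which(grid$end <= grid$start)
  if (length(bad))
    stop("malformed probe interval (end <= start) at row ", bad[1], call. = FALSE)
  for (ch in unique(grid$chrom)) {
    s <- grid$start[grid$chrom == ch]
    if (any(diff(s) <= 0))
      stop("probe starts not strictly increasing on ", ch, call. = FALSE)
  }
  invisible(grid)
}

#' @export
print.probe_grid <- function(x, ...) {
  cat(sprintf("probe_grid: %d probes on %d chromosome(s)\n",
              nrow(x), length(unique(x$chrom))))
  print(head(as.data.frame(x)), ...)
  invisible(x)
}

# row indices of probes overlapping [start, end) on chrom (>= 1 bp overlap)
probes_in_region <- function(grid, chrom, start, end) {
  which(grid$chrom == chrom & grid$start < end & grid$end > start)
}
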