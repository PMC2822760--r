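# Independent brute-force oracles, written loop-first and kept deliberately
# naive so they share no code path with the package implementation.

# two-sample pooled-variance relative difference, one probe at a time
oracle_d <- function(x, g2, s0) {
  vapply(seq_len(nrow(x)), function(i) {
    a <- x[i, !g2]; b <- x[i, g2]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) < 2 || length(b) < 2) return(NA_real_)
    ss <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
    s <- sqrt((1 / length(a) + 1 / length(b)) * ss / (length(a) + length(b) - 2))
    if (s + s0 == 0) return(NA_real_)
    (mean(b) - mean(a)) / (s + s0)
  }, 0)
}

# per-cell threshold comparison
oracle_calls <- function(fr, centers, sds, k) {
  out <- matrix(NA_integer_, nrow(fr), ncol(fr), dimnames = dimnames(fr))
  for (j in seq_len(ncol(fr))) for (i in seq_len(nrow(fr))) {
    v <- fr[i, j]
    if (is.na(v)) next
    out[i, j] <- if (sds[j] == 0) 0L
    else if (v > centers[j] + k * sds[j]) 1L
    else if (v < centers[j] - k * sds[j]) -1L else 0L
  }
  out
}

# run/recurrence screen via rle per sample, merged qualifying windows
oracle_loci <- function(calls, grid, min_adjacent, min_samples) {
  p <- nrow(calls)
  rows <- list()
  for (dir in c(-1L, 1L)) {
    # window support counts
    supp <- vector("list", p)
    for (s in seq_len(ncol(calls))) {
      for (ch in unique(grid$chrom)) {
        idx <- which(grid$chrom == ch)
        v <- calls[idx, s]
        r <- rle(!is.na(v) & v == dir)
        pos <- cumsum(c(1, r$lengths))
        for (q in which(r$values & r$lengths >= min_adjacent)) {
          from <- idx[pos[q]]; to <- idx[pos[q] + r$lengths[q] - 1]
          for (w in from:(to - min_adjacent + 1))
            supp[[w]] <- c(supp[[w]], colnames(calls)[s])
        }
      }
    }
    qual <- vapply(supp, length, 0L) >= min_samples
    if (!any(qual)) next
    starts <- which(qual)
    grps <- split(starts, cumsum(c(1, diff(starts) != 1)))
    for (g in grps) {
      i1 <- g[1]; i2 <- g[length(g)] + min_adjacent - 1
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = grid$chrom[i1], start = grid$start[i1], end = grid$end[i2],
        direction = dir,
        samples = paste(sort(unique(unlist(supp[g]))), collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(data.frame(chrom = character(), start = numeric(),
                                       end = numeric(), direction = integer(),
                                       samples = character()))
  out <- do.call(rbind, rows)
  out[order(out$chrom, out$start, out$direction), , drop = FALSE]
}

# interval union / overlap on a per-bp boolean genome
oracle_union <- function(intervals, genome_len) {
  cov <- rep(FALSE, genome_len)
  for (i in seq_len(nrow(intervals)))
    cov[(intervals$start[i] + 1):intervals$end[i]] <- TRUE
  r <- rle(cov)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  data.frame(start = starts[r$values] - 1, end = ends[r$values])
}

oracle_overlaps <- function(s1, e1, s2, e2) max(s1, s2) < min(e1, e2)

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# reduced 12-vs-62 study cohort used by the planted-design experiments
planted_config <- function(seed, n_probes = 10000, ...) {
  demo_simulation_config(
    n_probes = n_probes,
    class_counts = c(CP = 33, BCL = 10, BCM = 15, BCmix = 2, control = 14),
    seed = seed, ...)
}

# pure-noise cohort on an autosome-only genome (no events, no CNVs)
null_config <- function(seed, n_probes = 10000) {
  simulation_config(
    genome_spec = c(chr2 = 120e6, chr7 = 159e6, chr9 = 140e6, chr14 = 106.4e6),
    n_probes = n_probes,
    class_counts = c(CP = 33, BCL = 10, BCM = 15, BCmix = 2, control = 14),
    signature_regions = NULL, cnv_loci = NULL, seed = seed)
}

lymphoid_labels <- function(samples) {
  factor(ifelse(samples$class %in% c("BCL", "BCmix"), "lymphoid", "other"),
         levels = c("other", "lymphoid"))
}

tiny_grid <- function(chrom, n_per, spacing = 1000, len = 60) {
  df <- do.call(rbind, lapply(seq_along(chrom), function(i) {
    start <- seq(0, by = spacing, length.out = n_per[i])
    data.frame(chrom = chrom[i], start = start, end = start + len,
               stringsAsFactors = FALSE)
  }))
  df$probe_id <- sprintf("T%04d", seq_len(nrow(df)))
  df$gene <- NA_character_
  acghsig:::as_probe_grid(df)
}
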