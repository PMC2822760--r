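mk_qc <- function(ids, center = 1, sd = 0.1) {
  data.frame(sample_id = ids, center = center, sd = sd,
             n_iter = 1L, n_excluded = 0L, stringsAsFactors = FALSE)
}

test_that("threshold call semantics: centre gives 0, a 5-SD excursion is called", {
  ids <- paste0("S", 1:3)
  fr <- matrix(1, 10, 3, dimnames = list(sprintf("P%02d", 1:10), ids))
  qc <- mk_qc(ids)
  expect_true(all(call_matrix(fr, qc, 4) == 0L))

  fr[4, 2] <- 1 - 5 * 0.1
  cm <- call_matrix(fr, qc, 4)
  expect_equal(cm[4, 2], -1L)
  expect_equal(sum(cm != 0), 1L)
})

test_that("a zero-SD sample yields all-zero calls with a warning; missing stays missing", {
  ids <- c("A", "B")
  fr <- matrix(c(0.1, 2, NA, 1), 2, 2, dimnames = list(c("P1", "P2"), ids))
  qc <- mk_qc(ids, sd = c(0, 0.1))
  expect_warning(cm <- call_matrix(fr, qc, 4), "sd = 0")
  expect_equal(cm[, "A"], c(P1 = 0L, P2 = 0L))
  expect_true(is.na(cm["P1", "B"]))
})

test_that("calls equal the brute-force per-cell comparison on random instances", {
  set.seed(41)
  for (case in 1:100) {
    p <- 200; n <- 20
    ids <- paste0("S", 1:n)
    centers <- runif(n, 0.95, 1.05)
    sds <- runif(n, 0.05, 0.2)
    fr <- matrix(rnorm(p * n, 1, 0.3), p, n,
                 dimnames = list(sprintf("P%03d", 1:p), ids))
    fr[sample(p * n, 20)] <- NA
    k <- sample(c(3, 4), 1)
    cm <- call_matrix(fr, mk_qc(ids, centers, sds), k)
    expect_identical(unclass(cm)[, ], oracle_calls(fr, centers, sds, k))
  }
})

test_that("adjacency and recurrence thresholds behave as specified", {
  grid <- tiny_grid("chr1", 10)
  ids <- paste0("S", 1:4)
  calls <- matrix(0L, 10, 4, dimnames = list(grid$probe_id, ids))

  # an isolated single-probe call never forms a locus
  calls[5, 1] <- -1L
  cm <- structure(calls, k = 4, class = c("call_matrix", "matrix"))
  expect_equal(nrow(recurrent_adjacent_loci(cm, grid)), 0L)

  # the same adjacent pair deleted in 3 samples forms one locus with support 3
  calls[4:5, 1:3] <- -1L
  cm <- structure(calls, k = 4, class = c("call_matrix", "matrix"))
  loci <- recurrent_adjacent_loci(cm, grid, min_adjacent = 2, min_samples = 3)
  expect_equal(nrow(loci), 1L)
  expect_equal(loci$direction, -1L)
  expect_equal(loci$n_samples, 3L)
  expect_equal(loci$samples, "S1,S2,S3")
  expect_equal(loci$first_probe, grid$probe_id[4])

  # mixed directions on adjacent probes never pair up
  calls[] <- 0L; calls[4, 1:3] <- -1L; calls[5, 1:3] <- 1L
  cm <- structure(calls, k = 4, class = c("call_matrix", "matrix"))
  expect_equal(nrow(recurrent_adjacent_loci(cm, grid, min_samples = 3)), 0L)

  expect_error(recurrent_adjacent_loci(cm, grid, min_adjacent = 1), "invalid-config")
})

test_that("runs never span chromosome boundaries and missing calls break runs", {
  grid <- tiny_grid(c("chr1", "chr2"), c(3, 3))
  ids <- paste0("S", 1:3)
  calls <- matrix(0L, 6, 3, dimnames = list(grid$probe_id, ids))
  calls[3:4, ] <- -1L   # last probe of chr1 + first of chr2
  cm <- structure(calls, k = 4, class = c("call_matrix", "matrix"))
  expect_equal(nrow(recurrent_adjacent_loci(cm, grid, min_samples = 2)), 0L)

  calls[] <- 0L; calls[1:3, ] <- -1L; calls[2, 2] <- NA
  cm <- structure(calls, k = 4, class = c("call_matrix", "matrix"))
  loci <- recurrent_adjacent_loci(cm, grid, min_samples = 3)
  expect_equal(nrow(loci), 0L)   # S2's run is broken, support drops to 2
  loci <- recurrent_adjacent_loci(cm, grid, min_samples = 2)
  expect_equal(loci$n_samples, c(2L))
})

test_that("the locus screen equals exhaustive run enumeration on random sparse calls", {
  set.seed(42)
  for (case in 1:100) {
    grid <- tiny_grid(c("chr1", "chr2", "chr3"), c(8, 7, 5))
    n <- 8
    ids <- paste0("S", 1:n)
    calls <- matrix(sample(c(-1L, 0L, 0L, 1L, NA), 20 * n, replace = TRUE),
                    20, n, dimnames = list(grid$probe_id, ids))
    ma <- sample(2:3, 1); ms <- sample(1:3, 1)
    cm <- structure(calls, k = 4, class = c("call_matrix", "matrix"))
    got <- as.data.frame(recurrent_adjacent_loci(cm, grid, ma, ms))
    want <- oracle_loci(calls, grid, ma, ms)
    got <- got[order(got$chrom, got$start, got$direction),
               c("chrom", "start", "end", "direction", "samples")]
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("the locus screen is invariant to sample column order", {
  set.seed(43)
  grid <- tiny_grid("chr1", 30)
  calls <- matrix(sample(c(-1L, 0L, 0L), 30 * 6, replace = TRUE), 30, 6,
                  dimnames = list(grid$probe_id, paste0("S", 1:6)))
  cm1 <- structure(calls, k = 4, class = c("call_matrix", "matrix"))
  perm <- sample(6)
  cm2 <- structure(calls[, perm], k = 4, class = c("call_matrix", "matrix"))
  l1 <- as.data.frame(recurrent_adjacent_loci(cm1, grid, 2, 2))
  l2 <- as.data.frame(recurrent_adjacent_loci(cm2, grid, 2, 2))
  expect_equal(l1, l2)
})

test_that("CNV masking removes exactly the overlapping loci", {
  grid <- tiny_grid("chr1", 20)
  ids <- paste0("S", 1:3)
  calls <- matrix(0L, 20, 3, dimnames = list(grid$probe_id, ids))
  calls[3:4, ] <- -1L; calls[10:11, ] <- -1L
  cm <- structure(calls, k = 4, class = c("call_matrix", "matrix"))
  loci <- recurrent_adjacent_loci(cm, grid, min_samples = 3)
  expect_equal(nrow(loci), 2L)

  expect_equal(nrow(apply_cnv_mask(loci, acghsig:::empty_cnv_mask())), 2L)

  mask <- acghsig:::merge_intervals(
    data.frame(chrom = "chr1", start = grid$start[10], end = grid$end[11]))
  kept <- apply_cnv_mask(loci, mask)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$start, grid$start[3])
  expect_equal(attr(kept, "counts"), c(before = 2L, after = 1L))
})

test_that("CNV masking matches the per-bp boolean overlap oracle on random instances", {
  set.seed(44)
  for (case in 1:100) {
    n_loci <- 15
    loci <- data.frame(chrom = sample(c("chr1", "chr2"), n_loci, replace = TRUE),
                       start = sample(0:900, n_loci))
    loci$end <- loci$start + sample(10:100, n_loci, replace = TRUE)
    loci$first_probe <- loci$last_probe <- ""
    loci$n_probes <- 2L; loci$direction <- -1L
    loci$n_samples <- 3L; loci$samples <- ""
    loci <- structure(loci, class = c("recurrent_loci", "data.frame"))
    mask <- acghsig:::merge_intervals(
      data.frame(chrom = sample(c("chr1", "chr2"), 10, replace = TRUE),
                 start = s <- sample(0:900, 10), end = s + sample(10:150, 10, replace = TRUE)))
    kept <- apply_cnv_mask(loci, mask)
    keep_oracle <- vapply(seq_len(n_loci), function(i) {
      msub <- mask[mask$chrom == loci$chrom[i], , drop = FALSE]
      !any(vapply(seq_len(nrow(msub)), function(j)
        oracle_overlaps(loci$start[i], loci$end[i], msub$start[j], msub$end[j]),
        TRUE))
    }, TRUE)
    expect_equal(kept$start, loci$start[keep_oracle])
    expect_equal(kept$chrom, loci$chrom[keep_oracle])
  }
})

test_that("dropping sex chromosomes preserves autosomal rows and alignment", {
  grid <- tiny_grid(c("chr1", "chrX", "chr2", "chrY"), c(40, 5, 50, 5))
  fr <- matrix(rnorm(nrow(grid) * 3), nrow(grid), 3,
               dimnames = list(grid$probe_id, paste0("S", 1:3)))
  auto <- drop_sex_chromosomes(fr, grid)
  expect_equal(nrow(auto$grid), 90L)
  expect_false(any(auto$grid$chrom %in% c("chrX", "chrY")))
  for (pid in sample(auto$grid$probe_id, 10))
    expect_identical(auto$fr[pid, ], fr[pid, ])

  none <- drop_sex_chromosomes(fr[1:40, ], acghsig:::as_probe_grid(grid[1:40, ]))
  expect_equal(nrow(none$grid), 40L)
})
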