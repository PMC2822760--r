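test_that("identical samples merge first at height 0", {
  set.seed(81)
  x <- matrix(rnorm(20 * 4), 20, 4, dimnames = list(NULL, c("A", "B", "C", "D")))
  x[, "B"] <- x[, "A"]
  cl <- hierarchical_cluster(x)
  expect_equal(min(cl$tree$height), 0)
  first <- cl$tree$merge[1, ]
  expect_setequal(cl$tree$labels[-first], c("A", "B"))
})

test_that("a planted shift separates cleanly at the 2-cluster cut", {
  set.seed(82)
  x <- matrix(rnorm(12 * 6, 1, 0.1), 12, 6,
              dimnames = list(NULL, paste0("S", 1:6)))
  shifted <- c("S2", "S4", "S6")
  x[, shifted] <- x[, shifted] - 0.5
  cl <- hierarchical_cluster(x)
  part <- cut_clusters(cl, 2)
  expect_equal(length(unique(part[shifted])), 1L)
  expect_equal(length(unique(part[setdiff(names(part), shifted)])), 1L)
  expect_false(part[shifted][1] == part[setdiff(names(part), shifted)][1])
})

test_that("clustering is invariant to sample input order", {
  set.seed(83)
  x <- matrix(rnorm(15 * 8, 1, 0.2), 15, 8,
              dimnames = list(NULL, paste0("S", 1:8)))
  cl1 <- hierarchical_cluster(x)
  perm <- sample(8)
  cl2 <- hierarchical_cluster(x[, perm])
  expect_equal(sort(cl1$tree$height), sort(cl2$tree$height), tolerance = 1e-12)
  p1 <- cut_clusters(cl1, 3); p2 <- cut_clusters(cl2, 3)[names(p1)]
  expect_true(all(outer(p1, p1, "==") == outer(p2, p2, "==")))
})

test_that("missing cells are imputed by probe-wise median; all-missing columns are an error", {
  set.seed(84)
  x <- matrix(rnorm(10 * 4, 1, 0.1), 10, 4,
              dimnames = list(NULL, paste0("S", 1:4)))
  x[3, 2] <- NA
  expect_message(cl <- hierarchical_cluster(x), "imputed")
  expect_equal(cl$n_imputed, 1L)
  x[, 3] <- NA
  expect_error(hierarchical_cluster(x), "all-missing")
  expect_error(hierarchical_cluster(x[, 1, drop = FALSE]), ">= 2 samples")
})

test_that("region deletion flags follow the probe-fraction rule", {
  grid <- tiny_grid("chr7", 10, spacing = 1000)
  region <- list(name = "R", chrom = "chr7", start = 0, end = 2500)  # probes 1-3
  ids <- c("A", "B", "C")
  calls <- matrix(0L, 10, 3, dimnames = list(grid$probe_id, ids))
  calls[1:3, "A"] <- -1L                 # 3/3 deleted
  calls[1, "B"] <- -1L                   # 1/3 deleted
  calls[1:3, "C"] <- NA_integer_         # no data
  fl <- region_deletion_flag(calls, grid, region)
  expect_equal(unname(fl), c("deleted", "not_deleted", "no_data"))

  # 2/3 meets the 0.5 fraction
  calls[2, "B"] <- -1L
  expect_equal(unname(region_deletion_flag(calls, grid, region)["B"]), "deleted")

  empty <- list(name = "EMPTY", chrom = "chr7", start = 5e6, end = 6e6)
  expect_error(region_deletion_flag(calls, grid, empty), "EMPTY")
})

test_that("region flags equal brute-force per-region counting on random calls", {
  set.seed(85)
  grid <- tiny_grid(c("chr7", "chr9"), c(20, 20), spacing = 1000)
  regions <- data.frame(name = c("R1", "R2", "R3"),
                        chrom = c("chr7", "chr7", "chr9"),
                        start = c(0, 10000, 5000), end = c(5100, 15100, 12100),
                        role = c("primary", "secondary", "secondary"),
                        stringsAsFactors = FALSE)
  for (case in 1:50) {
    calls <- matrix(sample(c(-1L, 0L, 1L, NA), 40 * 6, replace = TRUE,
                           prob = c(0.3, 0.5, 0.1, 0.1)),
                    40, 6, dimnames = list(grid$probe_id, paste0("S", 1:6)))
    fl <- signature_flags(calls, grid, regions)
    for (r in 1:3) {
      idx <- which(grid$chrom == regions$chrom[r] &
                     grid$start < regions$end[r] & grid$end > regions$start[r])
      for (s in 1:6) {
        v <- calls[idx, s]
        want <- if (all(is.na(v))) "no_data"
        else if (sum(v == -1L, na.rm = TRUE) >= 0.5 * length(idx)) "deleted"
        else "not_deleted"
        expect_identical(fl[s, regions$name[r]], want)
      }
    }
  }
})

test_that("concomitant classification requires every secondary region and is monotone", {
  regions <- data.frame(name = c("P1", "S1", "S2"),
                        chrom = "chr7", start = 0, end = 1,
                        role = c("primary", "secondary", "secondary"),
                        stringsAsFactors = FALSE)
  fl <- rbind(A = c("deleted", "deleted", "deleted"),
              B = c("deleted", "deleted", "not_deleted"),
              C = c("not_deleted", "deleted", "deleted"))
  colnames(fl) <- regions$name
  sc <- classify_concomitant(fl, regions)
  expect_equal(unname(sc$concomitant), c(TRUE, FALSE, TRUE))  # primary irrelevant

  # monotone: flipping any flag to deleted never revokes concomitant
  set.seed(86)
  for (case in 1:20) {
    fl2 <- matrix(sample(c("deleted", "not_deleted"), 12, replace = TRUE), 4, 3,
                  dimnames = list(paste0("S", 1:4), regions$name))
    before <- classify_concomitant(fl2, regions)$concomitant
    flip <- which(fl2 != "deleted")
    if (!length(flip)) next
    fl3 <- fl2; fl3[sample(flip, 1)] <- "deleted"
    after <- classify_concomitant(fl3, regions)$concomitant
    expect_true(all(after >= before))
  }
})

test_that("cohort summaries count deletions per class correctly", {
  regions <- data.frame(name = c("R1", "S1"), chrom = "chr7", start = 0, end = 1,
                        role = c("primary", "secondary"), stringsAsFactors = FALSE)
  ids <- sprintf("S%02d", 1:14)
  samples <- data.frame(sample_id = ids,
                        class = rep(c("BCL", "BCM"), c(12, 2)),
                        sex = "M", stringsAsFactors = FALSE)
  fl <- matrix("not_deleted", 14, 2, dimnames = list(ids, regions$name))
  fl[1:12, "R1"] <- "deleted"
  fl[1:10, "S1"] <- "deleted"
  sc <- classify_concomitant(fl, regions)
  summ <- cohort_summary(sc, samples, "BCL")
  expect_equal(summ$fraction[summ$region == "R1"], 1.0)
  expect_equal(summ$fraction[summ$region == "S1"], 10 / 12)
  expect_equal(summ$n_class, rep(12L, 3))
  # concomitant row equals brute recount of the single secondary region
  expect_equal(summ$n_deleted[summ$region == "concomitant"], 10L)

  empty <- cohort_summary(sc, samples, "control")
  expect_true(all(is.na(empty$fraction)))
})
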