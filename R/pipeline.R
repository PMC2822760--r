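#' Pipeline configuration
#'
#' A single structured configuration covering every stage of the analysis:
#' either a simulated cohort (`simulate`) or on-disk inputs (`inputs` with
#' paths `probes`, `fr`, `samples`, and optionally `cnv_mask`), the screening
#' thresholds, the SAM class assignment, clustering and signature parameters,
#' and the output directory. Can also be written/read as a YAML file and
#' passed to [run_pipeline()] by path.
#'
#' @param simulate A [simulation_config()], or `NULL` when reading inputs.
#' @param inputs Named list of input paths, or `NULL` when simulating.
#' @param calling list: `k_screen` (SD multiplier of the preliminary screen,
#'   default 4), `k_signature` (region-level calls, default 3),
#'   `min_adjacent`, `min_samples`, `drop_sex`, `use_cnv_mask`.
#' @param sam list: `class_a` (classes forming SAM class 1, default the
#'   lymphoid classes), `class_b` (class 2), `n_permutations`, `seed`,
#'   `k_top` (delta-gap selection size, default 22), `fdr_convention`.
#' @param cluster list: `linkage`, `metric`.
#' @param signature list: `regions` (data.frame or TSV path; default
#'   [default_signature_regions()]), `min_fraction`, `target_class`.
#' @param outdir Output directory (created if missing).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(simulate = NULL, inputs = NULL,
                            calling = list(), sam = list(), cluster = list(),
                            signature = list(), outdir = tempfile("acghsig_run_")) {
  defaults <- list(
    calling = list(k_screen = 4, k_signature = 3, min_adjacent = 2,
                   min_samples = 3, drop_sex = TRUE, use_cnv_mask = TRUE),
    sam = list(class_a = c("BCL", "BCmix"),
               class_b = c("CP", "AP", "BCM", "unclassified", "control"),
               n_permutations = 1000, seed = 17L, k_top = 22,
               fdr_convention = "mean"),
    cluster = list(linkage = "average", metric = "euclidean"),
    signature = list(regions = NULL, min_fraction = 0.5,
                     target_class = c("BCL", "BCmix"))
  )
  cfg <- list(simulate = simulate, inputs = inputs,
              calling = utils::modifyList(defaults$calling, calling),
              sam = utils::modifyList(defaults$sam, sam),
              cluster = utils::modifyList(defaults$cluster, cluster),
              signature = utils::modifyList(defaults$signature, signature),
              outdir = outdir)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Demo pipeline configuration
#'
#' The bundled end-to-end demonstration: the desk-scale synthetic cohort
#' ([demo_simulation_config()]) analysed with default thresholds.
#'
#' @param outdir Output directory.
#' @param seed Cohort seed.
#' @param n_probes Probe count of the demo grid.
#' @return A `pipeline_config`.
#' @export
demo_pipeline_config <- function(outdir = tempfile("acghsig_demo_"), seed = 1L,
                                 n_probes = 10000) {
  pipeline_config(simulate = demo_simulation_config(n_probes = n_probes, seed = seed),
                  outdir = outdir)
}

#' Run the full analysis pipeline
#'
#' Executes simulate/load -> QC -> screen calls -> adjacency/recurrence screen
#' -> CNV masking -> two-class SAM -> probe selection -> hierarchical
#' clustering -> region signature -> cohort summary, writing every artifact
#' and a run manifest (parameters, stage counts, md5 digests) to the output
#' directory. Inputs are never mutated; deterministic stages are
#' byte-reproducible given the configured seeds. Any stage failure aborts with
#' the stage name.
#'
#' @param config A [pipeline_config()], or the path to a YAML file holding one.
#' @return The run manifest (list), invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- config_from_yaml(config)
  stopifnot(inherits(config, "pipeline_config"))
  preflight(config)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$outdir, f)
  manifest <- list(package_version = as.character(packageVersion("acghsig")),
                   config = config_snapshot(config), stages = list())
  counts <- list()

  stage <- function(name, code) {
    tryCatch(code, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  dat <- stage("input", {
    if (!is.null(config$simulate)) {
      cohort <- simulate_cohort(config$simulate)
      write_probe_table(cohort$grid, out("probes.tsv"))
      write_fr_matrix(cohort$fr, out("fr.tsv"))
      write_sample_sheet(cohort$samples, out("samples.tsv"))
      write_cnv_mask(cohort$cnv_mask, out("cnv_mask.bed"))
      write.table(cohort$truth$events, out("truth_events.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      cohort
    } else {
      grid <- read_probe_table(config$inputs$probes)
      list(grid = grid,
           fr = read_fr_matrix(config$inputs$fr, grid),
           samples = read_sample_sheet(config$inputs$samples),
           cnv_mask = if (!is.null(config$inputs$cnv_mask))
             load_cnv_mask(config$inputs$cnv_mask) else empty_cnv_mask(),
           truth = NULL)
    }
  })

  fr <- dat$fr; grid <- dat$grid
  if (isTRUE(config$calling$drop_sex)) {
    auto <- stage("drop_sex", drop_sex_chromosomes(fr, grid))
    fr <- auto$fr; grid <- auto$grid
  }
  counts$n_probes_analysed <- nrow(fr)
  counts$n_samples <- ncol(fr)

  qc <- stage("qc", sample_qc(fr))
  write.table(qc, out("qc.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  counts$median_sample_sd <- median(qc$sd)

  screen <- stage("screen", {
    calls4 <- call_matrix(fr, qc, config$calling$k_screen)
    loci <- recurrent_adjacent_loci(calls4, grid,
                                    config$calling$min_adjacent,
                                    config$calling$min_samples)
    write.table(as.data.frame(loci), out("screen_loci.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    masked <- if (isTRUE(config$calling$use_cnv_mask))
      apply_cnv_mask(loci, dat$cnv_mask, grid) else loci
    write.table(as.data.frame(masked), out("screen_loci_masked.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    list(loci = loci, masked = masked)
  })
  counts$n_screen_loci <- nrow(screen$loci)
  counts$n_screen_loci_after_cnv_mask <- nrow(screen$masked)

  cls <- dat$samples$class[match(colnames(fr), dat$samples$sample_id)]
  use <- cls %in% c(config$sam$class_a, config$sam$class_b)
  sam_res <- stage("sam", {
    labels <- factor(ifelse(cls[use] %in% config$sam$class_a, "class_a", "class_b"),
                     levels = c("class_b", "class_a"))  # positive d = higher in class_a
    cfg <- sam_config(n_permutations = config$sam$n_permutations,
                      seed = config$sam$seed,
                      fdr_convention = config$sam$fdr_convention)
    res <- sam_twoclass(fr[, use, drop = FALSE], labels, cfg)
    write.table(res$probes, out("sam_probes.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(res$delta_table, out("sam_delta_table.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    res
  })
  fdr0 <- select_fdr_zero(sam_res)
  writeLines(fdr0, out("sam_fdr0_probes.txt"))
  k_top <- min(config$sam$k_top, nrow(sam_res$probes))
  top <- top_by_delta_gap(sam_res, k_top)
  writeLines(top, out("sam_top_probes.txt"))
  counts$n_fdr0_probes <- length(fdr0)
  counts$s0 <- sam_res$s0
  counts$n_top_probes <- k_top

  clus <- stage("cluster", {
    sub <- fr[top, use, drop = FALSE]
    cl <- hierarchical_cluster(sub, config$cluster$linkage, config$cluster$metric)
    write_newick(cl$tree, out("cluster.nwk"))
    write_fr_matrix(sub[, cl$order, drop = FALSE], out("cluster_matrix.tsv"))
    cl
  })

  sig <- stage("signature", {
    regions <- config$signature$regions
    if (is.null(regions)) regions <- default_signature_regions()
    if (is.character(regions)) regions <- read_region_table(regions)
    calls3 <- call_matrix(fr, qc, config$calling$k_signature)
    flags <- signature_flags(calls3, grid, regions, config$signature$min_fraction)
    sc <- classify_concomitant(flags, regions)
    summ <- cohort_summary(sc, dat$samples, config$signature$target_class)
    write.table(data.frame(sample_id = rownames(flags), flags,
                           concomitant = sc$concomitant,
                           stringsAsFactors = FALSE),
                out("signature_flags.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(summ, out("signature_summary.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    list(signature = sc, summary = summ)
  })

  files <- list.files(config$outdir, full.names = TRUE)
  files <- files[!grepl("manifest", files)]
  manifest$counts <- counts
  manifest$files <- as.list(setNames(unname(tools::md5sum(files)), basename(files)))
  yaml::write_yaml(manifest, out("manifest.yaml"))

  manifest$results <- list(qc = qc, loci = screen$masked, sam = sam_res,
                           fdr0 = fdr0, top = top, clustering = clus,
                           signature = sig$signature, summary = sig$summary,
                           samples = dat$samples, truth = dat$truth,
                           grid = grid, fr = fr)
  invisible(manifest)
}

preflight <- function(config) {
  if (is.null(config$simulate) && is.null(config$inputs))
    stop_config("either 'simulate' or 'inputs' must be given")
  if (!is.null(config$inputs)) {
    need <- c("probes", "fr", "samples")
    paths <- unlist(config$inputs[c(need, "cnv_mask")])
    missing <- paths[!file.exists(paths)]
    if (length(missing))
      stop_config("missing input file(s): ", paste(missing, collapse = ", "))
    sheet <- read_sample_sheet(config$inputs$samples)
    check_sam_classes(sheet, config$sam)
  } else {
    cc <- config$simulate$class_counts
    sheet <- data.frame(sample_id = as.character(seq_len(sum(cc))),
                        class = rep(names(cc), cc), stringsAsFactors = FALSE)
    check_sam_classes(sheet, config$sam)
  }
  invisible(TRUE)
}

check_sam_classes <- function(sheet, sam_cfg) {
  na <- sum(sheet$class %in% sam_cfg$class_a)
  nb <- sum(sheet$class %in% sam_cfg$class_b)
  if (na < 2 || nb < 2)
    stop_config("SAM needs >= 2 samples in each class (have ", na, " vs ", nb, ")")
}

config_snapshot <- function(config) {
  snap <- unclass(config)
  if (!is.null(snap$simulate)) {
    sim <- unclass(snap$simulate)
    sim$genome_spec <- as.list(sim$genome_spec)
    sim$class_counts <- as.list(sim$class_counts)
    sim$signature_regions <- if (!is.null(sim$signature_regions))
      lapply(seq_len(nrow(sim$signature_regions)),
             function(i) as.list(sim$signature_regions[i, ]))
    sim$cnv_loci <- if (!is.null(sim$cnv_loci))
      lapply(seq_len(nrow(sim$cnv_loci)), function(i) as.list(sim$cnv_loci[i, ]))
    snap$simulate <- sim
  }
  snap
}

config_from_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  sim <- NULL
  if (!is.null(raw$simulate)) {
    s <- raw$simulate
    sim <- simulation_config(
      genome_spec = unlist(s$genome_spec),
      n_probes = s$n_probes %||% 10000,
      class_counts = unlist(s$class_counts),
      noise_sd_range = unlist(s$noise_sd_range) %||% c(0.057, 0.187),
      signature_regions = if (!is.null(s$signature_regions))
        do.call(rbind, lapply(s$signature_regions, as.data.frame))
      else default_signature_regions(),
      n_concomitant = s$n_concomitant %||% 7,
      cnv_loci = if (!is.null(s$cnv_loci))
        do.call(rbind, lapply(s$cnv_loci, as.data.frame))
      else default_cnv_loci(),
      seed = s$seed %||% 1L)
  }
  pipeline_config(simulate = sim, inputs = raw$inputs,
                  calling = raw$calling %||% list(),
                  sam = raw$sam %||% list(),
                  cluster = raw$cluster %||% list(),
                  signature = raw$signature %||% list(),
                  outdir = raw$outdir %||% tempfile("acghsig_run_"))
}

#' Derive a matched-reference ratio column
#'
#' Models the paired design in which a patient's blast-crisis DNA is
#' hybridized against their own chronic-phase DNA instead of the pooled
#' reference: per probe, the derived ratio is `fr_bc / fr_cp`, so aberrations
#' shared by CP and BC cancel towards 1, a BC-only deletion stays visible, and
#' a CP-only aberration appears as its reciprocal (a documented artefact of
#' the division). A zero CP ratio makes the derived value missing (logged in
#' the `n_undefined` attribute).
#'
#' @param fr_bc,fr_cp Numeric vectors or single-column matrices on the same
#'   probe grid.
#' @return Derived ratio vector/matrix with attribute `n_undefined`.
#' @export
paired_reference_mode <- function(fr_bc, fr_cp) {
  if (!is.null(dim(fr_bc)) && !is.null(dim(fr_cp)) &&
      !identical(rownames(fr_bc), rownames(fr_cp)))
    stop("columns are not on the same grid", call. = FALSE)
  if (length(fr_bc) != length(fr_cp))
    stop("columns are not on the same grid", call. = FALSE)
  out <- fr_bc / fr_cp
  undef <- !is.na(fr_cp) & fr_cp == 0
  out[undef] <- NA_real_
  if (any(undef)) message(sum(undef), " probe(s) with zero reference ratio set to missing")
  attr(out, "n_undefined") <- sum(undef)
  out
}
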