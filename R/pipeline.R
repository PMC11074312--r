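#' Load and validate a pipeline run configuration
#'
#' A run configuration is a YAML file (or an equivalent named list) with a
#' mandatory integer `seed`, an `outdir`, a `stages` vector drawn from
#' `simulate`, `quantify`, `doseresponse`, `spatial`, `enrichment`, `qpcr`,
#' and optional per-stage parameter blocks under the stage's name. Unknown
#' top-level keys are rejected. All stage randomness is derived from the
#' single seed, so identical configurations give identical outputs.
#'
#' @param config Path to a YAML file, or a named list.
#' @return A validated configuration list of class `run_config`.
#' @export
read_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  stages_all <- c("simulate", "quantify", "doseresponse", "spatial",
                  "enrichment", "qpcr")
  allowed <- c("seed", "outdir", "stages", stages_all)
  unknown <- setdiff(names(config), allowed)
  if (length(unknown) > 0) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(config$seed) || !is.finite(config$seed)) {
    stop("configuration must declare an integer seed", call. = FALSE)
  }
  if (is.null(config$outdir)) stop("configuration must declare outdir",
                                   call. = FALSE)
  if (is.null(config$stages)) config$stages <- stages_all
  bad <- setdiff(config$stages, stages_all)
  if (length(bad) > 0) {
    stop("unknown stages: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  deps <- list(quantify = "simulate", doseresponse = "quantify",
               spatial = "quantify")
  for (st in config$stages) {
    for (dep in deps[[st]]) {
      if (!dep %in% config$stages ||
          match(dep, config$stages) > match(st, config$stages)) {
        stop("stage '", st, "' requires stage '", dep,
             "' to run before it", call. = FALSE)
      }
    }
  }
  config$seed <- as.integer(config$seed)
  class(config) <- "run_config"
  config
}

stage_seed <- function(config, offset) (config$seed %% 1000000L) * 1000L + offset

#' Run the synthetic end-to-end analysis pipeline
#'
#' Executes the requested stages in order on fully synthetic data and writes
#' every output under the configured `outdir`:
#'
#' * `simulate` — one spread-packing (`wt`) and one tight-packing (`ko`)
#'   colony image with ground-truth tables (TIFF + TSV);
#' * `quantify` — nuclear segmentation and per-nucleus intensity tables;
#' * `doseresponse` — fold-over-background normalization, threshold
#'   classification and the binned response-negative dose-response curve
#'   for the `wt` condition;
#' * `spatial` — per-cell nearest-neighbor distances per condition and the
#'   tight-vs-spread comparison summary;
#' * `enrichment` — a synthetic gene universe and peak set, GREAT-style
#'   assignment and the bootstrap overlap test for a planted DE list;
#' * `qpcr` — a synthetic N0 table, housekeeping normalization and
#'   randomized-block ANOVA per gene.
#'
#' A manifest (JSON) records the configuration, the seed, package version
#' and an MD5 hash of every output file; identical configurations reproduce
#' identical hashes.
#'
#' @param config Path to a YAML configuration or a named list; see
#'   [read_run_config()].
#' @return The manifest, invisibly (also written to `manifest.json`).
#' @export
run_pipeline <- function(config) {
  cfg <- read_run_config(config)
  outdir <- cfg$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  emit <- function(path) outputs <<- c(outputs, path)

  sim_cfg <- cfg$simulate %||% list()
  shape <- unlist(sim_cfg$image_shape_px %||% c(400L, 400L))
  n_col <- sim_cfg$n_colonies %||% 4
  n_per <- sim_cfg$nuclei_per_colony %||% 18

  if ("simulate" %in% cfg$stages) {
    for (cond in c("wt", "ko")) {
      mode <- if (cond == "wt") "spread" else "tight"
      cp <- colony_params(n_colonies = n_col, nuclei_per_colony = n_per,
                          packing_mode = mode, image_shape_px = shape,
                          seed = stage_seed(cfg, if (cond == "wt") 11L else 12L))
      ep <- expression_params(seed = cp$seed)
      sim <- generate_colony_image(cp, ep)
      for (ch in names(sim$image$channels)) {
        f <- file.path(outdir, paste0(cond, "_", ch, ".tif"))
        write_image(sim$image$channels[[ch]], f); emit(f)
      }
      f <- file.path(outdir, paste0(cond, "_truth.tsv"))
      write_table_auto(sim$truth, f); emit(f)
    }
  }

  if ("quantify" %in% cfg$stages) {
    for (cond in c("wt", "ko")) {
      chans <- c("DAPI", "mCherry", "NANOG")
      imgs <- lapply(chans, function(ch) {
        read_image(file.path(outdir, paste0(cond, "_", ch, ".tif")))
      })
      names(imgs) <- chans
      labels <- segment_nuclei(imgs$DAPI)
      cells <- measure_nuclei(labels, imgs)
      f <- file.path(outdir, paste0(cond, "_cells.tsv"))
      write_table_auto(cells, f); emit(f)
    }
  }

  if ("doseresponse" %in% cfg$stages) {
    cells <- read_table_auto(file.path(outdir, "wt_cells.tsv"))
    driver_img <- read_image(file.path(outdir, "wt_mCherry.tif"))
    response_img <- read_image(file.path(outdir, "wt_NANOG.tif"))
    bg_d <- subtract_background(driver_img, "percentile", p = 25)$background
    bg_r <- subtract_background(response_img, "percentile", p = 25)$background
    fold_d <- fold_over_background(cells$mCherry, bg_d)
    fold_r <- fold_over_background(cells$NANOG, bg_r)
    state_r <- classify_on_off(fold_r, "threshold", cutoff = 2)$state
    curve <- dose_response(fold_d, state_r)
    f <- file.path(outdir, "wt_doseresponse.tsv")
    write_table_auto(curve, f); emit(f)
  }

  if ("spatial" %in% cfg$stages) {
    nn <- lapply(c("wt", "ko"), function(cond) {
      cells <- read_table_auto(file.path(outdir, paste0(cond, "_cells.tsv")))
      d <- nearest_neighbor_distances(cells$x, cells$y)
      f <- file.path(outdir, paste0(cond, "_nn.tsv"))
      write_table_auto(tibble::tibble(label = cells$label, nn_distance = d), f)
      emit(f)
      d
    })
    cmp <- compare_nn_distributions(nn[[2]], nn[[1]])  # a = tight KO, b = WT
    f <- file.path(outdir, "nn_comparison.tsv")
    write_table_auto(tibble::as_tibble(cmp), f); emit(f)
  }

  if ("enrichment" %in% cfg$stages) {
    en_cfg <- cfg$enrichment %||% list()
    n_genes <- en_cfg$n_genes %||% 1000
    frac <- en_cfg$peak_fraction %||% 0.137
    n_de <- en_cfg$n_de %||% 292
    n_de_peak <- en_cfg$n_de_peak %||% 114
    n_iter <- en_cfg$n_iter %||% 10000
    sseed <- stage_seed(cfg, 23L)
    uni <- generate_gene_universe(n_genes, frac, seed = sseed)
    genes <- assign_peaks_to_genes(uni$peaks, uni$genes)
    de <- withr::with_seed(sseed + 1L, {
      c(sample(genes$gene_id[genes$has_peak], n_de_peak),
        sample(genes$gene_id[!genes$has_peak], n_de - n_de_peak))
    })
    res <- bootstrap_overlap(de, genes, n_iter = n_iter, seed = sseed + 2L)
    f1 <- file.path(outdir, "gene_universe.tsv"); write_table_auto(genes, f1)
    f2 <- file.path(outdir, "peaks.bed"); write_bed(uni$peaks, f2)
    f3 <- file.path(outdir, "enrichment.tsv")
    write_table_auto(tibble::tibble(
      observed = res$observed, n_draw = res$n_draw,
      null_mean = res$null_mean, null_sd = res$null_sd,
      fold = res$fold, empirical_p = res$empirical_p), f3)
    emit(f1); emit(f2); emit(f3)
  }

  if ("qpcr" %in% cfg$stages) {
    qp_cfg <- cfg$qpcr %||% list()
    genes <- qp_cfg$genes %||% c("Nanog", "Sox3", "Oct6")
    conditions <- qp_cfg$conditions %||% c("2i+LIF", "EpiLC24h", "EpiLC48h")
    effects <- matrix(c(0, -1.5, -2.5,   # Nanog falls on differentiation
                        0, 2, 3,          # Sox3 rises
                        0, 3, 4),         # Oct6 rises
                      nrow = 3, byrow = TRUE)[seq_along(genes), , drop = FALSE]
    tab <- generate_qpcr_table(genes, conditions, effects = effects,
                               seed = stage_seed(cfg, 37L))
    norm <- normalize_expression(tab, control_condition = conditions[1])
    stats_rows <- lapply(genes, function(g) {
      sub <- norm[norm$gene == g, ]
      fit <- rbd_anova_tukey(sub$rel_log2_expr, sub$condition, sub$replicate)
      tibble::tibble(gene = g, F = fit$F, p = fit$p,
                     letters = paste(names(fit$letters), unname(fit$letters),
                                     sep = "=", collapse = ";"))
    })
    f1 <- file.path(outdir, "qpcr_normalized.tsv"); write_table_auto(norm, f1)
    f2 <- file.path(outdir, "qpcr_anova.tsv")
    write_table_auto(dplyr::bind_rows(stats_rows), f2)
    emit(f1); emit(f2)
  }

  hashes <- as.list(tools::md5sum(outputs))
  names(hashes) <- basename(names(hashes))
  manifest <- list(
    seed = cfg$seed,
    stages = cfg$stages,
    parameters = cfg[setdiff(names(cfg), c("seed", "stages", "outdir"))],
    package_version = as.character(utils::packageVersion("episwitch")),
    outputs = hashes[order(names(hashes))]
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
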