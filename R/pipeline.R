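#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis. Defaults follow the
#' package's conventions: 20% access-resistance QC bound, 30 V/s spike
#' threshold, the published spikelet/underdeveloped-AP bounds, and the
#' nine-feature clustering set.
#'
#' @param input_dir Directory of sweep files (`*.csv` with sidecars, or
#'   `*.h5`), or `NULL` when sweep sets are passed in memory.
#' @param metadata Path to the cell-metadata CSV, or a data.frame.
#' @param out_dir Output directory (created if needed); `NULL` disables
#'   file output.
#' @param qc_threshold Access-resistance fractional-change bound.
#' @param dvdt_threshold Spike-slope threshold in V/s.
#' @param classify Named list of [classify_response()] threshold overrides.
#' @param cluster_features Feature names used for clustering.
#' @param k_range Candidate cluster numbers (`NULL`: `2:min(10, n-1)`).
#' @param alpha Significance level used when reporting per-feature group
#'   contrasts.
#' @param stats_mode Mode for the rank tests (`"auto"`, `"exact"`,
#'   `"approx"`).
#' @param seed Integer seed recorded in the provenance block.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir = NULL, metadata = NULL, out_dir = NULL,
                            qc_threshold = 0.20, dvdt_threshold = 30,
                            classify = list(), cluster_features = clustering_feature_names(),
                            k_range = NULL, alpha = 0.05,
                            stats_mode = "auto", seed = 1) {
  if (qc_threshold <= 0) stop("qc_threshold must be positive")
  if (dvdt_threshold <= 0) stop("dvdt_threshold must be positive")
  structure(
    list(input_dir = input_dir, metadata = metadata, out_dir = out_dir,
         qc_threshold = qc_threshold, dvdt_threshold = dvdt_threshold,
         classify = classify, cluster_features = cluster_features,
         k_range = k_range, alpha = alpha, stats_mode = stats_mode,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Keys mirror the [pipeline_config()] arguments.
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  do.call(pipeline_config, cfg)
}

#' Extract the full feature row for one cell
#'
#' Passive properties from the hyperpolarizing sweeps, then either
#' rheobase/single-AP/train features (cells with at least one suprathreshold
#' sweep) or spikelet features with response classification (cells without).
#' Spiking cells are classed `mature_AP` through the same rule table applied
#' to their rheobase sweep.
#'
#' @param s A [sweep_set()].
#' @param cfg A [pipeline_config()].
#' @return Named list (one feature-table row), including `response_class`.
#' @export
extract_cell_features <- function(s, cfg = pipeline_config()) {
  pp <- passive_properties(s)
  row <- list(cell_id = s$cell_id, rmp_mV = pp$rmp_mV,
              rmp_is_held_baseline = pp$rmp_is_held_baseline,
              rin_Mohm = pp$rin_Mohm, tau_ms = pp$tau_ms, cap_pF = pp$cap_pF,
              rheobase_pA = NA_real_, ap_threshold_mV = NA_real_,
              ap_amplitude_mV = NA_real_, ahp_amplitude_mV = NA_real_,
              ap_halfwidth_ms = NA_real_, ap_latency_ms = NA_real_,
              n_spikes_2x = NA_real_, adapt_1_2 = NA_real_,
              adapt_1_last = NA_real_, spikelet_peak_mV = NA_real_,
              spikelet_amp_mV = NA_real_, response_class = NA_character_)
  ap <- tryCatch(
    ap_features_at_rheobase(s, dvdt_threshold = cfg$dvdt_threshold),
    error = function(e) NULL
  )
  amps <- vapply(s$sweeps, `[[`, numeric(1), "injected_current")
  if (!is.null(ap)) {
    tr <- train_features(s, ap$rheobase_pA, dvdt_threshold = cfg$dvdt_threshold)
    i_rheo <- which(abs(amps - ap$rheobase_pA) < 1e-9)[1]
    spl <- spikelet_features(s$sweeps[[i_rheo]], s$protocol,
                             dvdt_threshold = cfg$dvdt_threshold)
    row[c("rheobase_pA", "ap_threshold_mV", "ap_amplitude_mV",
          "ahp_amplitude_mV", "ap_halfwidth_ms", "ap_latency_ms")] <-
      ap[c("rheobase_pA", "ap_threshold_mV", "ap_amplitude_mV",
           "ahp_amplitude_mV", "ap_halfwidth_ms", "ap_latency_ms")]
    row[c("n_spikes_2x", "adapt_1_2", "adapt_1_last")] <-
      tr[c("n_spikes_2x", "adapt_1_2", "adapt_1_last")]
    row$spikelet_peak_mV <- spl$spikelet_peak_mV
    row$spikelet_amp_mV <- spl$spikelet_amp_mV
    row$response_class <- do.call(classify_response, c(list(spl), cfg$classify))
  } else {
    # no rheobase: route to spikelet analysis on the largest depolarizing sweep
    dep <- which(amps > 0)
    if (length(dep)) {
      i_max <- dep[which.max(amps[dep])]
      spl <- spikelet_features(s$sweeps[[i_max]], s$protocol,
                               dvdt_threshold = cfg$dvdt_threshold)
      row$spikelet_peak_mV <- spl$spikelet_peak_mV
      row$spikelet_amp_mV <- spl$spikelet_amp_mV
      row$ahp_amplitude_mV <- spl$ahp_amplitude_mV
      row$response_class <- do.call(classify_response, c(list(spl), cfg$classify))
    } else {
      row$response_class <- "none"
    }
  }
  row
}

read_input_sweepsets <- function(input_dir) {
  files <- c(
    list.files(input_dir, pattern = "\\.csv$", full.names = TRUE),
    list.files(input_dir, pattern = "\\.(h5|hdf5)$", full.names = TRUE)
  )
  if (length(files) == 0) stop("no sweep files (*.csv, *.h5) in ", input_dir)
  lapply(files, function(f) {
    fmt <- if (grepl("\\.csv$", f)) "csv" else "hdf5"
    read_sweepset(f, fmt)
  })
}

#' Run the end-to-end phenotyping pipeline
#'
#' Stages: access-resistance QC, per-cell feature extraction, per-feature
#' genotype contrasts (Mann-Whitney, with Holm-adjusted p-values reported
#' alongside the raw ones), z-scored Ward clustering with silhouette-based
#' k selection, and a Barnard test of cluster-by-genotype composition at
#' the selected k. Per-cell failures are recorded and skipped; the run
#' fails only when fewer than 3 cells survive.
#'
#' @param cfg A [pipeline_config()].
#' @param sweep_sets Optional list of in-memory [sweep_set()]s (otherwise
#'   read from `cfg$input_dir`).
#' @return A list of class `pipeline_report`: `features` (data.frame),
#'   `exclusions`, `group_tests`, `clustering`, `composition_test`,
#'   `provenance`. Written under `cfg$out_dir` when set.
#' @export
run_pipeline <- function(cfg, sweep_sets = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (is.null(sweep_sets)) {
    if (is.null(cfg$input_dir)) stop("either cfg$input_dir or sweep_sets is required")
    sweep_sets <- read_input_sweepsets(cfg$input_dir)
  }
  metadata <- if (is.data.frame(cfg$metadata)) cfg$metadata
              else if (!is.null(cfg$metadata)) read_cell_metadata(cfg$metadata)
              else NULL
  n_input <- length(sweep_sets)
  exclusions <- data.frame(cell_id = character(0), stage = character(0),
                           reason = character(0))
  exclude <- function(id, stage, reason) {
    exclusions <<- rbind(exclusions,
                         data.frame(cell_id = id, stage = stage, reason = reason))
  }
  rows <- list()
  for (s in sweep_sets) {
    if (!is.null(s$access_resistance)) {
      qc <- qc_access_resistance(s, cfg$qc_threshold)
      if (!qc$passed) {
        exclude(s$cell_id, "qc",
                sprintf("access resistance changed %.0f%% (> %.0f%%)",
                        100 * qc$max_fractional_change, 100 * cfg$qc_threshold))
        next
      }
    }
    row <- tryCatch(extract_cell_features(s, cfg), error = function(e) e)
    if (inherits(row, "error")) {
      exclude(s$cell_id, "features", conditionMessage(row))
    } else {
      rows[[length(rows) + 1]] <- row
    }
  }
  if (length(rows) < 3) {
    stop("fewer than 3 cells survived QC and feature extraction (",
         length(rows), " of ", n_input, ")")
  }
  features <- do.call(rbind, lapply(rows, function(r) {
    as.data.frame(r, stringsAsFactors = FALSE)
  }))
  if (!is.null(metadata)) {
    features <- merge(features, metadata, by = "cell_id", all.x = TRUE,
                      sort = FALSE)
  }
  # per-feature genotype contrasts
  group_tests <- NULL
  if (!is.null(metadata) && "genotype" %in% names(features) &&
      length(stats::na.omit(unique(features$genotype))) == 2) {
    groups <- sort(unique(stats::na.omit(features$genotype)))
    numeric_feats <- intersect(
      c("rmp_mV", "rin_Mohm", "tau_ms", "cap_pF", "rheobase_pA",
        "ap_threshold_mV", "ap_amplitude_mV", "ahp_amplitude_mV",
        "ap_halfwidth_ms", "ap_latency_ms", "n_spikes_2x", "adapt_1_2",
        "adapt_1_last", "spikelet_peak_mV", "spikelet_amp_mV"),
      names(features))
    res <- lapply(numeric_feats, function(f) {
      x <- features[features$genotype == groups[1], f]
      y <- features[features$genotype == groups[2], f]
      x <- x[is.finite(x)]; y <- y[is.finite(y)]
      if (length(x) == 0 || length(y) == 0) return(NULL)
      tr <- mann_whitney(x, y, mode = cfg$stats_mode)
      data.frame(feature = f, statistic = tr$statistic, p_value = tr$p_value,
                 n1 = length(x), n2 = length(y))
    })
    group_tests <- do.call(rbind, res)
    if (!is.null(group_tests)) {
      group_tests$p_holm <- stats::p.adjust(group_tests$p_value, "holm")
    }
  }
  # clustering on the configured feature set
  clustering <- NULL
  composition <- NULL
  feats_avail <- intersect(cfg$cluster_features, names(features))
  fmat <- as.matrix(features[, feats_avail, drop = FALSE])
  rownames(fmat) <- features$cell_id
  ft <- feature_table(fmat)
  cr <- complete_rows(ft)
  for (id in cr$excluded) exclude(id, "clustering", "missing feature value")
  if (nrow(cr$table$matrix) >= 3) {
    scaled <- zscore_scale(cr$table)
    d <- euclidean_distances(scaled)
    clustering <- tryCatch(select_k(d, cfg$k_range), error = function(e) NULL)
    if (!is.null(clustering) && !is.null(metadata) &&
        "genotype" %in% names(features)) {
      lab <- cut_dendrogram(clustering$dendrogram, 2)
      geno <- features$genotype[match(cr$table$cell_ids, features$cell_id)]
      gl <- sort(unique(stats::na.omit(geno)))
      if (length(gl) == 2) {
        tab <- rbind(
          c(sum(lab == 1 & geno == gl[1], na.rm = TRUE),
            sum(lab == 1 & geno == gl[2], na.rm = TRUE)),
          c(sum(lab == 2 & geno == gl[1], na.rm = TRUE),
            sum(lab == 2 & geno == gl[2], na.rm = TRUE)))
        composition <- tryCatch(barnard_test(tab), error = function(e) NULL)
      }
    }
  }
  report <- structure(
    list(features = features, exclusions = exclusions,
         group_tests = group_tests, clustering = clustering,
         composition_test = composition,
         provenance = list(
           package_version = as.character(utils::packageVersion("icephys")),
           seed = cfg$seed,
           n_input = n_input, n_analyzed = nrow(features),
           config = cfg[setdiff(names(cfg),
                                c("metadata", "input_dir", "out_dir"))])),
    class = "pipeline_report"
  )
  if (!is.null(cfg$out_dir)) write_report(report, cfg$out_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>", nrow(x$features), "cells analyzed;",
      nrow(x$exclusions), "exclusions\n")
  if (!is.null(x$clustering)) {
    cat("  clustering: best k =", x$clustering$best_k, "\n")
  }
  invisible(x)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$features, file.path(out_dir, "feature_table.csv"),
                   row.names = FALSE)
  utils::write.csv(report$exclusions, file.path(out_dir, "exclusions.csv"),
                   row.names = FALSE)
  if (!is.null(report$group_tests)) {
    utils::write.csv(report$group_tests, file.path(out_dir, "group_tests.csv"),
                     row.names = FALSE)
  }
  cl <- report$clustering
  if (!is.null(cl)) {
    utils::write.csv(
      data.frame(k = as.integer(names(cl$silhouette_by_k)),
                 mean_silhouette = as.numeric(cl$silhouette_by_k)),
      file.path(out_dir, "silhouette_by_k.csv"), row.names = FALSE)
    labs <- do.call(rbind, lapply(names(cl$labels_by_k), function(k) {
      data.frame(cell_id = names(cl$labels_by_k[[k]]), k = as.integer(k),
                 label = as.integer(cl$labels_by_k[[k]]))
    }))
    utils::write.csv(labs, file.path(out_dir, "cluster_labels.csv"),
                     row.names = FALSE)
    utils::write.csv(merge_table(cl$dendrogram),
                     file.path(out_dir, "merge_table.csv"), row.names = FALSE)
    writeLines(dendrogram_newick(cl$dendrogram),
               file.path(out_dir, "dendrogram.nwk"))
  }
  prov <- report$provenance
  if (!is.null(report$composition_test)) {
    prov$composition_test <- unclass(report$composition_test)
  }
  jsonlite::write_json(prov, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(out_dir)
}

#' Paired TTX analysis across cells
#'
#' Applies [ttx_effect()] to each cell's sweep series, then tests the
#' paired first-10 vs last-10 mean spikelet amplitudes across cells with
#' the exact Wilcoxon signed-rank test. With a single cell the reduction is
#' reported and the test marked not computable.
#'
#' @param series_list List of [sweep_set()]s, one 60-sweep series per cell.
#' @param mode Test mode passed to [wilcoxon_signed_rank()].
#' @return A list of class `ttx_report`: `per_cell` (data.frame with
#'   first/last means and percent reduction), `mean_percent_reduction`,
#'   `test` (a `test_result` or `NULL`).
#' @export
run_ttx_analysis <- function(series_list, mode = "auto") {
  stopifnot(is.list(series_list), length(series_list) >= 1)
  per_cell <- do.call(rbind, lapply(series_list, function(s) {
    r <- ttx_effect(s)
    data.frame(cell_id = s$cell_id, mean_amp_first10 = r$mean_amp_first10,
               mean_amp_last10 = r$mean_amp_last10,
               percent_reduction = r$percent_reduction)
  }))
  test <- NULL
  if (nrow(per_cell) >= 2) {
    diffs <- per_cell$mean_amp_first10 - per_cell$mean_amp_last10
    test <- wilcoxon_signed_rank(diffs, mode = mode)
  }
  structure(
    list(per_cell = per_cell,
         mean_percent_reduction = mean(per_cell$percent_reduction),
         test = test),
    class = "ttx_report"
  )
}

#' Write a TTX report as paired-long CSV
#'
#' Columns `cell_id, condition, mean_amp_mV` with conditions
#' `pre`/`post`.
#' @param report A [run_ttx_analysis()] result.
#' @param path Output CSV path.
#' @export
write_ttx_csv <- function(report, path) {
  long <- rbind(
    data.frame(cell_id = report$per_cell$cell_id, condition = "pre",
               mean_amp_mV = report$per_cell$mean_amp_first10),
    data.frame(cell_id = report$per_cell$cell_id, condition = "post",
               mean_amp_mV = report$per_cell$mean_amp_last10))
  utils::write.csv(long[order(long$cell_id), ], path, row.names = FALSE)
  invisible(path)
}
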