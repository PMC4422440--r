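# File formats and the end-to-end pipeline: dense and sparse-triplet
# connectivity matrices, run configuration, and the orchestration from raw
# matrices to parcellation volumes and metric tables.

#' Write a connectivity matrix to a text file
#'
#' Two plain-text formats are supported. `"dense"`: one whitespace-separated
#' row of counts per seed voxel. `"sparse"`: one `row column value` triplet
#' per line with 1-based indices and absent entries zero, the layout of
#' sparse matrix dumps from common tractography tools; a `# dims R C`
#' header records the matrix shape. Integer counts round-trip bit-exactly.
#'
#' @param m a `connectivity_matrix`.
#' @param path output file.
#' @param format `"dense"` or `"sparse"`.
#' @return The path, invisibly.
#' @export
write_connectivity <- function(m, path, format = c("dense", "sparse")) {
  format <- match.arg(format)
  stopifnot(inherits(m, "connectivity_matrix"))
  if (format == "dense") {
    utils::write.table(m$counts, path, row.names = FALSE, col.names = FALSE,
                       sep = " ", quote = FALSE)
  } else {
    nz <- which(m$counts != 0, arr.ind = TRUE)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# dims %d %d", nrow(m$counts), ncol(m$counts)), con)
    if (nrow(nz) > 0) {
      vals <- m$counts[nz]
      writeLines(sprintf("%d %d %s", nz[, 1], nz[, 2],
                         format(vals, scientific = FALSE, trim = TRUE)), con)
    }
  }
  invisible(path)
}

#' Read a connectivity matrix from a text file
#'
#' Inverse of [write_connectivity()]. For sparse files the matrix shape is
#' taken from the `# dims` header or, failing that, from `dims`. Malformed
#' lines raise a parse error naming the line; negative counts raise a
#' validation error.
#'
#' @param path input file.
#' @param format `"dense"` or `"sparse"`.
#' @param dims optional `c(rows, cols)` for headerless sparse files.
#' @param seed_index,target_grid,participant_id passed through to
#'   [connectivity_matrix()].
#' @return A `connectivity_matrix`.
#' @export
read_connectivity <- function(path, format = c("dense", "sparse"), dims = NULL,
                              seed_index = NULL, target_grid = NULL,
                              participant_id = NA_character_) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "dense") {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    rows <- lapply(seq_along(lines), function(i) {
      v <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]]))
      if (any(is.na(v)))
        stop(sprintf("parse error in %s at line %d: non-numeric field", path, i))
      v
    })
    ncols <- unique(lengths(rows))
    if (length(ncols) != 1)
      stop(sprintf("parse error in %s: ragged rows (widths %s)",
                   path, paste(ncols, collapse = ", ")))
    counts <- do.call(rbind, rows)
  } else {
    lines <- readLines(path)
    hdr <- grep("^#\\s*dims\\s", lines, value = TRUE)
    if (length(hdr) >= 1) {
      d <- suppressWarnings(as.integer(strsplit(trimws(sub("^#\\s*dims", "", hdr[1])),
                                                "\\s+")[[1]]))
      if (length(d) != 2 || any(is.na(d)))
        stop("parse error in ", path, ": malformed dims header")
      dims <- d
    }
    if (is.null(dims)) stop("sparse file has no dims header; supply dims = c(rows, cols)")
    counts <- matrix(0, dims[1], dims[2])
    body <- which(!grepl("^\\s*(#|$)", lines))
    for (i in body) {
      f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
      v <- suppressWarnings(as.numeric(f))
      if (length(f) != 3 || any(is.na(v)))
        stop(sprintf("parse error in %s at line %d: expected 'row column value'",
                     path, i))
      if (v[3] < 0)
        stop(sprintf("validation error in %s at line %d: negative count", path, i))
      if (v[1] < 1 || v[1] > dims[1] || v[2] < 1 || v[2] > dims[2])
        stop(sprintf("parse error in %s at line %d: index out of range", path, i))
      counts[v[1], v[2]] <- v[3]
    }
  }
  connectivity_matrix(counts, seed_index, target_grid, participant_id)
}

#' Run configuration for the full parcellation pipeline
#'
#' Bundles every tunable of the pipeline with study-scale defaults:
#' K = 2..8, 1000 k-means replicates, 100 split-half repetitions, 1% tract
#' threshold, 50% consistency cutoff, FWE alpha 0.01, base-10 VI.
#'
#' @param k_range contiguous K values starting at 2.
#' @param n_replicates k-means restarts per clustering.
#' @param n_repetitions split-half repetitions.
#' @param alpha_k one-sided level for the optimal-K rule.
#' @param alpha_fwe FWE level for tract contrasts.
#' @param tract_threshold proportion cutoff for tract maps.
#' @param consistency_cutoff cross-participant overlap cutoff.
#' @param log_base VI logarithm base.
#' @param clip_epsilon Fisher-Z clip margin.
#' @param downsample_mm optional target cell size for [downsample_targets()].
#' @param zero_variance policy for zero-variance seed rows (`"error"` or
#'   `"drop"`).
#' @param rng_seed integer master seed.
#' @return An object of class `run_config`.
#' @export
run_config <- function(k_range = 2:8, n_replicates = 1000, n_repetitions = 100,
                       alpha_k = 0.05, alpha_fwe = 0.01, tract_threshold = 0.01,
                       consistency_cutoff = 0.5, log_base = 10,
                       clip_epsilon = 1e-7, downsample_mm = NULL,
                       zero_variance = c("error", "drop"), rng_seed = 1L) {
  k_range <- as.integer(k_range)
  if (length(k_range) < 2 || k_range[1] != 2 || any(diff(k_range) != 1))
    stop("k_range must be contiguous from 2 (the optimal-K rule needs the K = 2 baseline)")
  stopifnot(n_replicates >= 1, n_repetitions >= 1,
            alpha_k > 0, alpha_k < 1, alpha_fwe > 0, alpha_fwe < 1,
            tract_threshold > 0, tract_threshold < 1,
            consistency_cutoff > 0, consistency_cutoff <= 1,
            log_base > 0, log_base != 1, clip_epsilon > 0)
  structure(list(k_range = k_range, n_replicates = as.integer(n_replicates),
                 n_repetitions = as.integer(n_repetitions), alpha_k = alpha_k,
                 alpha_fwe = alpha_fwe, tract_threshold = tract_threshold,
                 consistency_cutoff = consistency_cutoff, log_base = log_base,
                 clip_epsilon = clip_epsilon, downsample_mm = downsample_mm,
                 zero_variance = match.arg(zero_variance),
                 rng_seed = as.integer(rng_seed)),
            class = "run_config")
}

#' Read / write a run configuration as key = value text
#'
#' @param path file path.
#' @return `read_run_config`: a `run_config`. `write_run_config`: the path,
#'   invisibly.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- which(lengths(kv) != 2)
  if (length(bad) > 0) stop("malformed config line: ", lines[bad[1]])
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- trimws(vapply(kv, `[`, "", 2))
  args <- list()
  for (i in seq_along(keys)) {
    v <- vals[i]
    args[[keys[i]]] <- if (keys[i] == "k_range") {
      r <- as.integer(strsplit(v, ":", fixed = TRUE)[[1]])
      r[1]:r[2]
    } else if (keys[i] == "zero_variance") v
    else as.numeric(v)
  }
  do.call(run_config, args)
}

#' @rdname read_run_config
#' @param cfg a `run_config`.
#' @export
write_run_config <- function(cfg, path) {
  lines <- c(sprintf("k_range = %d:%d", cfg$k_range[1], cfg$k_range[length(cfg$k_range)]),
             sprintf("n_replicates = %d", cfg$n_replicates),
             sprintf("n_repetitions = %d", cfg$n_repetitions),
             sprintf("alpha_k = %g", cfg$alpha_k),
             sprintf("alpha_fwe = %g", cfg$alpha_fwe),
             sprintf("tract_threshold = %g", cfg$tract_threshold),
             sprintf("consistency_cutoff = %g", cfg$consistency_cutoff),
             sprintf("log_base = %g", cfg$log_base),
             sprintf("clip_epsilon = %g", cfg$clip_epsilon),
             if (!is.null(cfg$downsample_mm)) sprintf("downsample_mm = %g", cfg$downsample_mm),
             sprintf("zero_variance = %s", cfg$zero_variance),
             sprintf("rng_seed = %d", cfg$rng_seed))
  writeLines(lines, path)
  invisible(path)
}

#' Run the parcellation pipeline end to end
#'
#' From per-participant connectivity matrices to selected-K parcellation
#' and metric tables: optional target downsampling, cross-correlation,
#' Fisher-Z, split-half VI across `k_range`, optimal-K selection, final
#' parcellation of the full-group average at every K, cluster summaries and
#' the hierarchy profile. When `out_dir` is given, writes the label volume
#' per K (NIfTI), the VI / hierarchy / cluster tables (TSV) and a run log;
#' identical configurations produce identical outputs.
#'
#' @param matrices list of `connectivity_matrix` objects, or character
#'   paths read with [read_connectivity()].
#' @param mask a `seed_mask`, or a NIfTI path.
#' @param cfg a `run_config`.
#' @param out_dir optional output directory.
#' @param format matrix file format when `matrices` are paths.
#' @return A run report: `vi_curve`, `optimal_k`, `parcellations` (one per
#'   K), `summaries`, `hierarchy`, `group_profile`, `dropped_voxels`,
#'   `outputs` (paths written).
#' @export
run_pipeline <- function(matrices, mask, cfg = run_config(), out_dir = NULL,
                         format = c("dense", "sparse")) {
  format <- match.arg(format)
  stopifnot(inherits(cfg, "run_config"))
  if (is.character(mask)) mask <- read_seed_mask(mask)
  if (is.character(matrices))
    matrices <- lapply(matrices, read_connectivity, format = format)
  if (length(matrices) < 2)
    stop("pipeline stage connectivity: at least 2 participants are required")
  log_lines <- c(sprintf("cbparc run, seed %d", cfg$rng_seed),
                 sprintf("participants: %d", length(matrices)),
                 sprintf("seed voxels: %d", mask$n_voxels))
  step <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage %s: %s", stage, conditionMessage(e)), call. = FALSE))
  }
  if (!is.null(cfg$downsample_mm))
    matrices <- step("downsample", lapply(matrices, downsample_targets,
                                          cell_mm = cfg$downsample_mm))
  profiles <- step("cross-correlation", lapply(matrices, function(m) {
    fisher_z(cross_correlate(m, zero_variance = cfg$zero_variance),
             clip_epsilon = cfg$clip_epsilon)
  }))
  drop_sets <- lapply(profiles, `[[`, "dropped")
  dropped <- sort(unique(unlist(drop_sets)))
  if (length(dropped) > 0 &&
      !all(vapply(drop_sets, identical, logical(1), drop_sets[[1]])))
    stop("pipeline stage cross-correlation: zero-variance voxels differ by ",
         "participant; drop them consistently upstream (voxels ",
         paste(dropped, collapse = ", "), ")")
  if (length(dropped) > 0)  # keep mask aligned with the surviving rows
    mask <- seed_mask(mask$voxels[-dropped, , drop = FALSE], mask$dim,
                      mask$affine, mask$hemisphere)
  curve <- step("split-half VI",
                split_half_vi(profiles, cfg$k_range, cfg$n_repetitions,
                              cfg$n_replicates, rng_seed = cfg$rng_seed,
                              log_base = cfg$log_base))
  sel <- select_optimal_k(curve, alpha = cfg$alpha_k)
  log_lines <- c(log_lines,
                 sprintf("optimal K: %d%s", sel$k,
                         if (sel$no_selection) " (no K satisfied the rule)" else ""))
  group <- step("group average", average_group(profiles))
  parcellations <- lapply(cfg$k_range, function(k)
    step("clustering", kmeans_replicates(group, k, cfg$n_replicates,
                                         rng_seed = .child_seed(cfg$rng_seed, 9000, k))))
  names(parcellations) <- paste0("K", cfg$k_range)
  summaries <- lapply(parcellations, summarize_clusters, mask = mask)
  hier <- hierarchy_profile(parcellations)
  outputs <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    vi_path <- file.path(out_dir, "vi_curve.tsv")
    utils::write.table(data.frame(K = curve$k, mean_vi = curve$mean_vi,
                                  ci_low = curve$ci_low, ci_high = curve$ci_high,
                                  t = curve$t, p = curve$p),
                       vi_path, sep = "\t", row.names = FALSE, quote = FALSE)
    hier_path <- file.path(out_dir, "hierarchy.tsv")
    utils::write.table(hier, hier_path, sep = "\t", row.names = FALSE, quote = FALSE)
    sum_path <- file.path(out_dir, "cluster_summary.tsv")
    all_sum <- do.call(rbind, lapply(cfg$k_range, function(k) {
      s <- summaries[[paste0("K", k)]]
      cbind(K = k, s)
    }))
    utils::write.table(all_sum, sum_path, sep = "\t", row.names = FALSE, quote = FALSE)
    nii_paths <- vapply(cfg$k_range, function(k) {
      p <- file.path(out_dir, sprintf("parcellation_K%d.nii.gz", k))
      write_seed_mask(mask, p, values = parcellations[[paste0("K", k)]]$labels)
      p
    }, character(1))
    log_path <- file.path(out_dir, "run_log.txt")
    cfg_path <- file.path(out_dir, "run_config.txt")
    write_run_config(cfg, cfg_path)
    writeLines(c(log_lines,
                 sprintf("dropped voxels: %s",
                         if (length(dropped)) paste(dropped, collapse = ", ") else "none")),
               log_path)
    outputs <- c(vi_path, hier_path, sum_path, nii_paths, log_path, cfg_path)
  }
  list(vi_curve = curve, optimal_k = sel, parcellations = parcellations,
       summaries = summaries, hierarchy = hier, group_profile = group,
       dropped_voxels = dropped, outputs = outputs)
}
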