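#' Project-directory data store
#'
#' Pipeline stages exchange data through a plain-text project directory:
#' tab-separated tables for pixel streams, observation tables and merged
#' output, and JSON for metadata (cell, symmetry matrices, subdivision,
#' seeds, schema version), the fitted peak shape and the scaling model.
#' Every table re-reads round-trip without loss, and a run log records the
#' parameters and seeds of each stage.
#'
#' @param dir Project directory path (created if absent).
#' @return The normalized project path, invisibly.
#' @export
project_init <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sub in c("images", "background", "peaks", "observations", "model",
                "merged", "map", "stats"))
    dir.create(file.path(dir, sub), showWarnings = FALSE)
  invisible(normalizePath(dir))
}

write_tsv <- function(df, path) {
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}

read_tsv <- function(path, stage = "producing") {
  if (!file.exists(path)) stop("missing pipeline input: ", path,
                               " (run the ", stage, " stage first)")
  as.data.frame(data.table::fread(path, sep = "\t"))
}

write_meta <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

read_meta <- function(path, stage = "producing") {
  if (!file.exists(path)) stop("missing pipeline input: ", path,
                               " (run the ", stage, " stage first)")
  jsonlite::read_json(path, simplifyVector = TRUE)
}

log_stage <- function(dir, stage, ...) {
  line <- sprintf("[%s] %s %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  stage, paste(..., collapse = " "))
  message(line)
  cat(line, "\n", file = file.path(dir, "log.txt"), append = TRUE)
}

#' Write a merged intensity table as TSV
#'
#' Columns: fractional Miller indices `h,k,l` of the asymmetric-unit voxel
#' center, merged intensity, standard error, number of observations, plus
#' any half-set columns present.
#'
#' @param merged Merged table (see [merge_scaled()]), with `h,k,l` columns.
#' @param path Output file.
#' @export
write_merged <- function(merged, path) write_tsv(merged, path)

#' Read a merged intensity table written by [write_merged()]
#' @param path TSV file path.
#' @return data.frame.
#' @export
read_merged <- function(path) read_tsv(path)

model_to_list <- function(model) {
  pg_list <- function(pg) if (is.null(pg)) NULL else
    list(axes = pg$axes, dim = dim(pg$values), values = as.vector(pg$values))
  list(enabled = as.list(model$enabled), batches = model$batches,
       sweeps = lapply(model$sweeps, function(sw) lapply(sw, pg_list)),
       d = pg_list(model$d))
}

model_from_list <- function(x) {
  pg_back <- function(p) {
    if (is.null(p) || length(p) == 0) return(NULL)
    ax <- p$axes
    axes <- if (is.matrix(ax)) lapply(seq_len(nrow(ax)), function(r) ax[r, ])
            else if (is.list(ax)) lapply(ax, as.numeric)
            else list(as.numeric(ax))
    param_grid(axes, array(as.numeric(p$values), dim = unlist(p$dim)))
  }
  structure(list(enabled = unlist(x$enabled), batches = unlist(x$batches),
                 sweeps = lapply(x$sweeps, function(sw) lapply(sw, pg_back)),
                 d = pg_back(x$d)),
            class = "scaling_model")
}

#' Run the processing pipeline on a project directory
#'
#' Chains the stages of the workflow: `simulate` (synthetic experiment:
#' per-pixel image-mode stream, background stack and ground truth),
#' `bin-background`, `mask-peaks`, `integrate`, `correct`, `scale`,
#' `merge` (with optional half-set splitting), `stats` (shell statistics
#' and split correlations) and `map` (symmetry expansion).  Each stage
#' reads its inputs from and writes its outputs to the project directory,
#' logging parameters and seeds; rerunning with the same configuration and
#' seeds reproduces the outputs byte for byte.
#'
#' @param dir Project directory.
#' @param stages Character vector of stages to run, in order.
#' @param config A [simulation_config()] (used by `simulate`; stored in the
#'   project metadata).
#' @param scale_cfg A [scale_config()] for the `scale` stage.
#' @param split Data split for `merge`: `"none"`, `"randomHalf"` or
#'   `"Friedel"`.
#' @param count_threshold Strong-pixel photon threshold for `mask-peaks`.
#' @param sigma_cutoff Peak-mask cutoff in standard deviations.
#' @param n_shells Resolution shells for `stats`.
#' @param n_frames Frames rasterized per sweep by `simulate`.
#' @param frame_bin,pixel_bin Background binning factors.
#' @param nproc Worker processes for `integrate` (does not change results).
#' @return Invisibly, the project directory.
#' @export
run_pipeline <- function(dir,
                         stages = c("simulate", "bin-background",
                                    "mask-peaks", "integrate", "correct",
                                    "scale", "merge", "stats", "map"),
                         config = simulation_config(),
                         scale_cfg = scale_config(),
                         split = c("randomHalf", "none", "Friedel"),
                         count_threshold = 20, sigma_cutoff = 3,
                         n_shells = 10, n_frames = 40,
                         frame_bin = 5, pixel_bin = 8, nproc = 1) {
  split <- match.arg(split)
  project_init(dir)
  meta_path <- file.path(dir, "metadata.json")

  for (stage in stages) {
    switch(stage,
      "simulate" = {
        truth <- simulate_truth(config)
        old <- local_seed(config$seed)
        sub_seeds <- sample.int(.Machine$integer.max - 1L, config$n_sweeps)
        restore_seed(old)
        for (sw in seq_len(config$n_sweeps)) {
          sim <- simulate_images(truth, sweep = sw, seed = sub_seeds[sw],
                                 n_frames = n_frames)
          write_tsv(sim$pixels, file.path(dir, "images",
                                          sprintf("pixels-sweep%02d.tsv", sw)))
        }
        bg <- simulate_background_stack(config, seed = config$seed + 1L)
        bg_px <- data.frame(
          frame = as.vector(slice.index(bg$counts, 1)),
          x = as.vector(slice.index(bg$counts, 2)),
          y = as.vector(slice.index(bg$counts, 3)),
          count = as.vector(bg$counts))
        write_tsv(bg_px, file.path(dir, "background", "stack.tsv"))
        write_tsv(truth$table, file.path(dir, "observations", "truth.tsv"))
        grid <- truth$grid
        write_meta(list(schema_version = 1,
                        cell = list(a = grid$cell$a, b = grid$cell$b,
                                    c = grid$cell$c),
                        subdivision = grid$subdivision,
                        centering = grid$centering,
                        laue_ops = lapply(grid$laue_ops, as.vector),
                        seed = config$seed, sub_seeds = sub_seeds,
                        n_sweeps = config$n_sweeps,
                        phi_step = config$phi_step,
                        exposure = config$exposure,
                        bg_exposure = bg$exposure,
                        n_frames = n_frames), meta_path)
        log_stage(dir, "simulate", "seed", config$seed, "sweeps",
                  config$n_sweeps, "frames", n_frames)
      },
      "bin-background" = {
        meta <- read_meta(meta_path, "simulate")
        bg_px <- read_tsv(file.path(dir, "background", "stack.tsv"), "simulate")
        dims <- c(max(bg_px$frame), max(bg_px$x), max(bg_px$y))
        counts <- array(0, dims)
        counts[cbind(bg_px$frame, bg_px$x, bg_px$y)] <- bg_px$count
        bmap <- bin_image_stack(counts, exposure = meta$bg_exposure,
                                frame_bin = frame_bin, pixel_bin = pixel_bin)
        idx <- as.matrix(expand.grid(fb = seq_along(bmap$centers[[1]]),
                                     xb = seq_along(bmap$centers[[2]]),
                                     yb = seq_along(bmap$centers[[3]])))
        write_tsv(data.frame(
          frame = bmap$centers[[1]][idx[, 1]],
          x = bmap$centers[[2]][idx[, 2]],
          y = bmap$centers[[3]][idx[, 3]],
          rate = bmap$rate[idx], valid = bmap$valid[idx]),
          file.path(dir, "background", "map.tsv"))
        write_meta(list(dim = dim(bmap$rate), bin_size = bmap$bin_size,
                        centers = bmap$centers, exposure = bmap$exposure),
                   file.path(dir, "background", "map-meta.json"))
        log_stage(dir, "bin-background", "bins",
                  paste(dim(bmap$rate), collapse = "x"))
      },
      "mask-peaks" = {
        px <- read_pixel_stream(dir)
        strong <- px[px$count > count_threshold, , drop = FALSE]
        shape <- fit_peak_shape(as.matrix(strong[, c("h", "k", "l")]))
        mask <- build_peak_mask(shape, n_sigma = sigma_cutoff)
        outlier <- flag_outliers(as.matrix(strong[, c("h", "k", "l")]), mask)
        write_meta(list(mean = shape$mean, covariance = shape$covariance,
                        n_points = shape$n_points, n_sigma = sigma_cutoff,
                        count_threshold = count_threshold,
                        n_outliers = sum(outlier)),
                   file.path(dir, "peaks", "shape.json"))
        log_stage(dir, "mask-peaks", "strong", nrow(strong), "outliers",
                  sum(outlier))
      },
      "integrate" = {
        meta <- read_meta(meta_path, "simulate")
        px <- read_pixel_stream(dir)
        shape_meta <- read_meta(file.path(dir, "peaks", "shape.json"), "mask-peaks")
        shape <- structure(list(mean = as.numeric(shape_meta$mean),
                                covariance = matrix(unlist(shape_meta$covariance), 3, 3),
                                n_points = shape_meta$n_points),
                           class = "peak_shape")
        mask <- build_peak_mask(shape, n_sigma = shape_meta$n_sigma)
        strong_out <- px$count > shape_meta$count_threshold &
          flag_outliers(as.matrix(px[, c("h", "k", "l")]), mask)
        grid <- grid_from_meta(meta)
        obs <- integrate_counts(px, grid, exposure = meta$exposure,
                                mask = mask, exclude = strong_out,
                                nproc = nproc)
        write_tsv(obs, file.path(dir, "observations", "integrated.tsv"))
        log_stage(dir, "integrate", "pixels", nrow(px), "observations",
                  nrow(obs), "nproc", nproc)
      },
      "correct" = {
        meta <- read_meta(meta_path, "simulate")
        obs <- read_tsv(file.path(dir, "observations", "integrated.tsv"),
                        "integrate")
        bm <- read_meta(file.path(dir, "background", "map-meta.json"),
                        "bin-background")
        bmap_df <- read_tsv(file.path(dir, "background", "map.tsv"))
        bmap <- structure(list(
          rate = array(bmap_df$rate, unlist(bm$dim)),
          valid = array(bmap_df$valid, unlist(bm$dim)),
          bin_size = unlist(bm$bin_size),
          centers = lapply(bm$centers, as.numeric),
          exposure = bm$exposure), class = "background_map")
        # crystal frames and background frames share the rotation axis:
        # map the observation's phi to the background frame coordinate
        bg_frame <- obs$phi / meta$phi_step *
          meta$exposure / bm$exposure + 0.5
        r_bg <- background_rate(bmap, bg_frame, obs$x, obs$y)
        cor <- correct_observation(obs$n, obs$dt, r_bg, factors = 1)
        obs$r_bg <- r_bg
        obs$I <- cor$I
        obs$sigma <- cor$sigma
        write_tsv(obs, file.path(dir, "observations", "corrected.tsv"))
        log_stage(dir, "correct", "observations", nrow(obs))
      },
      "scale" = {
        meta <- read_meta(meta_path, "simulate")
        obs <- read_tsv(file.path(dir, "observations", "corrected.tsv"),
                        "correct")
        grid <- grid_from_meta(meta)
        fit <- refine_scaling(obs, config = scale_cfg, grid = grid)
        write_meta(model_to_list(fit$model), file.path(dir, "model", "model.json"))
        write_meta(fit$diagnostics, file.path(dir, "model", "diagnostics.json"))
        obs$scale_m <- fit$scale$m
        obs$scale_o <- fit$scale$o
        obs$active <- fit$active
        write_tsv(obs, file.path(dir, "observations", "scaled.tsv"))
        write_merged(fit$merged, file.path(dir, "merged", "merged.tsv"))
        log_stage(dir, "scale", "cycles", fit$diagnostics$cycles,
                  "chi2", signif(rev(fit$diagnostics$chi2)[1], 6))
      },
      "merge" = {
        meta <- read_meta(meta_path, "simulate")
        obs <- read_tsv(file.path(dir, "observations", "scaled.tsv"), "scale")
        grid <- grid_from_meta(meta)
        keep <- if (is.null(obs$active)) NULL else as.logical(obs$active)
        merged <- merge_scaled(obs, m = obs$scale_m, o = obs$scale_o,
                               grid = grid, keep = keep)
        if (split != "none") {
          half <- split_observations(obs, mode = split, seed = config$seed)
          for (hh in 1:2) {
            mh <- merge_scaled(obs, m = obs$scale_m, o = obs$scale_o,
                               grid = grid,
                               keep = (if (is.null(keep)) TRUE else keep) &
                                 half == hh)
            idx <- match(merged_key(merged), merged_key(mh))
            merged[[paste0("I_half", hh)]] <- mh$I[idx]
            merged[[paste0("sigma_half", hh)]] <- mh$sigma[idx]
          }
        }
        merged$s <- s_magnitude(as.matrix(merged[, c("h", "k", "l")]),
                                grid$cell)
        write_merged(merged, file.path(dir, "merged", "merged.tsv"))
        write_meta(list(split = split, seed = config$seed),
                   file.path(dir, "merged", "split.json"))
        log_stage(dir, "merge", "split", split, "voxels", nrow(merged))
      },
      "stats" = {
        meta <- read_meta(meta_path, "simulate")
        grid <- grid_from_meta(meta)
        merged <- read_tsv(file.path(dir, "merged", "merged.tsv"), "merge")
        scheme <- shell_scheme(merged$s, n_shells = n_shells)
        part <- halo_partition(merged, grid)
        st <- shell_statistics(merged, scheme, part)
        write_tsv(st, file.path(dir, "stats", "shell-stats.tsv"))
        if (!is.null(merged$I_half1)) {
          m1 <- merged[!is.na(merged$I_half1), ]
          m2 <- merged[!is.na(merged$I_half2), ]
          m1$I <- m1$I_half1
          m2$I <- m2$I_half2
          cc <- cc_by_shell(m1, m2, scheme)
          write_tsv(cc, file.path(dir, "stats", "cc.tsv"))
        }
        log_stage(dir, "stats", "shells", n_shells)
      },
      "map" = {
        meta <- read_meta(meta_path, "simulate")
        grid <- grid_from_meta(meta)
        merged <- read_tsv(file.path(dir, "merged", "merged.tsv"), "merge")
        nmax <- grid$subdivision[1] * 2L
        map <- expand_map(merged, grid,
                          bounds = list(i = c(-nmax, nmax), j = c(-nmax, nmax),
                                        k = c(-nmax, nmax)))
        vox <- as.matrix(expand.grid(i = map$i, j = map$j, k = map$k))
        write_tsv(data.frame(i = vox[, 1], j = vox[, 2], k = vox[, 3],
                             I = as.vector(map$values)),
                  file.path(dir, "map", "map.tsv"))
        log_stage(dir, "map", "voxels", length(map$values), "filled",
                  sum(!is.na(map$values)))
      },
      stop("unknown pipeline stage: ", stage))
  }
  invisible(dir)
}

read_pixel_stream <- function(dir) {
  files <- sort(list.files(file.path(dir, "images"), pattern = "^pixels-.*\\.tsv$",
                           full.names = TRUE))
  if (!length(files)) stop("missing pipeline input: pixel stream ",
                           "(run the simulate stage first)")
  do.call(rbind, lapply(files, read_tsv))
}

grid_from_meta <- function(meta) {
  raw <- meta$laue_ops
  if (is.matrix(raw)) raw <- split(raw, row(raw))
  ops <- lapply(raw, function(v) matrix(as.numeric(unlist(v)), 3, 3))
  miller_grid(unit_cell(meta$cell$a, meta$cell$b, meta$cell$c),
              subdivision = unlist(meta$subdivision),
              centering = meta$centering, laue_ops = ops)
}
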