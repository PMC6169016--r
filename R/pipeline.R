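#' Default pipeline configuration
#'
#' Defaults reproduce the study's chosen strategy: log-linearization +
#' ALS correction, reduction to the single most informative band,
#' multilevel thresholding for dark (topsoil-like) backgrounds with
#' fuzzy clustering the recommended alternative for bright ones.
#'
#' @param ... overrides (named, nested lists merged).
#' @return nested named list; serializable to YAML.
#' @export
default_pipeline_config <- function(...) {
  cfg <- list(
    trim = list(lo = 1000, hi = 1700),
    # Absolute score threshold, the field practice for defect masking:
    # true dead pixels / spikes toggle over most of the dynamic range
    # (difference-spectrum sd near 1 in reflectance units) while genuine
    # spectra stay below ~0.1; the robust median + k_mad * MAD rule is
    # available by setting abs_threshold to NULL, but over-flags sparse
    # high-contrast foreground when the background is very uniform.
    dead_pixels = list(k_mad = 5, abs_threshold = 0.3),
    pretreatment = list(linearization = "log_inv", detrend = "als",
                        multiplicative = "none",
                        params = list(als_lambda = 1e4, als_p = 1e-3,
                                      als_iter = 10, sg_window = 7,
                                      sg_polyorder = 2, poly_degree = 2)),
    selection = list(k_bands = 10, n_bins = 128, band_stride = 1,
                     criteria = c("bhattacharyya_single",
                                  "bhattacharyya_diff", "nongauss")),
    reduction = list(mode = "best1"),
    segmentation = list(algorithm = "threshold", n_classes = 3,
                        fuzzifier = 2, svm_cost = 1, seed = 1),
    postprocess = list(nominal_overlap = 0.1, min_extent_px = 10,
                       min_area_px = 20),
    quality = list(skew_threshold = 2.5),
    mm_per_px = 0.1,
    seed = 1)
  utils::modifyList(cfg, list(...))
}

#' Read / write a pipeline configuration (YAML)
#'
#' @param path YAML file path.
#' @return `read_pipeline_config`: config list merged over the defaults.
#' @export
read_pipeline_config <- function(path) {
  utils::modifyList(default_pipeline_config(), yaml::read_yaml(path))
}

#' @param config config list.
#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Stable hash of a configuration (FNV-1a, hex)
#'
#' Embedded in reports so reruns can be matched to their configuration.
#'
#' @param config any serializable object.
#' @return 8-hex-digit string.
#' @export
config_hash <- function(config) {
  s <- yaml::as.yaml(config)
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

config_spec <- function(config) {
  p <- config$pretreatment
  pretreatment_spec(p$linearization, p$detrend, p$multiplicative,
                    p$params %||% list())
}

# normalize -> trim -> dead-pixel mask -> pretreat, for one stride
preprocess_stride <- function(raw, cal, config, spec = NULL) {
  cube <- normalize_cube(raw, cal)
  cube <- trim_bands(cube, config$trim$lo, config$trim$hi)
  cube <- mask_dead_pixels(cube, config$dead_pixels$k_mad,
                           config$dead_pixels$abs_threshold)
  apply_pretreatment(cube, spec %||% config_spec(config))
}

segment_with <- function(algorithm, reduced, config, rois = NULL,
                         valid_mask = NULL, spec_id = NA_character_) {
  seg <- config$segmentation
  switch(algorithm,
    threshold = segment_threshold(reduced, seg$n_classes, valid_mask, spec_id),
    kmeans = segment_kmeans(reduced, seg$n_classes, seg$seed,
                            valid_mask = valid_mask, spec_id = spec_id),
    fcm = segment_fuzzy_cmeans(reduced, seg$n_classes, seg$fuzzifier,
                               seg$seed, valid_mask = valid_mask,
                               spec_id = spec_id),
    svm = {
      if (is.null(rois)) stop("svm segmentation needs ROIs")
      segment_svm(reduced, rois, seg$svm_cost, valid_mask, spec_id)
    },
    stop("unknown segmentation algorithm: ", algorithm))
}

#' Grid-search image processing strategies
#'
#' Runs every combination of pre-treatment spec x reduction mode x
#' segmentation algorithm on one (normalized, trimmed) stride cube,
#' recording root length and binary-image skewness per combination.
#' Stage failures are recorded as failed rows, never aborting the
#' search.
#'
#' @param cube a normalized reflectance [hypercube] (one stride or
#'   image section).
#' @param rois a [roi_set()] in the cube's coordinates.
#' @param config pipeline configuration; `config$search` may override
#'   `specs` (list of [pretreatment_spec()]), `reductions`, and
#'   `algorithms`.
#' @return list: `report` (data.frame with one row per combination:
#'   spec, reduction, algorithm, root_fraction, skewness, length_cm,
#'   failed, error), `ranking` (the [rank_pretreatments()] result) and
#'   `config_hash`.
#' @export
run_strategy_search <- function(cube, rois, config = default_pipeline_config()) {
  search <- config$search %||% list()
  specs <- search$specs %||% enumerate_pretreatments(
    config$pretreatment$params %||% list())
  reductions <- search$reductions %||% c("best1", "mean10", "pca1", "stack10")
  algorithms <- search$algorithms %||% c("threshold", "kmeans", "fcm", "svm")
  k_bands <- config$selection$k_bands
  n_bins <- config$selection$n_bins

  cubes_by_spec <- lapply(specs, function(sp) apply_pretreatment(cube, sp))
  names(cubes_by_spec) <- vapply(specs, format, character(1))
  ranking <- rank_pretreatments(cubes_by_spec, rois, n_bins,
                                config$selection$band_stride %||% 1)

  rows <- list()
  for (sname in names(cubes_by_spec)) {
    cb <- cubes_by_spec[[sname]]
    sc_single <- band_scores_roi(cb, rois, n_bins)
    sm <- nongauss_band_scores(cb, n_bins)
    oriented <- cbind(abs(sm[, "skewness"]), abs(sm[, "kurtosis"]),
                      -sm[, "entropy"], sm[, "negentropy"], sm[, "snr"],
                      sm[, "kl_divergence"])
    z <- scale(oriented); z[!is.finite(z)] <- 0
    tables <- list(bhattacharyya_single = sc_single,
                   nongauss = rowMeans(z))
    bands <- select_top_bands(tables, k_bands)
    for (red in reductions) {
      reduced <- tryCatch(reduce_dims(cb, bands, red, rois),
                          error = function(e) e)
      for (algo in algorithms) {
        row <- data.frame(spec = sname, reduction = red, algorithm = algo,
                          root_fraction = NA_real_, skewness = NA_real_,
                          length_cm = NA_real_, failed = TRUE,
                          error = NA_character_, stringsAsFactors = FALSE)
        if (inherits(reduced, "error")) {
          row$error <- conditionMessage(reduced)
        } else {
          res <- tryCatch({
            sr <- segment_with(algo, reduced, config, rois, cb$valid_mask,
                               sname)
            rm_ <- remove_noise_objects(sr$mask,
                                        config$postprocess$min_extent_px,
                                        config$postprocess$min_area_px,
                                        config$mm_per_px)
            sr$root_length_cm <- estimate_root_length(rm_)
            ev <- evaluate_segmentation(sr, NULL,
                                        config$quality$skew_threshold)
            list(sr = sr, ev = ev)
          }, error = function(e) e)
          if (inherits(res, "error")) {
            row$error <- conditionMessage(res)
          } else {
            row$root_fraction <- res$ev$root_fraction
            row$skewness <- res$ev$skewness
            row$length_cm <- res$sr$root_length_cm
            row$failed <- res$ev$failed
          }
        }
        rows[[length(rows) + 1]] <- row
      }
    }
  }
  list(report = do.call(rbind, rows), ranking = ranking,
       config_hash = config_hash(config))
}

#' Process a full rhizobox: strides to measured root system
#'
#' For each stride: normalize against its calibration frames, trim
#' bands, mask dead pixels, pre-treat, reduce (bands selected once on
#' the reference stride using the supplied ROIs), segment. Stride masks
#' are then stitched, de-noised and measured.
#'
#' @param strides list of raw-count [hypercube]s, ordered left to right.
#' @param calibrations a single [calibration_frames()] or a list, one
#'   per stride. Missing calibration is a hard error.
#' @param rois [roi_set()] in the reference stride's coordinates.
#' @param config pipeline configuration.
#' @param reference_stride stride used for band selection (default 1).
#' @return list: `mask` (a [root_mask()] of the stitched box),
#'   `length_cm`, `skewness`, `failed`, `layout`, `bands`, `log`
#'   (character vector, one entry per stage per stride), `config_hash`.
#' @export
run_full_box <- function(strides, calibrations, rois,
                         config = default_pipeline_config(),
                         reference_stride = 1) {
  stopifnot(length(strides) >= 1)
  if (is.null(calibrations)) stop("calibration frames are required")
  if (inherits(calibrations, "calibration_frames"))
    calibrations <- rep(list(calibrations), length(strides))
  if (length(calibrations) != length(strides))
    stop("need one calibration_frames per stride")
  log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))

  spec <- config_spec(config)
  pre <- vector("list", length(strides))
  for (i in seq_along(strides)) {
    note("stride %d: normalize", i)
    cube <- normalize_cube(strides[[i]], calibrations[[i]])
    note("stride %d: trim", i)
    cube <- trim_bands(cube, config$trim$lo, config$trim$hi)
    note("stride %d: dead-pixel mask (%s flagged)", i,
         { cube <- mask_dead_pixels(cube, config$dead_pixels$k_mad,
                                    config$dead_pixels$abs_threshold)
           cube$meta$n_dead_flagged })
    note("stride %d: pretreat %s", i, format(spec))
    pre[[i]] <- apply_pretreatment(cube, spec)
  }

  ref <- pre[[reference_stride]]
  sc_single <- band_scores_roi(ref, rois, config$selection$n_bins)
  sm <- nongauss_band_scores(ref, config$selection$n_bins)
  oriented <- cbind(abs(sm[, "skewness"]), abs(sm[, "kurtosis"]),
                    -sm[, "entropy"], sm[, "negentropy"], sm[, "snr"],
                    sm[, "kl_divergence"])
  z <- scale(oriented); z[!is.finite(z)] <- 0
  bands <- select_top_bands(list(bhattacharyya_single = sc_single,
                                 nongauss = rowMeans(z)),
                            config$selection$k_bands)
  note("band selection on stride %d: %s", reference_stride,
       paste(bands, collapse = ","))

  masks <- vector("list", length(strides))
  for (i in seq_along(strides)) {
    reduced <- reduce_dims(pre[[i]], bands, config$reduction$mode,
                           if (i == reference_stride) rois else NULL)
    sr <- segment_with(config$segmentation$algorithm, reduced, config,
                       if (i == reference_stride) rois else NULL,
                       pre[[i]]$valid_mask)
    masks[[i]] <- sr$mask
    note("stride %d: segment %s (%.2f%% root, skewness %.2f)", i,
         config$segmentation$algorithm, 100 * mean(sr$mask), sr$skewness)
  }

  st <- stitch_strides(masks, config$postprocess$nominal_overlap)
  note("stitched %d strides", length(strides))
  rm_ <- remove_noise_objects(st$image, config$postprocess$min_extent_px,
                              config$postprocess$min_area_px,
                              config$mm_per_px)
  rm_$length_cm <- estimate_root_length(rm_)
  note("denoise + length: %.2f cm", rm_$length_cm)
  sk <- binary_mask_skewness(rm_$mask)
  list(mask = rm_, length_cm = rm_$length_cm, skewness = sk,
       failed = !is.finite(sk) || sk < config$quality$skew_threshold,
       layout = st$layout, bands = bands, log = log,
       config_hash = config_hash(config))
}
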