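#' Pipeline configuration
#'
#' Validated bundle of every tunable the end-to-end runner consumes, in
#' processing order: input mode, compartment variants, tiling/filtering
#' parameters, feature backend, clustering settings, merge-level
#' definition and cutoff method.
#'
#' @param input_mode `"features"` (pre-extracted core features) or
#'   `"images"` (raw cores; runs the full image path).
#' @param variants Compartment variants to analyse.
#' @param patch_size Tile side length in pixels.
#' @param bg_threshold Background fraction above which a patch is dropped.
#' @param backend Patch feature backend, see [extract_patch_features()].
#' @param level_definition Merge-level definition, see [merge_level()].
#' @param cutoff_method Cutoff rule, see [select_cutoff()].
#' @param seed Integer seed recorded in the manifest.
#' @param output_dir Optional directory for delimited outputs.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(input_mode = c("features", "images"),
                            variants = c("original", "epithelium", "stroma"),
                            patch_size = 200, bg_threshold = 0.90,
                            backend = "builtin",
                            level_definition = "leaf_count",
                            cutoff_method = "auto",
                            seed = 1L, output_dir = NULL) {
  input_mode <- match.arg(input_mode)
  stopifnot(all(variants %in% c("original", "epithelium", "stroma")),
            patch_size >= 1, bg_threshold >= 0, bg_threshold <= 1)
  level_definition <- match.arg(level_definition,
                                c("leaf_count", "step_index", "depth"))
  cutoff_method <- match.arg(cutoff_method, c("auto", "antimode", "median"))
  backend <- match.arg(backend, c("builtin", "vgg16"))
  structure(list(input_mode = input_mode, variants = variants,
                 patch_size = patch_size, bg_threshold = bg_threshold,
                 backend = backend, level_definition = level_definition,
                 cutoff_method = cutoff_method, seed = as.integer(seed),
                 output_dir = output_dir),
            class = "pipeline_config")
}

# image path for one variant: tile, filter, featurize, aggregate
featurize_cores <- function(variant_images, masks, config) {
  cores <- list()
  dropped <- character(0)
  patches_total <- 0L
  patches_kept <- 0L
  for (i in seq_along(variant_images)) {
    img <- variant_images[[i]]
    tiles <- tile_patches(img, masks[[i]], patch_size = config$patch_size)
    kept <- filter_patches(tiles, bg_threshold = config$bg_threshold)
    patches_total <- patches_total + length(tiles)
    patches_kept <- patches_kept + length(kept)
    if (length(kept) == 0) {
      dropped <- c(dropped, img$core_id)
      next
    }
    vecs <- lapply(kept, extract_patch_features, backend = config$backend)
    cores[[length(cores) + 1L]] <-
      aggregate_core(vecs, img$patient_id, img$core_id, img$variant)
  }
  list(cores = cores, dropped = dropped,
       patches_total = patches_total, patches_kept = patches_kept)
}

#' Run the visual-ITH pipeline end to end
#'
#' Image mode executes, per core: stain normalization against a reference
#' core, segmentation, compartment-variant construction, tiling,
#' background/artifact filtering, patch featurization and mean pooling;
#' feature mode starts from supplied feature matrices. Both modes then
#' cluster each variant's cores (Euclidean + Ward), score per-patient
#' NML, select the group cutoff and assign visual-ITH groups. Every
#' exclusion is counted in the run manifest; given fixed inputs and the
#' built-in backend the run is fully deterministic.
#'
#' @param config A [pipeline_config()].
#' @param images List of `list(image, mask = NULL)` (image mode). Masks,
#'   when absent, come from [segment_tissue()].
#' @param feature_matrices Named list of [feature_matrix()] by variant
#'   (feature mode).
#' @param reference Reference [core_image()] for stain normalization
#'   (default: first input core).
#' @return List of class `ith_run`: `config`, `manifest` (per-variant
#'   counts), `feature_matrices`, `trees`, `nml`, `cutoffs`, `groups`.
#' @export
run_pipeline <- function(config, images = NULL, feature_matrices = NULL,
                         reference = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  manifest <- list()
  if (config$input_mode == "images") {
    if (is.null(images) || length(images) == 0) stop("image mode needs images")
    if (is.null(reference)) reference <- images[[1]]$image
    norm <- lapply(images, function(x) normalize_stain(x$image, reference))
    masks <- lapply(seq_along(images), function(i) {
      if (!is.null(images[[i]]$mask)) images[[i]]$mask else
        segment_tissue(norm[[i]])
    })
    variants_of <- lapply(seq_along(norm), function(i) {
      make_variants(norm[[i]], masks[[i]])
    })
    feature_matrices <- list()
    for (v in config$variants) {
      fz <- featurize_cores(lapply(variants_of, `[[`, v), masks, config)
      fm <- build_feature_matrix(fz$cores)
      feature_matrices[[v]] <- fm
      manifest[[v]] <- data.frame(
        variant = v, cores_in = length(images),
        patches_total = fz$patches_total, patches_kept = fz$patches_kept,
        cores_featurized = length(fz$cores),
        cores_dropped_no_patches = length(fz$dropped),
        cores_scored = nrow(fm$features),
        cores_dropped_min2 = length(fz$cores) - nrow(fm$features),
        stringsAsFactors = FALSE)
    }
  } else {
    if (is.null(feature_matrices)) stop("feature mode needs feature_matrices")
    if (inherits(feature_matrices, "feature_matrix")) {
      fmv <- feature_matrices$variant
      feature_matrices <- stats::setNames(list(feature_matrices), fmv)
    }
    feature_matrices <- feature_matrices[
      intersect(config$variants, names(feature_matrices))]
    if (length(feature_matrices) == 0) {
      stop("no feature matrix matches the configured variants")
    }
    for (v in names(feature_matrices)) {
      fm <- feature_matrices[[v]]
      manifest[[v]] <- data.frame(
        variant = v, cores_in = nrow(fm$features),
        patches_total = NA_integer_, patches_kept = NA_integer_,
        cores_featurized = nrow(fm$features),
        cores_dropped_no_patches = 0L,
        cores_scored = nrow(fm$features), cores_dropped_min2 = 0L,
        stringsAsFactors = FALSE)
    }
  }

  trees <- list(); nml <- list(); cutoffs <- list(); groups <- list()
  for (v in names(feature_matrices)) {
    fm <- feature_matrices[[v]]
    if (nrow(fm$features) < 2) {
      stop("variant ", v, ": fewer than 2 cores survived preprocessing")
    }
    trees[[v]] <- cluster_cores(fm)
    nml[[v]] <- patient_nml(trees[[v]], definition = config$level_definition)
    cutoffs[[v]] <- if (nrow(nml[[v]]) >= 10) {
      select_cutoff(nml[[v]]$nml, method = config$cutoff_method)
    } else {
      # too few patients for density estimation: median rule
      structure(list(method = "median", value = stats::median(nml[[v]]$nml),
                     diagnostics = list(modes = numeric(0),
                                        bandwidth = NA_real_,
                                        valley = NA_real_)),
                class = "ith_cutoff")
    }
    groups[[v]] <- assign_groups(nml[[v]], cutoffs[[v]])
    manifest[[v]]$patients_scored <- nrow(nml[[v]])
    manifest[[v]]$cutoff <- cutoffs[[v]]$value
    manifest[[v]]$cutoff_method <- cutoffs[[v]]$method
    manifest[[v]]$n_heterogeneous <-
      sum(groups[[v]]$ith_group == "heterogeneous")
  }
  manifest <- do.call(rbind, manifest)
  rownames(manifest) <- NULL
  run <- structure(list(config = config, manifest = manifest,
                        feature_matrices = feature_matrices, trees = trees,
                        nml = nml, cutoffs = cutoffs, groups = groups),
                   class = "ith_run")
  if (!is.null(config$output_dir)) write_run(run, config$output_dir)
  run
}

#' @export
print.ith_run <- function(x, ...) {
  cat("<visual-ITH pipeline run>\n")
  print(x$manifest)
  invisible(x)
}

#' Write pipeline outputs as delimited text
#'
#' Per variant: feature matrix, linkage-record table, NML table and group
#' table, plus the run manifest.
#'
#' @param run An `ith_run` from [run_pipeline()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  stopifnot(inherits(run, "ith_run"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wt <- function(df, name) {
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  wt(run$manifest, "manifest.tsv")
  for (v in names(run$nml)) {
    write_feature_matrix(run$feature_matrices[[v]],
                         file.path(dir, paste0("features_", v, ".tsv")))
    wt(as_linkage_table(run$trees[[v]]), paste0("linkage_", v, ".tsv"))
    wt(run$nml[[v]], paste0("nml_", v, ".tsv"))
    wt(run$groups[[v]], paste0("groups_", v, ".tsv"))
  }
  invisible(dir)
}
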