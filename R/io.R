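#' Convert an exposure concentration to an areal dose
#'
#' Multiplies a medium concentration (ug/mL) by the exposure volume per
#' growth area (mL/cm^2) to give the deposited dose per growth area
#' (ug/cm^2). The default geometry, 0.2816 mL/cm^2, makes 125 and
#' 500 ug/mL correspond to 35.2 and 140.8 ug/cm^2.
#'
#' @param concentration Concentration in ug/mL (nonnegative).
#' @param volume_per_area Exposure volume per growth area in mL/cm^2.
#' @return Areal dose in ug/cm^2.
#' @export
#' @examples
#' convert_dose(c(125, 500))  # 35.2, 140.8
convert_dose <- function(concentration, volume_per_area = 0.2816) {
  if (any(concentration < 0)) stop("concentration must be nonnegative")
  if (any(volume_per_area < 0)) stop("volume_per_area must be nonnegative")
  concentration * volume_per_area
}

#' Write and read per-cell feature tables
#'
#' Plain CSV with one row per cell; writing then reading is lossless for
#' numeric features (full double precision is written).
#'
#' @param data Feature tibble.
#' @param path CSV path.
#' @return `write_feature_csv()` returns `path` invisibly;
#'   `read_feature_csv()` returns a tibble.
#' @export
write_feature_csv <- function(data, path) {
  readr::write_csv(data, path)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Write and read 16-bit label/intensity TIFF images
#'
#' Label masks and intensity images are stored as single-channel 16-bit
#' TIFFs (0 = background). Values are integers in `[0, 65535]`.
#'
#' @param img Integer matrix.
#' @param path TIFF path.
#' @return `write_mask_tiff()` returns `path` invisibly; `read_mask_tiff()`
#'   returns an integer matrix.
#' @export
write_mask_tiff <- function(img, path) {
  if (any(img < 0) || any(img > 65535)) stop("values outside 16-bit range")
  tiff::writeTIFF(img / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' @rdname write_mask_tiff
#' @export
read_mask_tiff <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- tiff::readTIFF(path)
  matrix(as.integer(round(img * 65535)), nrow(img), ncol(img))
}

#' Write a `morph_masks` object to a directory
#'
#' One cell-mask, nucleus-mask and damage TIFF per field, plus a
#' `cells.csv` ground-truth/metadata table.
#'
#' @param masks A `morph_masks` object from [generate_population()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_masks <- function(masks, dir) {
  stopifnot(inherits(masks, "morph_masks"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (f in seq_along(masks$fields)) {
    write_mask_tiff(masks$fields[[f]]$cell,
                    file.path(dir, sprintf("field%03d_cell.tif", f)))
    write_mask_tiff(masks$fields[[f]]$nucleus,
                    file.path(dir, sprintf("field%03d_nucleus.tif", f)))
    write_mask_tiff(masks$fields[[f]]$damage,
                    file.path(dir, sprintf("field%03d_damage.tif", f)))
  }
  readr::write_csv(masks$cells, file.path(dir, "cells.csv"))
  invisible(dir)
}

#' Read paired label masks (and metadata) from a directory
#'
#' Reads `field*_cell.tif` / `field*_nucleus.tif` / optional
#' `field*_damage.tif` triples written by [write_masks()] (or any files
#' following that naming convention) together with `cells.csv` metadata
#' when present. The metadata must cover every (field, label) pair; masks of
#' mismatched shape raise an error.
#'
#' @param dir Directory containing the TIFFs.
#' @return A `morph_masks` object.
#' @export
read_masks <- function(dir) {
  cell_files <- sort(list.files(dir, "_cell\\.tif$", full.names = TRUE))
  if (!length(cell_files)) stop("no *_cell.tif files in ", dir)
  fields <- purrr::map(cell_files, function(cf) {
    nf <- sub("_cell\\.tif$", "_nucleus.tif", cf)
    if (!file.exists(nf)) stop("missing nucleus mask for ", basename(cf))
    cell <- read_mask_tiff(cf)
    nucleus <- read_mask_tiff(nf)
    if (!all(dim(cell) == dim(nucleus))) {
      stop("shape mismatch between compartment masks for ", basename(cf))
    }
    df <- sub("_cell\\.tif$", "_damage.tif", cf)
    damage <- if (file.exists(df)) read_mask_tiff(df) else NULL
    list(cell = cell, nucleus = nucleus, damage = damage)
  })
  cells <- NULL
  meta_path <- file.path(dir, "cells.csv")
  if (file.exists(meta_path)) {
    cells <- readr::read_csv(meta_path, show_col_types = FALSE, progress = FALSE)
    if (!all(c("field", "label") %in% names(cells))) {
      stop("metadata schema error: cells.csv must contain columns ",
           "'field' and 'label'")
    }
    if (anyDuplicated(cells[c("field", "label")])) {
      stop("duplicate (field, label) pairs in metadata")
    }
  }
  structure(list(fields = fields, cells = cells,
                 field_size = nrow(fields[[1]]$cell)),
            class = "morph_masks")
}

#' Pipeline configuration
#'
#' Builds (and validates) the configuration used by [run_pipeline()].
#' Unknown keys are rejected. `config_from_yaml()` reads the same structure
#' from a YAML file.
#'
#' @param n_cells Cells in the simulated fixture.
#' @param seed Base seed for all stochastic stages.
#' @param volume_per_area Exposure geometry for [convert_dose()] (mL/cm^2).
#' @param umap_n_neighbors,umap_min_dist UMAP settings.
#' @param k_range Candidate cluster numbers for [select_k()].
#' @param kmeans_n_init k-means restarts for the final clustering.
#' @param select_n_init k-means restarts per candidate during k selection.
#' @param n_groups Number of cluster-groups, or `"auto"`.
#' @param entropy_base Logarithm base for Shannon entropy.
#' @param bootstrap_n Bootstrap replicates for score intervals (0 = none).
#' @return A named list of class `morph_config`.
#' @export
pipeline_config <- function(n_cells = 10000L, seed = 1L,
                            volume_per_area = 0.2816,
                            umap_n_neighbors = 30L, umap_min_dist = 0.1,
                            k_range = 2:20, kmeans_n_init = 50L,
                            select_n_init = 10L,
                            n_groups = "auto", entropy_base = exp(1),
                            bootstrap_n = 0L) {
  cfg <- list(n_cells = as.integer(n_cells), seed = as.integer(seed),
              volume_per_area = volume_per_area,
              umap_n_neighbors = as.integer(umap_n_neighbors),
              umap_min_dist = umap_min_dist,
              k_range = as.integer(k_range),
              kmeans_n_init = as.integer(kmeans_n_init),
              select_n_init = as.integer(select_n_init),
              n_groups = n_groups, entropy_base = entropy_base,
              bootstrap_n = as.integer(bootstrap_n))
  validate_config(cfg)
}

validate_config <- function(cfg) {
  known <- c("n_cells", "seed", "volume_per_area", "umap_n_neighbors",
             "umap_min_dist", "k_range", "kmeans_n_init", "select_n_init",
             "n_groups", "entropy_base", "bootstrap_n")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  stopifnot(cfg$n_cells >= 10, cfg$volume_per_area >= 0,
            cfg$umap_n_neighbors >= 2, cfg$umap_min_dist >= 0,
            all(cfg$k_range >= 2), cfg$kmeans_n_init >= 1,
            cfg$select_n_init >= 1, cfg$bootstrap_n >= 0)
  if (!identical(cfg$n_groups, "auto")) stopifnot(cfg$n_groups >= 1)
  structure(cfg, class = "morph_config")
}

#' @rdname pipeline_config
#' @param path YAML file with a subset of the configuration keys.
#' @export
config_from_yaml <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}
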