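# Features that can legitimately reach zero get a small log offset; strictly
# positive features are logged without one.
eps_defaults <- function(features) {
  zeroable <- c("cell_eccentricity", "nucleus_eccentricity",
                "centroid_displacement", "normalized_centroid_displacement",
                "cytoplasm_area")
  stats::setNames(ifelse(features %in% zeroable, 1e-6, 0), features)
}

#' Log-normalize and standardize a feature table
#'
#' Every morphology parameter is independently log-normalized:
#' `x -> log10(x + eps)`, then z-scored with the fitting-set mean and
#' standard deviation (`n - 1` denominator). Constant columns map to zeros.
#' The fitted transform (per-feature offset, mean, sd) is stored on the
#' result so it can be re-applied to new cells or inverted.
#'
#' @param data A data frame containing the columns of `features` (typically
#'   the output of [extract_features()] or [generate_population()]); other
#'   columns are carried through unchanged.
#' @param features Feature columns to normalize; defaults to the 33
#'   morphology parameters.
#' @param eps Named per-feature log offsets; by default `1e-6` for features
#'   that may reach zero (eccentricities, centroid displacements, cytoplasm
#'   area) and `0` for strictly positive ones.
#' @return A tibble of class `morph_norm_tbl` with the feature columns
#'   replaced by their normalized values and the fitted transform in
#'   `attr(, "transform")`.
#' @seealso [apply_normalization()], [invert_normalization()]
#' @export
normalize_features <- function(data, features = morph_feature_names(),
                               eps = eps_defaults(features)) {
  missing <- setdiff(features, names(data))
  if (length(missing)) stop("missing feature columns: ", paste(missing, collapse = ", "))
  eps <- eps[features]
  logged <- purrr::imap(data[features], function(x, nm) {
    if (any(x + eps[[nm]] <= 0)) {
      stop("feature '", nm, "' has nonpositive values with eps = ", eps[[nm]])
    }
    log10(x + eps[[nm]])
  })
  mu <- purrr::map_dbl(logged, mean)
  sdv <- purrr::map_dbl(logged, stats::sd)
  transform <- list(features = features, eps = eps, mean = mu, sd = sdv)
  out <- data
  out[features] <- purrr::imap(logged, function(x, nm) {
    if (sdv[[nm]] < .Machine$double.eps) rep(0, length(x))
    else (x - mu[[nm]]) / sdv[[nm]]
  })
  out <- tibble::as_tibble(out)
  attr(out, "transform") <- transform
  class(out) <- c("morph_norm_tbl", class(out))
  out
}

#' Apply a fitted normalization transform to new data
#'
#' @param transform A transform list as stored by [normalize_features()]
#'   (or a `morph_norm_tbl`, whose transform is reused).
#' @param data Data frame with the transform's feature columns.
#' @return A `morph_norm_tbl` normalized with the stored parameters.
#' @export
apply_normalization <- function(transform, data) {
  if (inherits(transform, "morph_norm_tbl")) transform <- attr(transform, "transform")
  out <- data
  for (nm in transform$features) {
    x <- log10(data[[nm]] + transform$eps[[nm]])
    out[[nm]] <- if (transform$sd[[nm]] < .Machine$double.eps) rep(0, length(x))
                 else (x - transform$mean[[nm]]) / transform$sd[[nm]]
  }
  out <- tibble::as_tibble(out)
  attr(out, "transform") <- transform
  class(out) <- c("morph_norm_tbl", class(out))
  out
}

#' Invert a fitted normalization transform
#'
#' Maps normalized features back to their original scale. Constant columns
#' (sd ~ 0) are restored to their fitting-set value.
#'
#' @inheritParams apply_normalization
#' @param data Data frame with normalized feature columns.
#' @return A tibble with the feature columns on the original scale.
#' @export
invert_normalization <- function(transform, data) {
  if (inherits(transform, "morph_norm_tbl")) transform <- attr(transform, "transform")
  out <- data
  for (nm in transform$features) {
    z <- data[[nm]]
    lg <- if (transform$sd[[nm]] < .Machine$double.eps) rep(transform$mean[[nm]], length(z))
          else z * transform$sd[[nm]] + transform$mean[[nm]]
    out[[nm]] <- 10^lg - transform$eps[[nm]]
  }
  tibble::as_tibble(out)
}

norm_feature_matrix <- function(data, features = NULL) {
  tr <- attr(data, "transform")
  if (is.null(features)) {
    features <- if (!is.null(tr)) tr$features else intersect(morph_feature_names(), names(data))
  }
  as.matrix(data[features])
}
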