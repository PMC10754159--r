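#' Susceptibility score from a three-dose CG1 trajectory
#'
#' Scores how early a population abandons the large, "healthy" CG1
#' morphologies as dose increases. With CG1 fractions `c`, `ul`, `uh` at
#' control, low and high dose,
#' `S_SC = ((ul - c) - (uh - ul)) / (uh - c)`.
#' For a monotone decline (`c >= ul >= uh`) this equals `(a - b)/(a + b)`
#' with `a = c - ul`, `b = ul - uh`, and is bounded in `[-1, 1]`:
#' +1 means the whole shift happens already at low dose (most susceptible),
#' -1 that it happens only at high dose (resilient). Non-monotone
#' trajectories are scored as printed but flagged. Populations with
#' `uh == c` have an undefined score (`NA`) with the reason recorded.
#'
#' @param data Data frame with columns `population`, `cg1_control`,
#'   `cg1_low`, `cg1_high` (fractions in `[0, 1]`). The profile output of
#'   [cluster_fractions()] can be reshaped into this form with
#'   [cg1_trajectory()].
#' @return The input tibble with `s_sc`, `monotone` and `score_note`
#'   columns appended.
#' @export
#' @examples
#' susceptibility_score(tibble::tibble(
#'   population = "clone", cg1_control = 0.6, cg1_low = 0.3, cg1_high = 0.1
#' ))  # s_sc = 0.2
susceptibility_score <- function(data) {
  req <- c("population", "cg1_control", "cg1_low", "cg1_high")
  missing <- setdiff(req, names(data))
  if (length(missing)) stop("missing columns: ", paste(missing, collapse = ", "))
  fr <- c(data$cg1_control, data$cg1_low, data$cg1_high)
  if (any(fr < -1e-12 | fr > 1 + 1e-12)) stop("CG1 fractions must lie in [0, 1]")

  num <- (data$cg1_low - data$cg1_control) - (data$cg1_high - data$cg1_low)
  den <- data$cg1_high - data$cg1_control
  undefined <- abs(den) < .Machine$double.eps
  s <- ifelse(undefined, NA_real_, num / den)
  if (any(undefined)) {
    message("undefined susceptibility score (CG1 high = CG1 control) for: ",
            paste(data$population[undefined], collapse = ", "))
  }
  dplyr::mutate(tibble::as_tibble(data),
                s_sc = s,
                monotone = .data$cg1_control >= .data$cg1_low &
                           .data$cg1_low >= .data$cg1_high,
                score_note = ifelse(undefined,
                                    "undefined: no net CG1 change control to high",
                                    NA_character_))
}

#' Reshape cluster-fraction profiles into CG1 dose trajectories
#'
#' Pulls the CG1 fraction at the control, low and high dose condition for
#' each population out of a [cluster_fractions()] profile table.
#'
#' @param profiles Profile tibble with `population`, `condition`, `p_cg1`.
#' @param conditions Named character vector mapping the three doses to
#'   condition labels, e.g.
#'   `c(control = "control", low = "urban_low", high = "urban_high")`.
#' @return Tibble: `population`, `cg1_control`, `cg1_low`, `cg1_high`.
#' @export
cg1_trajectory <- function(profiles,
                           conditions = c(control = "control",
                                          low = "urban_low",
                                          high = "urban_high")) {
  if (!"p_cg1" %in% names(profiles)) {
    stop("profiles lack a 'p_cg1' column; supply a cg_map to cluster_fractions()")
  }
  missing <- setdiff(conditions, unique(profiles$condition))
  if (length(missing)) stop("conditions absent from profiles: ",
                            paste(missing, collapse = ", "))
  profiles |>
    dplyr::filter(.data$condition %in% conditions) |>
    dplyr::mutate(dose = names(conditions)[match(.data$condition, conditions)]) |>
    dplyr::select("population", "dose", "p_cg1") |>
    tidyr::pivot_wider(names_from = "dose", values_from = "p_cg1",
                       names_prefix = "cg1_")
}

#' Normalize susceptibility scores to the parental population
#'
#' Subtracts the parental population's raw score, so the parental maps to 0
#' and more positive values indicate higher susceptibility relative to it.
#' Subtraction preserves the ordering of populations.
#'
#' @param scores Output of [susceptibility_score()].
#' @param parental_id Population id of the parental line.
#' @return `scores` with an `s_norm` column appended.
#' @export
normalize_to_parental <- function(scores, parental_id = "parental") {
  i <- match(parental_id, scores$population)
  if (is.na(i)) stop("parental population '", parental_id, "' not found")
  ref <- scores$s_sc[i]
  if (is.na(ref)) stop("parental population has an undefined score")
  dplyr::mutate(scores, s_norm = .data$s_sc - ref)
}

#' Rank populations by susceptibility
#'
#' Orders populations by decreasing normalized score (raw score when no
#' parental normalization was applied), most susceptible first. Ties are
#' broken by population id; populations with undefined scores are listed
#' last, keeping their `score_note`.
#'
#' @param scores Output of [susceptibility_score()] or
#'   [normalize_to_parental()].
#' @return The scores tibble sorted with a `rank` column (NA scores get NA
#'   rank), of class `morph_scores` (has an `autoplot()` method).
#' @export
rank_populations <- function(scores) {
  if (sum(!is.na(scores$s_sc)) < 2) {
    stop("need at least 2 populations with defined scores")
  }
  key <- if ("s_norm" %in% names(scores)) "s_norm" else "s_sc"
  out <- scores |>
    dplyr::arrange(is.na(.data[[key]]), dplyr::desc(.data[[key]]),
                   .data$population) |>
    dplyr::mutate(rank = ifelse(is.na(.data[[key]]), NA_integer_,
                                dplyr::row_number()))
  class(out) <- unique(c("morph_scores", class(out)))
  out
}

#' Bootstrap confidence intervals for susceptibility scores
#'
#' Uncertainty layer (an extension beyond the deterministic score):
#' resamples cells with replacement within each (population, dose), recomputes
#' the CG1 fractions and the score, and reports percentile intervals.
#'
#' @param cells Per-cell tibble with `population`, `condition` and `cg`
#'   columns (cluster-group id per cell).
#' @param conditions Dose-to-condition mapping as in [cg1_trajectory()].
#' @param n_boot Number of bootstrap replicates.
#' @param level Interval coverage.
#' @param seed Integer seed.
#' @return Tibble: `population`, `s_sc`, `ci_lo`, `ci_hi`, `n_boot`.
#' @export
susceptibility_bootstrap <- function(cells,
                                     conditions = c(control = "control",
                                                    low = "urban_low",
                                                    high = "urban_high"),
                                     n_boot = 1000L, level = 0.95, seed = 1L) {
  stopifnot(all(c("population", "condition", "cg") %in% names(cells)))
  cells <- dplyr::filter(cells, .data$condition %in% conditions)
  split_cells <- split(cells$cg == 1L,
                       list(cells$population, cells$condition), drop = TRUE)
  pops <- unique(cells$population)
  alpha <- (1 - level) / 2

  withr::with_seed(seed, {
    purrr::map_dfr(pops, function(p) {
      frac <- function(dose, resample = FALSE) {
        v <- split_cells[[paste(p, conditions[[dose]], sep = ".")]]
        if (is.null(v)) stop("no cells for ", p, " at ", conditions[[dose]])
        if (resample) v <- v[sample.int(length(v), replace = TRUE)]
        mean(v)
      }
      score <- function(resample = FALSE) {
        cc <- frac("control", resample); ul <- frac("low", resample)
        uh <- frac("high", resample)
        if (abs(uh - cc) < .Machine$double.eps) return(NA_real_)
        ((ul - cc) - (uh - ul)) / (uh - cc)
      }
      reps <- replicate(n_boot, score(resample = TRUE))
      tibble::tibble(population = p, s_sc = score(),
                     ci_lo = stats::quantile(reps, alpha, na.rm = TRUE,
                                             names = FALSE),
                     ci_hi = stats::quantile(reps, 1 - alpha, na.rm = TRUE,
                                             names = FALSE),
                     n_boot = n_boot)
    })
  })
}
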