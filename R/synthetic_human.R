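#' Illusion strength of a set of adjusted bar angles
#'
#' Perceived tilt is measured by a method of adjustment: an observer sets the
#' orientation of four comparison bars to match the perceived orientation of
#' the four stimulus bars. Illusion strength is the mean of the absolute
#' values of those four signed angles, which removes the direction of the
#' tilt (clockwise vs counterclockwise) and keeps its magnitude.
#'
#' @param angles A numeric vector of four signed angles in degrees, or a
#'   matrix / data frame with four columns (one row per record).
#' @return A non-negative numeric: one strength per record, in degrees.
#' @examples
#' illusion_strength(c(0.3, -0.5, 0.4, -0.2)) # 0.35
#' @export
illusion_strength <- function(angles) {
  if (is.data.frame(angles)) angles <- as.matrix(angles)
  if (is.matrix(angles)) {
    if (ncol(angles) != 4) stop("expected four angles per record", call. = FALSE)
    if (any(!is.finite(angles))) stop("angles must be finite", call. = FALSE)
    return(rowMeans(abs(angles)))
  }
  if (length(angles) != 4) stop("expected four angles", call. = FALSE)
  if (any(!is.finite(angles))) stop("angles must be finite", call. = FALSE)
  mean(abs(angles))
}

#' Bin an illusion strength into one of eight 0.1-degree levels
#'
#' Strengths are binned into eight levels of 0.1 degrees each over the 0-0.8
#' degree range observed in adjustment data. Bins are half-open on the left,
#' `((k-1) * 0.1, k * 0.1]`, so a strength of exactly 0.4 falls in level 4;
#' a strength of 0 is level 1 and anything above 0.8 is clamped to level 8.
#'
#' @param strength_deg Non-negative numeric vector of strengths in degrees.
#' @return Integer vector of levels in 1-8.
#' @examples
#' assign_level(c(0, 0.35, 0.4, 0.95)) # 1 4 4 8
#' @export
assign_level <- function(strength_deg) {
  if (any(!is.finite(strength_deg)) || any(strength_deg < 0)) {
    stop("strengths must be finite and non-negative", call. = FALSE)
  }
  lev <- ceiling(round(strength_deg / 0.1, 9))
  as.integer(pmin(pmax(lev, 1L), 8L))
}

#' Assign the no-illusion / with-illusion class for a level
#'
#' Levels 1-4 (strength at or below 0.4 degrees) are class C1, "No-illusion";
#' levels 5-8 (strength above 0.4 degrees) are class C2, "With-illusion".
#'
#' @param level Integer vector of levels in 1-8.
#' @return A factor with levels `C1`, `C2`.
#' @export
assign_class <- function(level) {
  if (any(!(level %in% 1:8))) stop("levels must be integers in 1..8", call. = FALSE)
  factor(ifelse(level <= 4, "C1", "C2"), levels = c("C1", "C2"))
}

#' Default per-condition mean tilt magnitudes
#'
#' A base table of mean perceived-tilt magnitudes (degrees) per hue and
#' diamond width, encoding the hue/width structure seen in adjustment data:
#' five hues (green, spring green, cyan, yellow-green, yellow) stay below the
#' 0.4-degree threshold at every width, while the remaining seven hues exceed
#' it at widths 5-8 px and drop below it at widths 9-10 px. Magnitudes fall
#' off with diamond width and all lie within 0-0.8 degrees.
#'
#' @param palette Hue tibble, as from [default_color_ring()].
#' @param widths Diamond widths the table should cover.
#' @return A tibble with columns `color_name`, `diamond_width_px`,
#'   `base_strength_deg`.
#' @export
default_base_table <- function(palette = default_color_ring(), widths = 5:10) {
  weak_hues <- c("green", "spring green", "cyan", "yellow-green", "yellow")
  # width profiles, degrees, widths 5..10
  weak_profile <- c(0.30, 0.28, 0.26, 0.24, 0.20, 0.16)
  strong_profile <- c(0.62, 0.58, 0.52, 0.46, 0.34, 0.26)
  tab <- tidyr::expand_grid(
    color_name = palette$name,
    diamond_width_px = as.integer(widths)
  )
  # small deterministic per-hue offset for realistic between-hue variation,
  # kept well clear of the 0.4-degree boundary
  offset <- stats::setNames(
    rep_len(c(0.02, -0.02, 0, 0.01, -0.01), length(palette$name)),
    palette$name
  )
  idx <- match(tab$diamond_width_px, widths)
  base <- ifelse(tab$color_name %in% weak_hues,
    weak_profile[idx], strong_profile[idx]
  )
  tab$base_strength_deg <- unname(
    pmin(pmax(base + offset[tab$color_name], 0), 0.8)
  )
  tab
}

#' Response-model parameters for synthetic adjustment data
#'
#' @param base_strength Tibble mapping (hue, diamond width) to the mean
#'   perceived-tilt magnitude in degrees; see [default_base_table()].
#' @param participant_sd_deg Per-bar Gaussian adjustment noise, degrees.
#'   The default matches the fine adjustment step of the procedure.
#' @param n_participants Number of simulated observers.
#' @param seed Integer seed for the simulation.
#' @return A list of class `response_model_params`.
#' @export
response_model_params <- function(base_strength = default_base_table(),
                                  participant_sd_deg = 0.1,
                                  n_participants = 23L,
                                  seed = 1L) {
  stopifnot(
    n_participants >= 1, participant_sd_deg >= 0,
    all(base_strength$base_strength_deg >= 0),
    all(base_strength$base_strength_deg <= 0.8)
  )
  structure(
    list(
      base_strength = base_strength,
      participant_sd_deg = as.numeric(participant_sd_deg),
      n_participants = as.integer(n_participants),
      seed = as.integer(seed)
    ),
    class = "response_model_params"
  )
}

#' Simulate method-of-adjustment responses for a stimulus grid
#'
#' For every stimulus and simulated participant, draws four signed bar angles
#' whose mean magnitude is the base-table value for that (hue, width), with
#' independent Gaussian noise per bar. The sign follows the positional
#' setting: setting I induces clockwise (positive) perceived tilt, setting II
#' counterclockwise (negative).
#'
#' @param grid Stimulus grid from [enumerate_stimulus_grid()].
#' @param params A [response_model_params()] object.
#' @return A tibble of perceptual records: `stimulus_id`, `color_name`,
#'   `diamond_width_px`, `setting`, `participant_id`, `angle1`-`angle4`.
#' @export
simulate_responses <- function(grid, params = response_model_params()) {
  stopifnot(inherits(params, "response_model_params"))
  key <- paste(grid$color_name, grid$diamond_width_px)
  bkey <- paste(
    params$base_strength$color_name,
    params$base_strength$diamond_width_px
  )
  idx <- match(key, bkey)
  if (any(is.na(idx))) {
    stop(
      "base table is missing conditions: ",
      paste(unique(key[is.na(idx)]), collapse = ", "),
      call. = FALSE
    )
  }
  base <- params$base_strength$base_strength_deg[idx]
  sign <- ifelse(grid$setting == "I", 1, -1)
  n_p <- params$n_participants
  n_s <- nrow(grid)

  noise <- with_seed(
    params$seed,
    array(
      stats::rnorm(n_s * n_p * 4, sd = params$participant_sd_deg),
      dim = c(n_s, n_p, 4)
    )
  )

  rec <- tidyr::expand_grid(
    dplyr::select(
      grid, "stimulus_id", "color_name", "diamond_width_px", "setting"
    ),
    participant_id = seq_len(n_p)
  )
  s_idx <- rep(seq_len(n_s), each = n_p)
  p_idx <- rep(seq_len(n_p), times = n_s)
  for (a in 1:4) {
    rec[[paste0("angle", a)]] <-
      sign[s_idx] * base[s_idx] + noise[cbind(s_idx, p_idx, a)]
  }
  rec
}

#' Aggregate perceptual records into per-stimulus strengths
#'
#' Per stimulus: the strength is the across-participant mean of each record's
#' illusion strength (mean absolute angle); the level and C1/C2 class are
#' assigned from that mean. Signed per-bar means are retained for rendering
#' perceived-tilt counterparts of each stimulus.
#'
#' @param records Perceptual-record tibble from [simulate_responses()] or
#'   [read_angle_csv()].
#' @return A tibble with one row per stimulus: identification columns,
#'   `strength_deg`, `level`, `illusion_class`, `n_participants` and
#'   `mean_angle1`-`mean_angle4` (signed means, degrees).
#' @export
aggregate_strengths <- function(records) {
  if (nrow(records) == 0) stop("no perceptual records supplied", call. = FALSE)
  per_rec <- illusion_strength(
    as.matrix(records[, paste0("angle", 1:4)])
  )
  records$`..strength` <- per_rec
  id_cols <- intersect(
    c("stimulus_id", "color_name", "diamond_width_px", "setting"),
    names(records)
  )
  out <- dplyr::summarise(
    dplyr::group_by(records, dplyr::across(dplyr::all_of(id_cols))),
    strength_deg = mean(.data$`..strength`),
    dplyr::across(dplyr::all_of(paste0("angle", 1:4)), mean,
      .names = "mean_{.col}"
    ),
    n_participants = dplyr::n(),
    .groups = "drop"
  )
  out$level <- assign_level(out$strength_deg)
  out$illusion_class <- assign_class(out$level)
  class(out) <- c("illusion_strengths", class(out))
  out
}

#' Read / write perceptual-angle tables as CSV
#'
#' The on-disk format has one row per (stimulus, participant):
#' `stimulus_id, participant_id, angle1..angle4`, plus any extra
#' identification columns present.
#'
#' @param path CSV file path.
#' @param records A perceptual-record tibble.
#' @return `read_angle_csv()` returns a tibble; `write_angle_csv()` returns
#'   `path` invisibly.
#' @export
read_angle_csv <- function(path) {
  rec <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("stimulus_id", "participant_id", paste0("angle", 1:4))
  missing <- setdiff(need, names(rec))
  if (length(missing) > 0) {
    stop("angle CSV is missing columns: ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  rec
}

#' @rdname read_angle_csv
#' @export
write_angle_csv <- function(records, path) {
  readr::write_csv(records, path)
  invisible(path)
}
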