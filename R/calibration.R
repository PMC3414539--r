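#' Load a science-perception survey table
#'
#' Reads a survey CSV with columns `survey_id,label,text,yes_pct,no_pct` and
#' validates it. The packaged identifiers `"EU"` (Eurobarometer) and `"Mx"`
#' (Mexican national survey) load the transcribed 15-statement tables that
#' pair equivalent statements from the two questionnaires, ordered from
#' blatant fallacies to obvious facts. The residual answer mass
#' ("do not know" / "neither") is derived as `other_pct = 100 - yes - no`
#' and is never used in the agreement fraction.
#'
#' @param source `"EU"`, `"Mx"`, or a path to a CSV file.
#' @return a `survey_table`: data.frame with columns `survey_id`, `label`,
#'   `text`, `yes_pct`, `no_pct`, `other_pct`.
#' @export
load_survey <- function(source) {
  path <- switch(source,
    EU = system.file("extdata", "survey_eu.csv", package = "opinionfield"),
    Mx = system.file("extdata", "survey_mx.csv", package = "opinionfield"),
    source
  )
  if (!file.exists(path)) {
    stop("survey file not found: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("survey_id", "label", "text", "yes_pct", "no_pct")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0L) {
    stop("survey is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (r in seq_len(nrow(df))) {
    y <- df$yes_pct[r]; n <- df$no_pct[r]
    if (!is.finite(y) || !is.finite(n) || y < 0 || n < 0) {
      stop(sprintf("validation error in row '%s': negative or missing percentage",
                   df$label[r]), call. = FALSE)
    }
    if (y + n > 100 + 1e-9) {
      stop(sprintf("validation error in row '%s': yes + no = %g exceeds 100",
                   df$label[r], y + n), call. = FALSE)
    }
  }
  if (anyDuplicated(df$label)) {
    stop("validation error: duplicate statement label '",
         df$label[duplicated(df$label)][1L], "'", call. = FALSE)
  }
  df$other_pct <- 100 - df$yes_pct - df$no_pct
  class(df) <- c("survey_table", "data.frame")
  df
}

#' Agreement fraction of a statement
#'
#' Agreement and disagreement percentages normalised by their sum,
#' `n_A = yes / (yes + no)`, excluding the protocol-dependent residual
#' answers. Vectorised.
#'
#' @param yes_pct,no_pct non-negative percentages.
#' @return agreement fractions in `[0, 1]`.
#' @export
agreement_fraction <- function(yes_pct, no_pct) {
  if (any(yes_pct < 0 | no_pct < 0)) {
    stop("percentages must be non-negative", call. = FALSE)
  }
  tot <- yes_pct + no_pct
  if (any(tot == 0)) {
    stop("agreement fraction undefined: yes + no = 0", call. = FALSE)
  }
  yes_pct / tot
}

#' Monte-Carlo response curve <n+>(h)
#'
#' Runs the simulator over an ordered field grid, `replicates` independent
#' seeds per grid point, and records the final model agreement fraction
#' `n+` of each run. Per-point means are then smoothed with isotonic
#' regression (the model response is monotone in `h`, but finite ensembles
#' need not be) and linearly interpolated into an invertible non-decreasing
#' fit. The per-run seeds are derived from `params$seed` and stored, so the
#' same configuration always reproduces the same curve.
#'
#' By default `n+` counts decided agents only (`n_plus_mode = "frozen"`),
#' the analogue of the survey normalisation that drops "do not know"
#' answers; runs in which no agent froze fall back to the all-agent count.
#'
#' @param params a [model_params()]; `params$field` is overridden by the
#'   grid. Calibration is run at a single closure mix `q` (the response
#'   depends only weakly on it); set it via `params$closure_mix`.
#' @param h_grid ordered field values, default `seq(-3, 6, by = 0.75)`.
#' @param replicates runs per grid point.
#' @param n_plus_mode `"frozen"` (default) or `"all"`.
#' @return object of class `response_curve`: list with `h_grid`,
#'   `mean_agreement`, `sd_agreement`, `fitted` (isotonic values),
#'   `replicates`, `seeds` (matrix), `n_plus_mode`, and `fit` (a
#'   non-decreasing interpolating function of `h`).
#' @export
build_response_curve <- function(params,
                                 h_grid = seq(-3, 6, by = 0.75),
                                 replicates = 8L,
                                 n_plus_mode = c("frozen", "all")) {
  n_plus_mode <- match.arg(n_plus_mode)
  if (replicates < 1L) stop("replicates must be >= 1", call. = FALSE)
  if (is.unsorted(h_grid, strictly = TRUE)) {
    stop("h_grid must be strictly increasing", call. = FALSE)
  }
  seeds <- matrix(params$seed + outer(seq_along(h_grid) * 1000L,
                                      seq_len(replicates)),
                  nrow = length(h_grid))
  vals <- matrix(NA_real_, length(h_grid), replicates)
  for (i in seq_along(h_grid)) {
    for (r in seq_len(replicates)) {
      p <- params
      p$field <- h_grid[i]
      p$seed <- seeds[i, r]
      res <- run_simulation(p)
      np <- n_plus(res$states, n_plus_mode)
      if (is.na(np)) np <- n_plus(res$states, "all")
      vals[i, r] <- np
    }
  }
  mean_agreement <- rowMeans(vals)
  iso <- stats::isoreg(h_grid, mean_agreement)
  fitted <- iso$yf
  structure(list(h_grid = h_grid,
                 mean_agreement = mean_agreement,
                 sd_agreement = apply(vals, 1L, stats::sd),
                 fitted = fitted,
                 replicates = as.integer(replicates),
                 seeds = seeds,
                 n_plus_mode = n_plus_mode,
                 fit = stats::approxfun(h_grid, fitted, rule = 2)),
            class = "response_curve")
}

#' @export
print.response_curve <- function(x, ...) {
  cat(sprintf(paste0("response_curve: %d grid points on [%.3g, %.3g], ",
                     "%d replicates, <n+> in [%.3f, %.3f]\n"),
              length(x$h_grid), min(x$h_grid), max(x$h_grid), x$replicates,
              min(x$fitted), max(x$fitted)))
  invisible(x)
}

# invert the monotone fit: n_A -> h; flat segments collapse to their mean h
invert_response <- function(curve, n_a) {
  fy <- curve$fitted
  if (diff(range(fy)) < 1e-8) {
    stop("degenerate response curve: fitted agreement is constant",
         call. = FALSE)
  }
  agg <- tapply(curve$h_grid, fy, mean)
  ux <- as.numeric(names(agg))
  uh <- as.numeric(agg)
  h <- stats::approx(ux, uh, xout = n_a, rule = 2)$y
  clamped <- n_a < min(fy) | n_a > max(fy)
  # out-of-range fractions clamp to the nearest grid endpoint
  h[n_a < min(fy)] <- curve$h_grid[1L]
  h[n_a > max(fy)] <- curve$h_grid[length(curve$h_grid)]
  list(h = h, clamped = clamped)
}

#' Assign a field strength to each survey statement
#'
#' Inverts the monotone response curve at each statement's agreement
#' fraction `n_A = yes/(yes + no)`, so that the survey fraction and the
#' model fraction coincide. Fractions outside the calibrated range are
#' clamped to the nearest grid endpoint and flagged.
#'
#' @param table a [load_survey()] table.
#' @param curve a [build_response_curve()] result.
#' @return a `field_assignment`: data.frame with `survey_id`, `label`,
#'   `n_a`, `h`, `clamped`, in the input row order.
#' @export
assign_fields <- function(table, curve) {
  n_a <- agreement_fraction(table$yes_pct, table$no_pct)
  inv <- invert_response(curve, n_a)
  out <- data.frame(survey_id = table$survey_id,
                    label = table$label,
                    n_a = n_a,
                    h = inv$h,
                    clamped = inv$clamped)
  class(out) <- c("field_assignment", "data.frame")
  out
}

#' Synthetic survey generated by the model itself
#'
#' Produces a survey table whose "statements" are independent simulation
#' runs at a known field `h_star`: `yes` is the percentage of experts,
#' `no` the percentage of fundamentalists, the undecided remainder playing
#' the role of "do not know". Used for round-trip parameter recovery --
#' assigning fields to this table should recover `h_star`.
#'
#' @param params a [model_params()].
#' @param h_star generating field strength.
#' @param n_statements number of replicate rows.
#' @param seed_offset added to `params$seed` to decorrelate from the
#'   calibration curve's own seeds.
#' @return a `survey_table` with `survey_id = "synthetic"`.
#' @export
model_survey <- function(params, h_star, n_statements = 10L,
                         seed_offset = 777000L) {
  rows <- lapply(seq_len(n_statements), function(r) {
    p <- params
    p$field <- h_star
    p$seed <- params$seed + seed_offset + r
    res <- run_simulation(p)
    fr <- res$states$frozen
    data.frame(survey_id = "synthetic",
               label = sprintf("rep%02d", r),
               text = sprintf("model-generated replicate %d at h = %g",
                              r, h_star),
               yes_pct = 100 * mean(fr & res$states$opinion > 0),
               no_pct = 100 * mean(fr & res$states$opinion < 0))
  })
  df <- do.call(rbind, rows)
  df$other_pct <- 100 - df$yes_pct - df$no_pct
  class(df) <- c("survey_table", "data.frame")
  df
}
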