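#' A 12 x 25 m maximal swim test record
#'
#' Twelve consecutive maximal 25 m efforts separated by short passive rests;
#' the standard field test for locating a swimmer's critical speed and the
#' exercise-intensity-domain boundaries.
#'
#' @param lap_times twelve lap durations in seconds, all positive.
#' @param lap_distance lap length in meters (default 25).
#' @param rest_between rest between efforts in seconds (informational,
#'   default 5).
#' @param swimmer_id,stroke optional identifiers.
#' @return a `SwimTestRecord`.
#' @export
swim_test_record <- function(lap_times, lap_distance = 25, rest_between = 5,
                             swimmer_id = NA_character_,
                             stroke = NA_character_) {
  if (length(lap_times) != 12) {
    stop("a 12 x 25 m test needs exactly 12 lap times, got ",
         length(lap_times), call. = FALSE)
  }
  if (any(!is.finite(lap_times)) || any(lap_times <= 0)) {
    stop("lap times must all be positive", call. = FALSE)
  }
  structure(list(lap_times = as.numeric(lap_times),
                 lap_distance = lap_distance, rest_between = rest_between,
                 swimmer_id = swimmer_id, stroke = stroke),
            class = "SwimTestRecord")
}

lap_speeds <- function(record) record$lap_distance / record$lap_times

#' Peak speed: mean speed of the first 25 m effort
#' @param record a `SwimTestRecord`
#' @return peak speed in m/s
#' @export
compute_peak_speed <- function(record) {
  record$lap_distance / record$lap_times[1]
}

#' Critical speed from the 12 x 25 m test
#'
#' Mean speed of the slowest two 25 m efforts within the final four efforts
#' (laps 9-12): the two largest times are taken (ties resolved by the
#' descending sort, which cannot change the outcome since only the values
#' enter), each converted to speed, and the speeds averaged.
#'
#' @param record a `SwimTestRecord`
#' @return critical speed in m/s
#' @export
compute_critical_speed <- function(record) {
  final_four <- record$lap_times[9:12]
  slowest_two <- sort(final_four, decreasing = TRUE)[1:2]
  mean(record$lap_distance / slowest_two)
}

#' Drop-off percentage between peak speed and critical speed
#'
#' `100 * (peak - cs) / peak`. A CS above peak signals a pacing problem
#' (the test assumes the first effort is the fastest); the negative value
#' is returned with a warning as a data-quality signal.
#'
#' @param peak peak speed, m/s (> 0).
#' @param cs critical speed, m/s.
#' @return drop-off percent.
#' @export
compute_dropoff <- function(peak, cs) {
  if (peak <= 0) stop("peak speed must be positive", call. = FALSE)
  if (cs > peak) {
    warning("critical speed exceeds peak speed: check pacing", call. = FALSE)
  }
  100 * (peak - cs) / peak
}

# Cumulative swim time at each lap midpoint. Rests are excluded by default:
# the speed-time model describes swimming, not standing at the wall.
lap_midpoints <- function(record, include_rest = FALSE) {
  swim <- record$lap_times
  gap <- if (include_rest) record$rest_between else 0
  starts <- c(0, cumsum(swim + gap))[seq_along(swim)]
  starts + swim / 2
}

#' Exponential speed-time model of the 12 x 25 m test
#'
#' Nonlinear least-squares fit of `S(t) = a * exp(b * t) + c` to the lap
#' speeds against cumulative swim time at each lap midpoint
#' (Levenberg-Marquardt; initialized at `a = S1 - S12`, `b = -1/t1`,
#' `c = S12`; converged when the relative SSE change drops below 1e-10 or
#' after 500 iterations). Constant-speed data leave `b` unidentifiable: the
#' degenerate fit `a = 0, c = mean speed` is returned flagged. A fitted
#' `b >= 0` (non-decaying speed) is flagged as well.
#'
#' @param record a `SwimTestRecord`.
#' @param include_rest include the rest periods in the time axis
#'   (sensitivity analysis; default `FALSE`).
#' @return list with `a`, `b`, `c`, `sse`, `converged`, `flags` and the
#'   `(t, speed)` points used.
#' @export
fit_speed_time_model <- function(record, include_rest = FALSE) {
  s <- lap_speeds(record)
  t <- lap_midpoints(record, include_rest)
  if (length(unique(round(s, 12))) < 3) {
    return(list(a = 0, b = NA_real_, c = mean(s), sse = 0,
                converged = TRUE, flags = "constant-speed: b unidentifiable",
                t = t, speed = s))
  }
  t1 <- sum(record$lap_times)
  start <- list(a = s[1] - s[12], b = -1 / t1, c = s[12])
  fit <- tryCatch(
    minpack.lm::nlsLM(speed ~ a * exp(b * t) + c,
                      data = data.frame(t = t, speed = s), start = start,
                      control = minpack.lm::nls.lm.control(
                        maxiter = 500, ftol = 1e-10)),
    error = function(e) NULL)
  if (is.null(fit)) {
    stop("speed-time model did not converge; start values: a=",
         signif(start$a, 4), " b=", signif(start$b, 4), " c=",
         signif(start$c, 4), call. = FALSE)
  }
  cf <- stats::coef(fit)
  flags <- character(0)
  if (cf[["b"]] >= 0) flags <- "non-decaying fit (b >= 0)"
  list(a = cf[["a"]], b = cf[["b"]], c = cf[["c"]],
       sse = sum(stats::resid(fit)^2), converged = TRUE,
       flags = if (length(flags)) flags else NA_character_,
       t = t, speed = s)
}

#' Distance capacity above critical speed (D')
#'
#' The area between the fitted speed-time curve and the critical-speed line
#' over the test: `D' = integral over [0, t1] of max(S(t) - CS, 0) dt` with
#' `S(t) = a e^{bt} + c`, evaluated in closed form. When the curve crosses
#' CS at `t* = ln((CS - c)/a)/b` before `t1`, integration stops there;
#' when the curve stays above CS the full `[0, t1]` contributes.
#'
#' @param model list with `a`, `b` (< 0), `c` (as from
#'   [fit_speed_time_model()]).
#' @param cs critical speed, m/s.
#' @param t1 total swim time at the end of effort 12, seconds.
#' @return D' in meters (>= 0).
#' @export
compute_d_prime <- function(model, cs, t1) {
  a <- model$a; b <- model$b; cc <- model$c
  if (a == 0) {
    return(max(cc - cs, 0) * t1)
  }
  if (is.na(b) || b >= 0) {
    stop("D' requires a decaying speed-time model (b < 0)", call. = FALSE)
  }
  # antiderivative of S(t) - CS
  F <- function(t) (a / b) * exp(b * t) + (cc - cs) * t
  ratio <- (cs - cc) / a
  t_cross <- if (ratio > 0 && ratio < 1) log(ratio) / b else NA_real_
  excess0 <- a + cc - cs                 # S(0) - CS
  if (is.finite(t_cross) && t_cross > 0) {
    # S is monotone under b < 0: above CS before the crossing when decaying
    # (a > 0), after it when rising (a < 0)
    bounds <- if (a > 0) c(0, min(t1, t_cross)) else c(min(t1, t_cross), t1)
  } else {
    bounds <- if (excess0 > 0) c(0, t1) else c(0, 0)
  }
  max(F(bounds[2]) - F(bounds[1]), 0)
}

#' Discrete per-lap variant of D'
#'
#' Sums lap-by-lap excess distance above CS:
#' `sum over laps of max(S_lap - CS, 0) * lap_time`. Serves as a
#' model-free cross-check of the closed-form integral.
#'
#' @param record a `SwimTestRecord`.
#' @param cs critical speed, m/s.
#' @return D' in meters.
#' @export
compute_d_prime_discrete <- function(record, cs) {
  s <- lap_speeds(record)
  sum(pmax(s - cs, 0) * record$lap_times)
}

#' Full 12 x 25 m test analysis
#'
#' Peak speed, critical speed, drop-off, the exponential speed-time model
#' and D' (closed-form and discrete) for one record.
#'
#' @param record a `SwimTestRecord`.
#' @param include_rest passed to [fit_speed_time_model()].
#' @return a `CritSpeedResult` list.
#' @export
analyze_swim_test <- function(record, include_rest = FALSE) {
  peak <- compute_peak_speed(record)
  cs <- compute_critical_speed(record)
  dropoff <- compute_dropoff(peak, cs)
  model <- fit_speed_time_model(record, include_rest)
  t1 <- sum(record$lap_times)
  d_prime <- if (!is.na(model$b) && model$b < 0) {
    compute_d_prime(model, cs, t1)
  } else {
    compute_d_prime_discrete(record, cs)
  }
  structure(list(swimmer_id = record$swimmer_id, stroke = record$stroke,
                 peak_speed = peak, cs = cs, dropoff = dropoff,
                 model = model[c("a", "b", "c")], t1 = t1,
                 d_prime = d_prime,
                 d_prime_discrete = compute_d_prime_discrete(record, cs),
                 flags = model$flags),
            class = "CritSpeedResult")
}

#' @export
print.CritSpeedResult <- function(x, ...) {
  cat(sprintf(
    "CritSpeedResult%s: peak %.3f m/s, CS %.3f m/s, drop-off %.1f%%, D' %.1f m\n",
    if (is.na(x$swimmer_id)) "" else paste0(" [", x$swimmer_id, "]"),
    x$peak_speed, x$cs, x$dropoff, x$d_prime))
  invisible(x)
}

#' Analyze a lap-time CSV of 12 x 25 m tests
#'
#' Input columns: `swimmer_id`, `stroke`, `lap_index` (1-12), `lap_time_s`.
#' One result row per swimmer is returned (and optionally written):
#' `swimmer_id, stroke, peak_speed, cs, dropoff_pct, a, b, c, t1, d_prime`.
#'
#' @param path input CSV.
#' @param out_path optional output CSV.
#' @return data.frame of per-swimmer results.
#' @export
analyze_swim_csv <- function(path, out_path = NULL) {
  df <- utils::read.csv(path)
  need <- c("swimmer_id", "lap_index", "lap_time_s")
  if (!all(need %in% names(df))) {
    stop("lap-time CSV needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!"stroke" %in% names(df)) df$stroke <- NA_character_
  res <- lapply(split(df, df$swimmer_id), function(d) {
    d <- d[order(d$lap_index), ]
    r <- analyze_swim_test(swim_test_record(
      d$lap_time_s, swimmer_id = as.character(d$swimmer_id[1]),
      stroke = as.character(d$stroke[1])))
    data.frame(swimmer_id = r$swimmer_id, stroke = r$stroke,
               peak_speed = r$peak_speed, cs = r$cs,
               dropoff_pct = r$dropoff, a = r$model$a, b = r$model$b,
               c = r$model$c, t1 = r$t1, d_prime = r$d_prime)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  if (!is.null(out_path)) utils::write.csv(out, out_path, row.names = FALSE)
  out
}
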