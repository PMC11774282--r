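# Up-and-down von Frey threshold procedure and the saline-concentration
# pain-grade map.
#
# Starting from the smallest filament, a negative response ("O") steps to
# the next larger filament and a positive response ("X") to the next
# smaller one (clamped at the series ends). Once the first adjacent "OX" or
# "XO" pair is observed, exactly four additional stimulations are applied
# under the same rule, and the threshold is read from the resulting
# sequence.

#' Default von Frey filament series
#'
#' @param forces Strictly increasing filament forces in grams.
#' @return Object of class `filament_series`.
#' @export
filament_series <- function(forces = c(0.02, 0.04, 0.07, 0.16, 0.4, 0.6, 1.0, 1.4)) {
  if (any(forces <= 0)) stop("filament forces must be positive")
  if (any(diff(forces) <= 0)) stop("filament forces must be strictly increasing")
  structure(list(forces = forces), class = "filament_series")
}

#' Run one up-and-down session against a responder
#'
#' @param responder Function `force -> "O"/"X"` (may be stochastic; seed the
#'   RNG outside if reproducibility is needed).
#' @param series A [filament_series()].
#' @param start_index 0-based index of the first filament applied
#'   (default 0, i.e. the smallest).
#' @param max_stimulations Cap on total stimulations before declaring the
#'   responder degenerate (default 50).
#' @return Object of class `updown_session`: list with `stimuli` (forces),
#'   `responses` (character vector over O/X), `reversal_index` (position of
#'   the first element of the first reversal pair) and `threshold_g`.
#' @export
run_updown <- function(responder, series = filament_series(),
                       start_index = 0L, max_stimulations = 50L) {
  forces <- series$forces
  k <- length(forces)
  idx <- start_index + 1L
  if (idx < 1L || idx > k) stop("start_index out of range")
  stimuli <- numeric(0)
  responses <- character(0)
  reversal <- NA_integer_
  post <- 0L
  while (length(stimuli) < max_stimulations) {
    f <- forces[idx]
    r <- responder(f)
    if (!r %in% c("O", "X")) stop("responder must return 'O' or 'X'")
    stimuli <- c(stimuli, f)
    responses <- c(responses, r)
    n <- length(responses)
    if (is.na(reversal) && n >= 2L && responses[n] != responses[n - 1L])
      reversal <- n - 1L
    if (!is.na(reversal)) {
      post <- n - (reversal + 1L)
      if (post >= 4L) break
    }
    idx <- if (r == "O") min(idx + 1L, k) else max(idx - 1L, 1L)
  }
  if (is.na(reversal) || post < 4L)
    stop(sprintf("no reversal with four follow-up stimulations within %d stimulations: degenerate responder (responses all '%s'?)",
                 max_stimulations, responses[1]))
  session <- structure(list(stimuli = stimuli, responses = responses,
                            reversal_index = reversal,
                            series = series, threshold_g = NA_real_),
                       class = "updown_session")
  session$threshold_g <- threshold_from_sequence(session)
  session
}

#' Read the facial pain threshold from an up-down sequence
#'
#' The decision window starts at the second element of the first reversal
#' pair (the response that completed the first "OX"/"XO") and covers the
#' four additional stimulations; the threshold is the smallest force that
#' elicited a positive response within that window — the least force that
#' reliably evokes withdrawal.
#'
#' @param session An `updown_session`, or a list with `stimuli`,
#'   `responses` (reversal index recomputed if absent).
#' @return Threshold in grams.
#' @export
threshold_from_sequence <- function(session) {
  st <- session$stimuli
  rs <- session$responses
  if (length(st) != length(rs)) stop("stimuli and responses differ in length")
  rev_i <- session$reversal_index
  if (is.null(rev_i) || is.na(rev_i)) {
    flips <- which(rs[-1] != rs[-length(rs)])
    if (length(flips) == 0) stop("session contains no reversal")
    rev_i <- flips[1]
  }
  if (length(rs) < rev_i + 5L)
    stop("malformed session: four stimulations must follow the first reversal")
  window <- (rev_i + 1L):(rev_i + 5L)
  pos <- window[rs[window] == "X"]
  if (length(pos) == 0)
    stop("no positive response in the post-reversal window")
  min(st[pos])
}

#' Map saline concentration to pain grade
#'
#' 0.9% maps to NP (0); 6%, 12% and 18% to MP (1); 25% and 30% to HP (2).
#' Unknown concentrations are an error: the grading is defined only for the
#' calibrated concentration groups, with no interpolation.
#'
#' @param conc NaCl concentration in percent.
#' @return Integer grade (0/1/2), named NP/MP/HP.
#' @export
grade_from_concentration <- function(conc) {
  map <- c("0.9" = 0L, "6" = 1L, "12" = 1L, "18" = 1L, "25" = 2L, "30" = 2L)
  key <- format(conc, trim = TRUE, scientific = FALSE)
  key <- sub("\\.0+$", "", key)
  if (!key %in% names(map))
    stop(sprintf("unknown saline concentration %s%%: must be one of 0.9, 6, 12, 18, 25, 30", key))
  g <- map[[key]]
  stats::setNames(g, names(pain_grades())[g + 1L])
}

#' Simulate many up-down sessions with a logistic responder
#'
#' Convenience wrapper used for parameter-recovery checks: the responder
#' answers "X" with probability `plogis(slope * (log(f) - log(f_star)))`.
#'
#' @param f_star Centre of the logistic response curve in grams.
#' @param n_sessions Number of sessions.
#' @param slope Logistic slope on the log-force scale.
#' @param series A [filament_series()].
#' @param seed Integer seed.
#' @return Numeric vector of recovered thresholds (failed, i.e. degenerate,
#'   sessions are dropped).
#' @export
simulate_updown <- function(f_star, n_sessions = 500L, slope = 8,
                            series = filament_series(), seed = 1L) {
  out <- numeric(0)
  for (i in seq_len(n_sessions)) {
    th <- with_seed(derive_seed(seed, 404L, i), {
      responder <- function(f)
        if (runif(1) < stats::plogis(slope * (log(f) - log(f_star)))) "X" else "O"
      tryCatch(run_updown(responder, series)$threshold_g,
               error = function(e) NA_real_)
    })
    out <- c(out, th)
  }
  out[!is.na(out)]
}

#' @export
print.updown_session <- function(x, ...) {
  cat("<updown_session>\n")
  cat("  forces:   ", paste(format(x$stimuli), collapse = " "), "\n")
  cat("  responses:", paste(x$responses, collapse = " "), "\n")
  cat(sprintf("  first reversal at stimulation %d; threshold %g g\n",
              x$reversal_index, x$threshold_g))
  invisible(x)
}

#' Run up-down sessions from a CSV of recorded trials
#'
#' The CSV must have columns `session`, `force`, `response` (O/X) in trial
#' order; each session's threshold is computed with
#' [threshold_from_sequence()].
#'
#' @param path Input CSV path.
#' @return data.frame with one row per session: `session`, `threshold_g`.
#' @export
updown_from_csv <- function(path) {
  df <- read.csv(path)
  ids <- unique(df$session)
  res <- lapply(ids, function(id) {
    d <- df[df$session == id, ]
    th <- threshold_from_sequence(list(stimuli = d$force,
                                       responses = as.character(d$response)))
    data.frame(session = id, threshold_g = th)
  })
  do.call(rbind, res)
}
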