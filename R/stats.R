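#' Exact binomial test (two-sided, small-probability-mass method)
#'
#' Tests the observed success count against Binomial(n, p0). The two-sided
#' p-value is the sum of all point probabilities not exceeding that of the
#' observed count (with the customary (1 + 1e-7) relative tolerance for
#' floating-point ties) -- the same two-sided convention as R's
#' `binom.test`, stated explicitly because two-sided exact binomial
#' definitions differ between packages.
#'
#' @param successes Observed successes, `0 <= successes <= n`.
#' @param n Number of trials, >= 1.
#' @param p0 Null success probability (default 0.5).
#' @return A `binomial_test_result`: list with `successes`, `n`,
#'   `proportion`, `two_sided_p`.
#' @export
exact_binomial_test <- function(successes, n, p0 = 0.5) {
  if (length(successes) != 1L || length(n) != 1L ||
      !is.finite(successes) || !is.finite(n) ||
      successes != round(successes) || n != round(n) ||
      n < 1 || successes < 0 || successes > n) {
    stop("invalid counts: need 0 <= successes <= n, n >= 1")
  }
  if (p0 <= 0 || p0 >= 1) stop("p0 must be in (0, 1)")
  d_obs <- stats::dbinom(successes, n, p0)
  d_all <- stats::dbinom(0:n, n, p0)
  p <- min(1, sum(d_all[d_all <= d_obs * (1 + 1e-7)]))
  structure(list(successes = as.integer(successes), n = as.integer(n),
                 proportion = successes / n, two_sided_p = p),
            class = "binomial_test_result")
}

#' @export
print.binomial_test_result <- function(x, ...) {
  cat(sprintf("<exact binomial: %d/%d = %.3f, two-sided p = %.4g>\n",
              x$successes, x$n, x$proportion, x$two_sided_p))
  invisible(x)
}

#' Summarise behavioural choice trials
#'
#' For each prawn colour type: the number of decided trials, the number of
#' matched choices (green prawns choosing sea lettuce, red prawns choosing
#' dulse), the matched proportion and an [exact_binomial_test()] against
#' p0 = 0.5. `no_choice` rows are excluded from the per-type denominators
#' but counted in the overall decision rate.
#'
#' @param trials Trial table: columns `colour_type` (`green`/`red`) and
#'   `outcome` (`sea_lettuce`/`dulse`/`no_choice`).
#' @return List with `per_type` (tibble: `colour_type`, `n_choices`,
#'   `matched`, `proportion`, `two_sided_p`), `tests` (named list of
#'   `binomial_test_result`), `n_trials`, `n_decided`, `choice_rate`.
#' @export
summarise_choices <- function(trials) {
  stopifnot(is.data.frame(trials), nrow(trials) >= 1L,
            all(c("colour_type", "outcome") %in% names(trials)))
  ok <- c("sea_lettuce", "dulse", "no_choice")
  bad <- setdiff(unique(trials$outcome), ok)
  if (length(bad)) {
    stop("unknown outcome label(s): ", paste(bad, collapse = ", "))
  }
  decided <- trials[trials$outcome != "no_choice", , drop = FALSE]
  if (nrow(decided) == 0L) stop("no decisions to analyse")
  matched_sub <- c(green = "sea_lettuce", red = "dulse")
  tests <- list()
  rows <- lapply(unique(decided$colour_type), function(type) {
    d <- decided[decided$colour_type == type, , drop = FALSE]
    matched <- sum(d$outcome == matched_sub[[type]])
    t <- exact_binomial_test(matched, nrow(d))
    tests[[type]] <<- t
    tibble::tibble(colour_type = type, n_choices = nrow(d),
                   matched = matched, proportion = t$proportion,
                   two_sided_p = t$two_sided_p)
  })
  list(per_type = dplyr::bind_rows(rows), tests = tests,
       n_trials = nrow(trials), n_decided = nrow(decided),
       choice_rate = nrow(decided) / nrow(trials))
}

#' Grouped mean, standard error and count
#'
#' SE = sd / sqrt(n) with the sample (n - 1) standard deviation; groups with
#' a single value report `NA` SE, and empty groups are dropped with a
#' warning.
#'
#' @param data Data frame.
#' @param value Name of the value column (string).
#' @param ... Grouping column names (strings).
#' @return Tibble with the grouping columns plus `mean`, `se`, `n`.
#' @export
group_summary <- function(data, value, ...) {
  stopifnot(is.data.frame(data), value %in% names(data))
  keys <- c(...)
  stopifnot(all(keys %in% names(data)))
  drop <- is.na(data[[value]])
  if (any(drop)) {
    warning(sum(drop), " missing value(s) dropped")
    data <- data[!drop, , drop = FALSE]
  }
  data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      mean = mean(.data[[value]]),
      se = if (dplyr::n() > 1L) {
        stats::sd(.data[[value]]) / sqrt(dplyr::n())
      } else NA_real_,
      n = dplyr::n(), .groups = "drop")
}
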