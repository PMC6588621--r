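#' Receptor-noise limited chromatic distance (JND)
#'
#' Implements the Vorobyev-Osorio receptor-noise model of colour
#' discrimination for di- and trichromats. Receptor signals are log catch
#' ratios, Delta f_i = ln(q_i(a) / q_i(b)); the chromatic distance is
#'
#' dichromat:  DS = |Df_1 - Df_2| / sqrt(w_1^2 + w_2^2)
#'
#' trichromat: DS = sqrt( (w_1^2 (Df_2 - Df_3)^2 + w_2^2 (Df_1 - Df_3)^2 +
#'   w_3^2 (Df_1 - Df_2)^2) / ((w_1 w_2)^2 + (w_1 w_3)^2 + (w_2 w_3)^2) )
#'
#' with Weber fractions w from [weber_fractions()]. Distances are in just
#' noticeable differences (JNDs): values below 1 predict the two colours
#' cannot be discriminated by the receiver; values above 1 predict
#' increasingly reliable discrimination.
#'
#' @param a,b [cone_catch_record()]s on the same channel set, catches > 0.
#' @param system The [visual_system()] supplying the Weber fractions.
#' @return A `jnd_result`: list with `delta_s` (JND units), `delta_f`
#'   (per-channel log contrasts), `system`, `subject_id`, `background_id`,
#'   `discriminable` (`delta_s > 1`).
#' @export
jnd <- function(a, b, system) {
  stopifnot(inherits(a, "cone_catch_record"),
            inherits(b, "cone_catch_record"),
            inherits(system, "visual_system"))
  qa <- a$catches; qb <- b$catches
  if (length(qa) != n_channels(system) ||
      !identical(names(qa), system$channel_names) ||
      !identical(names(qb), system$channel_names)) {
    stop("channel-set mismatch between records and visual system '",
         system$name, "'")
  }
  if (any(qa <= 0) || any(qb <= 0)) stop("non-positive cone catch")
  w <- weber_fractions(system)
  df <- log(qa / qb)
  ds <- if (length(df) == 2L) {
    abs(df[1L] - df[2L]) / sqrt(w[1L]^2 + w[2L]^2)
  } else if (length(df) == 3L) {
    num <- w[1L]^2 * (df[2L] - df[3L])^2 +
      w[2L]^2 * (df[1L] - df[3L])^2 +
      w[3L]^2 * (df[1L] - df[2L])^2
    den <- (w[1L] * w[2L])^2 + (w[1L] * w[3L])^2 + (w[2L] * w[3L])^2
    sqrt(num / den)
  } else {
    stop("only di- and trichromatic systems are supported")
  }
  structure(list(delta_s = unname(ds), delta_f = df, system = system$name,
                 subject_id = a$subject_id, background_id = b$subject_id,
                 discriminable = unname(ds) > 1),
            class = "jnd_result")
}

#' @export
print.jnd_result <- function(x, ...) {
  cat(sprintf("<jnd %s vs %s (%s): dS = %.3f JND, %sdiscriminable>\n",
              x$subject_id, x$background_id, x$system, x$delta_s,
              if (x$discriminable) "" else "not "))
  invisible(x)
}

#' JND table between subjects and a background pool
#'
#' Pairs each subject record with background records and computes one JND per
#' pairing. With `pairing = "random"` each subject is paired with a single
#' background drawn from the pool (without replacement when the pool is at
#' least as large as the subject list, with replacement otherwise),
#' reproducibly under `seed`; `pairing = "all"` crosses every subject with
#' every background.
#'
#' @param subjects,backgrounds Lists of [cone_catch_record()]s.
#' @param system A [visual_system()].
#' @param pairing `"random"` (one-to-one) or `"all"` (cartesian).
#' @param seed Integer seed, required for random pairing.
#' @return A tibble: `subject_id`, `background_id`, `system`, `delta_s`,
#'   `discriminable`, plus subject metadata columns (`colour_type`, `day`,
#'   `substrate`, `size_mm`).
#' @export
jnd_table <- function(subjects, backgrounds, system,
                      pairing = c("random", "all"), seed = NULL) {
  pairing <- match.arg(pairing)
  if (length(subjects) == 0L) stop("empty subject list")
  if (length(backgrounds) == 0L) stop("empty background pool")
  if (pairing == "random") {
    if (is.null(seed)) stop("random pairing requires a seed")
    idx <- with_seed(seed, {
      if (length(backgrounds) >= length(subjects)) {
        sample.int(length(backgrounds), length(subjects))
      } else {
        sample.int(length(backgrounds), length(subjects), replace = TRUE)
      }
    })
    pairs <- cbind(seq_along(subjects), idx)
  } else {
    pairs <- as.matrix(expand.grid(seq_along(subjects),
                                   seq_along(backgrounds)))
  }
  rows <- lapply(seq_len(nrow(pairs)), function(k) {
    s <- subjects[[pairs[k, 1L]]]
    bg <- backgrounds[[pairs[k, 2L]]]
    r <- jnd(s, bg, system)
    tibble::tibble(subject_id = r$subject_id, background_id = r$background_id,
                   system = r$system, delta_s = r$delta_s,
                   discriminable = r$discriminable,
                   colour_type = s$colour_type, day = s$day,
                   substrate = bg$substrate, size_mm = s$size_mm)
  })
  dplyr::bind_rows(rows)
}
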