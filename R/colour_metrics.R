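#' Dichromat hue: short-wave / long-wave catch ratio
#'
#' For a dichromat the only chromatic channel is the ratio of the two cone
#' catches; hue is defined as q_short / q_long (for the pollack model this is
#' the 436 nm single-cone catch over the 521 nm double-cone catch).
#'
#' @param rec A two-channel [cone_catch_record()].
#' @return A `hue_value`: list with `value` (> 0) and `definition`.
#' @export
hue_dichromat <- function(rec) {
  stopifnot(inherits(rec, "cone_catch_record"))
  if (length(rec$catches) != 2L) {
    stop("dichromat hue needs exactly two channels, got ",
         length(rec$catches))
  }
  structure(list(value = unname(rec$catches[1L] / rec$catches[2L]),
                 definition = "dichromat"),
            class = "hue_value")
}

#' Trichromat hue: SWS / (MWS + LWS) opponent ratio
#'
#' Short-wave catch over the summed medium plus long-wave catches, a simple
#' opponent-style colour channel (the main axis of colour variation found by
#' [pca_colour_axis()] on green-red prawn data loads short against
#' medium+long, which motivates this ratio).
#'
#' @param rec A three-channel [cone_catch_record()].
#' @return A `hue_value`.
#' @export
hue_trichromat <- function(rec) {
  stopifnot(inherits(rec, "cone_catch_record"))
  if (length(rec$catches) != 3L) {
    stop("trichromat hue needs exactly three channels, got ",
         length(rec$catches))
  }
  structure(list(value = unname(rec$catches[1L] /
                                  (rec$catches[2L] + rec$catches[3L])),
                 definition = "trichromat"),
            class = "hue_value")
}

#' @export
print.hue_value <- function(x, ...) {
  cat(sprintf("<hue (%s): %.4f>\n", x$definition, x$value))
  invisible(x)
}

#' Hue for a record under a given visual system
#'
#' Dispatches to [hue_dichromat()] or [hue_trichromat()] by channel count and
#' returns the bare number; convenience for building tidy hue tables.
#'
#' @param rec A [cone_catch_record()].
#' @return Numeric hue value.
#' @export
hue_value <- function(rec) {
  if (length(rec$catches) == 2L) hue_dichromat(rec)$value
  else hue_trichromat(rec)$value
}

#' Principal axis of colour variation in cone-catch space
#'
#' PCA on the covariance matrix of per-channel z-scored (standardised) cone
#' catches. Loadings are unit-norm with the sign convention that the
#' short-wave (first) loading of each component is >= 0.
#'
#' @param records List of [cone_catch_record()]s (>= 3) on a common
#'   channel set.
#' @return List with `loadings` (channels x components matrix),
#'   `variance_fraction` (sums to 1) and `scores`.
#' @export
pca_colour_axis <- function(records) {
  if (length(records) < 3L) stop("need at least 3 records for a PCA")
  q <- t(vapply(records, function(r) r$catches,
                numeric(length(records[[1L]]$catches))))
  if (any(apply(q, 2L, stats::sd) == 0)) {
    stop("zero-variance channel: standardisation undefined")
  }
  p <- stats::prcomp(q, center = TRUE, scale. = TRUE)
  load <- p$rotation
  flip <- ifelse(load[1L, ] < 0, -1, 1)
  load <- sweep(load, 2L, flip, `*`)
  scores <- sweep(p$x, 2L, flip, `*`)
  list(loadings = load,
       variance_fraction = p$sdev^2 / sum(p$sdev^2),
       scores = scores)
}

#' Tidy hue table over records
#'
#' @param records List of [cone_catch_record()]s.
#' @param system A [visual_system()] (used only for labelling).
#' @return Tibble: `subject_id`, `colour_type`, `day`, `size_mm`, `system`,
#'   `hue`.
#' @export
hue_table <- function(records, system) {
  rows <- lapply(records, function(r) {
    tibble::tibble(subject_id = r$subject_id, colour_type = r$colour_type,
                   day = r$day, size_mm = r$size_mm, system = system$name,
                   hue = hue_value(r))
  })
  dplyr::bind_rows(rows)
}
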