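#' @keywords internal
#' @useDynLib fallseg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
"_PACKAGE"

#' Canonical body segments
#'
#' The 15-segment whole-body model: head/neck (HN), chest (T),
#' abdomen/pelvis (P), upper arms (LA/RA), forearms (LFA/RFA), hands
#' (LH/RH), thighs (LT/RT), shanks (LS/RS) and feet (LF/RF). This order is
#' canonical throughout the package: it fixes the channel layout of
#' acceleration matrices and breaks ties in segment rankings.
#'
#' @format Character vector of 15 segment codes.
#' @export
SEGMENTS <- c("HN", "T", "P", "LA", "RA", "LFA", "RFA", "LH", "RH",
              "LT", "RT", "LS", "RS", "LF", "RF")

#' Acceleration axes (global frame)
#' @format Character vector: x (antero-posterior), y (medio-lateral),
#'   z (vertical).
#' @export
AXES <- c("x", "y", "z")

# midline segments have no contralateral partner
MIDLINE_SEGMENTS <- c("HN", "T", "P")

# left <-> right partner lookup
CONTRALATERAL <- c(
  LA = "RA", RA = "LA", LFA = "RFA", RFA = "LFA", LH = "RH", RH = "LH",
  LT = "RT", RT = "LT", LS = "RS", RS = "LS", LF = "RF", RF = "LF"
)

#' Channel names for a set of segments
#'
#' Channels are ordered (segment, axis) with segments in canonical order
#' and axes x, y, z within each segment.
#'
#' @param segments character vector of segment codes (default all 15).
#' @return Character vector `"<SEG>_<axis>"`, length `3 * length(segments)`.
#' @export
channel_names <- function(segments = SEGMENTS) {
  stopifnot(all(segments %in% SEGMENTS))
  as.vector(t(outer(segments, AXES, paste, sep = "_")))
}

#' Map channels to segments
#'
#' @param segments character vector of segment codes.
#' @return Character vector giving, for each channel, its segment code.
#' @export
channel_segments <- function(segments = SEGMENTS) {
  rep(segments, each = length(AXES))
}

# row indices of a segment subset's channels within the full 45-channel layout
channel_indices <- function(segments) {
  match(channel_names(segments), channel_names(SEGMENTS))
}

#' Perturbation types
#'
#' The ten slipping perturbations delivered on a dual-belt treadmill:
#' five on the left foot (NL, NW, W, SW, SL) and five on the right
#' (NR, NE, E, SE, SR). Codes combine longitudinal (N/S) and transversal
#' (E/W) belt movements. Paired codes (NL/NR, NW/NE, W/E, SW/SE, SL/SR)
#' share a direction; the five directions are N, N-diag, transversal,
#' S-diag and S.
#'
#' @param code one of the ten perturbation codes.
#' @return Object of class `perturbation_type` with fields `code`, `side`
#'   (`"left"`/`"right"`) and `direction`.
#' @examples
#' perturbation_type("NE")
#' @export
perturbation_type <- function(code) {
  tab <- PERTURBATION_TABLE
  i <- match(code, tab$code)
  if (is.na(i)) {
    stop("unknown perturbation code: ", code,
         " (expected one of ", paste(tab$code, collapse = ", "), ")")
  }
  structure(list(code = tab$code[i], side = tab$side[i],
                 direction = tab$direction[i]),
            class = "perturbation_type")
}

PERTURBATION_TABLE <- data.frame(
  code      = c("NR", "NE", "E", "SE", "SR", "NL", "NW", "W", "SW", "SL"),
  side      = c(rep("right", 5), rep("left", 5)),
  direction = rep(c("N", "N-diag", "transversal", "S-diag", "S"), 2),
  stringsAsFactors = FALSE
)

#' All ten perturbation codes
#' @return Character vector of length 10.
#' @export
perturbation_codes <- function() PERTURBATION_TABLE$code

#' @export
print.perturbation_type <- function(x, ...) {
  cat(sprintf("perturbation %s (side %s, direction %s)\n",
              x$code, x$side, x$direction))
  invisible(x)
}
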