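#' The eight swimming-activity classes
#'
#' The activity vocabulary used throughout the package: wallpush (WP),
#' underwater (UN), the four stroke techniques butterfly (BU), backstroke
#' (BA), breaststroke (BR) and front crawl (FR), turn (TU) and rest (RS).
#' Integer codes are stable (0 to 7, in this order) and are the targets the
#' classifier is trained on.
#'
#' @return Character vector of the 8 class codes, in integer-code order.
#' @export
#' @examples
#' activity_levels()
#' activity_code("FR")
activity_levels <- function() {
  c("WP", "UN", "BU", "BA", "BR", "FR", "TU", "RS")
}

.stroke_classes <- c("BU", "BA", "BR", "FR")

#' @rdname activity_levels
#' @param x character vector of class codes.
#' @return `activity_code()`: integer codes in 0..7.
#' @export
activity_code <- function(x) {
  i <- match(x, activity_levels())
  if (anyNA(i)) {
    stop("unknown activity class: ", paste(unique(x[is.na(i)]), collapse = ", "))
  }
  i - 1L
}

#' @rdname activity_levels
#' @param code integer vector of codes in 0..7.
#' @return `activity_from_code()`: character class codes.
#' @export
activity_from_code <- function(code) {
  if (any(code < 0L | code > 7L)) stop("activity code outside 0..7")
  activity_levels()[code + 1L]
}

#' @rdname activity_levels
#' @return `is_stroke()`: logical, TRUE for BU/BA/BR/FR.
#' @export
is_stroke <- function(x) {
  activity_code(x) # validates
  x %in% .stroke_classes
}

#' @rdname activity_levels
#' @return `stroke_classes()`: the four stroke technique codes.
#' @export
stroke_classes <- function() .stroke_classes
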