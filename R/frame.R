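#' Construct a lung ultrasound frame
#'
#' A frame is one 8-bit grayscale B-mode still image plus minimal study
#' metadata. Pixels are stored as an integer matrix with values in
#' \code{[0, 255]}; row 1 is the most superficial image line (skin surface),
#' matching the usual top-down B-mode display.
#'
#' @param pixels numeric or integer matrix, values in \code{[0, 255]}
#' @param patient_id patient identifier (character scalar or `NA`)
#' @param view view label, one of the eight standard scan positions
#'   (four views per side) or `NA`
#' @param source_path path the frame was read from, if any
#' @return an object of class `lus_frame`
#' @export
lus_frame <- function(pixels, patient_id = NA_character_, view = NA_character_,
                      source_path = NA_character_) {
  assert_pixels(pixels)
  storage.mode(pixels) <- "integer"
  structure(
    list(pixels = pixels, patient_id = as.character(patient_id),
         view = as.character(view), source_path = as.character(source_path)),
    class = "lus_frame"
  )
}

#' @export
print.lus_frame <- function(x, ...) {
  cat(sprintf("<lus_frame> %d x %d, patient %s, view %s\n",
              nrow(x$pixels), ncol(x$pixels), x$patient_id, x$view))
  invisible(x)
}

#' @export
dim.lus_frame <- function(x) dim(x$pixels)

# Accept either a bare pixel matrix or an lus_frame anywhere a frame is used.
frame_pixels <- function(frame) {
  if (inherits(frame, "lus_frame")) frame$pixels
  else { assert_pixels(frame); frame }
}
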