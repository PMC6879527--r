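#' FDI tooth numbering (ISO-3950) and the fixed tooth-index map
#'
#' The package addresses all 32 permanent teeth by their two-digit FDI code:
#' the first digit is the quadrant (1 upper-right, 2 upper-left, 3 lower-left,
#' 4 lower-right), the second the position 1-8 counted from the midline.
#' Throughout the package a tooth-label vector has length 32 and a fixed
#' ordering: zero-based slot `(quadrant - 1) * 8 + (position - 1)`, so
#' quadrants 1-2 (maxillary, upper jaw) occupy slots 0-15 and quadrants 3-4
#' (mandibular, lower jaw) occupy slots 16-31. Positions 1-2 are incisors,
#' 3 canines, 4-5 premolars and 6-8 molars (8 incisors, 4 canines,
#' 8 premolars, 12 molars in total).
#'
#' `fdi_to_index()` and `index_to_fdi()` are inverse bijections between FDI
#' codes and the zero-based slot. `fdi_chart()` tabulates the whole map.
#'
#' @param quadrant Integer vector in 1..4.
#' @param position Integer vector in 1..8.
#' @return `fdi_to_index()`: zero-based integer slot(s) in 0..31.
#' @examples
#' fdi_to_index(1, 1)   # 0
#' fdi_to_index(3, 8)   # 23
#' index_to_fdi(23)
#' @export
fdi_to_index <- function(quadrant, position) {
  quadrant <- as.integer(quadrant)
  position <- as.integer(position)
  if (length(quadrant) != length(position))
    stop("quadrant and position must have equal length")
  bad <- is.na(quadrant) | is.na(position) |
    quadrant < 1L | quadrant > 4L | position < 1L | position > 8L
  if (any(bad))
    stop("invalid FDI tooth id: quadrant must be in 1..4 and position in 1..8 ",
         "(first offender: quadrant=", quadrant[which(bad)[1]],
         ", position=", position[which(bad)[1]], ")")
  (quadrant - 1L) * 8L + (position - 1L)
}

#' @rdname fdi_to_index
#' @param index Zero-based slot(s) in 0..31.
#' @return `index_to_fdi()`: a tibble with columns `index`, `quadrant`,
#'   `position` and the two-digit `code`.
#' @export
index_to_fdi <- function(index) {
  index <- as.integer(index)
  if (any(is.na(index) | index < 0L | index > 31L))
    stop("index must be in 0..31")
  quadrant <- index %/% 8L + 1L
  position <- index %% 8L + 1L
  tibble::tibble(index = index, quadrant = quadrant, position = position,
                 code = sprintf("%d%d", quadrant, position))
}

#' @rdname fdi_to_index
#' @return `fdi_chart()`: a 32-row tibble with columns `index`, `quadrant`,
#'   `position`, `code`, `jaw` (`"upper"`/`"lower"`), `type` (incisor, canine,
#'   premolar, molar) and `side` (`"right"`/`"left"`, the patient's side;
#'   in the panoramic image the patient's right appears on the image's left
#'   half).
#' @export
fdi_chart <- function() {
  ch <- index_to_fdi(0:31)
  ch$jaw <- ifelse(ch$quadrant <= 2L, "upper", "lower")
  ch$type <- fdi_tooth_type(ch$position)
  ch$side <- ifelse(ch$quadrant %in% c(1L, 4L), "right", "left")
  ch
}

#' @rdname fdi_to_index
#' @return `fdi_tooth_type()`: the tooth type for each position.
#' @export
fdi_tooth_type <- function(position) {
  position <- as.integer(position)
  if (any(is.na(position) | position < 1L | position > 8L))
    stop("position must be in 1..8")
  c("incisor", "incisor", "canine", "premolar", "premolar",
    "molar", "molar", "molar")[position]
}

#' @rdname fdi_to_index
#' @param type One of `"incisor"`, `"canine"`, `"premolar"`, `"molar"`.
#' @return `tooth_type_indices()`: the zero-based slots of that type.
#' @export
tooth_type_indices <- function(type) {
  type <- match.arg(type, c("incisor", "canine", "premolar", "molar"))
  ch <- fdi_chart()
  ch$index[ch$type == type]
}

# zero-based slots of the upper / lower jaws and image halves
upper_indices <- function() 0:15
lower_indices <- function() 16:31

# slots whose tooth lies in the left image half (patient's right:
# quadrants 1 and 4); the complement lies in the right half
left_half_indices <- function() {
  ch <- fdi_chart()
  ch$index[ch$side == "right"]
}
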