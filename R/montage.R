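#' Standard 32-channel 10-20 montage
#'
#' Returns the 32-electrode cap layout used throughout the package: the
#' international 10-20/10-10 labels FP1...O2 plus the mastoids A1/A2, with
#' planar (top-view) coordinates on a unit head circle. The mastoids sit
#' outside the scalp circle and are excluded from topographic statistics.
#'
#' @param reference Reference scheme the data are expressed in. Synthetic
#'   recordings are generated nose-referenced.
#' @return A tibble with columns `name`, `x`, `y` and attributes
#'   `reference` and `scalp` (logical, `FALSE` for A1/A2).
#' @examples
#' m <- montage_1020_32()
#' nrow(m)          # 32
#' sum(attr(m, "scalp"))  # 30 scalp electrodes
#' @export
montage_1020_32 <- function(reference = c("nose", "linked_mastoids", "average")) {
  reference <- match.arg(reference)
  ch <- tibble::tribble(
    ~name,  ~x,      ~y,
    "FP1", -0.309,  0.951,
    "FPz",  0.000,  1.000,
    "FP2",  0.309,  0.951,
    "Fz",   0.000,  0.500,
    "F3",  -0.425,  0.545,
    "F4",   0.425,  0.545,
    "F7",  -0.809,  0.588,
    "F8",   0.809,  0.588,
    "FC1", -0.250,  0.250,
    "FC2",  0.250,  0.250,
    "FC5", -0.670,  0.270,
    "FC6",  0.670,  0.270,
    "Cz",   0.000,  0.000,
    "C3",  -0.500,  0.000,
    "C4",   0.500,  0.000,
    "T7",  -1.000,  0.000,
    "T8",   1.000,  0.000,
    "CP1", -0.250, -0.250,
    "CP2",  0.250, -0.250,
    "CP5", -0.670, -0.270,
    "CP6",  0.670, -0.270,
    "Pz",   0.000, -0.500,
    "P3",  -0.425, -0.545,
    "P4",   0.425, -0.545,
    "P7",  -0.809, -0.588,
    "P8",   0.809, -0.588,
    "POz",  0.000, -0.750,
    "Oz",   0.000, -1.000,
    "O1",  -0.309, -0.951,
    "O2",   0.309, -0.951,
    "A1",  -1.250, -0.100,
    "A2",   1.250, -0.100
  )
  new_montage(ch, reference = reference)
}

new_montage <- function(channels, reference = "nose") {
  stopifnot(all(c("name", "x", "y") %in% names(channels)))
  if (anyDuplicated(channels$name)) {
    abort("Montage channel names must be unique.")
  }
  out <- tibble::as_tibble(channels[, c("name", "x", "y")])
  attr(out, "reference") <- reference
  attr(out, "scalp") <- !out$name %in% c("A1", "A2")
  class(out) <- c("mmn_montage", class(out))
  out
}

#' @export
print.mmn_montage <- function(x, ...) {
  cat(sprintf("<montage: %d channels (%d scalp), reference = %s>\n",
              nrow(x), sum(attr(x, "scalp")), attr(x, "reference")))
  NextMethod()
}

scalp_channels <- function(montage) {
  montage$name[attr(montage, "scalp")]
}

require_channels <- function(montage, needed) {
  missing <- setdiff(needed, montage$name)
  if (length(missing) > 0) {
    abort(sprintf("Montage is missing required channel(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  invisible(montage)
}

#' Read / write a montage table
#'
#' Montages are stored as TSV with columns `name`, `x`, `y`.
#'
#' @param path File path.
#' @param montage A montage tibble as returned by [montage_1020_32()].
#' @param reference Reference tag to attach on read.
#' @return `read_montage()` returns a montage tibble; `write_montage()`
#'   returns `path` invisibly.
#' @export
read_montage <- function(path, reference = "nose") {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    name = readr::col_character(),
    x = readr::col_double(),
    y = readr::col_double()
  ))
  new_montage(tab, reference = reference)
}

#' @rdname read_montage
#' @export
write_montage <- function(montage, path) {
  readr::write_tsv(montage[, c("name", "x", "y")], path)
  invisible(path)
}
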