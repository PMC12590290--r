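#' Write picked particles as a STAR file
#'
#' Emits a RELION-3.x style STAR file with one data block and one loop
#' carrying, per particle: `_rlnMicrographName`, `_rlnCoordinateX`,
#' `_rlnCoordinateY`, `_rlnAutopickFigureOfMerit`. Coordinates are particle
#' CENTERS in the original micrograph's pixel space, origin at the top-left
#' corner (some display tools use other conventions; CryoSPARC's
#' extract-from-coordinates expects this one). Coordinates and scores are
#' printed with six decimal places; identical inputs produce byte-identical
#' files. An empty particle table yields a valid file with a header and zero
#' rows. A detection-only picker has no pose estimate, so no rotation-angle
#' columns are written.
#'
#' @param particles data.frame with columns `micrograph_name`, `x`, `y`,
#'   `score` (score in `[0, 1]`).
#' @param out_path Output path.
#' @export
write_star <- function(particles, out_path) {
  stopifnot(all(c("micrograph_name", "x", "y", "score") %in% names(particles)))
  if (nrow(particles) > 0 &&
      (any(particles$score < 0) || any(particles$score > 1)))
    stop("scores must lie in [0, 1]")
  header <- c("", "data_", "", "loop_",
              "_rlnMicrographName #1",
              "_rlnCoordinateX #2",
              "_rlnCoordinateY #3",
              "_rlnAutopickFigureOfMerit #4")
  rows <- character(0)
  if (nrow(particles) > 0)
    rows <- sprintf("%s %.6f %.6f %.6f", particles$micrograph_name,
                    particles$x, particles$y, particles$score)
  writeLines(c(header, rows, ""), out_path, useBytes = TRUE)
  invisible(out_path)
}

#' Read a particle STAR file
#'
#' Minimal parser for the loop dialect written by [write_star()] (and other
#' RELION-style single-loop coordinate files): labels are taken from the
#' `_rln*` declarations, rows are whitespace-split.
#'
#' @param path STAR file path.
#' @return data.frame with one column per loop label (numeric where
#'   possible).
#' @export
read_star <- function(path) {
  lines <- readLines(path)
  lab_idx <- grep("^_", lines)
  if (length(lab_idx) == 0) stop("no loop labels found in ", path)
  labels <- sub("^_([^ #]+).*$", "\\1", lines[lab_idx])
  body <- lines[(max(lab_idx) + 1):length(lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0) {
    out <- as.data.frame(matrix(nrow = 0, ncol = length(labels)))
    names(out) <- labels
    return(out)
  }
  parts <- strsplit(trimws(body), "[[:space:]]+")
  if (any(lengths(parts) != length(labels)))
    stop("malformed STAR row(s) in ", path)
  out <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
  names(out) <- labels
  for (j in seq_along(out)) {
    num <- suppressWarnings(as.numeric(out[[j]]))
    if (!anyNA(num)) out[[j]] <- num
  }
  out
}

## picked-particle table -> STAR column layout
particles_to_star_df <- function(picks) {
  data.frame(micrograph_name = picks$micrograph_name,
             x = picks$x, y = picks$y, score = picks$score,
             stringsAsFactors = FALSE)
}
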