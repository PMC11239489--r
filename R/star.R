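# Minimal STAR-format particle metadata: one data_ block with a loop_ of
# image index, three ZYZ Euler angles (degrees, as the field convention has
# it), two shifts in Angstrom, and the half-set label.

#' Write particle metadata as a STAR file
#'
#' @param data a [particle_dataset()]. @param path destination.
#' @export
write_star_particles <- function(data, path) {
  P <- dim(data$images)[3]
  lines <- c("", "data_particles", "", "loop_",
             "_blushImageIndex #1", "_blushAngleRot #2", "_blushAngleTilt #3",
             "_blushAnglePsi #4", "_blushShiftX #5", "_blushShiftY #6",
             "_blushHalfSet #7")
  deg <- data$eulers * 180 / pi
  rows <- sprintf("%d %.6f %.6f %.6f %.4f %.4f %d",
                  seq_len(P), deg[, 1], deg[, 2], deg[, 3],
                  data$shifts[, 1], data$shifts[, 2], data$half)
  writeLines(c(lines, rows), path)
  invisible(path)
}

#' Read particle metadata from a STAR file
#'
#' @param path STAR file written by [write_star_particles()].
#' @param images optional image stack array to attach.
#' @param pixel_size pixel size (Angstrom), required when `images` is given.
#' @return A [particle_dataset()] if images are supplied, else a data.frame.
#' @export
read_star_particles <- function(path, images = NULL, pixel_size = NULL) {
  txt <- readLines(path)
  txt <- trimws(txt)
  loop_at <- which(txt == "loop_")
  if (length(loop_at) == 0) stop("no loop_ block found in STAR file")
  i <- loop_at[1] + 1
  labels <- character(0)
  while (i <= length(txt) && startsWith(txt[i], "_")) {
    labels <- c(labels, sub(" .*$", "", txt[i]))
    i <- i + 1
  }
  body <- txt[i:length(txt)]
  body <- body[nzchar(body)]
  df <- utils::read.table(text = body, col.names = sub("^_", "", labels))
  if (is.null(images)) return(df)
  eul <- as.matrix(df[, c("blushAngleRot", "blushAngleTilt", "blushAnglePsi")]) * pi / 180
  particle_dataset(images, eulers = eul,
                   shifts = as.matrix(df[, c("blushShiftX", "blushShiftY")]),
                   half = df$blushHalfSet, pixel_size = pixel_size)
}
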