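#' Accessibility tracks
#'
#' A track holds one unpaired probability per transcript base (the probability
#' that the base is single-stranded under local folding); high accessibility
#' favors protein binding. Tracks are read from files produced by an external
#' local-folding tool, or a uniform track (all 1) stands in when no structure
#' information is available.
#'
#' @name accessibility
NULL

new_track <- function(transcript_id, p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("unpaired probabilities must lie in [0, 1]")
  }
  structure(list(transcript_id = transcript_id, p = as.numeric(p)),
            class = "accessibility_track")
}

#' Uniform accessibility track (every base fully unpaired)
#'
#' @param transcript_id Transcript id.
#' @param length Transcript length in nt (>= 1).
#' @return An \code{accessibility_track} with all probabilities 1. With this
#'   track, every motif-site accessibility is 1 and region scores reduce to
#'   raw hit counts.
#' @export
uniform_track <- function(transcript_id, length) {
  if (length < 1) stop("track length must be >= 1")
  new_track(transcript_id, rep(1, length))
}

#' Load an unpaired-probability track in the `_lunp` dialect
#'
#' Parses the per-base unpaired-probability output of a local-folding tool
#' (e.g. RNAplfold run on the whole transcript with W=200, L=150, U=1):
#' lines starting with \code{#} are comments; data rows are whitespace
#' separated \code{position value_u1 [value_u2 ...]} with 1-based positions.
#' Only the u=1 column is consumed. \code{NA} entries and positions absent
#' from the file are recorded as missing.
#'
#' @param source File path.
#' @param transcript_id Transcript id to attach.
#' @param transcript_length Expected track length; positions beyond it error.
#' @return \code{accessibility_track}.
#' @export
load_unpaired_track <- function(source, transcript_id, transcript_length) {
  lines <- readLines(source)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  p <- rep(NA_real_, transcript_length)
  for (ln in lines) {
    f <- strsplit(ln, "[ \t]+")[[1]]
    pos <- suppressWarnings(as.integer(f[1]))
    if (is.na(pos) || pos < 1) stop("bad position in track file: ", ln)
    if (pos > transcript_length) {
      stop("position ", pos, " exceeds transcript length ", transcript_length,
           " for ", transcript_id)
    }
    val <- if (length(f) < 2 || f[2] == "NA") NA_real_ else
      suppressWarnings(as.numeric(f[2]))
    if (!is.na(val) && (val < 0 || val > 1)) {
      stop("unpaired probability out of [0,1] at position ", pos)
    }
    p[pos] <- val
  }
  new_track(transcript_id, p)
}

#' Serialize a track back to the `_lunp` dialect
#' @param track \code{accessibility_track}.
#' @param path Output path.
#' @export
write_unpaired_track <- function(track, path) {
  vals <- ifelse(is.na(track$p), "NA", formatC(track$p, digits = 8,
                                               format = "g"))
  writeLines(c("# unpaired probabilities (u=1)",
               paste(seq_along(track$p), vals)), path)
  invisible(path)
}

#' Mean single-base accessibility of a site
#'
#' A site's accessibility is the arithmetic mean of the unpaired probabilities
#' of its bases. Missing bases are dropped from the mean; a window with no
#' present value scores 0, so such a site contributes nothing.
#'
#' @param track \code{accessibility_track}.
#' @param start 0-based inclusive start.
#' @param end 0-based exclusive end.
#' @return Scalar in \[0, 1\].
#' @export
site_accessibility <- function(track, start, end) {
  n <- length(track$p)
  if (start < 0 || end > n || start >= end) {
    stop("invalid window [", start, ", ", end, ") for track of length ", n)
  }
  w <- track$p[(start + 1L):end]
  if (all(is.na(w))) 0 else mean(w, na.rm = TRUE)
}

#' Accessibility provider
#'
#' Returns a function \code{(transcript_id, length) -> accessibility_track}.
#' Provider \code{"uniform"} gives all-1 tracks; \code{"file"} loads
#' \code{<dir>/<transcript_id>_lunp}.
#'
#' @param provider \code{"uniform"} or \code{"file"}.
#' @param dir Directory of `_lunp` files (required for \code{"file"}).
#' @return Provider function.
#' @export
accessibility_provider <- function(provider = c("uniform", "file"),
                                   dir = NULL) {
  provider <- match.arg(provider)
  if (provider == "uniform") {
    function(transcript_id, length) uniform_track(transcript_id, length)
  } else {
    if (is.null(dir)) stop("provider 'file' needs a track directory")
    function(transcript_id, length) {
      f <- file.path(dir, paste0(transcript_id, "_lunp"))
      if (!file.exists(f)) stop("no accessibility track for ", transcript_id)
      load_unpaired_track(f, transcript_id, length)
    }
  }
}
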