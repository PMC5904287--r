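# Reading and writing LFP recordings.  Two formats: a self-describing CSV
# (key=value header lines prefixed with '#', then one sample per line) and
# a raw little-endian float64 binary with a JSON metadata sidecar.

#' Read or write an LFP recording
#'
#' \code{write_recording} followed by \code{read_recording} reproduces the
#' samples to numeric precision (exactly for \code{"bin"}) and the
#' metadata exactly.
#'
#' @param path File path.  For \code{format = "bin"} a \code{<path>.json}
#'   metadata sidecar is written next to the data file.
#' @param format \code{"csv"} or \code{"bin"}; default guessed from the
#'   file extension.
#' @return \code{read_recording} returns an \code{lfp_recording};
#'   \code{write_recording} returns \code{path} invisibly.
#' @export
read_recording <- function(path, format = NULL) {
  format <- .guess_format(path, format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "csv") {
    lines <- readLines(path)
    hdr <- grep("^#", lines, value = TRUE)
    meta <- list()
    for (h in hdr) {
      kv <- strsplit(sub("^#\\s*", "", h), "=", fixed = TRUE)[[1]]
      if (length(kv) == 2) meta[[trimws(kv[1])]] <- trimws(kv[2])
    }
    if (is.null(meta$fs)) stop("malformed CSV: missing 'fs' header", call. = FALSE)
    body <- lines[!grepl("^#", lines) & nzchar(lines)]
    samples <- suppressWarnings(as.numeric(body))
    if (anyNA(samples)) stop("malformed CSV: non-numeric samples", call. = FALSE)
    lfp_recording(samples, fs = as.numeric(meta$fs),
                  nucleus = if (is.null(meta$nucleus)) "OTHER" else meta$nucleus,
                  contact_pair = if (is.null(meta$contact_pair)) NA else meta$contact_pair,
                  subject_id = if (is.null(meta$subject_id)) NA else meta$subject_id)
  } else if (format == "bin") {
    side <- paste0(path, ".json")
    if (!file.exists(side)) stop("missing metadata sidecar ", side, call. = FALSE)
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    con <- file(path, "rb")
    on.exit(close(con))
    samples <- readBin(con, "double", n = meta$n, size = 8, endian = "little")
    lfp_recording(samples, fs = meta$fs,
                  nucleus = if (is.null(meta$nucleus)) "OTHER" else meta$nucleus,
                  contact_pair = if (is.null(meta$contact_pair)) NA else meta$contact_pair,
                  subject_id = if (is.null(meta$subject_id)) NA else meta$subject_id)
  } else stop("unsupported format '", format, "'", call. = FALSE)
}

#' @rdname read_recording
#' @param rec An \code{lfp_recording}.
#' @export
write_recording <- function(rec, path, format = NULL) {
  if (!inherits(rec, "lfp_recording")) stop("rec must be an lfp_recording", call. = FALSE)
  format <- .guess_format(path, format)
  if (format == "csv") {
    hdr <- c(sprintf("# fs=%.17g", rec$fs),
             sprintf("# nucleus=%s", rec$nucleus),
             if (!is.na(rec$contact_pair)) sprintf("# contact_pair=%s", rec$contact_pair),
             if (!is.na(rec$subject_id)) sprintf("# subject_id=%s", rec$subject_id))
    writeLines(c(hdr, sprintf("%.17g", rec$samples)), path)
  } else if (format == "bin") {
    con <- file(path, "wb")
    writeBin(rec$samples, con, size = 8, endian = "little")
    close(con)
    jsonlite::write_json(
      list(n = length(rec$samples), fs = rec$fs, nucleus = rec$nucleus,
           contact_pair = rec$contact_pair, subject_id = rec$subject_id),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA, null = "null")
  } else stop("unsupported format '", format, "'", call. = FALSE)
  invisible(path)
}

.guess_format <- function(path, format) {
  if (!is.null(format)) return(match.arg(format, c("csv", "bin")))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("csv", "txt")) "csv"
  else if (ext %in% c("bin", "dat", "raw")) "bin"
  else stop("cannot guess format from extension '", ext,
            "'; pass format explicitly", call. = FALSE)
}
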