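#' Write / read a photon stream as CSV with a JSON metadata sidecar
#'
#' The stream is stored as a two-column CSV (`timestamp_us`, `channel`);
#' measurement metadata (duration, salt, species, seed) goes to
#' `<path>.json`.
#'
#' @param stream A [photon_stream()].
#' @param path Path of the CSV file to write.
#' @return `write_photon_stream()` returns `path` invisibly;
#'   `read_photon_stream()` returns a [photon_stream()].
#' @export
write_photon_stream <- function(stream, path) {
  stopifnot(inherits(stream, "photon_stream"))
  utils::write.csv(as.data.frame(stream)[, c("timestamp_us", "channel")],
                   path, row.names = FALSE, quote = FALSE)
  meta <- list(duration = attr(stream, "duration"),
               salt = attr(stream, "salt"),
               species = attr(stream, "species"),
               seed = attr(stream, "seed"))
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_photon_stream
#' @export
read_photon_stream <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path))
    jsonlite::fromJSON(meta_path, simplifyVector = TRUE) else list()
  photon_stream(tab$timestamp_us, tab$channel,
                duration = meta$duration %||% (max(tab$timestamp_us) / 1e6),
                salt = meta$salt %||% NA_real_,
                species = meta$species %||% NA_character_,
                seed = meta$seed)
}
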