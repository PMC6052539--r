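## TPS landmark file reader/writer (the TPSdig dialect used for 2-D
## digitizing: LM=, coordinate lines, optional IMAGE=, ID=, SCALE=).

#' Construct a landmark configuration
#'
#' One specimen's k x 2 raw landmark coordinates with identifiers.
#'
#' @param coords k x 2 numeric matrix (digitizer units).
#' @param specimen_id Specimen identifier.
#' @param species_id Optional species identifier.
#' @param scale Optional TPS SCALE factor already applied to `coords`.
#' @return An object of class `landmark_config`.
#' @export
landmark_config <- function(coords, specimen_id, species_id = NA_character_,
                            scale = NULL) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 2L) .stopf("coords must be a k x 2 matrix")
  if (nrow(coords) < 1L) .stopf("empty configuration")
  if (any(!is.finite(coords))) .stopf("non-finite coordinates")
  structure(list(coords = unname(coords),
                 specimen_id = as.character(specimen_id),
                 species_id = as.character(species_id),
                 scale = scale),
            class = "landmark_config")
}

#' @export
print.landmark_config <- function(x, ...) {
  cat(sprintf("<landmark_config> %s (%s), %d landmarks\n",
              x$specimen_id,
              if (is.na(x$species_id)) "species unknown" else x$species_id,
              nrow(x$coords)))
  invisible(x)
}

#' Read a TPS landmark file
#'
#' Each block starts with `LM=k`, followed by k whitespace-separated
#' `x y` lines, then optional `IMAGE=`, `ID=`, `SCALE=` records.
#' Coordinates are multiplied by SCALE when present. The specimen id is
#' the ID record, falling back to the IMAGE basename, falling back to
#' the 1-based block index.
#'
#' @param file Path to a TPS file, or use `text` for a literal string.
#' @param text Optional TPS content as a single string.
#' @return List of [landmark_config] objects.
#' @export
read_tps <- function(file = NULL, text = NULL) {
  if (is.null(text)) {
    if (is.null(file) || !file.exists(file))
      .stopf("TPS file not found: %s", file %||% "<missing>")
    lines <- readLines(file, warn = FALSE)
  } else {
    lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  }
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) .stopf("empty TPS input")
  starts <- grep("^[Ll][Mm]=", lines)
  if (!length(starts)) .stopf("no LM= records found")
  if (starts[1] != 1L) .stopf("TPS input must start with an LM= record")
  ends <- c(starts[-1] - 1L, length(lines))
  out <- vector("list", length(starts))
  for (b in seq_along(starts)) {
    block <- lines[starts[b]:ends[b]]
    k <- suppressWarnings(as.integer(sub("^[Ll][Mm]=", "", block[1])))
    if (is.na(k) || k < 1L) .stopf("block %d: bad LM= record '%s'", b, block[1])
    body <- block[-1]
    is_kv <- grepl("^[A-Za-z]+=", body)
    coord_lines <- body[!is_kv]
    if (length(coord_lines) != k)
      .stopf("block %d: LM=%d but %d coordinate lines", b, k,
             length(coord_lines))
    xy <- suppressWarnings(
      lapply(strsplit(coord_lines, "[[:space:]]+"), as.numeric))
    if (any(vapply(xy, length, 1L) != 2L) || anyNA(unlist(xy)))
      .stopf("block %d: malformed coordinate line", b)
    coords <- do.call(rbind, xy)
    kv <- body[is_kv]
    key <- toupper(sub("=.*$", "", kv))
    val <- sub("^[A-Za-z]+=", "", kv)
    get <- function(k) if (k %in% key) val[match(k, key)] else NULL
    scale <- NULL
    if (!is.null(get("SCALE"))) {
      scale <- suppressWarnings(as.numeric(get("SCALE")))
      if (is.na(scale) || scale <= 0) .stopf("block %d: bad SCALE=", b)
      coords <- coords * scale
    }
    id <- get("ID")
    if (is.null(id) && !is.null(get("IMAGE")))
      id <- sub("\\.[^.]*$", "", basename(get("IMAGE")))
    out[[b]] <- landmark_config(coords, id %||% as.character(b),
                                scale = scale)
  }
  ks <- vapply(out, function(cfg) nrow(cfg$coords), 1L)
  if (length(unique(ks)) > 1L)
    .warnf("mixed landmark counts across blocks: %s",
           paste(unique(ks), collapse = ", "))
  out
}

#' Write landmark configurations as TPS
#'
#' Writes the package's own dialect: `LM=`, full-precision coordinate
#' lines, and `ID=`. SCALE is never written (coordinates are stored
#' as-is), so `read_tps(write_tps(x))` round-trips coordinates
#' bit-exactly.
#'
#' @param configs List of [landmark_config] objects.
#' @param file Output path; when `NULL` the TPS text is returned.
#' @export
write_tps <- function(configs, file = NULL) {
  blocks <- vapply(configs, function(cfg) {
    paste(c(sprintf("LM=%d", nrow(cfg$coords)),
            paste(.fmt_num(cfg$coords[, 1]), .fmt_num(cfg$coords[, 2])),
            sprintf("ID=%s", cfg$specimen_id)),
          collapse = "\n")
  }, character(1))
  txt <- paste(blocks, collapse = "\n")
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(file)
}
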