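#' Fingerprint set container
#'
#' A fingerprint set holds one band profile (integer multiset of band codes)
#' per clone, keyed by unique clone id, plus a provenance note.
#'
#' @param profiles named list of integer vectors (band codes). Names are
#'   clone ids and must be unique.
#' @param provenance free-text origin (file path or simulation id).
#' @return an object of class `fingerprint_set`.
#' @export
fingerprint_set <- function(profiles, provenance = NA_character_) {
  if (is.null(names(profiles)) && length(profiles) > 0) {
    stop("profiles must be named by clone id", call. = FALSE)
  }
  if (anyDuplicated(names(profiles))) {
    stop("duplicate clone ids: ",
         paste(unique(names(profiles)[duplicated(names(profiles))]), collapse = ", "),
         call. = FALSE)
  }
  profiles <- lapply(profiles, function(p) as.integer(sort(p)))
  structure(list(profiles = profiles, provenance = provenance),
            class = "fingerprint_set")
}

#' @export
print.fingerprint_set <- function(x, ...) {
  nb <- lengths(x$profiles)
  cat(sprintf("fingerprint_set: %d clones, %s bands/clone (median), provenance: %s\n",
              length(x$profiles),
              if (length(nb)) format(stats::median(nb)) else "-",
              x$provenance))
  invisible(x)
}

#' @export
length.fingerprint_set <- function(x) length(x$profiles)

#' Number of bands per clone
#' @param set a `fingerprint_set`.
#' @return named integer vector.
#' @export
n_bands <- function(set) lengths(set$profiles)

BAND_FILE_HEADER <- "# fingermap band file v1"

#' Read and write band files
#'
#' The band file dialect is plain text: a comment header line, then per clone
#' a line `>clone_id` followed by one whitespace-separated line of integer
#' band values. `read_band_file(write_band_file(s, f))` reproduces `s`
#' exactly, duplicates included; re-writing a read file is byte-identical.
#'
#' @param path file path.
#' @return `read_band_file` returns a `fingerprint_set`; `write_band_file`
#'   returns `path` invisibly.
#' @export
read_band_file <- function(path) {
  raw <- readLines(path)
  keep <- !grepl("^#", raw) & nzchar(trimws(raw))
  lines <- raw[keep]
  lineno <- which(keep)  # original file line numbers for error reporting
  is_hdr <- grepl("^>", lines)
  if (length(lines) && !is_hdr[1]) {
    stop(sprintf("malformed band file at line %d: expected '>clone_id'",
                 lineno[1]), call. = FALSE)
  }
  ids <- character(0)
  profiles <- list()
  i <- 1
  while (i <= length(lines)) {
    if (!is_hdr[i]) {
      stop(sprintf("malformed record at line %d", lineno[i]), call. = FALSE)
    }
    id <- sub("^>\\s*", "", lines[i])
    if (i + 1 > length(lines) || is_hdr[i + 1]) {
      bands <- integer(0)
      i <- i + 1
    } else {
      toks <- strsplit(trimws(lines[i + 1]), "\\s+")[[1]]
      bands <- suppressWarnings(as.integer(toks))
      if (anyNA(bands)) {
        stop(sprintf("malformed band values at line %d", lineno[i + 1]),
             call. = FALSE)
      }
      i <- i + 2
    }
    if (id %in% ids) stop("duplicate clone id: ", id, call. = FALSE)
    ids <- c(ids, id)
    profiles[[id]] <- bands
  }
  fingerprint_set(profiles, provenance = path)
}

#' @rdname read_band_file
#' @param set a `fingerprint_set`.
#' @export
write_band_file <- function(set, path) {
  stopifnot(inherits(set, "fingerprint_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(BAND_FILE_HEADER, con)
  for (id in names(set$profiles)) {
    writeLines(paste0(">", id), con)
    b <- set$profiles[[id]]
    if (length(b)) writeLines(paste(b, collapse = " "), con)
  }
  invisible(path)
}

#' Filter bands by size and drop poor-quality fingerprints
#'
#' Removes bands whose size component lies outside `[min_size, max_size]`,
#' then drops clones with fewer than `min_band_count` surviving bands
#' (poor-quality fingerprints). Filtering is idempotent.
#'
#' @param set a `fingerprint_set`.
#' @param min_size,max_size retained band size range in bp (defaults 50 and
#'   500, the analyzable HICF range).
#' @param min_band_count minimum surviving bands for a clone to be kept
#'   (default 5).
#' @return a list with `fingerprints` (the filtered `fingerprint_set`) and
#'   `report`, a data.frame with one row per input clone: `clone_id`,
#'   `n_bands_in`, `n_bands_kept`, `status` ("retained"/"dropped"),
#'   `reason`.
#' @export
filter_bands <- function(set, min_size = 50, max_size = 500, min_band_count = 5) {
  stopifnot(inherits(set, "fingerprint_set"))
  if (min_size > max_size) stop("min_size must be <= max_size", call. = FALSE)
  kept <- lapply(set$profiles, function(b) {
    sz <- band_size(b)
    b[sz >= min_size & sz <= max_size]
  })
  nk <- lengths(kept)
  keep <- nk >= min_band_count
  report <- data.frame(
    clone_id = names(set$profiles),
    n_bands_in = unname(lengths(set$profiles)),
    n_bands_kept = unname(nk),
    status = ifelse(keep, "retained", "dropped"),
    reason = ifelse(keep, "",
                    sprintf("poor_quality(<%d bands)", min_band_count)),
    stringsAsFactors = FALSE
  )
  list(
    fingerprints = fingerprint_set(kept[keep], provenance = set$provenance),
    report = report
  )
}
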