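#' Read / write protein FASTA
#'
#' FASTA parsing goes through Biostrings, so wrapped and unwrapped dialects
#' are both accepted. The record identifier is the first whitespace-delimited
#' token of the header; the remainder is kept as the description. Sequences
#' are uppercased. Duplicate identifiers are rejected.
#'
#' @param path Input path.
#' @return data.frame with columns `id`, `description`, `sequence`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- tryCatch(Biostrings::readAAStringSet(path),
                  error = function(e) stop("malformed FASTA '", path, "': ",
                                           conditionMessage(e)))
  if (length(set) == 0) stop("FASTA contains no records: ", path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids)) {
    stop("duplicate identifiers in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  data.frame(id = ids, description = desc,
             sequence = toupper(as.character(set)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' @rdname read_fasta
#' @param proteome data.frame with `id`, `description`, `sequence`.
#' @param width Line-wrap width for sequences.
#' @export
write_fasta <- function(proteome, path, width = 60) {
  proteome <- check_proteome(proteome)
  hdr <- ifelse(nzchar(proteome$description),
                paste(proteome$id, proteome$description), proteome$id)
  set <- Biostrings::AAStringSet(proteome$sequence)
  names(set) <- hdr
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read / write MGF peak lists
#'
#' Minimal reader/writer for the Mascot Generic Format: `BEGIN IONS` /
#' `END IONS` blocks with `PEPMASS` (interpreted as singly charged MH+),
#' `TITLE` as the spectrum identifier, and whitespace-separated `m/z
#' intensity` peak lines. Unsorted peak lists are sorted on load; spectra
#' whose precursor falls outside the instrument acquisition range are flagged
#' (`in_range = FALSE`), not dropped. Lines starting with `#` are ignored.
#'
#' @param path Input path.
#' @param instrument_range Acquisition m/z range used for the in-range flag.
#' @return `read_mgf()`: a list of [spectrum()] objects.
#' @export
read_mgf <- function(path, instrument_range = c(500, 4000)) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  begins <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(begins) != length(ends) || any(ends < begins)) {
    stop("malformed MGF (unbalanced BEGIN IONS/END IONS): ", path)
  }
  lapply(seq_along(begins), function(b) {
    block <- lines[(begins[b] + 1L):(ends[b] - 1L)]
    kv <- grepl("=", block, fixed = TRUE)
    keys <- sub("=.*$", "", block[kv])
    vals <- sub("^[^=]*=", "", block[kv])
    if (!"PEPMASS" %in% keys) {
      stop(sprintf("MGF block %d is missing PEPMASS (%s)", b, path))
    }
    pep <- as.numeric(strsplit(trimws(vals[match("PEPMASS", keys)]),
                               "\\s+")[[1]][1])
    title <- if ("TITLE" %in% keys) vals[match("TITLE", keys)] else
      sprintf("spectrum_%d", b)
    peaks <- block[!kv]
    if (length(peaks) > 0) {
      mat <- do.call(rbind, lapply(strsplit(peaks, "\\s+"), function(x)
        as.numeric(x[1:2])))
      if (anyNA(mat)) stop(sprintf("MGF block %d has malformed peak lines", b))
    } else {
      mat <- matrix(numeric(0), ncol = 2)
    }
    spectrum(id = title, precursor_mh = pep, mz = mat[, 1],
             intensity = ifelse(is.na(mat[, 2]), 0, mat[, 2]),
             instrument_range = instrument_range)
  })
}

#' @rdname read_mgf
#' @param spectra List of [spectrum()] objects.
#' @param meta Optional named list written as `#`-comment header lines.
#' @export
write_mgf <- function(spectra, path, meta = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(meta)) {
    for (k in names(meta)) writeLines(sprintf("# %s: %s", k, meta[[k]]), con)
  }
  for (s in spectra) {
    stopifnot(inherits(s, "spectrum"))
    writeLines("BEGIN IONS", con)
    writeLines(sprintf("TITLE=%s", s$id), con)
    writeLines(sprintf("PEPMASS=%.6f", s$precursor_mh), con)
    writeLines("CHARGE=1+", con)
    if (length(s$mz) > 0) {
      writeLines(sprintf("%.6f %.6f", s$mz, s$intensity), con)
    }
    writeLines("END IONS", con)
  }
  invisible(path)
}

#' Run configuration
#'
#' A run configuration bundles engine choice, motif and dibasic parameters,
#' PTM policy, tolerances and the seed; it round-trips losslessly through
#' JSON so runs can be reproduced exactly. `config_hash()` gives a short
#' digest recorded in output-file headers.
#'
#' @param engine `"cnidarian"` or `"dibasic"`.
#' @param cnidarian,dibasic Engine configurations.
#' @param ptms,cap Variant-expansion policy.
#' @param match A [match_config()].
#' @param seed Integer seed.
#' @return An object of class `run_config`.
#' @export
run_config <- function(engine = c("cnidarian", "dibasic"),
                       cnidarian = cnidarian_config(),
                       dibasic = dibasic_config(),
                       ptms = c("amidation", "pyroglu", "oxidation"),
                       cap = 64, match = match_config(), seed = 1) {
  engine <- match.arg(engine)
  structure(list(engine = engine, cnidarian = unclass(cnidarian),
                 dibasic = unclass(dibasic), ptms = ptms, cap = cap,
                 match = unclass(match), seed = as.integer(seed)),
            class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path JSON path.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  run_config(engine = x$engine,
             cnidarian = do.call(cnidarian_config, x$cnidarian),
             dibasic = do.call(dibasic_config, x$dibasic),
             ptms = x$ptms, cap = x$cap,
             match = do.call(match_config, x$match), seed = x$seed)
}

#' @rdname run_config
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA)
  substr(unname(tools::md5sum(tmp)), 1, 12)
}

# standard provenance header for output files
output_meta <- function(config = NULL, seed = NULL) {
  m <- list(tool = paste0("peptimine ",
                          as.character(utils::packageVersion("peptimine"))),
            date = format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
  if (!is.null(config)) m$config_hash <- config_hash(config)
  if (!is.null(seed)) m$seed <- seed
  m
}
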