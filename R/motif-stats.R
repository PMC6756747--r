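#' Census of neuropeptide hallmark motifs
#'
#' Computes, over a curated list of mature peptides in display notation, the
#' fractions carrying each structural hallmark: an early proline (position 2
#' or 3 by default, matching the `|XP` / `|XXP` extraction motifs), an
#' N-terminal glutamine (pyroglutamated Q counted as glutamine by default), a
#' C-terminal amide, either proline-or-glutamine hallmark, and compatibility
#' of the peptide length with the dibasic cleavage rule. This census is the
#' computation that motivates the choice of extraction motifs.
#'
#' @param peptides Character vector of display strings (`pQ...a`, `Mo`, ...)
#'   or a data.frame with a `sequence` column (see [read_curated_tsv()]).
#' @param proline_positions Residue positions (1-based) at which a proline
#'   counts as the proline hallmark.
#' @param count_pyroglu_as_Q Count pyroglutamated-Q (`pQ...`) peptides under
#'   the glutamine hallmark (pyroglutamate from E never counts as glutamine).
#' @param dibasic_range Length range compatible with the dibasic rule.
#' @return An object of class `hallmark_census`: list with `n`, `counts` and
#'   `fractions` (named: `proline`, `glutamine`, `either`, `amide`,
#'   `dibasic_compatible`), and the parsed table.
#' @examples
#' hallmark_frequencies(c("pQPPLDLGPAYFHIRa", "FPPGFHRPa", "AAAA"))
#' @export
hallmark_frequencies <- function(peptides, proline_positions = c(2, 3),
                                 count_pyroglu_as_Q = TRUE,
                                 dibasic_range = c(6, 40)) {
  if (is.data.frame(peptides)) peptides <- peptides$sequence
  peptides <- peptides[!is.na(peptides) & nzchar(peptides)]
  if (length(peptides) == 0) stop("empty peptide list")
  parsed <- lapply(peptides, parse_peptide_display)
  mature <- vapply(parsed, `[[`, character(1), "mature")
  pyro <- vapply(parsed, `[[`, character(1), "pyro")
  amid <- vapply(parsed, `[[`, logical(1), "amidated")
  pro <- vapply(mature, function(s) {
    pos <- proline_positions[proline_positions <= nchar(s)]
    any(substring(s, pos, pos) == "P")
  }, logical(1), USE.NAMES = FALSE)
  gln <- substr(mature, 1, 1) == "Q"
  if (!count_pyroglu_as_Q) gln <- gln & pyro != "Q"
  either <- pro | gln
  diba <- nchar(mature) >= dibasic_range[1] & nchar(mature) <= dibasic_range[2]
  counts <- c(proline = sum(pro), glutamine = sum(gln), either = sum(either),
              amide = sum(amid), dibasic_compatible = sum(diba))
  structure(list(n = length(peptides), counts = counts,
                 fractions = counts / length(peptides),
                 table = data.frame(sequence = peptides, mature = mature,
                                    proline = pro, glutamine = gln,
                                    either = either, amide = amid,
                                    dibasic_compatible = diba,
                                    stringsAsFactors = FALSE)),
            class = "hallmark_census")
}

#' @export
print.hallmark_census <- function(x, ...) {
  cat(sprintf("Hallmark census over %d peptide(s)\n", x$n))
  for (k in names(x$fractions)) {
    cat(sprintf("  %-18s %3d / %d  (%.3f)\n", k, x$counts[[k]], x$n,
                x$fractions[[k]]))
  }
  invisible(x)
}

#' Read a curated peptide table
#'
#' Reads a TSV of curated mature peptides with a header row; the `sequence`
#' column holds display-notation strings, remaining columns (species,
#' precursor, reference) are free-text annotation.
#'
#' @param path Path to the TSV; `#`-comment lines are skipped.
#' @return data.frame with at least a `sequence` column.
#' @export
read_curated_tsv <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!"sequence" %in% names(tab)) {
    stop("curated table must have a 'sequence' column: ", path)
  }
  tab
}

#' Search-space size comparison across engines
#'
#' Quantifies the database reduction: per extraction engine, the number of
#' candidate occurrences, unique stored sequences, and PTM variants, next to
#' the size of the no-cleavage search space (all substrings within the same
#' length bounds — the space a conventional no-enzyme search scores).
#'
#' @param proteome Proteome data.frame.
#' @param cnidarian,dibasic Engine configurations, or `NULL` to skip one.
#' @param ptms,cap Variant-expansion policy, see [peptide_database()].
#' @param substring_bounds Length bounds of the no-cleavage space; defaults to
#'   the cnidarian stored-length bounds.
#' @return data.frame with one row per engine plus a `no_cleavage` row
#'   (columns `engine`, `occurrences`, `unique_peptides`, `ptm_variants`).
#' @export
database_size_report <- function(proteome, cnidarian = cnidarian_config(),
                                 dibasic = dibasic_config(),
                                 ptms = c("amidation", "pyroglu", "oxidation"),
                                 cap = 64, substring_bounds = NULL) {
  proteome <- check_proteome(proteome)
  if (is.null(substring_bounds)) {
    substring_bounds <- if (!is.null(cnidarian)) {
      c(cnidarian$min_len, cnidarian$max_len)
    } else c(4, 50)
  }
  rows <- list()
  engine_row <- function(cands, name) {
    if (nrow(cands) == 0) {
      return(data.frame(engine = name, occurrences = 0L, unique_peptides = 0L,
                        ptm_variants = 0L, stringsAsFactors = FALSE))
    }
    db <- suppressWarnings(peptide_database(cands, ptms = ptms, cap = cap))
    data.frame(engine = name, occurrences = nrow(cands),
               unique_peptides = nrow(db$peptides),
               ptm_variants = nrow(db$variants), stringsAsFactors = FALSE)
  }
  if (!is.null(cnidarian)) {
    rows$cn <- engine_row(suppressWarnings(extract_cnidarian(proteome, cnidarian)),
                          "cnidarian")
  }
  if (!is.null(dibasic)) {
    rows$di <- engine_row(suppressWarnings(extract_dibasic(proteome, dibasic)),
                          "dibasic")
  }
  # no-cleavage space: count of substrings within bounds, standard runs only
  n_sub <- 0
  for (s in proteome$sequence) {
    for (seg in regmatches(s, gregexpr(sprintf("[%s]+", PM_ALPHABET), s))[[1]]) {
      L <- nchar(seg)
      lens <- seq.int(substring_bounds[1], min(substring_bounds[2], L))
      if (length(lens) > 0 && L >= substring_bounds[1]) {
        n_sub <- n_sub + sum(L - lens + 1)
      }
    }
  }
  rows$nc <- data.frame(engine = "no_cleavage", occurrences = as.integer(n_sub),
                        unique_peptides = NA_integer_,
                        ptm_variants = NA_integer_, stringsAsFactors = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
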