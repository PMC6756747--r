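#' Build a reduced peptide database from candidates
#'
#' Deduplicates candidate occurrences by stored sequence (multi-copy
#' precursors would otherwise inflate the database), retains full provenance,
#' and expands every unique stored sequence into its PTM variants. The result
#' is the searchable reduced database: precursor matching runs against the
#' variant table.
#'
#' @param candidates A `peptide_candidates` data.frame from
#'   [extract_cnidarian()] or [extract_dibasic()] (or both, row-bound).
#' @param ptms,cap,mass_table,ptm_table Passed to
#'   [apply_modification_variants()]. The dibasic engine's stored segments are
#'   expanded with the same policy.
#' @param decoy Logical flag recorded on the database (set for databases built
#'   from a [make_decoy()] proteome).
#' @return An object of class `peptide_db`: a list with
#'   * `peptides`: one row per unique stored sequence (`accession`, `stored`,
#'     `n_occurrences`, `n_parents`),
#'   * `provenance`: the occurrence table plus `accession`,
#'   * `variants`: the PTM-expanded search table (one row per mass-bearing
#'     variant, with `accession`),
#'   * `ptms`, `decoy`.
#' @examples
#' prot <- data.frame(id = "p1", description = "",
#'                    sequence = "AAAQPPLDLGPAYFHIRGRAAA")
#' db <- peptide_database(extract_cnidarian(prot))
#' db$peptides
#' @export
peptide_database <- function(candidates,
                             ptms = c("amidation", "pyroglu", "oxidation"),
                             cap = 64, decoy = FALSE,
                             mass_table = default_mass_table(),
                             ptm_table = default_ptm_table()) {
  if (!is.data.frame(candidates) || nrow(candidates) == 0) {
    stop("candidate list is empty")
  }
  # first occurrence (parent, start) fixes the stable ordering
  first <- !duplicated(candidates$stored)
  uniq <- candidates[first, , drop = FALSE]
  uniq <- uniq[order(uniq$parent_id, uniq$start0), , drop = FALSE]
  acc <- sprintf("pep%05d", seq_len(nrow(uniq)))
  names(acc) <- uniq$stored
  peptides <- data.frame(accession = acc,
                         stored = uniq$stored,
                         n_occurrences = as.integer(table(candidates$stored)[uniq$stored]),
                         n_parents = vapply(uniq$stored, function(s)
                           length(unique(candidates$parent_id[candidates$stored == s])),
                           integer(1)),
                         stringsAsFactors = FALSE, row.names = NULL)
  provenance <- as.data.frame(candidates)
  provenance$accession <- acc[provenance$stored]
  provenance <- provenance[order(provenance$accession, provenance$parent_id,
                                 provenance$start0), , drop = FALSE]
  rownames(provenance) <- NULL
  variants <- apply_modification_variants(peptides$stored, ptms = ptms,
                                          cap = cap, mass_table = mass_table,
                                          ptm_table = ptm_table)
  variants$accession <- acc[variants$stored]
  structure(list(peptides = peptides, provenance = provenance,
                 variants = variants, ptms = ptms, decoy = isTRUE(decoy)),
            class = "peptide_db")
}

#' @export
print.peptide_db <- function(x, ...) {
  cat(sprintf("Reduced peptide database%s: %d unique peptide(s), %d PTM variant(s), %d provenance row(s)\n",
              if (x$decoy) " (decoy)" else "",
              nrow(x$peptides), nrow(x$variants), nrow(x$provenance)))
  cat("PTM classes:", paste(x$ptms, collapse = ", "), "\n")
  invisible(x)
}

#' Write / read a peptide database
#'
#' The on-disk form mirrors the pipeline's interchange contract: a FASTA of
#' unique stored sequences (headers carry the accession plus the first
#' occurrence's parent and 0-based half-open coordinates) and a companion
#' provenance TSV (all occurrences, both coordinate conventions, motif
#' labels, applicable PTM classes).
#'
#' @param db A `peptide_db`.
#' @param fasta,tsv Output paths.
#' @param meta Optional named list written as `#`-comment header lines on the
#'   TSV (e.g. version, config hash, seed).
#' @return `write_peptide_database()`: invisibly, the two paths.
#' @export
write_peptide_database <- function(db, fasta, tsv, meta = NULL) {
  stopifnot(inherits(db, "peptide_db"))
  prov <- db$provenance
  firsts <- prov[!duplicated(prov$accession), , drop = FALSE]
  firsts <- firsts[match(db$peptides$accession, firsts$accession), , drop = FALSE]
  headers <- sprintf("%s parent=%s start0=%d end0=%d engine=%s",
                     db$peptides$accession, firsts$parent_id,
                     firsts$start0, firsts$end0, firsts$engine)
  write_fasta(data.frame(id = headers, description = "",
                         sequence = db$peptides$stored,
                         stringsAsFactors = FALSE), fasta)
  out <- prov
  out$start1 <- out$start0 + 1L   # 1-based inclusive, for human reading
  out$end1 <- out$end0            # half-open end == inclusive 1-based end
  out$ptms <- vapply(out$stored, function(s) {
    p <- character(0)
    if (endsWith(s, "G")) p <- c(p, "amidation")
    if (substr(s, 1, 1) %in% c("Q", "E")) p <- c(p, "pyroglu")
    if (grepl("M", s, fixed = TRUE)) p <- c(p, "oxidation")
    paste(p, collapse = ",")
  }, character(1), USE.NAMES = FALSE)
  write_tsv_with_header(out, tsv, meta)
  invisible(c(fasta = fasta, tsv = tsv))
}

# TSV writer with "#"-comment provenance header lines
write_tsv_with_header <- function(df, path, meta = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(meta)) {
    for (k in names(meta)) {
      writeLines(sprintf("# %s: %s", k, meta[[k]]), con)
    }
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
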