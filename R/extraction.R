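#' Cnidarian hallmark-motif configuration
#'
#' Parameters of the cnidarian extraction engine. The C-terminal motif is a
#' glycine (required for amidation) followed by a basic residue, with the cut
#' immediately after the basic residue (`GK|` / `GR|`). Candidate N-termini
#' within an upstream window are starts with glutamine at position 1 (`|Q`,
#' the pyroglutamate hallmark) or proline at position 2 (`|XP`) or 3 (`|XXP`).
#' The C-terminal K/R of each extracted segment is removed before storage, so
#' stored sequences stay glycine-extended and amidation is applied downstream
#' as a variable modification.
#'
#' @param c_motifs Character vector of two-letter C-terminal motifs
#'   (glycine + basic residue).
#' @param n_motifs Character subset of `c("Q", "XP", "XXP")`.
#' @param window Upstream search window (residues) for N-termini, counted from
#'   the cut.
#' @param min_len,max_len Stored-peptide length bounds (residues).
#' @param strip_extra_basic If `TRUE`, a basic residue immediately following a
#'   motif cut (as in `GKR`) yields an additional cut with both basic residues
#'   stripped. Default `FALSE` (the literal rule).
#' @return An object of class `cnidarian_config`.
#' @export
cnidarian_config <- function(c_motifs = c("GK", "GR"),
                             n_motifs = c("Q", "XP", "XXP"),
                             window = 50, min_len = 4, max_len = 50,
                             strip_extra_basic = FALSE) {
  n_motifs <- match.arg(n_motifs, several.ok = TRUE)
  stopifnot(length(c_motifs) >= 1, all(nchar(c_motifs) == 2),
            length(n_motifs) >= 1,
            min_len >= 1, min_len <= max_len, window >= max_len)
  structure(list(c_motifs = toupper(c_motifs), n_motifs = n_motifs,
                 window = as.integer(window), min_len = as.integer(min_len),
                 max_len = as.integer(max_len),
                 strip_extra_basic = isTRUE(strip_extra_basic)),
            class = "cnidarian_config")
}

#' Bilaterian dibasic cleavage configuration
#'
#' Parameters of the comparison engine modelling prohormone-convertase
#' processing in bilaterian precursors: peptides flanked on both sides by
#' basic-residue pairs `(K/R) X^m (K/R) | X_k (K/R) X^n (K/R) |`, where the
#' flanking residues are removed and the `X_k` segment is stored.
#'
#' @param spacers Allowed values of the intra-pair spacers m and n.
#' @param min_len,max_len Bounds on the stored segment length k.
#' @param basic Basic residue set.
#' @param relax_termini If `TRUE`, the protein N- and C-termini also count as
#'   cleavage boundaries (no flanking motif required there). Default `FALSE`:
#'   strict flanking motifs on both sides.
#' @return An object of class `dibasic_config`.
#' @export
dibasic_config <- function(spacers = c(0, 2, 4, 6), min_len = 6, max_len = 40,
                           basic = c("K", "R"), relax_termini = FALSE) {
  stopifnot(all(spacers >= 0), min_len >= 1, min_len <= max_len,
            length(basic) >= 1)
  structure(list(spacers = as.integer(sort(unique(spacers))),
                 min_len = as.integer(min_len), max_len = as.integer(max_len),
                 basic = toupper(basic), relax_termini = isTRUE(relax_termini)),
            class = "dibasic_config")
}

# validate a proteome data.frame (columns id, description, sequence)
check_proteome <- function(proteome) {
  if (!is.data.frame(proteome) || !all(c("id", "sequence") %in% names(proteome))) {
    stop("proteome must be a data.frame with columns 'id' and 'sequence'")
  }
  if (nrow(proteome) == 0) stop("proteome has zero records")
  if (anyDuplicated(proteome$id)) stop("duplicate protein identifiers")
  if (is.null(proteome$description)) proteome$description <- ""
  proteome$sequence <- toupper(proteome$sequence)
  proteome
}

#' Scan one protein for C-terminal motif cuts
#'
#' Positions of hallmark C-terminal cleavage sites: a cut falls immediately
#' after a basic residue preceded by glycine. Overlapping occurrences all
#' yield cuts.
#'
#' @param sequence One protein sequence (character scalar).
#' @param config A [cnidarian_config()].
#' @return Integer vector of 0-based cut positions (a cut at `c` means the
#'   cleaved segment ends at residue index `c - 1`), sorted ascending. The
#'   basic residue at index `c - 1` is the one stripped from storage.
#' @examples
#' scan_cterm_sites("AGKA")   # cut after the K
#' scan_cterm_sites("AGKRA")  # one cut: GK matches, KR is not a C-motif
#' @export
scan_cterm_sites <- function(sequence, config = cnidarian_config()) {
  stopifnot(length(sequence) == 1)
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (n < 2) return(integer(0))
  pair <- paste0(chars[-n], chars[-1])
  hit <- which(pair %in% config$c_motifs)  # hit i => motif at i..i+1 (1-based)
  cuts <- hit + 1L                          # 0-based cut after the basic residue
  n_strip <- rep.int(1L, length(cuts))
  if (config$strip_extra_basic && length(hit) > 0) {
    extra <- hit + 2L <= n & chars[pmin(hit + 2L, n)] %in% c("K", "R")
    if (any(extra)) {
      cuts <- c(cuts, hit[extra] + 2L)
      n_strip <- c(n_strip, rep.int(2L, sum(extra)))
    }
  }
  o <- order(cuts)
  structure(cuts[o], n_strip = n_strip[o])
}

#' Candidate N-terminal starts upstream of a cut
#'
#' All starts `s` (0-based) within the configured window upstream of a
#' C-terminal cut such that the stored peptide (start to the residue before
#' the stripped basic) begins with glutamine or has proline at its second or
#' third position, with stored length within bounds. A start satisfying
#' several motifs is reported once with all labels.
#'
#' @inheritParams scan_cterm_sites
#' @param cut 0-based cut position from [scan_cterm_sites()].
#' @param n_strip Number of trailing basic residues stripped at this cut.
#' @return data.frame with columns `start0` (0-based), `stored`, `n_motifs`
#'   (comma-joined labels among `Q`, `XP`, `XXP`).
#' @export
scan_nterm_starts <- function(sequence, cut, config = cnidarian_config(),
                              n_strip = 1L) {
  stopifnot(length(sequence) == 1, length(cut) == 1)
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  end_stored <- cut - n_strip            # 0-based exclusive end of stored seq
  lo <- max(0L, cut - config$window)
  hi <- end_stored - config$min_len
  if (hi < lo) {
    return(data.frame(start0 = integer(0), stored = character(0),
                      n_motifs = character(0), stringsAsFactors = FALSE))
  }
  starts <- seq.int(lo, hi)
  starts <- starts[end_stored - starts <= config$max_len &
                     end_stored - starts >= config$min_len]
  if (length(starts) == 0) {
    return(data.frame(start0 = integer(0), stored = character(0),
                      n_motifs = character(0), stringsAsFactors = FALSE))
  }
  lab <- vapply(starts, function(s) {
    hits <- character(0)
    if ("Q" %in% config$n_motifs && chars[s + 1L] == "Q") hits <- c(hits, "Q")
    if ("XP" %in% config$n_motifs && s + 2L <= end_stored &&
        chars[s + 2L] == "P") hits <- c(hits, "XP")
    if ("XXP" %in% config$n_motifs && s + 3L <= end_stored &&
        chars[s + 3L] == "P") hits <- c(hits, "XXP")
    paste(hits, collapse = ",")
  }, character(1))
  keep <- nzchar(lab)
  data.frame(start0 = starts[keep],
             stored = vapply(starts[keep], function(s)
               paste(chars[(s + 1L):end_stored], collapse = ""), character(1)),
             n_motifs = lab[keep], stringsAsFactors = FALSE)
}

#' Extract hallmark-motif peptide candidates from a proteome
#'
#' Runs the cnidarian engine over every protein: every C-terminal motif cut
#' combined with every admissible N-terminal start yields one candidate
#' occurrence. Stored sequences have the C-terminal basic residue(s) removed
#' and remain glycine-extended. Candidates whose stored window contains
#' non-standard letters (X, B, Z, U, *) are skipped with one summary warning.
#'
#' @param proteome data.frame with columns `id`, `description`, `sequence`
#'   (see [read_fasta()]).
#' @param config A [cnidarian_config()].
#' @return A data.frame of class `peptide_candidates`, one row per motif
#'   occurrence, ordered by (parent id, start): columns `stored`, `parent_id`,
#'   `start0`, `end0` (0-based half-open on the parent, stored segment),
#'   `n_motifs`, `c_motif`, `engine`.
#' @examples
#' prot <- data.frame(id = "p1", description = "",
#'                    sequence = "AAAQPPLDLGPAYFHIRGRAAA")
#' extract_cnidarian(prot)
#' @export
extract_cnidarian <- function(proteome, config = cnidarian_config()) {
  proteome <- check_proteome(proteome)
  rows <- vector("list", nrow(proteome))
  n_skipped <- 0L
  for (i in seq_len(nrow(proteome))) {
    seqi <- proteome$sequence[i]
    cuts <- scan_cterm_sites(seqi, config)
    if (length(cuts) == 0) next
    strips <- attr(cuts, "n_strip")
    chars <- strsplit(seqi, "", fixed = TRUE)[[1]]
    per_cut <- lapply(seq_along(cuts), function(j) {
      st <- scan_nterm_starts(seqi, cuts[j], config, n_strip = strips[j])
      if (nrow(st) == 0) return(NULL)
      st$end0 <- cuts[j] - strips[j]
      st$c_motif <- paste(chars[(cuts[j] - strips[j]):cuts[j]], collapse = "")
      st
    })
    tab <- do.call(rbind, per_cut)
    if (is.null(tab) || nrow(tab) == 0) next
    ok <- is_standard_sequence(tab$stored)
    n_skipped <- n_skipped + sum(!ok)
    tab <- tab[ok, , drop = FALSE]
    if (nrow(tab) == 0) next
    tab$parent_id <- proteome$id[i]
    rows[[i]] <- tab
  }
  if (n_skipped > 0) {
    warning(n_skipped, " candidate(s) skipped: non-standard residue letters")
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(stored = character(0), parent_id = character(0),
                      start0 = integer(0), end0 = integer(0),
                      n_motifs = character(0), c_motif = character(0),
                      stringsAsFactors = FALSE)
  }
  out$engine <- rep("cnidarian", nrow(out))
  out <- out[order(out$parent_id, out$start0, out$end0),
             c("stored", "parent_id", "start0", "end0", "n_motifs",
               "c_motif", "engine")]
  rownames(out) <- NULL
  class(out) <- c("peptide_candidates", "data.frame")
  attr(out, "config") <- config
  out
}

#' Extract dibasic-flanked peptide candidates
#'
#' The comparison engine: stores every `X_k` segment flanked by basic-residue
#' pairs `(K/R) X^m (K/R) | X_k (K/R) X^n (K/R) |` with m, n drawn from the
#' configured spacer set and k within the length range. All overlapping
#' matches are enumerated; identical coordinates reached through different
#' spacers are reported once with all spacer labels.
#'
#' @inheritParams extract_cnidarian
#' @param config A [dibasic_config()].
#' @return A `peptide_candidates` data.frame (as [extract_cnidarian()]), with
#'   `n_motifs` the left-flank spacer label(s) (`m=0`, ...) and `c_motif` the
#'   right-flank label(s) (`n=0`, ...).
#' @export
extract_dibasic <- function(proteome, config = dibasic_config()) {
  proteome <- check_proteome(proteome)
  rows <- vector("list", nrow(proteome))
  n_skipped <- 0L
  for (i in seq_len(nrow(proteome))) {
    chars <- strsplit(proteome$sequence[i], "", fixed = TRUE)[[1]]
    n <- length(chars)
    basic <- chars %in% config$basic
    # left flanks: B X^m B ending at position e (1-based); cut after e
    left <- list()   # cut position (0-based) -> labels
    right <- list()  # 1-based index of first residue of right flank -> labels
    for (m in config$spacers) {
      e <- which(basic)
      e <- e[e - m - 1L >= 1L & basic[pmax(e - m - 1L, 1L)]]
      for (pos in e) {
        key <- as.character(pos)  # cut after pos => stored starts at pos (0-based)
        left[[key]] <- c(left[[key]], sprintf("m=%d", m))
      }
      s <- which(basic)
      s <- s[s + m + 1L <= n & basic[pmin(s + m + 1L, n)]]
      for (pos in s) {
        key <- as.character(pos)
        right[[key]] <- c(right[[key]], sprintf("n=%d", m))
      }
    }
    if (config$relax_termini) {
      left[["0"]] <- c(left[["0"]], "nterm")
      right[[as.character(n + 1L)]] <- c(right[[as.character(n + 1L)]], "cterm")
    }
    if (length(left) == 0 || length(right) == 0) next
    lpos <- as.integer(names(left))
    rpos <- as.integer(names(right))
    combos <- expand.grid(l = lpos, r = rpos)
    k <- combos$r - combos$l - 1L
    combos <- combos[k >= config$min_len & k <= config$max_len, , drop = FALSE]
    if (nrow(combos) == 0) next
    tab <- data.frame(
      stored = vapply(seq_len(nrow(combos)), function(j)
        paste(chars[(combos$l[j] + 1L):(combos$r[j] - 1L)], collapse = ""),
        character(1)),
      parent_id = proteome$id[i],
      start0 = combos$l,
      end0 = combos$r - 1L,
      n_motifs = vapply(as.character(combos$l), function(key)
        paste(unique(left[[key]]), collapse = ","), character(1)),
      c_motif = vapply(as.character(combos$r), function(key)
        paste(unique(right[[key]]), collapse = ","), character(1)),
      stringsAsFactors = FALSE)
    ok <- is_standard_sequence(tab$stored)
    n_skipped <- n_skipped + sum(!ok)
    rows[[i]] <- tab[ok, , drop = FALSE]
  }
  if (n_skipped > 0) {
    warning(n_skipped, " candidate(s) skipped: non-standard residue letters")
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(stored = character(0), parent_id = character(0),
                      start0 = integer(0), end0 = integer(0),
                      n_motifs = character(0), c_motif = character(0),
                      stringsAsFactors = FALSE)
  }
  out$engine <- rep("dibasic", nrow(out))
  out <- out[order(out$parent_id, out$start0, out$end0),
             c("stored", "parent_id", "start0", "end0", "n_motifs",
               "c_motif", "engine")]
  rownames(out) <- NULL
  class(out) <- c("peptide_candidates", "data.frame")
  attr(out, "config") <- config
  out
}

#' @export
print.peptide_candidates <- function(x, ...) {
  eng <- unique(x$engine)
  cat(sprintf("Peptide candidates: %d occurrence(s), %d unique stored sequence(s), engine %s\n",
              nrow(x), length(unique(x$stored)),
              paste(eng, collapse = "/")))
  print(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

#' Shuffled-sequence decoy proteome
#'
#' Builds a decoy proteome by uniformly permuting each protein's residues
#' (per-protein shuffle, so the global and per-protein amino-acid compositions
#' are preserved). Identifiers are prefixed so decoy hits are recognizable
#' downstream.
#'
#' @inheritParams extract_cnidarian
#' @param seed Integer seed; the same seed and input give an identical decoy.
#' @param prefix Identifier prefix for decoy records.
#' @return A proteome data.frame of the same shape.
#' @export
make_decoy <- function(proteome, seed, prefix = "DECOY_") {
  proteome <- check_proteome(proteome)
  with_local_seed(seed, {
    proteome$sequence <- vapply(proteome$sequence, function(s) {
      ch <- strsplit(s, "", fixed = TRUE)[[1]]
      paste(sample(ch), collapse = "")
    }, character(1), USE.NAMES = FALSE)
  })
  proteome$id <- paste0(prefix, proteome$id)
  proteome
}

# run code under a temporary RNG state, restoring the caller's state after
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}
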