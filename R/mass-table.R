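#' Monoisotopic mass table
#'
#' Loads the residue mass table used throughout the package. The default table
#' ships with the package as a plain-text TSV
#' (`inst/extdata/monoisotopic_masses.tsv`) holding the monoisotopic residue
#' masses of the 20 standard amino acids plus the water and proton constants;
#' pointing `path` at an edited copy (e.g. average masses) swaps the mass
#' scale without code changes.
#'
#' @param path Path to a two-column TSV (`name`, `mass`) with one row per
#'   residue letter and rows named `water` and `proton`. Lines starting with
#'   `#` are ignored.
#' @return An object of class `mass_table`: a list with `residues` (named
#'   numeric vector of length 20), `water` and `proton` (Da).
#' @examples
#' mt <- load_mass_table()
#' mt$residues[["G"]]
#' @export
load_mass_table <- function(path = system.file("extdata", "monoisotopic_masses.tsv",
                                               package = "peptimine")) {
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("name", "mass") %in% names(tab))) {
    stop("mass table must have columns 'name' and 'mass': ", path)
  }
  masses <- stats::setNames(as.numeric(tab$mass), tab$name)
  if (!all(c("water", "proton") %in% names(masses))) {
    stop("mass table must define 'water' and 'proton' rows")
  }
  residues <- masses[setdiff(names(masses), c("water", "proton"))]
  if (!setequal(names(residues), strsplit(PM_ALPHABET, "")[[1]])) {
    stop("mass table must cover exactly the 20 standard residue letters")
  }
  if (any(!is.finite(masses)) || any(masses <= 0)) {
    stop("all masses must be finite and > 0")
  }
  structure(list(residues = residues[order(names(residues))],
                 water = unname(masses[["water"]]),
                 proton = unname(masses[["proton"]])),
            class = "mass_table")
}

#' Post-translational modification deltas
#'
#' Loads the PTM mass-delta table (amide vs free acid, pyroglutamate from Q or
#' E, methionine oxidation) from a plain-text TSV. The glycine removed when a
#' glycine-extended peptide is amidated is accounted at the sequence level, so
#' the `amidation` row carries only the amide-vs-acid delta (-0.984016 Da).
#'
#' @param path Path to a two-column TSV (`name`, `delta`).
#' @return Named numeric vector with elements `amidation`, `pyroglu_Q`,
#'   `pyroglu_E`, `oxidation_M` (Da).
#' @export
load_ptm_table <- function(path = system.file("extdata", "ptm_deltas.tsv",
                                              package = "peptimine")) {
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  deltas <- stats::setNames(as.numeric(tab$delta), tab$name)
  need <- c("amidation", "pyroglu_Q", "pyroglu_E", "oxidation_M")
  if (!all(need %in% names(deltas))) {
    stop("PTM table must define: ", paste(need, collapse = ", "))
  }
  deltas[need]
}

PM_ALPHABET <- "ACDEFGHIKLMNPQRSTVWY"

# package-level cache so the default tables are read once per session
.pm_cache <- new.env(parent = emptyenv())

#' @rdname load_mass_table
#' @export
default_mass_table <- function() {
  if (is.null(.pm_cache$mass_table)) .pm_cache$mass_table <- load_mass_table()
  .pm_cache$mass_table
}

#' @rdname load_ptm_table
#' @export
default_ptm_table <- function() {
  if (is.null(.pm_cache$ptm_table)) .pm_cache$ptm_table <- load_ptm_table()
  .pm_cache$ptm_table
}

#' @export
print.mass_table <- function(x, ...) {
  cat("Residue mass table (", length(x$residues), " residues)\n", sep = "")
  cat("  water  ", format(x$water, nsmall = 6), " Da\n", sep = "")
  cat("  proton ", format(x$proton, nsmall = 6), " Da\n", sep = "")
  print(round(x$residues, 5))
  invisible(x)
}

#' Monoisotopic peptide mass
#'
#' Neutral monoisotopic mass of one or more unmodified peptides: the sum of
#' residue masses plus one water.
#'
#' @param sequence Character vector of residue strings (20-letter alphabet).
#' @param mass_table A `mass_table`, by default the packaged monoisotopic one.
#' @return Numeric vector of masses in Da.
#' @examples
#' peptide_mass("G")    # 75.03203
#' peptide_mass(c("AG", "GA"))
#' @export
peptide_mass <- function(sequence, mass_table = default_mass_table()) {
  if (length(sequence) == 0) return(numeric(0))
  if (any(is.na(sequence)) || any(!nzchar(sequence))) {
    stop("invalid sequence: empty or NA")
  }
  chars <- strsplit(sequence, "", fixed = TRUE)
  lens <- lengths(chars)
  flat <- unlist(chars, use.names = FALSE)
  m <- mass_table$residues[flat]
  if (anyNA(m)) {
    bad <- unique(flat[is.na(m)])
    stop("invalid sequence: unknown residue letter(s) ",
         paste(bad, collapse = ", "))
  }
  grp <- rep.int(seq_along(sequence), lens)
  unname(rowsum(m, grp)[, 1]) + mass_table$water
}

#' Singly protonated ion m/z
#'
#' MH+ of a neutral mass: mass plus one proton (MALDI positive mode produces
#' predominantly singly charged ions).
#'
#' @param mass Numeric vector of neutral masses (Da), all > 0.
#' @inheritParams peptide_mass
#' @return Numeric vector, `mass + proton`.
#' @examples
#' mh_plus(peptide_mass("G"))  # 76.03931
#' @export
mh_plus <- function(mass, mass_table = default_mass_table()) {
  if (any(!is.finite(mass)) || any(mass <= 0)) {
    stop("mass must be positive and finite")
  }
  mass + mass_table$proton
}

# TRUE for strings made only of the 20 standard residue letters
is_standard_sequence <- function(sequence) {
  nzchar(sequence) & !grepl(sprintf("[^%s]", PM_ALPHABET), sequence)
}
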