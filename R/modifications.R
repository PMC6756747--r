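#' Enumerate PTM variants of a stored peptide
#'
#' A stored candidate is the in-silico cleaved segment with its C-terminal
#' basic residue removed, i.e. still glycine-extended where the mature peptide
#' is amidated. This function enumerates every legal combination of the
#' variable modifications considered:
#'
#' * C-terminal amidation of glycine-extended peptides (applies only when the
#'   stored sequence ends in `G`; the glycine is consumed),
#' * N-terminal pyroglutamate (applies only when the first residue is `Q` or
#'   `E`),
#' * methionine oxidation (each `M` independently oxidized or not).
#'
#' Each variant carries its neutral monoisotopic mass, MH+, and a display
#' string in the conventional compact notation: `p` prefixed to a cyclized
#' N-terminal Q/E, `a` appended for an amidated C-terminus, and `o` following
#' each oxidized methionine (so `pQPPLDLGPAYFHIRa`, `GPPMoIKIPVRHa`).
#'
#' @param stored Character vector of stored (glycine-extended,
#'   basic-residue-stripped) sequences.
#' @param ptms Character subset of `c("amidation", "pyroglu", "oxidation")`
#'   naming the modification classes to consider.
#' @param cap Maximum number of variants per stored sequence; oxidation-rich
#'   sequences are truncated (fewest oxidations kept) with a warning.
#' @param mass_table,ptm_table Mass configuration, see [load_mass_table()].
#' @return A data.frame with one row per variant: `stored`, `mature` (sequence
#'   after glycine loss, if any), `display`, `pyro` (`""`, `"Q"` or `"E"`),
#'   `amidated` (logical), `ox` (comma-separated 1-based positions of oxidized
#'   methionines in `mature`, `""` if none), `n_mods`, `mass`, `mh`.
#' @examples
#' v <- apply_modification_variants("QPPLDLGPAYFHIRG")
#' subset(v, display == "pQPPLDLGPAYFHIRa")
#' @export
apply_modification_variants <- function(stored,
                                        ptms = c("amidation", "pyroglu", "oxidation"),
                                        cap = 64,
                                        mass_table = default_mass_table(),
                                        ptm_table = default_ptm_table()) {
  ptms <- match.arg(ptms, several.ok = TRUE)
  stopifnot(length(stored) >= 1, cap >= 1)
  if (!all(is_standard_sequence(stored))) {
    stop("invalid stored sequence(s): ",
         paste(stored[!is_standard_sequence(stored)], collapse = ", "))
  }
  out <- lapply(stored, variants_one, ptms = ptms, cap = cap,
                mass_table = mass_table, ptm_table = ptm_table)
  do.call(rbind, out)
}

variants_one <- function(stored, ptms, cap, mass_table, ptm_table) {
  first <- substr(stored, 1, 1)
  last <- substr(stored, nchar(stored), nchar(stored))

  amid_opts <- FALSE
  if ("amidation" %in% ptms && last == "G" && nchar(stored) > 1) {
    amid_opts <- c(FALSE, TRUE)
  }
  pyro_opts <- ""
  if ("pyroglu" %in% ptms && first %in% c("Q", "E")) {
    pyro_opts <- c("", first)
  }

  rows <- list()
  for (amid in amid_opts) {
    mature <- if (amid) substr(stored, 1, nchar(stored) - 1) else stored
    m_pos <- which(strsplit(mature, "", fixed = TRUE)[[1]] == "M")
    ox_sets <- list(integer(0))
    if ("oxidation" %in% ptms && length(m_pos) > 0) {
      # enumerate subsets ordered by size so truncation keeps the lighter ones
      for (k in seq_along(m_pos)) {
        idx <- utils::combn(seq_along(m_pos), k, simplify = FALSE)
        ox_sets <- c(ox_sets, lapply(idx, function(j) m_pos[j]))
      }
      ox_sets <- ox_sets[order(lengths(ox_sets))]
    }
    base_mass <- peptide_mass(mature, mass_table)
    for (pyro in pyro_opts) {
      for (ox in ox_sets) {
        delta <- 0
        if (amid) delta <- delta + ptm_table[["amidation"]]
        if (pyro == "Q") delta <- delta + ptm_table[["pyroglu_Q"]]
        if (pyro == "E") delta <- delta + ptm_table[["pyroglu_E"]]
        delta <- delta + length(ox) * ptm_table[["oxidation_M"]]
        mass <- base_mass + delta
        rows[[length(rows) + 1L]] <- data.frame(
          stored = stored,
          mature = mature,
          display = format_peptide_display(mature, pyro = pyro,
                                           amidated = amid, ox = ox),
          pyro = pyro,
          amidated = amid,
          ox = paste(ox, collapse = ","),
          n_mods = (pyro != "") + amid + length(ox),
          mass = mass,
          mh = mh_plus(mass, mass_table),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (nrow(out) > cap) {
    warning(sprintf("variant cap reached for '%s': keeping %d of %d variants",
                    stored, cap, nrow(out)))
    out <- out[order(out$n_mods), , drop = FALSE][seq_len(cap), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Compact display notation for modified peptides
#'
#' Formats or parses the compact notation used for mature neuropeptides:
#' `p` before a pyroglutamated N-terminal Q/E, `o` after each oxidized
#' methionine, trailing `a` for a C-terminal amide.
#'
#' @param mature Mature residue sequence (glycine already removed if amidated).
#' @param pyro `""`, `"Q"` or `"E"`; must match the first residue.
#' @param amidated Logical.
#' @param ox Integer vector of 1-based oxidized-M positions in `mature`.
#' @return `format_peptide_display()`: the display string.
#'   `parse_peptide_display()`: a list with `stored` (glycine restored if
#'   amidated), `mature`, `pyro`, `amidated`, `ox`.
#' @examples
#' format_peptide_display("QPPLDLGPAYFHIR", pyro = "Q", amidated = TRUE)
#' parse_peptide_display("GPPMoIKIPVRHa")
#' @export
format_peptide_display <- function(mature, pyro = "", amidated = FALSE,
                                   ox = integer(0)) {
  stopifnot(length(mature) == 1, is_standard_sequence(mature))
  if (pyro != "" && substr(mature, 1, 1) != pyro) {
    stop("pyro residue does not match first residue of ", mature)
  }
  chars <- strsplit(mature, "", fixed = TRUE)[[1]]
  if (length(ox) > 0) {
    if (any(chars[ox] != "M")) stop("oxidation site is not an M in ", mature)
    chars[ox] <- "Mo"
  }
  paste0(if (pyro != "") "p" else "", paste(chars, collapse = ""),
         if (amidated) "a" else "")
}

#' @rdname format_peptide_display
#' @param display A display string such as `"pQPPLDLGPAYFHIRa"`.
#' @export
parse_peptide_display <- function(display) {
  stopifnot(length(display) == 1, is.character(display), nzchar(display))
  s <- display
  pyro <- ""
  if (substr(s, 1, 1) == "p") {
    s <- substr(s, 2, nchar(s))
    pyro <- substr(s, 1, 1)
    if (!pyro %in% c("Q", "E")) {
      stop("malformed display string (p not before Q/E): ", display)
    }
  }
  amidated <- FALSE
  if (substr(s, nchar(s), nchar(s)) == "a") {
    amidated <- TRUE
    s <- substr(s, 1, nchar(s) - 1)
  }
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  ox <- integer(0)
  keep <- logical(length(chars))
  pos <- 0L
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == "o") {
      if (i == 1L || chars[i - 1L] != "M") {
        stop("malformed display string (o not after M): ", display)
      }
      ox <- c(ox, pos)
    } else {
      keep[i] <- TRUE
      pos <- pos + 1L
    }
  }
  mature <- paste(chars[keep], collapse = "")
  if (!is_standard_sequence(mature)) {
    stop("malformed display string: ", display)
  }
  list(stored = if (amidated) paste0(mature, "G") else mature,
       mature = mature, pyro = pyro, amidated = amidated, ox = ox)
}

#' Mass of a parsed display string
#'
#' Convenience wrapper: monoisotopic mass / MH+ of a peptide given in display
#' notation.
#'
#' @inheritParams parse_peptide_display
#' @inheritParams apply_modification_variants
#' @return List with `mass` and `mh` (Da).
#' @export
display_mass <- function(display, mass_table = default_mass_table(),
                         ptm_table = default_ptm_table()) {
  p <- parse_peptide_display(display)
  mass <- peptide_mass(p$mature, mass_table) +
    (if (p$amidated) ptm_table[["amidation"]] else 0) +
    (if (p$pyro == "Q") ptm_table[["pyroglu_Q"]] else 0) +
    (if (p$pyro == "E") ptm_table[["pyroglu_E"]] else 0) +
    length(p$ox) * ptm_table[["oxidation_M"]]
  list(mass = mass, mh = mh_plus(mass, mass_table))
}
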