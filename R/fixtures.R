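#' Reference set of identified cnidarian neuropeptides
#'
#' The 20 mature neuropeptides identified from the sea anemone *Nematostella
#' vectensis* by reduced-database spectral matching, in display notation
#' (`p` = N-terminal pyroglutamate, `a` = C-terminal amide, `o` = oxidized
#' methionine), grouped into six precursor families by their shared C-terminal
#' motif. This set doubles as the ground truth for the end-to-end recovery
#' fixtures.
#'
#' @return data.frame with columns `family`, `id`, `display`.
#' @export
table1_peptides <- function() {
  data.frame(
    family = c(rep("HIRamide", 10), rep("PRGamide", 2), rep("QWamide", 3),
               rep("RFamide", 2), "RPamide", rep("RHamide", 2)),
    id = 1:20,
    display = c(
      "APPLDLSGPAYFHIRa",
      "GPPYIDLTEPSFFHIRa",
      "NPPIDLGPAYFHIRa",
      "pQPPIDLSPAAYFHIRa",
      "pQPPLDLGPAYFHIRa",
      "pQPPYLDLGEPSFFHIRa",
      "pQPPYLDLTPAYFHIRa",
      "pQPPYLDLTPSYFHIRa",
      "pQPPMIDLSEPAFFHIRa",
      "pQQPPMIDLSEPAFFHIRa",
      "GPRGGRATEFGPRGa",
      "GPRGGREVNLEGPRGa",
      "IPPQGFRFNQWa",
      "IPPQGLRFNQWa",
      "IPPQGLRFSQWa",
      "MPEQDANPQTRFDa",
      "pQGRFGREDQGRFa",
      "FPPGFHRPa",
      "GPPMIKIPVRHa",
      "GPPMoIKIPVRHa"),
    stringsAsFactors = FALSE)
}

#' De-modify a display string into its precursor-encoded form
#'
#' Inverts the maturation steps so a mature peptide can be written back into
#' a precursor sequence: pyroglutamate reverts to the encoded Q/E, oxidized
#' methionines revert to M, and an amidated C-terminus regains its glycine
#' plus a basic flanking residue (the amidation/cleavage signal).
#'
#' @param display Display string.
#' @param flank Basic residue to append after the glycine of amidated
#'   peptides (`"R"` or `"K"`).
#' @return List with `stored` (precursor-encoded segment, glycine-extended,
#'   without the flank), `flank` (`""` when the peptide is not amidated) and
#'   the parsed modification state.
#' @examples
#' demodify("pQPPLDLGPAYFHIRa")   # stored QPPLDLGPAYFHIRG + flank R
#' @export
demodify <- function(display, flank = c("R", "K")) {
  flank <- match.arg(flank)
  p <- parse_peptide_display(display)
  list(stored = p$stored, flank = if (p$amidated) flank else "",
       mature = p$mature, pyro = p$pyro, amidated = p$amidated, ox = p$ox)
}

# linker alphabet excludes P, Q, G, K, R so linkers can neither complete a
# C-terminal motif nor offer spurious N-terminal hallmarks
PM_LINKER_ALPHABET <- c("A", "L", "S", "T", "V", "D", "E")

# fixed hydrophobic stub standing in for a signal peptide; exercises the
# annotation field only, it is not a predicted signal sequence
PM_SIGNAL_STUB <- "MALWVTLLLASLLSV"

#' Assemble a synthetic neuropeptide precursor
#'
#' Builds one precursor protein in the canonical architecture: an N-terminal
#' hydrophobic stub (signal-peptide placeholder) followed by multiple copies
#' of mature peptide units, each written as its precursor-encoded segment plus
#' its basic flank, separated by random linkers drawn from an alphabet that
#' cannot create spurious extraction motifs. A truth table of embedded
#' coordinates is attached.
#'
#' @param displays Character vector of mature peptides (display notation) to
#'   embed, in order.
#' @param id Protein identifier.
#' @param seed Integer seed for linker construction.
#' @param copies Copies of the whole peptide list to embed.
#' @param flank Basic flank policy for amidated peptides.
#' @param linker_len Integer range (min, max) of linker lengths.
#' @param stub_length Length of the N-terminal hydrophobic stub (0 disables).
#' @param linker_alphabet Residues linkers are drawn from. Alphabets able to
#'   form motifs are retried a bounded number of times and then rejected.
#' @param max_retries Retries allowed when a custom alphabet creates motifs.
#' @return List with `record` (one-row proteome data.frame, with a
#'   `signal_stub` annotation column) and `truth` (data.frame: `parent_id`,
#'   `display`, `stored`, `start0`, `end0` of the stored segment).
#' @examples
#' p <- build_precursor(c("pQPPLDLGPAYFHIRa", "FPPGFHRPa"), id = "prec1", seed = 1)
#' p$truth
#' @export
build_precursor <- function(displays, id = "precursor", seed = 1, copies = 1,
                            flank = c("R", "K"), linker_len = c(2, 6),
                            stub_length = nchar(PM_SIGNAL_STUB),
                            linker_alphabet = PM_LINKER_ALPHABET,
                            max_retries = 20) {
  flank <- match.arg(flank)
  stopifnot(length(displays) >= 1, copies >= 1)
  units <- lapply(displays, demodify, flank = flank)
  stub <- if (stub_length > 0) {
    paste(rep(strsplit(PM_SIGNAL_STUB, "")[[1]],
              length.out = stub_length), collapse = "")
  } else ""
  for (attempt in seq_len(max_retries)) {
    built <- with_local_seed(seed + attempt - 1L, {
      seq_parts <- character(0)
      truth <- list()
      pos <- nchar(stub)
      for (cp in seq_len(copies)) {
        for (u in seq_along(units)) {
          lk <- paste(sample(linker_alphabet,
                             sample(seq.int(linker_len[1], linker_len[2]), 1),
                             replace = TRUE), collapse = "")
          pos <- pos + nchar(lk)
          unit <- units[[u]]
          truth[[length(truth) + 1L]] <- data.frame(
            parent_id = id, display = displays[u], stored = unit$stored,
            start0 = pos, end0 = pos + nchar(unit$stored),
            stringsAsFactors = FALSE)
          seq_parts <- c(seq_parts, lk, unit$stored, unit$flank)
          pos <- pos + nchar(unit$stored) + nchar(unit$flank)
        }
      }
      list(sequence = paste0(stub, paste(seq_parts, collapse = "")),
           truth = do.call(rbind, truth))
    })
    # reject assemblies with cut sites outside the embedded unit spans: every
    # legal cut (embedded flank or a motif internal to a peptide) lies within
    # (start0, end0 + 1] of some unit; linkers and stub must contribute none
    cuts <- scan_cterm_sites(built$sequence)
    in_unit <- vapply(cuts, function(cc)
      any(cc > built$truth$start0 & cc <= built$truth$end0 + 1L), logical(1))
    if (all(in_unit)) {
      rec <- data.frame(id = id, description = "synthetic precursor",
                        sequence = built$sequence,
                        signal_stub = stub_length > 0,
                        stringsAsFactors = FALSE)
      return(list(record = rec, truth = built$truth))
    }
  }
  stop("could not assemble a motif-clean precursor after ", max_retries,
       " retries; check the linker alphabet")
}

#' Simulate a fragment spectrum for a peptide variant
#'
#' Generates the complete singly charged b/y ion set of the variant with
#' Gaussian m/z jitter (truncated at the fragment tolerance), adds seeded
#' uniform noise peaks, and jitters the precursor MH+ uniformly within the
#' precursor tolerance. With zero jitter and zero noise the spectrum contains
#' exactly the theoretical ions.
#'
#' @param variant One variant row (see [apply_modification_variants()]).
#' @param id Spectrum identifier.
#' @param seed Integer seed.
#' @param jitter_sd Gaussian SD (Da) of the fragment m/z jitter.
#' @param n_noise Number of uniform noise peaks.
#' @param noise_intensity Upper bound of noise-peak intensity relative to the
#'   weakest fragment peak scale (fragments draw intensities in \[50, 100\],
#'   noise in \[0, `noise_intensity`\]).
#' @param config A [match_config()] supplying the truncation tolerances.
#' @inheritParams apply_modification_variants
#' @return A [spectrum()].
#' @export
simulate_spectrum <- function(variant, id = variant$display, seed = 1,
                              jitter_sd = 0.05, n_noise = 30,
                              noise_intensity = 30, config = match_config(),
                              mass_table = default_mass_table(),
                              ptm_table = default_ptm_table()) {
  frags <- theoretical_fragments(variant, nh3_loss = FALSE,
                                 mass_table = mass_table, ptm_table = ptm_table)
  with_local_seed(seed, {
    jit <- if (jitter_sd > 0) {
      j <- stats::rnorm(nrow(frags), 0, jitter_sd)
      pmin(pmax(j, -0.999 * config$fragment_tol), 0.999 * config$fragment_tol)
    } else 0
    mz <- frags$mz + jit
    intensity <- stats::runif(nrow(frags), 50, 100)
    if (n_noise > 0) {
      lo <- max(50, min(mz) - 50)
      hi <- max(mz) + 50
      mz <- c(mz, stats::runif(n_noise, lo, hi))
      intensity <- c(intensity, stats::runif(n_noise, 0, noise_intensity))
    }
    prec <- variant$mh + stats::runif(1, -0.9, 0.9) * config$precursor_tol
    spectrum(id = id, precursor_mh = prec, mz = mz, intensity = intensity,
             instrument_range = config$instrument_range)
  })
}

#' Synthetic fixture: proteome, truth table and spectra
#'
#' One-call generator of a complete seeded test scenario: one synthetic
#' precursor per peptide family, optional random background proteins, and one
#' simulated spectrum per embedded mature peptide.
#'
#' @param peptides data.frame with `family` and `display` columns; defaults to
#'   the packaged reference set ([table1_peptides()]).
#' @param seed Integer master seed.
#' @param n_background Number of random background proteins.
#' @param background_length Length range of background proteins.
#' @param copies,flank,linker_len Passed to [build_precursor()].
#' @param spectra If `TRUE`, simulate one spectrum per peptide.
#' @param jitter_sd,n_noise Spectrum noise model, see [simulate_spectrum()].
#' @param config A [match_config()].
#' @return List with `proteome`, `truth`, and (optionally) `spectra` plus the
#'   `variants` they were simulated from.
#' @export
build_fixture <- function(peptides = table1_peptides(), seed = 1,
                          n_background = 0, background_length = c(80, 200),
                          copies = 1, flank = "R", linker_len = c(2, 6),
                          spectra = FALSE, jitter_sd = 0.05, n_noise = 30,
                          config = match_config()) {
  stopifnot(all(c("family", "display") %in% names(peptides)))
  fams <- unique(peptides$family)
  recs <- list()
  truths <- list()
  for (f in seq_along(fams)) {
    fam <- fams[f]
    p <- build_precursor(peptides$display[peptides$family == fam],
                         id = paste0("PREC_", fam), seed = seed + f,
                         copies = copies, flank = flank,
                         linker_len = linker_len)
    recs[[f]] <- p$record[, c("id", "description", "sequence")]
    truths[[f]] <- p$truth
  }
  proteome <- do.call(rbind, recs)
  if (n_background > 0) {
    bg <- with_local_seed(seed + 10000L, {
      lens <- sample(seq.int(background_length[1], background_length[2]),
                     n_background, replace = TRUE)
      data.frame(id = sprintf("BG_%04d", seq_len(n_background)),
                 description = "background",
                 sequence = vapply(lens, function(L)
                   paste(sample(strsplit(PM_ALPHABET, "")[[1]], L,
                                replace = TRUE), collapse = ""), character(1)),
                 stringsAsFactors = FALSE)
    })
    proteome <- rbind(proteome, bg)
  }
  out <- list(proteome = proteome, truth = do.call(rbind, truths))
  if (spectra) {
    specs <- list()
    vars <- list()
    for (i in seq_len(nrow(out$truth))) {
      d <- out$truth$display[i]
      v <- apply_modification_variants(out$truth$stored[i])
      v <- v[v$display == d, , drop = FALSE]
      if (nrow(v) == 0) stop("embedded peptide not reachable by PTM expansion: ", d)
      vars[[i]] <- v[1, , drop = FALSE]
      specs[[i]] <- simulate_spectrum(vars[[i]], id = sprintf("sim%03d_%s", i, d),
                                      seed = seed + 500L + i,
                                      jitter_sd = jitter_sd, n_noise = n_noise,
                                      config = config)
    }
    out$spectra <- specs
    out$variants <- do.call(rbind, vars)
  }
  out
}
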