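#' MS/MS spectrum container
#'
#' A singly charged MALDI MS/MS peak list with its precursor MH+. Peaks are
#' sorted by m/z on construction; a precursor outside the instrument
#' acquisition range is flagged, not rejected.
#'
#' @param id Spectrum identifier.
#' @param precursor_mh Precursor MH+ (Da, singly charged).
#' @param mz,intensity Numeric peak vectors of equal length; intensities must
#'   be non-negative.
#' @param instrument_range Acquisition m/z range used for the in-range flag.
#' @param metadata Optional named list.
#' @return An object of class `spectrum`.
#' @export
spectrum <- function(id, precursor_mh, mz, intensity,
                     instrument_range = c(500, 4000), metadata = list()) {
  stopifnot(length(mz) == length(intensity), all(is.finite(mz)),
            all(is.finite(intensity)), all(intensity >= 0),
            length(precursor_mh) == 1, precursor_mh > 0)
  o <- order(mz)
  structure(list(id = as.character(id), precursor_mh = as.numeric(precursor_mh),
                 mz = as.numeric(mz[o]), intensity = as.numeric(intensity[o]),
                 in_range = precursor_mh >= instrument_range[1] &&
                   precursor_mh <= instrument_range[2],
                 metadata = metadata),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("Spectrum '%s': precursor MH+ %.4f, %d peak(s)%s\n",
              x$id, x$precursor_mh, length(x$mz),
              if (x$in_range) "" else " [precursor outside instrument range]"))
  invisible(x)
}

#' Matching configuration
#'
#' Tolerances and thresholds of the no-cleavage peptide-spectrum matching
#' step. Defaults follow the MALDI-TOF/TOF setting the pipeline targets:
#' precursor tolerance 0.4 Da, fragment tolerance 0.8 Da, significance
#' threshold 0.05 on the expectation-style score.
#'
#' @param precursor_tol,fragment_tol Mass tolerances in Da (> 0).
#' @param alpha Significance threshold on the match score.
#' @param nh3_loss Annotate ammonia-loss satellites in reported assignments.
#' @param instrument_range Acquisition m/z range.
#' @return An object of class `match_config`.
#' @export
match_config <- function(precursor_tol = 0.4, fragment_tol = 0.8,
                         alpha = 0.05, nh3_loss = FALSE,
                         instrument_range = c(500, 4000)) {
  stopifnot(precursor_tol > 0, fragment_tol > 0, alpha > 0, alpha <= 1)
  structure(list(precursor_tol = precursor_tol, fragment_tol = fragment_tol,
                 alpha = alpha, nh3_loss = isTRUE(nh3_loss),
                 instrument_range = instrument_range),
            class = "match_config")
}

#' Precursor-mass filtering against the variant database
#'
#' Intact-mass ("no cleavage") candidate selection: all PTM variants whose
#' theoretical MH+ lies within the precursor tolerance of the observed MH+,
#' sorted by absolute mass error.
#'
#' @param observed_mh Observed precursor MH+ (Da).
#' @param db A `peptide_db` from [peptide_database()].
#' @param config A [match_config()].
#' @return The matching rows of `db$variants` with an extra `delta` column
#'   (theoretical - observed), ordered by `abs(delta)`.
#' @export
match_precursor <- function(observed_mh, db, config = match_config()) {
  stopifnot(inherits(db, "peptide_db"))
  if (nrow(db$variants) == 0) stop("empty peptide database")
  delta <- db$variants$mh - observed_mh
  keep <- abs(delta) <= config$precursor_tol
  out <- db$variants[keep, , drop = FALSE]
  out$delta <- delta[keep]
  out <- out[order(abs(out$delta)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Score one peptide variant against one spectrum
#'
#' Greedy nearest-peak assignment of the theoretical b/y ions within the
#' fragment tolerance (each observed peak is consumed by at most one ion;
#' ions are processed in ascending m/z, and an equidistant tie between two
#' available peaks goes to the lower-m/z peak). The score is the binomial
#' tail probability of observing at least the matched number of successes in
#' `total` trials with per-trial probability
#' `p = 2 * fragment_tol * n_peaks / span(spectrum m/z)` — the chance that a
#' random theoretical m/z lands within tolerance of some peak — floored at
#' machine precision. Lower is better; it is an expectation-style
#' significance score, not a reimplementation of any proprietary engine.
#'
#' @param spec A [spectrum()].
#' @param variant One variant row (see [theoretical_fragments()]).
#' @param config A [match_config()].
#' @inheritParams apply_modification_variants
#' @return An object of class `match_result`: list with `peptide` (display
#'   string), `matched`, `total`, `assignments` (label, theoretical,
#'   observed, delta), `score`, `p_random`, `decoy`.
#' @export
score_match <- function(spec, variant, config = match_config(),
                        mass_table = default_mass_table(),
                        ptm_table = default_ptm_table()) {
  stopifnot(inherits(spec, "spectrum"))
  frags <- theoretical_fragments(variant, nh3_loss = FALSE,
                                 mass_table = mass_table, ptm_table = ptm_table)
  total <- nrow(frags)
  empty <- data.frame(label = character(0), theoretical = numeric(0),
                      observed = numeric(0), delta = numeric(0),
                      stringsAsFactors = FALSE)
  if (length(spec$mz) == 0) {
    return(structure(list(peptide = variant$display, matched = 0L,
                          total = total, assignments = empty, score = 1,
                          p_random = NA_real_,
                          decoy = isTRUE(variant$decoy %||% FALSE)),
                     class = "match_result"))
  }
  frags <- frags[order(frags$mz), , drop = FALSE]
  available <- rep(TRUE, length(spec$mz))
  rows <- empty
  for (r in seq_len(nrow(frags))) {
    d <- abs(spec$mz - frags$mz[r])
    d[!available] <- Inf
    j <- which.min(d)  # ties resolve to the lower-m/z peak (first minimum)
    if (is.finite(d[j]) && d[j] <= config$fragment_tol) {
      available[j] <- FALSE
      rows <- rbind(rows, data.frame(label = frags$label[r],
                                     theoretical = frags$mz[r],
                                     observed = spec$mz[j],
                                     delta = spec$mz[j] - frags$mz[r],
                                     stringsAsFactors = FALSE))
    }
  }
  matched <- nrow(rows)
  span <- diff(range(spec$mz))
  p <- if (span > 0) {
    min(1, 2 * config$fragment_tol * length(spec$mz) / span)
  } else 1
  score <- max(stats::pbinom(matched - 1L, total, p, lower.tail = FALSE),
               .Machine$double.xmin)
  structure(list(peptide = variant$display, matched = matched, total = total,
                 assignments = rows, score = score, p_random = p,
                 decoy = isTRUE(variant$decoy %||% FALSE)),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("%s%s: %d/%d ions matched, score %.3g\n",
              x$peptide, if (x$decoy) " [decoy]" else "",
              x$matched, x$total, x$score))
  invisible(x)
}

#' Search spectra against target (and decoy) databases
#'
#' For each spectrum: precursor-filter the variant databases, score every
#' candidate, and keep the best target and best decoy hit. The returned table
#' supports a target/decoy score-separation plot via [plot.pm_search()].
#'
#' @param spectra A list of [spectrum()] objects.
#' @param target_db A `peptide_db`.
#' @param decoy_db Optional decoy `peptide_db`.
#' @param config A [match_config()].
#' @inheritParams apply_modification_variants
#' @return An object of class `pm_search`: a data.frame with one row per
#'   spectrum (`spectrum_id`, `peptide`, `score`, `matched`, `total`,
#'   `n_candidates`, `significant`, and `decoy_peptide`/`decoy_score` when a
#'   decoy database is supplied).
#' @export
search_spectra <- function(spectra, target_db, decoy_db = NULL,
                           config = match_config(),
                           mass_table = default_mass_table(),
                           ptm_table = default_ptm_table()) {
  stopifnot(inherits(target_db, "peptide_db"))
  if (length(spectra) == 0) {
    out <- data.frame(spectrum_id = character(0), peptide = character(0),
                      score = numeric(0), matched = integer(0),
                      total = integer(0), n_candidates = integer(0),
                      significant = logical(0), stringsAsFactors = FALSE)
    class(out) <- c("pm_search", "data.frame")
    return(out)
  }
  best_hit <- function(spec, db, decoy) {
    cands <- match_precursor(spec$precursor_mh, db, config)
    if (nrow(cands) == 0) {
      return(list(peptide = NA_character_, score = NA_real_,
                  matched = NA_integer_, total = NA_integer_, n = 0L))
    }
    res <- lapply(seq_len(nrow(cands)), function(r) {
      v <- cands[r, , drop = FALSE]
      v$decoy <- decoy
      score_match(spec, v, config, mass_table, ptm_table)
    })
    scores <- vapply(res, `[[`, numeric(1), "score")
    b <- res[[which.min(scores)]]
    list(peptide = b$peptide, score = b$score, matched = b$matched,
         total = b$total, n = nrow(cands))
  }
  rows <- lapply(spectra, function(spec) {
    t <- best_hit(spec, target_db, decoy = FALSE)
    row <- data.frame(spectrum_id = spec$id, peptide = t$peptide,
                      score = t$score, matched = t$matched, total = t$total,
                      n_candidates = t$n,
                      significant = !is.na(t$score) & t$score < config$alpha,
                      stringsAsFactors = FALSE)
    if (!is.null(decoy_db)) {
      d <- best_hit(spec, decoy_db, decoy = TRUE)
      row$decoy_peptide <- d$peptide
      row$decoy_score <- d$score
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("pm_search", "data.frame")
  attr(out, "config") <- config
  out
}

#' @export
print.pm_search <- function(x, ...) {
  cat(sprintf("Spectral search: %d spectrum(s), %d significant target hit(s)\n",
              nrow(x), sum(x$significant, na.rm = TRUE)))
  print(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

#' Target/decoy score-separation plot
#'
#' Overlaid histograms of -log10 best-hit scores from the target and decoy
#' searches; a well-behaved reduced-database search shows the target
#' distribution clearly separated to the right of the decoy one.
#'
#' @param x A `pm_search` with decoy columns.
#' @param ... Passed to [graphics::hist()].
#' @export
plot.pm_search <- function(x, ...) {
  if (is.null(x$decoy_score)) stop("search was run without a decoy database")
  t <- -log10(x$score[!is.na(x$score)])
  d <- -log10(x$decoy_score[!is.na(x$decoy_score)])
  brk <- pretty(c(t, d), n = 30)
  ht <- graphics::hist(t, breaks = brk, plot = FALSE)
  hd <- graphics::hist(d, breaks = brk, plot = FALSE)
  ylim <- c(0, max(ht$counts, hd$counts))
  graphics::plot(ht, col = grDevices::adjustcolor("steelblue", 0.6),
                 ylim = ylim, xlab = "-log10(score)",
                 main = "Target vs decoy score separation", ...)
  graphics::plot(hd, col = grDevices::adjustcolor("firebrick", 0.6),
                 add = TRUE)
  graphics::legend("topright", fill = c("steelblue", "firebrick"),
                   legend = c("target", "decoy"), bty = "n")
  invisible(x)
}

#' Overlap fraction between two score samples
#'
#' Minimal achievable misclassification rate of a single score threshold
#' separating the two samples (0 = perfectly separable, ~0.5 =
#' indistinguishable). Used to quantify target/decoy separation; scores are
#' compared on the "lower is better" scale.
#'
#' @param better,worse Numeric score vectors (the `better` sample is expected
#'   to sit lower).
#' @return A fraction in \[0, 1\].
#' @export
score_overlap <- function(better, worse) {
  better <- better[is.finite(better)]
  worse <- worse[is.finite(worse)]
  stopifnot(length(better) > 0, length(worse) > 0)
  cand <- sort(unique(c(better, worse, Inf)))
  err <- vapply(cand, function(t) {
    (sum(better > t) / length(better) + sum(worse <= t) / length(worse)) / 2
  }, numeric(1))
  min(err)
}

#' Count the no-enzyme search space for one precursor mass
#'
#' The brute-force quantification of the conventional peptidomics search
#' space: the number of distinct protein substrings within the length bounds
#' for which some legal PTM variant (amidation where the substring is
#' glycine-extended, pyroglutamate where it starts with Q/E, any number of
#' methionine oxidations) has an MH+ within the precursor tolerance of the
#' observed mass.
#'
#' @param observed_mh Observed precursor MH+ (Da).
#' @param proteome Proteome data.frame.
#' @param config A [match_config()] (only the precursor tolerance is used).
#' @param min_len,max_len Substring length bounds (residues).
#' @inheritParams apply_modification_variants
#' @return Integer count of (protein, start, end) substrings.
#' @export
count_no_enzyme_candidates <- function(observed_mh, proteome,
                                       config = match_config(),
                                       min_len = 4, max_len = 50,
                                       ptms = c("amidation", "pyroglu", "oxidation"),
                                       mass_table = default_mass_table(),
                                       ptm_table = default_ptm_table()) {
  proteome <- check_proteome(proteome)
  ptms <- match.arg(ptms, several.ok = TRUE)
  tol <- config$precursor_tol
  total <- 0L
  # substrings never span non-standard letters: split each protein into
  # standard-alphabet runs and count within runs
  segs <- unlist(lapply(proteome$sequence, function(s) {
    regmatches(s, gregexpr(sprintf("[%s]+", PM_ALPHABET), s))[[1]]
  }), use.names = FALSE)
  for (seg in segs) {
    chars <- strsplit(seg, "", fixed = TRUE)[[1]]
    n <- length(chars)
    if (n < min_len) next
    res <- unname(mass_table$residues[chars])
    cs <- c(0, cumsum(res))
    is_m <- cumsum(chars == "M")
    for (len in seq.int(min_len, min(max_len, n))) {
      s <- seq_len(n - len + 1L)               # 1-based starts
      base <- cs[s + len] - cs[s] + mass_table$water + mass_table$proton
      ok <- is.finite(base)
      if (!any(ok)) next
      first <- chars[s]
      last <- chars[s + len - 1L]
      n_m <- is_m[s + len - 1L] - c(0L, is_m)[s]
      pyro_d <- rep(0, length(s))
      if ("pyroglu" %in% ptms) {
        pyro_d[first == "Q"] <- ptm_table[["pyroglu_Q"]]
        pyro_d[first == "E"] <- ptm_table[["pyroglu_E"]]
      }
      amide_d <- if ("amidation" %in% ptms) {
        ifelse(last == "G", ptm_table[["amidation"]] - mass_table$residues[["G"]], 0)
      } else rep(0, length(s))
      hit <- rep(FALSE, length(s))
      max_ox <- if ("oxidation" %in% ptms) max(n_m) else 0L
      for (pd in list(c(p = 0), c(p = 1))) {
        for (ad in list(c(a = 0), c(a = 1))) {
          for (k in 0:max_ox) {
            d <- pd[["p"]] * pyro_d + ad[["a"]] * amide_d +
              k * ptm_table[["oxidation_M"]]
            legal <- (pd[["p"]] == 0 | pyro_d != 0) &
              (ad[["a"]] == 0 | amide_d != 0) & (k <= n_m)
            hit <- hit | (ok & legal & abs(base + d - observed_mh) <= tol)
          }
        }
      }
      total <- total + sum(hit)
    }
  }
  total
}
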