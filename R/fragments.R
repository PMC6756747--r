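#' Theoretical singly charged b/y fragment ions
#'
#' Generates the b- and y-ion series (i, j = 1 .. n-1) of a modified peptide
#' at charge 1+. An N-terminal pyroglutamate shifts the whole b series; a
#' C-terminal amide shifts the whole y series; oxidized methionines shift
#' every ion whose residue span contains them. Optional ammonia-loss
#' satellites (`b3*`, `y5*`, -17.026549 Da) are generated only for ions whose
#' span contains K, R, Q or N; they are annotation aids (flagged in the `loss`
#' column) and are not counted by the scorer.
#'
#' @param variant One row of an [apply_modification_variants()] table (or any
#'   list with `mature`, `pyro`, `amidated`, `ox`).
#' @param nh3_loss If `TRUE`, append ammonia-loss satellite ions.
#' @inheritParams apply_modification_variants
#' @return data.frame with columns `label` (`b1`, `y2`, `b3*`, ...), `series`
#'   (`b`/`y`), `index`, `loss` (`""` or `"NH3"`), `mz` (Da).
#' @examples
#' v <- apply_modification_variants("AG")[1, ]
#' theoretical_fragments(v)
#' @export
theoretical_fragments <- function(variant, nh3_loss = FALSE,
                                  mass_table = default_mass_table(),
                                  ptm_table = default_ptm_table()) {
  mature <- variant$mature
  stopifnot(length(mature) == 1, is_standard_sequence(mature))
  chars <- strsplit(mature, "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (n < 2) stop("peptide must have at least 2 residues for fragmentation")
  res <- unname(mass_table$residues[chars])
  ox <- variant$ox
  if (is.character(ox)) {
    ox <- if (nzchar(ox)) as.integer(strsplit(ox, ",", fixed = TRUE)[[1]]) else integer(0)
  }
  if (length(ox) > 0) res[ox] <- res[ox] + ptm_table[["oxidation_M"]]
  nterm_delta <- switch(variant$pyro %||% "",
                        Q = ptm_table[["pyroglu_Q"]],
                        E = ptm_table[["pyroglu_E"]],
                        0)
  cterm_delta <- if (isTRUE(variant$amidated)) ptm_table[["amidation"]] else 0
  cs <- cumsum(res)
  i <- seq_len(n - 1L)
  b <- cs[i] + mass_table$proton + nterm_delta
  y <- (cs[n] - cs[n - i]) + mass_table$water + mass_table$proton + cterm_delta
  out <- data.frame(label = c(paste0("b", i), paste0("y", i)),
                    series = rep(c("b", "y"), each = n - 1L),
                    index = c(i, i), loss = "",
                    mz = c(b, y), stringsAsFactors = FALSE)
  if (nh3_loss) {
    has_nh3 <- chars %in% c("K", "R", "Q", "N")
    b_ok <- cumsum(has_nh3)[i] > 0                    # prefix 1..i
    y_ok <- rev(cumsum(rev(has_nh3)))[n - i + 1L] > 0 # suffix (n-j+1)..n
    sat <- rbind(
      if (any(b_ok)) data.frame(label = paste0("b", i[b_ok], "*"), series = "b",
                                index = i[b_ok], loss = "NH3",
                                mz = b[b_ok] - 17.026549, stringsAsFactors = FALSE),
      if (any(y_ok)) data.frame(label = paste0("y", i[y_ok], "*"), series = "y",
                                index = i[y_ok], loss = "NH3",
                                mz = y[y_ok] - 17.026549, stringsAsFactors = FALSE))
    out <- rbind(out, sat)
  }
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a)) b else a
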