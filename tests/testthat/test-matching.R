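variant_of <- function(display) {
  p <- parse_peptide_display(display)
  v <- suppressWarnings(apply_modification_variants(p$stored))
  v[v$display == display, , drop = FALSE]
}

test_that("b/y fragments match the independent fragment calculator", {
  f <- theoretical_fragments(variant_of("AG"))
  expect_equal(f$mz[f$label == "b1"], 72.04439, tolerance = 1e-5)
  expect_equal(f$mz[f$label == "y1"], 76.03931, tolerance = 1e-5)
})

test_that("fragment series identity b_i + y_(n-i) = MH+ + proton holds", {
  set.seed(11)
  displays <- c("pQPPLDLGPAYFHIRa", "GPPMoIKIPVRHa", "MPEQDANPQTRFDa",
                replicate(20, {
                  v <- suppressWarnings(apply_modification_variants(
                    random_peptide(sample(4:25, 1))))
                  v$display[sample(nrow(v), 1)]
                }))
  proton <- default_mass_table()$proton
  for (d in displays) {
    v <- variant_of(d)
    f <- theoretical_fragments(v)
    n <- nchar(v$mature)
    b <- f$mz[f$series == "b"][order(f$index[f$series == "b"])]
    y <- f$mz[f$series == "y"][order(f$index[f$series == "y"])]
    expect_equal(b + rev(y), rep(v$mh + proton, n - 1), tolerance = 1e-4,
                 label = d)
  }
})

test_that("amidation shifts every y ion and no b ion", {
  free <- variant_of("QPPLDLGPAYFHIRG")
  # same mature length: compare against the de-glycinated free acid
  acid <- suppressWarnings(apply_modification_variants("QPPLDLGPAYFHIR"))
  acid <- acid[acid$display == "QPPLDLGPAYFHIR", ]
  amide <- variant_of("QPPLDLGPAYFHIRa")
  fa <- theoretical_fragments(acid)
  fm <- theoretical_fragments(amide)
  d <- default_ptm_table()[["amidation"]]
  expect_equal(fm$mz[fm$series == "y"], fa$mz[fa$series == "y"] + d,
               tolerance = 1e-9)
  expect_equal(fm$mz[fm$series == "b"], fa$mz[fa$series == "b"],
               tolerance = 1e-9)
})

test_that("ammonia-loss satellites appear only for K/R/Q/N spans", {
  f <- theoretical_fragments(variant_of("ALKG"), nh3_loss = TRUE)
  # K is residue 3: b1, b2 have no satellite; b3 does; all y ions from y2 up
  expect_false("b1*" %in% f$label)
  expect_false("b2*" %in% f$label)
  expect_true("b3*" %in% f$label)
  expect_false("y1*" %in% f$label)   # suffix "G"
  expect_true("y2*" %in% f$label)    # suffix "KG"
  sat <- f[f$loss == "NH3", ]
  base <- f[f$loss == "", ]
  expect_equal(sat$mz, base$mz[match(sub("\\*$", "", sat$label), base$label)] -
                 17.026549, tolerance = 1e-9)
  expect_error(theoretical_fragments(variant_of("G")), "at least 2")
})

test_that("precursor filtering honours the tolerance and orders by error", {
  prot <- data.frame(id = "p", description = "",
                     sequence = "AAAQPPLDLGPAYFHIRGRAAAGPAVLDYFHIRGKAAA")
  db <- peptide_database(extract_cnidarian(prot))
  v <- db$variants[db$variants$display == "pQPPLDLGPAYFHIRa", ]
  hits <- match_precursor(v$mh, db)
  expect_identical(hits$display[1], "pQPPLDLGPAYFHIRa")
  expect_equal(hits$delta[1], 0, tolerance = 1e-12)
  expect_true(all(abs(hits$delta) <= 0.4))
  # off by twice the tolerance -> excluded
  hits2 <- match_precursor(v$mh + 0.8, db)
  expect_false("pQPPLDLGPAYFHIRa" %in% hits2$display)
  # isobaric variants (permuted sequence, equal residue multiset) both return
  iso <- peptide_database(data.frame(
    stored = c("ALKVFD", "LAKVFD"), parent_id = "x", start0 = 0L, end0 = 6L,
    n_motifs = "", c_motif = "", engine = "external",
    stringsAsFactors = FALSE))
  both <- match_precursor(iso$variants$mh[1], iso)
  expect_setequal(both$display, c("ALKVFD", "LAKVFD"))
})

test_that("a perfect spectrum matches every ion and dominates competitors", {
  v <- variant_of("pQPPLDLGPAYFHIRa")
  f <- theoretical_fragments(v)
  spec <- spectrum("perfect", v$mh, f$mz, rep(100, nrow(f)))
  res <- score_match(spec, v)
  expect_equal(res$matched, res$total)
  expect_true(all(abs(res$assignments$delta) <= 0.8))
  # shuffled-sequence competitor scores strictly worse on the same spectrum
  comp <- variant_of("PQLPDLPGAYFHIRa")   # same residues, different order
  expect_gt(score_match(spec, comp)$score, res$score)
})

test_that("empty and degenerate spectra give null scores", {
  v <- variant_of("ALKVFD")
  empty <- spectrum("empty", v$mh, numeric(0), numeric(0))
  res <- score_match(empty, v)
  expect_equal(res$matched, 0L)
  expect_equal(res$score, 1)
})

test_that("score is monotone in matched ions and noise peaks", {
  v <- variant_of("QPPLDLGPAYFHIRa")
  f <- theoretical_fragments(v)
  set.seed(3)
  # fixed span: the extreme peaks are noise peaks present in both spectra
  noise <- c(100, 1900, runif(38, 300, 1700))
  base_mz <- c(f$mz[1:10], noise)
  s1 <- score_match(spectrum("a", v$mh, base_mz, rep(1, length(base_mz))), v)
  # one more matched ion, same peak count and span: score improves (decreases)
  plus_mz <- c(f$mz[1:11], noise[-3])
  s2 <- score_match(spectrum("b", v$mh, plus_mz, rep(1, length(plus_mz))), v)
  expect_lte(s2$score, s1$score)
  # extra noise peak far from every ion: score worsens (increases)
  noisy_mz <- c(base_mz, max(f$mz) + 200)
  s3 <- score_match(spectrum("c", v$mh, noisy_mz, rep(1, length(noisy_mz))), v)
  expect_gte(s3$score, s1$score)
})

test_that("false-positive rate on pure noise respects the threshold", {
  v <- variant_of("QPPLDLGPAYFHIRa")
  alpha <- 0.05
  n_trials <- 1000
  set.seed(17)
  fp <- 0L
  for (t in seq_len(n_trials)) {
    mz <- runif(40, 200, 1800)
    s <- score_match(spectrum("n", v$mh, mz, rep(1, 40)), v)
    if (s$score < alpha) fp <- fp + 1L
  }
  # binomial 3-sigma margin around alpha
  expect_lte(fp / n_trials, alpha + 3 * sqrt(alpha * (1 - alpha) / n_trials))
})

test_that("true peptide outranks its shuffled twin on simulated spectra", {
  set.seed(23)
  wins <- 0L
  n <- 200
  for (i in seq_len(n)) {
    stored <- paste0(random_peptide(sample(8:16, 1)), "G")
    v <- suppressWarnings(apply_modification_variants(stored))
    v <- v[v$amidated & v$n_mods == 1, , drop = FALSE][1, , drop = FALSE]
    spec <- simulate_spectrum(v, seed = 7000 + i)
    truth <- score_match(spec, v)
    sh_mature <- paste(sample(strsplit(v$mature, "")[[1]]), collapse = "")
    shuffled <- data.frame(stored = paste0(sh_mature, "G"), mature = sh_mature,
                           display = paste0(sh_mature, "a"), pyro = "",
                           amidated = TRUE, ox = "", n_mods = 1L,
                           mass = v$mass, mh = v$mh, stringsAsFactors = FALSE)
    if (truth$score < score_match(spec, shuffled)$score) wins <- wins + 1L
  }
  expect_gte(wins / n, 0.95)
})

test_that("search returns per-spectrum best hits and separates decoys", {
  fx <- build_fixture(seed = 5, n_background = 15, spectra = TRUE)
  db <- peptide_database(extract_cnidarian(fx$proteome))
  decoy_db <- peptide_database(
    extract_cnidarian(make_decoy(fx$proteome, seed = 55)), decoy = TRUE)
  res <- search_spectra(fx$spectra[1:12], db, decoy_db)
  expect_s3_class(res, "pm_search")
  expect_equal(nrow(res), 12L)
  truth_displays <- fx$truth$display[1:12]
  expect_true(mean(res$peptide == truth_displays, na.rm = TRUE) >= 0.9)
  expect_true(all(res$score[!is.na(res$score)] <
                    res$decoy_score[!is.na(res$score)], na.rm = TRUE))
  # empty spectrum list -> empty table
  expect_equal(nrow(search_spectra(list(), db)), 0L)
})

test_that("no-enzyme counting is exact, monotone and bounds the reduced space", {
  mt <- default_mass_table()
  # a proteome of "GG": its own MH+ is counted
  gg <- data.frame(id = "g", description = "", sequence = "GGGG")
  expect_gte(count_no_enzyme_candidates(mh_plus(peptide_mass("GGGG")), gg,
                                        min_len = 4, max_len = 10), 1L)
  # shrinking tolerance never increases the count
  prot <- random_proteins(20, len_range = c(50, 120), seed = 606)
  q <- mh_plus(peptide_mass("QPPLDLGPAYFHIR"))
  cfgs <- lapply(c(1, 0.4, 0.1, 0.01), function(t)
    match_config(precursor_tol = t))
  counts <- vapply(cfgs, function(cf)
    count_no_enzyme_candidates(q, prot, cf), numeric(1))
  expect_true(all(diff(counts) <= 0))
  # reduced-database hits are a subset of the no-enzyme space
  cands <- extract_cnidarian(prot)
  if (nrow(cands) > 0) {
    db <- peptide_database(cands)
    for (mh in sample(db$variants$mh, min(5, nrow(db$variants)))) {
      n_red <- nrow(match_precursor(mh, db))
      n_all <- count_no_enzyme_candidates(mh, prot)
      expect_gte(n_all, n_red)
    }
  }
})

test_that("score overlap measures separation between score samples", {
  expect_equal(score_overlap(c(1e-8, 1e-7), c(0.5, 0.9)), 0)
  expect_gte(score_overlap(c(0.1, 0.5), c(0.1, 0.5)), 0.4)
})
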