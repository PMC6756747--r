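test_that("C-terminal motif scan finds all and only G+basic cuts", {
  expect_identical(as.integer(scan_cterm_sites("AAAA")), integer(0))
  # one cut after the K of GK
  expect_identical(as.integer(scan_cterm_sites("AGKA")), 3L)
  # GKR: GK matches, KR is not a C-motif -> exactly one cut
  expect_identical(as.integer(scan_cterm_sites("AGKRA")), 3L)
  # overlapping motifs each yield a cut
  expect_identical(as.integer(scan_cterm_sites("GKGRA")), c(2L, 4L))
  # opt-in stripping of the trailing extra basic adds the GKR cut
  cfg <- cnidarian_config(strip_extra_basic = TRUE)
  cuts <- scan_cterm_sites("AGKRA", cfg)
  expect_identical(as.integer(cuts), c(3L, 4L))
  expect_identical(attr(cuts, "n_strip"), c(1L, 2L))
})

test_that("N-terminal starts cover all hallmark motifs in the window", {
  seq <- "AAAQPPLDLGPAYFHIRGRAAA"
  cut <- scan_cterm_sites(seq)
  expect_identical(as.integer(cut), 19L)  # after the R of "GR"
  st <- scan_nterm_starts(seq, cut, cnidarian_config())
  # the three hallmark rules, traced by hand
  expect_true(all(c("QPPLDLGPAYFHIRG", "PPLDLGPAYFHIRG",
                    "LGPAYFHIRG", "GPAYFHIRG") %in% st$stored))
  # a start satisfying several motifs appears once, with all labels
  qrow <- st[st$stored == "QPPLDLGPAYFHIRG", ]
  expect_equal(nrow(qrow), 1L)
  expect_setequal(strsplit(qrow$n_motifs, ",")[[1]], c("Q", "XP", "XXP"))
  # full agreement with the exhaustive window-scan oracle
  oracle <- oracle_cnidarian(seq)
  expect_setequal(st$stored, oracle$stored)
  # no P, no Q upstream -> nothing
  st2 <- scan_nterm_starts("AAAAAAAGKA", scan_cterm_sites("AAAAAAAGKA"))
  expect_equal(nrow(st2), 0L)
})

test_that("hallmark extraction matches the brute-force oracle on random proteins", {
  prot <- random_proteins(200, seed = 101)
  cands <- extract_cnidarian(prot)
  for (i in seq_len(nrow(prot))) {
    got <- as.data.frame(cands)[cands$parent_id == prot$id[i],
                                c("start0", "end0", "stored")]
    want <- oracle_cnidarian(prot$sequence[i])
    expect_equal(nrow(got), nrow(want), label = prot$id[i])
    if (nrow(want) > 0) {
      rownames(got) <- rownames(want) <- NULL
      expect_equal(got, want, label = prot$id[i])
    }
  }
})

test_that("dibasic extraction matches the reference pattern engine", {
  # hand-traced examples
  c1 <- extract_dibasic(data.frame(id = "a", description = "",
                                   sequence = "KRAAAAAAAKR"))
  expect_identical(c1$stored, "AAAAAAA")
  expect_identical(c1$start0, 2L)
  c2 <- extract_dibasic(data.frame(id = "a", description = "",
                                   sequence = "KRAAAAAAAKAAK"))
  expect_true("AAAAAAA" %in% c2$stored)
  expect_true(any(grepl("n=2", c2$c_motif[c2$stored == "AAAAAAA"])))
  expect_equal(nrow(extract_dibasic(data.frame(id = "a", description = "",
                                               sequence = "AAAGAAAGAAA"))), 0L)
  # random-protein agreement with the lookahead-regex oracle
  prot <- random_proteins(150, len_range = c(30, 150), seed = 202)
  cands <- extract_dibasic(prot)
  want <- oracle_dibasic(prot$sequence)
  for (i in seq_len(nrow(prot))) {
    got <- unique(as.data.frame(cands)[cands$parent_id == prot$id[i],
                                       c("start0", "end0")])
    rownames(got) <- rownames(want[[i]]) <- NULL
    expect_equal(got, want[[i]], label = prot$id[i])
  }
})

test_that("dibasic termini are not implicit boundaries unless relaxed", {
  seq <- "AAAAAAAAKR"   # only a right flank; strict mode finds nothing
  prot <- data.frame(id = "a", description = "", sequence = seq)
  expect_equal(nrow(extract_dibasic(prot)), 0L)
  relaxed <- extract_dibasic(prot, dibasic_config(relax_termini = TRUE))
  expect_true("AAAAAAAA" %in% relaxed$stored)
})

test_that("window and length bounds are monotone: enlarging never removes", {
  prot <- random_proteins(40, seed = 303)
  small <- extract_cnidarian(prot, cnidarian_config(window = 30, min_len = 5,
                                                    max_len = 20))
  big <- extract_cnidarian(prot, cnidarian_config(window = 60, min_len = 4,
                                                  max_len = 40))
  key <- function(x) paste(x$parent_id, x$start0, x$end0)
  expect_true(all(key(small) %in% key(big)))
})

test_that("degenerate configs and empty proteomes are rejected", {
  expect_error(cnidarian_config(n_motifs = character(0)))
  expect_error(cnidarian_config(window = 10, max_len = 50))
  expect_error(extract_cnidarian(data.frame(id = character(0),
                                            description = character(0),
                                            sequence = character(0))),
               "zero records")
})

test_that("candidates with non-standard letters are skipped with a warning", {
  prot <- data.frame(id = "a", description = "",
                     sequence = "AAAQPXLDLGPAYFHIRGRAAA")
  expect_warning(cands <- extract_cnidarian(prot), "non-standard")
  expect_false(any(grepl("X", cands$stored, fixed = TRUE)))
})

test_that("decoy shuffling preserves composition and is seed-reproducible", {
  prot <- random_proteins(20, seed = 404)
  d1 <- make_decoy(prot, seed = 9)
  d2 <- make_decoy(prot, seed = 9)
  d3 <- make_decoy(prot, seed = 10)
  expect_identical(d1$sequence, d2$sequence)
  expect_false(identical(d1$sequence, d3$sequence))
  expect_identical(d1$id, paste0("DECOY_", prot$id))
  comp <- function(s) sort(strsplit(s, "")[[1]])
  for (i in seq_len(nrow(prot))) {
    expect_identical(comp(d1$sequence[i]), comp(prot$sequence[i]))
  }
  # length-1 protein is unchanged
  one <- make_decoy(data.frame(id = "x", description = "", sequence = "W"),
                    seed = 1)
  expect_identical(one$sequence, "W")
})

test_that("decoy candidate yield is comparable to the target's", {
  prot <- random_proteins(120, seed = 505)
  nt <- nrow(extract_cnidarian(prot))
  nd <- nrow(extract_cnidarian(make_decoy(prot, seed = 6)))
  expect_gt(nd, nt / 3)
  expect_lt(nd, nt * 3)
})

test_that("database build dedups by stored sequence and keeps provenance", {
  prot <- data.frame(id = c("p1", "p2"), description = "",
                     sequence = c("AAAQPPLDLGPAYFHIRGRAAA",
                                  "TTTQPPLDLGPAYFHIRGKTTT"))
  cands <- extract_cnidarian(prot)
  db <- peptide_database(cands)
  dup <- db$peptides[db$peptides$stored == "QPPLDLGPAYFHIRG", ]
  expect_equal(dup$n_parents, 2L)
  prov <- db$provenance[db$provenance$accession == dup$accession, ]
  expect_setequal(prov$parent_id, c("p1", "p2"))
  expect_equal(anyDuplicated(db$peptides$stored), 0L)
  expect_error(peptide_database(cands[0, ]), "empty")
})

test_that("database FASTA/TSV round-trips stored sequences and coordinates", {
  prot <- data.frame(id = "p1", description = "",
                     sequence = "AAAQPPLDLGPAYFHIRGRAAA")
  db <- peptide_database(extract_cnidarian(prot))
  fa <- tempfile(fileext = ".fasta")
  tsv <- tempfile(fileext = ".tsv")
  write_peptide_database(db, fa, tsv, meta = list(seed = 1))
  back <- read_fasta(fa)
  expect_setequal(back$sequence, db$peptides$stored)
  prov <- utils::read.delim(tsv, comment.char = "#")
  expect_setequal(prov$stored, db$provenance$stored)
  expect_true(any(startsWith(readLines(tsv, n = 2), "#")))
  # parent coordinates in the provenance recover the stored substring
  for (r in seq_len(nrow(prov))) {
    expect_identical(substr(prot$sequence, prov$start0[r] + 1, prov$end0[r]),
                     prov$stored[r])
  }
})
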