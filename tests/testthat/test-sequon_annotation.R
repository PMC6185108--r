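prot <- function(id, seq) tibble::tibble(protein_id = id, sequence = seq)

test_that("sequon scanning applies the N-X-S/T, X != Pro rule", {
  expect_equal(scan_sequons(prot("P", "ANGTM"))$position, 2L)
  expect_equal(scan_sequons(prot("P", "ANGTM"))$sequon, "NGT")
  expect_equal(scan_sequons(prot("P", "ANGTM"))$sequon_class, "NxT")
  # proline at +1 kills the sequon
  expect_equal(nrow(scan_sequons(prot("P", "ANPTM"))), 0L)
  # overlapping sequons are all reported
  nn <- scan_sequons(prot("P", "NNSS"))
  expect_equal(nn$position, c(1L, 2L))
  expect_equal(nn$sequon, c("NNS", "NSS"))
  # truncated +1/+2 window near the C-terminus is not a site
  expect_equal(nrow(scan_sequons(prot("P", "MN"))), 0L)
})

test_that("scanner agrees with the naive all-windows enumeration", {
  set.seed(42)
  for (i in 1:200) {
    seq <- random_protein(sample(10:300, 1))
    got <- scan_sequons(prot("P", seq))$position
    expect_identical(got, as.integer(naive_scan_positions(seq)))
  }
})

test_that("site classification captures class, -2 residue and aromaticity", {
  s <- classify_site(prot("P", "FANGS"), tibble::tibble(protein_id = "P",
                                                        position = 3))
  expect_equal(s$sequon_class, "NxS")
  expect_equal(s$minus2_residue, "F")
  expect_true(s$minus2_aromatic)

  # too close to the N-terminus: -2 context undefined
  s1 <- classify_site(prot("P", "NGSAA"), tibble::tibble(protein_id = "P",
                                                         position = 1))
  expect_true(is.na(s1$minus2_residue))
  expect_true(is.na(s1$minus2_aromatic))

  # +2 not S/T -> non-canonical
  s2 <- classify_site(prot("P", "MANAA"), tibble::tibble(protein_id = "P",
                                                         position = 3))
  expect_equal(s2$sequon_class, "non_canonical")

  # His counts as aromatic
  s3 <- classify_site(prot("P", "HANGS"), tibble::tibble(protein_id = "P",
                                                         position = 3))
  expect_true(s3$minus2_aromatic)

  expect_error(
    classify_site(prot("P", "MANAA"), tibble::tibble(protein_id = "P",
                                                     position = 2)),
    "not Asn"
  )
})

test_that("every site falls in exactly one sequon class", {
  set.seed(7)
  seqs <- prot(paste0("P", 1:50),
               vapply(1:50, function(i) random_protein(200), character(1)))
  sites <- scan_sequons(seqs)
  expect_true(all(sites$sequon_class %in% c("NxT", "NxS", "non_canonical")))
  counts <- table(factor(sites$sequon_class,
                         levels = c("NxT", "NxS", "non_canonical")))
  expect_equal(sum(counts), nrow(sites))
  # a scanned site is canonical by construction
  expect_true(all(sites$sequon_class != "non_canonical"))
})

test_that("reference glycoproteome requires control-sample detections", {
  proteins <- prot(c("PA", "PB", "PC"),
                   c(paste0(strrep("A", 9), "NGT", strrep("A", 5)),
                     paste0(strrep("G", 9), "NGS", strrep("G", 5)),
                     paste0(strrep("L", 9), "NVA", strrep("L", 5))))
  qm <- make_qm(list(
    "PA:10" = pattern_row(2, 0),   # 2 controls -> in
    "PB:10" = pattern_row(1, 4),   # 1 control, 4 mutants -> out
    "PC:10" = pattern_row(4, 4)    # non-canonical but detected -> in, kept
  ))
  ref <- build_reference_glycoproteome(qm, proteins,
                                       min_control_detections = 2)
  expect_setequal(ref$protein_id, c("PA", "PC"))
  expect_true(all(ref$evidence == "reference"))
  # non-canonical detected sites are retained in the reference
  expect_equal(ref$sequon_class[ref$protein_id == "PC"], "non_canonical")

  empty <- build_reference_glycoproteome(qm[0, ], proteins)
  expect_equal(nrow(empty), 0L)

  bad <- make_qm(list("PA" = pattern_row(4, 4)))
  expect_error(build_reference_glycoproteome(bad, proteins), "feature id",
               ignore.case = TRUE)
})

test_that("raising the detection threshold never adds a reference site", {
  set.seed(11)
  proteins <- prot(paste0("P", 1:30),
                   vapply(1:30, function(i) {
                     paste0(strrep("A", 9), "NGT", strrep("A", 5))
                   }, character(1)))
  rows <- setNames(
    lapply(1:30, function(i) pattern_row(sample(0:4, 1), sample(0:4, 1))),
    paste0("P", 1:30, ":10")
  )
  qm <- make_qm(rows)
  sizes <- vapply(1:4, function(k) {
    nrow(build_reference_glycoproteome(qm, proteins,
                                       min_control_detections = k))
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("novel-site calling compares against the union of known lists", {
  proteins <- prot("PA", paste0(strrep("A", 9), "NGT", strrep("A", 10),
                                "NGS", strrep("A", 3)))
  qm <- make_qm(list("PA:10" = pattern_row(4, 4), "PA:23" = pattern_row(3, 3)))
  ref <- build_reference_glycoproteome(qm, proteins)
  called <- call_novel_sites(ref, list(
    tibble::tibble(protein_id = "PA", position = 10L),
    tibble::tibble(protein_id = "ZZ", position = 1L)
  ))
  expect_equal(called$evidence[called$position == 10], "reference")
  expect_equal(called$evidence[called$position == 23], "novel")
  s <- novel_site_summary(called)
  expect_equal(s$novel_fraction, 0.5)
})

test_that("novel fraction follows from the counts", {
  # 10 reference sites, 2 absent from the known lists -> fraction 0.2
  sites <- tibble::tibble(
    protein_id = paste0("P", 1:10), position = 5L,
    sequon = "NGT", sequon_class = "NxT",
    minus2_residue = "A", minus2_aromatic = FALSE,
    evidence = "reference"
  )
  known <- tibble::tibble(protein_id = paste0("P", 1:8), position = 5L)
  called <- call_novel_sites(sites, known)
  expect_equal(novel_site_summary(called)$novel_fraction, 0.2)
})

test_that("multiplicity counts distinct reference positions per protein", {
  proteins <- prot(c("PA", "PB"),
                   c(paste0(strrep("A", 11), "NGT", strrep("A", 70),
                            "NGS", strrep("A", 3)),
                     strrep("A", 30)))
  ref <- tibble::tibble(
    protein_id = c("PA", "PA", "PA"),
    position = c(12L, 83L, 83L),  # duplicate position must not double-count
    sequon = "NGT", sequon_class = "NxT",
    minus2_residue = "A", minus2_aromatic = FALSE, evidence = "reference"
  )
  mp <- multiplicity_profiles(ref, proteins)
  expect_equal(mp$multiplicity[mp$protein_id == "PA"], 2L)
  expect_equal(mp$multiplicity[mp$protein_id == "PB"], 0L)
  expect_equal(mp$scanned_multiplicity[mp$protein_id == "PA"], 2L)
  expect_equal(mp$scanned_multiplicity[mp$protein_id == "PB"], 0L)
})
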