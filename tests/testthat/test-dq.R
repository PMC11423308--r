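test_that("the NMR-STAR reader extracts C and N assignments", {
  tab <- parse_assignments(ala_gly_star())
  expect_s3_class(tab, "assignment_table")
  expect_equal(nrow(tab), 6L)                    # 5 C + 1 N
  expect_setequal(unique(tab$atom_type), c("C", "N"))
  expect_equal(tab$shift[tab$residue == 1 & tab$atom == "CA"], 52.0)

  # protons are discarded
  mixed <- write_star_fixture(rbind(
    star_row(1, "ALA", "CA", 52.0),
    star_row(1, "ALA", "HA", 4.3),
    star_row(1, "ALA", "CB", 19.0)))
  expect_equal(nrow(parse_assignments(mixed)), 2L)

  dup <- write_star_fixture(rbind(
    star_row(1, "ALA", "CA", 52.0),
    star_row(1, "ALA", "CA", 52.4)))
  expect_error(parse_assignments(dup), "duplicate.*CA")

  expect_error(parse_assignments(tempfile()), "cannot read")
  nolines <- tempfile(); writeLines("data_x", nolines)
  expect_error(parse_assignments(nolines), "no _Atom_chem_shift loop")
})

test_that("DQ enumeration emits two peaks per bonded pair with summed shifts", {
  peaks <- enumerate_dq(parse_assignments(ala_gly_star()))
  # Ala: CA-CB and CA-C; Gly: CA-C -> 3 pairs, 6 peaks
  expect_equal(nrow(peaks), 6L)
  ala <- peaks[peaks$residue == 1, ]
  expect_equal(nrow(ala), 4L)
  expect_setequal(unique(ala$pair_label), c("A1CA-C", "A1CA-CB"))
  expect_equal(ala$dq_ppm[ala$pair_label == "A1CA-CB"], rep(71.0, 2))
  expect_equal(ala$dq_ppm[ala$pair_label == "A1CA-C"], rep(230.0, 2))
  # each pair yields exactly two rows whose SQ shifts sum to the shared DQ
  for (lab in unique(peaks$pair_label)) {
    sub <- peaks[peaks$pair_label == lab, ]
    expect_equal(nrow(sub), 2L)
    expect_identical(sub$dq_ppm[1], sub$dq_ppm[2])
    expect_identical(sum(sub$sq_ppm), sub$dq_ppm[1])
  }
})

test_that("pairs with a missing member are skipped and counted", {
  lys <- write_star_fixture(rbind(
    star_row(8, "LYS", "CA", 56.0),
    star_row(8, "LYS", "CB", 32.0),
    star_row(8, "LYS", "CE", 41.9)))  # CG, CD, C missing
  peaks <- enumerate_dq(parse_assignments(lys))
  expect_equal(unique(peaks$pair_label), "K8CA-CB")
  skipped <- attr(peaks, "skipped")
  expect_true("CD-CE" %in% skipped$pair)
  expect_equal(skipped$missing_atom[skipped$pair == "CD-CE"], "CD")

  odd <- data.frame(residue = 1, residue_type = "XXX", atom = "CA",
                    atom_type = "C", shift = 50)
  expect_warning(enumerate_dq(odd), "unknown residue type")
})

test_that("peak counts match brute-force pair enumeration on random assignment subsets", {
  # independent bond lists, typed out separately from the package topology
  oracle_bonds <- list(
    ALA = c("CA|C", "CA|CB"),
    GLY = c("CA|C"),
    LYS = c("CA|C", "CA|CB", "CB|CG", "CG|CD", "CD|CE"),
    THR = c("CA|C", "CA|CB", "CB|CG2"),
    PHE = c("CA|C", "CA|CB", "CB|CG", "CG|CD1", "CG|CD2", "CD1|CE1",
            "CD2|CE2", "CE1|CZ", "CE2|CZ"))
  all_atoms <- lapply(oracle_bonds, function(b)
    unique(unlist(strsplit(b, "|", fixed = TRUE))))
  set.seed(100)
  for (rep in 1:10) {
    types <- sample(names(oracle_bonds), 4, replace = TRUE)
    rows <- do.call(rbind, lapply(seq_along(types), function(i) {
      atoms <- all_atoms[[types[i]]]
      keep <- atoms[runif(length(atoms)) < 0.7]
      if (length(keep) == 0L) return(NULL)
      star_row(i, types[i], keep, shift = round(runif(length(keep), 10, 180), 2))
    }))
    if (is.null(rows)) next
    path <- write_star_fixture(rows)
    peaks <- enumerate_dq(parse_assignments(path))
    # brute force: count bonds with both members present, per residue
    n_pairs <- sum(vapply(seq_along(types), function(i) {
      present <- rows$atom[rows$residue == i]
      sum(vapply(strsplit(oracle_bonds[[types[i]]], "|", fixed = TRUE),
                 function(p) all(p %in% present), logical(1)))
    }, numeric(1)))
    expect_equal(nrow(peaks), 2L * n_pairs)
  }
})

test_that("peak lists are written deterministically in both dialects", {
  peaks <- enumerate_dq(parse_assignments(ala_gly_star()))
  f1 <- tempfile(fileext = ".list"); f2 <- tempfile(fileext = ".list")
  write_peaklists(peaks, f1, format = "sparky")
  write_peaklists(peaks, f2, format = "sparky")
  expect_identical(readLines(f1), readLines(f2))
  expect_length(readLines(f1), 7L)  # header + 6 peaks

  fc <- tempfile(fileext = ".csv")
  write_peaklists(peaks, fc, format = "csv")
  back <- read.csv(fc)
  expect_equal(nrow(back), 6L)
  expect_equal(back$dq_ppm, peaks$dq_ppm[order(peaks$residue,
                                               peaks$pair_label,
                                               peaks$member_atom)])
  expect_error(write_peaklists(peaks[0, ], tempfile()), "empty")
})
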