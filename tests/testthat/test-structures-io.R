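test_that("a PDB with a single CA atom reads back as a one-residue structure", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       1.000   2.000   3.000  1.00  0.00           C",
    "END"), f)
  s <- read_structure(f)
  expect_equal(length(s), 1L)
  expect_equal(as.numeric(s$xyz), c(1, 2, 3))
  expect_equal(s$aa, "A")
})

test_that("a file without CA atoms is a format error", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CB  ALA A   1       1.000   2.000   3.000  1.00  0.00           C",
    "END"), f)
  expect_error(read_structure(f), "no CA atoms")
})

test_that("altloc duplicates resolve to highest occupancy then first-listed", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AALA A   1       1.000   0.000   0.000  0.40  0.00           C",
    "ATOM      2  CA BALA A   1       2.000   0.000   0.000  0.60  0.00           C",
    "ATOM      3  CA AGLY A   2       3.000   0.000   0.000  0.50  0.00           C",
    "ATOM      4  CA BGLY A   2       4.000   0.000   0.000  0.50  0.00           C",
    "END"), f)
  s <- read_structure(f)
  expect_equal(s$xyz[, 1], c(2, 3))   # B wins res 1; tie keeps first at res 2
})

test_that("write/read round trip is the identity on identity fields and 1e-3 on coordinates", {
  set.seed(11)
  s <- ca_structure(rep("B", 25), 101:125,
                    sample(c("A", "W", "G", "K", "D"), 25, replace = TRUE),
                    matrix(rnorm(75, sd = 20), 25), name = "rt")
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(s, f)
  s2 <- read_structure(f, name = "rt")
  expect_identical(s2$chain, s$chain)
  expect_identical(s2$res_id, s$res_id)
  expect_identical(s2$aa, s$aa)
  expect_lt(max(abs(s2$xyz - s$xyz)), 1e-3)
})

test_that("structure construction rejects degenerate input", {
  expect_error(ca_structure(character(0), integer(0), character(0),
                            matrix(0, 0, 3)), "at least one residue")
  expect_error(ca_structure("A", c(1, 1), c("A", "G"), matrix(0, 2, 3)),
               "duplicate")
  expect_error(ca_structure("A", 1, "A", matrix(c(1, NA, 3), 1)), "finite")
  s <- ca_structure("A", 10000L, "A", matrix(0, 1, 3))
  expect_error(write_structure(s, tempfile()), "serialization error")
})

test_that("alignment maps identify ungapped columns and report discordance", {
  sa <- ca_structure("A", 1:5, c("A", "C", "D", "E", "F"),
                     matrix(seq_len(15), 5), name = "sa")
  sb <- ca_structure("A", 1:5, c("A", "C", "D", "E", "F"),
                     matrix(seq_len(15) + 1, 5), name = "sb")
  m <- alignment_map_from_strings(c(sa = "ACDEF", sb = "ACDEF"),
                                  list(sa, sb))
  expect_equal(m$ungapped_columns, 1:5)
  expect_equal(m$maps$sa, 1:5)

  sc <- ca_structure("A", 1:3, c("A", "C", "G"), matrix(0:8, 3), name = "sc")
  sd_ <- ca_structure("A", 1:4, c("A", "C", "T", "G"), matrix(1:12, 4),
                      name = "sd")
  m2 <- alignment_map_from_strings(c(sc = "AC-G", sd = "ACTG"),
                                   list(sc, sd_))
  expect_equal(m2$ungapped_columns, c(1L, 2L, 4L))

  se <- ca_structure("A", 1:3, c("A", "C", "W"), matrix(0:8, 3), name = "se")
  expect_error(alignment_map_from_strings(c(se = "AC-G", sd = "ACTG"),
                                          list(se, sd_)),
               "first discordant position 3")
})

test_that("ungapped columns match a brute-force scan and survive sequence reordering", {
  set.seed(21)
  base <- paste(sample(c("A", "C", "D", "E", "F", "G", "H"), 30,
                       replace = TRUE), collapse = "")
  plant_gaps <- function(seq, k) {
    chars <- strsplit(seq, "")[[1]]
    chars[sample(seq_along(chars), k)] <- "-"
    paste(chars, collapse = "")
  }
  seqs <- c(s1 = plant_gaps(base, 4), s2 = plant_gaps(base, 6),
            s3 = base, s4 = plant_gaps(base, 3))
  structs <- lapply(names(seqs), function(nm) {
    aa <- strsplit(gsub("-", "", seqs[[nm]]), "")[[1]]
    ca_structure("A", seq_along(aa), aa,
                 matrix(rnorm(3 * length(aa)), ncol = 3), name = nm)
  })
  m <- alignment_map_from_strings(seqs, structs)
  expect_equal(m$ungapped_columns, oracle_ungapped(seqs))

  ord <- c(3, 1, 4, 2)
  m2 <- alignment_map_from_strings(seqs[ord], structs[ord])
  expect_equal(m2$ungapped_columns, m$ungapped_columns)
})

test_that("clustal and fasta alignments parse identically", {
  seqs <- c(p1 = "MKV-LW", p2 = "MKVQLW")
  structs <- lapply(names(seqs), function(nm) {
    aa <- strsplit(gsub("-", "", seqs[[nm]]), "")[[1]]
    ca_structure("A", seq_along(aa), aa,
                 matrix(seq_len(3 * length(aa)), ncol = 3), name = nm)
  })
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">p1", seqs[1], ">p2", seqs[2]), fa)
  cl <- withr::local_tempfile(fileext = ".aln")
  writeLines(c("CLUSTAL W (1.83) multiple sequence alignment", "",
               sprintf("p1    %s", seqs[1]),
               sprintf("p2    %s", seqs[2])), cl)
  m_fa <- read_alignment(fa, structs)
  m_cl <- read_alignment(cl, structs)
  expect_equal(m_cl$ungapped_columns, m_fa$ungapped_columns)
  expect_equal(m_cl$maps, m_fa$maps)
})

test_that("corrected subset equals the column-intersection of full and truncated", {
  ## identity case
  s <- ca_structure("A", 1:6, c("A", "C", "D", "E", "F", "G"),
                    matrix(seq_len(18), 6), name = "fl")
  s2 <- ca_structure("A", 1:6, s$aa, s$xyz + 1, name = "tr")
  m <- alignment_map_from_strings(c(fl = "ACDEFG", tr = "ACDEFG"),
                                  list(s, s2))
  cs <- corrected_subset(s, s2, m)
  expect_equal(cs$res_id, s$res_id)
  expect_equal(cs$xyz, s$xyz)

  ## pure prefix truncation: length 10 full, first 7 aligned
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L")
  fl <- ca_structure("A", 1:10, aa, matrix(seq_len(30), 10), name = "fl")
  tr <- ca_structure("A", 1:7, aa[1:7], matrix(seq_len(21), 7), name = "tr")
  m2 <- alignment_map_from_strings(
    c(fl = paste(aa, collapse = ""),
      tr = paste(c(aa[1:7], "-", "-", "-"), collapse = "")),
    list(fl, tr))
  cs2 <- corrected_subset(fl, tr, m2)
  expect_equal(cs2$res_id, 1:7)
  expect_equal(length(cs2), min(length(fl), length(tr)))

  ## randomized truncation pattern vs set-intersection oracle
  set.seed(31)
  for (rep in 1:5) {
    keep_fl <- sort(sample(1:12, 9))
    keep_tr <- sort(sample(1:12, 8))
    aa12 <- sample(c("A", "C", "D", "E"), 12, replace = TRUE)
    mk <- function(keep, nm) {
      chars <- rep("-", 12); chars[keep] <- aa12[keep]
      list(seq = paste(chars, collapse = ""),
           s = ca_structure("A", seq_along(keep), aa12[keep],
                            matrix(rnorm(3 * length(keep)), ncol = 3),
                            name = nm))
    }
    a <- mk(keep_fl, "fl"); b <- mk(keep_tr, "tr")
    m3 <- alignment_map_from_strings(c(fl = a$seq, tr = b$seq),
                                     list(a$s, b$s))
    cs3 <- corrected_subset(a$s, b$s, m3)
    shared <- intersect(keep_fl, keep_tr)
    expect_equal(length(cs3), length(shared))
    expect_equal(cs3$aa, aa12[shared])
    expect_lte(length(cs3), min(length(a$s), length(b$s)))
  }
})

test_that("domain annotations enforce disjointness and resolve lookups", {
  dom <- domain_annotation(list(GH9 = c(1, 450), L = c(451, 510),
                                CBM49 = c(511, 620)))
  expect_equal(domain_of(dom, c(1, 450, 451, 510, 511, 620)),
               c("GH9", "GH9", "L", "L", "CBM49", "CBM49"))
  expect_true(is.na(domain_of(dom, 621)))
  expect_error(domain_annotation(list(GH9 = c(1, 10), L = c(10, 20))),
               "disjoint")
  expect_error(domain_annotation(list(GH9 = rbind(c(1, 5), c(4, 8)))),
               "overlapping")
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("domains:", "  GH9:", "  - [1, 450]", "  L:",
               "  - [451, 510]", "  CBM49:", "  - [511, 620]"), f)
  dom2 <- read_domains_yaml(f)
  expect_equal(dom2$intervals$L[1, ], c(451L, 510L))
})
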