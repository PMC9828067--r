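# Proteoform registry, masses, hydrophobicity, subgroup classification.

test_that("sequence registry satisfies the documented sequence constraints", {
  seqs <- amyloid_sequences()
  expect_equal(nchar(seqs[["ABri"]]), 34)
  expect_equal(nchar(seqs[["ADan"]]), 34)
  expect_equal(nchar(seqs[["Abeta"]]), 42)
  # ABri and ADan are identical over residues 1-22 and diverge after
  expect_equal(substr(seqs[["ABri"]], 1, 22), substr(seqs[["ADan"]], 1, 22))
  expect_false(substr(seqs[["ABri"]], 23, 34) == substr(seqs[["ADan"]], 23, 34))
  ncys <- function(s) sum(strsplit(s, "")[[1]] == "C")
  expect_equal(ncys(seqs[["ABri"]]), 2)
  expect_equal(ncys(seqs[["ADan"]]), 2)
  expect_equal(ncys(seqs[["Abeta"]]), 0)
})

test_that("get_sequence extracts validated spans", {
  expect_equal(nchar(get_sequence("Abeta", 1, 42)), 42)
  expect_equal(get_sequence("Abeta", 17, 17), "L")
  expect_equal(get_sequence("ABri", 1, 22), get_sequence("ADan", 1, 22))
  expect_equal(get_sequence(proteoform("ADan", 3, 33)),
               substr(amyloid_sequences()[["ADan"]], 3, 33))
  expect_error(get_sequence("Abeta", 0, 10), "span")
  expect_error(get_sequence("ABri", 1, 35), "span")
  expect_error(get_sequence("APP", 1, 10))
})

test_that("monoisotopic masses follow residue additivity and modification deltas", {
  expect_equal(peptide_mass("GG"), 132.053485, tolerance = 1e-8)
  # peptide-bond additivity: concatenation loses one water
  set.seed(42)
  aas <- strsplit("GASPVTCLINDQKEMHFRYW", "")[[1]]
  for (i in 1:20) {
    s1 <- paste(sample(aas, sample(3:15, 1), replace = TRUE), collapse = "")
    s2 <- paste(sample(aas, sample(3:15, 1), replace = TRUE), collapse = "")
    expect_equal(peptide_mass(paste0(s1, s2)),
                 peptide_mass(s1) + peptide_mass(s2) - 18.010565,
                 tolerance = 1e-9)
  }
  # pyroglutamate from Glu removes one water
  expect_equal(monoisotopic_mass(proteoform("ABri", 1, 34)) -
                 monoisotopic_mass(proteoform("ABri", 1, 34, pyroglu = TRUE)),
               18.010565, tolerance = 1e-9)
  # ... and from Gln removes ammonia
  expect_equal(peptide_mass("QAG") - peptide_mass("QAG", pyroglu = TRUE),
               17.026549, tolerance = 1e-9)
  # each disulfide bond removes two hydrogens
  expect_equal(monoisotopic_mass(proteoform("ABri", 1, 34)) -
                 monoisotopic_mass(proteoform("ABri", 1, 34, disulfides = 1)),
               2 * 1.007825, tolerance = 1e-9)
  expect_error(peptide_mass("GAG", pyroglu = TRUE), "pyroglutamate")
  expect_error(peptide_mass("GXG"), "unknown residue")
  expect_error(peptide_mass(""), "empty")
})

test_that("hydrophobic fractions reproduce the published truncation-series values", {
  golden <- list(
    list("ABri", 1, 34, 38.2), list("ABri", 1, 29, 37.9),
    list("ADan", 1, 34, 41.2), list("ADan", 1, 29, 48.3),
    list("ADan", 1, 28, 50.0), list("Abeta", 1, 40, 42.5),
    list("Abeta", 1, 42, 45.2))
  for (g in golden)
    expect_equal(hydrophobic_fraction(get_sequence(g[[1]], g[[2]], g[[3]])),
                 g[[4]], info = paste(g[[1]], g[[2]], g[[3]]))
  # ADan1-33 under integer residue counting (documented open question):
  expect_equal(hydrophobic_fraction(get_sequence("ADan", 1, 33)), 42.4)
  expect_equal(hydrophobic_fraction("AAAA"), 100.0)
  expect_equal(hydrophobic_fraction("SSSS"), 0.0)
  expect_error(hydrophobic_fraction("ABZ"), "unknown residue")
})

test_that("hydrophobic fraction is permutation/duplication invariant and monotone under non-hydrophobic trimming", {
  set.seed(7)
  aas <- strsplit("GASPVTCLINDQKEMHFRYW", "")[[1]]
  for (i in 1:10) {
    s <- sample(aas, 30, replace = TRUE)
    f <- hydrophobic_fraction(paste(s, collapse = ""), digits = 6)
    expect_equal(hydrophobic_fraction(paste(sample(s), collapse = ""),
                                      digits = 6), f)
    expect_equal(hydrophobic_fraction(paste(rep(paste(s, collapse = ""), 2),
                                            collapse = ""), digits = 6), f)
  }
  # trimming a non-hydrophobic C-terminal residue never lowers the fraction
  # (exhaustive over all truncation spans of all three precursors)
  hydro <- c("A", "F", "I", "L", "M", "V", "W")
  for (p in c("ABri", "ADan", "Abeta")) {
    cterm <- canonical_c_terminus(p)
    sq <- strsplit(amyloid_sequences()[[p]], "")[[1]]
    for (i in 1:3) for (j in seq(cterm, i + 2)) {
      if (!sq[j] %in% hydro && j > i + 1)
        expect_gte(hydrophobic_fraction(get_sequence(p, i, j - 1), digits = 8),
                   hydrophobic_fraction(get_sequence(p, i, j), digits = 8))
    }
  }
})

test_that("subgroup classification follows the four-group convention", {
  expect_setequal(classify_subgroups(proteoform("ABri", 1, 34, pyroglu = TRUE)),
                  c("n_truncated", "pyroglu"))
  expect_setequal(classify_subgroups(proteoform("ABri", 1, 34, pyroglu = TRUE),
                                     pyroglu_counts_n_truncated = FALSE),
                  "pyroglu")
  expect_equal(classify_subgroups(proteoform("Abeta", 1, 42)), "full_length")
  expect_setequal(classify_subgroups(proteoform("Abeta", 3, 40, pyroglu = TRUE)),
                  c("c_truncated", "n_truncated", "pyroglu"))
  expect_setequal(classify_subgroups(proteoform("ADan", 3, 33)),
                  c("c_truncated", "n_truncated"))
})

test_that("preset species tables validate and full_length excludes truncation labels", {
  counts <- c(FBD = 8L, FDD = 16L, CAA = 15L)
  for (cohort in names(counts)) {
    tab <- species_preset(cohort)
    expect_equal(nrow(tab), counts[[cohort]])
    expect_false(anyDuplicated(tab$display_name) > 0)
    for (i in seq_len(nrow(tab))) {
      labs <- classify_subgroups(as_proteoform(tab[i, ]))
      if ("full_length" %in% labs)
        expect_false(any(c("c_truncated", "n_truncated") %in% labs))
      # masses are in the linear-TOF amyloid window
      expect_gt(tab$mz[i], 2500); expect_lt(tab$mz[i], 5000)
    }
  }
  # species invariants are enforced at construction
  expect_error(proteoform("Abeta", 1, 42, disulfides = 1), "disulfide")
  expect_error(proteoform("ABri", 1, 34, disulfides = 2), "disulfide")
  expect_error(proteoform("Abeta", 4, 42, pyroglu = TRUE), "pyroglutamate")
})
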